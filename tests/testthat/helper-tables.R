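# Shared fixtures and independent oracles. Everything here is computed
# from first principles (plain arithmetic on counts), independent of the
# package's own collapse/fit code paths.

# random 3x2 tables with all-positive cells
random_positive_table <- function(min = 1L, max = 300L) {
  genotype_table(sample(min:max, 3L, replace = TRUE),
                 sample(min:max, 3L, replace = TRUE))
}

# Brute-force 2x2-collapse oracle: build the collapsed table explicitly and
# compute the odds ratio and Woolf variance by hand.
oracle_2x2 <- function(table, which = c("additive", "co-dominant",
                                        "dominant", "recessive")) {
  which <- match.arg(which)
  n <- table$counts  # rows wtwt, wtmt, mtmt; cols controls, cases
  two <- switch(which,
    additive = rbind(exposed = c(n["mtmt", "cases"], n["mtmt", "controls"]),
                     referent = c(n["wtwt", "cases"], n["wtwt", "controls"])),
    `co-dominant` = rbind(
      exposed = c(n["wtmt", "cases"], n["wtmt", "controls"]),
      referent = c(n["wtwt", "cases"] + n["mtmt", "cases"],
                   n["wtwt", "controls"] + n["mtmt", "controls"])),
    dominant = rbind(
      exposed = c(n["wtmt", "cases"] + n["mtmt", "cases"],
                  n["wtmt", "controls"] + n["mtmt", "controls"]),
      referent = c(n["wtwt", "cases"], n["wtwt", "controls"])),
    recessive = rbind(
      exposed = c(n["mtmt", "cases"], n["mtmt", "controls"]),
      referent = c(n["wtwt", "cases"] + n["wtmt", "cases"],
                   n["wtwt", "controls"] + n["wtmt", "controls"])))
  or <- unname((two["exposed", 1L] * two["referent", 2L]) /
               (two["referent", 1L] * two["exposed", 2L]))
  list(log_or = log(or), variance = sum(1 / two))
}

# Likelihood-ratio G statistic computed directly from the contingency
# table margins (the closed-form oracle for the GLM deviance).
oracle_g_stat <- function(table) {
  o <- table$counts
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  2 * sum(o * log(o / e))
}

# Weir control-frequency model written out by hand (round-trip oracle).
weir_frequencies_for_test <- function(p, D) {
  q <- 1 - p
  c(p^2 + D, 2 * p * q - 2 * D, q^2 + D)
}
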