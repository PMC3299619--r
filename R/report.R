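# Full-pipeline analysis report and batch mode. A report bundles the table
# echo, all four descriptive contrasts, the deviance decomposition, the
# HWE state of the controls and the dominance call, plus the configuration
# that produced it, and round-trips losslessly through JSON.

REPORT_SCHEMA_VERSION <- "1.0"

#' Analyze a genotype table end to end
#'
#' Runs contrasts, deviance decomposition, control HWE estimation and the
#' mode-of-inheritance classification, and assembles an `analysis_report`.
#' The dominant and recessive contrasts are included for description only;
#' they are not orthogonal to the additive/co-dominant pair and play no
#' role in the inference.
#'
#' @param table A [genotype_table()], or a path to a TSV/CSV file readable
#'   by [read_genotype_table()].
#' @param alpha Significance level for the classification (default 0.05).
#' @param correction Continuity policy for the contrasts.
#' @param hwe_method HWE test method, `"chisq"` or `"exact"`.
#' @return An `analysis_report` list.
#' @examples
#' r <- analyze_table(example_tables()$adh2)
#' r$dominance$mode
#' @export
analyze_table <- function(table, alpha = 0.05,
                          correction = c("haldane", "strict"),
                          hwe_method = c("chisq", "exact")) {
  correction <- match.arg(correction)
  hwe_method <- match.arg(hwe_method)
  source_path <- NULL
  if (is.character(table)) {
    source_path <- table
    table <- read_genotype_table(table)
  }
  assert_genotype_table(table)
  contrasts <- lapply(c(additive = "additive", codominant = "co-dominant",
                        dominant = "dominant", recessive = "recessive"),
                      function(ct) genotype_contrast(table, ct, correction))
  call <- classify_dominance(table, alpha = alpha, correction = correction)
  structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("degdom")),
    input = list(
      path = source_path,
      md5 = if (!is.null(source_path)) unname(tools::md5sum(source_path))
            else NULL,
      name = table$name),
    table = as.data.frame(table),
    maf = as.list(maf(table)),
    contrasts = contrasts,
    deviance = call$deviance,
    hwe = estimate_disequilibrium(table, hwe_method),
    dominance = call,
    config = list(alpha = alpha, correction = correction,
                  hwe_method = hwe_method)
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== degdom analysis report ==\n")
  if (!is.null(x$input$name)) cat("study:", x$input$name, "\n")
  df <- x$table
  cat(sprintf("counts (controls/cases): %s\n",
              paste(sprintf("%s %d/%d", df$genotype, df$controls, df$cases),
                    collapse = ", ")))
  cat(sprintf("maf(mt): controls %.2f, cases %.2f\n",
              x$maf$controls, x$maf$cases))
  for (ct in x$contrasts) print(ct)
  print(x$deviance)
  print(x$hwe)
  print(x$dominance)
  invisible(x)
}

# Strip closures/classes down to plain lists so jsonlite serialises cleanly.
.report_payload <- function(report) {
  ser_contrast <- function(ct) {
    ct$cells <- as.list(ct$cells)
    unclass(ct)
  }
  rep <- unclass(report)
  rep$contrasts <- lapply(rep$contrasts, ser_contrast)
  rep$deviance <- unclass(rep$deviance)
  rep$hwe <- unclass(rep$hwe)
  dom <- unclass(rep$dominance)
  dom$codominant <- ser_contrast(dom$codominant)
  dom$additive <- ser_contrast(dom$additive)
  dom$deviance <- unclass(dom$deviance)
  rep$dominance <- dom
  rep
}

#' Write an analysis report as JSON
#'
#' Full double precision (no rounding); the human-readable `print` method
#' rounds to 2 decimals instead.
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(.report_payload(report), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read an analysis report back from JSON
#'
#' @param path Path written by [write_report_json()].
#' @return A plain list mirroring the report structure.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Batch-classify a directory of genotype tables
#'
#' Reads every `*.tsv`/`*.csv` in `dir`, classifies each, and returns a
#' per-study summary plus an aggregate count of studies per mode of
#' inheritance. Unreadable files are skipped with a warning and flagged.
#'
#' @param dir Directory of genotype tables.
#' @param alpha Per-study significance level.
#' @param multiplicity `"none"` (default) or `"bonferroni"`: divide `alpha`
#'   by the number of readable tables before classifying.
#' @param correction Continuity policy.
#' @return List with `studies` (data frame: file, name, h, mode, p-values,
#'   HWE D and its sign), `aggregate` (mode counts), and `n_failed`.
#' @export
batch_analyze <- function(dir, alpha = 0.05,
                          multiplicity = c("none", "bonferroni"),
                          correction = c("haldane", "strict")) {
  multiplicity <- match.arg(multiplicity)
  correction <- match.arg(correction)
  files <- list.files(dir, pattern = "\\.(tsv|csv)$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    abort_degdom(sprintf("no .tsv/.csv genotype tables found in '%s'", dir),
                 class = "degdom_format_error")
  alpha_eff <- if (multiplicity == "bonferroni") alpha / length(files) else alpha
  rows <- list(); n_failed <- 0L
  for (f in files) {
    res <- tryCatch({
      tab <- read_genotype_table(f)
      call <- quiet_haldane(classify_dominance(tab, alpha_eff, correction))
      hw <- estimate_disequilibrium(tab)
      data.frame(file = basename(f), name = tab$name,
                 h = call$h, mode = call$mode,
                 codominant_p = call$codominant_p,
                 additive_p = call$additive$p_two_sided,
                 d_g = call$deviance$d_g, p_g = call$deviance$p_g,
                 hwe_D = hw$D, hwe_D_sign = sign(hw$D), hwe_p = hw$p_hwe)
    }, degdom_error = function(e) {
      warning(sprintf("skipping '%s': %s", f, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L)
    abort_degdom("no table in the directory could be analyzed",
                 class = "degdom_format_error")
  studies <- do.call(rbind, rows)
  modes <- c("non-dominance", "dominance-of-wt", "dominance-of-mt",
             "over-dominance", "under-dominance", "dominance-unresolved")
  aggregate <- data.frame(mode = modes,
                          n = vapply(modes, function(m) sum(studies$mode == m),
                                     integer(1L)),
                          row.names = NULL)
  list(studies = studies, aggregate = aggregate, n_failed = n_failed,
       alpha = alpha, alpha_effective = alpha_eff,
       multiplicity = multiplicity)
}
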