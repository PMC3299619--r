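#' Construct a 3x2 case-control genotype table
#'
#' The elementary data structure of a case-control genetic association study
#' of a bi-allelic variant: counts of the three genotypes (wild-type
#' homozygote, heterozygote, mutant homozygote) among control and diseased
#' subjects. Rows are always stored in the fixed order wtwt, wtmt, mtmt with
#' the mutant allele `mt` the putative risk allele; readers mapping external
#' files onto this layout must match rows by label, never by position.
#'
#' @param controls Integer vector of length 3: control counts for
#'   (wtwt, wtmt, mtmt).
#' @param cases Integer vector of length 3: case counts in the same order.
#' @param labels Character vector of length 3 naming the genotypes, default
#'   `c("wtwt", "wtmt", "mtmt")`.
#' @param alleles Character vector of length 2 naming (wild-type, mutant)
#'   alleles, default `c("wt", "mt")`.
#' @param name Optional study identifier carried through reports.
#'
#' @return An object of class `genotype_table`: a list with a 3x2 integer
#'   `counts` matrix (columns `controls`, `cases`), `labels`, `alleles`
#'   and `name`.
#' @examples
#' tab <- genotype_table(controls = c(64, 94, 51), cases = c(34, 89, 82))
#' maf(tab)
#' @export
genotype_table <- function(controls, cases,
                           labels = c("wtwt", "wtmt", "mtmt"),
                           alleles = c("wt", "mt"),
                           name = NULL) {
  for (v in list(controls, cases)) {
    if (length(v) != 3L || anyNA(v) || !is.numeric(v))
      abort_degdom("'controls' and 'cases' must be numeric vectors of length 3 with no NA",
                   class = "degdom_value_error")
    if (any(v < 0) || any(v != round(v)))
      abort_degdom("genotype counts must be non-negative integers",
                   class = "degdom_value_error")
  }
  if (sum(controls) < 1 || sum(cases) < 1)
    abort_degdom("each column of the genotype table must contain at least one subject",
                 class = "degdom_value_error")
  if (length(labels) != 3L || anyDuplicated(labels))
    abort_degdom("'labels' must be 3 distinct genotype names",
                 class = "degdom_value_error")
  counts <- cbind(controls = as.integer(round(controls)),
                  cases = as.integer(round(cases)))
  rownames(counts) <- labels
  structure(list(counts = counts, labels = labels, alleles = alleles,
                 name = name),
            class = "genotype_table")
}

is_genotype_table <- function(x) inherits(x, "genotype_table")

assert_genotype_table <- function(x) {
  if (!is_genotype_table(x))
    abort_degdom("expected a 'genotype_table' object", class = "degdom_value_error")
  invisible(x)
}

#' Mutant allele frequency per column
#'
#' Frequency of the mutant allele, `(n_het + 2 n_mtmt) / (2 n)`, computed
#' separately for controls and cases.
#'
#' @param table A [genotype_table()].
#' @return Named numeric vector `c(controls = , cases = )`, each in `[0, 1]`.
#' @export
maf <- function(table) {
  assert_genotype_table(table)
  n <- table$counts
  (n[2L, ] + 2 * n[3L, ]) / (2 * colSums(n))
}

#' @export
print.genotype_table <- function(x, ...) {
  if (!is.null(x$name)) cat("Genotype table:", x$name, "\n")
  m <- x$counts
  q <- maf(x)
  cat(sprintf("  bi-allelic variant, alleles %s/%s (mt = putative risk allele)\n",
              x$alleles[1L], x$alleles[2L]))
  print(m)
  cat(sprintf("  maf(mt): controls %.4f, cases %.4f\n", q[1L], q[2L]))
  invisible(x)
}

#' @export
as.data.frame.genotype_table <- function(x, ...) {
  data.frame(genotype = x$labels,
             controls = x$counts[, 1L],
             cases = x$counts[, 2L],
             row.names = NULL)
}

# --- reading and writing ----------------------------------------------------

.label_aliases <- function(labels) {
  # canonical row -> accepted spellings (case-insensitive); copy-number
  # coding 0/1/2 counts copies of the mutant allele
  list(
    wtwt = c(tolower(labels[1L]), "wtwt", "wt/wt", "0"),
    wtmt = c(tolower(labels[2L]), "wtmt", "wt/mt", "mtwt", "1", "het"),
    mtmt = c(tolower(labels[3L]), "mtmt", "mt/mt", "2")
  )
}

#' Read a genotype table from a delimited file
#'
#' Expects a header `genotype, controls, cases` (case-insensitive) and
#' exactly three data rows whose genotype labels map onto wtwt/wtmt/mtmt;
#' copy-number coding 0/1/2 (copies of the mutant allele) is also accepted.
#' Row order in the file is irrelevant: rows are matched by label.
#'
#' @param path Path to a TSV or CSV file.
#' @param format `"tsv"` or `"csv"`; default guessed from the file extension
#'   (anything not ending in `.csv` is read as tab-separated).
#' @param name Study identifier for the resulting table; defaults to the
#'   file name without extension.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, format = c("auto", "tsv", "csv"),
                                name = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      colClasses = "character", strip.white = TRUE),
    error = function(e) abort_degdom(
      sprintf("cannot parse '%s' as %s: %s", path, format, conditionMessage(e)),
      class = "degdom_format_error"))
  names(df) <- tolower(names(df))
  need <- c("genotype", "controls", "cases")
  if (!all(need %in% names(df)))
    abort_degdom(sprintf("'%s' must have header columns %s", path,
                         paste(need, collapse = ", ")),
                 class = "degdom_format_error")
  if (nrow(df) != 3L)
    abort_degdom(sprintf("'%s' must have exactly 3 data rows, found %d",
                         path, nrow(df)),
                 class = "degdom_format_error")
  aliases <- .label_aliases(c("wtwt", "wtmt", "mtmt"))
  slot <- vapply(tolower(trimws(df$genotype)), function(g) {
    hit <- which(vapply(aliases, function(a) g %in% a, logical(1L)))
    if (length(hit) != 1L)
      abort_degdom(sprintf("cannot map genotype label '%s' onto wtwt/wtmt/mtmt (or 0/1/2)", g),
                   class = "degdom_label_error")
    hit
  }, integer(1L))
  if (anyDuplicated(slot))
    abort_degdom(sprintf("'%s' maps two rows onto the same genotype", path),
                 class = "degdom_label_error")
  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      abort_degdom(sprintf("non-numeric count in '%s'", path),
                   class = "degdom_value_error")
    v
  }
  controls <- num(df$controls)[order(slot)]
  cases <- num(df$cases)[order(slot)]
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  genotype_table(controls, cases, name = name)
}

#' Write a genotype table to a delimited file
#'
#' @param table A [genotype_table()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path, format = c("tsv", "csv")) {
  assert_genotype_table(table)
  format <- match.arg(format)
  utils::write.table(as.data.frame(table), path,
                     sep = if (format == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Worked-example genotype tables
#'
#' The three published case-control tables used throughout the documentation
#' and tests: the ACE D/I polymorphism vs coronary artery disease (an
#' example of non-dominance), ADH2 *2/*1 vs alcoholism (dominance of the
#' risk allele), and BDNF G196A vs schizophrenia (under-dominance). Counts
#' are built in code; the same tables ship as TSV fixtures under
#' `system.file("extdata", package = "degdom")`.
#'
#' @return Named list of three [genotype_table()] objects
#'   (`ace`, `adh2`, `bdnf`).
#' @examples
#' classify_dominance(example_tables()$ace)
#' @export
example_tables <- function() {
  list(
    ace = genotype_table(c(64, 94, 51), c(34, 89, 82),
                         labels = c("II", "ID", "DD"),
                         alleles = c("I", "D"), name = "ACE_D_I_CAD"),
    adh2 = genotype_table(c(448, 93, 4), c(238, 85, 17),
                          labels = c("*2*2", "*2*1", "*1*1"),
                          alleles = c("*2", "*1"), name = "ADH2_alcoholism"),
    bdnf = genotype_table(c(208, 131, 11), c(229, 83, 9),
                          labels = c("GG", "GA", "AA"),
                          alleles = c("G", "A"), name = "BDNF_G196A_schizophrenia")
  )
}

#' Write the worked-example fixtures to a directory
#'
#' @param dir Target directory (created if absent).
#' @return Character vector of the written paths, invisibly.
#' @export
write_example_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- example_tables()
  paths <- character(0L)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    # fixtures keep the canonical wtwt/wtmt/mtmt labels so they re-read
    # without a label map
    canon <- genotype_table(tabs[[nm]]$counts[, 1L], tabs[[nm]]$counts[, 2L],
                            name = tabs[[nm]]$name)
    write_genotype_table(canon, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
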