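# Delimited-table readers and writers. Only plain TSV/CSV score tables are
# supported: the scan operates on categorical score matrices (0/1/2 dosage
# codes, -1/0/1 bin scores), not on variant calls, so VCF/PLINK ingestion is
# deliberately out of scope.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) err_format(paste0("empty file: ", path))
  if (grepl("\t", first)) "\t" else ","
}

read_table_checked <- function(path, sep, header) {
  tryCatch(
    utils::read.table(path, sep = sep, header = header,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", comment.char = "#",
                      fill = FALSE, blank.lines.skip = TRUE,
                      strip.white = TRUE),
    error = function(e) err_format(paste0("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  )
}

#' Read a genotype matrix from a delimited text file
#'
#' Expects TSV or CSV (auto-detected from the first line) with a header row
#' of marker ids and a first column of individual ids; `#`-prefixed lines are
#' ignored. Labels are preserved verbatim as categories, so `{0,1,2}` and
#' `{-1,0,1}` codings both work unchanged.
#'
#' @param path File path.
#' @param transpose If `TRUE`, the file is markers-in-rows (header of
#'   individual ids) and is transposed after reading.
#' @param missing_sentinel Cell content treated as missing (besides `NA`),
#'   e.g. `"."`.
#' @return An `hh_genotype_matrix`.
#' @export
read_genotypes <- function(path, transpose = FALSE, missing_sentinel = NA) {
  sep <- detect_sep(path)
  df <- read_table_checked(path, sep, header = TRUE)
  if (ncol(df) < 2L) err_format("genotype table needs id column + >= 1 marker")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  g <- genotype_matrix(m, individual_ids = ids, marker_ids = colnames(df)[-1],
                       missing_sentinel = missing_sentinel)
  if (transpose) g <- genotype_matrix(unclass(g), transpose = TRUE)
  g
}

#' Read a phenotype vector from a two-column delimited text file
#'
#' Columns are individual id and trait value; TSV or CSV auto-detected, a
#' header row is optional and recognised by a non-numeric second field.
#'
#' @param path File path.
#' @return An [phenotype_vector()].
#' @export
read_phenotypes <- function(path) {
  sep <- detect_sep(path)
  df <- read_table_checked(path, sep, header = FALSE)
  if (ncol(df) != 2L) err_format("phenotype table must have exactly 2 columns")
  # header detection: non-numeric value field on row 1
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) {
    if (nrow(df) < 2L) err_format("phenotype table has a header but no data")
    df <- df[-1, , drop = FALSE]
  }
  vals <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(vals))
    err_format(paste0("non-numeric phenotype value(s) in ", path))
  phenotype_vector(df[[1]], vals)
}

#' Write a scan result (or simulation profile) as annotated TSV
#'
#' Writes `#`-prefixed metadata lines (tool version plus any `metadata`
#' entries) followed by a plain TSV table, keeping the stream pipeline-safe.
#'
#' @param result A data frame ([scan_markers()] result, [run_simulation()]
#'   profile, or any table).
#' @param path Output file path (or `""` for stdout).
#' @param metadata Named character vector/list recorded as `# key: value`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(result, path, metadata = NULL) {
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  ver <- as.character(utils::packageVersion("hhccdf"))
  writeLines(sprintf("# hhccdf %s", ver), con)
  for (key in names(metadata))
    writeLines(sprintf("# %s: %s", key, metadata[[key]]), con)
  utils::write.table(as.data.frame(result), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an annotated TSV written by [write_scan_tsv()]
#'
#' @param path File path.
#' @return A data frame (metadata lines are skipped).
#' @export
read_scan_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Paths to the bundled worked-example fixture
#'
#' The 20-individual example dataset (one three-class marker with scores
#' 0/1/2 and a quantitative trait) used throughout the documentation and by
#' [hhccdf_demo()].
#'
#' @return Named character vector with elements `geno` and `pheno`.
#' @export
example_paths <- function() {
  c(geno = system.file("extdata", "example_geno.tsv", package = "hhccdf",
                       mustWork = TRUE),
    pheno = system.file("extdata", "example_pheno.tsv", package = "hhccdf",
                        mustWork = TRUE))
}

#' Walk through the worked example
#'
#' Loads the bundled 20-individual fixture, prints the class phenotype means
#' in stratified order, the per-boundary hypergeometric counts
#' `(N, d, K, k)` and tail factors, and the combined HH-CCDF P value.
#'
#' @return Invisibly, a list with the stratification, counts, tail factors
#'   and the final P value.
#' @export
hhccdf_demo <- function() {
  paths <- example_paths()
  gm <- read_genotypes(paths["geno"])
  ph <- read_phenotypes(paths["pheno"])
  mk <- marker_genotypes(rownames(gm), gm[, 1])
  det <- hh_ccdf(ph, mk, details = TRUE)
  strat <- det$strat
  cat("Worked example:", strat$N, "individuals,",
      strat$n, "genotype classes\n\n")
  cat("Class means (ascending):\n")
  for (g in strat$groups)
    cat(sprintf("  score %-3s n = %2d  mean = %.3f\n",
                g$label, g$size, g$mean))
  cat("\nPer-boundary hypergeometric counts and tail factors:\n")
  for (i in seq_len(nrow(det$counts)))
    cat(sprintf("  boundary %d: N = %d, d = %d, K = %d, k = %d  ->  tail = %.6f\n",
                det$counts$boundary[i], det$counts$N[i], det$counts$d[i],
                det$counts$K[i], det$counts$k[i], det$tails[i]))
  cat(sprintf("\nHH-CCDF P value (geometric mean of %d tails): %.6f (= %.3f)\n",
              length(det$tails), det$p, round(det$p, 3)))
  invisible(det)
}
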