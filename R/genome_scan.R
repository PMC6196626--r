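#' Construct a genotype matrix
#'
#' A rectangular table of categorical genotype scores, individuals in rows and
#' markers in columns. Labels are kept verbatim as categories; any cell equal
#' to the missing sentinel becomes `NA`.
#'
#' @param labels Matrix (or data frame) of genotype labels.
#' @param individual_ids Row identifiers (unique); defaults to existing
#'   rownames or `ind_1..ind_n`.
#' @param marker_ids Column identifiers (unique); defaults to existing
#'   colnames or `m_1..m_p`.
#' @param missing_sentinel Label treated as missing.
#' @param transpose If `TRUE`, the input is markers-in-rows and is transposed.
#' @return Object of class `hh_genotype_matrix`: a character matrix with
#'   individual rownames and marker colnames, plus a `missing_sentinel`
#'   attribute.
#' @export
genotype_matrix <- function(labels, individual_ids = NULL, marker_ids = NULL,
                            missing_sentinel = NA, transpose = FALSE) {
  m <- as.matrix(labels)
  storage.mode(m) <- "character"
  if (transpose) m <- t(m)
  if (is.null(individual_ids)) individual_ids <- rownames(m)
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(nrow(m)))
  if (is.null(marker_ids)) marker_ids <- colnames(m)
  if (is.null(marker_ids)) marker_ids <- paste0("m_", seq_len(ncol(m)))
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (length(individual_ids) != nrow(m) || length(marker_ids) != ncol(m))
    err_format("id lengths do not match matrix dimensions")
  if (anyDuplicated(individual_ids))
    err_duplicate_id("duplicate individual ids in genotype matrix")
  if (anyDuplicated(marker_ids))
    err_duplicate_id("duplicate marker ids in genotype matrix")
  if (!is.na(missing_sentinel))
    m[m == as.character(missing_sentinel)] <- NA_character_
  dimnames(m) <- list(individual_ids, marker_ids)
  structure(m, class = "hh_genotype_matrix")
}

#' @export
print.hh_genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d markers\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Negative log10 transform with a floor
#'
#' `-log10(max(p, floor))`, the Manhattan-plot score. The floor keeps exact
#' zeros (perfect splits) displayable.
#'
#' @param p P value(s) in `[0, 1]` (NAs pass through).
#' @param floor Positive lower bound applied before the log; default `1e-300`.
#' @return Numeric score(s).
#' @examples
#' neg_log10(c(0.01, 1, 0))  # 2 0 300
#' @export
neg_log10 <- function(p, floor = 1e-300) {
  stopifnot(floor > 0)
  -log10(pmax(p, floor))
}

#' Scan all markers of a genotype matrix against a phenotype
#'
#' Applies any subset of the three per-marker methods — the HH-CCDF statistic
#' ([hh_ccdf()]), the one-way F test ([f_test()]) and the hierarchical
#' association coefficient ([ha_coefficient()]) — to every marker column and
#' returns a tidy one-row-per-marker table in input marker order. Markers
#' that are degenerate after missing-data removal (fewer than 2 genotype
#' classes) get `status = "degenerate"` and `NA` statistics rather than
#' P = 1: no test was performed, which is distinct from no evidence.
#'
#' The hierarchical association coefficient requires strictly positive trait
#' values. By default (`ha_normalize = NULL`) the phenotype is min-max
#' normalized onto `[0, 1]` first only when non-positive values are present,
#' with a warning; pass `TRUE` or `FALSE` to force either behaviour.
#'
#' @param geno An `hh_genotype_matrix` (see [genotype_matrix()]).
#' @param pheno An [phenotype_vector()].
#' @param methods Subset of `c("hhccdf", "ftest", "ha")`.
#' @param ha_normalize `NULL` (auto), `TRUE` or `FALSE`.
#' @param p_floor Floor passed to [neg_log10()].
#' @return Data frame of class `hh_scan_result` with columns `marker`,
#'   `n_categories`, `n_used`, `status`, and per requested method:
#'   `hh_ccdf_p`/`hh_ccdf_neglog10`, `f_stat`/`f_p`/`f_neglog10`, `ha`.
#' @examples
#' ph <- phenotype_vector(paste0("i", 1:8), c(3, 1, 4, 1, 5, 9, 2, 6))
#' gm <- genotype_matrix(matrix(rep(c(0, 1), each = 4), ncol = 1),
#'                       individual_ids = paste0("i", 1:8))
#' scan_markers(gm, ph, methods = "hhccdf")
#' @export
scan_markers <- function(geno, pheno,
                         methods = c("hhccdf", "ftest", "ha"),
                         ha_normalize = NULL, p_floor = 1e-300) {
  stopifnot(inherits(geno, "hh_genotype_matrix"),
            inherits(pheno, "hh_phenotype"))
  methods <- match.arg(methods, c("hhccdf", "ftest", "ha"),
                       several.ok = TRUE)
  if (!any(rownames(geno) %in% pheno$ids))
    err_empty_join("no shared individual ids between genotypes and phenotype")

  ph <- pheno
  if ("ha" %in% methods) {
    nonpos <- any(ph$values <= 0, na.rm = TRUE)
    if (is.null(ha_normalize)) ha_normalize <- nonpos
    if (ha_normalize) {
      if (nonpos)
        warning("non-positive trait values: min-max normalizing phenotype ",
                "for the hierarchical association coefficient")
      ph <- phenotype_vector(ph$ids, normalize_minmax(ph$values))
    }
  }

  p <- ncol(geno)
  ids <- rownames(geno)
  res <- data.frame(
    marker = colnames(geno), n_categories = NA_integer_,
    n_used = NA_integer_, status = "ok",
    stringsAsFactors = FALSE
  )
  if ("hhccdf" %in% methods) res$hh_ccdf_p <- NA_real_
  if ("ftest" %in% methods) { res$f_stat <- NA_real_; res$f_p <- NA_real_ }
  if ("ha" %in% methods) res$ha <- NA_real_

  ha_same_pheno <- !("ha" %in% methods) || identical(ph$values, pheno$values)
  for (j in seq_len(p)) {
    mk <- marker_genotypes(ids, geno[, j])
    strat <- tryCatch(stratify(pheno, mk),
                      hh_error_degenerate_marker = function(e) NULL,
                      hh_error_empty_join = function(e) NULL)
    if (is.null(strat) || strat$n < 2L) {
      res$status[j] <- "degenerate"
      if (!is.null(strat)) {
        res$n_categories[j] <- strat$n
        res$n_used[j] <- strat$N
      }
      next
    }
    res$n_categories[j] <- strat$n
    res$n_used[j] <- strat$N
    if ("hhccdf" %in% methods) {
      cnt <- boundary_counts(strat)
      res$hh_ccdf_p[j] <- geometric_mean(
        mapply(hccdf_tail, cnt$N, cnt$K, cnt$d, cnt$k))
    }
    if ("ftest" %in% methods) {
      ft <- tryCatch(f_test_strat(strat), hh_error = function(e) NULL)
      if (!is.null(ft)) { res$f_stat[j] <- ft$F; res$f_p[j] <- ft$p }
    }
    if ("ha" %in% methods) {
      res$ha[j] <- tryCatch(
        if (ha_same_pheno) ha_strat(strat)
        else ha_coefficient(ph, mk),
        hh_error = function(e) NA_real_)
    }
  }
  if ("hhccdf" %in% methods)
    res$hh_ccdf_neglog10 <- neg_log10(res$hh_ccdf_p, p_floor)
  if ("ftest" %in% methods)
    res$f_neglog10 <- neg_log10(res$f_p, p_floor)
  class(res) <- c("hh_scan_result", "data.frame")
  res
}

#' Min-max normalize a scan-result column
#'
#' Adds `<column>_norm`, the min-max normalization of a score column over its
#' non-NA entries (NA rows stay NA). Used to overlay scores from different
#' methods on one `[0, 1]` scale; apply it to the `-log10 P` columns of the
#' two tests and to raw coefficient values.
#'
#' @param result An `hh_scan_result` from [scan_markers()].
#' @param column Name of the numeric column to normalize.
#' @return The result with the extra column appended.
#' @export
normalize_scores <- function(result, column) {
  stopifnot(inherits(result, "data.frame"), column %in% names(result))
  result[[paste0(column, "_norm")]] <- normalize_minmax(result[[column]])
  result
}
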