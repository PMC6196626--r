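#' Configuration for the triangle-pattern QTL-signal simulation
#'
#' The benchmark dataset: a genotype table of i.i.d. uniform `{0,1,2}`
#' background noise carrying three marker blocks, each with a pair of
#' vertically symmetric triangles — 0s filling a triangle on the top rows,
#' 2s filling its mirror on the bottom rows. The triangle height controls how
#' many individuals at the phenotype extremes carry a deterministic genotype,
#' i.e. the magnitude of the simulated gene signal; the default heights
#' 20, 30, 40 give three signals increasing at a regular interval. The
#' phenotype rises with slope 1 to the tallest triangle's height, plateaus,
#' then rises again to the bottom edge.
#'
#' @param n_individuals Rows of the genotype table (default 500).
#' @param n_markers Columns (default 450 = 3 blocks of 150).
#' @param block_width Markers per triangle block (default 150).
#' @param heights Triangle heights, left to right (default `c(20, 30, 40)`);
#'   each must be at most `n_individuals / 2`.
#' @param n_reps Number of simulation replicates to average (default 100).
#' @param seed Master seed; per-replicate child seeds are derived from it so
#'   any replicate is independently re-creatable.
#' @param methods Methods to score each replicate with (see [scan_markers()]).
#' @return A list of class `hh_sim_config`.
#' @export
triangle_sim_config <- function(n_individuals = 500, n_markers = 450,
                                block_width = 150,
                                heights = c(20, 30, 40),
                                n_reps = 100, seed = 1,
                                methods = c("hhccdf", "ftest", "ha")) {
  stopifnot(n_individuals >= 2, block_width >= 1, n_reps >= 1,
            length(heights) >= 1, all(heights >= 0),
            all(heights <= n_individuals / 2),
            n_markers == length(heights) * block_width)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_markers = as.integer(n_markers),
    block_width = as.integer(block_width),
    heights = as.integer(heights),
    n_reps = as.integer(n_reps),
    seed = as.integer(seed),
    methods = methods
  ), class = "hh_sim_config")
}

#' Tip (peak) marker columns of the simulation blocks
#'
#' @param config An `hh_sim_config`.
#' @return Integer vector: one column index per block, where the triangle
#'   depth is maximal.
#' @export
sim_tip_columns <- function(config) {
  w <- config$block_width
  (seq_along(config$heights) - 1L) * w + 1L + w %/% 2L
}

#' Generate one simulated genotype matrix
#'
#' Background cells are i.i.d. uniform over `{0, 1, 2}`. Each block `b` with
#' height `h` has tip column `c_b` at its centre; at column `j` the triangle
#' depth is `round(h * (1 - |j - c_b| / (block_width / 2)))` (zero outside the
#' block), and the top `depth` rows are set to 0 while the bottom `depth`
#' rows are set to 2 — so the top and bottom triangles are symmetric by
#' construction.
#'
#' @param config An `hh_sim_config` from [triangle_sim_config()].
#' @param seed Optional seed set before drawing the background (the
#'   per-replicate child seed in [run_simulation()]).
#' @return An `hh_genotype_matrix`.
#' @export
make_genotype_matrix <- function(config, seed = NULL) {
  stopifnot(inherits(config, "hh_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  m <- matrix(sample(c("0", "1", "2"), n * config$n_markers, replace = TRUE),
              nrow = n)
  w <- config$block_width
  half <- w / 2
  tips <- sim_tip_columns(config)
  for (b in seq_along(config$heights)) {
    h <- config$heights[b]
    cols <- ((b - 1L) * w + 1L):(b * w)
    for (j in cols) {
      depth <- round(h * (1 - abs(j - tips[b]) / half))
      if (depth >= 1) {
        m[seq_len(depth), j] <- "0"
        m[seq.int(n - depth + 1L, n), j] <- "2"
      }
    }
  }
  genotype_matrix(m)
}

#' Generate the simulation phenotype
#'
#' Deterministic given the configuration: with `h_max` the tallest triangle
#' height, individual `i` has value `i` for `i <= h_max` (slope 1), `h_max`
#' through the plateau `h_max < i <= n - h_max`, and
#' `h_max + (i - (n - h_max))` beyond it (slope 2). With the defaults the
#' values run 1..40, then 40 repeated, then 41..80.
#'
#' @param config An `hh_sim_config`.
#' @return An [phenotype_vector()] with ids `ind_1..ind_n`.
#' @export
make_phenotype <- function(config) {
  stopifnot(inherits(config, "hh_sim_config"))
  n <- config$n_individuals
  h <- max(config$heights)
  i <- seq_len(n)
  v <- ifelse(i <= h, i, ifelse(i <= n - h, h, h + (i - (n - h))))
  phenotype_vector(paste0("ind_", i), v)
}

#' Run the repeated-scan simulation experiment
#'
#' Draws `n_reps` genotype matrices (each from a deterministically derived
#' child seed), scans each against the fixed phenotype with the configured
#' methods, and averages per-marker scores across replicates: `-log10 P` for
#' the HH-CCDF and F test, the raw coefficient for the hierarchical
#' association method. The averaged profile exhibits one peak per triangle
#' block whose height tracks the simulated gene-signal magnitude.
#'
#' @param config An `hh_sim_config`.
#' @return Data frame of class `hh_sim_profile`: `marker_index` plus a mean
#'   score column per method (`hh_ccdf_score`, `f_score`, `ha_score`), with
#'   the configuration attached as attribute `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "hh_sim_config"))
  set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max, config$n_reps)
  pheno <- make_phenotype(config)
  acc <- list()
  for (r in seq_len(config$n_reps)) {
    gm <- make_genotype_matrix(config, seed = child_seeds[r])
    sc <- scan_markers(gm, pheno, methods = config$methods)
    sr <- list()
    if ("hhccdf" %in% config$methods) sr$hh_ccdf_score <- sc$hh_ccdf_neglog10
    if ("ftest" %in% config$methods) sr$f_score <- sc$f_neglog10
    if ("ha" %in% config$methods) sr$ha_score <- sc$ha
    acc[[r]] <- sr
  }
  out <- data.frame(marker_index = seq_len(config$n_markers))
  for (colname in names(acc[[1]])) {
    mat <- vapply(acc, `[[`, numeric(config$n_markers), colname)
    out[[colname]] <- rowMeans(matrix(mat, nrow = config$n_markers),
                               na.rm = TRUE)
  }
  attr(out, "config") <- config
  class(out) <- c("hh_sim_profile", "data.frame")
  out
}
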