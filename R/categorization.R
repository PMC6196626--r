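#' Construct a phenotype vector
#'
#' Bundles individual identifiers with quantitative trait values. This is the
#' phenotypic variable of a marker-trait association scan: one finite real
#' value per uniquely identified individual, in arbitrary units.
#'
#' @param ids Character (or coercible) vector of unique individual identifiers.
#' @param values Numeric vector of trait values, same length as `ids`.
#'   Non-finite values are allowed here; individuals carrying them are dropped
#'   per marker before stratification.
#' @return An object of class `hh_phenotype`: a list with elements `ids` and
#'   `values`.
#' @examples
#' ph <- phenotype_vector(c("a", "b", "c"), c(1.2, 3.4, 2.2))
#' @export
phenotype_vector <- function(ids, values) {
  ids <- as.character(ids)
  values <- as.numeric(values)
  if (length(ids) != length(values))
    err_format("phenotype ids and values differ in length")
  if (anyDuplicated(ids))
    err_duplicate_id("duplicate individual ids in phenotype vector")
  structure(list(ids = ids, values = values), class = "hh_phenotype")
}

#' Construct a single marker's genotype labels
#'
#' Genotype scores are treated as opaque categorical labels: `{0,1,2}` dosage
#' codes and `{-1,0,1}` bin scores are equally valid, and no ordering or
#' numeric meaning is assumed beyond category identity.
#'
#' @param ids Individual identifiers (unique).
#' @param labels Categorical genotype scores, same length as `ids`.
#' @param missing_sentinel Label treated as missing (in addition to `NA`).
#' @return An object of class `hh_marker`: list with `ids` and `labels`
#'   (character; missing entries are `NA`).
#' @export
marker_genotypes <- function(ids, labels, missing_sentinel = NA) {
  ids <- as.character(ids)
  labels <- as.character(labels)
  if (length(ids) != length(labels))
    err_format("marker ids and labels differ in length")
  if (anyDuplicated(ids))
    err_duplicate_id("duplicate individual ids in marker genotypes")
  if (!is.na(missing_sentinel))
    labels[labels == as.character(missing_sentinel)] <- NA_character_
  structure(list(ids = ids, labels = labels), class = "hh_marker")
}

#' Hierarchically stratify genotype classes by ascending phenotype mean
#'
#' Joins the phenotype and marker on individual id (inner-join semantics),
#' drops individuals with missing genotype or non-finite phenotype, groups the
#' rest by genotype label, and orders the groups by ascending class mean.
#' Ties between class means are broken by ascending lexicographic sort of the
#' label text, so the order is deterministic.
#'
#' @param pheno An [phenotype_vector()] object.
#' @param geno A [marker_genotypes()] object.
#' @return An object of class `hh_stratification`: a list with
#'   * `groups` — list of groups, each with `label`, `values`, `mean`, `size`,
#'     ordered ascending by mean;
#'   * `n` — number of groups; `N` — total retained individuals;
#'   * `values` — all retained trait values in group order.
#' @examples
#' ph <- phenotype_vector(letters[1:6], c(5, 7, 2, 9, 4, 6))
#' mk <- marker_genotypes(letters[1:6], c(0, 1, 0, 1, 0, 1))
#' s <- stratify(ph, mk)
#' s$n          # 2 genotype classes
#' sapply(s$groups, `[[`, "mean")
#' @export
stratify <- function(pheno, geno) {
  stopifnot(inherits(pheno, "hh_phenotype"), inherits(geno, "hh_marker"))
  idx <- match(geno$ids, pheno$ids)
  keep <- !is.na(idx)
  if (!any(keep))
    err_empty_join("no shared individual ids between phenotype and genotypes")
  vals <- pheno$values[idx[keep]]
  labs <- geno$labels[keep]
  ok <- !is.na(labs) & is.finite(vals)
  vals <- vals[ok]
  labs <- labs[ok]
  if (length(labs) == 0L)
    err_degenerate_marker("all genotypes missing (or phenotypes non-finite)")

  split_vals <- split(vals, labs)
  means <- vapply(split_vals, mean, numeric(1))
  # ascending by mean, ties by label text (split() already sorts labels)
  ord <- order(means)
  groups <- lapply(ord, function(i) {
    list(label = names(split_vals)[i],
         values = split_vals[[i]],
         mean = means[[i]],
         size = length(split_vals[[i]]))
  })
  structure(list(
    groups = groups,
    n = length(groups),
    N = length(vals),
    values = unlist(lapply(groups, `[[`, "values"), use.names = FALSE)
  ), class = "hh_stratification")
}

#' @export
print.hh_stratification <- function(x, ...) {
  cat(sprintf("Hierarchical stratification: %d classes, N = %d\n", x$n, x$N))
  for (g in x$groups)
    cat(sprintf("  class %-4s size %3d  mean %.4f\n", g$label, g$size, g$mean))
  invisible(x)
}

# Size of the multiset intersection of two numeric vectors: tied values are
# matched up to the minimum multiplicity on either side.
multiset_intersection_size <- function(a, b) {
  a <- sort(a)
  b <- sort(b)
  i <- 1L; j <- 1L; k <- 0L
  na <- length(a); nb <- length(b)
  while (i <= na && j <= nb) {
    if (a[i] < b[j]) i <- i + 1L
    else if (a[i] > b[j]) j <- j + 1L
    else { k <- k + 1L; i <- i + 1L; j <- j + 1L }
  }
  k
}

#' Per-boundary hypergeometric counts
#'
#' For each of the `n - 1` categorical boundaries of a hierarchical
#' stratification, collapses the boundary into a binary split and reports the
#' quadruple feeding the hypergeometric tail: `N` (population size),
#' `d` (size of the right, higher-mean subset `s1`), `K` (total possible
#' successes, equal to `d`), and `k` (size of the multiset intersection
#' between the `d` largest trait values in the population and the trait
#' values observed in `s1`; tied values are matched up to multiplicity, which
#' yields the maximal tie-consistent intersection).
#'
#' @param strat An `hh_stratification` from [stratify()].
#' @return A data frame with one row per boundary `x = 1..n-1` and columns
#'   `boundary`, `N`, `d`, `K`, `k`.
#' @export
boundary_counts <- function(strat) {
  stopifnot(inherits(strat, "hh_stratification"))
  if (strat$n < 2L)
    err_degenerate_marker("marker has a single genotype class; no boundaries")
  all_sorted <- sort(strat$values, decreasing = TRUE)
  nb <- strat$n - 1L
  d <- k <- integer(nb)
  for (x in seq_len(nb)) {
    right <- unlist(lapply(strat$groups[(x + 1L):strat$n], `[[`, "values"),
                    use.names = FALSE)
    d[x] <- length(right)
    k[x] <- multiset_intersection_size(right, all_sorted[seq_len(d[x])])
  }
  data.frame(boundary = seq_len(nb), N = strat$N, d = d, K = d, k = k)
}

#' Per-boundary subset sums
#'
#' For each categorical boundary, reports the sums feeding the hierarchical
#' association coefficient: `y` (sum of all trait values), `obs` (sum over the
#' observed right subset `s1`), `top` (sum of the `d` largest values — `s1`
#' under the top categorization), and `btm` (sum of the `d` smallest values —
#' `s1` under the bottom categorization).
#'
#' @inheritParams boundary_counts
#' @return Data frame with columns `boundary`, `y`, `obs`, `top`, `btm`.
#' @export
boundary_sums <- function(strat) {
  stopifnot(inherits(strat, "hh_stratification"))
  if (strat$n < 2L)
    err_degenerate_marker("marker has a single genotype class; no boundaries")
  desc <- sort(strat$values, decreasing = TRUE)
  asc <- rev(desc)
  y <- sum(strat$values)
  nb <- strat$n - 1L
  obs <- top <- btm <- numeric(nb)
  for (x in seq_len(nb)) {
    right <- unlist(lapply(strat$groups[(x + 1L):strat$n], `[[`, "values"),
                    use.names = FALSE)
    d <- length(right)
    obs[x] <- sum(right)
    top[x] <- sum(desc[seq_len(d)])
    btm[x] <- sum(asc[seq_len(d)])
  }
  data.frame(boundary = seq_len(nb), y = y, obs = obs, top = top, btm = btm)
}
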