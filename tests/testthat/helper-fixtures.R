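# Shared fixtures and independent oracles.

# The 20-individual worked-example dataset: one marker with scores {0,1,2}
# and a quantitative trait.
example20_values <- c(140, 122, 116, 114, 112, 108, 108, 105, 105, 102,
                      101, 99, 98, 97, 95, 94, 91, 86, 84, 76)
example20_scores <- c(1, 1, 2, 1, 1, 2, 2, 0, 1, 1,
                      0, 0, 0, 2, 0, 1, 2, 2, 1, 0)
example20_ids <- paste0("ID_", 1:20)

example20_pheno <- function() phenotype_vector(example20_ids, example20_values)
example20_marker <- function() marker_genotypes(example20_ids, example20_scores)

# Independent exact-enumeration oracle for the hypergeometric upper tail.
# choose() is exact in double precision for N <= 25, so the sum is the exact
# rational value up to one rounding.
tail_oracle <- function(N, K, d, k) {
  i <- 0:min(K, d)
  i <- i[i > k & (d - i) <= (N - K)]
  if (length(i) == 0L) return(0)
  sum(choose(K, i) * choose(N - K, d - i)) / choose(N, d)
}

# Brute-force tie-consistent oracle for the boundary intersection count k:
# enumerate every subset of d individuals whose value multiset equals the
# top-d value multiset (i.e. every tie-consistent top categorization) and
# take the maximal overlap with the observed right subset.
brute_force_k <- function(values, s1_idx, d) {
  topd <- sort(values, decreasing = TRUE)[seq_len(d)]
  combs <- utils::combn(length(values), d)
  best <- -1L
  for (c in seq_len(ncol(combs))) {
    idx <- combs[, c]
    if (isTRUE(all.equal(sort(values[idx]), sort(topd))))
      best <- max(best, length(intersect(idx, s1_idx)))
  }
  best
}

# Random positive-valued fixture with n_classes genotype classes; optionally
# forces duplicated trait values to exercise tie handling.
random_fixture <- function(n, n_classes = 3, ties = FALSE) {
  vals <- if (ties) sample(1:max(2, n %/% 2), n, replace = TRUE)
          else sample(seq(1, 10 * n), n)
  labs <- sample(seq_len(n_classes) - 1, n, replace = TRUE)
  # ensure at least 2 observed classes
  if (length(unique(labs)) < 2) labs[1:2] <- c(0, 1)
  list(pheno = phenotype_vector(paste0("i", seq_len(n)), vals),
       geno = marker_genotypes(paste0("i", seq_len(n)), labs),
       values = vals, labels = labs)
}

# Arrange trait values so the observed categorization IS the top
# categorization: class 0 gets the smallest values, class 1 the middle,
# class 2 the largest.
top_categorized_fixture <- function(sizes) {
  n <- sum(sizes)
  vals <- sort(sample(seq(1, 10 * n), n))
  labs <- rep(seq_along(sizes) - 1, sizes)
  list(pheno = phenotype_vector(paste0("i", seq_len(n)), vals),
       geno = marker_genotypes(paste0("i", seq_len(n)), labs))
}
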