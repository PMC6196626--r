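test_that("hypergeometric tail matches exact enumeration on the worked example", {
  # exact rationals: P(X > 10) = 8730/38760; P(X > 5) = 1945/125970
  expect_equal(hccdf_tail(20, 14, 14, 10), 8730 / 38760, tolerance = 1e-12)
  expect_equal(hccdf_tail(20, 8, 8, 5), 1945 / 125970, tolerance = 1e-12)
  # k = d: the full CDF sums to 1
  expect_identical(hccdf_tail(20, 8, 8, 8), 0)
  expect_identical(hccdf_tail(10, 4, 7, 4), 0)  # k = min(K, d)
  # k below the support minimum: empty lower sum
  expect_identical(hccdf_tail(20, 14, 14, 7), 1)
  expect_identical(hccdf_tail(20, 14, 14, 0), 1)
})

test_that("invalid counts are rejected", {
  expect_error(hccdf_tail(10, 5, 11, 2), class = "hh_error_invalid_counts")
  expect_error(hccdf_tail(10, 11, 5, 2), class = "hh_error_invalid_counts")
  expect_error(hccdf_tail(10, 5, 5, 6), class = "hh_error_invalid_counts")
  expect_error(hccdf_tail(10, 5, 5, -1), class = "hh_error_invalid_counts")
  expect_error(hccdf_tail(10, 5, 5, 2.5), class = "hh_error_invalid_counts")
})

test_that("tail matches exact enumeration and phyper over the full N <= 25 grid", {
  worst <- 0
  for (N in 1:25) {
    for (K in 0:N) {
      for (d in 0:N) {
        ks <- 0:d
        got <- vapply(ks, function(k) hccdf_tail(N, K, d, k), numeric(1))
        want <- vapply(ks, function(k) tail_oracle(N, K, d, k), numeric(1))
        worst <- max(worst, abs(got - want))
        # independent distribution-function cross-check
        ref <- stats::phyper(ks, K, N - K, d, lower.tail = FALSE)
        worst <- max(worst, abs(got - ref))
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("tail is strictly decreasing in k over the support and symmetric in (K, d)", {
  for (case in list(c(20, 14, 14), c(25, 10, 15), c(12, 6, 9))) {
    N <- case[1]; K <- case[2]; d <- case[3]
    lo <- max(0, K + d - N); hi <- min(K, d)
    tails <- vapply(lo:hi, function(k) hccdf_tail(N, K, d, k), numeric(1))
    expect_true(all(diff(tails) < 0))
  }
  set.seed(3)
  for (rep in 1:25) {
    N <- sample(5:25, 1); K <- sample(0:N, 1); d <- sample(0:N, 1)
    k <- sample(0:min(K, d), 1)
    expect_equal(hccdf_tail(N, K, d, k), hccdf_tail(N, d, K, k),
                 tolerance = 1e-12)
  }
})

test_that("combined statistic reproduces the worked example", {
  p <- hh_ccdf(example20_pheno(), example20_marker())
  expect_equal(p, sqrt((8730 / 38760) * (1945 / 125970)), tolerance = 1e-10)
  expect_equal(p, 0.0589714, tolerance = 1e-6)
  expect_equal(round(p, 3), 0.059)
})

test_that("binary markers reduce to a single tail and perfect splits give 0", {
  ids <- paste0("i", 1:12)
  vals <- c(3, 8, 1, 9, 4, 7, 2, 10, 5, 6, 11, 12)
  labs <- rep(c("A", "B"), 6)
  p <- hh_ccdf(phenotype_vector(ids, vals), marker_genotypes(ids, labs))
  cnt <- boundary_counts(stratify(phenotype_vector(ids, vals),
                                  marker_genotypes(ids, labs)))
  expect_equal(nrow(cnt), 1)
  expect_equal(p, hccdf_tail(cnt$N, cnt$K, cnt$d, cnt$k))

  # perfect split at any boundary forces the combined value to exactly 0
  ph <- phenotype_vector(ids, 1:12)
  mk <- marker_genotypes(ids, rep(c(0, 1, 2), each = 4))
  expect_identical(hh_ccdf(ph, mk), 0)
})

test_that("combined statistic is in [0,1] and invariant to reordering", {
  set.seed(17)
  for (rep in 1:20) {
    fx <- random_fixture(n = 14, n_classes = 3, ties = rep %% 3 == 0)
    s <- stratify(fx$pheno, fx$geno)
    if (s$n < 2) next
    p <- hh_ccdf(fx$pheno, fx$geno)
    expect_gte(p, 0); expect_lte(p, 1)
    perm <- sample(14)
    p2 <- hh_ccdf(phenotype_vector(fx$pheno$ids[perm], fx$pheno$values[perm]),
                  marker_genotypes(fx$geno$ids[perm], fx$geno$labels[perm]))
    expect_equal(p2, p)
    cnt <- boundary_counts(s)
    expect_identical(p == 0, any(cnt$k == cnt$d))
  }
})

test_that("association coefficient hits its analytic limits", {
  set.seed(23)
  for (rep in 1:100) {
    sizes <- sample(2:5, sample(2:3, 1), replace = TRUE)
    fx <- top_categorized_fixture(sizes)
    expect_equal(ha_coefficient(fx$pheno, fx$geno), 1, tolerance = 1e-12)
    # bottom categorization: evaluate the formula with obs forced to btm
    sums <- boundary_sums(stratify(fx$pheno, fx$geno))
    sums$obs <- sums$btm
    expect_identical(ha_from_sums(sums), 0)
  }
})

test_that("association coefficient matches the worked-example arithmetic", {
  res <- ha_coefficient(example20_pheno(), example20_marker(),
                        details = TRUE)
  # independent oracle: direct evaluation of f(t) = y ln t - t at the sums
  expect_equal(res$ratios, c(0.7821746362, 0.7828301757), tolerance = 1e-9)
  expect_equal(res$value, 0.7825023373, tolerance = 1e-9)
  expect_equal(round(res$value, 2), 0.78)
})

test_that("association coefficient stays in [0,1] and rejects bad input", {
  set.seed(31)
  for (rep in 1:25) {
    fx <- random_fixture(n = 12, n_classes = 3, ties = TRUE)
    if (stratify(fx$pheno, fx$geno)$n < 2) next
    v <- ha_coefficient(fx$pheno, fx$geno)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  ids <- paste0("i", 1:6)
  expect_error(
    ha_coefficient(phenotype_vector(ids, c(-1, 2, 3, 4, 5, 6)),
                   marker_genotypes(ids, rep(c(0, 1), 3))),
    class = "hh_error_non_positive_input")
  # constant phenotype: top = btm at every boundary
  expect_error(
    ha_coefficient(phenotype_vector(ids, rep(5, 6)),
                   marker_genotypes(ids, rep(c(0, 1), 3))),
    class = "hh_error_degenerate_spread")
})

test_that("one-way F test matches hand-computed sums of squares", {
  ft <- f_test(example20_pheno(), example20_marker())
  expect_equal(ft$df_between, 2)
  expect_equal(ft$df_within, 17)
  expect_equal(ft$ss_between, 644.3416667, tolerance = 1e-8)
  expect_equal(ft$ss_within, 3262.2083333, tolerance = 1e-8)
  expect_equal(ft$ss_between + ft$ss_within,
               sum((example20_values - mean(example20_values))^2),
               tolerance = 1e-9)
  expect_equal(ft$F, 1.6788947, tolerance = 1e-6)
  expect_equal(ft$p, 0.2160755, tolerance = 1e-6)
  expect_equal(round(ft$F, 2), 1.68)
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(5)
  ids <- paste0("i", 1:16)
  vals <- rnorm(16, 10, 2)
  labs <- rep(c("A", "B"), each = 8)
  ft <- f_test(phenotype_vector(ids, vals), marker_genotypes(ids, labs))
  tt <- t.test(vals[1:8], vals[9:16], var.equal = TRUE)
  expect_equal(ft$F, unname(tt$statistic^2), tolerance = 1e-9)
  expect_equal(ft$p, tt$p.value, tolerance = 1e-9)
})

test_that("F decomposition is additive and the zero-between case is handled", {
  set.seed(13)
  for (rep in 1:10) {
    fx <- random_fixture(n = 15, n_classes = 3)
    s <- stratify(fx$pheno, fx$geno)
    if (s$n < 2) next
    ft <- f_test(fx$pheno, fx$geno)
    tot <- sum((s$values - mean(s$values))^2)
    expect_equal(ft$ss_between + ft$ss_within, tot,
                 tolerance = 1e-9 * max(1, tot))
  }
  # equal group means with within-group spread: zero numerator, F = 0
  ids <- paste0("i", 1:8)
  ft0 <- f_test(phenotype_vector(ids, c(1, 3, 1, 3, 1, 3, 1, 3)),
                marker_genotypes(ids, rep(c("A", "B"), each = 4)))
  expect_equal(ft0$F, 0)
  expect_error(f_test(phenotype_vector(ids, rep(2, 8)),
                      marker_genotypes(ids, rep(c("A", "B"), each = 4))),
               class = "hh_error_degenerate_spread")
})

test_that("min-max normalization forces endpoints and preserves order", {
  expect_equal(normalize_minmax(c(-2, 0, 2)), c(0, 0.5, 1))
  x <- c(0, 0.25, 0.9, 1)
  expect_equal(normalize_minmax(x), x)
  set.seed(2)
  v <- rnorm(30)
  z <- normalize_minmax(v)
  expect_equal(min(z), 0); expect_equal(max(z), 1)
  expect_equal(order(z), order(v))
  expect_error(normalize_minmax(rep(3, 5)),
               class = "hh_error_degenerate_spread")
  expect_error(normalize_minmax(c(1, NA)),
               class = "hh_error_degenerate_spread")
  # NA entries pass through
  expect_equal(normalize_minmax(c(1, NA, 3)), c(0, NA, 1))
})
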