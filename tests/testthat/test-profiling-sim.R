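# Independent Welch t-test oracle, coded from the textbook formulas.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(t), df)
}

test_that("gene replicate sampling is seeded, clamped and matches the closed-form mean", {
  spec <- list(control_mean = 2, treated_mean = 1, sd_ribosomes = 1)
  a <- sample_gene_replicate(spec, "control", 100, seed = 42)
  b <- sample_gene_replicate(spec, "control", 100, seed = 42)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  # sd -> 0 limit: all draws collapse onto the mean
  tight <- sample_gene_replicate(list(control_mean = 5, treated_mean = 1,
                                      sd_ribosomes = 1e-9), "control", 3, seed = 1)
  expect_equal(tight, rep(5, 3), tolerance = 1e-6)
  # clamped-normal moment: E[max(N(2,1), 0)] = 2*pnorm(2) + dnorm(2)
  big <- sample_gene_replicate(spec, "control", 1e5, seed = 7)
  expected <- 2 * stats::pnorm(2) + stats::dnorm(2)
  expect_lt(abs(mean(big) - expected) / expected, 0.01)
})

test_that("polysome estimator equals a brute-force count and respects bounds", {
  expect_equal(estimate_polyprof(c(1, 2, 3, 4)), 0.25)
  expect_equal(estimate_polyprof(rep(5, 10)), 1)
  expect_error(estimate_polyprof(numeric(0)), "non-empty")
  set.seed(11)
  for (i in 1:50) {
    loads <- stats::runif(sample(1:40, 1), 0, 8)
    brute <- 0
    for (x in loads) if (x > 3) brute <- brute + 1
    expect_equal(estimate_polyprof(loads), brute / length(loads))
  }
  # strictly increasing in the distribution mean at fixed sd
  props <- vapply(c(2, 4, 6), function(mu) {
    estimate_polyprof(sample_gene_replicate(
      list(control_mean = mu, treated_mean = 1, sd_ribosomes = 1.5),
      "control", 2e4, seed = mu))
  }, numeric(1))
  expect_true(all(diff(props) > 0))
})

test_that("ribosome-profiling estimator scales with load and abundance", {
  loads <- c(2, 3, 2.5)  # mean 2.5
  expect_equal(estimate_riboprof(loads, abundance = 10, noise = "none"), 25)
  expect_equal(estimate_riboprof(loads, abundance = 20, noise = "none"), 50)
  expect_error(estimate_riboprof(loads, abundance = 0), "> 0")
  # Poisson mean oracle
  set.seed(3)
  draws <- replicate(5e3, estimate_riboprof(c(10), abundance = 10,
                                            noise = "poisson"))
  expect_lt(abs(mean(draws) - 100) / 100, 0.02)
})

test_that("differential test matches an independent Welch implementation", {
  r <- differential_test(c(8, 10, 12, 10), c(4, 5, 6, 5))
  expect_equal(r$fold_change, 2)
  expect_equal(r$pvalue, welch_oracle(log2(c(8, 10, 12, 10)), log2(c(4, 5, 6, 5))),
               tolerance = 1e-6)
  set.seed(5)
  for (i in 1:25) {
    a <- stats::rlnorm(4, 3, 0.4); b <- stats::rlnorm(4, 2.5, 0.4)
    r <- differential_test(a, b)
    expect_equal(r$pvalue, welch_oracle(log2(a), log2(b)), tolerance = 1e-6)
    sw <- differential_test(b, a)
    expect_equal(sw$fold_change, 1 / r$fold_change, tolerance = 1e-12)
    expect_equal(sw$pvalue, r$pvalue, tolerance = 1e-12)
  }
})

test_that("differential test handles degenerate replicates inside (0, 1]", {
  same <- differential_test(c(4, 4, 4, 4), c(4, 4, 4, 4))
  expect_equal(same$fold_change, 1)
  expect_equal(same$pvalue, 1)
  sep <- differential_test(c(8, 8, 8), c(2, 2, 2))  # perfect separation
  expect_equal(sep$fold_change, 4)
  expect_gt(sep$pvalue, 0)
  expect_lt(sep$pvalue, 1e-100)
  expect_error(differential_test(c(1), c(2, 3)), "2 replicates")
  expect_error(differential_test(c(1, -2), c(2, 3)), "positive")
})

test_that("ranking selects the stated count with lexicographic tie-breaks", {
  res <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    pvalue_poly = seq(0.01, 0.1, by = 0.01),
                    fold_change_poly = 2^(10:1))
  sel <- rank_and_select(res, "poly", "pvalue", 0.2)
  expect_length(sel, 2)
  expect_identical(sel, c("g01", "g02"))
  # ties fall back to gene id order
  res$pvalue_poly <- 0.5
  expect_identical(rank_and_select(res, "poly", "pvalue", 0.2), c("g01", "g02"))
  # fold-change ranking uses |log2 fc| descending
  sel_fc <- rank_and_select(res, "poly", "fold_change", 0.2)
  expect_identical(sel_fc, c("g01", "g02"))
})

test_that("bias report arithmetic and invariances", {
  specs <- gene_spec_table(gene_id = sprintf("g%02d", 1:20),
                           gene_class = rep(c("a", "b", "c", "d"), each = 5),
                           abundance = 1, control_mean = 5, treated_mean = 1,
                           sd_ribosomes = 1)
  uniform <- compute_bias(c("g01", "g06", "g11", "g16"), specs)
  expect_equal(uniform$bias_sum, 0)
  one_class <- compute_bias(sprintf("g%02d", 1:5), specs)
  expect_equal(one_class$bias_sum, 150)
  expect_equal(sum(one_class$table$observed_pct), 100)
  # permuting selected ids within a class leaves the report unchanged
  alt <- compute_bias(sprintf("g%02d", c(2, 3, 4, 5, 1)), specs)
  expect_equal(alt$bias_sum, one_class$bias_sum)
  expect_error(compute_bias(character(0), specs), "empty")
})
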