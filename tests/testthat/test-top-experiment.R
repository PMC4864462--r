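# small population configuration shared by the sweep tests: the class
# structure and shifts are the defaults, only the problem size shrinks
small_pop <- function(n_sim = 2L) {
  population_config(n_genes = 400L, n_simulations = n_sim)
}

test_that("population construction apportions classes and abundances", {
  cfg <- population_config(n_genes = 1000L)
  specs <- build_population(cfg, seed = 1)
  counts <- table(specs$gene_class)
  expect_equal(unname(counts[c("TOP", "NONTOP", "NONMOVER")]),
               c(35L, 165L, 800L), ignore_attr = TRUE)
  for (s in 1:5) {
    sp <- build_population(cfg, seed = s)
    expect_gt(mean(sp$abundance[sp$gene_class == "TOP"]),
              mean(sp$abundance[sp$gene_class == "NONTOP"]))
  }
  expect_error(population_config(fraction_top = 0.5, fraction_nontop = 0.5,
                                 fraction_nonmover = 0.5), "sum to 1")
  # no TOP genes requested -> none emitted
  cfg0 <- population_config(fraction_top = 0, fraction_nonmover = 0.835)
  expect_false("TOP" %in% build_population(cfg0, seed = 1)$gene_class)
})

test_that("global centring fixes the median log2 fold change at zero", {
  expect_equal(global_center(c(2, 2, 2, 1)), c(1, 1, 1, 0.5))
  expect_equal(global_center(rep(3, 5)), rep(1, 5))
  set.seed(9)
  x <- stats::rlnorm(101, 0, 1)
  expect_equal(stats::median(log2(global_center(x))), 0)
  expect_error(global_center(c(1, -1)), "positive")
})

test_that("TOP-fraction sweep attenuates relative fold changes, most for ribosome-profiling", {
  sw <- sweep_top_changing_fraction(small_pop(), fractions = c(0, 0.035, 0.1),
                                    seed = 1)
  s <- sw$sweep
  pick <- function(meth, quant, cls = "NONTOP")
    s$fold_change[s$class == cls & s$method == meth & s$quantification == quant]
  # absolute poly fold change at f = 0 matches the simulated truth
  p_ctrl <- 1 - stats::pnorm(3, 5, 1.5)
  p_trt <- 1 - stats::pnorm(3, 3.5, 1.5)
  expect_lt(abs(log2(pick("poly", "absolute")[1] / (p_ctrl / p_trt))), 0.1)
  # relative non-TOP fold changes are non-increasing in f (tolerating noise)
  for (meth in c("poly", "ribo")) {
    rel <- pick(meth, "relative")
    expect_true(all(diff(log2(rel)) < 0.05))
  }
  # attenuation (absolute vs relative) is at least as large for ribo at every f
  att_ribo <- log2(pick("ribo", "absolute") / pick("ribo", "relative"))
  att_poly <- log2(pick("poly", "absolute") / pick("poly", "relative"))
  expect_true(all(att_ribo >= att_poly - 0.05))
  # absolute fold changes do not depend on the swept fraction
  for (meth in c("poly", "ribo")) {
    ab <- pick(meth, "absolute")
    expect_lt(max(abs(diff(log2(ab)))), 0.15)
  }
})

test_that("global-reduction sweep keeps TOP above non-TOP and validates input", {
  sw <- sweep_global_reduction(small_pop(), reduction_factors = c(1, 0.7, 0.5),
                               seed = 2)
  s <- sw$sweep
  for (f in unique(s$sweep_value)) {
    for (meth in c("poly", "ribo")) {
      top <- s$fold_change[s$sweep_value == f & s$class == "TOP" &
                             s$method == meth & s$quantification == "relative"]
      ntop <- s$fold_change[s$sweep_value == f & s$class == "NONTOP" &
                              s$method == meth & s$quantification == "relative"]
      expect_gt(top, ntop)
    }
  }
  expect_error(sweep_global_reduction(small_pop(), reduction_factors = c(1.5)),
               "0, 1")
  expect_error(sweep_global_reduction(small_pop(), reduction_factors = c(0)),
               "0, 1")
})

test_that("count threshold diagnostic counts consistent genes and flags noisy low counts", {
  m <- matrix(c(300, 400, 300, 100, 500, 600), nrow = 3, byrow = TRUE)
  res <- count_threshold_analysis(m, thresholds = c(256))
  expect_equal(res$threshold_counts$n_genes, 2L)
  res0 <- count_threshold_analysis(m, thresholds = c(0))
  expect_equal(res0$threshold_counts$n_genes, 3L)
  expect_error(count_threshold_analysis(matrix(1:3, ncol = 1)), "2 replicates")
  # overdispersed counts: CV inflates below 64 reads relative to above 256
  counts <- simulate_count_matrix(n_genes = 4000, n_replicates = 4,
                                  dispersion = 0.1, seed = 5)
  mv <- count_threshold_analysis(counts)$mean_var
  cv_low <- mean(mv$cv[mv$mean < 64 & mv$mean > 0], na.rm = TRUE)
  cv_high <- mean(mv$cv[mv$mean > 256], na.rm = TRUE)
  expect_gt(cv_low, cv_high)
})
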