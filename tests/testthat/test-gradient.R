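test_that("sedimentation map is anchored, bounded and monotone", {
  m <- gradient_mapping()
  expect_equal(ribosomes_to_sedimentation(0, m), 0)
  expect_equal(ribosomes_to_sedimentation(m$n_max, m), 1)
  expect_equal(ribosomes_to_sedimentation(1, m), m$monosome_position)
  expect_lt(ribosomes_to_sedimentation(5, m), ribosomes_to_sedimentation(10, m))
  n <- seq(0, m$n_max, length.out = 200)
  d <- ribosomes_to_sedimentation(n, m)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diff(d) >= 0))
  expect_error(ribosomes_to_sedimentation(-1, m), "non-negative")
})

test_that("mapping parameters are validated", {
  expect_error(gradient_mapping(n_max = 0), "positive")
  expect_error(gradient_mapping(alpha = -1), "positive")
  expect_error(gradient_mapping(monosome_position = 1.2), "0, 1")
})

test_that("fitting recovers planted distribution parameters from clean traces", {
  m <- gradient_mapping()
  cases <- list(c(6, 2), c(1, 0.5), c(8, 1.5))
  for (cs in cases) {
    tr <- simulate_absorbance_trace(ribosome_distribution(cs[1], cs[2]), m,
                                    noise_sd = 0, seed = 1)
    fit <- fit_ribosome_distribution(tr, m)
    expect_lt(abs(fit$mean_ribosomes - cs[1]) / cs[1], 0.05)
    expect_lt(abs(fit$sd_ribosomes - cs[2]) / cs[2], 0.10)
  }
})

test_that("degenerate traces are rejected", {
  m <- gradient_mapping()
  flat <- data.frame(position = seq(0, 1, length.out = 50),
                     absorbance = rep(1, 50))
  expect_error(fit_ribosome_distribution(flat, m), "flat trace")
  short <- data.frame(position = seq(0, 1, length.out = 5),
                      absorbance = stats::runif(5))
  expect_error(fit_ribosome_distribution(short, m), "at least 10")
})

test_that("absorbance traces survive a TSV round trip", {
  m <- gradient_mapping()
  tr <- simulate_absorbance_trace(ribosome_distribution(5, 1.5), m,
                                  noise_sd = 0.02, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_absorbance_trace(tr, path)
  back <- read_absorbance_trace(path)
  expect_equal(back$position, tr$position, tolerance = 1e-8)
  expect_equal(back$absorbance, tr$absorbance, tolerance = 1e-8)
})
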