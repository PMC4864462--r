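test_that("absorbance traces are reproducible and shift mass with the mean", {
  m <- gradient_mapping()
  t1 <- simulate_absorbance_trace(ribosome_distribution(4, 1), m, seed = 5)
  t2 <- simulate_absorbance_trace(ribosome_distribution(4, 1), m, seed = 5)
  expect_identical(t1, t2)
  lo <- simulate_absorbance_trace(ribosome_distribution(1, 1.5), m,
                                  noise_sd = 0, seed = 1)
  hi <- simulate_absorbance_trace(ribosome_distribution(8, 1.5), m,
                                  noise_sd = 0, seed = 1)
  beyond <- lo$position > m$monosome_position
  dx <- mean(diff(lo$position))
  expect_gt(sum(hi$absorbance[beyond]) * dx, sum(lo$absorbance[beyond]) * dx)
})

test_that("toy transcriptome honours planted fractions and length classes", {
  all_top <- make_toy_transcriptome(n_transcripts = 20, fraction_top = 1,
                                    fraction_tisu = 0, seed = 3)
  expect_true(all(all_top$truth$is_top))
  expect_false(any(all_top$truth$has_tisu))
  fixed <- make_toy_transcriptome(
    n_transcripts = 10, fraction_top = 0, fraction_tisu = 0,
    utr_length_model = list(short_fraction = 1, short_range = c(25L, 25L),
                            long_range = c(30L, 40L)),
    seed = 4)
  expect_true(all(fixed$truth$true_utr_length == 25))
  expect_true(all(fixed$truth$length_class == "short"))
  # planted flags are consistent with the emitted sequences by construction:
  # verified through the classifier round-trip in the utr tests
  expect_error(make_toy_transcriptome(
    n_transcripts = 4, fraction_top = 0, fraction_tisu = 1,
    utr_length_model = list(short_fraction = 1, short_range = c(2L, 3L),
                            long_range = c(30L, 40L)), seed = 1),
    "cannot host")
})

test_that("CTSS simulation is seeded and respects the no-downstream rule", {
  tx <- make_toy_transcriptome(n_transcripts = 12, seed = 8)
  a <- simulate_ctss(tx, seed = 9)
  b <- simulate_ctss(tx, seed = 9)
  expect_identical(a, b)
  # signal tags (no background) never land downstream of the start codon
  sig <- simulate_ctss(tx, background_rate = 0, seed = 10)
  for (i in seq_len(nrow(tx$transcripts))) {
    m <- tx$transcripts[i, ]
    near <- sig[sig$chrom == m$chrom & sig$strand == m$strand &
                  abs(sig$pos - tx$truth$true_tss[i]) < 500, ]
    if (m$strand == "+") expect_true(all(near$pos < m$cds_start))
    else expect_true(all(near$pos > m$cds_start))
  }
})

test_that("count matrix generator matches its Poisson limit and is seeded", {
  poisson <- simulate_count_matrix(n_genes = 10000, n_replicates = 2,
                                   mean_meanlog = log(100), mean_sdlog = 0,
                                   dispersion = 0, seed = 6)
  vm <- stats::var(as.vector(poisson)) / mean(poisson)
  expect_lt(abs(vm - 1), 0.05)
  a <- simulate_count_matrix(n_genes = 50, seed = 2)
  b <- simulate_count_matrix(n_genes = 50, seed = 2)
  expect_identical(a, b)
  expect_true(all(a >= 0))
})
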