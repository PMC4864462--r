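ctss_df <- function(pos, count, chrom = "chr1", strand = "+") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
             strand = rep_len(strand, n), count = as.integer(count),
             stringsAsFactors = FALSE)
}

test_that("CTSS clustering applies the gap and read thresholds as stated", {
  recs <- ctss_df(c(100, 101, 150), c(10, 8, 3))
  cl <- cluster_ctss(recs, max_gap = 20, min_peak_reads = 5)
  retained <- cl[cl$retained, ]
  expect_equal(nrow(retained), 1)
  expect_equal(retained$start, 100)
  expect_equal(retained$end, 102)
  expect_equal(retained$total_count, 18)
  expect_equal(retained$summit, 100)
  # the 3-read cluster is present but not retained (not > 5 reads)
  expect_equal(sum(!cl$retained), 1)
  expect_equal(cl$total_count[!cl$retained], 3)
  # empty input
  expect_equal(nrow(cluster_ctss(ctss_df(integer(0), integer(0)))), 0)
  # identical positions on opposite strands stay separate
  two <- rbind(ctss_df(500, 10, strand = "+"), ctss_df(500, 10, strand = "-"))
  expect_equal(nrow(cluster_ctss(two)), 2)
})

test_that("clustering conserves reads and never overlaps peaks on a strand", {
  set.seed(21)
  for (i in 1:10) {
    recs <- ctss_df(sample(1:2000, 150), sample(1:20, 150, replace = TRUE))
    cl <- cluster_ctss(recs, max_gap = sample(5:40, 1))
    expect_equal(sum(cl$total_count), sum(recs$count))
    cl <- cl[order(cl$start), ]
    if (nrow(cl) > 1) expect_true(all(cl$start[-1] >= cl$end[-nrow(cl)]))
  }
})

test_that("UTR lengths follow the stated peak and weighted-mean definitions", {
  # lengths 50 (30 reads) and 10 (10 reads) upstream of cds_start 100
  r <- compute_utr_lengths(c(50, 90), c(30, 10), cds_start = 100, strand = "+")
  expect_equal(r$peak_length, 50L)
  expect_equal(r$weighted_mean_length, 40)
  single <- compute_utr_lengths(70, 12, cds_start = 100, strand = "+")
  expect_equal(single$peak_length, as.integer(single$weighted_mean_length))
  # equal counts at lengths 20 and 80: tie resolves toward the start codon
  tie <- compute_utr_lengths(c(80, 20), c(10, 10), cds_start = 100, strand = "+")
  expect_equal(tie$peak_length, 20L)
  expect_equal(tie$weighted_mean_length, 50)
  # minus strand mirrors the arithmetic
  minus <- compute_utr_lengths(c(150, 110), c(30, 10), cds_start = 100, strand = "-")
  expect_equal(minus$peak_length, 50L)
  expect_equal(minus$weighted_mean_length, 40)
  expect_error(compute_utr_lengths(c(100, 120), c(5, 5), 100, "+"), "downstream")
  # splitting one position's count across records leaves the weighted mean unchanged
  split <- compute_utr_lengths(c(50, 50, 90), c(20, 10, 10), 100, "+")
  expect_equal(split$weighted_mean_length, 40)
})

test_that("TOP classification matches its definition and a regex oracle", {
  expect_true(classify_top("CTTTCAGG"))
  expect_false(classify_top("CAAAGG"))
  expect_false(classify_top("ATTTTTT"))
  expect_true(classify_top("CUUUUAGG"))  # RNA alphabet normalised
  expect_error(classify_top("CTNTTAGG"), "non-nucleotide")
  set.seed(31)
  seqs <- vapply(1:10000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE,
                 prob = c(0.2, 0.3, 0.2, 0.3)), collapse = "")
  }, character(1))
  oracle <- grepl("^C[CT]{4}", seqs)
  mine <- vapply(seqs, classify_top, logical(1), USE.NAMES = FALSE)
  expect_identical(mine, oracle)
})

test_that("TISU detection enforces the consensus, the AUG anchor and the mismatch budget", {
  expect_true(detect_tisu("CAAGATGGCGGC"))
  expect_true(detect_tisu("GAACATGGCGGC"))
  expect_false(detect_tisu("TAAGATGGCGGC"))
  expect_false(detect_tisu("CAAGATGGCGGA"))
  expect_true(detect_tisu("CAAGATGGCGGA", max_mismatch = 1))
  expect_error(detect_tisu("CAAGAGGGCGGC"), "ATG")
  expect_error(detect_tisu("CAAGATGGCGG"), "12 nt")
})

test_that("reference comparison counts transcripts at half length or shorter", {
  models <- data.frame(transcript_id = c("t1", "t2", "t3"),
                       gene_id = c("g1", "g2", "g3"),
                       chrom = "chr1", strand = "+",
                       reference_tss = c(0, 40, 100),
                       cds_start = c(100, 100, 100))
  ann <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    peak_length = c(40L, 60L, 10L),
                    weighted_mean_length = c(40, 60, 10))
  cmp <- compare_to_reference(ann, models)
  expect_equal(cmp$ratios$ratio_peak[1], 0.4)
  expect_equal(cmp$ratios$ratio_peak[2], 1)
  expect_true(cmp$ratios$skipped[3])  # zero reference length
  expect_equal(unname(cmp$fraction_half_or_shorter["peak"]), 0.5)
})

test_that("enrichment test equals the hypergeometric enumeration oracle", {
  r <- enrichment_test(5, 10, 50, 1000)
  expect_equal(r$fold_enrichment, 10)
  zero <- enrichment_test(0, 10, 50, 1000)
  expect_equal(zero$fold_enrichment, 0)
  expect_equal(zero$pvalue, 1)
  inf <- enrichment_test(3, 10, 0, 50)
  expect_equal(inf$fold_enrichment, Inf)
  expect_lt(inf$pvalue, 1)
  # enumeration oracle from binomial coefficients, all tables with small backgrounds
  tail_oracle <- function(h, s, hb, bs) {
    total <- s + bs; hits <- h + hb
    ks <- seq(h, min(hits, s))
    sum(choose(hits, ks) * choose(total - hits, s - ks)) / choose(total, s)
  }
  for (bs in c(20, 40, 60)) {
    for (s in c(5, 8)) {
      for (hb in c(0, 3, 10)) {
        for (h in 0:s) {
          expect_equal(enrichment_test(h, s, hb, bs)$pvalue,
                       tail_oracle(h, s, hb, bs), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("planted UTR features round-trip exactly without jitter", {
  tx <- make_toy_transcriptome(n_transcripts = 40, seed = 17)
  ctss <- simulate_ctss(tx, tss_jitter_sd = 0, background_rate = 0, seed = 17)
  expect_true(all(ctss$pos %in% tx$truth$true_tss))
  ann <- annotate_utrs(ctss, tx$transcripts, tx$sequences)
  truth <- tx$truth[match(ann$transcript_id, tx$truth$transcript_id), ]
  expect_equal(ann$tss, truth$true_tss)
  expect_equal(ann$peak_length, truth$true_utr_length)
  expect_identical(ann$is_top, truth$is_top)
  expect_identical(ann$has_tisu, truth$has_tisu)
  expect_identical(ann$length_class, truth$length_class)
})

test_that("CTSS records and transcript models survive their TSV formats", {
  tx <- make_toy_transcriptome(n_transcripts = 8, seed = 2)
  ctss <- simulate_ctss(tx, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_ctss(ctss, p1)
  expect_equal(read_ctss(p1), ctss, ignore_attr = TRUE)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tx$transcripts, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  models <- read_transcript_models(p2)
  expect_equal(models$cds_start, tx$transcripts$cds_start)
  # BED6 output for retained peaks
  p3 <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(cluster_ctss(ctss), p3)
  bed <- utils::read.delim(p3, header = FALSE)
  expect_equal(ncol(bed), 6)
  expect_true(all(bed$V5 > 5))
})
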