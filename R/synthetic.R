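# Generators for every input the pipeline consumes, with planted ground truth.

#' Render a synthetic polysome absorbance trace
#'
#' Pushes a clamped-normal ribosome-association law through the gradient
#' mapping: molecules are binned at integer ribosome counts, each bin appears
#' as a narrow Gaussian peak at its sedimentation position (so discrete 80S /
#' polysome peaks are visible), Gaussian noise is added, negative values are
#' clamped and the curve is normalised to unit area.
#'
#' @param dist A [ribosome_distribution()].
#' @param mapping A [gradient_mapping()].
#' @param noise_sd Standard deviation of additive Gaussian noise, on the
#'   unit-area absorbance scale (>= 0).
#' @param n_points Number of equally spaced positions on \[0, 1\].
#' @param peak_sd Width of the per-peak kernel (normalised distance units).
#' @param seed Integer seed; the trace is a pure function of (arguments, seed).
#' @return Data frame with columns `position`, `absorbance`.
#' @examples
#' tr <- simulate_absorbance_trace(ribosome_distribution(6, 2), gradient_mapping(),
#'                                 noise_sd = 0, seed = 1)
#' fit_ribosome_distribution(tr, gradient_mapping())
#' @export
simulate_absorbance_trace <- function(dist, mapping, noise_sd = 0.05,
                                      n_points = 200L, peak_sd = 0.015,
                                      seed = 1L) {
  assert_that(inherits(dist, "ribosome_distribution"), "`dist` must be a ribosome_distribution")
  assert_that(inherits(mapping, "gradient_mapping"), "`mapping` must be a gradient_mapping")
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  positions <- seq(0, 1, length.out = n_points)
  y <- trace_model(dist$mean_ribosomes, dist$sd_ribosomes, mapping, positions, peak_sd)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(n_points, 0, noise_sd)
  }
  y <- pmax(y, 0)
  area <- sum(y) * mean(diff(positions))
  if (area > 0) y <- y / area
  data.frame(position = positions, absorbance = y)
}

IUPAC_S <- c("G", "C")
PYRIMIDINES <- c("C", "T")
TISU_CONSENSUS <- "SAASATGGCGGC"  # 12-mer spanning [AUG-4, AUG+8)

# sample one random DNA string of length n
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

expand_iupac <- function(consensus) {
  vapply(strsplit(consensus, "")[[1]], function(ch) {
    if (ch == "S") sample(IUPAC_S, 1) else ch
  }, character(1))
}

#' Generate a toy transcriptome with planted 5' UTR features
#'
#' Emits a single synthetic chromosome per strand, transcripts at fixed
#' spacing, each with a planted transcription start site, start codon, 5' UTR
#' length class, and optionally a 5' TOP motif (cap-proximal C followed by a
#' sampled run of 4--15 pyrimidines) and/or a TISU element
#' (`SAASATGGCGGC` across the start codon). Every planted flag round-trips
#' through [classify_top()] / [detect_tisu()] on the emitted sequence.
#'
#' @param n_transcripts Number of transcripts (> 0).
#' @param fraction_top Fraction carrying a planted TOP motif, in \[0, 1\].
#' @param fraction_tisu Fraction carrying a planted TISU element, in \[0, 1\].
#' @param utr_length_model List with `short_fraction` (fraction of transcripts
#'   in the short class), `short_range` (inclusive UTR length range < 30) and
#'   `long_range` (range >= 30). Lengths are sampled uniformly within range.
#' @param cds_length Length of the coding stretch placed after the start codon.
#' @param spacing Distance in nt between consecutive transcript starts.
#' @param ref_inflated_fraction Fraction of transcripts whose RefSeq-style
#'   `reference_tss` annotates a 5' UTR `ref_inflation`-fold longer than the
#'   true one (emulating database TSSs upstream of the real start); the rest
#'   annotate the true TSS.
#' @param ref_inflation Length multiplier for the inflated annotations (> 1).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance model.
#' @param seed Integer seed.
#' @return List of class `toy_transcriptome` with elements `sequences`
#'   (a [Biostrings::DNAStringSet] of chromosomes), `transcripts` (annotation
#'   data frame: `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `reference_tss`, `cds_start`) and `truth` (planted ground truth:
#'   `transcript_id`, `true_tss`, `true_utr_length`, `is_top`, `has_tisu`,
#'   `length_class`, `abundance`).
#' @export
make_toy_transcriptome <- function(n_transcripts = 60L,
                                   fraction_top = 0.25,
                                   fraction_tisu = 0.25,
                                   utr_length_model = list(short_fraction = 0.5,
                                                           short_range = c(5L, 29L),
                                                           long_range = c(30L, 150L)),
                                   cds_length = 120L,
                                   spacing = 2000L,
                                   ref_inflated_fraction = 0.3,
                                   ref_inflation = 2.2,
                                   abundance_meanlog = log(10),
                                   abundance_sdlog = 0.4,
                                   seed = 1L) {
  assert_that(n_transcripts >= 1, "`n_transcripts` must be >= 1")
  assert_that(fraction_top >= 0 && fraction_top <= 1, "`fraction_top` must be in [0, 1]")
  assert_that(fraction_tisu >= 0 && fraction_tisu <= 1, "`fraction_tisu` must be in [0, 1]")
  sf <- utr_length_model$short_fraction
  assert_that(is.numeric(sf) && sf >= 0 && sf <= 1,
              "`utr_length_model$short_fraction` must be in [0, 1]")
  set.seed(seed)

  n_top <- largest_remainder(n_transcripts, c(fraction_top, 1 - fraction_top))[1]
  n_tisu <- largest_remainder(n_transcripts, c(fraction_tisu, 1 - fraction_tisu))[1]
  n_short <- largest_remainder(n_transcripts, c(sf, 1 - sf))[1]

  is_top <- seq_len(n_transcripts) <= n_top
  has_tisu <- rep(FALSE, n_transcripts)
  if (n_tisu > 0) has_tisu[sample.int(n_transcripts, n_tisu)] <- TRUE
  short_class <- rep(FALSE, n_transcripts)
  if (n_short > 0) short_class[sample.int(n_transcripts, n_short)] <- TRUE

  utr_len <- integer(n_transcripts)
  for (i in seq_len(n_transcripts)) {
    rng <- if (short_class[i]) utr_length_model$short_range else utr_length_model$long_range
    lo <- rng[1]; hi <- rng[2]
    # a TOP motif needs >= 5 nt of UTR; a TISU needs >= 4 nt upstream of AUG;
    # both together need >= 9 so the pyrimidine run ends before the TISU
    min_needed <- if (is_top[i] && has_tisu[i]) 9L else
                  max(if (is_top[i]) 5L else 1L, if (has_tisu[i]) 4L else 1L)
    if (hi < min_needed)
      stop(sprintf("transcript %d: UTR length range [%d, %d] cannot host the planted motifs",
                   i, lo, hi), call. = FALSE)
    lo <- max(lo, min_needed)
    utr_len[i] <- if (lo >= hi) lo else sample(seq(lo, hi), 1)
  }

  build_tx_seq <- function(i) {
    repeat {
      utr <- strsplit(random_dna(utr_len[i]), "")[[1]]
      if (is_top[i]) {
        run <- sample(4:15, 1)
        # keep the run clear of the TISU's upstream half when both are planted
        run <- min(run, utr_len[i] - if (has_tisu[i]) 5L else 1L)
        utr[1] <- "C"
        utr[1 + seq_len(run)] <- sample(PYRIMIDINES, run, replace = TRUE)
        if (run + 1 < utr_len[i]) utr[run + 2] <- "A"  # terminate the run
      }
      cds <- strsplit(paste0("ATG", random_dna(cds_length - 3L)), "")[[1]]
      if (has_tisu[i]) {
        cons <- expand_iupac(TISU_CONSENSUS)
        utr[utr_len[i] - 3:0] <- cons[1:4]
        cds[1:8] <- cons[5:12]
      }
      s <- paste(c(utr, cds), collapse = "")
      ok_top <- classify_top(substr(s, 1, min(nchar(s), 20))) == is_top[i]
      ok_tisu <- if (utr_len[i] >= 4) {
        detect_tisu(substr(s, utr_len[i] - 3, utr_len[i] + 8)) == has_tisu[i]
      } else !has_tisu[i]  # too little UTR to host the upstream half
      if (ok_top && ok_tisu) return(s)
    }
  }

  tx_seq <- vapply(seq_len(n_transcripts), build_tx_seq, character(1))
  strand <- rep(c("+", "-"), length.out = n_transcripts)

  pad <- 200L  # upstream slack so jittered tags keep positive coordinates
  tx_span <- nchar(tx_seq)
  chrom_len <- n_transcripts * spacing + pad
  plus_chr <- rep("N", chrom_len)
  minus_chr <- rep("N", chrom_len)

  true_tss <- integer(n_transcripts)
  cds_start <- integer(n_transcripts)
  chrom <- ifelse(strand == "+", "toy_plus", "toy_minus")
  for (i in seq_len(n_transcripts)) {
    offset <- pad + (i - 1L) * spacing  # 0-based start of the transcript slot
    chars <- strsplit(tx_seq[i], "")[[1]]
    if (strand[i] == "+") {
      true_tss[i] <- offset
      cds_start[i] <- offset + utr_len[i]
      plus_chr[offset + seq_along(chars)] <- chars
    } else {
      # transcript runs right-to-left on the genome; TSS is the highest coord
      true_tss[i] <- offset + tx_span[i] - 1L
      cds_start[i] <- true_tss[i] - utr_len[i]
      rc <- rev(chartr("ACGT", "TGCA", chars))
      minus_chr[offset + seq_along(rc)] <- rc
    }
  }

  # fill unused positions with random background sequence
  plus_chr[plus_chr == "N"] <- sample(c("A", "C", "G", "T"), sum(plus_chr == "N"), replace = TRUE)
  minus_chr[minus_chr == "N"] <- sample(c("A", "C", "G", "T"), sum(minus_chr == "N"), replace = TRUE)
  sequences <- Biostrings::DNAStringSet(c(toy_plus = paste(plus_chr, collapse = ""),
                                          toy_minus = paste(minus_chr, collapse = "")))

  inflated <- rep(FALSE, n_transcripts)
  n_inf <- largest_remainder(n_transcripts, c(ref_inflated_fraction, 1 - ref_inflated_fraction))[1]
  if (n_inf > 0) inflated[sample.int(n_transcripts, n_inf)] <- TRUE
  ref_len <- ifelse(inflated, pmax(utr_len + 1L, round(utr_len * ref_inflation)), utr_len)
  reference_tss <- ifelse(strand == "+", cds_start - ref_len, cds_start + ref_len)

  abundance <- stats::rlnorm(n_transcripts, abundance_meanlog, abundance_sdlog)

  transcripts <- data.frame(
    transcript_id = sprintf("tx%04d", seq_len(n_transcripts)),
    gene_id = sprintf("gene%04d", seq_len(n_transcripts)),
    chrom = chrom, strand = strand,
    reference_tss = as.integer(reference_tss),
    cds_start = as.integer(cds_start),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    transcript_id = transcripts$transcript_id,
    true_tss = true_tss,
    true_utr_length = utr_len,
    is_top = is_top, has_tisu = has_tisu,
    length_class = ifelse(utr_len < 30L, "short", "long"),
    ref_inflated = inflated,
    abundance = abundance,
    stringsAsFactors = FALSE)

  structure(list(sequences = sequences, transcripts = transcripts, truth = truth),
            class = "toy_transcriptome")
}

#' @export
print.toy_transcriptome <- function(x, ...) {
  cat(sprintf("<toy_transcriptome> %d transcripts (%d TOP, %d TISU, %d short 5' UTR)\n",
              nrow(x$truth), sum(x$truth$is_top), sum(x$truth$has_tisu),
              sum(x$truth$length_class == "short")))
  invisible(x)
}

#' Simulate nanoCAGE-style CTSS tags over a toy transcriptome
#'
#' Per-transcript tag totals are negative-binomial, scaled by planted
#' abundance. Tag positions scatter around the true TSS with discretised
#' Gaussian jitter, clipped so no signal tag lands downstream of the start
#' codon (5'-end tags mark transcription starts). Uniform background tags are
#' added at `background_rate` per nucleotide per strand.
#'
#' @param tx A [make_toy_transcriptome()] result.
#' @param tags_per_transcript Expected tag count for a transcript of mean
#'   abundance (> 0).
#' @param tss_jitter_sd Standard deviation (nt) of the jitter around the TSS.
#' @param background_rate Expected background tags per nt per strand (>= 0).
#' @param dispersion Negative-binomial dispersion of per-transcript totals
#'   (0 degenerates to Poisson).
#' @param seed Integer seed.
#' @return Data frame of CTSS records: `chrom`, `pos` (0-based), `strand`,
#'   `count` (all > 0).
#' @export
simulate_ctss <- function(tx, tags_per_transcript = 200, tss_jitter_sd = 2,
                          background_rate = 0.0005, dispersion = 0.1, seed = 1L) {
  assert_that(inherits(tx, "toy_transcriptome"), "`tx` must be a toy_transcriptome")
  assert_that(tags_per_transcript > 0, "`tags_per_transcript` must be > 0")
  assert_that(tss_jitter_sd >= 0, "`tss_jitter_sd` must be >= 0")
  assert_that(background_rate >= 0, "`background_rate` must be >= 0")
  assert_that(dispersion >= 0, "`dispersion` must be >= 0")
  set.seed(seed)

  tr <- tx$transcripts
  truth <- tx$truth
  mu <- tags_per_transcript * truth$abundance / mean(truth$abundance)
  totals <- if (dispersion == 0) stats::rpois(nrow(tr), mu)
            else stats::rnbinom(nrow(tr), mu = mu, size = 1 / dispersion)

  recs <- vector("list", nrow(tr) + 2L)
  for (i in seq_len(nrow(tr))) {
    if (totals[i] == 0) next
    jit <- if (tss_jitter_sd == 0) rep(0L, totals[i])
           else as.integer(round(stats::rnorm(totals[i], 0, tss_jitter_sd)))
    pos <- truth$true_tss[i] + jit
    if (tr$strand[i] == "+") {
      pos <- pmin(pos, tr$cds_start[i] - 1L)  # never downstream of the AUG
      pos <- pmax(pos, 0L)
    } else {
      pos <- pmax(pos, tr$cds_start[i] + 1L)
    }
    recs[[i]] <- data.frame(chrom = tr$chrom[i], pos = pos, strand = tr$strand[i],
                            stringsAsFactors = FALSE)
  }

  chrom_len <- Biostrings::width(tx$sequences)
  names(chrom_len) <- names(tx$sequences)
  bg <- list()
  for (ch in names(chrom_len)) {
    for (st in c("+", "-")) {
      n_bg <- stats::rpois(1, background_rate * chrom_len[[ch]])
      if (n_bg > 0)
        bg[[paste(ch, st)]] <- data.frame(
          chrom = ch,
          pos = sample.int(chrom_len[[ch]], n_bg, replace = TRUE) - 1L,
          strand = st, stringsAsFactors = FALSE)
    }
  }

  all <- do.call(rbind, c(recs[!vapply(recs, is.null, logical(1))], unname(bg)))
  if (is.null(all) || nrow(all) == 0)
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      count = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(count = rep(1L, nrow(all))),
                          by = list(chrom = all$chrom, pos = all$pos, strand = all$strand),
                          FUN = sum)
  agg <- agg[order(agg$chrom, agg$strand, agg$pos), ]
  rownames(agg) <- NULL
  agg$pos <- as.integer(agg$pos)
  agg$count <- as.integer(agg$count)
  agg
}

#' Simulate a genes x replicates read-count matrix
#'
#' Negative-binomial counts with per-gene means drawn from a log-normal;
#' `dispersion = 0` degenerates to Poisson. Used by the read-count
#' sensitivity diagnostic.
#'
#' @param n_genes,n_replicates Matrix dimensions.
#' @param mean_meanlog,mean_sdlog Log-normal law of per-gene mean counts.
#' @param dispersion Negative-binomial dispersion (>= 0).
#' @param seed Integer seed.
#' @return Integer matrix `n_genes` x `n_replicates` with gene rownames.
#' @export
simulate_count_matrix <- function(n_genes = 5000L, n_replicates = 2L,
                                  mean_meanlog = log(50), mean_sdlog = 1.5,
                                  dispersion = 0.1, seed = 1L) {
  assert_that(n_genes >= 1 && n_replicates >= 1, "matrix dimensions must be >= 1")
  assert_that(dispersion >= 0, "`dispersion` must be >= 0")
  set.seed(seed)
  mu <- stats::rlnorm(n_genes, mean_meanlog, mean_sdlog)
  draw <- function(m) {
    if (dispersion == 0) stats::rpois(n_genes, m)
    else stats::rnbinom(n_genes, mu = m, size = 1 / dispersion)
  }
  counts <- vapply(seq_len(n_replicates), function(r) draw(mu), numeric(n_genes))
  counts <- matrix(as.integer(counts), nrow = n_genes,
                   dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                                   sprintf("rep%d", seq_len(n_replicates))))
  counts
}
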