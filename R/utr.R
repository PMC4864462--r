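# TSS peak calling from 5'-end tag counts, 5' UTR lengths, TOP / TISU
# classification, reference comparison and enrichment testing.
# Coordinates are 0-based, half-open, strand-aware throughout.

#' Cluster CTSS tag positions into TSS peaks
#'
#' Per chromosome and strand, tag positions within `max_gap` nt of the
#' previously retained position merge into one cluster. Clusters with total
#' tag count strictly greater than `min_peak_reads` are retained as peaks;
#' smaller clusters are kept in the output with `retained = FALSE` so no tag
#' is lost from the accounting. The summit is the member position with the
#' most tags (leftmost on ties).
#'
#' @param records Data frame of CTSS records: `chrom`, `pos` (0-based
#'   integer), `strand` (`+`/`-`), `count` (> 0).
#' @param max_gap Maximum merge distance in nt (>= 0, default 20).
#' @param min_peak_reads Retention threshold; strictly more reads required
#'   (default 5, i.e., "more than five reads").
#' @return Data frame of clusters: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `summit`, `total_count`, `retained`.
#' @export
cluster_ctss <- function(records, max_gap = 20L, min_peak_reads = 5L) {
  assert_that(is.data.frame(records) &&
                all(c("chrom", "pos", "strand", "count") %in% names(records)),
              "`records` needs columns chrom, pos, strand, count")
  assert_that(max_gap >= 0, "`max_gap` must be >= 0")
  if (nrow(records) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), summit = integer(),
                      total_count = integer(), retained = logical(),
                      stringsAsFactors = FALSE))
  if (any(records$count <= 0)) stop("tag counts must be positive", call. = FALSE)

  out <- list()
  for (key in unique(paste(records$chrom, records$strand))) {
    sub <- records[paste(records$chrom, records$strand) == key, ]
    sub <- sub[order(sub$pos), ]
    # duplicate positions collapse first
    if (anyDuplicated(sub$pos)) {
      agg <- stats::aggregate(count ~ pos, sub, sum)
      sub <- data.frame(chrom = sub$chrom[1], pos = agg$pos,
                        strand = sub$strand[1], count = agg$count)
    }
    cl <- cumsum(c(1L, as.integer(diff(sub$pos) > max_gap)))
    for (g in unique(cl)) {
      grp <- sub[cl == g, ]
      summit <- grp$pos[which.max(grp$count)]
      out[[length(out) + 1]] <- data.frame(
        chrom = grp$chrom[1], start = min(grp$pos), end = max(grp$pos) + 1L,
        strand = grp$strand[1], summit = summit,
        total_count = sum(grp$count),
        stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, out)
  peaks$retained <- peaks$total_count > min_peak_reads
  peaks <- peaks[order(peaks$chrom, peaks$strand, peaks$start), ]
  rownames(peaks) <- NULL
  peaks
}

# strand-aware 5' UTR length of a tag position relative to the start codon
utr_distance <- function(pos, cds_start, strand) {
  n <- max(length(pos), length(cds_start), length(strand))
  ifelse(rep_len(strand, n) == "+",
         rep_len(cds_start, n) - rep_len(pos, n),
         rep_len(pos, n) - rep_len(cds_start, n))
}

#' 5' UTR lengths of a transcript from its assigned tag positions
#'
#' Each tag position implies a UTR length (strand-aware distance to the start
#' codon). The peak length is the length implied by the position with the
#' most tags (ties resolved toward the start codon, i.e., the shortest
#' length); the weighted mean length lets every tag contribute.
#'
#' @param positions Integer tag positions (0-based) assigned to the transcript.
#' @param counts Tag counts per position (> 0).
#' @param cds_start 0-based genomic position of the initiation codon's first
#'   base.
#' @param strand `"+"` or `"-"`.
#' @return List with `peak_length` (integer) and `weighted_mean_length`
#'   (real). Positions at or downstream of the start codon (length <= 0) are
#'   an annotation error: if no position is upstream the function signals an
#'   error.
#' @examples
#' compute_utr_lengths(c(50, 90), c(30, 10), cds_start = 100, strand = "+")
#' @export
compute_utr_lengths <- function(positions, counts, cds_start, strand) {
  assert_that(length(positions) == length(counts) && length(positions) > 0,
              "`positions` and `counts` must be equal-length and non-empty")
  assert_that(all(counts > 0), "`counts` must be positive")
  len <- utr_distance(positions, cds_start, strand)
  keep <- len > 0
  if (!any(keep))
    stop("all tag positions lie at or downstream of the start codon", call. = FALSE)
  len <- len[keep]; cnt <- counts[keep]
  best <- which(cnt == max(cnt))
  peak_length <- min(len[best])  # tie toward the start codon
  list(peak_length = as.integer(peak_length),
       weighted_mean_length = sum(cnt * len) / sum(cnt))
}

#' Classify a cap-proximal sequence as a 5' TOP motif
#'
#' A TOP motif is a cytosine immediately after the cap followed by an
#' uninterrupted run of at least `min_run` pyrimidines (C/T). Runs longer
#' than the 4--15 range observed in canonical TOP mRNAs still classify as
#' TOP: the range describes observations, not an exclusion rule.
#'
#' @param cap_proximal_seq Nucleotide string starting at the transcription
#'   start site, length >= `min_run + 1`; U is normalised to T.
#' @param min_run Minimum pyrimidine run length after the initial C.
#' @return `TRUE` or `FALSE`.
#' @examples
#' classify_top("CTTTCAGG")  # TRUE
#' classify_top("CAAAGG")    # FALSE
#' @export
classify_top <- function(cap_proximal_seq, min_run = 4L) {
  assert_that(is.character(cap_proximal_seq) && length(cap_proximal_seq) == 1,
              "`cap_proximal_seq` must be a single string")
  s <- chartr("uU", "tT", cap_proximal_seq)
  s <- toupper(s)
  assert_that(nchar(s) >= min_run + 1,
              sprintf("sequence must be at least %d nt", min_run + 1))
  if (grepl("[^ACGT]", s)) stop("sequence contains non-nucleotide characters",
                                call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  if (chars[1] != "C") return(FALSE)
  run <- 0L
  for (ch in chars[-1]) {
    if (ch %in% c("C", "T")) run <- run + 1L else break
  }
  run >= min_run
}

#' Detect a TISU element across a start codon
#'
#' Matches the 12-nt translation-initiator-of-short-5'-UTR consensus
#' `SAASATGGCGGC` (S = G or C) against the sequence spanning
#' `[AUG - 4, AUG + 8)`. The AUG itself is invariant; up to `max_mismatch`
#' mismatches are tolerated at the nine non-AUG positions.
#'
#' @param context_seq Nucleotide string of length exactly 12 with `ATG` at
#'   offset 4 (0-based); U is normalised to T.
#' @param max_mismatch Allowed mismatches outside the AUG (default 0).
#' @return `TRUE` or `FALSE`.
#' @examples
#' detect_tisu("CAAGATGGCGGC")  # TRUE
#' detect_tisu("TAAGATGGCGGC")  # FALSE (T does not match S)
#' @export
detect_tisu <- function(context_seq, max_mismatch = 0L) {
  assert_that(is.character(context_seq) && length(context_seq) == 1,
              "`context_seq` must be a single string")
  s <- toupper(chartr("uU", "tT", context_seq))
  assert_that(nchar(s) == 12, "`context_seq` must be exactly 12 nt")
  chars <- strsplit(s, "")[[1]]
  if (paste(chars[5:7], collapse = "") != "ATG")
    stop("no ATG at offset 4 of the context sequence", call. = FALSE)
  cons <- strsplit(TISU_CONSENSUS, "")[[1]]
  mm <- 0L
  for (i in setdiff(seq_len(12), 5:7)) {
    ok <- if (cons[i] == "S") chars[i] %in% c("G", "C") else chars[i] == cons[i]
    if (!ok) mm <- mm + 1L
  }
  mm <= max_mismatch
}

# Assign retained peaks to transcripts: a peak belongs to a transcript when
# its summit lies strictly upstream of the start codon (transcript
# orientation) and within `window` nt of it; on conflicts the nearest
# transcript wins.
assign_peaks <- function(peaks, models, window = 1000L) {
  peaks <- peaks[peaks$retained, , drop = FALSE]
  if (nrow(peaks) == 0) return(cbind(peaks, transcript_id = character(0)))
  assign <- rep(NA_character_, nrow(peaks))
  dist_best <- rep(Inf, nrow(peaks))
  for (j in seq_len(nrow(models))) {
    m <- models[j, ]
    d <- utr_distance(peaks$summit, m$cds_start, m$strand)
    ok <- peaks$chrom == m$chrom & peaks$strand == m$strand & d > 0 & d <= window
    better <- ok & d < dist_best
    assign[better] <- m$transcript_id
    dist_best[better] <- d[better]
  }
  peaks$transcript_id <- assign
  peaks
}

#' Annotate transcripts with nanoCAGE-derived 5' UTR features
#'
#' Full downstream pipeline: clusters CTSS records into peaks, assigns
#' retained peaks to transcripts (summit upstream of the start codon within
#' `window` nt, nearest transcript on conflicts), computes peak and weighted
#' mean 5' UTR lengths from the member tag positions, classifies the
#' cap-proximal sequence at the peak TSS as TOP or not, tests the start-codon
#' context for a TISU element, and partitions transcripts into short
#' (< 30 nt) and long 5' UTR classes by peak length.
#'
#' @param records CTSS data frame (`chrom`, `pos`, `strand`, `count`).
#' @param models Transcript model data frame: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `reference_tss`, `cds_start`.
#' @param sequences Optional [Biostrings::DNAStringSet] of chromosome
#'   sequences (names matching `chrom`); required for TOP/TISU calls.
#' @param max_gap,min_peak_reads Passed to [cluster_ctss()].
#' @param min_gene_reads A transcript is `supported` when the tags assigned
#'   to it total strictly more than this (default 50).
#' @param window Maximum summit-to-start-codon distance for assignment.
#' @param short_boundary Peak lengths strictly below this are `short`.
#' @return Data frame of class `utr_annotation`: `transcript_id`, `gene_id`,
#'   `n_tags`, `supported`, `tss`, `peak_length`, `weighted_mean_length`,
#'   `is_top`, `has_tisu`, `length_class`.
#' @export
annotate_utrs <- function(records, models, sequences = NULL,
                          max_gap = 20L, min_peak_reads = 5L,
                          min_gene_reads = 50L, window = 1000L,
                          short_boundary = 30L) {
  peaks <- cluster_ctss(records, max_gap, min_peak_reads)
  peaks <- assign_peaks(peaks, models, window)
  rows <- list()
  for (j in seq_len(nrow(models))) {
    m <- models[j, ]
    mine <- peaks[!is.na(peaks$transcript_id) & peaks$transcript_id == m$transcript_id, ,
                  drop = FALSE]
    if (nrow(mine) == 0) next
    # member tag positions of the assigned peaks
    member <- records[records$chrom == m$chrom & records$strand == m$strand, ]
    in_peak <- rep(FALSE, nrow(member))
    for (q in seq_len(nrow(mine)))
      in_peak <- in_peak | (member$pos >= mine$start[q] & member$pos < mine$end[q])
    member <- member[in_peak & utr_distance(member$pos, m$cds_start, m$strand) > 0, ]
    if (nrow(member) == 0) next
    lens <- compute_utr_lengths(member$pos, member$count, m$cds_start, m$strand)
    # TSS = the position behind the peak length (most-supported position)
    tss <- if (m$strand == "+") m$cds_start - lens$peak_length
           else m$cds_start + lens$peak_length
    is_top <- NA
    has_tisu <- NA
    if (!is.null(sequences)) {
      is_top <- classify_top(extract_seq(sequences, m$chrom, m$strand, tss, 20L))
      ctx <- extract_context(sequences, m$chrom, m$strand, m$cds_start)
      has_tisu <- if (is.null(ctx)) FALSE else detect_tisu(ctx)
    }
    rows[[length(rows) + 1]] <- data.frame(
      transcript_id = m$transcript_id, gene_id = m$gene_id,
      n_tags = sum(member$count),
      supported = sum(member$count) > min_gene_reads,
      tss = as.integer(tss),
      peak_length = lens$peak_length,
      weighted_mean_length = lens$weighted_mean_length,
      is_top = is_top, has_tisu = has_tisu,
      length_class = if (lens$peak_length < short_boundary) "short" else "long",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(transcript_id = character(), gene_id = character(),
                         n_tags = integer(), supported = logical(), tss = integer(),
                         peak_length = integer(), weighted_mean_length = numeric(),
                         is_top = logical(), has_tisu = logical(),
                         length_class = character(), stringsAsFactors = FALSE)
  class(out) <- c("utr_annotation", class(out))
  out
}

# sequence of `len` nt starting at `tss` reading in transcript orientation
extract_seq <- function(sequences, chrom, strand, tss, len) {
  chr <- sequences[[chrom]]
  if (strand == "+") {
    s <- Biostrings::subseq(chr, start = tss + 1L,
                            end = min(tss + len, length(chr)))
    as.character(s)
  } else {
    s <- Biostrings::subseq(chr, start = max(1L, tss + 1L - len + 1L),
                            end = tss + 1L)
    as.character(Biostrings::reverseComplement(s))
  }
}

# 12-nt start-codon context [AUG-4, AUG+8) in transcript orientation
extract_context <- function(sequences, chrom, strand, cds_start) {
  chr <- sequences[[chrom]]
  if (strand == "+") {
    if (cds_start - 4L < 0 || cds_start + 8L > length(chr)) return(NULL)
    as.character(Biostrings::subseq(chr, cds_start - 3L, cds_start + 8L))
  } else {
    if (cds_start - 7L < 1L || cds_start + 5L > length(chr)) return(NULL)
    s <- Biostrings::subseq(chr, cds_start - 7L + 1L, cds_start + 4L + 1L)
    as.character(Biostrings::reverseComplement(s))
  }
}

#' Compare observed 5' UTR lengths to a reference annotation
#'
#' Computes, per transcript, the ratio of the nanoCAGE-derived length to the
#' reference length (`reference_tss` to `cds_start`), for both the peak and
#' the weighted mean lengths, and summarises the fraction of transcripts
#' whose observed UTR is half the reference length or shorter (ratio <= 0.5).
#' Transcripts with a non-positive reference length are skipped and flagged.
#'
#' @param annotations A [annotate_utrs()] result.
#' @param models Transcript model data frame (see [annotate_utrs()]).
#' @return List of class `reference_comparison`: `ratios` (per-transcript
#'   data frame with `ratio_peak`, `ratio_weighted`, `skipped`) and
#'   `fraction_half_or_shorter` (named vector for peak and weighted lengths).
#' @export
compare_to_reference <- function(annotations, models) {
  m <- models[match(annotations$transcript_id, models$transcript_id), ]
  ref_len <- utr_distance(m$reference_tss, m$cds_start, m$strand)
  skipped <- !is.finite(ref_len) | ref_len <= 0
  ratios <- data.frame(
    transcript_id = annotations$transcript_id,
    reference_length = ref_len,
    ratio_peak = ifelse(skipped, NA_real_, annotations$peak_length / ref_len),
    ratio_weighted = ifelse(skipped, NA_real_,
                            annotations$weighted_mean_length / ref_len),
    skipped = skipped, stringsAsFactors = FALSE)
  frac <- c(peak = mean(ratios$ratio_peak[!skipped] <= 0.5),
            weighted = mean(ratios$ratio_weighted[!skipped] <= 0.5))
  structure(list(ratios = ratios, fraction_half_or_shorter = frac),
            class = "reference_comparison")
}

#' Exact test for motif enrichment in a gene set
#'
#' Fold enrichment is the hit rate in the set over the hit rate in the
#' background; the p-value is a one-sided hypergeometric tail (probability of
#' at least the observed number of set hits when drawing `set_size` genes
#' from the pooled set + background urn). The background excludes the query
#' set by default.
#'
#' @param hits_in_set,set_size Hits and size of the query set.
#' @param hits_in_background,background_size Hits and size of the background.
#' @param background_includes_set If `TRUE`, the background counts include
#'   the set and are first reduced to the disjoint remainder.
#' @return List with `fold_enrichment` and `pvalue`. A zero background hit
#'   rate with set hits gives `fold_enrichment = Inf` with the exact p still
#'   computed.
#' @examples
#' enrichment_test(5, 10, 50, 1000)  # fold = 10
#' @export
enrichment_test <- function(hits_in_set, set_size, hits_in_background,
                            background_size, background_includes_set = FALSE) {
  assert_that(hits_in_set >= 0 && hits_in_set <= set_size,
              "`hits_in_set` must lie in [0, set_size]")
  assert_that(hits_in_background >= 0 && hits_in_background <= background_size,
              "`hits_in_background` must lie in [0, background_size]")
  if (background_includes_set) {
    hits_in_background <- hits_in_background - hits_in_set
    background_size <- background_size - set_size
    assert_that(hits_in_background >= 0 && background_size > 0,
                "background must contain the set when `background_includes_set`")
  }
  rate_set <- hits_in_set / set_size
  rate_bg <- hits_in_background / background_size
  fold <- if (rate_bg == 0) {
    if (hits_in_set == 0) 0 else Inf
  } else rate_set / rate_bg
  total_hits <- hits_in_set + hits_in_background
  total <- set_size + background_size
  pvalue <- stats::phyper(hits_in_set - 1, total_hits, total - total_hits,
                          set_size, lower.tail = FALSE)
  list(fold_enrichment = fold, pvalue = pvalue)
}

#' Read CTSS records from a BED-like TSV
#'
#' Four tab-separated columns with a header: `chrom`, `pos` (0-based),
#' `strand`, `count`.
#'
#' @param path File path.
#' @return CTSS data frame.
#' @export
read_ctss <- function(path) {
  x <- utils::read.delim(path, header = TRUE)
  assert_that(all(c("chrom", "pos", "strand", "count") %in% names(x)),
              "CTSS file must have columns chrom, pos, strand, count")
  x$pos <- as.integer(x$pos); x$count <- as.integer(x$count)
  x
}

#' Write CTSS records to a BED-like TSV
#' @param records CTSS data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctss <- function(records, path) {
  utils::write.table(records[, c("chrom", "pos", "strand", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models from a six-column TSV
#'
#' Columns: `transcript_id`, `gene_id`, `chrom`, `strand`, `reference_tss`,
#' `cds_start` (0-based).
#'
#' @param path File path.
#' @return Transcript model data frame.
#' @export
read_transcript_models <- function(path) {
  x <- utils::read.delim(path, header = TRUE)
  need <- c("transcript_id", "gene_id", "chrom", "strand", "reference_tss", "cds_start")
  assert_that(all(need %in% names(x)),
              paste("transcript model file must have columns",
                    paste(need, collapse = ", ")))
  x[, need]
}

#' Write TSS peaks as BED6
#'
#' Standard six columns (chrom, start, end, name, score, strand), score being
#' the peak's total tag count. Only retained peaks are written.
#'
#' @param peaks A [cluster_ctss()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  p <- peaks[peaks$retained, , drop = FALSE]
  bed <- data.frame(p$chrom, p$start, p$end,
                    sprintf("peak_%d", seq_len(nrow(p))),
                    p$total_count, p$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
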