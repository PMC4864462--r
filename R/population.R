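# TOP / non-TOP / nonmover population simulations: absolute vs relative
# quantification, the TOP-fraction sweep, the global-reduction sweep, and the
# read-count sensitivity diagnostic.

#' Configuration of the TOP / non-TOP / nonmover population
#'
#' Class proportions and per-class abundance and shift models. TOP mRNAs are
#' highly expressed and collapse to one ribosome under MTOR inhibition;
#' non-TOP MTOR-sensitive mRNAs shift moderately (intermediate-heavy to light
#' polysomes); nonmovers do not change. Abundances are log-normal with the
#' TOP class mean a multiple of the non-TOP mean.
#'
#' @param n_genes Total genes in the population.
#' @param fraction_top,fraction_nontop,fraction_nonmover Class fractions,
#'   summing to 1.
#' @param abundance_meanlog Baseline log-normal meanlog (non-TOP, nonmover).
#' @param abundance_sdlog Log-normal sdlog for all classes.
#' @param top_abundance_factor Multiplier on the TOP class's mean abundance.
#' @param top_shift Control and treated means for TOP mRNAs.
#' @param nontop_shift Control and treated means for non-TOP mRNAs.
#' @param nonmover_mean Shared control = treated mean for nonmovers.
#' @param sd_ribosomes Standard deviation of every ribosome-association law.
#' @param n_replicates Replicates per condition.
#' @param n_mrna_per_gene Molecules sampled per gene per replicate.
#' @param n_simulations Replicated simulations averaged in the sweeps.
#' @param depth_factor Sequencing-depth scale for absolute-mode counts.
#' @return Object of class `population_config`.
#' @export
population_config <- function(n_genes = 2000L,
                              fraction_top = 0.035,
                              fraction_nontop = 0.165,
                              fraction_nonmover = 0.8,
                              abundance_meanlog = log(2),
                              abundance_sdlog = 1,
                              top_abundance_factor = 8,
                              top_shift = c(control = 6, treated = 1),
                              nontop_shift = c(control = 5, treated = 3.5),
                              nonmover_mean = 5,
                              sd_ribosomes = 1.5,
                              n_replicates = 4L,
                              n_mrna_per_gene = 200L,
                              n_simulations = 4L,
                              depth_factor = 1) {
  fr <- c(fraction_top, fraction_nontop, fraction_nonmover)
  assert_that(all(fr >= 0 & fr <= 1), "class fractions must be in [0, 1]")
  assert_that(abs(sum(fr) - 1) < 1e-8, "class fractions must sum to 1")
  assert_that(top_abundance_factor > 1,
              "`top_abundance_factor` must exceed 1 (TOP mRNAs are the abundant class)")
  assert_that(sd_ribosomes > 0, "`sd_ribosomes` must be > 0")
  structure(list(n_genes = as.integer(n_genes),
                 fraction_top = fraction_top, fraction_nontop = fraction_nontop,
                 fraction_nonmover = fraction_nonmover,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 top_abundance_factor = top_abundance_factor,
                 top_shift = top_shift, nontop_shift = nontop_shift,
                 nonmover_mean = nonmover_mean, sd_ribosomes = sd_ribosomes,
                 n_replicates = as.integer(n_replicates),
                 n_mrna_per_gene = as.integer(n_mrna_per_gene),
                 n_simulations = as.integer(n_simulations),
                 depth_factor = depth_factor),
            class = "population_config")
}

#' Build the population gene-specification table
#'
#' Class counts use largest-remainder apportionment so they sum exactly to
#' `n_genes`. TOP abundances are drawn with meanlog shifted by
#' `log(top_abundance_factor)`, so the TOP class mean exceeds the non-TOP
#' mean by construction.
#'
#' @param config A [population_config()].
#' @param seed Integer seed.
#' @return A [gene_spec_table()] with classes `TOP`, `NONTOP`, `NONMOVER`.
#' @export
build_population <- function(config, seed = 1L) {
  assert_that(inherits(config, "population_config"), "`config` must be a population_config")
  counts <- largest_remainder(config$n_genes,
                              c(config$fraction_top, config$fraction_nontop,
                                config$fraction_nonmover))
  set.seed(derive_seed(seed, 1L))
  cls <- rep(c("TOP", "NONTOP", "NONMOVER"), counts)
  meanlog <- ifelse(cls == "TOP",
                    config$abundance_meanlog + log(config$top_abundance_factor),
                    config$abundance_meanlog)
  abundance <- stats::rlnorm(length(cls), meanlog, config$abundance_sdlog)
  ctrl <- c(TOP = unname(config$top_shift["control"]),
            NONTOP = unname(config$nontop_shift["control"]),
            NONMOVER = config$nonmover_mean)
  trt <- c(TOP = unname(config$top_shift["treated"]),
           NONTOP = unname(config$nontop_shift["treated"]),
           NONMOVER = config$nonmover_mean)
  gene_spec_table(gene_id = sprintf("p%05d", seq_along(cls)),
                  gene_class = cls,
                  abundance = abundance,
                  control_mean = ctrl[cls],
                  treated_mean = trt[cls],
                  sd_ribosomes = config$sd_ribosomes)
}

#' Globally centre fold changes at a geometric median of 1
#'
#' Divides positive fold changes by `2^median(log2(fc))`, so the median log2
#' fold change of the output is exactly zero. This is the standard global
#' centring used for per-gene ratio data (e.g., polysome-profiling
#' proportions), expressing each gene's change relative to the
#' transcriptome-wide trend.
#'
#' @param fold_changes Numeric vector, all > 0.
#' @return Centred fold changes, same length.
#' @examples
#' global_center(c(2, 2, 2, 1))  # median log2 = 1 -> c(1, 1, 1, 0.5)
#' @export
global_center <- function(fold_changes) {
  if (any(fold_changes <= 0) || any(!is.finite(fold_changes)))
    stop("fold changes must be positive and finite", call. = FALSE)
  fold_changes / 2^stats::median(log2(fold_changes))
}

# Vectorised molecule sampling for a whole population: one matrix of clamped
# normal draws per replicate and condition.  Streams are per-(simulation,
# sweep point, replicate, condition) -- coarser than the gene-level streams of
# the shift experiment, in exchange for tractable sweep runtimes.
sample_population_estimates <- function(specs, config, seed, sim, point) {
  n <- nrow(specs); nr <- config$n_replicates; nm <- config$n_mrna_per_gene
  poly <- ribo_raw <- list(control = matrix(0, n, nr), treated = matrix(0, n, nr))
  for (r in seq_len(nr)) {
    for (cond in c("control", "treated")) {
      set.seed(derive_seed(seed, sim, point, r, if (cond == "control") 0L else 1L))
      mu <- if (cond == "control") specs$control_mean else specs$treated_mean
      draws <- matrix(pmax(stats::rnorm(nm * n, rep(mu, each = nm),
                                        rep(specs$sd_ribosomes, each = nm)), 0),
                      nrow = nm)
      mean_load <- colMeans(draws)
      poly[[cond]][, r] <- colMeans(draws > 3)
      # expected footprint signal per gene; counting noise applied per mode below
      ribo_raw[[cond]][, r] <- stats::rpois(n, mean_load * specs$abundance *
                                              config$depth_factor)
    }
  }
  list(poly = poly, ribo = ribo_raw)
}

# Per-gene fold changes for one simulated population under the four
# quantification schemes.  Relative quantification differs by technology:
# ribosome-profiling counts are library-size normalised (each replicate
# scaled to the mean total -- the count-weighted global centring inherent in
# sequencing), while polysome proportions are per-gene ratios centred at
# their geometric median via global_center().
population_fold_changes <- function(specs, config, seed, sim = 1L, point = 1L) {
  est <- sample_population_estimates(specs, config, seed, sim, point)
  nm <- config$n_mrna_per_gene
  eps_p <- 0.5 / nm; eps_r <- 0.5
  gm_ratio <- function(c_mat, t_mat, eps)
    2^(rowMeans(log2(c_mat + eps)) - rowMeans(log2(t_mat + eps)))

  fc_poly_abs <- gm_ratio(est$poly$control, est$poly$treated, eps_p)
  fc_ribo_abs <- gm_ratio(est$ribo$control, est$ribo$treated, eps_r)

  # sequencing yields a fixed read budget per library: scale every replicate
  # (both conditions jointly) to the grand mean total, so a collapse of the
  # abundant classes inflates everyone else's relative counts
  grand <- mean(c(colSums(est$ribo$control), colSums(est$ribo$treated)))
  libnorm <- function(m) sweep(m, 2, colSums(m) / grand, "/")
  fc_ribo_rel <- gm_ratio(libnorm(est$ribo$control), libnorm(est$ribo$treated), eps_r)
  fc_poly_rel <- global_center(fc_poly_abs)

  data.frame(gene_id = specs$gene_id, gene_class = specs$gene_class,
             fc_poly_absolute = fc_poly_abs, fc_poly_relative = fc_poly_rel,
             fc_ribo_absolute = fc_ribo_abs, fc_ribo_relative = fc_ribo_rel,
             stringsAsFactors = FALSE)
}

summarise_sweep_point <- function(fc, sweep_value, sim) {
  long <- do.call(rbind, lapply(c("poly", "ribo"), function(m) {
    do.call(rbind, lapply(c("absolute", "relative"), function(q) {
      col <- paste0("fc_", m, "_", q)
      agg <- tapply(log2(fc[[col]]), fc$gene_class, mean)
      data.frame(sweep_value = sweep_value, simulation = sim,
                 class = names(agg), method = m, quantification = q,
                 fold_change = 2^as.numeric(agg), stringsAsFactors = FALSE)
    }))
  }))
  long
}

#' Sweep the proportion of TOP mRNAs undergoing their translational shift
#'
#' At each sweep fraction `f`, the population is rebuilt so that `f` of all
#' genes are TOP mRNAs undergoing their full shift, non-TOP genes always
#' undergo their moderate shift, and nonmovers absorb the remainder. Reports
#' per-class geometric-mean fold changes for both technologies under absolute
#' and relative quantification, averaged over replicated simulations.
#'
#' @param config A [population_config()].
#' @param fractions Sweep grid of TOP fractions, each in \[0, 1\] (with
#'   `fraction_nontop` they must leave a non-negative nonmover remainder).
#' @param seed Master integer seed.
#' @return Object of class `sweep_result`: `sweep` (tidy data frame:
#'   sweep_value, class, method, quantification, fold_change averaged over
#'   simulations) and `per_simulation` (the unaveraged rows).
#' @export
sweep_top_changing_fraction <- function(config = population_config(),
                                        fractions = c(0, 0.005, 0.01, 0.02,
                                                      0.035, 0.05, 0.1),
                                        seed = 1L) {
  assert_that(all(fractions >= 0 & fractions <= 1), "`fractions` must be in [0, 1]")
  assert_that(all(fractions + config$fraction_nontop <= 1),
              "TOP fraction plus non-TOP fraction exceeds 1")
  rows <- list()
  for (pi in seq_along(fractions)) {
    f <- fractions[pi]
    cfg_f <- config
    cfg_f$fraction_top <- f
    cfg_f$fraction_nonmover <- 1 - f - config$fraction_nontop
    for (sim in seq_len(config$n_simulations)) {
      specs <- build_population(cfg_f, seed = derive_seed(seed, sim, pi))
      fc <- population_fold_changes(specs, cfg_f, seed, sim, pi)
      rows[[length(rows) + 1]] <- summarise_sweep_point(fc, f, sim)
    }
  }
  per_sim <- do.call(rbind, rows)
  sweep <- stats::aggregate(fold_change ~ sweep_value + class + method + quantification,
                            per_sim, function(x) 2^mean(log2(x)))
  structure(list(sweep = sweep, per_simulation = per_sim,
                 sweep_variable = "fraction_top_changing"),
            class = "sweep_result")
}

#' Sweep a global reduction of nonmover translation
#'
#' Emulates the global down-regulation of protein synthesis under MTOR
#' inhibition: nonmover treated means are multiplied by each reduction factor
#' while TOP and non-TOP mRNAs keep their class shifts. Reports per-class
#' fold changes as in [sweep_top_changing_fraction()].
#'
#' @param config A [population_config()].
#' @param reduction_factors Factors in (0, 1\]; 1 reproduces the
#'   no-reduction baseline.
#' @param seed Master integer seed.
#' @return A `sweep_result` (see [sweep_top_changing_fraction()]).
#' @export
sweep_global_reduction <- function(config = population_config(),
                                   reduction_factors = seq(1, 0.5, by = -0.1),
                                   seed = 1L) {
  assert_that(all(reduction_factors > 0 & reduction_factors <= 1),
              "`reduction_factors` must lie in (0, 1]")
  rows <- list()
  for (pi in seq_along(reduction_factors)) {
    rf <- reduction_factors[pi]
    for (sim in seq_len(config$n_simulations)) {
      specs <- build_population(config, seed = derive_seed(seed, sim, 500L + pi))
      nm <- specs$gene_class == "NONMOVER"
      specs$treated_mean[nm] <- specs$treated_mean[nm] * rf
      fc <- population_fold_changes(specs, config, seed, sim, 500L + pi)
      rows[[length(rows) + 1]] <- summarise_sweep_point(fc, rf, sim)
    }
  }
  per_sim <- do.call(rbind, rows)
  sweep <- stats::aggregate(fold_change ~ sweep_value + class + method + quantification,
                            per_sim, function(x) 2^mean(log2(x)))
  structure(list(sweep = sweep, per_simulation = per_sim,
                 sweep_variable = "global_reduction_factor"),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> over %s (%d points)\n", x$sweep_variable,
              length(unique(x$sweep$sweep_value))))
  print(utils::head(x$sweep, 12), row.names = FALSE)
  if (nrow(x$sweep) > 12) cat("...\n")
  invisible(x)
}

#' Read-count sensitivity diagnostic
#'
#' For each threshold `t`, counts the genes whose read count exceeds `t` in
#' every replicate ("consistently"), and tabulates each gene's mean count and
#' coefficient of variation for the mean--variance diagnostic (count noise
#' inflates the CV of low-count genes, limiting sensitivity).
#'
#' @param counts Non-negative integer matrix, genes x replicates (>= 2
#'   replicates).
#' @param thresholds Integer thresholds (default `c(64, 256)`).
#' @return List of class `count_threshold_analysis`: `threshold_counts`
#'   (threshold, n_genes) and `mean_var` (gene, mean, cv).
#' @export
count_threshold_analysis <- function(counts, thresholds = c(64L, 256L)) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("at least 2 replicates are required", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  consistent <- vapply(thresholds,
                       function(t) sum(apply(counts > t, 1, all)),
                       numeric(1))
  m <- rowMeans(counts)
  s <- apply(counts, 1, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  structure(list(
    threshold_counts = data.frame(threshold = thresholds, n_genes = as.integer(consistent)),
    mean_var = data.frame(gene = rownames(counts) %||% sprintf("g%d", seq_len(nrow(counts))),
                          mean = m, cv = cv, stringsAsFactors = FALSE)),
    class = "count_threshold_analysis")
}

#' @export
print.count_threshold_analysis <- function(x, ...) {
  cat("<count_threshold_analysis>\n")
  print(x$threshold_counts, row.names = FALSE)
  invisible(x)
}
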