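# Per-gene shift simulation and the polysome- vs ribosome-profiling
# bias analysis.

#' Configuration for the shift-grid simulation
#'
#' Defines the study conditions for comparing how the two profiling
#' technologies rank and select differentially translated genes across a
#' range of shift sizes. Control-condition mRNAs are efficiently translated
#' (means well above the three-ribosome polysome threshold); under MTOR
#' inhibition every gene collapses to a mean of one ribosome, so the shift
#' classes differ only in where they start.
#'
#' @param shift_grid Strictly increasing control-condition mean ribosome
#'   loads, one shift class per value. All classes get equal gene counts.
#' @param treated_mean Mean ribosome load under MTOR inhibition (default 1;
#'   sub-80S shifts cannot be represented by a normal law, so the inhibited
#'   state is pinned at the monosome).
#' @param sd_ribosomes Standard deviation of every ribosome-association law.
#' @param n_per_class Genes per shift class.
#' @param n_replicates Replicates per condition (>= 2).
#' @param n_mrna_per_gene mRNA molecules sampled per gene per replicate.
#' @param top_k_fraction Fraction of genes selected by each ranking, in (0, 1).
#' @param n_simulations Number of replicated simulations summarised.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance model
#'   (RPKM-like units) shared by all classes.
#' @param depth_factor Sequencing-depth scaling of expected footprint counts.
#' @param noise Counting-noise model for ribosome-profiling counts:
#'   `"poisson"` (default), `"nb"` (negative binomial) or `"none"`.
#' @param dispersion Negative-binomial dispersion when `noise = "nb"`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(shift_grid = c(6, 8, 10, 12, 14, 16),
                              treated_mean = 1,
                              sd_ribosomes = 1.5,
                              n_per_class = 500L,
                              n_replicates = 4L,
                              n_mrna_per_gene = 200L,
                              top_k_fraction = 0.1,
                              n_simulations = 4L,
                              abundance_meanlog = log(2),
                              abundance_sdlog = 1,
                              depth_factor = 1,
                              noise = c("poisson", "nb", "none"),
                              dispersion = 0.1) {
  noise <- match.arg(noise)
  assert_that(length(shift_grid) >= 1 && all(diff(shift_grid) > 0),
              "`shift_grid` must be non-empty and strictly increasing")
  assert_that(n_replicates >= 2, "`n_replicates` must be >= 2")
  assert_that(top_k_fraction > 0 && top_k_fraction < 1,
              "`top_k_fraction` must be in (0, 1)")
  assert_that(sd_ribosomes > 0, "`sd_ribosomes` must be > 0")
  assert_that(n_mrna_per_gene >= 1, "`n_mrna_per_gene` must be >= 1")
  structure(list(shift_grid = shift_grid, treated_mean = treated_mean,
                 sd_ribosomes = sd_ribosomes, n_per_class = as.integer(n_per_class),
                 n_replicates = as.integer(n_replicates),
                 n_mrna_per_gene = as.integer(n_mrna_per_gene),
                 top_k_fraction = top_k_fraction,
                 n_simulations = as.integer(n_simulations),
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 depth_factor = depth_factor, noise = noise,
                 dispersion = dispersion),
            class = "simulation_config")
}

#' Construct a table of simulated gene specifications
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param gene_class Class label per gene (shift class or TOP/NONTOP/NONMOVER).
#' @param abundance Positive expression level per gene (RPKM-like).
#' @param control_mean,treated_mean Means of the control / treated
#'   ribosome-association laws.
#' @param sd_ribosomes Standard deviation(s) of those laws.
#' @return Data frame of class `gene_spec_table`.
#' @export
gene_spec_table <- function(gene_id, gene_class, abundance,
                            control_mean, treated_mean, sd_ribosomes) {
  assert_that(!anyDuplicated(gene_id), "`gene_id` must be unique")
  assert_that(all(abundance > 0), "`abundance` must be > 0")
  assert_that(all(sd_ribosomes > 0), "`sd_ribosomes` must be > 0")
  out <- data.frame(gene_id = as.character(gene_id),
                    gene_class = as.character(gene_class),
                    abundance = abundance,
                    control_mean = control_mean,
                    treated_mean = treated_mean,
                    sd_ribosomes = sd_ribosomes,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_spec_table", class(out))
  out
}

#' Sample per-molecule ribosome loads for one gene, condition and replicate
#'
#' Draws `n_mrna` ribosome loads from the condition's normal law, clamped at
#' zero (negative draws represent free mRNPs and count as zero ribosomes,
#' preserving the sub-polysome mass that MTOR inhibition creates).
#' Reproducible: the draw is a pure function of the `seed`.
#'
#' @param spec One row of a [gene_spec_table()] (or any list with
#'   `control_mean`, `treated_mean`, `sd_ribosomes`).
#' @param condition `"control"` or `"treated"`.
#' @param n_mrna Number of molecules to sample (>= 1).
#' @param seed Integer seed for this gene/replicate stream.
#' @return Numeric vector of `n_mrna` non-negative ribosome loads.
#' @export
sample_gene_replicate <- function(spec, condition = c("control", "treated"),
                                  n_mrna, seed) {
  condition <- match.arg(condition)
  assert_that(n_mrna >= 1, "`n_mrna` must be >= 1")
  mu <- if (condition == "control") spec$control_mean else spec$treated_mean
  set.seed(seed)
  pmax(stats::rnorm(n_mrna, mu, spec$sd_ribosomes), 0)
}

#' Polysome-profiling estimator: fraction of mRNAs on more than `threshold` ribosomes
#'
#' Efficient translation is conventionally defined as association with more
#' than three ribosomes; the polysome-profiling readout for a gene is the
#' proportion of its molecules past that cutoff.
#'
#' @param loads Non-empty numeric vector of per-molecule ribosome loads.
#' @param threshold Ribosome cutoff (default 3); strictly greater counts as
#'   efficiently translated.
#' @return Proportion in \[0, 1\].
#' @examples
#' estimate_polyprof(c(1, 2, 3, 4))  # 0.25
#' @export
estimate_polyprof <- function(loads, threshold = 3) {
  if (length(loads) == 0) stop("`loads` must be non-empty", call. = FALSE)
  mean(loads > threshold)
}

#' Ribosome-profiling estimator: footprint count with counting noise
#'
#' The expected footprint signal is `mean(loads) * abundance * depth_factor`
#' (footprints scale with both ribosome load and mRNA copy number); the
#' returned count is one draw from the chosen counting distribution with that
#' expectation.
#'
#' @param loads Non-empty numeric vector of per-molecule ribosome loads.
#' @param abundance Positive mRNA abundance.
#' @param depth_factor Positive sequencing-depth scale.
#' @param noise `"poisson"` (default), `"nb"`, or `"none"` (deterministic
#'   rounded expectation).
#' @param dispersion Negative-binomial dispersion for `noise = "nb"`.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return A single non-negative integer count.
#' @export
estimate_riboprof <- function(loads, abundance, depth_factor = 1,
                              noise = c("poisson", "nb", "none"),
                              dispersion = 0.1, seed = NULL) {
  noise <- match.arg(noise)
  if (length(loads) == 0) stop("`loads` must be non-empty", call. = FALSE)
  if (abundance <= 0 || depth_factor <= 0)
    stop("`abundance` and `depth_factor` must be > 0", call. = FALSE)
  lambda <- mean(loads) * abundance * depth_factor
  if (!is.null(seed)) set.seed(seed)
  switch(noise,
         poisson = stats::rpois(1, lambda),
         nb = stats::rnbinom(1, mu = lambda, size = 1 / dispersion),
         none = round(lambda))
}

#' Two-group differential test on replicate estimates
#'
#' Fold change is the ratio of geometric means (control over treated); the
#' p-value comes from a Welch two-sample t-test on log2 estimates. Estimates
#' must be strictly positive -- any pseudocount is the caller's job. Degenerate
#' replicates (zero variance in both groups) give p = 1 when the group means
#' agree, and the smallest representable double when they differ (perfect
#' separation), keeping p in (0, 1].
#'
#' @param control_estimates,treated_estimates Numeric vectors, >= 2 replicates
#'   each, all values > 0.
#' @return Named list with `fold_change` and `pvalue`.
#' @examples
#' differential_test(c(8, 10, 12, 10), c(4, 5, 6, 5))  # fold_change = 2
#' @export
differential_test <- function(control_estimates, treated_estimates) {
  if (length(control_estimates) < 2 || length(treated_estimates) < 2)
    stop("at least 2 replicates per condition are required", call. = FALSE)
  if (any(control_estimates <= 0) || any(treated_estimates <= 0))
    stop("estimates must be strictly positive (apply a pseudocount first)",
         call. = FALSE)
  lc <- log2(control_estimates)
  lt <- log2(treated_estimates)
  fc <- 2^(mean(lc) - mean(lt))
  if (stats::var(lc) == 0 && stats::var(lt) == 0) {
    p <- if (mean(lc) == mean(lt)) 1 else .Machine$double.xmin
  } else {
    p <- stats::t.test(lc, lt, var.equal = FALSE)$p.value
    if (p == 0) p <- .Machine$double.xmin
  }
  list(fold_change = fc, pvalue = p)
}

#' Select top-ranked genes by p-value or fold change
#'
#' Orders genes by ascending p-value or descending absolute log2 fold change
#' and returns the first `ceiling(top_k_fraction * N)` gene ids. Ties are
#' broken by lexicographic gene id so reruns are deterministic.
#'
#' @param results Data frame with columns `gene_id`, and `pvalue_<method>`,
#'   `fold_change_<method>` for the chosen method.
#' @param method `"ribo"` or `"poly"`.
#' @param ranking `"pvalue"` or `"fold_change"`.
#' @param top_k_fraction Fraction selected, in (0, 1).
#' @return Character vector of selected gene ids.
#' @export
rank_and_select <- function(results, method = c("ribo", "poly"),
                            ranking = c("pvalue", "fold_change"),
                            top_k_fraction) {
  method <- match.arg(method)
  ranking <- match.arg(ranking)
  assert_that(nrow(results) > 0, "`results` must be non-empty")
  assert_that(top_k_fraction > 0 && top_k_fraction < 1,
              "`top_k_fraction` must be in (0, 1)")
  k <- ceiling(top_k_fraction * nrow(results))
  key <- if (ranking == "pvalue") {
    results[[paste0("pvalue_", method)]]
  } else {
    -abs(log2(results[[paste0("fold_change_", method)]]))
  }
  ord <- order(key, results$gene_id)
  results$gene_id[ord][seq_len(k)]
}

#' Per-class selection bias of a gene selection
#'
#' Compares the class composition of the selected genes to the composition of
#' the full gene set: `expected_pct` is each class's share of all genes,
#' `observed_pct` its share of the selection, and `bias_sum` the summed
#' absolute deviation.
#'
#' @param selected Character vector of selected gene ids (non-empty, subset of
#'   `specs$gene_id`).
#' @param specs A [gene_spec_table()] (or data frame with `gene_id`,
#'   `gene_class`).
#' @return List of class `bias_report`: `table` (class, expected_pct,
#'   observed_pct, deviation) and `bias_sum`.
#' @export
compute_bias <- function(selected, specs) {
  if (length(selected) == 0) stop("empty selection", call. = FALSE)
  assert_that(all(selected %in% specs$gene_id),
              "`selected` must be a subset of `specs$gene_id`")
  classes <- unique(specs$gene_class)
  expected <- 100 * table(factor(specs$gene_class, levels = classes)) / nrow(specs)
  sel_class <- specs$gene_class[match(selected, specs$gene_id)]
  observed <- 100 * table(factor(sel_class, levels = classes)) / length(selected)
  tab <- data.frame(class = classes,
                    expected_pct = as.numeric(expected),
                    observed_pct = as.numeric(observed),
                    stringsAsFactors = FALSE)
  tab$deviation <- tab$observed_pct - tab$expected_pct
  structure(list(table = tab, bias_sum = sum(abs(tab$deviation))),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> bias_sum = %.1f\n", x$bias_sum))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Simulate one full experiment (all genes, replicates, both technologies) and
# test each gene.  Per-(simulation, replicate, gene) seed streams mean that
# enlarging the gene set leaves existing genes' draws untouched.
simulate_gene_results <- function(specs, config, seed, sim_index = 1L) {
  n <- nrow(specs)
  nr <- config$n_replicates
  nm <- config$n_mrna_per_gene
  poly_c <- poly_t <- ribo_c <- ribo_t <- matrix(0, n, nr)
  for (r in seq_len(nr)) {
    for (i in seq_len(n)) {
      s <- derive_seed(seed, sim_index, r, i)
      loads_c <- sample_gene_replicate(specs[i, ], "control", nm, s)
      poly_c[i, r] <- estimate_polyprof(loads_c)
      ribo_c[i, r] <- estimate_riboprof(loads_c, specs$abundance[i],
                                        config$depth_factor, config$noise,
                                        config$dispersion)
      s2 <- derive_seed(seed, sim_index, r, i, 7L)
      loads_t <- sample_gene_replicate(specs[i, ], "treated", nm, s2)
      poly_t[i, r] <- estimate_polyprof(loads_t)
      ribo_t[i, r] <- estimate_riboprof(loads_t, specs$abundance[i],
                                        config$depth_factor, config$noise,
                                        config$dispersion)
    }
  }
  eps_poly <- 0.5 / nm   # half a molecule
  eps_ribo <- 0.5        # half a read
  res <- specs[, c("gene_id", "gene_class")]
  fc_p <- p_p <- fc_r <- p_r <- numeric(n)
  for (i in seq_len(n)) {
    dp <- differential_test(poly_c[i, ] + eps_poly, poly_t[i, ] + eps_poly)
    dr <- differential_test(ribo_c[i, ] + eps_ribo, ribo_t[i, ] + eps_ribo)
    fc_p[i] <- dp$fold_change; p_p[i] <- dp$pvalue
    fc_r[i] <- dr$fold_change; p_r[i] <- dr$pvalue
  }
  res$fold_change_poly <- fc_p
  res$pvalue_poly <- p_p
  res$fold_change_ribo <- fc_r
  res$pvalue_ribo <- p_r
  res
}

build_shift_specs <- function(config, seed, sim_index = 1L) {
  n <- config$n_per_class * length(config$shift_grid)
  set.seed(derive_seed(seed, sim_index, 999L))
  abundance <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  gene_spec_table(
    gene_id = sprintf("g%05d", seq_len(n)),
    gene_class = rep(sprintf("shift_%g", config$shift_grid), each = config$n_per_class),
    abundance = abundance,
    control_mean = rep(config$shift_grid, each = config$n_per_class),
    treated_mean = config$treated_mean,
    sd_ribosomes = config$sd_ribosomes)
}

#' Run the shift-grid experiment comparing the two profiling technologies
#'
#' For each of `n_simulations` replicated simulations: builds the gene set
#' (equal genes per shift class), samples molecule-level ribosome loads per
#' replicate and condition, computes both profiling readouts, tests every
#' gene, ranks by p-value and by fold change for each technology, selects the
#' top fraction, and quantifies per-shift-class selection bias.
#'
#' @param config A [simulation_config()].
#' @param seed Master integer seed.
#' @return Object of class `shift_experiment`: `bias` (data frame with one row
#'   per simulation x method x ranking: `bias_sum`), `bias_summary` (mean and
#'   sd of `bias_sum` per method x ranking), `class_deviation` (per-class mean
#'   observed and expected percentages across simulations), and `results`
#'   (per-gene estimates of the first simulation).
#' @export
run_shift_experiment <- function(config = simulation_config(), seed = 1L) {
  assert_that(inherits(config, "simulation_config"), "`config` must be a simulation_config")
  bias_rows <- list()
  dev_rows <- list()
  first_results <- NULL
  for (sim in seq_len(config$n_simulations)) {
    specs <- build_shift_specs(config, seed, sim)
    res <- simulate_gene_results(specs, config, seed, sim)
    if (sim == 1) first_results <- res
    for (method in c("poly", "ribo")) {
      for (ranking in c("pvalue", "fold_change")) {
        sel <- rank_and_select(res, method, ranking, config$top_k_fraction)
        b <- compute_bias(sel, specs)
        bias_rows[[length(bias_rows) + 1]] <- data.frame(
          simulation = sim, method = method, ranking = ranking,
          bias_sum = b$bias_sum, stringsAsFactors = FALSE)
        tb <- b$table
        tb$simulation <- sim; tb$method <- method; tb$ranking <- ranking
        dev_rows[[length(dev_rows) + 1]] <- tb
      }
    }
  }
  bias <- do.call(rbind, bias_rows)
  devs <- do.call(rbind, dev_rows)
  bias_summary <- stats::aggregate(bias_sum ~ method + ranking, bias,
                                   function(x) c(mean = mean(x), sd = stats::sd(x)))
  bias_summary <- do.call(data.frame, bias_summary)
  names(bias_summary) <- c("method", "ranking", "bias_sum_mean", "bias_sum_sd")
  class_deviation <- stats::aggregate(cbind(observed_pct, expected_pct, deviation) ~
                                        class + method + ranking, devs, mean)
  structure(list(config = config, seed = seed, bias = bias,
                 bias_summary = bias_summary, class_deviation = class_deviation,
                 results = first_results),
            class = "shift_experiment")
}

#' @export
print.shift_experiment <- function(x, ...) {
  cat(sprintf("<shift_experiment> %d simulations, %d genes each\n",
              x$config$n_simulations,
              x$config$n_per_class * length(x$config$shift_grid)))
  print(x$bias_summary, row.names = FALSE)
  invisible(x)
}

#' Zero-shift (null) simulation for type-I error control
#'
#' Every gene keeps the same ribosome-association law in both conditions, at
#' the nonmover regime (default mean 5 ribosomes) where the polysome-fraction
#' estimator has non-degenerate sampling variance. Under this null the
#' per-gene p-values should be approximately uniform and the median fold
#' change approximately 1 for both technologies.
#'
#' @param n_genes Number of null genes.
#' @param mean_ribosomes Shared control = treated mean.
#' @param config A [simulation_config()] supplying replicate counts, noise
#'   and abundance models.
#' @param seed Master integer seed.
#' @return Per-gene results data frame (as in [run_shift_experiment()]).
#' @export
run_null_experiment <- function(n_genes = 1000L, mean_ribosomes = 5,
                                config = simulation_config(), seed = 1L) {
  set.seed(derive_seed(seed, 999L))
  abundance <- stats::rlnorm(n_genes, config$abundance_meanlog, config$abundance_sdlog)
  specs <- gene_spec_table(
    gene_id = sprintf("null%05d", seq_len(n_genes)),
    gene_class = "null",
    abundance = abundance,
    control_mean = mean_ribosomes,
    treated_mean = mean_ribosomes,
    sd_ribosomes = config$sd_ribosomes)
  simulate_gene_results(specs, config, seed, sim_index = 1L)
}
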