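# Ribosome load <-> sucrose-gradient sedimentation model and trace fitting.

#' Gradient mapping between ribosome load and sedimentation distance
#'
#' Describes how many ribosomes an mRNA carries versus how far it sediments in
#' a 5\%--50\% sucrose gradient, on a normalised \[0, 1\] axis (0 = top of the
#' gradient, 1 = bottom). Sedimentation coefficients grow sublinearly with
#' particle mass, so the map is a power law `(n / n_max)^alpha` anchored so
#' that the monosome (80S, one bound ribosome) sits at `monosome_position` and
#' `n_max` ribosomes sediment at the bottom.
#'
#' @param n_max Ribosome count that sediments at the gradient bottom (> 0).
#' @param alpha Mass-to-sedimentation exponent (> 0). The default 0.6
#'   approximates the scaling of sedimentation coefficient with polysome mass.
#' @param monosome_position Normalised position of the 80S peak, in (0, 1).
#' @return An object of class `gradient_mapping`.
#' @examples
#' m <- gradient_mapping()
#' ribosomes_to_sedimentation(c(0, 1, 10, 20), m)
#' @export
gradient_mapping <- function(n_max = 20L, alpha = 0.6, monosome_position = 0.25) {
  assert_that(is.numeric(n_max) && length(n_max) == 1 && n_max > 0,
              "`n_max` must be a single positive number")
  assert_that(is.numeric(alpha) && length(alpha) == 1 && alpha > 0,
              "`alpha` must be a single positive number")
  assert_that(is.numeric(monosome_position) && length(monosome_position) == 1 &&
                monosome_position > 0 && monosome_position < 1,
              "`monosome_position` must lie in (0, 1)")
  assert_that(n_max > 1, "`n_max` must exceed the monosome count of 1")
  structure(list(n_max = n_max, alpha = alpha,
                 monosome_position = monosome_position),
            class = "gradient_mapping")
}

#' @export
print.gradient_mapping <- function(x, ...) {
  cat(sprintf(
    "<gradient_mapping> n_max = %g, alpha = %g, 80S at %.2f of gradient\n",
    x$n_max, x$alpha, x$monosome_position))
  invisible(x)
}

#' Convert ribosome counts to normalised sedimentation distance
#'
#' Applies the power-law map `d(n) = (n / n_max)^alpha`, piecewise-affinely
#' rescaled so that `d(1)` equals the calibrated monosome position and
#' `d(n_max) = 1`. The map is monotone non-decreasing with `d(0) = 0`.
#'
#' @param n Numeric vector of ribosome counts (all >= 0).
#' @param mapping A [gradient_mapping()].
#' @return Numeric vector of distances in \[0, 1\].
#' @export
ribosomes_to_sedimentation <- function(n, mapping) {
  assert_that(inherits(mapping, "gradient_mapping"), "`mapping` must be a gradient_mapping")
  assert_that(is.numeric(n) && all(is.finite(n)), "`n` must be finite numeric")
  if (any(n < 0)) stop("ribosome counts must be non-negative", call. = FALSE)
  raw <- (pmin(n, mapping$n_max) / mapping$n_max)^mapping$alpha
  r1 <- (1 / mapping$n_max)^mapping$alpha
  mp <- mapping$monosome_position
  d <- ifelse(raw <= r1,
              mp * raw / r1,
              mp + (1 - mp) * (raw - r1) / (1 - r1))
  pmin(pmax(d, 0), 1)
}

#' Per-gene ribosome-association distribution
#'
#' The number of ribosomes bound per mRNA molecule of a gene is modelled as a
#' normal law clamped at zero (molecules drawn below zero are free mRNPs and
#' recorded as carrying zero ribosomes).
#'
#' @param mean_ribosomes Mean of the underlying normal, in ribosomes (>= 0).
#' @param sd_ribosomes Standard deviation, in ribosomes (> 0).
#' @return An object of class `ribosome_distribution`.
#' @export
ribosome_distribution <- function(mean_ribosomes, sd_ribosomes) {
  assert_that(is.numeric(mean_ribosomes) && length(mean_ribosomes) == 1 &&
                mean_ribosomes >= 0, "`mean_ribosomes` must be >= 0")
  assert_that(is.numeric(sd_ribosomes) && length(sd_ribosomes) == 1 &&
                sd_ribosomes > 0, "`sd_ribosomes` must be > 0")
  structure(list(mean_ribosomes = mean_ribosomes, sd_ribosomes = sd_ribosomes),
            class = "ribosome_distribution")
}

#' @export
print.ribosome_distribution <- function(x, ...) {
  cat(sprintf("<ribosome_distribution> mean = %g, sd = %g ribosomes\n",
              x$mean_ribosomes, x$sd_ribosomes))
  invisible(x)
}

# Deterministic forward model: expected (noise-free) absorbance profile of a
# ribosome distribution pushed through the gradient mapping.  Molecules are
# binned at integer ribosome counts 0..n_max; each bin contributes a narrow
# Gaussian peak at its sedimentation position, giving the discrete polysome
# peaks seen in A254 tracings.  Returned curve is unit-area on `positions`.
trace_model <- function(mean, sd, mapping, positions, peak_sd = 0.015) {
  ks <- 0:mapping$n_max
  breaks <- c(-Inf, ks[-length(ks)] + 0.5, Inf)
  p <- stats::pnorm(breaks[-1], mean, sd) - stats::pnorm(breaks[-length(breaks)], mean, sd)
  # clamping at zero sends all sub-zero mass to the k = 0 bin
  centres <- ribosomes_to_sedimentation(ks, mapping)
  y <- rowSums(vapply(seq_along(ks),
                      function(i) p[i] * stats::dnorm(positions, centres[i], peak_sd),
                      numeric(length(positions))))
  area <- sum(y) * mean(diff(positions))
  if (area > 0) y <- y / area
  y
}

#' Fit a ribosome-association distribution to an absorbance trace
#'
#' Finds the `(mean, sd)` in ribosome units whose clamped-normal law, pushed
#' through the gradient mapping and rendered as a peaked absorbance profile,
#' minimises the sum of squared differences to the unit-area normalised trace.
#' The search is a deterministic coarse-to-fine grid (no gradient optimiser),
#' so repeated fits of the same trace give identical answers.
#'
#' @param trace Data frame with columns `position` (strictly increasing, in
#'   \[0, 1\]) and `absorbance` (>= 0); at least 10 points, non-constant.
#' @param mapping A [gradient_mapping()].
#' @param peak_sd Width (normalised distance units) of the per-polysome-peak
#'   kernel used by the forward model; must match the width used when the
#'   trace was rendered or recorded.
#' @return A [ribosome_distribution()] with attributes `rss` (residual sum of
#'   squares) and `grid_step` (final grid resolution).
#' @export
fit_ribosome_distribution <- function(trace, mapping, peak_sd = 0.015) {
  assert_that(is.data.frame(trace) && all(c("position", "absorbance") %in% names(trace)),
              "`trace` must have columns `position` and `absorbance`")
  if (nrow(trace) < 10) stop("trace must contain at least 10 points", call. = FALSE)
  assert_that(all(diff(trace$position) > 0), "trace positions must be strictly increasing")
  if (stats::sd(trace$absorbance) == 0)
    stop("flat trace: absorbance is constant, cannot fit a distribution", call. = FALSE)
  assert_that(all(trace$absorbance >= 0), "absorbance must be non-negative")

  pos <- trace$position
  obs <- trace$absorbance
  obs <- obs / (sum(obs) * mean(diff(pos)))  # unit area, absorbance units drop out

  rss_of <- function(m, s) sum((trace_model(m, s, mapping, pos, peak_sd) - obs)^2)

  # coarse pass
  means <- seq(0, mapping$n_max, by = 0.5)
  sds <- seq(0.2, mapping$n_max / 3, by = 0.4)
  grid <- expand.grid(mean = means, sd = sds)
  rss <- mapply(rss_of, grid$mean, grid$sd)
  best <- grid[which.min(rss), ]

  # two refinement passes around the incumbent
  step <- 0.5
  for (pass in 1:2) {
    step <- step / 10
    means <- seq(max(0, best$mean - 6 * step * 5), best$mean + 6 * step * 5, by = step)
    sds <- seq(max(0.05, best$sd - 6 * step * 5), best$sd + 6 * step * 5, by = step)
    grid <- expand.grid(mean = means, sd = sds)
    rss <- mapply(rss_of, grid$mean, grid$sd)
    best <- grid[which.min(rss), ]
  }

  out <- ribosome_distribution(best$mean, best$sd)
  attr(out, "rss") <- min(rss)
  attr(out, "grid_step") <- step
  out
}

#' Read an absorbance trace from a two-column TSV
#'
#' Expects a header line and two columns, `position` and `absorbance`.
#'
#' @param path File path.
#' @return Data frame with columns `position` and `absorbance`.
#' @export
read_absorbance_trace <- function(path) {
  x <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  assert_that(all(c("position", "absorbance") %in% names(x)),
              "trace file must have header columns `position` and `absorbance`")
  x[, c("position", "absorbance")]
}

#' Write an absorbance trace to a two-column TSV
#'
#' @param trace Data frame with columns `position` and `absorbance`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_absorbance_trace <- function(trace, path) {
  utils::write.table(trace[, c("position", "absorbance")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
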