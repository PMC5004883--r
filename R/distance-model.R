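#' Mixture model for true inter-probe 3D separations
#'
#' Parametric stand-in for the empirical distance distributions measured
#' between a gene probe and an enhancer probe in nuclei. An allele's true
#' separation is drawn, with probability `p_coloc`, from a short-range
#' half-normal component (the colocalised/looped state) and otherwise from a
#' long-range normal component truncated at zero (the open state). Both
#' components have closed-form CDFs, so the model can be checked analytically.
#'
#' @param p_coloc Probability in `[0, 1]` that a separation is drawn from the
#'   short component.
#' @param short_scale_nm Scale (sigma) of the half-normal short component, nm.
#' @param tail_mean_nm,tail_sd_nm Mean and sd of the long component before
#'   truncation at zero, nm.
#' @return An object of class `distance_model`.
#' @examples
#' m <- distance_model(0.5, 120, 800, 250)
#' distance_cdf(m, 200)   # analytic P(d < 200 nm)
#' @export
distance_model <- function(p_coloc, short_scale_nm, tail_mean_nm, tail_sd_nm) {
  stopifnot(is.numeric(p_coloc), length(p_coloc) == 1L, is.finite(p_coloc))
  if (p_coloc < 0 || p_coloc > 1)
    stop("'p_coloc' must lie in [0, 1]")
  for (s in c(short_scale_nm, tail_mean_nm, tail_sd_nm))
    if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
      stop("all model scales must be finite positive scalars")
  structure(
    list(p_coloc = p_coloc, short_scale_nm = short_scale_nm,
         tail_mean_nm = tail_mean_nm, tail_sd_nm = tail_sd_nm),
    class = "distance_model")
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf(
    "distance_model: P(short) = %.3f, half-normal scale %.0f nm, tail %.0f +/- %.0f nm\n",
    x$p_coloc, x$short_scale_nm, x$tail_mean_nm, x$tail_sd_nm))
  cat(sprintf("  analytic P(d < 200 nm) = %.3f\n", distance_cdf(x, 200)))
  invisible(x)
}

#' Analytic CDF of the separation mixture
#'
#' @param model A [distance_model()].
#' @param q Vector of distances, nm.
#' @return `P(d <= q)` for each element of `q`.
#' @export
distance_cdf <- function(model, q) {
  stopifnot(inherits(model, "distance_model"))
  q <- pmax(q, 0)
  f_short <- 2 * stats::pnorm(q / model$short_scale_nm) - 1
  a <- stats::pnorm(-model$tail_mean_nm / model$tail_sd_nm)
  f_tail <- (stats::pnorm((q - model$tail_mean_nm) / model$tail_sd_nm) - a) / (1 - a)
  model$p_coloc * f_short + (1 - model$p_coloc) * f_tail
}

#' Sample true inter-probe separations
#'
#' Draws from the mixture: component membership is Bernoulli(`p_coloc`); the
#' short component is |N(0, short_scale)|, the tail is N(tail_mean, tail_sd)
#' truncated at zero (sampled by inverse-CDF, so no rejection loop).
#' Randomness comes from R's global RNG; seed with [set.seed()].
#'
#' @param model A [distance_model()].
#' @param n Number of draws.
#' @return Numeric vector of `n` non-negative distances, nm.
#' @export
sample_pair_distance <- function(model, n = 1L) {
  stopifnot(inherits(model, "distance_model"), n >= 0)
  if (n == 0L) return(numeric(0))
  short <- stats::runif(n) < model$p_coloc
  d <- numeric(n)
  n1 <- sum(short)
  if (n1 > 0L)
    d[short] <- abs(stats::rnorm(n1, 0, model$short_scale_nm))
  if (n1 < n) {
    a <- stats::pnorm(-model$tail_mean_nm / model$tail_sd_nm)
    u <- stats::runif(n - n1)
    d[!short] <- model$tail_mean_nm +
      model$tail_sd_nm * stats::qnorm(a + u * (1 - a))
  }
  d
}

#' Calibrate the mixture to a target colocalised fraction
#'
#' Solves for `p_coloc` such that the analytic `P(d < threshold)` equals
#' `target`, holding the component shapes fixed. Used to build simulation
#' groups whose true colocalisation frequencies match reported levels (for
#' example the ~35% expressing-tissue and ~79% super-resolution levels).
#'
#' @param target Desired `P(d < threshold_nm)`.
#' @param short_scale_nm,tail_mean_nm,tail_sd_nm Component parameters.
#' @param threshold_nm Colocalisation threshold, default 200 nm.
#' @return A [distance_model()] whose CDF at `threshold_nm` equals `target`.
#' @export
distance_model_for_fraction <- function(target, short_scale_nm = 120,
                                        tail_mean_nm = 800, tail_sd_nm = 250,
                                        threshold_nm = 200) {
  stopifnot(target >= 0, target <= 1)
  f_short <- 2 * stats::pnorm(threshold_nm / short_scale_nm) - 1
  a <- stats::pnorm(-tail_mean_nm / tail_sd_nm)
  f_tail <- (stats::pnorm((threshold_nm - tail_mean_nm) / tail_sd_nm) - a) / (1 - a)
  p <- (target - f_tail) / (f_short - f_tail)
  if (p < 0 || p > 1)
    stop(sprintf(
      "target fraction %.3f not reachable with these components (feasible range %.3f..%.3f)",
      target, f_tail, f_short))
  distance_model(p, short_scale_nm, tail_mean_nm, tail_sd_nm)
}

#' Illustrative per-tissue separation presets
#'
#' Named presets whose true colocalised fractions (P(d < 200 nm)) anchor to
#' reported levels: ~0.79 for expressing distal-posterior limb tissue seen at
#' super-resolution, ~0.35 for the same tissue by conventional widefield,
#' ~0.25 for distal anterior tissue, ~0.10 for flank, and ~0.03 for a distant
#' control locus outside the regulatory domain. The component shapes are
#' illustrative (only binned histograms are reported, not a parametric law).
#'
#' @return Named list of [distance_model()] objects.
#' @export
distance_model_presets <- function() {
  list(
    zpa          = distance_model_for_fraction(0.79),
    zpa_widefield = distance_model_for_fraction(0.35),
    distal_anterior = distance_model_for_fraction(0.25),
    flank        = distance_model_for_fraction(0.10),
    control_distal = distance_model_for_fraction(0.03, tail_mean_nm = 1000,
                                                 tail_sd_nm = 300))
}
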