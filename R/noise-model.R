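#' Firing-rate noise model with logarithmic variance-mean law
#'
#' Trial-to-trial variability of firing rates follows a Gaussian whose
#' variance depends on the mean rate through
#' \deqn{\sigma^2(\bar r) = s \cdot v_1 \ln(1 + v_2 \bar r),}
#' with `noise_scale` \eqn{s} a dimensionless multiplier (1 = fitted level).
#' For small rates \eqn{\sigma^2 \approx s\, v_1 v_2 \bar r}; with
#' \eqn{v_1 v_2 = 1/T} (stimulus duration \eqn{T}) the spike-count variance
#' equals the count mean, i.e. the model is Poisson-like at low rates, while
#' at high rates the variance grows sublinearly. Negative rates are excluded
#' by clipping: the conditional rate distribution is a Gaussian truncated at
#' zero and renormalised (a point-mass-at-zero variant is available).
#'
#' @param v1 variance-law scale in Hz^2.
#' @param v2 variance-law rate constant in 1/Hz.
#' @param duration stimulus duration in seconds.
#' @param noise_scale dimensionless variance multiplier (default 1).
#' @param clip one of "renormalize" (truncated Gaussian density,
#'   default) or "point_mass" (clipped mass assigned to rate 0).
#' @return object of class `rate_noise_model`. The defaults satisfy
#'   `v1 * v2 == 1/duration` exactly; a deviation beyond 20 percent from
#'   Poisson consistency triggers a warning.
#' @export
rateNoiseModel <- function(v1 = 25, v2 = 0.2, duration = 0.2,
                           noise_scale = 1,
                           clip = c("renormalize", "point_mass")) {
  stopifnot(v1 > 0, v2 > 0, duration > 0, noise_scale >= 0)
  clip <- match.arg(clip)
  if (abs(v1 * v2 * duration - 1) > 0.2)
    warning(sprintf(
      "v1*v2 = %.3g differs from 1/duration = %.3g; count noise is not Poisson-like at low rates",
      v1 * v2, 1 / duration))
  structure(list(v1 = v1, v2 = v2, duration = duration,
                 noise_scale = noise_scale, clip = clip),
            class = "rate_noise_model")
}

#' @export
print.rate_noise_model <- function(x, ...) {
  cat(sprintf(
    "Rate noise model: var = %.3g * %.3g * ln(1 + %.3g r), T = %.3g s, clip = %s\n",
    x$noise_scale, x$v1, x$v2, x$duration, x$clip))
  invisible(x)
}

#' Variance of the firing rate at a given mean rate
#'
#' @param model a [rateNoiseModel()].
#' @param mean_rate mean rates in Hz (>= 0).
#' @return variances in Hz^2 (0 at mean 0 when noise_scale > 0).
#' @export
rateVariance <- function(model, mean_rate) {
  if (any(mean_rate < 0)) stop("mean rate must be >= 0")
  model$noise_scale * model$v1 * log1p(model$v2 * mean_rate)
}

# standard deviation with a tiny floor so degenerate (zero-variance)
# conditions stay well-defined as near-delta distributions
rateSd <- function(model, mean_rate, floor = 1e-6) {
  sqrt(pmax(rateVariance(model, mean_rate), floor^2))
}

#' Fit the logarithmic variance-mean law
#'
#' Least-squares fit of \eqn{\sigma^2 = v_1 \ln(1 + v_2 \bar r)} to pooled
#' (mean rate, variance) pairs.
#'
#' @param mean_rate mean rates in Hz.
#' @param variance rate variances in Hz^2 (must be positive).
#' @param duration stimulus duration in seconds carried into the returned
#'   model.
#' @return a [rateNoiseModel()] with the fitted `v1`, `v2` and an `sse`
#'   attribute.
#' @export
fitVarianceMean <- function(mean_rate, variance, duration = 0.2) {
  stopifnot(length(mean_rate) == length(variance))
  if (length(mean_rate) < 5L) stop("need at least 5 (mean, variance) pairs")
  if (any(variance <= 0)) stop("variances must be positive")
  obj <- function(lp) {
    v1 <- exp(lp[1]); v2 <- exp(lp[2])
    sum((v1 * log1p(v2 * mean_rate) - variance)^2)
  }
  # moment-based start: slope at origin ~ v1*v2, curvature sets v2
  s0 <- sum(mean_rate * variance) / sum(mean_rate^2)
  best <- NULL
  for (v2_0 in c(0.02, 0.1, 0.5, 2)) {
    fit <- stats::optim(c(log(max(s0 / v2_0, 1e-8)), log(v2_0)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  m <- rateNoiseModel(v1 = exp(best$par[1]), v2 = exp(best$par[2]),
                      duration = duration)
  attr(m, "sse") <- best$value
  m
}

#' Conditional density of the firing rate given its mean
#'
#' Gaussian in the rate with model variance, clipped at zero. With
#' `clip = "renormalize"` the truncated density is rescaled to unit mass on
#' r >= 0; with `clip = "point_mass"` the sub-zero mass sits at r = 0 (the
#' returned density is then the absolutely continuous part only).
#'
#' @param r rates in Hz at which to evaluate.
#' @param mean_rate the conditional mean in Hz (scalar, >= 0).
#' @param model a [rateNoiseModel()].
#' @return density values; 0 for r < 0.
#' @export
conditionalRateDensity <- function(r, mean_rate, model) {
  if (length(mean_rate) != 1L || mean_rate < 0)
    stop("mean_rate must be a single value >= 0")
  s <- rateSd(model, mean_rate)
  d <- stats::dnorm(r, mean_rate, s)
  d[r < 0] <- 0
  if (model$clip == "renormalize") {
    mass <- stats::pnorm(0, mean_rate, s, lower.tail = FALSE)
    d <- d / mass
  }
  d
}

#' Sample firing rates from the clipped Gaussian
#'
#' @param mean_rate mean rates in Hz; recycled against `n` (pass a vector of
#'   per-trial means with `n = length(mean_rate)` for heterogeneous draws).
#' @param model a [rateNoiseModel()].
#' @param n number of draws.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return `n` nonnegative rates in Hz.
#' @export
sampleRates <- function(mean_rate, model, n, seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  mu <- rep_len(mean_rate, n)
  s <- rateSd(model, mu)
  draw <- function() {
    u <- stats::runif(n)
    if (model$clip == "renormalize") {
      # inverse-CDF sampling of the zero-truncated Gaussian
      f0 <- stats::pnorm(0, mu, s)
      stats::qnorm(f0 + u * (1 - f0), mu, s)
    } else {
      pmax(stats::qnorm(u, mu, s), 0)
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
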