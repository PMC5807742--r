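# Weibull freeze-and-recovery curve: parameters, evaluation, closed-form
# features. The curve models tank-mean activity after an acute stressor as a
# dip below baseline that relaxes back asymptotically.

#' Parameters of the Weibull freeze-and-recovery curve
#'
#' The post-stressor activity model is
#' \deqn{f(x) = y_{max} - \frac{\alpha k}{\lambda}\, u^{k+1} e^{-u^k},
#'       \qquad u = \frac{x + t_{min}}{\lambda},}
#' where `x` is time since the stressor in seconds and `f(x)` is tank-mean
#' activity in % body length/s. `y_max` is the baseline (and asymptotic)
#' activity; `alpha` scales the depth of the freezing dip; `k` and `lam`
#' control the dip's shape and time scale; `t_min` shifts the curve along the
#' time axis. With `alpha = 0` the curve is flat at `y_max`.
#'
#' The exponent `k + 1` on `u` (rather than the `k - 1` of the standard
#' Weibull density) is intentional: it is what produces a smooth dip leaving
#' `f(-t_min) = y_max` exactly. Set `exponent_convention = "k_minus_1"` in
#' [weibull_recovery()] to use the density-style exponent instead.
#'
#' @param y_max baseline/asymptotic activity (% body length/s); finite.
#' @param alpha dip amplitude scale, `>= 0`.
#' @param k shape, `> 0`.
#' @param lam time scale in seconds, `> 0`.
#' @param t_min time offset in seconds (the curve's domain is
#'   `x >= -t_min`).
#' @return An object of class `weibull_params`.
#' @seealso [weibull_recovery()], [freeze_features()], [nls_fit()]
#' @export
#' @examples
#' p <- weibull_params(y_max = 100, alpha = 500, k = 2, lam = 10)
#' weibull_recovery(c(0, 10), p)
#' freeze_features(p)
weibull_params <- function(y_max, alpha, k, lam, t_min = 0) {
  vals <- c(y_max = y_max, alpha = alpha, k = k, lam = lam, t_min = t_min)
  if (any(!is.finite(vals))) {
    stop("weibull_params: all parameters must be finite, got ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "),
         call. = FALSE)
  }
  if (alpha < 0) stop("weibull_params: 'alpha' must be >= 0", call. = FALSE)
  if (k <= 0) stop("weibull_params: 'k' must be > 0", call. = FALSE)
  if (lam <= 0) stop("weibull_params: 'lam' must be > 0", call. = FALSE)
  structure(as.list(vals), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat("Weibull freeze-recovery parameters:\n")
  cat(sprintf("  y_max = %.4g %%BL/s, alpha = %.4g, k = %.4g, lambda = %.4g s, t_min = %.4g s\n",
              x$y_max, x$alpha, x$k, x$lam, x$t_min))
  invisible(x)
}

#' Evaluate the freeze-and-recovery curve
#'
#' @param x time since the stressor, in seconds (vectorized). Must satisfy
#'   `x >= -t_min` so that the scaled time `u` is nonnegative.
#' @param p a [weibull_params()] object.
#' @param exponent_convention `"k_plus_1"` (default; the dip-shaped form
#'   with exponent `k + 1`) or `"k_minus_1"` (standard Weibull-density
#'   exponent).
#' @return activity in % body length/s, same length as `x`.
#' @export
weibull_recovery <- function(x, p,
                             exponent_convention = c("k_plus_1", "k_minus_1")) {
  exponent_convention <- match.arg(exponent_convention)
  stopifnot(inherits(p, "weibull_params"))
  u <- (x + p$t_min) / p$lam
  if (any(u < 0)) {
    stop("weibull_recovery: x must be >= -t_min (scaled time u >= 0)",
         call. = FALSE)
  }
  expo <- if (exponent_convention == "k_plus_1") p$k + 1 else p$k - 1
  p$y_max - (p$alpha * p$k / p$lam) * u^expo * exp(-u^p$k)
}

#' Closed-form freezing features of a fitted curve
#'
#' The dip term `u^{k+1} e^{-u^k}` is maximized at
#' `u* = ((k+1)/k)^{1/k}` (set the derivative of its log to zero), so the
#' curve attains its minimum at `x* = lambda u* - t_min` with value
#' `f(x*) = y_max - (alpha k / lambda) u*^{k+1} e^{-(k+1)/k}`. These are the
#' two behavioral endpoints: the time needed to reach freezing and the
#' freezing intensity (minimum activity).
#'
#' @param p a [weibull_params()] object.
#' @return A list of class `freeze_features` with elements
#'   `time_to_freeze` (s; `NA` when `alpha = 0`, no dip), `freezing_intensity`
#'   (% body length/s) and `depth` (`y_max` minus the minimum).
#' @export
freeze_features <- function(p) {
  stopifnot(inherits(p, "weibull_params"))
  if (p$alpha == 0) {
    out <- list(time_to_freeze = NA_real_,
                freezing_intensity = p$y_max,
                depth = 0)
  } else {
    u_star <- ((p$k + 1) / p$k)^(1 / p$k)
    x_star <- p$lam * u_star - p$t_min
    f_min <- p$y_max -
      (p$alpha * p$k / p$lam) * u_star^(p$k + 1) * exp(-(p$k + 1) / p$k)
    out <- list(time_to_freeze = x_star,
                freezing_intensity = f_min,
                depth = p$y_max - f_min)
  }
  class(out) <- "freeze_features"
  out
}

#' Brute-force minimizer of the freeze curve (reference oracle)
#'
#' Locates the activity minimum by successively refined grid search, with no
#' use of the closed-form argmin. Minimizing `f` is maximizing the dip term
#' `u^{k+1} e^{-u^k}` (the additive `y_max` and the positive factor
#' `alpha k / lambda` cannot move the argmin), and the grid searches its
#' logarithm `(k+1) log u - u^k`, whose relative curvature near the optimum
#' is O(1) for every parameter draw — a direct grid on `f` loses the argmin
#' in floating-point flatness when the dip is shallow. Intended for
#' validating [freeze_features()]; `freeze_features()` itself never calls
#' this.
#'
#' @param p a [weibull_params()] object with `alpha > 0`.
#' @param x_upper upper end of the search interval (default `20 * lam`,
#'   far beyond the dip for any valid shape).
#' @param n_grid points per refinement level.
#' @param n_refine number of refinement levels.
#' @param exponent_convention as [weibull_recovery()].
#' @return list with `time_to_freeze` and `freezing_intensity`.
#' @export
freeze_features_grid <- function(p, x_upper = 20 * p$lam, n_grid = 4001,
                                 n_refine = 4,
                                 exponent_convention = c("k_plus_1",
                                                         "k_minus_1")) {
  exponent_convention <- match.arg(exponent_convention)
  stopifnot(inherits(p, "weibull_params"), p$alpha > 0)
  expo <- if (exponent_convention == "k_plus_1") p$k + 1 else p$k - 1
  # log of the dip term; maximal where f is minimal
  obj <- function(xs) {
    u <- (xs + p$t_min) / p$lam
    ifelse(u > 0, expo * log(u) - u^p$k, -Inf)
  }
  lo <- -p$t_min
  hi <- x_upper
  for (i in seq_len(n_refine)) {
    xs <- seq(lo, hi, length.out = n_grid)
    j <- which.max(obj(xs))
    step <- xs[2] - xs[1]
    lo <- max(-p$t_min, xs[j] - step)
    hi <- xs[j] + step
  }
  xs <- seq(lo, hi, length.out = n_grid)
  j <- which.max(obj(xs))
  list(time_to_freeze = xs[j],
       freezing_intensity = weibull_recovery(xs[j], p, exponent_convention))
}
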