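# Per-unit nonlinear least squares fitting of the freeze-recovery curve and
# the two-stage (fit-then-mixed-model) population analysis. Each tank
# (aquarium) on each experimental day is one statistical unit.

#' Construct a tank-mean activity series
#'
#' @param time_s time relative to the stressor (s), strictly increasing;
#'   the stressor is at 0 by convention.
#' @param speed_blps tank-mean speed in % body length/s, nonnegative.
#' @param n_fish number of fish contributing per frame (recycled).
#' @param aquarium,day,zone,trial unit labels carried through to fits.
#' @return data frame of class `activity_series` with a `unit` attribute.
#' @export
activity_series <- function(time_s, speed_blps, n_fish = NA_integer_,
                            aquarium = NA, day = NA, zone = NA, trial = NA) {
  stopifnot(length(time_s) == length(speed_blps))
  if (any(diff(time_s) <= 0)) {
    stop("activity_series: time_s must be strictly increasing", call. = FALSE)
  }
  if (any(speed_blps < 0, na.rm = TRUE)) {
    stop("activity_series: speeds must be >= 0", call. = FALSE)
  }
  out <- data.frame(time_s = time_s, speed_blps = speed_blps, n_fish = n_fish)
  attr(out, "unit") <- list(aquarium = aquarium, day = day, zone = zone,
                            trial = trial)
  class(out) <- c("activity_series", "data.frame")
  out
}

#' Data-driven starting values for the freeze-curve fit
#'
#' The baseline start is the pre-stress mean speed; the dip location start
#' is the observed post-stress argmin; the shape start is `k = 2`; the time
#' scale is recovered by inverting the closed-form argmin relation
#' `x* = lambda ((k+1)/k)^{1/k} - t_min` at `t_min = 0`; and the amplitude
#' start inverts the closed-form dip depth at the observed depth, so that
#' the starting curve reproduces the observed minimum.
#'
#' @param series an [activity_series()].
#' @return a [weibull_params()] start vector (flat with `alpha = 0` for an
#'   all-equal series).
#' @export
default_starts <- function(series) {
  stopifnot(inherits(series, "activity_series"), nrow(series) > 0)
  pre <- series$speed_blps[series$time_s < 0]
  post <- series[series$time_s >= 0, , drop = FALSE]
  y0 <- if (length(pre)) mean(pre) else mean(series$speed_blps)
  if (nrow(post) == 0 || stats::sd(series$speed_blps) == 0) {
    return(weibull_params(y_max = y0, alpha = 0, k = 2, lam = 1, t_min = 0))
  }
  j <- which.min(post$speed_blps)
  x_obs <- post$time_s[j]
  depth <- y0 - post$speed_blps[j]
  if (depth <= 0) {
    return(weibull_params(y_max = y0, alpha = 0, k = 2,
                          lam = max(x_obs, 1), t_min = 0))
  }
  k0 <- 2
  u_star <- ((k0 + 1) / k0)^(1 / k0)
  lam0 <- max(x_obs, 1e-2) / u_star
  alpha0 <- depth * lam0 / (k0 * u_star^(k0 + 1) * exp(-(k0 + 1) / k0))
  weibull_params(y_max = y0, alpha = alpha0, k = k0, lam = lam0, t_min = 0)
}

fit_rss <- function(par, x, y, exponent_convention) {
  y_max <- par[1]
  alpha <- max(par[2], 0)
  k <- max(par[3], 1e-8)
  lam <- max(par[4], 1e-8)
  t_min <- max(par[5], 0)
  u <- (x + t_min) / lam
  expo <- if (exponent_convention == "k_plus_1") k + 1 else k - 1
  pred <- y_max - (alpha * k / lam) * u^expo * exp(-u^k)
  sum((y - pred)^2)
}

#' Fit the freeze-recovery curve to one activity series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}, polished with `L-BFGS-B`) on the post-stress portion of
#' the series, under the constraints `alpha >= 0`, `k > 0`, `lambda > 0`,
#' `t_min >= 0`. If the first attempt fails or stalls, up to 8 restarts
#' perturb the `alpha`, `k` and `lambda` starts by factors of 2; a fit that
#' still fails is returned with `converged = FALSE` and its diagnostics,
#' never silently replaced.
#'
#' @param series an [activity_series()] whose post-stress window covers the
#'   dip; at least 10 post-stress points are required.
#' @param starts optional [weibull_params()] starting values; default
#'   [default_starts()].
#' @param skip_s seconds after the stressor to exclude from the fit
#'   (default 0). The dip model describes freeze and recovery, not the
#'   initial flight transient; setting `skip_s` to the stressor duration
#'   fits only the post-transient decline and recovery.
#' @param exponent_convention passed to [weibull_recovery()].
#' @return an object of class `weibull_fit`: `params`, `features`
#'   ([freeze_features()]), `rss`, `n_points`, `converged`, `starts` and the
#'   series' unit labels.
#' @export
nls_fit <- function(series, starts = NULL, skip_s = 0,
                    exponent_convention = c("k_plus_1", "k_minus_1")) {
  exponent_convention <- match.arg(exponent_convention)
  stopifnot(inherits(series, "activity_series"), skip_s >= 0)
  post <- series[series$time_s >= skip_s & is.finite(series$speed_blps), ,
                 drop = FALSE]
  if (nrow(post) < 10L) {
    stop("nls_fit: need >= 10 post-stress points", call. = FALSE)
  }
  if (is.null(starts)) starts <- default_starts(series)
  stopifnot(inherits(starts, "weibull_params"))
  x <- post$time_s
  y <- post$speed_blps

  # degenerate target: no dip to fit
  if (starts$alpha == 0 && stats::sd(y) == 0) {
    p <- weibull_params(mean(y), 0, starts$k, starts$lam, 0)
    return(structure(list(params = p, features = freeze_features(p),
                          rss = 0, n_points = nrow(post), converged = TRUE,
                          starts = starts, restarts_used = 0L,
                          exponent_convention = exponent_convention,
                          unit = attr(series, "unit")),
                     class = "weibull_fit"))
  }

  lower <- c(y_max = -Inf, alpha = 0, k = 1e-6, lam = 1e-6, t_min = 0)
  form <- if (exponent_convention == "k_plus_1") {
    y ~ y_max - (alpha * k / lam) * ((x + t_min) / lam)^(k + 1) *
      exp(-((x + t_min) / lam)^k)
  } else {
    y ~ y_max - (alpha * k / lam) * ((x + t_min) / lam)^(k - 1) *
      exp(-((x + t_min) / lam)^k)
  }
  lm_once <- function(p0) {
    tryCatch(suppressWarnings(minpack.lm::nlsLM(
      form,
      start = as.list(p0), lower = lower,
      data = list(x = x, y = y),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))),
      error = function(e) NULL)
  }
  # t_min is only weakly identified jointly with k and lambda (a long
  # curved valley in the RSS); profiling it out first - fit the other four
  # parameters at fixed t_min, then release all five from that solution -
  # is far more reliable than a direct 5-parameter descent
  form4 <- if (exponent_convention == "k_plus_1") {
    y ~ y_max - (alpha * k / lam) * ((x + t_fix) / lam)^(k + 1) *
      exp(-((x + t_fix) / lam)^k)
  } else {
    y ~ y_max - (alpha * k / lam) * ((x + t_fix) / lam)^(k - 1) *
      exp(-((x + t_fix) / lam)^k)
  }
  lm_profiled <- function(p0) {
    f4 <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      form4,
      start = as.list(p0[c("y_max", "alpha", "k", "lam")]),
      lower = lower[c("y_max", "alpha", "k", "lam")],
      data = list(x = x, y = y, t_fix = p0[["t_min"]]),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))),
      error = function(e) NULL)
    if (is.null(f4)) return(NULL)
    c(stats::coef(f4), t_min = p0[["t_min"]])
  }
  one_attempt <- function(st) {
    p0 <- c(y_max = st$y_max, alpha = max(st$alpha, 1e-8), k = st$k,
            lam = st$lam, t_min = st$t_min)
    p4 <- lm_profiled(p0)
    fit <- lm_once(if (is.null(p4)) p0 else p4)
    if (is.null(fit) && !is.null(p4)) {
      # keep the profiled solution if the full release fails
      rss4 <- fit_rss(p4, x, y, exponent_convention)
      return(list(par = p4, rss = rss4, ok = TRUE))
    }
    if (!is.null(fit)) {
      # Levenberg-Marquardt can stop early while crawling along the flat
      # t_min/lambda/k valley; a bounded quasi-Newton polish from its
      # solution reaches a stationary point, making refits idempotent
      par <- stats::coef(fit)
      op <- tryCatch(suppressWarnings(stats::optim(
        par, fit_rss, x = x, y = y,
        exponent_convention = exponent_convention,
        method = "L-BFGS-B", lower = lower,
        control = list(maxit = 2000, factr = 10))),
        error = function(e) NULL)
      cand <- list(list(par = par,
                        rss = fit_rss(par, x, y, exponent_convention)))
      if (!is.null(op)) {
        cand <- c(cand, list(list(par = op$par, rss = op$value)))
      }
      if (!is.null(p4)) {
        cand <- c(cand, list(list(
          par = p4, rss = fit_rss(p4, x, y, exponent_convention))))
      }
      best_i <- which.min(vapply(cand, `[[`, numeric(1), "rss"))
      return(list(par = cand[[best_i]]$par, rss = cand[[best_i]]$rss,
                  ok = TRUE))
    }
    # rescue nlsLM failures with bounded quasi-Newton on the RSS
    op <- tryCatch(suppressWarnings(stats::optim(
      p0, fit_rss, x = x, y = y,
      exponent_convention = exponent_convention,
      method = "L-BFGS-B", lower = lower,
      control = list(maxit = 500, factr = 1e3))),
      error = function(e) NULL)
    if (is.null(op)) {
      list(par = p0, rss = fit_rss(p0, x, y, exponent_convention), ok = FALSE)
    } else {
      list(par = op$par, rss = op$value, ok = TRUE)
    }
  }

  best <- one_attempt(starts)
  restarts_used <- 0L
  if (!best$ok || !is.finite(best$rss)) best$rss <- Inf
  tol <- 1e-10
  rel_rss <- function(rss) rss / max(sum((y - mean(y))^2), .Machine$double.eps)
  needs_restart <- function(b) !b$ok || !is.finite(b$rss)
  if (needs_restart(best) || rel_rss(best$rss) > 0.5) {
    grid <- expand.grid(fa = c(0.5, 2), fk = c(0.5, 2), fl = c(0.5, 2))
    for (i in seq_len(nrow(grid))) {
      st <- weibull_params(starts$y_max, starts$alpha * grid$fa[i],
                           starts$k * grid$fk[i], starts$lam * grid$fl[i],
                           starts$t_min)
      cand <- one_attempt(st)
      restarts_used <- restarts_used + 1L
      if (is.finite(cand$rss) && cand$rss < best$rss * (1 - tol)) best <- cand
      if (cand$ok && is.finite(cand$rss) && cand$rss < best$rss) best <- cand
    }
  }
  converged <- best$ok && is.finite(best$rss)
  par <- best$par
  p <- weibull_params(par[["y_max"]], max(par[["alpha"]], 0),
                      max(par[["k"]], 1e-6), max(par[["lam"]], 1e-6),
                      max(par[["t_min"]], 0))
  feats <- if (exponent_convention == "k_plus_1") {
    freeze_features(p)
  } else {
    g <- freeze_features_grid(p)
    structure(list(time_to_freeze = g$time_to_freeze,
                   freezing_intensity = g$freezing_intensity,
                   depth = p$y_max - g$freezing_intensity),
              class = "freeze_features")
  }
  structure(list(params = p, features = feats, rss = best$rss,
                 n_points = nrow(post), converged = converged,
                 starts = starts, restarts_used = restarts_used,
                 exponent_convention = exponent_convention,
                 unit = attr(series, "unit")),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  u <- x$unit
  cat(sprintf("Weibull freeze fit (%s, day %s, zone %s, trial %s)\n",
              u$aquarium, u$day, u$zone, u$trial))
  print(x$params)
  cat(sprintf("  time_to_freeze = %.3f s, freezing_intensity = %.3f %%BL/s\n",
              x$features$time_to_freeze, x$features$freezing_intensity))
  cat(sprintf("  rss = %.4g over %d points, converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}

#' Collect per-unit fits into a feature table
#'
#' @param fits list of [nls_fit()] results with unit labels.
#' @return data frame: trial, aquarium, zone, day, the five curve
#'   parameters, freezing_intensity, time_to_freeze, rss, converged.
#' @export
fits_to_table <- function(fits) {
  stopifnot(length(fits) > 0, all(vapply(fits, inherits, logical(1),
                                         "weibull_fit")))
  do.call(rbind, lapply(fits, function(f) {
    u <- f$unit
    data.frame(trial = u$trial, aquarium = u$aquarium, zone = u$zone,
               day = u$day, y_max = f$params$y_max, alpha = f$params$alpha,
               k = f$params$k, lam = f$params$lam, t_min = f$params$t_min,
               freezing_intensity = f$features$freezing_intensity,
               time_to_freeze = f$features$time_to_freeze,
               rss = f$rss, converged = f$converged)
  }))
}

#' Two-stage population analysis of freeze features
#'
#' Stage 1 is the per-unit NLS fit ([nls_fit()], supplied here as its
#' results); stage 2 models each extracted feature with a linear mixed model
#' (aquarium as random intercept, day and zone as fixed effects, interaction
#' AIC-selected via [analyze_behavior()]). Units whose stage-1 fit did not
#' converge are excluded and reported.
#'
#' @param fits list of [nls_fit()] results covering >= 2 aquaria per zone.
#' @param features which extracted features to model.
#' @param design `"pooled"` or `"per_trial"`, as [analyze_behavior()].
#' @return list of class `two_stage_fit`: `feature_table`, `excluded`
#'   (labels of non-converged units), and per-feature `analyses`
#'   (`response_analysis` objects with the selected fixed-effect tables).
#' @export
two_stage_fit <- function(fits,
                          features = c("freezing_intensity", "time_to_freeze"),
                          design = c("pooled", "per_trial")) {
  design <- match.arg(design)
  features <- match.arg(features, several.ok = TRUE)
  tab <- fits_to_table(fits)
  excluded <- tab[!tab$converged, c("trial", "aquarium", "zone", "day"),
                  drop = FALSE]
  if (nrow(excluded)) {
    warning("two_stage_fit: excluding ", nrow(excluded),
            " non-converged stage-1 unit(s)", call. = FALSE)
  }
  tab <- tab[tab$converged, , drop = FALSE]
  per_zone <- tapply(tab$aquarium, tab$zone,
                     function(a) length(unique(a)))
  if (any(per_zone < 2)) {
    stop("two_stage_fit: need >= 2 aquaria per zone (random effect ",
         "unidentifiable otherwise)", call. = FALSE)
  }
  analyses <- lapply(features, function(fv) analyze_behavior(tab, fv, design))
  names(analyses) <- features
  structure(list(feature_table = tab, excluded = excluded,
                 analyses = analyses),
            class = "two_stage_fit")
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat(sprintf("Two-stage freeze analysis: %d units (%d excluded)\n",
              nrow(x$feature_table), nrow(x$excluded)))
  for (fv in names(x$analyses)) {
    cat("\n==", fv, "==\n")
    for (nm in names(x$analyses[[fv]]$fixed_effects)) {
      cat(" [", nm, "]\n")
      print(x$analyses[[fv]]$fixed_effects[[nm]], digits = 3)
    }
  }
  invisible(x)
}
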