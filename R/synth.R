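# Seeded simulators for the three data streams the pipeline consumes: tank
# trajectories, waterborne-cortisol time courses and qPCR tables. The
# generators carry the statistical structure the downstream analyses assume,
# so every stage is testable without external data.

canonical_genes <- c("gr", "mr", "neurod1", "pcna", "gapdh", "18S")

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("sim_config: '", name, "' must be finite and > 0", call. = FALSE)
  }
}

#' Configuration of the trajectory simulator
#'
#' Defaults emulate the study conditions: 17 fish per 30 L aquarium, six
#' aquaria per zone, five experimental days, a 20-minute recording with the
#' mechanical stressor at its midpoint, fish of 25 +/- 5 mm standard length.
#' The post-stressor tank-mean speed follows a multiplicative flight spike
#' (gain `flight_gain`, exponential decay `flight_decay_s`) times the
#' zone's Weibull freezing envelope, plus additive Gaussian noise truncated
#' at zero.
#'
#' @param seed integer RNG seed.
#' @param n_aquaria_per_zone aquaria per zone (4 in the June trial, 6 in
#'   August; default 6).
#' @param fish_per_aquarium fish per tank (default 17).
#' @param n_days experimental days (default 5).
#' @param tank_width_cm,tank_height_cm tank footprint (cm; default 40 x 25,
#'   a standard 30 L footprint — the source recordings do not fix the
#'   geometry).
#' @param frame_rate_hz camera rate (default 10 Hz).
#' @param duration_s recording length (default 1200 s: 10 min pre +
#'   10 min post stress).
#' @param stress_time_s stressor onset (default 600 s); must be
#'   `< duration_s`.
#' @param body_length_mm_mean,body_length_mm_sd fish size distribution
#'   (default 25 +/- 5 mm).
#' @param baseline_speed_blps pre-stress tank-mean speed (% body length/s).
#' @param flight_gain peak multiplicative spike at the stressor (1 = none).
#' @param flight_decay_s spike e-folding time (s).
#' @param weibull_truth per-zone freezing envelopes: a named list of
#'   [weibull_params()] (names = zones) or a single `weibull_params` used
#'   for all zones. The default gives the control zone a dip from 200 down
#'   to 100 %BL/s at ~12 s post-stress and the tourism zone a 20 %BL/s
#'   deeper dip.
#' @param thigmotaxis_bias per-zone wall-attraction strength in `[0, 1]`
#'   (named vector or scalar).
#' @param speed_noise_sd additive Gaussian noise SD on tank-mean speed
#'   (% body length/s), truncated at zero.
#' @param heading_sd heading diffusion (rad per sqrt s) of the per-fish
#'   random walk.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_aquaria_per_zone = 6L,
                       fish_per_aquarium = 17L,
                       n_days = 5L,
                       tank_width_cm = 40,
                       tank_height_cm = 25,
                       frame_rate_hz = 10,
                       duration_s = 1200,
                       stress_time_s = 600,
                       body_length_mm_mean = 25,
                       body_length_mm_sd = 5,
                       baseline_speed_blps = 200,
                       flight_gain = 3,
                       flight_decay_s = 2,
                       weibull_truth = list(
                         CZ = weibull_params(200, 1220, 2, 10, 0),
                         TZ = weibull_params(200, 1464, 2, 10, 0)),
                       thigmotaxis_bias = c(CZ = 0.2, TZ = 0.35),
                       speed_noise_sd = 10,
                       heading_sd = 1.5) {
  for (nm in c("n_aquaria_per_zone", "fish_per_aquarium", "n_days",
               "tank_width_cm", "tank_height_cm", "frame_rate_hz",
               "duration_s", "stress_time_s", "body_length_mm_mean",
               "baseline_speed_blps", "flight_decay_s", "heading_sd")) {
    check_positive(get(nm), nm)
  }
  for (nm in c("body_length_mm_sd", "speed_noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || !is.finite(v) || v < 0) {
      stop("sim_config: '", nm, "' must be finite and >= 0", call. = FALSE)
    }
  }
  if (!is.finite(flight_gain) || flight_gain < 1) {
    stop("sim_config: 'flight_gain' must be >= 1", call. = FALSE)
  }
  if (stress_time_s >= duration_s) {
    stop("sim_config: 'stress_time_s' must be < duration_s", call. = FALSE)
  }
  if (inherits(weibull_truth, "weibull_params")) {
    weibull_truth <- list(CZ = weibull_truth, TZ = weibull_truth)
  }
  if (!all(vapply(weibull_truth, inherits, logical(1), "weibull_params"))) {
    stop("sim_config: 'weibull_truth' must hold weibull_params objects",
         call. = FALSE)
  }
  zones <- names(weibull_truth)
  if (length(thigmotaxis_bias) == 1L && is.null(names(thigmotaxis_bias))) {
    thigmotaxis_bias <- stats::setNames(rep(thigmotaxis_bias, length(zones)),
                                        zones)
  }
  if (any(!is.finite(thigmotaxis_bias)) || any(thigmotaxis_bias < 0) ||
      any(thigmotaxis_bias > 1)) {
    stop("sim_config: 'thigmotaxis_bias' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_aquaria_per_zone = as.integer(n_aquaria_per_zone),
                 fish_per_aquarium = as.integer(fish_per_aquarium),
                 n_days = as.integer(n_days),
                 tank_width_cm = tank_width_cm,
                 tank_height_cm = tank_height_cm,
                 frame_rate_hz = frame_rate_hz, duration_s = duration_s,
                 stress_time_s = stress_time_s,
                 body_length_mm_mean = body_length_mm_mean,
                 body_length_mm_sd = body_length_mm_sd,
                 baseline_speed_blps = baseline_speed_blps,
                 flight_gain = flight_gain, flight_decay_s = flight_decay_s,
                 weibull_truth = weibull_truth,
                 thigmotaxis_bias = thigmotaxis_bias,
                 speed_noise_sd = speed_noise_sd, heading_sd = heading_sd,
                 zones = zones),
            class = "sim_config")
}

# tank-mean target speed (%BL/s) at absolute recording times, before noise
target_speed <- function(t_abs, cfg, zone) {
  p <- cfg$weibull_truth[[zone]]
  s <- rep(cfg$baseline_speed_blps, length(t_abs))
  post <- t_abs >= cfg$stress_time_s
  if (any(post)) {
    x <- t_abs[post] - cfg$stress_time_s
    spike <- 1 + (cfg$flight_gain - 1) * exp(-x / cfg$flight_decay_s)
    s[post] <- spike * weibull_recovery(x, p)
  }
  s
}

simulate_one_trajectory <- function(cfg, zone, aquarium, trial, day) {
  n_fish <- cfg$fish_per_aquarium
  dt <- 1 / cfg$frame_rate_hz
  times <- seq(0, cfg$duration_s, by = dt)
  n_t <- length(times)
  W <- cfg$tank_width_cm
  H <- cfg$tank_height_cm
  b <- cfg$thigmotaxis_bias[[zone]]

  bl_mm <- pmax(cfg$body_length_mm_mean +
                  cfg$body_length_mm_sd * stats::rnorm(n_fish), 5)
  bl_cm <- bl_mm / 10

  tank_speed <- pmax(target_speed(times, cfg, zone) +
                       cfg$speed_noise_sd * stats::rnorm(n_t), 0)

  x <- matrix(NA_real_, n_t, n_fish)
  y <- matrix(NA_real_, n_t, n_fish)
  x[1, ] <- stats::runif(n_fish, 0, W)
  y[1, ] <- stats::runif(n_fish, 0, H)
  theta <- stats::runif(n_fish, -pi, pi)
  cx <- W / 2
  cy <- H / 2
  for (i in 2:n_t) {
    theta <- theta + cfg$heading_sd * sqrt(dt) * stats::rnorm(n_fish)
    hx <- cos(theta)
    hy <- sin(theta)
    ox <- x[i - 1, ] - cx
    oy <- y[i - 1, ] - cy
    onorm <- sqrt(ox^2 + oy^2)
    ok <- onorm > 1e-9
    ox <- ifelse(ok, ox / onorm, hx)
    oy <- ifelse(ok, oy / onorm, hy)
    dx <- (1 - b) * hx + b * ox
    dy <- (1 - b) * hy + b * oy
    dnorm <- sqrt(dx^2 + dy^2)
    small <- dnorm < 1e-12
    dx <- ifelse(small, hx, dx / pmax(dnorm, 1e-12))
    dy <- ifelse(small, hy, dy / pmax(dnorm, 1e-12))
    # each fish realizes the tank speed in its own body lengths, so the
    # tank-mean of per-fish %BL/s speeds equals tank_speed exactly
    step <- tank_speed[i] / 100 * bl_cm * dt
    sx <- dx * step
    sy <- dy * step
    # specular walls: flip the step component before moving, preserving
    # the step length (and hence the recovered speed) exactly
    out_x <- x[i - 1, ] + sx < 0 | x[i - 1, ] + sx > W
    sx[out_x] <- -sx[out_x]
    out_y <- y[i - 1, ] + sy < 0 | y[i - 1, ] + sy > H
    sy[out_y] <- -sy[out_y]
    x[i, ] <- pmin(pmax(x[i - 1, ] + sx, 0), W)
    y[i, ] <- pmin(pmax(y[i - 1, ] + sy, 0), H)
    theta <- ifelse(step > 0, atan2(sy, sx), theta)
  }
  frames <- data.frame(
    fish_id = rep(sprintf("%s_f%02d", aquarium, seq_len(n_fish)),
                  each = n_t),
    frame = rep(seq_len(n_t), n_fish),
    time_s = rep(times, n_fish),
    x_cm = as.numeric(x), y_cm = as.numeric(y))
  fish <- data.frame(fish_id = sprintf("%s_f%02d", aquarium, seq_len(n_fish)),
                     body_length_mm = bl_mm)
  trajectory(frames, fish, tank_width_cm = W, tank_height_cm = H,
             aquarium = aquarium, zone = zone, trial = trial, day = day)
}

#' Simulate tank trajectories for a trial
#'
#' One trajectory per aquarium-day. Per-fish motion is a heading random
#' walk whose step direction is blended with the outward radial direction
#' in proportion to the zone's `thigmotaxis_bias`; walls reflect steps
#' specularly so the step length — and hence the speed recovered by
#' [compute_speed()] — is preserved exactly. All fish in a tank share the
#' tank-level speed target at each frame, so the tank-mean activity equals
#' the (noisy) generating envelope by construction.
#'
#' @param cfg a [sim_config()].
#' @param trial trial label (default `"June"`).
#' @return list of [trajectory()] objects, ordered zone, aquarium, day;
#'   reproducible from `cfg$seed`.
#' @export
simulate_trajectories <- function(cfg, trial = "June") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  out <- list()
  for (zone in cfg$zones) {
    for (a in seq_len(cfg$n_aquaria_per_zone)) {
      aqua <- sprintf("%s%d", zone, a)
      for (d in seq_len(cfg$n_days)) {
        out[[length(out) + 1L]] <-
          simulate_one_trajectory(cfg, zone, aqua, trial, d)
      }
    }
  }
  out
}

#' Simulate tank-mean activity series directly
#'
#' Generates the [activity_series()] each trajectory would yield through
#' [compute_speed()] + [tank_mean_activity()] — by construction the two
#' routes share the same tank-level speed process — without paying for
#' per-fish positions. Used for simulation studies of the freeze-curve
#' fitting stage.
#'
#' @param cfg a [sim_config()].
#' @param trial trial label.
#' @param pre_s,post_s window around the stressor (s).
#' @return list of `activity_series`, one per aquarium-day, seeded from
#'   `cfg$seed`.
#' @export
simulate_activity <- function(cfg, trial = "June", pre_s = 10, post_s = 40) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dt <- 1 / cfg$frame_rate_hz
  t_rel <- seq(-pre_s, post_s, by = dt)
  t_abs <- t_rel + cfg$stress_time_s
  out <- list()
  for (zone in cfg$zones) {
    for (a in seq_len(cfg$n_aquaria_per_zone)) {
      aqua <- sprintf("%s%d", zone, a)
      for (d in seq_len(cfg$n_days)) {
        v <- pmax(target_speed(t_abs, cfg, zone) +
                    cfg$speed_noise_sd * stats::rnorm(length(t_abs)), 0)
        out[[length(out) + 1L]] <-
          activity_series(t_rel, v, cfg$fish_per_aquarium,
                          aquarium = aqua, day = d, zone = zone,
                          trial = trial)
      }
    }
  }
  out
}

#' Generating parameters of the cortisol mixed model
#'
#' Defaults are anchored to the magnitudes of the pooled cortisol analysis:
#' intercept 0.45, tourism-zone offset 0.42, time slope 0.08 per sampling
#' step, aquarium intercept SD 0.23, aquarium slope SD 0.12, residual SD
#' 0.41 (response in ng/L/mm). Sampling times are the baseline draw 1 h 20
#' before the stressor and 0.5, 1.5, 2.5, 3.5 h after.
#'
#' @param intercept_alpha fixed intercept.
#' @param zone_effect_beta fixed tourism-zone offset.
#' @param time_slope_beta_t fixed slope per sampling step.
#' @param zone_time_interaction extra slope per sampling step in the
#'   tourism zone (default 0: additive generating structure).
#' @param sd_aquarium_intercept,sd_aquarium_slope,sd_residual SDs, `>= 0`.
#' @param sampling_times_h strictly increasing sampling times (h relative
#'   to the stressor).
#' @return list of class `cortisol_truth`.
#' @export
cortisol_truth <- function(intercept_alpha = 0.45,
                           zone_effect_beta = 0.42,
                           time_slope_beta_t = 0.08,
                           zone_time_interaction = 0,
                           sd_aquarium_intercept = 0.23,
                           sd_aquarium_slope = 0.12,
                           sd_residual = 0.41,
                           sampling_times_h = c(-4 / 3, 0.5, 1.5, 2.5, 3.5)) {
  sds <- c(sd_aquarium_intercept = sd_aquarium_intercept,
           sd_aquarium_slope = sd_aquarium_slope, sd_residual = sd_residual)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("cortisol_truth: SDs must be finite and >= 0", call. = FALSE)
  }
  if (any(diff(sampling_times_h) <= 0)) {
    stop("cortisol_truth: sampling_times_h must be strictly increasing",
         call. = FALSE)
  }
  structure(list(intercept_alpha = intercept_alpha,
                 zone_effect_beta = zone_effect_beta,
                 time_slope_beta_t = time_slope_beta_t,
                 zone_time_interaction = zone_time_interaction,
                 sd_aquarium_intercept = sd_aquarium_intercept,
                 sd_aquarium_slope = sd_aquarium_slope,
                 sd_residual = sd_residual,
                 sampling_times_h = sampling_times_h),
            class = "cortisol_truth")
}

#' Simulate a long-format cortisol table
#'
#' Per aquarium i (nested within trial) and sampling step t (0-based index):
#' `Y = (alpha + a_i) + beta_zone * Z + (beta_t + b_i) * t + eps`, with
#' `a_i`, `b_i` and `eps` Gaussian with the SDs in `truth`. Zones are CZ
#' (reference) and TZ.
#'
#' @param truth a [cortisol_truth()].
#' @param n_aquaria_per_zone aquaria per zone per trial, `>= 1`.
#' @param n_trials number of trials (default 2; the first two are labeled
#'   June and August).
#' @param seed RNG seed.
#' @return data frame: trial, aquarium, zone, time_h, time_index, cortisol.
#' @export
simulate_cortisol <- function(truth, n_aquaria_per_zone = 6L, n_trials = 2L,
                              seed = 1L) {
  stopifnot(inherits(truth, "cortisol_truth"))
  if (n_aquaria_per_zone < 1L) {
    stop("simulate_cortisol: n_aquaria_per_zone must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  trials <- if (n_trials <= 2L) c("June", "August")[seq_len(n_trials)] else
    sprintf("trial%d", seq_len(n_trials))
  tt <- truth$sampling_times_h
  t_idx <- seq_along(tt) - 1
  rows <- list()
  for (tr in trials) {
    for (zone in c("CZ", "TZ")) {
      for (a in seq_len(n_aquaria_per_zone)) {
        a_i <- truth$sd_aquarium_intercept * stats::rnorm(1)
        b_i <- truth$sd_aquarium_slope * stats::rnorm(1)
        eps <- truth$sd_residual * stats::rnorm(length(tt))
        y <- truth$intercept_alpha + a_i +
          truth$zone_effect_beta * (zone == "TZ") +
          (truth$time_slope_beta_t + b_i +
             truth$zone_time_interaction * (zone == "TZ")) * t_idx + eps
        rows[[length(rows) + 1L]] <- data.frame(
          trial = tr, aquarium = sprintf("%s%d", zone, a), zone = zone,
          time_h = tt, time_index = t_idx, cortisol = y)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generating parameters of the qPCR simulator
#'
#' Log-scale generative model per fish and gene: baseline + zone effect (TZ
#' only) + gene-specific trial intercept + fish residual; the two technical
#' duplicates jitter around the fish value with SD `sd_duplicate`.
#' Housekeeping genes (gapdh, 18S) default to a zero zone effect; the
#' target-gene defaults give mr and neurod1 clear tourism-zone upregulation
#' and gr/pcna weak effects.
#'
#' @param baseline_log named per-gene baseline log-expression (default 0).
#' @param zone_log_effect named per-gene tourism-zone log-effect.
#' @param sd_trial,sd_residual,sd_duplicate SDs, `>= 0`.
#' @return list of class `expression_truth`.
#' @export
expression_truth <- function(baseline_log = stats::setNames(
                               rep(0, length(canonical_genes)),
                               canonical_genes),
                             zone_log_effect = c(gr = 0.2, mr = 0.35,
                                                 neurod1 = 0.5, pcna = 0.15,
                                                 gapdh = 0, "18S" = 0),
                             sd_trial = 0.2, sd_residual = 0.4,
                             sd_duplicate = 0.05) {
  bad <- setdiff(union(names(baseline_log), names(zone_log_effect)),
                 canonical_genes)
  if (length(bad)) {
    stop("expression_truth: unknown gene name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sds <- c(sd_trial, sd_residual, sd_duplicate)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("expression_truth: SDs must be finite and >= 0", call. = FALSE)
  }
  base <- stats::setNames(rep(0, length(canonical_genes)), canonical_genes)
  base[names(baseline_log)] <- baseline_log
  eff <- stats::setNames(rep(0, length(canonical_genes)), canonical_genes)
  eff[names(zone_log_effect)] <- zone_log_effect
  structure(list(baseline_log = base, zone_log_effect = eff,
                 sd_trial = sd_trial, sd_residual = sd_residual,
                 sd_duplicate = sd_duplicate, genes = canonical_genes),
            class = "expression_truth")
}

#' Simulate a duplicate-well qPCR table
#'
#' @param truth an [expression_truth()].
#' @param n_fish_per_zone_trial fish per zone per trial (default 5).
#' @param n_trials number of trials (default 3: June, July, August).
#' @param seed RNG seed.
#' @return data frame: trial, zone, fish_id, gene, dup1, dup2 (instrument
#'   "standard quantity" units, strictly positive).
#' @export
simulate_expression <- function(truth, n_fish_per_zone_trial = 5L,
                                n_trials = 3L, seed = 1L) {
  stopifnot(inherits(truth, "expression_truth"))
  set.seed(seed)
  trials <- if (n_trials <= 3L) c("June", "July", "August")[seq_len(n_trials)]
  else sprintf("trial%d", seq_len(n_trials))
  rows <- list()
  for (tr in trials) {
    trial_fx <- stats::setNames(
      truth$sd_trial * stats::rnorm(length(truth$genes)), truth$genes)
    for (zone in c("CZ", "TZ")) {
      for (f in seq_len(n_fish_per_zone_trial)) {
        fid <- sprintf("%s_%s_f%d", tr, zone, f)
        for (g in truth$genes) {
          mu <- truth$baseline_log[[g]] +
            truth$zone_log_effect[[g]] * (zone == "TZ") + trial_fx[[g]] +
            truth$sd_residual * stats::rnorm(1)
          dups <- exp(mu + truth$sd_duplicate * stats::rnorm(2))
          rows[[length(rows) + 1L]] <- data.frame(
            trial = tr, zone = zone, fish_id = fid, gene = g,
            dup1 = dups[1], dup2 = dups[2])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to plain-text files
#'
#' Writes trajectory, body-length, cortisol and qPCR CSVs plus a JSON
#' sidecar recording the configuration and seeds.
#'
#' @param dir output directory (created if needed).
#' @param trajs optional list of [trajectory()] objects.
#' @param cortisol optional [simulate_cortisol()] table.
#' @param qpcr optional [simulate_expression()] table.
#' @param config optional list recorded verbatim in `config.json` (requires
#'   \pkg{jsonlite}).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(dir, trajs = NULL, cortisol = NULL, qpcr = NULL,
                             config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(trajs)) {
    frames <- do.call(rbind, lapply(trajs, function(tr) {
      cbind(data.frame(trial = tr$trial, aquarium = tr$aquarium,
                       zone = tr$zone, day = tr$day), tr$frames)
    }))
    fish <- unique(do.call(rbind, lapply(trajs, `[[`, "fish")))
    p1 <- file.path(dir, "trajectories.csv")
    p2 <- file.path(dir, "body_lengths.csv")
    utils::write.csv(frames, p1, row.names = FALSE)
    utils::write.csv(fish, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  if (!is.null(cortisol)) {
    p <- file.path(dir, "cortisol.csv")
    utils::write.csv(cortisol, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(qpcr)) {
    p <- file.path(dir, "qpcr.csv")
    utils::write.csv(qpcr, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(config)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("write_simulation: jsonlite required for the config sidecar",
           call. = FALSE)
    }
    p <- file.path(dir, "config.json")
    jsonlite::write_json(config, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
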