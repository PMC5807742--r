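# From per-frame positions to the behavioral measures: body-length-
# normalized speed, tank-mean activity around the stressor, thigmotaxis.

#' Construct a trajectory object
#'
#' One trajectory is one aquarium filmed on one experimental day: per-frame
#' positions of identified fish in tank coordinates, plus the fish body
#' lengths used to normalize speed.
#'
#' @param frames data frame with columns `fish_id`, `time_s`, `x_cm`,
#'   `y_cm`; time strictly increasing within fish at a fixed frame spacing.
#' @param fish data frame with columns `fish_id`, `body_length_mm` (> 0).
#' @param tank_width_cm,tank_height_cm tank dimensions (cm), required for
#'   any distance-to-center computation.
#' @param aquarium,zone,trial,day unit labels.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(frames, fish, tank_width_cm = NA_real_,
                       tank_height_cm = NA_real_, aquarium = NA, zone = NA,
                       trial = NA, day = NA) {
  req <- c("fish_id", "time_s", "x_cm", "y_cm")
  if (!all(req %in% names(frames))) {
    stop("trajectory: frames must contain ",
         paste(setdiff(req, names(frames)), collapse = ", "), call. = FALSE)
  }
  if (!all(c("fish_id", "body_length_mm") %in% names(fish))) {
    stop("trajectory: fish must contain fish_id and body_length_mm",
         call. = FALSE)
  }
  if (any(!is.finite(frames$x_cm)) || any(!is.finite(frames$y_cm))) {
    stop("trajectory: positions must be finite", call. = FALSE)
  }
  if (any(fish$body_length_mm <= 0)) {
    stop("trajectory: body lengths must be > 0", call. = FALSE)
  }
  structure(list(frames = frames, fish = fish,
                 tank_width_cm = tank_width_cm,
                 tank_height_cm = tank_height_cm,
                 aquarium = aquarium, zone = zone, trial = trial, day = day),
            class = "trajectory")
}

#' Per-fish swimming speed in % body length/s
#'
#' Speed at frame `t` is the Euclidean displacement from the previous frame,
#' divided by the frame interval and the fish's body length, times 100. The
#' first frame of each fish carries no speed. Frames separated by more than
#' `gap_tol` times the nominal interval are flagged as tracking gaps (`gap =
#' TRUE`); speed across a gap is still the raw chord speed and is never
#' interpolated, so gapped rows can be filtered by the caller.
#'
#' @param traj a [trajectory()].
#' @param smooth_width moving-average width in frames applied to each fish's
#'   speed series (default 1 = no smoothing).
#' @param gap_tol multiple of the nominal frame interval beyond which a
#'   frame-to-frame step is flagged as a gap.
#' @return data frame: `fish_id`, `time_s`, `speed_blps`, `gap`.
#' @export
compute_speed <- function(traj, smooth_width = 1L, gap_tol = 1.5) {
  stopifnot(inherits(traj, "trajectory"))
  bl <- stats::setNames(traj$fish$body_length_mm, traj$fish$fish_id)
  out <- lapply(split(traj$frames, traj$frames$fish_id), function(d) {
    if (nrow(d) < 2L) {
      stop("compute_speed: >= 2 frames per fish required", call. = FALSE)
    }
    d <- d[order(d$time_s), , drop = FALSE]
    dt <- diff(d$time_s)
    if (any(dt == 0)) {
      stop("compute_speed: zero frame interval", call. = FALSE)
    }
    nominal <- stats::median(dt)
    disp_mm <- 10 * sqrt(diff(d$x_cm)^2 + diff(d$y_cm)^2)
    v <- disp_mm / dt / bl[[as.character(d$fish_id[1])]] * 100
    if (smooth_width > 1L) {
      v <- stats::filter(v, rep(1 / smooth_width, smooth_width), sides = 2)
      v <- as.numeric(v)
    }
    data.frame(fish_id = d$fish_id[-1L], time_s = d$time_s[-1L],
               speed_blps = v, gap = dt > gap_tol * nominal)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tank-mean activity series around the stressor
#'
#' Frame-wise arithmetic mean of the per-fish speeds over the fish present
#' at each frame, restricted to the window from `pre_s` seconds before to
#' `post_s` seconds after the stressor. Times are re-expressed relative to
#' the stressor (stressor at 0).
#'
#' @param speeds output of [compute_speed()].
#' @param stress_time_s stressor onset on the recording clock (s).
#' @param pre_s,post_s window half-widths in seconds (defaults 10 and 40).
#' @param unit optional list of unit labels (aquarium, day, zone, trial).
#' @return an [activity_series()].
#' @export
tank_mean_activity <- function(speeds, stress_time_s, pre_s = 10,
                               post_s = 40, unit = list()) {
  t_rel <- speeds$time_s - stress_time_s
  keep <- t_rel >= -pre_s & t_rel <= post_s & is.finite(speeds$speed_blps)
  if (!any(keep)) {
    stop("tank_mean_activity: requested window contains no frames",
         call. = FALSE)
  }
  if (min(speeds$time_s) > stress_time_s - pre_s ||
      max(speeds$time_s) < stress_time_s + post_s) {
    stop("tank_mean_activity: window [", -pre_s, ", ", post_s,
         "] s exceeds the recording", call. = FALSE)
  }
  d <- speeds[keep, , drop = FALSE]
  tr <- round(d$time_s - stress_time_s, 9)
  mean_v <- tapply(d$speed_blps, tr, mean)
  n_fish <- tapply(d$speed_blps, tr, length)
  tt <- as.numeric(names(mean_v))
  o <- order(tt)
  activity_series(tt[o], as.numeric(mean_v)[o], as.integer(n_fish)[o],
                  aquarium = unit$aquarium %||% NA, day = unit$day %||% NA,
                  zone = unit$zone %||% NA, trial = unit$trial %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thigmotaxis: mean distance to the tank center
#'
#' Pools all fish positions over all frames of the window (by default the
#' 10 minutes before the stressor) and averages the Euclidean distance to
#' the geometric center of the tank rectangle. Larger values mean fish stay
#' closer to the walls. Set `per_fish_first = TRUE` to average within fish
#' before averaging across fish.
#'
#' @param traj a [trajectory()] with tank dimensions set.
#' @param window two-element numeric, window on the recording clock in
#'   seconds; default `c(stress_time_s - 600, stress_time_s)` when
#'   `stress_time_s` is given, otherwise the whole recording.
#' @param stress_time_s stressor onset (s), used for the default window.
#' @param per_fish_first average per fish before pooling (default FALSE:
#'   every position of every fish counts equally).
#' @return list of class `thigmotaxis_summary`: `mean_dist_cm`, `n_positions`,
#'   `window`, unit labels.
#' @export
thigmotaxis <- function(traj, window = NULL, stress_time_s = NULL,
                        per_fish_first = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.finite(traj$tank_width_cm) || !is.finite(traj$tank_height_cm)) {
    stop("thigmotaxis: tank dimensions unknown, center undefined",
         call. = FALSE)
  }
  if (is.null(window)) {
    window <- if (is.null(stress_time_s)) {
      range(traj$frames$time_s)
    } else {
      c(stress_time_s - 600, stress_time_s)
    }
  }
  d <- traj$frames[traj$frames$time_s >= window[1] &
                     traj$frames$time_s <= window[2], , drop = FALSE]
  if (nrow(d) == 0) {
    stop("thigmotaxis: window contains no frames", call. = FALSE)
  }
  cx <- traj$tank_width_cm / 2
  cy <- traj$tank_height_cm / 2
  dist <- sqrt((d$x_cm - cx)^2 + (d$y_cm - cy)^2)
  m <- if (per_fish_first) {
    mean(tapply(dist, d$fish_id, mean))
  } else {
    mean(dist)
  }
  structure(list(mean_dist_cm = m, n_positions = nrow(d), window = window,
                 aquarium = traj$aquarium, zone = traj$zone,
                 trial = traj$trial, day = traj$day),
            class = "thigmotaxis_summary")
}

#' Behavioral feature table for a set of trajectories
#'
#' Convenience wrapper running [compute_speed()], [tank_mean_activity()],
#' [nls_fit()] and [thigmotaxis()] over a list of trajectories, returning
#' one row per aquarium-day with the freeze features and thigmotaxis.
#'
#' @param trajs list of [trajectory()] objects.
#' @param stress_time_s stressor onset on the recording clock (s).
#' @param pre_s,post_s activity window, as [tank_mean_activity()].
#' @param skip_s seconds excluded from the start of the freeze fit
#'   (default 10, the stressor duration: the flight transient during the
#'   mechanical stress is not part of the freeze-recovery episode).
#' @return list with `fits` (the [nls_fit()] objects) and `features`
#'   (data frame with freeze features and `thigmotaxis_cm`).
#' @export
behavior_features <- function(trajs, stress_time_s, pre_s = 10, post_s = 40,
                              skip_s = 10) {
  fits <- vector("list", length(trajs))
  thig <- numeric(length(trajs))
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    sp <- compute_speed(tr)
    act <- tank_mean_activity(sp, stress_time_s, pre_s, post_s,
                              unit = list(aquarium = tr$aquarium,
                                          day = tr$day, zone = tr$zone,
                                          trial = tr$trial))
    fits[[i]] <- nls_fit(act, skip_s = skip_s)
    thig[i] <- thigmotaxis(tr, stress_time_s = stress_time_s)$mean_dist_cm
  }
  tab <- fits_to_table(fits)
  tab$thigmotaxis_cm <- thig
  list(fits = fits, features = tab)
}
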