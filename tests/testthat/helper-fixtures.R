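# Shared fixtures, built in code.

# noiseless activity series generated from known curve parameters
make_series <- function(p, pre_s = 10, post_s = 40, dt = 0.1,
                        baseline = p$y_max, noise_sd = 0, unit = list()) {
  x <- seq(-pre_s, post_s, by = dt)
  y <- ifelse(x < 0, baseline, weibull_recovery(pmax(x, 0), p))
  if (noise_sd > 0) y <- pmax(y + stats::rnorm(length(y), 0, noise_sd), 0)
  activity_series(x, y,
                  aquarium = unit$aquarium %||% NA, day = unit$day %||% NA,
                  zone = unit$zone %||% NA, trial = unit$trial %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random valid curve parameters spanning realistic magnitudes
random_params <- function(n) {
  lapply(seq_len(n), function(i) {
    k <- stats::runif(1, 0.5, 5)
    lam <- stats::runif(1, 2, 60)
    y_max <- stats::runif(1, 50, 300)
    alpha <- stats::runif(1, 10, 3000)
    t_min <- stats::runif(1, 0, 10)
    weibull_params(y_max, alpha, k, lam, t_min)
  })
}

# minimal stationary trajectory: fish fixed at given positions
fixed_trajectory <- function(positions, body_length_mm = 25,
                             tank = c(40, 25), n_frames = 5, dt = 0.1) {
  frames <- do.call(rbind, lapply(seq_len(nrow(positions)), function(i) {
    data.frame(fish_id = sprintf("f%d", i),
               time_s = seq(0, by = dt, length.out = n_frames),
               x_cm = positions[i, 1], y_cm = positions[i, 2])
  }))
  fish <- data.frame(fish_id = sprintf("f%d", seq_len(nrow(positions))),
                     body_length_mm = body_length_mm)
  trajectory(frames, fish, tank_width_cm = tank[1], tank_height_cm = tank[2])
}

# exact 4PL responses for the assay's standard ladder
standard_ladder <- function(a = 2, d = 0.1, c0 = 60, b = 1.2,
                            conc = 3.9 * 2^(0:8)) {
  list(conc = conc, response = d + (a - d) / (1 + (conc / c0)^b),
       a = a, d = d, c0 = c0, b = b)
}
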