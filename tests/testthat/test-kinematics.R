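test_that("speed converts displacement to % body length per second", {
  # 5 mm per frame at 10 Hz with a 25 mm fish: 50 mm/s / 25 mm = 200 %BL/s
  frames <- data.frame(fish_id = "f1", time_s = seq(0, 0.5, by = 0.1),
                       x_cm = 0.5 * (0:5), y_cm = 0)
  tr <- trajectory(frames, data.frame(fish_id = "f1", body_length_mm = 25))
  sp <- compute_speed(tr)
  expect_equal(sp$speed_blps, rep(200, 5))
})

test_that("a stationary fish has zero speed everywhere", {
  tr <- fixed_trajectory(matrix(c(10, 10), 1))
  expect_equal(compute_speed(tr)$speed_blps, rep(0, 4))
})

test_that("zero frame interval is an error", {
  frames <- data.frame(fish_id = "f1", time_s = c(0, 0, 0.1),
                       x_cm = 1:3, y_cm = 0)
  tr <- trajectory(frames, data.frame(fish_id = "f1", body_length_mm = 25))
  expect_error(compute_speed(tr), "zero frame interval")
})

test_that("tracking gaps are flagged, not interpolated", {
  frames <- data.frame(fish_id = "f1", time_s = c(0, 0.1, 0.2, 0.6, 0.7),
                       x_cm = c(0, 1, 2, 3, 4), y_cm = 0)
  tr <- trajectory(frames, data.frame(fish_id = "f1", body_length_mm = 25))
  sp <- compute_speed(tr)
  expect_equal(sp$gap, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(nrow(sp), 4)
})

test_that("programmed constant speed survives the simulator round trip", {
  cfg <- sim_config(seed = 17, n_aquaria_per_zone = 1, fish_per_aquarium = 4,
                    n_days = 1, duration_s = 60, stress_time_s = 30,
                    speed_noise_sd = 0, flight_gain = 1,
                    weibull_truth = weibull_params(150, 0, 2, 10, 0),
                    baseline_speed_blps = 150)
  tr <- simulate_trajectories(cfg)[[1]]
  sp <- compute_speed(tr)
  expect_lt(max(abs(sp$speed_blps - 150)), 1e-9)
})

test_that("speed is invariant to rigid translation of coordinates", {
  set.seed(12)
  frames <- data.frame(fish_id = "f1", time_s = seq(0, 1, 0.1),
                       x_cm = cumsum(runif(11)), y_cm = cumsum(runif(11)))
  tr1 <- trajectory(frames, data.frame(fish_id = "f1", body_length_mm = 20))
  frames2 <- transform(frames, x_cm = x_cm + 7, y_cm = y_cm - 3)
  tr2 <- trajectory(frames2, data.frame(fish_id = "f1", body_length_mm = 20))
  expect_equal(compute_speed(tr1)$speed_blps, compute_speed(tr2)$speed_blps)
})

test_that("tank mean is the arithmetic mean over fish present", {
  frames <- rbind(
    data.frame(fish_id = "f1", time_s = seq(0, 2, 0.1),
               x_cm = seq(0, 2, 0.1) * 2.5, y_cm = 0),   # 100 %BL/s
    data.frame(fish_id = "f2", time_s = seq(0, 2, 0.1),
               x_cm = seq(0, 2, 0.1) * 7.5, y_cm = 0))   # 300 %BL/s
  tr <- trajectory(frames, data.frame(fish_id = c("f1", "f2"),
                                      body_length_mm = 25))
  act <- tank_mean_activity(compute_speed(tr), stress_time_s = 1,
                            pre_s = 0.5, post_s = 0.5)
  expect_equal(act$speed_blps, rep(200, nrow(act)))
  expect_equal(act$n_fish, rep(2L, nrow(act)))
  expect_equal(range(act$time_s), c(-0.5, 0.5))
})

test_that("a window exceeding the recording is an error", {
  tr <- fixed_trajectory(matrix(c(10, 10), 1), n_frames = 20)
  sp <- compute_speed(tr)
  expect_error(tank_mean_activity(sp, stress_time_s = 1, pre_s = 10,
                                  post_s = 40),
               "exceeds the recording")
})

test_that("tank-mean activity of identical fish equals a single fish's speed", {
  cfg <- sim_config(seed = 4, n_aquaria_per_zone = 1, fish_per_aquarium = 5,
                    n_days = 1, duration_s = 60, stress_time_s = 30,
                    speed_noise_sd = 5, body_length_mm_sd = 0)
  tr <- simulate_trajectories(cfg)[[1]]
  sp <- compute_speed(tr)
  act <- tank_mean_activity(sp, 30, pre_s = 5, post_s = 20)
  one <- sp[sp$fish_id == sp$fish_id[1], ]
  one <- one[one$time_s >= 25 & one$time_s <= 50, ]
  expect_equal(act$speed_blps, one$speed_blps, tolerance = 1e-9)
})

test_that("thigmotaxis is zero at the center and exact off-center", {
  tr0 <- fixed_trajectory(matrix(c(20, 12.5), 1))
  expect_equal(thigmotaxis(tr0, window = c(0, 1))$mean_dist_cm, 0)
  tr5 <- fixed_trajectory(matrix(c(25, 12.5), 1))
  expect_equal(thigmotaxis(tr5, window = c(0, 1))$mean_dist_cm, 5)
})

test_that("distance to center is invariant to reflection about tank axes", {
  set.seed(3)
  pos <- cbind(runif(6, 0, 40), runif(6, 0, 25))
  tr <- fixed_trajectory(pos)
  tr_rx <- fixed_trajectory(cbind(40 - pos[, 1], pos[, 2]))
  tr_ry <- fixed_trajectory(cbind(pos[, 1], 25 - pos[, 2]))
  d <- thigmotaxis(tr, window = c(0, 1))$mean_dist_cm
  expect_equal(thigmotaxis(tr_rx, window = c(0, 1))$mean_dist_cm, d)
  expect_equal(thigmotaxis(tr_ry, window = c(0, 1))$mean_dist_cm, d)
})

test_that("thigmotaxis requires known tank dimensions", {
  frames <- data.frame(fish_id = "f1", time_s = c(0, 0.1), x_cm = 1, y_cm = 1)
  tr <- trajectory(frames, data.frame(fish_id = "f1", body_length_mm = 25))
  expect_error(thigmotaxis(tr, window = c(0, 1)), "center undefined")
})

test_that("wall attraction pushes the position distribution outward", {
  one_dist <- function(seed, bias) {
    cfg <- sim_config(seed = seed, n_aquaria_per_zone = 1,
                      fish_per_aquarium = 4, n_days = 1, duration_s = 60,
                      stress_time_s = 59, flight_gain = 1,
                      thigmotaxis_bias = bias,
                      weibull_truth = weibull_params(200, 0, 2, 10, 0))
    tr <- simulate_trajectories(cfg)[[1]]
    thigmotaxis(tr, window = c(20, 59))$mean_dist_cm
  }
  n_rep <- 20
  wins <- sum(vapply(seq_len(n_rep), function(s) {
    one_dist(1000 + s, 0.8) > one_dist(2000 + s, 0)
  }, logical(1)))
  expect_gte(wins, n_rep - 1)
})

test_that("unbiased walk approaches the uniform distance-to-center mean", {
  cfg <- sim_config(seed = 5, n_aquaria_per_zone = 1, fish_per_aquarium = 10,
                    n_days = 1, duration_s = 600, stress_time_s = 599,
                    thigmotaxis_bias = 0, flight_gain = 1,
                    weibull_truth = weibull_params(200, 0, 2, 10, 0))
  tr <- simulate_trajectories(cfg)[[1]]
  obs <- thigmotaxis(tr, window = c(100, 599))$mean_dist_cm
  # uniform expectation over the 40 x 25 rectangle by numeric integration
  xs <- seq(0, 40, length.out = 201)
  ys <- seq(0, 25, length.out = 201)
  expected <- mean(outer(xs, ys, function(x, y)
    sqrt((x - 20)^2 + (y - 12.5)^2)))
  expect_lt(abs(obs - expected) / expected, 0.10)
})
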