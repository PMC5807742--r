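test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(duration_s = -5), "duration_s")
  expect_error(sim_config(frame_rate_hz = 0), "frame_rate_hz")
  expect_error(sim_config(stress_time_s = 2000), "stress_time_s")
  expect_error(sim_config(thigmotaxis_bias = 1.4), "thigmotaxis_bias")
  expect_error(sim_config(flight_gain = 0.5), "flight_gain")
})

test_that("identical seeds reproduce byte-identical trajectories", {
  cfg <- sim_config(seed = 9, n_aquaria_per_zone = 1, fish_per_aquarium = 3,
                    n_days = 1, duration_s = 20, stress_time_s = 10)
  t1 <- simulate_trajectories(cfg)
  t2 <- simulate_trajectories(cfg)
  expect_identical(t1, t2)
  cfg2 <- sim_config(seed = 10, n_aquaria_per_zone = 1, fish_per_aquarium = 3,
                     n_days = 1, duration_s = 20, stress_time_s = 10)
  t3 <- simulate_trajectories(cfg2)
  expect_false(identical(t1[[1]]$frames$x_cm, t3[[1]]$frames$x_cm))
})

test_that("all simulated positions stay inside the tank", {
  cfg <- sim_config(seed = 2, n_aquaria_per_zone = 1, fish_per_aquarium = 8,
                    n_days = 1, duration_s = 60, stress_time_s = 30,
                    thigmotaxis_bias = c(CZ = 0.9, TZ = 0.9))
  for (tr in simulate_trajectories(cfg)) {
    expect_gte(min(tr$frames$x_cm), 0)
    expect_lte(max(tr$frames$x_cm), cfg$tank_width_cm)
    expect_gte(min(tr$frames$y_cm), 0)
    expect_lte(max(tr$frames$y_cm), cfg$tank_height_cm)
  }
})

test_that("null envelope and no noise give baseline speed at every frame", {
  cfg <- sim_config(seed = 3, n_aquaria_per_zone = 1, fish_per_aquarium = 3,
                    n_days = 1, duration_s = 40, stress_time_s = 20,
                    flight_gain = 1, speed_noise_sd = 0,
                    weibull_truth = weibull_params(200, 0, 2, 10, 0))
  tr <- simulate_trajectories(cfg)[[1]]
  act <- tank_mean_activity(compute_speed(tr), 20, pre_s = 10, post_s = 15)
  expect_lt(max(abs(act$speed_blps - 200)), 1e-9)
})

test_that("a deeper generating envelope yields a lower realized minimum", {
  deep <- weibull_params(200, 1600, 2, 10, 0)
  shallow <- weibull_params(200, 800, 2, 10, 0)
  min_of <- function(seed, p) {
    cfg <- sim_config(seed = seed, n_aquaria_per_zone = 1, n_days = 1,
                      weibull_truth = list(CZ = shallow, TZ = p),
                      speed_noise_sd = 10)
    acts <- simulate_activity(cfg)
    zones <- vapply(acts, function(a) attr(a, "unit")$zone, character(1))
    vapply(acts[zones == "TZ"], function(a)
      min(a$speed_blps[a$time_s >= 5]), numeric(1))
  }
  n_rep <- 30
  deep_mins <- vapply(seq_len(n_rep),
                      function(s) mean(min_of(s, deep)), numeric(1))
  shal_mins <- vapply(seq_len(n_rep),
                      function(s) mean(min_of(400 + s, shallow)), numeric(1))
  expect_lt(mean(deep_mins), mean(shal_mins))
  gap_truth <- freeze_features(shallow)$freezing_intensity -
    freeze_features(deep)$freezing_intensity
  expect_gt(gap_truth, 0)
})

test_that("noiseless cortisol is exactly additive in its effects", {
  tr0 <- cortisol_truth(sd_aquarium_intercept = 0, sd_aquarium_slope = 0,
                        sd_residual = 0)
  tab <- simulate_cortisol(tr0, 2, 1, seed = 1)
  cz <- tab[tab$zone == "CZ", ]
  tz <- tab[tab$zone == "TZ", ]
  expect_equal(cz$cortisol,
               tr0$intercept_alpha + tr0$time_slope_beta_t * cz$time_index)
  expect_equal(tz$cortisol - cz$cortisol,
               rep(tr0$zone_effect_beta, nrow(tz)))
})

test_that("cortisol residual variance matches the generating SD", {
  tr0 <- cortisol_truth(sd_aquarium_intercept = 0, sd_aquarium_slope = 0,
                        sd_residual = 0.5, zone_effect_beta = 0)
  tab <- simulate_cortisol(tr0, 100, 1, seed = 8)
  resid <- tab$cortisol -
    (tr0$intercept_alpha + tr0$time_slope_beta_t * tab$time_index)
  expect_gt(length(resid), 900)
  expect_lt(abs(stats::var(resid) - 0.25) / 0.25, 0.10)
})

test_that("cortisol simulation rejects an empty design", {
  expect_error(simulate_cortisol(cortisol_truth(), 0), ">= 1")
})

test_that("expression truth rejects unknown gene names", {
  expect_error(expression_truth(zone_log_effect = c(actb = 1)), "actb")
})

test_that("noise-free expression is identical across zones", {
  et <- expression_truth(zone_log_effect = c(mr = 0), sd_trial = 0,
                         sd_residual = 0, sd_duplicate = 0)
  et$zone_log_effect[] <- 0
  q <- simulate_expression(et, 3, 2, seed = 1)
  cz <- q[q$zone == "CZ", ]
  tz <- q[q$zone == "TZ", ]
  expect_equal(cz$dup1, tz$dup1)
  expect_equal(q$dup1, q$dup2)
})

test_that("detection power of a zone effect grows with effect size", {
  rate_for <- function(effect, n_sims = 25) {
    hits <- vapply(seq_len(n_sims), function(s) {
      et <- expression_truth(zone_log_effect = c(mr = effect))
      q <- simulate_expression(et, 5, 3, seed = 5000 + s)
      g <- suppressWarnings(analyze_gene(expression_table(q), genes = "mr"))
      g$p < 0.05
    }, logical(1))
    mean(hits)
  }
  expect_gt(rate_for(1.2), rate_for(0))
})

test_that("written simulation files round-trip through CSV", {
  tmp <- tempfile("sim")
  tab <- simulate_cortisol(cortisol_truth(), 2, 1, seed = 3)
  q <- simulate_expression(expression_truth(), 2, 2, seed = 3)
  paths <- write_simulation(tmp, cortisol = tab, qpcr = q,
                            config = list(seed = 3))
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(tmp, "cortisol.csv"))
  expect_equal(back$cortisol, tab$cortisol, tolerance = 1e-12)
  unlink(tmp, recursive = TRUE)
})
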