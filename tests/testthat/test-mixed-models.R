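test_that("the AIC identity holds for every fitted candidate", {
  tab <- simulate_cortisol(cortisol_truth(), 4, 2, seed = 31)
  tab <- stressphen:::prepare_response_table(tab, "time_h")
  cmp <- suppressWarnings(compare_four_models(tab, "cortisol",
                                              grouping = "aquarium_in_trial"))
  for (f in cmp$fits) {
    expect_equal(f$aic, 2 * f$n_par - 2 * f$logLik, tolerance = 1e-12)
  }
})

test_that("ML log-likelihood is monotone in nested fixed effects", {
  tab <- simulate_cortisol(cortisol_truth(), 4, 2, seed = 32)
  tab <- stressphen:::prepare_response_table(tab, "time_h")
  cmp <- suppressWarnings(compare_four_models(tab, "cortisol",
                                              grouping = "aquarium_in_trial"))
  # interaction nests additive at equal random structure
  expect_gte(cmp$fits$model2$logLik, cmp$fits$model1$logLik - 1e-6)
  if (!is.null(cmp$fits$model4) && !is.null(cmp$fits$model3)) {
    expect_gte(cmp$fits$model4$logLik, cmp$fits$model3$logLik - 1e-6)
  }
})

test_that("equal likelihoods select the model with fewer parameters", {
  # an interaction effect of exactly zero: model2 can do no better than
  # model1, so the parsimony rule must keep the additive candidate
  tr0 <- cortisol_truth(sd_aquarium_slope = 0)
  tab <- simulate_cortisol(tr0, 6, 2, seed = 33)
  cmp <- suppressWarnings(analyze_cortisol(tab, "pooled"))$comparisons$pooled
  sel <- cmp$table[cmp$table$selected, ]
  tied <- cmp$table[!is.na(cmp$table$aic) &
                      cmp$table$aic - min(cmp$table$aic, na.rm = TRUE) < 2, ]
  expect_equal(sel$n_par, min(tied$n_par))
})

test_that("a noiseless linear response is fitted exactly", {
  d <- expand.grid(aquarium = sprintf("a%d", 1:6), time = 0:4)
  d$trial <- "June"
  d$zone <- factor(ifelse(d$aquarium %in% sprintf("a%d", 1:3), "CZ", "TZ"))
  d$y <- 2 + 3 * d$time + 0.7 * (d$zone == "TZ")
  spec <- model_spec("y", fixed = "additive", random = "intercept",
                     grouping = "aquarium", method = "ML")
  f <- suppressWarnings(fit_lmm(d, spec))
  est <- f$fixed$estimate[match(c("(Intercept)", "zoneTZ", "time"),
                                f$fixed$term)]
  expect_equal(est, c(2, 0.7, 3), tolerance = 1e-6)
  expect_lt(f$varcor$variance[f$varcor$group == "Residual"], 1e-10)
})

test_that("with zero group variance the t statistic matches ordinary OLS", {
  set.seed(44)
  d <- data.frame(aquarium = rep(sprintf("a%d", 1:8), each = 5),
                  zone = factor(rep(c("CZ", "TZ"), each = 20)),
                  time = rep(0:4, 8))
  # no aquarium effect at all: the mixed model hits the boundary
  d$y <- 1 + 0.5 * (d$zone == "TZ") + 0.1 * d$time + rnorm(40, 0, 1)
  spec <- model_spec("y", fixed = "additive", random = "intercept",
                     grouping = "aquarium", method = "REML")
  f <- suppressWarnings(fit_lmm(d, spec))
  ols <- summary(stats::lm(y ~ zone + time, d))$coefficients
  if (f$singular) {
    expect_equal(f$fixed$t[f$fixed$term == "zoneTZ"],
                 ols["zoneTZ", "t value"], tolerance = 1e-4)
  } else {
    succeed("group variance not at boundary for this draw")
  }
})

test_that("boundary variance is reported, not treated as failure", {
  tr0 <- cortisol_truth(sd_aquarium_intercept = 0, sd_aquarium_slope = 0)
  tab <- simulate_cortisol(tr0, 6, 1, seed = 5)
  a <- suppressWarnings(analyze_cortisol(tab, "pooled"))
  cmp <- a$comparisons$pooled
  expect_true(any(cmp$table$singular, na.rm = TRUE))
  expect_true(cmp$selected %in% cmp$table$model)
})

test_that("singular fixed designs fail with the collinear term named", {
  d <- data.frame(aquarium = rep(c("a1", "a2"), each = 4),
                  zone = factor(rep(c("CZ", "TZ"), each = 4)),
                  time = 1, trial = "June",
                  y = rnorm(8))
  spec <- model_spec("y", fixed = "additive", random = "intercept",
                     grouping = "aquarium", method = "ML")
  expect_error(fit_lmm(d, spec), "collinear")
})

test_that("a noiseless zone offset is estimated exactly", {
  tr0 <- cortisol_truth(sd_aquarium_intercept = 0, sd_aquarium_slope = 0,
                        sd_residual = 0, zone_effect_beta = 0.42)
  tab <- simulate_cortisol(tr0, 3, 2, seed = 1)
  tab$cortisol <- tab$cortisol + rnorm(nrow(tab), 0, 1e-8)
  a <- suppressWarnings(analyze_cortisol(tab, "pooled"))
  fe <- a$fixed_effects$pooled
  expect_equal(fe$estimate[fe$term == "zoneTZ"], 0.42, tolerance = 1e-5)
})

test_that("per-trial cortisol analyses use aquarium grouping", {
  tab <- simulate_cortisol(cortisol_truth(), 4, 2, seed = 3)
  a <- suppressWarnings(analyze_cortisol(tab, "per_trial"))
  expect_setequal(names(a$comparisons), c("June", "August"))
  fe <- a$fixed_effects$June
  expect_true("zoneTZ" %in% fe$term)
})

test_that("behavior analysis with a single day drops the time term", {
  p_cz <- weibull_params(200, 1220, 2, 10, 0)
  p_tz <- weibull_params(200, 1464, 2, 10, 0)
  cfg <- sim_config(seed = 6, n_aquaria_per_zone = 3, n_days = 1,
                    weibull_truth = list(CZ = p_cz, TZ = p_tz))
  acts <- simulate_activity(cfg)
  fits <- lapply(acts, nls_fit, skip_s = 10)
  tab <- fits_to_table(fits)
  expect_warning(a <- analyze_behavior(tab, "freezing_intensity"),
                 "time term dropped")
  fe <- a$fixed_effects$pooled
  expect_false("time" %in% fe$term)
  expect_true("zoneTZ" %in% fe$term)
})

test_that("gene analysis requires at least two trials", {
  q <- simulate_expression(expression_truth(), 3, 3, seed = 9)
  ex <- expression_table(q)
  expect_error(analyze_gene(ex[ex$trial == "June", ]), ">= 2 trials")
})

test_that("AIC selection favors the generating structure class", {
  n_sims <- 30
  add_hits <- 0
  int_hits <- 0
  for (s in seq_len(n_sims)) {
    tab_a <- simulate_cortisol(cortisol_truth(sd_aquarium_slope = 0.02),
                               6, 2, seed = 6000 + s)
    cmp_a <- suppressWarnings(analyze_cortisol(tab_a, "pooled"))
    sel_a <- cmp_a$comparisons$pooled$selected
    add_hits <- add_hits + (sel_a %in% c("model1", "model3"))
    tab_i <- simulate_cortisol(
      cortisol_truth(zone_time_interaction = 0.4, sd_aquarium_slope = 0.02),
      6, 2, seed = 7000 + s)
    cmp_i <- suppressWarnings(analyze_cortisol(tab_i, "pooled"))
    sel_i <- cmp_i$comparisons$pooled$selected
    int_hits <- int_hits + (sel_i %in% c("model2", "model4"))
  }
  expect_gte(add_hits / n_sims, 0.8)
  expect_gte(int_hits / n_sims, 0.8)
})
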