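test_that("an exact 4PL ladder is recovered to high precision", {
  sl <- standard_ladder()
  cv <- fit_standard_curve(sl$conc, sl$response)
  expect_equal(cv$a, sl$a, tolerance = 1e-6)
  expect_equal(cv$d, sl$d, tolerance = 1e-6)
  expect_equal(cv$c0, sl$c0, tolerance = 1e-6)
  expect_equal(cv$b, sl$b, tolerance = 1e-6)
})

test_that("too few or non-monotone standards are rejected", {
  sl <- standard_ladder(conc = c(10, 100, 1000))
  expect_error(fit_standard_curve(sl$conc, sl$response), ">= 4")
  resp <- c(2, 1.5, 1.7, 1.0, 0.5)
  expect_error(fit_standard_curve(c(4, 8, 16, 32, 64), resp), "monotone")
})

test_that("the midpoint response back-calculates to the inflection", {
  sl <- standard_ladder()
  cv <- fit_standard_curve(sl$conc, sl$response)
  mid <- (cv$a + cv$d) / 2
  inv <- invert_standard_curve(mid, cv)
  expect_equal(inv$conc, cv$c0, tolerance = 1e-6)
})

test_that("quantification applies the volume chain arithmetic", {
  sl <- standard_ladder()
  cv <- fit_standard_curve(sl$conc, sl$response)
  resp100 <- sl$d + (sl$a - sl$d) / (1 + (100 / sl$c0)^sl$b)
  q <- quantify(resp100, cv)
  expect_equal(q$conc_pg_well, 100, tolerance = 1e-6)
  # 100 pg/50 ul * (300/50) / 0.5 L = 1200 pg/L = 1.2 ng/L
  expect_equal(q$ng_per_l, 1.2, tolerance = 1e-6)
})

test_that("responses outside the calibrated span are censored", {
  sl <- standard_ladder()
  cv <- fit_standard_curve(sl$conc, sl$response)
  resp_low <- sl$d + (sl$a - sl$d) / (1 + (1 / sl$c0)^sl$b)   # below 3.9 pg
  resp_high <- sl$d + (sl$a - sl$d) / (1 + (5000 / sl$c0)^sl$b)
  q <- quantify(c(resp_low, resp_high), cv)
  expect_equal(q$censored, c("below", "above"))
  expect_true(all(is.na(q$ng_per_l)))
})

test_that("a sample and its dilution agree after dilution correction", {
  sl <- standard_ladder()
  cv <- fit_standard_curve(sl$conc, sl$response)
  r_full <- sl$d + (sl$a - sl$d) / (1 + (200 / sl$c0)^sl$b)
  r_half <- sl$d + (sl$a - sl$d) / (1 + (100 / sl$c0)^sl$b)
  q_full <- quantify(r_full, cv, dilution = 1)
  q_half <- quantify(r_half, cv, dilution = 2)
  expect_equal(q_full$ng_per_l, q_half$ng_per_l, tolerance = 1e-6)
})

test_that("ideal parallel dilutions give slope ratio 1, doubled slope 2", {
  sl <- standard_ladder()
  cv <- fit_standard_curve(sl$conc, sl$response)
  dil <- c(1, 2, 4, 8, 16)
  pooled <- 400
  r_par <- sl$d + (sl$a - sl$d) / (1 + ((pooled / dil) / sl$c0)^sl$b)
  pc <- parallelism_check(dil, r_par, cv)
  expect_equal(pc$ratio, 1, tolerance = 1e-9)
  expect_true(pc$pass)
  r_steep <- sl$d + (sl$a - sl$d) /
    (1 + ((pooled / dil) / sl$c0)^(2 * sl$b))
  pc2 <- parallelism_check(dil, r_steep, cv)
  expect_equal(pc2$ratio, 2, tolerance = 1e-9)
  expect_false(pc2$pass)
  expect_error(parallelism_check(c(1, 2), r_par[1:2], cv), ">= 3")
})

test_that("noisy parallel dilutions stay near ratio 1", {
  sl <- standard_ladder()
  cv <- fit_standard_curve(sl$conc, sl$response)
  dil <- c(1, 2, 4, 8, 16)
  r_par <- sl$d + (sl$a - sl$d) / (1 + ((400 / dil) / sl$c0)^sl$b)
  set.seed(61)
  ratios <- replicate(100, {
    r <- r_par * (1 + stats::rnorm(length(r_par), 0, 0.02))
    r <- pmin(pmax(r, sl$d + 1e-4), sl$a - 1e-4)
    parallelism_check(dil, r, cv)$ratio
  })
  expect_gte(mean(ratios >= 0.9 & ratios <= 1.1), 0.95)
})

test_that("duplicate CVs follow sd/mean with the 10% gate", {
  qc <- cv_qc(c(100, 90), c(100, 110))
  expect_equal(qc$intra$cv, c(0, 14.142136 / 100), tolerance = 1e-6)
  expect_equal(qc$intra$pass, c(TRUE, FALSE))
  expect_false(qc$intra_pass)
  qc2 <- cv_qc(c(50, 80), c(50, 80))
  expect_true(qc2$intra_pass)
})

test_that("inter-assay CV uses the per-plate control means", {
  qc <- cv_qc(dup1 = c(100, 105, 95, 5), dup2 = c(100, 105, 95, 5),
              plate = c("p1", "p2", "p3", "p3"),
              is_control = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(qc$inter_cv, stats::sd(c(100, 105, 95)) / 100)
  expect_true(qc$inter_pass)
})

test_that("length normalization divides by the summed body length", {
  # 120 ng/L over 17 fish totaling 400 mm -> 0.3 ng/L/mm
  lengths <- rep(400 / 17, 17)
  expect_equal(normalize_cortisol(120, lengths), 0.3)
  expect_equal(normalize_cortisol(120, lengths * 2),
               normalize_cortisol(120, lengths) / 2)
  expect_equal(normalize_cortisol(c(120, 240), lengths),
               c(0.3, 0.6))
  expect_equal(normalize_cortisol(120, lengths, denominator = "mean"),
               120 / (400 / 17))
  expect_error(normalize_cortisol(120, c(10, 0)), "> 0")
})

test_that("quantify inverts the fitted curve within the calibrated span", {
  sl <- standard_ladder()
  cv <- fit_standard_curve(sl$conc, sl$response)
  conc <- c(5, 20, 80, 320, 900)
  resp <- sl$d + (sl$a - sl$d) / (1 + (conc / sl$c0)^sl$b)
  q <- quantify(resp, cv)
  expect_equal(q$conc_pg_well, conc, tolerance = 1e-6)
  expect_true(all(q$censored == "none"))
})
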