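# Waterborne cortisol quantification: 4-parameter logistic standard curve,
# back-calculation with volume scaling, parallelism and CV quality control,
# and normalization to ng per liter per mm of fish.

logistic4 <- function(conc, a, d, c0, b) {
  d + (a - d) / (1 + (conc / c0)^b)
}

#' Fit a four-parameter logistic standard curve
#'
#' `R(c) = d + (a - d) / (1 + (c / c0)^b)`: `a` is the zero-dose asymptote,
#' `d` the infinite-dose asymptote, `c0` the inflection concentration and
#' `b` the slope. For a competitive immunoassay the response decreases with
#' concentration (`a > d`, `b > 0`); an increasing curve is accepted too.
#' Standards must be strictly monotone in concentration.
#'
#' @param conc standard concentrations (pg per assay well, e.g. pg/50 ul),
#'   strictly positive; at least 4 distinct levels.
#' @param response measured responses at `conc`.
#' @return list of class `standard_curve`: coefficients `a`, `d`, `c0`,
#'   `b`, the calibrated span, residuals and RSS.
#' @export
fit_standard_curve <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) {
    stop("fit_standard_curve: concentrations must be > 0", call. = FALSE)
  }
  if (length(unique(conc)) < 4L) {
    stop("fit_standard_curve: >= 4 standard levels required", call. = FALSE)
  }
  mr <- tapply(response, conc, mean)
  cs <- as.numeric(names(mr))
  o <- order(cs)
  dr <- diff(mr[o])
  if (!(all(dr < 0) || all(dr > 0))) {
    stop("fit_standard_curve: standards are not monotone in concentration",
         call. = FALSE)
  }
  decreasing <- all(dr < 0)
  a0 <- if (decreasing) max(mr) else min(mr)
  d0 <- if (decreasing) min(mr) else max(mr)
  span <- a0 - d0
  a0 <- a0 + 0.05 * span
  d0 <- d0 - 0.05 * span
  c00 <- exp(mean(log(range(cs))))
  fit <- minpack.lm::nlsLM(
    response ~ d + (a - d) / (1 + (conc / c0)^b),
    start = list(a = a0, d = d0, c0 = c00, b = 1),
    data = data.frame(conc = conc, response = response),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- stats::coef(fit)
  structure(list(a = cf[["a"]], d = cf[["d"]], c0 = cf[["c0"]], b = cf[["b"]],
                 conc_range = range(conc),
                 response_range = range(logistic4(range(conc), cf[["a"]],
                                                  cf[["d"]], cf[["c0"]],
                                                  cf[["b"]])),
                 residuals = stats::resid(fit),
                 rss = sum(stats::resid(fit)^2),
                 decreasing = decreasing),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("4PL standard curve:\n")
  cat(sprintf("  a = %.4g, d = %.4g, c0 = %.4g, b = %.4g (rss %.3g)\n",
              x$a, x$d, x$c0, x$b, x$rss))
  cat(sprintf("  calibrated span: %.4g - %.4g pg/well\n",
              x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' Back-calculate assay concentration from a response
#'
#' Inverts the 4PL: `c = c0 * ((a - d)/(R - d) - 1)^(1/b)`. Responses whose
#' back-calculated concentration falls outside the calibrated span are
#' censored (`NA` with a `censored` code), never extrapolated.
#'
#' @param response measured response (vectorized).
#' @param curve a [fit_standard_curve()] result.
#' @return data frame: `response`, `conc` (same units as the standards),
#'   `censored` (`"none"`, `"below"`, `"above"`).
#' @export
invert_standard_curve <- function(response, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  ratio <- (curve$a - curve$d) / (response - curve$d) - 1
  conc <- ifelse(ratio > 0, curve$c0 * ratio^(1 / curve$b), NA_real_)
  lo <- curve$conc_range[1]
  hi <- curve$conc_range[2]
  censored <- rep("none", length(response))
  below <- !is.finite(conc) & (curve$decreasing == (response > curve$a)) |
    (is.finite(conc) & conc < lo)
  above <- (is.finite(conc) & conc > hi) |
    (!is.finite(conc) & !(curve$decreasing == (response > curve$a)))
  censored[below] <- "below"
  censored[above] <- "above"
  conc[censored != "none"] <- NA_real_
  data.frame(response = response, conc = conc, censored = censored)
}

#' Quantify waterborne cortisol in ng/L
#'
#' Back-calculates the assayed mass from the standard curve, then scales by
#' the volume chain: the dry extract was redissolved in
#' `redissolution_ul` of buffer of which `assay_ul` went into the well, and
#' the extract derives from `water_volume_l` of tank water. With the
#' defaults (300 ul, 50 ul, 0.5 L) an assayed 100 pg/50 ul becomes
#' `100 * 6 / 0.5 = 1200` pg/L = 1.2 ng/L.
#'
#' @param response measured response(s).
#' @param curve a [fit_standard_curve()] result.
#' @param redissolution_ul redissolution volume (ul; default 300).
#' @param assay_ul volume assayed per well (ul; default 50).
#' @param water_volume_l water sample volume (L; default 0.5).
#' @param dilution extra dilution factor applied to the extract before
#'   assay (default 1; a 1:2 dilution is `dilution = 2`).
#' @return data frame: `response`, `conc_pg_well`, `ng_per_l`, `censored`.
#' @export
quantify <- function(response, curve, redissolution_ul = 300, assay_ul = 50,
                     water_volume_l = 0.5, dilution = 1) {
  stopifnot(redissolution_ul > 0, assay_ul > 0, water_volume_l > 0,
            dilution >= 1)
  inv <- invert_standard_curve(response, curve)
  pg_per_l <- inv$conc * dilution * (redissolution_ul / assay_ul) /
    water_volume_l
  data.frame(response = response, conc_pg_well = inv$conc,
             ng_per_l = pg_per_l / 1000, censored = inv$censored)
}

#' Parallelism check of serial extract dilutions against the standards
#'
#' Linearizes both curves with the logit-log transform
#' `logit((R - d)/(a - d)) ~ log(relative concentration)` using the fitted
#' asymptotes, regresses the transformed extract responses on log relative
#' dose, and reports the ratio of the extract slope to the standard-curve
#' slope `b`. A ratio near 1 means the extract displaces parallel to the
#' standards (matrix effects negligible).
#'
#' @param dilution_factor serial dilution factors of the pooled extract
#'   (e.g. `c(1, 2, 4, 8, 16)` for 1:1 to 1:16); at least 3 levels.
#' @param response extract responses at those dilutions.
#' @param curve a [fit_standard_curve()] result.
#' @param pass_band acceptable slope-ratio interval (default `[0.8, 1.25]`).
#' @return list of class `parallelism_check`: `slope_extract`,
#'   `slope_standard`, `ratio`, `pass`.
#' @export
parallelism_check <- function(dilution_factor, response, curve,
                              pass_band = c(0.8, 1.25)) {
  stopifnot(inherits(curve, "standard_curve"),
            length(dilution_factor) == length(response))
  if (length(unique(dilution_factor)) < 3L) {
    stop("parallelism_check: >= 3 dilution levels required", call. = FALSE)
  }
  frac <- (response - curve$d) / (curve$a - curve$d)
  if (any(frac <= 0 | frac >= 1)) {
    stop("parallelism_check: responses must lie strictly between the ",
         "fitted asymptotes", call. = FALSE)
  }
  ylin <- log(frac / (1 - frac))
  # relative dose: a 1:f dilution holds 1/f of the pooled concentration
  xlin <- log(1 / dilution_factor)
  slope_extract <- stats::coef(stats::lm(ylin ~ xlin))[["xlin"]]
  # same transform applied to the standards gives slope -b exactly
  slope_standard <- -curve$b
  ratio <- slope_extract / slope_standard
  structure(list(slope_extract = slope_extract,
                 slope_standard = slope_standard, ratio = ratio,
                 pass = ratio >= pass_band[1] && ratio <= pass_band[2],
                 pass_band = pass_band),
            class = "parallelism_check")
}

#' Intra- and inter-assay coefficients of variation
#'
#' Intra-assay CV is `sd/mean` of each duplicate pair; inter-assay CV is
#' `sd/mean` of the per-plate means of the control sample. Both are
#' checked against the 10% quality threshold.
#'
#' @param dup1,dup2 duplicate measurements (same length).
#' @param plate optional plate label per pair; when given together with
#'   `is_control`, the inter-assay CV is computed from the control pairs.
#' @param is_control logical, marks the control-sample pairs.
#' @param threshold CV pass threshold (default 0.10).
#' @return list of class `cv_qc`: `intra` (per-pair CV table),
#'   `intra_pass`, and when controls are given `inter_cv`, `inter_pass`.
#' @export
cv_qc <- function(dup1, dup2, plate = NULL, is_control = NULL,
                  threshold = 0.10) {
  stopifnot(length(dup1) == length(dup2))
  m <- (dup1 + dup2) / 2
  s <- apply(cbind(dup1, dup2), 1, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  intra <- data.frame(dup1 = dup1, dup2 = dup2, mean = m, sd = s, cv = cv,
                      pass = cv < threshold)
  out <- list(intra = intra, intra_pass = all(intra$pass, na.rm = TRUE),
              threshold = threshold)
  if (!is.null(plate) && !is.null(is_control) && any(is_control)) {
    ctrl <- tapply(m[is_control], plate[is_control], mean)
    out$inter_cv <- stats::sd(ctrl) / mean(ctrl)
    out$inter_pass <- out$inter_cv < threshold
  }
  structure(out, class = "cv_qc")
}

#' Normalize cortisol to ng per liter per mm of fish
#'
#' Tank-water cortisol is the pooled release of all fish present, so the
#' default denominator is the summed body length of the fish in the
#' aquarium; `denominator = "mean"` divides by the mean length instead.
#'
#' @param ng_per_l raw concentration(s), ng/L.
#' @param lengths_mm body lengths (mm) of the fish in the aquarium, all
#'   `> 0`.
#' @param denominator `"total"` (default) or `"mean"`.
#' @return normalized value(s), ng/L/mm.
#' @export
normalize_cortisol <- function(ng_per_l, lengths_mm,
                               denominator = c("total", "mean")) {
  denominator <- match.arg(denominator)
  if (any(!is.finite(lengths_mm)) || any(lengths_mm <= 0)) {
    stop("normalize_cortisol: fish lengths must be finite and > 0",
         call. = FALSE)
  }
  den <- if (denominator == "total") sum(lengths_mm) else mean(lengths_mm)
  ng_per_l / den
}
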