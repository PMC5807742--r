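# Four-candidate linear mixed model comparison with AIC selection, and the
# per-response analyses built on it (cortisol, freeze features, thigmotaxis,
# gene expression).
#
# The candidate set crosses fixed structure {zone + time, zone x time} with
# random structure {intercept, intercept + slope(time)} on the grouping
# factor. Candidates are fitted by maximum likelihood so their AICs are
# comparable; among candidates within 2 AIC units of the best, the one with
# the fewest parameters is kept (parsimony rule).

#' Specify a single mixed-model candidate
#'
#' @param response name of the response column.
#' @param fixed fixed-effect structure: `"additive"` (`zone + time`),
#'   `"interaction"` (`zone * time`) or `"zone_only"`.
#' @param random random-effect structure on the grouping factor:
#'   `"intercept"` or `"slope"` (random intercept + random slope on time).
#' @param grouping grouping factor: `"aquarium_in_trial"` (aquarium nested
#'   within trial), `"aquarium"` or `"trial"`.
#' @param method `"ML"` (required for AIC comparison) or `"REML"`.
#' @param time_var,zone_var,aquarium_var,trial_var column names in the data.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response,
                       fixed = c("additive", "interaction", "zone_only"),
                       random = c("intercept", "slope"),
                       grouping = c("aquarium_in_trial", "aquarium", "trial"),
                       method = c("ML", "REML"),
                       time_var = "time", zone_var = "zone",
                       aquarium_var = "aquarium", trial_var = "trial") {
  fixed <- match.arg(fixed)
  random <- match.arg(random)
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  stopifnot(is.character(response), length(response) == 1L)
  structure(list(response = response, fixed = fixed, random = random,
                 grouping = grouping, method = method,
                 time_var = time_var, zone_var = zone_var,
                 aquarium_var = aquarium_var, trial_var = trial_var),
            class = "model_spec")
}

spec_formula <- function(spec) {
  fx <- switch(spec$fixed,
               additive = paste(spec$zone_var, "+", spec$time_var),
               interaction = paste(spec$zone_var, "*", spec$time_var),
               zone_only = spec$zone_var)
  g <- switch(spec$grouping,
              aquarium_in_trial = paste(spec$trial_var, "/", spec$aquarium_var),
              aquarium = spec$aquarium_var,
              trial = spec$trial_var)
  rnd <- if (spec$random == "intercept") {
    sprintf("(1 | %s)", g)
  } else {
    sprintf("(1 + %s | %s)", spec$time_var, g)
  }
  stats::as.formula(paste(spec$response, "~", fx, "+", rnd))
}

#' Fit one linear mixed model candidate
#'
#' Fits the model described by a [model_spec()] with `lmerTest::lmer()`
#' (Satterthwaite degrees of freedom for the fixed-effect t tests). Boundary
#' variance estimates (a random-effect variance of exactly 0) are legitimate
#' outcomes and are reported via the `singular` flag, not treated as
#' failures.
#'
#' @param data a data frame containing the response and the columns named in
#'   the spec.
#' @param spec a [model_spec()].
#' @param inference compute Satterthwaite df and p-values for the fixed
#'   effects (default TRUE; `FALSE` fits with plain \pkg{lme4}, leaving
#'   `df` and `p` as `NA` — used for the AIC screening fits, where only the
#'   likelihood matters).
#' @return an object of class `lmm_fit`: the fitted model plus `logLik`,
#'   `n_par`, `aic` (`2 * n_par - 2 * logLik`), a `fixed` table
#'   (estimate/SE/df/t/p), `varcor` table, and `singular`/`converged` flags.
#' @export
fit_lmm <- function(data, spec, inference = TRUE) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  if (!spec$response %in% names(data)) {
    stop("fit_lmm: response column '", spec$response, "' not found",
         call. = FALSE)
  }
  gvar <- switch(spec$grouping,
                 aquarium_in_trial = spec$aquarium_var,
                 aquarium = spec$aquarium_var,
                 trial = spec$trial_var)
  if (!gvar %in% names(data) || length(unique(data[[gvar]])) < 2L) {
    stop("fit_lmm: grouping factor '", gvar,
         "' must be present with >= 2 levels", call. = FALSE)
  }
  # reject rank-deficient fixed-effect designs, naming the collinear terms
  fx <- switch(spec$fixed,
               additive = paste(spec$zone_var, "+", spec$time_var),
               interaction = paste(spec$zone_var, "*", spec$time_var),
               zone_only = spec$zone_var)
  mm <- stats::model.matrix(stats::as.formula(paste("~", fx)), data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("fit_lmm: singular fixed-effect design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  form <- spec_formula(spec)
  conv_warning <- NULL
  fitter <- if (inference) lmerTest::lmer else lme4::lmer
  fit <- withCallingHandlers(
    fitter(form, data = data, REML = (spec$method == "REML")),
    warning = function(w) {
      conv_warning <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  ll <- stats::logLik(fit)
  n_par <- attr(ll, "df")
  coefs <- as.data.frame(stats::coef(summary(fit)))
  fixed <- data.frame(term = rownames(coefs),
                      estimate = coefs[["Estimate"]],
                      se = coefs[["Std. Error"]],
                      df = if (inference) coefs[["df"]] else NA_real_,
                      t = coefs[["t value"]],
                      p = if (inference) coefs[["Pr(>|t|)"]] else NA_real_,
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcor <- data.frame(group = vc$grp, name = ifelse(is.na(vc$var1), "", vc$var1),
                       variance = vc$vcov, sd = vc$sdcor)
  varcor <- varcor[is.na(vc$var2) | vc$var2 == "", , drop = FALSE]
  structure(list(model = fit, spec = spec, formula = form,
                 logLik = as.numeric(ll), n_par = n_par,
                 aic = 2 * n_par - 2 * as.numeric(ll),
                 fixed = fixed, varcor = varcor,
                 singular = lme4::isSingular(fit),
                 converged = is.null(conv_warning),
                 convergence_message = conv_warning),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model:", deparse(x$formula), "\n")
  cat(sprintf("  %s fit, logLik = %.3f, n_par = %d, AIC = %.3f%s\n",
              x$spec$method, x$logLik, x$n_par, x$aic,
              if (x$singular) " (boundary variance)" else ""))
  print(x$fixed, digits = 3)
  invisible(x)
}

#' Compare the four candidate mixed models by AIC
#'
#' Fits, under maximum likelihood, the four candidates obtained by crossing
#' fixed structure (additive `zone + time` vs interaction `zone x time`) with
#' random structure (intercept vs intercept + slope on time), and selects by
#' AIC with a parsimony rule: candidates within `tie_delta` AIC units of the
#' minimum are considered tied and the tied candidate with the fewest
#' parameters is kept.
#'
#' Candidates that fail outright (an error from the optimizer) are recorded
#' and excluded from selection with a warning; boundary (singular) fits are
#' retained.
#'
#' @param data data frame with the response, zone, time and grouping columns.
#' @param response name of the response column.
#' @param grouping grouping structure, as in [model_spec()].
#' @param time_var,zone_var,aquarium_var,trial_var column names.
#' @param tie_delta AIC difference under which two candidates are tied
#'   (default 2).
#' @return an object of class `model_comparison`: `fits` (named list of
#'   [fit_lmm()] results, `model1`..`model4`), `table` (one row per
#'   candidate with structure, n_par, logLik, AIC), `selected` (name of the
#'   kept candidate) and `selection_rule`.
#' @export
compare_four_models <- function(data, response,
                                grouping = c("aquarium_in_trial", "aquarium",
                                             "trial"),
                                time_var = "time", zone_var = "zone",
                                aquarium_var = "aquarium", trial_var = "trial",
                                tie_delta = 2) {
  grouping <- match.arg(grouping)
  layout <- list(
    model1 = c(fixed = "additive", random = "intercept"),
    model2 = c(fixed = "interaction", random = "intercept"),
    model3 = c(fixed = "additive", random = "slope"),
    model4 = c(fixed = "interaction", random = "slope")
  )
  fits <- lapply(layout, function(ly) {
    spec <- model_spec(response, fixed = ly[["fixed"]], random = ly[["random"]],
                       grouping = grouping, method = "ML",
                       time_var = time_var, zone_var = zone_var,
                       aquarium_var = aquarium_var, trial_var = trial_var)
    tryCatch(fit_lmm(data, spec, inference = FALSE), error = function(e) e)
  })
  failed <- vapply(fits, inherits, logical(1), what = "error")
  if (all(failed)) {
    stop("compare_four_models: all four candidates failed to fit",
         call. = FALSE)
  }
  if (any(failed)) {
    warning("compare_four_models: excluded candidate(s) ",
            paste(names(fits)[failed], collapse = ", "),
            " after fitting error", call. = FALSE)
  }
  ok <- fits[!failed]
  aic <- vapply(ok, `[[`, numeric(1), "aic")
  npar <- vapply(ok, `[[`, numeric(1), "n_par")
  tied <- names(ok)[aic - min(aic) < tie_delta]
  sel <- tied[order(npar[tied], aic[tied])][1L]
  tab <- data.frame(
    model = names(layout),
    fixed = vapply(layout, `[[`, character(1), "fixed"),
    random = vapply(layout, `[[`, character(1), "random"),
    n_par = ifelse(failed, NA_real_, vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$n_par, numeric(1))),
    logLik = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$logLik, numeric(1)),
    aic = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$aic, numeric(1)),
    singular = vapply(fits, function(f)
      if (inherits(f, "error")) NA else f$singular, logical(1)),
    selected = names(layout) == sel,
    row.names = NULL
  )
  # the AIC screen is ML; the selected model's reported coefficients and
  # Satterthwaite tests come from a REML refit of the same structure
  sel_spec <- model_spec(response, fixed = layout[[sel]][["fixed"]],
                         random = layout[[sel]][["random"]],
                         grouping = grouping, method = "REML",
                         time_var = time_var, zone_var = zone_var,
                         aquarium_var = aquarium_var, trial_var = trial_var)
  inference_fit <- tryCatch(fit_lmm(data, sel_spec), error = function(e) NULL)
  structure(list(fits = fits[!failed], table = tab, selected = sel,
                 inference_fit = inference_fit,
                 selection_rule = sprintf(
                   "min AIC; candidates within %.3g AIC units tied, fewest parameters kept",
                   tie_delta)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Four-candidate mixed model comparison (ML):\n")
  print(x$table, digits = 4)
  cat("Selected:", x$selected, "-", x$selection_rule, "\n")
  invisible(x)
}

#' Extract the selected model's fixed-effect table
#'
#' Coefficients, SEs and Satterthwaite tests come from the REML refit of
#' the selected structure when available (the ML fit only served the AIC
#' comparison).
#'
#' @param comparison a `model_comparison`.
#' @return the `fixed` data frame of the selected candidate.
#' @export
selected_fixed_effects <- function(comparison) {
  stopifnot(inherits(comparison, "model_comparison"))
  if (!is.null(comparison$inference_fit)) {
    comparison$inference_fit$fixed
  } else {
    comparison$fits[[comparison$selected]]$fixed
  }
}

# Nesting aquarium within trial needs >= 2 trials; with a single trial the
# pooled design reduces to plain aquarium grouping.
pooled_grouping <- function(tab) {
  if (length(unique(tab$trial)) >= 2L) "aquarium_in_trial" else "aquarium"
}

# Shared preparation: zone as factor (first sorted level = reference,
# i.e. the control zone when labels are CZ/TZ) and time as the 0-based
# ordinal index of the sampling points.
prepare_response_table <- function(tab, time_source, time_name = "time") {
  tab <- as.data.frame(tab)
  tab$zone <- factor(tab$zone)
  tt <- tab[[time_source]]
  tab[[time_name]] <- match(tt, sort(unique(tt))) - 1
  tab
}

#' Analyze cortisol time courses with the four-candidate comparison
#'
#' The pooled design nests aquarium within trial (both trials analyzed
#' together); the per-trial design analyzes each trial separately with
#' aquarium as the grouping factor. Time is coded as the 0-based ordinal
#' index of the sampling points (baseline = 0).
#'
#' @param tab long cortisol table with columns `trial`, `aquarium`, `zone`,
#'   `time_h` and `cortisol`.
#' @param design `"pooled"` or `"per_trial"`.
#' @return list of class `response_analysis`: `design`, `comparisons` (one
#'   `model_comparison`, or one per trial), and `fixed_effects` (selected
#'   model's table(s)).
#' @export
analyze_cortisol <- function(tab, design = c("pooled", "per_trial")) {
  design <- match.arg(design)
  req <- c("trial", "aquarium", "zone", "time_h", "cortisol")
  if (!all(req %in% names(tab))) {
    stop("analyze_cortisol: table must contain ",
         paste(setdiff(req, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab <- prepare_response_table(tab, "time_h")
  if (length(unique(tab$time_h)) < 2L) {
    stop("analyze_cortisol: need baseline and post-stress sampling times",
         call. = FALSE)
  }
  if (design == "pooled") {
    grouping <- pooled_grouping(tab)
    cmp <- compare_four_models(tab, "cortisol", grouping = grouping)
    comparisons <- list(pooled = cmp)
  } else {
    comparisons <- lapply(split(tab, tab$trial), function(d) {
      d$aquarium <- droplevels(factor(d$aquarium))
      compare_four_models(d, "cortisol", grouping = "aquarium")
    })
  }
  structure(list(response = "cortisol", design = design,
                 comparisons = comparisons,
                 fixed_effects = lapply(comparisons, selected_fixed_effects)),
            class = "response_analysis")
}

#' Analyze a behavioral feature with the four-candidate comparison
#'
#' Behavioral features (freezing intensity, time to freeze, thigmotaxis) are
#' one value per aquarium-day; the experimental day plays the role of the
#' time covariate and aquarium is the grouping factor (nested within trial
#' in the pooled design). With a single day the time term is unidentifiable
#' and is dropped with a warning (zone-only candidates are compared).
#'
#' @param tab feature table with columns `trial`, `aquarium`, `zone`, `day`
#'   and the response column.
#' @param response name of the feature column.
#' @param design `"pooled"` or `"per_trial"`.
#' @return a `response_analysis` list, as [analyze_cortisol()].
#' @export
analyze_behavior <- function(tab, response, design = c("pooled", "per_trial")) {
  design <- match.arg(design)
  req <- c("trial", "aquarium", "zone", "day", response)
  if (!all(req %in% names(tab))) {
    stop("analyze_behavior: table must contain ",
         paste(setdiff(req, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab <- prepare_response_table(tab, "day")
  single_day <- length(unique(tab$day)) < 2L
  if (single_day) {
    warning("analyze_behavior: single experimental day; time term dropped",
            call. = FALSE)
  }
  one <- function(d, grouping) {
    if (single_day) {
      one_per_aq <- max(table(d$aquarium)) < 2L
      if (one_per_aq) {
        # a single observation per aquarium cannot separate the aquarium
        # variance from the residual: ordinary least squares on zone
        lm_fit <- stats::lm(stats::as.formula(paste(response, "~ zone")), d)
        cf <- summary(lm_fit)$coefficients
        fixed <- data.frame(term = rownames(cf), estimate = cf[, 1],
                            se = cf[, 2], df = lm_fit$df.residual,
                            t = cf[, 3], p = cf[, 4], row.names = NULL)
        ll <- as.numeric(stats::logLik(lm_fit))
        np <- attr(stats::logLik(lm_fit), "df")
        f <- structure(list(model = lm_fit, spec = NULL,
                            formula = stats::formula(lm_fit), logLik = ll,
                            n_par = np, aic = 2 * np - 2 * ll, fixed = fixed,
                            varcor = data.frame(), singular = NA,
                            converged = TRUE, convergence_message = NULL),
                       class = "lmm_fit")
      } else {
        spec <- model_spec(response, fixed = "zone_only",
                           random = "intercept", grouping = grouping,
                           method = "REML")
        f <- fit_lmm(d, spec)
      }
      tab1 <- data.frame(model = "zone_only", fixed = "zone_only",
                         random = if (one_per_aq) "none" else "intercept",
                         n_par = f$n_par, logLik = f$logLik, aic = f$aic,
                         singular = f$singular, selected = TRUE)
      structure(list(fits = list(zone_only = f), table = tab1,
                     selected = "zone_only",
                     selection_rule = "single candidate (time term dropped)"),
                class = "model_comparison")
    } else {
      compare_four_models(d, response, grouping = grouping)
    }
  }
  if (design == "pooled") {
    comparisons <- list(pooled = one(tab, pooled_grouping(tab)))
  } else {
    comparisons <- lapply(split(tab, tab$trial), function(d) {
      d$aquarium <- droplevels(factor(d$aquarium))
      one(d, "aquarium")
    })
  }
  structure(list(response = response, design = design,
                 comparisons = comparisons,
                 fixed_effects = lapply(comparisons, selected_fixed_effects)),
            class = "response_analysis")
}

#' Per-gene zone test with trial as random intercept
#'
#' Fits `expression ~ zone + (1 | trial)` for each gene (REML, Satterthwaite
#' t tests) and reports the zone fixed effect, mirroring the layout of a
#' per-gene summary table.
#'
#' @param tab per-fish relative-expression table with columns `trial`,
#'   `zone`, `fish_id`, `gene`, `rel_expr`.
#' @param genes optional subset of genes to analyze.
#' @return data frame: gene, n, estimate, se, df, t, p, singular.
#' @export
analyze_gene <- function(tab, genes = NULL) {
  req <- c("trial", "zone", "fish_id", "gene", "rel_expr")
  if (!all(req %in% names(tab))) {
    stop("analyze_gene: table must contain ",
         paste(setdiff(req, names(tab)), collapse = ", "), call. = FALSE)
  }
  if (length(unique(tab$trial)) < 2L) {
    stop("analyze_gene: >= 2 trials required for the trial random intercept",
         call. = FALSE)
  }
  if (is.null(genes)) genes <- unique(tab$gene)
  tab$zone <- factor(tab$zone)
  out <- lapply(genes, function(g) {
    d <- tab[tab$gene == g & is.finite(tab$rel_expr), , drop = FALSE]
    spec <- model_spec("rel_expr", fixed = "zone_only", random = "intercept",
                       grouping = "trial", method = "REML")
    f <- fit_lmm(d, spec)
    zrow <- f$fixed[grep("^zone", f$fixed$term), , drop = FALSE]
    data.frame(gene = g, n = nrow(d), estimate = zrow$estimate, se = zrow$se,
               df = zrow$df, t = zrow$t, p = zrow$p, singular = f$singular)
  })
  do.call(rbind, out)
}
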