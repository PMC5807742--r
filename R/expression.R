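# Relative gene expression: duplicate averaging and geometric-mean
# housekeeping normalization, plus a stability check on the housekeeping
# genes themselves.

#' Relative expression of one target measurement
#'
#' The mean of the two technical duplicates divided by the geometric mean
#' of the two housekeeping quantities (gapdh and 18S):
#' `mean(dup_target) / sqrt(gapdh * s18)`.
#'
#' @param dup_target numeric vector of target duplicates (usually length 2).
#' @param gapdh,s18 housekeeping quantities, both `> 0`.
#' @return dimensionless relative expression.
#' @export
relative_expression <- function(dup_target, gapdh, s18) {
  if (any(!is.finite(c(gapdh, s18))) || gapdh <= 0 || s18 <= 0) {
    stop("relative_expression: housekeeping quantities must be > 0",
         call. = FALSE)
  }
  mean(dup_target) / sqrt(gapdh * s18)
}

#' Per-fish relative expression from a duplicate-well qPCR table
#'
#' Averages the duplicates per fish and gene, then divides each target
#' gene's mean by the geometric mean of the same fish's gapdh and 18S
#' means. Fish with a missing or non-positive housekeeping value get
#' `NA` relative expression and `flag = "no_housekeeping"`.
#'
#' @param qpcr table with columns `trial`, `zone`, `fish_id`, `gene`,
#'   `dup1`, `dup2` (see [simulate_expression()]); duplicate quantities
#'   must be `>= 0` (undetected wells are `NA`, not zero).
#' @param housekeeping the two normalizer genes (default gapdh and 18S).
#' @return data frame: trial, zone, fish_id, gene, rel_expr, flag. Only
#'   non-housekeeping genes appear.
#' @export
expression_table <- function(qpcr, housekeeping = c("gapdh", "18S")) {
  req <- c("trial", "zone", "fish_id", "gene", "dup1", "dup2")
  if (!all(req %in% names(qpcr))) {
    stop("expression_table: table must contain ",
         paste(setdiff(req, names(qpcr)), collapse = ", "), call. = FALSE)
  }
  if (any(c(qpcr$dup1, qpcr$dup2) < 0, na.rm = TRUE)) {
    stop("expression_table: standard quantities must be >= 0", call. = FALSE)
  }
  qpcr$mean_q <- rowMeans(cbind(qpcr$dup1, qpcr$dup2), na.rm = FALSE)
  out <- lapply(split(qpcr, qpcr$fish_id), function(d) {
    hk <- d$mean_q[match(housekeeping, d$gene)]
    targets <- d[!(d$gene %in% housekeeping), , drop = FALSE]
    ok <- all(is.finite(hk)) && all(hk > 0)
    data.frame(trial = targets$trial, zone = targets$zone,
               fish_id = targets$fish_id, gene = targets$gene,
               rel_expr = if (ok) targets$mean_q / sqrt(prod(hk))
                          else NA_real_,
               flag = if (ok) "ok" else "no_housekeeping")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Zone-stability test of the housekeeping genes
#'
#' Fits `quantity ~ zone + (1 | trial)` to each housekeeping gene's
#' duplicate-mean quantities (the same mixed model used for the target
#' genes) and reports the zone effect; a small p-value flags a housekeeping
#' gene that is not stable across zones and should not be used as a
#' normalizer.
#'
#' @param qpcr duplicate-well table, as [expression_table()].
#' @param housekeeping genes to test (default gapdh and 18S).
#' @return data frame: gene, n, estimate, se, df, t, p, singular.
#' @export
housekeeping_stability <- function(qpcr, housekeeping = c("gapdh", "18S")) {
  if (length(unique(qpcr$zone)) < 2L) {
    stop("housekeeping_stability: both zones must be present", call. = FALSE)
  }
  d <- qpcr[qpcr$gene %in% housekeeping, , drop = FALSE]
  d$rel_expr <- rowMeans(cbind(d$dup1, d$dup2))
  analyze_gene(d, genes = housekeeping)
}

#' Per-zone geometric mean of relative expression
#'
#' @param expr output of [expression_table()].
#' @return data frame: gene, zone, n, mean, geomean.
#' @export
zone_expression_summary <- function(expr) {
  d <- expr[is.finite(expr$rel_expr), , drop = FALSE]
  agg <- function(f) stats::aggregate(rel_expr ~ gene + zone, d, f)
  m <- agg(mean)
  g <- agg(function(v) exp(mean(log(v))))
  n <- agg(length)
  out <- data.frame(gene = m$gene, zone = m$zone, n = n$rel_expr,
                    mean = m$rel_expr, geomean = g$rel_expr)
  out[order(out$gene, out$zone), ]
}
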