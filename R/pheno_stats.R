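#' Pearson correlation with confidence interval and p value
#'
#' Product-moment correlation; two-sided p value from the t transform
#' with n-2 degrees of freedom, 95% confidence interval via the Fisher
#' inverse-hyperbolic-tangent transform (as reported alongside
#' editing-phenotype correlations).
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-zero variance.
#' @param conf_level confidence level for the interval.
#' @return list of class `correlation_result`: `r`, `p`, `ci` (length 2),
#'   `n`.
#' @export
#' @examples
#' pearson(1:10, 2 * (1:10) + 1)$r  # 1
pearson <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) {
    bq_stop("bequant_stat_error", "x and y differ in length")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) bq_stop("bequant_stat_error", "need n >= 3 complete pairs, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    bq_stop("bequant_stat_error", "undefined correlation: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 ci = as.numeric(ct$conf.int), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f [%.3f, %.3f], p = %.3g, n = %d\n",
              x$r, x$ci[1], x$ci[2], x$p, x$n))
  invisible(x)
}

#' Percent change of a treated mean over a control mean
#'
#' `100 * (treated - control) / control`. The returned value is exact;
#' [round_report()] renders it to one decimal (half away from zero) for
#' reporting.
#'
#' @param mean_treated,mean_control group means; `mean_control` must be
#'   positive.
#' @return percentage (exact).
#' @export
#' @examples
#' round_report(percent_change(25.0, 24.0))  # 4.2
percent_change <- function(mean_treated, mean_control) {
  if (!isTRUE(mean_control > 0)) {
    bq_stop("bequant_stat_error", "control mean must be > 0")
  }
  100 * (mean_treated - mean_control) / mean_control
}

#' Fold ratio of two quantities
#'
#' `a / b`, exact; reporting rounds half away from zero to one decimal
#' (so 1.25 renders as 1.3).
#'
#' @param a,b numerator and denominator; `b` must be positive.
#' @return fold (exact).
#' @export
#' @examples
#' round_report(fold_ratio(8.0e10, 4.8e10))  # 1.7
fold_ratio <- function(a, b) {
  if (!isTRUE(b > 0)) bq_stop("bequant_stat_error", "denominator must be > 0")
  a / b
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct(gene) - Ct(reference gene)`; then
#' `ddCt = mean dCt(group) - mean dCt(calibrator group)` and the fold
#' change is `2^(-ddCt)`.
#'
#' @param ct long-format data frame with columns `sample`, `group`,
#'   `gene`, `ct`.
#' @param gene gene of interest.
#' @param reference_gene normalizer gene (must be measured for every
#'   sample of both groups).
#' @param sample_group,calibrator_group group labels.
#' @return fold change (numeric).
#' @export
#' @examples
#' ct <- data.frame(sample = c("s1", "s1", "s2", "s2"),
#'                  group = c("trt", "trt", "ctl", "ctl"),
#'                  gene = c("Atf4", "Akt", "Atf4", "Akt"),
#'                  ct = c(24, 20, 23, 20))
#' ddct_fold_change(ct, "Atf4", "Akt", "trt", "ctl")  # 0.5
ddct_fold_change <- function(ct, gene, reference_gene, sample_group,
                             calibrator_group) {
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(ct))) {
    bq_stop("bequant_stat_error", "ct table needs columns %s",
            paste(need, collapse = ", "))
  }
  dct_of <- function(grp) {
    sub <- ct[ct$group == grp, , drop = FALSE]
    g <- sub[sub$gene == gene, , drop = FALSE]
    r <- sub[sub$gene == reference_gene, , drop = FALSE]
    if (nrow(g) == 0L) {
      bq_stop("bequant_stat_error", "gene '%s' missing in group '%s'", gene, grp)
    }
    if (!all(g$sample %in% r$sample)) {
      bq_stop("bequant_stat_error",
              "reference gene '%s' missing for some samples of group '%s'",
              reference_gene, grp)
    }
    mean(g$ct - r$ct[match(g$sample, r$sample)])
  }
  ddct <- dct_of(sample_group) - dct_of(calibrator_group)
  2^(-ddct)
}

#' Welch two-sample t test
#'
#' Unpaired t statistic with Welch's correction (Satterthwaite degrees of
#' freedom), two-sided.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    bq_stop("bequant_stat_error", "each group needs n >= 2")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Composite ataxia score
#'
#' Sum of four 0-3 items (hindlimb clasping, gait, kyphosis, ledge
#' walking) plus a 0/1 pelvic-tilt item: an integer between 0 and 13,
#' higher meaning stronger neurological deterioration.
#'
#' @param hindlimb,gait,kyphosis,ledge integer scores 0-3.
#' @param pelvic_tilt 0 (absent) or 1 (present).
#' @return composite score in `[0, 13]`.
#' @export
#' @examples
#' ataxia_composite(3, 3, 3, 3, 1)  # 13
ataxia_composite <- function(hindlimb, gait, kyphosis, ledge, pelvic_tilt) {
  items <- c(hindlimb = hindlimb, gait = gait, kyphosis = kyphosis,
             ledge = ledge)
  if (any(items != as.integer(items)) || any(items < 0) || any(items > 3)) {
    bad <- names(items)[which(items < 0 | items > 3 | items != as.integer(items))[1]]
    bq_stop("bequant_stat_error", "item '%s' outside its 0-3 range", bad)
  }
  if (!pelvic_tilt %in% c(0, 1)) {
    bq_stop("bequant_stat_error", "pelvic_tilt must be 0 or 1")
  }
  as.integer(sum(items) + pelvic_tilt)
}
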