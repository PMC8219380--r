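#' Power-law fit of potency against affinity
#'
#' The discriminatory power of a receptor is the exponent alpha of the
#' empirical power law \eqn{P_X = 10^C K_D^\alpha}, fitted as an ordinary
#' least-squares line in log space:
#' \deqn{\log_{10} P_X = C + \alpha \log_{10} K_D.}
#' alpha is the factor by which fold-changes in affinity are amplified into
#' fold-changes in the dose needed for a fixed response; alpha = 1 is the
#' receptor-occupancy baseline. C (the log10 potency of a 1 uM-affinity
#' ligand) measures antigen sensitivity. When on-rates vary across ligands
#' the affinity axis should be koff instead of KD (alpha is unchanged under
#' any multiplicative rescaling of either axis; C is not).
#'
#' @param records Data.frame with a \code{potency} column and an affinity
#'   column (\code{kd_uM} or \code{koff_per_s}).
#' @param affinity_axis \code{"kd"} or \code{"koff"}; the axis choice is
#'   always explicit, never automatic.
#' @return An object of class \code{power_law_fit}: \code{alpha}, \code{c0},
#'   \code{r_squared}, \code{p_slope} (t-test of alpha = 0, n-2 df),
#'   \code{alpha_ci} (95\%), \code{n_points}, \code{affinity_axis}.
#' @export
fit_power_law <- function(records, affinity_axis = c("kd", "koff")) {
  affinity_axis <- match.arg(affinity_axis)
  col <- if (affinity_axis == "kd") "kd_uM" else "koff_per_s"
  if (!col %in% names(records)) stop("records lack column ", col)
  aff <- records[[col]]
  pot <- records$potency
  ok <- is.finite(aff) & is.finite(pot) & aff > 0 & pot > 0
  if ("flag" %in% names(records)) ok <- ok & !nzchar(records$flag)
  if (sum(ok) < 3) stop("insufficient points for regression (need >= 3)")
  x <- log10(aff[ok])
  y <- log10(pot[ok])
  if (stats::var(x) == 0) stop("zero variance in affinity")
  lf <- stats::lm(y ~ x)
  sm <- summary(lf)
  ci <- stats::confint(lf, "x", level = 0.95)
  structure(list(alpha = unname(stats::coef(lf)[2]),
                 c0 = unname(stats::coef(lf)[1]),
                 r_squared = sm$r.squared,
                 p_slope = unname(sm$coefficients["x", "Pr(>|t|)"]),
                 alpha_ci = unname(ci[1, ]),
                 n_points = sum(ok),
                 affinity_axis = affinity_axis,
                 lm = lf),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law (axis: %s, n = %d): alpha = %.3g [%.3g, %.3g], C = %.3g\n",
              x$affinity_axis, x$n_points, x$alpha, x$alpha_ci[1],
              x$alpha_ci[2], x$c0))
  cat(sprintf("  R^2 = %.3f, p(alpha = 0) = %.3g\n", x$r_squared, x$p_slope))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(alpha = object$alpha, C = object$c0)
}

#' @export
predict.power_law_fit <- function(object, affinity, ...) {
  10^(object$c0 + object$alpha * log10(affinity))
}

#' Apply the inclusion rules for discrimination-power fits
#'
#' Drops records in the affinity saturation regime (KD below
#' \code{kd_floor}, default 1 uM, where further affinity gains no longer
#' improve potency and would bias alpha downward) and records whose potency
#' was flagged (extrapolated beyond the tested dose range, unreachable,
#' below-threshold). Every dropped record is listed in an audit log with the
#' rule that removed it.
#'
#' @param records Potency table (data.frame); flags in a \code{flag} column.
#' @param kd_floor Saturation-regime cut, uM.
#' @return List with \code{records} (retained rows) and \code{audit}
#'   (data.frame of dropped rows: identifiers plus \code{rule}).
#' @export
apply_inclusion_rules <- function(records, kd_floor = 1) {
  rule <- rep("", nrow(records))
  if ("flag" %in% names(records)) {
    fl <- !is.na(records$flag) & nzchar(records$flag)
    rule[fl] <- paste0("flagged: ", records$flag[fl])
  }
  if ("kd_uM" %in% names(records)) {
    low <- !is.na(records$kd_uM) & records$kd_uM < kd_floor
    rule[low & rule == ""] <- sprintf("KD < %g uM (saturation regime)", kd_floor)
  }
  drop <- rule != ""
  audit <- records[drop, !(names(records) %in% "flag"), drop = FALSE]
  audit$rule <- rule[drop]
  rownames(audit) <- NULL
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, audit = audit)
}

#' Aggregate discrimination powers across fits
#'
#' Keeps only fits whose slope is statistically significant (p <
#' \code{significance_alpha}) — unless \code{include_nonsignificant} is set,
#' the documented exception for sparse legacy datasets — and returns the
#' arithmetic mean of alpha with a t-based 95 percent confidence interval.
#'
#' @param fits List of \code{power_law_fit} objects.
#' @param significance_alpha Slope p-value threshold, default 0.05.
#' @param include_nonsignificant Override flag, default \code{FALSE}.
#' @return List with \code{mean_alpha}, \code{ci} (length 2),
#'   \code{n_included}, \code{alphas}.
#' @export
aggregate_alpha <- function(fits, significance_alpha = 0.05,
                            include_nonsignificant = FALSE) {
  stopifnot(length(fits) >= 1)
  p <- vapply(fits, function(f) f$p_slope, numeric(1))
  a <- vapply(fits, function(f) f$alpha, numeric(1))
  keep <- if (include_nonsignificant) rep(TRUE, length(fits))
          else p < significance_alpha
  if (!any(keep)) stop("no significant fits to aggregate")
  a <- a[keep]
  n <- length(a)
  m <- mean(a)
  ci <- if (n >= 2) {
    se <- stats::sd(a) / sqrt(n)
    m + c(-1, 1) * stats::qt(0.975, n - 1) * se
  } else c(NA_real_, NA_real_)
  list(mean_alpha = m, ci = ci, n_included = n, alphas = a)
}

#' One-sample test of discrimination powers against the occupancy baseline
#'
#' Tests whether alpha differs from 1 (the receptor-occupancy baseline)
#' with a two-sided one-sample t-test on log-transformed values
#' (log10 alpha against 0), the scale on which alpha estimates are
#' approximately normal.
#'
#' @param alphas Numeric vector of at least 2 positive alpha estimates.
#' @return List with \code{t}, \code{p_value}, \code{df}.
#' @export
test_alpha_vs_one <- function(alphas) {
  stopifnot(length(alphas) >= 2, all(alphas > 0))
  y <- log10(alphas)
  n <- length(y)
  s <- stats::sd(y)
  if (s == 0) {
    if (mean(y) == 0) return(list(t = 0, p_value = 1, df = n - 1))
    stop("zero variance in log-transformed alphas")
  }
  t <- mean(y) / (s / sqrt(n))
  list(t = t, p_value = 2 * stats::pt(-abs(t), n - 1), df = n - 1)
}
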