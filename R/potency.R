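#' Four-parameter sigmoid fit of a dose-response curve
#'
#' Least-squares fit, on the linear response scale, of
#' \deqn{R(x) = E_{min} + \frac{E_{max} - E_{min}}{1 + (EC_{50}/x)^H}}
#' to percent-activation data, where \eqn{x} is the ligand dose (peptide
#' concentration for pulsing, or amount of ligand coated per well).
#' Responses are fitted as given in percent with no renormalisation.
#'
#' @param doses Ligand doses (> 0, at least 5 points).
#' @param responses Percent activation at each dose.
#' @return An object of class \code{hill_fit} with \code{emin}, \code{emax},
#'   \code{ec50}, \code{h}, \code{sse}.
#' @export
fit_hill <- function(doses, responses) {
  stopifnot(length(doses) == length(responses), length(doses) >= 5,
            all(doses > 0))
  if (diff(range(responses)) == 0) stop("flat response")
  x <- doses
  r <- responses
  fit <- minpack.lm::nls.lm(
    par = c(Emin = min(r), Emax = max(r), EC50 = exp(mean(log(x))), H = 1),
    lower = c(-Inf, -Inf, 1e-12, 1e-6),
    fn = function(p) r - (p[1] + (p[2] - p[1]) / (1 + (p[3] / x)^p[4])),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info < 1 || fit$info > 4) {
    stop("sigmoid fit did not converge: ", fit$message)
  }
  co <- fit$par
  if (co["Emax"] <= co["Emin"]) stop("fit degenerate: Emax <= Emin")
  structure(list(emin = unname(co["Emin"]), emax = unname(co["Emax"]),
                 ec50 = unname(co["EC50"]), h = unname(co["H"]),
                 sse = fit$deviance,
                 doses = x, responses = r),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: Emin = %.3g%%, Emax = %.3g%%, EC50 = %.4g, H = %.3g\n",
              x$emin, x$emax, x$ec50, x$h))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(Emin = object$emin, Emax = object$emax, EC50 = object$ec50, H = object$h)
}

#' @export
predict.hill_fit <- function(object, doses = NULL, ...) {
  x <- if (is.null(doses)) object$doses else doses
  object$emin + (object$emax - object$emin) / (1 + (object$ec50 / x)^object$h)
}

.potency_result <- function(px = NA_real_, excluded = FALSE,
                            reason = NA_character_) {
  list(px = px, excluded = excluded, reason = reason)
}

#' Interpolate threshold potency from a fitted sigmoid
#'
#' The potency PX is the dose at which the fitted curve crosses X percent
#' activation, obtained by analytic inversion of the sigmoid:
#' \deqn{P_X = EC_{50} \Big/ \left(\frac{E_{max}-E_{min}}{X-E_{min}} -
#'   1\right)^{1/H}.}
#' A ligand whose fitted plateau never reaches X is excluded with reason
#' \code{"below-threshold response"}; a PX beyond the highest dose actually
#' tested is excluded with reason \code{"extrapolated"} (no extrapolated
#' potencies are ever returned).
#'
#' @param fit A \code{\link{fit_hill}} result.
#' @param x_percent Threshold X in percent (must exceed the fitted baseline).
#' @param max_dose Highest dose tested.
#' @return List with \code{px}, \code{excluded}, \code{reason}.
#' @export
interpolate_potency <- function(fit, x_percent, max_dose) {
  stopifnot(inherits(fit, "hill_fit"))
  if (x_percent <= fit$emin) stop("threshold X is at or below the baseline Emin")
  if (fit$emax <= x_percent) {
    return(.potency_result(excluded = TRUE, reason = "below-threshold response"))
  }
  px <- fit$ec50 / ((fit$emax - fit$emin) / (x_percent - fit$emin) - 1)^(1 / fit$h)
  if (px > max_dose) {
    return(.potency_result(px = px, excluded = TRUE, reason = "extrapolated"))
  }
  .potency_result(px = px)
}

#' Threshold potency directly from tabulated curve points
#'
#' Literature mode: with only plotted dose-response points available, PX is
#' estimated by drawing a horizontal line at X and interpolating the first
#' pair of points that brackets it, linearly in (log10 dose, response) —
#' dose-response graphs are log-scaled in dose. If the data never cross X
#' within the tested range the ligand is excluded (never extrapolated).
#'
#' @param doses Strictly increasing doses (at least 2).
#' @param responses Responses (percent) at each dose.
#' @param x_percent Threshold X.
#' @return List with \code{px}, \code{excluded}, \code{reason}. If the curve
#'   crosses X more than once the first crossing is used with a warning.
#' @export
potency_from_points <- function(doses, responses, x_percent) {
  stopifnot(length(doses) == length(responses), length(doses) >= 2,
            all(diff(doses) > 0), all(doses > 0))
  s <- responses - x_percent
  n <- length(s)
  exact <- which(s == 0)                       # points landing on X
  strict <- which(s[-n] * s[-1] < 0)           # sign-change intervals
  pos <- c(exact, strict + 0.5)                # order along the dose axis
  if (length(pos) == 0) {
    return(.potency_result(excluded = TRUE, reason = "no crossing in range"))
  }
  if (length(pos) > 1) {
    warning("multiple threshold crossings; using the first")
  }
  first <- sort(pos)[1]
  if (first == floor(first)) {
    return(.potency_result(px = doses[first]))
  }
  i <- floor(first)
  f <- s[i] / (s[i] - s[i + 1])
  lp <- log10(doses[i]) + f * (log10(doses[i + 1]) - log10(doses[i]))
  .potency_result(px = 10^lp)
}

#' Potency table from dose-response data
#'
#' Fits a sigmoid per (experiment, ligand) group and interpolates PX at the
#' configured threshold, recording exclusions.
#'
#' @param dose_response Data.frame in the \code{dose_response} schema.
#' @param x_percent Threshold X in percent.
#' @return Data.frame with \code{experiment_id}, \code{ligand_id},
#'   \code{potency}, \code{flag} (empty, \code{"extrapolated"}, or
#'   \code{"below-threshold response"}).
#' @export
potency_report <- function(dose_response, x_percent = 15) {
  key <- interaction(dose_response$experiment_id, dose_response$ligand_id,
                     drop = TRUE)
  rows <- lapply(split(dose_response, key), function(d) {
    d <- d[order(d$dose), ]
    res <- tryCatch({
      fit <- fit_hill(d$dose, d$response_percent)
      interpolate_potency(fit, x_percent, max(d$dose))
    }, error = function(e) .potency_result(excluded = TRUE,
                                           reason = conditionMessage(e)))
    data.frame(experiment_id = d$experiment_id[1],
               ligand_id = d$ligand_id[1],
               potency = res$px,
               flag = if (res$excluded) res$reason else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
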