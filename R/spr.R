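#' Steady-state SPR binding curve
#'
#' Container for one double-referenced steady-state titration: injected TCR
#' concentrations (uM, strictly increasing, at least 4 points) and the
#' steady-state binding response (RU).
#'
#' @param tcr_conc_uM Numeric vector of TCR concentrations, uM.
#' @param response_RU Numeric vector of steady-state responses, RU.
#' @param ligand_id,replicate_id Identifiers.
#' @return An object of class \code{binding_curve}.
#' @export
binding_curve <- function(tcr_conc_uM, response_RU, ligand_id = "ligand",
                          replicate_id = "1") {
  stopifnot(length(tcr_conc_uM) == length(response_RU),
            length(tcr_conc_uM) >= 4,
            all(tcr_conc_uM > 0),
            all(diff(tcr_conc_uM) > 0))
  structure(list(tcr_conc_uM = as.numeric(tcr_conc_uM),
                 response_RU = as.numeric(response_RU),
                 ligand_id = ligand_id, replicate_id = replicate_id),
            class = "binding_curve")
}

#' Double referencing of SPR series
#'
#' Subtracts the reference flow-cell signal and the mean of the two closest
#' (already reference-subtracted) buffer injections, removing both bulk
#' refractive-index differences and slow drifts between flow cells.
#'
#' @param signal Raw signal series (RU).
#' @param reference Reference flow-cell series (RU), same length.
#' @param buffer_before,buffer_after Reference-subtracted buffer-injection
#'   series flanking the analyte injection, same length.
#' @return Double-referenced series.
#' @export
double_reference <- function(signal, reference, buffer_before, buffer_after) {
  n <- length(signal)
  if (length(reference) != n || length(buffer_before) != n ||
      length(buffer_after) != n) {
    stop("all series must have equal length")
  }
  (signal - reference) - (buffer_before + buffer_after) / 2
}

.langmuir_sse <- function(kd, bmax, t, b) {
  sum((b - bmax * t / (kd + t))^2)
}

.new_langmuir_fit <- function(kd, bmax, method, sse, curve) {
  structure(list(kd = kd, bmax = bmax, method = method, sse = sse,
                 saturation_ratio = max(curve$tcr_conc_uM) / kd,
                 curve = curve),
            class = "langmuir_fit")
}

#' Free-Bmax Langmuir fit of a steady-state SPR titration
#'
#' Least-squares fit of the Langmuir isotherm
#' \eqn{B = B_{max} [TCR] / (K_D + [TCR])} with both \eqn{K_D} and
#' \eqn{B_{max}} free (the standard steady-state method). For curves that do
#' not approach saturation the sum-of-squares surface has a ridge along
#' \eqn{B_{max}/K_D \approx} const and the individual parameters are poorly
#' identified; see \code{\link{fit_langmuir_constrained}}.
#'
#' Levenberg-Marquardt least squares with positivity bounds; initial values
#' \eqn{K_D^{(0)} = } median concentration, \eqn{B_{max}^{(0)} = 1.2 \max B}.
#'
#' @param curve A \code{\link{binding_curve}}.
#' @return An object of class \code{langmuir_fit} with components \code{kd}
#'   (uM), \code{bmax} (RU), \code{method}, \code{sse},
#'   \code{saturation_ratio} (max concentration / fitted KD).
#' @export
fit_langmuir_free <- function(curve) {
  stopifnot(inherits(curve, "binding_curve"))
  t <- curve$tcr_conc_uM
  b <- curve$response_RU
  if (diff(range(b)) == 0) stop("degenerate flat curve")
  fit <- minpack.lm::nls.lm(
    par = c(KD = stats::median(t), Bmax = 1.2 * max(b)),
    lower = c(1e-9, 1e-9),
    fn = function(p) b - p[2] * t / (p[1] + t),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info < 1 || fit$info > 4) {
    stop("Langmuir fit did not converge: ", fit$message)
  }
  .new_langmuir_fit(unname(fit$par["KD"]), unname(fit$par["Bmax"]), "free",
                    fit$deviance, curve)
}

#' Fit the maximal antibody binding of a W6/32 trace
#'
#' The conformation-sensitive W6/32 antibody binds only correctly folded
#' pMHC, so its maximal binding reports the active ligand density on the
#' surface. Its slow-binding trace is summarised by the empirical model
#' \eqn{R = R_{max} t / (K_t + t)}, with \eqn{K_t} a nuisance timescale.
#'
#' @param time_s Time since injection start, s (at least 5 points, > 0).
#' @param response_RU Double-referenced antibody response, RU.
#' @return An object of class \code{w632_fit} with \code{rmax}, \code{kt},
#'   \code{sse}.
#' @export
fit_w632_rmax <- function(time_s, response_RU) {
  stopifnot(length(time_s) == length(response_RU), length(time_s) >= 5,
            all(time_s > 0))
  t <- time_s
  r <- response_RU
  fit <- minpack.lm::nls.lm(
    par = c(Rmax = max(r), Kt = stats::median(t)),
    lower = c(1e-9, 0),
    fn = function(p) r - p[1] * t / (p[2] + t),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info < 1 || fit$info > 4) {
    stop("antibody trace fit did not converge: ", fit$message)
  }
  structure(list(rmax = unname(fit$par["Rmax"]), kt = unname(fit$par["Kt"]),
                 sse = fit$deviance),
            class = "w632_fit")
}

#' Build the antibody-to-Bmax standard curve
#'
#' Relates maximal W6/32 antibody binding (Rmax) to the fitted Langmuir
#' Bmax across surfaces where Bmax is reliable. Only free fits whose
#' titration reached \code{min_saturation_ratio} times the fitted KD are
#' retained — the inclusion rule that guarantees the binding curve actually
#' saturated. An ordinary least-squares line \eqn{B_{max} = a R_{max} + b}
#' is fitted over the retained pairs and the Rmax range over which
#' interpolation is valid is recorded.
#'
#' @param rmax Numeric vector of W6/32 Rmax values (RU).
#' @param fits List of free \code{langmuir_fit} objects, same length.
#' @param min_saturation_ratio Inclusion threshold, default 2.5.
#' @return An object of class \code{standard_curve} with \code{slope},
#'   \code{intercept}, \code{n_points}, \code{rmax_range}.
#' @export
build_standard_curve <- function(rmax, fits, min_saturation_ratio = 2.5) {
  stopifnot(length(rmax) == length(fits))
  for (f in fits) {
    stopifnot(inherits(f, "langmuir_fit"))
    if (f$method != "free") stop("standard curve requires free-Bmax fits")
  }
  sat <- vapply(fits, function(f) f$saturation_ratio, numeric(1))
  keep <- sat >= min_saturation_ratio
  if (sum(keep) < 3) {
    stop("fewer than 3 pairs with saturation ratio >= ", min_saturation_ratio)
  }
  x <- rmax[keep]
  y <- vapply(fits[keep], function(f) f$bmax, numeric(1))
  lf <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(lf)[2]),
                 intercept = unname(stats::coef(lf)[1]),
                 n_points = sum(keep),
                 rmax_range = range(x)),
            class = "standard_curve")
}

#' Interpolate Bmax from the standard curve
#'
#' @param std A \code{standard_curve}.
#' @param rmax W6/32 Rmax of the surface (RU); must lie inside the standard
#'   curve's fitted Rmax range (interpolation only, never extrapolation).
#' @return Predicted Bmax (RU).
#' @export
predict_bmax <- function(std, rmax) {
  stopifnot(inherits(std, "standard_curve"))
  if (rmax < std$rmax_range[1] || rmax > std$rmax_range[2]) {
    stop("rmax ", format(rmax), " outside the standard curve range [",
         format(std$rmax_range[1]), ", ", format(std$rmax_range[2]),
         "]; extrapolation refused")
  }
  std$slope * rmax + std$intercept
}

#' Constrained-Bmax Langmuir fit
#'
#' Fixes \eqn{B_{max}} at the value interpolated from the W6/32 standard
#' curve and solves a one-dimensional least-squares problem over \eqn{K_D}
#' alone (golden-section search on \eqn{\log_{10} K_D}). This removes the
#' ridge degeneracy of the free fit on non-saturating curves, extending
#' reliable affinity estimation into the very-low-affinity (high KD) regime.
#'
#' @param curve A \code{\link{binding_curve}}.
#' @param std A \code{\link{build_standard_curve}} result.
#' @param rmax W6/32 Rmax of this surface (RU); interpolation-only.
#' @return A \code{langmuir_fit} with \code{method = "constrained"}.
#' @export
fit_langmuir_constrained <- function(curve, std, rmax) {
  stopifnot(inherits(curve, "binding_curve"))
  bmax <- predict_bmax(std, rmax)
  if (bmax <= 0) stop("interpolated Bmax is non-positive")
  t <- curve$tcr_conc_uM
  b <- curve$response_RU
  opt <- stats::optimize(function(lkd) .langmuir_sse(10^lkd, bmax, t, b),
                         interval = c(-6, 7), tol = 1e-10)
  .new_langmuir_fit(10^opt$minimum, bmax, "constrained", opt$objective, curve)
}

#' Select the reported KD between free and constrained fits
#'
#' The constrained method is most valuable where curves cannot saturate;
#' for high affinities the free fit is reliable and less dependent on the
#' standard curve. The reporting rule: if the constrained KD is strictly
#' above \code{switch_threshold} (default 20 uM) report the constrained KD,
#' otherwise report the free-fit KD.
#'
#' @param free,constrained \code{langmuir_fit} objects for the same curve.
#' @param switch_threshold KD threshold, uM.
#' @return List with \code{kd} and \code{method}.
#' @export
select_reported_kd <- function(free, constrained, switch_threshold = 20) {
  stopifnot(inherits(free, "langmuir_fit"), free$method == "free",
            inherits(constrained, "langmuir_fit"),
            constrained$method == "constrained")
  if (constrained$kd > switch_threshold) {
    list(kd = constrained$kd, method = "constrained")
  } else {
    list(kd = free$kd, method = "free")
  }
}

#' Coefficient of variation across replicate KD estimates
#'
#' Sample standard deviation divided by the mean; the replicate-precision
#' diagnostic used to compare the free and constrained methods.
#'
#' @param kds Numeric vector of at least 2 replicate KD estimates.
#' @return CV (dimensionless).
#' @export
replicate_cv <- function(kds) {
  stopifnot(length(kds) >= 2)
  m <- mean(kds)
  if (m <= 0) stop("mean KD must be positive")
  stats::sd(kds) / m
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("Langmuir fit (%s Bmax): KD = %.4g uM, Bmax = %.4g RU\n",
              x$method, x$kd, x$bmax))
  cat(sprintf("  SSE %.4g, saturation ratio max[TCR]/KD = %.3g\n",
              x$sse, x$saturation_ratio))
  invisible(x)
}

#' @export
coef.langmuir_fit <- function(object, ...) {
  c(KD = object$kd, Bmax = object$bmax)
}

#' @export
predict.langmuir_fit <- function(object, tcr_conc_uM = NULL, ...) {
  t <- if (is.null(tcr_conc_uM)) object$curve$tcr_conc_uM else tcr_conc_uM
  object$bmax * t / (object$kd + t)
}

#' @export
residuals.langmuir_fit <- function(object, ...) {
  object$curve$response_RU - predict(object)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: Bmax = %.4g * Rmax + %.4g (n = %d)\n",
              x$slope, x$intercept, x$n_points))
  cat(sprintf("  valid Rmax range [%.4g, %.4g] RU\n",
              x$rmax_range[1], x$rmax_range[2]))
  invisible(x)
}

#' Per-ligand KD report combining free and constrained methods
#'
#' Runs the full affinity workflow on tabulated data: free Langmuir fits on
#' every curve, W6/32 Rmax fits per ligand, the saturation-filtered standard
#' curve, constrained fits, the reporting rule, and replicate CVs.
#'
#' @param binding Data.frame in the \code{binding_curve} schema.
#' @param traces Data.frame in the \code{antibody_trace} schema.
#' @param config A \code{\link{pipeline_config}}.
#' @return Data.frame with one row per ligand/replicate: \code{ligand_id},
#'   \code{replicate_id}, \code{kd_free}, \code{kd_constrained},
#'   \code{kd_reported}, \code{method}, \code{bmax}, \code{rmax},
#'   \code{saturation_ratio}, \code{cv}.
#' @export
kd_report <- function(binding, traces, config = pipeline_config()) {
  if (!"replicate_id" %in% names(binding)) binding$replicate_id <- "1"
  key <- interaction(binding$ligand_id, binding$replicate_id, drop = TRUE)
  curves <- lapply(split(binding, key), function(d) {
    d <- d[order(d$tcr_conc_uM), ]
    binding_curve(d$tcr_conc_uM, d$response_RU, d$ligand_id[1],
                  d$replicate_id[1])
  })
  free_fits <- lapply(curves, fit_langmuir_free)
  rmax_by_ligand <- vapply(split(traces, traces$ligand_id), function(d) {
    fit_w632_rmax(d$time_s, d$response_RU)$rmax
  }, numeric(1))
  rmax <- rmax_by_ligand[vapply(curves, `[[`, "", "ligand_id")]
  std <- build_standard_curve(unname(rmax), free_fits,
                              config$spr$saturation_ratio)
  rows <- lapply(seq_along(curves), function(i) {
    cons <- tryCatch(fit_langmuir_constrained(curves[[i]], std, rmax[i]),
                     error = function(e) NULL)
    if (is.null(cons)) {
      # surface outside the standard curve's interpolation range: only the
      # free fit is available
      rep_kd <- list(kd = free_fits[[i]]$kd, method = "free")
    } else {
      rep_kd <- select_reported_kd(free_fits[[i]], cons,
                                   config$spr$kd_switch_threshold)
    }
    data.frame(ligand_id = curves[[i]]$ligand_id,
               replicate_id = curves[[i]]$replicate_id,
               kd_free = free_fits[[i]]$kd,
               kd_constrained = if (is.null(cons)) NA_real_ else cons$kd,
               kd_reported = rep_kd$kd,
               method = rep_kd$method,
               bmax = if (is.null(cons)) NA_real_ else cons$bmax,
               rmax = unname(rmax[i]),
               saturation_ratio = free_fits[[i]]$saturation_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cv <- tapply(out$kd_reported, out$ligand_id, function(k) {
    if (length(k) >= 2) replicate_cv(k) else NA_real_
  })
  out$cv <- as.numeric(cv[out$ligand_id])
  rownames(out) <- NULL
  out
}
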