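#' Exact stochastic simulation of the proofreading chain
#'
#' Gillespie simulation of the reaction network
#' \eqn{L + R \to C_0} (rate \eqn{k_{on} L R}, per-molecule \eqn{k_{on}}),
#' \eqn{C_i \to C_{i+1}} (rate \eqn{k_p C_i}, \eqn{i < N}),
#' \eqn{C_i \to L + R} (rate \eqn{k_{off} C_i}), starting from all
#' molecules free, run to \code{t_end}. Molecule counts are conserved at
#' every event. Uses R's RNG: seed with \code{set.seed()} for
#' reproducibility.
#'
#' @param n Integer number of proofreading steps (>= 0).
#' @param kp Proofreading rate, s^-1.
#' @param kon Per-molecule association rate, s^-1 per pair.
#' @param koff Dissociation rate, s^-1.
#' @param l0,r0 Initial ligand and receptor counts (non-negative integers).
#' @param t_end Simulated time, s.
#' @param n_realisations Number of independent realisations.
#' @return Numeric vector of final-step counts \eqn{C_N(t_{end})}, one per
#'   realisation.
#' @export
gillespie_kp <- function(n, kp, kon, koff, l0, r0, t_end,
                         n_realisations = 1L) {
  stopifnot(n >= 0, n == round(n), kp >= 0, kon >= 0, koff >= 0,
            l0 >= 0, r0 >= 0, t_end > 0, n_realisations >= 1)
  .gillespie_cn_cpp(as.integer(n), kp, kon, koff, l0, r0, t_end,
                    as.integer(n_realisations))
}

#' Ensemble mean of the final-step occupancy
#'
#' Mean of \eqn{C_N(t_{end})} over independent realisations, with its
#' standard error (sample SD over the square root of the ensemble size).
#'
#' @inheritParams gillespie_kp
#' @return List with \code{mean}, \code{se}, \code{values}.
#' @export
ensemble_mean_cn <- function(n, kp, kon, koff, l0, r0, t_end = 100,
                             n_realisations = 250L) {
  v <- gillespie_kp(n, kp, kon, koff, l0, r0, t_end, n_realisations)
  list(mean = mean(v),
       se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
       values = v)
}

#' Sensitivity/discrimination phase map over (N, tau)
#'
#' Classifies each grid point (N proofreading steps, per-step time
#' tau = 1/kp) as sensitive and/or discriminating. Two scenarios are
#' evaluated: sensitivity uses a single high-affinity ligand with
#' koff = 1 s^-1 and asks whether the final-step occupancy exceeds the
#' activation threshold lambda; discrimination raises the ligand count to
#' \code{l_high} and lowers affinity by \eqn{\Delta_A = l_{high}^{1/\alpha}}
#' (so koff = \eqn{\Delta_A}) and asks whether occupancy stays below
#' lambda. A receptor achieving both can detect a rare strong ligand while
#' rejecting an abundant weak one at the discrimination power alpha.
#'
#' In deterministic mode the closed-form criteria
#' (\code{\link{sensitivity_ok}}, \code{\link{discrimination_ok}}) are
#' evaluated (N may be fractional); in stochastic mode Gillespie ensembles
#' are compared to lambda (integer N), and the ensemble means and standard
#' errors are recorded per cell. Cells exactly at threshold do not pass
#' (strict inequalities).
#'
#' The per-molecule association rate defaults to
#' \code{100 * koff_sens / r0}, making receptor occupancy of the single
#' sensitivity-scenario ligand > 99 percent, the binding-dominated regime
#' the deterministic criteria assume.
#'
#' @param n_values Grid of step numbers N.
#' @param tau_values Grid of per-step times tau = 1/kp, s.
#' @param alpha Discrimination power defining the affinity penalty.
#' @param mode \code{"deterministic"} or \code{"stochastic"}.
#' @param lambda Activation threshold (complex count), default 0.1.
#' @param l_high Ligand count of the weak-ligand scenario, default 10000.
#' @param r0 Receptor count, default 30000.
#' @param koff_sens Dissociation rate of the strong ligand, default 1 s^-1.
#' @param kon Per-molecule association rate; default
#'   \code{100 * koff_sens / r0}.
#' @param n_realisations,t_end Stochastic-mode ensemble size and end time
#'   (s). \code{t_end} may be a length-2 vector giving the sensitivity and
#'   discrimination scenario end times separately.
#' @param seed Seed for stochastic mode.
#' @return Data.frame of class \code{phase_map}: \code{n}, \code{tau},
#'   \code{sensitive}, \code{discriminating}, plus (stochastic mode)
#'   \code{mean_cn_sens}, \code{se_sens}, \code{mean_cn_disc},
#'   \code{se_disc}; attributes \code{mode} and \code{alpha}.
#' @export
phase_map <- function(n_values, tau_values, alpha = 2,
                      mode = c("deterministic", "stochastic"),
                      lambda = 0.1, l_high = 10000, r0 = 30000,
                      koff_sens = 1, kon = NULL,
                      n_realisations = 250L, t_end = 100, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, all(tau_values > 0), all(n_values >= 0))
  if (is.null(kon)) kon <- 100 * koff_sens / r0
  delta_a <- l_high^(1 / alpha)
  t_end <- rep_len(t_end, 2)
  grid <- expand.grid(n = n_values, tau = tau_values,
                      KEEP.OUT.ATTRS = FALSE)
  if (mode == "deterministic") {
    grid$sensitive <- mapply(function(n, tau) {
      sensitivity_ok(n, 1 / tau, koff_sens, lambda)
    }, grid$n, grid$tau)
    grid$discriminating <- mapply(function(n, tau) {
      discrimination_ok(n, 1 / tau, koff_sens, lambda, alpha, l_high, r0)
    }, grid$n, grid$tau)
  } else {
    stopifnot(all(n_values == round(n_values)))
    set.seed(seed)
    res <- mapply(function(n, tau) {
      kp <- 1 / tau
      sens <- ensemble_mean_cn(n, kp, kon, koff_sens, l0 = 1, r0 = r0,
                               t_end = t_end[1],
                               n_realisations = n_realisations)
      disc <- ensemble_mean_cn(n, kp, kon, koff = delta_a, l0 = l_high,
                               r0 = r0, t_end = t_end[2],
                               n_realisations = n_realisations)
      c(sens$mean, sens$se, disc$mean, disc$se)
    }, grid$n, grid$tau)
    grid$mean_cn_sens <- res[1, ]
    grid$se_sens <- res[2, ]
    grid$mean_cn_disc <- res[3, ]
    grid$se_disc <- res[4, ]
    grid$sensitive <- grid$mean_cn_sens > lambda
    grid$discriminating <- grid$mean_cn_disc < lambda
  }
  structure(grid, mode = mode, alpha = alpha, lambda = lambda,
            class = c("phase_map", "data.frame"))
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("Phase map (%s mode, alpha = %g, lambda = %g): %d cells\n",
              attr(x, "mode"), attr(x, "alpha"), attr(x, "lambda"), nrow(x)))
  both <- x$sensitive & x$discriminating
  cat(sprintf("  sensitive %d, discriminating %d, both %d\n",
              sum(x$sensitive), sum(x$discriminating), sum(both)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Diagnostic plot of a phase map
#'
#' Sensitivity (circles) and discrimination (squares) over the (tau, N)
#' grid; filled symbols mark cells achieving both.
#'
#' @param x A \code{\link{phase_map}}.
#' @param ... Passed to \code{plot}.
#' @export
plot.phase_map <- function(x, ...) {
  both <- x$sensitive & x$discriminating
  plot(x$tau, x$n, type = "n", log = "x", xlab = "tau = 1/kp (s)",
       ylab = "N (proofreading steps)",
       main = sprintf("alpha = %g", attr(x, "alpha")), ...)
  points(x$tau[x$sensitive], x$n[x$sensitive], pch = 1, col = "red", cex = 1.8)
  points(x$tau[x$discriminating], x$n[x$discriminating], pch = 0,
         col = "blue", cex = 1.2)
  points(x$tau[both], x$n[both], pch = 16, col = "purple", cex = 0.6)
  invisible(x)
}
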