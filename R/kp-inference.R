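#' Prior specification for the hierarchical KP fit
#'
#' Uniform priors, in log10 space for every parameter except the number of
#' steps N (linear). The global parameters are N, gamma, delta_hat; each
#' experiment contributes a local proofreading rate kp and rescaled
#' threshold lambda_hat, so a fit to I experiments has 3 + 2I parameters
#' (27 for 12 experiments, 37 for 17).
#'
#' Bounds: N ~ Unif(0, 4); log10(kp) ~ Unif(-1, 1);
#' log10(lambda_hat) ~ Unif(-4, 1) for plate-presented ligand data or
#' Unif(-6, -3) for cell (APC) data; log10(gamma) ~ Unif(-6, -4);
#' log10(delta_hat) ~ Unif(-7, -5).
#'
#' @param n_experiments Number of experiments I.
#' @param mode \code{"plate"} or \code{"cell"} (changes the lambda_hat
#'   prior).
#' @return Object of class \code{kp_priors}: data.frame with \code{name},
#'   \code{lower}, \code{upper}, \code{scale} plus attribute
#'   \code{n_experiments}.
#' @export
kp_priors <- function(n_experiments, mode = c("plate", "cell")) {
  mode <- match.arg(mode)
  stopifnot(n_experiments >= 1)
  lh <- if (mode == "plate") c(-4, 1) else c(-6, -3)
  df <- rbind(
    data.frame(name = "N", lower = 0, upper = 4, scale = "linear"),
    data.frame(name = "log10_gamma", lower = -6, upper = -4, scale = "log10"),
    data.frame(name = "log10_delta_hat", lower = -7, upper = -5,
               scale = "log10"),
    data.frame(name = sprintf("log10_kp_%d", seq_len(n_experiments)),
               lower = -1, upper = 1, scale = "log10"),
    data.frame(name = sprintf("log10_lambda_hat_%d", seq_len(n_experiments)),
               lower = lh[1], upper = lh[2], scale = "log10")
  )
  stopifnot(all(df$lower < df$upper))
  structure(df, n_experiments = n_experiments, mode = mode,
            class = c("kp_priors", "data.frame"))
}

#' Annealing schedule for the Metropolis-Hastings KP fit
#'
#' The acceptance temperature xi starts at 10 and is lowered to successive
#' values as the chain's distance first reaches successive thresholds; the
#' chain terminates once the distance falls below
#' \code{termination_distance}. The built-in schedules are those used for
#' the plate data (thresholds 50, 30, 20, 18, 17.5 -> xi 1, 0.1, 0.01,
#' 0.005, 0.001; termination 11.08) and the cell data (100, 75, 50, 40, 35;
#' termination 39.2). Those distances are tuned to the residual level of
#' the corresponding datasets; for synthetic data with known noise use
#' \code{\link{synthetic_schedule}}.
#'
#' @param mode \code{"plate"} or \code{"cell"}, or supply all pieces.
#' @param xi0 Initial temperature.
#' @param thresholds Strictly decreasing distance thresholds.
#' @param xi_values Strictly decreasing temperatures, same length.
#' @param termination_distance Stop when distance < this.
#' @param max_steps Safeguard on proposals per chain.
#' @return Object of class \code{anneal_schedule}.
#' @export
anneal_schedule <- function(mode = c("plate", "cell"), xi0 = 10,
                            thresholds = NULL, xi_values = NULL,
                            termination_distance = NULL, max_steps = 5e6) {
  mode <- match.arg(mode)
  if (is.null(thresholds)) {
    thresholds <- if (mode == "plate") c(50, 30, 20, 18, 17.5)
                  else c(100, 75, 50, 40, 35)
  }
  if (is.null(xi_values)) xi_values <- c(1, 0.1, 0.01, 0.005, 0.001)
  if (is.null(termination_distance)) {
    termination_distance <- if (mode == "plate") 11.08 else 39.2
  }
  stopifnot(length(thresholds) == length(xi_values),
            all(diff(thresholds) < 0), all(diff(xi_values) < 0),
            xi0 > xi_values[1], termination_distance > 0, max_steps >= 1)
  structure(list(xi0 = xi0, thresholds = thresholds, xi_values = xi_values,
                 termination_distance = termination_distance,
                 max_steps = max_steps),
            class = "anneal_schedule")
}

#' Annealing schedule scaled to a synthetic dataset's noise level
#'
#' The termination distance defaults to \code{n_points * sigma_log^2 * 1.2}
#' (20 percent above the expected residual sum at truth); the xi-switch
#' thresholds and the temperatures themselves are the plate schedule's
#' scaled by the same factor relative to its termination distance — the
#' distance and the temperature enter the acceptance rule only through
#' \eqn{\Delta D / \xi}, so both must carry the dataset's residual scale.
#'
#' @param n_points Total data points entering the distance.
#' @param sigma_log Known lognormal potency noise, log10 units.
#' @param max_steps Safeguard on proposals per chain.
#' @return An \code{\link{anneal_schedule}}.
#' @export
synthetic_schedule <- function(n_points, sigma_log, max_steps = 5e6) {
  stopifnot(n_points >= 1, sigma_log > 0)
  term <- n_points * sigma_log^2 * 1.2
  s <- term / 11.08
  anneal_schedule("plate", xi0 = 10 * s,
                  thresholds = c(50, 30, 20, 18, 17.5) * s,
                  xi_values = c(1, 0.1, 0.01, 0.005, 0.001) * s,
                  termination_distance = term, max_steps = max_steps)
}

# Internal: reshape a potency table for fitting. Rows with flags, missing
# potency, or missing KD are dropped (unreachable ligands carry no potency).
.kp_prepare_data <- function(potency_table) {
  tab <- potency_table
  if ("flag" %in% names(tab)) {
    tab <- tab[is.na(tab$flag) | !nzchar(tab$flag), , drop = FALSE]
  }
  tab <- tab[is.finite(tab$potency) & tab$potency > 0 &
             is.finite(tab$kd_uM) & tab$kd_uM > 0, , drop = FALSE]
  if (nrow(tab) == 0) stop("no usable potency records")
  expts <- sort(unique(tab$experiment_id))
  list(kd = tab$kd_uM, logp = log10(tab$potency),
       expt = match(tab$experiment_id, expts) - 1L,
       experiments = expts, n_points = nrow(tab))
}

#' Distance between KP model and multi-experiment potency data
#'
#' Sum over experiments i and data points j of the squared log10 residuals
#' \eqn{(\rho(N, k_{p,i}, \hat\lambda_i, \gamma, \hat\delta; K_{D,ij}) -
#' \log_{10} P_{ij})^2}. If the model predicts any observed ligand to be
#' unreachable the distance is \code{+Inf} (a valid return, never an
#' error). This reference implementation is plain R; the chain sampler uses
#' an equivalent compiled kernel.
#'
#' @param theta Parameter vector on the fitting scale: \code{c(N,
#'   log10(gamma), log10(delta_hat), log10(kp_1..I),
#'   log10(lambda_hat_1..I))}.
#' @param potency_table Data.frame with \code{experiment_id}, \code{kd_uM},
#'   \code{potency} (and optional \code{flag}).
#' @param kon Association rate, uM^-1 s^-1.
#' @return Scalar distance D.
#' @export
kp_distance <- function(theta, potency_table, kon = KON_DEFAULT) {
  d <- .kp_prepare_data(potency_table)
  ii <- length(d$experiments)
  stopifnot(length(theta) == 3 + 2 * ii)
  n <- theta[1]
  gamma <- 10^theta[2]
  delta_hat <- 10^theta[3]
  kp <- 10^theta[3 + seq_len(ii)]
  lh <- 10^theta[3 + ii + seq_len(ii)]
  rho <- log_potency_rho(n, kp[d$expt + 1L], lh[d$expt + 1L], gamma,
                         delta_hat, d$kd, kon)
  if (anyNA(rho)) return(Inf)
  sum((rho - d$logp)^2)
}

#' Perturbation kernel of the KP chain
#'
#' Shifts every coordinate independently by a uniform draw on
#' \code{[-step_frac, step_frac]} times the width of its prior, on the
#' fitting scale (linear for N, log10 otherwise); with the default
#' step_frac = 0.005 the N shift is drawn from [-0.02, 0.02]. Values
#' falling outside the prior bounds are reflected symmetrically back
#' inside.
#'
#' @param theta Current parameter vector (fitting scale, within bounds).
#' @param priors A \code{\link{kp_priors}}.
#' @param step_frac Half-width of the shift as a fraction of prior width.
#' @return Candidate parameter vector.
#' @export
kp_perturb <- function(theta, priors, step_frac = 0.005) {
  lower <- priors$lower
  upper <- priors$upper
  stopifnot(length(theta) == length(lower))
  w <- step_frac * (upper - lower)
  cand <- theta + stats::runif(length(theta), -w, w)
  below <- cand < lower
  cand[below] <- 2 * lower[below] - cand[below]
  above <- cand > upper
  cand[above] <- 2 * upper[above] - cand[above]
  cand
}

#' Metropolis acceptance rule of the annealed chain
#'
#' A candidate with smaller distance is always accepted; otherwise it is
#' accepted with probability \eqn{\exp(-(D_{cand} - D_{curr})/\xi)}.
#'
#' @param d_current,d_candidate Distances.
#' @param xi Current temperature.
#' @return Logical: accept the candidate.
#' @export
mh_accept <- function(d_current, d_candidate, xi) {
  if (d_candidate < d_current) return(TRUE)
  if (!is.finite(d_candidate)) return(FALSE)
  stats::runif(1) < exp(-(d_candidate - d_current) / xi)
}

#' Run one annealed Metropolis-Hastings chain
#'
#' Draws the initial parameters from the priors, then iterates
#' perturbation and the Metropolis rule, lowering xi per the schedule when
#' the distance first reaches each threshold, until the distance drops
#' below the termination value or \code{max_steps} proposals have been
#' made (flagged as a failed chain).
#'
#' @param potency_table Potency data (see \code{\link{kp_distance}}).
#' @param priors A \code{\link{kp_priors}} matching the experiment count.
#' @param schedule An \code{\link{anneal_schedule}}.
#' @param seed Integer seed for this chain.
#' @param kon Association rate, uM^-1 s^-1.
#' @param switch_on_candidate Whether the xi thresholds are checked against
#'   candidate distances (as worded in the source protocol) or accepted
#'   distances (default; the two differ only for rejected candidates).
#' @return List: \code{theta} (fitting scale), \code{distance},
#'   \code{steps}, \code{accepted}, \code{converged}.
#' @export
run_kp_chain <- function(potency_table, priors, schedule, seed = 1L,
                         kon = KON_DEFAULT, switch_on_candidate = FALSE) {
  d <- .kp_prepare_data(potency_table)
  ii <- length(d$experiments)
  stopifnot(nrow(priors) == 3 + 2 * ii)
  set.seed(seed)
  # draw the starting point from the prior conditioned on a finite
  # distance: a start that predicts an observed ligand unreachable has
  # D = +Inf everywhere in its neighbourhood and the small perturbation
  # kernel could never leave it
  theta0 <- NULL
  for (try in seq_len(10000)) {
    cand <- stats::runif(nrow(priors), priors$lower, priors$upper)
    if (is.finite(.kp_distance_cpp(cand, ii, d$kd, d$logp, d$expt, kon))) {
      theta0 <- cand
      break
    }
  }
  if (is.null(theta0)) {
    stop("could not find a prior draw with finite distance; ",
         "check that the data are compatible with the priors")
  }
  res <- .kp_chain_cpp(theta0, priors$lower, priors$upper, ii, d$kd, d$logp,
                       d$expt, kon, schedule$xi0, schedule$thresholds,
                       schedule$xi_values, schedule$termination_distance,
                       schedule$max_steps, 0.005, switch_on_candidate)
  names(res$theta) <- priors$name
  res$experiments <- d$experiments
  res
}

# theta (fitting scale) -> named natural-scale parameter vector
.theta_natural <- function(theta, ii) {
  c(N = theta[[1]], gamma = 10^theta[[2]], delta_hat = 10^theta[[3]],
    stats::setNames(10^theta[3 + seq_len(ii)], sprintf("kp_%d", seq_len(ii))),
    stats::setNames(10^theta[3 + ii + seq_len(ii)],
                    sprintf("lambda_hat_%d", seq_len(ii))))
}

#' Ensemble fit of the hierarchical KP model
#'
#' Runs \code{n_chains} independent annealed Metropolis-Hastings chains
#' (each from its own prior draw, with sub-seeds derived deterministically
#' from \code{seed}) and collects every chain that terminates below the
#' schedule's distance threshold. The ensemble of final parameter vectors
#' captures the distribution of parameter values compatible with the data;
#' N is summarised by its median with min/max, per-experiment kp by
#' medians, and the proofreading time delay tau_KP = N/kp per chain and
#' experiment, pooled as the mean over per-experiment medians with a 95
#' percent percentile interval across the ensemble.
#'
#' @param potency_table Potency data grouped by \code{experiment_id}.
#' @param n_chains Number of chains (1000 reproduces the full protocol;
#'   scale down for quick studies).
#' @param priors \code{\link{kp_priors}}; defaults to plate priors sized to
#'   the data.
#' @param schedule \code{\link{anneal_schedule}}; required.
#' @param seed Master seed.
#' @param kon Association rate.
#' @param switch_on_candidate Passed to \code{\link{run_kp_chain}}.
#' @return Object of class \code{kp_ensemble}: \code{theta} (matrix of
#'   converged chains, natural scale), \code{distance}, \code{n_failed},
#'   \code{experiments}, \code{summary} (list with \code{n_median},
#'   \code{n_range}, \code{kp_median} per experiment, \code{tau_kp_mean},
#'   \code{tau_kp_ci}).
#' @export
fit_kp_ensemble <- function(potency_table, n_chains = 1000L, priors = NULL,
                            schedule = NULL, seed = 1L, kon = KON_DEFAULT,
                            switch_on_candidate = FALSE) {
  d <- .kp_prepare_data(potency_table)
  ii <- length(d$experiments)
  if (is.null(priors)) priors <- kp_priors(ii, "plate")
  stopifnot(!is.null(schedule), inherits(schedule, "anneal_schedule"))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_chains)
  chains <- lapply(seq_len(n_chains), function(i) {
    run_kp_chain(potency_table, priors, schedule, sub_seeds[i], kon,
                 switch_on_candidate)
  })
  ok <- vapply(chains, `[[`, logical(1), "converged")
  if (!any(ok)) stop("all ", n_chains, " chains failed to converge")
  theta <- do.call(rbind, lapply(chains[ok], function(ch) {
    .theta_natural(ch$theta, ii)
  }))
  dist <- vapply(chains[ok], `[[`, numeric(1), "distance")
  kp_cols <- sprintf("kp_%d", seq_len(ii))
  tau <- theta[, "N"] / theta[, kp_cols, drop = FALSE]   # per chain x expt
  tau_by_expt <- apply(tau, 2, stats::median)
  tau_pooled <- rowMeans(tau)                             # one per chain
  summ <- list(
    n_median = stats::median(theta[, "N"]),
    n_range = range(theta[, "N"]),
    kp_median = stats::setNames(apply(theta[, kp_cols, drop = FALSE], 2,
                                      stats::median), d$experiments),
    kp_range = apply(theta[, kp_cols, drop = FALSE], 2, range),
    kp_pooled_mean = mean(rowMeans(theta[, kp_cols, drop = FALSE])),
    kp_pooled_ci = unname(stats::quantile(
      rowMeans(theta[, kp_cols, drop = FALSE]), c(0.025, 0.975))),
    tau_kp_by_expt = stats::setNames(tau_by_expt, d$experiments),
    tau_kp_mean = mean(tau_pooled),
    tau_kp_ci = unname(stats::quantile(tau_pooled, c(0.025, 0.975)))
  )
  structure(list(theta = theta, distance = dist,
                 n_chains = n_chains, n_failed = sum(!ok),
                 n_parameters = 3L + 2L * ii,
                 experiments = d$experiments, priors = priors,
                 schedule = schedule, summary = summ),
            class = "kp_ensemble")
}

#' @export
print.kp_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("KP ensemble fit: %d/%d chains converged (%d parameters, %d experiments)\n",
              x$n_chains - x$n_failed, x$n_chains, x$n_parameters,
              length(x$experiments)))
  cat(sprintf("  N (steps): median %.3g, range [%.3g, %.3g]\n",
              s$n_median, s$n_range[1], s$n_range[2]))
  cat(sprintf("  kp pooled mean %.3g s^-1 (95%% interval %.3g-%.3g)\n",
              s$kp_pooled_mean, s$kp_pooled_ci[1], s$kp_pooled_ci[2]))
  cat(sprintf("  tau_KP = N/kp pooled mean %.3g s (95%% interval %.3g-%.3g)\n",
              s$tau_kp_mean, s$tau_kp_ci[1], s$tau_kp_ci[2]))
  invisible(x)
}

#' @export
summary.kp_ensemble <- function(object, ...) object$summary

#' @export
coef.kp_ensemble <- function(object, ...) {
  apply(object$theta, 2, stats::median)
}
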