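#' Ground truth for synthetic steady-state SPR data
#'
#' Describes a set of immobilised pMHC surfaces probed with a TCR titration.
#' Only a fraction \code{f_active} of the immobilised ligand is correctly
#' folded and able to bind, so the effective Bmax of a surface is
#' \code{bmax_true * f_active}; the conformation-sensitive antibody reads
#' this active density through the linear relation
#' \code{Bmax_active = slope * Rmax + intercept}.
#'
#' Defaults mimic the study conditions: immobilisation near 1000 RU, KD
#' panels spanning a few uM to the mM regime, an 8-point two-fold TCR
#' dilution series, and additive response noise of ~2 RU.
#'
#' @param kd Named vector of true per-ligand KD values, uM.
#' @param bmax_true Total immobilised density per ligand, RU (recycled).
#' @param f_active Active (folded) fraction in (0, 1].
#' @param slope,intercept Standard-curve coefficients (Bmax over Rmax).
#' @param sigma_ru Additive Gaussian response noise SD, RU.
#' @param tcr_conc_uM Strictly increasing TCR concentration series, uM.
#' @param kt_s Antibody-trace nuisance timescale, s.
#' @return Object of class \code{spr_ground_truth}.
#' @export
spr_ground_truth <- function(kd = c(L1 = 5, L2 = 20, L3 = 60, L4 = 150,
                                    L5 = 500, L6 = 1200),
                             bmax_true = 1000, f_active = 0.7,
                             slope = 1.5, intercept = 20,
                             sigma_ru = 2,
                             tcr_conc_uM = 0.625 * 2^(0:7),
                             kt_s = 30) {
  stopifnot(all(kd > 0), f_active > 0, f_active <= 1, sigma_ru >= 0,
            all(diff(tcr_conc_uM) > 0), all(tcr_conc_uM > 0),
            all(bmax_true > 0), slope > 0)
  if (is.null(names(kd))) names(kd) <- paste0("L", seq_along(kd))
  structure(list(kd = kd,
                 bmax_true = rep_len(bmax_true, length(kd)),
                 f_active = f_active, slope = slope, intercept = intercept,
                 sigma_ru = sigma_ru, tcr_conc_uM = tcr_conc_uM, kt_s = kt_s),
            class = "spr_ground_truth")
}

#' Generate a synthetic SPR dataset
#'
#' Binding responses are drawn from the Langmuir isotherm
#' \eqn{B = B_{max,true} f_{active} T/(K_D + T)} plus Gaussian noise;
#' antibody traces follow \eqn{R = R_{max} t/(K_t + t)} with
#' \eqn{R_{max} = (B_{max,true} f_{active} - b)/s}, so the standard curve
#' holds exactly before noise.
#'
#' @param truth An \code{\link{spr_ground_truth}}.
#' @param seed Integer seed.
#' @param n_replicates Replicate titrations per ligand.
#' @return List with \code{binding_curve} and \code{antibody_trace}
#'   data.frames (pipeline schemas) and the \code{truth} record.
#' @export
generate_spr_dataset <- function(truth, seed = 1L, n_replicates = 1L) {
  stopifnot(inherits(truth, "spr_ground_truth"))
  set.seed(seed)
  tt <- truth$tcr_conc_uM
  bc <- do.call(rbind, lapply(seq_along(truth$kd), function(i) {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      mu <- truth$bmax_true[i] * truth$f_active * tt / (truth$kd[i] + tt)
      data.frame(ligand_id = names(truth$kd)[i],
                 tcr_conc_uM = tt,
                 response_RU = mu + stats::rnorm(length(tt), 0, truth$sigma_ru),
                 replicate_id = as.character(r),
                 stringsAsFactors = FALSE)
    }))
  }))
  times <- seq(10, 600, by = 10)
  at <- do.call(rbind, lapply(seq_along(truth$kd), function(i) {
    rmax <- (truth$bmax_true[i] * truth$f_active - truth$intercept) / truth$slope
    mu <- rmax * times / (truth$kt_s + times)
    data.frame(ligand_id = names(truth$kd)[i],
               time_s = times,
               response_RU = mu + stats::rnorm(length(times), 0, truth$sigma_ru),
               stringsAsFactors = FALSE)
  }))
  rownames(bc) <- rownames(at) <- NULL
  list(binding_curve = bc, antibody_trace = at, truth = unclass(truth))
}

#' Ground truth for synthetic kinetic-proofreading potency data
#'
#' Global parameters (number of steps N, dose-scale conversion gamma,
#' affinity-scale conversion delta_hat) are shared across experiments;
#' the proofreading rate kp and rescaled threshold lambda_hat vary per
#' experiment. Defaults sit mid-prior: N = 2.67 (the fitted number of
#' steps), kp = 1 s^-1, lambda_hat = 10^-1.5, gamma = 10^-5,
#' delta_hat = 10^-6, with KD panels of 8 ligands log-spaced over
#' 3-1500 uM and lognormal potency noise of 0.1 log10 units.
#'
#' @param n Global number of proofreading steps.
#' @param gamma,delta_hat Global conversion constants.
#' @param kp Per-experiment proofreading rates, s^-1 (recycled to
#'   \code{n_experiments} by the generator).
#' @param lambda_hat Per-experiment rescaled thresholds.
#' @param kon Shared association rate, uM^-1 s^-1.
#' @param kd_panel KD values (uM) measured in every experiment; must span
#'   at least two decades for the global parameters to be identifiable.
#' @param sigma_log Lognormal potency noise SD, log10 units.
#' @return Object of class \code{kp_ground_truth}.
#' @export
kp_ground_truth <- function(n = 2.67, gamma = 1e-5, delta_hat = 1e-6,
                            kp = 1, lambda_hat = 10^-1.5,
                            kon = KON_DEFAULT,
                            kd_panel = 10^seq(log10(3), log10(1500),
                                              length.out = 8),
                            sigma_log = 0.1) {
  stopifnot(n >= 0, gamma > 0, delta_hat > 0, all(kp > 0),
            all(lambda_hat > 0), kon > 0, all(kd_panel > 0), sigma_log >= 0)
  if (diff(range(log10(kd_panel))) < 2) {
    warning("KD panel spans fewer than 2 decades; fit may be unidentifiable")
  }
  structure(list(n = n, gamma = gamma, delta_hat = delta_hat, kp = kp,
                 lambda_hat = lambda_hat, kon = kon, kd_panel = kd_panel,
                 sigma_log = sigma_log),
            class = "kp_ground_truth")
}

#' Generate a synthetic multi-experiment potency table from the KP model
#'
#' For each experiment i and ligand j, log10 potency is drawn as
#' \eqn{\rho(N, k_{p,i}, \hat\lambda_i, \gamma, \hat\delta; K_{D,ij}) +
#' \mathcal{N}(0, \sigma_{log})}. Ligands for which the potency expression
#' is undefined (too weak ever to reach threshold) are emitted with an
#' empty potency and flag \code{"unreachable"}; they mirror ligands with no
#' measurable response and are excluded from fitting.
#'
#' @param truth A \code{\link{kp_ground_truth}}.
#' @param n_experiments Number of experiments (>= 1).
#' @param seed Integer seed.
#' @return List with \code{potency_table} (pipeline schema, plus
#'   \code{kd_uM} and \code{flag}) and \code{truth} (per-experiment kp and
#'   lambda_hat expanded).
#' @export
generate_kp_potency_dataset <- function(truth, n_experiments = 12L,
                                        seed = 1L) {
  stopifnot(inherits(truth, "kp_ground_truth"), n_experiments >= 1)
  set.seed(seed)
  kp <- rep_len(truth$kp, n_experiments)
  lh <- rep_len(truth$lambda_hat, n_experiments)
  rows <- do.call(rbind, lapply(seq_len(n_experiments), function(i) {
    rho <- log_potency_rho(truth$n, kp[i], lh[i], truth$gamma,
                           truth$delta_hat, truth$kd_panel, truth$kon)
    lp <- rho + stats::rnorm(length(rho), 0, truth$sigma_log)
    data.frame(study_id = "synthetic",
               experiment_id = sprintf("E%02d", i),
               ligand_id = sprintf("K%02d", seq_along(truth$kd_panel)),
               kd_uM = truth$kd_panel,
               potency = ifelse(is.na(rho), NA_real_, 10^lp),
               readout = "CD69",
               flag = ifelse(is.na(rho), "unreachable", ""),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  expanded <- unclass(truth)
  expanded$kp <- kp
  expanded$lambda_hat <- lh
  expanded$n_experiments <- n_experiments
  list(potency_table = rows, truth = expanded)
}

#' Generate a synthetic potency table from a pure power law
#'
#' Potencies follow \eqn{P = 10^{C + \alpha \log_{10} K_D +
#' \mathcal{N}(0,\sigma_{log})}}; used for end-to-end recovery of the
#' discrimination power.
#'
#' @param alpha,c0 Power-law slope and intercept.
#' @param kd_uM KD panel, uM.
#' @param sigma_log Lognormal noise SD, log10 units.
#' @param seed Integer seed.
#' @param experiment_id,study_id Identifiers.
#' @return Data.frame in the \code{potency_table} schema.
#' @export
generate_powerlaw_potency <- function(alpha = 2, c0 = -1,
                                      kd_uM = 10^seq(0.5, 3, length.out = 8),
                                      sigma_log = 0.1, seed = 1L,
                                      experiment_id = "E01",
                                      study_id = "synthetic") {
  set.seed(seed)
  lp <- c0 + alpha * log10(kd_uM) + stats::rnorm(length(kd_uM), 0, sigma_log)
  data.frame(study_id = study_id, experiment_id = experiment_id,
             ligand_id = sprintf("K%02d", seq_along(kd_uM)),
             kd_uM = kd_uM, potency = 10^lp, readout = "CD69", flag = "",
             stringsAsFactors = FALSE)
}

#' Generate dose-response curves realising a potency table
#'
#' Inverts the threshold-potency relation: for each ligand the sigmoid's
#' EC50 is chosen so that the curve crosses \code{x_percent} exactly at the
#' ligand's potency in the noiseless case,
#' \eqn{EC_{50} = P_X \left(\frac{E_{max}-E_{min}}{X-E_{min}} -
#' 1\right)^{1/H}}. Ligands whose potency lies beyond the top dose are still
#' emitted (their fitted PX is then flagged as extrapolated downstream),
#' exercising the no-extrapolation rule.
#'
#' @param potency_table Data.frame with \code{experiment_id},
#'   \code{ligand_id}, \code{potency} (rows with empty potency are skipped).
#' @param emin,emax,h Sigmoid shape: baseline, plateau (percent), Hill
#'   coefficient. \code{emin < x_percent < emax} is required.
#' @param doses Dose series used for every curve.
#' @param x_percent Threshold the potencies refer to.
#' @param sigma Additive Gaussian response noise SD, percent.
#' @param seed Integer seed.
#' @return Data.frame in the \code{dose_response} schema.
#' @export
generate_dose_response_dataset <- function(potency_table, emin = 0,
                                           emax = 60, h = 1,
                                           doses = 10^seq(-2, 3,
                                                          length.out = 10),
                                           x_percent = 15, sigma = 0,
                                           seed = 1L) {
  stopifnot(emin < x_percent, x_percent < emax, all(doses > 0))
  set.seed(seed)
  tab <- potency_table[is.finite(potency_table$potency), , drop = FALSE]
  scale <- ((emax - emin) / (x_percent - emin) - 1)^(1 / h)
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(k) {
    ec50 <- tab$potency[k] * scale
    mu <- emin + (emax - emin) / (1 + (ec50 / doses)^h)
    data.frame(experiment_id = tab$experiment_id[k],
               ligand_id = tab$ligand_id[k],
               dose = doses,
               response_percent = mu + stats::rnorm(length(doses), 0, sigma),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}
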