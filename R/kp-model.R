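#' Default TCR/pMHC association rate constant
#'
#' Average on-rate (uM^-1 s^-1) measured at 37C across a panel of closely
#' related peptide variants; used to convert equilibrium affinities (KD) into
#' dissociation rates when koff cannot be measured directly.
#' @export
KON_DEFAULT <- 0.0447

#' Convert an equilibrium affinity to a dissociation rate
#'
#' Uses \code{koff = kon * KD}, assuming a shared association rate across
#' ligands. This is the standard approximation for panels of single- or
#' few-amino-acid peptide variants, whose on-rates vary little.
#'
#' @param kd Equilibrium dissociation constant(s), uM. Must be positive.
#' @param kon Association rate constant, uM^-1 s^-1.
#' @return Dissociation rate(s) koff in s^-1.
#' @examples
#' koff_from_kd(100)        # 4.47
#' koff_from_kd(2, kon = 1) # 2
#' @export
koff_from_kd <- function(kd, kon = KON_DEFAULT) {
  stopifnot(is.numeric(kd), all(kd > 0), is.numeric(kon), kon > 0)
  kon * kd
}

#' Steady state of the kinetic-proofreading binding chain
#'
#' A ligand L binds a receptor R at rate \code{kon} to form a complex C0,
#' which advances through N sequential proofreading steps at rate \code{kp};
#' the ligand can unbind from any step at rate \code{koff}. At steady state
#' the total complex concentration follows the usual bimolecular quadratic
#' root and the occupancy of the final step is geometrically discounted by
#' the per-step survival probability:
#' \deqn{C_{tot} = \frac{L_0 + R_0 + k_{off}/k_{on} -
#'   \sqrt{(L_0 + R_0 + k_{off}/k_{on})^2 - 4 L_0 R_0}}{2}, \quad
#'   C_N = (1 + k_{off}/k_p)^{-N} C_{tot}.}
#'
#' N may be fractional in this analytic form (the proofreading chain is then
#' interpreted through its continuous interpolation); stochastic simulation
#' requires integer N.
#'
#' @param n Number of proofreading steps (real, >= 0).
#' @param kp Proofreading rate, s^-1. Required positive unless \code{n == 0}.
#' @param kon Association rate (same units as used for \code{l0}, \code{r0},
#'   \code{koff}; only the ratio \code{koff/kon} enters).
#' @param koff Dissociation rate, s^-1.
#' @param l0,r0 Total ligand and receptor amounts.
#' @return A list with components \code{ctot} and \code{cn}.
#' @examples
#' kp_steady_state(n = 0, kp = 1, kon = 0.05, koff = 2, l0 = 100, r0 = 300)
#' @export
kp_steady_state <- function(n, kp, kon, koff, l0, r0) {
  stopifnot(n >= 0, koff >= 0, l0 >= 0, r0 >= 0, kon >= 0)
  if (n > 0 && !(kp > 0)) stop("kp must be > 0 when n > 0")
  if (kon == 0) {
    # no binding: all mass stays free
    return(list(ctot = 0, cn = 0))
  }
  s <- l0 + r0 + koff / kon
  disc <- s^2 - 4 * l0 * r0
  # guard tiny negative values from cancellation
  ctot <- (s - sqrt(max(disc, 0))) / 2
  cn <- if (n == 0) ctot else (1 + koff / kp)^(-n) * ctot
  list(ctot = ctot, cn = cn)
}

#' Closed-form ligand potency of the kinetic-proofreading model
#'
#' Solving the steady-state activation condition \eqn{C_N = \lambda R_0} for
#' the ligand dose (in rescaled units \eqn{x = L_0/R_0}) gives the potency
#' \deqn{x = \frac{\lambda B}{\gamma}\left[1 -
#'   \frac{\delta K_D}{\lambda B - 1}\right], \quad B = (1+k_{off}/k_p)^N,}
#' where \eqn{\gamma} and \eqn{\delta} are proportionality constants mapping
#' model dose and affinity scales onto experimental units.
#'
#' @param n,kp Proofreading steps and rate.
#' @param lambda Activation threshold as a fraction of total receptors.
#' @param gamma Dose-scale conversion constant.
#' @param delta Affinity-scale conversion constant.
#' @param kd Affinity, uM.
#' @param kon Association rate, uM^-1 s^-1.
#' @return Potency x (rescaled dose units); \code{NA} where the ligand cannot
#'   reach threshold at any dose.
#' @export
kp_potency <- function(n, kp, lambda, gamma, delta, kd, kon = KON_DEFAULT) {
  koff <- koff_from_kd(kd, kon)
  b <- (1 + koff / kp)^n
  lb <- lambda * b
  x <- (lb / gamma) * (1 - delta * kd / (lb - 1))
  # activation is unreachable at any dose once lambda*(1+koff/kp)^N >= 1
  x[lb >= 1 | x <= 0 | !is.finite(x)] <- NA_real_
  x
}

#' Log10 potency under the orthogonalised parameterisation
#'
#' The fitted form of the kinetic-proofreading potency uses the rescaled
#' threshold \eqn{\hat\lambda = \lambda/\gamma} and affinity conversion
#' \eqn{\hat\delta = \delta/\gamma}, which decorrelate the parameters:
#' \deqn{\rho = \log_{10}\hat\lambda + N \log_{10}(1 + k_{off}/k_p) +
#'   \log_{10}\!\left(1 - \frac{\hat\delta K_D}
#'   {\hat\lambda (1 + k_{off}/k_p)^N - 1/\gamma}\right),}
#' with \eqn{k_{off} = k_{on} K_D}. A ligand can reach the activation
#' threshold at some dose only while
#' \eqn{\lambda (1 + k_{off}/k_p)^N < 1} (equivalently, the denominator of
#' the final term is negative); ligands violating this — too weak ever to
#' trigger activation — are "unreachable" and returned as \code{NA}.
#'
#' @param n,kp Proofreading steps and rate.
#' @param lambda_hat Rescaled threshold (lambda/gamma).
#' @param gamma Dose-scale conversion.
#' @param delta_hat Rescaled affinity conversion (delta/gamma).
#' @param kd Affinity, uM (vectorised).
#' @param kon Association rate, uM^-1 s^-1.
#' @return log10 potency; \code{NA} for unreachable ligands.
#' @examples
#' log_potency_rho(2.67, 1, 1e-2, 1e-5, 1e-1, kd = c(3, 30, 300))
#' @export
log_potency_rho <- function(n, kp, lambda_hat, gamma, delta_hat, kd,
                            kon = KON_DEFAULT) {
  stopifnot(n >= 0, kp > 0, lambda_hat > 0, gamma > 0, delta_hat > 0)
  koff <- koff_from_kd(kd, kon)
  lb <- log1p(koff / kp) / log(10)          # log10(1 + koff/kp)
  denom <- lambda_hat * 10^(n * lb) - 1 / gamma
  # reachability requires lambda * (1 + koff/kp)^N < 1, i.e. denom < 0
  # (activation is impossible at any dose otherwise); the log argument is
  # then automatically positive
  arg <- 1 - delta_hat * kd / denom
  arg[denom >= 0] <- NA_real_
  rho <- log10(lambda_hat) + n * lb + ifelse(!is.na(arg) & arg > 0,
                                             log10(arg), NA_real_)
  rho[!is.finite(rho)] <- NA_real_
  rho
}

#' Deterministic sensitivity criterion
#'
#' A single highest-affinity ligand (dissociation rate \code{koff1}) is
#' "sensed" when the final-step occupancy exceeds the activation threshold.
#' With binding-dominated occupancy (\eqn{C_{tot} \approx \min(L_0, R_0) = 1}
#' for one ligand among many receptors) this reduces to
#' \eqn{(1 + k_{off,1}/k_p)^{-N} > \lambda}.
#'
#' @param n,kp Proofreading steps and rate.
#' @param koff1 Dissociation rate of the high-affinity ligand, s^-1.
#' @param lambda Activation threshold (absolute complex count here, since the
#'   reference ligand count is 1).
#' @return Logical.
#' @export
sensitivity_ok <- function(n, kp, koff1, lambda) {
  stopifnot(n >= 0, kp > 0, koff1 >= 0, lambda > 0)
  (1 + koff1 / kp)^(-n) > lambda
}

#' Deterministic discrimination criterion
#'
#' Under the empirical power law, a ligand whose affinity is \eqn{\Delta}-fold
#' lower needs a \eqn{\Delta^\alpha}-fold higher dose. Discrimination holds
#' when a ligand presented at \code{l_high} copies with a
#' \eqn{\Delta_A = l_{high}^{1/\alpha}}-fold lower affinity stays below
#' threshold:
#' \eqn{\min(l_{high}, R_0)\,(1 + \Delta_A k_{off,1}/k_p)^{-N} < \lambda}.
#'
#' @param n,kp Proofreading steps and rate.
#' @param koff1 Dissociation rate of the reference high-affinity ligand.
#' @param lambda Activation threshold (complex count).
#' @param alpha Discrimination power defining the affinity penalty.
#' @param l_high Dose of the low-affinity ligand (default 10000).
#' @param r0 Total receptor count (default 30000).
#' @return Logical.
#' @export
discrimination_ok <- function(n, kp, koff1, lambda, alpha,
                              l_high = 10000, r0 = 30000) {
  stopifnot(alpha > 0, n >= 0, kp > 0, koff1 >= 0, lambda > 0)
  delta_a <- l_high^(1 / alpha)
  min(l_high, r0) * (1 + delta_a * koff1 / kp)^(-n) < lambda
}

#' Fold-change in dose compensating a fold-change in affinity
#'
#' Under the power law \eqn{P = 10^C K_D^\alpha}, a \code{fold_kd}-fold drop
#' in affinity is compensated by a \code{fold_kd^alpha}-fold rise in dose.
#' At the receptor-occupancy baseline (alpha = 1) the two are equal; at
#' alpha = 2 a 5-fold affinity loss costs a 25-fold dose increase; at
#' alpha = 9 it would cost about 2 million-fold.
#'
#' @param fold_kd Fold-change in KD (> 0).
#' @param alpha Discrimination power.
#' @return Fold-change in potency (dose).
#' @examples
#' fold_amplification(5, 2)  # 25
#' fold_amplification(5, 9)  # 1953125
#' @export
fold_amplification <- function(fold_kd, alpha) {
  stopifnot(fold_kd > 0)
  fold_kd^alpha
}
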