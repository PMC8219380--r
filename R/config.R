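#' Pipeline configuration
#'
#' Builds a validated configuration object holding every fixed constant of
#' the analysis. All defaults reflect the study conditions the pipeline
#' assumes and every one is overridable; units are recorded so that results
#' stay interpretable (the discrimination power alpha is unit-invariant, its
#' intercept C is not).
#'
#' @param seed Integer seed for the single global RNG; per-chain sub-seeds
#'   are derived deterministically from it.
#' @param units Labels for the concentration and dose axes.
#' @param spr SPR block: \code{saturation_ratio} (minimum max(TCR)/KD for a
#'   curve to enter the standard curve, default 2.5) and
#'   \code{kd_switch_threshold} (constrained KD above which the constrained
#'   fit is the reported one, default 20 uM).
#' @param potency Potency block: \code{threshold_percent} per readout (15
#'   for CD69, 10 for IL-2 by default).
#' @param powerlaw Power-law block: \code{kd_exclusion_floor} (records with
#'   KD below this are in the saturation regime and dropped, default 1 uM)
#'   and \code{significance_alpha} (slope p-value cut for aggregation,
#'   default 0.05).
#' @param kpfit KP-fit block: prior mode, number of chains, annealing
#'   schedule overrides, termination distance, max steps.
#' @param heatmap Phase-map block: realisations, end time, activation
#'   threshold, ligand/receptor counts.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L,
                            units = list(concentration = "uM", dose = "uM"),
                            spr = list(),
                            potency = list(),
                            powerlaw = list(),
                            kpfit = list(),
                            heatmap = list()) {
  cfg <- list(
    seed = as.integer(seed),
    units = utils::modifyList(list(concentration = "uM", dose = "uM"), units),
    spr = utils::modifyList(list(
      saturation_ratio = 2.5,
      kd_switch_threshold = 20
    ), spr),
    potency = utils::modifyList(list(
      threshold_percent = c(CD69 = 15, IL2 = 10)
    ), potency),
    powerlaw = utils::modifyList(list(
      kd_exclusion_floor = 1,
      significance_alpha = 0.05
    ), powerlaw),
    kpfit = utils::modifyList(list(
      mode = "plate",
      n_chains = 1000L,
      kon = KON_DEFAULT,
      xi0 = 10,
      xi_thresholds = NULL,   # NULL -> mode defaults (see anneal_schedule)
      xi_values = NULL,
      termination_distance = NULL,
      max_steps = 5e6
    ), kpfit),
    heatmap = utils::modifyList(list(
      n_realisations = 250L,
      t_end = 100,
      lambda_threshold = 0.1,
      l_high = 10000,
      r0 = 30000,
      alpha = 2,
      n_values = 0:4,
      tau_values = c(0.1, 0.5, 2, 8, 20)
    ), heatmap)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks positivity of all thresholds, chain counts, and that any explicit
#' annealing schedule is strictly decreasing in both distance thresholds and
#' temperatures.
#'
#' @param cfg A \code{pipeline_config}.
#' @return \code{cfg}, invisibly classed, or an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  with(cfg, {
    if (spr$saturation_ratio <= 0) stop("saturation_ratio must be positive")
    if (spr$kd_switch_threshold <= 0) stop("kd_switch_threshold must be positive")
    if (any(potency$threshold_percent <= 0)) stop("potency thresholds must be positive")
    if (powerlaw$kd_exclusion_floor <= 0) stop("kd_exclusion_floor must be positive")
    if (powerlaw$significance_alpha <= 0 || powerlaw$significance_alpha >= 1)
      stop("significance_alpha must lie in (0,1)")
    if (kpfit$n_chains < 1) stop("n_chains must be >= 1")
    if (!is.null(kpfit$xi_values) && any(diff(kpfit$xi_values) >= 0))
      stop("xi schedule must be strictly decreasing")
    if (!is.null(kpfit$xi_thresholds) && any(diff(kpfit$xi_thresholds) >= 0))
      stop("xi thresholds must be strictly decreasing")
    if (heatmap$n_realisations < 1) stop("n_realisations must be >= 1")
    if (heatmap$t_end <= 0) stop("t_end must be positive")
    if (heatmap$lambda_threshold <= 0) stop("lambda_threshold must be positive")
  })
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration (seed ", x$seed, ")\n", sep = "")
  cat("  units: concentration ", x$units$concentration,
      ", dose ", x$units$dose, "\n", sep = "")
  cat("  spr: saturation_ratio ", x$spr$saturation_ratio,
      ", kd_switch_threshold ", x$spr$kd_switch_threshold, " uM\n", sep = "")
  cat("  potency thresholds (%):",
      paste(names(x$potency$threshold_percent),
            x$potency$threshold_percent, sep = "=", collapse = ", "), "\n")
  cat("  powerlaw: KD floor ", x$powerlaw$kd_exclusion_floor,
      " uM, significance ", x$powerlaw$significance_alpha, "\n", sep = "")
  cat("  kpfit: ", x$kpfit$n_chains, " chains, mode ", x$kpfit$mode,
      "\n", sep = "")
  cat("  heatmap: ", x$heatmap$n_realisations, " realisations, t_end ",
      x$heatmap$t_end, " s, lambda ", x$heatmap$lambda_threshold,
      "\n", sep = "")
  invisible(x)
}
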