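#' Run a pipeline stage
#'
#' Ties the modules together file-to-file: each stage reads the CSV tables
#' a previous stage (or the user) placed in \code{out_dir}, runs the
#' corresponding analysis, writes its outputs as CSV, and records run
#' metadata (seed, config hash, package version) as JSON.
#'
#' Stages:
#' \describe{
#'   \item{synth}{Generate synthetic SPR, KP-potency and dose-response
#'     tables with a \code{truth.json} sidecar.}
#'   \item{spr-fit}{\code{binding_curve.csv} + \code{antibody_trace.csv}
#'     -> \code{kd_report.csv}.}
#'   \item{potency}{\code{dose_response.csv} -> \code{potency_estimates.csv}.}
#'   \item{powerlaw}{\code{potency_table.csv} -> \code{powerlaw.csv}
#'     (per-experiment alpha, C, R^2, p) + \code{powerlaw_audit.csv}.}
#'   \item{kp-fit}{\code{potency_table.csv} -> \code{ensemble.csv} +
#'     \code{kp_summary.json}.}
#'   \item{kp-map}{-> \code{phase_map.csv} (deterministic and stochastic).}
#' }
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param stage One of \code{"synth"}, \code{"spr-fit"}, \code{"potency"},
#'   \code{"powerlaw"}, \code{"kp-fit"}, \code{"kp-map"}.
#' @param out_dir Directory for inputs/outputs (created if missing).
#' @return Invisibly, a character vector of files written.
#' @export
run_pipeline <- function(config, stage, out_dir = ".") {
  validate_config(config)
  stage <- match.arg(stage, c("synth", "spr-fit", "potency", "powerlaw",
                              "kp-fit", "kp-map"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  need <- function(f) {
    if (!file.exists(p(f))) stop("stage '", stage, "' requires ", f,
                                 " in ", out_dir)
    p(f)
  }
  written <- character()

  if (stage == "synth") {
    spr <- generate_spr_dataset(spr_ground_truth(), seed = config$seed,
                                n_replicates = 3L)
    write_table(spr$binding_curve, p("binding_curve.csv"))
    write_table(spr$antibody_trace, p("antibody_trace.csv"))
    kp <- generate_kp_potency_dataset(kp_ground_truth(),
                                      n_experiments = 12L,
                                      seed = config$seed)
    write_table(kp$potency_table, p("potency_table.csv"))
    dr <- generate_dose_response_dataset(
      kp$potency_table, x_percent = config$potency$threshold_percent[["CD69"]],
      sigma = 2, seed = config$seed)
    write_table(dr, p("dose_response.csv"))
    spr_truth <- spr$truth
    spr_truth$kd <- as.list(spr_truth$kd)   # keep ligand ids in the JSON
    jsonlite::write_json(list(spr = spr_truth, kp = kp$truth),
                         p("truth.json"), auto_unbox = TRUE, digits = NA)
    written <- c("binding_curve.csv", "antibody_trace.csv",
                 "potency_table.csv", "dose_response.csv", "truth.json")
  } else if (stage == "spr-fit") {
    binding <- read_table(need("binding_curve.csv"), "binding_curve")
    traces <- read_table(need("antibody_trace.csv"), "antibody_trace")
    write_table(kd_report(binding, traces, config), p("kd_report.csv"))
    written <- "kd_report.csv"
  } else if (stage == "potency") {
    dr <- read_table(need("dose_response.csv"), "dose_response")
    rep <- potency_report(dr, config$potency$threshold_percent[["CD69"]])
    write_table(rep, p("potency_estimates.csv"))
    written <- "potency_estimates.csv"
  } else if (stage == "powerlaw") {
    tab <- read_table(need("potency_table.csv"), "potency_table")
    inc <- apply_inclusion_rules(tab, config$powerlaw$kd_exclusion_floor)
    fits <- lapply(split(inc$records, inc$records$experiment_id),
                   fit_power_law)
    out <- do.call(rbind, lapply(names(fits), function(id) {
      f <- fits[[id]]
      data.frame(experiment_id = id, alpha = f$alpha, c = f$c0,
                 r_squared = f$r_squared, p_slope = f$p_slope,
                 alpha_lo = f$alpha_ci[1], alpha_hi = f$alpha_ci[2],
                 n_points = f$n_points, stringsAsFactors = FALSE)
    }))
    write_table(out, p("powerlaw.csv"))
    write_table(inc$audit, p("powerlaw_audit.csv"))
    written <- c("powerlaw.csv", "powerlaw_audit.csv")
  } else if (stage == "kp-fit") {
    tab <- read_table(need("potency_table.csv"), "potency_table")
    kf <- config$kpfit
    dprep <- .kp_prepare_data(tab)
    sched <- if (!is.null(kf$termination_distance)) {
      anneal_schedule(kf$mode, xi0 = kf$xi0,
                      thresholds = kf$xi_thresholds, xi_values = kf$xi_values,
                      termination_distance = kf$termination_distance,
                      max_steps = kf$max_steps)
    } else {
      anneal_schedule(kf$mode, xi0 = kf$xi0, max_steps = kf$max_steps)
    }
    ens <- fit_kp_ensemble(tab, n_chains = kf$n_chains,
                           priors = kp_priors(length(dprep$experiments),
                                              kf$mode),
                           schedule = sched, seed = config$seed,
                           kon = kf$kon)
    edf <- data.frame(chain = seq_len(nrow(ens$theta)), ens$theta,
                      distance = ens$distance, check.names = FALSE)
    write_table(edf, p("ensemble.csv"))
    jsonlite::write_json(ens$summary, p("kp_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c("ensemble.csv", "kp_summary.json")
  } else if (stage == "kp-map") {
    hm <- config$heatmap
    det <- phase_map(hm$n_values, hm$tau_values, hm$alpha, "deterministic",
                     lambda = hm$lambda_threshold, l_high = hm$l_high,
                     r0 = hm$r0)
    sto <- phase_map(hm$n_values[hm$n_values == round(hm$n_values)],
                     hm$tau_values, hm$alpha, "stochastic",
                     lambda = hm$lambda_threshold, l_high = hm$l_high,
                     r0 = hm$r0, n_realisations = hm$n_realisations,
                     t_end = hm$t_end, seed = config$seed)
    det$mode <- "deterministic"
    sto$mode <- "stochastic"
    all_cols <- union(names(sto), names(det))
    for (cc in setdiff(all_cols, names(det))) det[[cc]] <- NA_real_
    write_table(rbind(det[all_cols], sto[all_cols]), p("phase_map.csv"))
    written <- "phase_map.csv"
  }

  meta <- list(stage = stage, seed = config$seed,
               config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("tcrpower")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               files = written)
  jsonlite::write_json(meta, p(paste0("run_", gsub("-", "_", stage),
                                      "_metadata.json")),
                       auto_unbox = TRUE)
  invisible(file.path(out_dir, written))
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical JSON serialisation; recorded in run metadata so a
#' result can be traced to the exact configuration that produced it.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
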