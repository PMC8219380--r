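test_that("tables round-trip through CSV and validate against their schemas", {
  tab <- generate_powerlaw_potency(alpha = 2, c0 = -1, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_table(tab, f)
  back <- read_table(f, "potency_table")
  expect_identical(back$potency, tab$potency)
  expect_identical(back$kd_uM, tab$kd_uM)
  expect_identical(back$ligand_id, tab$ligand_id)
  # a second write of the re-read table is byte-identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_table(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("read_table rejects malformed input with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  expect_error(read_table(f, "nonsense"), "unknown schema")
  writeLines(c("ligand_id,tcr_conc_uM,response_RU",
               "A,1,10", "A,2,NA", "A,4,30"), f)
  expect_error(read_table(f, "binding_curve"), "row 2")
  writeLines(c("ligand_id,tcr_conc_uM,response_RU",
               "A,1,10", "A,two,20"), f)
  expect_error(read_table(f, "binding_curve"), "non-numeric")
  writeLines("ligand_id,tcr_conc_uM,response_RU", f)
  expect_error(read_table(f, "binding_curve"), "empty")
  writeLines(c("study_id,experiment_id,ligand_id,potency", "s,e,l,1"), f)
  expect_error(read_table(f, "potency_table"), "affinity column")
})

test_that("pipeline config validates thresholds and schedules", {
  cfg <- pipeline_config(seed = 7)
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$spr$saturation_ratio, 2.5)
  expect_equal(cfg$spr$kd_switch_threshold, 20)
  expect_equal(cfg$powerlaw$kd_exclusion_floor, 1)
  expect_error(pipeline_config(spr = list(saturation_ratio = -1)),
               "saturation_ratio")
  expect_error(pipeline_config(kpfit = list(n_chains = 0)), "n_chains")
  expect_error(pipeline_config(kpfit = list(xi_values = c(0.1, 1))),
               "decreasing")
})

test_that("synth stage is byte-identical under a fixed seed", {
  cfg <- pipeline_config(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(cfg, "synth", d1)
  run_pipeline(cfg, "synth", d2)
  for (f in c("binding_curve.csv", "antibody_trace.csv",
              "potency_table.csv", "dose_response.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  meta <- jsonlite::read_json(file.path(d1, "run_synth_metadata.json"))
  expect_equal(meta$seed, 7)
  expect_match(meta$config_hash, "^[0-9a-f]{32}$")
})

test_that("pipeline stages chain file-to-file and recover the truth", {
  cfg <- pipeline_config(seed = 11)
  d <- withr::local_tempdir()
  run_pipeline(cfg, "synth", d)
  run_pipeline(cfg, "spr-fit", d)
  rep <- utils::read.csv(file.path(d, "kd_report.csv"))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  # reported KDs land near the generating values (median over replicates)
  kd_true <- unlist(truth$spr$kd)
  med <- tapply(rep$kd_reported, rep$ligand_id, median)
  expect_equal(as.numeric(med[names(kd_true)]), unname(kd_true),
               tolerance = 0.25)
  run_pipeline(cfg, "potency", d)
  pot <- utils::read.csv(file.path(d, "potency_estimates.csv"))
  expect_true(all(c("experiment_id", "ligand_id", "potency", "flag") %in%
                  names(pot)))
  run_pipeline(cfg, "powerlaw", d)
  pl <- utils::read.csv(file.path(d, "powerlaw.csv"))
  expect_true(all(is.finite(pl$alpha)))
  expect_true(file.exists(file.path(d, "powerlaw_audit.csv")))
})

test_that("kp-fit and kp-map stages write ensembles and maps", {
  s <- (96 * 0.1^2 * 1.2) / 11.08       # synthetic-noise distance scale
  cfg <- pipeline_config(
    seed = 5,
    kpfit = list(n_chains = 2L, xi0 = 10 * s,
                 xi_thresholds = c(50, 30, 20, 18, 17.5) * s,
                 xi_values = c(1, 0.1, 0.01, 0.005, 0.001) * s,
                 termination_distance = 96 * 0.1^2 * 1.2,
                 max_steps = 5e5),
    heatmap = list(n_values = c(0L, 2L), tau_values = 0.5,
                   n_realisations = 30L, t_end = 1, alpha = 2,
                   r0 = 3000, l_high = 1000))
  d <- withr::local_tempdir()
  run_pipeline(cfg, "synth", d)
  run_pipeline(cfg, "kp-fit", d)
  ens <- utils::read.csv(file.path(d, "ensemble.csv"))
  expect_equal(ncol(ens), 1 + 27 + 1)   # chain id, 27 parameters, distance
  summ <- jsonlite::read_json(file.path(d, "kp_summary.json"),
                              simplifyVector = TRUE)
  expect_true(summ$n_median >= 0 && summ$n_median <= 4)
  run_pipeline(cfg, "kp-map", d)
  pm <- utils::read.csv(file.path(d, "phase_map.csv"))
  expect_setequal(unique(pm$mode), c("deterministic", "stochastic"))
  expect_true(all(pm$sensitive[pm$n == 0]))
  expect_false(any(pm$discriminating[pm$n == 0]))
})

test_that("power-law stage refuses degenerate tables", {
  d <- withr::local_tempdir()
  write_table(data.frame(study_id = "s", experiment_id = "e",
                         ligand_id = "l", kd_uM = 10, potency = 1,
                         readout = "CD69", flag = ""),
              file.path(d, "potency_table.csv"))
  expect_error(run_pipeline(pipeline_config(), "powerlaw", d),
               "insufficient points")
})

test_that("end-to-end dose-response chain recovers the generating alpha", {
  truth_alpha <- 2
  tab <- generate_powerlaw_potency(alpha = truth_alpha, c0 = -1.5,
                                   kd_uM = 10^seq(0.5, 3, length.out = 8),
                                   sigma_log = 0.05, seed = 21)
  dr <- generate_dose_response_dataset(tab, emin = 0, emax = 60, h = 1,
                                       doses = 10^seq(-3, 3.5,
                                                      length.out = 10),
                                       x_percent = 15, sigma = 1, seed = 22)
  est <- potency_report(dr, x_percent = 15)
  est$kd_uM <- tab$kd_uM[match(est$ligand_id, tab$ligand_id)]
  est$study_id <- "s"
  fit <- fit_power_law(est)
  expect_equal(fit$alpha, truth_alpha, tolerance = 0.1)
})
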