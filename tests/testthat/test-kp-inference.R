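test_that("priors carry the documented bounds and parameter counts", {
  p <- kp_priors(12, "plate")
  expect_equal(nrow(p), 27)            # 3 global + 2 x 12 local
  expect_equal(nrow(kp_priors(17, "cell")), 37)
  expect_equal(p$lower[p$name == "N"], 0)
  expect_equal(p$upper[p$name == "N"], 4)
  expect_equal(unname(unlist(p[p$name == "log10_kp_1", c("lower", "upper")])),
               c(-1, 1))
  expect_equal(unname(unlist(p[p$name == "log10_lambda_hat_1",
                               c("lower", "upper")])), c(-4, 1))
  pc <- kp_priors(2, "cell")
  expect_equal(unname(unlist(pc[pc$name == "log10_lambda_hat_1",
                                c("lower", "upper")])), c(-6, -3))
  expect_equal(unname(unlist(p[p$name == "log10_gamma",
                               c("lower", "upper")])), c(-6, -4))
  expect_equal(unname(unlist(p[p$name == "log10_delta_hat",
                               c("lower", "upper")])), c(-7, -5))
})

test_that("built-in annealing schedules match the fitting protocol", {
  pl <- anneal_schedule("plate")
  expect_equal(pl$xi0, 10)
  expect_equal(pl$thresholds, c(50, 30, 20, 18, 17.5))
  expect_equal(pl$xi_values, c(1, 0.1, 0.01, 0.005, 0.001))
  expect_equal(pl$termination_distance, 11.08)
  ce <- anneal_schedule("cell")
  expect_equal(ce$thresholds, c(100, 75, 50, 40, 35))
  expect_equal(ce$termination_distance, 39.2)
  expect_error(anneal_schedule("plate", thresholds = c(10, 20, 30, 40, 50)),
               "decreasing|thresholds")
})

test_that("distance matches a hand-computed two-experiment table", {
  # 2 experiments x 2 points, residuals worked out per point
  theta <- c(2, -5, -6, 0, 0.3, -1, -2)   # N, lg g, lg dh, lg kp, lg lh
  kd <- c(10, 100, 30, 300)
  expt <- c("A", "A", "B", "B")
  rho <- c(
    log_potency_rho(2, 1, 1e-1, 1e-5, 1e-6, c(10, 100)),
    log_potency_rho(2, 10^0.3, 1e-2, 1e-5, 1e-6, c(30, 300))
  )
  obs <- rho + c(0.5, -0.5, 0.1, -0.2)
  tab <- data.frame(study_id = "s", experiment_id = expt, ligand_id = "l",
                    kd_uM = kd, potency = 10^obs)
  expect_equal(kp_distance(theta, tab), 0.25 + 0.25 + 0.01 + 0.04,
               tolerance = 1e-9)
  # one residual of 0.5 log10 units contributes exactly 0.25
  tab1 <- tab[1, , drop = FALSE]
  theta1 <- c(2, -5, -6, 0, -1)
  expect_equal(kp_distance(theta1, tab1), 0.25, tolerance = 1e-9)
  # compiled kernel agrees with the R reference implementation
  cpp <- tcrpower:::.kp_distance_cpp(theta, 2L, kd, obs,
                                     c(0L, 0L, 1L, 1L), 0.0447)
  expect_equal(cpp, kp_distance(theta, tab), tolerance = 1e-12)
})

test_that("unreachable model points give infinite distance, not errors", {
  tab <- data.frame(study_id = "s", experiment_id = "e", ligand_id = "l",
                    kd_uM = 223.7, potency = 1)
  # parameters that make this ligand unreachable (cf. model tests)
  theta <- c(3, -4, log10(20), 0, 1)
  expect_identical(kp_distance(theta, tab), Inf)
})

test_that("perturbation kernel is uniform, scaled to the priors, reflected", {
  p <- kp_priors(1, "plate")
  theta <- (p$lower + p$upper) / 2
  set.seed(41)
  draws <- t(replicate(4e4, kp_perturb(theta, p)))
  shifts_n <- draws[, 1] - theta[1]
  # N shift spans [-0.02, 0.02] (0.005 x prior width 4) and is uniform
  expect_lt(max(abs(shifts_n)), 0.02 + 1e-12)
  ks <- suppressWarnings(ks.test(shifts_n, "punif", -0.02, 0.02))
  expect_gt(ks$p.value, 0.001)
  # log10(kp) shift spans 0.005 x width 2 = +/- 0.01
  expect_lt(max(abs(draws[, 4] - theta[4])), 0.01 + 1e-12)
  # reflection at the upper bound
  at_top <- p$upper
  set.seed(42)
  out <- t(replicate(2000, kp_perturb(at_top, p)))
  expect_true(all(out <= matrix(p$upper, 2000, 5, byrow = TRUE)))
  expect_true(all(out >= matrix(p$lower, 2000, 5, byrow = TRUE)))
  # a positive shift s from the bound lands at bound - s: uniform below top
  expect_gt(max(at_top[1] - out[, 1]), 0.019)
})

test_that("acceptance rule is greedy downhill, Boltzmann uphill", {
  expect_true(mh_accept(10, 5, xi = 0.001))
  set.seed(43)
  acc <- mean(replicate(1e5, mh_accept(5, 5 + 2, xi = 2)))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / 1e5))
  # greedy limit: xi -> 0 rejects any uphill move
  expect_false(any(replicate(100, mh_accept(5, 5.001, xi = 1e-300))))
})

test_that("chains are reproducible and terminate trivially when allowed", {
  tr <- kp_ground_truth(sigma_log = 0.1)
  dat <- generate_kp_potency_dataset(tr, 2, seed = 3)
  pri <- kp_priors(2, "plate")
  sch <- synthetic_schedule(nrow(dat$potency_table), 0.1, max_steps = 500)
  c1 <- run_kp_chain(dat$potency_table, pri, sch, seed = 5)
  c2 <- run_kp_chain(dat$potency_table, pri, sch, seed = 5)
  expect_identical(c1, c2)
  # termination distance above the starting distance returns immediately
  loose <- anneal_schedule("plate", termination_distance = 1e9)
  c3 <- run_kp_chain(dat$potency_table, pri, loose, seed = 5)
  expect_true(c3$converged)
  expect_equal(c3$steps, 0)
})

test_that("a chain on noiseless data converges towards zero distance", {
  tr <- kp_ground_truth(sigma_log = 0)
  dat <- generate_kp_potency_dataset(tr, 2, seed = 6)
  pri <- kp_priors(2, "plate")
  sch <- synthetic_schedule(nrow(dat$potency_table), 0.03, max_steps = 3e5)
  ch <- run_kp_chain(dat$potency_table, pri, sch, seed = 8)
  expect_true(ch$converged)
  expect_lt(ch$distance, sch$termination_distance)
  expect_true(all(ch$theta >= pri$lower & ch$theta <= pri$upper))
})

test_that("ensemble summaries expose N, kp and the time delay tau_KP", {
  tr <- kp_ground_truth(sigma_log = 0.1)
  dat <- generate_kp_potency_dataset(tr, 2, seed = 12)
  sch <- synthetic_schedule(nrow(dat$potency_table), 0.1, max_steps = 3e5)
  ens <- fit_kp_ensemble(dat$potency_table, n_chains = 8, schedule = sch,
                         priors = kp_priors(2, "plate"), seed = 2)
  expect_s3_class(ens, "kp_ensemble")
  expect_equal(ens$n_parameters, 7)
  expect_true(all(ens$distance < sch$termination_distance))
  # tau_KP = N/kp, checked against the raw ensemble matrix
  th <- ens$theta
  tau <- th[, "N"] / th[, c("kp_1", "kp_2"), drop = FALSE]
  expect_equal(ens$summary$tau_kp_mean, mean(rowMeans(tau)))
  out <- capture.output(print(ens))
  expect_match(out[1], "chains converged")
})
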