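test_that("double referencing removes reference signal and buffer drift", {
  s <- c(10, 20, 30)
  expect_equal(double_reference(s, s, rep(0, 3), rep(0, 3)), c(0, 0, 0))
  # constant drift c in both buffers shifts the output by -c (linearity)
  out <- double_reference(s, rep(0, 3), rep(4, 3), rep(4, 3))
  expect_equal(out, s - 4)
  # asymmetric buffers average
  out <- double_reference(s, rep(1, 3), rep(2, 3), rep(6, 3))
  expect_equal(out, s - 1 - 4)
  expect_error(double_reference(s, s[1:2], s, s), "equal length")
})

test_that("double referencing suppresses drift to below the noise floor", {
  set.seed(3)
  n <- 50
  sigma <- 1
  drift <- seq(0, 5, length.out = n)            # slow linear drift, RU
  signal <- 20 + drift + rnorm(n, 0, sigma)
  reference <- drift + rnorm(n, 0, sigma)
  buf1 <- rnorm(n, 0, sigma)
  buf2 <- rnorm(n, 0, sigma)
  out <- double_reference(signal, reference, buf1, buf2)
  expect_lt(abs(mean(out - 20)), 3 * sigma / sqrt(n))
})

test_that("free Langmuir fit inverts a noiseless saturating curve", {
  fit <- fit_langmuir_free(langmuir_fixture(10, 100))
  expect_equal(fit$kd, 10, tolerance = 1e-6)
  expect_equal(fit$bmax, 100, tolerance = 1e-6)
  expect_equal(fit$saturation_ratio, 8, tolerance = 1e-6)
  expect_error(fit_langmuir_free(binding_curve(1:4, rep(5, 4))), "flat")
})

test_that("non-saturating free fits sit on a flat SSE ridge", {
  # max T = KD/5: brute-force SSE along Bmax/KD ~ const varies < 1%
  kd <- 500
  curve <- langmuir_fixture(kd, 1000, conc = c(1.5625, 3.125, 6.25, 12.5,
                                               25, 50, 100))
  t <- curve$tcr_conc_uM
  b <- curve$response_RU
  sse <- function(kd_, bmax_) sum((b - bmax_ * t / (kd_ + t))^2)
  kd_grid <- kd * 10^seq(-0.5, 0.5, length.out = 21)
  ridge <- vapply(kd_grid, function(k) {
    # best Bmax at fixed KD is linear least squares
    f <- t / (k + t)
    sse(k, sum(b * f) / sum(f * f))
  }, numeric(1))
  scale <- sum(b^2)
  expect_lt(diff(range(ridge)) / scale, 0.01)
})

test_that("W6/32 trace fit recovers Rmax", {
  t <- seq(10, 600, by = 10)
  w <- fit_w632_rmax(t, 50 * t / (20 + t))
  expect_equal(w$rmax, 50, tolerance = 1e-6)
  expect_equal(w$kt, 20, tolerance = 1e-4)
  # constant trace: Rmax -> c, Kt -> 0
  w2 <- fit_w632_rmax(t, rep(30, length(t)))
  expect_equal(w2$rmax, 30, tolerance = 1e-3)
  expect_lt(w2$kt, 1e-3)
  # noisy trace
  set.seed(11)
  w3 <- fit_w632_rmax(t, 50 * t / (20 + t) + rnorm(length(t), 0, 1))
  expect_equal(w3$rmax, 50, tolerance = 0.05)
})

test_that("standard curve keeps only saturating pairs and fits the line", {
  std <- standard_curve_fixture(slope = 2, intercept = 0)
  expect_equal(std$slope, 2, tolerance = 1e-6)
  expect_equal(std$intercept, 0, tolerance = 1e-3)
  expect_equal(std$n_points, 5)
  # two non-saturating pairs (max T / KD = 100/500 << 2.5) are filtered out
  rmax <- c(100, 200, 300, 50, 60)
  fits <- c(lapply(rmax[1:3], function(r) {
    fit_langmuir_free(langmuir_fixture(5, 2 * r))
  }), lapply(rmax[4:5], function(r) {
    fit_langmuir_free(langmuir_fixture(500, 2 * r,
                                       conc = c(1.25, 2.5, 5, 10, 20, 40, 100)))
  }))
  std2 <- build_standard_curve(rmax, fits)
  expect_equal(std2$n_points, 3)
  expect_equal(std2$rmax_range, c(100, 300))
  expect_error(build_standard_curve(rmax[4:5], fits[4:5]), "fewer than 3")
})

test_that("constrained fit matches the free fit on saturating curves", {
  std <- standard_curve_fixture(slope = 2, intercept = 0)
  curve <- langmuir_fixture(10, 2 * 150)       # Bmax = 300 at rmax = 150
  free <- fit_langmuir_free(curve)
  cons <- fit_langmuir_constrained(curve, std, rmax = 150)
  expect_equal(cons$kd, free$kd, tolerance = 1e-6)
  expect_equal(cons$bmax, 300, tolerance = 1e-9)
})

test_that("constrained fit resolves the ridge on non-saturating curves", {
  std <- standard_curve_fixture(slope = 2, intercept = 0)
  # max T = KD/10: free fit cannot separate KD from Bmax, constrained can
  kd <- 800
  curve <- langmuir_fixture(kd, 2 * 250, conc = c(1.25, 2.5, 5, 10, 20, 40, 80))
  cons <- fit_langmuir_constrained(curve, std, rmax = 250)
  expect_equal(cons$kd, kd, tolerance = 1e-5)
})

test_that("interpolation outside the standard curve range is refused", {
  std <- standard_curve_fixture(slope = 2, intercept = 0,
                                rmax = c(100, 200, 300, 400, 500))
  curve <- langmuir_fixture(10, 100)
  expect_error(fit_langmuir_constrained(curve, std, rmax = 550),
               "extrapolation refused")
  expect_error(fit_langmuir_constrained(curve, std, rmax = 50),
               "extrapolation refused")
})

test_that("reporting rule switches to the constrained KD above 20 uM only", {
  mk <- function(kd, method) {
    f <- fit_langmuir_free(langmuir_fixture(kd, 100))
    f$method <- method
    f$kd <- kd
    f
  }
  pick <- select_reported_kd(mk(30, "free"), mk(50, "constrained"))
  expect_equal(pick$kd, 50)
  expect_identical(pick$method, "constrained")
  pick <- select_reported_kd(mk(7, "free"), mk(5, "constrained"))
  expect_equal(pick$kd, 7)
  expect_identical(pick$method, "free")
  # boundary: exactly 20 uM is not "above", so the free fit is reported
  pick <- select_reported_kd(mk(7, "free"), mk(20, "constrained"))
  expect_identical(pick$method, "free")
})

test_that("replicate CV matches direct arithmetic", {
  expect_equal(replicate_cv(c(10, 10, 10)), 0)
  expect_equal(replicate_cv(c(10, 20)), sd(c(10, 20)) / 15)
  expect_equal(replicate_cv(c(10, 20)), 0.4714, tolerance = 1e-4)
  expect_error(replicate_cv(c(-10, 2)), "positive")
})

test_that("constrained method beats the free method on low-affinity replicates", {
  # the qualitative replicate-precision contrast: KD = 500 uM curves cannot
  # saturate at 80 uM TCR, so the free fit rides the SSE ridge while the
  # constrained fit stays anchored by the antibody-derived Bmax
  set.seed(31)
  kd <- 500
  bmax <- 700
  conc <- 0.625 * 2^(0:7)
  std <- standard_curve_fixture(slope = 2, intercept = 0)
  kd_free <- kd_cons <- numeric(20)
  for (r in 1:20) {
    b <- bmax * conc / (kd + conc) + rnorm(length(conc), 0, 2)
    curve <- binding_curve(conc, b)
    kd_free[r] <- fit_langmuir_free(curve)$kd
    kd_cons[r] <- fit_langmuir_constrained(curve, std, rmax = bmax / 2)$kd
  }
  expect_lt(replicate_cv(kd_cons), replicate_cv(kd_free))
  expect_lt(abs(median(kd_cons) - kd) / kd, 0.1)
})

test_that("constrained KD is invariant to a common response/Bmax rescaling", {
  std1 <- standard_curve_fixture(slope = 2, intercept = 0)
  std3 <- standard_curve_fixture(slope = 6, intercept = 0)
  conc <- c(1.25, 2.5, 5, 10, 20, 40, 80)
  b <- 400 * conc / (300 + conc)
  k1 <- fit_langmuir_constrained(binding_curve(conc, b), std1,
                                 rmax = 200)$kd
  k3 <- fit_langmuir_constrained(binding_curve(conc, 3 * b), std3,
                                 rmax = 200)$kd
  expect_equal(k1, k3, tolerance = 1e-6)
})
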