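# Shared fixture builders. Everything is generated in code; no data files.

# Noiseless Langmuir curve
langmuir_fixture <- function(kd, bmax, conc = c(1.25, 2.5, 5, 10, 20, 40, 80)) {
  binding_curve(conc, bmax * conc / (kd + conc))
}

# Exact standard curve Bmax = slope * rmax + intercept built from
# saturating noiseless curves
standard_curve_fixture <- function(slope = 2, intercept = 0,
                                   rmax = c(100, 200, 300, 400, 500),
                                   kd = 5) {
  fits <- lapply(rmax, function(r) {
    fit_langmuir_free(langmuir_fixture(kd, slope * r + intercept))
  })
  build_standard_curve(rmax, fits)
}

# Reference R implementation of the proofreading ODE system, used as the
# independent oracle for the closed-form steady state. Terminal equation:
# dCN/dt = kp*C_{N-1} - koff*CN.
kp_ode_cn <- function(n, kp, kon, koff, l0, r0, t_end,
                      rtol = 1e-11, atol = 1e-13) {
  deriv <- function(t, y, parms) {
    L <- y[1]; R <- y[2]; C <- y[-(1:2)]
    ctot <- sum(C)
    dL <- koff * ctot - kon * L * R
    dC <- numeric(n + 1)
    if (n == 0) {
      dC[1] <- kon * L * R - koff * C[1]
    } else {
      dC[1] <- kon * L * R - (koff + kp) * C[1]
      if (n >= 2) {
        for (i in 2:n) dC[i] <- kp * C[i - 1] - (koff + kp) * C[i]
      }
      dC[n + 1] <- kp * C[n] - koff * C[n + 1]
    }
    list(c(dL, dL, dC))
  }
  y0 <- c(l0, r0, numeric(n + 1))
  out <- deSolve::lsoda(y0, c(0, t_end), deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  unname(out[nrow(out), 2 + (n + 1) + 1])
}

# Draw KP parameters from the plate priors that yield a valid potency
# (activation reachable and the pre-squaring branch condition met)
valid_kp_draw <- function() {
  repeat {
    n <- stats::runif(1, 0, 4)
    kp <- 10^stats::runif(1, -1, 1)
    lh <- 10^stats::runif(1, -4, 1)
    g <- 10^stats::runif(1, -6, -4)
    dh <- 10^stats::runif(1, -7, -5)
    kd <- 10^stats::runif(1, 0, 3.2)
    lam <- lh * g
    b <- (1 + koff_from_kd(kd) / kp)^n
    if (lam * b >= 1) next
    x <- kp_potency(n, kp, lam, g, dh * g, kd)
    if (is.na(x) || x <= 0) next
    return(list(n = n, kp = kp, lambda_hat = lh, gamma = g, delta_hat = dh,
                kd = kd, lambda = lam, delta = dh * g, b = b, x = x))
  }
}
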