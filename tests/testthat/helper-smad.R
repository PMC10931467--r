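# Shared fixtures: the two reference parameter sets and random draws from
# the published plausible ranges.

case1_params <- function() {
  smad_params(Lambda = 0.5, chi = 0.25, phi = 0.8, sigma = 0.25,
              Phi = 0.7, beta = 0.01, tau = 0.09, alpha = 0.5,
              psi = 0.0027, omega = 0.8, upsilon = 0.7, rho = 0.01,
              lam = 0.4, zeta = 0.35)
}

case2_params <- function() {
  smad_params(Lambda = 0.60556, chi = 0.26104, phi = 0.89339,
              sigma = 0.22874, Phi = 0.80142, beta = 0.010014,
              tau = 0.095, alpha = 0.47155, psi = 0.002909,
              omega = 0.8, upsilon = 0.7, rho = 0.01, lam = 0.4,
              zeta = 0.35)
}

case1_dfe_printed <- c(5, 0, 0, 0, 0, 0.5556)
case2_eep_printed <- c(4.3123, 0.5588, 0.1799, 0.1055, 0.2013, 1.0055)
reference_ic <- smad_state(S = 100, E = 1, I1 = 5, I2 = 2, R = 0, Q = 10)

# Random parameter draw from the published ranges (ranged parameters drawn
# across their full range, point values jittered +/-50%).
random_params <- function() {
  smad_params(
    Lambda = runif(1, 0.25, 1),
    zeta = runif(1, 0.1, 0.6),
    lam = runif(1, 0.2, 0.6),
    tau = runif(1, 0.05, 0.25),
    alpha = runif(1, 0.3, 0.5),
    beta = runif(1, 0.005, 0.02),
    chi = runif(1, 0.1, 0.4),
    upsilon = runif(1, 0.35, 1),
    sigma = runif(1, 0.1, 0.4),
    omega = runif(1, 0.4, 1),
    psi = runif(1, 0.001, 0.005),
    Phi = runif(1, 0.35, 1),
    rho = runif(1, 0.005, 0.02),
    phi = runif(1, 0.1, 0.8))
}

random_state <- function(scale = 10) {
  smad_state(S = runif(1, 0, scale), E = runif(1, 0, scale),
             I1 = runif(1, 0, scale), I2 = runif(1, 0, scale),
             R = runif(1, 0, scale), Q = runif(1, 0, scale))
}

# Central finite-difference Jacobian of the vector field (independent
# oracle for the analytic Jacobian).
fd_jacobian <- function(state, params, rel = 1e-6) {
  J <- matrix(0, 6, 6)
  for (j in 1:6) {
    h <- rel * max(1, abs(state[j]))
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (smad_rhs(up, params) - smad_rhs(dn, params)) / (2 * h)
  }
  J
}

# Damped Newton iteration on the steady-state system; independent of the
# algebraic cascade used by smad_eep().
newton_equilibrium <- function(params, start, max_iter = 200) {
  y <- as.numeric(start)
  for (i in seq_len(max_iter)) {
    f <- smad_rhs(y, params)
    if (max(abs(f)) < 1e-12) break
    step <- tryCatch(solve(smad_jacobian(y, params), f),
                     error = function(e) return(NULL))
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      y_new <- y - lambda * step
      if (all(is.finite(y_new)) &&
          max(abs(smad_rhs(pmax(y_new, 1e-12), params))) <=
            max(abs(f)) * (1 - 0.25 * lambda) + 1e-14) break
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    y <- pmax(y - lambda * step, 1e-12)
  }
  y
}
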