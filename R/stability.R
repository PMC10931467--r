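#' Analytic Jacobian of the model
#'
#' The 6x6 matrix of partial derivatives of the vector field with respect
#' to the state, evaluated at an arbitrary state. Only the incidence term
#' `phi*chi*I1*S` is nonlinear; every other entry is a constant rate.
#'
#' @param state length-6 state vector.
#' @param params a [smad_params()] object.
#' @return 6x6 numeric matrix with rows/columns named S, E, I1, I2, R, Q.
#' @export
smad_jacobian <- function(state, params) {
  y <- as_state_vector(state)
  p <- setNames(as.list(as_param_vector(params)), .smad_param_names)
  J <- matrix(0, 6, 6, dimnames = list(.smad_state_names,
                                       .smad_state_names))
  fS <- p$phi * p$chi * y[["S"]]    # d(incidence)/dI1
  fI <- p$phi * p$chi * y[["I1"]]   # d(incidence)/dS
  J["S", "S"]  <- -fI - p$beta - p$tau
  J["S", "I1"] <- -fS
  J["S", "R"]  <- p$zeta * p$lam
  J["E", "S"]  <- fI
  J["E", "E"]  <- -(p$sigma + p$tau)
  J["E", "I1"] <- fS
  J["I1", "E"]  <- p$Phi * p$sigma
  J["I1", "I1"] <- -(p$tau + p$alpha + p$psi)
  J["I2", "I1"] <- p$alpha + p$psi * (1 - p$omega)
  J["I2", "I2"] <- -(p$upsilon + p$rho + p$tau)
  J["R", "E"]  <- (1 - p$Phi) * p$sigma
  J["R", "I1"] <- p$omega * p$psi
  J["R", "I2"] <- p$upsilon
  J["R", "R"]  <- -(p$tau + p$lam)
  J["Q", "S"]  <- p$beta
  J["Q", "R"]  <- (1 - p$zeta) * p$lam
  J["Q", "Q"]  <- -p$tau
  J
}

# Shared eigenvalue-based classification.
stability_report <- function(state, params, tol) {
  ev <- eigen(smad_jacobian(state, params), only.values = TRUE)$values
  mx <- max(Re(ev))
  verdict <- if (abs(mx) <= tol) "marginal" else
    if (mx < 0) "stable" else "unstable"
  structure(list(equilibrium = state, eigenvalues = ev,
                 max_real_part = mx, verdict = verdict, tol = tol),
            class = "smad_stability")
}

#' @export
print.smad_stability <- function(x, ...) {
  cat(sprintf("<smad_stability> verdict = %s (max Re eigenvalue %.3e)\n",
              x$verdict, x$max_real_part))
  print(round(x$eigenvalues, 6))
  invisible(x)
}

#' Local stability of the disease-free equilibrium
#'
#' Numerically computes the six eigenvalues of the Jacobian at the
#' disease-free equilibrium. The verdict is `stable` exactly when
#' `R0 < 1` (all real parts negative), `unstable` when `R0 > 1`, and
#' `marginal` within `tol` of the threshold; `-tau` and `-(beta+tau)`
#' always appear among the eigenvalues.
#'
#' @inheritParams smad_jacobian
#' @param tol absolute tolerance on the largest eigenvalue real part below
#'   which the verdict is `marginal`.
#' @return An object of class `"smad_stability"` with fields
#'   `equilibrium`, `eigenvalues`, `max_real_part`, `verdict`.
#' @export
dfe_stability <- function(params, tol = 1e-9) {
  stability_report(smad_dfe(params)$state, params, tol)
}

#' Local stability of the endemic equilibrium
#'
#' @inheritParams dfe_stability
#' @return An object of class `"smad_stability"`.
#' @export
eep_stability <- function(params, tol = 1e-9) {
  eq <- smad_eep(params)
  if (is.null(eq))
    stop("no endemic equilibrium: R0 <= 1 for these parameters",
         call. = FALSE)
  stability_report(eq$state, params, tol)
}

#' Routh--Hurwitz check for a quadratic
#'
#' Both roots of `lambda^2 + a1*lambda + a2 = 0` have strictly negative
#' real parts if and only if `a1 > 0` and `a2 > 0`. For this model the
#' nontrivial quadratic factor of the characteristic polynomial at the
#' disease-free equilibrium has
#' `a2 = (sigma+tau)(alpha+psi+tau)(1 - R0)`, so the criterion reduces to
#' the `R0 < 1` threshold.
#'
#' @param a1,a2 real coefficients of the monic quadratic.
#' @return `TRUE` iff both roots lie in the open left half plane.
#' @export
routh_hurwitz_quadratic <- function(a1, a2) {
  stopifnot(is.numeric(a1), is.numeric(a2), is.finite(a1), is.finite(a2))
  a1 > 0 && a2 > 0
}

#' Center-manifold bifurcation coefficients
#'
#' At the critical contact rate `phi = phi_star(params)` the Jacobian at
#' the disease-free equilibrium has a simple zero eigenvalue. This
#' computes the associated right (`w`) and left (`v`) null vectors by the
#' closed-form cascade (scale fixed by `w2 = 1`; `v` has nonzero entries
#' only in the E and I1 slots, with `v3 = (sigma+tau)/(Phi*sigma) * v2`,
#' rescaled so `v . w = 1`) and evaluates the normal-form coefficients
#' \deqn{a = 2 v_2 w_1 w_3 \phi^* \chi, \qquad
#'       b = v_2 w_3 S^0 \chi}
#' with `S0 = Lambda/(beta+tau)`. A negative `a` together with a positive
#' `b` certifies a forward (supercritical) bifurcation: a stable endemic
#' branch emerges continuously as R0 crosses 1 from below, so the
#' disease-free and endemic states never coexist below threshold.
#'
#' @inheritParams smad_r0
#' @return A list of class `"smad_bifurcation"` with `a`, `b`, `w`, `v`
#'   and `phi_star`.
#' @export
bifurcation_coefficients <- function(params) {
  p <- setNames(as.list(as_param_vector(params)), .smad_param_names)
  ps <- phi_star(params)
  p_crit <- unclass(params)
  p_crit[["phi"]] <- ps
  p_crit <- structure(p_crit, class = "smad_params")
  S0 <- p$Lambda / (p$beta + p$tau)

  ev <- eigen(smad_jacobian(smad_dfe(p_crit)$state, p_crit),
              only.values = TRUE)$values
  near_zero <- sum(abs(ev) < 1e-7)
  if (near_zero != 1L)
    stop("zero eigenvalue at phi* is not simple (found ", near_zero,
         " near-zero eigenvalues)", call. = FALSE)

  A <- p$tau + p$alpha + p$psi
  B <- p$upsilon + p$rho + p$tau
  C <- p$tau + p$lam
  # right null vector, free scale fixed by w2 = 1
  w2 <- 1
  w3 <- p$Phi * p$sigma * w2 / A
  w4 <- (p$alpha + p$psi * (1 - p$omega)) * w3 / B
  w5 <- ((1 - p$Phi) * p$sigma * w2 + p$omega * p$psi * w3 +
           p$upsilon * w4) / C
  w1 <- (p$zeta * p$lam * w5 - ps * p$chi * S0 * w3) / (p$beta + p$tau)
  w6 <- (p$beta * w1 + (1 - p$zeta) * p$lam * w5) / p$tau
  w <- c(S = w1, E = w2, I1 = w3, I2 = w4, R = w5, Q = w6)
  # left null vector: only the E and I1 slots are nonzero
  v2 <- 1
  v3 <- (p$sigma + p$tau) / (p$Phi * p$sigma) * v2
  v <- c(S = 0, E = v2, I1 = v3, I2 = 0, R = 0, Q = 0)
  v <- v / sum(v * w)  # normalise v . w = 1
  v2 <- v[["E"]]

  structure(list(a = 2 * v2 * w1 * w3 * ps * p$chi,
                 b = v2 * w3 * S0 * p$chi,
                 w = w, v = v, phi_star = ps),
            class = "smad_bifurcation")
}

#' @export
print.smad_bifurcation <- function(x, ...) {
  cat(sprintf("<smad_bifurcation> a = %.6g, b = %.6g, phi* = %.6g\n",
              x$a, x$b, x$phi_star))
  cat(sprintf("forward bifurcation: %s\n", x$a < 0 && x$b > 0))
  invisible(x)
}
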