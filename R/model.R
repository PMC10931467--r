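#' smadsim: compartmental dynamics of social media addiction and depression
#'
#' Tools to simulate and analyse a six-compartment ODE model in which
#' susceptible individuals are recruited into social media use, become
#' exposed through contact with addicted users, progress to addiction and
#' possibly depression, and recover or quit permanently. The package covers
#' the basic reproduction number, equilibria, local stability and forward
#' bifurcation diagnostics, local and global sensitivity analysis, and
#' fixed-step RK-4 simulation.
#'
#' @useDynLib smadsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor pt setNames rnorm runif
#' @keywords internal
"_PACKAGE"

#' Vector field of the addiction--depression model
#'
#' Time derivative of the six compartments:
#' \deqn{S' = \Lambda + \zeta\lambda R - \phi\chi I_1 S - (\beta+\tau)S}
#' \deqn{E' = \phi\chi I_1 S - (\varsigma+\tau)E}
#' \deqn{I_1' = \Phi\varsigma E - (\tau+\psi+\alpha)I_1}
#' \deqn{I_2' = \alpha I_1 + \psi(1-\omega)I_1 - (\upsilon+\rho+\tau)I_2}
#' \deqn{R' = (1-\Phi)\varsigma E + \upsilon I_2 + \psi\omega I_1 -
#'   (\tau+\lambda)R}
#' \deqn{Q' = \beta S + (1-\zeta)\lambda R - \tau Q}
#'
#' Transfer terms appear with equal magnitude and opposite sign in their
#' source and destination compartments, so the population balance
#' `sum(smad_rhs(y, p)) == Lambda - tau*N - rho*I2` holds identically.
#' States are not clamped: admissibility (all components nonnegative) is a
#' precondition on the caller.
#'
#' @param state length-6 state vector (see [smad_state()]).
#' @param params a [smad_params()] object or named vector.
#' @return Named numeric vector of the six derivatives (individuals/time).
#' @examples
#' p <- smad_params(tau = 0.09, alpha = 0.5, phi = 0.8)
#' smad_rhs(smad_dfe(p)$state, p)  # ~ 0 at the disease-free equilibrium
#' @export
smad_rhs <- function(state, params) {
  y <- as_state_vector(state)
  p <- as.list(as_param_vector(params))
  names(p) <- .smad_param_names
  force_inf <- p$phi * p$chi * y[["I1"]] * y[["S"]]
  dy <- c(
    S  = p$Lambda + p$zeta * p$lam * y[["R"]] - force_inf -
      (p$beta + p$tau) * y[["S"]],
    E  = force_inf - (p$sigma + p$tau) * y[["E"]],
    I1 = p$Phi * p$sigma * y[["E"]] - (p$tau + p$psi + p$alpha) * y[["I1"]],
    I2 = p$alpha * y[["I1"]] + p$psi * (1 - p$omega) * y[["I1"]] -
      (p$upsilon + p$rho + p$tau) * y[["I2"]],
    R  = (1 - p$Phi) * p$sigma * y[["E"]] + p$upsilon * y[["I2"]] +
      p$psi * p$omega * y[["I1"]] - (p$tau + p$lam) * y[["R"]],
    Q  = p$beta * y[["S"]] + (1 - p$zeta) * p$lam * y[["R"]] -
      p$tau * y[["Q"]]
  )
  dy
}

#' Total population of a state
#'
#' @param state length-6 state vector.
#' @return `S + E + I1 + I2 + R + Q`.
#' @examples
#' total_population(smad_state(100, 1, 5, 2, 0, 10))  # 118
#' @export
total_population <- function(state) {
  sum(as_state_vector(state))
}
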