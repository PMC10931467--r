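#' Basic reproduction number (closed form)
#'
#' The threshold quantity
#' \deqn{R_0 = \frac{\Lambda\varsigma\phi\chi\Phi}
#'   {(\alpha+\psi+\tau)(\beta+\tau)(\varsigma+\tau)}}
#' i.e. the expected number of new addicts generated by one addicted
#' individual introduced into the disease-free population. The addiction
#' dies out when `R0 < 1` and persists when `R0 > 1`.
#'
#' @param params a [smad_params()] object.
#' @return A single nonnegative number.
#' @examples
#' smad_r0(smad_params(tau = 0.09, alpha = 0.5, phi = 0.8))  # 0.8684
#' @export
smad_r0 <- function(params) {
  p <- setNames(as.list(as_param_vector(params)), .smad_param_names)
  den <- (p$alpha + p$psi + p$tau) * (p$beta + p$tau) * (p$sigma + p$tau)
  if (den == 0)
    stop("degenerate parameters: a denominator factor of R0 is zero",
         call. = FALSE)
  p$Lambda * p$sigma * p$phi * p$chi * p$Phi / den
}

#' Basic reproduction number via the next-generation matrix
#'
#' Builds the new-infection matrix F and transition matrix V of the
#' infected block (E, I1, I2, R) linearised at the disease-free
#' equilibrium and returns the spectral radius of `F V^-1`. Agrees with
#' the closed form [smad_r0()] to machine precision; kept as an
#' independent construction for cross-checking.
#'
#' @inheritParams smad_r0
#' @return Spectral radius of the next-generation matrix.
#' @export
smad_r0_ngm <- function(params) {
  p <- setNames(as.list(as_param_vector(params)), .smad_param_names)
  S0 <- p$Lambda / (p$beta + p$tau)
  # infected block order: E, I1, I2, R
  F <- matrix(0, 4, 4)
  F[1, 2] <- p$phi * p$chi * S0
  V <- rbind(
    c(p$sigma + p$tau,            0,                          0, 0),
    c(-p$Phi * p$sigma,           p$tau + p$psi + p$alpha,    0, 0),
    c(0, -(p$alpha + p$psi * (1 - p$omega)), p$upsilon + p$rho + p$tau, 0),
    c(-(1 - p$Phi) * p$sigma,     -p$psi * p$omega, -p$upsilon,
      p$tau + p$lam))
  if (abs(det(V)) < .Machine$double.xmin)
    stop("degenerate parameters: transition matrix V is singular",
         call. = FALSE)
  K <- F %*% solve(V)
  max(abs(eigen(K, only.values = TRUE)$values))
}

#' Disease-free equilibrium
#'
#' The unique steady state with no exposed, addicted, depressed or
#' recovered individuals:
#' \deqn{E_{q0} = \left(\frac{\Lambda}{\beta+\tau}, 0, 0, 0, 0,
#'   \frac{\beta\Lambda}{(\beta+\tau)\tau}\right).}
#'
#' @inheritParams smad_r0
#' @return An object of class `"smad_equilibrium"`: a list with `state`,
#'   `kind` (`"DFE"`), `residual` (max absolute component of the vector
#'   field at the state) and `admissible`.
#' @examples
#' smad_dfe(smad_params(tau = 0.09, alpha = 0.5, phi = 0.8))
#' @export
smad_dfe <- function(params) {
  p <- setNames(as.list(as_param_vector(params)), .smad_param_names)
  state <- smad_state(S = p$Lambda / (p$beta + p$tau),
                      Q = p$beta * p$Lambda / ((p$beta + p$tau) * p$tau))
  new_equilibrium(state, "DFE", params)
}

#' Endemic equilibrium
#'
#' The steady state with all compartments strictly positive, which exists
#' exactly when `R0 > 1`. The susceptible component has the closed form
#' \deqn{S^1 = \frac{(\varsigma+\tau)(\tau+\alpha+\psi)}
#'   {\varsigma\phi\chi\Phi},}
#' equivalently `S1 = S0 / R0`. Given `S1`, every steady-state equation is
#' linear in E, so the remaining components follow from an exact algebraic
#' cascade (I1, I2 and R proportional to E; one linear balance fixes E; Q
#' is recovered last since nothing feeds back from it). No iterative
#' root-finding is involved and the residual is at machine-precision
#' level.
#'
#' @inheritParams smad_r0
#' @return An object of class `"smad_equilibrium"` (`kind = "EEP"`), or
#'   `NULL` when `R0 <= 1` (no admissible endemic state).
#' @examples
#' p <- smad_params(Lambda = 0.60556, chi = 0.26104, phi = 0.89339,
#'                  sigma = 0.22874, Phi = 0.80142, beta = 0.010014,
#'                  tau = 0.095, alpha = 0.47155, psi = 0.002909)
#' smad_eep(p)$state  # (4.3123, 0.5588, 0.1799, 0.1055, 0.2013, 1.0055)
#' @export
smad_eep <- function(params) {
  p <- setNames(as.list(as_param_vector(params)), .smad_param_names)
  if (smad_r0(params) <= 1) return(NULL)
  A <- p$tau + p$psi + p$alpha      # addicted-class exit rate
  B <- p$upsilon + p$rho + p$tau    # depressed-class exit rate
  C <- p$tau + p$lam                # recovered-class exit rate
  S1 <- (p$sigma + p$tau) * A / (p$sigma * p$phi * p$chi * p$Phi)
  k1 <- p$Phi * p$sigma / A                        # I1 = k1 E
  k2 <- (p$alpha + p$psi * (1 - p$omega)) * k1 / B # I2 = k2 E
  k3 <- ((1 - p$Phi) * p$sigma + p$omega * p$psi * k1 +
           p$upsilon * k2) / C                     # R  = k3 E
  # S-balance with phi*chi*I1*S = (sigma+tau)E substituted is linear in E
  E1 <- (p$Lambda - (p$beta + p$tau) * S1) /
    ((p$sigma + p$tau) - p$zeta * p$lam * k3)
  R1 <- k3 * E1
  Q1 <- (p$beta * S1 + (1 - p$zeta) * p$lam * R1) / p$tau
  state <- smad_state(S = S1, E = E1, I1 = k1 * E1, I2 = k2 * E1,
                      R = R1, Q = Q1)
  eq <- new_equilibrium(state, "EEP", params)
  if (eq$residual > 1e-10)
    stop("endemic equilibrium residual ", format(eq$residual),
         " exceeds tolerance 1e-10", call. = FALSE)
  eq
}

# Build an equilibrium report; components in (-1e-9, 0) are treated as
# exact zeros for the admissibility verdict.
new_equilibrium <- function(state, kind, params) {
  res <- max(abs(smad_rhs(state, params)))
  structure(list(state = state, kind = kind, residual = res,
                 admissible = all(state > -1e-9)),
            class = "smad_equilibrium")
}

#' @export
print.smad_equilibrium <- function(x, ...) {
  cat(sprintf("<smad_equilibrium> kind = %s, admissible = %s\n",
              x$kind, x$admissible))
  print(round(x$state, 6))
  cat(sprintf("max |rhs| residual: %.3g\n", x$residual))
  invisible(x)
}

#' Strength number
#'
#' Second-order analogue of the reproduction number obtained from the
#' nonlinear part of the incidence at the disease-free equilibrium:
#' \deqn{A = -\frac{2\tau^2\phi\chi\Lambda}{\tau+\beta} \le 0.}
#' Its strictly negative sign (for positive transmission parameters)
#' indicates that the epidemic has no renewal process: a single wave that
#' eventually dies out rather than self-reinforcing growth of incidence.
#'
#' @inheritParams smad_r0
#' @return A nonpositive number.
#' @export
strength_number <- function(params) {
  p <- setNames(as.list(as_param_vector(params)), .smad_param_names)
  -2 * p$tau^2 * p$phi * p$chi * p$Lambda / (p$tau + p$beta)
}

#' Critical contact rate
#'
#' The value of the contact rate `phi` at which `R0 = 1`, used as the
#' bifurcation parameter:
#' \deqn{\phi^* = \frac{(\alpha+\psi+\tau)(\beta+\tau)(\varsigma+\tau)}
#'   {\Lambda\varsigma\chi\Phi}.}
#' Since R0 is linear in `phi`, this equals `phi / R0(params)`.
#'
#' @inheritParams smad_r0
#' @return The critical contact rate (1/time).
#' @export
phi_star <- function(params) {
  p <- setNames(as.list(as_param_vector(params)), .smad_param_names)
  den <- p$Lambda * p$sigma * p$chi * p$Phi
  if (den == 0)
    stop("degenerate parameters: Lambda * sigma * chi * Phi must be positive",
         call. = FALSE)
  (p$alpha + p$psi + p$tau) * (p$beta + p$tau) * (p$sigma + p$tau) / den
}
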