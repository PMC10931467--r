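# Canonical parameter slot order; shared with the compiled integrator.
.smad_param_names <- c("Lambda", "zeta", "lam", "tau", "alpha", "beta",
                       "chi", "upsilon", "sigma", "omega", "psi", "Phi",
                       "rho", "phi")

.smad_fractions <- c("zeta", "omega", "Phi", "chi")

.smad_state_names <- c("S", "E", "I1", "I2", "R", "Q")

#' Model parameters
#'
#' Construct and validate the 14 rates and fractions governing the
#' addiction--depression dynamics. All parameters are nonnegative; the
#' natural death rate `tau` must be strictly positive, and the fractions
#' `zeta`, `omega`, `Phi`, `chi` must lie in \[0, 1\]. Time is treated as
#' dimensionless throughout: rates are "per unit time" in whatever unit the
#' user attaches to the trajectory grid.
#'
#' Defaults are the baseline parameterisation used by the packaged
#' `table1_baseline` scenario (for the three parameters published only as
#' ranges, the baseline pins `tau = 0.05`, `alpha = 0.4`, `phi = 0.45`).
#'
#' @param Lambda recruitment rate of susceptibles (individuals/time).
#' @param zeta fraction of recovered individuals that become susceptible
#'   again (the rest quit permanently).
#' @param lam rate of leaving the recovered class (1/time).
#' @param tau natural death rate (1/time); must be positive.
#' @param alpha rate at which addiction induces depression (1/time).
#' @param beta rate at which susceptibles quit social media outright
#'   (1/time).
#' @param chi probability of transmission per contact with an addicted
#'   individual.
#' @param upsilon treatment rate moving depressed individuals to the
#'   recovered class (1/time).
#' @param sigma rate of leaving the exposed class (1/time).
#' @param omega probability that treatment of an addicted individual
#'   succeeds.
#' @param psi rate of leaving treatment (1/time).
#' @param Phi fraction of exposed individuals that become addicted (the
#'   remainder recover directly).
#' @param rho depression-induced death rate (1/time).
#' @param phi contact rate of susceptibles with addicted individuals
#'   (1/time).
#' @return A named numeric vector of class `"smad_params"`.
#' @examples
#' p <- smad_params(tau = 0.09, alpha = 0.5, phi = 0.8)
#' smad_r0(p)
#' @export
smad_params <- function(Lambda = 0.5, zeta = 0.35, lam = 0.4, tau = 0.05,
                        alpha = 0.4, beta = 0.01, chi = 0.25,
                        upsilon = 0.7, sigma = 0.25, omega = 0.8,
                        psi = 0.0027, Phi = 0.7, rho = 0.01, phi = 0.45) {
  p <- c(Lambda = Lambda, zeta = zeta, lam = lam, tau = tau, alpha = alpha,
         beta = beta, chi = chi, upsilon = upsilon, sigma = sigma,
         omega = omega, psi = psi, Phi = Phi, rho = rho, phi = phi)
  validate_smad_params(p)
  structure(p, class = "smad_params")
}

#' Validate a parameter vector
#'
#' @param p named numeric vector with the 14 parameter names.
#' @return `p`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_smad_params <- function(p) {
  p <- unclass(p)
  if (!is.numeric(p) || !all(.smad_param_names %in% names(p)))
    stop("parameters must be a named numeric vector containing: ",
         paste(.smad_param_names, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(p), .smad_param_names)
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(p)))
    stop("non-finite parameter(s): ",
         paste(names(p)[!is.finite(p)], collapse = ", "), call. = FALSE)
  if (any(p < 0))
    stop("negative parameter(s): ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  if (p[["tau"]] <= 0)
    stop("`tau` (natural death rate) must be strictly positive",
         call. = FALSE)
  frac_bad <- .smad_fractions[p[.smad_fractions] > 1]
  if (length(frac_bad))
    stop("fraction parameter(s) above 1: ",
         paste(frac_bad, collapse = ", "), call. = FALSE)
  invisible(p)
}

# Coerce to the canonical slot order as a bare double vector (C++ contract).
as_param_vector <- function(params) {
  p <- unclass(params)
  validate_smad_params(p)
  as.numeric(p[.smad_param_names])
}

#' @export
print.smad_params <- function(x, ...) {
  cat("<smad_params>\n")
  print(round(unclass(x), 6))
  r0 <- tryCatch(smad_r0(x), error = function(e) NA_real_)
  cat(sprintf("R0 = %.4f\n", r0))
  invisible(x)
}

#' Compartmental state vector
#'
#' The six compartments: susceptible (S), exposed (E), addicted (I1),
#' depressed (I2), recovered (R), and permanent quitters (Q). Admissible
#' states have all components nonnegative and finite.
#'
#' @param S,E,I1,I2,R,Q compartment sizes (individuals).
#' @return Named numeric vector in the order S, E, I1, I2, R, Q.
#' @examples
#' smad_state(S = 100, E = 1, I1 = 5, I2 = 2, R = 0, Q = 10)
#' @export
smad_state <- function(S = 0, E = 0, I1 = 0, I2 = 0, R = 0, Q = 0) {
  y <- c(S = S, E = E, I1 = I1, I2 = I2, R = R, Q = Q)
  if (!all(is.finite(y))) stop("state components must be finite",
                               call. = FALSE)
  y
}

# Accept a bare length-6 vector (named or not) as a state.
as_state_vector <- function(state) {
  if (length(state) != 6L)
    stop("a state must have exactly 6 components (S, E, I1, I2, R, Q)",
         call. = FALSE)
  if (!is.numeric(state) || !all(is.finite(state)))
    stop("state components must be finite numbers", call. = FALSE)
  y <- as.numeric(state)
  names(y) <- .smad_state_names
  y
}
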