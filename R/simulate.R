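#' One classical RK-4 step
#'
#' Advances the state by a single step of the classical fourth-order
#' Runge--Kutta scheme with step size `h`.
#'
#' @param state length-6 state vector.
#' @param params a [smad_params()] object.
#' @param h step size (time units), positive.
#' @return The updated state (named length-6 vector).
#' @export
rk4_step <- function(state, params, h) {
  stopifnot(h > 0)
  y <- as_state_vector(state)
  out <- .rk4_step_cpp(y, as_param_vector(params), h)
  if (!all(is.finite(out)))
    stop("non-finite intermediate in RK-4 step", call. = FALSE)
  setNames(out, .smad_state_names)
}

#' Fixed-step RK-4 integration
#'
#' Integrates the model on the uniform grid `0, h, 2h, ..., t_end` with
#' the classical fourth-order Runge--Kutta scheme (compiled loop). To keep
#' trajectories small only every `thin`-th step is stored (plus the final
#' state), but positivity and boundedness are audited over **all** steps:
#' a warning is raised if any component ever drops below `-1e-9`, and the
#' trajectory records the extreme component and population values seen.
#'
#' @inheritParams rk4_step
#' @param state0 initial state.
#' @param t_end final time, positive; the number of steps is
#'   `round(t_end / h)`.
#' @param h step size; the default `0.001` matches the resolution used for
#'   the reference scenario runs.
#' @param thin store every `thin`-th step (default 100, i.e. every 0.1
#'   time units at the default `h`).
#' @return An object of class `"smad_trajectory"`: list with `times`,
#'   `states` (matrix, one row per stored time, columns S, E, I1, I2, R,
#'   Q), `params`, `h`, `min_component`, `max_population`.
#' @examples
#' p <- smad_params(tau = 0.09, alpha = 0.5, phi = 0.8)
#' tr <- smad_integrate(p, smad_state(100, 1, 5, 2, 0, 10), t_end = 50)
#' utils::tail(as.data.frame(tr), 1)
#' @export
smad_integrate <- function(params, state0, h = 0.001, t_end = 500,
                           thin = 100L) {
  stopifnot(h > 0, t_end > 0)
  y0 <- as_state_vector(state0)
  n_steps <- as.integer(round(t_end / h))
  raw <- .rk4_integrate_cpp(y0, as_param_vector(params), h, n_steps,
                            as.integer(thin))
  states <- raw$states
  colnames(states) <- .smad_state_names
  if (raw$min_component < -1e-9)
    warning(sprintf("positivity violation: a component reached %.3g",
                    raw$min_component), call. = FALSE)
  structure(list(times = raw$times, states = states, params = params,
                 h = h, thin = as.integer(thin),
                 min_component = raw$min_component,
                 max_population = raw$max_population),
            class = "smad_trajectory")
}

#' @export
print.smad_trajectory <- function(x, ...) {
  cat(sprintf(
    "<smad_trajectory> %d stored states on [0, %g], h = %g (thin %d)\n",
    length(x$times), max(x$times), x$h, x$thin))
  cat("final state:\n")
  print(round(x$states[nrow(x$states), ], 6))
  invisible(x)
}

#' @export
as.data.frame.smad_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states)
}

#' Write a trajectory as CSV
#'
#' Plain-text export with header `t,S,E,I1,I2,R,Q` at full double
#' precision.
#'
#' @param traj a [smad_integrate()] trajectory.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Steady-state detection
#'
#' Declares a trajectory converged if the vector field is below `tol` (in
#' max norm) at every one of the trailing `window` stored states, and
#' returns the final state in that case.
#'
#' @param traj a [smad_integrate()] trajectory.
#' @param tol max-norm tolerance on the vector field.
#' @param window number of trailing stored states that must all satisfy
#'   the tolerance.
#' @return The final state, or `NULL` if the criterion is not met.
#' @export
detect_steady_state <- function(traj, tol = 1e-6, window = 10L) {
  stopifnot(inherits(traj, "smad_trajectory"))
  n <- nrow(traj$states)
  if (n < window) return(NULL)
  idx <- seq.int(n - window + 1L, n)
  resid <- vapply(idx, function(i)
    max(abs(smad_rhs(traj$states[i, ], traj$params))), numeric(1))
  if (all(resid < tol)) traj$states[n, ] else NULL
}

#' Parameter sweep
#'
#' Re-integrates the model once per value of a single parameter, holding
#' everything else fixed. Used e.g. to study how the addiction fraction
#' `Phi`, the death rate `tau`, the contact rate `phi` or the
#' depression rate `alpha` reshape the epidemic curves.
#'
#' @param base_params baseline [smad_params()].
#' @param name parameter to vary (one of the 14 parameter names).
#' @param values numeric vector of values to assign.
#' @inheritParams smad_integrate
#' @return Named list of `"smad_trajectory"` objects, one per value.
#' @examples
#' p <- smad_params(tau = 0.09, alpha = 0.5, phi = 0.8)
#' sw <- parameter_sweep(p, "Phi", c(0.5, 0.7, 0.9),
#'                       smad_state(100, 1, 5, 2, 0, 10), t_end = 50)
#' sapply(sw, function(tr) max(tr$states[, "I1"]))  # peak increases in Phi
#' @export
parameter_sweep <- function(base_params, name, values, state0, h = 0.001,
                            t_end = 500) {
  if (!name %in% .smad_param_names)
    stop("unknown parameter name: ", name, call. = FALSE)
  out <- lapply(values, function(v) {
    p <- unclass(base_params)
    p[[name]] <- v
    smad_integrate(structure(p, class = "smad_params"), state0,
                   h = h, t_end = t_end)
  })
  names(out) <- paste0(name, "=", values)
  out
}
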