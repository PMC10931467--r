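.scenario_keys <- c("schema", "name", "note", "extends", "parameters",
                    "initial_state", "integration")

#' Load a packaged scenario
#'
#' Three scenarios ship with the package:
#' \describe{
#'   \item{`table1_baseline`}{the published baseline parameterisation
#'     (ranged parameters pinned at `tau = 0.05`, `alpha = 0.4`,
#'     `phi = 0.45`).}
#'   \item{`case1_r0_lt_1`}{the below-threshold scenario (`R0 = 0.8684`):
#'     the addiction dies out and the population settles at the
#'     disease-free equilibrium.}
#'   \item{`case2_r0_gt_1`}{the above-threshold scenario (`R0 = 1.3372`):
#'     the addiction persists at the endemic equilibrium.}
#' }
#'
#' @param name scenario name.
#' @return An object of class `"smad_scenario"`: list with `name`,
#'   `note`, `params` ([smad_params()]), `state0`, `h`, `t_end`.
#' @examples
#' sc <- smad_scenario("case1_r0_lt_1")
#' smad_r0(sc$params)
#' @export
smad_scenario <- function(name = c("table1_baseline", "case1_r0_lt_1",
                                   "case2_r0_gt_1")) {
  name <- match.arg(name)
  load_scenario(system.file("extdata", "scenarios",
                            paste0(name, ".yaml"), package = "smadsim",
                            mustWork = TRUE))
}

#' Load and validate a scenario configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) scenario description.
#' Unknown top-level keys and unknown parameter names are rejected.
#' Parameters may be left out only when an `extends` field names a
#' packaged scenario to inherit from; otherwise all 14 must be present.
#'
#' @param path path to the configuration file.
#' @return An object of class `"smad_scenario"`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .scenario_keys)
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  pars <- cfg$parameters
  state <- cfg$initial_state
  integ <- cfg$integration
  bad_par <- setdiff(names(pars), .smad_param_names)
  if (length(bad_par))
    stop("unknown parameter(s): ", paste(bad_par, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$extends)) {
    base <- smad_scenario(cfg$extends)
    full <- as.list(unclass(base$params))
    full[names(pars)] <- pars
    pars <- full
    if (is.null(state)) state <- as.list(base$state0)
    if (is.null(integ)) integ <- list(h = base$h, t_end = base$t_end)
  }
  missing_p <- setdiff(.smad_param_names, names(pars))
  if (length(missing_p))
    stop("missing parameter(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  params <- do.call(smad_params, pars[.smad_param_names])
  if (is.null(state))
    stop("scenario must provide `initial_state`", call. = FALSE)
  state0 <- do.call(smad_state, as.list(state)[.smad_state_names])
  if (any(state0 < 0))
    stop("initial state components must be nonnegative", call. = FALSE)
  structure(list(name = cfg$name %||% basename(path),
                 note = cfg$note %||% "",
                 params = params, state0 = state0,
                 h = integ$h %||% 0.001,
                 t_end = integ$t_end %||% 500),
            class = "smad_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a scenario configuration
#'
#' Writes a scenario back to YAML in the schema accepted by
#' [load_scenario()]; save/load round-trips are exact.
#'
#' @param scenario an `"smad_scenario"` object.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "smad_scenario"))
  yaml::write_yaml(list(
    schema = 1L,
    name = scenario$name,
    note = scenario$note,
    parameters = as.list(unclass(scenario$params)),
    initial_state = as.list(scenario$state0),
    integration = list(h = scenario$h, t_end = scenario$t_end)), path,
    precision = 15L)
  invisible(path)
}

#' @export
print.smad_scenario <- function(x, ...) {
  cat(sprintf("<smad_scenario> %s (h = %g, t_end = %g)\n", x$name, x$h,
              x$t_end))
  if (nzchar(x$note)) cat(x$note, "\n")
  print(x$params)
  invisible(x)
}

#' Full analysis report for a scenario
#'
#' Runs every analysis in the package on one scenario: reproduction
#' number, equilibria with residuals, stability verdicts, bifurcation
#' coefficients, the closed-form sensitivity table, and the RK-4
#' simulation with steady-state detection. The endemic entries are
#' omitted when `R0 <= 1` (no endemic state exists).
#'
#' @param scenario an `"smad_scenario"` object (see [smad_scenario()]).
#' @param steady_tol tolerance handed to [detect_steady_state()].
#' @return A nested list suitable for JSON serialisation via
#'   [write_report()].
#' @export
run_report <- function(scenario, steady_tol = 1e-6) {
  stopifnot(inherits(scenario, "smad_scenario"))
  p <- scenario$params
  r0 <- smad_r0(p)
  dfe <- smad_dfe(p)
  eep <- smad_eep(p)
  bif <- bifurcation_coefficients(p)
  traj <- smad_integrate(p, scenario$state0, h = scenario$h,
                         t_end = scenario$t_end)
  steady <- detect_steady_state(traj, tol = steady_tol)
  rep <- list(
    package_version = as.character(utils::packageVersion("smadsim")),
    scenario = scenario$name,
    R0 = r0,
    dfe = list(state = as.list(dfe$state), residual = dfe$residual,
               stability = dfe_stability(p)$verdict),
    bifurcation = list(a = bif$a, b = bif$b, phi_star = bif$phi_star,
                       forward = bif$a < 0 && bif$b > 0),
    nfsi = nfsi_table(p),
    simulation = list(h = scenario$h, t_end = scenario$t_end,
                      final_state = as.list(traj$states[nrow(traj$states), ]),
                      steady_state_reached = !is.null(steady),
                      min_component = traj$min_component,
                      max_population = traj$max_population))
  if (!is.null(eep))
    rep$eep <- list(state = as.list(eep$state), residual = eep$residual,
                    stability = eep_stability(p)$verdict)
  rep
}

#' Write a report as JSON
#'
#' @param report output of [run_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
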