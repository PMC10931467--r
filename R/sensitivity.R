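.nfsi_names <- c("sigma", "phi", "chi", "Phi", "beta", "tau", "alpha",
                 "psi")

#' Normalized forward sensitivity index of R0 (closed form)
#'
#' The elasticity of the basic reproduction number with respect to a
#' parameter p, `(dR0/dp) * (p/R0)`. Because R0 is multiplicatively
#' separable in `phi`, `chi` and `Phi`, their indices are exactly 1 for
#' any parameter values. The remaining closed forms are
#' \itemize{
#'   \item `sigma`: `tau / (tau + sigma)`
#'   \item `beta`: `-beta / (beta + tau)`
#'   \item `alpha`: `-alpha / (tau + alpha + psi)`
#'   \item `psi`: `-psi / (tau + alpha + psi)`
#'   \item `tau`: `-tau * (1/(alpha+psi+tau) + 1/(beta+tau) +
#'     1/(sigma+tau))`, since `tau` enters all three denominator factors.
#' }
#'
#' @param params a [smad_params()] object.
#' @param name one of `"sigma"`, `"phi"`, `"chi"`, `"Phi"`, `"beta"`,
#'   `"tau"`, `"alpha"`, `"psi"`.
#' @return The dimensionless elasticity.
#' @examples
#' nfsi_closed_form(smad_params(tau = 0.05, sigma = 0.25), "sigma")
#' # 0.1667: a 1% rise in the exposed exit rate raises R0 by 0.17%
#' @export
nfsi_closed_form <- function(params, name) {
  p <- setNames(as.list(as_param_vector(params)), .smad_param_names)
  switch(name,
    sigma = p$tau / (p$tau + p$sigma),
    phi   = 1,
    chi   = 1,
    Phi   = 1,
    beta  = -p$beta / (p$beta + p$tau),
    alpha = -p$alpha / (p$tau + p$alpha + p$psi),
    psi   = -p$psi / (p$tau + p$alpha + p$psi),
    tau   = -p$tau * (1 / (p$alpha + p$psi + p$tau) +
                        1 / (p$beta + p$tau) + 1 / (p$sigma + p$tau)),
    stop("unknown or unsupported parameter name: ", name, call. = FALSE))
}

#' Normalized forward sensitivity index of R0 (central differences)
#'
#' Numeric elasticity `(dR0/dp) * (p/R0)` by a central difference with
#' relative step `rel_step`, as an independent check on
#' [nfsi_closed_form()].
#'
#' @inheritParams nfsi_closed_form
#' @param rel_step relative perturbation of the parameter.
#' @return The elasticity estimate.
#' @export
nfsi_numeric <- function(params, name, rel_step = 1e-6) {
  if (!name %in% .nfsi_names)
    stop("unknown or unsupported parameter name: ", name, call. = FALSE)
  p0 <- unclass(params)
  val <- p0[[name]]
  if (val <= 0)
    stop("numeric elasticity needs a strictly positive parameter value",
         call. = FALSE)
  r0 <- smad_r0(params)
  if (r0 == 0) stop("R0 = 0: elasticity undefined", call. = FALSE)
  perturb <- function(x) {
    p <- p0; p[[name]] <- x
    smad_r0(structure(p, class = "smad_params"))
  }
  d <- val * rel_step
  (perturb(val + d) - perturb(val - d)) / (2 * d) * val / r0
}

#' Sensitivity index table
#'
#' Closed-form elasticities of R0 for all supported parameters at a given
#' baseline.
#'
#' @inheritParams nfsi_closed_form
#' @return A data frame with columns `parameter` and `index`, ordered by
#'   decreasing absolute index.
#' @export
nfsi_table <- function(params) {
  idx <- vapply(.nfsi_names, nfsi_closed_form, numeric(1),
                params = params)
  out <- data.frame(parameter = .nfsi_names, index = unname(idx))
  out[order(-abs(out$index)), , drop = FALSE]
}

#' Latin hypercube sample
#'
#' Stratified uniform design: each parameter's range is partitioned into
#' `n` equal strata and exactly one point is drawn per stratum
#' (via [lhs::randomLHS()]), then rescaled to the requested ranges.
#' Reproducible for a fixed seed.
#'
#' @param ranges named list of `c(lower, upper)` ranges, or a 2-column
#'   matrix with rownames.
#' @param n number of samples (rows), at least 2.
#' @param seed integer seed recorded with the design.
#' @return An object of class `"smad_lhs"`: list with `samples`
#'   (`n x p` matrix with parameter columns), `ranges`, `seed`.
#' @export
lhs_sample <- function(ranges, n, seed) {
  if (is.matrix(ranges))
    ranges <- setNames(lapply(seq_len(nrow(ranges)),
                              function(i) ranges[i, ]), rownames(ranges))
  stopifnot(n >= 2, length(ranges) >= 1)
  lo <- vapply(ranges, `[`, numeric(1), 1L)
  hi <- vapply(ranges, `[`, numeric(1), 2L)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("each range must be finite with lower < upper", call. = FALSE)
  set.seed(seed)
  u <- lhs::randomLHS(n, length(ranges))
  samples <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(samples) <- names(ranges)
  structure(list(samples = samples, ranges = ranges, seed = seed),
            class = "smad_lhs")
}

#' Partial rank correlation coefficients
#'
#' For each column of the design, the Spearman-type partial correlation
#' between that input and the output after removing the linear effect of
#' all other inputs on the rank scale: ranks are computed, the focal
#' column's ranks and the output's ranks are each regressed on the
#' remaining rank-transformed columns, and the residuals are correlated
#' (the residual-regression formulation of partial correlation).
#' Significance uses the t statistic with `n - 2 - (p - 1)` degrees of
#' freedom, the standard convention with `p - 1` controlled variables.
#'
#' @param design an `"smad_lhs"` object or a numeric matrix with named
#'   columns.
#' @param output_values numeric output, one value per design row.
#' @return A data frame of class `"smad_prcc"` with columns `parameter`,
#'   `prcc`, `p_value`.
#' @export
prcc <- function(design, output_values) {
  X <- if (inherits(design, "smad_lhs")) design$samples else design
  stopifnot(is.matrix(X), length(output_values) == nrow(X))
  if (!all(is.finite(output_values)))
    stop("output values must be finite", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2)
    stop("need more design rows than parameters + 2", call. = FALSE)
  const <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("constant design column(s): ",
         paste(colnames(X)[const], collapse = ", "),
         "; partial correlation undefined", call. = FALSE)
  RX <- apply(X, 2, rank)
  ry <- rank(output_values)
  df <- n - 2 - (p - 1)
  out <- lapply(seq_len(p), function(j) {
    others <- cbind(1, RX[, -j, drop = FALSE])
    res_x <- stats::lm.fit(others, RX[, j])$residuals
    res_y <- stats::lm.fit(others, ry)$residuals
    r <- cor(res_x, res_y)
    tstat <- r * sqrt(df / (1 - r^2))
    data.frame(parameter = colnames(X)[j], prcc = r,
               p_value = 2 * pt(-abs(tstat), df))
  })
  structure(do.call(rbind, out), class = c("smad_prcc", "data.frame"))
}

#' Global sensitivity experiment (LHS + PRCC)
#'
#' Draws a Latin hypercube design over the nine parameters entering R0
#' (by default a symmetric `span` window around the baseline, truncated
#' so rates stay nonnegative and fractions stay within \[0, 1\]),
#' evaluates each requested output on every design row, and returns one
#' PRCC report per output. `"R0"` is evaluated in closed form;
#' compartment outputs (`"S"`, ..., `"Q"`) are read off an RK-4
#' trajectory at time `t_eval`.
#'
#' @param baseline a [smad_params()] baseline.
#' @param n number of hypercube samples.
#' @param seed integer seed (required: the design is stochastic).
#' @param outputs character vector drawn from
#'   `c("R0", "S", "E", "I1", "I2", "R", "Q")`.
#' @param span half-width of each parameter range, as a fraction of its
#'   baseline value.
#' @param state0 initial state for compartment outputs.
#' @param t_eval evaluation time for compartment outputs.
#' @param h step size for compartment outputs (coarser than the scenario
#'   default since only a pointwise state is needed).
#' @return A list with one `"smad_prcc"` data frame per output, plus a
#'   `manifest` recording seed, n, ranges and evaluation settings.
#' @export
run_prcc_experiment <- function(baseline, n = 5000, seed,
                                outputs = "R0", span = 0.25,
                                state0 = smad_state(100, 1, 5, 2, 0, 10),
                                t_eval = 50, h = 0.01) {
  stopifnot(!missing(seed))
  bad <- setdiff(outputs, c("R0", .smad_state_names))
  if (length(bad))
    stop("unknown output(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  vary <- c("Lambda", "sigma", "phi", "chi", "Phi", "beta", "tau",
            "alpha", "psi")
  b <- unclass(baseline)
  ranges <- lapply(vary, function(nm) {
    lo <- max(0, b[[nm]] * (1 - span))
    hi <- b[[nm]] * (1 + span)
    if (nm %in% .smad_fractions) hi <- min(1, hi)
    c(lo, hi)
  })
  names(ranges) <- vary
  design <- lhs_sample(ranges, n, seed)

  param_row <- function(i) {
    p <- b
    p[vary] <- design$samples[i, vary]
    structure(p, class = "smad_params")
  }
  need_traj <- any(outputs %in% .smad_state_names)
  reports <- list()
  vals <- matrix(NA_real_, n, length(outputs),
                 dimnames = list(NULL, outputs))
  for (i in seq_len(n)) {
    pi <- param_row(i)
    if ("R0" %in% outputs) vals[i, "R0"] <- smad_r0(pi)
    if (need_traj) {
      tr <- smad_integrate(pi, state0, h = h, t_end = t_eval,
                           thin = max(1L, as.integer(t_eval / h)))
      final <- tr$states[nrow(tr$states), ]
      for (out in intersect(outputs, .smad_state_names))
        vals[i, out] <- final[[out]]
    }
  }
  for (out in outputs) reports[[out]] <- prcc(design, vals[, out])
  reports$manifest <- list(seed = seed, n = n, span = span,
                           ranges = ranges, t_eval = t_eval, h = h,
                           outputs = outputs)
  reports
}
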