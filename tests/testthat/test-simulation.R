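test_that("equilibria are fixed points of the RK-4 map", {
  p <- case1_params()
  dfe <- smad_dfe(p)$state
  for (h in c(0.001, 0.1, 0.5))
    expect_lt(max(abs(rk4_step(dfe, p, h) - dfe)), 1e-12)
  p2 <- case2_params()
  eep <- smad_eep(p2)$state
  expect_lt(max(abs(rk4_step(eep, p2, 0.1) - eep)), 1e-12)
})

test_that("compiled step agrees with an R-level RK-4 step", {
  # independent single-step oracle assembled from the R vector field
  r_rk4 <- function(y, p, h) {
    k1 <- smad_rhs(y, p)
    k2 <- smad_rhs(y + h / 2 * k1, p)
    k3 <- smad_rhs(y + h / 2 * k2, p)
    k4 <- smad_rhs(y + h * k3, p)
    y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  set.seed(41)
  for (i in 1:20) {
    p <- random_params()
    y <- random_state()
    expect_equal(rk4_step(y, p, 0.05), r_rk4(y, p, 0.05),
                 tolerance = 1e-14)
  }
})

test_that("one step on the linear sub-problem matches the exponential", {
  # with E = I1 = I2 = R = Q = 0 and zeta = 0 the S-equation is linear:
  # dS/dt = Lambda - (beta+tau) S, S(0) = 0
  p <- unclass(case1_params()); p[["zeta"]] <- 0
  p <- structure(p, class = "smad_params")
  h <- 0.001
  k <- p[["beta"]] + p[["tau"]]
  exact <- p[["Lambda"]] / k * (1 - exp(-k * h))
  stepped <- rk4_step(rep(0, 6), p, h)
  expect_lt(abs(stepped[["S"]] - exact), 1e-15)
  expect_equal(unname(stepped[2:6]), rep(0, 5))
})

test_that("the scheme converges at fourth order", {
  p <- case1_params()
  y0 <- reference_ic
  final_at <- function(h) {
    tr <- smad_integrate(p, y0, h = h, t_end = 1, thin = 1e9L)
    tr$states[nrow(tr$states), ]
  }
  ref <- final_at(1e-5)
  e1 <- max(abs(final_at(0.02) - ref))
  e2 <- max(abs(final_at(0.01) - ref))
  expect_gt(e1 / e2, 13)
  expect_lt(e1 / e2, 19)
})

test_that("reference scenarios converge to their printed equilibria", {
  tr1 <- smad_integrate(case1_params(), reference_ic, h = 0.001,
                        t_end = 500)
  final1 <- tr1$states[nrow(tr1$states), ]
  expect_lt(max(abs(final1 - case1_dfe_printed)), 1e-3)
  tr2 <- smad_integrate(case2_params(), reference_ic, h = 0.001,
                        t_end = 500)
  final2 <- tr2$states[nrow(tr2$states), ]
  expect_lt(abs(final2[["E"]] - 0.5588), 1e-3)
  expect_lt(abs(final2[["I1"]] - 0.1799), 1e-3)
})

test_that("empty system with no recruitment stays identically zero", {
  p <- unclass(case1_params()); p[["Lambda"]] <- 0
  tr <- smad_integrate(structure(p, class = "smad_params"), rep(0, 6),
                       h = 0.01, t_end = 10)
  expect_true(all(tr$states == 0))
})

test_that("positivity and boundedness hold along fixture trajectories", {
  for (make in list(case1_params, case2_params)) {
    p <- make()
    tr <- smad_integrate(p, reference_ic, h = 0.001, t_end = 500)
    expect_gt(tr$min_component, -1e-9)       # audited over all steps
    bound <- max(total_population(reference_ic),
                 unclass(p)[["Lambda"]] / unclass(p)[["tau"]])
    expect_lte(tr$max_population, bound + 1e-6)
    # away from the limit (where the small rho*I2 leak is negligible)
    # N(t) decays monotonically toward Lambda/tau
    n_t <- rowSums(tr$states)
    gap <- abs(n_t - unclass(p)[["Lambda"]] / unclass(p)[["tau"]])
    outside <- which(gap > 0.05)
    expect_true(all(diff(gap[outside]) < 1e-8))
  }
})

test_that("steady-state detection separates converged from transient runs", {
  p <- case1_params()
  long <- smad_integrate(p, reference_ic, h = 0.001, t_end = 500)
  found <- detect_steady_state(long, tol = 1e-6)
  expect_false(is.null(found))
  expect_lt(max(abs(found - smad_dfe(p)$state)), 1e-5)
  expect_lt(max(abs(smad_rhs(found, p))), 1e-6)
  short <- smad_integrate(p, reference_ic, h = 0.001, t_end = 2)
  expect_null(detect_steady_state(short, tol = 1e-6))
})

test_that("detected steady state of the endemic scenario matches smad_eep", {
  p <- case2_params()
  tr <- smad_integrate(p, reference_ic, h = 0.001, t_end = 500)
  found <- detect_steady_state(tr, tol = 1e-8)
  expect_false(is.null(found))
  expect_lt(max(abs(found - smad_eep(p)$state)), 1e-6)
})

test_that("parameter sweeps reproduce the comparative-statics patterns", {
  p <- case1_params()
  sw_phi_cap <- parameter_sweep(p, "Phi", c(0.5, 0.7, 0.9), reference_ic,
                                h = 0.01, t_end = 100)
  peaks <- sapply(sw_phi_cap, function(tr) max(tr$states[, "I1"]))
  expect_true(all(diff(peaks) > 0))  # more conversion, higher addiction peak
  sw_phi <- parameter_sweep(p, "phi", c(0.6, 0.8, 1), reference_ic,
                            h = 0.01, t_end = 100)
  mean_s <- sapply(sw_phi, function(tr) mean(tr$states[, "S"]))
  expect_true(all(diff(mean_s) < 0))  # more contact, fewer susceptibles
  # a single-value sweep is just integrate
  one <- parameter_sweep(p, "tau", 0.09, reference_ic, h = 0.01,
                         t_end = 10)[[1]]
  direct <- smad_integrate(p, reference_ic, h = 0.01, t_end = 10)
  expect_identical(one$states, direct$states)
  expect_error(parameter_sweep(p, "nonsense", 1, reference_ic),
               "unknown parameter")
})

test_that("trajectories round-trip through CSV at full precision", {
  tr <- smad_integrate(case1_params(), reference_ic, h = 0.01, t_end = 5)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("t", "S", "E", "I1", "I2", "R", "Q"))
  expect_equal(as.matrix(back[, -1]), tr$states, tolerance = 1e-15,
               ignore_attr = TRUE)
})
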