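test_that("analytic Jacobian has the published structure", {
  set.seed(31)
  p <- random_params()
  y <- random_state()
  pl <- unclass(p)
  J <- smad_jacobian(y, p)
  expect_equal(J["S", "S"],
               -pl[["phi"]] * pl[["chi"]] * y[["I1"]] - pl[["beta"]] -
                 pl[["tau"]])
  expect_equal(J["S", "I1"], -pl[["phi"]] * pl[["chi"]] * y[["S"]])
  expect_equal(J["E", "I1"], pl[["phi"]] * pl[["chi"]] * y[["S"]])
  expect_equal(smad_jacobian(rep(0, 6), p)["S", "I1"], 0)
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(32)
  for (i in 1:100) {
    p <- random_params()
    y <- random_state()
    expect_lt(max(abs(smad_jacobian(y, p) - fd_jacobian(y, p))), 1e-6)
  }
})

test_that("disease-free point is stable below threshold, unstable above", {
  s1 <- dfe_stability(case1_params())
  expect_identical(s1$verdict, "stable")
  # -tau and -(beta+tau) always belong to the spectrum
  re <- sort(Re(s1$eigenvalues))
  expect_true(any(abs(s1$eigenvalues - (-0.09)) < 1e-9))
  expect_true(any(abs(s1$eigenvalues - (-0.10)) < 1e-9))
  expect_identical(dfe_stability(case2_params())$verdict, "unstable")
})

test_that("the spectrum is marginal exactly at the critical contact rate", {
  p <- unclass(case1_params())
  p[["phi"]] <- phi_star(case1_params())
  s <- dfe_stability(structure(p, class = "smad_params"), tol = 1e-8)
  expect_identical(s$verdict, "marginal")
  expect_lt(abs(s$max_real_part), 1e-8)
})

test_that("Routh-Hurwitz quadratic criterion", {
  expect_true(routh_hurwitz_quadratic(1, 1))
  expect_false(routh_hurwitz_quadratic(1, -1))
  expect_false(routh_hurwitz_quadratic(-1, 1))
  # model quadratic factor: a2 = (sigma+tau)(alpha+psi+tau)(1-R0)
  p <- unclass(case1_params())
  a1 <- p[["sigma"]] + p[["alpha"]] + p[["psi"]] + 2 * p[["tau"]]
  a2 <- (p[["sigma"]] + p[["tau"]]) *
    (p[["alpha"]] + p[["psi"]] + p[["tau"]]) * (1 - smad_r0(case1_params()))
  expect_true(routh_hurwitz_quadratic(a1, a2))
  expect_gt(a2, 0)
  # oracle: explicit roots of the quadratic
  roots <- polyroot(c(a2, a1, 1))
  expect_true(all(Re(roots) < 0))
})

test_that("endemic point is locally stable above threshold", {
  s <- eep_stability(case2_params())
  expect_identical(s$verdict, "stable")
  expect_true(all(Re(s$eigenvalues) < 0))
  expect_error(eep_stability(case1_params()), "R0 <= 1")
  # just past the bifurcation the endemic branch is already attracting
  p <- unclass(case1_params())
  p[["phi"]] <- 1.001 * phi_star(case1_params())
  p <- structure(p, class = "smad_params")
  expect_true(smad_eep(p)$admissible)
  expect_lt(eep_stability(p)$max_real_part, 0)
  # eigenvalues agree with the finite-difference Jacobian
  eq <- smad_eep(case2_params())$state
  ev_fd <- eigen(fd_jacobian(eq, case2_params()), only.values = TRUE)$values
  ev <- eep_stability(case2_params())$eigenvalues
  expect_lt(max(abs(sort(Re(ev)) - sort(Re(ev_fd)))), 1e-6)
})

test_that("stability verdict tracks the sign of R0 - 1", {
  set.seed(33)
  for (i in 1:500) {
    p <- random_params()
    r0 <- smad_r0(p)
    if (abs(r0 - 1) < 1e-3) next
    expect_identical(dfe_stability(p)$verdict,
                     if (r0 < 1) "stable" else "unstable")
  }
})

test_that("bifurcation is forward: a < 0 and b > 0", {
  bc <- bifurcation_coefficients(case1_params())
  expect_lt(bc$a, 0)
  expect_gt(bc$b, 0)
  set.seed(34)
  for (i in 1:25) {
    bb <- bifurcation_coefficients(random_params())
    expect_lt(bb$a, 0)
    expect_gt(bb$b, 0)
  }
})

test_that("null vectors annihilate the critical Jacobian and normalise", {
  p0 <- case1_params()
  bc <- bifurcation_coefficients(p0)
  p <- unclass(p0); p[["phi"]] <- bc$phi_star
  p <- structure(p, class = "smad_params")
  J <- smad_jacobian(smad_dfe(p)$state, p)
  expect_lt(max(abs(J %*% bc$w)), 1e-8)
  expect_lt(max(abs(bc$v %*% J)), 1e-8)
  expect_equal(sum(bc$v * bc$w), 1, tolerance = 1e-12)
  # SVD null space agrees with the closed-form vectors up to scale
  sv <- svd(J)
  w_num <- sv$v[, 6]
  v_num <- sv$u[, 6]
  cos_w <- abs(sum(w_num * bc$w)) /
    sqrt(sum(w_num^2) * sum(bc$w^2))
  cos_v <- abs(sum(v_num * bc$v)) /
    sqrt(sum(v_num^2) * sum(bc$v^2))
  expect_gt(cos_w, 1 - 1e-8)
  expect_gt(cos_v, 1 - 1e-8)
})

test_that("coefficient b and all signs are invariant to eigenvector scale", {
  bc <- bifurcation_coefficients(case1_params())
  c_scale <- 3.7
  w2 <- bc$w * c_scale
  v2 <- bc$v / c_scale          # keeps v.w = 1
  p <- unclass(case1_params())
  S0 <- p[["Lambda"]] / (p[["beta"]] + p[["tau"]])
  b_rescaled <- v2[["E"]] * w2[["I1"]] * S0 * p[["chi"]]
  expect_equal(b_rescaled, bc$b, tolerance = 1e-12)
  a_rescaled <- 2 * v2[["E"]] * w2[["S"]] * w2[["I1"]] * bc$phi_star *
    p[["chi"]]
  expect_equal(a_rescaled, bc$a * c_scale, tolerance = 1e-12)  # degree-1
  expect_identical(sign(a_rescaled), sign(bc$a))
})

test_that("trajectories converge globally to the threshold-selected state", {
  set.seed(35)
  p1 <- case1_params(); p2 <- case2_params()
  dfe1 <- smad_dfe(p1)$state
  eep2 <- smad_eep(p2)$state
  for (i in 1:10) {
    y0 <- smad_state(S = runif(1, 0.1, 3), E = runif(1, 0, 1),
                     I1 = runif(1, 0, 1), I2 = runif(1, 0, 1),
                     R = runif(1, 0, 1), Q = runif(1, 0, 1))
    f1 <- smad_integrate(p1, y0, h = 0.01, t_end = 500)$states
    expect_lt(max(abs(f1[nrow(f1), ] - dfe1)), 1e-4)
    f2 <- smad_integrate(p2, y0, h = 0.01, t_end = 500)$states
    expect_lt(max(abs(f2[nrow(f2), ] - eep2)), 1e-4)
  }
})
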