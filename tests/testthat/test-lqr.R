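test_that("Hill substitution maps TGF-beta to [0,1) and back exactly", {
  expect_equal(tgf_to_u(2.51e-12, 1e-10), 2.51e-12 / (1e-10 + 2.51e-12),
               tolerance = 1e-15)
  expect_equal(tgf_to_u(2.51e-12, 1e-10), 0.024485, tolerance = 1e-4)
  expect_identical(tgf_to_u(0, 1e-10), 0)
  expect_equal(tgf_to_u(1e-10, 1e-10), 0.5)
  expect_error(tgf_to_u(-1e-12, 1e-10), "non-negative")

  expect_equal(u_to_tgf(0.5, 1e-10), 1e-10)
  expect_identical(u_to_tgf(0, 1e-10), 0)
  expect_error(u_to_tgf(1, 1e-10), "singularity")
  for (U in c(0, 0.024485, 0.9)) {
    expect_equal(tgf_to_u(u_to_tgf(U, 1e-10), 1e-10), U, tolerance = 1e-12)
  }
  # the algebraic inverse extends below zero (negative concentrations
  # arise as diagnostics of infeasible controls)
  tgf_neg <- u_to_tgf(-0.5, 1e-10)
  expect_equal(tgf_neg / (1e-10 + tgf_neg), -0.5, tolerance = 1e-12)
})

test_that("algebraic Riccati solve matches scalar closed forms", {
  # default 1-node coefficients
  r1 <- solve_riccati(matrix(-0.0166), matrix(5.7e-4))
  expect_equal(drop(r1$P), scalar_care(-0.0166, 5.7e-4), tolerance = 1e-10)
  # pure double integrator: P^2 = I
  expect_equal(drop(solve_riccati(matrix(0), matrix(1))$P), 1,
               tolerance = 1e-12)
  # no control authority: Lyapunov limit -1/(2A)
  expect_equal(drop(solve_riccati(matrix(-0.0166), matrix(0))$P),
               1 / (2 * 0.0166), tolerance = 1e-10)
})

test_that("grid Riccati solution agrees with the spectral oracle and is SPD", {
  # independent route: A symmetric and B = theta I commute, so P shares
  # A's eigenvectors with scalar-care eigenvalues
  sys <- assemble_myofibroblast_system(grid = build_grid(6))
  ric <- solve_riccati(sys$A, sys$B)
  es <- eigen(sys$A, symmetric = TRUE)
  theta <- sys$theta
  P_oracle <- es$vectors %*% diag(scalar_care(es$values, theta)) %*%
    t(es$vectors)
  expect_equal(ric$P, P_oracle, tolerance = 1e-8)
  expect_equal(ric$P, t(ric$P), tolerance = 1e-12)
  expect_gt(min(eigen(ric$P, symmetric = TRUE)$values), 0)
  expect_lte(ric$residual, 1e-8 * (1 + norm(ric$P, "F")))
})

test_that("closed-loop dynamics matrix is Hurwitz for the default system", {
  sys <- assemble_myofibroblast_system(grid = build_grid(6))
  ric <- solve_riccati(sys$A, sys$B)
  Acl <- sys$A - tcrossprod(sys$B) %*% ric$P
  expect_lt(max(Re(eigen(Acl)$values)), 0)
})

test_that("affine offset matches the scalar adjoint and eta oracles", {
  A <- -0.0166; B <- 5.7e-4; b <- 5.7e-4
  P <- scalar_care(A, B)
  adj <- solve_affine(matrix(A), matrix(B), matrix(P), b, mode = "adjoint")
  s_oracle <- -P * b / (A - B^2 * P)
  expect_equal(drop(adj$value), s_oracle, tolerance = 1e-12)
  expect_equal(adj$rho, -B * s_oracle, tolerance = 1e-12)
  expect_equal(adj$rho, -5.9e-4, tolerance = 2e-2)

  eta <- solve_affine(matrix(A), matrix(B), matrix(P), b, mode = "paper_eta")
  eta_oracle <- P / (A - B^2 * P)
  expect_equal(drop(eta$value), eta_oracle, tolerance = 1e-12)
  expect_equal(eta$rho, B * eta_oracle * b, tolerance = 1e-12)

  # zero source: zero offset in both modes
  for (mode in c("adjoint", "paper_eta")) {
    expect_identical(solve_affine(matrix(A), matrix(B), matrix(P), 0,
                                  mode = mode)$rho, 0)
  }
})

test_that("feedback law is K = -B'P with the affine offset", {
  P <- scalar_care(-0.0166, 5.7e-4)
  law <- feedback_law(matrix(P), NULL, matrix(5.7e-4))
  expect_equal(drop(law$K), -5.7e-4 * P, tolerance = 1e-14)
  expect_equal(drop(law$K), -1.72e-2, tolerance = 1e-2)
  expect_identical(law$rho, 0)
  expect_identical(drop(feedback_law(matrix(0), NULL, matrix(1))$K), 0)

  # B = theta I with symmetric P: the gain stays symmetric
  sys <- assemble_myofibroblast_system(grid = build_grid(2))
  ric <- solve_riccati(sys$A, sys$B)
  K <- feedback_law(ric$P, NULL, sys$B)$K
  expect_equal(K, t(K), tolerance = 1e-12)
})

test_that("closed loop reproduces the scalar exponential and its symmetry", {
  p <- myofibroblast_params()
  sys <- scalar_system(-p$d_m, p$lambda_mfT * p$f0, 0)
  P <- scalar_care(-p$d_m, sys$theta)
  law <- feedback_law(matrix(P), NULL, sys$B)
  st <- simulation_settings(tf = 100, dt = 0.01, n_interior_per_side = 1)
  run <- closed_loop_simulate(sys, law, p$m0, st, P = matrix(P))
  rate <- p$d_m + sys$theta^2 * P
  expect_equal(rate, 0.016610, tolerance = 1e-4)
  m100 <- p$m0 * exp(-rate * 100)
  expect_equal(run$trajectory$density[10001, 1], m100, tolerance = 1e-3)
  # time to 1/e of the initial density
  expect_equal(time_to_fraction(run$trajectory, exp(-1)), 1 / rate,
               tolerance = 0.01)

  # zero start, zero source: identically zero state and control
  run0 <- closed_loop_simulate(sys, law, 0, st, P = matrix(P))
  expect_identical(unique(as.vector(run0$trajectory$density)), 0)
  expect_identical(unique(as.vector(run0$control$U)), 0)

  # uniform field on a grid with b = 0: every node equals the 1-node run
  sysg <- assemble_myofibroblast_system(p, grid = build_grid(3))
  sysg$b <- rep(0, 9)
  ricg <- solve_riccati(sysg$A, sysg$B)
  lawg <- feedback_law(ricg$P, NULL, sysg$B)
  rung <- closed_loop_simulate(sysg, lawg, p$m0,
                               simulation_settings(tf = 20, dt = 0.5,
                                                   n_interior_per_side = 3),
                               P = ricg$P)
  expect_equal(rung$trajectory$density,
               matrix(rung$trajectory$density[, 1], ncol = 9, nrow = 41),
               tolerance = 1e-12)
})

test_that("optimal cost is the quadratic form 0.5 m0' P m0", {
  expect_equal(optimal_cost(matrix(30.2), 8.5e-3), 0.5 * 30.2 * 8.5e-3^2)
  expect_identical(optimal_cost(matrix(30.2), 0), 0)
  # additivity over decoupled identical nodes
  P2 <- diag(30.2, 2)
  expect_equal(optimal_cost(P2, rep(8.5e-3, 2)),
               2 * optimal_cost(matrix(30.2), 8.5e-3))
})

test_that("finite-horizon Riccati integration approaches the stationary solution", {
  A <- matrix(-0.0166); B <- matrix(5.7e-4)
  ric <- solve_riccati(A, B, mode = "differential", tf = 2000, dt = 0.5)
  expect_equal(drop(ric$P), scalar_care(-0.0166, 5.7e-4), tolerance = 1e-4)
  # terminal condition honoured
  expect_identical(ric$P_path[, , dim(ric$P_path)[3]], 0)
  # P(t) decreases toward the terminal time
  expect_true(all(diff(ric$P_path[1, 1, ]) <= 0))
})

test_that("running cost agrees with the finite-horizon Riccati value for b = 0", {
  # time-varying gains from the backward family, integrated forward
  p <- myofibroblast_params()
  A <- -p$d_m; B <- p$lambda_mfT * p$f0
  dt <- 1e-3; tf <- 50
  ric <- solve_riccati(matrix(A), matrix(B), mode = "differential",
                       tf = tf, dt = dt)
  Pt <- ric$P_path[1, 1, ]
  nt <- length(Pt)
  m <- p$m0
  mpath <- numeric(nt); upath <- numeric(nt)
  for (k in seq_len(nt)) {
    u <- -B * Pt[k] * m
    mpath[k] <- m; upath[k] <- u
    if (k < nt) m <- m + dt * (A * m + B * u)
  }
  J_running <- tgfctrl:::trapezoid(ric$times, 0.5 * (mpath^2 + upath^2))
  J_star <- 0.5 * Pt[1] * p$m0^2
  expect_equal(J_running, J_star, tolerance = 0.01)
})

test_that("the default unconstrained regulator demands negative control", {
  # the documented failure of the unconstrained problem: the optimal
  # Hill fraction goes negative, i.e. no physical TGF-beta realizes it
  st <- simulation_settings(tf = 50, dt = 0.1)
  run <- solve_lqr_model(settings = st)
  expect_true(any(run$control$U < 0))
  expect_true(any(!run$control$feasible))
  expect_true(all(run$control$TGF[run$control$U < 0] < 0))
})
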