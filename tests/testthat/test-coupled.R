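test_that("coupled assembly shares the grid and tabulated coefficients", {
  csys <- assemble_coupled(grid = build_grid(6))
  expect_identical(nrow(csys$sys_m$A), 36L)
  expect_identical(nrow(csys$sys_f$A), 36L)
  expect_equal(csys$sys_m$r / csys$sys_f$r, 10, tolerance = 1e-12)
  expect_equal(csys$sys_m$c, 5.700e-4, tolerance = 1e-4)
  expect_equal(csys$sys_f$c, 0.19975, tolerance = 1e-12)

  # zero diffusivity: both systems collapse to their loss diagonals
  csys0 <- assemble_coupled(myofibroblast_params(D_m = 0),
                            fibroblast_params(D_f = 0),
                            grid = build_grid(2))
  expect_identical(csys0$sys_m$A, diag(-1.66e-2, 4))
  expect_equal(csys0$sys_f$A, diag(-csys0$sys_f$alpha, 4), tolerance = 1e-15)
})

test_that("feedback synthesis decouples into two Riccati/affine pairs", {
  st <- simulation_settings(n_interior_per_side = 2)
  fx <- make_fixture("symmetric_pair")
  fb <- coupled_feedback(fx$coupled, st)
  expect_identical(fb$law_m$K, fb$law_f$K)
  expect_identical(fb$law_m$rho, fb$law_f$rho)

  # no source: no offset
  csys0 <- fx$coupled
  csys0$sys_m$b <- rep(0, 4); csys0$sys_f$b <- rep(0, 4)
  fb0 <- coupled_feedback(csys0, st)
  expect_true(all(fb0$law_m$rho == 0) && all(fb0$law_f$rho == 0))

  # 1-node fibroblast Riccati against the scalar closed form
  sysf <- assemble_fibroblast_system(grid = build_grid(1))
  ric <- solve_riccati(matrix(-sysf$alpha), matrix(sysf$theta))
  expect_equal(drop(ric$P), scalar_care(-sysf$alpha, sysf$theta),
               tolerance = 1e-10)
  expect_equal(drop(ric$P), 3.418, tolerance = 1e-3)
})

test_that("case 4 holds both TGF-beta concentrations constant at their initial values", {
  st <- simulation_settings(tf = 60, dt = 0.1)
  csys <- assemble_coupled(grid = build_grid(6))
  fb <- coupled_feedback(csys, st)
  run <- solve_coupled_case(4, csys, st, fb)
  expect_identical(unique(as.vector(run$control_m$TGF)), 2.51e-12)
  expect_identical(unique(as.vector(run$control_f$TGF)), 2.51e-12)
  expect_true(run$admissible)
  expect_true(all(run$mu_m) && all(run$mu_f))
})

test_that("free-feedback cases are inadmissible under the default kinetics", {
  st <- simulation_settings(tf = 60, dt = 0.1)
  csys <- assemble_coupled(grid = build_grid(6))
  fb <- coupled_feedback(csys, st)
  run1 <- solve_coupled_case(1, csys, st, fb)
  expect_false(run1$admissible)
  expect_true(any(run1$control_m$U < 0))

  # asymmetric activation: exactly one control is clamped constant
  run2 <- solve_coupled_case(2, csys, st, fb)
  expect_gt(length(unique(as.vector(run2$control_m$U))), 1L)
  expect_identical(unique(as.vector(run2$control_f$TGF)), 2.51e-12)
  run3 <- solve_coupled_case(3, csys, st, fb)
  expect_identical(unique(as.vector(run3$control_m$TGF)), 2.51e-12)
  expect_gt(length(unique(as.vector(run3$control_f$U))), 1L)
})

test_that("default selection accepts case 4", {
  st <- simulation_settings(tf = 60, dt = 0.1)
  out <- solve_coupled_model(settings = st)
  expect_identical(out$selected$case, 4L)
  expect_identical(vapply(out$runs, function(r) r$admissible, logical(1)),
                   c(FALSE, FALSE, FALSE, TRUE))
})

test_that("selection picks the cheapest admissible case and breaks ties upward", {
  st <- simulation_settings(tf = 300, dt = 0.1, n_interior_per_side = 1)
  csys <- synthetic_case1_coupled()
  fb <- coupled_feedback(csys, st)
  runs <- lapply(1:4, solve_coupled_case, csys = csys, settings = st,
                 feedback = fb)
  expect_true(all(vapply(runs, function(r) r$admissible, logical(1))))
  J <- vapply(runs, function(r) r$cost$J_running, numeric(1))
  expect_identical(which.min(J), 1L)
  expect_identical(select_admissible_case(runs)$case, 1L)

  # artificial ties go to the highest case number
  tied <- runs
  for (i in 1:4) tied[[i]]$cost$J_running <- 1
  expect_identical(select_admissible_case(tied)$case, 4L)

  # no admissible run is an error
  for (i in 1:4) tied[[i]]$admissible <- FALSE
  expect_error(select_admissible_case(tied), "admissible")
})

test_that("identical subsystems give zero state-difference cost", {
  fx <- make_fixture("symmetric_pair")
  st <- simulation_settings(tf = 30, dt = 0.1, n_interior_per_side = 2)
  fb <- coupled_feedback(fx$coupled, st)
  for (cs in c(1L, 4L)) {
    run <- solve_coupled_case(cs, fx$coupled, st, fb)
    expect_identical(run$trajectory_m$density, run$trajectory_f$density)
    diff2 <- rowSums((run$trajectory_m$density - run$trajectory_f$density)^2)
    expect_identical(max(diff2), 0)
  }
})

test_that("coupled cost formula reduces and cancels as printed", {
  expect_identical(coupled_cost(matrix(3), matrix(3), 0.1, 0.1), 0)
  expect_equal(coupled_cost(matrix(30.2), matrix(3.4), 8.5e-3, 0),
               optimal_cost(matrix(30.2), 8.5e-3))
  # 1-node default arithmetic from the two scalar Riccati oracles
  sysm <- assemble_myofibroblast_system(grid = build_grid(1))
  sysf <- assemble_fibroblast_system(grid = build_grid(1))
  Pm <- scalar_care(-1.66e-2, sysm$theta)
  Pf <- scalar_care(-sysf$alpha, sysf$theta)
  expect_equal(coupled_cost(matrix(Pm), matrix(Pf), 8.5e-3, 4.75e-3),
               0.5 * (Pm * 8.5e-3^2 - Pf * 4.75e-3^2), tolerance = 1e-14)
  expect_equal(coupled_cost(matrix(Pm), matrix(Pf), 8.5e-3, 4.75e-3),
               1.05e-3, tolerance = 5e-3)
})

test_that("strict cross-term synthesis solves the joint difference objective", {
  st <- simulation_settings(tf = 60, dt = 0.1, n_interior_per_side = 2)
  csys <- assemble_coupled(grid = build_grid(2))
  fb <- coupled_feedback(csys, st, strict_cross_term = TRUE)
  n <- 4L
  # the joint Riccati solution satisfies the difference-weighted ARE
  Z <- matrix(0, n, n)
  Aj <- rbind(cbind(csys$sys_m$A, Z), cbind(Z, csys$sys_f$A))
  Bj <- rbind(cbind(csys$sys_m$B, Z), cbind(Z, csys$sys_f$B))
  I <- diag(n)
  Q <- rbind(cbind(I, -I), cbind(-I, I))
  res <- t(Aj) %*% fb$P_joint + fb$P_joint %*% Aj -
    fb$P_joint %*% tcrossprod(Bj) %*% fb$P_joint + Q
  expect_lt(norm(res, "F"), 1e-8 * (1 + norm(fb$P_joint, "F")))
  # the gain genuinely couples the two species
  expect_gt(max(abs(fb$law_m$K[, n + seq_len(n)])), 0)
  run <- solve_coupled_case(4, csys, st, fb)
  expect_true(run$admissible)
})

test_that("live fibroblast coupling feeds the simulated density into activation", {
  st <- simulation_settings(tf = 60, dt = 0.1, n_interior_per_side = 2)
  csys <- assemble_coupled(grid = build_grid(2))
  fb <- coupled_feedback(csys, st)
  frozen <- solve_coupled_case(4, csys, st, fb)
  live <- solve_coupled_case(4, csys, st, fb, live_fibroblast = TRUE)
  # fibroblast dynamics are untouched; myofibroblast growth accelerates
  # as the fibroblast pool rises above its homeostatic value
  expect_identical(live$trajectory_f$density, frozen$trajectory_f$density)
  expect_gt(utils::tail(mean_density(live$trajectory_m), 1),
            utils::tail(mean_density(frozen$trajectory_m), 1))
})
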