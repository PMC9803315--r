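#' Map a TGF-beta concentration to its Hill control fraction
#'
#' The control variable of every regulator problem is the saturated
#' fraction `U = TGF / (K_TGF + TGF)`, which lies in `[0, 1)` for
#' non-negative concentrations.
#'
#' @param TGF concentration, g cm^-3 (vectorized, non-negative).
#' @param K_TGF saturation constant, g cm^-3.
#' @return dimensionless fraction in `[0, 1)`.
#' @export
#' @examples
#' tgf_to_u(2.51e-12, 1e-10)   # about 0.0245
tgf_to_u <- function(TGF, K_TGF = 1e-10) {
  if (any(TGF < 0)) stop("TGF must be non-negative", call. = FALSE)
  TGF / (K_TGF + TGF)
}

#' Map a control fraction back to a TGF-beta concentration
#'
#' Exact inverse of [tgf_to_u()] on `[0, 1)`. Values of `U` at or above
#' `1 - 1e-12` are a singularity (infinite concentration) and raise an
#' error. Negative `U` maps to a negative concentration, which callers
#' flag as physically infeasible.
#'
#' @param U dimensionless control (vectorized, `< 1 - 1e-12`).
#' @param K_TGF saturation constant, g cm^-3.
#' @return concentration `K_TGF * U / (1 - U)`, g cm^-3.
#' @export
u_to_tgf <- function(U, K_TGF = 1e-10) {
  if (any(U >= 1 - 1e-12)) {
    stop("u_to_tgf: U at or above 1 is a singularity of the Hill inverse",
         call. = FALSE)
  }
  K_TGF * U / (1 - U)
}

#' Solve the regulator Riccati equation
#'
#' With state weight `Q = I` and control weight `R = I`, solves either
#' the continuous algebraic Riccati equation
#' `A'P + PA - P BB' P + I = 0` (mode `"algebraic"`, the stationary
#' infinite-horizon solution) or the matrix Riccati differential
#' equation integrated backward from the terminal condition
#' `P(tf) = 0` by explicit Euler in reverse time (mode
#' `"differential"`).
#'
#' The algebraic solve uses the stable invariant subspace of the
#' Hamiltonian matrix `[[A, -BB'], [-Q, -A']]`: the columns spanning
#' the eigenspace of the `n` stable eigenvalues are split into blocks
#' `X1`, `X2` and `P = Re(X2 X1^{-1})`, symmetrized. The residual is
#' checked against `1e-8 * (1 + ||P||_F)`.
#'
#' @param A,B square system and control-injection matrices (day^-1).
#' @param mode `"algebraic"` or `"differential"`.
#' @param tf,t0 horizon for the differential mode, days.
#' @param dt backward Euler step for the differential mode, days.
#' @param Q state weight (defaults to identity).
#' @return An object of class `riccati_solution`: for `"algebraic"` a
#'   list with the stationary `P` and its `residual`; for
#'   `"differential"` additionally `P_path` (array `n x n x
#'   length(times)`, `P_path[,,k] = P(times[k])`) and `times`, with `P`
#'   the value at `t0`.
#' @export
#' @examples
#' solve_riccati(matrix(-0.0166), matrix(5.7e-4))$P   # about 30.1
solve_riccati <- function(A, B, mode = c("algebraic", "differential"),
                          tf = 300, t0 = 0, dt = 0.1, Q = NULL) {
  mode <- match.arg(mode)
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  if (is.null(Q)) Q <- diag(n)
  BBt <- tcrossprod(B)
  if (mode == "algebraic") {
    H <- rbind(cbind(A, -BBt), cbind(-Q, -t(A)))
    ev <- eigen(H)
    stable <- which(Re(ev$values) < 0)
    if (length(stable) != n) {
      stop(sprintf(
        "Riccati solve failed: Hamiltonian matrix has %d stable eigenvalues, expected %d",
        length(stable), n), call. = FALSE)
    }
    X <- ev$vectors[, stable, drop = FALSE]
    X1 <- X[seq_len(n), , drop = FALSE]
    X2 <- X[n + seq_len(n), , drop = FALSE]
    P <- Re(X2 %*% solve(X1))
    P <- (P + t(P)) / 2
    res <- riccati_residual(A, BBt, P, Q)
    if (res > 1e-8 * (1 + norm(P, "F"))) {
      stop(sprintf("Riccati residual %.3g exceeds tolerance", res),
           call. = FALSE)
    }
    out <- list(P = P, mode = mode, residual = res)
  } else {
    times <- seq(t0, tf, by = dt)
    nt <- length(times)
    P_path <- array(0, c(n, n, nt))
    P <- matrix(0, n, n)                       # P(tf) = 0
    P_path[, , nt] <- P
    for (k in seq(nt - 1L, 1L)) {
      # reverse time: P(t - dt) = P(t) + dt * (PA + A'P - P BB' P + Q)
      step <- times[k + 1L] - times[k]
      P <- P + step * (P %*% A + t(A) %*% P - P %*% BBt %*% P + Q)
      P <- (P + t(P)) / 2
      P_path[, , k] <- P
    }
    out <- list(P = P, P_path = P_path, times = times, mode = mode,
                residual = NA_real_)
  }
  structure(out, class = "riccati_solution")
}

riccati_residual <- function(A, BBt, P, Q = diag(nrow(A))) {
  norm(t(A) %*% P + P %*% A - P %*% BBt %*% P + Q, "F")
}

#' Solve for the affine offset of the regulator
#'
#' The constant source vector `b` shifts the optimal control away from
#' pure state feedback by an offset `rho`. Two realizations are
#' provided.
#'
#' Mode `"adjoint"` (default) decomposes the costate as
#' `lambda = P m + s` with `s` the stationary solution of
#' `(A - BB'P)' s = -P b`, giving `rho = -B' s`; this is the unique
#' decomposition consistent with the costate equation
#' `lambda' = -m - A' lambda`.
#'
#' Mode `"paper_eta"` realizes the square-matrix recursion
#' `eta (A - B'PB) = P` (stationary form), with the costate read as
#' `lambda = P m - eta b` and `rho = B' eta b`. The two modes coincide
#' for scalar systems.
#'
#' @param A,B system matrices.
#' @param P stationary Riccati solution (matrix).
#' @param b constant source vector.
#' @param mode `"adjoint"` or `"paper_eta"`.
#' @return An object of class `affine_term`: list with `value` (vector
#'   `s` or matrix `eta`), `rho` (offset vector) and `mode`.
#' @export
solve_affine <- function(A, B, P, b, mode = c("adjoint", "paper_eta")) {
  mode <- match.arg(mode)
  A <- as.matrix(A); B <- as.matrix(B); P <- as.matrix(P)
  b <- as.numeric(b)
  if (all(b == 0)) {
    value <- if (mode == "adjoint") rep(0, nrow(A)) else matrix(0, nrow(A), nrow(A))
    return(structure(list(value = value, rho = rep(0, ncol(B)), mode = mode),
                     class = "affine_term"))
  }
  if (mode == "adjoint") {
    Acl <- A - tcrossprod(B) %*% P
    s <- solve(t(Acl), -P %*% b)
    rho <- drop(-t(B) %*% s)
    value <- drop(s)
  } else {
    M <- A - t(B) %*% P %*% B
    eta <- P %*% solve(M)
    rho <- drop(t(B) %*% eta %*% b)
    value <- eta
  }
  structure(list(value = value, rho = rho, mode = mode),
            class = "affine_term")
}

#' Assemble the linear state-feedback law
#'
#' @param P stationary Riccati solution.
#' @param affine an `affine_term` (or `NULL` for zero offset).
#' @param B control-injection matrix.
#' @return An object of class `feedback_law` with gain `K = -B'P` and
#'   offset `rho`, so that the optimal control is `U = K m + rho`.
#' @export
feedback_law <- function(P, affine, B) {
  B <- as.matrix(B)
  K <- -t(B) %*% as.matrix(P)
  rho <- if (is.null(affine)) rep(0, nrow(K)) else affine$rho
  structure(list(K = K, rho = rho), class = "feedback_law")
}

#' Minimum achievable performance index
#'
#' @param P stationary Riccati solution (or `riccati_solution`).
#' @param m0_field initial state vector.
#' @return `0.5 * m0' P m0`.
#' @export
optimal_cost <- function(P, m0_field) {
  if (inherits(P, "riccati_solution")) P <- P$P
  0.5 * drop(crossprod(m0_field, P %*% m0_field))
}

# shared quadrature: trapezoid rule on a uniform time grid
trapezoid <- function(times, values) {
  n <- length(times)
  if (n < 2L) return(0)
  sum(diff(times) * (values[-1L] + values[-n]) / 2)
}

#' Simulate the closed loop under a feedback law
#'
#' Integrates `dm/dt = (A + B K) m + B rho + b` by explicit Euler and
#' records the control history `U = K m + rho` together with its
#' TGF-beta image. Steps where any component of `U` is negative are
#' flagged infeasible (a negative Hill fraction has no physical
#' TGF-beta concentration; the corresponding mapped concentration is
#' still reported, negative, for diagnosis). The cost report carries
#' both the trapezoid quadrature of the running integrand
#' `0.5 (m'm + U'U)` and the Riccati value `0.5 m0' P m0`.
#'
#' @param system a `linear_system`.
#' @param law a `feedback_law`.
#' @param m0_field initial state vector (scalar recycled over nodes).
#' @param settings [simulation_settings()] (time window and step).
#' @param P optional stationary Riccati matrix for the cost report.
#' @param K_TGF saturation used for the TGF-beta mapping.
#' @return An object of class `lqr_run`: list with `trajectory`
#'   (`density_trajectory`), `control` (class `control_trajectory`:
#'   `times`, `U` matrix, `TGF` matrix, `feasible` logical per step)
#'   and `cost` (class `cost_report`: `J_running`, `J_star`).
#' @export
closed_loop_simulate <- function(system, law, m0_field,
                                 settings = simulation_settings(),
                                 P = NULL, K_TGF = 1e-10) {
  n <- nrow(system$A)
  m <- rep_len(m0_field, n)
  times <- seq(settings$t0, settings$tf, by = settings$dt)
  nt <- length(times)
  density <- matrix(NA_real_, nt, n)
  U <- matrix(NA_real_, nt, nrow(law$K))
  for (k in seq_len(nt)) {
    density[k, ] <- m
    U[k, ] <- drop(law$K %*% m) + law$rho
    if (k < nt) {
      m <- m + settings$dt *
        (drop(system$A %*% m) + drop(system$B %*% U[k, ]) + system$b)
      if (any(!is.finite(m))) {
        stop(sprintf("closed loop unstable at step %d (t = %g)", k,
                     times[k + 1L]), call. = FALSE)
      }
    }
  }
  control <- new_control_trajectory(times, U, K_TGF)
  traj <- new_density_trajectory(times, density, system$species, system$grid)
  cost <- new_cost_report(times, density, U, P, density[1L, ])
  structure(list(trajectory = traj, control = control, cost = cost),
            class = "lqr_run")
}

new_control_trajectory <- function(times, U, K_TGF) {
  feasible <- apply(U, 1L, function(u) all(u >= 0 & u < 1))
  TGF <- K_TGF * U / (1 - U)    # negative where U < 0: reported, flagged
  TGF[U >= 1 - 1e-12] <- NA_real_
  structure(
    list(times = times, U = U, TGF = TGF, feasible = feasible,
         K_TGF = K_TGF),
    class = "control_trajectory"
  )
}

new_cost_report <- function(times, density, U, P, m0) {
  integrand <- 0.5 * (rowSums(density^2) + rowSums(U^2))
  J_running <- trapezoid(times, integrand)
  J_star <- if (is.null(P)) NA_real_ else optimal_cost(P, m0)
  structure(list(J_running = J_running, J_star = J_star),
            class = "cost_report")
}

#' Solve the unconstrained regulator problem end to end
#'
#' Convenience driver: assembles the myofibroblast system, solves the
#' Riccati and affine equations in the configured modes, forms the
#' feedback law and simulates the closed loop from the homeostatic
#' initial field.
#'
#' @param params [myofibroblast_params()].
#' @param homog [homogenization_constants()].
#' @param settings [simulation_settings()].
#' @return An `lqr_run` (see [closed_loop_simulate()]) with the
#'   additional fields `system`, `riccati`, `affine`, `law`.
#' @export
solve_lqr_model <- function(params = myofibroblast_params(),
                            homog = homogenization_constants(),
                            settings = simulation_settings()) {
  grid <- build_grid(settings$n_interior_per_side)
  system <- assemble_myofibroblast_system(params, homog, grid,
                                          settings$scheme)
  ric <- solve_riccati(system$A, system$B, mode = settings$riccati_mode,
                       tf = settings$tf, t0 = settings$t0, dt = settings$dt)
  aff <- solve_affine(system$A, system$B, ric$P, system$b,
                      mode = settings$affine_mode)
  law <- feedback_law(ric$P, aff, system$B)
  m0 <- initial_field(params$m0, grid, settings)
  run <- closed_loop_simulate(system, law, m0, settings, P = ric$P,
                              K_TGF = params$K_TGF)
  run$system <- system
  run$riccati <- ric
  run$affine <- aff
  run$law <- law
  run
}

#' @export
print.lqr_run <- function(x, ...) {
  cat("<lqr_run> closed-loop regulator solution\n")
  m <- mean_density(x$trajectory)
  cat(sprintf("  mean density %.4g -> %.4g g/cm^3 over %g days\n",
              m[1L], m[length(m)], max(x$trajectory$times)))
  cat(sprintf("  J_running = %.6g, J_star = %.6g\n",
              x$cost$J_running, x$cost$J_star))
  infeas <- sum(!x$control$feasible)
  if (infeas > 0) {
    cat(sprintf("  %d of %d steps have infeasible (negative) control\n",
                infeas, length(x$control$feasible)))
  }
  invisible(x)
}

#' @export
print.riccati_solution <- function(x, ...) {
  cat(sprintf("<riccati_solution> mode = %s, dim = %d", x$mode, nrow(x$P)))
  if (!is.na(x$residual)) cat(sprintf(", residual = %.3g", x$residual))
  cat("\n")
  invisible(x)
}
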