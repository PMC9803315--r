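#' KKT branch of the lower-bounded control
#'
#' The constrained problem requires the control fraction never to fall
#' below its homeostatic value `U0`. Complementary slackness gives a
#' two-way branch per node and step: if the unconstrained candidate
#' exceeds the bound the multiplier `mu` is zero and the candidate is
#' applied; otherwise `mu > 0` and the control sits exactly at the
#' bound.
#'
#' @param U_candidate unconstrained feedback value(s).
#' @param U0 lower bound, the initial control fraction in `[0, 1)`.
#' @return list with `U_applied` (same shape as `U_candidate`) and
#'   `mu_positive` (logical; `TRUE` where the bound is active).
#' @export
#' @examples
#' kkt_branch(-0.3, 0.0245)   # bound active
#' kkt_branch(0.5, 0.0245)    # bound inactive
kkt_branch <- function(U_candidate, U0) {
  if (!(is.numeric(U0) && all(U0 >= 0 & U0 < 1))) {
    stop("U0 must lie in [0, 1)", call. = FALSE)
  }
  active <- U_candidate <= U0
  list(
    U_applied = ifelse(active, U0, U_candidate),
    mu_positive = active
  )
}

#' Solve the lower-bound-constrained control problem
#'
#' Forward integration of the myofibroblast system where at every step
#' the unconstrained feedback `U = K m + rho` is computed and projected
#' through [kkt_branch()] before being applied, so the TGF-beta
#' concentration never falls below its initial value. At active steps
#' the applied concentration equals `TGF(t0)` exactly.
#'
#' With `global_branch = TRUE` the branch is decided once for the whole
#' horizon instead of per step: if the unconstrained closed loop would
#' violate the bound anywhere, the control is held at `U0` for all
#' times (the all-or-nothing reading of the active case).
#'
#' @param params [myofibroblast_params()].
#' @param homog [homogenization_constants()].
#' @param settings [simulation_settings()].
#' @param global_branch decide the branch once for the whole horizon.
#' @return An object of class `constrained_run`: list with
#'   `trajectory`, `control` (applied `U`/`TGF` with feasibility
#'   flags), `status` (class `constraint_status`: `times`,
#'   `mu_positive` logical matrix steps x nodes, `U_applied`), `cost`,
#'   and the solver internals `system`, `riccati`, `affine`, `law`.
#' @export
solve_constrained_model <- function(params = myofibroblast_params(),
                                    homog = homogenization_constants(),
                                    settings = simulation_settings(),
                                    global_branch = FALSE) {
  grid <- build_grid(settings$n_interior_per_side)
  system <- assemble_myofibroblast_system(params, homog, grid,
                                          settings$scheme)
  ric <- solve_riccati(system$A, system$B, mode = settings$riccati_mode,
                       tf = settings$tf, t0 = settings$t0, dt = settings$dt)
  aff <- solve_affine(system$A, system$B, ric$P, system$b,
                      mode = settings$affine_mode)
  law <- feedback_law(ric$P, aff, system$B)
  U0 <- tgf_to_u(params$TGF0, params$K_TGF)
  m0 <- initial_field(params$m0, grid, settings)

  run <- integrate_constrained(system, law, m0, U0, settings,
                               global_branch = global_branch, P = ric$P,
                               K_TGF = params$K_TGF, TGF0 = params$TGF0)
  run$system <- system
  run$riccati <- ric
  run$affine <- aff
  run$law <- law
  run
}

integrate_constrained <- function(system, law, m0, U0, settings,
                                  global_branch = FALSE, P = NULL,
                                  K_TGF = 1e-10, TGF0 = u_to_tgf(U0, K_TGF)) {
  n <- nrow(system$A)
  m <- rep_len(m0, n)
  times <- seq(settings$t0, settings$tf, by = settings$dt)
  nt <- length(times)

  clamp_all <- FALSE
  if (global_branch) {
    # probe the unconstrained closed loop; any violation clamps the
    # whole horizon at the bound
    probe <- closed_loop_simulate(system, law, m, settings, P = P,
                                  K_TGF = K_TGF)
    clamp_all <- any(probe$control$U <= U0)
  }

  density <- matrix(NA_real_, nt, n)
  U_app <- matrix(NA_real_, nt, n)
  mu <- matrix(NA, nt, n)
  for (k in seq_len(nt)) {
    density[k, ] <- m
    if (clamp_all) {
      U_app[k, ] <- U0
      mu[k, ] <- TRUE
    } else {
      cand <- drop(law$K %*% m) + law$rho
      br <- kkt_branch(cand, U0)
      U_app[k, ] <- br$U_applied
      mu[k, ] <- br$mu_positive
    }
    if (k < nt) {
      m <- m + settings$dt *
        (drop(system$A %*% m) + drop(system$B %*% U_app[k, ]) + system$b)
      if (any(!is.finite(m))) {
        stop(sprintf("constrained run unstable at step %d (t = %g)", k,
                     times[k + 1L]), call. = FALSE)
      }
    }
  }
  control <- new_control_trajectory(times, U_app, K_TGF)
  # Theorem-level exactness: at active steps the optimal concentration
  # is TGF(t0) itself, not its floating-point round trip
  control$TGF[mu] <- TGF0
  traj <- new_density_trajectory(times, density, system$species, system$grid)
  cost <- new_cost_report(times, density, U_app, P, density[1L, ])
  status <- structure(
    list(times = times, mu_positive = mu, U_applied = U_app, U0 = U0),
    class = "constraint_status"
  )
  structure(
    list(trajectory = traj, control = control, status = status, cost = cost),
    class = "constrained_run"
  )
}

#' @export
print.constrained_run <- function(x, ...) {
  cat("<constrained_run> lower-bounded control solution\n")
  frac <- mean(x$status$mu_positive)
  cat(sprintf("  constraint active on %.1f%% of node-steps (U0 = %.4g)\n",
              100 * frac, x$status$U0))
  m <- mean_density(x$trajectory)
  cat(sprintf("  mean density %.4g -> %.4g g/cm^3; J_running = %.6g\n",
              m[1L], m[length(m)], x$cost$J_running))
  invisible(x)
}
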