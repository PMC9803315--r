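#' Assemble the coupled two-species system
#'
#' Builds the myofibroblast and fibroblast state-space systems on one
#' shared grid for the joint control problem
#' `dm/dt = A_m m + B_m U_m + b_m`, `df/dt = A_f f + B_f U_f + b_f`.
#'
#' @param params [myofibroblast_params()].
#' @param fparams [fibroblast_params()].
#' @param homog [homogenization_constants()].
#' @param grid [build_grid()] result, shared by both species.
#' @param scheme assembly scheme, see [assemble_myofibroblast_system()].
#' @return An object of class `coupled_system` with fields `sys_m`,
#'   `sys_f` and `grid`.
#' @export
assemble_coupled <- function(params = myofibroblast_params(),
                             fparams = fibroblast_params(),
                             homog = homogenization_constants(),
                             grid = build_grid(6),
                             scheme = c("neumann5", "paper_literal")) {
  scheme <- match.arg(scheme)
  sys_m <- assemble_myofibroblast_system(params, homog, grid, scheme)
  sys_f <- assemble_fibroblast_system(fparams, params, homog, grid, scheme)
  if (nrow(sys_m$A) != nrow(sys_f$A)) {
    stop("coupled assembly: subsystem dimensions differ", call. = FALSE)
  }
  structure(list(sys_m = sys_m, sys_f = sys_f, grid = grid,
                 params = params, fparams = fparams),
            class = "coupled_system")
}

#' Feedback synthesis for the coupled problem
#'
#' By default the two subsystems are synthesized independently: one
#' Riccati/affine pair per species, each with unit state weight, which
#' is the decoupled derivation of the joint problem. With
#' `strict_cross_term = TRUE` the difference-penalizing objective
#' `integral (m - f)'(m - f) + U_m'U_m + U_f'U_f dt` is honoured
#' literally instead: the joint block state `[m; f]` is regulated with
#' state weight `[[I, -I], [-I, I]]` in a single Riccati solve, and
#' the returned gains couple the two species.
#'
#' @param csys a `coupled_system`.
#' @param settings [simulation_settings()] (Riccati/affine modes).
#' @param strict_cross_term use the joint difference-weight synthesis.
#' @return list with `law_m`, `law_f` (class `feedback_law`; in strict
#'   mode their `K` has `2n` columns and acts on `[m; f]`), `P_m`,
#'   `P_f` (in strict mode the diagonal blocks of the joint solution,
#'   plus `P_joint`) and `strict_cross_term`.
#' @export
coupled_feedback <- function(csys, settings = simulation_settings(),
                             strict_cross_term = FALSE) {
  if (!strict_cross_term) {
    ric_m <- solve_riccati(csys$sys_m$A, csys$sys_m$B,
                           mode = settings$riccati_mode,
                           tf = settings$tf, t0 = settings$t0,
                           dt = settings$dt)
    ric_f <- solve_riccati(csys$sys_f$A, csys$sys_f$B,
                           mode = settings$riccati_mode,
                           tf = settings$tf, t0 = settings$t0,
                           dt = settings$dt)
    aff_m <- solve_affine(csys$sys_m$A, csys$sys_m$B, ric_m$P, csys$sys_m$b,
                          mode = settings$affine_mode)
    aff_f <- solve_affine(csys$sys_f$A, csys$sys_f$B, ric_f$P, csys$sys_f$b,
                          mode = settings$affine_mode)
    list(
      law_m = feedback_law(ric_m$P, aff_m, csys$sys_m$B),
      law_f = feedback_law(ric_f$P, aff_f, csys$sys_f$B),
      P_m = ric_m$P, P_f = ric_f$P,
      strict_cross_term = FALSE
    )
  } else {
    n <- nrow(csys$sys_m$A)
    Z <- matrix(0, n, n)
    Aj <- rbind(cbind(csys$sys_m$A, Z), cbind(Z, csys$sys_f$A))
    Bj <- rbind(cbind(csys$sys_m$B, Z), cbind(Z, csys$sys_f$B))
    bj <- c(csys$sys_m$b, csys$sys_f$b)
    I <- diag(n)
    Q <- rbind(cbind(I, -I), cbind(-I, I))
    ric <- solve_riccati(Aj, Bj, mode = "algebraic", Q = Q)
    aff <- solve_affine(Aj, Bj, ric$P, bj, mode = "adjoint")
    Kj <- -t(Bj) %*% ric$P
    rj <- aff$rho
    idm <- seq_len(n); idf <- n + seq_len(n)
    list(
      law_m = structure(list(K = Kj[idm, , drop = FALSE], rho = rj[idm]),
                        class = "feedback_law"),
      law_f = structure(list(K = Kj[idf, , drop = FALSE], rho = rj[idf]),
                        class = "feedback_law"),
      P_m = ric$P[idm, idm], P_f = ric$P[idf, idf], P_joint = ric$P,
      strict_cross_term = TRUE
    )
  }
}

#' Minimum performance index of the coupled problem
#'
#' The value formula of the decoupled synthesis,
#' `0.5 * (m0' P_m m0 - f0' P_f f0)`. Note the minus sign: this
#' quantity can be negative even though the running integrand is a sum
#' of squares; a negative value is flagged in the run summary.
#'
#' @param P_m,P_f subsystem Riccati solutions.
#' @param m0_field,f0_field initial state vectors.
#' @return the formula value.
#' @export
coupled_cost <- function(P_m, P_f, m0_field, f0_field) {
  0.5 * (drop(crossprod(m0_field, as.matrix(P_m) %*% m0_field)) -
           drop(crossprod(f0_field, as.matrix(P_f) %*% f0_field)))
}

#' Solve one admissibility case of the coupled problem
#'
#' The joint problem bounds both control fractions below by their
#' homeostatic values, giving one KKT multiplier per species and four
#' sign cases: case 1 has both multipliers zero (both controls follow
#' their unconstrained feedback laws), case 2 clamps only the
#' fibroblast control at its initial value, case 3 clamps only the
#' myofibroblast control, and case 4 clamps both, so both TGF-beta
#' concentrations stay constant at `2.51e-12 g cm^-3` over the whole
#' horizon. The states are integrated under the resulting controls and
#' the run is marked admissible when both mapped TGF-beta trajectories
#' are non-negative, at or above their initial values, and free of the
#' Hill singularity (`U < 1`).
#'
#' @param case integer 1..4.
#' @param csys a `coupled_system`.
#' @param settings [simulation_settings()].
#' @param feedback result of [coupled_feedback()] (computed if `NULL`).
#' @param live_fibroblast re-evaluate the fibroblast density inside the
#'   myofibroblast activation term at every step (replacing the frozen
#'   homeostatic value) — an exploratory coupling variant, off by
#'   default.
#' @return An object of class `coupled_run`: trajectories and controls
#'   for both species, `case`, `admissible`, `mu_m`/`mu_f` logical
#'   vectors, and `cost` (running quadrature of
#'   `0.5 ((m-f)'(m-f) + U_m'U_m + U_f'U_f)` plus the
#'   [coupled_cost()] formula value).
#' @export
solve_coupled_case <- function(case, csys, settings = simulation_settings(),
                               feedback = NULL, live_fibroblast = FALSE) {
  if (!(length(case) == 1L && case %in% 1:4)) {
    stop("case must be one of 1, 2, 3, 4", call. = FALSE)
  }
  if (is.null(feedback)) feedback <- coupled_feedback(csys, settings)
  clamp_m <- case %in% c(3L, 4L)
  clamp_f <- case %in% c(2L, 4L)

  pm <- csys$params; pf <- csys$fparams
  U0_m <- tgf_to_u(pm$TGF0, pm$K_TGF)
  U0_f <- tgf_to_u(pf$TGFf0, pm$K_TGF)
  n <- nrow(csys$sys_m$A)
  m <- initial_field(pm$m0, csys$grid, settings)
  f <- initial_field(pm$f0, csys$grid, settings)

  times <- seq(settings$t0, settings$tf, by = settings$dt)
  nt <- length(times)
  dm <- matrix(NA_real_, nt, n); df_ <- matrix(NA_real_, nt, n)
  Um <- matrix(NA_real_, nt, n); Uf <- matrix(NA_real_, nt, n)
  joint <- isTRUE(feedback$strict_cross_term)

  # myofibroblast activation pathway split out so the frozen f0 can be
  # optionally replaced by the live fibroblast field
  act_gain <- pm$lambda_mfT                       # per unit f density
  pdgf_rate <- pm$lambda_mfG * pm$G0 / (pm$K_G + pm$G0)

  for (k in seq_len(nt)) {
    dm[k, ] <- m; df_[k, ] <- f
    state_m <- if (joint) c(m, f) else m
    state_f <- if (joint) c(m, f) else f
    Um[k, ] <- if (clamp_m) rep(U0_m, n) else
      drop(feedback$law_m$K %*% state_m) + feedback$law_m$rho
    Uf[k, ] <- if (clamp_f) rep(U0_f, n) else
      drop(feedback$law_f$K %*% state_f) + feedback$law_f$rho
    if (k < nt) {
      if (live_fibroblast) {
        # replace the frozen f0 in the activation term by the live field:
        # A m + B U + b describes activation of f0; the correction adds
        # (lambda_mfT U + pdgf_rate) * (f - f0)
        rhs_m <- drop(csys$sys_m$A %*% m) +
          drop(csys$sys_m$B %*% Um[k, ]) + csys$sys_m$b +
          (act_gain * Um[k, ] + pdgf_rate) * (f - pm$f0)
      } else {
        rhs_m <- drop(csys$sys_m$A %*% m) +
          drop(csys$sys_m$B %*% Um[k, ]) + csys$sys_m$b
      }
      rhs_f <- drop(csys$sys_f$A %*% f) +
        drop(csys$sys_f$B %*% Uf[k, ]) + csys$sys_f$b
      m <- m + settings$dt * rhs_m
      f <- f + settings$dt * rhs_f
      if (any(!is.finite(m)) || any(!is.finite(f))) {
        stop(sprintf("coupled run unstable at step %d (t = %g)", k,
                     times[k + 1L]), call. = FALSE)
      }
    }
  }

  ctrl_m <- new_control_trajectory(times, Um, pm$K_TGF)
  ctrl_f <- new_control_trajectory(times, Uf, pm$K_TGF)
  # clamped concentrations equal the initial value exactly
  if (clamp_m) ctrl_m$TGF[] <- pm$TGF0
  if (clamp_f) ctrl_f$TGF[] <- pf$TGFf0

  admissible <- control_admissible(ctrl_m, pm$TGF0) &&
    control_admissible(ctrl_f, pf$TGFf0)

  diff2 <- rowSums((dm - df_)^2)
  integrand <- 0.5 * (diff2 + rowSums(Um^2) + rowSums(Uf^2))
  J_running <- trapezoid(times, integrand)
  J_formula <- coupled_cost(feedback$P_m, feedback$P_f, dm[1L, ], df_[1L, ])

  structure(list(
    trajectory_m = new_density_trajectory(times, dm, "myofibroblast",
                                          csys$grid),
    trajectory_f = new_density_trajectory(times, df_, "fibroblast",
                                          csys$grid),
    control_m = ctrl_m, control_f = ctrl_f,
    case = as.integer(case), admissible = admissible,
    mu_m = rep(clamp_m, nt), mu_f = rep(clamp_f, nt),
    cost = structure(list(J_running = J_running, J_star = J_formula),
                     class = "cost_report")
  ), class = "coupled_run")
}

control_admissible <- function(ctrl, tgf0) {
  all(is.finite(ctrl$TGF)) &&
    all(ctrl$TGF >= 0) &&
    all(ctrl$TGF >= tgf0 * (1 - 1e-9)) &&
    all(ctrl$U < 1)
}

#' Select the admissible case with the lowest running cost
#'
#' @param runs list of four `coupled_run` objects (cases 1..4).
#' @return the admissible run with the lowest `J_running`; ties are
#'   broken toward the highest case number. Errors if no case is
#'   admissible.
#' @export
select_admissible_case <- function(runs) {
  ok <- vapply(runs, function(r) isTRUE(r$admissible), logical(1))
  if (!any(ok)) stop("no admissible coupled case", call. = FALSE)
  cand <- runs[ok]
  J <- vapply(cand, function(r) r$cost$J_running, numeric(1))
  lab <- vapply(cand, function(r) r$case, integer(1))
  best <- which(J == min(J))
  pick <- best[which.max(lab[best])]
  cand[[pick]]
}

#' Solve the coupled two-species control problem end to end
#'
#' Runs all four admissibility cases of [solve_coupled_case()] and
#' selects the accepted one. All four runs are retained for reporting.
#'
#' @inheritParams assemble_coupled
#' @param settings [simulation_settings()].
#' @param strict_cross_term see [coupled_feedback()].
#' @return list with `selected` (the accepted `coupled_run`), `runs`
#'   (all four), `feedback` and `system`.
#' @export
solve_coupled_model <- function(params = myofibroblast_params(),
                                fparams = fibroblast_params(),
                                homog = homogenization_constants(),
                                settings = simulation_settings(),
                                strict_cross_term = FALSE) {
  grid <- build_grid(settings$n_interior_per_side)
  csys <- assemble_coupled(params, fparams, homog, grid, settings$scheme)
  fb <- coupled_feedback(csys, settings, strict_cross_term)
  runs <- lapply(1:4, solve_coupled_case, csys = csys, settings = settings,
                 feedback = fb)
  list(selected = select_admissible_case(runs), runs = runs,
       feedback = fb, system = csys)
}

#' @export
print.coupled_run <- function(x, ...) {
  cat(sprintf("<coupled_run> case %d (%s)\n", x$case,
              if (x$admissible) "admissible" else "inadmissible"))
  mm <- mean_density(x$trajectory_m); mf <- mean_density(x$trajectory_f)
  cat(sprintf("  myofibroblast %.4g -> %.4g, fibroblast %.4g -> %.4g g/cm^3\n",
              mm[1L], mm[length(mm)], mf[1L], mf[length(mf)]))
  cat(sprintf("  J_running = %.6g, value formula = %.6g%s\n",
              x$cost$J_running, x$cost$J_star,
              if (is.finite(x$cost$J_star) && x$cost$J_star < 0)
                " (negative; see run summary)" else ""))
  invisible(x)
}
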