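settings_keys <- function() {
  c("t0", "tf", "dt", "n_interior_per_side", "scheme", "riccati_mode",
    "affine_mode", "vanish_fraction", "damage_extent", "global_branch",
    "strict_cross_term")
}

#' Read a flat key-value configuration file
#'
#' The configuration is a flat YAML document whose keys are either
#' simulation settings (`dt`, `tf`, `n_interior_per_side`, `scheme`,
#' ...) or parameter overrides named after the fields of
#' [myofibroblast_params()], [fibroblast_params()] and
#' [homogenization_constants()]. Unknown keys are an error naming the
#' key; invariant violations are an error naming the violated
#' invariant. An empty (or absent content) file yields all defaults.
#'
#' @param path path to the YAML file.
#' @return list with `settings` ([simulation_settings()]), `params`
#'   (the bundle of [default_parameters()] with overrides applied),
#'   `global_branch` and `strict_cross_term` flags, and `overrides`
#'   (the raw override list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (length(raw) > 0L && (is.null(names(raw)) || any(names(raw) == ""))) {
    stop("config must be a flat mapping of named keys", call. = FALSE)
  }

  myo_f <- names(myofibroblast_params())
  fib_f <- names(fibroblast_params())
  hom_f <- names(homogenization_constants())
  known <- c(settings_keys(), myo_f, fib_f, hom_f)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  take <- function(keys) raw[intersect(names(raw), keys)]
  s_over <- take(setdiff(settings_keys(), c("global_branch",
                                            "strict_cross_term")))
  settings <- do.call(simulation_settings, s_over)
  params <- list(
    myo = do.call(myofibroblast_params, take(setdiff(myo_f, fib_f))),
    fib = do.call(fibroblast_params, take(fib_f)),
    homog = do.call(homogenization_constants, take(hom_f))
  )
  for (obj in list(settings, params$myo, params$fib, params$homog)) {
    rep <- validate(obj)
    if (length(rep) > 0L) {
      stop("config invariant violation: ", paste(rep, collapse = "; "),
           call. = FALSE)
    }
  }
  list(
    settings = settings,
    params = params,
    global_branch = isTRUE(raw$global_branch),
    strict_cross_term = isTRUE(raw$strict_cross_term),
    overrides = raw
  )
}

control_frame <- function(ctrl) {
  data.frame(
    U_mean = rowMeans(ctrl$U),
    TGF_mean = rowMeans(ctrl$TGF),
    feasible_flag = ctrl$feasible
  )
}

run_frame <- function(run) {
  if (inherits(run, "density_trajectory")) {
    trajectory_frame(run)
  } else if (inherits(run, c("lqr_run", "constrained_run"))) {
    out <- cbind(trajectory_frame(run$trajectory), control_frame(run$control))
    if (inherits(run, "constrained_run")) {
      out$constraint_active <- apply(run$status$mu_positive, 1L, any)
    }
    out
  } else if (inherits(run, "coupled_run")) {
    fm <- trajectory_frame(run$trajectory_m)
    ff <- trajectory_frame(run$trajectory_f)
    cm <- control_frame(run$control_m)
    cf <- control_frame(run$control_f)
    data.frame(
      time = fm$time,
      mean_m = fm$mean_density, min_m = fm$min, max_m = fm$max,
      mean_f = ff$mean_density, min_f = ff$min, max_f = ff$max,
      Um_mean = cm$U_mean, TGFm_mean = cm$TGF_mean, feasible_m = cm$feasible_flag,
      Uf_mean = cf$U_mean, TGFf_mean = cf$TGF_mean, feasible_f = cf$feasible_flag
    )
  } else {
    stop("run_frame: unsupported run object", call. = FALSE)
  }
}

#' Build a run summary
#'
#' Collects the resolved settings, scheme and mode choices, solver
#' residuals, cost values, selected case and vanish times into a flat
#' list that serializes losslessly to JSON.
#'
#' @param run a run bundle (`density_trajectory`, `lqr_run`,
#'   `constrained_run`, `coupled_run`, or the list returned by
#'   [solve_coupled_model()]).
#' @param settings the [simulation_settings()] used.
#' @return named list (class `run_summary`).
#' @export
run_summary <- function(run, settings = simulation_settings()) {
  out <- list(
    software = paste0("tgfctrl ",
                      as.character(utils::packageVersion("tgfctrl"))),
    t0 = settings$t0, tf = settings$tf, dt = settings$dt,
    n_interior_per_side = settings$n_interior_per_side,
    scheme = settings$scheme,
    riccati_mode = settings$riccati_mode,
    affine_mode = settings$affine_mode,
    vanish_fraction = settings$vanish_fraction,
    stencil_weight_formula = "r = a_diag * D / (gamma * dx^2)",
    wall_clock = format(Sys.time(), tz = "UTC")
  )
  if (inherits(run, "density_trajectory")) {
    out$vanish_time <- time_to_fraction(run, settings$vanish_fraction)
    out$final_mean_density <- utils::tail(mean_density(run), 1L)
  }
  if (inherits(run, c("lqr_run", "constrained_run"))) {
    out$vanish_time <- time_to_fraction(run$trajectory,
                                        settings$vanish_fraction)
    out$final_mean_density <- utils::tail(mean_density(run$trajectory), 1L)
    out$J_running <- run$cost$J_running
    out$J_star <- run$cost$J_star
    out$riccati_residual <- run$riccati$residual
    out$infeasible_steps <- sum(!run$control$feasible)
    if (inherits(run, "constrained_run")) {
      out$constraint_active_fraction <- mean(run$status$mu_positive)
    }
  }
  if (is.list(run) && !is.null(run$selected) &&
      inherits(run$selected, "coupled_run")) {
    sel <- run$selected
    out$selected_case <- sel$case
    out$case_admissible <- vapply(run$runs, function(r) r$admissible,
                                  logical(1))
    out$case_J_running <- vapply(run$runs, function(r) r$cost$J_running,
                                 numeric(1))
    out$J_running <- sel$cost$J_running
    out$J_star <- sel$cost$J_star
    out$J_star_negative <- is.finite(sel$cost$J_star) && sel$cost$J_star < 0
    out$vanish_time_myofibroblast <-
      time_to_fraction(sel$trajectory_m, settings$vanish_fraction)
    out$vanish_time_fibroblast <-
      time_to_fraction(sel$trajectory_f, settings$vanish_fraction)
  }
  structure(out, class = "run_summary")
}

#' Write trajectory CSVs and a run-summary document
#'
#' @param run a run bundle (see [run_summary()]).
#' @param out_dir output directory, created if needed.
#' @param settings the settings used (recorded in the summary).
#' @param per_node also write a wide per-node CSV.
#' @return (invisibly) character vector of the files written:
#'   `trajectory.csv`, `summary.json`, per-case CSVs for coupled runs,
#'   optionally `trajectory_nodes.csv`.
#' @export
write_outputs <- function(run, out_dir, settings = simulation_settings(),
                          per_node = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  files <- character(0)
  write1 <- function(df, name) {
    f <- file.path(out_dir, name)
    # print doubles at 17 significant digits so a reread is lossless
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    }
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  if (is.list(run) && !is.null(run$selected) &&
      inherits(run$selected, "coupled_run")) {
    write1(run_frame(run$selected), "trajectory.csv")
    for (r in run$runs) {
      write1(run_frame(r), sprintf("trajectory_case%d.csv", r$case))
    }
  } else {
    write1(run_frame(run), "trajectory.csv")
    if (per_node) {
      traj <- if (inherits(run, "density_trajectory")) run else run$trajectory
      write1(trajectory_frame(traj, per_node = TRUE), "trajectory_nodes.csv")
    }
  }
  sm <- run_summary(run, settings)
  sf <- file.path(out_dir, "summary.json")
  jsonlite::write_json(unclass(sm), sf, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  files <- c(files, sf)
  invisible(files)
}

#' Deterministic small test instances
#'
#' @param kind `"one_node"` (single-node myofibroblast system with the
#'   tabulated coefficients), `"tiny_grid"` (2x2 interior grid,
#'   4-dimensional systems for both species), `"symmetric_pair"`
#'   (coupled system whose fibroblast subsystem is a copy of the
#'   myofibroblast one), or `"random_one_node"` (stable scalar system
#'   with seeded random coefficients).
#' @param seed RNG seed for `"random_one_node"` (ignored otherwise).
#' @return a list bundle; contents depend on `kind`. All kinds carry
#'   the generating parameters so tests can recompute expectations.
#' @export
make_fixture <- function(kind = c("one_node", "tiny_grid", "symmetric_pair",
                                  "random_one_node"),
                         seed = 1L) {
  kind <- match.arg(kind)
  pm <- myofibroblast_params()
  pf <- fibroblast_params()
  hg <- homogenization_constants()
  if (kind == "one_node") {
    # single well-mixed node: A = -d_m, B = theta_m, b = c_m
    grid <- build_grid(1)
    theta <- pm$lambda_mfT * pm$f0
    cs <- pm$lambda_mfG * pm$G0 / (pm$K_G + pm$G0) * pm$f0
    sys <- new_linear_system(matrix(-pm$d_m), matrix(theta), cs, r = 0,
                             theta = theta, c = cs, alpha = 0,
                             species = "myofibroblast", grid = grid,
                             scheme = "neumann5")
    list(kind = kind, system = sys, params = pm, homog = hg, grid = grid)
  } else if (kind == "tiny_grid") {
    grid <- build_grid(2)
    list(
      kind = kind,
      system_m = assemble_myofibroblast_system(pm, hg, grid),
      system_f = assemble_fibroblast_system(pf, pm, hg, grid),
      params = pm, fparams = pf, homog = hg, grid = grid
    )
  } else if (kind == "symmetric_pair") {
    grid <- build_grid(2)
    csys <- assemble_coupled(pm, pf, hg, grid)
    csys$sys_f <- csys$sys_m
    csys$sys_f$species <- "fibroblast"
    csys$params$f0 <- csys$params$m0   # equal initial fields for symmetry
    list(kind = kind, coupled = csys, params = pm, homog = hg, grid = grid)
  } else {
    set.seed(seed)
    a <- -stats::runif(1, 0.005, 0.5)
    b <- stats::runif(1, 1e-4, 1e-2)
    cc <- stats::runif(1, 0, 1e-3)
    grid <- build_grid(1)
    sys <- new_linear_system(matrix(a), matrix(b), cc, r = 0, theta = b,
                             c = cc, alpha = 0, species = "myofibroblast",
                             grid = grid, scheme = "neumann5")
    list(kind = kind, system = sys, a = a, b = b, c = cc, params = pm,
         homog = hg, grid = grid)
  }
}
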