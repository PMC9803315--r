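#' Myofibroblast reaction term
#'
#' Net local production rate of myofibroblast density: activation of
#' the homeostatic fibroblast pool by TGF-beta and PDGF through Hill
#' saturation, minus apoptosis.
#'
#' @param m myofibroblast density, g cm^-3 (vectorized).
#' @param TGF TGF-beta concentration, g cm^-3 (non-negative).
#' @param params [myofibroblast_params()].
#' @return rate, g cm^-3 day^-1:
#'   `(lambda_mfT * TGF/(K_TGF + TGF) + lambda_mfG * G0/(K_G + G0)) * f0
#'    - d_m * m`.
#' @export
reaction_myofibroblast <- function(m, TGF, params = myofibroblast_params()) {
  if (any(TGF < 0)) stop("TGF must be non-negative", call. = FALSE)
  if (params$K_TGF <= 0 || params$K_G <= 0) {
    stop("saturation constants must be strictly positive", call. = FALSE)
  }
  act <- params$lambda_mfT * TGF / (params$K_TGF + TGF) +
    params$lambda_mfG * params$G0 / (params$K_G + params$G0)
  act * params$f0 - params$d_m * m
}

#' Fibroblast reaction term
#'
#' Net local production rate of fibroblast density: constant AEC
#' source, TGF-beta-driven production, and four linear drains
#' (apoptosis, transformation to myofibroblast by PDGF, TGF-beta
#' production, ECM deposition).
#'
#' @param f fibroblast density, g cm^-3 (vectorized).
#' @param TGFf TGF-beta concentration seen by fibroblasts, g cm^-3.
#' @param params [fibroblast_params()].
#' @param myo [myofibroblast_params()] (PDGF transformation term and
#'   the shared TGF-beta saturation constant).
#' @return rate, g cm^-3 day^-1.
#' @export
reaction_fibroblast <- function(f, TGFf, params = fibroblast_params(),
                                myo = myofibroblast_params()) {
  if (any(TGFf < 0)) stop("TGFf must be non-negative", call. = FALSE)
  if (myo$K_TGF <= 0 || params$K_E <= 0) {
    stop("saturation constants must be strictly positive", call. = FALSE)
  }
  esat <- params$E / (params$E + params$K_E)
  params$lambda_Ef * params$E0 +
    params$lambda_fE * TGFf / (myo$K_TGF + TGFf) * esat -
    params$d_f * f -
    myo$lambda_mfG * myo$G0 / (myo$K_G + myo$G0) * f -
    params$lambda_TGFf * esat * f -
    params$lambda_rhof * f
}

#' One explicit Euler step of a linear state-space system
#'
#' @param field density vector over the interior nodes.
#' @param system a `linear_system`.
#' @param U control value (scalar, recycled, or one value per node).
#' @param dt step, days. A step above [cfl_max_step()] (with the
#'   system's own loss rate) triggers a warning, not an error.
#' @return updated field `field + dt * (A field + B U + b)`.
#' @export
step_explicit <- function(field, system, U = 0, dt) {
  loss <- if (system$alpha > 0) system$alpha else -min(diag(system$A)) - 4 * system$r
  guard <- cfl_max_step(system, max(loss, 0))
  if (dt > guard) {
    warning(sprintf("dt = %g exceeds the stability guard %.4g days", dt, guard),
            call. = FALSE)
  }
  U <- rep_len(U, nrow(system$B))
  out <- field + dt * drop(system$A %*% field + system$B %*% U + system$b)
  if (any(!is.finite(out))) {
    stop("non-finite state after explicit step", call. = FALSE)
  }
  out
}

initial_field <- function(value, grid, settings) {
  field <- rep(value, grid$n_interior)
  de <- settings$damage_extent
  if (!is.null(de)) {
    # elevate the initial density tenfold inside a centred square of
    # side damage_extent
    ns <- grid$n_side
    x <- seq_len(ns) * grid$dx
    inside <- abs(x - 0.5) <= de / 2
    mask <- as.vector(outer(inside, inside, "&"))
    field[mask] <- 10 * value
  }
  field
}

#' Simulate the uncontrolled nonlinear reaction-diffusion kinetics
#'
#' Explicit Euler integration of the homogenized density equation for
#' one species, with TGF-beta held at a scheduled (by default constant
#' homeostatic) concentration and the Hill factor re-evaluated at every
#' step.
#'
#' @param species `"myofibroblast"` or `"fibroblast"`.
#' @param params parameter bundle as returned by [default_parameters()].
#' @param settings [simulation_settings()].
#' @param tgf_schedule `NULL` (constant at the tabulated initial
#'   concentration), a single concentration, or a function of time
#'   returning the concentration in g cm^-3.
#' @param save_every record every k-th step (1 = all steps).
#' @return An object of class `density_trajectory`: list with `times`
#'   (days), `density` (matrix, one row per recorded time, one column
#'   per interior node, row-major over (i, j) with i fastest),
#'   `species` and `grid`.
#' @export
#' @examples
#' traj <- simulate_species("myofibroblast",
#'   settings = simulation_settings(tf = 50, dt = 0.5, n_interior_per_side = 2))
#' utils::tail(rowMeans(traj$density), 1)
simulate_species <- function(species = c("myofibroblast", "fibroblast"),
                             params = default_parameters(),
                             settings = simulation_settings(),
                             tgf_schedule = NULL,
                             save_every = 1L) {
  species <- match.arg(species)
  stop_if_invalid(settings, "settings")
  grid <- build_grid(settings$n_interior_per_side)
  homog <- params$homog
  if (species == "myofibroblast") {
    p <- params$myo
    D <- p$D_m
    init <- p$m0
    tgf0 <- p$TGF0
    react <- function(x, tgf) reaction_myofibroblast(x, tgf, p)
  } else {
    p <- params$fib
    D <- p$D_f
    init <- params$myo$f0
    tgf0 <- p$TGFf0
    react <- function(x, tgf) reaction_fibroblast(x, tgf, p, params$myo)
  }
  sched <- if (is.null(tgf_schedule)) {
    function(t) tgf0
  } else if (is.function(tgf_schedule)) {
    tgf_schedule
  } else {
    force(tgf_schedule)
    function(t) tgf_schedule
  }
  r <- homog$a_diag * D / (homog$gamma * grid$dx^2)
  Lap <- laplacian_2d(grid$n_side, r, neumann = (settings$scheme == "neumann5"))
  field <- initial_field(init, grid, settings)
  times <- seq(settings$t0, settings$tf, by = settings$dt)
  nsteps <- length(times) - 1L
  keep <- unique(c(seq(1L, length(times), by = save_every), length(times)))
  density <- matrix(NA_real_, length(keep), grid$n_interior)
  density[1L, ] <- field
  krow <- 1L
  for (k in seq_len(nsteps)) {
    t <- times[k]
    field <- field + settings$dt *
      (drop(Lap %*% field) + react(field, sched(t)))
    if (any(!is.finite(field))) {
      stop(sprintf("simulation unstable: non-finite density at step %d (t = %g)",
                   k, times[k + 1L]), call. = FALSE)
    }
    if ((k + 1L) %in% keep) {
      krow <- krow + 1L
      density[krow, ] <- field
    }
  }
  new_density_trajectory(times[keep], density, species, grid)
}

new_density_trajectory <- function(times, density, species, grid) {
  structure(
    list(times = times, density = density, species = species, grid = grid),
    class = "density_trajectory"
  )
}

#' Spatial mean density over time
#'
#' @param traj a `density_trajectory`.
#' @return numeric vector, one mean per recorded time.
#' @export
mean_density <- function(traj) rowMeans(traj$density)

#' First time the mean density falls to a fraction of its initial value
#'
#' Operationalizes "the population vanishes": the first recorded time
#' at which the spatial mean density is at most `fraction` times its
#' initial mean.
#'
#' @param traj a `density_trajectory`.
#' @param fraction threshold fraction in (0, 1].
#' @return time in days, or `NA_real_` if the threshold is never
#'   reached.
#' @export
time_to_fraction <- function(traj, fraction) {
  if (!(is.numeric(fraction) && length(fraction) == 1L &&
        fraction > 0 && fraction <= 1)) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (length(traj$times) == 0L) stop("empty trajectory", call. = FALSE)
  m <- mean_density(traj)
  hit <- which(m <= fraction * m[1L])
  if (length(hit) == 0L) NA_real_ else traj$times[hit[1L]]
}

#' @export
print.density_trajectory <- function(x, ...) {
  m <- mean_density(x)
  cat(sprintf(
    "<density_trajectory> %s, %d nodes, t = [%g, %g] days (%d samples)\n",
    x$species, ncol(x$density), min(x$times), max(x$times), length(x$times)))
  cat(sprintf("  mean density: %.4g -> %.4g g/cm^3\n", m[1L], m[length(m)]))
  invisible(x)
}

#' Export a trajectory as a tidy data frame
#'
#' @param traj a `density_trajectory`.
#' @param per_node also include one column per interior node (named
#'   `node_i_j`, 1-based interior indices, i fastest).
#' @return data.frame with columns `time`, `mean_density`, `min`, `max`
#'   and optionally the per-node columns.
#' @export
trajectory_frame <- function(traj, per_node = FALSE) {
  out <- data.frame(
    time = traj$times,
    mean_density = mean_density(traj),
    min = apply(traj$density, 1L, min),
    max = apply(traj$density, 1L, max)
  )
  if (per_node) {
    ns <- traj$grid$n_side
    ij <- expand.grid(i = seq_len(ns), j = seq_len(ns))
    nodes <- as.data.frame(traj$density)
    names(nodes) <- sprintf("node_%d_%d", ij$i, ij$j)
    out <- cbind(out, nodes)
  }
  out
}
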