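#' Myofibroblast subsystem parameters
#'
#' Rate, saturation and initial-value constants of the myofibroblast
#' reaction-diffusion model. Defaults are the homeostatic values used
#' throughout: densities in g cm^-3, rates in day^-1, diffusivities in
#' cm^2 day^-1. Any field can be overridden by name; unknown names are
#' an error.
#'
#' @param ... named overrides of the default fields.
#'
#' @return An object of class `myofibroblast_params`: a named list with
#'   fields `m0`, `f0`, `G0`, `TGF0` (initial myofibroblast, fibroblast,
#'   PDGF and TGF-beta levels), `d_m` (apoptosis rate), `D_m`
#'   (diffusivity), `lambda_mfT` and `lambda_mfG` (fibroblast-to-
#'   myofibroblast activation rates via TGF-beta and PDGF), `K_G` and
#'   `K_TGF` (Hill saturation constants).
#' @export
#' @examples
#' p <- myofibroblast_params()
#' p$d_m
#' myofibroblast_params(d_m = 0.02)$d_m
myofibroblast_params <- function(...) {
  p <- list(
    m0         = 8.5e-3,
    f0         = 4.75e-3,
    G0         = 0.58e-3,
    TGF0       = 2.51e-12,
    d_m        = 1.66e-2,
    D_m        = 1.47e-5,
    lambda_mfT = 1.2e-1,
    lambda_mfG = 1.2e-1,
    K_G        = 1.5e-8,
    K_TGF      = 1e-10
  )
  p <- apply_overrides(p, list(...), "myofibroblast_params")
  structure(p, class = "myofibroblast_params")
}

#' Fibroblast subsystem parameters
#'
#' Constants of the fibroblast reaction-diffusion model: alveolar
#' epithelial cell (AEC) densities `E` (activated) and `E0`
#' (homeostatic), the initial TGF-beta concentrations seen by the
#' fibroblast and myofibroblast populations, the ECM density
#' `rho_ecm0` (recorded for completeness; it enters no equation), and
#' the kinetic rates. `lambda_Ef` is carried in the units it is
#' tabulated in (g cm^-3) and used as the strength of the constant
#' source term `lambda_Ef * E0`.
#'
#' @param ... named overrides of the default fields.
#' @return An object of class `fibroblast_params`.
#' @export
fibroblast_params <- function(...) {
  p <- list(
    E           = 7.99e-1,
    E0          = 7.99e-1,
    TGFf0       = 2.51e-12,
    TGFm0       = 2.51e-12,
    rho_ecm0    = 3e-3,
    d_f         = 1.66e-2,
    D_f         = 1.47e-6,
    lambda_fE   = 5e-4,
    lambda_rhof = 3e-3,
    lambda_TGFf = 7.5e-3,
    lambda_Ef   = 2.5e-1,
    K_E         = 1e-1
  )
  p <- apply_overrides(p, list(...), "fibroblast_params")
  structure(p, class = "fibroblast_params")
}

#' Homogenization constants of the effective tissue medium
#'
#' The alveolar microstructure is replaced by an effective medium with
#' tissue volume fraction `gamma` and an isotropic effective diffusion
#' coefficient `a_diag`, so that a species with molecular diffusivity D
#' diffuses with effective coefficient `(a_diag / gamma) * D`.
#'
#' @param ... named overrides (`gamma`, `a_diag`).
#' @return An object of class `homogenization_constants`.
#' @export
#' @examples
#' homogenization_constants()$gamma   # 127/343
homogenization_constants <- function(...) {
  p <- list(gamma = 127 / 343, a_diag = 0.11)
  p <- apply_overrides(p, list(...), "homogenization_constants")
  structure(p, class = "homogenization_constants")
}

#' Default parameter bundle
#'
#' @return A list with components `myo` ([myofibroblast_params()]),
#'   `fib` ([fibroblast_params()]) and `homog`
#'   ([homogenization_constants()]), all at their default values.
#' @export
#' @examples
#' default_parameters()$homog$gamma
default_parameters <- function() {
  list(
    myo   = myofibroblast_params(),
    fib   = fibroblast_params(),
    homog = homogenization_constants()
  )
}

#' Simulation and solver settings
#'
#' @param t0,tf simulation window, days.
#' @param dt explicit Euler step, days.
#' @param n_interior_per_side interior nodes per side of the unit
#'   square; the full grid has `(n_interior_per_side)^2` interior
#'   unknowns (6 gives the 36-node layout, 8 gives 64 nodes).
#' @param scheme `"neumann5"` (five-point zero-flux Laplacian, the
#'   default) or `"paper_literal"` (the printed block-matrix variant;
#'   see [assemble_myofibroblast_system()]).
#' @param riccati_mode `"algebraic"` (stationary solve) or
#'   `"differential"` (backward-integrated finite-horizon family).
#' @param affine_mode `"adjoint"` (offset from the adjoint equation of
#'   the costate) or `"paper_eta"` (matrix-eta recursion).
#' @param vanish_fraction fraction of the initial mean density below
#'   which a population counts as vanished (see [time_to_fraction()]).
#' @param damage_extent side length (cm) of a centred square in which
#'   the initial density is elevated tenfold, or `NULL` (default) for a
#'   uniform initial field.
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(t0 = 0, tf = 300, dt = 0.1,
                                n_interior_per_side = 6,
                                scheme = c("neumann5", "paper_literal"),
                                riccati_mode = c("algebraic", "differential"),
                                affine_mode = c("adjoint", "paper_eta"),
                                vanish_fraction = 0.01,
                                damage_extent = NULL) {
  s <- list(
    t0 = t0, tf = tf, dt = dt,
    n_interior_per_side = n_interior_per_side,
    scheme = match.arg(scheme),
    riccati_mode = match.arg(riccati_mode),
    affine_mode = match.arg(affine_mode),
    vanish_fraction = vanish_fraction,
    damage_extent = damage_extent
  )
  structure(s, class = "simulation_settings")
}

apply_overrides <- function(defaults, overrides, what) {
  if (length(overrides) == 0L) return(defaults)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == "")) {
    stop("all overrides for ", what, " must be named", call. = FALSE)
  }
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown ", what, " field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[nm] <- overrides
  defaults
}

#' Validate a parameter or settings object
#'
#' Checks every invariant of the object (positivity of rates,
#' saturations and diffusivities, non-negativity of initial values,
#' range of the volume fraction, ordering of the time window) and
#' returns a character vector naming each violation. An empty vector
#' means all invariants hold. Validation reports; it never aborts, so
#' callers decide how to react.
#'
#' @param params a `myofibroblast_params`, `fibroblast_params`,
#'   `homogenization_constants` or `simulation_settings` object.
#' @return character vector of violation messages (length 0 if valid).
#' @export
#' @examples
#' validate(myofibroblast_params())            # character(0)
#' validate(myofibroblast_params(d_m = -1))    # names d_m
validate <- function(params) UseMethod("validate")

check_positive <- function(p, fields) {
  bad <- fields[!vapply(fields, function(f) {
    v <- p[[f]]
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0
  }, logical(1))]
  if (length(bad) == 0L) character(0) else
    paste0(bad, " must be a strictly positive finite number")
}

check_nonneg <- function(p, fields) {
  bad <- fields[!vapply(fields, function(f) {
    v <- p[[f]]
    is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0
  }, logical(1))]
  if (length(bad) == 0L) character(0) else
    paste0(bad, " must be non-negative and finite")
}

#' @export
validate.myofibroblast_params <- function(params) {
  c(
    check_positive(params, c("d_m", "lambda_mfT", "lambda_mfG",
                             "K_G", "K_TGF")),
    # a vanishing diffusivity is admissible (well-mixed limit)
    check_nonneg(params, c("D_m", "m0", "f0", "G0", "TGF0"))
  )
}

#' @export
validate.fibroblast_params <- function(params) {
  c(
    check_positive(params, c("d_f", "lambda_fE", "lambda_rhof",
                             "lambda_TGFf", "lambda_Ef", "K_E")),
    check_nonneg(params, c("D_f", "E", "E0", "TGFf0", "TGFm0", "rho_ecm0"))
  )
}

#' @export
validate.homogenization_constants <- function(params) {
  out <- character(0)
  g <- params$gamma
  if (!(is.numeric(g) && length(g) == 1L && is.finite(g) &&
        g > 0 && g <= 1)) {
    out <- c(out, "gamma must lie in (0, 1]")
  }
  out <- c(out, check_positive(params, "a_diag"))
  out
}

#' @export
validate.simulation_settings <- function(params) {
  out <- character(0)
  if (!(params$t0 < params$tf)) out <- c(out, "t0 must be strictly less than tf")
  out <- c(out, check_positive(params, "dt"))
  n <- params$n_interior_per_side
  if (!(is.numeric(n) && length(n) == 1L && is.finite(n) &&
        n >= 1 && n == round(n))) {
    out <- c(out, "n_interior_per_side must be an integer >= 1")
  }
  vf <- params$vanish_fraction
  if (!(is.numeric(vf) && length(vf) == 1L && vf > 0 && vf <= 1)) {
    out <- c(out, "vanish_fraction must lie in (0, 1]")
  }
  de <- params$damage_extent
  if (!is.null(de) && !(is.numeric(de) && length(de) == 1L &&
                        de > 0 && de < 1)) {
    out <- c(out, "damage_extent must be NULL or a length in (0, 1) cm")
  }
  out
}

#' @export
validate.default <- function(params) {
  stop("no validator for objects of class ",
       paste(class(params), collapse = "/"), call. = FALSE)
}

stop_if_invalid <- function(params, what = deparse(substitute(params))) {
  rep <- validate(params)
  if (length(rep) > 0L) {
    stop("invalid ", what, ": ", paste(rep, collapse = "; "), call. = FALSE)
  }
  invisible(params)
}
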