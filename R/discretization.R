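#' Build a uniform 2-D grid on the unit tissue square
#'
#' The tissue is the unit square, subdivided into `n` intervals per
#' side with nodes `x_i = i/n`. Only interior nodes carry unknowns;
#' boundary nodes enter through the no-flux (or frozen-value) boundary
#' treatment of the assembly routines.
#'
#' @param n_interior_per_side interior nodes per side (integer >= 1).
#' @return An object of class `grid2d` with fields `n` (subdivisions
#'   per side, `n_interior_per_side + 1`), `dx` (spacing, cm),
#'   `n_side` (interior nodes per side), `n_interior` (total interior
#'   nodes) and `k` (inverse-square spacing `1/dx^2`).
#' @export
#' @examples
#' build_grid(6)$n_interior   # 36
build_grid <- function(n_interior_per_side) {
  if (!(is.numeric(n_interior_per_side) && length(n_interior_per_side) == 1L &&
        is.finite(n_interior_per_side) && n_interior_per_side >= 1 &&
        n_interior_per_side == round(n_interior_per_side))) {
    stop("n_interior_per_side must be a positive integer", call. = FALSE)
  }
  ns <- as.integer(n_interior_per_side)
  n <- ns + 1L
  structure(
    list(n = n, dx = 1 / n, n_side = ns, n_interior = ns * ns, k = n^2),
    class = "grid2d"
  )
}

#' Effective diffusivity of the homogenized medium
#'
#' @param D molecular diffusivity, cm^2 day^-1 (non-negative).
#' @param homog [homogenization_constants()].
#' @return `(a_diag / gamma) * D`.
#' @export
effective_diffusion <- function(D, homog = homogenization_constants()) {
  if (!is.numeric(D) || any(D < 0)) stop("D must be non-negative", call. = FALSE)
  (homog$a_diag / homog$gamma) * D
}

# 1-D second-difference matrix on ns interior nodes, scaled by r.
# neumann: mirror rule at both walls (corner entries -r, row sums 0).
# dirichlet-style literal variant: corners stay -2r (boundary values are
# injected through b instead).
second_difference_1d <- function(ns, r, neumann) {
  Tm <- diag(-2 * r, ns)
  if (ns > 1L) {
    idx <- seq_len(ns - 1L)
    Tm[cbind(idx, idx + 1L)] <- r
    Tm[cbind(idx + 1L, idx)] <- r
  }
  if (neumann) {
    Tm[1L, 1L] <- Tm[1L, 1L] + r
    Tm[ns, ns] <- Tm[ns, ns] + r
  }
  Tm
}

# 2-D five-point Laplacian (times r) on the interior nodes, row-major
# over (i, j) with i fastest, via Kronecker sums.
laplacian_2d <- function(ns, r, neumann = TRUE) {
  Tm <- second_difference_1d(ns, r, neumann)
  I <- diag(ns)
  kronecker(I, Tm) + kronecker(Tm, I)
}

# Block-tridiagonal matrix with blocks diagb on the diagonal, sub below
# and t(sub) above.
block_tridiagonal <- function(diagb, sub, nblocks) {
  ns <- nrow(diagb)
  M <- matrix(0, ns * nblocks, ns * nblocks)
  for (j in seq_len(nblocks)) {
    rows <- (j - 1L) * ns + seq_len(ns)
    M[rows, rows] <- diagb
    if (j > 1L) {
      prev <- (j - 2L) * ns + seq_len(ns)
      M[rows, prev] <- sub
      M[prev, rows] <- t(sub)
    }
  }
  M
}

new_linear_system <- function(A, B, b, r, theta, c, alpha, species, grid,
                              scheme, diffusion = NULL) {
  n <- nrow(A)
  stopifnot(ncol(A) == n, nrow(B) == n, ncol(B) == n, length(b) == n)
  if (is.null(diffusion)) diffusion <- matrix(0, n, n)
  structure(
    list(A = A, B = B, b = b, r = r, theta = theta, c = c, alpha = alpha,
         species = species, grid = grid, scheme = scheme,
         diffusion = diffusion),
    class = "linear_system"
  )
}

#' Assemble the myofibroblast state-space system
#'
#' Discretizes the homogenized myofibroblast equation (with the
#' TGF-beta Hill fraction frozen as the control U and the fibroblast
#' density frozen at its homeostatic value) into
#' `dm/dt = A m + B U + b` on the interior nodes.
#'
#' Two assemblies are available. `"neumann5"` (default) is the
#' physically consistent scheme: `A` is the five-point zero-flux
#' Laplacian scaled by the stencil weight `r = a_diag * D_m / (gamma *
#' dx^2)` minus the apoptosis rate `d_m` on the diagonal, `B = theta *
#' I` with control gain `theta = lambda_mfT * f0`, and `b = c * 1` with
#' constant source `c = lambda_mfG * G0 / (K_G + G0) * f0`.
#' `"paper_literal"` reproduces the printed block matrices instead:
#' diagonal blocks tridiagonal with `-2r - d_m` on the diagonal,
#' off-diagonal blocks with `r` on the first sub-diagonal, `B` block
#' tridiagonal with `theta * I` diagonal blocks and identity
#' off-diagonal blocks, and `b` carrying frozen boundary-density
#' entries `r * m0` at the first and last node of each row block in
#' addition to the constant source.
#'
#' @param params [myofibroblast_params()].
#' @param homog [homogenization_constants()].
#' @param grid [build_grid()] result.
#' @param scheme `"neumann5"` or `"paper_literal"`.
#' @return A `linear_system` with fields `A`, `B`, `b`, the scalars
#'   `r` (stencil weight), `theta` (control gain), `c` (source) and
#'   `alpha` (0 here; the loss rate is `d_m`), and `diffusion` (the
#'   pure diffusion operator, so `A = diffusion - loss * I`).
#' @export
#' @examples
#' sys <- assemble_myofibroblast_system(grid = build_grid(6))
#' sys$r       # about 2.14e-4 per day
assemble_myofibroblast_system <- function(params = myofibroblast_params(),
                                          homog = homogenization_constants(),
                                          grid = build_grid(6),
                                          scheme = c("neumann5",
                                                     "paper_literal")) {
  scheme <- match.arg(scheme)
  stop_if_invalid(params, "myofibroblast params")
  stop_if_invalid(homog, "homogenization constants")
  r <- homog$a_diag * params$D_m / (homog$gamma * grid$dx^2)
  theta <- params$lambda_mfT * params$f0
  cs <- params$lambda_mfG * params$G0 / (params$K_G + params$G0) * params$f0
  assemble_species(grid, scheme, r, loss = params$d_m, theta = theta,
                   cs = cs, boundary_value = params$m0, alpha = 0,
                   species = "myofibroblast")
}

#' Assemble the fibroblast state-space system
#'
#' Same construction as [assemble_myofibroblast_system()] for the
#' fibroblast equation `df/dt = A f + B U + b`: stencil weight
#' `r = a_diag * D_f / (gamma * dx^2)`, total loss rate
#' `alpha = lambda_mfG * G0/(K_G + G0) + lambda_TGFf * E/(E + K_E) +
#' lambda_rhof + d_f` (transformation to myofibroblast, TGF-beta
#' production drain, ECM deposition and apoptosis), control gain
#' `theta = lambda_fE * E/(E + K_E)` and constant source
#' `c = lambda_Ef * E0`.
#'
#' @param params [fibroblast_params()].
#' @param myo [myofibroblast_params()] (supplies the PDGF transformation
#'   term shared by both equations).
#' @inheritParams assemble_myofibroblast_system
#' @return A `linear_system`; `alpha` holds the total loss rate.
#' @export
assemble_fibroblast_system <- function(params = fibroblast_params(),
                                       myo = myofibroblast_params(),
                                       homog = homogenization_constants(),
                                       grid = build_grid(6),
                                       scheme = c("neumann5",
                                                  "paper_literal")) {
  scheme <- match.arg(scheme)
  stop_if_invalid(params, "fibroblast params")
  stop_if_invalid(myo, "myofibroblast params")
  stop_if_invalid(homog, "homogenization constants")
  r <- homog$a_diag * params$D_f / (homog$gamma * grid$dx^2)
  alpha <- myo$lambda_mfG * myo$G0 / (myo$K_G + myo$G0) +
    params$lambda_TGFf * params$E / (params$E + params$K_E) +
    params$lambda_rhof + params$d_f
  theta <- params$lambda_fE * params$E / (params$E + params$K_E)
  cs <- params$lambda_Ef * params$E0
  assemble_species(grid, scheme, r, loss = alpha, theta = theta, cs = cs,
                   boundary_value = myo$f0, alpha = alpha,
                   species = "fibroblast")
}

assemble_species <- function(grid, scheme, r, loss, theta, cs,
                             boundary_value, alpha, species) {
  ns <- grid$n_side
  ni <- grid$n_interior
  if (scheme == "neumann5") {
    D <- laplacian_2d(ns, r, neumann = TRUE)
    B <- diag(theta, ni)
    b <- rep(cs, ni)
  } else {
    # printed block form: 1-D tridiagonal diagonal blocks, sub-diagonal
    # coupling blocks, boundary densities frozen at the homeostatic value
    Gm <- second_difference_1d(ns, r, neumann = FALSE)
    Lb <- matrix(0, ns, ns)
    if (ns > 1L) {
      idx <- seq_len(ns - 1L)
      Lb[cbind(idx + 1L, idx)] <- r
    }
    D <- block_tridiagonal(Gm, Lb, ns)
    B <- block_tridiagonal(diag(theta, ns), diag(ns), ns)
    bj <- rep(0, ns)
    bj[c(1L, ns)] <- r * boundary_value
    b <- rep(bj + cs, ns)
  }
  A <- D - diag(loss, ni)
  new_linear_system(A, B, b, r = r, theta = theta, c = cs, alpha = alpha,
                    species = species, grid = grid, scheme = scheme,
                    diffusion = D)
}

#' Largest stable explicit time step for diffusion plus decay
#'
#' Returns `2 / (4 r + loss_rate)`, the largest step for which the
#' explicit Euler update of the five-point diffusion stencil combined
#' with linear decay is non-expanding.
#'
#' @param system a `linear_system`.
#' @param loss_rate linear loss rate, day^-1 (`d_m` for the
#'   myofibroblast system, `alpha` for the fibroblast system).
#' @return maximal stable step, days.
#' @export
cfl_max_step <- function(system, loss_rate) {
  2 / (4 * system$r + loss_rate)
}

#' @export
print.linear_system <- function(x, ...) {
  cat(sprintf(
    "<linear_system> %s, %d interior nodes (%s scheme)\n",
    x$species, nrow(x$A), x$scheme))
  cat(sprintf("  r = %.4g /day, theta = %.4g /day, c = %.4g g/cm^3/day\n",
              x$r, x$theta, x$c))
  invisible(x)
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> n = %d, dx = %.4g cm, %d interior nodes\n",
              x$n, x$dx, x$n_interior))
  invisible(x)
}
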