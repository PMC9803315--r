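# shared builders for small control systems used across test files

scalar_system <- function(a, b, cc, species = "myofibroblast") {
  grid <- build_grid(1)
  tgfctrl:::new_linear_system(matrix(a), matrix(b), cc, r = 0, theta = b,
                              c = cc, alpha = 0, species = species,
                              grid = grid, scheme = "neumann5")
}

# scalar continuous algebraic Riccati solution with q = r = 1
scalar_care <- function(a, b) (a + sqrt(a^2 + b^2)) / b^2

# the constant forcing of the uncontrolled myofibroblast kinetics when
# TGF-beta is held at its homeostatic concentration
uncontrolled_source <- function(p = myofibroblast_params()) {
  U0 <- tgf_to_u(p$TGF0, p$K_TGF)
  (p$lambda_mfT * U0 + p$lambda_mfG * p$G0 / (p$K_G + p$G0)) * p$f0
}

# 1-node coupled system with zero control lower bound (TGF0 = 0) and
# negative sources, built so that all four KKT cases are admissible and
# the free-feedback case is cheapest
synthetic_case1_coupled <- function() {
  structure(
    list(
      sys_m = scalar_system(-0.05, 0.5, -0.05),
      sys_f = scalar_system(-0.5, 0.5, -0.05, species = "fibroblast"),
      grid = build_grid(1),
      params = myofibroblast_params(m0 = 0, TGF0 = 0),
      fparams = fibroblast_params(TGFf0 = 0)
    ),
    class = "coupled_system"
  )
}
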