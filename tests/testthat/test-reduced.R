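test_that("radial substrate saturates when delivery dominates uptake", {
  # near-complete vascular support (CD31 reference ~ 0) drives n toward the
  # intravascular level throughout a weakly consuming domain
  p <- model_parameters(lambda_upt_V = 1e-9, lambda_upt_H = 1e-9,
                        D_nV = 1e-10, f_CD31_ref = 1e-6)
  prof <- radial_substrate(0.5, p, supply = "core")
  expect_true(all(prof$n > 0.999))
  expect_error(radial_substrate(0, model_parameters()), "positive")
})

test_that("uptake-only annulus matches the spherical screening closed form", {
  # outside a delivering core, pure uptake: n = C exp(-r/L)/r + C2 exp(r/L)/r;
  # in an effectively unbounded domain the decaying branch dominates
  p <- model_parameters()
  prof <- radial_substrate(2.8, p, supply = "core", dr = 0.002, pad = 0.2)
  u <- lymphosim:::sim_units(p)
  L <- sqrt(u$D_n / u$upt_V)
  sel <- prof$r > 0.4 & prof$r < 1.2       # annulus away from core and walls
  r <- prof$r[sel]; n <- prof$n[sel]
  r0 <- r[1]
  ana <- n[1] * (r0 / r) * exp(-(r - r0) / L)
  expect_lt(max(abs(n - ana) / ana), 0.01)
})

test_that("radius growth rate reduces to analytic forms", {
  p <- model_parameters()
  u <- lymphosim:::sim_units(p)
  # saturated substrate: dR/dt = lambda_M (1 - A) R / 3
  prof <- radial_substrate(1, p)
  prof$n[] <- 1
  expect_equal(radius_rhs(prof, p), u$lam_M * (1 - 0.4) * 1 / 3,
               tolerance = 1e-3)
  # A >= 1: shrinkage for any admissible profile
  pA <- model_parameters(lambda_A = 1.3 * 1.2)
  for (R in c(0.3, 1, 2)) {
    prof <- radial_substrate(R, pA)
    expect_lt(radius_rhs(prof, pA), 0)
  }
})

test_that("radius rhs agrees with an independent quadrature oracle", {
  skip_if_not_installed("pracma")
  p <- model_parameters()
  u <- lymphosim:::sim_units(p)
  prof <- radial_substrate(1.3, p, dr = 0.005)
  sel <- prof$in_tumor
  r <- prof$r[sel]; n <- prof$n[sel]
  f <- (u$lam_M * n * (n > u$n_N) - u$lam_A - u$lam_N * (n <= u$n_N)) * r^2
  oracle <- (pracma::trapz(r, f) + f[1] * r[1] +
             f[length(f)] * (prof$R - r[length(r)])) / prof$R^2
  expect_equal(radius_rhs(prof, p), oracle, tolerance = 1e-10)
})

test_that("dR/dt is continuous in R across the threshold crossing", {
  p <- model_parameters()
  Rs <- seq(2.6, 3.2, by = 0.005)
  vals <- vapply(Rs, function(R)
    radius_rhs(radial_substrate(R, p, dr = 0.002), p), numeric(1))
  # the Heaviside enters only through the radial integrand, so steps in
  # dR/dt are bounded by one mesh shell of the necrosis term
  u <- lymphosim:::sim_units(p)
  bound <- (u$lam_M + u$lam_N) * 3 * 0.002 / 2.6 * 2 + 0.005
  expect_lt(max(abs(diff(vals))), bound)
})

test_that("terminal diameter is ~6 mm at A = 0.4 and monotone in A", {
  p <- model_parameters()
  td <- terminal_diameter(0.4, p)
  expect_gt(td, 5.4); expect_lt(td, 6.6)
  tds <- vapply(c(0.2, 0.4, 0.6, 0.8), function(A)
    as.numeric(terminal_diameter(A, p)), numeric(1))
  expect_true(all(diff(tds) < 0))
  # strong enough death: never grows beyond the seed
  td9 <- terminal_diameter(0.95, p)
  expect_lte(td9, 2 * p$seed_radius + 0.05)
})

test_that("terminal size is invariant to the initial nutrient level", {
  tds <- vapply(c(0.3, 0.5, 1.0), function(ni) {
    p <- model_parameters(n_init = ni)
    as.numeric(terminal_diameter(0.4, p))
  }, numeric(1))
  expect_lt(diff(range(tds)) / mean(tds), 0.01)
})

test_that("growth phase depends on the initial nutrient level", {
  d21 <- vapply(c(0.5, 1.0), function(ni) {
    p <- model_parameters(n_init = ni)
    tr <- grow_radius(p, t_end = 21, record_every = 2)
    tr$diameter_mm[nrow(tr)]
  }, numeric(1))
  expect_gt(d21[2], 2 * d21[1])   # n_init = 1 grows far ahead by Day 21
})
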