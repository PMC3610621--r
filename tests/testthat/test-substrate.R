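# The 1D slab with a single vessel plane admits the closed form
# n(x) = n(0) exp(-x/L), L = sqrt(D_n/lambda_upt); these tests anchor the
# discrete solver against it and against the 80 um hypoxia-onset distance.

slab_grid <- function(h_um, len = 6.4) make_grid(c(len, len / 8), h_um, dim = 2)

# uniform-in-y configuration: vessel plane at the first x-column
slab_fields <- function(g, upt_rho = 1) {
  deliv <- array(0, dim = g$n)
  deliv[1, ] <- 1e7            # strong delivery pins n(0) near 1
  rho_V <- array(upt_rho, dim = g$n)
  rho_H <- array(0, dim = g$n)
  list(delivery = deliv, rho_V = rho_V, rho_H = rho_H)
}

test_that("full vascularization with no uptake saturates the substrate", {
  g <- make_grid(1.6, 200, dim = 2)
  p <- model_parameters()
  f <- array(1e6, dim = g$n)
  n <- solve_substrate(g, f, array(0, g$n), array(0, g$n), p)
  expect_true(all(abs(n - 1) < 1e-6))
})

test_that("1D slab profile matches exp(-x/L) within 1% at h = L/8", {
  p <- model_parameters()
  L <- 0.08  # mm
  g <- slab_grid(h_um = 10, len = 0.8)   # h = L/8
  f <- slab_fields(g)
  n <- solve_substrate(g, f$delivery, f$rho_V, f$rho_H, p)
  x <- g$coords[[1]]
  prof <- n[, 1]
  sel <- x > 0.05 & x < 0.4    # away from the source cell and far wall
  ana <- prof[which.min(abs(x - 0.05))] *
    exp(-(x[sel] - x[which.min(abs(x - 0.05))]) / L)
  expect_lt(max(abs(prof[sel] - ana) / ana), 0.01)
})

test_that("grid refinement shows second-order convergence of the slab profile", {
  p <- model_parameters()
  L <- 0.08
  err_for <- function(h_um) {
    g <- slab_grid(h_um, len = 0.8)
    f <- slab_fields(g)
    n <- solve_substrate(g, f$delivery, f$rho_V, f$rho_H, p, tol = 1e-12)
    x <- g$coords[[1]]
    sel <- x > 0.1 & x < 0.4
    ref <- n[which.min(abs(x - 0.1)), 1]
    x0 <- x[which.min(abs(x - 0.1))]
    max(abs(n[sel, 1] - ref * exp(-(x[sel] - x0) / L)))
  }
  e1 <- err_for(20); e2 <- err_for(10)
  expect_gt(e1 / e2, 3)   # ~4x for second order
})

test_that("hypoxia onset sits 80 +/- 20 um from an isolated vessel plane", {
  p <- model_parameters()
  g <- slab_grid(h_um = 10, len = 0.8)
  f <- slab_fields(g)
  n <- solve_substrate(g, f$delivery, f$rho_V, f$rho_H, p)
  x <- g$coords[[1]]
  prof <- n[, 1]
  cross <- approx(prof, x, xout = p$n_N)$y   # distance where n = n_N
  expect_gt(cross, 0.06)
  expect_lt(cross, 0.10)
})

test_that("maximum principle and monotonicity in uptake and delivery", {
  p <- model_parameters()
  g <- make_grid(1.6, 100, dim = 2)
  set.seed(7)
  for (i in 1:5) {
    deliv <- array(runif(prod(g$n)) * 1e5 * (runif(prod(g$n)) < 0.1), g$n)
    rv <- array(runif(prod(g$n)), g$n)
    rh <- array(runif(prod(g$n)) * 0.5, g$n)
    n <- solve_substrate(g, deliv, rv, rh, p)
    expect_true(all(n >= 0 & n <= 1))
    # doubling uptake cannot raise n anywhere
    n_hi <- solve_substrate(g, deliv, 2 * pmin(rv, 0.5), rh, p)
    base <- solve_substrate(g, deliv, pmin(rv, 0.5), rh, p)
    expect_true(all(n_hi <= base + 1e-9))
    # doubling delivery cannot lower n anywhere
    n_del <- solve_substrate(g, 2 * deliv, pmin(rv, 0.5), rh, p)
    expect_true(all(n_del >= base - 1e-9))
  }
})

test_that("discrete solve agrees with an independent sparse direct solve", {
  skip_if_not_installed("Matrix")
  p <- model_parameters()
  g <- make_grid(1.6, 200, dim = 2)
  set.seed(11)
  deliv <- array(1e5 * (runif(prod(g$n)) < 0.15), g$n)
  rv <- array(runif(prod(g$n)), g$n)
  rh <- array(0.3, g$n)
  n <- solve_substrate(g, deliv, rv, rh, p, tol = 1e-12)
  # independent assembly of the same operator with Matrix
  u <- lymphosim:::sim_units(p)
  nx <- g$n[1]; ny <- g$n[2]; N <- nx * ny
  idx <- function(i, j) (j - 1) * nx + i
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  add <- function(i, j, v) {
    trip$i <<- c(trip$i, i); trip$j <<- c(trip$j, j); trip$x <<- c(trip$x, v)
  }
  cf <- as.numeric(deliv + u$upt_V * rv + u$upt_H * rh)
  for (jj in 1:ny) for (ii in 1:nx) {
    me <- idx(ii, jj); diagv <- cf[me]
    for (nb in list(c(ii - 1, jj), c(ii + 1, jj), c(ii, jj - 1), c(ii, jj + 1))) {
      if (nb[1] < 1 || nb[1] > nx || nb[2] < 1 || nb[2] > ny) next
      oth <- idx(nb[1], nb[2])
      diagv <- diagv + u$D_n / g$h^2
      add(me, oth, -u$D_n / g$h^2)
    }
    add(me, me, diagv)
  }
  A <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(N, N))
  ref <- as.numeric(Matrix::solve(A, as.numeric(deliv)))
  expect_lt(max(abs(as.numeric(n) - ref)), 1e-7)
})

test_that("VEGF field is zero without hypoxia and bounded with it", {
  p <- model_parameters()
  g <- make_grid(1.6, 100, dim = 2)
  zero <- array(0, g$n)
  nv <- solve_vegf(g, zero + 1, zero, zero + 0.5, p)
  expect_true(all(nv == 0))
  hyp <- zero; hyp[6:10, 6:10] <- 1
  deliv <- zero; deliv[1, ] <- 1e5
  nv <- solve_vegf(g, deliv, hyp, zero + 0.8, p)
  expect_true(all(nv >= 0 & nv <= 1))
  expect_gt(max(nv), 0)
  # peak where the secretion is
  expect_gt(mean(nv[6:10, 6:10]), mean(nv[14:16, 14:16]))
})

test_that("hypoxic fraction handles saturation, anoxia and the half-space", {
  p <- model_parameters()
  g <- make_grid(1.6, 100, dim = 2)
  one <- array(1, g$n)
  st <- structure(list(grid = g, rho_V = one, n = one), class = "tissue_state")
  expect_equal(hypoxic_fraction_of_tumor(st, p), 0)
  st$n <- one * 0
  expect_equal(hypoxic_fraction_of_tumor(st, p), 1)
  # n crossing n_N at the midplane
  st$n <- array(rep(seq(0, 1, length.out = g$n[1]), g$n[2]), g$n)
  expect_equal(hypoxic_fraction_of_tumor(st, p), p$n_N, tolerance = 0.05)
  st$rho_V <- one * 0
  expect_error(hypoxic_fraction_of_tumor(st, p), "empty tumor")
})
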