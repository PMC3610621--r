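setup_net <- function(spacing = 200) {
  p <- model_parameters()
  g <- make_grid(6.4, spacing, dim = 3)
  node <- make_node(g, p$node_radius, p$mobility_reduction)
  list(p = p, g = g, node = node,
       net = initialize_vasculature(node, g, p, node_vessel_density = 0))
}

test_that("pre-existing vasculature is a connected, perfused core-plus-stems", {
  s <- setup_net()
  expect_gt(lymphosim:::net_size(s$net), 0)
  expect_true(all(s$net$perfused))
  expect_true(all(s$net$type == "root"))
  expect_true(lymphosim:::network_connected(s$net))
  # central ball voxel count close to the analytic ball
  p0 <- model_parameters(root_radius = 0)
  stems <- initialize_vasculature(s$node, s$g, p0, node_vessel_density = 0)
  ballvox <- lymphosim:::net_size(s$net) - lymphosim:::net_size(stems)
  ana <- 4 / 3 * pi * (s$p$root_radius / s$g$h)^3
  expect_lt(abs(ballvox - ana), 4 * pi * (s$p$root_radius / s$g$h)^2 + 8)
  # stems reach the node radius
  expect_gt(lymphosim:::net_size(stems), 3 * (s$p$node_radius / s$g$h) - 6)
})

test_that("parenchymal scatter stays inside the node at the set density", {
  s <- setup_net()
  set.seed(10)
  net <- initialize_vasculature(s$node, s$g, s$p, node_vessel_density = 0.25)
  extra <- setdiff(net$voxel, s$net$voxel)
  ctr <- s$node$center
  vox <- lymphosim:::idx_to_vox(s$g, extra)
  r <- sqrt(colSums((t(vox) * s$g$h - s$g$h / 2 - ctr)^2))
  expect_true(all(r <= s$node$radius + s$g$h))
  node_vox <- sum(lymphosim:::ball_fraction(s$g, s$node$radius) >= 0.5)
  expect_equal(length(extra) / node_vox, 0.25, tolerance = 0.2)
  expect_true(all(net$perfused))
})

test_that("no sprouting occurs without VEGF", {
  s <- setup_net()
  nv <- array(0, s$g$n)
  set.seed(1)
  net2 <- sprout_step(s$net, nv, s$p, dt = 0.5)
  expect_identical(net2$voxel, s$net$voxel)
  expect_equal(nrow(net2$tips), 0)
})

test_that("strong gradient bias drives tips deterministically up-gradient", {
  p <- model_parameters(beta_sprout = 1e4, tip_speed = 1e4, p_sprout = 0,
                        branch_rate = 0)
  g <- make_grid(6.4, 200, dim = 3)
  net <- lymphosim:::new_network(g)
  start <- matrix(c(16L, 16L, 16L), 1)
  net <- lymphosim:::add_nodes(net, lymphosim:::vox_to_idx(g, start), 0L,
                               "root", TRUE)
  net$tips <- data.frame(node = 1L, lastdir = 0L)
  nv <- array(rep(seq(0, 1, length.out = g$n[1]), g$n[2] * g$n[3]), g$n)
  set.seed(2)
  for (i in 1:8) net <- sprout_step(net, nv, p, dt = 1)
  vox <- lymphosim:::idx_to_vox(g, net$voxel)
  expect_equal(vox[nrow(vox), 1], 16L + 8L)   # marched straight in +x
  expect_true(all(vox[, 2] == 16L))
})

test_that("tip drift matches the analytic softmax expectation", {
  beta <- 30
  p <- model_parameters(beta_sprout = beta, tip_speed = 1e4, p_sprout = 0,
                        branch_rate = 0)
  g <- make_grid(6.4, 100, dim = 3)
  slope <- 0.01   # VEGF difference between neighbours along x
  nv <- array(rep((seq_len(g$n[1]) - 1) * slope, g$n[2] * g$n[3]), g$n)
  # analytic one-step drift without backtracking exclusion (first step):
  w <- c(exp(beta * slope), exp(-beta * slope), 1, 1, 1, 1)
  drift1 <- (w[1] - w[2]) / sum(w)
  set.seed(33)
  nrep <- 400
  disp <- numeric(nrep)
  for (k in seq_len(nrep)) {
    net <- lymphosim:::new_network(g)
    net <- lymphosim:::add_nodes(net, lymphosim:::vox_to_idx(g, matrix(c(10L, 32L, 32L), 1)),
                                 0L, "root", TRUE)
    net$tips <- data.frame(node = 1L, lastdir = 0L)
    net <- sprout_step(net, nv, p, dt = 1)
    vox <- lymphosim:::idx_to_vox(g, net$voxel)
    disp[k] <- vox[nrow(vox), 1] - 10L
  }
  se <- sd(disp) / sqrt(nrep)
  expect_lt(abs(mean(disp) - drift1), 3 * se + 1e-9)
})

test_that("anastomosis retires tips and never breaks connectivity", {
  p <- model_parameters(beta_sprout = 0, tip_speed = 1e4, p_sprout = 50,
                        branch_rate = 2, theta_sprout = 0.01)
  g <- make_grid(3.2, 200, dim = 3)
  node <- make_node(g, 1.2, 10)
  net <- initialize_vasculature(node, g, p)
  nv <- array(0.5, g$n)
  set.seed(5)
  tipmax <- 0
  for (i in 1:30) {
    net <- sprout_step(net, nv, p, dt = 0.05)
    expect_true(lymphosim:::network_connected(net))
    tipmax <- max(tipmax, nrow(net$tips))
  }
  expect_gt(lymphosim:::net_size(net), 100)  # it actually grew
  expect_gt(tipmax, 0)
})

test_that("rasterization covers exactly the unique vessel voxels", {
  s <- setup_net()
  ind <- rasterize_network(s$net)
  expect_true(all(ind %in% c(0, 1)))
  expect_equal(sum(ind), length(unique(s$net$voxel)))
  empty <- lymphosim:::new_network(s$g)
  expect_true(all(rasterize_network(empty) == 0))
  # perfusion gating excludes unperfused sprouts
  net <- s$net
  net <- lymphosim:::add_nodes(net, lymphosim:::vox_to_idx(s$g, matrix(c(2L, 2L, 2L), 1)),
                               1L, "sprout", FALSE)
  expect_equal(sum(rasterize_network(net)),
               sum(rasterize_network(net, perfusion_gated = TRUE)) + 1)
})

test_that("fixed seed reproduces the network sequence exactly", {
  s <- setup_net()
  p <- model_parameters(theta_sprout = 0.01)
  nv <- array(0.3, s$g$n)
  runseq <- function(seed) {
    set.seed(seed)
    net <- s$net
    for (i in 1:10) net <- sprout_step(net, nv, p, dt = 0.05)
    net$voxel
  }
  expect_identical(runseq(99), runseq(99))
  expect_false(identical(runseq(99), runseq(100)))
})
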