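# Discrete sprouting angiogenesis on the simulation lattice.
#
# The network is a set of vessel-occupied voxels with parent links: roots are
# the pre-existing node vasculature (a central ball plus three radial stems),
# sprouts extend from active tips that take biased random-walk steps up the
# VEGF gradient (softmax weights), branch at a rate increasing with local
# VEGF, and anastomose when a tip enters an occupied voxel.  Vessels are
# permanent; perfusion spreads from the roots and closes through anastomosed
# loops.

new_network <- function(grid) {
  structure(list(grid = grid,
                 voxel = integer(0),     # linear voxel index of each node
                 parent = integer(0),    # parent node id (0 = root)
                 type = character(0),    # "root" or "sprout"
                 perfused = logical(0),
                 occ = array(0L, dim = grid$n),  # voxel -> node id (0 empty)
                 tips = data.frame(node = integer(0), lastdir = integer(0)),
                 stalled = 0L),
            class = "vessel_network")
}

net_size <- function(net) length(net$voxel)

vox_to_idx <- function(grid, vox) {
  # vox: matrix of 1-based integer coordinates (rows)
  idx <- vox[, 1]
  mult <- 1
  for (a in seq_len(grid$dim - 1)) {
    mult <- mult * grid$n[a]
    idx <- idx + (vox[, a + 1] - 1L) * mult
  }
  idx
}

idx_to_vox <- function(grid, idx) {
  out <- matrix(0L, length(idx), grid$dim)
  rem <- idx - 1L
  for (a in seq_len(grid$dim)) {
    out[, a] <- rem %% grid$n[a] + 1L
    rem <- rem %/% grid$n[a]
  }
  out
}

add_nodes <- function(net, idx, parent, type, perfused) {
  keep <- net$occ[idx] == 0L
  idx <- idx[keep]
  if (!length(idx)) return(net)
  ids <- net_size(net) + seq_along(idx)
  net$voxel <- c(net$voxel, idx)
  net$parent <- c(net$parent, rep_len(parent, length(idx)))
  net$type <- c(net$type, rep_len(type, length(idx)))
  net$perfused <- c(net$perfused, rep_len(perfused, length(idx)))
  net$occ[idx] <- ids
  net
}

#' Initialize the pre-existing node vasculature
#'
#' Roots occupy a dense central ball (default radius `root_radius`) plus
#' three radial stems reaching the node surface — the confluence of large
#' vessels in the node core — and a sparse scatter of parenchymal
#' capillaries throughout the node sphere at volume density
#' `node_vessel_density` (the vasculature is concentrated in, but not
#' confined to, the core).  All roots are perfused.  The scatter draws from
#' the R RNG stream.
#'
#' @param node a `lympho_node`.
#' @param grid the simulation grid.
#' @param params a `lympho_params` (for `root_radius`).
#' @param node_vessel_density fraction of node voxels carrying a parenchymal
#'   capillary.
#' @return a `vessel_network`.
#' @export
initialize_vasculature <- function(node, grid = node$grid,
                                   params = model_parameters(),
                                   node_vessel_density = 0.25) {
  net <- new_network(grid)
  ctr <- node$center
  ball <- which(ball_fraction(grid, params$root_radius, ctr) >= 0.5)
  if (length(ball)) net <- add_nodes(net, ball, 0L, "root", TRUE)
  # three radial stems: +x, -x, +y (afferent/efferent axis marker)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  for (dvec in dirs) {
    dvec <- dvec[seq_len(grid$dim)]
    tpos <- ctr
    repeat {
      tpos <- tpos + dvec * grid$h
      if (sqrt(sum((tpos - ctr)^2)) > node$radius) break
      vox <- pmin(pmax(ceiling(tpos / grid$h), 1L), grid$n)
      net <- add_nodes(net, vox_to_idx(grid, matrix(as.integer(vox), 1)),
                       0L, "root", TRUE)
    }
  }
  if (node_vessel_density > 0) {
    in_node <- which(ball_fraction(grid, node$radius, ctr) >= 0.5)
    scatter <- in_node[runif(length(in_node)) < node_vessel_density]
    if (length(scatter)) net <- add_nodes(net, scatter, 0L, "root", TRUE)
  }
  net
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("vessel network: %d voxels (%d roots, %d sprouted), %d active tips, %d perfused\n",
              net_size(x), sum(x$type == "root"), sum(x$type == "sprout"),
              nrow(x$tips), sum(x$perfused)))
  invisible(x)
}

# neighbour linear-index offsets (2*dim lattice directions)
lattice_dirs <- function(grid) {
  step <- cumprod(c(1, grid$n[-grid$dim]))
  out <- integer(0)
  for (a in seq_len(grid$dim)) out <- c(out, step[a], -step[a])
  out
}

# mark the parent chain of `id` perfused up to the first perfused ancestor
mark_perfused <- function(net, id) {
  while (id != 0L && !net$perfused[id]) {
    net$perfused[id] <- TRUE
    id <- net$parent[id]
  }
  net
}

#' One sprouting-angiogenesis step
#'
#' (i) New tips initiate on perfused vessel voxels where VEGF exceeds
#' `theta_sprout`, with probability `p_sprout * dt`; (ii) each tip takes at
#' most one lattice step (probability `tip_speed * dt / h`) toward a
#' neighbour chosen with softmax weights `exp(beta * (n_V[nb] - n_V[cur]))`,
#' never immediately backtracking; (iii) tips branch with probability
#' `branch_rate * n_V * dt`; (iv) a tip stepping into an occupied voxel
#' anastomoses: the loop becomes perfused and the tip retires.  Tips with no
#' admissible move stall and are counted in `net$stalled`.
#'
#' @param net a `vessel_network`.
#' @param n_V VEGF field on the grid.
#' @param params a `lympho_params`.
#' @param dt time step in days.
#' @return the updated network (uses the R RNG stream).
#' @export
sprout_step <- function(net, n_V, params = model_parameters(), dt = 0.01) {
  grid <- net$grid
  dirs <- lattice_dirs(grid)
  ndirs <- length(dirs)
  # local working copies: the hot loop must not copy the occupancy array
  voxel <- net$voxel; parent <- net$parent; type <- net$type
  perfused <- net$perfused; occ <- net$occ; stalled <- net$stalled
  tip_node <- net$tips$node; tip_last <- net$tips$lastdir
  nnode <- length(voxel)
  mark <- function(id) {
    while (id != 0L && !perfused[id]) {
      perfused[id] <<- TRUE
      id <- parent[id]
    }
  }
  # --- tip initiation on perfused segments above the VEGF threshold
  elig <- which(perfused & n_V[voxel] > params$theta_sprout)
  if (length(elig)) {
    fire <- elig[runif(length(elig)) < params$p_sprout * dt]
    tip_node <- c(tip_node, fire)
    tip_last <- c(tip_last, rep(0L, length(fire)))
  }
  if (length(tip_node)) {
    move_p <- min(1, params$tip_speed * dt / grid$h)
    keep <- rep(TRUE, length(tip_node))
    new_node <- integer(0); new_last <- integer(0)
    nmax <- vapply(seq_len(grid$dim), function(a) grid$n[a], integer(1))
    for (ti in seq_along(tip_node)) {
      id <- tip_node[ti]
      cur <- voxel[id]
      if (runif(1) >= move_p) next
      curvox <- idx_to_vox(grid, cur)[1, ]
      w <- numeric(ndirs); cand <- integer(ndirs)
      for (d in seq_len(ndirs)) {
        a <- (d + 1L) %/% 2L
        sgn <- if (d %% 2L == 1L) 1L else -1L
        pos <- curvox[a] + sgn
        if (pos < 1L || pos > nmax[a]) next
        if (d == tip_last[ti]) next              # no backtracking
        j <- cur + dirs[d]                       # dirs are signed offsets
        cand[d] <- j
        w[d] <- exp(params$beta_sprout * (n_V[j] - n_V[cur]))
      }
      if (all(w == 0)) { stalled <- stalled + 1L; next }
      d <- sample.int(ndirs, 1, prob = w)
      j <- cand[d]
      occ_id <- occ[j]
      if (occ_id != 0L) {
        # anastomosis: perfuse the closed loop and retire the tip
        mark(id); mark(occ_id)
        keep[ti] <- FALSE
        next
      }
      nnode <- nnode + 1L
      voxel[nnode] <- j; parent[nnode] <- id
      type[nnode] <- "sprout"; perfused[nnode] <- FALSE
      occ[j] <- nnode
      tip_node[ti] <- nnode
      tip_last[ti] <- if (d %% 2L == 1L) d + 1L else d - 1L
      # --- branching at the vacated node
      if (runif(1) < params$branch_rate * n_V[cur] * dt) {
        new_node <- c(new_node, id); new_last <- c(new_last, 0L)
      }
    }
    tip_node <- c(tip_node[keep], new_node)
    tip_last <- c(tip_last[keep], new_last)
  }
  net$voxel <- voxel; net$parent <- parent; net$type <- type
  net$perfused <- perfused; net$occ <- occ; net$stalled <- stalled
  net$tips <- data.frame(node = tip_node, lastdir = tip_last)
  net
}

#' Rasterize a vessel network to the vessel indicator field
#'
#' @param net a `vessel_network`.
#' @param grid target grid (must match the network's grid).
#' @param perfusion_gated if `TRUE`, only perfused segments are marked
#'   (delivery from all segments is the default, as peripheral sprouts still
#'   carry some flow).
#' @return a binary (0/1) array on the grid.
#' @export
rasterize_network <- function(net, grid = net$grid, perfusion_gated = FALSE) {
  ind <- array(0, dim = grid$n)
  sel <- if (perfusion_gated) net$voxel[net$perfused] else net$voxel
  ind[sel] <- 1
  ind
}

# Connectivity check: every node reaches a root through parent links.
network_connected <- function(net) {
  if (!net_size(net)) return(TRUE)
  ok <- logical(net_size(net))
  for (id in seq_len(net_size(net))) {
    j <- id; hop <- 0
    while (j != 0L && !ok[j]) {
      if (net$parent[j] == 0L) { ok[j] <- TRUE; break }
      j <- net$parent[j]
      hop <- hop + 1
      if (hop > net_size(net)) return(FALSE)
    }
    # mark the path
    j <- id
    while (j != 0L && !ok[j]) { ok[j] <- TRUE; j <- net$parent[j] }
  }
  all(ok)
}
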