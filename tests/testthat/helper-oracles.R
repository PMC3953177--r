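# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive every quantity by the most direct route available
# (brute-force double loops, eigen decompositions, direct formulas) and never
# call the implementation paths they check.

random_angles <- function(n) {
  matrix(stats::runif(3 * n, -179.9, 180), n, 3,
         dimnames = list(NULL, c("phi", "psi", "omega")))
}

random_conformation <- function(n, sequence = NULL) {
  if (is.null(sequence))
    sequence <- sample(c("A", "L", "S", "K", "G", "F"), n, replace = TRUE)
  conformation(sequence, random_angles(n))
}

# quaternion (Kearsley) superposition: least RMSD as the smallest eigenvalue
# of the 4x4 key matrix -- fully independent of the Kabsch/SVD route
quaternion_lrmsd <- function(a, b) {
  m <- nrow(a)
  x <- a - rep(colMeans(a), each = m)
  y <- b - rep(colMeans(b), each = m)
  xm <- x - y
  xp <- x + y
  K <- matrix(0, 4, 4)
  K[1, 1] <- sum(xm^2)
  K[2, 2] <- sum(xm[, 1]^2 + xp[, 2]^2 + xp[, 3]^2)
  K[3, 3] <- sum(xp[, 1]^2 + xm[, 2]^2 + xp[, 3]^2)
  K[4, 4] <- sum(xp[, 1]^2 + xp[, 2]^2 + xm[, 3]^2)
  K[1, 2] <- K[2, 1] <- sum(xp[, 2] * xm[, 3] - xm[, 2] * xp[, 3])
  K[1, 3] <- K[3, 1] <- sum(xm[, 1] * xp[, 3] - xp[, 1] * xm[, 3])
  K[1, 4] <- K[4, 1] <- sum(xp[, 1] * xm[, 2] - xm[, 1] * xp[, 2])
  K[2, 3] <- K[3, 2] <- sum(xm[, 1] * xm[, 2] - xp[, 1] * xp[, 2])
  K[2, 4] <- K[4, 2] <- sum(xm[, 1] * xm[, 3] - xp[, 1] * xp[, 3])
  K[3, 4] <- K[4, 3] <- sum(xm[, 2] * xm[, 3] - xp[, 2] * xp[, 3])
  lam <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(lam, 0) / m)
}

# direct 4-point dihedral via normal-vector projections
bf_dihedral <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

# flat atom table for brute-force pair loops
atom_rows <- function(coords) {
  n <- nrow(coords$CA)
  out <- list()
  for (i in seq_len(n))
    for (a in c("N", "CA", "C", "O", "CB")) {
      xyz <- coords[[a]][i, ]
      if (all(is.finite(xyz)))
        out[[length(out) + 1L]] <- list(res = i, type = a, xyz = xyz)
    }
  out
}

bf_lj <- function(coords, params = amw_params()) {
  at <- atom_rows(coords)
  e <- 0
  for (i in seq_along(at)) for (j in seq_along(at)) {
    if (j <= i) next
    if (abs(at[[i]]$res - at[[j]]$res) < params$sep_nonlocal) next
    r <- sqrt(sum((at[[i]]$xyz - at[[j]]$xyz)^2))
    rmin <- params$lj_radius[at[[i]]$type] + params$lj_radius[at[[j]]$type]
    eps <- sqrt(params$lj_eps[at[[i]]$type] * params$lj_eps[at[[j]]$type])
    rc <- params$lj_cap_frac * rmin
    if (r >= rc) {
      q <- (rmin / r)^6
      e <- e + eps * (q^2 - 2 * q)
    } else {
      qc <- (rmin / rc)^6
      ec <- eps * (qc^2 - 2 * qc)
      sl <- eps * (-12 * qc^2 + 12 * qc) / rc
      e <- e + ec + sl * (r - rc)
    }
  }
  unname(e)
}

bf_hbond <- function(coords, params = amw_params()) {
  n <- nrow(coords$CA)
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < params$sep_hbond) next
    v2 <- coords$N[i, ] - coords$O[j, ]
    d <- sqrt(sum(v2^2))
    if (abs(d - params$hb_d0) > params$hb_tol) next
    v1 <- coords$C[j, ] - coords$O[j, ]
    ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    if (ct < 0)
      e <- e - params$hb_w *
        exp(-(d - params$hb_d0)^2 / (2 * params$hb_sigma^2)) * ct^2
  }
  unname(e)
}

bf_compaction <- function(coords, params = amw_params()) {
  ca <- coords$CA
  n <- nrow(ca)
  cen <- colMeans(ca)
  rg <- sqrt(sum(sweep(ca, 2, cen)^2) / n)
  params$w_compact * max(0, rg - params$rg_a * n^params$rg_b)^2
}

bf_side_centers <- function(coords) {
  sc <- coords$CB
  g <- coords$sequence == "G"
  sc[g, ] <- coords$CA[g, , drop = FALSE]
  sc
}

bf_burial_counts <- function(coords, params = amw_params()) {
  sc <- bf_side_centers(coords)
  n <- nrow(sc)
  counts <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || abs(i - j) < params$sep_nonlocal) next
    if (sqrt(sum((sc[i, ] - sc[j, ])^2)) <= params$burial_shell)
      counts[i] <- counts[i] + 1L
  }
  counts
}

bf_burial <- function(coords, params = amw_params()) {
  counts <- bf_burial_counts(coords, params)
  hph <- coords$sequence %in% params$hydrophobic
  e <- 0
  for (i in seq_along(counts)) {
    e <- e + if (hph[i])
      params$w_burial * max(0, params$burial_t_hphob - counts[i])
    else params$w_burial * max(0, counts[i] - params$burial_t_polar)
  }
  e
}

bf_water <- function(coords, params = amw_params()) {
  sc <- bf_side_centers(coords)
  n <- nrow(sc)
  hph <- coords$sequence %in% params$hydrophobic
  sw <- function(r) {
    if (r >= params$water_inner && r <= params$water_outer) return(1)
    if (r > params$water_inner - params$water_taper && r < params$water_inner)
      return(0.5 * (1 - cos(pi * (r - (params$water_inner -
                                         params$water_taper)) /
                              params$water_taper)))
    if (r > params$water_outer && r < params$water_outer + params$water_taper)
      return(0.5 * (1 + cos(pi * (r - params$water_outer) /
                              params$water_taper)))
    0
  }
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || j - i < params$sep_nonlocal) next
    r <- sqrt(sum((sc[i, ] - sc[j, ])^2))
    cls <- if (hph[i] && hph[j]) "HH" else if (!hph[i] && !hph[j]) "PP"
    else "HP"
    e <- e + params$w_water[cls] * sw(r)
  }
  unname(e)
}

# rigid transform of a backbone_coords object (proper rotation + shift)
rigid_transform <- function(coords, angle = 0.83, shift = c(3, -2, 5)) {
  ca <- cos(angle); sa <- sin(angle)
  R <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  out <- coords
  for (a in c("N", "CA", "C", "O", "CB"))
    out[[a]] <- coords[[a]] %*% R + rep(shift, each = nrow(coords[[a]]))
  out
}

# enumerate every per-window library assignment applied as a chain sweep and
# return the minimum toy energy (direct wrapped-deviation formula)
enumerate_sweep_optimum <- function(lib, reference, weight = 1) {
  refv <- as.vector(t(reference$angles))
  n <- lib$n
  res <- rep(seq_len(n), each = 3)
  mult <- pmin(n - 2, res) - pmax(1, res - 2) + 1
  ks <- vapply(lib$windows, nrow, integer(1))
  grid <- expand.grid(lapply(ks, seq_len))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    v <- rep(180, 3 * n)
    for (w in seq_along(ks)) {
      slots <- (3 * (w - 1) + 1):(3 * (w - 1) + 9)
      v[slots] <- lib$windows[[w]][grid[g, w], ]
    }
    d <- abs(v - refv) %% 360
    d <- pmin(d, 360 - d)
    best <- min(best, sum(weight * mult * d * d))
  }
  best
}

# deterministic toy run helper shared by search tests
toy_run <- function(sys, algorithm, pop_size, num_child, eval_max, seed,
                    ...) {
  sample_decoys(sys$sequence, sys$library, toy_energy_model(sys$target),
                algorithm = algorithm, pop_size = pop_size,
                num_child = num_child, eval_max = eval_max, seed = seed, ...)
}
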