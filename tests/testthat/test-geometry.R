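# Independent vector-algebra oracle for the six internal coordinates,
# written directly from dot/cross products (kept separate from the
# implementation's atan2 formulation).
oracle_internal <- function(P, L) {
  ang <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  dih <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
    phi <- acos(pmin(1, pmax(-1, cosphi))) * 180 / pi
    if (sum(cr(n1, n2) * b2) < 0) phi <- -phi
    phi
  }
  c(r_PL = sqrt(sum((P$A - L$A)^2)),
    theta_P = ang(P$B, P$A, L$A), tau_P = dih(P$C, P$B, P$A, L$A),
    theta_L = ang(L$B, L$A, P$A), tau_L = dih(L$C, L$B, L$A, P$A),
    tau_PL = dih(P$B, P$A, L$A, L$B))
}

rand_triple <- function() {
  repeat {
    pts <- matrix(rnorm(9, sd = 2), 3)
    v1 <- pts[2, ] - pts[1, ]; v2 <- pts[3, ] - pts[1, ]
    if (vnorm(cross3(v1, v2)) > 0.5) break
  }
  list(A = pts[1, ], B = pts[2, ], C = pts[3, ])
}

test_that("measured internal coordinates agree with the vector-algebra oracle", {
  set.seed(101)
  for (i in 1:100) {
    P <- rand_triple()
    L <- rand_triple()
    L$A <- L$A + c(8, 0, 0)  # keep frames apart
    got <- as_numeric_ic(measure_internal(P, L))
    want <- oracle_internal(P, L)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("internal <-> Cartesian round trip closes to 1e-8", {
  fx <- fixtures()
  mono_P <- fx$protein_monomers$water
  mono_L <- fx$ligand_monomers$methanol
  sP <- find_site(fx$protein_sites, "water", "general")
  sL <- find_site(fx$ligand_sites, "methanol", "HBA")
  set.seed(7)
  for (i in 1:500) {
    ic <- internal_coords(runif(1, 1.5, 9), runif(1, 1, 179), runif(1, -179, 179),
                          runif(1, 1, 179), runif(1, -179, 179), runif(1, -179, 179))
    cfg <- cartesian_from_internal(mono_P, mono_L, sP, sL, ic)
    back <- internal_from_cartesian(cfg, sP, sL, mono_P, mono_L)
    d <- abs(as_numeric_ic(ic) - as_numeric_ic(back))
    d[-1] <- pmin(d[-1], 360 - d[-1])  # angles modulo wrap
    expect_lt(max(d), 1e-8)
  }
})

test_that("placement is rigid and tau_PL acts as a rotation about the axis", {
  fx <- fixtures()
  mono_P <- fx$protein_monomers$water
  mono_L <- fx$ligand_monomers$methanol
  sP <- find_site(fx$protein_sites, "water", "general")
  sL <- find_site(fx$ligand_sites, "methanol", "general")
  D0 <- as.matrix(dist(mono_L$coords))
  set.seed(11)
  for (i in 1:20) {
    ic <- internal_coords(runif(1, 2, 8), runif(1, 5, 175), runif(1, -179, 179),
                          runif(1, 5, 175), runif(1, -179, 179), runif(1, -179, 179))
    cfg <- cartesian_from_internal(mono_P, mono_L, sP, sL, ic)
    expect_lt(max(abs(as.matrix(dist(cfg$ligand$coords)) - D0)), 1e-10)
  }
  # tau_PL = 0 vs 180: related by rotation about A_P-A_L, so A_L (and r_PL)
  # is unchanged while B_L moves
  ic0 <- internal_coords(4, 70, 30, 110, -60, 0)
  ic180 <- internal_coords(4, 70, 30, 110, -60, 180)
  c0 <- cartesian_from_internal(mono_P, mono_L, sP, sL, ic0)
  c180 <- cartesian_from_internal(mono_P, mono_L, sP, sL, ic180)
  L0 <- map_site_points(mono_L$coords, c0$ligand$coords, sL)
  L180 <- map_site_points(mono_L$coords, c180$ligand$coords, sL)
  expect_lt(vnorm(L0$A - L180$A), 1e-8)
  expect_gt(vnorm(L0$B - L180$B), 0.1)
})

test_that("vdW separation matches the exhaustive pair oracle and its closed forms", {
  radii <- vdw_radii()
  # one pair: centres 4.0 apart, radii 1.5 each -> separation 1.0
  r15 <- vdw_radii(c(X = 1.5))
  expect_equal(vdw_separation("X", matrix(0, 1, 3), "X", matrix(c(4, 0, 0), 1), r15), 1.0)
  # tangent surfaces -> exactly zero
  expect_equal(vdw_separation("X", matrix(0, 1, 3), "X", matrix(c(3, 0, 0), 1), r15), 0.0)
  set.seed(5)
  els <- names(radii)
  for (i in 1:200) {
    eP <- sample(els, 5, replace = TRUE); eL <- sample(els, 4, replace = TRUE)
    cP <- matrix(rnorm(15, sd = 3), 5); cL <- matrix(rnorm(12, sd = 3), 4) + 4
    brute <- Inf
    for (p in 1:5) for (l in 1:4)
      brute <- min(brute, vnorm(cP[p, ] - cL[l, ]) - radii[eP[p]] - radii[eL[l]])
    expect_equal(vdw_separation(eP, cP, eL, cL, radii), unname(brute),
                 tolerance = 1e-12)
    # symmetric under monomer swap
    expect_equal(vdw_separation(eL, cL, eP, cP, radii),
                 vdw_separation(eP, cP, eL, cL, radii))
    # invariant under a joint rigid motion
    th <- runif(3, 0, 2 * pi)
    R <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0), c(0, 0, 1)) %*%
         rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])), c(0, sin(th[2]), cos(th[2])))
    t <- rnorm(3, sd = 5)
    expect_equal(vdw_separation(eP, sweep(cP %*% t(R), 2, t, "+"),
                                eL, sweep(cL %*% t(R), 2, t, "+"), radii),
                 vdw_separation(eP, cP, eL, cL, radii), tolerance = 1e-9)
  }
  expect_error(vdw_separation("Zz", matrix(0, 1, 3), "O", matrix(1, 1, 3), radii),
               "Zz")
})

test_that("solve_translation hits the target separation and is monotone", {
  fx <- fixtures()
  radii <- vdw_radii()
  mono_P <- fx$protein_monomers$sodium
  mono_L <- fx$ligand_monomers$chlorideL
  sP <- find_site(fx$protein_sites, "sodium", "general")
  sL <- find_site(fx$ligand_sites, "chlorideL", "general")
  ang <- c(theta_P = 90, tau_P = 0, theta_L = 90, tau_L = 0, tau_PL = 0)
  # single atoms with A on the atoms: r_PL = target + both radii
  expect_equal(solve_translation(mono_P, mono_L, sP, sL, ang, 1.0, radii),
               1.0 + 1.50 + 1.82, tolerance = 1e-6)
  expect_equal(solve_translation(mono_P, mono_L, sP, sL, ang, 0.0, radii),
               1.50 + 1.82, tolerance = 1e-6)
  # monotone in the target for a multi-atom pair
  mono_P2 <- fx$protein_monomers$water
  mono_L2 <- fx$ligand_monomers$methanol
  sP2 <- find_site(fx$protein_sites, "water", "general")
  sL2 <- find_site(fx$ligand_sites, "methanol", "general")
  set.seed(21)
  a2 <- c(theta_P = 60, tau_P = 40, theta_L = 120, tau_L = -30, tau_PL = 75)
  targets <- seq(-0.8, 2.5, by = 0.3)
  rpl <- vapply(targets, function(tr)
    solve_translation(mono_P2, mono_L2, sP2, sL2, a2, tr, radii), numeric(1))
  expect_true(all(diff(rpl) > 0))
  # every solution reproduces its target separation
  for (k in seq_along(targets)) {
    ic <- internal_coords(rpl[k], a2[["theta_P"]], a2[["tau_P"]],
                          a2[["theta_L"]], a2[["tau_L"]], a2[["tau_PL"]])
    cfg <- cartesian_from_internal(mono_P2, mono_L2, sP2, sL2, ic)
    expect_equal(config_vdw_separation(cfg, radii), targets[k], tolerance = 1e-5)
  }
  # infeasible when the target lies below the deepest achievable clash
  expect_error(solve_translation(mono_P, mono_L, sP, sL, ang, -5, radii),
               class = "dimergen_infeasible_separation")
})

test_that("solve_translation agrees with a fine grid-scan oracle", {
  fx <- fixtures()
  radii <- vdw_radii()
  mono_P <- fx$protein_monomers$water
  mono_L <- fx$ligand_monomers$methanol
  sP <- find_site(fx$protein_sites, "water", "general")
  sL <- find_site(fx$ligand_sites, "methanol", "general")
  sep_at <- function(r_PL, ang) {
    ic <- internal_coords(r_PL, ang[["theta_P"]], ang[["tau_P"]],
                          ang[["theta_L"]], ang[["tau_L"]], ang[["tau_PL"]])
    config_vdw_separation(
      cartesian_from_internal(mono_P, mono_L, sP, sL, ic), radii)
  }
  set.seed(33)
  for (i in 1:40) {
    ang <- c(theta_P = runif(1, 10, 170), tau_P = runif(1, -179, 179),
             theta_L = runif(1, 10, 170), tau_L = runif(1, -179, 179),
             tau_PL = runif(1, -179, 179))
    target <- runif(1, -0.8, 2.5)
    got <- solve_translation(mono_P, mono_L, sP, sL, ang, target, radii)
    # grid scan at 0.001 A around the coarse crossing, outermost root
    grid <- seq(got + 0.05, got - 0.05, by = -0.001)
    seps <- vapply(grid, sep_at, numeric(1), ang = ang)
    k <- which(seps < target)[1]
    expect_false(is.na(k))
    # linear interpolation between the bracketing grid points
    x0 <- grid[k - 1]; x1 <- grid[k]
    s0 <- seps[k - 1]; s1 <- seps[k]
    oracle <- x0 + (target - s0) * (x1 - x0) / (s1 - s0)
    expect_lt(abs(got - oracle), 2e-3)
  }
})

test_that("map_site_points is exact under rigid motions and bounded under noise", {
  fx <- fixtures()
  m <- fx$ligand_monomers$methanol
  s <- find_site(fx$ligand_sites, "methanol", "HBA")
  # identity
  p0 <- map_site_points(m$coords, m$coords, s)
  expect_lt(vnorm(p0$A - s$A) + vnorm(p0$B - s$B) + vnorm(p0$C - s$C), 1e-9)
  # equivariance under a known rigid motion
  set.seed(9)
  for (i in 1:20) {
    th <- runif(1, 0, 2 * pi); ax <- unit(rnorm(3))
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    t <- rnorm(3, sd = 4)
    newc <- sweep(m$coords %*% t(R), 2, t, "+")
    p <- map_site_points(m$coords, newc, s)
    expect_lt(vnorm(p$A - (as.numeric(R %*% s$A) + t)), 1e-8)
    expect_lt(vnorm(p$B - (as.numeric(R %*% s$B) + t)), 1e-8)
    expect_lt(vnorm(p$C - (as.numeric(R %*% s$C) + t)), 1e-8)
    # with <= 0.1 A per-atom noise the fitted points stay within 0.2 A
    noisy <- newc + matrix(runif(length(newc), -0.1, 0.1) / sqrt(3), ncol = 3)
    pn <- map_site_points(m$coords, noisy, s)
    expect_lt(vnorm(pn$A - p$A), 0.2)
  }
  expect_error(map_site_points(m$coords, m$coords[-1, ], s), "mismatch")
})
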