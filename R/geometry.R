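# ---- vector primitives ------------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at p2 in degrees
#'
#' @param p1,p2,p3 numeric length-3 points.
#' @return angle p1-p2-p3 in degrees, in \[0, 180\].
#' @export
angle_deg <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) stop("coincident points: angle undefined")
  # atan2 form is more accurate than acos near 0/180
  atan2(vnorm(cross3(u, v)), sum(u * v)) * 180 / pi
}

#' Signed dihedral p1-p2-p3-p4 in degrees
#'
#' Right-hand (IUPAC) sign convention; result in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 points.
#' @export
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12)
    stop("collinear points: dihedral undefined")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unit(b2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

# Place point D given chain A-B-C, |C-D| = dist, angle(B,C,D) = ang (deg),
# dihedral(A,B,C,D) = dih (deg). Natural-extension reference frame.
nerf_place <- function(A, B, C, dist, ang, dih) {
  ang <- ang * pi / 180; dih <- dih * pi / 180
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  m <- cross3(n, bc)
  d2 <- dist * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ---- internal coordinates ---------------------------------------------------

#' Construct the six intermolecular internal coordinates
#'
#' One distance and five angular coordinates relate the two site frames:
#' `r_PL` is the A_P-A_L distance; `theta_P`/`theta_L` the polar angles at
#' A_P/A_L; `tau_P`, `tau_L`, `tau_PL` the three dihedrals. `r` is the van der
#' Waals surface separation that results from the placement (negative values
#' quantify surface clash).
#'
#' @param r_PL A_P-A_L distance in Angstrom (> 0).
#' @param theta_P,theta_L polar angles in degrees, \[0, 180\].
#' @param tau_P,tau_L,tau_PL dihedrals in degrees, wrapped to (-180, 180].
#' @param r optional van der Waals separation in Angstrom.
#' @return object of class `internal_coords`.
#' @export
internal_coords <- function(r_PL, theta_P, tau_P, theta_L, tau_L, tau_PL,
                            r = NA_real_) {
  if (!is.finite(r_PL) || r_PL <= 0) stop("r_PL must be positive")
  ic <- list(r_PL = r_PL,
             theta_P = theta_P, tau_P = wrap_angle(tau_P),
             theta_L = theta_L, tau_L = wrap_angle(tau_L),
             tau_PL = wrap_angle(tau_PL), r = r)
  if (ic$theta_P < 0 || ic$theta_P > 180 || ic$theta_L < 0 || ic$theta_L > 180)
    stop("theta angles must lie in [0, 180] degrees")
  class(ic) <- "internal_coords"
  ic
}

#' @export
print.internal_coords <- function(x, ...) {
  cat(sprintf(
    "<internal coords: r_PL=%.4f A, theta_P=%.2f, tau_P=%.2f, theta_L=%.2f, tau_L=%.2f, tau_PL=%.2f deg, r=%s>\n",
    x$r_PL, x$theta_P, x$tau_P, x$theta_L, x$tau_L, x$tau_PL,
    if (is.na(x$r)) "NA" else sprintf("%.4f A", x$r)))
  invisible(x)
}

as_numeric_ic <- function(ic) {
  c(r_PL = ic$r_PL, theta_P = ic$theta_P, tau_P = ic$tau_P,
    theta_L = ic$theta_L, tau_L = ic$tau_L, tau_PL = ic$tau_PL)
}

#' Measure internal coordinates from two site-point triples
#'
#' @param P,L lists with numeric points `A`, `B`, `C` for the protein- and
#'   ligand-side frames (as mapped onto the current poses).
#' @return [internal_coords] (with `r` unset; see [vdw_separation]).
#' @export
measure_internal <- function(P, L) {
  internal_coords(
    r_PL = vnorm(P$A - L$A),
    theta_P = angle_deg(P$B, P$A, L$A),
    tau_P = dihedral_deg(P$C, P$B, P$A, L$A),
    theta_L = angle_deg(L$B, L$A, P$A),
    tau_L = dihedral_deg(L$C, L$B, L$A, P$A),
    tau_PL = dihedral_deg(P$B, P$A, L$A, L$B)
  )
}

#' Internal coordinates of a dimer configuration
#'
#' Maps each site's reference points onto the configuration's current monomer
#' poses (rigid least-squares fit) and measures the six intermolecular
#' coordinates; `r` is filled in when `radii` is supplied.
#'
#' @param config a `dimer_config`.
#' @param site_P,site_L the originating [interaction_site]s.
#' @param mono_P,mono_L the reference [monomer]s (site points are defined in
#'   their frames).
#' @param radii optional [vdw_radii] table.
#' @return [internal_coords].
#' @export
internal_from_cartesian <- function(config, site_P, site_L, mono_P, mono_L,
                                    radii = NULL) {
  P <- map_site_points(mono_P$coords, config$protein$coords, site_P)
  L <- map_site_points(mono_L$coords, config$ligand$coords, site_L)
  ic <- measure_internal(P, L)
  if (!is.null(radii))
    ic$r <- vdw_separation(config$protein$elements, config$protein$coords,
                           config$ligand$elements, config$ligand$coords, radii)
  ic
}

#' Place a dimer from internal coordinates
#'
#' The protein monomer stays in its input frame; the ligand is rigidly
#' transformed so the six intermolecular coordinates measured on the result
#' equal `ic`. Intra-monomer geometry is preserved exactly.
#'
#' @param mono_P,mono_L [monomer]s.
#' @param site_P,site_L their [interaction_site]s.
#' @param ic target [internal_coords].
#' @param site_dimer_id,index provenance fields stored on the configuration.
#' @return object of class `dimer_config`.
#' @export
cartesian_from_internal <- function(mono_P, mono_L, site_P, site_L, ic,
                                    site_dimer_id = NA_character_,
                                    index = NA_integer_) {
  AP <- site_P$A; BP <- site_P$B; CP <- site_P$C
  AL0 <- site_L$A; BL0 <- site_L$B; CL0 <- site_L$C
  dAB <- vnorm(AL0 - BL0); dBC <- vnorm(BL0 - CL0)
  angABC <- angle_deg(AL0, BL0, CL0)
  # target ligand frame points in the protein frame
  AL <- nerf_place(CP, BP, AP, ic$r_PL, ic$theta_P, ic$tau_P)
  BL <- nerf_place(BP, AP, AL, dAB, ic$theta_L, ic$tau_PL)
  CL <- nerf_place(AP, AL, BL, dBC, angABC, ic$tau_L)
  tr <- rigid_from_triples(AL0, BL0, CL0, AL, BL, CL)
  lig_coords <- apply_rigid(tr, mono_L$coords)
  config <- list(
    protein = list(name = mono_P$name, elements = mono_P$elements,
                   coords = mono_P$coords, charge = mono_P$charge,
                   partial_charges = mono_P$partial_charges),
    ligand = list(name = mono_L$name, elements = mono_L$elements,
                  coords = lig_coords, charge = mono_L$charge,
                  partial_charges = mono_L$partial_charges),
    site_dimer_id = site_dimer_id, index = index,
    target_internal = ic, perturbed = FALSE
  )
  class(config) <- "dimer_config"
  config
}

#' @export
print.dimer_config <- function(x, ...) {
  cat(sprintf("<dimer config %s #%s: %s / %s (%d + %d atoms)%s>\n",
              x$site_dimer_id, x$index, x$protein$name, x$ligand$name,
              length(x$protein$elements), length(x$ligand$elements),
              if (isTRUE(x$perturbed)) ", perturbed" else ""))
  invisible(x)
}

# Exact proper rigid transform mapping triple (A0,B0,C0) onto (A1,B1,C1)
# (congruent triangles assumed). Returns list(R, t) acting on row vectors.
rigid_from_triples <- function(A0, B0, C0, A1, B1, C1) {
  frame_of <- function(A, B, C) {
    e1 <- unit(B - A)
    v <- C - A
    e2 <- unit(v - sum(v * e1) * e1)
    cbind(e1, e2, cross3(e1, e2))
  }
  F0 <- frame_of(A0, B0, C0)
  F1 <- frame_of(A1, B1, C1)
  R <- F1 %*% t(F0)
  list(R = R, t = A1 - as.numeric(R %*% A0))
}

apply_rigid <- function(tr, coords) {
  sweep(coords %*% t(tr$R), 2, tr$t, "+")
}

# ---- van der Waals separation -----------------------------------------------

#' Van der Waals surface separation between two monomers
#'
#' Minimum over all intermolecular atom pairs of centre distance minus both
#' van der Waals radii: positive when the surfaces are apart, zero at
#' tangency, negative at the deepest surface clash.
#'
#' @param elements_P,elements_L element symbol vectors.
#' @param coords_P,coords_L n x 3 coordinate matrices in Angstrom.
#' @param radii named radius table from [vdw_radii].
#' @return separation in Angstrom.
#' @export
vdw_separation <- function(elements_P, coords_P, elements_L, coords_L, radii) {
  missing_el <- setdiff(unique(c(elements_P, elements_L)), names(radii))
  if (length(missing_el) > 0)
    stop("element(s) missing from the radius table: ",
         paste(missing_el, collapse = ", "))
  if (length(elements_P) == 0 || length(elements_L) == 0)
    stop("both coordinate sets must be nonempty")
  coords_P <- matrix(coords_P, ncol = 3); coords_L <- matrix(coords_L, ncol = 3)
  d2 <- outer(rowSums(coords_P^2), rowSums(coords_L^2), "+") -
    2 * coords_P %*% t(coords_L)
  d <- sqrt(pmax(d2, 0))
  rs <- outer(radii[elements_P], radii[elements_L], "+")
  min(d - rs)
}

config_vdw_separation <- function(config, radii) {
  vdw_separation(config$protein$elements, config$protein$coords,
                 config$ligand$elements, config$ligand$coords, radii)
}

# ---- translation solver -----------------------------------------------------

#' Solve for the A_P-A_L distance achieving a target vdW separation
#'
#' With the five angular coordinates fixed, the ligand is translated along
#' the A_P-A_L vector until the van der Waals separation equals `target_r`.
#' The min-over-pairs separation is 1-Lipschitz and monotone on the outer
#' branch, so the solver brackets from a far separation inward and bisects;
#' the largest-`r_PL` root is returned so configurations always lie on the
#' physically approachable branch.
#'
#' @param mono_P,mono_L [monomer]s.
#' @param site_P,site_L their [interaction_site]s.
#' @param angles named numeric: `theta_P`, `tau_P`, `theta_L`, `tau_L`,
#'   `tau_PL` in degrees.
#' @param target_r target vdW separation in Angstrom.
#' @param radii [vdw_radii] table.
#' @param tol bisection tolerance in Angstrom.
#' @return `r_PL` in Angstrom.
#' @export
solve_translation <- function(mono_P, mono_L, site_P, site_L, angles,
                              target_r, radii, tol = 1e-6) {
  sep_at <- function(r_PL) {
    ic <- internal_coords(r_PL, angles[["theta_P"]], angles[["tau_P"]],
                          angles[["theta_L"]], angles[["tau_L"]],
                          angles[["tau_PL"]])
    config_vdw_separation(
      cartesian_from_internal(mono_P, mono_L, site_P, site_L, ic), radii)
  }
  span <- function(m, site) max(sqrt(rowSums(sweep(m$coords, 2, site$A)^2)))
  rmax <- max(radii[c(mono_P$elements, mono_L$elements)])
  hi <- max(target_r, 0) + span(mono_P, site_P) + span(mono_L, site_L) +
    2 * rmax + 1
  while (sep_at(hi) < target_r) hi <- hi * 2
  # scan inward for the outermost crossing
  lo <- hi
  floor_r <- 1e-3
  step <- 0.25
  found <- FALSE
  while (lo > floor_r) {
    nxt <- max(lo - step, floor_r)
    if (sep_at(nxt) < target_r) { found <- TRUE; lo <- nxt; break }
    lo <- nxt
  }
  if (!found) {
    cond <- simpleError(sprintf(
      "infeasible separation: target r = %.3f A below the deepest achievable clash for this orientation",
      target_r))
    class(cond) <- c("dimergen_infeasible_separation", class(cond))
    stop(cond)
  }
  a <- lo; b <- min(lo + step, hi)
  while (b - a > tol) {
    mid <- (a + b) / 2
    if (sep_at(mid) < target_r) a <- mid else b <- mid
  }
  (a + b) / 2
}

# ---- site-point mapping -----------------------------------------------------

#' Map a site's reference points onto new monomer coordinates
#'
#' Fits the reference monomer coordinates onto `new_coords` by rigid
#' least-squares (Kabsch, proper rotation) and applies the fitted transform to
#' the site's A, B, C points. This lets internal coordinates be evaluated on
#' posed, perturbed or optimized structures.
#'
#' @param ref_coords reference n x 3 coordinates (frame in which the site is
#'   defined).
#' @param new_coords n x 3 coordinates of the same atoms in the new pose.
#' @param site [interaction_site] (or a list with points `A`, `B`, `C`).
#' @return list with transformed points `A`, `B`, `C`.
#' @export
map_site_points <- function(ref_coords, new_coords, site) {
  ref_coords <- matrix(ref_coords, ncol = 3)
  new_coords <- matrix(new_coords, ncol = 3)
  if (nrow(ref_coords) != nrow(new_coords))
    stop("atom count mismatch between reference and new coordinates")
  fit <- kabsch_fit(ref_coords, new_coords, allow_reflection = FALSE)
  pts <- rbind(site$A, site$B, site$C)
  out <- apply_rigid(fit, pts)
  list(A = out[1, ], B = out[2, ], C = out[3, ])
}

# Least-squares rigid fit of P onto Q (rows are points). Returns list(R, t,
# rmsd) with Q ~ P %*% t(R) + t. Proper rotation unless allow_reflection.
kabsch_fit <- function(P, Q, allow_reflection = FALSE) {
  if (nrow(P) == 1) {
    return(list(R = diag(3), t = Q[1, ] - P[1, ], rmsd = 0))
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- diag(3)
  if (!allow_reflection)
    d[3, 3] <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% d %*% t(sv$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(R = R, t = cq - as.numeric(R %*% cp), rmsd = rmsd)
}

#' Superposed RMSD between two coordinate sets
#'
#' @param P,Q n x 3 matrices with corresponding rows.
#' @param allow_reflection also consider improper (mirror) superposition.
#' @return RMSD in Angstrom after optimal superposition.
#' @export
kabsch_rmsd <- function(P, Q, allow_reflection = FALSE) {
  r <- kabsch_fit(P, Q, allow_reflection = FALSE)$rmsd
  if (allow_reflection)
    r <- min(r, kabsch_fit(P, Q, allow_reflection = TRUE)$rmsd)
  r
}
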