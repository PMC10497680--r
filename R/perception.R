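# Rule-based draft interaction-site perception.
#
# Curated site files always take precedence; perception is a convenience for
# fixtures and new monomers. Rules:
#   HBD  - every H bound to N, O, S, or sp-hybridized C
#   HBA  - every O; N except formally positive or trivalent N in/conjugated
#          to a pi system (amides, arylamines, guanidines)
#   LB   - F; carbonyl O; monocyclic-heterocycle N; alkylamine N; N-oxide O
#   LA   - aryl Cl/Br; aromatic S (one site per adjacent atom when
#          asymmetric); carbonyl C
#   general - one per monomer, A at the heavy-atom centroid
# Restricted default ranges: theta [90,180] for HBD and carbonyl HBA;
# tau [-45,45] u [135,225] for carbonyl LB.

# All atoms bonded to atom i (heavy-graph neighbours plus assigned hydrogens).
bonded_atoms <- function(mono, i) {
  g <- mono$graph
  heavy_atoms <- igraph::V(g)$atom
  nb <- integer(0)
  if (mono$elements[i] != "H") {
    v <- match(i, heavy_atoms)
    nb <- heavy_atoms[as.integer(igraph::neighbors(g, v))]
    nb <- c(nb, which(mono$h_assignment == i))
  } else {
    nb <- mono$h_assignment[i]
  }
  sort(nb[!is.na(nb)])
}

# sp-hybridized carbon: two-coordinate with a near-linear bond angle.
is_sp_carbon <- function(mono, i) {
  if (mono$elements[i] != "C") return(FALSE)
  nb <- bonded_atoms(mono, i)
  if (length(nb) != 2) return(FALSE)
  angle_deg(mono$coords[nb[1], ], mono$coords[i, ], mono$coords[nb[2], ]) > 175
}

# Distance between atoms.
atom_dist <- function(mono, i, j) vnorm(mono$coords[i, ] - mono$coords[j, ])

# Carbonyl carbon: C with a terminal O at a short (double-bond-like) distance.
is_carbonyl_c <- function(mono, i) {
  if (mono$elements[i] != "C") return(FALSE)
  nb <- bonded_atoms(mono, i)
  any(vapply(nb, function(j) {
    mono$elements[j] == "O" &&
      length(setdiff(bonded_atoms(mono, j), which(mono$elements == "H"))) == 1 &&
      atom_dist(mono, i, j) < 1.30
  }, logical(1)))
}

is_carbonyl_o <- function(mono, i) {
  if (mono$elements[i] != "O") return(FALSE)
  nb <- setdiff(bonded_atoms(mono, i), which(mono$elements == "H"))
  length(nb) == 1 && mono$elements[nb] == "C" && atom_dist(mono, i, nb) < 1.30
}

# Atom lies on a ring (2-core of the heavy graph).
in_ring <- function(mono, i) {
  g <- mono$graph
  v <- match(i, igraph::V(g)$atom)
  if (is.na(v)) return(FALSE)
  igraph::coreness(g)[v] >= 2
}

# Cyclomatic number of the heavy graph (1 = monocyclic).
n_rings <- function(mono) {
  g <- mono$graph
  igraph::ecount(g) - igraph::vcount(g) + igraph::count_components(g)
}

# Positively charged nitrogen: four-coordinate N (heuristic; atomic formal
# charges are not modelled, only the monomer total).
is_positive_n <- function(mono, i) {
  mono$elements[i] == "N" && mono$charge > 0 && length(bonded_atoms(mono, i)) >= 4
}

# Trivalent N conjugated to a pi system: bonded to a carbon that carries a
# short C-O or C-N contact (carbonyl, imine, guanidine) or sits in a ring of
# sp2-like carbons.
is_pi_conjugated_n <- function(mono, i) {
  if (mono$elements[i] != "N") return(FALSE)
  nb <- bonded_atoms(mono, i)
  heavy_nb <- nb[mono$elements[nb] != "H"]
  for (c_at in heavy_nb[mono$elements[heavy_nb] == "C"]) {
    c_nb <- setdiff(bonded_atoms(mono, c_at), i)
    c_nb <- c_nb[mono$elements[c_nb] %in% c("O", "N")]
    if (any(vapply(c_nb, function(j) atom_dist(mono, c_at, j) < 1.35, logical(1))))
      return(TRUE)
    if (in_ring(mono, c_at) && length(bonded_atoms(mono, c_at)) == 3)
      return(TRUE)
  }
  FALSE
}

is_alkylamine_n <- function(mono, i) {
  if (mono$elements[i] != "N") return(FALSE)
  if (is_positive_n(mono, i) || is_pi_conjugated_n(mono, i)) return(FALSE)
  if (in_ring(mono, i)) return(FALSE)
  nb <- bonded_atoms(mono, i)
  all(mono$elements[nb] %in% c("C", "H"))
}

is_n_oxide_o <- function(mono, i) {
  if (mono$elements[i] != "O") return(FALSE)
  nb <- setdiff(bonded_atoms(mono, i), which(mono$elements == "H"))
  length(nb) == 1 && mono$elements[nb] == "N"
}

is_aryl_halogen <- function(mono, i) {
  if (!mono$elements[i] %in% c("Cl", "Br")) return(FALSE)
  nb <- bonded_atoms(mono, i)
  length(nb) == 1 && mono$elements[nb] == "C" && in_ring(mono, nb)
}

is_aromatic_s <- function(mono, i) {
  mono$elements[i] == "S" && in_ring(mono, i)
}

# Deterministic B/C choice for a site anchored on atom `a`: prefer bonded
# neighbours with lowest indices, fall back to any non-collinear atom.
pick_bc <- function(mono, a, prefer_b = NULL) {
  A <- mono$coords[a, ]
  candidates_b <- if (!is.null(prefer_b)) prefer_b else bonded_atoms(mono, a)
  if (length(candidates_b) == 0)
    candidates_b <- setdiff(seq_along(mono$elements), a)
  b <- candidates_b[1]
  B <- mono$coords[b, ]
  noncollinear <- function(Cpt) {
    v1 <- B - A; v2 <- Cpt - A
    vnorm(cross3(v1, v2)) > 1e-6 * max(1, vnorm(v1) * vnorm(v2))
  }
  c_pool <- c(setdiff(bonded_atoms(mono, b), a),
              setdiff(bonded_atoms(mono, a), b),
              setdiff(seq_along(mono$elements), c(a, b)))
  for (cc in c_pool) {
    if (noncollinear(mono$coords[cc, ])) return(list(B = B, C = mono$coords[cc, ]))
  }
  # collinear molecule: synthesize C perpendicular to A-B
  v <- unit(B - A)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  list(B = B, C = A + unit(cross3(v, ref)))
}

#' Perceive draft interaction sites on a monomer
#'
#' Applies the category rules above to the monomer's perceived connectivity
#' and geometry. Monoatomic species get exactly one general site with
#' synthetic B/C points offset along the axes. Curated site files should take
#' precedence over these drafts.
#'
#' @param mono [monomer].
#' @param general create the general site (default TRUE; a few monomers are
#'   deliberately defined without one).
#' @return list of [interaction_site] drafts.
#' @export
perceive_sites <- function(mono, general = TRUE) {
  sites <- list()
  n <- length(mono$elements)
  add <- function(category, a, prefer_b = NULL, theta = NULL, tau = NULL) {
    bc <- pick_bc(mono, a, prefer_b)
    sites[[length(sites) + 1L]] <<- interaction_site(
      mono$name, category, A = mono$coords[a, ], B = bc$B, C = bc$C,
      theta_range = theta, tau_range = tau,
      id = paste(mono$name, category, length(sites) + 1L, sep = ":"))
  }
  if (general) {
    if (n == 1) {
      A <- mono$coords[1, ]
      sites[[length(sites) + 1L]] <- interaction_site(
        mono$name, "general", A = A, B = A + c(1, 0, 0), C = A + c(0, 1, 0),
        id = paste(mono$name, "general", 1, sep = ":"))
    } else {
      heavy <- which(mono$elements != "H")
      if (length(heavy) == 0) heavy <- seq_len(n)
      A <- colMeans(mono$coords[heavy, , drop = FALSE])
      # two lowest-index atoms noncollinear with the centroid
      B <- NULL; C <- NULL
      for (i in seq_len(n)) {
        Bi <- mono$coords[i, ]
        if (vnorm(Bi - A) < 1e-6) next
        for (j in seq_len(n)) {
          if (j == i) next
          v1 <- Bi - A; v2 <- mono$coords[j, ] - A
          if (vnorm(cross3(v1, v2)) > 1e-6) { B <- Bi; C <- mono$coords[j, ]; break }
        }
        if (!is.null(B)) break
      }
      if (is.null(B)) {  # linear molecule
        B <- mono$coords[1, ]
        v <- unit(B - A)
        ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        C <- A + unit(cross3(v, ref))
      }
      sites[[length(sites) + 1L]] <- interaction_site(
        mono$name, "general", A = A, B = B, C = C,
        id = paste(mono$name, "general", 1, sep = ":"))
    }
  }
  if (n > 1) {
    for (i in seq_len(n)) {
      el <- mono$elements[i]
      if (el == "H") {
        donor <- mono$h_assignment[i]
        if (!is.na(donor) &&
            (mono$elements[donor] %in% c("N", "O", "S") ||
             is_sp_carbon(mono, donor)))
          add("HBD", i, prefer_b = donor, theta = matrix(c(90, 180), 1))
      } else if (el == "O") {
        th <- if (is_carbonyl_o(mono, i)) matrix(c(90, 180), 1) else NULL
        add("HBA", i, theta = th)
        if (is_carbonyl_o(mono, i))
          add("LB", i, tau = matrix(c(-45, 45, 135, 225), 2, byrow = TRUE))
        else if (is_n_oxide_o(mono, i))
          add("LB", i)
      } else if (el == "N") {
        if (!is_positive_n(mono, i) && !is_pi_conjugated_n(mono, i))
          add("HBA", i)
        if (in_ring(mono, i) && n_rings(mono) == 1)
          add("LB", i)
        else if (is_alkylamine_n(mono, i))
          add("LB", i)
      } else if (el == "F") {
        add("LB", i)
      } else if (el %in% c("Cl", "Br")) {
        if (is_aryl_halogen(mono, i)) add("LA", i)
      } else if (el == "S") {
        if (is_aromatic_s(mono, i)) {
          ring_nb <- Filter(function(j) in_ring(mono, j),
                            bonded_atoms(mono, i))
          ring_el <- mono$elements[ring_nb]
          if (length(unique(ring_el)) > 1) {
            for (j in ring_nb) add("LA", i, prefer_b = j)
          } else {
            add("LA", i)
          }
        }
      }
      if (el == "C" && is_carbonyl_c(mono, i)) {
        o_nb <- Filter(function(j) mono$elements[j] == "O" &&
                         atom_dist(mono, i, j) < 1.30, bonded_atoms(mono, i))
        add("LA", i, prefer_b = o_nb[[1]])
      }
    }
  }
  sites
}
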