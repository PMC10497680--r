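# Z-matrix-style construction of small rigid fixture molecules.
# Each row: element, j (bond ref), dist, k (angle ref), angle, l (dihedral
# ref), dihedral. First three atoms use the reduced forms.
zmat_build <- function(rows) {
  n <- length(rows)
  el <- character(n)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    el[i] <- r[[1]]
    if (i == 1) {
      xyz[i, ] <- c(0, 0, 0)
    } else if (i == 2) {
      xyz[i, ] <- xyz[r[[2]], ] + c(r[[3]], 0, 0)
    } else if (i == 3) {
      j <- r[[2]]; k <- r[[4]]
      ang <- r[[5]] * pi / 180
      d <- unit(xyz[k, ] - xyz[j, ])
      xyz[i, ] <- xyz[j, ] + r[[3]] * (cos(ang) * d + sin(ang) * c(-d[2], d[1], 0))
    } else {
      xyz[i, ] <- nerf_place(xyz[r[[6]], ], xyz[r[[4]], ], xyz[r[[2]], ],
                             r[[3]], r[[5]], r[[7]])
    }
  }
  list(elements = el, coords = xyz)
}

fixture_geometries <- function() {
  z <- function(...) list(...)
  list(
    water = zmat_build(list(
      z("O"), z("H", 1, 0.9572), z("H", 1, 0.9572, 2, 104.52))),
    acetamide = zmat_build(list(
      z("C"), z("O", 1, 1.23), z("N", 1, 1.35, 2, 122),
      z("C", 1, 1.51, 2, 120, 3, 180),
      z("H", 3, 1.01, 1, 119, 2, 0), z("H", 3, 1.01, 1, 120, 2, 180),
      z("H", 4, 1.09, 1, 109.5, 2, 0), z("H", 4, 1.09, 1, 109.5, 2, 120),
      z("H", 4, 1.09, 1, 109.5, 2, 240))),
    methylammonium = zmat_build(list(
      z("C"), z("N", 1, 1.50), z("H", 1, 1.09, 2, 109.5),
      z("H", 1, 1.09, 2, 109.5, 3, 120), z("H", 1, 1.09, 2, 109.5, 3, 240),
      z("H", 2, 1.02, 1, 109.5, 3, 60), z("H", 2, 1.02, 1, 109.5, 3, 180),
      z("H", 2, 1.02, 1, 109.5, 3, 300))),
    formate = zmat_build(list(
      z("C"), z("O", 1, 1.25), z("O", 1, 1.25, 2, 130),
      z("H", 1, 1.10, 2, 115, 3, 180))),
    sodium = list(elements = "Na", coords = matrix(0, 1, 3)),
    chloride = list(elements = "Cl", coords = matrix(0, 1, 3)),
    methanol = zmat_build(list(
      z("C"), z("O", 1, 1.43), z("H", 2, 0.96, 1, 108.5),
      z("H", 1, 1.09, 2, 109.5, 3, 180), z("H", 1, 1.09, 2, 109.5, 3, 60),
      z("H", 1, 1.09, 2, 109.5, 3, 300))),
    formaldehyde = zmat_build(list(
      z("C"), z("O", 1, 1.21), z("H", 1, 1.10, 2, 122),
      z("H", 1, 1.10, 2, 122, 3, 180))),
    methylamine = zmat_build(list(
      z("C"), z("N", 1, 1.47), z("H", 2, 1.01, 1, 110),
      z("H", 2, 1.01, 1, 110, 3, 120),
      z("H", 1, 1.09, 2, 109.5, 3, 180), z("H", 1, 1.09, 2, 109.5, 3, 60),
      z("H", 1, 1.09, 2, 109.5, 3, 300))),
    fluoromethane = zmat_build(list(
      z("C"), z("F", 1, 1.38), z("H", 1, 1.09, 2, 109.5),
      z("H", 1, 1.09, 2, 109.5, 3, 120), z("H", 1, 1.09, 2, 109.5, 3, 240))),
    methane = zmat_build(list(
      z("C"), z("H", 1, 1.09), z("H", 1, 1.09, 2, 109.47),
      z("H", 1, 1.09, 2, 109.47, 3, 120), z("H", 1, 1.09, 2, 109.47, 3, 240))),
    ethane = zmat_build(list(
      z("C"), z("C", 1, 1.54), z("H", 1, 1.09, 2, 111),
      z("H", 1, 1.09, 2, 111, 3, 120), z("H", 1, 1.09, 2, 111, 3, 240),
      z("H", 2, 1.09, 1, 111, 3, 60), z("H", 2, 1.09, 1, 111, 3, 180),
      z("H", 2, 1.09, 1, 111, 3, 300)))
  )
}

fixture_partial_charges <- function() {
  list(
    water = c(-0.8, 0.4, 0.4),
    acetamide = c(0.55, -0.55, -0.8, -0.3, 0.4, 0.4, 0.1, 0.1, 0.1),
    methylammonium = c(0.25, -0.3, 0.02, 0.02, 0.02, 0.33, 0.33, 0.33),
    formate = c(0.4, -0.8, -0.8, 0.2),
    sodium = 1.0,
    chloride = -1.0,
    methanol = c(0.15, -0.65, 0.44, 0.02, 0.02, 0.02),
    formaldehyde = c(0.45, -0.45, 0, 0),
    methylamine = c(0.1, -0.9, 0.36, 0.36, 0.08 / 3, 0.08 / 3, 0.08 / 3),
    fluoromethane = c(0.13, -0.25, 0.04, 0.04, 0.04),
    methane = c(-0.24, 0.06, 0.06, 0.06, 0.06),
    ethane = c(-0.18, -0.18, 0.06, 0.06, 0.06, 0.06, 0.06, 0.06)
  )
}

#' Build the deterministic toy fixture set
#'
#' Authored small-molecule monomers spanning both sets, all three charge
#' states and all five site categories: a protein-like set (water, an amide
#' mimic defined without a general site, methylammonium, formate, Na+, Cl-)
#' and a ligand-like set (methanol, formaldehyde, methylamine, fluoromethane,
#' methane, ethane, a methylammonium cation, a formate anion, Na+, Cl-).
#' Methane, ethane and the two ligand ions carry only a general site, so the
#' amide mimic (which lacks one) is never paired with them. Coordinates are
#' idealized rigid geometries; the pipeline treats them as optimized
#' monomers. Per-atom partial charges for the surrogate backend are authored
#' alongside.
#'
#' @param seed unused (the set is fully deterministic); kept for interface
#'   symmetry with the stochastic generators.
#' @return list of class `fixture_set` with `protein_monomers`,
#'   `ligand_monomers` (named lists of [monomer]), `protein_sites`,
#'   `ligand_sites` (lists of [interaction_site]).
#' @export
make_fixtures <- function(seed = 1) {
  geo <- fixture_geometries()
  pq <- fixture_partial_charges()
  charges <- c(water = 0, acetamide = 0, methylammonium = 1, formate = -1,
               sodium = 1, chloride = -1,
               methanol = 0, formaldehyde = 0, methylamine = 0,
               fluoromethane = 0, methane = 0, ethane = 0)
  protein_names <- c("water", "acetamide", "methylammonium", "formate",
                     "sodium", "chloride")
  ligand_names <- c("methanol", "formaldehyde", "methylamine", "fluoromethane",
                    "methane", "ethane", "methylammonium", "formate",
                    "sodium", "chloride")
  build <- function(nm, set) {
    out_name <- if (set == "ligand" && nm %in% protein_names &&
                    nm %in% c("methylammonium", "formate", "sodium", "chloride"))
      paste0(nm, "L") else nm
    monomer(out_name, geo[[nm]]$elements, geo[[nm]]$coords,
            charge = charges[[nm]], set = set, partial_charges = pq[[nm]])
  }
  pm <- lapply(protein_names, build, set = "protein")
  names(pm) <- vapply(pm, function(m) m$name, character(1))
  lm <- lapply(ligand_names, build, set = "ligand")
  names(lm) <- vapply(lm, function(m) m$name, character(1))
  psites <- unlist(lapply(pm, function(m)
    perceive_sites(m, general = m$name != "acetamide")), recursive = FALSE)
  lsites <- unlist(lapply(lm, perceive_sites), recursive = FALSE)
  structure(list(protein_monomers = pm, ligand_monomers = lm,
                 protein_sites = unname(psites), ligand_sites = unname(lsites)),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("<fixture set: %d protein / %d ligand monomers, %d / %d sites>\n",
              length(x$protein_monomers), length(x$ligand_monomers),
              length(x$protein_sites), length(x$ligand_sites)))
  invisible(x)
}
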