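# ---- bond perception --------------------------------------------------------

#' Perceive the heavy-atom bond graph from coordinates
#'
#' Two heavy atoms are bonded when their distance is below the sum of their
#' covalent radii plus a 0.4 A tolerance. Hydrogens are excluded from the
#' graph; their heavy-atom assignment is handled separately (see
#' [assign_hydrogens]). Only graph equality matters downstream, so bond
#' orders, stereochemistry and charges are not represented; vertices carry
#' element labels.
#'
#' @param elements element symbols.
#' @param coords n x 3 coordinates in Angstrom.
#' @param tol bond tolerance in Angstrom (default 0.4).
#' @return igraph undirected graph with vertex attributes `element` and
#'   `atom` (original atom index).
#' @export
bond_graph <- function(elements, coords, tol = 0.4) {
  coords <- matrix(coords, ncol = 3)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  unknown <- setdiff(unique(elements), names(covalent_radii))
  if (length(unknown) > 0)
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  heavy <- which(elements != "H")
  nh <- length(heavy)
  g <- igraph::make_empty_graph(nh, directed = FALSE)
  igraph::V(g)$element <- elements[heavy]
  igraph::V(g)$atom <- heavy
  if (nh >= 2) {
    hc <- coords[heavy, , drop = FALSE]
    rc <- covalent_radii[elements[heavy]]
    edges <- integer(0)
    for (i in seq_len(nh - 1)) {
      d <- sqrt(rowSums(sweep(hc[(i + 1):nh, , drop = FALSE], 2, hc[i, ])^2))
      hit <- which(d < rc[i] + rc[(i + 1):nh] + tol)
      if (length(hit) > 0) edges <- c(edges, rbind(i, i + hit))
    }
    if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  }
  g
}

#' Assign each hydrogen to its nearest heavy atom
#'
#' @param elements element symbols.
#' @param coords n x 3 coordinates.
#' @return integer vector over all atoms: for hydrogens, the index of the
#'   nearest heavy atom; NA for heavy atoms. Monoatomic hydrogen-free
#'   species give all-NA.
#' @export
assign_hydrogens <- function(elements, coords) {
  coords <- matrix(coords, ncol = 3)
  heavy <- which(elements != "H")
  out <- rep(NA_integer_, length(elements))
  if (length(heavy) == 0) return(out)
  for (i in which(elements == "H")) {
    d <- sqrt(rowSums(sweep(coords[heavy, , drop = FALSE], 2, coords[i, ])^2))
    out[i] <- heavy[which.min(d)]
  }
  out
}

# Element-coloured graph equality.
graphs_identical <- function(g1, g2) {
  if (igraph::vcount(g1) != igraph::vcount(g2)) return(FALSE)
  if (igraph::ecount(g1) != igraph::ecount(g2)) return(FALSE)
  lev <- sort(unique(c(igraph::V(g1)$element, igraph::V(g2)$element)))
  c1 <- as.integer(factor(igraph::V(g1)$element, levels = lev))
  c2 <- as.integer(factor(igraph::V(g2)$element, levels = lev))
  igraph::isomorphic(g1, g2, method = "vf2", vertex.color1 = c1,
                     vertex.color2 = c2)
}

# Which monomer owns each atom of the dimer, and transfer detection.
config_partition <- function(config) {
  np <- length(config$protein$elements)
  nl <- length(config$ligand$elements)
  list(elements = c(config$protein$elements, config$ligand$elements),
       coords = rbind(config$protein$coords, config$ligand$coords),
       owner = rep(c("protein", "ligand"), c(np, nl)),
       np = np)
}

# Detect hydrogens whose nearest heavy atom lies in the other monomer.
detect_proton_transfer <- function(config) {
  d <- config_partition(config)
  assign <- assign_hydrogens(d$elements, d$coords)
  moved <- which(d$elements == "H" &
                   d$owner[assign] != d$owner & !is.na(assign))
  data.frame(h_atom = moved,
             from = d$owner[moved],
             acceptor_atom = assign[moved],
             stringsAsFactors = FALSE)
}

# ---- post-optimization filtering --------------------------------------------

#' Filter optimized dimer configurations
#'
#' Sequential curation of structures returned by geometry optimization:
#' (1) redundancy — drop configurations within `rmsd_threshold` heavy-atom
#' RMSD (reflection- and symmetry-aware) of an earlier-kept one;
#' (2) separation — drop configurations with `r_PL` > `sep_threshold`;
#' (3) graph change — compare each monomer's heavy-atom graph to its
#' reference: skeleton changes are removed, while hydrogens reassigned across
#' monomers with intact heavy graphs are flagged as proton transfers.
#'
#' @param configs list of optimized `dimer_config`s.
#' @param mono_P,mono_L reference [monomer]s.
#' @param sites named list, site_dimer_id -> list(P =, L =) sites, used to
#'   measure `r_PL` per configuration.
#' @param rmsd_threshold redundancy threshold in Angstrom (default 0.1).
#' @param sep_threshold separation threshold in Angstrom (default 3.6).
#' @param allow_reflection,symmetry_maps passed to [heavy_rmsd].
#' @return object of class `curation_report`: lists `kept`,
#'   `removed_redundant`, `removed_far`, `removed_graph_change`,
#'   `proton_transfers` (each transfer: config, h_atom, donor, acceptor).
#'   Every input lands in exactly one bucket.
#' @export
filter_optimized <- function(configs, mono_P, mono_L, sites,
                             rmsd_threshold = 0.1, sep_threshold = 3.6,
                             allow_reflection = TRUE, symmetry_maps = NULL) {
  if (is.null(symmetry_maps) && length(configs) > 1)
    symmetry_maps <- dimer_symmetry_maps(mono_P, mono_L)
  report <- structure(list(kept = list(), removed_redundant = list(),
                           removed_far = list(), removed_graph_change = list(),
                           proton_transfers = list()),
                      class = "curation_report")
  survivors <- list()
  # (1) redundancy: first kept wins
  for (cfg in configs) {
    dup <- FALSE
    for (prev in survivors) {
      if (heavy_rmsd(cfg, prev, allow_reflection = allow_reflection,
                     symmetry_maps = symmetry_maps) < rmsd_threshold) {
        dup <- TRUE; break
      }
    }
    if (dup) report$removed_redundant[[length(report$removed_redundant) + 1L]] <- cfg
    else survivors[[length(survivors) + 1L]] <- cfg
  }
  # (2) separation
  near <- list()
  for (cfg in survivors) {
    sd <- sites[[cfg$site_dimer_id]]
    if (is.null(sd)) stop("no sites registered for ", cfg$site_dimer_id)
    P <- map_site_points(mono_P$coords, cfg$protein$coords, sd$P)
    L <- map_site_points(mono_L$coords, cfg$ligand$coords, sd$L)
    if (vnorm(P$A - L$A) > sep_threshold)
      report$removed_far[[length(report$removed_far) + 1L]] <- cfg
    else near[[length(near) + 1L]] <- cfg
  }
  # (3) molecular-graph change / proton transfer
  for (cfg in near) {
    gP <- bond_graph(cfg$protein$elements, cfg$protein$coords)
    gL <- bond_graph(cfg$ligand$elements, cfg$ligand$coords)
    if (!graphs_identical(gP, mono_P$graph) || !graphs_identical(gL, mono_L$graph)) {
      report$removed_graph_change[[length(report$removed_graph_change) + 1L]] <- cfg
      next
    }
    pt <- detect_proton_transfer(cfg)
    if (nrow(pt) > 0) {
      report$proton_transfers[[length(report$proton_transfers) + 1L]] <-
        list(config = cfg, transfers = pt)
    } else {
      report$kept[[length(report$kept) + 1L]] <- cfg
    }
  }
  report
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf(
    "<curation report: %d kept, %d redundant, %d far, %d graph-change, %d proton transfers>\n",
    length(x$kept), length(x$removed_redundant), length(x$removed_far),
    length(x$removed_graph_change), length(x$proton_transfers)))
  invisible(x)
}

# ---- proton-transfer recapture ----------------------------------------------

#' Return a transferred proton to its original donor
#'
#' For a configuration whose heavy-atom graphs are intact but where a
#' hydrogen's nearest heavy atom has crossed to the other monomer, the proton
#' is placed back along the current donor-to-proton direction at the
#' reference donor-H bond length. Heavy atoms are untouched. The result is a
#' chemically consistent structure of the original dimer, though not a
#' gas-phase minimum (`recaptured = TRUE` marks this).
#'
#' @param config `dimer_config` flagged as a simple proton transfer.
#' @param mono_P,mono_L reference [monomer]s (for donor identification and
#'   reference bond lengths).
#' @return the recaptured `dimer_config`.
#' @export
recapture_proton <- function(config, mono_P, mono_L) {
  pt <- detect_proton_transfer(config)
  if (nrow(pt) == 0) return(config)
  d <- config_partition(config)
  for (i in seq_len(nrow(pt))) {
    h_global <- pt$h_atom[i]
    if (pt$from[i] == "protein") {
      mono <- mono_P; h_local <- h_global; side <- "protein"
    } else {
      mono <- mono_L; h_local <- h_global - d$np; side <- "ligand"
    }
    donor_local <- mono$h_assignment[h_local]
    if (is.na(donor_local)) {
      # reference ambiguous: report all heavy atoms tied for nearest
      stop("ambiguous donor for hydrogen ", h_local, " of ", mono$name)
    }
    ref_len <- vnorm(mono$coords[h_local, ] - mono$coords[donor_local, ])
    donor_now <- config[[side]]$coords[donor_local, ]
    h_now <- config[[side]]$coords[h_local, ]
    config[[side]]$coords[h_local, ] <- donor_now + unit(h_now - donor_now) * ref_len
  }
  config$recaptured <- TRUE
  config
}

#' Classify a proton-transfer outcome against a dimer registry
#'
#' After a transfer, the post-transfer monomer pair (acceptor gains the
#' proton, donor loses it) is compared against the registry of standard
#' monomers by element-coloured heavy-graph isomorphism, hydrogen count, and
#' formal charge. A match on both sides classifies the configuration as
#' `reassigned-standard`; otherwise it is `nonstandard`, unless a rejection
#' rule flags the post-transfer species as implausible (`discarded`).
#'
#' @param config `dimer_config` with a confirmed transfer.
#' @param registry named list of [monomer]s defining the standard inventory.
#' @param rules list of functions(species) -> logical; each species is a list
#'   with `elements`, `coords`, `graph`, `h_count`, `charge`,
#'   `donor_or_acceptor`. The default rule flags a deprotonated amide
#'   nitrogen (N that lost an H while bonded to a carbonyl carbon).
#' @return character disposition: "reassigned-standard", "nonstandard" or
#'   "discarded".
#' @export
classify_transfer <- function(config, registry, rules = list(rule_amide_anion)) {
  pt <- detect_proton_transfer(config)
  if (nrow(pt) == 0) stop("configuration has no proton transfer")
  d <- config_partition(config)
  sides <- list(
    protein = list(elements = config$protein$elements,
                   coords = config$protein$coords,
                   charge = config$protein$charge),
    ligand = list(elements = config$ligand$elements,
                  coords = config$ligand$coords,
                  charge = config$ligand$charge))
  # move transferred protons between the species descriptions
  for (i in seq_len(nrow(pt))) {
    from <- pt$from[i]; to <- setdiff(c("protein", "ligand"), from)
    h_global <- pt$h_atom[i]
    h_local <- if (from == "protein") h_global else h_global - d$np
    hxyz <- sides[[from]]$coords[h_local, ]
    sides[[from]]$coords <- sides[[from]]$coords[-h_local, , drop = FALSE]
    sides[[from]]$elements <- sides[[from]]$elements[-h_local]
    sides[[from]]$charge <- sides[[from]]$charge - 1L
    sides[[from]]$donor_or_acceptor <- "donor"
    sides[[to]]$coords <- rbind(sides[[to]]$coords, hxyz)
    sides[[to]]$elements <- c(sides[[to]]$elements, "H")
    sides[[to]]$charge <- sides[[to]]$charge + 1L
    sides[[to]]$donor_or_acceptor <- "acceptor"
  }
  species <- lapply(sides, function(s) {
    s$graph <- bond_graph(s$elements, s$coords)
    s$h_count <- sum(s$elements == "H")
    s
  })
  for (rule in rules) {
    if (any(vapply(species, rule, logical(1)))) return("discarded")
  }
  matches_registry <- function(s) {
    for (m in registry) {
      if (m$charge == s$charge && sum(m$elements == "H") == s$h_count &&
          graphs_identical(m$graph, s$graph)) return(TRUE)
    }
    FALSE
  }
  if (all(vapply(species, matches_registry, logical(1)))) "reassigned-standard"
  else "nonstandard"
}

#' Rejection rule: deprotonated amide nitrogen
#'
#' Flags a post-transfer species as implausible when the proton donor is a
#' nitrogen bonded to a carbonyl carbon (an amide N- conjugate base).
#'
#' @param species post-transfer species description (see [classify_transfer]).
#' @return logical.
#' @export
rule_amide_anion <- function(species) {
  if (!identical(species$donor_or_acceptor, "donor")) return(FALSE)
  g <- species$graph
  el <- igraph::V(g)$element
  heavy_idx <- igraph::V(g)$atom
  coords <- species$coords
  for (v in which(el == "N")) {
    nb <- as.integer(igraph::neighbors(g, v))
    for (c_v in nb[el[nb] == "C"]) {
      c_nb <- as.integer(igraph::neighbors(g, c_v))
      o_nb <- c_nb[el[c_nb] == "O"]
      for (o_v in o_nb) {
        d <- vnorm(coords[heavy_idx[c_v], ] - coords[heavy_idx[o_v], ])
        if (d < 1.32 && igraph::degree(g, o_v) == 1) {
          # N attached to a carbonyl carbon that lost its proton
          n_atom <- heavy_idx[v]
          h_on_n <- sum(species$elements == "H" &
                          assign_hydrogens(species$elements, species$coords) == n_atom,
                        na.rm = TRUE)
          if (h_on_n <= 1) return(TRUE)
        }
      }
    }
  }
  FALSE
}
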