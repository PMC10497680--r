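# ---- symmetry-aware heavy-atom RMSD -----------------------------------------

config_heavy <- function(config) {
  el <- c(config$protein$elements, config$ligand$elements)
  xyz <- rbind(config$protein$coords, config$ligand$coords)
  keep <- el != "H"
  list(elements = el[keep], coords = xyz[keep, , drop = FALSE],
       n_protein = sum(config$protein$elements != "H"))
}

#' Heavy-atom permutations from a monomer's bond-graph automorphisms
#'
#' Enumerates the automorphism group of the element-coloured heavy-atom bond
#' graph (closure over igraph's generators), capped for combinatorial safety.
#'
#' @param mono [monomer].
#' @param cap maximum number of permutations; a warning is issued and the
#'   enumeration truncated beyond it.
#' @return list of integer permutations of the monomer's heavy atoms
#'   (identity first).
#' @export
monomer_symmetry_maps <- function(mono, cap = 10000) {
  g <- mono$graph
  nh <- igraph::vcount(g)
  if (nh <= 1) return(list(seq_len(max(nh, 1))))
  colors <- as.integer(factor(igraph::V(g)$element))
  gens <- igraph::automorphism_group(g, colors = colors)
  perms <- lapply(gens, function(p) as.integer(p))
  ident <- seq_len(nh)
  seen <- new.env(hash = TRUE)
  key <- function(p) paste(p, collapse = ",")
  assign(key(ident), TRUE, envir = seen)
  out <- list(ident)
  queue <- list(ident)
  capped <- FALSE
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (g1 in perms) {
      nxt <- cur[g1]
      k <- key(nxt)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        out[[length(out) + 1L]] <- nxt
        if (length(out) >= cap) { capped <- TRUE; break }
        queue[[length(queue) + 1L]] <- nxt
      }
    }
    if (capped) break
  }
  if (capped)
    warning("symmetry permutations for ", mono$name, " capped at ", cap)
  out
}

#' Symmetry permutations for a dimer's heavy atoms
#'
#' Combines per-monomer bond-graph automorphisms blockwise (protein heavy
#' atoms first, then ligand), capped at `cap` total maps.
#'
#' @param mono_P,mono_L [monomer]s.
#' @param cap total cap on combined permutations.
#' @return list of integer permutations over the dimer's heavy atoms.
#' @export
dimer_symmetry_maps <- function(mono_P, mono_L, cap = 10000) {
  pp <- monomer_symmetry_maps(mono_P, cap)
  pl <- monomer_symmetry_maps(mono_L, cap)
  np <- length(pp[[1]])
  out <- vector("list", min(length(pp) * length(pl), cap))
  k <- 0L
  for (a in pp) {
    for (b in pl) {
      k <- k + 1L
      if (k > cap) {
        warning("dimer symmetry permutations capped at ", cap)
        return(out)
      }
      out[[k]] <- c(a, b + np)
    }
  }
  out[seq_len(k)]
}

#' Symmetry- and reflection-aware heavy-atom RMSD
#'
#' Minimum least-squares superposed RMSD over all heavy atoms of the dimer,
#' taken over the supplied symmetry permutations and, optionally, mirror
#' images.
#'
#' @param a,b `dimer_config`s of the same molecular dimer.
#' @param allow_reflection also consider improper superpositions.
#' @param symmetry_maps list of integer permutations of the dimer's heavy
#'   atoms (identity used when NULL).
#' @return RMSD in Angstrom.
#' @export
heavy_rmsd <- function(a, b, allow_reflection = TRUE, symmetry_maps = NULL) {
  ha <- config_heavy(a); hb <- config_heavy(b)
  if (nrow(ha$coords) != nrow(hb$coords))
    stop("heavy-atom count mismatch between configurations")
  if (is.null(symmetry_maps)) symmetry_maps <- list(seq_len(nrow(ha$coords)))
  best <- Inf
  for (p in symmetry_maps) {
    r <- kabsch_rmsd(ha$coords[p, , drop = FALSE], hb$coords,
                     allow_reflection = allow_reflection)
    if (r < best) best <- r
  }
  best
}

# ---- greedy maximin selection -----------------------------------------------

#' Greedy maximin diversity selection
#'
#' Iteratively adds the candidate maximizing its minimum distance to the
#' current set, until the set reaches `k` members or candidates are
#' exhausted. Ties are broken by lowest candidate ordinal. When the set is
#' empty, it is seeded with the first candidate in deterministic order.
#'
#' @param dist_matrix full symmetric distance matrix over
#'   candidates-plus-members (rows/cols indexed consistently with `R_idx`
#'   and `S_idx`).
#' @param R_idx integer indices of the candidate pool.
#' @param S_idx integer indices of the current set (disjoint from `R_idx`).
#' @param k target total set size.
#' @return integer indices added to the set, in selection order.
#' @export
maximin_select <- function(dist_matrix, R_idx, S_idx, k) {
  R_idx <- as.integer(R_idx); S_idx <- as.integer(S_idx)
  if (length(intersect(R_idx, S_idx)) > 0) stop("R and S must be disjoint")
  added <- integer(0)
  if (length(S_idx) == 0 && length(R_idx) > 0 && k > 0) {
    added <- R_idx[1]
    S_idx <- added
    R_idx <- R_idx[-1]
  }
  while (length(S_idx) < k && length(R_idx) > 0) {
    mind <- vapply(R_idx, function(r) min(dist_matrix[r, S_idx]), numeric(1))
    pick <- R_idx[which.max(mind)]  # which.max takes the first (lowest ordinal) tie
    added <- c(added, pick)
    S_idx <- c(S_idx, pick)
    R_idx <- setdiff(R_idx, pick)
  }
  added
}

# ---- start-set assembly -----------------------------------------------------

#' Select optimization starting configurations for a molecular dimer
#'
#' Step 1 seeds the set with each interaction-site dimer's lowest-energy
#' configuration, provided that energy is negative. Step 2 tops the set up by
#' greedy maximin heavy-atom RMSD: for all-neutral dimers the maximin runs
#' per interaction-site dimer (up to 5 members each); for dimers with a
#' charged monomer it runs once over the union (up to 5 members total).
#' If any admitted member has `r_PL` > 3.6 A, further configurations are
#' added (without removing any) until at least 5 members have `r_PL` < 3.2 A
#' or candidates run out. Like-charged dimers return an empty set.
#'
#' @param batches named list, site_dimer_id -> list of `dimer_config`s (each
#'   carrying an energy record in `$energies`).
#' @param mono_P,mono_L the [monomer]s of the molecular dimer.
#' @param sites named list, site_dimer_id -> list(P = site_P, L = site_L),
#'   used to measure `r_PL` on each configuration.
#' @param k_per_unit target set size per selection unit (default 5).
#' @param allow_reflection,symmetry_maps passed to [heavy_rmsd]; symmetry
#'   maps default to the dimer's bond-graph automorphisms.
#' @param r_far,r_near supplementation thresholds in Angstrom (3.6 / 3.2).
#' @return list of class `start_set`: `members` (configs), `provenance`
#'   (per-member label: energy-seeded / diversity-selected / supplemental),
#'   `r_PL` (per member).
#' @export
select_starts <- function(batches, mono_P, mono_L, sites, k_per_unit = 5,
                          allow_reflection = TRUE, symmetry_maps = NULL,
                          r_far = 3.6, r_near = 3.2) {
  out <- structure(list(members = list(), provenance = character(0),
                        r_PL = numeric(0),
                        protein = mono_P$name, ligand = mono_L$name),
                   class = "start_set")
  if (mono_P$charge != 0 && mono_L$charge != 0 &&
      sign(mono_P$charge) == sign(mono_L$charge)) {
    return(out)  # like-charged dimers are excluded from optimization
  }
  all_configs <- unlist(batches, recursive = FALSE, use.names = FALSE)
  if (length(all_configs) == 0) {
    warning("empty candidate pool for ", mono_P$name, "/", mono_L$name)
    return(out)
  }
  if (is.null(symmetry_maps)) symmetry_maps <- dimer_symmetry_maps(mono_P, mono_L)
  origin <- rep(names(batches), vapply(batches, length, integer(1)))
  rpl <- vapply(seq_along(all_configs), function(i) {
    sd <- sites[[origin[i]]]
    cfg <- all_configs[[i]]
    P <- map_site_points(mono_P$coords, cfg$protein$coords, sd$P)
    L <- map_site_points(mono_L$coords, cfg$ligand$coords, sd$L)
    vnorm(P$A - L$A)
  }, numeric(1))
  totals <- vapply(all_configs, function(c) c$energies[[1]]$total, numeric(1))

  n <- length(all_configs)
  D <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- heavy_rmsd(all_configs[[i]], all_configs[[j]],
                                       allow_reflection = allow_reflection,
                                       symmetry_maps = symmetry_maps)
    }
  }

  S <- integer(0)
  prov <- character(0)
  # Step 1: per site dimer, seed with the minimum-energy configuration if negative
  for (sd_id in names(batches)) {
    idx <- which(origin == sd_id)
    if (length(idx) == 0) next
    best <- idx[which.min(totals[idx])]
    if (totals[best] < 0) {
      S <- c(S, best)
      prov <- c(prov, "energy-seeded")
    }
  }
  # Step 2: maximin top-up
  neutral_mode <- mono_P$charge == 0 && mono_L$charge == 0
  if (neutral_mode) {
    for (sd_id in names(batches)) {
      idx <- which(origin == sd_id)
      S_here <- intersect(S, idx)
      R_here <- setdiff(idx, S)
      add <- maximin_select(D, R_here, S_here, k_per_unit)
      S <- c(S, add)
      prov <- c(prov, rep("diversity-selected", length(add)))
    }
  } else {
    add <- maximin_select(D, setdiff(seq_len(n), S), S, k_per_unit)
    S <- c(S, add)
    prov <- c(prov, rep("diversity-selected", length(add)))
  }
  # Supplementation: members were never removed, but far members must not
  # leave the set short of near starting points.
  if (any(rpl[S] > r_far)) {
    while (sum(rpl[S] < r_near) < k_per_unit) {
      R_near <- setdiff(which(rpl < r_near), S)
      if (length(R_near) == 0) break
      add <- maximin_select(D, R_near, S, length(S) + 1L)
      S <- c(S, add)
      prov <- c(prov, rep("supplemental", length(add)))
    }
  }
  out$members <- all_configs[S]
  out$provenance <- prov
  out$r_PL <- rpl[S]
  out
}

#' @export
print.start_set <- function(x, ...) {
  cat(sprintf("<start set %s/%s: %d members (%s)>\n", x$protein, x$ligand,
              length(x$members),
              paste(sprintf("%d %s", table(x$provenance),
                            names(table(x$provenance))), collapse = ", ")))
  invisible(x)
}
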