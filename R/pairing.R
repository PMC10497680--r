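# Allowed pairings of a protein-set site category with a ligand-set category.
pair_rules <- data.frame(
  protein_category = c("general", "HBD", "HBA", "LB", "LA"),
  ligand_category  = c("general", "HBA", "HBD", "LA", "LB"),
  pair_class = c("general/general", "pHBD/lHBA", "pHBA/lHBD",
                 "pLB/lLA", "pLA/lLB"),
  stringsAsFactors = FALSE
)

dimer_charge_class <- function(qp, ql) {
  ifelse(qp == 0 & ql == 0, "neutral/neutral",
  ifelse(qp == 0 | ql == 0, "charged/neutral",
  ifelse(sign(qp) == sign(ql), "like-charged", "opposite-charged")))
}

as_site_table <- function(sites, monomers = NULL) {
  if (is.data.frame(sites)) {
    req <- c("site_id", "monomer", "category", "charge")
    if (!all(req %in% names(sites)))
      stop("site table needs columns: ", paste(req, collapse = ", "))
    return(sites)
  }
  site_table(sites, monomers)
}

#' Enumerate interaction-site dimers
#'
#' Pairs protein-set sites with ligand-set sites under the five allowed class
#' combinations: general x general, protein HBD x ligand HBA, protein HBA x
#' ligand HBD, protein LB x ligand LA, and protein LA x ligand LB. No other
#' combination is produced.
#'
#' @param protein_sites,ligand_sites lists of [interaction_site] objects, or
#'   site tables (data.frames with columns `site_id`, `monomer`, `category`,
#'   `charge`).
#' @param protein_monomers,ligand_monomers named lists of [monomer]s (needed
#'   only when sites are given as objects, to resolve charges).
#' @return data.frame, one row per site dimer, sorted deterministically by
#'   (protein monomer, ligand monomer, pair class, site ids), with columns
#'   `site_dimer_id`, `protein_site`, `ligand_site`, `protein_monomer`,
#'   `ligand_monomer`, `protein_charge`, `ligand_charge`, `pair_class`,
#'   `charge_class`.
#' @export
enumerate_site_dimers <- function(protein_sites, ligand_sites,
                                  protein_monomers = NULL,
                                  ligand_monomers = NULL) {
  empty <- data.frame(site_dimer_id = character(0), protein_site = character(0),
                      ligand_site = character(0), protein_monomer = character(0),
                      ligand_monomer = character(0), protein_charge = integer(0),
                      ligand_charge = integer(0), pair_class = character(0),
                      charge_class = character(0), stringsAsFactors = FALSE)
  if (length(protein_sites) == 0 || length(ligand_sites) == 0) return(empty)
  pt <- as_site_table(protein_sites, protein_monomers)
  lt <- as_site_table(ligand_sites, ligand_monomers)
  out <- list()
  for (k in seq_len(nrow(pair_rules))) {
    p <- pt[pt$category == pair_rules$protein_category[k], , drop = FALSE]
    l <- lt[lt$category == pair_rules$ligand_category[k], , drop = FALSE]
    if (nrow(p) == 0 || nrow(l) == 0) next
    idx <- expand.grid(pi = seq_len(nrow(p)), li = seq_len(nrow(l)))
    out[[k]] <- data.frame(
      protein_site = p$site_id[idx$pi], ligand_site = l$site_id[idx$li],
      protein_monomer = p$monomer[idx$pi], ligand_monomer = l$monomer[idx$li],
      protein_charge = p$charge[idx$pi], ligand_charge = l$charge[idx$li],
      pair_class = pair_rules$pair_class[k], stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(empty)
  d <- do.call(rbind, out)
  d$charge_class <- dimer_charge_class(d$protein_charge, d$ligand_charge)
  d <- d[order(d$protein_monomer, d$ligand_monomer, d$pair_class,
               d$protein_site, d$ligand_site), , drop = FALSE]
  rownames(d) <- NULL
  d$site_dimer_id <- paste(d$protein_site, d$ligand_site, sep = "|")
  d[, c("site_dimer_id", "protein_site", "ligand_site", "protein_monomer",
        "ligand_monomer", "protein_charge", "ligand_charge", "pair_class",
        "charge_class")]
}

#' Aggregate site dimers into molecular dimers
#'
#' A molecular dimer is a unique (protein monomer, ligand monomer) pair
#' irrespective of which interaction sites paired them.
#'
#' @param site_dimers data.frame from [enumerate_site_dimers].
#' @return data.frame with one row per molecular dimer: `protein_monomer`,
#'   `ligand_monomer`, charges, `charge_class`, `n_site_dimers`.
#' @export
aggregate_molecular <- function(site_dimers) {
  if (nrow(site_dimers) == 0)
    return(data.frame(protein_monomer = character(0), ligand_monomer = character(0),
                      protein_charge = integer(0), ligand_charge = integer(0),
                      charge_class = character(0), n_site_dimers = integer(0)))
  key <- paste(site_dimers$protein_monomer, site_dimers$ligand_monomer, sep = "\r")
  agg <- site_dimers[!duplicated(key), c("protein_monomer", "ligand_monomer",
                                         "protein_charge", "ligand_charge",
                                         "charge_class")]
  agg$n_site_dimers <- as.integer(table(key)[unique(key)])
  agg <- agg[order(agg$protein_monomer, agg$ligand_monomer), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Charge-stratified count table of dimers
#'
#' Cross-tabulates dimers by the protein and ligand monomer charge classes
#' (neutral / cation / anion), with marginal "all" row and column.
#'
#' @param dimers data.frame from [enumerate_site_dimers] (level `"site"`) or
#'   [aggregate_molecular] (level `"molecular"`); when `level = "molecular"`
#'   a site-dimer table is aggregated first.
#' @param level `"site"` or `"molecular"`.
#' @return 4 x 4 integer matrix with rows/columns neutral, cation, anion, all.
#' @export
charge_count_table <- function(dimers, level = c("site", "molecular")) {
  level <- match.arg(level)
  if (level == "molecular" && "site_dimer_id" %in% names(dimers))
    dimers <- aggregate_molecular(dimers)
  classes <- c("neutral", "cation", "anion")
  pcls <- vapply(dimers$protein_charge, charge_class, character(1))
  lcls <- vapply(dimers$ligand_charge, charge_class, character(1))
  tab <- matrix(0L, 4, 4, dimnames = list(
    protein = c(classes, "all"), ligand = c(classes, "all")))
  for (i in classes) for (j in classes)
    tab[i, j] <- sum(pcls == i & lcls == j)
  tab[, "all"] <- rowSums(tab[, classes, drop = FALSE])
  tab["all", ] <- colSums(tab[classes, , drop = FALSE])
  tab
}

#' Expand per-monomer site counts into an abstract site inventory
#'
#' Convenience for working with published inventory summaries: given monomers
#' and how many sites of each category each one carries, builds the site
#' table consumed by [enumerate_site_dimers] without requiring geometry.
#'
#' @param monomers data.frame with columns `monomer`, `charge`.
#' @param site_counts data.frame with columns `monomer`, `category`, `n`.
#' @return site table data.frame (`site_id`, `monomer`, `category`, `charge`).
#' @export
expand_site_inventory <- function(monomers, site_counts) {
  stopifnot(all(c("monomer", "charge") %in% names(monomers)),
            all(c("monomer", "category", "n") %in% names(site_counts)))
  site_counts <- site_counts[site_counts$n > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(site_counts)), function(i) {
    r <- site_counts[i, ]
    q <- monomers$charge[match(r$monomer, monomers$monomer)]
    if (is.na(q)) stop("unknown monomer in site_counts: ", r$monomer)
    data.frame(
      site_id = paste0(r$monomer, ":", r$category, ":", seq_len(r$n)),
      monomer = r$monomer, category = r$category, charge = q,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
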