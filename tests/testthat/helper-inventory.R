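# Abstract site inventory reproducing the published per-category counts:
# 31 protein monomers (19 neutral / 5 cationic / 7 anionic) and 306 ligand
# monomers (250/23/33). One neutral protein monomer (the amide mimic) has no
# general site but carries HBD/HBA/LB/LA; 22 neutral and 1 cationic ligand
# monomers carry only a general site. Within a charge class the distribution
# of sites over monomers is round-robin: pair counts depend only on the
# category totals and on which monomers lack compatible categories.
published_site_inventory <- function(exclude_general = TRUE) {
  mk_names <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

  protein_monomers <- data.frame(
    monomer = c(mk_names("Pn", 19), mk_names("Pc", 5), mk_names("Pa", 7)),
    charge = c(rep(0L, 19), rep(1L, 5), rep(-1L, 7)))
  ligand_monomers <- data.frame(
    monomer = c(mk_names("Ln", 250), mk_names("Lc", 23), mk_names("La", 33)),
    charge = c(rep(0L, 250), rep(1L, 23), rep(-1L, 33)))

  round_robin <- function(monos, n_sites, category) {
    if (n_sites == 0) return(NULL)
    idx <- ((seq_len(n_sites) - 1L) %% length(monos)) + 1L
    data.frame(monomer = monos[idx], category = category)
  }
  counts_to_df <- function(rows) {
    d <- do.call(rbind, rows)
    agg <- aggregate(list(n = rep(1L, nrow(d))),
                     by = d[c("monomer", "category")], FUN = sum)
    agg
  }

  # protein sites: general 21/5/7 (Pn001 excluded, three neutrals doubled),
  # HBD 14/12/1, HBA 11/1/11, LB 10/1/12, LA 8/1/1
  pn <- mk_names("Pn", 19); pc <- mk_names("Pc", 5); pa <- mk_names("Pa", 7)
  gen_pn <- if (exclude_general) c(pn[2:19], pn[2:4]) else c(pn[2:19], pn[2:4], pn[1])
  p_rows <- list(
    data.frame(monomer = gen_pn, category = "general"),
    data.frame(monomer = pc, category = "general"),
    data.frame(monomer = pa, category = "general"),
    round_robin(pn, 14, "HBD"), round_robin(pc, 12, "HBD"),
    round_robin(pa, 1, "HBD"),
    round_robin(pn, 11, "HBA"), round_robin(pc, 1, "HBA"),
    round_robin(pa, 11, "HBA"),
    round_robin(pn, 10, "LB"), round_robin(pc, 1, "LB"),
    round_robin(pa, 12, "LB"),
    round_robin(pn, 8, "LA"), round_robin(pc, 1, "LA"),
    round_robin(pa, 1, "LA"))

  # ligand sites: general one per monomer; HBD 143/32/2, HBA 293/0/66,
  # LB 254/0/84, LA 129/0/9. The last 22 neutral and last 1 cationic
  # monomers are general-only.
  ln <- mk_names("Ln", 250); lc <- mk_names("Lc", 23); la <- mk_names("La", 33)
  ln_use <- ln[1:228]; lc_use <- lc[1:22]
  l_rows <- list(
    data.frame(monomer = c(ln, lc, la), category = "general"),
    round_robin(ln_use, 143, "HBD"), round_robin(lc_use, 32, "HBD"),
    round_robin(la, 2, "HBD"),
    round_robin(ln_use, 293, "HBA"), round_robin(la, 66, "HBA"),
    round_robin(ln_use, 254, "LB"), round_robin(la, 84, "LB"),
    round_robin(ln_use, 129, "LA"), round_robin(la, 9, "LA"))

  list(
    protein = expand_site_inventory(protein_monomers, counts_to_df(p_rows)),
    ligand = expand_site_inventory(ligand_monomers, counts_to_df(l_rows)))
}
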