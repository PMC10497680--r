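# ---- run configuration ------------------------------------------------------

#' Assemble a run configuration
#'
#' Defaults reproduce the standard generation protocol: batches of 50
#' accepted configurations per interaction-site dimer, the six-row radial
#' bounds table, 20/200 kcal/mol rejection thresholds with 0.1 A expansion,
#' and 0.1 A per-atom perturbation.
#'
#' @param out output root directory.
#' @param seed integer run seed; per-site-dimer substreams are derived from
#'   it so batch order does not matter.
#' @param batch_size accepted configurations per site dimer.
#' @param backend `"surrogate"`, `"stub"`, or a backend function.
#' @param radial_table bounds table as in [default_radial_table].
#' @param policy [rejection_policy].
#' @param max_disp perturbation bound in Angstrom.
#' @param radii [vdw_radii] table.
#' @return list of class `run_config`; serializable with
#'   [jsonlite::write_json] and reloadable via [load_run_config].
#' @export
run_config <- function(out = "dataset", seed = 1, batch_size = 50,
                       backend = "surrogate",
                       radial_table = default_radial_table(),
                       policy = rejection_policy(), max_disp = 0.1,
                       radii = vdw_radii()) {
  structure(list(out = out, seed = as.integer(seed),
                 batch_size = as.integer(batch_size), backend = backend,
                 radial_table = radial_table, policy = policy,
                 max_disp = max_disp, radii = radii),
            class = "run_config")
}

#' Save / load a run configuration (JSON)
#'
#' @param config [run_config].
#' @param path JSON file.
#' @return `path` / the reloaded `run_config`.
#' @export
save_run_config <- function(config, path) {
  x <- unclass(config)
  x$policy <- unclass(x$policy)
  x$radii <- as.list(x$radii)
  if (is.function(x$backend)) x$backend <- "custom"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(out = x$out, seed = x$seed, batch_size = x$batch_size,
             backend = x$backend, radial_table = x$radial_table,
             policy = do.call(rejection_policy, as.list(x$policy)),
             max_disp = x$max_disp, radii = unlist(x$radii))
}

resolve_backend <- function(backend, monomers) {
  if (is.function(backend)) return(backend)
  switch(backend,
         surrogate = surrogate_backend(),
         stub = backend_constant(-1),
         stop("unknown backend: ", backend))
}

# ---- end-to-end generation --------------------------------------------------

#' Run the full generation pipeline over a fixture or user inventory
#'
#' Enumerates interaction-site dimers, generates an accepted batch for each
#' (seeded substream per site dimer), and writes the dataset tree plus
#' JSON-lines manifests and charge-stratified count tables (CSV).
#'
#' @param fixtures a `fixture_set` (see [make_fixtures]) or a list with the
#'   same four elements built from user monomers/sites.
#' @param config [run_config].
#' @return invisible list: `site_dimers`, `molecular_dimers`, `counts_site`,
#'   `counts_molecular`, `n_written`, `manifest_path`, plus per-dimer batch
#'   summaries.
#' @export
run_generate <- function(fixtures, config = run_config()) {
  pm <- fixtures$protein_monomers; lm <- fixtures$ligand_monomers
  psites <- fixtures$protein_sites; lsites <- fixtures$ligand_sites
  site_by_id <- c(setNames(psites, vapply(psites, function(s) s$id, character(1))),
                  setNames(lsites, vapply(lsites, function(s) s$id, character(1))))
  sd <- enumerate_site_dimers(psites, lsites, pm, lm)
  md <- aggregate_molecular(sd)
  backend <- resolve_backend(config$backend, c(pm, lm))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out, "manifest.jsonl")
  if (file.exists(manifest_path)) file.remove(manifest_path)
  mcon <- file(manifest_path, open = "wt")
  on.exit(close(mcon), add = TRUE)
  dataset <- list()
  n_written <- 0L
  for (i in seq_len(nrow(sd))) {
    row <- sd[i, ]
    mono_P <- pm[[row$protein_monomer]]; mono_L <- lm[[row$ligand_monomer]]
    site_P <- site_by_id[[row$protein_site]]; site_L <- site_by_id[[row$ligand_site]]
    spec <- radial_spec_for(row$charge_class, row$pair_class, config$radial_table)
    like <- identical(row$charge_class, "like-charged")
    set.seed(substream_seed(config$seed, i))
    batch <- generate_batch(
      mono_P, mono_L, site_P, site_L, spec, backend,
      policy = config$policy, n = config$batch_size, like_charged = like,
      radii = config$radii, max_disp = config$max_disp,
      site_dimer_id = row$site_dimer_id)
    lg <- attr(batch, "attempt_log")
    dimer_key <- paste(row$protein_monomer, row$ligand_monomer, sep = "__")
    if (is.null(dataset[[dimer_key]])) dataset[[dimer_key]] <- list(random = list())
    for (cfg in batch) {
      ic <- cfg$target_internal
      stem <- make_filename(mono_P$name, site_P$category, mono_L$name,
                            site_L$category, cfg$index, ic)
      rec <- cfg$energies[[1]]
      slots <- c(jun.unscaled.total = rec$total,
                 jun.unscaled.electrostatic = rec$electrostatic,
                 jun.unscaled.exchange = rec$exchange,
                 jun.unscaled.induction = rec$induction,
                 jun.unscaled.dispersion = rec$dispersion)
      dataset[[dimer_key]]$random[[length(dataset[[dimer_key]]$random) + 1L]] <-
        list(config = cfg, energies = slots, name = stem)
      n_written <- n_written + 1L
    }
    writeLines(jsonlite::toJSON(list(
      site_dimer_id = row$site_dimer_id, ordinal = i,
      pair_class = row$pair_class, charge_class = row$charge_class,
      threshold = if (like) config$policy$charged_repulsive_threshold
                  else config$policy$threshold,
      n_accepted = length(batch), n_attempts = nrow(lg),
      rejected_r = lg$r_target[!lg$accepted]
    ), auto_unbox = TRUE, digits = NA), mcon)
  }
  write_splinter_tree(dataset, file.path(config$out, "tree"))
  cs <- charge_count_table(sd, "site")
  cm <- charge_count_table(sd, "molecular")
  write.csv(cs, file.path(config$out, "counts_site_dimers.csv"))
  write.csv(cm, file.path(config$out, "counts_molecular_dimers.csv"))
  invisible(list(site_dimers = sd, molecular_dimers = md,
                 counts_site = cs, counts_molecular = cm,
                 n_written = n_written, manifest_path = manifest_path))
}

# ---- energy-vs-separation scan ----------------------------------------------

#' Scan energy against the vdW separation for one site dimer
#'
#' Samples `n` configurations with `r` uniform over `r_range` (unbiased, for
#' diagnostic coverage) and random angles within the sites' allowed ranges,
#' evaluates the backend, and tabulates energies; the non-electrostatic sum
#' is included for charged dimers, whose bare Coulomb tail obscures the
#' short-range behaviour.
#'
#' @param mono_P,mono_L [monomer]s.
#' @param site_P,site_L their [interaction_site]s.
#' @param backend energy backend function.
#' @param n number of configurations.
#' @param r_range numeric length-2 scan range in Angstrom.
#' @param radii [vdw_radii] table.
#' @param perturb logical, apply the 0.1 A perturbation.
#' @return data.frame: `r`, `r_PL`, `total`, `electrostatic`, `exchange`,
#'   `induction`, `dispersion`, and `nonelectrostatic` when either monomer
#'   is charged.
#' @export
scan_energy_vs_r <- function(mono_P, mono_L, site_P, site_L, backend, n = 100,
                             r_range = c(-2, 5), radii = vdw_radii(),
                             perturb = FALSE) {
  charged <- mono_P$charge != 0 || mono_L$charge != 0
  cols <- c("r", "r_PL", "total", "electrostatic", "exchange", "induction",
            "dispersion", if (charged) "nonelectrostatic")
  rows <- vector("list", n)
  i <- 1L
  while (i <= n) {
    angles <- sample_angles(site_P, site_L)
    r <- runif(1, r_range[1], r_range[2])
    r_PL <- tryCatch(
      solve_translation(mono_P, mono_L, site_P, site_L, angles, r, radii),
      dimergen_infeasible_separation = function(e) NA_real_)
    if (is.na(r_PL)) next
    ic <- internal_coords(r_PL, angles[["theta_P"]], angles[["tau_P"]],
                          angles[["theta_L"]], angles[["tau_L"]],
                          angles[["tau_PL"]], r = r)
    cfg <- cartesian_from_internal(mono_P, mono_L, site_P, site_L, ic)
    if (perturb) cfg <- perturb_coordinates(cfg)
    rec <- backend(cfg)
    rows[[i]] <- c(r = r, r_PL = r_PL, total = rec$total,
                   electrostatic = rec$electrostatic, exchange = rec$exchange,
                   induction = rec$induction, dispersion = rec$dispersion,
                   if (charged) c(nonelectrostatic = nonelectrostatic_total(rec)))
    i <- i + 1L
  }
  out <- as.data.frame(do.call(rbind, rows))
  if (n == 0) out <- as.data.frame(matrix(numeric(0), 0, length(cols),
                                          dimnames = list(NULL, cols)))
  out
}
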