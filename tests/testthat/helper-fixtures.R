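# Shared fixture set, built once per test run.
.fx_cache <- new.env(parent = emptyenv())

fixtures <- function() {
  if (is.null(.fx_cache$fx)) .fx_cache$fx <- make_fixtures()
  .fx_cache$fx
}

# Find a fixture site by monomer name and category (first match).
find_site <- function(sites, monomer, category) {
  for (s in sites) if (s$monomer == monomer && s$category == category) return(s)
  stop("no such site: ", monomer, "/", category)
}

# A posed water/methanol configuration used across tests.
wm_config <- function(ic = internal_coords(3.5, 70, 30, 110, -60, 100),
                      id = "wm") {
  fx <- fixtures()
  cartesian_from_internal(
    fx$protein_monomers$water, fx$ligand_monomers$methanol,
    find_site(fx$protein_sites, "water", "general"),
    find_site(fx$ligand_sites, "methanol", "general"),
    ic, site_dimer_id = id, index = 1L)
}
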