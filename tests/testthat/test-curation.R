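test_that("bond perception follows covalent radii with 0.4 A tolerance", {
  # ethane-like: two heavy atoms, one edge
  g <- bond_graph(c("C", "C", "H"), rbind(c(0, 0, 0), c(1.54, 0, 0), c(-1, 0.5, 0)))
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  # stretched far beyond the cutoff: no edge
  g2 <- bond_graph(c("C", "C"), rbind(c(0, 0, 0), c(3.0, 0, 0)))
  expect_equal(igraph::ecount(g2), 0)
  expect_error(bond_graph("Xx", matrix(0, 1, 3)), "unknown element")
  # fixture library: perceived graphs match the authored connectivity
  fx <- fixtures()
  expected_edges <- c(water = 0, acetamide = 3, methylammonium = 1,
                      formate = 2, sodium = 0, chloride = 0)
  for (nm in names(expected_edges)) {
    m <- fx$protein_monomers[[nm]]
    expect_equal(igraph::ecount(m$graph), unname(expected_edges[nm]),
                 info = nm)
    expect_true(igraph::is_connected(m$graph) || igraph::vcount(m$graph) <= 1)
  }
})

test_that("hydrogens are assigned to their nearest heavy atom", {
  fx <- fixtures()
  m <- fx$ligand_monomers$methanol
  # atom 3 is the hydroxyl H (bonded to O, atom 2); 4-6 are methyl H on C (1)
  expect_equal(m$h_assignment[3], 2L)
  expect_equal(m$h_assignment[4:6], rep(1L, 3))
  expect_true(all(is.na(m$h_assignment[1:2])))
})

curation_fixture <- function(jitter_sd = 1e-5, seed = 61) {
  fx <- fixtures()
  mono_P <- fx$protein_monomers$water
  mono_L <- fx$ligand_monomers$methanol
  sP <- find_site(fx$protein_sites, "water", "general")
  sL <- find_site(fx$ligand_sites, "methanol", "general")
  id <- "cur"
  mk <- function(ic) cartesian_from_internal(mono_P, mono_L, sP, sL, ic,
                                             site_dimer_id = id, index = 1L)
  set.seed(seed)
  a <- mk(internal_coords(3.0, 70, 30, 110, -60, 100))
  dup <- a
  dup$ligand$coords <- dup$ligand$coords + matrix(rnorm(18, sd = jitter_sd), 6, 3)
  far <- mk(internal_coords(4.2, 70, 30, 110, -60, 100))
  broken <- a
  broken$ligand$coords[2, ] <- broken$ligand$coords[2, ] + c(0, 0, 3)  # snap C-O
  other <- mk(internal_coords(3.2, 120, -90, 60, 140, -20))
  list(fx = fx, mono_P = mono_P, mono_L = mono_L,
       sites = setNames(list(list(P = sP, L = sL)), id),
       a = a, dup = dup, far = far, broken = broken, other = other)
}

test_that("optimized-structure filters bucket redundancy, separation and graph change", {
  cf <- curation_fixture()
  rep <- filter_optimized(list(cf$a, cf$dup, cf$far, cf$broken, cf$other),
                          cf$mono_P, cf$mono_L, cf$sites)
  expect_length(rep$kept, 2)               # a and other
  expect_length(rep$removed_redundant, 1)  # the jittered copy
  expect_length(rep$removed_far, 1)        # r_PL = 4.2 > 3.6
  expect_length(rep$removed_graph_change, 1)
  expect_length(rep$proton_transfers, 0)
  # buckets partition the input
  total <- length(rep$kept) + length(rep$removed_redundant) +
    length(rep$removed_far) + length(rep$removed_graph_change) +
    length(rep$proton_transfers)
  expect_equal(total, 5)
  # idempotent on its own kept output
  rep2 <- filter_optimized(rep$kept, cf$mono_P, cf$mono_L, cf$sites)
  expect_length(rep2$kept, length(rep$kept))
  expect_length(rep2$removed_redundant, 0)
  expect_length(rep2$removed_far, 0)
  expect_length(rep2$removed_graph_change, 0)
})

proton_transfer_fixture <- function() {
  cf <- curation_fixture()
  pt <- cf$a
  # shove the methanol hydroxyl proton (ligand atom 3) next to the water O
  wO <- pt$protein$coords[1, ]
  dirH <- unit(pt$ligand$coords[2, ] - wO)  # from water O toward methanol O
  pt$ligand$coords[3, ] <- wO + 0.99 * dirH
  c(cf, list(pt = pt))
}

test_that("proton transfers are detected and recaptured at the reference bond length", {
  cf <- proton_transfer_fixture()
  det <- detect_proton_transfer(cf$pt)
  expect_equal(nrow(det), 1)
  expect_identical(det$from, "ligand")
  rep <- filter_optimized(list(cf$pt), cf$mono_P, cf$mono_L, cf$sites)
  expect_length(rep$proton_transfers, 1)
  expect_length(rep$kept, 0)
  # recapture restores the donor O-H bond to the reference length
  rc <- recapture_proton(cf$pt, cf$mono_P, cf$mono_L)
  ref_len <- vnorm(cf$fx$ligand_monomers$methanol$coords[3, ] -
                     cf$fx$ligand_monomers$methanol$coords[2, ])
  got_len <- vnorm(rc$ligand$coords[3, ] - rc$ligand$coords[2, ])
  expect_lt(abs(got_len - ref_len), 1e-6)
  expect_true(isTRUE(rc$recaptured))
  # heavy atoms untouched
  expect_equal(rc$ligand$coords[-3, ], cf$pt$ligand$coords[-3, ])
  expect_equal(rc$protein$coords, cf$pt$protein$coords)
  # the detector no longer fires on the recaptured structure
  expect_equal(nrow(detect_proton_transfer(rc)), 0)
  # identity on a configuration without transfer
  same <- recapture_proton(cf$a, cf$mono_P, cf$mono_L)
  expect_equal(same$ligand$coords, cf$a$ligand$coords)
})

test_that("transfers classify as standard, nonstandard or discarded", {
  cf <- proton_transfer_fixture()
  fx <- cf$fx
  base_registry <- c(fx$protein_monomers, fx$ligand_monomers)
  # water + H+ -> hydronium; methanol - H+ -> methoxide. Neither is in the
  # standard inventory: nonstandard.
  expect_identical(classify_transfer(cf$pt, base_registry), "nonstandard")
  # with synthetic hydronium / methoxide entries registered, the pair becomes
  # a standard dimer
  hyd <- monomer("hydronium", c("O", "H", "H", "H"),
                 rbind(c(0, 0, 0), c(0.98, 0, 0), c(-0.3, 0.93, 0),
                       c(-0.3, -0.4, 0.85)),
                 charge = 1L, set = "protein")
  met <- monomer("methoxide", fx$ligand_monomers$methanol$elements[-3],
                 fx$ligand_monomers$methanol$coords[-3, ],
                 charge = -1L, set = "ligand")
  expect_identical(classify_transfer(cf$pt, c(base_registry,
                                              list(hyd = hyd, met = met))),
                   "reassigned-standard")
  # a rule can discard the species outright
  reject_all <- function(species) TRUE
  expect_identical(classify_transfer(cf$pt, base_registry,
                                     rules = list(reject_all)), "discarded")
  expect_error(classify_transfer(cf$a, base_registry), "no proton transfer")
})

test_that("the amide rule flags a deprotonated amide nitrogen donor", {
  fx <- fixtures()
  # acetamide N-H proton transferred onto a water: donor species is the
  # deprotonated amide
  mono_P <- fx$protein_monomers$acetamide
  mono_L <- fx$ligand_monomers$methanol
  sP <- find_site(fx$protein_sites, "acetamide", "HBD")
  sL <- find_site(fx$ligand_sites, "methanol", "HBA")
  cfg <- cartesian_from_internal(mono_P, mono_L, sP, sL,
                                 internal_coords(2.6, 170, 0, 120, 0, 0),
                                 site_dimer_id = "am", index = 1L)
  # move the amide H (atom 5, on N) next to the methanol O (ligand atom 2)
  lO <- cfg$ligand$coords[2, ]
  dirN <- unit(cfg$protein$coords[3, ] - lO)
  cfg$protein$coords[5, ] <- lO + 0.99 * dirN
  det <- detect_proton_transfer(cfg)
  expect_equal(nrow(det), 1)
  expect_identical(classify_transfer(cfg, c(fx$protein_monomers,
                                            fx$ligand_monomers)),
                   "discarded")
})
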