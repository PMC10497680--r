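test_that("heavy RMSD handles identity, reflection and symmetry permutations", {
  fx <- fixtures()
  cfg <- wm_config()
  expect_lt(heavy_rmsd(cfg, cfg), 1e-12)
  # mirror image is recovered only with reflections allowed
  mir <- cfg
  mir$protein$coords[, 1] <- -mir$protein$coords[, 1]
  mir$ligand$coords[, 1] <- -mir$ligand$coords[, 1]
  expect_lt(heavy_rmsd(cfg, mir, allow_reflection = TRUE), 1e-8)
  # formate's two oxygens are graph-equivalent: swapping them is recognized
  # only with the symmetry maps
  fcfg <- cartesian_from_internal(
    fx$protein_monomers$formate, fx$ligand_monomers$methane,
    find_site(fx$protein_sites, "formate", "general"),
    find_site(fx$ligand_sites, "methane", "general"),
    internal_coords(4, 90, 0, 90, 0, 0), site_dimer_id = "fm", index = 1L)
  swapped <- fcfg
  swapped$protein$coords <- fcfg$protein$coords[c(1, 3, 2, 4), ]
  maps <- dimer_symmetry_maps(fx$protein_monomers$formate,
                              fx$ligand_monomers$methane)
  expect_gt(length(maps), 1)
  expect_lt(heavy_rmsd(fcfg, swapped, symmetry_maps = maps), 1e-8)
  bad <- fcfg
  bad$ligand$elements <- c(bad$ligand$elements, "C")
  bad$ligand$coords <- rbind(bad$ligand$coords, c(9, 9, 9))
  expect_error(heavy_rmsd(fcfg, bad), "mismatch")
})

test_that("heavy RMSD equals an exhaustive permutation x reflection oracle", {
  fx <- fixtures()
  maps <- dimer_symmetry_maps(fx$protein_monomers$formate,
                              fx$ligand_monomers$methane)
  set.seed(41)
  mk <- function() cartesian_from_internal(
    fx$protein_monomers$formate, fx$ligand_monomers$methane,
    find_site(fx$protein_sites, "formate", "general"),
    find_site(fx$ligand_sites, "methane", "general"),
    internal_coords(runif(1, 3, 6), runif(1, 20, 160), runif(1, -170, 170),
                    runif(1, 20, 160), runif(1, -170, 170), runif(1, -170, 170)))
  for (i in 1:10) {
    a <- mk(); b <- mk()
    ha <- config_heavy(a); hb <- config_heavy(b)
    oracle <- Inf
    for (p in maps) for (refl in c(FALSE, TRUE)) {
      oracle <- min(oracle, kabsch_fit(ha$coords[p, , drop = FALSE], hb$coords,
                                       allow_reflection = refl)$rmsd)
    }
    expect_equal(heavy_rmsd(a, b, allow_reflection = TRUE, symmetry_maps = maps),
                 oracle, tolerance = 1e-10)
  }
})

test_that("greedy maximin equals the exhaustive greedy oracle", {
  # 1D toy from the selection rule: S = {0}, R = {1, 5, 6}, k = 2 additions;
  # first add 6 (distance 6), then the tie between 1 and 5 (both at min
  # distance 1) goes to the lower ordinal, i.e. the point 1
  x <- c(0, 1, 5, 6)
  D <- as.matrix(dist(x))
  got <- maximin_select(D, R_idx = 2:4, S_idx = 1, k = 3)
  expect_equal(got, c(4L, 2L))
  # k <= |S|: nothing added
  expect_length(maximin_select(D, R_idx = 2:4, S_idx = 1, k = 1), 0)
  # empty S: seeded with the first candidate in deterministic order
  expect_equal(maximin_select(D, R_idx = c(3L, 2L), S_idx = integer(0), k = 2)[1], 3L)
  # oracle equivalence on random pools up to 20
  oracle_greedy <- function(D, R, S, k) {
    added <- integer(0)
    if (length(S) == 0 && length(R) > 0 && k > 0) {
      added <- R[1]; S <- R[1]; R <- R[-1]
    }
    while (length(S) < k && length(R) > 0) {
      best <- NA_integer_; best_d <- -Inf
      for (r in R) {  # ties resolved to the earliest candidate
        d <- min(D[r, S])
        if (d > best_d) { best_d <- d; best <- r }
      }
      added <- c(added, best); S <- c(S, best); R <- setdiff(R, best)
    }
    added
  }
  set.seed(43)
  for (i in 1:300) {
    n <- sample(2:20, 1)
    # small integer coordinates force frequent exact ties
    D <- as.matrix(dist(sample(0:6, n, replace = TRUE)))
    ns <- sample(0:(n - 1), 1)
    S <- if (ns > 0) sample(n, ns) else integer(0)
    R <- setdiff(seq_len(n), S)
    k <- sample.int(n, 1)
    expect_identical(maximin_select(D, R, S, k), oracle_greedy(D, R, S, k))
  }
})

make_batches <- function(fx, n_per = 6, seed = 50) {
  mono_P <- fx$protein_monomers$water
  mono_L <- fx$ligand_monomers$methanol
  ids <- list(
    c("water", "general", "methanol", "general", "neutral/neutral", "general/general"),
    c("water", "HBD", "methanol", "HBA", "neutral/neutral", "pHBD/lHBA"))
  sites <- list(); batches <- list()
  set.seed(seed)
  for (d in ids) {
    sP <- find_site(fx$protein_sites, d[1], d[2])
    sL <- find_site(fx$ligand_sites, d[3], d[4])
    id <- paste(sP$id, sL$id, sep = "|")
    sites[[id]] <- list(P = sP, L = sL)
    batches[[id]] <- generate_batch(mono_P, mono_L, sP, sL,
                                    radial_spec_for(d[5], d[6]),
                                    surrogate_backend(), n = n_per,
                                    site_dimer_id = id)
  }
  list(batches = batches, sites = sites, mono_P = mono_P, mono_L = mono_L)
}

test_that("start sets seed on negative minima and top up by diversity", {
  fx <- fixtures()
  mb <- make_batches(fx)
  ss <- select_starts(mb$batches, mb$mono_P, mb$mono_L, mb$sites)
  # neutral dimer with 2 site dimers: up to 5 per site dimer, plus any
  # supplementation triggered by far (r_PL > 3.6 A) members
  expect_gte(length(ss$members), 5)
  expect_lte(sum(ss$provenance != "supplemental"), 10)
  if (any(ss$provenance == "supplemental"))
    expect_true(any(ss$r_PL > 3.6))
  expect_true(all(ss$provenance %in% c("energy-seeded", "diversity-selected",
                                       "supplemental")))
  # no duplicate members
  ids <- vapply(ss$members, function(m)
    paste(m$site_dimer_id, m$index, sep = "#"), character(1))
  expect_false(any(duplicated(ids)))
  # deterministic for fixed inputs
  ss2 <- select_starts(mb$batches, mb$mono_P, mb$mono_L, mb$sites)
  expect_identical(ss$provenance, ss2$provenance)
  expect_identical(ids, vapply(ss2$members, function(m)
    paste(m$site_dimer_id, m$index, sep = "#"), character(1)))
})

test_that("step 1 is skipped when every candidate energy is positive", {
  fx <- fixtures()
  mb <- make_batches(fx, n_per = 4)
  # overwrite all stored energies with positive totals
  for (id in names(mb$batches))
    mb$batches[[id]] <- lapply(mb$batches[[id]], function(cfg) {
      cfg$energies <- list(energy_record(5, 5, 0, 0, 0))
      cfg
    })
  ss <- select_starts(mb$batches, mb$mono_P, mb$mono_L, mb$sites)
  expect_false("energy-seeded" %in% ss$provenance)
  expect_true(all(ss$provenance == "diversity-selected"))
})

test_that("like-charged dimers yield empty start sets, small pools are returned whole", {
  fx <- fixtures()
  ss <- select_starts(list(), fx$protein_monomers$sodium,
                      fx$ligand_monomers$methylammoniumL, list())
  expect_length(ss$members, 0)
  # pool smaller than 5: the whole pool comes back
  mb <- make_batches(fx, n_per = 2)
  one <- mb$batches[1]
  ss2 <- select_starts(one, mb$mono_P, mb$mono_L, mb$sites)
  expect_length(ss2$members, 2)
})

test_that("charged dimers select over the union of site dimers", {
  fx <- fixtures()
  mono_P <- fx$protein_monomers$methylammonium
  mono_L <- fx$ligand_monomers$formateL
  pairs <- list(
    list(P = find_site(fx$protein_sites, "methylammonium", "general"),
         L = find_site(fx$ligand_sites, "formateL", "general")),
    list(P = find_site(fx$protein_sites, "methylammonium", "HBD"),
         L = find_site(fx$ligand_sites, "formateL", "HBA")))
  sites <- list(); batches <- list()
  set.seed(51)
  for (p in pairs) {
    id <- paste(p$P$id, p$L$id, sep = "|")
    sites[[id]] <- p
    batches[[id]] <- generate_batch(mono_P, mono_L, p$P, p$L,
                                    radial_spec_for("opposite-charged",
                                                    "general/general"),
                                    surrogate_backend(), n = 4,
                                    site_dimer_id = id)
  }
  ss <- select_starts(batches, mono_P, mono_L, sites)
  # union mode: 5 total (not 5 per site dimer), plus any step-1 seeds
  expect_gte(length(ss$members), 5)
  expect_lte(length(ss$members), 5 + length(batches))
})
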