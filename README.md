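# dimergen

Quantum-chemistry datasets of noncovalent interaction energies are built from
enormous numbers of *dimer configurations*: two rigid monomers posed against
each other at controlled separations and orientations, each configuration
later labelled with an interaction energy (e.g. a SAPT0 decomposition into
electrostatic, exchange, induction and dispersion components). `dimergen`
implements the configuration-generation and curation machinery for such
datasets, aimed at protein–ligand fragment interactions:

* **Interaction sites.** Each monomer carries one or more sites — a triple of
  noncollinear points (A, B, C), a category (general, hydrogen-bond donor
  HBD, acceptor HBA, Lewis base LB, Lewis acid LA) and allowed angular
  ranges. Rule-based site perception drafts sites for new monomers;
  curated site files take precedence.
* **Pairing.** Protein-set sites are paired with ligand-set sites under five
  class rules (general×general, HBD×HBA, HBA×HBD, LB×LA, LA×LB), giving
  *interaction-site dimers* that aggregate into *molecular dimers* (unique
  monomer pairs), with charge-stratified count tables.
* **Placement.** Six intermolecular internal coordinates
  (r_PL, θ_P, τ_P, θ_L, τ_L, τ_PL) relate the two site frames. The
  radial coordinate actually sampled is the **van der Waals separation**

      r = min over p∈P, l∈L of ( r_pl − r_vdW,p − r_vdW,l ),

  the closest approach of the two vdW surfaces (negative at clash). A
  bracketing/bisection solver translates the ligand along the A_P–A_L vector
  until the separation hits its target.
* **Sampling.** Angles are drawn uniformly within each site's allowed
  interval unions; r is drawn from a biased density — uniform on
  [r_min, r_switch], decreasing linearly to zero at r_max — with class-specific
  bounds. Every atom is then perturbed by ≤ 0.1 Å. Configurations whose total
  energy exceeds 20 kcal/mol (200 for like-charged pairs) are rejected, and
  the next attempt draws r from [r_min, r_rejected + 0.1·k] after the k-th
  consecutive failure, so low-r coverage is not silently lost.
* **Selection.** For each molecular dimer, optimization starting points are
  the lowest-energy configuration of each site dimer (if negative) topped up
  by greedy maximin heavy-atom RMSD (symmetry- and reflection-aware) to at
  least five members.
* **Curation.** Optimized structures are filtered for redundancy
  (RMSD < 0.1 Å), excessive separation (r_PL > 3.6 Å) and heavy-atom
  bond-graph changes; simple proton transfers are recaptured by returning the
  proton to its donor at the reference bond length and classified against the
  standard-dimer registry.
* **I/O.** Reads/writes the Splinter `.xyz` dialect (25-field metadata line:
  title, three charges, 20 energy slots, monomer-1 atom count), the
  11-token underscore filename convention, the
  `random`/`opt_raw`/`opt_perturb` directory tree, and SD files for monomers
  and sites.

The energy backend is a pluggable contract (`dimer_config -> energy_record`);
a classical Coulomb + Lennard-Jones surrogate ships with the package so the
whole pipeline runs and is testable at desk scale without any quantum
chemistry.

## Worked example

```r
library(dimergen)

fx <- make_fixtures()          # deterministic toy protein/ligand sets
fx
#> <fixture set: 6 protein / 10 ligand monomers, 21 / 28 sites>

sd <- enumerate_site_dimers(fx$protein_sites, fx$ligand_sites,
                            fx$protein_monomers, fx$ligand_monomers)
table(sd$pair_class)
#> general/general       pHBA/lHBD       pHBD/lHBA         pLA/lLB         pLB/lLA
#>              50              24              35              10               6
nrow(aggregate_molecular(sd))
#> [1] 56

water  <- fx$protein_monomers$water
meoh   <- fx$ligand_monomers$methanol
site_w <- Filter(function(s) s$monomer == "water"    && s$category == "HBD",
                 fx$protein_sites)[[1]]
site_m <- Filter(function(s) s$monomer == "methanol" && s$category == "HBA",
                 fx$ligand_sites)[[1]]

set.seed(1)
batch <- generate_batch(water, meoh, site_w, site_m,
                        radial_spec_for("neutral/neutral", "pHBD/lHBA"),
                        surrogate_backend(), n = 5)
batch[[1]]$target_internal
#> <internal coords: r_PL=2.1577 A, theta_P=172.85, tau_P=-74.16, theta_L=109.75,
#>                   tau_L=-27.68, tau_PL=-48.04 deg, r=-0.5423 A>
batch[[1]]$energies[[1]]
#> <surrogate energy: total -2.3569 (elst -3.9587, exch 3.8580, ind 0.0000,
#>                    disp -2.2563) kcal/mol>
```

The water HBD site restricts θ_P to [90°, 180°], so the donor O–H points at
the acceptor (here θ_P ≈ 173°); the sampled vdW separation of −0.54 Å is a
mild surface interpenetration typical of a hydrogen bond, and the surrogate
scores the pose favourably at −2.36 kcal/mol. `run_generate()` wraps the
whole loop — enumeration, batches, dataset tree, manifests and count tables —
for a fixture set or user-supplied SD inputs.

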