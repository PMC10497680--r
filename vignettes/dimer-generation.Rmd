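---
title: "Generating and curating rigid-body dimer configurations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and curating rigid-body dimer configurations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimergen)
```

## The problem

Machine-learned models of noncovalent interactions are trained on large sets
of dimer configurations — two small rigid molecules posed against each other —
each labelled with a quantum-chemical interaction energy. The value of such a
set depends almost entirely on *where* on the potential energy surface the
configurations sit: random poses drift to large separations where every
energy is near zero, while naive close-contact sampling produces mostly
violently repulsive structures. `dimergen` implements a placement and
sampling scheme that concentrates configurations in the chemically
informative band around van der Waals contact, plus the bookkeeping that
surrounds it: site-based pairing, diverse selection of optimization starting
points, post-optimization curation, and a round-trippable file dialect.

## The coordinate model

A monomer is rigid: its internal geometry never changes. An *interaction
site* on a monomer is three noncollinear points A, B, C (not necessarily
atoms) plus a category and allowed angular ranges. Given one protein-side and
one ligand-side site, six internal coordinates fix the relative pose:

* `r_PL` — the A_P–A_L distance;
* `theta_P` = angle(B_P, A_P, A_L) and `theta_L` = angle(B_L, A_L, A_P);
* `tau_P` = dihedral(C_P, B_P, A_P, A_L), `tau_L` = dihedral(C_L, B_L, A_L, A_P),
  and `tau_PL` = dihedral(B_P, A_P, A_L, B_L).

`cartesian_from_internal()` keeps the protein monomer in its input frame and
places the ligand by natural-extension construction of the target A/B/C
triple followed by an exact rigid map; `internal_from_cartesian()` inverts
it. The round trip closes to ~1e-12 in practice (the tests assert 1e-8 over
10^4 random poses). Which monomer stays fixed is a pure convention — energies
are frame-invariant, file coordinates are not — and the protein frame was
chosen; users comparing raw coordinates against other datasets should expect
an overall rigid motion.

The radial quantity that is actually *sampled* is not `r_PL` but the van der
Waals separation `r`: the minimum over intermolecular atom pairs of centre
distance minus both vdW radii. Unlike `r_PL`, `r` has the same physical
meaning for every monomer pair regardless of size and shape, so one set of
bounds covers the whole inventory. Radii are the Alvarez values with sodium
reduced to 1.50 Å: with the published 2.50 Å value, sodium complexes sample
an `r` axis shifted by about 1 Å relative to every other cation, and the
radii exist here only to make sampling consistent — they never enter the
energies. `solve_translation()` converts a target `r` into `r_PL` by sliding
the ligand along the A_P–A_L vector: the min-over-pairs separation is
1-Lipschitz in the translation and monotone on the outer approach branch, so
a derivative-free inward scan plus bisection (tolerance 1e-6 Å) is robust to
the function's piecewise-smooth kinks, and the largest-`r_PL` root is taken
so poses always lie on the physically approachable side. Targets below the
deepest achievable clash raise a typed condition that the sampler treats as
"resample", not as an energy rejection.

## Sites, pairing and counts

Site categories follow fixed perception rules (`perceive_sites()`): HBD on
every H bound to N/O/S or sp-carbon; HBA on every O and on N except
positively charged or π-conjugated trivalent N; LB on F, carbonyl O,
monocyclic-heterocycle N, alkylamine N and N-oxide O; LA on aryl Cl/Br,
aromatic S (one site per adjacent atom when the ring is asymmetric) and
carbonyl C; and one general site per monomer anchored at the heavy-atom
centroid. Perception is a convenience for fixtures and new monomers — curated
site files, which in real inventories encode a good deal of hand tuning,
always take precedence. Hybridization is inferred geometrically (a
two-coordinate carbon with bond angle above 175° counts as sp), because a
deterministic geometric test needs no electronic-structure input. B and C
default to bonded neighbours with the lowest atom indices, falling back to
any non-collinear atom; monoatomic ions get synthetic B/C points offset along
the axes.

Restricted angular defaults keep the specific sites near their productive
geometries without over-constraining them: θ ∈ [90°, 180°] for all HBD sites
and for carbonyl HBA sites, and τ within ±45° of the carbonyl plane
(the union [−45°, 45°] ∪ [135°, 225°]) for carbonyl LB sites. τ intervals are
normalized into (−180°, 180°], splitting at the branch cut, and sampling is
length-weighted across the intervals of a union. `tau_PL` is always
unrestricted.

Pairing is hard-coded to five class products — general×general, pHBD×lHBA,
pHBA×lHBD, pLB×lLA, pLA×lLB — and nothing else; other chemically conceivable
pairings are rejected by construction. Site dimers aggregate to molecular
dimers (unique monomer pairs), and `charge_count_table()` reproduces the
neutral/cation/anion stratification used to report inventory sizes. Site
dimers are sorted deterministically (monomer names, class, site ids) so batch
ordinals, and hence per-dimer random substreams, are reproducible.

## Radial bias and energy rejection

`sample_r()` draws from a density constant on [r_min, r_switch] and
decreasing linearly to zero at r_max (inverse-CDF, closed form). The default
bounds depend only on the charge classes and on whether the site pair is
general or specific; specific (HBD/HBA, LB/LA) pairs are allowed ~0.3–0.6 Å
deeper clash because their attractive wells survive closer approach, and
like-charged pairs start at r_min = 0 since they never clash favourably.

Accepted configurations must have total energy ≤ 20 kcal/mol (≤ 200 for
like-charged pairs, whose electrostatic floor is high everywhere). Rejection
almost always means deep clash, so resampling from the full radial range
would bias the set away from low `r`. Instead the retry chain truncates the
radial density: after the k-th consecutive failure the next draw comes from
[r_min, r_first_rejected + 0.1·k] (renormalized; plain truncation also below
r_switch), and the range resets on acceptance. The anchor is the *first*
rejected `r` of the chain, which reproduces the published retry bounds
literally. "A batch of 50" is interpreted as 50 *accepted* configurations;
rejected attempts are replaced, not counted. Angular draws are uniform in the
angle value, not solid-angle uniform — the sampled quantities are the
coordinates themselves — and every atom of an accepted pose is perturbed by a
uniformly oriented displacement of uniform magnitude ≤ 0.1 Å, with
pre-perturbation coordinates kept in provenance because filenames encode the
sampled (unperturbed) parameters.

Randomness uses R's Mersenne-Twister; `run_generate()` seeds an integer
substream per site dimer derived from the run seed and the dimer's ordinal,
so batches are independent of generation order and bit-reproducible for a
fixed seed.

## The energy backend and its surrogate

The pipeline only requires a function `dimer_config -> energy_record`, where
a record carries total, electrostatic, exchange, induction and dispersion
components in kcal/mol (20 labelled slots per configuration in the file
dialect: two basis sets × scaled/unscaled × five values; Hartree/kcal
conversion 627.509474 applied only at the dataset-tree boundary). The bundled
surrogate is a classical pairwise model over intermolecular atom pairs:
Coulomb electrostatics from authored partial charges (constant 332.0637
kcal·Å/(mol·e²)), a 12-power repulsion reported as "exchange", a −6-power
attraction reported as "dispersion" (ε·((r_m/r)^12 − 2(r_m/r)^6), minimum −ε
at r_m, Lorentz–Berthelot combination) and zero induction. It is not a
force field fit — its job is to be cheap, smooth, and to exhibit the
qualitative features the sampler interacts with: a repulsive wall, a well
near vdW contact, and decay to zero. Stub backends (constant, scripted) drive
the rejection-schedule tests deterministically. For charged dimers the
interaction-range diagnostics use the non-electrostatic sum
(exchange + induction + dispersion), since a bare Coulomb tail between net
charges would not fall below 1 kcal/mol until several hundred Å.

## Start selection and curation

For each molecular dimer not involving like charges (those are excluded —
optimization would just drive the monomers apart), the starting set is seeded
with each site dimer's minimum-energy configuration provided that minimum is
negative, then topped up by greedy maximin over symmetry- and
reflection-aware heavy-atom RMSD: per site dimer (target 5 each) for
all-neutral dimers, once over the union (target 5 total) otherwise. Ties in
the maximin argmax go to the lowest candidate ordinal; seeds count toward the
per-unit quota; a pool smaller than the quota is returned whole. Members at
r_PL > 3.6 Å are kept (never removed), but the set is supplemented until at
least five members sit at r_PL < 3.2 Å, because nearly-separated starts tend
to stall on flat parts of the surface. Symmetry permutations come from the
element-coloured bond-graph automorphism group, enumerated by closure over
igraph's generators and capped at 10,000 per monomer with a warning.

Post-optimization curation applies three filters in a fixed order —
redundancy (heavy-atom RMSD < 0.1 Å to an earlier-kept structure, first kept
wins), separation (r_PL > 3.6 Å), then per-monomer heavy-atom graph
comparison — with redundancy first simply because it is the cheapest way to
shrink the set before graph work. Bonds are perceived as distance <
covalent-radius sum + 0.4 Å, and graphs compare as element-coloured
isomorphism with bond orders, stereochemistry and charges deliberately
ignored; only graph *equality* matters, so an external connectivity
perception tool would add dependencies without changing answers. Skeleton
changes are removed; a hydrogen whose nearest heavy atom crossed monomers
with both heavy graphs intact is a simple proton transfer. Such structures
are recaptured by placing the proton back along the current donor→H direction
at the reference donor–H bond length — heavy atoms untouched, result flagged
as not a gas-phase minimum. This purely geometric restoration replaces the
hydrogen-only molecular-mechanics relaxation used in the original protocol;
that is a known fidelity gap, acceptable because recaptured structures are
marked and never presented as minima. Transfers are then classified against
the standard-monomer registry (element-coloured graph + hydrogen count +
formal charge on both sides): reassigned-standard, nonstandard, or discarded
when a rejection rule flags an implausible species (the shipped default
flags a deprotonated amide nitrogen; the rule list is user-editable, standing
in for manual inspection).

The curation separation filter reuses r_PL measured from the originating
site dimer's mapped points. Whether the published > 3.6 Å curation cutoff was
measured as r_PL or as closest contact is not stated; r_PL was chosen for
consistency with the start-selection rule, and this remains an open point
rather than a settled fact.

## File dialect

Records are standard `.xyz` with a 25-field comma-separated metadata line
(title; total, monomer-1 and monomer-2 charges; 20 energy slots in kcal/mol —
jun then aug basis, unscaled then scaled, total/elst/exch/ind/disp; monomer-1
atom count). Missing energies are empty fields, keeping the line parseable.
Coordinates print at 6 decimals and energies at 8 significant digits, which
makes write→read→write byte-identical. Filenames join eleven items with
underscores — protein name, protein site type, ligand name, ligand site type,
index, r, θ_P, τ_P, θ_L, τ_L, τ_PL — with r at one decimal and angles as
integer degrees by default (the deposited convention prints no example, so
precision is configurable); names must be alphanumeric, enforced via a fixed
substitution map (e.g. "(" → "x"). The dataset tree holds one directory per
molecular dimer with `random`, `opt_raw` and `opt_perturb` subdirectories,
omitted when empty, plus a JSON energy table per dimer keyed by filename with
the two basis-set labels and unscaled totals in Hartrees.

## The fixture set, and what passing tests do and do not show

`make_fixtures()` authors a deterministic toy inventory: six protein-side
monomers (water; an amide mimic defined *without* a general site; methylammonium;
formate; Na⁺; Cl⁻) and ten ligand-side monomers (methanol, formaldehyde,
methylamine, fluoromethane, methane, ethane, plus methylammonium, formate,
Na⁺ and Cl⁻ relabelled into the ligand set). Geometries are idealized
z-matrix constructions (standard bond lengths and angles), treated by the
pipeline as optimized monomers; partial charges are authored per atom and sum
to the formal charges. The set covers all three charge states on both sides,
all five site categories, every charge-class row of the radial-bounds table,
and the pairing edge case of a general-less monomer against general-only
partners (methane, ethane and the two ligand ions carry only general sites).

The fixtures emulate the *structure* of a real fragment inventory, not its
chemistry: geometries are not QM-optimized, charges are not fitted, and the
surrogate is not a trained potential. Tests passing on fixtures therefore
demonstrate the correctness of the combinatorics, geometry, sampling laws,
selection and curation logic — not that the surrogate energies resemble
SAPT0 values, and not that perception reproduces any hand-curated site file.
Published inventory counts are reproduced exactly from abstract site tables
(category counts by charge state and the exclusion structure are sufficient;
the per-monomer distribution within a charge class provably does not affect
the pair counts).

## Problem sizes and numerical choices

Default test and acceptance runs use deliberately modest sizes chosen as the
smallest that make the statistical assertions sharp: 10^4 round-trip poses,
10^5 radial draws (the 2/3 below-switch fraction is tested at 3 binomial σ;
the full density by χ² over 40 bins at α = 0.01), 10^3 greedy-selection
trials on pools ≤ 20, batches of a few configurations per site dimer in
end-to-end runs. Other numerical choices: bisection tolerance 1e-6 Å;
site-point noncollinearity tolerance 1e-8 (relative); dihedrals follow the
IUPAC right-hand sign convention; angles are stored in degrees and
coordinates in Å throughout; degenerate radial specs collapse gracefully
(r_switch = r_max gives the uniform law, r_min = r_max a point mass).

## Known limitations

* No QM backend ships with the package; the adapter surface is the energy
  contract, and SAPT0 labels are carried as data, never computed.
* Proton-transfer recapture is geometric only (no hydrogen relaxation).
* Site perception is a best-effort reconstruction of stated rules; real
  inventories hand-tune site points and ranges per monomer.
* Monomers are strictly rigid; no conformer enumeration or flexible-torsion
  sampling.
* The amide-anion rejection rule is a single shipped example of what was a
  manual-inspection step; real use should extend the rule list.
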