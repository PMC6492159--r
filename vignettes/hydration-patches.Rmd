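---
title: "Predicting protein binding interfaces from hydration patches and docking-pose triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein binding interfaces from hydration patches and docking-pose triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydropatch)
```

## The problem

Where on a protein surface will another protein bind? `hydropatch`
implements two independent computational answers for the case of a
small adaptor protein (GABARAP, the ligand) binding the intracellular
domain of a pentameric ion channel (the GABA-A receptor, the receptor),
and the machinery generalises to any ligand/receptor pair:

1. **Docking-pose triage.** A flexible-docking server produces hundreds
   of candidate rigid placements per ligand conformer. The package
   transfers each pose into a common receptor frame, rejects poses that
   clash sterically with the full receptor, keeps poses whose interface
   contains residues implicated by NMR and two-hybrid experiments, and
   finally applies a median-split selection over seven score and
   contact metrics. The survivors are summarised as a C-alpha RMSD
   matrix and a contact-pair frequency table.

2. **Hydration patches.** Water near a surface that is *easily
   desolvated* marks a favourable binding footprint. From an ensemble
   of water positions around the fixed solute the package identifies
   discrete hydration sites, scores each with an inhomogeneous fluid
   solvation theory (IFST) free energy, removes sites inside the ion
   channel lumen and near the membrane, and then runs an exact
   combinatoric search for the connected clusters of 7–18 sites with
   the lowest total displacement cost. The union of the best clusters,
   split into connected components ("clustering of clusters"), gives
   hydration *patches* — candidate binding footprints. Repeating the
   search after removing patch sites yields multiple passes ranked by
   displaceability.

Both analyses are driven by synthetic data with planted ground truth,
so every stage is testable without external downloads; the generator is
first-class, seeded, and bit-reproducible.

## Structures, conformers, and atom properties

PDB input goes through `read_models()` (one structure per `MODEL`
block; alternate locations and occupancies preserved) and
`expand_altlocs()`, which expands residues with alternative side-chain
conformations combinatorially: three dual-altloc residues give
$2^3 = 8$ conformers, labelled `aaa` … `bbb`. An NMR ensemble of 15
models plus those 8 X-ray conformers yields the 23 coordinate sets a
docking campaign would use.

`assign_atom_properties()` attaches van der Waals radii (Bondi by
default — the docking server's own convention is unpublished, so the
table is a configuration choice, and results sensitive to it should be
reported with the table name) and flags hydrophobic heavy atoms.
"Hydrophobic" is defined here as the heavy atoms of carbon and sulfur;
this rule is deliberately simple and configurable, since no standard
definition exists at atom level.

## Dock triage

A **contact** is an inter-structure heavy-atom pair closer than the sum
of the two vdW radii plus 20% (`atomic_contacts()`, strict `<`); a
**clash** is any atom pair closer than 1 Å (`steric_clash()`, strict
`<`). The triage (`select_docks()`) proceeds in the order

1. clash rejection,
2. interface criteria: all required ligand residues (defaults Lys 46,
   Val 51, Phe 60) at the interface, plus at least one receptor residue
   from each of two groups (defaults 425–429 and 433–442),
3. median-split selection on the surviving candidate set: the docking
   energy must lie in the favourable half of the candidate
   distribution and six contact-count metrics in the upper half.

Medians use the lower order statistic $x_{(\lceil n/2 \rceil)}$
(deterministic for even $n$) and ties are inclusive — a value equal to
its median counts as in the favourable half, which keeps "all seven
criteria met" achievable with small discrete counts. Contact counts
default to contacting atom *pairs* (a stricter, order-free reading than
distinct atoms; `count = "atoms"` switches). `contact_pair_table()`
reports residue pairs with more than `min_atoms` contacts per pose in
at least `min_freq` poses, as `"k/N"` frequencies.

`ca_rmsd_matrix()` compares selected poses in the common receptor frame
*without* re-fitting, because the poses share one receptor placement;
`refit = TRUE` exposes the alternative reading. Superposition itself is
a standard SVD Kabsch fit (`kabsch_fit()`), reflection-free, verified
in the tests against an independent quaternion-method oracle.

```{r dock-example}
ds <- make_dock_set(40, fraction_good = 0.2, fraction_clash = 0.2,
                    seed = 4)
sel <- select_docks(ds$poses)
c(no_clash = length(sel$no_clash), primary = length(sel$primary),
  selected = length(sel$selected))
head(contact_pair_table(sel$selected, min_atoms = 3,
                        min_freq = length(sel$selected)), 3)
```

## Hydration sites

`pick_sites()` histograms water-oxygen positions on a cubic grid
(default 0.5 Å — the granularity of the hydration-site literature; the
original site-picking method's estimator is unpublished, so the grid is
a declared stand-in) and picks sites greedily from the densest voxel
downward. The site centre is refined to the mean oxygen position within
the 1.2 Å site radius of the voxel, no site is accepted within 2.4 Å
of an existing one, ties between equal-density voxels break
lexicographically on (z, y, x), and picking stops below a relative
density of 1 (bulk). Sites whose sphere would leave the sampled box are
skipped: a clipped sphere has biased density and position statistics.
Each site carries density (relative to bulk), occupancy (fraction of
frames with a water in the sphere), and distances to the nearest heavy
and nearest hydrophobic heavy solute atoms.

## IFST site thermodynamics

For each site, `score_sites()` computes

$$\Delta G_{hyd} = \Delta E - T\,(\Delta S_{trans} + \Delta S_{orient}),
\qquad \text{cost} = -\Delta G_{hyd}$$

* $\Delta E$: mean interaction energy of the site's water (solute
  Lennard-Jones/Coulomb + any potential wells + **half** the
  water–water energy, the standard IFST bookkeeping against double
  counting) minus the same mean over a bulk reference region — waters
  farther than 8 Å from any solute heavy atom or potential well,
  where site free energies have decayed to zero.
* $\Delta S_{trans}$: minus the Kullback–Leibler divergence of the site
  water positions against the uniform distribution over the site
  sphere, estimated with a first-nearest-neighbour
  (Kozachenko–Leonenko) differential entropy. The reference entropy is
  computed on a *matched-size* uniform sample with a private seeded RNG
  stream, so the estimator bias cancels exactly: uniform water scores
  ~0, localised water scores negative.
* $\Delta S_{orient}$: the same construction over water orientations
  (quaternion metric with antipodal identification, isotropic
  reference). Frozen orientations score strongly negative.

The estimators need at least 50 in-sphere samples (configurable);
undersampled sites are reported as `NA` rather than guessed. All
in-sphere waters are used (not, say, the nearest to the centre, whose
conditional distribution would be biased inward). Temperature defaults
to 300 K.

Two sign conventions coexist in the field's tables — favourable
hydration free energies (negative) and positive displacement prices.
Both conventions cannot be reconstructed from one another's
publications without the original scripts, so the package always
reports **both** `dG_hyd` and `displacement_cost` and ranks patches by
ascending cost (easiest-to-desolvate first).

### Selection effects worth knowing about

Sites are picked at density maxima of the same frames they are scored
on. At 2000 frames the residual selection bias on bulk-like sites is
well below one standard error, but for short ensembles
`ens_subset()` supports split-sample scoring (pick on one half,
score on the other), which removes the bias entirely.

## Channel and membrane geometry filters

With the pore axis along z, `fit_channel_midplane()` converts heavy
atoms to cylindrical coordinates and least-squares fits
$r(z) = az^2 + bz + c$ over all atoms (equivalent to angle-averaging
under uniform angular sampling; a binned-by-z variant is behind
`binned = TRUE`). `filter_channel_interior()` removes sites with
$r < r(z)$ (boundary kept; out-of-range z clamps to the nearest
endpoint), and `filter_membrane_zone()` removes sites with $z$ above a
configurable cut (default −48 Å, kept inclusively). The z-origin is
meaningful only in the aligned frame of the structure under study, so
the cut is a parameter, not a constant. The two filters commute.

## The combinatoric patch search

Sites eligible for clustering lie within `cutoff_any` of any heavy atom
**or** within the larger `cutoff_hydrophobic` of a hydrophobic heavy
atom — OR-semantics, since an AND-reading would make the larger
hydrophobic cutoff vacuous. The canonical classes are near (3.1, 3.6),
regular (3.6, 4.1) and far (4.1, 4.5) Å.

`site_adjacency()` links sites within 4.0 Å (just above second-shell
O–O spacing, given the 2.4 Å site exclusion; the notion of cluster
contiguity is otherwise undefined, so the cutoff is configurable).
`best_clusters()` then enumerates **connected induced subgraphs** of
each size 7–18 by depth-first include/exclude branching with a
canonical minimum-vertex root (each subgraph visited exactly once) and
an admissible lower bound (the cheapest conceivable completion),
pruning only branches that provably cannot reach the retention window.
Retention keeps clusters within 12.5 kJ/mol of the best cluster of the
*same size* (a global-reference mode is available; the window's
reference is ambiguous in the field) up to 1000 per size. Exactness —
identical membership and order versus exhaustive enumeration — is
asserted in the test suite on 100 seeded random instances.

`clusters_to_patches()` takes the union of all retained clusters'
sites and splits it into connected components: the patches. Patch
statistics (mean, median, sd with $n-1$, count) are computed over the
member sites' values. `multi_pass_patches()` iterates search → patch →
remove-sites until no cluster of minimum size remains; earlier passes
are the most displaceable. `annotate_patch_residues()` lists residues
with heavy atoms within a cutoff (5 Å for neighbourhood tables, 3 Å
for tight annotation), with frequency = number of patch sites near the
residue (a frame-count reading is also conceivable; the site-count
reading is deterministic and documented). `classify_patch_role()` calls
a patch *overlapping* a binding face when at least half its sites lie
within the 3 Å annotation cutoff of interface residues, *surrounding*
when any site lies within twice that, else *unrelated*.

```{r patch-example}
mkregion <- function(x0, depth)
  data.frame(x = x0 + rep(seq(0, 12, 3), 2), y = rep(c(0, 3), each = 5),
             z = 0, depth = depth, width = 0.35)
wells <- rbind(mkregion(0, 6), mkregion(30, 15), mkregion(60, 24))
gen <- make_water_ensemble(400, box = rbind(c(-8, -8, -8), c(80, 11, 8)),
                           bulk_density = 0, wells = wells, seed = 9)
sites <- pick_sites(gen$ensemble)
st <- score_sites(gen$ensemble, NULL, sites, gen$potential)
pat <- multi_pass_patches(st, costs = setNames(st$displacement_cost,
                                               st$site_id))
as.data.frame(pat)
```

## The synthetic generator: what it emulates, and what it does not

`make_water_ensemble()` emulates the *statistics* a hydration-site
analysis consumes: a bulk-like background (uniform placement at
0.0334 waters/Å³, ambient water density, with a 2.4 Å hard core
against degenerate overlaps and exclusion from the solute) plus planted
attractive Gaussian wells. A well of depth $d$ and width $w$ is
occupied with probability increasing in $d$ (Poisson occupancy of a
Boltzmann-enhanced local volume, capped at 0.98) and its water is
placed with the harmonic-order Boltzmann spread
$\sigma = w\sqrt{k_BT/d}$. Orientations are isotropic (rigid
TIP3P-like internal geometry) unless a well is marked ordered. The
returned `potential_model` contains the *same* wells, so generator and
scorer share one Hamiltonian; because placements are mutually
independent, that Hamiltonian has no water–water term and the returned
potential zeroes the water LJ depth and charges. The full water–water
machinery (LJ + 3×3-site Coulomb) is exercised against explicit
frame-loop oracles in the unit tests and is used when scoring real MD
ensembles with the default `potential_model()` (TIP3P-like water,
generic per-element solute classes, Lorentz–Berthelot combining, plain
cutoff Coulomb).

What the generator does **not** emulate: liquid-state pair structure,
hydrogen-bond networks, polarisation, long-range electrostatics, or
membrane/ion environments. Passing tests therefore demonstrate the
correctness of the *pipeline* — site identification, estimator
calibration, exact search, filtering — not force-field realism on real
trajectories.

`make_dock_set()` emulates a docking campaign: a declared fraction of
planted "good" poses (jittered copies of a constructed template that
provably satisfies the interface criteria), a declared fraction of
clashing poses, and guaranteed-separated random decoys, with scores
drawn per category (good poses more favourable). Ground-truth labels
ride in a sidecar, never in the coordinates. The toy ligand/receptor
pair (`make_interface_toys()`) is a pair of ideal helices with extended
side chains on the criterion residues, built so that the good pose
brings exactly those residues into vdW+20% contact.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 2000-frame bulk
ensembles in a 16 Å box (~137 waters/frame) for estimator calibration;
1000-frame ensembles for the five-depth well ladder, with the bulk
background disabled — a weak (5 kJ/mol) well surrounded by bulk is
~25% bulk-contaminated, which dilutes its depth response into an
occupancy effect, so the ladder isolates the property it calibrates
(without bulk, adjacent-depth dG gaps are ≥2 kJ/mol against ≈0.2
kJ/mol per-site noise); 600-frame ensembles for the three-region
multi-pass fixture (bulk off there too — a clean control of pass
ordering); ≤12-site instances
for exhaustive cross-checks of the cluster search, whose brute-force
oracle is only feasible at that size; and 23 × 468 = 10 764 poses for
the dock bookkeeping. These sizes were chosen so each statistical
assertion has comfortable power at desk scale.

Other numerical choices: strict inequalities at the contact (4.08 Å
for two carbons) and clash (1 Å) boundaries and inclusive boundaries
for the mid-plane and membrane filters; `1e-9` slack when comparing
cluster costs against the retention window; distances floored at
`1e-10` inside entropy logarithms; sample standard deviations
throughout.

## Known limitations

* The IFST implementation covers first-order energy and entropy terms;
  higher-order correlations (water–water entropy, solute–water
  coupling terms) are out of scope.
* Electrostatics are plain cutoff Coulomb — adequate for the synthetic
  Hamiltonian, crude for real trajectories (no Ewald).
* The exact cluster search is exponential in the worst case; it is
  intended for the post-filter site counts (tens of eligible sites per
  region) where the admissible bound prunes effectively. Cluster sizes
  beyond 18 (e.g. the ~30-site clusters a larger ligand would displace)
  are out of scope.
* Insertion codes and mmCIF input are unsupported; one altloc set per
  residue is assumed complete.
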