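# hydropatch

Predicting protein–protein binding interfaces by two independent
routes, for structural bioinformaticians studying cases like the
adaptor protein GABARAP binding the intracellular domain of the GABA-A
receptor:

1. **Docking-pose triage** — given a set of flexible-docking poses,
   reject steric clashes (any inter-protein atom pair < 1 Å), require
   experimentally implicated residues at the interface (contacts =
   heavy-atom pairs within 1.2 × the sum of their van der Waals
   radii), and select the poses that fall on the favourable side of
   the candidate-set median for the docking score and six contact
   metrics. Survivors are summarised as a Cα-RMSD matrix and a
   contact-pair frequency table.

2. **Hydration-patch analysis** — from an ensemble of water positions
   around a fixed solute, pick 1.2 Å hydration sites by greedy density
   maxima (2.4 Å exclusion), score each with an inhomogeneous fluid
   solvation theory (IFST) free energy

   `dG_hyd = dE − T (dS_trans + dS_orient)`, `cost = −dG_hyd`,

   (interaction energy plus nearest-neighbour translational and
   orientational entropy estimates, all relative to bulk), remove
   sites inside the ion-channel lumen (quadratic mid-plane fit
   `r(z) = a z² + b z + c`) and in the membrane-proximal zone, and run
   an **exact** combinatoric search for the best-scoring connected
   clusters of 7–18 sites within a 12.5 kJ/mol window. The union of
   the retained clusters, split into connected components, gives
   hydration *patches* — candidate binding footprints — extracted over
   multiple passes in order of displaceability.

A first-class synthetic-data generator (seeded, bit-reproducible)
emulates docking campaigns and water ensembles with planted ground
truth, so the whole pipeline is testable offline.

## Worked example

Triage a synthetic 40-pose dock set (20% planted good poses, 20%
planted clashes):

```r
library(hydropatch)
ds  <- make_dock_set(40, fraction_good = 0.2, fraction_clash = 0.2, seed = 4)
sel <- select_docks(ds$poses)
c(no_clash = length(sel$no_clash), primary = length(sel$primary),
  selected = length(sel$selected))
#> no_clash  primary selected
#>       32        8        4
contact_pair_table(sel$selected, min_atoms = 3, min_freq = length(sel$selected))
#>   receptor_residue ligand_residue n_poses freq
#> 1          THR 426         LYS 46       4  4/4
```

The 8 clash-free poses passing the interface criteria are exactly the
planted good poses; the median split keeps the best half; and the
Lys 46–Thr 426 contact recurs in every selected pose — the kind of
high-frequency contact pair the triage is designed to surface.

Extract hydration patches from three planted well regions of
increasing depth (6, 15, 24 kJ/mol):

```r
mkregion <- function(x0, depth)
  data.frame(x = x0 + rep(seq(0, 12, 3), 2), y = rep(c(0, 3), each = 5),
             z = 0, depth = depth, width = 0.35)
wells <- rbind(mkregion(0, 6), mkregion(30, 15), mkregion(60, 24))
gen   <- make_water_ensemble(400, box = rbind(c(-8, -8, -8), c(80, 11, 8)),
                             bulk_density = 0, wells = wells, seed = 9)
sites <- pick_sites(gen$ensemble)
st    <- score_sites(gen$ensemble, NULL, sites, gen$potential)
pat   <- multi_pass_patches(st, costs = setNames(st$displacement_cost,
                                                 st$site_id))
as.data.frame(pat)
#>   patch_id   class pass n_sites      mean    median        sd
#> 1     P1.1 regular    1      10 -2.264850 -2.358917 0.4724276
#> 2     P2.1 regular    2      10  2.678251  2.657374 0.2549609
#> 3     P3.1 regular    3      10  9.764119  9.795562 0.3247838
```

Each pass recovers one planted region (10 sites), in order of
increasing mean displacement cost: the shallowest wells — the most
easily desolvated surface — come out first, which is exactly the
ranking a binding-footprint prediction relies on.

The methods vignette (`vignettes/hydration-patches.Rmd`) documents the
model, estimators, parameters and their defaults, the design choices,
and what the synthetic benchmarks do and do not demonstrate.

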