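two_carbons <- function(d) {
  a <- assign_atom_properties(toy_structure(rbind(c(0, 0, 0))))
  b <- assign_atom_properties(toy_structure(rbind(c(d, 0, 0))))
  list(a = a, b = b)
}

test_that("the vdW+20% contact rule is strict at the boundary", {
  # two carbons, Bondi r = 1.70: threshold 1.2 * 3.40 = 4.08
  expect_equal(nrow(atomic_contacts(two_carbons(4.00)$a,
                                    two_carbons(4.00)$b)), 1)
  expect_equal(nrow(atomic_contacts(two_carbons(4.08)$a,
                                    two_carbons(4.08)$b)), 0)
  expect_equal(nrow(atomic_contacts(two_carbons(30)$a,
                                    two_carbons(30)$b)), 0)
  # unassigned radii error
  bare <- toy_structure(rbind(c(0, 0, 0)))
  expect_error(atomic_contacts(bare, bare), "radii not assigned")
})

test_that("interface residues are exactly those with a contacting heavy atom", {
  toys <- make_interface_toys()
  pose <- dock_pose("g", toys$good_ligand, toys$receptor, -30)
  iface <- interface_residues(pose)
  # planted construction: ligand 46/51/60 face receptor 426/431/440
  expect_true(all(c(46, 51, 60) %in% iface$ligand$resseq))
  expect_true(all(c(426, 431, 440) %in% iface$receptor$resseq))

  # far-apart pose -> empty interface
  far <- toys$ligand; far$x <- far$x + 100
  pose_far <- dock_pose("far", far, toys$receptor, 0)
  iface_far <- interface_residues(pose_far)
  expect_equal(nrow(iface_far$receptor), 0)
  expect_equal(nrow(iface_far$ligand), 0)
})

test_that("criteria 1-3 require all ligand residues and one of each group", {
  toys <- make_interface_toys()
  pose <- dock_pose("g", toys$good_ligand, toys$receptor, -30)
  expect_true(primary_filter(pose)[1])

  # requiring an absent ligand residue fails criterion 1
  expect_false(primary_filter(pose, ligand_required = c(46, 51, 60, 44))[1])
  # an unreachable group B fails criterion 3
  expect_false(primary_filter(pose, receptor_groupB = 442)[1])
  expect_error(primary_filter(pose, ligand_required = integer(0)),
               "non-empty")
})

test_that("criterion metrics count residues and contact pairs correctly", {
  toys <- make_interface_toys()
  pose <- dock_pose("g", toys$good_ligand, toys$receptor, -30)
  m <- criterion_metrics(pose)
  ct <- atomic_contacts(pose$receptor, pose$ligand)
  in_A <- ct$a_resseq %in% 425:429
  in_B <- ct$a_resseq %in% 433:442
  expect_equal(unname(m["energy"]), -30)
  expect_equal(unname(m["n_lig_res_AB"]),
               length(unique(ct$b_resseq[in_A | in_B])))
  expect_equal(unname(m["n_lig_res_A"]), length(unique(ct$b_resseq[in_A])))
  expect_equal(unname(m["n_lig_res_B"]), length(unique(ct$b_resseq[in_B])))
  expect_equal(unname(m["n_rec_res"]), length(unique(ct$a_resseq)))
  expect_equal(unname(m["n_contacts_AB"]), sum(in_A | in_B))
  expect_equal(unname(m["n_contacts_all"]), nrow(ct))
  expect_lte(m["n_contacts_AB"], m["n_contacts_all"])

  far <- toys$ligand; far$x <- far$x + 100
  m0 <- criterion_metrics(dock_pose("far", far, toys$receptor, 0))
  expect_true(all(m0[-1] == 0))
})

test_that("median-split selection matches the brute-force 7-condition check", {
  toys <- make_interface_toys()
  set.seed(201)
  for (trial in 1:6) {
    ds <- make_dock_set(16, ligand = toys$ligand, receptor = toys$receptor,
                        good_template = toys$good_ligand,
                        fraction_good = 0.5, fraction_clash = 0,
                        seed = 300 + trial)
    rep_df <- median_split_select(ds$poses)
    sel_oracle <- brute_median_split(
      rep_df[, c("energy", "n_lig_res_AB", "n_lig_res_A", "n_lig_res_B",
                 "n_rec_res", "n_contacts_AB", "n_contacts_all")])
    manual <- sel_oracle & !rep_df$clash & rep_df$crit_ligand &
      rep_df$crit_groupA & rep_df$crit_groupB
    expect_equal(rep_df$selected, manual)
  }
})

test_that("ties at the median are inclusive and dominance selects", {
  toys <- make_interface_toys()
  pose <- dock_pose("p", toys$good_ligand, toys$receptor, -20)
  # identical poses: every metric equals its median -> all selected
  clones <- lapply(1:4, function(i)
    dock_pose(paste0("c", i), toys$good_ligand, toys$receptor, -20))
  rep_df <- median_split_select(clones)
  expect_true(all(rep_df$selected))

  # a pose strictly dominating on all metrics is always selected:
  # give one clone a better energy (counts only favour it equally)
  better <- dock_pose("best", toys$good_ligand, toys$receptor, -25)
  rep2 <- median_split_select(c(clones, list(better)))
  expect_true(rep2$selected[rep2$pose_id == "best"])
})

test_that("selection is permutation-invariant", {
  toys <- make_interface_toys()
  ds <- make_dock_set(12, ligand = toys$ligand, receptor = toys$receptor,
                      good_template = toys$good_ligand,
                      fraction_good = 0.5, fraction_clash = 0, seed = 7)
  r1 <- median_split_select(ds$poses)
  perm <- sample(length(ds$poses))
  r2 <- median_split_select(ds$poses[perm])
  expect_equal(r2$selected[match(r1$pose_id, r2$pose_id)], r1$selected)
})

test_that("the triage pipeline applies clash, criteria and medians in order", {
  ds <- make_dock_set(30, fraction_good = 0.2, fraction_clash = 0.2,
                      seed = 11)
  sel <- select_docks(ds$poses)
  ids <- function(l) vapply(l, `[[`, "", "pose_id")
  expect_true(all(ids(sel$primary) %in% ids(sel$no_clash)))
  expect_true(all(ids(sel$selected) %in% ids(sel$primary)))
  # clash-labelled poses never survive stage 1
  expect_false(any(ds$truth$pose_id[ds$truth$planted_clash] %in%
                     ids(sel$no_clash)))
})

test_that("contact-pair table applies strict count and frequency cuts", {
  toys <- make_interface_toys()
  poses <- lapply(1:11, function(i)
    dock_pose(paste0("p", i), toys$good_ligand, toys$receptor, -30))
  # find a pair's true per-pose count, then set min_atoms just
  # below/at it to check strictness
  ct <- atomic_contacts(toys$receptor, toys$good_ligand)
  key <- paste(ct$a_resseq, ct$b_resseq)
  top <- sort(table(key), decreasing = TRUE)[1]
  tab_in <- contact_pair_table(poses, min_atoms = top - 1, min_freq = 9)
  expect_true(any(tab_in$n_poses == 11))
  expect_true(all(grepl("^11/11$", tab_in$freq)))
  # exactly equal to min_atoms -> excluded (strict >)
  tab_out <- contact_pair_table(poses, min_atoms = top, min_freq = 9)
  expect_equal(nrow(tab_out), 0)

  # a pair present in only 8 of 11 poses is excluded at min_freq 9
  far <- toys$ligand; far$x <- far$x + 100
  mixed <- c(poses[1:8], lapply(9:11, function(i)
    dock_pose(paste0("f", i), far, toys$receptor, 0)))
  tab8 <- contact_pair_table(mixed, min_atoms = 1, min_freq = 9)
  expect_equal(nrow(tab8), 0)
  tab8b <- contact_pair_table(mixed, min_atoms = 1, min_freq = 8)
  expect_true(all(tab8b$n_poses == 8))

  # monotonicity: raising either threshold never grows the table
  t1 <- contact_pair_table(poses, min_atoms = 1, min_freq = 1)
  t2 <- contact_pair_table(poses, min_atoms = 3, min_freq = 1)
  t3 <- contact_pair_table(poses, min_atoms = 1, min_freq = 12)
  expect_lte(nrow(t2), nrow(t1))
  expect_lte(nrow(t3), nrow(t1))
})
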