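#' Ideal alpha-helix toy structure
#'
#' Builds a poly-alanine alpha-helix backbone (rise 1.5 Angstrom and
#' 100 degrees twist per residue, C-alpha radius 2.3 Angstrom) with
#' N, CA, C, O and a C-beta stub per residue; the helix axis is z.
#' Purely geometric: a stand-in for helical fragments such as the
#' receptor's intracellular MA helices.
#'
#' @param n_residues number of residues (>= 4).
#' @param chain chain identifier.
#' @param resno residue numbers (default 1..n).
#' @param resnames residue names (recycled; default ALA).
#' @param face_residues optional residue numbers that receive an
#'   extended side chain (CG/CD pseudo-atoms) reaching `face_reach`
#'   Angstrom from the axis toward `face_direction` — a toy for long
#'   interface side chains (Lys, Arg, Gln).
#' @param face_direction unit 2-vector in the xy plane (default +x).
#' @param face_reach radial reach of the extension tip, Angstrom.
#' @return a `pdb_structure` (properties not yet assigned).
#' @export
make_helix <- function(n_residues, chain = "A", resno = NULL,
                       resnames = "ALA", face_residues = NULL,
                       face_direction = c(1, 0), face_reach = 6.5) {
  if (n_residues < 4) stop("a helix needs at least 4 residues")
  resno <- resno %||% seq_len(n_residues)
  stopifnot(length(resno) == n_residues)
  resnames <- rep_len(resnames, n_residues)
  rise <- 1.5; twist <- 100 * pi / 180; r_ca <- 2.3
  fdir <- unit(c(face_direction[1L], face_direction[2L], 0))

  rows <- list()
  serial <- 0L
  add <- function(name, element, resseq, resname, pos) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, resname = resname,
      chain = chain, resseq = resseq, altloc = "", occupancy = 1,
      x = pos[1L], y = pos[2L], z = pos[3L], stringsAsFactors = FALSE)
  }
  helix_point <- function(i, radius, dtheta, dz) {
    th <- twist * i + dtheta
    c(radius * cos(th), radius * sin(th), rise * i + dz)
  }
  for (i in seq_len(n_residues)) {
    rs <- resno[i]; rn <- resnames[i]
    ca <- helix_point(i, r_ca, 0, 0)
    add("N", "N", rs, rn, helix_point(i, 1.6, -0.52, -0.95))
    add("CA", "C", rs, rn, ca)
    add("C", "C", rs, rn, helix_point(i, 1.7, 0.50, 0.55))
    add("O", "O", rs, rn, helix_point(i, 2.0, 0.55, 1.75))
    outward <- unit(c(ca[1L], ca[2L], 0))
    add("CB", "C", rs, rn, ca + outward * 1.53)
    if (rs %in% face_residues) {
      # extension toward the face direction, at the residue's height
      for (k in seq_len(2L)) {
        reach <- r_ca + (face_reach - r_ca) * k / 2
        add(c("CG", "CD")[k], "C", rs, rn,
            c(fdir[1L] * reach, fdir[2L] * reach, ca[3L]))
      }
    }
  }
  new_structure(do.call(rbind, rows))
}

#' Altloc test fixture
#'
#' PDB text of a small three-segment structure in which exactly three
#' residues (two serines and an arginine) carry two alternate side
#' chain conformations, each at occupancy 1/2 — the layout seen in
#' high-resolution crystal structures where combinatorial expansion
#' yields 2^3 = 8 conformers.
#'
#' @return PDB text (character scalar).
#' @export
make_altloc_fixture <- function() {
  resno <- c(14:18, 51:55, 63:67)
  resnames <- rep("ALA", length(resno))
  resnames[resno == 16] <- "SER"
  resnames[resno == 53] <- "SER"
  resnames[resno == 65] <- "ARG"
  s <- make_helix(length(resno), chain = "A", resno = resno,
                  resnames = resnames)
  dual <- c(16, 53, 65)
  out <- s[!(s$resseq %in% dual & s$name == "CB"), , drop = FALSE]
  for (rs in dual) {
    cb <- s[s$resseq == rs & s$name == "CB", , drop = FALSE]
    a <- cb; a$altloc <- "A"; a$occupancy <- 0.5
    b <- cb; b$altloc <- "B"; b$occupancy <- 0.5
    b$x <- b$x + 0.8; b$y <- b$y - 0.6
    out <- rbind(out, a, b)
  }
  out <- out[order(out$resseq, out$serial, out$altloc), , drop = FALSE]
  out$serial <- seq_len(nrow(out))
  write_model(new_structure(out))
}

#' Multi-model (NMR-style) test fixture
#'
#' PDB text with `n_models` slightly perturbed copies of a toy helix,
#' mimicking an NMR conformer ensemble.
#'
#' @param n_models number of MODEL blocks.
#' @param seed RNG seed (private stream).
#' @export
make_multimodel_fixture <- function(n_models = 15, seed = 1) {
  base <- make_helix(10)
  with_local_seed(seed, {
    models <- lapply(seq_len(n_models), function(m) {
      s <- base
      s$x <- s$x + stats::rnorm(nrow(s), 0, 0.15)
      s$y <- s$y + stats::rnorm(nrow(s), 0, 0.15)
      s$z <- s$z + stats::rnorm(nrow(s), 0, 0.15)
      attr(s, "model_id") <- as.character(m)
      s
    })
    write_model(new_conformer_set(models))
  })
}

# Random sequential adsorption: place up to `n_target` points with
# hard-core separation `min_sep`, proposing uniform candidates in the
# box (minus the exclusion set) until the target or the proposal budget
# is reached.
hardcore_place <- function(n_target, lo, hi, min_sep, excl_xyz = NULL,
                           excl_dist = 2.6, max_rounds = 12L) {
  kept <- matrix(numeric(0), ncol = 3L)
  for (round in seq_len(max_rounds)) {
    need <- n_target - nrow(kept)
    if (need <= 0L) break
    raw <- cbind(stats::runif(2L * need, lo[1L], hi[1L]),
                 stats::runif(2L * need, lo[2L], hi[2L]),
                 stats::runif(2L * need, lo[3L], hi[3L]))
    if (!is.null(excl_xyz) && nrow(excl_xyz) > 0) {
      d2 <- cross_dist(raw, excl_xyz)^2
      raw <- raw[apply(d2, 1L, min) >= excl_dist^2, , drop = FALSE]
    }
    for (i in seq_len(nrow(raw))) {
      if (nrow(kept) >= n_target) break
      if (nrow(kept) == 0L ||
          min(dist2_to_point(kept, raw[i, ])) >= min_sep^2)
        kept <- rbind(kept, raw[i, ])
    }
  }
  kept
}

# Rigid TIP3P-like internal geometry: O-H 0.9572 A, H-O-H 104.52 deg.
water_hydrogens <- function(o, q) {
  rOH <- 0.9572; half <- 104.52 / 2 * pi / 180
  h_local <- rbind(c(rOH * cos(half), rOH * sin(half), 0),
                   c(rOH * cos(half), -rOH * sin(half), 0))
  R <- quat_to_rot(q)
  sweep(h_local %*% t(R), 2L, -o)
}

#' Synthetic water ensemble with planted hydration structure
#'
#' Generates frames of water positions: a bulk-like background (uniform
#' hard-core placement at `bulk_density`, excluded from the solute) plus
#' optional planted attractive wells. Each well is occupied with a
#' probability increasing in its depth and, when occupied, its water is
#' placed with the Boltzmann (harmonic-order) spread of the matching
#' Gaussian well potential, so the ensemble and the returned
#' [potential_model()] describe the same Hamiltonian. Orientations are
#' isotropic unless a well is marked `ordered`. Fully determined by
#' `seed`.
#'
#' @param n_frames number of frames (>= 1).
#' @param box 2 x 3 matrix (rows min/max) or length-2 vector applied to
#'   all axes.
#' @param bulk_density waters/Angstrom^3; 0 disables the bulk
#'   background.
#' @param wells optional data frame (x, y, z, depth, width, and
#'   optionally ordered); depths kJ/mol >= 0, widths Angstrom.
#' @param solute optional `pdb_structure` the bulk is excluded from.
#' @param temperature K (controls the Boltzmann spread).
#' @param seed integer; every output is reproducible bit-for-bit.
#' @param frame_interval ps.
#' @param hydrogens generate hydrogen positions too.
#' @param min_well_sep minimum distance allowed between wells.
#' @param water_exclusion hard-core distance between placed waters,
#'   Angstrom (avoids degenerate overlaps).
#' @return list with `ensemble` (a [water_ensemble()]), `potential`
#'   (the matching [potential_model()]) and `truth` (planted wells).
#'   The ensemble's `bulk_density` is the realised bulk density, so
#'   relative site densities are normalised consistently. Because the
#'   generator places waters independently of one another, the matching
#'   Hamiltonian has no water-water term: the returned potential zeroes
#'   the water LJ well depth and charges (wells and solute terms
#'   remain). Score real MD ensembles with a full [potential_model()]
#'   instead.
#' @export
make_water_ensemble <- function(n_frames, box = c(0, 16),
                                bulk_density = 0.0334, wells = NULL,
                                solute = NULL, temperature = 300,
                                seed = 1, frame_interval = 0.5,
                                hydrogens = TRUE, min_well_sep = 2.4,
                                water_exclusion = 2.4) {
  stopifnot(n_frames >= 1)
  if (is.null(dim(box))) box <- rbind(rep(box[1L], 3), rep(box[2L], 3))
  lo <- box[1L, ]; hi <- box[2L, ]
  vol <- prod(hi - lo)
  kT <- GAS_CONSTANT * temperature
  if (!is.null(wells) && nrow(wells) >= 2L) {
    d <- stats::dist(cbind(wells$x, wells$y, wells$z))
    if (min(d) < min_well_sep)
      stop("planted wells closer than min_well_sep (",
           min_well_sep, " A)")
  }
  if (!is.null(wells) && is.null(wells$ordered)) wells$ordered <- FALSE
  solute_xyz <- if (!is.null(solute) && nrow(solute) > 0)
    coords(heavy_atoms(solute)) else NULL

  n_bulk <- 0L
  if (bulk_density > 0) {
    free_frac <- 1
    if (!is.null(solute_xyz)) {
      # Monte Carlo estimate of the solute-excluded volume fraction
      free_frac <- with_local_seed(seed + 101L, {
        probe <- cbind(stats::runif(4000L, lo[1L], hi[1L]),
                       stats::runif(4000L, lo[2L], hi[2L]),
                       stats::runif(4000L, lo[3L], hi[3L]))
        d2 <- cross_dist(probe, solute_xyz)^2
        mean(apply(d2, 1L, min) >= 2.6^2)
      })
    }
    n_bulk <- max(0L, round(bulk_density * vol * free_frac))
  }
  # occupancy rises with well depth: Poisson occupancy of a Boltzmann-
  # enhanced local volume, capped below 1
  p_occ <- if (is.null(wells)) numeric(0) else
    pmin(0.98, 1 - exp(-pmin(
      bulk_density_for_wells(bulk_density) *
        (4 / 3) * pi * (2 * wells$width)^3 * exp(wells$depth / kT), 50)))
  sigma_well <- if (is.null(wells)) numeric(0) else
    pmin(wells$width * sqrt(kT / pmax(wells$depth, 1e-6)),
         1.5 * wells$width)

  oxy <- vector("list", n_frames)
  hyd <- if (hydrogens) vector("list", n_frames) else NULL
  n_placed_bulk <- numeric(n_frames)
  with_local_seed(seed, {
    fixed_quats <- if (!is.null(wells)) quat_random(nrow(wells)) else NULL
    for (k in seq_len(n_frames)) {
      pts <- matrix(numeric(0), ncol = 3L)
      if (n_bulk > 0L)
        pts <- hardcore_place(n_bulk, lo, hi, water_exclusion, solute_xyz)
      n_placed_bulk[k] <- nrow(pts)
      well_row <- integer(0)   # row index in pts of each occupied well
      well_idx <- integer(0)   # which well that row belongs to
      if (!is.null(wells) && nrow(wells) > 0) {
        occ <- stats::runif(nrow(wells)) < p_occ
        for (w in which(occ)) {
          p <- c(wells$x[w], wells$y[w], wells$z[w]) +
            stats::rnorm(3L, 0, sigma_well[w])
          # the well water displaces clashing bulk waters
          if (nrow(pts) > 0) {
            clash <- dist2_to_point(pts, p) < water_exclusion^2
            clash[well_row] <- FALSE  # never displace a planted water
            if (any(clash)) {
              shift <- cumsum(clash)
              well_row <- well_row - shift[well_row]
              n_placed_bulk[k] <- n_placed_bulk[k] - sum(clash)
              pts <- pts[!clash, , drop = FALSE]
            }
          }
          pts <- rbind(pts, p)
          well_row <- c(well_row, nrow(pts))
          well_idx <- c(well_idx, w)
        }
      }
      oxy[[k]] <- pts
      if (hydrogens) {
        nw <- nrow(pts)
        hm <- matrix(0, nrow = 2L * nw, ncol = 3L)
        if (nw > 0) {
          qs <- quat_random(nw)
          if (length(well_idx) > 0) {
            is_ord <- wells$ordered[well_idx]
            qs[well_row[is_ord], ] <- fixed_quats[well_idx[is_ord], ]
          }
          for (i in seq_len(nw))
            hm[c(2L * i - 1L, 2L * i), ] <- water_hydrogens(pts[i, ],
                                                            qs[i, ])
        }
        hyd[[k]] <- hm
      }
    }
  })
  # matching Hamiltonian: no water-water term (see @return)
  cls <- default_potential_classes()
  cls$epsilon[cls$class == "OW"] <- 0
  cls$charge[cls$class %in% c("OW", "HW")] <- 0
  pot <- potential_model(classes = cls, wells = wells)
  realised <- if (bulk_density > 0)
    mean(n_placed_bulk) / (vol * free_frac) else 0.0334
  ens <- water_ensemble(oxy, hydrogens = hyd,
                        frame_interval = frame_interval,
                        bulk_density = realised,
                        box = box)
  list(ensemble = ens, potential = pot,
       truth = list(wells = wells, seed = seed,
                    temperature = temperature))
}

# Bulk density used in the well-occupancy model; falls back to ambient
# water density when the background is disabled.
bulk_density_for_wells <- function(bulk_density) {
  if (bulk_density > 0) bulk_density else 0.0334
}

#' Synthetic dock set with planted ground truth
#'
#' Generates rigid placements of a ligand around a receptor:
#' a declared fraction of planted "good" poses (jittered copies of a
#' constructed pose that satisfies the interface criteria 1-3 and is
#' clash-free), a declared fraction of clashing poses (ligand overlaps
#' the receptor within 1 Angstrom), and random clash-free decoys.
#' Energy scores are drawn from pose-category normal distributions
#' (good poses more favourable). Ground-truth labels are returned in a
#' sidecar, never embedded in the structures.
#'
#' @param n_poses number of poses.
#' @param ligand,receptor structures with assigned properties; by
#'   default the toy pair from [make_interface_toys()].
#' @param fraction_good,fraction_clash planted fractions (sum <= 1).
#' @param score_params list with `good` and `other`: c(mean, sd) of the
#'   energy-score distributions (lower = more favourable).
#' @param seed integer seed (private stream).
#' @param good_template optional pre-built good pose ligand (in the
#'   receptor frame); built by [make_interface_toys()] otherwise.
#' @param verify re-check planted labels (clash / criteria 1-3) and
#'   error on construction failure.
#' @param ligand_required,receptor_groupA,receptor_groupB criteria used
#'   for verification.
#' @return list: `poses` (list of [dock_pose()]), `truth` (data frame
#'   pose_id, planted_good, planted_clash).
#' @export
make_dock_set <- function(n_poses, ligand = NULL, receptor = NULL,
                          fraction_good = 0.1, fraction_clash = 0.1,
                          score_params = list(good = c(-30, 3),
                                              other = c(-15, 5)),
                          seed = 1, good_template = NULL, verify = TRUE,
                          ligand_required = c(46, 51, 60),
                          receptor_groupA = 425:429,
                          receptor_groupB = 433:442) {
  if (is.null(ligand) || is.null(receptor)) {
    toys <- make_interface_toys()
    ligand <- ligand %||% toys$ligand
    receptor <- receptor %||% toys$receptor
    good_template <- good_template %||% toys$good_ligand
  }
  n_good <- round(fraction_good * n_poses)
  n_clash <- round(fraction_clash * n_poses)
  stopifnot(n_good + n_clash <= n_poses)
  if (n_good > 0 && is.null(good_template))
    stop("infeasible interface spec: no good-pose template available")

  rxyz <- coords(receptor)
  rc <- colMeans(rxyz)
  r_rad <- sqrt(max(dist2_to_point(rxyz, rc)))
  lxyz <- coords(ligand)
  lc <- colMeans(lxyz)
  l_rad <- sqrt(max(dist2_to_point(lxyz, lc)))

  place_ligand <- function(R, target_center) {
    s <- ligand
    xyz <- sweep(lxyz, 2L, lc) %*% t(R)
    s$x <- xyz[, 1L] + target_center[1L]
    s$y <- xyz[, 2L] + target_center[2L]
    s$z <- xyz[, 3L] + target_center[3L]
    s
  }

  categories <- c(rep("good", n_good), rep("clash", n_clash),
                  rep("other", n_poses - n_good - n_clash))
  poses <- vector("list", n_poses)
  with_local_seed(seed, {
    for (i in seq_len(n_poses)) {
      cat_i <- categories[i]
      if (cat_i == "good") {
        lig <- good_template
        # small jitter that cannot break the criteria
        jitter_axis <- unit(stats::rnorm(3L))
        ang <- stats::runif(1, -1, 1) * pi / 180
        q <- c(cos(ang / 2), sin(ang / 2) * jitter_axis)
        gc <- colMeans(coords(lig))
        gxyz <- sweep(coords(lig), 2L, gc) %*% t(quat_to_rot(q))
        shift <- stats::rnorm(3L, 0, 0.1)
        lig$x <- gxyz[, 1L] + gc[1L] + shift[1L]
        lig$y <- gxyz[, 2L] + gc[2L] + shift[2L]
        lig$z <- gxyz[, 3L] + gc[3L] + shift[3L]
        if (verify) {
          pose_ok <- !steric_clash(lig, receptor) &&
            isTRUE(primary_filter(
              dock_pose("tmp", lig, receptor, 0), ligand_required,
              receptor_groupA, receptor_groupB)[1L])
          if (!pose_ok) lig <- good_template
        }
        sc <- stats::rnorm(1, score_params$good[1L],
                           score_params$good[2L])
      } else if (cat_i == "clash") {
        repeat {
          target_atom <- rxyz[sample.int(nrow(rxyz), 1L), ]
          R <- quat_to_rot(quat_random(1L)[1L, ])
          lig <- place_ligand(R, target_atom)
          if (steric_clash(lig, receptor)) break
        }
        sc <- stats::rnorm(1, score_params$other[1L],
                           score_params$other[2L])
      } else {
        # guaranteed-separated placement: centre distance exceeds the
        # two bounding radii plus the clash threshold
        u <- unit(stats::rnorm(3L))
        dist <- r_rad + l_rad + 1.5 + stats::runif(1, 0, 6)
        R <- quat_to_rot(quat_random(1L)[1L, ])
        lig <- place_ligand(R, rc + u * dist)
        sc <- stats::rnorm(1, score_params$other[1L],
                           score_params$other[2L])
      }
      poses[[i]] <- dock_pose(sprintf("pose%05d", i), lig, receptor, sc)
    }
  })
  truth <- data.frame(
    pose_id = vapply(poses, `[[`, "", "pose_id"),
    planted_good = categories == "good",
    planted_clash = categories == "clash",
    stringsAsFactors = FALSE)
  if (verify && n_clash > 0) {
    flags <- vapply(poses, function(p)
      steric_clash(p$ligand, p$receptor), logical(1))
    if (!identical(flags, truth$planted_clash))
      stop("infeasible dock spec: clash labels could not be realised")
  }
  list(poses = poses, truth = truth)
}

#' Toy ligand/receptor pair with a constructible interface
#'
#' Builds a receptor helix spanning residues 420-442 (chain R) and a
#' ligand helix spanning 40-68 (chain L), both with extended side
#' chains on the residues the interface criteria reference (ligand
#' Lys 46 / Val 51 / Phe 60; receptor 426 / 431 / 440), plus a "good"
#' placement of the ligand facing the receptor in which criteria 1-3
#' hold and no steric clash occurs.
#'
#' @param separation axis-to-axis distance of the good pose, Angstrom.
#' @return list: `ligand`, `receptor`, `good_ligand` (all with assigned
#'   properties).
#' @export
make_interface_toys <- function(separation = 13.2) {
  rec_resno <- 420:442
  rec_names <- rep("ALA", length(rec_resno))
  rec_names[rec_resno == 426] <- "THR"
  rec_names[rec_resno == 431] <- "HIS"
  rec_names[rec_resno == 440] <- "LYS"
  receptor <- make_helix(length(rec_resno), chain = "R",
                         resno = rec_resno, resnames = rec_names,
                         face_residues = c(426, 431, 440),
                         face_direction = c(1, 0), face_reach = 5.0)
  lig_resno <- 40:68
  lig_names <- rep("ALA", length(lig_resno))
  lig_names[lig_resno == 46] <- "LYS"
  lig_names[lig_resno == 51] <- "VAL"
  lig_names[lig_resno == 60] <- "PHE"
  ligand <- make_helix(length(lig_resno), chain = "L",
                       resno = lig_resno, resnames = lig_names,
                       face_residues = c(46, 51, 60),
                       face_direction = c(1, 0), face_reach = 6.5)
  receptor <- assign_atom_properties(receptor)
  ligand <- assign_atom_properties(ligand)

  # good pose: rotate the ligand 180 deg about z so its face points -x,
  # then offset along +x and align residue 46 with receptor height 426
  good <- ligand
  xyz <- coords(ligand)
  xyz[, 1L] <- -xyz[, 1L]
  xyz[, 2L] <- -xyz[, 2L]
  z46 <- xyz[ligand$resseq == 46 & ligand$name == "CA", 3L]
  z426 <- receptor$z[receptor$resseq == 426 & receptor$name == "CA"]
  xyz[, 1L] <- xyz[, 1L] + separation
  xyz[, 3L] <- xyz[, 3L] + (z426 - z46)
  good$x <- xyz[, 1L]; good$y <- xyz[, 2L]; good$z <- xyz[, 3L]
  list(ligand = ligand, receptor = receptor, good_ligand = good)
}
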