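#' Docked pose container
#'
#' A `dock_pose` bundles a ligand placement, the receptor it was docked
#' against, and the docking energy score (dimensionless; lower is more
#' favourable).
#'
#' @param pose_id label.
#' @param ligand,receptor non-empty `pdb_structure`s.
#' @param energy_score finite docking score.
#' @export
dock_pose <- function(pose_id, ligand, receptor, energy_score) {
  stopifnot(is_structure(ligand), is_structure(receptor),
            nrow(ligand) > 0, nrow(receptor) > 0,
            is.finite(energy_score))
  structure(list(pose_id = as.character(pose_id), ligand = ligand,
                 receptor = receptor, energy_score = energy_score),
            class = "dock_pose")
}

#' Atomic contacts between two structures
#'
#' A heavy-atom pair is in contact when its distance is strictly below
#' `scale` times the sum of the two van der Waals radii; the default
#' scale 1.2 is the vdW-sum-plus-20% rule. Radii must have been assigned
#' with [assign_atom_properties()].
#'
#' @param a,b structures with assigned radii.
#' @param scale multiplier on the vdW-radius sum.
#' @return data frame of contacting pairs with residue identities and
#'   distances; zero rows when no pair qualifies.
#' @export
atomic_contacts <- function(a, b, scale = 1.2) {
  ha <- heavy_atoms(a); hb <- heavy_atoms(b)
  if (anyNA(ha$vdw) || anyNA(hb$vdw))
    stop("van der Waals radii not assigned; call assign_atom_properties()")
  if (nrow(ha) == 0 || nrow(hb) == 0)
    return(empty_contacts())
  d <- cross_dist(coords(ha), coords(hb))
  thr <- outer(ha$vdw, hb$vdw, "+") * scale
  hit <- which(d < thr, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_contacts())
  i <- hit[, 1L]; j <- hit[, 2L]
  data.frame(
    a_chain = ha$chain[i], a_resseq = ha$resseq[i],
    a_resname = ha$resname[i], a_name = ha$name[i],
    b_chain = hb$chain[j], b_resseq = hb$resseq[j],
    b_resname = hb$resname[j], b_name = hb$name[j],
    distance = d[hit], stringsAsFactors = FALSE)
}

empty_contacts <- function() {
  data.frame(a_chain = character(0), a_resseq = integer(0),
             a_resname = character(0), a_name = character(0),
             b_chain = character(0), b_resseq = integer(0),
             b_resname = character(0), b_name = character(0),
             distance = numeric(0), stringsAsFactors = FALSE)
}

pose_contacts <- function(pose, scale = 1.2) {
  atomic_contacts(pose$receptor, pose$ligand, scale = scale)
}

#' Interface residues of a docked pose
#'
#' A residue is at the interface iff at least one of its heavy atoms
#' participates in a vdW+20% contact across the interface.
#'
#' @param pose a `dock_pose` (radii assigned on both partners).
#' @param scale contact scale, see [atomic_contacts()].
#' @return list with data frames `receptor` and `ligand` (chain, resseq,
#'   resname).
#' @export
interface_residues <- function(pose, scale = 1.2) {
  ct <- pose_contacts(pose, scale)
  rec <- unique(data.frame(chain = ct$a_chain, resseq = ct$a_resseq,
                           resname = ct$a_resname, stringsAsFactors = FALSE))
  lig <- unique(data.frame(chain = ct$b_chain, resseq = ct$b_resseq,
                           resname = ct$b_resname, stringsAsFactors = FALSE))
  list(receptor = rec[order(rec$resseq), , drop = FALSE],
       ligand = lig[order(lig$resseq), , drop = FALSE])
}

#' Experimentally-derived interface criteria (criteria 1-3)
#'
#' A pose passes iff every required ligand residue is at the interface,
#' at least one receptor residue of group A is, and at least one of
#' group B is. Defaults encode the GABARAP / GABA-A receptor case:
#' ligand Lys 46, Val 51, Phe 60; receptor groups Arg 425-Trp 429 and
#' Arg 433-Asp 442.
#'
#' @param pose a `dock_pose`.
#' @param ligand_required,receptor_groupA,receptor_groupB residue
#'   numbers (non-empty).
#' @param scale contact scale.
#' @return logical scalar; attribute `"per_criterion"` carries the three
#'   individual verdicts.
#' @export
primary_filter <- function(pose,
                           ligand_required = c(46, 51, 60),
                           receptor_groupA = 425:429,
                           receptor_groupB = 433:442,
                           scale = 1.2) {
  if (length(ligand_required) == 0 || length(receptor_groupA) == 0 ||
      length(receptor_groupB) == 0)
    stop("required residue sets must be non-empty")
  iface <- interface_residues(pose, scale)
  crit <- c(
    ligand_all = all(ligand_required %in% iface$ligand$resseq),
    groupA_any = any(receptor_groupA %in% iface$receptor$resseq),
    groupB_any = any(receptor_groupB %in% iface$receptor$resseq))
  structure(all(crit), per_criterion = crit)
}

#' Distribution metrics for median-split selection (criteria 4-10)
#'
#' Returns the seven numbers the median-split selection compares:
#' `energy` (the docking score), `n_lig_res_AB` / `n_lig_res_A` /
#' `n_lig_res_B` (ligand residues contacting the union / the
#' cytoplasmic-side group A / the membrane-side group B of receptor
#' residues), `n_rec_res` (receptor residues contacting any ligand
#' residue), and `n_contacts_AB` / `n_contacts_all` (atomic contacts to
#' the grouped receptor residues / to any receptor residue). Contacts
#' are counted as contacting atom pairs by default; set
#' `count = "atoms"` for distinct ligand atoms.
#'
#' @inheritParams primary_filter
#' @param count `"pairs"` or `"atoms"`.
#' @return named numeric vector of length 7.
#' @export
criterion_metrics <- function(pose,
                              receptor_groupA = 425:429,
                              receptor_groupB = 433:442,
                              scale = 1.2, count = c("pairs", "atoms")) {
  count <- match.arg(count)
  ct <- pose_contacts(pose, scale)
  in_A <- ct$a_resseq %in% receptor_groupA
  in_B <- ct$a_resseq %in% receptor_groupB
  in_AB <- in_A | in_B
  n_ct <- function(sel) {
    if (count == "pairs") sum(sel)
    else length(unique(paste(ct$b_resseq[sel], ct$b_name[sel])))
  }
  c(energy = pose$energy_score,
    n_lig_res_AB = length(unique(ct$b_resseq[in_AB])),
    n_lig_res_A = length(unique(ct$b_resseq[in_A])),
    n_lig_res_B = length(unique(ct$b_resseq[in_B])),
    n_rec_res = length(unique(ct$a_resseq)),
    n_contacts_AB = n_ct(in_AB),
    n_contacts_all = n_ct(rep(TRUE, nrow(ct))))
}

METRIC_NAMES <- c("energy", "n_lig_res_AB", "n_lig_res_A", "n_lig_res_B",
                  "n_rec_res", "n_contacts_AB", "n_contacts_all")

#' Median-split selection over a candidate pose set
#'
#' Evaluates the seven metrics of [criterion_metrics()] on every pose of
#' the candidate list, takes the (lower) median of each metric over that
#' same list, and selects the poses whose energy lies in the favourable
#' half (`energy <= median`) and whose six contact metrics lie in the
#' higher half (`metric >= median`). Ties at a median count as in the
#' favourable half. Steric clash and the criteria 1-3 verdicts are
#' reported alongside; a selected pose is always clash-free and passes
#' criteria 1-3.
#'
#' @param poses list of `dock_pose` (>= 2): the candidate set over which
#'   the medians are taken (normally the criteria 1-3 survivors).
#' @inheritParams primary_filter
#' @param clash_threshold Angstrom for the clash test.
#' @param count contact counting mode, see [criterion_metrics()].
#' @return data frame (one row per pose): pose id, clash flag, the three
#'   criteria 1-3 verdicts, the seven metrics and `selected`.
#' @export
median_split_select <- function(poses,
                                ligand_required = c(46, 51, 60),
                                receptor_groupA = 425:429,
                                receptor_groupB = 433:442,
                                scale = 1.2, clash_threshold = 1.0,
                                count = "pairs") {
  if (length(poses) == 0) stop("empty pose list")
  rows <- lapply(poses, function(p) {
    pf <- primary_filter(p, ligand_required, receptor_groupA,
                         receptor_groupB, scale)
    m <- criterion_metrics(p, receptor_groupA, receptor_groupB, scale,
                           count)
    crit <- attr(pf, "per_criterion")
    data.frame(pose_id = p$pose_id,
               clash = steric_clash(p$ligand, p$receptor, clash_threshold),
               crit_ligand = unname(crit["ligand_all"]),
               crit_groupA = unname(crit["groupA_any"]),
               crit_groupB = unname(crit["groupB_any"]),
               as.list(m), stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  med <- vapply(METRIC_NAMES, function(nm) lower_median(rep_df[[nm]]),
                numeric(1))
  ok <- rep_df$energy <= med["energy"]
  for (nm in METRIC_NAMES[-1L])
    ok <- ok & rep_df[[nm]] >= med[nm]
  rep_df$selected <- ok & !rep_df$clash & rep_df$crit_ligand &
    rep_df$crit_groupA & rep_df$crit_groupB
  attr(rep_df, "medians") <- med
  rep_df
}

#' Full dock triage pipeline
#'
#' Applies the selection stages in order: steric-clash rejection,
#' the experimental interface criteria 1-3, then median-split selection
#' of the seven distribution metrics over the surviving candidate set.
#'
#' @inheritParams median_split_select
#' @return list with the per-stage survivors (`no_clash`, `primary`,
#'   `selected`: lists of poses) and the median-split `report` over the
#'   candidate set.
#' @export
select_docks <- function(poses,
                         ligand_required = c(46, 51, 60),
                         receptor_groupA = 425:429,
                         receptor_groupB = 433:442,
                         scale = 1.2, clash_threshold = 1.0,
                         count = "pairs") {
  no_clash <- Filter(function(p)
    !steric_clash(p$ligand, p$receptor, clash_threshold), poses)
  primary <- Filter(function(p)
    isTRUE(primary_filter(p, ligand_required, receptor_groupA,
                          receptor_groupB, scale)[1L]), no_clash)
  if (length(primary) == 0)
    return(list(no_clash = no_clash, primary = primary,
                selected = list(), report = NULL))
  report <- median_split_select(primary, ligand_required, receptor_groupA,
                                receptor_groupB, scale, clash_threshold,
                                count)
  selected <- primary[report$selected]
  list(no_clash = no_clash, primary = primary, selected = selected,
       report = report)
}

#' Contact-pair frequency table over selected poses
#'
#' Tabulates receptor/ligand residue pairs whose per-pose atomic contact
#' count strictly exceeds `min_atoms`, retained when they occur in at
#' least `min_freq` of the poses. Frequencies are reported as `"k/N"`.
#'
#' @param poses non-empty list of selected `dock_pose`s.
#' @param min_atoms per-pose contact count that must be exceeded.
#' @param min_freq minimum number of poses the pair must appear in.
#' @param scale contact scale.
#' @param count `"pairs"` (contacting atom pairs) or `"atoms"`.
#' @return data frame (receptor_residue, ligand_residue, n_poses, freq)
#'   sorted by decreasing frequency.
#' @export
contact_pair_table <- function(poses, min_atoms = 10, min_freq = 9,
                               scale = 1.2, count = c("pairs", "atoms")) {
  count <- match.arg(count)
  stopifnot(length(poses) >= 1)
  n <- length(poses)
  tallies <- new.env(parent = emptyenv())
  for (p in poses) {
    ct <- pose_contacts(p, scale)
    if (nrow(ct) == 0) next
    key <- paste0(ct$a_resname, " ", ct$a_resseq, "\t",
                  ct$b_resname, " ", ct$b_resseq)
    cnt <- if (count == "pairs") {
      table(key)
    } else {
      tapply(paste(ct$b_name), key, function(v) length(unique(v)))
    }
    qual <- names(cnt)[cnt > min_atoms]
    for (k in qual)
      assign(k, (if (exists(k, tallies)) get(k, tallies) else 0L) + 1L,
             tallies)
  }
  keys <- ls(tallies)
  if (length(keys) == 0)
    return(data.frame(receptor_residue = character(0),
                      ligand_residue = character(0),
                      n_poses = integer(0), freq = character(0)))
  freq <- vapply(keys, get, integer(1), envir = tallies)
  keep <- freq >= min_freq
  keys <- keys[keep]; freq <- freq[keep]
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(
    receptor_residue = vapply(parts, `[`, "", 1L),
    ligand_residue = vapply(parts, `[`, "", 2L),
    n_poses = as.integer(freq),
    freq = sprintf("%d/%d", freq, n),
    stringsAsFactors = FALSE)
  out[order(-out$n_poses, out$receptor_residue), , drop = FALSE]
}
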