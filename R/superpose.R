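#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two matched coordinate sets; reflections are excluded. The returned
#' transform maps mobile coordinates onto the target frame via
#' [apply_transform()], i.e. `x %*% t(rotation) + translation`.
#'
#' @param mobile,target n x 3 coordinate matrices (n >= 3, matched rows).
#' @return list with elements `rotation` (3 x 3, det +1), `translation`
#'   (length-3, Angstrom) and `rmsd` (Angstrom after superposition).
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target))
    stop("coordinate sets differ in length (", nrow(mobile), " vs ",
         nrow(target), ")")
  if (nrow(mobile) < 3L) stop("need at least 3 points to superpose")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2L, cm); Q <- sweep(target, 2L, ct)
  sv_p <- svd(P)$d
  if (sv_p[2L] < 1e-8 * max(sv_p[1L], 1))
    stop("degenerate geometry: points are collinear")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- as.numeric(ct - R %*% cm)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' @rdname kabsch_fit
#' @param x coordinate matrix or `pdb_structure` to transform.
#' @param tf transform from `kabsch_fit()`.
#' @export
apply_transform <- function(x, tf) {
  if (is_structure(x)) {
    xyz <- coords(x) %*% t(tf$rotation)
    x$x <- xyz[, 1L] + tf$translation[1L]
    x$y <- xyz[, 2L] + tf$translation[2L]
    x$z <- xyz[, 3L] + tf$translation[3L]
    return(x)
  }
  sweep(as.matrix(x) %*% t(tf$rotation), 2L, -tf$translation)
}

ca_keyed_coords <- function(s) {
  ca <- s[s$name == "CA", , drop = FALSE]
  key <- paste(ca$chain, ca$resseq)
  m <- coords(ca)
  rownames(m) <- key
  m[order(key), , drop = FALSE]
}

#' Transfer a docked ligand pose onto a reference receptor frame
#'
#' Superimposes the dock's receptor onto a reference copy of the same
#' receptor (matched C-alpha atoms by chain and residue number) and
#' applies the identical rigid transform to the ligand, leaving the
#' ligand's internal geometry untouched.
#'
#' @param dock_receptor,reference_receptor receptor structures sharing
#'   C-alpha sets.
#' @param ligand ligand structure in the dock frame.
#' @return the ligand re-placed in the reference frame.
#' @export
transfer_ligand_pose <- function(dock_receptor, reference_receptor, ligand) {
  a <- ca_keyed_coords(dock_receptor)
  b <- ca_keyed_coords(reference_receptor)
  missing <- c(setdiff(rownames(a), rownames(b)),
               setdiff(rownames(b), rownames(a)))
  if (length(missing) > 0)
    stop("receptor C-alpha sets do not match; missing residues: ",
         paste(unique(missing), collapse = ", "))
  tf <- kabsch_fit(a, b[rownames(a), , drop = FALSE])
  apply_transform(ligand, tf)
}

#' Steric clash test between two structures
#'
#' `TRUE` iff any inter-structure atom pair lies strictly closer than
#' `threshold` (default 1 Angstrom, the dock-rejection rule).
#'
#' @param a,b non-empty structures.
#' @param threshold Angstrom.
#' @export
steric_clash <- function(a, b, threshold = 1.0) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  min_cross_dist(coords(a), coords(b)) < threshold
}

#' Pairwise C-alpha RMSD matrix of docked poses
#'
#' Computes the symmetric matrix of C-alpha RMSDs between poses that
#' already sit in a common receptor frame; by default no pairwise
#' re-superposition is performed (set `refit = TRUE` to re-fit each
#' pair).
#'
#' @param poses list of ligand structures sharing C-alpha sets.
#' @param refit re-superpose each pair before measuring.
#' @return symmetric matrix (Angstrom) with zero diagonal.
#' @export
ca_rmsd_matrix <- function(poses, refit = FALSE) {
  mats <- lapply(poses, function(s) {
    m <- ca_keyed_coords(s)
    if (nrow(m) == 0) stop("pose has no C-alpha atoms")
    m
  })
  keys <- rownames(mats[[1L]])
  for (m in mats)
    if (!identical(rownames(m), keys))
      stop("poses do not share C-alpha sets")
  n <- length(mats)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (refit) {
      out[i, j] <- kabsch_fit(mats[[i]], mats[[j]])$rmsd
    } else {
      out[i, j] <- sqrt(mean(rowSums((mats[[i]] - mats[[j]])^2)))
    }
    out[j, i] <- out[i, j]
  }
  dimnames(out) <- list(names(poses), names(poses))
  out
}

resolve_selection <- function(s, selection) {
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > nrow(s)))
      stop("selection indices out of range")
    return(idx)
  }
  if (!is.data.frame(selection))
    stop("selection must be atom indices or a data frame ",
         "(chain, resseq, name)")
  idx <- integer(0)
  for (i in seq_len(nrow(selection))) {
    hit <- which(s$resseq == selection$resseq[i] &
                   s$name == selection$name[i] &
                   (is.null(selection$chain) | s$chain == selection$chain[i]))
    if (length(hit) == 0)
      stop(sprintf("selection cannot be resolved: %s %s %s",
                   selection$chain[i] %||% "", selection$resseq[i],
                   selection$name[i]))
    idx <- c(idx, hit[1L])
  }
  idx
}

#' Per-frame series from a trajectory of structures
#'
#' Either the RMSD of each frame to a reference (the first frame unless
#' supplied), optionally after least-squares superposition, or the
#' distance between one atom pair (e.g. a Lys N-zeta to Asp C-gamma
#' contact monitor).
#'
#' @param frames list of structures sharing atom ordering.
#' @param mode `"rmsd"` or `"distance"`.
#' @param selection atom indices or data frame (chain, resseq, name);
#'   `"distance"` requires exactly 2 atoms.
#' @param reference optional reference structure for `"rmsd"`.
#' @param superpose superpose each frame onto the reference first.
#' @param frame_interval time between frames, ns.
#' @return data frame (`time`, `value`) of class `series_result`.
#' @export
trajectory_series <- function(frames, mode = c("rmsd", "distance"),
                              selection = NULL, reference = NULL,
                              superpose = FALSE, frame_interval = 1) {
  mode <- match.arg(mode)
  stopifnot(length(frames) >= 1, frame_interval > 0)
  s1 <- frames[[1L]]
  idx <- if (is.null(selection)) seq_len(nrow(s1))
         else resolve_selection(s1, selection)
  if (mode == "distance" && length(idx) != 2L)
    stop("distance mode requires a selection of exactly 2 atoms, got ",
         length(idx))
  ref <- if (is.null(reference)) s1 else reference
  refxyz <- coords(ref)[idx, , drop = FALSE]
  values <- vapply(frames, function(f) {
    xyz <- coords(f)[idx, , drop = FALSE]
    if (mode == "distance") return(vnorm(xyz[1L, ] - xyz[2L, ]))
    if (superpose) {
      tf <- kabsch_fit(xyz, refxyz)
      xyz <- apply_transform(xyz, tf)
    }
    sqrt(mean(rowSums((xyz - refxyz)^2)))
  }, numeric(1))
  out <- data.frame(time = (seq_along(frames) - 1L) * frame_interval,
                    value = values)
  class(out) <- c("series_result", "data.frame")
  out
}

#' @rdname trajectory_series
#' @param series a `series_result`.
#' @param path output TSV path (columns time_ns, value_A).
#' @export
write_series_tsv <- function(series, path) {
  utils::write.table(
    data.frame(time_ns = series$time, value_A = series$value),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
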