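#' Water-position ensembles
#'
#' Frames of water oxygen (and optionally hydrogen) coordinates around a
#' fixed solute, as produced by an MD trajectory or by
#' [make_water_ensemble()]. Oxygen positions are a list of per-frame
#' n_i x 3 matrices; hydrogens, when present, a list of 2*n_i x 3
#' matrices with rows 2i-1, 2i belonging to oxygen i.
#'
#' @param oxygens list of per-frame oxygen coordinate matrices.
#' @param hydrogens optional list of per-frame hydrogen matrices.
#' @param frame_interval sampling interval, ps (> 0).
#' @param bulk_density bulk water number density, waters/Angstrom^3.
#' @param box optional 2 x 3 matrix (min/max per axis).
#' @export
water_ensemble <- function(oxygens, hydrogens = NULL, frame_interval = 0.5,
                           bulk_density = 0.0334, box = NULL) {
  stopifnot(is.list(oxygens), length(oxygens) >= 1, frame_interval > 0,
            bulk_density > 0)
  oxygens <- lapply(oxygens, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 3L)
    m
  })
  if (!is.null(hydrogens)) {
    stopifnot(length(hydrogens) == length(oxygens))
    hydrogens <- lapply(hydrogens, as.matrix)
    nh <- vapply(hydrogens, nrow, 0L)
    no <- vapply(oxygens, nrow, 0L)
    if (!all(nh == 2L * no))
      stop("hydrogen counts inconsistent with oxygen counts")
  }
  structure(list(n_frames = length(oxygens),
                 frame_interval = frame_interval,
                 oxygens = oxygens, hydrogens = hydrogens,
                 bulk_density = bulk_density, box = box),
            class = "water_ensemble")
}

#' @export
print.water_ensemble <- function(x, ...) {
  n <- vapply(x$oxygens, nrow, 0L)
  cat(sprintf(
    "<water_ensemble: %d frames @ %.2f ps, %.1f waters/frame (mean)%s>\n",
    x$n_frames, x$frame_interval, mean(n),
    if (is.null(x$hydrogens)) "" else ", with hydrogens"))
  invisible(x)
}

# Pool all oxygen positions; attribute "frame" maps rows to frames.
pooled_oxygens <- function(ens) {
  n <- vapply(ens$oxygens, nrow, 0L)
  p <- do.call(rbind, ens$oxygens)
  attr(p, "frame") <- rep.int(seq_along(ens$oxygens), n)
  p
}

#' Pick hydration sites by greedy density maxima
#'
#' Water density is histogrammed on a cubic grid; starting from the
#' densest voxel and working down, each candidate site centre is the
#' mean oxygen position within `radius` of that voxel, accepted only if
#' at least `min_sep` from every already-picked site. Picking stops when
#' the remaining maximum voxel density falls below `stop_density` (in
#' units of bulk) or `max_sites` is reached.
#'
#' @param ens a [water_ensemble()].
#' @param solute optional `pdb_structure` used to attach per-site
#'   distances `d_heavy` / `d_hydrophobic` (requires assigned
#'   properties for the hydrophobic distance).
#' @param radius site radius, Angstrom.
#' @param min_sep exclusion distance between site centres, Angstrom.
#' @param grid density grid spacing, Angstrom.
#' @param stop_density relative density below which picking stops.
#' @param max_sites optional cap on the number of sites.
#' @return data frame of class `hydration_sites`: site_id, x, y, z,
#'   radius, density (relative to bulk), occupancy, d_heavy,
#'   d_hydrophobic; ordered by decreasing density.
#' @export
pick_sites <- function(ens, solute = NULL, radius = 1.2, min_sep = 2.4,
                       grid = 0.5, stop_density = 1.0, max_sites = Inf) {
  stopifnot(inherits(ens, "water_ensemble"), ens$n_frames >= 1)
  p <- pooled_oxygens(ens)
  frame_of <- attr(p, "frame")
  if (nrow(p) == 0) stop("empty ensemble: no water positions")

  ix <- floor(p[, 1L] / grid); iy <- floor(p[, 2L] / grid)
  iz <- floor(p[, 3L] / grid)
  key <- paste(ix, iy, iz)
  counts <- table(key)
  voxel_rel <- as.numeric(counts) /
    (ens$n_frames * grid^3 * ens$bulk_density)
  vox <- do.call(rbind, strsplit(names(counts), " ", fixed = TRUE))
  vox <- matrix(as.numeric(vox), ncol = 3L)
  # decreasing density; ties broken lowest (z, y, x), deterministically
  ord <- order(-voxel_rel, vox[, 3L], vox[, 2L], vox[, 1L])
  vox <- vox[ord, , drop = FALSE]
  voxel_rel <- voxel_rel[ord]

  point_index <- split(seq_len(nrow(p)), key)
  reach <- ceiling(radius / grid) + 1L
  offsets <- as.matrix(expand.grid(dx = -reach:reach, dy = -reach:reach,
                                   dz = -reach:reach))
  nearby_points <- function(v) {
    keys <- paste(v[1L] + offsets[, 1L], v[2L] + offsets[, 2L],
                  v[3L] + offsets[, 3L])
    unlist(point_index[keys], use.names = FALSE)
  }

  # a site sphere must lie wholly inside the sampled region: clipped
  # spheres have biased density and position statistics
  in_bounds <- function(ctr) {
    is.null(ens$box) ||
      (all(ctr - radius >= ens$box[1L, ]) &&
         all(ctr + radius <= ens$box[2L, ]))
  }

  v_sphere <- 4 / 3 * pi * radius^3
  centers <- matrix(numeric(0), ncol = 3L)
  dens <- occ <- numeric(0)
  for (k in seq_len(nrow(vox))) {
    if (voxel_rel[k] < stop_density || nrow(centers) >= max_sites) break
    vc <- (vox[k, ] + 0.5) * grid
    if (!in_bounds(vc)) next
    if (nrow(centers) > 0 &&
        min(dist2_to_point(centers, vc)) < min_sep^2) next
    cand <- nearby_points(vox[k, ])
    d2 <- dist2_to_point(p[cand, , drop = FALSE], vc)
    inside <- cand[d2 <= radius^2]
    if (length(inside) == 0) next
    ctr <- colMeans(p[inside, , drop = FALSE])
    if (!in_bounds(ctr)) next
    if (nrow(centers) > 0 &&
        min(dist2_to_point(centers, ctr)) < min_sep^2) next
    # recount around the refined centre
    cand2 <- nearby_points(floor(ctr / grid))
    d2c <- dist2_to_point(p[cand2, , drop = FALSE], ctr)
    members <- cand2[d2c <= radius^2]
    centers <- rbind(centers, ctr)
    dens <- c(dens, length(members) /
                (ens$n_frames * v_sphere * ens$bulk_density))
    occ <- c(occ, length(unique(frame_of[members])) / ens$n_frames)
  }

  if (nrow(centers) == 0) {
    out <- data.frame(site_id = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), radius = numeric(0),
                      density = numeric(0), occupancy = numeric(0),
                      d_heavy = numeric(0), d_hydrophobic = numeric(0))
    class(out) <- c("hydration_sites", "data.frame")
    return(out)
  }

  ord2 <- order(-dens)
  centers <- centers[ord2, , drop = FALSE]
  dens <- dens[ord2]; occ <- occ[ord2]
  out <- data.frame(
    site_id = sprintf("S%03d", seq_len(nrow(centers))),
    x = centers[, 1L], y = centers[, 2L], z = centers[, 3L],
    radius = radius, density = dens, occupancy = occ,
    d_heavy = NA_real_, d_hydrophobic = NA_real_,
    stringsAsFactors = FALSE)
  out <- attach_solute_distances(out, solute)
  class(out) <- c("hydration_sites", "data.frame")
  rownames(out) <- NULL
  out
}

attach_solute_distances <- function(sites, solute) {
  if (is.null(solute) || nrow(solute) == 0) {
    sites$d_heavy <- Inf
    sites$d_hydrophobic <- Inf
    return(sites)
  }
  hv <- heavy_atoms(solute)
  hxyz <- coords(hv)
  phob <- !is.na(hv$hydrophobic) & hv$hydrophobic
  for (i in seq_len(nrow(sites))) {
    p <- c(sites$x[i], sites$y[i], sites$z[i])
    d2 <- dist2_to_point(hxyz, p)
    sites$d_heavy[i] <- sqrt(min(d2))
    sites$d_hydrophobic[i] <- if (any(phob)) sqrt(min(d2[phob])) else Inf
  }
  sites
}

#' Frame subset of a water ensemble
#'
#' Used for split-sample scoring: picking sites on one half of the
#' frames and estimating site thermodynamics on the other removes the
#' selection bias of scoring density maxima on the frames that defined
#' them.
#'
#' @param ens a [water_ensemble()].
#' @param frames integer frame indices to keep.
#' @export
ens_subset <- function(ens, frames) {
  stopifnot(all(frames >= 1), all(frames <= ens$n_frames))
  water_ensemble(ens$oxygens[frames],
                 hydrogens = if (is.null(ens$hydrogens)) NULL
                 else ens$hydrogens[frames],
                 frame_interval = ens$frame_interval,
                 bulk_density = ens$bulk_density, box = ens$box)
}

#' Occupancy of a hydration site
#'
#' Fraction of frames with at least one water oxygen within the site
#' radius of the site centre.
#'
#' @param ens a [water_ensemble()].
#' @param site one row of a `hydration_sites` frame (or any list with
#'   x, y, z, radius).
#' @return fraction in \[0, 1\].
#' @export
site_occupancy <- function(ens, site) {
  ctr <- c(site$x, site$y, site$z)
  r2 <- site$radius^2
  hit <- vapply(ens$oxygens, function(m) {
    nrow(m) > 0 && min(dist2_to_point(m, ctr)) <= r2
  }, logical(1))
  mean(hit)
}

#' @rdname pick_sites
#' @param sites a `hydration_sites` frame.
#' @param path output path.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pick_sites
#' @export
write_sites_pdb <- function(sites, path = NULL) {
  s <- new_structure(data.frame(
    serial = seq_len(nrow(sites)), name = "O", element = "O",
    resname = "HOH", chain = "W", resseq = seq_len(nrow(sites)),
    altloc = "", occupancy = pmin(1, sites$occupancy),
    x = sites$x, y = sites$y, z = sites$z, stringsAsFactors = FALSE))
  write_model(s, path)
}
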