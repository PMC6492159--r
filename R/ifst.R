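#' Simple nonbonded potential model
#'
#' A pairwise Lennard-Jones + plain-Coulomb potential used to score
#' water interaction energies, plus optional isotropic Gaussian
#' attractive wells (the planted wells of the synthetic generator are
#' part of the same Hamiltonian the generator samples from). Parameters
#' follow a TIP3P-like water (epsilon_O 0.6364 kJ/mol, sigma_O 3.1507 A,
#' q_O -0.834 e, q_H +0.417 e) and generic per-element solute classes.
#' Combining rules are Lorentz-Berthelot; electrostatics are plain
#' Coulomb screened by a relative permittivity.
#'
#' @param classes data frame (class, epsilon, sigma, charge); must
#'   include rows `OW` and `HW` for water.
#' @param cutoff interaction cutoff on oxygen/heavy-atom distances, A.
#' @param dielectric relative permittivity for the Coulomb term.
#' @param wells optional data frame (x, y, z, depth, width): attractive
#'   wells U(r) = -depth * exp(-|r - c|^2 / (2 width^2)) acting on water
#'   oxygens; depths in kJ/mol, widths in A.
#' @export
potential_model <- function(classes = default_potential_classes(),
                            cutoff = 10, dielectric = 1, wells = NULL) {
  stopifnot(all(c("class", "epsilon", "sigma", "charge") %in%
                  names(classes)),
            all(c("OW", "HW") %in% classes$class),
            all(classes$epsilon >= 0), cutoff > max(classes$sigma))
  if (!is.null(wells)) {
    stopifnot(all(c("x", "y", "z", "depth", "width") %in% names(wells)),
              all(wells$depth >= 0), all(wells$width > 0))
  }
  structure(list(classes = classes, cutoff = cutoff,
                 dielectric = dielectric, wells = wells),
            class = "potential_model")
}

#' @rdname potential_model
#' @export
default_potential_classes <- function() {
  data.frame(
    class   = c("OW", "HW", "C", "N", "O", "S", "H", "X"),
    epsilon = c(0.6364, 0, 0.30, 0.71, 0.88, 1.05, 0, 0.30),
    sigma   = c(3.1507, 1.0, 3.40, 3.25, 3.00, 3.55, 1.0, 3.40),
    charge  = c(-0.834, 0.417, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

# Coulomb prefactor: e^2 / (4 pi eps0), in kJ/mol * Angstrom.
COULOMB_KJ_A <- 138.935458

pot_row <- function(pot, cls) {
  i <- match(cls, pot$classes$class)
  if (anyNA(i)) stop("potential model lacks class(es): ",
                     paste(unique(cls[is.na(i)]), collapse = ", "))
  pot$classes[i, , drop = FALSE]
}

# LJ + Coulomb of one water (O position o, optional 2x3 H positions)
# against a set of partner atoms; vectorised over partners.
water_site_energy_terms <- function(o, h, pxyz, peps, psig, pq, pot) {
  if (nrow(pxyz) == 0) return(0)
  d2 <- dist2_to_point(pxyz, o)
  keep <- d2 <= pot$cutoff^2 & d2 > 1e-12
  if (!any(keep)) return(0)
  d <- sqrt(d2[keep])
  ow <- pot_row(pot, "OW")
  eps <- sqrt(ow$epsilon * peps[keep])
  sig <- (ow$sigma + psig[keep]) / 2
  sr6 <- (sig / d)^6
  e <- sum(4 * eps * (sr6^2 - sr6))
  # electrostatics: water charges against partner charges
  qs <- pq[keep]
  if (any(qs != 0)) {
    hw <- pot_row(pot, "HW")
    if (ow$charge != 0)
      e <- e + sum(COULOMB_KJ_A * ow$charge * qs / d) / pot$dielectric
    if (!is.null(h) && hw$charge != 0) {
      for (k in 1:2) {
        dh <- sqrt(dist2_to_point(pxyz[keep, , drop = FALSE], h[k, ]))
        e <- e + sum(COULOMB_KJ_A * hw$charge * qs / pmax(dh, 1e-6)) /
          pot$dielectric
      }
    }
  }
  e
}

wells_energy <- function(o, pot) {
  if (is.null(pot$wells) || nrow(pot$wells) == 0) return(0)
  w <- pot$wells
  d2 <- (w$x - o[1L])^2 + (w$y - o[2L])^2 + (w$z - o[3L])^2
  -sum(w$depth * exp(-d2 / (2 * w$width^2)))
}

# Total energy of water i in frame k: solute term + wells + half the
# water-water term (standard IFST bookkeeping to avoid double counting).
energy_of_water <- function(ens, frame, i, solute_xyz, solute_pars, pot) {
  om <- ens$oxygens[[frame]]
  o <- om[i, ]
  h <- if (!is.null(ens$hydrogens))
    ens$hydrogens[[frame]][c(2L * i - 1L, 2L * i), , drop = FALSE]
  else NULL
  e <- wells_energy(o, pot)
  if (!is.null(solute_xyz) && nrow(solute_xyz) > 0)
    e <- e + water_site_energy_terms(o, h, solute_xyz,
                                     solute_pars$epsilon,
                                     solute_pars$sigma,
                                     solute_pars$charge, pot)
  if (nrow(om) > 1L) {
    others <- setdiff(seq_len(nrow(om)), i)
    d2 <- dist2_to_point(om[others, , drop = FALSE], o)
    near <- others[d2 <= pot$cutoff^2]
    if (length(near) > 0) {
      ow <- pot_row(pot, "OW"); hw <- pot_row(pot, "HW")
      d <- sqrt(dist2_to_point(om[near, , drop = FALSE], o))
      sr6 <- (ow$sigma / d)^6
      ew <- sum(4 * ow$epsilon * (sr6^2 - sr6))
      if (!is.null(ens$hydrogens) && ow$charge != 0) {
        # 3x3 charge-site Coulomb, vectorised over the near partners
        hm <- ens$hydrogens[[frame]]
        self_sites <- rbind(o, h)
        self_q <- c(ow$charge, hw$charge, hw$charge)
        part <- list(om[near, , drop = FALSE],
                     hm[2L * near - 1L, , drop = FALSE],
                     hm[2L * near, , drop = FALSE])
        part_q <- c(ow$charge, hw$charge, hw$charge)
        for (si in 1:3) for (ti in 1:3) {
          dd <- sqrt(dist2_to_point(part[[ti]], self_sites[si, ]))
          ew <- ew + sum(COULOMB_KJ_A * self_q[si] * part_q[ti] /
                           pmax(dd, 1e-6)) / pot$dielectric
        }
      }
      e <- e + 0.5 * ew
    }
  }
  e
}

solute_param_table <- function(solute, pot) {
  if (is.null(solute) || nrow(solute) == 0) return(NULL)
  hv <- heavy_atoms(solute)
  pars <- pot_row(pot, toupper(hv$element))
  list(xyz = coords(hv), pars = pars)
}

# All (frame, oxygen) instances inside the site sphere. Using every
# in-sphere water (rather than e.g. the nearest to the centre) keeps
# the position sample unbiased: under a uniform fluid the in-sphere
# positions are exactly uniform.
site_waters <- function(ens, site) {
  ctr <- c(site$x, site$y, site$z)
  r2 <- site$radius^2
  frames <- integer(0); idx <- integer(0)
  for (k in seq_len(ens$n_frames)) {
    m <- ens$oxygens[[k]]
    if (nrow(m) == 0) next
    j <- which(dist2_to_point(m, ctr) <= r2)
    if (length(j) > 0) {
      frames <- c(frames, rep.int(k, length(j)))
      idx <- c(idx, j)
    }
  }
  list(frames = frames, index = idx)
}

#' Bulk reference interaction energy
#'
#' Mean energy (solute + wells + half water-water) of waters in the bulk
#' reference region: farther than `bulk_min_dist` from any solute heavy
#' atom and from any well centre of the potential (i.e. where the
#' Hamiltonian is flat). Sampled deterministically (every k-th bulk
#' water) up to `max_samples` instances. Returns 0 when the region is
#' empty.
#'
#' @param ens a [water_ensemble()].
#' @param solute optional solute structure.
#' @param pot a [potential_model()].
#' @param bulk_min_dist Angstrom; default 8 (site free energies decay to
#'   zero by 7-8 A from the surface).
#' @param max_samples cap on water-frame instances averaged.
#' @export
bulk_reference_energy <- function(ens, solute = NULL, pot,
                                  bulk_min_dist = 8, max_samples = 4000) {
  sp <- solute_param_table(solute, pot)
  excl <- sp$xyz
  if (!is.null(pot$wells) && nrow(pot$wells) > 0)
    excl <- rbind(excl, cbind(pot$wells$x, pot$wells$y, pot$wells$z))
  inst <- list()
  for (k in seq_len(ens$n_frames)) {
    m <- ens$oxygens[[k]]
    if (nrow(m) == 0) next
    ok <- if (is.null(excl)) seq_len(nrow(m)) else {
      d2 <- cross_dist(m, excl)^2
      which(apply(d2, 1L, min) > bulk_min_dist^2)
    }
    if (length(ok) > 0)
      inst[[length(inst) + 1L]] <- cbind(k, ok)
  }
  if (length(inst) == 0) return(0)
  inst <- do.call(rbind, inst)
  if (nrow(inst) > max_samples) {
    step <- nrow(inst) / max_samples
    inst <- inst[floor(seq(1, nrow(inst), by = step)), , drop = FALSE]
  }
  e <- vapply(seq_len(nrow(inst)), function(r)
    energy_of_water(ens, inst[r, 1L], inst[r, 2L],
                    sp$xyz %||% NULL,
                    sp$pars %||% NULL, pot), numeric(1))
  mean(e)
}

#' Per-site interaction energy relative to bulk
#'
#' Mean, over the in-sphere water instances of the site's occupied
#' frames, of the water's solute interaction plus half its water-water
#' interaction, minus the same mean over the bulk reference region.
#'
#' @inheritParams bulk_reference_energy
#' @param site one row of a `hydration_sites` frame.
#' @param bulk_ref precomputed [bulk_reference_energy()] (computed here
#'   when `NULL`; pass it explicitly when scoring many sites).
#' @return energy difference, kJ/mol.
#' @export
site_interaction_energy <- function(ens, solute = NULL, site, pot,
                                    bulk_ref = NULL, bulk_min_dist = 8) {
  sw <- site_waters(ens, site)
  if (length(sw$frames) == 0)
    stop("site has zero occupancy: interaction energy undefined")
  sp <- solute_param_table(solute, pot)
  e <- vapply(seq_along(sw$frames), function(r)
    energy_of_water(ens, sw$frames[r], sw$index[r],
                    sp$xyz %||% NULL, sp$pars %||% NULL, pot),
    numeric(1))
  if (is.null(bulk_ref))
    bulk_ref <- bulk_reference_energy(ens, solute, pot, bulk_min_dist)
  mean(e) - bulk_ref
}

# Kozachenko-Leonenko first-nearest-neighbour differential entropy
# (nats) of d-dimensional samples given their NN distances.
kl_entropy_from_nn <- function(r, d, c_d) {
  n <- length(r)
  d * mean(log(pmax(r, 1e-10))) + log(c_d) + log(n - 1) +
    -digamma(1)
}

nn_dists <- function(x) {
  dm <- as.matrix(stats::dist(x))
  diag(dm) <- Inf
  apply(dm, 1L, min)
}

quat_nn_dists <- function(q) {
  # geodesic rotation distance with antipodal identification
  dot <- abs(tcrossprod(q))
  dot[dot > 1] <- 1
  ang <- 2 * acos(dot)
  diag(ang) <- Inf
  apply(ang, 1L, min)
}

water_orientation_quats <- function(ens, frames, idx) {
  q <- matrix(0, nrow = length(frames), ncol = 4L)
  for (r in seq_along(frames)) {
    k <- frames[r]; i <- idx[r]
    o <- ens$oxygens[[k]][i, ]
    h <- ens$hydrogens[[k]][c(2L * i - 1L, 2L * i), , drop = FALSE]
    ex <- unit((h[1L, ] - o) + (h[2L, ] - o))
    ez <- unit(cross3(h[1L, ] - o, h[2L, ] - o))
    ey <- cross3(ez, ex)
    q[r, ] <- rot_to_quat(cbind(ex, ey, ez))
  }
  q
}

#' Per-site translational and orientational entropy relative to bulk
#'
#' Translational term: minus the Kullback-Leibler divergence of the site
#' water's position distribution against the uniform distribution over
#' the site sphere; orientational term: the same against isotropic
#' orientations (quaternion metric). Both are estimated with
#' first-nearest-neighbour differential entropies; the reference entropy
#' is computed on a matched-size sample (same n, same estimator) so the
#' estimator bias cancels, making both terms ~0 for uniform/isotropic
#' water and negative for localised or ordered water.
#'
#' @inheritParams site_interaction_energy
#' @param n_min minimum number of occupied frames (estimator floor).
#' @param max_samples cap on frames used (deterministic thinning).
#' @param ref_seed seed of the private RNG stream used for the matched
#'   reference samples.
#' @param n_ref number of matched reference replicates averaged (their
#'   mean reduces the reference's own estimation noise).
#' @return list with `dS_trans` and `dS_orient`, kJ/mol/K (`dS_orient`
#'   is 0 when the ensemble has no hydrogens).
#' @export
site_entropy <- function(ens, site, n_min = 50, max_samples = 2000,
                         ref_seed = 20260925, n_ref = 8) {
  sw <- site_waters(ens, site)
  n <- length(sw$frames)
  if (n < n_min)
    stop(sprintf("insufficient samples for entropy estimate: %d occupied frames (need >= %d)",
                 n, n_min))
  if (n > max_samples) {
    keep <- floor(seq(1, n, length.out = max_samples))
    sw$frames <- sw$frames[keep]; sw$index <- sw$index[keep]
    n <- length(sw$frames)
  }
  ctr <- c(site$x, site$y, site$z)
  x <- t(vapply(seq_along(sw$frames), function(r)
    ens$oxygens[[sw$frames[r]]][sw$index[r], ] - ctr, numeric(3)))

  c3 <- 4 / 3 * pi
  h_site <- kl_entropy_from_nn(nn_dists(x), 3L, c3)
  h_ref <- mean(vapply(seq_len(n_ref), function(r) {
    ref <- with_local_seed(ref_seed + n + 131L * r, {
      u <- matrix(stats::rnorm(3L * n), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      u * (stats::runif(n)^(1 / 3) * site$radius)
    })
    kl_entropy_from_nn(nn_dists(ref), 3L, c3)
  }, numeric(1)))
  dS_trans <- GAS_CONSTANT * (h_site - h_ref)

  dS_orient <- 0
  if (!is.null(ens$hydrogens)) {
    q <- water_orientation_quats(ens, sw$frames, sw$index)
    h_o <- kl_entropy_from_nn(quat_nn_dists(q), 3L, c3)
    h_oref <- mean(vapply(seq_len(n_ref), function(r) {
      qref <- with_local_seed(ref_seed + 7L * n + 131L * r,
                              quat_random(n))
      kl_entropy_from_nn(quat_nn_dists(qref), 3L, c3)
    }, numeric(1)))
    dS_orient <- GAS_CONSTANT * (h_o - h_oref)
  }
  list(dS_trans = dS_trans, dS_orient = dS_orient)
}

#' Combine energy and entropy terms into site thermodynamics
#'
#' `dG_hyd = dE - T (dS_trans + dS_orient)` is the free energy of
#' hydrating the site with a single water relative to bulk (mostly
#' negative: solvation is favourable); `displacement_cost = -dG_hyd` is
#' the price of evicting that water. Patch ranking uses
#' `displacement_cost` ascending (easiest-to-desolvate first).
#'
#' @param dE interaction energy difference, kJ/mol.
#' @param dS_trans,dS_orient entropy differences, kJ/mol/K.
#' @param temperature K.
#' @param site_id optional label.
#' @return one-row data frame (site_id, dE, dS_trans, dS_orient,
#'   temperature, dG_hyd, displacement_cost).
#' @export
site_free_energy <- function(dE, dS_trans, dS_orient, temperature = 300,
                             site_id = NA_character_) {
  stopifnot(is.finite(dE), is.finite(dS_trans), is.finite(dS_orient),
            temperature > 0)
  dG <- dE - temperature * (dS_trans + dS_orient)
  data.frame(site_id = site_id, dE = dE, dS_trans = dS_trans,
             dS_orient = dS_orient, temperature = temperature,
             dG_hyd = dG, displacement_cost = -dG,
             stringsAsFactors = FALSE)
}

#' Score a set of hydration sites with IFST thermodynamics
#'
#' Convenience pipeline: one bulk reference, then per-site energy,
#' entropy and free energy. Sites with too few occupied frames for the
#' entropy estimator are returned with `NA` thermodynamics (and a
#' warning) rather than dropped.
#'
#' @inheritParams site_interaction_energy
#' @param sites a `hydration_sites` frame.
#' @param temperature K.
#' @param n_min entropy estimator floor (occupied frames).
#' @return `sites` with columns dE, dS_trans, dS_orient, dG_hyd,
#'   displacement_cost appended.
#' @export
score_sites <- function(ens, solute = NULL, sites, pot = potential_model(),
                        temperature = 300, bulk_min_dist = 8, n_min = 50) {
  stopifnot(nrow(sites) >= 1)
  bulk_ref <- bulk_reference_energy(ens, solute, pot, bulk_min_dist)
  out <- sites
  out$dE <- out$dS_trans <- out$dS_orient <- out$dG_hyd <-
    out$displacement_cost <- NA_real_
  skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    th <- tryCatch({
      dE <- site_interaction_energy(ens, solute, site, pot,
                                    bulk_ref = bulk_ref)
      ds <- site_entropy(ens, site, n_min = n_min)
      site_free_energy(dE, ds$dS_trans, ds$dS_orient, temperature,
                       site_id = site$site_id)
    }, error = function(e) NULL)
    if (is.null(th)) { skipped <- skipped + 1L; next }
    out$dE[i] <- th$dE
    out$dS_trans[i] <- th$dS_trans
    out$dS_orient[i] <- th$dS_orient
    out$dG_hyd[i] <- th$dG_hyd
    out$displacement_cost[i] <- th$displacement_cost
  }
  if (skipped > 0)
    warning(skipped, " site(s) left unscored (undersampled)")
  attr(out, "bulk_reference") <- bulk_ref
  out
}
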