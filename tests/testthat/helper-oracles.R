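# Independent oracles and fixture builders shared across the suite.

# Horn's quaternion-method absolute orientation: an independent oracle
# for least-squares rigid superposition (no SVD, no shared code path).
horn_fit_rmsd <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  S <- crossprod(P, Q)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
}

# Exhaustive connected-subset enumeration (combn + BFS connectivity):
# the oracle for the branch-and-bound cluster search.
brute_force_clusters <- function(sites, costs, smin, smax, window,
                                 link_cutoff = 4.0) {
  xyz <- cbind(sites$x, sites$y, sites$z)
  n <- nrow(sites)
  adj <- as.matrix(stats::dist(xyz)) <= link_cutoff
  diag(adj) <- FALSE
  connected <- function(v) {
    seen <- v[1]; queue <- v[1]
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      nb <- v[adj[u, v] & !(v %in% seen)]
      seen <- c(seen, nb); queue <- c(queue, nb)
    }
    length(seen) == length(v)
  }
  out <- list()
  for (s in smin:min(smax, n)) {
    if (s > n) next
    cs <- utils::combn(n, s)
    res_cost <- numeric(0); res_key <- character(0)
    for (ci in seq_len(ncol(cs))) {
      v <- cs[, ci]
      if (connected(v)) {
        res_cost <- c(res_cost, sum(costs[v]))
        res_key <- c(res_key,
                     paste(sort(sites$site_id[v]), collapse = ","))
      }
    }
    if (length(res_cost) == 0) next
    keep <- res_cost <= min(res_cost) + window + 1e-9
    res_cost <- res_cost[keep]; res_key <- res_key[keep]
    ord <- order(res_cost, res_key)
    out[[length(out) + 1]] <- data.frame(
      size = s, total_cost = res_cost[ord], key = res_key[ord],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

cluster_keys <- function(bc) {
  if (nrow(bc) == 0) return(character(0))
  paste(bc$size,
        vapply(bc$members, function(m) paste(m, collapse = ","), ""),
        signif(bc$total_cost, 12))
}

# Minimal hydration_sites frame from coordinates.
toy_sites <- function(xyz, d_heavy = 1, d_hydrophobic = 1, radius = 1.2) {
  xyz <- as.matrix(xyz)
  out <- data.frame(
    site_id = sprintf("S%03d", seq_len(nrow(xyz))),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = radius,
    density = 1, occupancy = 1,
    d_heavy = rep_len(d_heavy, nrow(xyz)),
    d_hydrophobic = rep_len(d_hydrophobic, nrow(xyz)),
    stringsAsFactors = FALSE)
  class(out) <- c("hydration_sites", "data.frame")
  out
}

# Minimal structure from a coordinate matrix (all carbon CA atoms).
toy_structure <- function(xyz, element = "C", name = "CA",
                          resseq = NULL, chain = "A", resname = "ALA") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  new_structure(data.frame(
    serial = seq_len(n), name = rep_len(name, n),
    element = rep_len(element, n), resname = rep_len(resname, n),
    chain = rep_len(chain, n),
    resseq = resseq %||% seq_len(n), altloc = "", occupancy = 1,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct 7-condition median-split check, independent of the package's
# vectorised implementation (lower median, inclusive ties).
brute_median_split <- function(metric_df) {
  lower_med <- function(x) sort(x)[ceiling(length(x) / 2)]
  meds <- vapply(metric_df, lower_med, numeric(1))
  sel <- logical(nrow(metric_df))
  for (i in seq_len(nrow(metric_df))) {
    ok <- metric_df$energy[i] <= meds["energy"]
    for (nm in setdiff(names(metric_df), "energy"))
      ok <- ok && metric_df[[nm]][i] >= meds[nm]
    sel[i] <- ok
  }
  sel
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}
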