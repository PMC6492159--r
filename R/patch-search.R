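#' Eligibility classes for cluster membership
#'
#' A hydration site may join a cluster of a given class when it lies
#' within `cutoff_any` of the nearest solute heavy atom or within the
#' (larger) `cutoff_hydrophobic` of the nearest hydrophobic heavy atom.
#' Canonical classes: near (3.1, 3.6), regular (3.6, 4.1), far
#' (4.1, 4.5) Angstrom.
#'
#' @param name `"near"`, `"regular"` or `"far"`, or a custom label when
#'   both cutoffs are supplied.
#' @param cutoff_any,cutoff_hydrophobic optional custom cutoffs
#'   (`cutoff_hydrophobic >= cutoff_any`).
#' @export
eligibility_class <- function(name = c("regular", "near", "far"),
                              cutoff_any = NULL,
                              cutoff_hydrophobic = NULL) {
  if (is.null(cutoff_any)) {
    name <- match.arg(name)
    cuts <- switch(name, near = c(3.1, 3.6), regular = c(3.6, 4.1),
                   far = c(4.1, 4.5))
    cutoff_any <- cuts[1L]; cutoff_hydrophobic <- cuts[2L]
  }
  stopifnot(cutoff_hydrophobic >= cutoff_any)
  structure(list(name = name, cutoff_any = cutoff_any,
                 cutoff_hydrophobic = cutoff_hydrophobic),
            class = "eligibility_class")
}

#' Sites eligible to join clusters of a class
#'
#' @param sites `hydration_sites` with `d_heavy` / `d_hydrophobic`
#'   populated (see [pick_sites()]).
#' @param cls an [eligibility_class()] or class name.
#' @return the eligible subset of `sites`.
#' @export
eligible_sites <- function(sites, cls = "regular") {
  if (!inherits(cls, "eligibility_class")) cls <- eligibility_class(cls)
  if (nrow(sites) == 0) return(sites)
  keep <- sites$d_heavy <= cls$cutoff_any |
    sites$d_hydrophobic <= cls$cutoff_hydrophobic
  sites[keep, , drop = FALSE]
}

#' Spatial adjacency graph of hydration sites
#'
#' Sites are linked when their centres lie within `link_cutoff`
#' (default 4.0 Angstrom, just above second-shell O-O spacing given the
#' 2.4 Angstrom site exclusion distance).
#'
#' @param sites a `hydration_sites` frame.
#' @param link_cutoff Angstrom.
#' @return an undirected [igraph::graph] with vertex names = site ids.
#' @export
site_adjacency <- function(sites, link_cutoff = 4.0) {
  stopifnot(nrow(sites) >= 1)
  xyz <- cbind(sites$x, sites$y, sites$z)
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= link_cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sites$site_id
  g
}

# Enumerate connected induced subgraphs with sizes in [smin, smax] whose
# total cost is within `window` of the per-size running best, by
# depth-first expansion with a canonical root (each subgraph visited
# once: its minimum-index vertex) and an admissible lower bound (sum of
# the cheapest remaining costs needed to reach each size).
connected_cluster_search <- function(adj_list, costs, smin, smax, window,
                                     global_window = FALSE) {
  n <- length(adj_list)
  best <- rep(Inf, smax)           # per-size running minimum
  found <- vector("list", smax)    # per-size list of (members, cost)
  sorted_costs <- sort(costs)

  # admissible: cheapest conceivable completion uses the globally
  # smallest costs (excluding none in particular; still a lower bound)
  completion_lb <- function(cur_size, target_size) {
    need <- target_size - cur_size
    if (need <= 0) return(0)
    sum(sorted_costs[seq_len(need)])
  }
  prune <- function(cur_cost, cur_size) {
    for (s in max(cur_size, smin):smax) {
      lim <- if (global_window) min(best) + window else best[s] + window
      if (cur_cost + completion_lb(cur_size, s) <= lim) return(FALSE)
    }
    TRUE
  }

  record <- function(members, cost) {
    s <- length(members)
    if (s >= smin) {
      lim <- if (global_window) min(best) + window else best[s] + window
      if (cost <= lim) {
        found[[s]][[length(found[[s]]) + 1L]] <<-
          list(members = members, cost = cost)
        if (cost < best[s]) best[s] <<- cost
      }
    }
  }

  expand <- function(members, cost, frontier, forbidden) {
    if (length(members) == smax || length(frontier) == 0) return()
    if (prune(cost, length(members))) return()
    # branch on the first frontier vertex: include or exclude
    v <- frontier[1L]
    rest <- frontier[-1L]
    new_frontier <- c(rest,
                      setdiff(adj_list[[v]],
                              c(members, frontier, forbidden)))
    record(c(members, v), cost + costs[v])
    expand(c(members, v), cost + costs[v], new_frontier, forbidden)
    expand(members, cost, rest, c(forbidden, v))
  }

  for (root in seq_len(n)) {
    # subgraphs whose minimum vertex is `root`: vertices < root forbidden
    record(root, costs[root])
    frontier <- adj_list[[root]][adj_list[[root]] > root]
    expand(root, costs[root], sort(frontier), seq_len(root - 1L))
  }
  list(found = found, best = best)
}

#' Exact search for the best connected clusters of hydration sites
#'
#' For each cluster size in `size_range`, enumerates connected induced
#' subgraphs of the site adjacency graph, ranks them by ascending total
#' displacement cost, and retains those within `window` kJ/mol of the
#' best cluster (per-size reference by default; set
#' `window_reference = "global"` to reference the minimum over all
#' sizes), truncated to `max_per_size`. The search is exact: no
#' qualifying cluster is lost.
#'
#' @param sites eligible `hydration_sites` (>= 1 row gives results;
#'   an empty frame returns an empty list with a warning).
#' @param costs per-site displacement cost, kJ/mol: numeric vector
#'   named by site id (or in site order).
#' @param graph optional precomputed [site_adjacency()] graph.
#' @param size_range integer range of cluster sizes (default 7-18).
#' @param window kJ/mol window above the best cluster (default 12.5).
#' @param max_per_size cap on retained clusters per size (default 1000).
#' @param link_cutoff used when `graph` is not supplied.
#' @param window_reference `"per_size"` or `"global"`.
#' @return data frame of class `site_clusters`: size, total_cost, and a
#'   list-column `members` of site-id vectors; ordered by size then
#'   ascending cost (ties by membership).
#' @export
best_clusters <- function(sites, costs, graph = NULL,
                          size_range = c(7, 18), window = 12.5,
                          max_per_size = 1000, link_cutoff = 4.0,
                          window_reference = c("per_size", "global")) {
  window_reference <- match.arg(window_reference)
  if (!is.null(graph) && !inherits(graph, "igraph"))
    stop("`graph` must be an igraph object (from site_adjacency())")
  empty <- data.frame(size = integer(0), total_cost = numeric(0))
  empty$members <- list()
  class(empty) <- c("site_clusters", "data.frame")
  if (nrow(sites) == 0) {
    warning("no eligible site: empty cluster set")
    return(empty)
  }
  if (!is.null(names(costs))) costs <- costs[sites$site_id]
  stopifnot(length(costs) == nrow(sites), all(is.finite(costs)))
  smin <- size_range[1L]; smax <- min(size_range[2L], nrow(sites))
  if (smax < smin) return(empty)
  if (is.null(graph)) graph <- site_adjacency(sites, link_cutoff)
  adj <- igraph::as_adj_list(graph)
  adj_list <- lapply(adj, function(v) sort(as.integer(v)))

  res <- connected_cluster_search(adj_list, costs, smin, smax, window,
                                  global_window =
                                    window_reference == "global")
  out <- list()
  for (s in smin:smax) {
    cl <- res$found[[s]]
    if (length(cl) == 0) next
    cost_s <- vapply(cl, `[[`, numeric(1), "cost")
    lim <- if (window_reference == "global")
      min(res$best) + window else res$best[s] + window
    keep <- which(cost_s <= lim + 1e-9)
    if (length(keep) == 0) next
    memb <- lapply(cl[keep], `[[`, "members")
    memb_key <- vapply(memb, function(m) paste(sort(m), collapse = ","),
                       "")
    ord <- order(cost_s[keep], memb_key)
    ord <- ord[seq_len(min(length(ord), max_per_size))]
    out[[length(out) + 1L]] <- data.frame(
      size = s, total_cost = cost_s[keep][ord])
    out[[length(out)]]$members <-
      lapply(memb[ord], function(m) sites$site_id[sort(m)])
  }
  if (length(out) == 0) {
    warning("no connected cluster within the size range")
    return(empty)
  }
  res_df <- do.call(rbind, out)
  class(res_df) <- c("site_clusters", "data.frame")
  rownames(res_df) <- NULL
  res_df
}

#' Merge best clusters into hydration patches
#'
#' The union of all member sites of the retained clusters is
#' partitioned into connected components of the adjacency graph (the
#' "clustering of clusters"); each component becomes one patch carrying
#' sample statistics of the per-site values of its members.
#'
#' @param clusters a `site_clusters` frame from [best_clusters()]
#'   (one eligibility class).
#' @param sites the `hydration_sites` the clusters refer to.
#' @param values per-site values for the patch statistics (numeric,
#'   named by site id or in site order); typically `dG_hyd` or
#'   `displacement_cost`.
#' @param graph optional precomputed adjacency graph.
#' @param link_cutoff used when `graph` is not supplied.
#' @param class_name label stored on each patch.
#' @param pass_index pass number recorded on each patch.
#' @return list of class `hydration_patches`; each element has
#'   patch_id, class, pass_index, site_ids and stats (mean, median, sd,
#'   n). Patches are ordered by ascending mean value (most displaceable
#'   first when `values` are displacement costs).
#' @export
clusters_to_patches <- function(clusters, sites, values, graph = NULL,
                                link_cutoff = 4.0, class_name = "regular",
                                pass_index = 1L) {
  if (nrow(clusters) == 0)
    return(structure(list(), class = "hydration_patches"))
  if (!is.null(names(values))) values <- values[sites$site_id]
  stopifnot(length(values) == nrow(sites))
  member_ids <- sort(unique(unlist(clusters$members)))
  sub <- sites[sites$site_id %in% member_ids, , drop = FALSE]
  if (is.null(graph)) {
    g <- site_adjacency(sub, link_cutoff)
  } else {
    g <- igraph::induced_subgraph(graph, member_ids)
  }
  comp <- igraph::components(g)
  vals <- stats::setNames(values, sites$site_id)
  patches <- lapply(seq_len(comp$no), function(ci) {
    ids <- names(comp$membership)[comp$membership == ci]
    v <- vals[ids]
    list(patch_id = NA_character_, class = class_name,
         pass_index = pass_index, site_ids = sort(ids),
         stats = patch_statistics(v))
  })
  means <- vapply(patches, function(p) p$stats["mean"], numeric(1))
  patches <- patches[order(means)]
  for (i in seq_along(patches))
    patches[[i]]$patch_id <- sprintf("P%d.%d", pass_index, i)
  structure(patches, class = "hydration_patches")
}

#' Sample statistics of a patch's per-site values
#'
#' @param values numeric vector (n >= 1); the standard deviation uses
#'   the n-1 denominator.
#' @return named vector: mean, median, sd, n.
#' @export
patch_statistics <- function(values) {
  stopifnot(length(values) >= 1)
  c(mean = mean(values), median = stats::median(values),
    sd = stats::sd(values), n = length(values))
}

#' Multi-pass extraction of hydration patches
#'
#' Repeats the best-cluster search and patch formation, removing the
#' sites of previously identified patches after each pass, until no
#' cluster of the minimum size remains (or `max_passes` is reached).
#' Earlier passes contain the most displaceable (cheapest) patches.
#'
#' @param sites scored `hydration_sites` (already filtered for
#'   eligibility, or pass `cls` to filter here).
#' @param costs per-site displacement costs driving the search.
#' @param values per-site values for the patch statistics (defaults to
#'   `costs`).
#' @param cls optional [eligibility_class()] applied before the first
#'   pass.
#' @param max_passes safety cap.
#' @inheritParams best_clusters
#' @return `hydration_patches` list across passes (pass_index recorded
#'   per patch).
#' @export
multi_pass_patches <- function(sites, costs, values = costs, cls = NULL,
                               size_range = c(7, 18), window = 12.5,
                               max_per_size = 1000, link_cutoff = 4.0,
                               max_passes = 10L) {
  if (!is.null(names(costs))) costs <- stats::setNames(
    costs[sites$site_id], sites$site_id)
  else costs <- stats::setNames(costs, sites$site_id)
  if (!is.null(names(values))) values <- values[sites$site_id]
  values <- stats::setNames(values, sites$site_id)
  if (!is.null(cls)) sites <- eligible_sites(sites, cls)
  class_name <- if (is.null(cls)) "regular"
  else if (inherits(cls, "eligibility_class")) cls$name else cls

  all_patches <- list()
  remaining <- sites
  for (pass in seq_len(max_passes)) {
    if (nrow(remaining) < size_range[1L]) break
    cl <- withCallingHandlers(
      best_clusters(remaining, costs[remaining$site_id],
                    size_range = size_range, window = window,
                    max_per_size = max_per_size,
                    link_cutoff = link_cutoff),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(cl) == 0) break
    patches <- clusters_to_patches(cl, remaining,
                                   values[remaining$site_id],
                                   link_cutoff = link_cutoff,
                                   class_name = class_name,
                                   pass_index = pass)
    all_patches <- c(all_patches, patches)
    used <- unlist(lapply(patches, `[[`, "site_ids"))
    remaining <- remaining[!remaining$site_id %in% used, , drop = FALSE]
  }
  structure(all_patches, class = "hydration_patches")
}

#' @rdname clusters_to_patches
#' @param x a `hydration_patches` list.
#' @param ... unused.
#' @export
as.data.frame.hydration_patches <- function(x, ...) {
  if (length(x) == 0)
    return(data.frame(patch_id = character(0), class = character(0),
                      pass = integer(0), n_sites = integer(0),
                      mean = numeric(0), median = numeric(0),
                      sd = numeric(0)))
  do.call(rbind, lapply(x, function(p) data.frame(
    patch_id = p$patch_id, class = p$class, pass = p$pass_index,
    n_sites = unname(p$stats["n"]), mean = unname(p$stats["mean"]),
    median = unname(p$stats["median"]), sd = unname(p$stats["sd"]),
    stringsAsFactors = FALSE)))
}

#' @export
print.hydration_patches <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<hydration_patches: %d patch(es)>\n", length(x)))
  if (nrow(df) > 0) print(df)
  invisible(x)
}

#' Residues near a hydration patch
#'
#' For every solute residue with at least one heavy atom within
#' `cutoff` of at least one patch site, the frequency is the number of
#' patch sites within `cutoff` of that residue; sorted descending.
#'
#' @param patch one patch (element of a `hydration_patches` list).
#' @param sites the `hydration_sites` frame the patch refers to.
#' @param solute a `pdb_structure`.
#' @param cutoff Angstrom (> 0); 5 for patch neighbourhoods, 3 for
#'   tight annotation.
#' @return data frame (chain, resseq, resname, frequency).
#' @export
annotate_patch_residues <- function(patch, sites, solute, cutoff = 5) {
  stopifnot(cutoff > 0)
  hv <- heavy_atoms(solute)
  sxyz <- coords(hv)
  sel <- sites[sites$site_id %in% patch$site_ids, , drop = FALSE]
  reskey <- paste(hv$chain, hv$resseq)
  res_list <- split(seq_len(nrow(hv)), reskey)
  counts <- vapply(res_list, function(idx) {
    m <- sxyz[idx, , drop = FALSE]
    sum(vapply(seq_len(nrow(sel)), function(i) {
      min(dist2_to_point(m, c(sel$x[i], sel$y[i], sel$z[i]))) <= cutoff^2
    }, logical(1)))
  }, numeric(1))
  keep <- counts > 0
  if (!any(keep))
    return(data.frame(chain = character(0), resseq = integer(0),
                      resname = character(0), frequency = integer(0)))
  first <- vapply(res_list[keep], `[`, 0L, 1L)
  out <- data.frame(chain = hv$chain[first], resseq = hv$resseq[first],
                    resname = hv$resname[first],
                    frequency = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$resseq), , drop = FALSE]
}

#' Classify a patch against a binding interface
#'
#' `"overlapping"` when at least half the patch sites lie within
#' `cutoff` of the interface residues' heavy atoms, `"surrounding"`
#' when not overlapping but at least one site lies within `2 * cutoff`,
#' otherwise `"unrelated"`.
#'
#' @inheritParams annotate_patch_residues
#' @param interface_residues residue numbers of the binding face
#'   (non-empty).
#' @param cutoff Angstrom; default 3 (the tight annotation cutoff).
#' @export
classify_patch_role <- function(patch, sites, solute, interface_residues,
                                cutoff = 3) {
  stopifnot(length(interface_residues) > 0)
  hv <- heavy_atoms(solute)
  hv <- hv[hv$resseq %in% interface_residues, , drop = FALSE]
  if (nrow(hv) == 0) stop("interface residues not found in solute")
  m <- coords(hv)
  sel <- sites[sites$site_id %in% patch$site_ids, , drop = FALSE]
  d <- vapply(seq_len(nrow(sel)), function(i)
    sqrt(min(dist2_to_point(m, c(sel$x[i], sel$y[i], sel$z[i])))),
    numeric(1))
  if (mean(d <= cutoff) >= 0.5) "overlapping"
  else if (any(d <= 2 * cutoff)) "surrounding"
  else "unrelated"
}

#' @rdname clusters_to_patches
#' @param patches a `hydration_patches` list.
#' @param path output TSV path.
#' @export
write_patch_tsv <- function(patches, path) {
  utils::write.table(as.data.frame(patches), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
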