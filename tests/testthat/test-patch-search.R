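test_that("eligibility uses the any-heavy OR hydrophobic rule", {
  near <- eligibility_class("near")
  expect_equal(c(near$cutoff_any, near$cutoff_hydrophobic), c(3.1, 3.6))
  expect_equal(unlist(eligibility_class("regular")[2:3]),
               c(cutoff_any = 3.6, cutoff_hydrophobic = 4.1))
  expect_equal(unlist(eligibility_class("far")[2:3]),
               c(cutoff_any = 4.1, cutoff_hydrophobic = 4.5))

  sites <- toy_sites(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)),
                     d_heavy = c(3.0, 3.4, 5.0),
                     d_hydrophobic = c(9, 3.4, 5.0))
  # polar atom at 3.0 <= 3.1 -> eligible even with no hydrophobic nearby
  # hydrophobic at 3.4 <= 3.6 -> eligible although 3.4 > 3.1
  el <- eligible_sites(sites, "near")
  expect_setequal(el$site_id, c("S001", "S002"))
  # 5.0 from everything fails even the far class
  expect_false("S003" %in% eligible_sites(sites, "far")$site_id)

  # widening the class never removes sites
  for (pair in list(c("near", "regular"), c("regular", "far"))) {
    a <- eligible_sites(sites, pair[1])$site_id
    b <- eligible_sites(sites, pair[2])$site_id
    expect_true(all(a %in% b))
  }
})

test_that("adjacency links sites within the cutoff", {
  sites <- toy_sites(rbind(c(0, 0, 0), c(2.4, 0, 0), c(8.4, 0, 0)))
  g <- site_adjacency(sites)
  expect_true(igraph::are_adjacent(g, "S001", "S002"))
  expect_false(igraph::are_adjacent(g, "S002", "S003"))

  # chain at 3 A spacing -> a path graph
  chain <- toy_sites(cbind(seq(0, 21, 3), 0, 0))
  gc <- site_adjacency(chain)
  expect_equal(igraph::ecount(gc), nrow(chain) - 1)
  expect_equal(max(igraph::degree(gc)), 2)
})

test_that("an 8-site path graph yields the two expected size-7 windows", {
  chain <- toy_sites(cbind(seq(0, 21, 3), 0, 0))
  costs <- c(5, 1, 1, 1, 1, 1, 1, 5)
  bc <- best_clusters(chain, costs, size_range = c(7, 7), window = 12.5)
  expect_equal(nrow(bc), 2)
  # both windows cost 11; deterministic tie-break by membership
  expect_equal(bc$total_cost, c(11, 11))
  expect_equal(bc$members[[1]], sprintf("S%03d", 1:7))
  expect_equal(bc$members[[2]], sprintf("S%03d", 2:8))
})

test_that("the search equals exhaustive enumeration on random instances", {
  set.seed(501)
  for (trial in 1:25) {
    n <- sample(8:12, 1)
    sites <- toy_sites(matrix(runif(3 * n, 0, 9), ncol = 3))
    costs <- runif(n, 0, 30)
    bc <- suppressWarnings(
      best_clusters(sites, costs, size_range = c(7, 9), window = 12.5))
    bf <- brute_force_clusters(sites, costs, 7, 9, 12.5)
    if (is.null(bf)) {
      expect_equal(nrow(bc), 0)
    } else {
      expect_identical(
        cluster_keys(bc),
        paste(bf$size, bf$key, signif(bf$total_cost, 12)))
    }
  }
})

test_that("degenerate ties retain every connected subgraph up to the cap", {
  chain <- toy_sites(cbind(seq(0, 27, 3), 0, 0))  # path of 10
  costs <- rep(2, 10)
  bc <- best_clusters(chain, costs, size_range = c(7, 8), window = 0)
  # a path of n has n-s+1 connected windows of size s
  expect_equal(sum(bc$size == 7), 4)
  expect_equal(sum(bc$size == 8), 3)
  capped <- best_clusters(chain, costs, size_range = c(7, 8), window = 0,
                          max_per_size = 2)
  expect_equal(as.vector(table(capped$size)), c(2, 2))
})

test_that("shrinking window or cap never adds clusters", {
  set.seed(502)
  sites <- toy_sites(matrix(runif(33, 0, 8), ncol = 3))
  costs <- runif(11, 0, 20)
  big <- suppressWarnings(
    best_clusters(sites, costs, size_range = c(7, 9), window = 12.5))
  small <- suppressWarnings(
    best_clusters(sites, costs, size_range = c(7, 9), window = 4))
  expect_true(all(cluster_keys(small) %in% cluster_keys(big)))
  expect_lte(nrow(small), nrow(big))
})

test_that("clusters merge into patches by connected components", {
  # two well-separated planted regions
  regionA <- cbind(seq(0, 21, 3), 0, 0)
  regionB <- cbind(seq(40, 61, 3), 0, 0)
  sites <- toy_sites(rbind(regionA, regionB))
  costs <- c(rep(1, 8), rep(2, 8))
  bc <- best_clusters(sites, costs, size_range = c(7, 8), window = 100)
  patches <- clusters_to_patches(bc, sites, values = costs)
  expect_length(patches, 2)
  expect_setequal(patches[[1]]$site_ids, sprintf("S%03d", 1:8))
  expect_setequal(patches[[2]]$site_ids, sprintf("S%03d", 9:16))
  # patch size is the union size, not the sum of cluster sizes
  expect_equal(unname(patches[[1]]$stats["n"]), 8)
  # all clusters overlapping one region -> one patch equal to the union
  bcA <- best_clusters(toy_sites(regionA), rep(1, 8),
                       size_range = c(7, 8), window = 100)
  pA <- clusters_to_patches(bcA, toy_sites(regionA), values = rep(1, 8))
  expect_length(pA, 1)
  expect_equal(unname(pA[[1]]$stats["n"]), 8)
})

test_that("patch statistics match direct formulas", {
  expect_equal(patch_statistics(c(-40, -40, -40)),
               c(mean = -40, median = -40, sd = 0, n = 3))
  expect_equal(unname(patch_statistics(c(-30, -40, -50))["median"]), -40)
  set.seed(503)
  v <- rnorm(244, -40, 5)
  ps <- patch_statistics(v)
  expect_equal(unname(ps["mean"]), sum(v) / 244, tolerance = 1e-12)
  expect_equal(unname(ps["sd"]),
               sqrt(sum((v - mean(v))^2) / 243), tolerance = 1e-12)
  expect_equal(unname(ps["median"]), sort(v)[122] / 2 + sort(v)[123] / 2,
               tolerance = 1e-12)
})

test_that("multi-pass extraction recovers planted regions in cost order", {
  regions <- list(a = cbind(seq(0, 21, 3), 0, 0),
                  b = cbind(seq(40, 61, 3), 5, 0),
                  c = cbind(seq(80, 101, 3), -5, 0))
  sites <- toy_sites(do.call(rbind, regions))
  costs <- rep(c(1, 5, 20), each = 8)
  pat <- multi_pass_patches(sites, costs, size_range = c(7, 8))
  expect_length(pat, 3)
  expect_equal(vapply(pat, `[[`, 0L, "pass_index"), 1:3)
  expect_setequal(pat[[1]]$site_ids, sprintf("S%03d", 1:8))
  expect_setequal(pat[[2]]$site_ids, sprintf("S%03d", 9:16))
  expect_setequal(pat[[3]]$site_ids, sprintf("S%03d", 17:24))
  # pairwise disjoint across passes
  all_ids <- unlist(lapply(pat, `[[`, "site_ids"))
  expect_equal(anyDuplicated(all_ids), 0L)
  # earlier passes are cheaper
  means <- vapply(pat, function(p) unname(p$stats["mean"]), 0)
  expect_true(all(diff(means) > 0))

  # fewer than 7 eligible sites -> no pass
  few <- toy_sites(cbind(seq(0, 15, 3), 0, 0))
  expect_length(multi_pass_patches(few[1:6, ], rep(1, 6)), 0)

  # removing pass-1 sites and re-running reproduces pass 2
  rest <- sites[!sites$site_id %in% pat[[1]]$site_ids, ]
  manual <- multi_pass_patches(rest, costs[9:24], size_range = c(7, 8),
                               max_passes = 1)
  expect_setequal(manual[[1]]$site_ids, pat[[2]]$site_ids)
})

test_that("patch residue annotation counts sites within the cutoff", {
  solute <- toy_structure(rbind(c(0, 0, 0), c(20, 0, 0)),
                          resseq = c(1, 2))
  sites <- toy_sites(rbind(c(4, 0, 0), c(2, 0, 0), c(19, 0, 0)))
  patch <- list(site_ids = c("S001", "S002", "S003"))
  ann5 <- annotate_patch_residues(patch, sites, solute, cutoff = 5)
  expect_equal(ann5$frequency[ann5$resseq == 1], 2)
  expect_equal(ann5$frequency[ann5$resseq == 2], 1)
  # tighter cutoff drops the 4-A site
  ann3 <- annotate_patch_residues(patch, sites, solute, cutoff = 3)
  expect_equal(ann3$frequency[ann3$resseq == 1], 1)
  # planted incidence oracle on a random geometry
  set.seed(504)
  solute2 <- toy_structure(matrix(runif(15, 0, 10), ncol = 3),
                           resseq = 1:5)
  sites2 <- toy_sites(matrix(runif(24, 0, 10), ncol = 3))
  patch2 <- list(site_ids = sites2$site_id)
  ann <- annotate_patch_residues(patch2, sites2, solute2, cutoff = 4)
  inc <- outer(1:5, seq_len(nrow(sites2)), Vectorize(function(r, s) {
    sqrt(sum((coords(solute2)[r, ] -
                c(sites2$x[s], sites2$y[s], sites2$z[s]))^2)) <= 4
  }))
  truth <- rowSums(inc)
  for (r in which(truth > 0))
    expect_equal(ann$frequency[ann$resseq == r], unname(truth[r]))
  expect_setequal(ann$resseq, which(truth > 0))
})

test_that("patch roles split into overlapping / surrounding / unrelated", {
  solute <- toy_structure(rbind(c(0, 0, 0), c(3, 0, 0)), resseq = c(1, 2))
  near_sites <- toy_sites(rbind(c(1, 0, 0), c(2, 1, 0)))
  patch <- list(site_ids = near_sites$site_id)
  expect_equal(classify_patch_role(patch, near_sites, solute, 1:2),
               "overlapping")
  shell <- toy_sites(rbind(c(8, 0, 0), c(0, 5, 0)))
  expect_equal(classify_patch_role(list(site_ids = shell$site_id),
                                   shell, solute, 1:2), "surrounding")
  away <- toy_sites(rbind(c(20, 0, 0), c(0, 20, 0)))
  expect_equal(classify_patch_role(list(site_ids = away$site_id),
                                   away, solute, 1:2), "unrelated")
})
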