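fixed_water_ensemble <- function(pos, n_frames, jitter = 0, seed = 1,
                                 hydrogens = FALSE) {
  set.seed(seed)
  oxy <- lapply(seq_len(n_frames), function(k)
    rbind(pos + rnorm(3, 0, jitter)))
  hyd <- NULL
  if (hydrogens) {
    hyd <- lapply(oxy, function(m) {
      q <- rnorm(4); q <- q / sqrt(sum(q^2))
      hydropatch:::water_hydrogens(m[1, ], q)
    })
  }
  water_ensemble(oxy, hydrogens = hyd)
}

test_that("zero potential gives zero interaction energy", {
  cls <- default_potential_classes()
  cls$epsilon[] <- 0; cls$charge[] <- 0
  pot <- potential_model(classes = cls)
  ens <- fixed_water_ensemble(c(5, 5, 5), 60)
  site <- list(x = 5, y = 5, z = 5, radius = 1.2)
  expect_equal(site_interaction_energy(ens, NULL, site, pot), 0)
})

test_that("a single water at an LJ minimum scores -epsilon", {
  # one carbon solute; water at r_min = 2^(1/6) * sigma_CO
  cls <- default_potential_classes()
  cls$charge[] <- 0
  pot <- potential_model(classes = cls)
  sig <- (cls$sigma[cls$class == "OW"] + cls$sigma[cls$class == "C"]) / 2
  eps <- sqrt(cls$epsilon[cls$class == "OW"] *
                cls$epsilon[cls$class == "C"])
  rmin <- 2^(1 / 6) * sig
  solute <- assign_atom_properties(toy_structure(rbind(c(0, 0, 0))))
  ens <- fixed_water_ensemble(c(rmin, 0, 0), 60)
  site <- list(x = rmin, y = 0, z = 0, radius = 1.2)
  # no bulk waters exist: the reference is 0
  expect_equal(site_interaction_energy(ens, solute, site, pot),
               -eps, tolerance = 1e-10)
})

test_that("site energy matches a naive frame-loop oracle", {
  pot <- potential_model()
  solute <- assign_atom_properties(toy_structure(
    rbind(c(0, 0, 0), c(3, 1, 0)), element = c("C", "O")))
  set.seed(31)
  oxy <- lapply(1:40, function(k) {
    rbind(c(3.2, 0, 0) + rnorm(3, 0, 0.2),
          c(8, 8, 8) + rnorm(3, 0, 0.2))
  })
  ens <- water_ensemble(oxy)
  site <- list(x = 3.2, y = 0, z = 0, radius = 1.2)
  got <- site_interaction_energy(ens, solute, site, pot, bulk_ref = 0)

  # independent naive oracle: double loop over frames/atoms, O-O LJ only
  lj <- function(eps, sig, d) 4 * eps * ((sig / d)^12 - (sig / d)^6)
  cls <- pot$classes
  ow <- cls[cls$class == "OW", ]
  e_oracle <- vapply(1:40, function(k) {
    w <- oxy[[k]][1, ]
    e <- 0
    for (j in 1:2) {
      at <- c("C", "O")[j]
      p <- cls[cls$class == at, ]
      d <- sqrt(sum((w - coords(solute)[j, ])^2))
      if (d <= pot$cutoff)
        e <- e + lj(sqrt(ow$epsilon * p$epsilon), (ow$sigma + p$sigma) / 2, d)
    }
    d2 <- sqrt(sum((w - oxy[[k]][2, ])^2))
    if (d2 <= pot$cutoff) e <- e + 0.5 * lj(ow$epsilon, ow$sigma, d2)
    e
  }, 0)
  expect_equal(got, mean(e_oracle), tolerance = 1e-10)
})

test_that("zero-occupancy sites are an error", {
  ens <- fixed_water_ensemble(c(5, 5, 5), 30)
  expect_error(
    site_interaction_energy(ens, NULL, list(x = -50, y = 0, z = 0,
                                            radius = 1.2),
                            potential_model()),
    "zero occupancy")
})

test_that("entropy terms are ~0 for uniform positions and isotropic orientations", {
  # uniform-in-sphere positions with isotropic orientations, replicated;
  # the replicate spread bounds the estimator bias
  reps <- vapply(1:20, function(r) {
    set.seed(400 + r)
    n <- 300
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pos <- u * (runif(n)^(1 / 3) * 1.2)
    oxy <- lapply(seq_len(n), function(i) rbind(pos[i, ] + c(5, 5, 5)))
    hyd <- lapply(seq_len(n), function(i) {
      q <- rnorm(4); q <- q / sqrt(sum(q^2))
      hydropatch:::water_hydrogens(oxy[[i]][1, ], q)
    })
    ens <- water_ensemble(oxy, hydrogens = hyd)
    ds <- site_entropy(ens, list(x = 5, y = 5, z = 5, radius = 1.2),
                       ref_seed = 999 + r)
    c(ds$dS_trans, ds$dS_orient)
  }, numeric(2))
  # mean within 3 SE of zero for both terms
  for (i in 1:2) {
    m <- mean(reps[i, ]); se <- sd(reps[i, ]) / sqrt(ncol(reps))
    expect_lt(abs(m), 3 * se + 1e-5)
  }
})

test_that("localisation and ordering lower the entropy terms", {
  set.seed(41)
  n <- 300
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- u * (runif(n)^(1 / 3) * 1.2)
  mk_ens <- function(scale, fixed_orient = FALSE) {
    oxy <- lapply(seq_len(n), function(i)
      rbind(pos[i, ] * scale + c(5, 5, 5)))
    hyd <- lapply(seq_len(n), function(i) {
      q <- if (fixed_orient) c(1, 0, 0, 0) else {
        qq <- rnorm(4); qq / sqrt(sum(qq^2))
      }
      hydropatch:::water_hydrogens(oxy[[i]][1, ], q)
    })
    water_ensemble(oxy, hydrogens = hyd)
  }
  site <- list(x = 5, y = 5, z = 5, radius = 1.2)
  full <- site_entropy(mk_ens(1), site)
  half <- site_entropy(mk_ens(0.5), site)
  expect_lt(half$dS_trans, full$dS_trans)

  frozen <- site_entropy(mk_ens(1, fixed_orient = TRUE), site)
  expect_lt(frozen$dS_orient, full$dS_orient)
  expect_lt(frozen$dS_orient, -0.01)
})

test_that("the entropy estimator floor reports the sample count", {
  ens <- fixed_water_ensemble(c(5, 5, 5), 20, jitter = 0.1)
  expect_error(site_entropy(ens, list(x = 5, y = 5, z = 5, radius = 1.2)),
               "20 occupied")
})

test_that("free energy combines terms with the documented sign convention", {
  th <- site_free_energy(0, 0, 0)
  expect_equal(th$dG_hyd, 0)
  expect_equal(th$displacement_cost, 0)

  # dE = -50, T(dS) = -10 => dG = -40, cost = +40
  th2 <- site_free_energy(-50, -10 / 300, 0, temperature = 300)
  expect_equal(th2$dG_hyd, -40)
  expect_equal(th2$displacement_cost, 40)
  expect_equal(th2$displacement_cost, -th2$dG_hyd)
})

test_that("deepening a planted well monotonically lowers dG_hyd", {
  depths <- c(5, 10, 15, 20, 25)
  wells <- data.frame(x = seq(4, 20, 4), y = 5, z = 5,
                      depth = depths, width = 0.35)
  gen <- make_water_ensemble(500, box = rbind(c(0, 0, 0), c(24, 10, 10)),
                             bulk_density = 0, wells = wells, seed = 42)
  sites <- pick_sites(gen$ensemble)
  st <- score_sites(gen$ensemble, NULL, sites, gen$potential)
  dg <- vapply(seq_len(nrow(wells)), function(i) {
    j <- which.min((st$x - wells$x[i])^2 + (st$y - wells$y[i])^2 +
                     (st$z - wells$z[i])^2)
    st$dG_hyd[j]
  }, 0)
  expect_true(all(is.finite(dg)))
  expect_true(all(diff(dg) < 0))
  # weak wells cost less to displace than strong wells
  expect_lt(st$displacement_cost[match(dg[1], st$dG_hyd)],
            st$displacement_cost[match(dg[5], st$dG_hyd)])
})

test_that("the energy term is invariant to global rotation/translation", {
  pot <- potential_model()
  solute <- assign_atom_properties(toy_structure(
    rbind(c(0, 0, 0), c(3, 0, 0))))
  set.seed(43)
  oxy <- lapply(1:60, function(k) rbind(c(3.4, 0.5, 0) + rnorm(3, 0, 0.15)))
  ens <- water_ensemble(oxy)
  site <- list(x = 3.4, y = 0.5, z = 0, radius = 1.2)
  e0 <- site_interaction_energy(ens, solute, site, pot, bulk_ref = 0)

  R <- random_rotation_matrix(); shift <- c(4, -2, 7)
  rot_solute <- solute
  xyz <- coords(solute) %*% t(R)
  rot_solute$x <- xyz[, 1] + shift[1]
  rot_solute$y <- xyz[, 2] + shift[2]
  rot_solute$z <- xyz[, 3] + shift[3]
  oxy_r <- lapply(oxy, function(m) sweep(m %*% t(R), 2, -shift))
  ens_r <- water_ensemble(oxy_r)
  ctr <- as.numeric(c(3.4, 0.5, 0) %*% t(R)) + shift
  site_r <- list(x = ctr[1], y = ctr[2], z = ctr[3], radius = 1.2)
  e1 <- site_interaction_energy(ens_r, rot_solute, site_r, pot,
                                bulk_ref = 0)
  expect_equal(e1, e0, tolerance = 1e-9)
})
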