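# small hand-built ensemble: two marker atoms at fixed separation
fixed_pair_ensemble <- function(n_frames = 10, d = 12) {
  coords <- array(0, c(n_frames, 2, 3))
  coords[, 2, 1] <- d
  trajectory_ensemble(coords, c("a", "b"),
                      list(A = "a", B = "b"))
}

test_that("distance series report fixed and generated separations", {
  ens <- fixed_pair_ensemble(d = 12)
  expect_equal(distance_series(ens, "A", "B"), rep(12, 10))
  # min and centroid agree on single-atom groups
  expect_equal(distance_series(ens, "A", "B", mode = "min"),
               distance_series(ens, "A", "B", mode = "centroid"))
  expect_error(distance_series(ens, "missing", "B"), "selection")

  tr <- traj_cached()
  d <- distance_series(tr$ensemble, "B8", "AE1")
  expect_equal(d, abs(tr$truth$b8_ae1_distance), tolerance = 1e-10)
  # bimodal: per-state means near the generator means 17 and 24
  m_in <- mean(d[tr$truth$conformation == "inward"])
  m_out <- mean(d[tr$truth$conformation == "outward"])
  expect_lt(abs(m_in - 17), 0.15)
  expect_lt(abs(m_out - 24), 0.15)
})

test_that("rolling average is a centered mean with shrinking edges", {
  expect_equal(rolling_average(c(1, 2, 3, 4, 5), 3),
               c(1.5, 2, 3, 4, 4.5))
  x <- rnorm(50)
  expect_equal(rolling_average(x, 1), x)
  expect_equal(rolling_average(rep(3.7, 20), 7), rep(3.7, 20))
  expect_length(rolling_average(x, 9), 50)
  expect_error(rolling_average(x, 51), "window")
  expect_error(rolling_average(x, 0), "window")
})

test_that("conformational classification recovers the generated states", {
  tr <- traj_cached()
  gates <- gating_definition(list("gate_in_a", "gate_in_b"),
                             list("gate_out_a", "gate_out_b"))
  lab <- classify_conformations(tr$ensemble, gates)
  expect_gte(mean(lab == tr$truth$conformation), 0.95)
  expect_equal(attr(lab, "leak_count"), sum(lab == "leak"))
  # order invariance: a permuted copy classifies frame-wise identically
  perm <- sample(tr$ensemble$n_frames)
  ens_p <- trajectory_ensemble(tr$ensemble$coords[perm, , , drop = FALSE],
                               tr$ensemble$atom_ids,
                               lapply(tr$ensemble$atom_groups, identity))
  lab_p <- classify_conformations(ens_p, gates)
  expect_equal(as.character(lab_p), as.character(lab)[perm])
})

test_that("degenerate gate geometries give occluded and leak labels", {
  # both gates closed (4 A) in every frame
  mk <- function(d_in, d_out, n = 5) {
    coords <- array(0, c(n, 4, 3))
    coords[, 2, 1] <- d_in
    coords[, 3, 2] <- 20
    coords[, 4, 1] <- d_out; coords[, 4, 2] <- 20
    trajectory_ensemble(coords, c("ia", "ib", "oa", "ob"),
                        list(ia = "ia", ib = "ib", oa = "oa", ob = "ob"))
  }
  gates <- gating_definition(list("ia", "ib"), list("oa", "ob"))
  lab_occ <- classify_conformations(mk(4, 4), gates)
  expect_true(all(lab_occ == "occluded"))
  expect_equal(attr(lab_occ, "leak_count"), 0L)
  lab_leak <- classify_conformations(mk(11, 11), gates)
  expect_true(all(lab_leak == "leak"))
  expect_equal(attr(lab_leak, "leak_count"), 5L)
  expect_error(gating_definition(list("a", "b"), list("c", "d"),
                                 open_A = 5, closed_A = 6), "exceed")
})

test_that("ion-pair fractions recover the per-state open probabilities", {
  ens <- fixed_pair_ensemble(d = 3)
  expect_equal(unname(ion_pair_fraction(ens, "A", "B")), 1.0)
  expect_equal(unname(ion_pair_fraction(ens, "A", "B", cutoff_A = 0)), 0.0)

  tr <- traj_cached()
  frac <- ion_pair_fraction(tr$ensemble, "ion_pair_N", "ion_pair_O",
                            labels = tr$truth$conformation)
  # generator: open probability 0.1 inward / 0.8 outward -> closed
  # fractions 0.9 / 0.2, binomial 3-sigma at the class sizes
  n_in <- sum(tr$truth$conformation == "inward")
  n_out <- sum(tr$truth$conformation == "outward")
  expect_lt(abs(frac[["inward"]] - 0.9), 3 * sqrt(0.9 * 0.1 / n_in))
  expect_lt(abs(frac[["outward"]] - 0.2), 3 * sqrt(0.2 * 0.8 / n_out))
})

test_that("axial densities integrate to one and localize fixed ions", {
  n <- 20
  coords <- array(0, c(n, 2, 3))
  coords[, 2, 3] <- 5.5  # ion fixed at a bin midpoint relative to the reference
  ens <- trajectory_ensemble(coords, c("ref", "ion"),
                             list(ref = "ref", ion = "ion"))
  dp <- sodium_axial_density(ens, "ion", "ref", breaks = seq(-10, 10, 1))
  w <- diff(seq(-10, 10, 1))[1]
  expect_equal(sum(dp$density) * w, 1, tolerance = 1e-12)
  expect_equal(sum(dp$density > 0), 1L)
  expect_equal(dp$z_mid[dp$density > 0], 5.5)

  # uniform ions: flat within multinomial error
  set.seed(4)
  nf <- 2000
  coords <- array(0, c(nf, 2, 3))
  coords[, 2, 3] <- runif(nf, -10, 10)
  ens_u <- trajectory_ensemble(coords, c("ref", "ion"),
                               list(ref = "ref", ion = "ion"))
  dp_u <- sodium_axial_density(ens_u, "ion", "ref",
                               breaks = seq(-10, 10, 2))
  p_bin <- dp_u$density * 2
  expect_true(all(abs(p_bin - 0.1) < 3 * sqrt(0.1 * 0.9 / nf) + 1e-12))
})

test_that("the buried-site peak appears only in reduced-cluster frames", {
  tr <- traj_cached()
  lab <- ifelse(tr$truth$reduced, "reduced", "oxidized")
  br <- seq(-20, 20, 1)
  inward <- tr$truth$conformation == "inward"
  dp <- sodium_axial_density(tr$ensemble, "na_tracked", "AE1",
                             breaks = br, labels = lab,
                             frames = which(inward))
  near0 <- function(cl) {
    sub <- dp[dp$class == cl, ]
    sum(sub$density[abs(sub$z_mid) < 2])
  }
  # occupancy 0.8 (reduced) vs 0.2 (oxidized) concentrates density at the
  # site; the reduced-state peak must dominate by the occupancy ratio
  expect_gt(near0("reduced"), 2.5 * near0("oxidized"))
})

test_that("Boltzmann inversion recovers a Gaussian's curvature within 10%", {
  set.seed(12)
  sig <- 1.5
  n <- 50000
  x <- rnorm(n, 0, sig); y <- rnorm(n, 0, sig)
  pm <- pmf_2d(x, y, temperature_K = 310, bins = 25)
  rt <- 1.987204259e-3 * 310
  X <- outer(pm$x_mid, rep(1, length(pm$y_mid)))
  Y <- outer(rep(1, length(pm$x_mid)), pm$y_mid)
  ok <- !is.na(pm$F_kcal) & (X^2 + Y^2 < (2.5 * sig)^2)
  fit <- lm(pm$F_kcal[ok] ~ I(X[ok]^2) + I(Y[ok]^2))
  curv <- 2 * unname(coef(fit)[2:3])
  expect_lt(max(abs(curv - rt / sig^2)) / (rt / sig^2), 0.10)

  # uniform samples: flat within sampling error
  xu <- runif(n); yu <- runif(n)
  pmu <- pmf_2d(xu, yu, 310, bins = 10)
  # spread of -RT log p over 100 bins of ~500 counts each stays below
  # ~0.25 kcal/mol at 3.5 sigma multinomial error
  expect_lt(max(pmu$F_kcal, na.rm = TRUE), 0.25)

  # doubling the temperature scales the surface by exactly 2
  pm2 <- pmf_2d(x, y, temperature_K = 620, bins = 25)
  expect_equal(pm2$F_kcal, 2 * pm$F_kcal, tolerance = 1e-12)

  # degenerate input
  expect_error(pmf_2d(rep(1, 500), rep(2, 500)), "degenerate")
})

test_that("pathway continuity distinguishes bored from sealed membranes", {
  fx <- toy_complex_cached()
  slab <- fx$atoms[fx$atoms$chain == "M", ]
  res <- pathway_continuity(slab, z_bounds = c(-12, 12))
  expect_true(res$continuous)
  expect_gt(nrow(res$path_voxels), 0)

  sealed <- make_toy_complex(toy_complex_config(bore = FALSE),
                             out_dir = file.path(tempdir(), "toy-sealed"))
  at_s <- load_structure(sealed$pdb_path)
  res_s <- pathway_continuity(at_s[at_s$chain == "M", ],
                              z_bounds = c(-12, 12))
  expect_false(res_s$continuous)

  # a bore narrower than the probe diameter reads as sealed
  narrow <- make_toy_complex(toy_complex_config(bore_radius_A = 2.5),
                             out_dir = file.path(tempdir(), "toy-narrow"))
  at_n <- load_structure(narrow$pdb_path)
  res_n <- pathway_continuity(at_n[at_n$chain == "M", ],
                              z_bounds = c(-12, 12))
  expect_false(res_n$continuous)

  # monotone in probe radius: a larger probe never opens a closed path
  res_big <- pathway_continuity(slab, z_bounds = c(-12, 12),
                                probe_radius_A = 2.2, grid_A = 0.8)
  expect_true(res$continuous || !res_big$continuous)
  expect_lte(res_big$n_free, res$n_free)

  expect_error(pathway_continuity(slab, c(-12, 12), probe_radius_A = 0.5,
                                  grid_A = 0.8), "grid")
})
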