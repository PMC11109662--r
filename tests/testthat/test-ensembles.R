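test_that("Kabsch superposition: identity, rigid copies, collinear pair", {
  set.seed(1)
  ref <- matrix(rnorm(30), ncol = 3)
  s <- superpose(ref, ref)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  tr <- random_rigid(ref, seed = 2)
  s2 <- superpose(tr$coords, ref)
  expect_lt(s2$rmsd, 1e-9)
  expect_equal(s2$coords, ref, tolerance = 1e-9)
  # 2-atom collinear pair: ref (+-1, 0, 0), model (+-2, 0, 0): RMSD 1 after centering
  refc <- rbind(c(-1, 0, 0), c(1, 0, 0))
  mod <- rbind(c(-2, 0, 0), c(2, 0, 0))
  s3 <- superpose(mod, refc)
  expect_equal(s3$rmsd, 1, tolerance = 1e-9)
  # cross-check against the independent bio3d implementation
  fitted <- bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(tr$coords)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
  expect_equal(matrix(fitted, ncol = 3, byrow = TRUE), s2$coords,
               tolerance = 1e-6)
})

test_that("DCC: diagonal, planted anticorrelation, independence baseline", {
  ens <- make_ensemble(n_frames = 5000, n_residues = 12, seed = 10,
                       dcc = list(block_a = 2:4, block_b = 8:10, rho = -0.6))
  d <- dcc_map(ens, superpose = FALSE)
  expect_true(all(abs(diag(unclass(d)) - 1) < 1e-12))
  expect_equal(unclass(d), t(unclass(d)), tolerance = 1e-10)
  expect_true(all(abs(unclass(d)) <= 1 + 1e-12, na.rm = TRUE))
  truth <- ensemble_truth(ens)$dcc
  for (k in seq_along(truth$block_a)) {
    got <- unclass(d)[as.character(truth$block_a[k]),
                      as.character(truth$block_b[k])]
    expect_lt(abs(got - truth$rho), 0.05)
  }
  # independent residues: mean |off-diagonal| below 3 / sqrt(n_frames)
  ens0 <- make_ensemble(n_frames = 4000, n_residues = 10, seed = 11,
                        dcc = list(block_a = integer(0), block_b = integer(0),
                                   rho = 0))
  d0 <- unclass(dcc_map(ens0, superpose = FALSE))
  off <- d0[upper.tri(d0)]
  expect_lt(mean(abs(off)), 3 / sqrt(4000))
})

test_that("perfectly anti-correlated planted displacement gives DCC -1", {
  ens <- make_ensemble(n_frames = 200, n_residues = 6, seed = 3,
                       dcc = list(block_a = 2, block_b = 5, rho = -1))
  d <- dcc_map(ens, superpose = FALSE)
  expect_equal(unclass(d)["2", "5"], -1, tolerance = 1e-10)
})

test_that("zero-variance residues are reported as missing, not zero", {
  ens <- make_ensemble(n_frames = 50, n_residues = 6, seed = 4,
                       dcc = list(block_a = 2, block_b = 5, rho = 0.5))
  # residues other than 2 and 5 also fluctuate; rebuild with sigma on the
  # blocks only by zeroing the others through a fresh template ensemble
  ens0 <- make_ensemble(n_frames = 50, n_residues = 6, seed = 4)
  d <- dcc_map(ens0, superpose = FALSE)  # rigid template: all variances zero
  expect_true(all(is.na(unclass(d))))
})

test_that("contact occupancy recovers the planted fraction and respects the cutoff", {
  ens <- make_ensemble(n_frames = 1500, n_residues = 8, seed = 6,
                       contact = list(pair = c(2, 7), prob = 0.6))
  truth <- ensemble_truth(ens)$contact
  occ <- contact_occupancy(ens, c(2, 7), cutoff = truth$cutoff)
  expect_equal(occ$occupancy, truth$realized, tolerance = 1e-12)
  expect_lt(abs(occ$occupancy - 0.6), 3 * sqrt(0.6 * 0.4 / 1500))
  # monotone non-decreasing in cutoff
  cuts <- c(0.2, 0.3, 0.45, 0.7, 1.2)
  occs <- vapply(cuts, function(cc)
    contact_occupancy(ens, c(2, 7), cutoff = cc)$occupancy, numeric(1))
  expect_true(all(diff(occs) >= 0))
  expect_error(contact_occupancy(ens, c(2, 99)), "99")
})

test_that("helicity: ideal helix 1, extended chain 0, planted fraction recovered", {
  helix <- make_ensemble(n_frames = 5, n_residues = 8, seed = 1)
  h <- helicity(helix)
  interior <- !is.na(h$helicity)
  expect_true(all(h$helicity[interior] == 1))
  expect_true(is.na(h$helicity[1]) && is.na(h$helicity[8]))  # termini

  coil <- make_ensemble(n_frames = 5, n_residues = 8, seed = 2,
                        helix_prob = 0)
  hc <- helicity(coil)
  expect_true(all(hc$helicity[!is.na(hc$helicity)] == 0))

  half <- make_ensemble(n_frames = 600, n_residues = 10, seed = 3,
                        helix_prob = 0.5)
  hh <- helicity(half)
  truth <- ensemble_truth(half)$helicity
  ok <- !is.na(hh$helicity)
  # estimator matches the generator's realised draws (up to rare jitter flips)
  expect_equal(hh$helicity[ok], truth$realized[ok], tolerance = 0.02)
  # pooled over interior residues: binomial standard error of the mean
  n_eff <- 600 * sum(ok)
  expect_lt(abs(mean(hh$helicity[ok]) - 0.5), 3 * sqrt(0.25 / n_eff))
})

test_that("helicity and occupancy are invariant under per-frame rigid motion", {
  ens <- make_ensemble(n_frames = 40, n_residues = 8, seed = 9,
                       helix_prob = 0.5,
                       contact = list(pair = c(2, 7), prob = 0.5))
  moved <- ens
  set.seed(77)
  for (f in seq_len(n_frames(ens))) {
    moved$coords[, , f] <- random_rigid(ens$coords[, , f])$coords
  }
  expect_equal(helicity(moved)$helicity, helicity(ens)$helicity,
               tolerance = 1e-9)
  expect_equal(contact_occupancy(moved, c(2, 7))$occupancy,
               contact_occupancy(ens, c(2, 7))$occupancy, tolerance = 1e-12)
})

test_that("delta RMSF: identity zero, antisymmetry, planted increment", {
  wt <- make_ensemble(n_frames = 2000, n_residues = 30, seed = 20,
                      fluct_sigma = 0.5)
  mut <- make_ensemble(n_frames = 2000, n_residues = 30, seed = 21,
                       fluct_sigma = 0.8)
  sel <- which(wt$atoms$resno %in% 12:20)
  fit_all <- seq_len(nrow(wt$atoms))
  expect_equal(delta_rmsf(wt, wt, selection = sel), 0, tolerance = 1e-12)
  d_ab <- delta_rmsf(mut, wt, selection = sel, fit_selection = fit_all)
  d_ba <- delta_rmsf(wt, mut, selection = sel, fit_selection = fit_all)
  expect_equal(d_ab, -d_ba, tolerance = 1e-12)
  expected <- (0.8 - 0.5) * sqrt(3)  # chi-distribution mean-square identity
  expect_lt(abs(d_ab - expected) / expected, 0.05)
  # uniform +0.1 A RMSF inflation shifts the measure by +0.1 (linearity)
  wt_s <- superpose_ensemble(wt)
  rm_wt <- rmsf_profile(wt_s, sel)
  expect_equal((sum(rm_wt + 0.01) - sum(rm_wt)) / length(sel) * 10, 0.1,
               tolerance = 1e-9)
  expect_error(delta_rmsf(mut, make_ensemble(2, n_residues = 4, seed = 1),
                          selection = 1:5),
               "atom table")
})

test_that("C-alpha distance statistics use the population convention", {
  ens <- make_ensemble(n_frames = 1, n_residues = 6, seed = 1)
  st <- ca_distance_stats(ens, c(2, 4, 6))
  expect_equal(st$sd, rep(0, 3))
  # two frames with distances 10 and 12 A -> mean 11, population sd 1
  atoms <- data.frame(serial = 1:2, name = "CA", resname = "ALA",
                      resno = c(1, 2), chain = "A", element = "C",
                      x = 0, y = 0, z = 0)
  co <- array(0, c(2, 3, 2))
  co[2, 1, 1] <- 1.0   # 10 A in nm
  co[2, 1, 2] <- 1.2   # 12 A
  ens2 <- labeled_ensemble(structure_model(atoms), co)
  st2 <- ca_distance_stats(ens2, c(1, 2))
  expect_equal(st2$mean, 11)
  expect_equal(st2$sd, 1)
  # planted Gaussian distance is recovered within its standard error
  set.seed(5)
  nfr <- 800
  co3 <- array(0, c(2, 3, nfr))
  co3[2, 1, ] <- rnorm(nfr, 1.5, 0.05)
  ens3 <- labeled_ensemble(structure_model(atoms), co3)
  st3 <- ca_distance_stats(ens3, c(1, 2))
  expect_lt(abs(st3$mean - 15), 3 * 0.5 / sqrt(nfr))
  expect_lt(abs(st3$sd - 0.5), 0.1)
})

test_that("helicity contrast between folded and unfolded generators", {
  folded <- make_ensemble(n_frames = 300, n_residues = 10, seed = 30,
                          helix_prob = 0.98)
  unfolded <- make_ensemble(n_frames = 300, n_residues = 10, seed = 31,
                            helix_prob = 0.25)
  hf <- helicity(folded); hu <- helicity(unfolded)
  expect_gt(mean(hf$helicity, na.rm = TRUE), 0.95)
  expect_lt(mean(hu$helicity, na.rm = TRUE), 0.35)
})
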