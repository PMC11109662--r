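test_that("well-tempered height rule: initial height, decay, limit", {
  p <- metad_params(height0 = 1.0, sigma = 0.1, pace = 500, bias_factor = 16)
  expect_equal(wt_height(0, p), 1.0)
  expect_equal(wt_height(1.0, p), exp(-1 / (15 * kT300)), tolerance = 1e-12)
  expect_lt(wt_height(1e6, p), 1e-10)
  v <- wt_height(seq(0, 50, 5), p)
  expect_true(all(diff(v) < 0))
})

test_that("bias potential: empty sum, center value, 1-sigma falloff, additivity", {
  h0 <- empty_hills_log(1)
  expect_equal(bias_potential(h0, 0.3), 0)
  h1 <- hills_log(data.frame(time = 1, cv1 = 0.5, sigma_cv1 = 0.2,
                             height = 1.0, biasf = 16))
  expect_equal(bias_potential(h1, 0.5), 1.0)
  expect_equal(bias_potential(h1, 0.7), exp(-0.5), tolerance = 1e-12)
  h2 <- hills_log(data.frame(time = 1:2, cv1 = c(0.5, 0.9),
                             sigma_cv1 = 0.2, height = c(1, 0.7), biasf = 16))
  expect_equal(bias_potential(h2, 0.6),
               bias_potential(h1, 0.6) +
                 0.7 * exp(-(0.6 - 0.9)^2 / (2 * 0.04)), tolerance = 1e-12)
  expect_error(bias_potential(h1, c(0.1, 0.2)), "dimensionality")
})

test_that("zero steps produce only the initial state and no hills", {
  toy <- make_toy("harmonic")
  run <- langevin_metad_run(toy$system,
                            metad_params(sigma = 0.1, pace = 10),
                            "x", n_steps = 0, seed = 1)
  expect_equal(nrow(run$hills), 0)
  expect_equal(nrow(run$trajectory), 1)
})

test_that("identical seeds give bit-identical hills; different seeds differ", {
  toy <- make_toy("double_well_1d", timestep = 0.005)
  p <- metad_params(height0 = 1.2, sigma = 0.1, pace = 100, bias_factor = 16)
  args <- list(toy$system, p, "x", n_steps = 2e4, x0 = c(-1, 0, 0),
               grid = list(x = c(-2.5, 2.5, 1001)))
  r1 <- do.call(langevin_metad_run, c(args, seed = 123))
  r2 <- do.call(langevin_metad_run, c(args, seed = 123))
  r3 <- do.call(langevin_metad_run, c(args, seed = 124))
  expect_identical(as.data.frame(r1$hills), as.data.frame(r2$hills))
  expect_identical(r1$trajectory, r2$trajectory)
  expect_false(identical(as.data.frame(r1$hills), as.data.frame(r3$hills)))
})

test_that("unbiased harmonic sampling satisfies equipartition", {
  toy <- make_toy("harmonic")
  run <- langevin_metad_run(toy$system, NULL, "x", n_steps = 4e5, seed = 2,
                            stride = 5)
  v <- var(run$trajectory$x)
  expect_equal(v, toy$truth$position_variance, tolerance = 0.05)
})

test_that("unbiased stationary histogram matches exp(-U/kBT) (chi-square)", {
  toy <- make_toy("harmonic")  # Boltzmann marginal on x is N(0, kT/k)
  run <- langevin_metad_run(toy$system, NULL, "x", n_steps = 1e6, seed = 4,
                            stride = 50)  # decorrelated samples
  x <- run$trajectory$x[-1]
  sd_th <- sqrt(toy$truth$position_variance)
  breaks <- qnorm(seq(0.05, 0.95, 0.1), 0, sd_th)
  obs <- table(cut(x, c(-Inf, breaks, Inf)))
  expected <- length(x) * diff(pnorm(c(-Inf, breaks, Inf), 0, sd_th))
  chi2 <- sum((as.numeric(obs) - expected)^2 / expected)
  # 10 cells -> df = 9; 0.999 quantile ~ 27.9
  expect_lt(chi2, qchisq(0.999, df = 9))
})

test_that("well-tempered damping: heights bounded and decaying on revisits", {
  res <- dw_metad_run(n_steps = 2e5, seed = 21)
  h <- res$run$hills$height
  expect_true(all(h <= 1.2 + 1e-12))
  # late hills are far smaller than early ones once the walker has revisited
  expect_lt(mean(tail(h, 50)), 0.5 * mean(head(h, 20)))
})

test_that("funnel wall keeps an unbiased bound particle inside the funnel", {
  fun <- funnel_geometry()  # default k_wall 10000
  ft <- make_toy("funnel_trap_3d", params = list(depth = 40), funnel = fun)
  run <- langevin_metad_run(ft$system, NULL, "axial", n_steps = 2e5,
                            x0 = c(0, 0, 0), seed = 6, stride = 10)
  expect_lt(run$wall_violation_fraction, 0.001)
})

test_that("grid-cached bias matches exact hill summation within 0.01 kJ/mol", {
  res <- dw_metad_run(n_steps = 1e5, seed = 31)
  hills <- res$run$hills
  # the height of hill k was computed from the cached bias of hills 1..k-1;
  # invert the well-tempered rule to recover the cache value and compare
  p <- metad_params(height0 = 1.2, sigma = 0.1, pace = 250, bias_factor = 16)
  for (k in c(50, 200, nrow(hills))) {
    prior <- hills_log(as.data.frame(hills)[seq_len(k - 1), ])
    v_exact <- bias_potential(prior, hills$cv1[k])
    v_cache <- -(p$bias_factor - 1) * kT300 * log(hills$height[k] / p$height0)
    expect_lt(abs(v_exact - v_cache), 0.01)
  }
})

test_that("RAMD update rule: keep above threshold, resample at or below", {
  st <- ramd_state(threshold = 0.025, last_com = c(0, 0, 0))
  dir0 <- st$direction
  set.seed(1)
  # displacement 0.03 A > 0.025 A: direction kept
  st1 <- ramd_update(st, c(0.03, 0, 0))
  expect_identical(st1$direction, dir0)
  expect_equal(st1$last_com, c(0.03, 0, 0))
  # displacement 0.01 A: resampled to a unit vector
  st2 <- ramd_update(st, c(0.01, 0, 0))
  expect_false(identical(st2$direction, dir0))
  expect_equal(sum(st2$direction^2), 1, tolerance = 1e-12)
  # exact equality counts as "not exceeded": resample
  st3 <- ramd_update(st, c(0.025, 0, 0))
  expect_false(identical(st3$direction, dir0))
})

test_that("sphere resampling is uniform in expectation", {
  st <- ramd_state()
  set.seed(8)
  dirs <- t(replicate(2000, ramd_update(st, c(0, 0, 0))$direction))
  expect_equal(colMeans(dirs), c(0, 0, 0), tolerance = 0.05)
  expect_equal(apply(dirs, 2, var), rep(1 / 3, 3), tolerance = 0.05)
})

test_that("RAMD egress: bounded well without force stays, strong pull exits forward", {
  # no egress: plain harmonic well, no RAMD force possible with magnitude > 0,
  # so use a tiny force that cannot beat the confinement
  toy <- make_toy("harmonic", params = list(k = 500))
  st <- ramd_state(force_magnitude = 0.01)
  run <- ramd_egress_run(toy$system, st, exit_radius = 2, max_steps = 5e4,
                         seed = 3)
  expect_false(run$egressed)
  # ballistic limit: huge force in a nearly free potential exits along the
  # initial direction
  free <- make_toy("harmonic", params = list(k = 0.001))
  st2 <- ramd_state(force_magnitude = 50, direction = c(1, 0, 0))
  run2 <- ramd_egress_run(free$system, st2, exit_radius = 3, max_steps = 5e4,
                          seed = 3)
  expect_true(run2$egressed)
  exit_dir <- run2$final_position / sqrt(sum(run2$final_position^2))
  expect_gt(sum(exit_dir * c(1, 0, 0)), 0.9)
})

test_that("two-channel egress statistics are self-consistent across replica counts", {
  toy <- make_toy("two_channel_exit", params = list(k_z = 2000),
                  timestep = 0.002)
  channel_counts <- function(n_rep, seed0) {
    wide <- 0; total <- 0
    for (r in seq_len(n_rep)) {
      st <- ramd_state(force_magnitude = 2)
      run <- ramd_egress_run(toy$system, st, exit_radius = 1.2,
                             max_steps = 4e4, seed = seed0 + r)
      if (run$egressed) {
        total <- total + 1
        if (run$final_position[1] > 0) wide <- wide + 1
      }
    }
    c(wide = wide, total = total)
  }
  small <- channel_counts(40, 1000)   # the standard 40-replica protocol
  big <- channel_counts(400, 5000)    # 10x reference
  expect_gt(small[["total"]], 30)
  p_ref <- big[["wide"]] / big[["total"]]
  # wide channel dominates, and the 40-replica count sits inside the
  # binomial 95% interval of the reference fraction
  expect_gt(p_ref, 0.5)
  ci <- qbinom(c(0.025, 0.975), small[["total"]], p_ref)
  expect_gte(small[["wide"]], ci[1])
  expect_lte(small[["wide"]], ci[2])
})

test_that("non-finite dynamics raise an error naming the step", {
  toy <- toy_system("harmonic", params = list(k = 1), timestep = 0.01)
  # inject instability via an absurd starting point and huge wall
  fun <- funnel_geometry(k_wall = 1e8)
  sys <- toy_system("harmonic", params = list(k = 1e8), timestep = 0.01,
                    funnel = fun)
  expect_error(langevin_metad_run(sys, NULL, "x", n_steps = 1000,
                                  x0 = c(50, 50, 50), seed = 1),
               "step")
})

test_that("two-CV protocol: axial + compactness biasing, 2-D surface, projection", {
  fun <- funnel_geometry()
  ft <- make_toy("funnel_trap_3d", funnel = fun)
  p <- metad_params(height0 = 1.0, sigma = c(0.08, 0.05), pace = 200,
                    bias_factor = 12)
  run <- langevin_metad_run(ft$system, p, cvs = c("axial", "compactness"),
                            n_steps = 2e5, x0 = c(0, 0, 0), seed = 2,
                            stride = 100,
                            grid = list(axial = c(-0.7, 2.2, 401),
                                        compactness = c(-0.05, 1.05, 241)))
  expect_equal(names(run$hills),
               c("time", "cv1", "cv2", "sigma_cv1", "sigma_cv2",
                 "height", "biasf"))
  expect_gt(nrow(run$hills), 0)
  # compactness CV is a logistic of distance: bounded in (0, 1)
  expect_true(all(run$colvar$compactness >= 0 & run$colvar$compactness <= 1))
  fes2 <- reconstruct_fes(run$hills,
                          list(cv1 = seq(-0.5, 2, length.out = 201),
                               cv2 = seq(0, 1, length.out = 101)))
  expect_equal(dim(fes2$values), c(201, 101))
  proj <- project_fes(fes2, onto = 1)
  # the deep region of the projected profile sits in the bound zone (small z)
  expect_lt(proj$axes[[1]][which.min(proj$values)], 0.5)
  # 2-CV hills round-trip through the HILLS dialect
  f <- withr::local_tempfile()
  write_hills(run$hills, f)
  back <- read_hills(f)
  expect_equal(nrow(back), nrow(run$hills))
  expect_equal(back$cv2, as.numeric(sprintf("%.6f", run$hills$cv2)))
})
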