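test_that("flat profile reduces to the closed-form volume term", {
  geom <- funnel_geometry(r_cyl = 0.1)
  z <- seq(-0.2, 2, length.out = 1101)
  fes <- free_energy_surface(list(z = z), rep(0, length(z)),
                             temperature = 300)
  bound <- c(0, 0.5)
  est <- binding_delta_g(fes, geom, bound, c(1, 1.8))
  dg_expected <- -kT300 * log(pi * 0.1^2 * 0.5 * 0.6022140857) / 4.184
  expect_equal(est$delta_g, dg_expected, tolerance = 1e-6)
})

test_that("square axial well reproduces the quadrature Delta G (~ +0.388 kcal/mol)", {
  geom <- funnel_geometry(r_cyl = 0.1)
  kT <- kT300
  z <- seq(-0.3, 2, length.out = 4601)
  w <- ifelse(z >= 0 & z <= 0.5, -10, 0)  # ideal box well
  fes <- free_energy_surface(list(z = z), w, reference = "plateau",
                             temperature = 300)
  est <- binding_delta_g(fes, geom, c(0, 0.5), c(1, 1.8))
  # closed form: Kb = pi r_cyl^2 L e^{beta D}
  kb <- pi * 0.01 * 0.5 * exp(10 / kT)
  dg <- -kT * log(kb * 0.6022140857) / 4.184
  expect_lt(abs(est$delta_g - dg), 2e-3)
  expect_lt(abs(est$delta_g - 0.388), 0.01)
  # the lightly smoothed simulation preset sits close to the ideal box value
  toy <- make_toy("square_well_axial", params = list(softness = 0.005),
                  timestep = 0.0005)
  expect_lt(abs(toy$truth$delta_g_kcal - 0.388), 0.02)
})

test_that("deepening the well by 1 kBT lowers Delta G by ~ kBT in the deep-well limit", {
  geom <- funnel_geometry(r_cyl = 0.1)
  z <- seq(-0.3, 2, length.out = 2301)
  mk <- function(depth) {
    w <- ifelse(z >= 0 & z <= 0.5, -depth, 0)
    free_energy_surface(list(z = z), w, reference = "plateau",
                        temperature = 300)
  }
  dg <- function(depth) binding_delta_g(mk(depth), geom, c(-0.1, 0.6),
                                        c(1, 1.8))$delta_g
  shift_kcal <- dg(30 + kT300) - dg(30)
  expect_equal(shift_kcal * 4.184, -kT300, tolerance = 0.01)
})

test_that("binding estimate: kd/Delta G consistency, plateau warning, block errors", {
  geom <- funnel_geometry()
  z <- seq(-0.2, 2, length.out = 1101)
  w <- -15 * exp(-z^2 / (2 * 0.09))
  fes <- free_energy_surface(list(z = z), w, reference = "plateau",
                             temperature = 300)
  est <- binding_delta_g(fes, geom, c(-0.2, 0.6), c(1, 1.8))
  # declared convention kd = C0 exp(dG / RT), within 1e-6 relative
  kd_from_dg <- 1 * exp(est$delta_g * 4.184 / kT300) * 1e9
  expect_equal(est$kd, kd_from_dg, tolerance = 1e-6)
  expect_false(est$convergence_warning)

  # Delta G invariant to the unbound-window choice within the flat plateau
  est2 <- binding_delta_g(fes, geom, c(-0.2, 0.6), c(1.2, 1.6))
  expect_lt(abs(est2$delta_g - est$delta_g), 0.1)

  # a sloped "plateau" raises the convergence warning and flags the result
  w_bad <- w + 2 * z
  fes_bad <- free_energy_surface(list(z = z), w_bad, reference = "plateau",
                                 temperature = 300)
  expect_warning(est3 <- binding_delta_g(fes_bad, geom, c(-0.2, 0.6), c(1, 1.8)),
                 "plateau")
  expect_true(est3$convergence_warning)
  expect_error(binding_delta_g(fes, geom, c(-0.2, 0.6), c(0.2, 0.4)),
               "cylinder")

  # block uncertainty from per-block profiles propagates to kd
  set.seed(2)
  blocks <- lapply(1:5, function(b) {
    free_energy_surface(list(z = z), w + rnorm(1, 0, 0.3) *
                          exp(-z^2 / 0.2), reference = "plateau",
                        temperature = 300)
  })
  est4 <- binding_delta_g(fes, geom, c(-0.2, 0.6), c(1, 1.8),
                          fes_blocks = blocks)
  expect_gt(est4$uncertainty, 0)
  expect_gt(est4$kd_uncertainty, 0)
  # broom-style accessors
  td <- tidy(est4)
  expect_equal(td$term, c("delta_g", "kd"))
  expect_equal(glance(est4)$delta_g, est4$delta_g)
})

test_that("block standard errors: constant, iid, and correlated series", {
  expect_equal(block_errors(rep(3.2, 1000), 10), 0)
  set.seed(1)
  x <- rnorm(10000)
  se <- block_errors(x, 10)
  expect_equal(se, 0.01, tolerance = 0.5)  # sampling-theory scale 1/sqrt(n)
  # AR(1): block SE exceeds the naive iid SE
  phi <- 0.95
  ar <- as.numeric(stats::arima.sim(list(ar = phi), 10000))
  expect_gt(block_errors(ar, 10), sd(ar) / sqrt(length(ar)))
  expect_error(block_errors(1:10, 1), "n_blocks")
  expect_error(block_errors(1:3, 7), "n_blocks")
})

test_that("binding_delta_g on the exact funnel-trap profile matches direct 3-D integration", {
  fun <- funnel_geometry(k_wall = 2e5)
  ft <- make_toy("funnel_trap_3d", timestep = 0.001, funnel = fun)
  sys <- ft$system
  zg <- seq(-0.45, 2.0, length.out = 401)
  w_exact <- axial_pmf(sys, zg)
  est <- suppressWarnings(binding_delta_g(w_exact, fun,
                                          bound_region = ft$truth$bound_region,
                                          unbound_region = ft$truth$unbound_region))
  # direct Cartesian 3-D integral of the partition function over the site
  kT <- kT300
  n <- 61
  xs <- seq(-1.2, 1.2, length.out = n)
  zs <- seq(ft$truth$bound_region[1], ft$truth$bound_region[2],
            length.out = n)
  dx <- diff(xs)[1]; dz <- diff(zs)[1]
  g <- expand.grid(x = xs, y = xs, z = zs)
  u <- toy_energy(sys, as.matrix(g), include_wall = TRUE)
  kb_direct <- sum(exp(-u / kT)) * dx * dx * dz
  dg_direct <- -kT * log(kb_direct * 0.6022140857) / 4.184
  expect_equal(est$delta_g, dg_direct, tolerance = 0.05)
})
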