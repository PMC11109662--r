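test_that("single-hill reconstruction has depression gamma/(gamma-1) * h at the center", {
  h <- hills_log(data.frame(time = 1, cv1 = 0, sigma_cv1 = 0.2,
                            height = 1.0, biasf = 16))
  grid <- list(cv1 = seq(-3, 3, length.out = 601))
  fes <- reconstruct_fes(h, grid)
  expect_equal(min(fes$values), 0)
  i0 <- which.min(abs(grid$cv1))
  expect_equal(fes$values[i0], 0)  # the minimum sits at the hill center
  # far from the hill the surface rises to gamma/(gamma-1) * height
  expect_equal(max(fes$values), 16 / 15 * 1.0, tolerance = 1e-6)
  expect_error(reconstruct_fes(empty_hills_log(1), grid), "empty")
})

test_that("reconstruction recovers a synthesised double well and is grid-stable", {
  x <- seq(-2, 2, length.out = 401)
  target <- free_energy_surface(list(cv1 = x),
                                20 * ((x)^2 - 1)^2 + 1.5 * x,
                                temperature = 300)
  p <- metad_params(height0 = 1, sigma = 0.08, pace = 100, bias_factor = 16)
  hills <- suppressWarnings(hills_from_fes(target, p, n_hills = 4000, seed = 2))
  fes <- reconstruct_fes(hills, list(cv1 = x))
  df_target <- basin_delta_f(target)
  df_rec <- basin_delta_f(fes)
  expect_lt(abs(df_rec - df_target), 0.5)
  # doubling the grid changes the basin free-energy difference by < 0.1
  x2 <- seq(-2, 2, length.out = 801)
  fes2 <- reconstruct_fes(hills, list(cv1 = x2))
  expect_lt(abs(basin_delta_f(fes2) - df_rec), 0.1)
})

test_that("basin detection: analytic double well, monotone surface, perturbation", {
  x <- seq(-2, 2, length.out = 401)
  scale10 <- 10  # (x^2-1)^2 scaled to a 10 kJ/mol barrier
  fes <- free_energy_surface(list(cv1 = x), scale10 * (x^2 - 1)^2)
  b <- find_basins(fes, depth_min = 5)
  expect_equal(nrow(b), 2)
  expect_equal(sort(b$cv1), c(-1, 1), tolerance = 0.02)
  s <- saddle_estimate(fes, b[1, ], b[2, ])
  expect_equal(unname(s$point), 0, tolerance = 0.02)
  expect_equal(s$barrier, 10, tolerance = 0.1)

  # monotone surface: no basins deeper than the threshold
  mono <- free_energy_surface(list(cv1 = x), 3 * (x + 2.5))
  expect_equal(nrow(find_basins(mono, depth_min = 1)), 0)

  # random-perturbed double well (20 kJ/mol barrier, 1 kJ/mol perturbation
  # amplitude) still yields exactly two basins at a 5 kBT depth threshold
  set.seed(12)
  pert <- free_energy_surface(list(cv1 = x),
                              20 * (x^2 - 1)^2 + runif(401, -0.5, 0.5))
  b2 <- find_basins(pert, depth_min = 5 * kT300)
  expect_equal(nrow(b2), 2)
  expect_equal(sort(b2$cv1), c(-1, 1), tolerance = 0.05)
})

test_that("2-D basins and minimax saddle agree with a brute-force path search", {
  x <- seq(-1.5, 1.5, length.out = 30)
  y <- seq(-1, 1, length.out = 30)
  f <- outer(x, y, function(a, b) 8 * (a^2 - 1)^2 + 10 * b^2)
  fes <- free_energy_surface(list(cv1 = x, cv2 = y), f)
  b <- find_basins(fes, depth_min = 2)
  expect_equal(nrow(b), 2)
  s <- saddle_estimate(fes, b[1, ], b[2, ])

  # brute-force minimax over all grid paths by breadth-first threshold search
  connected_at <- function(vals, start, goal, L) {
    ok <- vals <= L
    nx <- nrow(vals); ny <- ncol(vals)
    if (!ok[start[1], start[2]]) return(FALSE)
    seen <- matrix(FALSE, nx, ny)
    seen[start[1], start[2]] <- TRUE
    queue <- list(start)
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        i <- cur[1] + di; j <- cur[2] + dj
        if (i >= 1 && i <= nx && j >= 1 && j <= ny && ok[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
    seen[goal[1], goal[2]]
  }
  minimax_bf <- function(vals, start, goal) {
    lv <- sort(unique(as.vector(vals)))
    lo <- 1; hi <- length(lv)   # binary search over candidate levels
    while (lo < hi) {
      mid <- (lo + hi) %/% 2
      if (connected_at(vals, start, goal, lv[mid])) hi <- mid else lo <- mid + 1
    }
    lv[lo]
  }
  i_a <- c(which.min(abs(x + 1)), which.min(abs(y)))
  i_b <- c(which.min(abs(x - 1)), which.min(abs(y)))
  level <- minimax_bf(f, i_a, i_b)
  # the stored surface is shifted so its minimum is zero
  expect_equal(s$value, level - min(f), tolerance = 1e-10)

  # labelling by a CV1 threshold
  b_lab <- find_basins(fes, depth_min = 2, cv1_threshold = 0)
  expect_setequal(b_lab$state, c("bound", "unbound"))
})

test_that("basins on disconnected structures are reported unreachable", {
  x <- seq(-2, 2, length.out = 201)
  v <- 10 * (x^2 - 1)^2
  v[abs(x) < 0.05] <- 1e8   # an effectively infinite wall
  fes <- free_energy_surface(list(cv1 = x), v)
  b <- find_basins(fes, depth_min = 5)
  # flooding the wall eventually connects them at the wall height
  s <- saddle_estimate(fes, b[1, ], b[2, ])
  expect_gte(s$value, 1e7)
  expect_error(saddle_estimate(fes, b[1, ], b[1, ]), "distinct")
})

test_that("2-D projection marginalises by Boltzmann weighting", {
  x <- seq(-1, 1, length.out = 101)
  y <- seq(-1, 1, length.out = 81)
  f <- outer(x, y, function(a, b) 5 * a^2 + 3 * b^2)
  fes <- free_energy_surface(list(cv1 = x, cv2 = y), f, temperature = 300)
  p1 <- project_fes(fes, onto = 1)
  # separable surface: projection is the x-part up to a constant
  expect_equal(p1$values, 5 * x^2 - min(5 * x^2), tolerance = 1e-9)
})

test_that("convergence profile decays for damped hills and errors on bad windows", {
  x <- seq(-1.5, 1.5, length.out = 201)
  target <- free_energy_surface(list(cv1 = x), 10 * (x^2 - 1)^2)
  p <- metad_params(height0 = 1, sigma = 0.1, pace = 10, bias_factor = 16)
  hills <- suppressWarnings(hills_from_fes(target, p, n_hills = 3000, seed = 4))
  prof <- convergence_profile(hills, window = 500, grid = list(cv1 = x))
  expect_true(all(prof$max_delta_f >= 0))
  expect_lt(tail(prof$max_delta_f, 1), 0.5)
  expect_lt(tail(prof$max_delta_f, 1), head(prof$max_delta_f, 1))
  expect_error(convergence_profile(hills, window = 1e6, grid = list(cv1 = x)),
               "window")
})

test_that("assign_frames labels by extent with deep-basin tie-break", {
  x <- seq(-2, 2, length.out = 401)
  fes <- free_energy_surface(list(cv1 = x), 20 * (x^2 - 1)^2 + 1.5 * x)
  b <- find_basins(fes, depth_min = 5)
  cv <- tibble::tibble(time = 0:3, cv1 = c(b$cv1[1], b$cv1[2], 0, 1.9))
  lab <- assign_frames(cv, b)
  expect_equal(lab$basin[1], b$label[1])
  expect_equal(lab$basin[2], b$label[2])
  expect_equal(lab$basin[4], "unassigned")
  # synthetic points drawn inside known extents match exactly
  set.seed(3)
  for (k in 1:2) {
    ext <- b$extent[[k]]$cv1
    pts <- tibble::tibble(cv1 = runif(50, ext[1], ext[2]))
    expect_true(all(assign_frames(pts, b)$basin == b$label[k]))
  }
})
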