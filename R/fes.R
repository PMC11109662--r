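#' Free-energy surface on a grid
#'
#' Container for a gridded free-energy estimate over one or two collective
#' variables (or a single axial coordinate). When `reference = "minimum"`
#' the values are shifted so the global minimum is exactly zero.
#'
#' @param axes Named list of strictly increasing grid vectors (one or two).
#' @param values Numeric vector (1-D) or matrix (2-D, rows follow the first
#'   axis), kJ mol^-1, all finite.
#' @param reference Zeroing convention: `"minimum"` (default) or
#'   `"plateau"` (left as supplied).
#' @param temperature Temperature, K.
#' @param bias_factor Bias factor of the generating protocol (NA if not
#'   applicable).
#' @return An object of class `fes`.
#' @export
free_energy_surface <- function(axes, values, reference = c("minimum", "plateau"),
                                temperature = 300, bias_factor = NA_real_) {
  reference <- match.arg(reference)
  if (!is.list(axes) || length(axes) < 1 || length(axes) > 2)
    abort("`axes` must be a named list of one or two grid vectors")
  if (is.null(names(axes)) || any(names(axes) == ""))
    abort("`axes` must be named")
  for (a in axes) {
    if (any(diff(a) <= 0)) abort("grid axes must be strictly increasing")
  }
  dims <- vapply(axes, length, integer(1))
  if (length(axes) == 1) {
    values <- as.numeric(values)
    if (length(values) != dims[1]) abort("values do not match the grid")
  } else {
    values <- as.matrix(values)
    if (!all(dim(values) == dims)) abort("values do not match the grid")
  }
  if (!all(is.finite(values))) abort("free-energy values must be finite")
  if (reference == "minimum") values <- values - min(values)
  structure(list(axes = axes, values = values, reference = reference,
                 temperature = temperature, bias_factor = bias_factor),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  dims <- paste(vapply(x$axes, length, integer(1)), collapse = " x ")
  cat(sprintf("<fes> %s grid over (%s); range 0 - %.3f kJ/mol; T = %g K; gamma = %s\n",
              dims, paste(names(x$axes), collapse = ", "),
              max(x$values) - min(x$values), x$temperature,
              format(x$bias_factor)))
  invisible(x)
}

fes_ndim <- function(fes) length(fes$axes)

#' Reconstruct the free-energy surface from a hills log
#'
#' Well-tempered estimator: `F(s) = -(gamma / (gamma - 1)) * V_hills(s)`,
#' shifted so the minimum is zero; as `gamma` grows the scale factor tends
#' to 1 and the estimator reduces to the plain `-V_hills`.
#'
#' @param hills A non-empty [hills_log()].
#' @param grid Named list of grid vectors spanning the hill centers (one per
#'   CV).
#' @param temperature Temperature recorded on the surface; defaults to the
#'   hills log's.
#' @return A [free_energy_surface()] with `reference = "minimum"`.
#' @export
reconstruct_fes <- function(hills, grid, temperature = NULL) {
  if (nrow(hills) == 0) abort("cannot estimate a surface from an empty hills log")
  ncv <- hills_ncv(hills)
  if (length(grid) != ncv) abort("grid dimensionality must match the hills")
  gamma <- hills_bias_factor(hills)
  scale <- gamma / (gamma - 1)
  h <- hills$height
  if (ncv == 1) {
    e1 <- exp(-outer(grid[[1]], hills$cv1, "-")^2 /
                matrix(2 * hills$sigma_cv1^2, length(grid[[1]]),
                       nrow(hills), byrow = TRUE))
    v <- drop(e1 %*% h)
  } else {
    e1 <- exp(-outer(grid[[1]], hills$cv1, "-")^2 /
                matrix(2 * hills$sigma_cv1^2, length(grid[[1]]),
                       nrow(hills), byrow = TRUE))
    e2 <- exp(-outer(grid[[2]], hills$cv2, "-")^2 /
                matrix(2 * hills$sigma_cv2^2, length(grid[[2]]),
                       nrow(hills), byrow = TRUE))
    v <- e1 %*% (h * t(e2))
  }
  free_energy_surface(grid, -scale * v, reference = "minimum",
                      temperature = temperature %||%
                        attr(hills, "temperature") %||% 300,
                      bias_factor = gamma)
}

#' Project a 2-D surface onto one axis
#'
#' Boltzmann marginalisation: `F1(s1) = -kB T log sum_s2 exp(-F(s1, s2) /
#' (kB T))`, re-zeroed at its minimum. Used to turn the two-CV binding
#' surface into the axial profile that enters the funnel correction.
#'
#' @param fes A 2-D [free_energy_surface()].
#' @param onto Axis to keep: index (1 or 2) or axis name.
#' @return A 1-D [free_energy_surface()].
#' @export
project_fes <- function(fes, onto = 1) {
  stopifnot(inherits(fes, "fes"))
  if (fes_ndim(fes) != 2) abort("`project_fes` expects a 2-D surface")
  if (is.character(onto)) onto <- match(onto, names(fes$axes))
  if (is.na(onto) || !(onto %in% 1:2)) abort("unknown projection axis")
  kT <- .kB * fes$temperature
  margin <- if (onto == 1) 1 else 2
  w <- apply(fes$values, margin, function(col) -kT * log(sum(exp(-col / kT))))
  free_energy_surface(fes$axes[onto], w, reference = "minimum",
                      temperature = fes$temperature,
                      bias_factor = fes$bias_factor)
}

# neighbours of cell k on the grid (8-neighbourhood in 2-D, 2 in 1-D)
grid_neighbours <- function(dims) {
  if (length(dims) == 1) {
    function(k) {
      out <- c(k - 1L, k + 1L)
      out[out >= 1L & out <= dims[1]]
    }
  } else {
    nx <- dims[1]; ny <- dims[2]
    function(k) {
      i <- ((k - 1L) %% nx) + 1L
      j <- ((k - 1L) %/% nx) + 1L
      ii <- pmax(1L, i - 1L):pmin(nx, i + 1L)
      jj <- pmax(1L, j - 1L):pmin(ny, j + 1L)
      cells <- as.vector(outer(ii, jj, function(a, b) a + (b - 1L) * nx))
      cells[cells != k]
    }
  }
}

# union-find with path compression
uf_find <- function(parent, k) {
  while (parent[k] != k) k <- parent[k]
  k
}

#' Detect free-energy basins
#'
#' Finds local minima on the grid whose depth below the lowest surrounding
#' saddle (topographic persistence, computed by a flooding sweep with
#' union-find merging; 8-neighbourhood in 2-D) exceeds `depth_min`. Basins
#' are labelled `"Minimum 1"`, `"Minimum 2"`, ... in order of decreasing
#' depth; when `cv1_threshold` is supplied each basin is additionally
#' flagged bound (first-axis location below the threshold) or unbound. Each
#' basin's extent is the bounding box, at the basin's iso-level, of the grid
#' cells in its own catchment (steepest-descent watershed), so extents of
#' different basins never overlap.
#'
#' @param fes A [free_energy_surface()].
#' @param depth_min Minimum depth for a basin to be reported, kJ mol^-1.
#'   Default `2 * 4.184` (2 kcal mol^-1: only pronounced minima).
#' @param cv1_threshold Optional first-axis value separating bound from
#'   unbound basins.
#' @return A tibble of class `basin_set`: `label`, one column per axis
#'   (minimum location), `value` (F at the minimum), `depth`, `iso_level`,
#'   `state` (`"bound"`/`"unbound"`/NA) and a list-column `extent` of named
#'   per-axis ranges. Possibly zero rows.
#' @export
find_basins <- function(fes, depth_min = 2 * 4.184, cv1_threshold = NULL) {
  stopifnot(inherits(fes, "fes"))
  dims <- vapply(fes$axes, length, integer(1))
  vals <- as.vector(fes$values)  # column-major: first axis fastest
  n <- length(vals)
  nb <- grid_neighbours(dims)
  ord <- order(vals, seq_len(n))  # deterministic tie-break by index
  parent <- seq_len(n)
  comp_min <- integer(n)          # root -> cell index of its minimum
  visited <- logical(n)
  death_level <- rep(NA_real_, n) # per minimum cell
  merged_into <- integer(n)       # per minimum cell -> minimum it died into
  saddle_cell <- integer(n)
  minima <- integer(0)
  for (c in ord) {
    nbs <- nb(c)
    nbs <- nbs[visited[nbs]]
    roots <- unique(vapply(nbs, function(x) uf_find(parent, x), integer(1)))
    if (length(roots) == 0) {
      visited[c] <- TRUE
      comp_min[c] <- c
      minima <- c(minima, c)
      next
    }
    # survivor: component with the deepest minimum (tie: lowest cell index)
    mins <- comp_min[roots]
    o <- order(vals[mins], mins)
    surv <- roots[o[1]]
    for (r in roots) {
      if (r == surv) next
      m <- comp_min[r]
      death_level[m] <- vals[c]
      merged_into[m] <- comp_min[surv]
      saddle_cell[m] <- c
      parent[r] <- surv
    }
    parent[c] <- surv
    visited[c] <- TRUE
  }
  persistence <- ifelse(is.na(death_level[minima]),
                        max(vals) - vals[minima],
                        death_level[minima] - vals[minima])
  # a "minimum" on the grid edge is a domain-boundary artefact (e.g. of a
  # monotone surface), not a basin
  on_boundary <- if (length(dims) == 1) {
    function(k) k == 1L || k == dims[1]
  } else {
    function(k) {
      i <- ((k - 1L) %% dims[1]) + 1L
      j <- ((k - 1L) %/% dims[1]) + 1L
      i == 1L || i == dims[1] || j == 1L || j == dims[2]
    }
  }
  boundary_min <- vapply(minima, on_boundary, logical(1))
  keep <- minima[persistence > depth_min & !boundary_min]
  pers <- persistence[match(keep, minima)]
  ord2 <- order(-pers, vals[keep])
  keep <- keep[ord2]; pers <- pers[ord2]
  if (length(keep) == 0) {
    out <- tibble(label = character(0))
    for (nm in names(fes$axes)) out[[nm]] <- numeric(0)
    out$value <- numeric(0); out$depth <- numeric(0)
    out$iso_level <- numeric(0); out$state <- character(0)
    out$extent <- list()
    class(out) <- c("basin_set", class(out))
    return(out)
  }
  # watershed: steepest-descent assignment of every cell to a local minimum,
  # then chase merged_into chains down to a retained basin (if any)
  assign_min <- integer(n)
  for (c in ord) {
    nbs <- nb(c)
    lower <- nbs[vals[nbs] < vals[c] | (vals[nbs] == vals[c] & nbs < c)]
    if (length(lower) == 0) {
      assign_min[c] <- c
    } else {
      best <- lower[order(vals[lower], lower)][1]
      assign_min[c] <- assign_min[best]
    }
  }
  resolve <- function(m) {
    seen <- integer(0)
    while (!(m %in% keep) && merged_into[m] != 0L && !(m %in% seen)) {
      seen <- c(seen, m)
      m <- merged_into[m]
    }
    m
  }
  resolved <- vapply(unique(assign_min), resolve, integer(1))
  names(resolved) <- as.character(unique(assign_min))
  basin_of <- resolved[as.character(assign_min)]

  cell_coords <- function(cells) {
    if (length(dims) == 1) {
      list(fes$axes[[1]][cells])
    } else {
      i <- ((cells - 1L) %% dims[1]) + 1L
      j <- ((cells - 1L) %/% dims[1]) + 1L
      list(fes$axes[[1]][i], fes$axes[[2]][j])
    }
  }
  finite_deaths <- death_level[minima][is.finite(death_level[minima])]
  top_level <- if (length(finite_deaths) > 0) max(finite_deaths) else max(vals)
  out <- tibble(label = paste("Minimum", seq_along(keep)))
  locs <- cell_coords(keep)
  for (d in seq_along(fes$axes)) out[[names(fes$axes)[d]]] <- locs[[d]]
  out$value <- vals[keep]
  out$depth <- pers
  out$iso_level <- pmin(vals[keep] + pers, top_level)
  out$state <- if (is.null(cv1_threshold)) NA_character_ else
    ifelse(locs[[1]] <= cv1_threshold, "bound", "unbound")
  out$extent <- lapply(seq_along(keep), function(k) {
    cells <- which(basin_of == keep[k] & vals <= out$iso_level[k])
    cc <- cell_coords(cells)
    ext <- lapply(cc, range)
    names(ext) <- names(fes$axes)
    ext
  })
  class(out) <- c("basin_set", class(out))
  out
}

#' Saddle point and barrier between two basins
#'
#' Minimax path value between two basin minima over grid paths
#' (8-neighbourhood in 2-D), found by flooding the surface in order of
#' increasing value until the two minima become connected; the cell that
#' first connects them is the saddle estimate. The barrier is the saddle
#' value minus the free energy at basin `a`.
#'
#' @param fes A [free_energy_surface()].
#' @param a,b Basin rows (from [find_basins()]) or numeric minimum
#'   locations (length = number of axes); `a != b`.
#' @return A list with `point` (named saddle location), `value` (F at the
#'   saddle) and `barrier` (kJ mol^-1, relative to `a`).
#' @export
saddle_estimate <- function(fes, a, b) {
  stopifnot(inherits(fes, "fes"))
  dims <- vapply(fes$axes, length, integer(1))
  vals <- as.vector(fes$values)
  locate <- function(p) {
    if (is.data.frame(p)) p <- unlist(p[1, names(fes$axes)])
    idx <- vapply(seq_along(fes$axes), function(d)
      which.min(abs(fes$axes[[d]] - p[d])), integer(1))
    if (length(dims) == 1) idx[1] else idx[1] + (idx[2] - 1L) * dims[1]
  }
  ca <- locate(a); cb <- locate(b)
  if (ca == cb) abort("`a` and `b` must be distinct basins")
  nb <- grid_neighbours(dims)
  ord <- order(vals, seq_along(vals))
  parent <- seq_along(vals)
  visited <- logical(length(vals))
  for (c in ord) {
    visited[c] <- TRUE
    for (x in nb(c)) {
      if (visited[x]) {
        rx <- uf_find(parent, x); rc <- uf_find(parent, c)
        if (rx != rc) parent[rx] <- rc
      }
    }
    if (uf_find(parent, ca) == uf_find(parent, cb)) {
      pt <- if (length(dims) == 1) {
        setNames(fes$axes[[1]][c], names(fes$axes)[1])
      } else {
        i <- ((c - 1L) %% dims[1]) + 1L
        j <- ((c - 1L) %/% dims[1]) + 1L
        setNames(c(fes$axes[[1]][i], fes$axes[[2]][j]), names(fes$axes))
      }
      va <- vals[ca]
      return(list(point = pt, value = vals[c], barrier = vals[c] - va))
    }
  }
  abort("basins are not connected on the grid")
}

#' Free-energy convergence profile over deposition time
#'
#' For each window boundary `t`, reconstructs the surface from all hills up
#' to `t` and up to `t - window`, aligns both to their minima and reports
#' the maximum absolute difference on the grid — the flatness of this series
#' in late windows is the convergence diagnostic of a well-tempered run.
#'
#' @param hills A [hills_log()].
#' @param window Window length, ps (> 0); the run must cover at least two
#'   windows.
#' @param grid Named list of grid vectors (as in [reconstruct_fes()]).
#' @return A tibble with columns `time` and `max_delta_f` (kJ mol^-1).
#' @export
convergence_profile <- function(hills, window, grid) {
  if (nrow(hills) == 0) abort("empty hills log")
  t_max <- max(hills$time)
  if (window <= 0 || window * 2 > t_max)
    abort("`window` must be positive and at most half the run length")
  boundaries <- seq(2 * window, t_max, by = window)
  subset_hills <- function(tmax) {
    hills_log(as.data.frame(hills)[hills$time <= tmax, ],
              temperature = attr(hills, "temperature") %||% 300)
  }
  res <- vapply(boundaries, function(t) {
    f_now <- reconstruct_fes(subset_hills(t), grid)
    f_prev <- reconstruct_fes(subset_hills(t - window), grid)
    max(abs(f_now$values - f_prev$values))
  }, numeric(1))
  tibble(time = boundaries, max_delta_f = res)
}

#' Boltzmann free-energy difference between the two halves of a profile
#'
#' For a 1-D surface split at `divide_at`, returns
#' `-kB T log(Z_right / Z_left)` with `Z` the Boltzmann weight of each side
#' — the basin free-energy difference (right minus left), insensitive to
#' the surface's zero.
#'
#' @param fes A 1-D [free_energy_surface()].
#' @param divide_at Dividing coordinate (default 0).
#' @return Free-energy difference, kJ mol^-1.
#' @export
basin_delta_f <- function(fes, divide_at = 0) {
  stopifnot(inherits(fes, "fes"))
  if (fes_ndim(fes) != 1) abort("`basin_delta_f` expects a 1-D surface")
  kT <- .kB * fes$temperature
  x <- fes$axes[[1]]
  w <- exp(-fes$values / kT)
  zl <- trapz(x[x < divide_at], w[x < divide_at])
  zr <- trapz(x[x >= divide_at], w[x >= divide_at])
  -kT * log(zr / zl)
}

#' Tail-averaged free-energy reconstruction
#'
#' Averages the well-tempered reconstruction over several checkpoints in
#' the tail of the deposition history (the standard damping of the
#' late-time oscillation of the estimator): the surface is reconstructed
#' from the first `k` hills for `n_checkpoints` values of `k` spaced
#' evenly between `from * n_hills` and `n_hills`, and the values are
#' averaged after aligning each reconstruction at its minimum.
#'
#' @param hills A [hills_log()].
#' @param grid Named list of grid vectors.
#' @param from Fraction of the history where averaging starts. Default 0.7.
#' @param n_checkpoints Number of reconstructions averaged. Default 8.
#' @return A [free_energy_surface()].
#' @export
fes_tail_average <- function(hills, grid, from = 0.7, n_checkpoints = 8) {
  nh <- nrow(hills)
  if (nh < 2) abort("too few hills for tail averaging")
  cks <- unique(round(seq(max(1, from * nh), nh, length.out = n_checkpoints)))
  temp <- attr(hills, "temperature") %||% 300
  acc <- NULL
  for (k in cks) {
    f <- reconstruct_fes(hills_log(as.data.frame(hills)[seq_len(k), ],
                                   temperature = temp), grid)
    acc <- if (is.null(acc)) f$values else acc + f$values
  }
  free_energy_surface(grid, acc / length(cks), reference = "minimum",
                      temperature = temp,
                      bias_factor = hills_bias_factor(hills))
}
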