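#' Toy system with analytic ground truth
#'
#' Builds a [toy_system()] and computes, by high-accuracy quadrature at
#' construction, the thermodynamic ground truth that the sampling and
#' free-energy machinery is expected to recover:
#' \describe{
#'   \item{harmonic}{`position_variance = kB T / k` (per coordinate, nm^2).}
#'   \item{double_well_1d}{`delta_f`, the free-energy difference (right
#'     minus left basin, kJ mol^-1) from quadrature of `exp(-U/kBT)` over
#'     each half-line.}
#'   \item{square_well_axial}{`delta_g_kcal`, the standard-state binding
#'     free energy of the axial well inside the funnel cylinder.}
#'   \item{funnel_trap_3d}{`delta_g_kcal` and `kb_nm3` from 2-D (z, rho)
#'     quadrature of the full Boltzmann factor (potential plus funnel wall)
#'     over the bound region.}
#'   \item{two_channel_exit}{no scalar truth; egress statistics are checked
#'     by self-consistency at higher replica counts.}
#' }
#'
#' A basic integration-stability check rejects parameter combinations whose
#' stiffest curvature would require a smaller timestep (the documented rule
#' is `timestep <= 0.5 / sqrt(k_max / mass)`).
#'
#' @inheritParams toy_system
#' @param bound_region,unbound_region z-intervals (nm) used for the binding
#'   presets' ground truth (defaults suit the default parameters).
#' @return A list with elements `system` (the [toy_system()]) and `truth`
#'   (named list as above).
#' @export
make_toy <- function(preset, params = list(), mass = 1, friction = 1,
                     temperature = 300, timestep = 0.002, funnel = NULL,
                     bound_region = NULL, unbound_region = NULL) {
  if (preset %in% c("square_well_axial", "funnel_trap_3d") && is.null(funnel))
    funnel <- funnel_geometry()
  sys <- toy_system(preset, params, mass, friction, temperature, timestep,
                    funnel)
  check_stability(sys)
  kT <- .kB * temperature
  p <- sys$params
  truth <- switch(preset,
    harmonic = list(position_variance = kT / p[["k"]]),
    double_well_1d = {
      a <- p[["halfwidth"]]
      ux <- function(x) toy_energy(sys, cbind(x, 0, 0), include_wall = FALSE)
      zl <- integrate(function(x) exp(-ux(x) / kT), -4 * a, 0,
                      rel.tol = 1e-10)$value
      zr <- integrate(function(x) exp(-ux(x) / kT), 0, 4 * a,
                      rel.tol = 1e-10)$value
      list(delta_f = -kT * log(zr / zl))
    },
    square_well_axial = {
      bound_region <- bound_region %||% c(-0.2, sys$params[["length"]] + 0.2)
      wz <- function(z) toy_energy(sys, cbind(0, 0, z), include_wall = FALSE)
      kb <- pi * funnel$r_cyl^2 *
        integrate(function(z) exp(-wz(z) / kT), bound_region[1],
                  bound_region[2], rel.tol = 1e-10)$value
      dg <- -kT * log(kb * 0.6022140857)
      list(delta_g_kcal = dg / .kJ_per_kcal, kb_nm3 = kb,
           bound_region = bound_region)
    },
    funnel_trap_3d = {
      bound_region <- bound_region %||% c(p[["z_min"]], 0.45)
      kb <- kb_quadrature(sys, bound_region)
      dg <- -kT * log(kb * 0.6022140857)
      list(delta_g_kcal = dg / .kJ_per_kcal, kb_nm3 = kb,
           bound_region = bound_region,
           unbound_region = unbound_region %||% c(1.0, 1.8))
    },
    two_channel_exit = list())
  list(system = sys, truth = truth)
}

check_stability <- function(sys) {
  p <- sys$params
  k_max <- switch(sys$preset,
    harmonic = p[["k"]],
    double_well_1d = max(8 * p[["barrier"]] / p[["halfwidth"]]^2,
                         p[["k_perp"]]),
    square_well_axial = p[["depth"]] / (4 * p[["softness"]]^2),
    funnel_trap_3d = max(p[["depth"]] / (4 * p[["softness"]]^2),
                         p[["k_axial"]]),
    two_channel_exit = max(p[["barrier"]] / p[["ring_width"]]^2, p[["k_z"]]))
  if (!is.null(sys$funnel)) k_max <- max(k_max, sys$funnel$k_wall)
  dt_max <- 0.5 / sqrt(k_max / sys$mass)
  if (sys$timestep > dt_max)
    abort(sprintf(
      "timestep %.4g ps unstable for preset '%s': requires <= %.4g ps (0.5/sqrt(k_max/m))",
      sys$timestep, sys$preset, dt_max))
  invisible(TRUE)
}

# binding constant of an axisymmetric trap by 2-D (z, rho) quadrature of the
# Boltzmann factor (potential + funnel wall), bulk reference U = 0
kb_quadrature <- function(sys, bound_region, rho_max = NULL) {
  kT <- .kB * sys$temperature
  geom <- sys$funnel
  rho_max <- rho_max %||% (funnel_radius(bound_region[1], geom) + 0.3)
  inner <- function(z) {
    vapply(z, function(zz) {
      integrate(function(rho) {
        pos <- cbind(rho, 0, zz)  # axisymmetric: any azimuth
        2 * pi * rho * exp(-toy_energy(sys, pos, include_wall = TRUE) / kT)
      }, 0, rho_max, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  integrate(inner, bound_region[1], bound_region[2], rel.tol = 1e-8)$value
}

#' Axial potential of mean force by radial quadrature
#'
#' The exact axial profile `W(z) = -kB T log integral exp(-U_total/kBT)
#' 2 pi rho d rho` of an axisymmetric toy system inside its funnel, on a
#' grid — the quadrature reference against which the metadynamics estimate
#' of the same profile is compared.
#'
#' @param sys An axisymmetric [toy_system()] with a funnel.
#' @param z_grid Axial grid, nm.
#' @param rho_max Radial integration limit, nm (default: a margin beyond
#'   the widest funnel radius on the grid).
#' @return A 1-D [free_energy_surface()] over `z` (reference = minimum).
#' @export
axial_pmf <- function(sys, z_grid, rho_max = NULL) {
  stopifnot(inherits(sys, "toy_system"))
  if (is.null(sys$funnel)) abort("`axial_pmf` requires a funnel")
  kT <- .kB * sys$temperature
  rho_max <- rho_max %||% (max(funnel_radius(z_grid, sys$funnel)) + 0.3)
  w <- vapply(z_grid, function(zz) {
    val <- integrate(function(rho) {
      pos <- cbind(rho, 0, zz)
      2 * pi * rho * exp(-toy_energy(sys, pos, include_wall = TRUE) / kT)
    }, 0, rho_max, rel.tol = 1e-9)$value
    -kT * log(val)
  }, numeric(1))
  free_energy_surface(list(z = z_grid), w, reference = "minimum",
                      temperature = sys$temperature)
}

#' Synthesise a hills log consistent with a known surface
#'
#' Inverse generator for reconstruction tests: emits Gaussian hills whose
#' sum approximates the converged well-tempered bias
#' `V = (1 - 1/gamma) (max F - F)` of the target surface, so that
#' [reconstruct_fes()] recovers the target. Hills are placed greedily at
#' the maximum of the running residual (with a small seeded jitter) with
#' heights capped by the well-tempered rule; the residual reached is
#' attached as the `residual` attribute, with a warning when `n_hills` was
#' insufficient to bring it under half the initial hill height.
#'
#' @param target A [free_energy_surface()] (1-D or 2-D).
#' @param p A [metad_params()] (widths, initial height, bias factor).
#' @param n_hills Number of hills to emit.
#' @param seed Optional integer seed for the jitter.
#' @return A [hills_log()]; empty (with a warning) when `n_hills = 0`.
#' @export
hills_from_fes <- function(target, p, n_hills, seed = NULL) {
  stopifnot(inherits(target, "fes"), inherits(p, "metad_params"))
  if (!is.null(seed)) set.seed(seed)
  ncv <- fes_ndim(target)
  if (length(p$sigma) != ncv) abort("sigma dimensionality must match target")
  if (n_hills == 0) {
    warn("n_hills = 0: empty hills log cannot approximate the target")
    return(empty_hills_log(ncv, temperature = p$temperature))
  }
  gamma <- p$bias_factor
  kT <- .kB * p$temperature
  v_target <- (1 - 1 / gamma) * (max(target$values) - target$values)
  axes <- target$axes
  dx <- vapply(axes, function(a) a[2] - a[1], numeric(1))
  v_cur <- array(0, dim = dim(as.array(target$values)))
  if (ncv == 1) v_cur <- as.numeric(v_cur)
  centers <- matrix(NA_real_, n_hills, ncv)
  heights <- numeric(n_hills)
  grids <- if (ncv == 1) list(axes[[1]]) else axes
  for (k in seq_len(n_hills)) {
    resid <- v_target - v_cur
    i_max <- which.max(resid)
    r_max <- resid[i_max]
    if (ncv == 1) {
      c_k <- axes[[1]][i_max] + runif(1, -dx[1] / 2, dx[1] / 2)
      centers[k, 1] <- c_k
      h <- max(min(wt_height(v_cur[i_max], p), r_max), 1e-6)
      v_cur <- v_cur + h * exp(-(axes[[1]] - c_k)^2 / (2 * p$sigma[1]^2))
    } else {
      ij <- arrayInd(i_max, dim(v_cur))
      c_k <- c(axes[[1]][ij[1]] + runif(1, -dx[1] / 2, dx[1] / 2),
               axes[[2]][ij[2]] + runif(1, -dx[2] / 2, dx[2] / 2))
      centers[k, ] <- c_k
      h <- max(min(wt_height(v_cur[i_max], p), r_max), 1e-6)
      v_cur <- v_cur + h * outer(
        exp(-(axes[[1]] - c_k[1])^2 / (2 * p$sigma[1]^2)),
        exp(-(axes[[2]] - c_k[2])^2 / (2 * p$sigma[2]^2)))
    }
    heights[k] <- h
  }
  residual <- max(abs(v_target - v_cur))
  if (residual > p$height0 / 2)
    warn(sprintf("hills_from_fes: residual %.3f kJ/mol after %d hills",
                 residual, n_hills))
  df <- data.frame(time = seq_len(n_hills))
  for (d in seq_len(ncv)) df[[paste0("cv", d)]] <- centers[, d]
  for (d in seq_len(ncv)) df[[paste0("sigma_cv", d)]] <- p$sigma[d]
  df$height <- heights
  df$biasf <- gamma
  out <- hills_log(df, temperature = p$temperature)
  attr(out, "residual") <- residual
  out
}
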