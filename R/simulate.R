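#' Analytic toy systems for Langevin sampling
#'
#' Registers one of the analytic potential presets together with the Langevin
#' parameters of the bath. Internal units: kJ mol^-1 (energy), nm (length),
#' ps (time), amu (mass) — so forces are kJ mol^-1 nm^-1 and the thermal
#' velocity is `sqrt(kB T / m)` nm/ps.
#'
#' Presets and their parameters (defaults in parentheses):
#' \describe{
#'   \item{`harmonic`}{`k` (100): isotropic 3-D well `U = k|r|^2/2`.
#'     Stable for `timestep <= 0.01` ps at the default stiffness.}
#'   \item{`double_well_1d`}{`barrier` (20), `halfwidth` (1), `asymmetry`
#'     (3), `k_perp` (200): tilted quartic
#'     `U = barrier ((x/a)^2 - 1)^2 + asymmetry/2 * (x/a)` along x, harmonic
#'     confinement across. `asymmetry` is the energy offset between the two
#'     minima. Stable for `timestep <= 0.005` ps.}
#'   \item{`square_well_axial`}{`depth` (10), `length` (0.5), `softness`
#'     (0.02): smoothed axial box well of depth `-depth` on z in
#'     `[0, length]`; combine with a funnel for radial confinement.}
#'   \item{`funnel_trap_3d`}{`depth` (25), `radius` (0.25), `softness`
#'     (0.05), `z_min` (-0.5), `z_max` (2), `k_axial` (1000): smooth
#'     spherical well at the origin with soft axial end walls; the canonical
#'     end-to-end binding fixture when paired with a funnel.}
#'   \item{`two_channel_exit`}{`barrier` (25), `ring_radius` (0.5),
#'     `ring_width` (0.1), `kappa_wide` (10), `kappa_narrow` (40), `k_z`
#'     (100): planar ring barrier with a wide gap at +x and a narrow gap at
#'     -x, used to exercise the RAMD egress statistics.}
#' }
#'
#' @param preset Preset name (see Details).
#' @param params Named list overriding preset parameters.
#' @param mass Particle mass, amu (> 0).
#' @param friction Langevin friction, ps^-1 (> 0).
#' @param temperature Bath temperature, K (> 0).
#' @param timestep Integration step, ps (> 0).
#' @param funnel Optional [funnel_geometry()] restraint.
#' @return An object of class `toy_system`.
#' @export
toy_system <- function(preset = c("harmonic", "double_well_1d",
                                  "square_well_axial", "funnel_trap_3d",
                                  "two_channel_exit"),
                       params = list(), mass = 1, friction = 1,
                       temperature = 300, timestep = 0.002, funnel = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    harmonic = c(k = 100),
    double_well_1d = c(barrier = 20, halfwidth = 1, asymmetry = 3,
                       k_perp = 200),
    square_well_axial = c(depth = 10, length = 0.5, softness = 0.02),
    funnel_trap_3d = c(depth = 25, radius = 0.25, softness = 0.05,
                       z_min = -0.5, z_max = 2, k_axial = 1000),
    two_channel_exit = c(barrier = 25, ring_radius = 0.5, ring_width = 0.1,
                         kappa_wide = 10, kappa_narrow = 40, k_z = 100))
  if (length(params) > 0) {
    bad <- setdiff(names(params), names(defaults))
    if (length(bad) > 0)
      abort(paste0("unknown parameter(s) for preset '", preset, "': ",
                   paste(bad, collapse = ", ")))
    defaults[names(params)] <- unlist(params)
  }
  for (nm in c("mass", "friction", "temperature", "timestep")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) abort(paste0("`", nm, "` must be > 0"))
  }
  if (!is.null(funnel)) stopifnot(inherits(funnel, "funnel_geometry"))
  structure(
    list(preset = preset, params = defaults, mass = mass,
         friction = friction, temperature = temperature,
         timestep = timestep, funnel = funnel),
    class = "toy_system")
}

preset_code <- function(preset) {
  match(preset, c("harmonic", "double_well_1d", "square_well_axial",
                  "funnel_trap_3d", "two_channel_exit")) - 1L
}

#' Potential energy of a toy system at given positions
#'
#' @param sys A [toy_system()].
#' @param pos A 3-vector or n x 3 matrix of positions, nm.
#' @param include_wall Include the funnel wall energy (if a funnel is set)?
#' @return Energy (energies), kJ mol^-1.
#' @export
toy_energy <- function(sys, pos, include_wall = TRUE) {
  stopifnot(inherits(sys, "toy_system"))
  toy_energy_cpp(preset_code(sys$preset), unname(sys$params),
                 as_funnel_list(sys$funnel), to_coord_matrix(pos),
                 include_wall)
}

#' Force of a toy system at given positions
#'
#' @inheritParams toy_energy
#' @return An n x 3 matrix of forces, kJ mol^-1 nm^-1.
#' @export
toy_force <- function(sys, pos, include_wall = TRUE) {
  stopifnot(inherits(sys, "toy_system"))
  toy_force_cpp(preset_code(sys$preset), unname(sys$params),
                as_funnel_list(sys$funnel), to_coord_matrix(pos),
                include_wall)
}

#' Well-tempered metadynamics parameters
#'
#' @param height0 Initial Gaussian height w0, kJ mol^-1 (> 0). Default 1.0.
#' @param sigma Per-CV Gaussian widths (nm for a distance CV, dimensionless
#'   for a contact CV); all > 0.
#' @param pace Steps between depositions (>= 1).
#' @param bias_factor Bias factor gamma (> 1); each hill's height decays as
#'   `exp(-V_bias / ((gamma - 1) kB T))`. Default 16.
#' @param temperature Temperature entering the tempering rule, K.
#' @return An object of class `metad_params`.
#' @export
metad_params <- function(height0 = 1.0, sigma, pace, bias_factor = 16,
                         temperature = 300) {
  if (!is.finite(height0) || height0 <= 0) abort("`height0` must be > 0")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) abort("`sigma` must be > 0")
  if (length(sigma) > 2) abort("at most two collective variables supported")
  if (pace < 1) abort("`pace` must be >= 1")
  if (!is.finite(bias_factor) || bias_factor <= 1)
    abort("`bias_factor` must be > 1")
  structure(list(height0 = height0, sigma = as.numeric(sigma),
                 pace = as.integer(pace), bias_factor = bias_factor,
                 temperature = temperature),
            class = "metad_params")
}

#' Well-tempered Gaussian height
#'
#' Height of the next hill given the bias already accumulated at the current
#' CV point: `height0 * exp(-V / ((gamma - 1) kB T))`. Equal to `height0` at
#' zero bias and strictly decreasing in the accumulated bias.
#'
#' @param current_bias Accumulated bias at the deposition point, kJ mol^-1.
#' @param p A [metad_params()].
#' @return Height, kJ mol^-1 (vectorised over `current_bias`).
#' @export
wt_height <- function(current_bias, p) {
  stopifnot(inherits(p, "metad_params"))
  p$height0 * exp(-current_bias / ((p$bias_factor - 1) * .kB * p$temperature))
}

cv_registry <- function() {
  c(x = 0L, y = 1L, z = 2L, axial = 3L, radial = 4L, dist = 5L,
    compactness = 6L)
}

resolve_cvs <- function(cvs, cv_params) {
  reg <- cv_registry()
  codes <- reg[cvs]
  if (any(is.na(codes)))
    abort(paste0("unknown collective variable(s): ",
                 paste(cvs[is.na(codes)], collapse = ", "),
                 " (known: ", paste(names(reg), collapse = ", "), ")"))
  pm <- matrix(0, length(cvs), 2)
  for (k in seq_along(cvs)) {
    if (cvs[k] == "compactness") {
      pp <- cv_params[[cvs[k]]] %||% c(10, 0.5)
      pm[k, ] <- pp[1:2]
    }
  }
  list(codes = unname(codes), params = pm)
}

default_cv_grid <- function(cv) {
  switch(cv,
    compactness = c(-0.05, 1.05, 441),
    c(-4, 4, 1601))
}

#' Langevin dynamics with well-tempered metadynamics in a funnel
#'
#' Integrates BAOAB Langevin dynamics on a [toy_system()] under the preset
#' potential, the optional funnel wall, and the accumulating metadynamics
#' bias; a Gaussian hill is deposited every `pace` steps with the
#' well-tempered height evaluated at the current CV point. The bias and its
#' gradient are kept on a grid cache refreshed at each deposition
#' (interpolation error is far below the hill height for the default grids).
#' Identical seeds give bit-identical output.
#'
#' @param sys A [toy_system()].
#' @param p A [metad_params()], or `NULL` for unbiased dynamics.
#' @param cvs Character vector (length 1 or 2) naming registered CV maps:
#'   one of `"x"`, `"y"`, `"z"`, `"axial"`, `"radial"`, `"dist"`,
#'   `"compactness"` (a smooth logistic of the distance from the funnel
#'   origin, so the two-CV protocol can be exercised without a protein).
#' @param n_steps Number of integration steps.
#' @param x0 Initial position, nm.
#' @param stride Recording stride (steps between saved frames).
#' @param seed Optional integer seed (calls `set.seed()`).
#' @param grid Optional named list of CV grids, each `c(min, max, n)`;
#'   defaults cover `[-4, 4]` nm (distance-like CVs) or `[-0.05, 1.05]`
#'   (compactness).
#' @param cv_params Optional named list of CV parameters (only
#'   `"compactness"` takes `c(beta, r_half)`).
#' @return An object of class `metad_run`: list with `trajectory` (tibble:
#'   time, x, y, z), `colvar` (tibble: time + one column per CV), `hills`
#'   (a `hills_log` tibble, empty when `p` is NULL), `wall_violation_fraction`,
#'   `system`, and `params`.
#' @export
langevin_metad_run <- function(sys, p = NULL, cvs = "x", n_steps, x0 = c(0, 0, 0),
                               stride = 10, seed = NULL, grid = NULL,
                               cv_params = list()) {
  stopifnot(inherits(sys, "toy_system"))
  if (!is.null(seed)) set.seed(seed)
  rc <- resolve_cvs(cvs, cv_params)
  ncv <- length(cvs)
  metad <- !is.null(p)
  if (metad) {
    stopifnot(inherits(p, "metad_params"))
    if (length(p$sigma) != ncv)
      abort("length of `p$sigma` must match the number of CVs")
  }
  gmat <- sapply(cvs, function(cv) {
    g <- grid[[cv]] %||% default_cv_grid(cv)
    if (length(g) != 3) abort("each grid must be c(min, max, n)")
    g
  })
  res <- run_langevin_cpp(
    preset_code(sys$preset), unname(sys$params), as_funnel_list(sys$funnel),
    as.numeric(x0), sys$mass, sys$friction, sys$temperature, sys$timestep,
    as.integer(n_steps), as.integer(stride),
    if (metad) p$pace else -1L,
    if (metad) p$height0 else 0,
    if (metad) p$bias_factor else 2,
    if (metad) p$sigma else rep(0.1, ncv),
    rc$codes, rc$params,
    as.numeric(gmat[1, ]), as.numeric(gmat[2, ]), as.integer(gmat[3, ]),
    -1, 1L, 0, c(0, 0, 1), -1)
  finish_run(res, sys, p, cvs)
}

finish_run <- function(res, sys, p, cvs) {
  ncv <- length(cvs)
  traj <- as_tibble(as.data.frame(res$trajectory))
  names(traj) <- c("time", "x", "y", "z")
  colv <- as_tibble(as.data.frame(res$colvar))
  names(colv) <- c("time", cvs)
  hl <- res$hills
  hills <- if (nrow(hl) > 0) {
    df <- as.data.frame(hl)
    names(df) <- hills_columns(ncv)
    hills_log(df, temperature = if (!is.null(p)) p$temperature else
      sys$temperature)
  } else {
    empty_hills_log(ncv, temperature = sys$temperature)
  }
  structure(
    list(trajectory = traj, colvar = colv, hills = hills,
         egressed = res$egressed,
         final_position = res$final_position,
         final_direction = res$final_direction,
         steps_done = res$steps_done,
         wall_violation_fraction = res$wall_violation_frames /
           max(res$frames_recorded, 1),
         system = sys, params = p, cvs = cvs),
    class = "metad_run")
}

#' @export
print.metad_run <- function(x, ...) {
  cat(sprintf("<metad_run> preset '%s', %d steps, %d frames, %d hills\n",
              x$system$preset, x$steps_done, nrow(x$trajectory),
              nrow(x$hills)))
  invisible(x)
}

#' Metadynamics bias potential from an explicit hill list
#'
#' Exact Gaussian summation `V(s) = sum_h height_h *
#' exp(-sum_d (s_d - c_d)^2 / (2 sigma_d^2))`; non-negative and additive in
#' hills. This is the reference evaluation that the simulator's grid cache
#' approximates.
#'
#' @param hills A `hills_log` tibble (see [hills_log()]); may be empty.
#' @param s A CV-space point (vector) or matrix of points (rows), with the
#'   same dimensionality as the hills.
#' @return Bias value(s), kJ mol^-1.
#' @export
bias_potential <- function(hills, s) {
  ncv <- hills_ncv(hills)
  if (is.matrix(s)) {
    if (ncol(s) != ncv) abort("point dimensionality does not match hills")
    pts <- s
  } else {
    if (length(s) != ncv) abort("point dimensionality does not match hills")
    pts <- matrix(s, nrow = 1)
  }
  out <- numeric(nrow(pts))
  if (nrow(hills) == 0) return(if (is.matrix(s)) out else out[1])
  centers <- as.matrix(hills[, paste0("cv", seq_len(ncv)), drop = FALSE])
  sigmas <- as.matrix(hills[, paste0("sigma_cv", seq_len(ncv)), drop = FALSE])
  h <- hills$height
  for (k in seq_len(nrow(pts))) {
    expo <- 0
    for (d in seq_len(ncv)) {
      expo <- expo + (pts[k, d] - centers[, d])^2 / (2 * sigmas[, d]^2)
    }
    out[k] <- sum(h * exp(-expo))
  }
  if (is.matrix(s)) out else out[1]
}

#' Random-accelerated egress state
#'
#' Parameters of the randomly re-oriented constant pull on the ligand centre
#' of mass: the force acts along `direction`; every `checkpoint_interval` the
#' displacement of the COM since the last checkpoint is compared with
#' `threshold`, and the direction is kept only if the displacement strictly
#' exceeds it — otherwise it is resampled uniformly on the unit sphere
#' (normalised Gaussian triple).
#'
#' @param force_magnitude Pull force, kcal mol^-1 A^-1 (> 0). Default 16.
#' @param direction Initial unit 3-vector; default `c(0, 0, 1)`.
#' @param checkpoint_interval Checkpoint period, fs (> 0). Default 100.
#' @param threshold Displacement threshold, Angstrom (> 0). Default 0.025.
#' @param last_com COM position at the last checkpoint (same length unit as
#'   the positions handed to [ramd_update()]).
#' @return An object of class `ramd_state`.
#' @export
ramd_state <- function(force_magnitude = 16, direction = c(0, 0, 1),
                       checkpoint_interval = 100, threshold = 0.025,
                       last_com = c(0, 0, 0)) {
  if (!is.finite(force_magnitude) || force_magnitude <= 0)
    abort("`force_magnitude` must be > 0")
  if (!is.finite(checkpoint_interval) || checkpoint_interval <= 0)
    abort("`checkpoint_interval` must be > 0")
  if (!is.finite(threshold) || threshold <= 0) abort("`threshold` must be > 0")
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) abort("`direction` must be non-zero")
  structure(list(force_magnitude = force_magnitude,
                 direction = direction / nrm,
                 checkpoint_interval = checkpoint_interval,
                 threshold = threshold, last_com = as.numeric(last_com)),
            class = "ramd_state")
}

#' Apply the RAMD checkpoint rule
#'
#' If the COM displacement since the last checkpoint strictly exceeds the
#' threshold the force direction is kept; otherwise (including exact
#' equality) it is resampled uniformly on the unit sphere from R's RNG. The
#' stored COM is updated either way.
#'
#' @param state A [ramd_state()].
#' @param new_com Current COM position (same units as `state$threshold`).
#' @return The updated `ramd_state`.
#' @export
ramd_update <- function(state, new_com) {
  stopifnot(inherits(state, "ramd_state"))
  disp <- sqrt(sum((new_com - state$last_com)^2))
  if (!(disp > state$threshold)) {
    d <- rnorm(3)
    state$direction <- d / sqrt(sum(d^2))
  }
  state$last_com <- as.numeric(new_com)
  state
}

#' Langevin egress run under a randomly re-oriented constant force
#'
#' Runs Langevin dynamics on a toy system with the constant RAMD force
#' applied along the state's direction, the checkpoint rule of
#' [ramd_update()] applied every checkpoint interval, and termination when
#' the particle leaves a spherical shell of radius `exit_radius` around the
#' funnel origin (or after `max_steps`). The RAMD parameters are given in
#' their customary units (kcal mol^-1 A^-1, fs, Angstrom) and converted to
#' the internal nm/kJ/ps system.
#'
#' @param sys A [toy_system()].
#' @param state A [ramd_state()].
#' @param exit_radius Egress shell radius, nm (> 0).
#' @param max_steps Maximum number of steps.
#' @param x0 Initial position, nm.
#' @param stride Recording stride.
#' @param seed Optional integer seed.
#' @return A `metad_run` object whose `egressed` flag records whether the
#'   particle left the shell, with `final_position` the exit position.
#' @export
ramd_egress_run <- function(sys, state, exit_radius, max_steps,
                            x0 = c(0, 0, 0), stride = 10, seed = NULL) {
  stopifnot(inherits(sys, "toy_system"), inherits(state, "ramd_state"))
  if (!is.null(seed)) set.seed(seed)
  f_nm <- state$force_magnitude * .kJ_per_kcal * 10      # kcal/mol/A -> kJ/mol/nm
  check_steps <- max(1L, as.integer(round(
    state$checkpoint_interval * 1e-3 / sys$timestep)))   # fs -> ps -> steps
  thr_nm <- state$threshold * 0.1                        # A -> nm
  res <- run_langevin_cpp(
    preset_code(sys$preset), unname(sys$params), as_funnel_list(sys$funnel),
    as.numeric(x0), sys$mass, sys$friction, sys$temperature, sys$timestep,
    as.integer(max_steps), as.integer(stride),
    -1L, 0, 2, 0.1, 5L, matrix(0, 1, 2),
    -4, 4, 101L,
    f_nm, check_steps, thr_nm, state$direction, exit_radius)
  finish_run(res, sys, NULL, "dist")
}
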