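#' Funnel-corrected standard-state binding free energy
#'
#' Converts an axial potential of mean force W(z), obtained inside a funnel
#' restraint, into an absolute binding constant and a standard-state binding
#' free energy. Because the unbound ligand is confined to a cylinder of
#' known cross-section `pi * r_cyl^2`, the binding constant is
#'
#'   Kb = pi * r_cyl^2 * integral_bound exp(-beta (W(z) - W_unbound)) dz
#'
#' with `W_unbound` the mean of W over the unbound plateau. The
#' standard-state free energy is `Delta G = -kB T log(Kb * C0 * NA)` (with
#' the concentration factor expressed in nm^-3: 1 M = 0.6022140857 nm^-3),
#' reported in kcal mol^-1, and the dissociation constant follows the
#' declared convention `kd = C0 * exp(Delta G / (R T))`.
#'
#' @param fes_axial A 1-D [free_energy_surface()] over the axial coordinate
#'   z (nm).
#' @param geom The [funnel_geometry()] under which W was obtained.
#' @param bound_region Length-2 z-interval (nm) integrated as the bound
#'   state.
#' @param unbound_region Length-2 z-interval (nm) used as the unbound
#'   reference; must lie in the cylinder section (`z >= z_cc`).
#' @param temperature Temperature, K; defaults to the surface's.
#' @param c0 Standard concentration, M. Default 1.
#' @param plateau_tol Tolerance on the flatness of W over the unbound
#'   region, kJ mol^-1; a larger spread raises a convergence warning that is
#'   also carried on the result. Default 1.
#' @param fes_blocks Optional list of 1-D surfaces (e.g. block
#'   reconstructions over the final stretch of a run); when supplied, the
#'   spread of the per-block Delta G estimates gives the reported
#'   uncertainty (standard error over blocks, see [block_errors()]).
#' @return An object of class `binding_estimate` with elements `delta_g`
#'   (kcal mol^-1), `kd` (nM), `kb_nm3`, `uncertainty` (kcal mol^-1, NA
#'   without blocks), `kd_uncertainty` (nM), `temperature`,
#'   `standard_concentration` and `convergence_warning`.
#' @export
binding_delta_g <- function(fes_axial, geom, bound_region, unbound_region,
                            temperature = NULL, c0 = 1, plateau_tol = 1,
                            fes_blocks = NULL) {
  stopifnot(inherits(fes_axial, "fes"), inherits(geom, "funnel_geometry"))
  if (fes_ndim(fes_axial) != 1)
    abort("`fes_axial` must be one-dimensional (project a 2-D surface first)")
  temperature <- temperature %||% fes_axial$temperature
  kT <- .kB * temperature
  z <- fes_axial$axes[[1]]
  w <- fes_axial$values
  if (min(unbound_region) < geom$z_cc)
    abort("the unbound region must lie in the cylinder section (z >= z_cc)")
  in_unb <- z >= min(unbound_region) & z <= max(unbound_region)
  in_bnd <- z >= min(bound_region) & z <= max(bound_region)
  if (sum(in_unb) < 2) abort("unbound region contains fewer than 2 grid points")
  if (sum(in_bnd) < 2) abort("bound region contains fewer than 2 grid points")
  spread <- diff(range(w[in_unb]))
  conv_warn <- spread > plateau_tol
  if (conv_warn)
    warn(sprintf(
      "unbound plateau varies by %.2f kJ/mol (> %.2f): the profile may not be converged",
      spread, plateau_tol))
  w_unb <- mean(w[in_unb])
  one_dg <- function(zv, wv) {
    integrand <- exp(-(wv - w_unb) / kT)
    kb <- pi * geom$r_cyl^2 * trapz(zv, integrand)
    dg_kj <- -kT * log(kb * c0 * 0.6022140857)
    list(kb = kb, dg_kj = dg_kj)
  }
  est <- one_dg(z[in_bnd], w[in_bnd])
  dg_kcal <- est$dg_kj / .kJ_per_kcal
  kd_nM <- c0 * exp(est$dg_kj / kT) * 1e9
  unc <- NA_real_; kd_unc <- NA_real_
  if (!is.null(fes_blocks) && length(fes_blocks) >= 2) {
    dgs <- vapply(fes_blocks, function(fb) {
      zb <- fb$axes[[1]]; wb <- fb$values
      iu <- zb >= min(unbound_region) & zb <= max(unbound_region)
      ib <- zb >= min(bound_region) & zb <= max(bound_region)
      wub <- mean(wb[iu])
      intg <- exp(-(wb[ib] - wub) / kT)
      kb <- pi * geom$r_cyl^2 * trapz(zb[ib], intg)
      -kT * log(kb * c0 * 0.6022140857) / .kJ_per_kcal
    }, numeric(1))
    unc <- sd(dgs) / sqrt(length(dgs))
    # first-order propagation through kd = C0 exp(dG / RT)
    kd_unc <- kd_nM * unc * .kJ_per_kcal / kT
  }
  structure(
    list(delta_g = dg_kcal, kd = kd_nM, kb_nm3 = est$kb,
         uncertainty = unc, kd_uncertainty = kd_unc,
         temperature = temperature, standard_concentration = c0,
         convergence_warning = conv_warn, w_unbound = w_unb),
    class = "binding_estimate")
}

#' @export
print.binding_estimate <- function(x, ...) {
  cat("<binding_estimate>\n")
  cat(sprintf("  Delta G = %.3f%s kcal/mol (standard state %g M, T = %g K)\n",
              x$delta_g,
              if (is.na(x$uncertainty)) "" else sprintf(" +/- %.3f", x$uncertainty),
              x$standard_concentration, x$temperature))
  cat(sprintf("  Kd = %.4g%s nM   [kd = C0 * exp(dG/RT)]\n", x$kd,
              if (is.na(x$kd_uncertainty)) "" else
                sprintf(" +/- %.2g", x$kd_uncertainty)))
  if (isTRUE(x$convergence_warning))
    cat("  warning: unbound plateau not flat within tolerance\n")
  invisible(x)
}

#' Block standard error of a series
#'
#' Standard error of the mean computed over contiguous blocks: the series is
#' split into `n_blocks` equal contiguous blocks and the standard deviation
#' of the block means is divided by `sqrt(n_blocks)`. For correlated series
#' this exceeds the naive iid standard error.
#'
#' @param x Numeric vector.
#' @param n_blocks Number of contiguous blocks (>= 2, <= length(x)).
#' @return The block standard error (0 for a constant series).
#' @export
block_errors <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n_blocks < 2 || n_blocks > n)
    abort("`n_blocks` must be between 2 and length(x)")
  idx <- floor(seq_len(n) * n_blocks / (n + 1)) + 1
  means <- vapply(split(x, idx), mean, numeric(1))
  if (length(means) < 2) abort("degenerate blocks")
  sd(means) / sqrt(length(means))
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
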