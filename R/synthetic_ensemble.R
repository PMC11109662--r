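# ---------------------------------------------------------------------------
# Internal-coordinate backbone builder (NeRF placement with ideal geometry)
# ---------------------------------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place atom D given A-B-C with bond |C-D|, angle B-C-D and dihedral A-B-C-D
# (degrees); coordinates in Angstrom
place_atom <- function(a, b, c, bond, angle, dihedral) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
         -bond * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# ideal peptide geometry (Angstrom / degrees)
.bb <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
            a_n_ca_c = 111.2, a_ca_c_n = 116.6, a_c_n_ca = 121.7,
            omega = 180)

#' Build an N-CA-C backbone from per-residue dihedrals
#'
#' Places a poly-alanine style backbone (N, CA, C per residue) with ideal
#' bond lengths and angles and the supplied `(phi, psi)` per residue, in
#' Angstrom. `phi[1]` and `psi[n]` are undefined for a chain and ignored.
#'
#' @param phi,psi Numeric vectors (degrees), one per residue.
#' @return A `3 n x 3` coordinate matrix (rows N1, CA1, C1, N2, ...),
#'   Angstrom.
#' @export
build_backbone <- function(phi, psi) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res, n_res >= 2)
  xyz <- matrix(NA_real_, 3 * n_res, 3)
  g <- .bb
  xyz[1, ] <- c(0, 0, 0)                          # N1
  xyz[2, ] <- c(g$b_n_ca, 0, 0)                   # CA1
  ang <- g$a_n_ca_c * pi / 180
  xyz[3, ] <- xyz[2, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)  # C1
  for (i in 2:n_res) {
    iN <- 3 * (i - 1) + 1; iCA <- iN + 1; iC <- iN + 2
    pN <- 3 * (i - 2) + 1; pCA <- pN + 1; pC <- pN + 2
    xyz[iN, ] <- place_atom(xyz[pN, ], xyz[pCA, ], xyz[pC, ],
                            g$b_c_n, g$a_ca_c_n, psi[i - 1])
    xyz[iCA, ] <- place_atom(xyz[pCA, ], xyz[pC, ], xyz[iN, ],
                             g$b_n_ca, g$a_c_n_ca, g$omega)
    xyz[iC, ] <- place_atom(xyz[pC, ], xyz[iN, ], xyz[iCA, ],
                            g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  xyz
}

backbone_atom_table <- function(n_res, chain = "A") {
  tibble(
    serial = seq_len(3 * n_res),
    name = rep(c("N", "CA", "C"), n_res),
    resname = "ALA",
    resno = rep(seq_len(n_res), each = 3),
    chain = chain,
    element = rep(c("N", "C", "C"), n_res))
}

#' Synthetic ensemble with planted structure
#'
#' Generates a backbone ensemble around an ideal-helix template with any
#' combination of planted features, each with machine-readable ground truth
#' attached (the `truth` attribute, see [ensemble_truth()]), so estimator
#' tests never rely on hand-copied numbers:
#' \describe{
#'   \item{helicity}{per-residue per-frame helix/coil emission: helical
#'     residues get `(phi, psi) = (-57, -47)` and coil `(-120, +120)`
#'     degrees, both with 5-degree Gaussian jitter; `helix_prob` gives the
#'     per-residue Bernoulli probability (scalar or named per residue;
#'     default 1, a rigid helix template). Realised per-residue fractions
#'     are recorded as truth.}
#'   \item{dcc}{paired residue blocks with planted displacement
#'     correlation: residues of `block_a` receive iid Gaussian rigid
#'     translations (sd `sigma` nm), the paired residue of `block_b`
#'     receives `rho * u + sqrt(1 - rho^2) * eps`, giving an expected
#'     cross-correlation of exactly `rho`; all other residues move
#'     independently.}
#'   \item{contact}{a residue pair planted in contact in a Bernoulli
#'     fraction of frames: the second residue is rigidly placed near the
#'     first (well inside `cutoff`) in contact frames and far beyond
#'     it otherwise; realised occupancy recorded.}
#'   \item{fluctuations}{iid per-atom isotropic Gaussian noise of sd
#'     `fluct_sigma` Angstrom per coordinate, giving an expected per-atom
#'     RMSF of `fluct_sigma * sqrt(3)`.}
#' }
#'
#' Features are applied in the order listed; the contact placement
#' overrides the block translation of its second residue.
#'
#' @param n_frames Number of frames.
#' @param n_residues Number of residues. Default 20.
#' @param seed Optional integer seed.
#' @param helix_prob Scalar or per-residue vector (named by residue number)
#'   of helix probabilities.
#' @param dcc Optional list with `block_a`, `block_b` (equal-length residue
#'   number vectors), `rho` (in [-1, 1]) and optionally `sigma` (nm,
#'   default 0.05).
#' @param contact Optional list with `pair` (two residue numbers), `prob`,
#'   and optionally `cutoff` (nm, default 0.45).
#' @param fluct_sigma Per-atom per-coordinate noise sd, Angstrom. Default 0.
#' @param basin_label Optional label stored on the ensemble.
#' @return A [labeled_ensemble()] with a `truth` attribute.
#' @export
make_ensemble <- function(n_frames, n_residues = 20, seed = NULL,
                          helix_prob = NULL, dcc = NULL, contact = NULL,
                          fluct_sigma = 0, basin_label = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  atoms <- backbone_atom_table(n_residues)
  n_atoms <- nrow(atoms)
  truth <- list()

  hp <- rep(1, n_residues)
  if (!is.null(helix_prob)) {
    if (length(helix_prob) == 1 && is.null(names(helix_prob))) {
      hp <- rep(helix_prob, n_residues)
    } else {
      hp[as.integer(names(helix_prob))] <- unname(helix_prob)
    }
    if (any(hp < 0 | hp > 1)) abort("helix probabilities must lie in [0, 1]")
  }
  per_frame_backbone <- !is.null(helix_prob) && any(hp < 1)

  template <- build_backbone(rep(-57, n_residues), rep(-47, n_residues))
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  helix_draws <- matrix(TRUE, n_frames, n_residues)
  for (f in seq_len(n_frames)) {
    if (per_frame_backbone) {
      is_helix <- runif(n_residues) < hp
      helix_draws[f, ] <- is_helix
      phi <- ifelse(is_helix, -57, -120) + rnorm(n_residues, 0, 5)
      psi <- ifelse(is_helix, -47, 120) + rnorm(n_residues, 0, 5)
      coords[, , f] <- build_backbone(phi, psi) / 10
    } else {
      coords[, , f] <- template / 10
    }
  }
  truth$helicity <- tibble(resno = seq_len(n_residues),
                           planted_prob = hp,
                           realized = colMeans(helix_draws))

  if (!is.null(dcc)) {
    rho <- dcc$rho
    sig <- dcc$sigma %||% 0.05
    if (abs(rho) > 1) abort("planted correlation must lie in [-1, 1]")
    ba <- dcc$block_a; bb2 <- dcc$block_b
    if (length(ba) != length(bb2))
      abort("dcc blocks must pair residues one-to-one")
    others <- setdiff(seq_len(n_residues), c(ba, bb2))
    for (f in seq_len(n_frames)) {
      u <- matrix(rnorm(3 * n_residues, 0, sig), n_residues, 3)
      u[bb2, ] <- rho * u[ba, , drop = FALSE] +
        sqrt(1 - rho^2) * matrix(rnorm(3 * length(bb2), 0, sig),
                                 length(bb2), 3)
      for (r in seq_len(n_residues)) {
        idx <- which(atoms$resno == r)
        coords[idx, , f] <- sweep(coords[idx, , f, drop = TRUE], 2, u[r, ], "+")
      }
    }
    truth$dcc <- list(block_a = ba, block_b = bb2, rho = rho, sigma = sig)
  }

  if (!is.null(contact)) {
    pr <- contact$pair
    prob <- contact$prob
    cutoff <- contact$cutoff %||% 0.45
    ia <- which(atoms$resno == pr[1]); ib <- which(atoms$resno == pr[2])
    ca_a <- which(atoms$resno == pr[1] & atoms$name == "CA")
    ca_b <- which(atoms$resno == pr[2] & atoms$name == "CA")
    in_contact <- runif(n_frames) < prob
    for (f in seq_len(n_frames)) {
      u <- coords[ca_b, , f] - coords[ca_a, , f]
      u <- u / sqrt(sum(u^2))
      target <- if (in_contact[f]) 0.5 * cutoff else cutoff + 0.8
      new_ca <- coords[ca_a, , f] + u * target
      shift <- new_ca - coords[ca_b, , f]
      coords[ib, , f] <- sweep(coords[ib, , f, drop = TRUE], 2, shift, "+")
    }
    truth$contact <- list(pair = pr, planted_prob = prob,
                          realized = mean(in_contact), cutoff = cutoff)
  }

  if (fluct_sigma > 0) {
    coords <- coords + array(rnorm(length(coords), 0, fluct_sigma / 10),
                             dim(coords))
    truth$rmsf <- list(sigma_A = fluct_sigma,
                       expected_rmsf_A = fluct_sigma * sqrt(3))
  }

  atoms$x <- template[, 1] / 10
  atoms$y <- template[, 2] / 10
  atoms$z <- template[, 3] / 10
  ens <- labeled_ensemble(structure_model(atoms, source = "synthetic"),
                          coords, basin_label = basin_label)
  attr(ens, "truth") <- truth
  ens
}

#' Ground truth attached to a synthetic ensemble
#'
#' @param ens An ensemble produced by [make_ensemble()].
#' @return The generator's ground-truth record (a named list).
#' @export
ensemble_truth <- function(ens) {
  attr(ens, "truth")
}
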