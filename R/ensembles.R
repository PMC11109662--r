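#' Conformational ensemble with a shared atom table
#'
#' Frames of a trajectory (or basin-assigned sub-ensemble) sharing one atom
#' table, with optional per-frame weights and a basin label.
#'
#' @param atoms A [structure_model()] (or atom table acceptable to it).
#' @param coords A numeric array of dimension `n_atoms x 3 x n_frames`, nm.
#' @param weights Optional per-frame weights (non-negative; normalised to
#'   sum to one). Default uniform.
#' @param basin_label Optional text label.
#' @return An object of class `labeled_ensemble`.
#' @export
labeled_ensemble <- function(atoms, coords, weights = NULL,
                             basin_label = NULL) {
  if (!inherits(atoms, "structure_model")) atoms <- structure_model(atoms)
  coords <- as.array(coords)
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    abort("`coords` must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(atoms))
    abort("frame atom count does not match the atom table")
  nf <- dim(coords)[3]
  if (is.null(weights)) {
    weights <- rep(1 / nf, nf)
  } else {
    if (length(weights) != nf) abort("one weight per frame required")
    if (any(weights < 0)) abort("weights must be non-negative")
    weights <- weights / sum(weights)
  }
  structure(list(atoms = atoms, coords = coords, weights = weights,
                 basin_label = basin_label),
            class = "labeled_ensemble")
}

#' @export
print.labeled_ensemble <- function(x, ...) {
  cat(sprintf("<labeled_ensemble> %d frames x %d atoms%s\n",
              n_frames(x), nrow(x$atoms),
              if (is.null(x$basin_label)) "" else
                paste0(" [", x$basin_label, "]")))
  invisible(x)
}

#' Number of frames of an ensemble
#' @param ens A [labeled_ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' Assign frames to basins by their CV coordinates
#'
#' Each frame is labelled with the basin whose extent (as produced by
#' [find_basins()]) contains its CV point; frames outside every extent are
#' `"unassigned"`. Should extents overlap, the deeper basin wins (recorded
#' in the `tie_broken` column).
#'
#' @param cv_series A data frame with columns matching the basin axes
#'   (e.g. `cv1`, `cv2`).
#' @param basins A `basin_set` from [find_basins()] (must carry extents).
#' @return The input tibble with `basin` and `tie_broken` columns appended.
#' @export
assign_frames <- function(cv_series, basins) {
  cv_series <- as_tibble(cv_series)
  if (nrow(basins) == 0) {
    cv_series$basin <- rep("unassigned", nrow(cv_series))
    cv_series$tie_broken <- FALSE
    return(cv_series)
  }
  axis_names <- names(basins$extent[[1]])
  missing <- setdiff(axis_names, names(cv_series))
  if (length(missing) > 0)
    abort(paste0("cv series lacks column(s): ", paste(missing, collapse = ", ")))
  labels <- character(nrow(cv_series))
  ties <- logical(nrow(cv_series))
  # basins are sorted by decreasing depth, so first match is the deepest
  inside <- sapply(seq_len(nrow(basins)), function(b) {
    ext <- basins$extent[[b]]
    ok <- rep(TRUE, nrow(cv_series))
    for (ax in axis_names) {
      v <- cv_series[[ax]]
      ok <- ok & v >= ext[[ax]][1] & v <= ext[[ax]][2]
    }
    ok
  })
  inside <- matrix(inside, nrow = nrow(cv_series))
  for (k in seq_len(nrow(cv_series))) {
    hits <- which(inside[k, ])
    if (length(hits) == 0) {
      labels[k] <- "unassigned"
    } else {
      labels[k] <- basins$label[hits[1]]
      ties[k] <- length(hits) > 1
    }
  }
  cv_series$basin <- labels
  cv_series$tie_broken <- ties
  cv_series
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `frame` onto `reference` using the fit
#' selection, by singular value decomposition of the covariance of the
#' centred fit coordinates (with the determinant correction that excludes
#' reflections). The RMSD is computed on `report_selection` (default: the
#' fit selection) after the transform. Rank-deficient (e.g. collinear) fit
#' sets are accepted — the optimal rotation is then not unique but the
#' optimum is still attained.
#'
#' @param frame,reference n x 3 coordinate matrices (same atom count), nm.
#' @param fit_selection Atom indices used for the fit (default: all).
#' @param report_selection Atom indices for the reported RMSD (default:
#'   `fit_selection`).
#' @return A list with `coords` (the transformed frame) and `rmsd` (same
#'   length unit as the input).
#' @export
superpose <- function(frame, reference, fit_selection = NULL,
                      report_selection = NULL) {
  frame <- frame_coords(frame); reference <- frame_coords(reference)
  if (nrow(frame) != nrow(reference))
    abort("frame and reference must have the same atom count")
  fit_selection <- fit_selection %||% seq_len(nrow(frame))
  report_selection <- report_selection %||% fit_selection
  if (length(fit_selection) < 1) abort("empty fit selection")
  a <- frame[fit_selection, , drop = FALSE]
  b <- reference[fit_selection, , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- t(a0) %*% b0
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(sweep(frame, 2, ca) %*% t(rot), 2, cb, "+")
  dev <- moved[report_selection, , drop = FALSE] -
    reference[report_selection, , drop = FALSE]
  list(coords = moved, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Superpose every frame of an ensemble onto its mean structure
#'
#' Iterated mean fit: frames are superposed onto the running mean structure
#' and the mean is recomputed, for `passes` rounds (two passes suffice for
#' the analytics here).
#'
#' @param ens A [labeled_ensemble()].
#' @param fit_selection Atom indices used for the fit (default: all).
#' @param passes Number of mean-fit iterations. Default 2.
#' @return The ensemble with superposed coordinates.
#' @export
superpose_ensemble <- function(ens, fit_selection = NULL, passes = 2) {
  stopifnot(inherits(ens, "labeled_ensemble"))
  nf <- n_frames(ens)
  ref <- ens$coords[, , 1]
  coords <- ens$coords
  for (p in seq_len(passes)) {
    for (f in seq_len(nf)) {
      coords[, , f] <- superpose(coords[, , f], ref, fit_selection)$coords
    }
    ref <- apply(coords, c(1, 2), mean)
  }
  ens$coords <- coords
  ens
}

#' Dynamic cross-correlation map over C-alpha atoms
#'
#' Normalised covariance of residue displacement vectors:
#' `DCC_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with `dr` the
#' deviation of each residue's C-alpha position from its ensemble mean,
#' after superposing every frame onto the ensemble mean structure (iterated
#' mean fit, two passes). Values lie in [-1, 1], the diagonal is 1 and
#' negative values flag anti-correlated motion. Residues with zero variance
#' get `NA` (undefined, never coerced to 0).
#'
#' @param ens A [labeled_ensemble()] with at least 10 frames.
#' @param selection Optional residue numbers (default: every residue with a
#'   CA atom).
#' @param superpose Superpose frames first? Default TRUE (set FALSE if the
#'   ensemble is already fitted).
#' @param threshold_display Display threshold stored for plotting. Default
#'   0.4.
#' @return A matrix of class `dcc_matrix` with residue numbers as
#'   dimnames and the display threshold as an attribute.
#' @export
dcc_map <- function(ens, selection = NULL, superpose = TRUE,
                    threshold_display = 0.4) {
  stopifnot(inherits(ens, "labeled_ensemble"))
  if (n_frames(ens) < 10) abort("at least 10 frames required for a DCC map")
  ca <- which(trimws(ens$atoms$name) == "CA")
  if (!is.null(selection)) ca <- ca[ens$atoms$resno[ca] %in% selection]
  if (length(ca) < 2) abort("fewer than 2 C-alpha atoms selected")
  if (superpose) ens <- superpose_ensemble(ens, fit_selection = ca)
  nf <- n_frames(ens)
  w <- ens$weights
  n <- length(ca)
  # deviations: n x 3 x nf
  sub <- ens$coords[ca, , , drop = FALSE]
  mean_pos <- apply(sub, c(1, 2), function(v) sum(v * w))
  dev <- sweep(sub, c(1, 2), mean_pos)
  # covariance of dot products: sum over xyz of weighted frame covariance
  cov <- matrix(0, n, n)
  for (d in 1:3) {
    m <- matrix(dev[, d, ], n, nf)
    cov <- cov + (m * rep(w, each = n)) %*% t(m)
  }
  v <- diag(cov)
  # guard against pure floating-point residue of the mean subtraction:
  # variances far below any physical fluctuation are zero (undefined DCC)
  v[v < 1e-12 * (1 + rowSums(mean_pos^2))] <- 0
  denom <- sqrt(outer(v, v))
  dcc <- cov / denom
  dcc[!is.finite(dcc)] <- NA_real_
  diag(dcc)[v > 0] <- 1
  resnos <- ens$atoms$resno[ca]
  dimnames(dcc) <- list(resnos, resnos)
  attr(dcc, "threshold_display") <- threshold_display
  attr(dcc, "selection") <- resnos
  class(dcc) <- c("dcc_matrix", class(dcc))
  dcc
}

#' Contact occupancy of residue pairs
#'
#' Fraction of frames (weights respected) in which any heavy-atom pair
#' across the two residues is within `cutoff`.
#'
#' @param ens A [labeled_ensemble()].
#' @param residue_pairs A length-2 vector of residue numbers, or a
#'   two-column matrix/data frame of residue-number pairs.
#' @param cutoff Contact distance threshold, nm. Default 0.45.
#' @return A tibble with columns `resno_i`, `resno_j`, `occupancy`.
#' @export
contact_occupancy <- function(ens, residue_pairs, cutoff = 0.45) {
  stopifnot(inherits(ens, "labeled_ensemble"))
  if (is.null(dim(residue_pairs))) residue_pairs <- matrix(residue_pairs, ncol = 2)
  residue_pairs <- as.matrix(residue_pairs)
  heavy <- which(is_heavy(ens$atoms$element))
  nf <- n_frames(ens)
  out <- tibble(resno_i = residue_pairs[, 1], resno_j = residue_pairs[, 2],
                occupancy = NA_real_)
  for (k in seq_len(nrow(residue_pairs))) {
    ia <- heavy[ens$atoms$resno[heavy] == residue_pairs[k, 1]]
    ib <- heavy[ens$atoms$resno[heavy] == residue_pairs[k, 2]]
    if (length(ia) == 0)
      abort(sprintf("residue %s not found", residue_pairs[k, 1]))
    if (length(ib) == 0)
      abort(sprintf("residue %s not found", residue_pairs[k, 2]))
    hit <- vapply(seq_len(nf), function(f) {
      xa <- matrix(ens$coords[ia, , f], ncol = 3)
      xb <- matrix(ens$coords[ib, , f], ncol = 3)
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
      min(d2) <= cutoff^2
    }, logical(1))
    out$occupancy[k] <- sum(ens$weights[hit])
  }
  out
}

# dihedral angle (degrees) defined by four points, rows of a matrix
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Per-residue backbone helicity
#'
#' Fraction of frames in which a residue's backbone dihedrals fall in the
#' alpha-helical window `phi` in [-100, -30] degrees and `psi` in [-67, -7]
#' degrees. Chain termini (lacking a phi or psi) are reported as `NA`. The
#' dihedral-window criterion is self-contained and exactly specified — no
#' secondary-structure program is involved.
#'
#' @param ens A [labeled_ensemble()] whose atom table contains backbone
#'   N, CA, C atoms.
#' @param residues Residue numbers to analyse (default: all with a
#'   complete backbone).
#' @return A tibble with columns `resno` and `helicity` (weighted fraction
#'   in [0, 1], or NA for termini).
#' @export
helicity <- function(ens, residues = NULL) {
  stopifnot(inherits(ens, "labeled_ensemble"))
  at <- ens$atoms
  bb <- function(res, nm) which(at$resno == res & trimws(at$name) == nm)[1]
  all_res <- sort(unique(at$resno[trimws(at$name) == "CA"]))
  residues <- residues %||% all_res
  nf <- n_frames(ens)
  w <- ens$weights
  out <- tibble(resno = residues, helicity = NA_real_)
  for (k in seq_along(residues)) {
    res <- residues[k]
    iN <- bb(res, "N"); iCA <- bb(res, "CA"); iC <- bb(res, "C")
    iCprev <- bb(res - 1, "C"); iNnext <- bb(res + 1, "N")
    if (any(is.na(c(iN, iCA, iC, iCprev, iNnext)))) next  # terminus: NA
    helical <- vapply(seq_len(nf), function(f) {
      x <- ens$coords[, , f]
      phi <- dihedral_deg(x[iCprev, ], x[iN, ], x[iCA, ], x[iC, ])
      psi <- dihedral_deg(x[iN, ], x[iCA, ], x[iC, ], x[iNnext, ])
      phi >= -100 && phi <= -30 && psi >= -67 && psi <= -7
    }, logical(1))
    out$helicity[k] <- sum(w[helical])
  }
  out
}

#' Per-atom root-mean-square fluctuations
#'
#' RMSF about the weighted ensemble mean, per atom of `selection`; the
#' ensemble should be superposed first (see [superpose_ensemble()]).
#'
#' @param ens A [labeled_ensemble()].
#' @param selection Atom indices (default: all).
#' @return Numeric vector of RMSF values, nm.
#' @export
rmsf_profile <- function(ens, selection = NULL) {
  stopifnot(inherits(ens, "labeled_ensemble"))
  selection <- selection %||% seq_len(nrow(ens$atoms))
  w <- ens$weights
  sub <- ens$coords[selection, , , drop = FALSE]
  mean_pos <- apply(sub, c(1, 2), function(v) sum(v * w))
  dev <- sweep(sub, c(1, 2), mean_pos)
  sq <- apply(dev^2, c(1, 3), sum)       # atoms x frames, |dr|^2
  sqrt(drop(sq %*% w))
}

#' Fluctuation increment between mutant and wild-type ensembles
#'
#' Mean per-atom difference of summed RMSF over a shared atom selection:
#' `(sum RMSF_mut - sum RMSF_wt) / N`, reported in Angstrom. The sign is
#' preserved (negative when the mutant fluctuates less) and the measure is
#' antisymmetric in its two arguments. Each ensemble must be superposed to
#' its own mean beforehand (or pass `superpose = TRUE`).
#'
#' @param ens_mut,ens_wt [labeled_ensemble()] objects whose selections map
#'   to the same atom count.
#' @param selection Atom indices of the analysed region (e.g. main-chain
#'   heavy atoms of a functional surface); default: all atoms.
#' @param superpose Superpose each ensemble to its own mean first? Default
#'   TRUE.
#' @param fit_selection Atom indices for the superposition fit (default:
#'   all atoms outside `selection`, i.e. the stable remainder; falls back
#'   to all atoms if that leaves fewer than 3).
#' @return The fluctuation increment, Angstrom.
#' @export
delta_rmsf <- function(ens_mut, ens_wt, selection = NULL, superpose = TRUE,
                       fit_selection = NULL) {
  stopifnot(inherits(ens_mut, "labeled_ensemble"),
            inherits(ens_wt, "labeled_ensemble"))
  selection <- selection %||% seq_len(nrow(ens_wt$atoms))
  n_sel_mut <- length(selection)
  if (nrow(ens_mut$atoms) != nrow(ens_wt$atoms))
    abort("ensembles must share the atom table layout")
  if (superpose) {
    fit <- fit_selection %||% setdiff(seq_len(nrow(ens_wt$atoms)), selection)
    if (length(fit) < 3) fit <- seq_len(nrow(ens_wt$atoms))
    ens_mut <- superpose_ensemble(ens_mut, fit_selection = fit)
    ens_wt <- superpose_ensemble(ens_wt, fit_selection = fit)
  }
  rm_mut <- rmsf_profile(ens_mut, selection)
  rm_wt <- rmsf_profile(ens_wt, selection)
  (sum(rm_mut) - sum(rm_wt)) / n_sel_mut * 10  # nm -> Angstrom
}

#' C-alpha distance statistics over an ensemble
#'
#' Mean and population standard deviation of the C-alpha/C-alpha distance
#' for each pair among the given residues (e.g. the three coactivator
#' anchor residues of a nuclear receptor's activation surface), in
#' Angstrom.
#'
#' @param ens A [labeled_ensemble()].
#' @param residues Vector of residue numbers (>= 2; typically 3).
#' @return A tibble with columns `resno_i`, `resno_j`, `mean` and `sd`
#'   (Angstrom; `sd` is the population standard deviation).
#' @export
ca_distance_stats <- function(ens, residues) {
  stopifnot(inherits(ens, "labeled_ensemble"))
  at <- ens$atoms
  idx <- vapply(residues, function(res) {
    i <- which(at$resno == res & trimws(at$name) == "CA")[1]
    if (is.na(i)) abort(sprintf("no C-alpha atom for residue %s", res))
    i
  }, integer(1))
  pairs <- utils::combn(seq_along(residues), 2)
  w <- ens$weights
  out <- tibble(resno_i = residues[pairs[1, ]], resno_j = residues[pairs[2, ]],
                mean = NA_real_, sd = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- idx[pairs[1, k]]; b <- idx[pairs[2, k]]
    xa <- matrix(ens$coords[a, , ], nrow = 3)
    xb <- matrix(ens$coords[b, , ], nrow = 3)
    d <- sqrt(colSums((xa - xb)^2)) * 10
    mu <- sum(w * d)
    out$mean[k] <- mu
    out$sd[k] <- sqrt(sum(w * (d - mu)^2))
  }
  out
}
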