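#' Native-contact definition
#'
#' A frozen list of atom pairs together with the logistic switching
#' parameters that turn instantaneous pair distances into a smooth contact
#' count: each pair at distance r contributes
#' `1 / (1 + exp(beta * (r - lam * r0)))`, and the contact value of a frame
#' is the sum over all pairs (between 0 and `m`, the number of pairs). The
#' pair list is defined once on a reference structure and never recomputed
#' per frame (native-contact semantics).
#'
#' @param pairs A two-column matrix (or data frame) of atom indices
#'   referencing rows of a structure's atom table; no duplicate unordered
#'   pairs, `i != j`.
#' @param beta Logistic steepness, nm^-1 (> 0). Default 50.
#' @param lam Dimensionless midpoint scale (> 0). Default 1.8.
#' @param r0 Reference distance, nm (> 0). Default 0.45.
#' @return An object of class `contact_definition` with element `m` equal to
#'   the number of pairs.
#' @export
contact_definition <- function(pairs, beta = 50, lam = 1.8, r0 = 0.45) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0) pairs <- matrix(integer(0), ncol = 2)
  if (ncol(pairs) != 2) abort("`pairs` must have two columns")
  storage.mode(pairs) <- "integer"
  if (any(pairs[, 1] == pairs[, 2])) abort("pairs must join two distinct atoms")
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  if (anyDuplicated(key)) abort("duplicate unordered pairs in `pairs`")
  if (!is.finite(beta) || beta <= 0) abort("`beta` must be > 0")
  if (!is.finite(lam) || lam <= 0) abort("`lam` must be > 0")
  if (!is.finite(r0) || r0 <= 0) abort("`r0` must be > 0")
  structure(
    list(pairs = pairs, beta = beta, lam = lam, r0 = r0, m = nrow(pairs)),
    class = "contact_definition")
}

#' @export
print.contact_definition <- function(x, ...) {
  cat(sprintf(
    "<contact_definition> m = %d pairs, beta = %g nm^-1, lambda = %g, r0 = %g nm (midpoint %.3f nm)\n",
    x$m, x$beta, x$lam, x$r0, x$lam * x$r0))
  invisible(x)
}

#' Logistic switching function for a single pair distance
#'
#' `1 / (1 + exp(beta * (r - lam * r0)))`: strictly decreasing in r, equal to
#' 1/2 at the midpoint `r = lam * r0`, saturating to 1 at r = 0 and to 0 at
#' large r. Overflow in the exponential saturates cleanly (never NaN).
#'
#' @param r Distance(s), nm (>= 0); vectorised.
#' @inheritParams contact_definition
#' @return Value(s) in (0, 1).
#' @examples
#' switching_value(1.8 * 0.45) # exactly 1/2 at the midpoint
#' @export
switching_value <- function(r, beta = 50, lam = 1.8, r0 = 0.45) {
  1 / (1 + exp(beta * (r - lam * r0)))
}

#' Contact value of a conformation
#'
#' Sum of [switching_value()] over all pairs of a [contact_definition()],
#' evaluated at the instantaneous pair distances of `frame`. Bounded by
#' `[0, m]` and differentiable in the coordinates (see
#' [contact_gradient()]).
#'
#' @param frame An n x 3 coordinate matrix (nm) or a [structure_model()].
#' @param cdef A [contact_definition()].
#' @return A single contact value.
#' @export
contact_number <- function(frame, cdef) {
  stopifnot(inherits(cdef, "contact_definition"))
  xyz <- frame_coords(frame)
  if (cdef$m == 0) return(0)
  check_pair_indices(cdef$pairs, nrow(xyz))
  d <- pair_distances(xyz, cdef$pairs)
  sum(switching_value(d, cdef$beta, cdef$lam, cdef$r0))
}

#' Gradient of the contact value with respect to coordinates
#'
#' Analytic derivative of the logistic switching function, summed per atom;
#' needed for biased forces in the toy simulator and for property tests.
#'
#' @inheritParams contact_number
#' @return An n x 3 matrix, d(contact value)/d(coordinate), nm^-1.
#' @export
contact_gradient <- function(frame, cdef) {
  stopifnot(inherits(cdef, "contact_definition"))
  xyz <- frame_coords(frame)
  grad <- matrix(0, nrow(xyz), 3)
  if (cdef$m == 0) return(grad)
  check_pair_indices(cdef$pairs, nrow(xyz))
  i <- cdef$pairs[, 1]; j <- cdef$pairs[, 2]
  dvec <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  s <- switching_value(r, cdef$beta, cdef$lam, cdef$r0)
  # ds/dr = -beta * s * (1 - s); chain rule through r
  dsdr <- -cdef$beta * s * (1 - s)
  coef <- ifelse(r > 1e-12, dsdr / r, 0)
  contrib <- dvec * coef
  for (k in 1:3) {
    grad[, k] <- grad[, k] +
      tapply_add(contrib[, k], i, nrow(xyz)) -
      tapply_add(contrib[, k], j, nrow(xyz))
  }
  grad
}

pair_distances <- function(xyz, pairs) {
  d <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Identify native atom pairs from a reference structure
#'
#' For each listed residue pair, every heavy-atom pair (one atom from each
#' residue) whose reference distance does not exceed `cutoff` is recorded.
#' Heavy atoms only: the pair list is meant to be defined on a crystal
#' structure, which lacks hydrogens. Ordering is deterministic (ascending by
#' atom serials).
#'
#' @param ref A [structure_model()] (coordinates in nm).
#' @param residue_pairs Two-column matrix or data frame of residue numbers.
#' @param cutoff Distance cutoff, nm (> 0). Default 0.45 (i.e. 4.5 Angstrom).
#' @param beta,lam,r0 Switching parameters stored on the resulting
#'   [contact_definition()].
#' @return A [contact_definition()] whose `pairs` reference rows of `ref`;
#'   the reference distances and residue annotation are attached as the
#'   `pair_table` attribute (a tibble).
#' @export
identify_native_pairs <- function(ref, residue_pairs, cutoff = 0.45,
                                  beta = 50, lam = 1.8, r0 = 0.45) {
  stopifnot(inherits(ref, "structure_model"))
  if (!is.finite(cutoff) || cutoff <= 0) abort("`cutoff` must be > 0")
  residue_pairs <- as.matrix(residue_pairs)
  if (ncol(residue_pairs) != 2) abort("`residue_pairs` must have two columns")
  heavy <- which(is_heavy(ref$element))
  xyz <- coords(ref)
  rows <- list()
  for (k in seq_len(nrow(residue_pairs))) {
    ra <- residue_pairs[k, 1]; rb <- residue_pairs[k, 2]
    ia <- heavy[ref$resno[heavy] == ra]
    ib <- heavy[ref$resno[heavy] == rb]
    if (length(ia) == 0)
      abort(sprintf("residue %s not found in reference structure", ra))
    if (length(ib) == 0)
      abort(sprintf("residue %s not found in reference structure", rb))
    grid <- expand.grid(i = ia, j = ib)
    d <- sqrt(rowSums((xyz[grid$i, , drop = FALSE] -
                         xyz[grid$j, , drop = FALSE])^2))
    keep <- d <= cutoff
    if (any(keep)) {
      rows[[length(rows) + 1]] <- tibble(
        i = grid$i[keep], j = grid$j[keep], distance = d[keep],
        resno_i = ra, resno_j = rb)
    }
  }
  tab <- if (length(rows) > 0) bind_rows(rows) else
    tibble(i = integer(), j = integer(), distance = numeric(),
           resno_i = numeric(), resno_j = numeric())
  # orient each pair by ascending serial, then sort
  si <- ref$serial[tab$i]; sj <- ref$serial[tab$j]
  flip <- si > sj
  tmp <- tab$i[flip]; tab$i[flip] <- tab$j[flip]; tab$j[flip] <- tmp
  ord <- order(ref$serial[tab$i], ref$serial[tab$j])
  tab <- tab[ord, ]
  cdef <- contact_definition(cbind(tab$i, tab$j), beta = beta, lam = lam,
                             r0 = r0)
  attr(cdef, "pair_table") <- mutate(tab,
                                     serial_i = ref$serial[.data$i],
                                     serial_j = ref$serial[.data$j])
  cdef
}

#' Mass-weighted centre-of-mass distance between two atom groups
#'
#' @param frame An n x 3 coordinate matrix (nm) or a [structure_model()].
#' @param group_a,group_b Atom index vectors (non-empty, rows of `frame`).
#' @param masses Optional per-atom masses (length n, positive); defaults to
#'   unit masses (geometric centroids).
#' @return Euclidean distance between the two mass-weighted centroids, nm.
#' @export
com_distance <- function(frame, group_a, group_b, masses = NULL) {
  xyz <- frame_coords(frame)
  if (length(group_a) == 0 || length(group_b) == 0)
    abort("atom selections must be non-empty")
  if (is.null(masses)) masses <- rep(1, nrow(xyz))
  if (any(masses <= 0)) abort("masses must be positive")
  com <- function(idx) {
    w <- masses[idx]
    colSums(xyz[idx, , drop = FALSE] * w) / sum(w)
  }
  sqrt(sum((com(group_a) - com(group_b))^2))
}

#' Collective variables of every frame of an ensemble
#'
#' Computes the two reaction coordinates of the binding protocol for each
#' frame: CV1, the centre-of-mass distance between a ligand selection and a
#' protein selection, and CV2, the native-contact value under a frozen
#' [contact_definition()].
#'
#' @param ens A [labeled_ensemble()].
#' @param ligand,protein Atom index vectors for the two COM groups.
#' @param cdef A [contact_definition()] referencing the ensemble's atom table.
#' @param masses Optional per-atom masses.
#' @param dt Time between frames, ps (for the `time` column). Default 1.
#' @return A tibble with columns `time`, `cv1` (nm), `cv2` (dimensionless).
#' @export
cv_series <- function(ens, ligand, protein, cdef, masses = NULL, dt = 1) {
  stopifnot(inherits(ens, "labeled_ensemble"))
  nf <- n_frames(ens)
  cv1 <- numeric(nf); cv2 <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- ens$coords[, , f]
    cv1[f] <- com_distance(xyz, ligand, protein, masses)
    cv2[f] <- contact_number(xyz, cdef)
  }
  tibble(time = (seq_len(nf) - 1) * dt, cv1 = cv1, cv2 = cv2)
}

frame_coords <- function(frame) {
  if (inherits(frame, "structure_model")) return(coords(frame))
  if (is.matrix(frame)) {
    if (ncol(frame) != 3) abort("coordinate matrix must have 3 columns")
    return(frame)
  }
  abort("`frame` must be an n x 3 matrix or a structure_model")
}

check_pair_indices <- function(pairs, n_atoms) {
  bad <- pairs < 1 | pairs > n_atoms
  if (any(bad)) {
    k <- which(rowSums(bad) > 0)[1]
    abort(sprintf("pair (%d, %d) references an atom outside the frame (n = %d)",
                  pairs[k, 1], pairs[k, 2], n_atoms))
  }
  invisible(TRUE)
}
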