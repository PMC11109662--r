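# Fixed float formatting (6 decimal places) makes writer output byte-stable
# and round-trip tests bit-exact.
fmt_num <- function(x) sprintf("%.6f", x)

#' Write a hills log in the PLUMED HILLS dialect
#'
#' Header line `#! FIELDS time cv1 [cv2] sigma_cv1 [sigma_cv2] height biasf`
#' followed by whitespace-separated rows in fixed 6-decimal notation;
#' deterministic for identical input.
#'
#' @param hills A [hills_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  ncv <- hills_ncv(hills)
  cols <- hills_columns(ncv)
  lines <- c(paste("#! FIELDS", paste(cols, collapse = " ")))
  if (nrow(hills) > 0) {
    body <- apply(as.data.frame(hills)[, cols], 1,
                  function(r) paste(fmt_num(r), collapse = " "))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a hills log in the PLUMED HILLS dialect
#'
#' Expects the `#! FIELDS` comment header; rows must match the header
#' arity and carry strictly increasing times. Round-trips bit-exactly with
#' [write_hills()] on well-formed input.
#'
#' @param path Input path.
#' @param temperature Temperature attached to the log, K.
#' @return A [hills_log()].
#' @export
read_hills <- function(path, temperature = 300) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    abort("line 1: missing '#! FIELDS' header")
  fields <- strsplit(sub("^#! FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  ncv <- if ("cv2" %in% fields) 2L else 1L
  expected <- hills_columns(ncv)
  if (!identical(fields, expected))
    abort(paste0("line 1: unexpected FIELDS (want: ",
                 paste(expected, collapse = " "), ")"))
  body <- lines[-1]
  body <- body[!grepl("^\\s*(#|$)", body)]
  if (length(body) == 0) return(empty_hills_log(ncv, temperature))
  rows <- strsplit(trimws(body), "\\s+")
  arity <- lengths(rows)
  if (any(arity != length(fields))) {
    bad <- which(arity != length(fields))[1]
    abort(sprintf("line %d: expected %d fields, found %d",
                  bad + 1, length(fields), arity[bad]))
  }
  m <- matrix(as.numeric(unlist(rows)), ncol = length(fields), byrow = TRUE)
  if (any(!is.finite(m))) abort("non-numeric value in hills table")
  df <- as.data.frame(m)
  names(df) <- fields
  if (any(diff(df$time) <= 0)) {
    bad <- which(diff(df$time) <= 0)[1]
    abort(sprintf("line %d: hill times must be strictly increasing", bad + 2))
  }
  hills_log(df, temperature = temperature)
}

#' Write a CV time series in the PLUMED COLVAR dialect
#'
#' @param df A data frame whose first column is `time`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(df, path) {
  lines <- c(paste("#! FIELDS", paste(names(df), collapse = " ")))
  if (nrow(df) > 0) {
    body <- apply(df, 1, function(r) paste(fmt_num(as.numeric(r)), collapse = " "))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a CV time series in the PLUMED COLVAR dialect
#'
#' @param path Input path.
#' @return A tibble with the header's columns.
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    abort("line 1: missing '#! FIELDS' header")
  fields <- strsplit(sub("^#! FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  body <- body[!grepl("^\\s*(#|$)", body)]
  if (length(body) == 0)
    return(as_tibble(setNames(rep(list(numeric(0)), length(fields)), fields)))
  rows <- strsplit(trimws(body), "\\s+")
  arity <- lengths(rows)
  if (any(arity != length(fields))) {
    bad <- which(arity != length(fields))[1]
    abort(sprintf("line %d: expected %d fields, found %d",
                  bad + 1, length(fields), arity[bad]))
  }
  m <- matrix(as.numeric(unlist(rows)), ncol = length(fields), byrow = TRUE)
  df <- as.data.frame(m)
  names(df) <- fields
  as_tibble(df)
}

#' Write a free-energy surface as a delimited text grid
#'
#' A comment header records the axes, temperature, bias factor and zeroing
#' convention, followed by one row per grid point (axis coordinates then
#' the value).
#'
#' @param fes A [free_energy_surface()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fes <- function(fes, path) {
  hdr <- c(
    sprintf("# funnelmeta free-energy surface"),
    sprintf("# reference: %s", fes$reference),
    sprintf("# temperature: %s", fmt_num(fes$temperature)),
    sprintf("# bias_factor: %s", format(fes$bias_factor)),
    vapply(names(fes$axes), function(nm) {
      a <- fes$axes[[nm]]
      sprintf("# axis %s: %s %s %d", nm, fmt_num(min(a)), fmt_num(max(a)),
              length(a))
    }, character(1)),
    sprintf("#! FIELDS %s free_energy", paste(names(fes$axes), collapse = " ")))
  if (fes_ndim(fes) == 1) {
    body <- paste(fmt_num(fes$axes[[1]]), fmt_num(fes$values))
  } else {
    g <- expand.grid(i = seq_along(fes$axes[[1]]), j = seq_along(fes$axes[[2]]))
    body <- paste(fmt_num(fes$axes[[1]][g$i]), fmt_num(fes$axes[[2]][g$j]),
                  fmt_num(fes$values[cbind(g$i, g$j)]))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a free-energy surface written by [write_fes()]
#'
#' @param path Input path.
#' @return A [free_energy_surface()].
#' @export
read_fes <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  get1 <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (length(ln) == 0) abort(paste0("missing header: ", key))
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  temperature <- as.numeric(get1("temperature"))
  bias_factor <- suppressWarnings(as.numeric(get1("bias_factor")))
  reference <- get1("reference")
  axis_lines <- hdr[grepl("^# axis ", hdr)]
  axes <- list()
  for (ln in axis_lines) {
    parts <- strsplit(sub("^# axis ", "", ln), ":\\s*")[[1]]
    nm <- trimws(parts[1])
    spec <- as.numeric(strsplit(trimws(parts[2]), "\\s+")[[1]])
    axes[[nm]] <- seq(spec[1], spec[2], length.out = spec[3])
  }
  vals <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  m <- do.call(rbind, vals)
  nd <- length(axes)
  values <- if (nd == 1) m[, 2] else {
    v <- matrix(NA_real_, length(axes[[1]]), length(axes[[2]]))
    i <- match(round(m[, 1], 6), round(axes[[1]], 6))
    j <- match(round(m[, 2], 6), round(axes[[2]], 6))
    v[cbind(i, j)] <- m[, 3]
    v
  }
  free_energy_surface(axes, values,
                      reference = if (reference == "minimum") "minimum" else "plateau",
                      temperature = temperature, bias_factor = bias_factor)
}

#' Read a structure from a PDB file
#'
#' Parses via bio3d, keeps the highest-occupancy alternate location per
#' atom, converts Angstrom to nm, and infers missing element symbols from
#' atom names.
#'
#' @param path Path to a PDB file.
#' @return A [structure_model()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  # altloc: keep the highest-occupancy record per (chain, resno, name)
  alt <- at$alt
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$elety)
  keep <- rep(TRUE, nrow(at))
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    idx <- which(key == k)
    best <- idx[which.max(occ[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, ]
  elem <- at$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- infer_element(at$elety[blank])
  structure_model(
    data.frame(serial = at$eleno, name = at$elety, resname = at$resid,
               resno = at$resno, chain = at$chain, element = elem,
               x = at$x / 10, y = at$y / 10, z = at$z / 10),
    source = basename(path))
}

#' Read a conformational ensemble from a trajectory file
#'
#' Multi-model PDB files are self-contained; DCD files need a `topology`
#' PDB for the atom table. Coordinates are converted to nm. XTC is not
#' supported (no installed reader); convert to DCD or multi-model PDB.
#'
#' @param path Trajectory path (`.pdb` or `.dcd`).
#' @param topology Path to a topology PDB (required for DCD).
#' @return A [labeled_ensemble()].
#' @export
read_trajectory <- function(path, topology = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xtc")
    abort("XTC input is not supported; supply a DCD or multi-model PDB")
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    model <- read_structure(path)
    xyz <- pdb$xyz
    nf <- nrow(xyz)
    n_atoms <- ncol(xyz) / 3
    if (n_atoms != nrow(model))
      abort("trajectory frame atom count does not match the topology")
    coords <- array(NA_real_, c(n_atoms, 3, nf))
    for (f in seq_len(nf)) {
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
    }
    return(labeled_ensemble(model, coords))
  }
  if (ext == "dcd") {
    if (is.null(topology)) abort("DCD input requires a `topology` PDB")
    model <- read_structure(topology)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    nf <- nrow(xyz)
    n_atoms <- ncol(xyz) / 3
    if (n_atoms != nrow(model))
      abort("trajectory frame atom count does not match the topology")
    coords <- array(NA_real_, c(n_atoms, 3, nf))
    for (f in seq_len(nf)) {
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
    }
    return(labeled_ensemble(model, coords))
  }
  abort(paste0("unsupported trajectory format: .", ext))
}

#' Write an ensemble as a multi-model PDB
#'
#' @param ens A [labeled_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "labeled_ensemble"))
  at <- ens$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens$coords[, , f] * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$serial, at$name, at$resname, at$chain, at$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration (YAML): defaults reproduce the published protocol
# parameters exactly.
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' Structured configuration whose defaults are the published protocol
#' values: contact parameters beta = 50 nm^-1, lambda = 1.8, r0 = 0.45 nm
#' (pair cutoff 0.45 nm); metadynamics height 1.0 kJ mol^-1, widths 0.1
#' (CV1, nm) and 10 (CV2), pace 2 ps, bias factor 16; funnel z_cc = 0.5 nm,
#' r_cyl = 0.1 nm, alpha = 1.1 rad; RAMD force 16 kcal mol^-1 A^-1,
#' checkpoint 100 fs, threshold 0.025 A. All quantities carry their units
#' in the key names where ambiguous.
#'
#' @return A nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    system = list(preset = "double_well_1d", mass_amu = 1,
                  friction_per_ps = 1, temperature_K = 300,
                  timestep_ps = 0.002),
    funnel = list(origin_nm = c(0, 0, 0), axis = c(0, 0, 1),
                  z_cc_nm = 0.5, r_cyl_nm = 0.1, alpha_rad = 1.1,
                  k_wall_kj_nm2 = 10000),
    contacts = list(beta_per_nm = 50, lambda = 1.8, r0_nm = 0.45,
                    cutoff_nm = 0.45),
    metad = list(height_kj = 1.0, sigma = c(0.1, 10), pace_ps = 2,
                 bias_factor = 16),
    ramd = list(force_kcal_A = 16, checkpoint_fs = 100, threshold_A = 0.025),
    output = list(prefix = "funnelmeta")),
    class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config` (see [default_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Unknown keys (top-level or nested) are rejected; missing keys fall back
#' to the defaults of [default_config()].
#'
#' @param path YAML path.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- unclass(default_config())
  check_keys <- function(x, template, prefix = "") {
    bad <- setdiff(names(x), names(template))
    if (length(bad) > 0)
      abort(paste0("unknown config key(s): ",
                   paste0(prefix, bad, collapse = ", ")))
    for (nm in names(x)) {
      if (is.list(template[[nm]]) && !is.null(names(template[[nm]])))
        check_keys(x[[nm]], template[[nm]], paste0(prefix, nm, "."))
    }
  }
  check_keys(raw, ref)
  merged <- utils::modifyList(ref, raw)
  structure(merged, class = "run_config")
}
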