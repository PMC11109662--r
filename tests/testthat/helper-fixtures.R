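# Shared fixture builders (all generated in code; no stored data files)

kB <- 0.0083144621
kT300 <- kB * 300

# random rigid transform applied to an n x 3 coordinate matrix
random_rigid <- function(xyz, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  r <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  t_vec <- rnorm(3)
  list(coords = sweep(xyz %*% t(r), 2, t_vec, "+"), rotation = r,
       translation = t_vec)
}

# a small synthetic structure: n_res residues of n_atom dummy heavy atoms
# placed on a jittered lattice
lattice_structure <- function(n_res = 6, atoms_per_res = 5, spacing = 0.3,
                              seed = 1) {
  set.seed(seed)
  n <- n_res * atoms_per_res
  df <- data.frame(
    serial = seq_len(n),
    name = paste0("C", rep(seq_len(atoms_per_res), n_res)),
    resname = "LIG",
    resno = rep(seq_len(n_res), each = atoms_per_res),
    chain = "A",
    element = "C",
    x = rep(seq_len(n_res) * spacing, each = atoms_per_res) + runif(n, 0, 0.12),
    y = runif(n, 0, 0.12),
    z = runif(n, 0, 0.12))
  structure_model(df, source = "synthetic lattice")
}

# brute-force O(n^2) native-pair count over heavy atoms of listed residues
brute_force_pairs <- function(ref, residue_pairs, cutoff) {
  xyz <- coords(ref)
  heavy <- which(toupper(ref$element) != "H")
  count <- 0
  for (k in seq_len(nrow(residue_pairs))) {
    ia <- heavy[ref$resno[heavy] == residue_pairs[k, 1]]
    ib <- heavy[ref$resno[heavy] == residue_pairs[k, 2]]
    for (i in ia) for (j in ib) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) count <- count + 1
    }
  }
  count
}

# quick double-well metadynamics run used by several tests
dw_metad_run <- function(n_steps = 1e6, seed = 11) {
  tw <- make_toy("double_well_1d", timestep = 0.005)
  p <- metad_params(height0 = 1.2, sigma = 0.1, pace = 250, bias_factor = 16)
  run <- langevin_metad_run(tw$system, p, "x", n_steps = n_steps,
                            x0 = c(-1, 0, 0), seed = seed, stride = 200,
                            grid = list(x = c(-2.5, 2.5, 2001)))
  list(toy = tw, run = run)
}
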