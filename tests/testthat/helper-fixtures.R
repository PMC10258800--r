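# Shared fixtures built in code.

# bare trajectory from a list of per-frame coordinate matrices (n x 3)
make_traj <- function(frames, box = 6, dt = 10, atoms = NULL) {
  na <- nrow(frames[[1]])
  coords <- array(NA_real_, dim = c(na, 3L, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  if (is.null(atoms))
    atoms <- data.frame(name = paste0("X", seq_len(na)), resname = "HFP",
                        resid = seq_len(na), role = "other",
                        mol_id = seq_len(na), stringsAsFactors = FALSE)
  trajectory(coords, box_edge = box, dt = dt, atoms = atoms)
}

# H at the box centre plus one fluorine following the given offsets
# (n_frames x 3 matrix, relative to the hydrogen)
make_hf_traj <- function(offsets, box = 8, dt = 10) {
  nf <- nrow(offsets)
  coords <- array(box / 2, dim = c(2L, 3L, nf))
  for (f in seq_len(nf)) coords[2L, , f] <- box / 2 + offsets[f, ]
  atoms <- data.frame(name = c("HE1", "F1"), resname = c("TRP", "HFP"),
                      resid = c(6L, 1L), role = c("peptide-H", "fluorine"),
                      mol_id = c(0L, 1L), stringsAsFactors = FALSE)
  trajectory(coords, box_edge = box, dt = dt, atoms = atoms)
}

# small free-diffusion solvent system
small_free <- function(n_hfip = 30, n_water = 0, box = 6, b = 0.3,
                       d_hfip = 21.8e-10, d_water = 17e-10, n_frames = 400,
                       dt = 10, seed = 1, ...) {
  generate_free_trajectory(simulation_spec(
    box_edge = box, n_hfip = n_hfip, n_water = n_water, d_hfip = d_hfip,
    d_water = d_water, closest_approach_b = b, snapshot_dt = dt,
    n_frames = n_frames, seed = seed, ...))
}

# hand-made expfit object for unit conversions and sign checks
manual_fit <- function(amplitude, tau, reference = "6TrpHE1") {
  out <- list(terms = data.frame(amplitude = amplitude, tau = tau),
              order = length(tau), residual_rms = 0, converged = TRUE,
              order_selection_trace = NULL, negative_amplitudes =
                any(amplitude < 0), non_decaying = FALSE,
              G0_observed = sum(amplitude), G0_fitted = sum(amplitude))
  attr(out, "units") <- list(G = "nm^-6", t = "ps")
  attr(out, "reference") <- reference
  class(out) <- "expfit"
  out
}
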