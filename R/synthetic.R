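#' Specification of a synthetic Brownian solvent system
#'
#' Defines a periodic cubic box of force-free Brownian solvent particles
#' (HFIP molecules carrying six rigid fluorine sites, and water oxygens)
#' around a fixed model solute: a reflecting sphere of radius
#' `closest_approach_b` centred in the box, holding the reference peptide
#' hydrogen at its centre.  Defaults emulate the composition and sampling
#' cadence of the microsecond simulations this pipeline is designed to
#' analyse: a 6.7 nm box with 482 HFIP and 7434 waters, snapshots every
#' 10 ps, and translational diffusion coefficients of 4.8e-10 (HFIP) and
#' 17e-10 (water) m^2 s^-1.
#'
#' @param box_edge cubic box edge, nm.
#' @param n_hfip number of HFIP molecules (6 fluorine sites each).
#' @param n_water number of water particles (oxygen sites).
#' @param d_hfip,d_water translational diffusion coefficients, m^2 s^-1.
#' @param closest_approach_b reflecting solute-sphere radius, nm.
#' @param snapshot_dt snapshot interval, ps.
#' @param n_frames number of stored snapshots (>= 2).
#' @param substeps_per_snapshot Brownian substeps per snapshot interval.
#' @param seed integer RNG seed; identical spec + seed gives a
#'   bit-identical trajectory.
#' @param sticky optional list `list(k_off =, capture_shell =,
#'   bound_d_scale =)`: unbinding rate (ns^-1), capture radius (nm) and
#'   bound-state diffusion scale in (0, 1].
#' @param d_profile optional list `list(breaks =, scales =)` imposing a
#'   piecewise-constant diffusion scale below each break distance (nm).
#' @param site_offset_max largest fluorine-site offset from the molecule
#'   centre, nm (must not exceed 0.2).
#' @param reflect_scheme how the solute sphere repels solvent:
#'   `"reject"` (default) rejects substeps that would penetrate the sphere,
#'   a Metropolis move whose equilibrium density is exactly uniform outside
#'   the sphere; `"mirror"` reflects the radial coordinate specularly off
#'   the surface, which transports slightly more faithfully near the wall
#'   but biases the near-wall density by O(step/b).
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(box_edge = 6.7, n_hfip = 482, n_water = 7434,
                            d_hfip = 4.8e-10, d_water = 17e-10,
                            closest_approach_b = 0.3, snapshot_dt = 10,
                            n_frames = 1000, substeps_per_snapshot = 10,
                            seed = 1, sticky = NULL, d_profile = NULL,
                            site_offset_max = 0.05,
                            reflect_scheme = c("reject", "mirror")) {
  spec <- list(box_edge = box_edge, n_hfip = n_hfip, n_water = n_water,
               d_hfip = d_hfip, d_water = d_water,
               closest_approach_b = closest_approach_b,
               snapshot_dt = snapshot_dt, n_frames = n_frames,
               substeps_per_snapshot = substeps_per_snapshot,
               seed = as.integer(seed), sticky = sticky,
               d_profile = d_profile, site_offset_max = site_offset_max,
               reflect_scheme = match.arg(reflect_scheme))
  class(spec) <- "simulation_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (box_edge <= 2 * closest_approach_b)
      stop("box_edge must exceed twice the closest-approach radius")
    if (d_hfip < 0 || d_water < 0)
      stop("diffusion coefficients must be non-negative")
    if (snapshot_dt <= 0) stop("snapshot_dt must be positive")
    if (n_frames < 2) stop("n_frames must be at least 2")
    if (substeps_per_snapshot < 1) stop("need at least one substep")
    if (site_offset_max < 0 || site_offset_max > 0.2)
      stop("site_offset_max must lie in [0, 0.2] nm")
    if (!is.null(sticky)) {
      need <- c("k_off", "capture_shell", "bound_d_scale")
      if (!all(need %in% names(sticky)))
        stop("sticky mode needs fields: ", paste(need, collapse = ", "))
      if (sticky$bound_d_scale <= 0 || sticky$bound_d_scale > 1)
        stop("sticky$bound_d_scale must lie in (0, 1]")
      if (sticky$capture_shell <= closest_approach_b)
        stop("sticky$capture_shell must exceed the solute radius")
    }
    if (!is.null(d_profile)) {
      if (is.unsorted(d_profile$breaks, strictly = TRUE))
        stop("d_profile$breaks must be strictly increasing")
      if (length(d_profile$breaks) != length(d_profile$scales))
        stop("d_profile breaks/scales length mismatch")
    }
  })
  # substep accuracy: the rms 3D substep displacement must stay below b/2
  # for first-order accuracy of the specular reflection
  dmax <- .d_si_to_nmps(max(spec$d_hfip, spec$d_water))
  dts <- spec$snapshot_dt / spec$substeps_per_snapshot
  rms <- sqrt(6 * dmax * dts)
  if (spec$closest_approach_b > 0 && rms > spec$closest_approach_b / 2) {
    need <- ceiling(spec$substeps_per_snapshot * (rms /
                      (spec$closest_approach_b / 2))^2)
    stop(sprintf(paste0(
      "substep rms displacement %.3g nm exceeds b/2 = %.3g nm; ",
      "increase substeps_per_snapshot to at least %d"),
      rms, spec$closest_approach_b / 2, need))
  }
  invisible(spec)
}

.ground_truth <- function(spec) {
  list(spec = spec, d_hfip = spec$d_hfip, d_water = spec$d_water,
       b = spec$closest_approach_b,
       n_f_density = 6 * spec$n_hfip / spec$box_edge^3)
}

# shared machinery of the free and sticky generators
.generate <- function(spec, sticky) {
  validate_spec(spec)
  set.seed(spec$seed)
  box <- spec$box_edge
  dh <- .d_si_to_nmps(spec$d_hfip)
  dw <- .d_si_to_nmps(spec$d_water)
  pb <- if (is.null(spec$d_profile)) numeric(0) else spec$d_profile$breaks
  ps <- if (is.null(spec$d_profile)) numeric(0) else spec$d_profile$scales
  st <- spec$sticky
  # fixed random internal geometry: 6 sites per molecule, isotropic
  # directions, offsets within site_offset_max of the centre
  offsets <- NULL
  if (spec$n_hfip > 0) {
    nsite <- 6L * spec$n_hfip
    u <- stats::rnorm(nsite * 3)
    dir <- matrix(u, ncol = 3L)
    dir <- dir / sqrt(rowSums(dir^2))
    rad <- stats::runif(nsite, 0, spec$site_offset_max)
    offsets <- dir * rad
  }
  events <- NULL
  hfip <- NULL
  if (spec$n_hfip > 0) {
    res <- .gen_species_cpp(
      spec$n_hfip, spec$n_frames, spec$substeps_per_snapshot,
      spec$snapshot_dt, dh, box, spec$closest_approach_b, pb, ps,
      sticky, if (sticky) st$k_off * 1e-3 else 0,
      if (sticky) st$capture_shell else 0,
      if (sticky) st$bound_d_scale else 1,
      if (sticky) st$capture_shell - spec$site_offset_max else 0,
      identical(spec$reflect_scheme, "mirror"))
    hfip <- res$coords
    if (sticky) {
      events <- res$events
      events$duration_ps <- events$end_ps - events$start_ps
      events$censored_end <- as.logical(events$censored_end)
    }
  }
  water <- NULL
  if (spec$n_water > 0) {
    res <- .gen_species_cpp(
      spec$n_water, spec$n_frames, spec$substeps_per_snapshot,
      spec$snapshot_dt, dw, box, spec$closest_approach_b, pb, ps,
      FALSE, 0, 0, 1, 0, identical(spec$reflect_scheme, "mirror"))
    water <- res$coords
  }
  na <- 1L + 7L * spec$n_hfip + spec$n_water
  coords <- array(NA_real_, dim = c(na, 3L, spec$n_frames))
  coords[1L, , ] <- box / 2  # reference hydrogen fixed at the box centre
  atoms <- data.frame(name = "HE1", resname = "TRP", resid = 6L,
                      role = "peptide-H", mol_id = 0L,
                      stringsAsFactors = FALSE)
  if (spec$n_hfip > 0) {
    idx_c <- 1L + seq_len(spec$n_hfip)
    coords[idx_c, , ] <- hfip
    sites <- .place_sites_cpp(hfip, offsets, 6L, box)
    idx_f <- 1L + spec$n_hfip + seq_len(6L * spec$n_hfip)
    coords[idx_f, , ] <- sites
    atoms <- rbind(atoms,
      data.frame(name = "C2", resname = "HFP", resid = seq_len(spec$n_hfip),
                 role = "other", mol_id = seq_len(spec$n_hfip),
                 stringsAsFactors = FALSE),
      data.frame(name = paste0("F", rep(1:6, spec$n_hfip)), resname = "HFP",
                 resid = rep(seq_len(spec$n_hfip), each = 6L),
                 role = "fluorine",
                 mol_id = rep(seq_len(spec$n_hfip), each = 6L),
                 stringsAsFactors = FALSE))
  }
  if (spec$n_water > 0) {
    idx_w <- 1L + 7L * spec$n_hfip + seq_len(spec$n_water)
    coords[idx_w, , ] <- water
    atoms <- rbind(atoms,
      data.frame(name = "OW", resname = "SOL",
                 resid = spec$n_hfip + seq_len(spec$n_water),
                 role = "water-O",
                 mol_id = spec$n_hfip + seq_len(spec$n_water),
                 stringsAsFactors = FALSE))
  }
  traj <- trajectory(coords, box_edge = box, dt = spec$snapshot_dt,
                     atoms = atoms)
  out <- list(trajectory = traj, ground_truth = .ground_truth(spec))
  if (sticky) out$events <- events
  out
}

#' Generate a free-diffusion synthetic trajectory
#'
#' Every molecule centre performs an isotropic Gaussian random walk
#' (variance `2 D dt` per dimension per substep) with periodic wrapping and
#' specular reflection off the central solute sphere; solvent-solvent
#' overlap is ignored (force-free model).  Fluorine sites ride rigidly on
#' their molecule centres.  The known input parameters are returned as
#' ground truth so downstream estimators can be validated against them.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `trajectory` and `ground_truth` (input
#'   diffusion coefficients, solute radius `b`, and the fluorine number
#'   density `n_f_density = 6 n_hfip / box_edge^3` in nm^-3).
#' @export
generate_free_trajectory <- function(spec) {
  .generate(spec, sticky = FALSE)
}

#' Generate a sticky-surface synthetic trajectory
#'
#' As [generate_free_trajectory()], but HFIP molecules whose centres enter
#' the capture shell become bound: their diffusion is scaled by
#' `bound_d_scale` and they are confined to the shell until they unbind,
#' which occurs as a Poisson process with rate `k_off` (ns^-1).  A log of
#' the true bound intervals accompanies the trajectory, serving as the
#' reference for contact-persistence detectors.  After unbinding a molecule
#' must leave the capture shell before it can rebind.
#'
#' @param spec a [simulation_spec()] with the `sticky` field set.
#' @return list with `trajectory`, `ground_truth` and `events` (data frame
#'   of `mol_id`, `start_ps`, `end_ps`, `duration_ps`, `censored_end`).
#' @export
generate_sticky_trajectory <- function(spec) {
  if (is.null(spec$sticky)) stop("spec$sticky is required for sticky mode")
  .generate(spec, sticky = TRUE)
}

#' Deterministic single-solvent distance fixture
#'
#' Builds a trajectory holding one solvent atom on a fixed axis at the
#' given distance from the reference hydrogen in each frame; useful for
#' exercising contact and shell logic against hand-computable answers.
#'
#' @param series distances in nm, one per frame (non-negative).
#' @param dt snapshot interval, ps.
#' @param species `"fluorine"` or `"water"`.
#' @return a [trajectory] of `length(series)` frames.
#' @export
make_distance_fixture <- function(series, dt = 10, species = "fluorine") {
  if (length(series) == 0) stop("'series' must be non-empty")
  if (any(series < 0)) stop("distances must be non-negative")
  species <- match.arg(species, c("fluorine", "water"))
  box <- max(4, 4 * max(series))
  nf <- length(series)
  coords <- array(0, dim = c(2L, 3L, nf))
  coords[1L, , ] <- box / 2
  coords[2L, 1L, ] <- box / 2 + series
  coords[2L, 2L, ] <- box / 2
  coords[2L, 3L, ] <- box / 2
  atoms <- data.frame(
    name = c("HE1", if (species == "fluorine") "F1" else "OW"),
    resname = c("TRP", if (species == "fluorine") "HFP" else "SOL"),
    resid = c(6L, 1L),
    role = c("peptide-H", if (species == "fluorine") "fluorine" else
      "water-O"),
    mol_id = c(0L, 1L), stringsAsFactors = FALSE)
  trajectory(coords, box_edge = box, dt = dt, atoms = atoms)
}
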