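# Translational diffusion estimators: Einstein MSD slope, fixed-interval
# displacement, and distance-resolved local diffusion near the reference
# hydrogen.

.species_centers <- function(traj, species) {
  species <- match.arg(species, c("hfip", "water"))
  if (species == "hfip") {
    idx <- which(traj$atoms$role == "other" & traj$atoms$resname == "HFP")
    if (!length(idx)) {  # fall back: mean of fluorine sites per molecule
      fl <- which(traj$atoms$role == "fluorine")
      if (!length(fl)) stop("no HFIP molecules in trajectory")
      stop("HFIP centre atoms not present; cannot form molecule centres")
    }
    idx
  } else {
    idx <- which(traj$atoms$role == "water-O")
    if (!length(idx)) stop("no water in trajectory")
    idx
  }
}

#' Bulk self-diffusion via the Einstein relation
#'
#' Fits the slope of the mean squared displacement of molecule centres
#' over a lag window, averaged over molecules and time origins;
#' `D = slope / 6`.  Requires unwrapped paths, which are derived from the
#' wrapped coordinates by minimum-image accumulation.
#'
#' @param traj a [trajectory].
#' @param species `"hfip"` or `"water"`.
#' @param fit_window `c(min, max)` lag window in ps.
#' @param origin_stride origin spacing, frames.
#' @return object of class `diffusion_estimate`: `d` (m^2 s^-1), `se`
#'   (standard error over molecules), `window_ps`, `method`, `n_molecules`.
#' @export
einstein_diffusion <- function(traj, species = "hfip", fit_window = NULL,
                               origin_stride = 1L) {
  idx <- .species_centers(traj, species)
  dt <- traj$dt
  nt <- n_frames(traj)
  if (is.null(fit_window)) fit_window <- c(dt, min(20 * dt, (nt - 1) * dt))
  lag_frames <- seq(ceiling(fit_window[1] / dt), floor(fit_window[2] / dt))
  if (length(lag_frames) > 25L)
    lag_frames <- unique(round(seq(min(lag_frames), max(lag_frames),
                                   length.out = 25L)))
  if (length(lag_frames) < 5L)
    stop("fit window too short: need at least 5 lag points")
  unw <- .unwrap_cpp(traj$coords[idx, , , drop = FALSE], traj$box_edge)
  msd <- .msd_cpp(unw, lag_frames, max(1L, origin_stride))
  tl <- lag_frames * dt
  d_mol <- apply(msd, 2L, function(m)
    stats::lm.fit(cbind(1, tl), m)$coefficients[2L] / 6)
  d_nmps <- mean(d_mol)
  se <- if (length(d_mol) > 1L) stats::sd(d_mol) / sqrt(length(d_mol))
    else NA_real_
  structure(list(d = .d_nmps_to_si(d_nmps), se = .d_nmps_to_si(se),
                 window_ps = range(tl), method = "einstein_msd",
                 n_molecules = length(idx)),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g m^2/s (se %.2g), %s, window %g-%g ps\n", x$d,
              x$se, x$method, x$window_ps[1], x$window_ps[2]))
  invisible(x)
}

#' Diffusion from fixed-interval displacements
#'
#' Estimates D from the mean squared displacement of a selection's
#' centroid over successive fixed intervals:
#' `D = <dr^2(interval)> / (6 interval)`.  This is the estimator used for
#' a slowly moving solute followed over many short intervals.
#'
#' @param traj a [trajectory].
#' @param selection atom identifiers forming the selection (centroid is
#'   tracked); defaults to the peptide-H.
#' @param interval displacement interval, ps (multiple of `dt`).
#' @param n_intervals number of successive intervals to use.
#' @return a `diffusion_estimate`.
#' @export
interval_displacement_diffusion <- function(traj, selection = NULL,
                                            interval = 10,
                                            n_intervals = 1000L) {
  idx <- if (is.null(selection)) .default_ref(traj) else
    vapply(selection, function(s) select_atom(traj, s), 0L)
  step <- round(interval / traj$dt)
  if (step < 1L) stop("interval shorter than the snapshot spacing")
  nt <- n_frames(traj)
  if (nt < n_intervals * step + 1L)
    stop(sprintf("need %d frames for %d intervals, have %d",
                 n_intervals * step + 1L, n_intervals, nt))
  unw <- .unwrap_cpp(traj$coords[idx, , , drop = FALSE], traj$box_edge)
  cen <- apply(unw, c(2L, 3L), mean)  # 3 x nT centroid path
  at <- seq(1L, 1L + n_intervals * step, by = step)
  disp2 <- colSums((cen[, at[-1L]] - cen[, at[-length(at)]])^2)
  d_nmps <- mean(disp2) / (6 * interval)
  se <- stats::sd(disp2) / sqrt(length(disp2)) / (6 * interval)
  structure(list(d = .d_nmps_to_si(d_nmps), se = .d_nmps_to_si(se),
                 window_ps = c(interval, interval),
                 method = "interval_displacement",
                 n_molecules = length(idx)),
            class = "diffusion_estimate")
}

#' Distance-resolved local diffusion profile
#'
#' Assigns solvent molecules to radial bins by their distance to the
#' reference hydrogen at each time origin and estimates a local diffusion
#' coefficient per bin from the mean squared displacement over one lag:
#' `D_local = <dr^2(lag)>_bin / (6 lag)`.  Bin membership is decided at
#' the origin only; molecules are followed wherever they move during the
#' lag.  Bins with too few samples are masked (NA), not zero-filled.
#' The bin touching the solute surface reads low by construction: the
#' reflecting boundary clips displacements within one lag's diffusion
#' length of the wall.
#'
#' @param traj a [trajectory].
#' @param ref reference hydrogen.
#' @param bin_width radial bin width, nm.
#' @param lag displacement lag, ps (>= dt; default 20 ps).
#' @param r_max outermost profile radius, nm.
#' @param min_count smallest per-bin sample count before masking.
#' @param origin_stride origin spacing, frames.
#' @return data frame of class `diffusion_profile`: `bin_lo`, `bin_mid`,
#'   `bin_hi` (nm), `d_hfip`, `d_water` (m^2 s^-1, NA when masked),
#'   `n_hfip`, `n_water` sample counts.
#' @export
local_diffusion_profile <- function(traj, ref = NULL, bin_width = 0.25,
                                    lag = 20, r_max = 3.0, min_count = 50L,
                                    origin_stride = 1L) {
  ref <- if (is.null(ref)) .default_ref(traj) else select_atom(traj, ref)
  dt <- traj$dt
  lag_frames <- round(lag / dt)
  if (lag_frames < 1L) stop("lag must be at least one snapshot interval")
  nt <- n_frames(traj)
  if (lag_frames >= nt) stop("lag exceeds the trajectory")
  breaks <- seq(0, r_max, by = bin_width)
  if (max(breaks) < r_max) breaks <- c(breaks, max(breaks) + bin_width)
  nb <- length(breaks) - 1L
  species <- list(hfip = tryCatch(.species_centers(traj, "hfip"),
                                  error = function(e) integer(0)),
                  water = tryCatch(.species_centers(traj, "water"),
                                   error = function(e) integer(0)))
  if (!length(species$hfip) && !length(species$water))
    stop("no solvent molecules: empty profile")
  origins <- seq(1L, nt - lag_frames, by = max(1L, origin_stride))
  res <- list()
  for (sp in names(species)) {
    idx <- species[[sp]]
    if (!length(idx)) {
      res[[sp]] <- list(d = rep(NA_real_, nb), n = rep(0L, nb))
      next
    }
    dmat <- .dist_to_ref_cpp(traj$coords, ref - 1L, idx - 1L,
                             traj$box_edge)
    unw <- .unwrap_cpp(traj$coords[idx, , , drop = FALSE], traj$box_edge)
    ssum <- numeric(nb); scnt <- integer(nb)
    for (o in origins) {
      bin <- findInterval(dmat[o, ], breaks, rightmost.closed = FALSE)
      ok <- bin >= 1L & bin <= nb
      if (!any(ok)) next
      dd <- matrix(unw[, , o + lag_frames] - unw[, , o],
                   nrow = length(idx))
      disp2 <- rowSums(dd^2)
      tb <- tapply(disp2[ok], bin[ok], sum)
      tc <- table(bin[ok])
      bi <- as.integer(names(tb))
      ssum[bi] <- ssum[bi] + as.numeric(tb)
      scnt[bi] <- scnt[bi] + as.integer(tc)
    }
    d <- ifelse(scnt >= min_count, ssum / pmax(scnt, 1L) / (6 * lag),
                NA_real_)
    res[[sp]] <- list(d = .d_nmps_to_si(d), n = scnt)
  }
  out <- data.frame(bin_lo = breaks[-length(breaks)],
                    bin_mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                    bin_hi = breaks[-1L],
                    d_hfip = res$hfip$d, d_water = res$water$d,
                    n_hfip = res$hfip$n, n_water = res$water$n)
  attr(out, "lag_ps") <- lag_frames * dt
  attr(out, "reference") <- traj$atoms$id[ref]
  class(out) <- c("diffusion_profile", "data.frame")
  out
}
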