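#' Solvation-shell definition
#'
#' Contiguous concentric shells of equal width around a reference
#' hydrogen, indexed from 1; the default width of 0.556 nm is the
#' estimated diameter of a rapidly rotating HFIP molecule, so shell 1 is
#' the solvent layer from 0 to 0.556 nm, shell 2 from 0.556 to 1.112 nm,
#' and so on.
#'
#' @param width shell width, nm.
#' @param n_shells number of shells.
#' @return object of class `shell_definition` with `bounds`
#'   (length `n_shells + 1`, starting at 0).
#' @export
shell_definition <- function(width = 0.556, n_shells = 5L) {
  if (width <= 0) stop("shell width must be positive")
  if (n_shells < 1) stop("need at least one shell")
  structure(list(width = width, n_shells = as.integer(n_shells),
                 bounds = seq(0, by = width, length.out = n_shells + 1L)),
            class = "shell_definition")
}

#' Solvent composition arithmetic
#'
#' Bulk solvent-mixture descriptors implied by a box composition: the
#' water-to-fluorine ratio (each HFIP carries six fluorines) and the HFIP
#' mole fraction.
#'
#' @param n_hfip,n_water molecule counts.
#' @return list with `water_fluorine_ratio`, `hfip_mole_fraction`,
#'   `n_fluorines`.
#' @examples
#' solvent_composition(482, 7434)  # ratio 2.57, mole fraction 0.061
#' @export
solvent_composition <- function(n_hfip = 482, n_water = 7434) {
  list(water_fluorine_ratio = n_water / (6 * n_hfip),
       hfip_mole_fraction = n_hfip / (n_hfip + n_water),
       n_fluorines = 6 * n_hfip)
}

#' Per-frame shell occupancies around a reference hydrogen
#'
#' Bins every fluorine atom and water oxygen into solvation shells by
#' minimum-image distance to the reference hydrogen, per frame.
#'
#' @param traj a [trajectory].
#' @param ref reference hydrogen (see [select_atom()]).
#' @param shells a [shell_definition()].
#' @return object of class `shell_occupancy`: list with matrices
#'   `fluorine` and `water` (`n_frames x n_shells` counts), the shell
#'   definition, the reference id and `dt`.
#' @export
shell_occupancy <- function(traj, ref = NULL, shells = shell_definition()) {
  ref <- if (is.null(ref)) .default_ref(traj) else select_atom(traj, ref)
  if (max(shells$bounds) > traj$box_edge / 2)
    stop("outermost shell exceeds half the box edge: minimum-image ",
         "distances would be ambiguous")
  count1 <- function(role) {
    idx <- which(traj$atoms$role == role)
    n <- matrix(0L, n_frames(traj), shells$n_shells)
    if (length(idx)) {
      d <- .dist_to_ref_cpp(traj$coords, ref - 1L, idx - 1L,
                            traj$box_edge)
      for (s in seq_len(shells$n_shells))
        n[, s] <- rowSums(d >= shells$bounds[s] &
                            d < shells$bounds[s + 1L])
    }
    n
  }
  structure(list(fluorine = count1("fluorine"), water = count1("water-O"),
                 shells = shells, reference = traj$atoms$id[ref],
                 dt = traj$dt),
            class = "shell_occupancy")
}

#' @export
print.shell_occupancy <- function(x, ...) {
  cat(sprintf("shell occupancy around %s (%d frames):\n", x$reference,
              nrow(x$fluorine)))
  m <- data.frame(shell = seq_len(ncol(x$fluorine)),
                  mean_F = colMeans(x$fluorine),
                  mean_Ow = colMeans(x$water))
  print(m, row.names = FALSE)
  invisible(x)
}

#' Average shell-occupancy table across replicate series
#'
#' Per reference hydrogen and shell: mean fluorine and water-oxygen
#' counts, the water-to-fluorine ratio, the mean deviation across
#' replicate series, and an enrichment flag relative to the bulk solvent
#' ratio (a shell ratio above the bulk value marks local enrichment in
#' water; below, enrichment in HFIP).
#'
#' @param series list of `shell_occupancy` (replicates, possibly for
#'   several hydrogens).
#' @param bulk_ratio bulk water-to-fluorine ratio used as the enrichment
#'   threshold; 2.57 follows from the default 482/7434 box composition.
#' @param tol relative half-width of the bulk-like band: shells whose
#'   ratio is within `tol` of `bulk_ratio` are flagged `"bulk-like"`.
#' @return data frame with one row per (hydrogen, shell).
#' @export
shell_average_table <- function(series, bulk_ratio = 2.57, tol = 0.1) {
  if (!length(series)) stop("need at least one occupancy series")
  refs <- vapply(series, `[[`, "", "reference")
  out <- NULL
  for (r in unique(refs)) {
    grp <- series[refs == r]
    ns <- ncol(grp[[1L]]$fluorine)
    mf <- sapply(grp, function(g) colMeans(g$fluorine))
    mw <- sapply(grp, function(g) colMeans(g$water))
    mf <- matrix(mf, nrow = ns); mw <- matrix(mw, nrow = ns)
    mean_f <- rowMeans(mf); mean_w <- rowMeans(mw)
    dev_f <- rowMeans(abs(mf - mean_f))
    dev_w <- rowMeans(abs(mw - mean_w))
    ratio <- ifelse(mean_f > 0, mean_w / mean_f, NA_real_)
    out <- rbind(out, data.frame(
      hydrogen = r, shell = seq_len(ns), mean_F = mean_f,
      mean_Ow = mean_w, ratio_Ow_F = ratio, mean_dev_F = dev_f,
      mean_dev_Ow = dev_w,
      ratio_undefined = mean_f == 0,
      enriched = ifelse(mean_f == 0, NA_character_,
                 ifelse(ratio > bulk_ratio * (1 + tol), "water",
                 ifelse(ratio < bulk_ratio * (1 - tol), "HFIP",
                        "bulk-like")))))
  }
  rownames(out) <- NULL
  attr(out, "bulk_ratio") <- bulk_ratio
  out
}

#' Solvent-contact events
#'
#' A solvent atom is in contact with the reference hydrogen while its
#' minimum-image distance stays at or below the species cutoff (0.5 nm
#' for fluorine, 0.4 nm for water oxygen by default).  A contact is
#' persistent only across strictly consecutive snapshots: a single-frame
#' gap ends the event, so contact durations are resolved to about one
#' snapshot interval.  Events touching either end of the trajectory are
#' flagged censored.
#'
#' @param traj a [trajectory].
#' @param ref reference hydrogen.
#' @param cutoffs named cutoffs in nm for `fluorine` and `water`.
#' @param species species to scan.
#' @param per_molecule collapse fluorine-atom contacts to the molecule
#'   level (a molecule is in contact while any of its fluorines is)?
#' @return data frame of class `contact_events`: `atom` (index), `id`,
#'   `species`, `mol_id`, `start_frame`, `end_frame`, `duration_ps`,
#'   `censored_start`, `censored_end`.
#' @export
contact_events <- function(traj, ref = NULL,
                           cutoffs = c(fluorine = 0.5, water = 0.4),
                           species = c("fluorine", "water"),
                           per_molecule = FALSE) {
  ref <- if (is.null(ref)) .default_ref(traj) else select_atom(traj, ref)
  species <- match.arg(species, c("fluorine", "water"), several.ok = TRUE)
  nt <- n_frames(traj)
  out <- NULL
  for (sp in species) {
    if (!sp %in% names(cutoffs)) stop("no cutoff given for ", sp)
    role <- if (sp == "fluorine") "fluorine" else "water-O"
    idx <- which(traj$atoms$role == role)
    if (!length(idx)) next
    d <- .dist_to_ref_cpp(traj$coords, ref - 1L, idx - 1L, traj$box_edge)
    inc <- d <= cutoffs[[sp]]
    if (per_molecule) {
      mol <- traj$atoms$mol_id[idx]
      um <- unique(mol)
      inc <- vapply(um, function(m)
        rowSums(inc[, mol == m, drop = FALSE]) > 0, logical(nt))
      idx <- um  # now columns are molecules
    }
    for (j in seq_len(ncol(inc))) {
      r <- rle(inc[, j])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      if (!length(keep)) next
      out <- rbind(out, data.frame(
        atom = if (per_molecule) NA_integer_ else idx[j],
        id = if (per_molecule) sprintf("mol%d", idx[j]) else
          traj$atoms$id[idx[j]],
        species = sp,
        mol_id = if (per_molecule) idx[j] else traj$atoms$mol_id[idx[j]],
        start_frame = starts[keep], end_frame = ends[keep],
        duration_ps = r$lengths[keep] * traj$dt,
        censored_start = starts[keep] == 1L,
        censored_end = ends[keep] == nt))
    }
  }
  if (is.null(out))
    out <- data.frame(atom = integer(0), id = character(0),
                      species = character(0), mol_id = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      duration_ps = numeric(0), censored_start = logical(0),
                      censored_end = logical(0))
  attr(out, "dt") <- traj$dt
  attr(out, "n_frames") <- nt
  attr(out, "reference") <- traj$atoms$id[ref]
  class(out) <- c("contact_events", "data.frame")
  out
}

#' Contact-persistence statistics
#'
#' Summarises contact events for one species: events started per ns, the
#' percentage of events outlasting a threshold, and the mean duration of
#' the over-threshold events.  Censored events count toward the rate and
#' the percentage but are excluded from the long-duration mean (their true
#' durations are unknown); the number excluded is flagged.
#'
#' @param events a `contact_events` data frame (one species).
#' @param trajectory_length_ns trajectory length in ns.
#' @param threshold duration threshold, ps.
#' @return list of class `contact_stats`: `contacts_per_ns`,
#'   `percent_long`, `mean_long_duration_ps`, `n_events`,
#'   `n_censored_excluded`, `no_events` flag.
#' @export
contact_stats <- function(events, trajectory_length_ns = NULL,
                          threshold = 60) {
  if (is.null(trajectory_length_ns)) {
    nt <- attr(events, "n_frames"); dt <- attr(events, "dt")
    if (is.null(nt) || is.null(dt))
      stop("supply 'trajectory_length_ns'")
    trajectory_length_ns <- (nt - 1) * dt / 1000
  }
  if (trajectory_length_ns <= 0) stop("zero-length trajectory")
  if (length(unique(events$species)) > 1L)
    stop("contact_stats expects events of a single species")
  n <- nrow(events)
  if (n == 0L) {
    out <- list(contacts_per_ns = 0, percent_long = 0,
                mean_long_duration_ps = NA_real_, n_events = 0L,
                n_censored_excluded = 0L, no_events = TRUE,
                threshold_ps = threshold)
    class(out) <- "contact_stats"
    return(out)
  }
  long <- events$duration_ps > threshold
  cens <- events$censored_start | events$censored_end
  use <- long & !cens
  out <- list(
    contacts_per_ns = n / trajectory_length_ns,
    percent_long = 100 * sum(long) / n,
    mean_long_duration_ps = if (any(use))
      mean(events$duration_ps[use]) else NA_real_,
    n_events = n,
    n_censored_excluded = sum(long & cens),
    no_events = FALSE,
    threshold_ps = threshold)
  class(out) <- "contact_stats"
  out
}

#' @export
print.contact_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "contacts: %.3g per ns; %.2f%% longer than %g ps; mean long ",
    "duration %.3g ps (%d events)\n"),
    x$contacts_per_ns, x$percent_long, x$threshold_ps,
    x$mean_long_duration_ps, x$n_events))
  invisible(x)
}

#' Interval overlap between detected events and a reference log
#'
#' Time-weighted agreement between two sets of per-molecule intervals:
#' total intersection time divided by total union time, matched by
#' molecule id.  Used to validate contact detection against the
#' generator's true bound-interval log.
#'
#' @param events a `contact_events` (typically `per_molecule = TRUE`),
#'   or any data frame with `mol_id`, `start_frame`, `end_frame`.
#' @param log data frame with `mol_id`, `start_ps`, `end_ps`.
#' @param dt snapshot interval, ps (taken from `events` when present).
#' @return overlap fraction in [0, 1].
#' @export
interval_overlap <- function(events, log, dt = NULL) {
  if (is.null(dt)) dt <- attr(events, "dt")
  mols <- union(unique(events$mol_id), unique(log$mol_id))
  inter <- 0; uni <- 0
  for (m in mols) {
    ev <- events[events$mol_id == m, , drop = FALSE]
    lg <- log[log$mol_id == m, , drop = FALSE]
    # rasterise on a fine grid: snapshot resolution is the natural scale
    t0 <- min(c((ev$start_frame - 1) * dt, lg$start_ps, 0))
    t1 <- max(c(ev$end_frame * dt, lg$end_ps, t0 + dt))
    grid <- seq(t0, t1, by = dt / 2)
    ina <- rep(FALSE, length(grid)); inb <- ina
    for (k in seq_len(nrow(ev)))
      ina[grid >= (ev$start_frame[k] - 1) * dt &
            grid <= (ev$end_frame[k] - 1) * dt] <- TRUE
    for (k in seq_len(nrow(lg)))
      inb[grid >= lg$start_ps[k] & grid <= lg$end_ps[k]] <- TRUE
    inter <- inter + sum(ina & inb)
    uni <- uni + sum(ina | inb)
  }
  if (uni == 0) return(NA_real_)
  inter / uni
}
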