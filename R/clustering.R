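# HFIP aggregate detection: connected components of the molecule-contact
# graph, where two molecules are linked when their minimum interatomic
# (min-image) distance is at or below a cutoff.

# union-find with path compression over sorted molecule ids; labels =
# smallest molecule id per component (canonical, independent of atom or
# edge order)
.components <- function(ids, edges) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    ea <- match(edges[, 1L], ids)
    eb <- match(edges[, 2L], ids)
    for (k in seq_len(nrow(edges))) {
      a <- find(ea[k]); b <- find(eb[k])
      if (a != b) {
        if (a < b) parent[b] <- a else parent[a] <- b
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  stats::setNames(ids[roots], ids)
}

#' Detect HFIP aggregates in one frame
#'
#' Links two HFIP molecules when their minimum interatomic (or
#' centre-centre) minimum-image distance is at or below `cutoff`, and
#' returns the connected components.  Labels are deterministic: each
#' cluster is named by its smallest molecule id.  The distance criterion
#' is a first-class parameter — reported outputs embed it — since typical
#' first-minimum contact distances (about 0.35 nm between heavy atoms)
#' vary with the system.
#'
#' @param traj a [trajectory] containing HFIP molecules.
#' @param frame frame index.
#' @param cutoff link distance, nm.
#' @param mode `"atoms"` (minimum interatomic distance over all HFIP
#'   atoms) or `"centers"` (molecule centres only).
#' @return named integer vector: cluster label per molecule id.
#' @export
find_clusters <- function(traj, frame = 1L, cutoff = 0.35,
                          mode = c("atoms", "centers")) {
  mode <- match.arg(mode)
  if (cutoff >= traj$box_edge / 2)
    stop("cutoff must be below half the box edge")
  sel <- if (mode == "atoms")
    which(traj$atoms$resname == "HFP")
  else
    which(traj$atoms$resname == "HFP" & traj$atoms$role == "other")
  if (!length(sel)) stop("no HFIP molecules in trajectory")
  mol <- traj$atoms$mol_id[sel]
  fr <- matrix(traj$coords[sel, , frame], ncol = 3L)
  edges <- .contact_edges_cpp(fr, mol, traj$box_edge, cutoff)
  edges <- unique(edges)
  labels <- .components(sort(unique(mol)), edges)
  storage.mode(labels) <- "integer"
  labels
}

#' Aggregation statistics over a trajectory
#'
#' Applies [find_clusters()] to every `stride`-th frame and summarises:
#' the time-averaged fraction of HFIP molecules in aggregates (clusters of
#' two or more), the maximum aggregate size, the pooled size histogram,
#' and the mean cluster lifetime.  A cluster is deemed to survive from one
#' analysed frame to the next when at least half of the larger of the two
#' memberships is shared.
#'
#' @param traj a [trajectory].
#' @param cutoff link distance, nm.
#' @param stride frame stride.
#' @param mode see [find_clusters()].
#' @return object of class `cluster_stats`: `fraction_aggregated`,
#'   `fraction_by_frame`, `max_size`, `size_distribution` (table),
#'   `mean_lifetime_ps`, `cutoff`, `mode`.
#' @export
aggregation_stats <- function(traj, cutoff = 0.35, stride = 1L,
                              mode = "atoms") {
  frames <- seq(1L, n_frames(traj), by = max(1L, stride))
  if (!length(frames)) stop("no frames after stride")
  frac <- numeric(length(frames))
  sizes_all <- integer(0)
  max_size <- 0L
  clusters_prev <- NULL
  lifetimes <- numeric(0)
  open <- list()  # clusters alive at previous analysed frame
  dt_eff <- traj$dt * max(1L, stride)
  for (fi in seq_along(frames)) {
    labels <- find_clusters(traj, frames[fi], cutoff, mode)
    sizes <- table(labels)
    frac[fi] <- sum(sizes[sizes >= 2]) / length(labels)
    sizes_all <- c(sizes_all, as.integer(sizes))
    max_size <- max(max_size, max(as.integer(sizes)))
    members <- split(as.integer(names(labels)), labels)
    if (is.null(clusters_prev)) {
      open <- lapply(members, function(m) list(members = m, age = 1L))
    } else {
      newopen <- list()
      matched_prev <- rep(FALSE, length(open))
      for (m in members) {
        best <- 0; besti <- 0L
        for (i in seq_along(open)) {
          if (matched_prev[i]) next
          ov <- length(intersect(m, open[[i]]$members)) /
            max(length(m), length(open[[i]]$members))
          if (ov > best) { best <- ov; besti <- i }
        }
        if (best >= 0.5) {
          matched_prev[besti] <- TRUE
          newopen[[length(newopen) + 1L]] <-
            list(members = m, age = open[[besti]]$age + 1L)
        } else {
          newopen[[length(newopen) + 1L]] <- list(members = m, age = 1L)
        }
      }
      for (i in seq_along(open))
        if (!matched_prev[i]) lifetimes <- c(lifetimes, open[[i]]$age)
      open <- newopen
    }
    clusters_prev <- members
  }
  lifetimes <- c(lifetimes, vapply(open, `[[`, 0L, "age"))
  out <- list(fraction_aggregated = mean(frac), fraction_by_frame = frac,
              max_size = max_size,
              size_distribution = table(sizes_all),
              mean_lifetime_ps = mean(lifetimes) * dt_eff,
              n_frames_analysed = length(frames),
              cutoff = cutoff, mode = mode)
  class(out) <- "cluster_stats"
  out
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "HFIP aggregation (cutoff %.3g nm, %s): %.1f%% of molecules in ",
    "aggregates; largest %d; mean lifetime %.3g ps\n"),
    x$cutoff, x$mode, 100 * x$fraction_aggregated, x$max_size,
    x$mean_lifetime_ps))
  invisible(x)
}
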