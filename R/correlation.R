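#' Intermolecular dipolar correlation function G(t)
#'
#' Computes the correlation function of the dipolar lattice function
#' between a reference peptide hydrogen and solvent fluorines,
#' \deqn{G(t) = \langle \sum_k P_2(\cos\theta_k(t_0,t_0+t)) /
#'   (r_k(t_0)^3\, r_k(t_0+t)^3) \rangle_{t_0},}
#' averaged over time origins.  The sum runs over fluorines within
#' `cutoff` of the hydrogen at the origin frame; selected pairs are then
#' followed for the full lag even if they leave the cutoff, with the
#' dipolar vector tracked along the minimum-image-consistent (unwrapped)
#' relative displacement.
#'
#' The lag grid is uniform at the snapshot spacing up to 1000 points; a
#' longer `max_lag` is covered by logarithmic thinning (flagged in the
#' `thinned` attribute).
#'
#' @param traj a [trajectory].
#' @param ref reference hydrogen (see [select_atom()]); default: the
#'   trajectory's peptide-H.
#' @param max_lag largest lag, ps.
#' @param origin_stride spacing of time origins, frames.
#' @param cutoff origin-frame selection radius, nm (default 3.0).
#' @return object of class `correlation_function`: data frame with columns
#'   `lag_ps`, `G` (nm^-6), `n_eval` (pair evaluations per lag), `se`
#'   (standard error over origins); attributes `reference`, `cutoff`,
#'   `dt`, `shell`, `n_origins`, `units`.
#' @export
dipolar_correlation <- function(traj, ref = NULL, max_lag = NULL,
                                origin_stride = 1L, cutoff = 3.0) {
  res <- .shell_corr(traj, ref, max_lag, origin_stride,
                     shell_breaks = cutoff)
  res[[1L]]
}

#' Shell-resolved dipolar correlation functions
#'
#' As [dipolar_correlation()], but each fluorine's contribution is routed
#' to the solvation shell it occupies at the origin frame.  The per-shell
#' functions use identical origins, so they sum exactly to the all-solvent
#' G(t).
#'
#' @inheritParams dipolar_correlation
#' @param shells a [shell_definition()]; the outermost bound acts as the
#'   selection cutoff.
#' @return list of `correlation_function`, one per shell (shell labels in
#'   the `shell` attribute).
#' @export
shell_resolved_correlation <- function(traj, ref = NULL, shells = NULL,
                                       max_lag = NULL, origin_stride = 1L) {
  if (is.null(shells)) shells <- shell_definition()
  .shell_corr(traj, ref, max_lag, origin_stride,
              shell_breaks = shells$bounds[-1L])
}

.shell_corr <- function(traj, ref, max_lag, origin_stride, shell_breaks) {
  if (is.unsorted(shell_breaks, strictly = TRUE) || any(shell_breaks <= 0))
    stop("shell bounds must be positive and strictly increasing")
  ref <- if (is.null(ref)) .default_ref(traj) else select_atom(traj, ref)
  nt <- n_frames(traj)
  dt <- traj$dt
  if (is.null(max_lag)) max_lag <- min((nt - 1) * dt, 1000 * dt)
  max_lag_frames <- floor(max_lag / dt)
  if (max_lag_frames >= nt)
    stop("max_lag must be shorter than the trajectory")
  if (max_lag_frames < 1) stop("max_lag must cover at least one snapshot")
  thinned <- max_lag_frames > 1000L
  lags <- if (!thinned) 0:max_lag_frames else
    unique(c(0L, as.integer(round(exp(seq(0, log(max_lag_frames),
                                          length.out = 1000L))))))
  origins <- seq(1L, nt - max_lag_frames, by = max(1L, origin_stride))
  fidx <- which(traj$atoms$role == "fluorine")
  if (length(fidx) == 0L) stop("trajectory has no fluorine atoms")
  fw <- traj$coords[fidx, , , drop = FALSE]
  hw <- t(matrix(traj$coords[ref, , ], nrow = 3L))
  res <- .dipolar_corr_cpp(fw, hw, traj$box_edge, origins - 1L, lags,
                           shell_breaks)
  if (res$n_origins == 0L || sum(res$n_pairs[1L, ]) == 0)
    stop("no fluorines within the cutoff at any origin")
  ns <- length(shell_breaks)
  lower <- c(0, shell_breaks[-ns])
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    cf <- data.frame(lag_ps = lags * dt, G = res$G[, s],
                     n_eval = res$n_pairs[, s], se = res$se[, s])
    attr(cf, "reference") <- traj$atoms$id[ref]
    attr(cf, "cutoff") <- shell_breaks[ns]
    attr(cf, "shell") <- if (ns == 1L) "all" else s
    attr(cf, "shell_bounds") <- c(lower[s], shell_breaks[s])
    attr(cf, "dt") <- dt
    attr(cf, "n_origins") <- res$n_origins
    attr(cf, "thinned") <- thinned
    attr(cf, "units") <- list(G = "nm^-6", t = "ps")
    class(cf) <- c("correlation_function", "data.frame")
    out[[s]] <- cf
  }
  out
}

#' @export
print.correlation_function <- function(x, ...) {
  cat(sprintf(paste0(
    "dipolar correlation function: ref %s, shell %s, %d lags to %g ps\n",
    " G(0) = %.4g nm^-6 (%d origins)\n"),
    attr(x, "reference"), as.character(attr(x, "shell")), nrow(x),
    max(x$lag_ps), x$G[1], attr(x, "n_origins")))
  invisible(x)
}

#' Sum shell-resolved correlation functions
#'
#' Pointwise sum of per-shell G(t) sharing the same origins, reproducing
#' the all-solvent correlation function.
#'
#' @param corrs list of `correlation_function` from
#'   [shell_resolved_correlation()].
#' @return a `correlation_function`.
#' @export
sum_correlations <- function(corrs) {
  out <- corrs[[1L]]
  for (k in seq_along(corrs)[-1L]) {
    stopifnot(all(corrs[[k]]$lag_ps == out$lag_ps))
    out$G <- out$G + corrs[[k]]$G
    out$n_eval <- out$n_eval + corrs[[k]]$n_eval
    out$se <- sqrt(out$se^2 + corrs[[k]]$se^2)
  }
  attr(out, "shell") <- "all"
  attr(out, "shell_bounds") <- c(0, attr(corrs[[length(corrs)]],
                                         "shell_bounds")[2])
  out
}

#' Tabulate a correlation function
#'
#' Writes the (lag, G, n_eval, se) table as TSV.
#'
#' @param corr a `correlation_function`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(corr, path) {
  utils::write.table(as.data.frame(corr), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
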