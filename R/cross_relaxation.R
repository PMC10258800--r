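#' Cross-relaxation rate from a fitted correlation function
#'
#' Converts the spectral density of the H-F dipolar correlation function
#' into the heteronuclear cross-relaxation rate
#' \deqn{\Sigma_{HF} = \tfrac{1}{10} (\mu_0/4\pi)^2 \hbar^2 \gamma_H^2
#'   \gamma_F^2 \left[6 J(\omega_H+\omega_F) - J(\omega_H-\omega_F)\right],}
#' with J the one-sided cosine transform of G(t).  The rate is small and
#' signed: it is the difference of two larger quantities, positive in the
#' fast-motion (extreme-narrowing) regime and negative when solvent motion
#' is slow on the inverse-frequency scale.
#'
#' @param fit an `expfit` of a correlation function in nm^-6 vs ps.
#' @param nmr [nmr_parameters()].
#' @param units unit metadata `list(G=, t=)`; taken from the fit when it
#'   carries it.  Fits of unit-less data are rejected: silent unit errors
#'   dominate this computation.
#' @return object of class `cross_relaxation`: list with `sigma_hf`
#'   (s^-1), `J_sum`, `J_diff` (nm^-6 ps), `B0`, `reference`.
#' @export
sigma_hf <- function(fit, nmr = nmr_parameters(), units = NULL) {
  if (!inherits(fit, "expfit")) stop("'fit' must be an expfit object")
  if (!fit$converged) stop("fit did not converge")
  if (is.null(units)) units <- attr(fit, "units", exact = TRUE)
  if (is.null(units) || !identical(units$G, "nm^-6") ||
      !identical(units$t, "ps"))
    stop("missing or wrong unit metadata: expected G in nm^-6, lags in ps")
  j_sum <- spectral_density(fit, nmr$omega_sum_ps)
  j_diff <- spectral_density(fit, nmr$omega_diff_ps)
  out <- list(sigma_hf = .sigma_from_J(j_sum, j_diff, nmr),
              J_sum = j_sum, J_diff = j_diff, B0 = nmr$B0,
              reference = attr(fit, "reference", exact = TRUE),
              shell_contributions = NULL, uncertainty = NA_real_)
  class(out) <- "cross_relaxation"
  out
}

#' @export
print.cross_relaxation <- function(x, ...) {
  cat(sprintf("Sigma_HF = %.4g x 10^-3 s^-1 at B0 = %.3f T",
              x$sigma_hf * 1e3, x$B0))
  if (is.finite(x$uncertainty))
    cat(sprintf(" (mean deviation %.2g x 10^-3)", x$uncertainty * 1e3))
  cat("\n")
  if (!is.null(x$shell_contributions)) {
    cat(" shell contributions x 10^-3 s^-1: ",
        paste(sprintf("%.3g", x$shell_contributions * 1e3),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Shell decomposition of the cross-relaxation rate
#'
#' Fits each shell-resolved correlation function separately and converts
#' it to a per-shell rate; the total is their sum.  Because the shells
#' partition the fluorines at each origin, the per-shell G(t) sum exactly
#' to the all-solvent one, and the per-shell rates sum to the total within
#' fit tolerance.
#'
#' @param shell_corrs list of `correlation_function` from
#'   [shell_resolved_correlation()].
#' @param nmr [nmr_parameters()].
#' @param max_terms per-shell fit order cap.
#' @return a `cross_relaxation` with `shell_contributions`.
#' @export
sigma_shell_decomposition <- function(shell_corrs, nmr = nmr_parameters(),
                                      max_terms = 5L) {
  contr <- numeric(length(shell_corrs))
  orders <- integer(length(shell_corrs))
  for (s in seq_along(shell_corrs)) {
    corr <- shell_corrs[[s]]
    if (all(corr$n_eval == 0) || all(corr$G == 0)) {
      contr[s] <- 0
      orders[s] <- 0L
      next
    }
    fit <- fit_multiexponential(corr, max_terms = max_terms)
    contr[s] <- sigma_hf(fit, nmr)$sigma_hf
    orders[s] <- fit$order
  }
  used <- orders[orders > 0L]
  if (length(used) > 1L && diff(range(used)) > 2L)
    warning("shell fits used widely different model orders: ",
            paste(orders, collapse = ", "))
  out <- list(sigma_hf = sum(contr), J_sum = NA_real_, J_diff = NA_real_,
              B0 = nmr$B0,
              reference = attr(shell_corrs[[1L]], "reference", exact = TRUE),
              shell_contributions = contr, uncertainty = NA_real_)
  class(out) <- "cross_relaxation"
  out
}

#' Average cross-relaxation results over replicate trajectories
#'
#' Reports the mean rate and the mean absolute deviation from the mean,
#' the uncertainty convention used for replicate simulation averages.
#'
#' @param results list of `cross_relaxation` for the same hydrogen and
#'   field.
#' @return a `cross_relaxation` with `uncertainty` set.
#' @export
average_replicates <- function(results) {
  if (length(results) < 2L) stop("need at least two replicate results")
  refs <- unique(vapply(results, function(r)
    if (is.null(r$reference)) NA_character_ else r$reference, ""))
  if (length(refs[!is.na(refs)]) > 1L)
    stop("results refer to different hydrogens: ",
         paste(refs, collapse = ", "))
  b0 <- unique(vapply(results, `[[`, 0, "B0"))
  if (length(b0) > 1L) stop("results use different fields")
  s <- vapply(results, `[[`, 0, "sigma_hf")
  out <- list(sigma_hf = mean(s), J_sum = NA_real_, J_diff = NA_real_,
              B0 = b0, reference = refs[1L],
              shell_contributions = NULL,
              uncertainty = mean(abs(s - mean(s))),
              n_replicates = length(s))
  class(out) <- "cross_relaxation"
  out
}

#' End-to-end rate from a trajectory
#'
#' Convenience wrapper: correlation function, multi-exponential fit, and
#' cross-relaxation rate in one call.
#'
#' @inheritParams dipolar_correlation
#' @param nmr [nmr_parameters()].
#' @param max_terms fit order cap.
#' @return a `cross_relaxation`; the fit and correlation function are
#'   attached as attributes `fit` and `corr`.
#' @export
sigma_from_trajectory <- function(traj, ref = NULL, max_lag = NULL,
                                  origin_stride = 1L, cutoff = 3.0,
                                  nmr = nmr_parameters(), max_terms = 5L) {
  corr <- dipolar_correlation(traj, ref = ref, max_lag = max_lag,
                              origin_stride = origin_stride,
                              cutoff = cutoff)
  fit <- fit_multiexponential(corr, max_terms = max_terms)
  out <- sigma_hf(fit, nmr)
  attr(out, "fit") <- fit
  attr(out, "corr") <- corr
  out
}
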