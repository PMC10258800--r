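# Analytic force-free hard-sphere (Ayant / Hwang-Freed) model of
# translational intermolecular dipolar relaxation.  Serves as the
# independent oracle for the trajectory pipeline and as a standalone
# calculator.

.solvnoe_cache <- new.env(parent = emptyenv())

# eigenmode representation of the reflecting-boundary force-free
# correlation decay: g(t) = (54/pi) Int du u^2/(81+9u^2-2u^4+u^6)
# exp(-u^2 t/tau_b).  The ratio below is J(0)/(G(0) tau_b); it is computed
# once by quadrature and cached (the quadrature also fixes the overall
# scale under the same G(t) normalisation the pipeline uses).
.hs_denom <- function(u) 81 + 9 * u^2 - 2 * u^4 + u^6

.hs_tauc_ratio <- function() {
  if (is.null(.solvnoe_cache$tauc_ratio)) {
    i0 <- stats::integrate(function(u) 1 / .hs_denom(u), 0, Inf,
                           rel.tol = 1e-12)$value
    i1 <- stats::integrate(function(u) u^2 / .hs_denom(u), 0, Inf,
                           rel.tol = 1e-12)$value
    .solvnoe_cache$norm_i1 <- i1
    .solvnoe_cache$tauc_ratio <- i0 / i1
  }
  .solvnoe_cache$tauc_ratio
}

#' Hard-sphere model parameters
#'
#' Parameters of the force-free translational relaxation model: the
#' distance of closest approach of the spin-bearing entities, their mutual
#' translational diffusion coefficient, and the number density of solvent
#' fluorine spins.
#'
#' @param b distance of closest approach, nm.
#' @param d_mutual mutual translational diffusion coefficient, m^2 s^-1.
#' @param n_f fluorine number density, nm^-3.
#' @param nmr [nmr_parameters()].
#' @return object of class `hard_sphere_params` with derived `tau_b`
#'   (= b^2/D, ps) and `G0` (= 4 pi n_f / (3 b^3), nm^-6).
#' @export
hard_sphere_params <- function(b, d_mutual, n_f, nmr = nmr_parameters()) {
  if (b <= 0 || d_mutual <= 0 || n_f <= 0)
    stop("b, d_mutual and n_f must all be positive")
  p <- list(b = b, d_mutual = d_mutual, n_f = n_f, nmr = nmr,
            tau_b = b^2 / .d_si_to_nmps(d_mutual),
            G0 = 4 * pi * n_f / (3 * b^3))
  class(p) <- "hard_sphere_params"
  p
}

#' Reduced force-free spectral density j(z)
#'
#' The dimensionless spectral-density shape of the force-free hard-sphere
#' model, `j(0) = 1`, with `z = sqrt(2 omega tau_b)`:
#' \deqn{j(z) = \frac{1 + 5z/8 + z^2/8}{1 + z + z^2/2 + z^3/6 + 4z^4/81 +
#'   z^5/81 + z^6/648}.}
#'
#' @param z non-negative reduced frequency (vectorised).
#' @return j(z).
#' @export
ayant_reduced_j <- function(z) {
  if (any(z < 0)) stop("z must be non-negative")
  (1 + 5 * z / 8 + z^2 / 8) /
    (1 + z + z^2 / 2 + z^3 / 6 + 4 * z^4 / 81 + z^5 / 81 + z^6 / 648)
}

#' Analytic spectral density of the hard-sphere model
#'
#' `J(omega) = J(0) j(z)` with `z = sqrt(2 omega tau_b)`.  The absolute
#' scale `J(0) = G(0) tau_b (J(0)/G(0)tau_b)` is fixed by numerical
#' quadrature of the reflecting-boundary diffusion propagator under the
#' same G(t) normalisation used by the trajectory pipeline (result cached).
#' `method = "quadrature"` evaluates the full eigenmode integral at each
#' frequency instead of the closed-form shape.
#'
#' @param p [hard_sphere_params()].
#' @param omega angular frequency, rad ps^-1 (vectorised, >= 0).
#' @param method `"closed"` (default) or `"quadrature"`.
#' @return J in nm^-6 ps.
#' @export
ayant_spectral_density <- function(p, omega, method = c("closed",
                                                        "quadrature")) {
  method <- match.arg(method)
  if (any(omega < 0)) stop("omega must be non-negative")
  J0 <- p$G0 * p$tau_b * .hs_tauc_ratio()
  if (method == "closed") {
    z <- sqrt(2 * omega * p$tau_b)
    return(J0 * ayant_reduced_j(z))
  }
  .hs_tauc_ratio()  # ensure cache
  i1 <- .solvnoe_cache$norm_i1
  vapply(omega, function(w) {
    wt <- w * p$tau_b
    p$G0 * p$tau_b *
      stats::integrate(function(u) u^2 / .hs_denom(u) *
                         u^2 / (u^4 + wt^2), 0, Inf,
                       rel.tol = 1e-10)$value / i1
  }, 0)
}

#' Analytic dipolar correlation function of the hard-sphere model
#'
#' Evaluates G(t) for force-free diffusion outside a reflecting sphere by
#' quadrature over the eigenmode representation of the diffusion
#' propagator, normalised as in the trajectory pipeline:
#' `G(0) = 4 pi n_f / (3 b^3)`.
#'
#' @param p [hard_sphere_params()].
#' @param t lag times, ps (vectorised, >= 0).
#' @return G(t) in nm^-6.
#' @export
ayant_correlation <- function(p, t) {
  if (any(t < 0)) stop("t must be non-negative")
  .hs_tauc_ratio()  # ensure cache
  i1 <- .solvnoe_cache$norm_i1
  vapply(t, function(tt) {
    p$G0 * stats::integrate(function(u) u^2 / .hs_denom(u) *
                              exp(-u^2 * tt / p$tau_b), 0, Inf,
                            rel.tol = 1e-10)$value / i1
  }, 0)
}

#' Analytic cross-relaxation rate of the hard-sphere model
#'
#' Evaluates the same prefactor and frequency combination as [sigma_hf()]
#' on the analytic spectral density, giving the baseline rate against
#' which trajectory results are compared; deviations from it signal
#' interactions longer-lived than simple diffusive encounters.
#'
#' The trajectory pipeline seeds its pair sum with fluorines inside a
#' finite cutoff of the hydrogen at each origin, while the plain model
#' integrates over all space.  Supplying `seed_cutoff` subtracts the
#' model's own estimate of the beyond-cutoff share — the hard-sphere
#' spectral density with closest approach equal to the cutoff — giving a
#' baseline on the same seeding convention as the pipeline.  The
#' correction is a few percent of J(w_H - w_F) at typical cutoffs and
#' vanishes as the cutoff grows.
#'
#' @param p [hard_sphere_params()].
#' @param seed_cutoff optional origin-frame seeding radius (nm) matching
#'   the pipeline's `cutoff`; `NULL` for the infinite-medium rate.
#' @return a `cross_relaxation`.
#' @export
ayant_sigma <- function(p, seed_cutoff = NULL) {
  nmr <- p$nmr
  j <- ayant_spectral_density(p, c(nmr$omega_sum_ps, nmr$omega_diff_ps))
  if (!is.null(seed_cutoff)) {
    if (seed_cutoff <= p$b)
      stop("seed_cutoff must exceed the closest-approach radius")
    pout <- hard_sphere_params(seed_cutoff, p$d_mutual, p$n_f, nmr)
    j <- j - ayant_spectral_density(pout, c(nmr$omega_sum_ps,
                                            nmr$omega_diff_ps))
  }
  out <- list(sigma_hf = .sigma_from_J(j[1], j[2], nmr),
              J_sum = j[1], J_diff = j[2], B0 = nmr$B0,
              reference = "hard-sphere model",
              shell_contributions = NULL, uncertainty = NA_real_)
  class(out) <- "cross_relaxation"
  out
}

#' Scan the analytic rate along one parameter
#'
#' Evaluates Sigma_HF on a grid of one of `B0`, `D_mutual` or `b`, holding
#' the rest fixed, and reports sign-change (crossover) locations refined
#' by bisection.  Useful for interpreting small rates of either sign.
#'
#' @param p [hard_sphere_params()] (baseline parameters).
#' @param variable one of `"B0"`, `"D_mutual"`, `"b"`.
#' @param grid sorted grid of values for the scanned variable.
#' @return data frame of `value`, `sigma_hf`; crossover locations in the
#'   `crossovers` attribute.
#' @export
sigma_scan <- function(p, variable = c("D_mutual", "B0", "b"), grid) {
  variable <- match.arg(variable)
  if (length(grid) == 0) stop("empty grid")
  if (is.unsorted(grid)) stop("grid must be sorted")
  eval1 <- function(v) {
    q <- switch(variable,
      D_mutual = hard_sphere_params(p$b, v, p$n_f, p$nmr),
      b = hard_sphere_params(v, p$d_mutual, p$n_f, p$nmr),
      B0 = hard_sphere_params(p$b, p$d_mutual, p$n_f,
                              nmr_parameters(B0 = v)))
    ayant_sigma(q)$sigma_hf
  }
  s <- vapply(grid, eval1, 0)
  out <- data.frame(value = grid, sigma_hf = s)
  cross <- numeric(0)
  sgn <- sign(s)
  for (k in seq_len(length(grid) - 1L)) {
    if (sgn[k] != 0 && sgn[k + 1L] != 0 && sgn[k] != sgn[k + 1L]) {
      root <- stats::uniroot(eval1, c(grid[k], grid[k + 1L]),
                             tol = .Machine$double.eps^0.5 *
                               max(abs(grid)))$root
      cross <- c(cross, root)
    }
  }
  attr(out, "crossovers") <- cross
  attr(out, "variable") <- variable
  out
}
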