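# Internal unit conventions: lengths in nm, times in ps, correlation
# functions in nm^-6, spectral densities in nm^-6 ps.  Diffusion
# coefficients cross the API in SI (m^2 s^-1); 1 m^2 s^-1 = 1e6 nm^2 ps^-1.

#' @keywords internal
.D_SI_TO_NMPS <- 1e6

#' @keywords internal
.J_NM6PS_TO_SI <- 1e42  # nm^-6 ps -> m^-6 s

.d_si_to_nmps <- function(d) d * .D_SI_TO_NMPS
.d_nmps_to_si <- function(d) d / .D_SI_TO_NMPS

#' NMR parameters for 1H-19F cross-relaxation
#'
#' Collects the static magnetic field, gyromagnetic ratios and physical
#' constants entering the heteronuclear cross-relaxation prefactor, and the
#' derived Larmor frequencies.  The default field of 11.744 T corresponds to
#' a 500 MHz proton spectrometer; the field actually used is embedded in
#' every downstream report.
#'
#' @param B0 static field in tesla.
#' @return An object of class `nmr_parameters`: a list with gyromagnetic
#'   ratios `gamma_h`, `gamma_f` (rad s^-1 T^-1), Larmor frequencies
#'   `omega_h`, `omega_f` (rad s^-1), their sum/difference combination
#'   frequencies in rad ps^-1 (`omega_sum_ps`, `omega_diff_ps`), and the
#'   dipolar prefactor `prefactor` (SI) such that
#'   `sigma = prefactor * (6 J(w_H + w_F) - J(w_H - w_F))` with J in SI.
#' @examples
#' p <- nmr_parameters()
#' p$omega_h / (2 * pi * 1e6)  # proton frequency, MHz
#' @export
nmr_parameters <- function(B0 = 11.744) {
  if (!is.numeric(B0) || length(B0) != 1L || !is.finite(B0) || B0 <= 0)
    stop("'B0' must be a single positive number (tesla)")
  gamma_h <- 2.675222e8   # rad s^-1 T^-1
  gamma_f <- 2.518148e8
  mu0_4pi <- 1e-7         # T^2 J^-1 m^3
  hbar <- 1.054572e-34    # J s
  out <- list(
    B0 = B0,
    gamma_h = gamma_h, gamma_f = gamma_f,
    omega_h = gamma_h * B0, omega_f = gamma_f * B0,
    omega_sum_ps = (gamma_h + gamma_f) * B0 * 1e-12,
    omega_diff_ps = (gamma_h - gamma_f) * B0 * 1e-12,
    mu0_4pi = mu0_4pi, hbar = hbar,
    prefactor = 0.1 * mu0_4pi^2 * hbar^2 * gamma_h^2 * gamma_f^2
  )
  class(out) <- "nmr_parameters"
  out
}

#' @export
print.nmr_parameters <- function(x, ...) {
  cat(sprintf("NMR parameters: B0 = %.4f T (1H %.2f MHz, 19F %.2f MHz)\n",
              x$B0, x$omega_h / (2 * pi * 1e6), x$omega_f / (2 * pi * 1e6)))
  invisible(x)
}

# sigma = prefactor * (6 J(w+) - J(w-)), J supplied in nm^-6 ps
.sigma_from_J <- function(j_sum, j_diff, nmr) {
  nmr$prefactor * (6 * j_sum - j_diff) * .J_NM6PS_TO_SI
}
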