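# Foerster spectral overlap and Foerster radius.
#
# J = int F_D(l) e_A(l) l^4 dl / int F_D(l) dl with l in nm, F_D the donor
# emission (arbitrary units; normalization built in) and e_A the acceptor
# molar absorptivity (M^-1 cm^-1), so J is in M^-1 cm^-1 nm^4. The radius
# follows the standard convention R0^6 = 8.79e-5 k^2 n^-4 Phi_D J (R0 in
# angstrom for J in M^-1 cm^-1 nm^4), reported in nm.

R0_CONSTANT_NM6 <- 8.79e-5 * 1e-6  # angstrom^6 -> nm^6

#' Spectral overlap integral
#'
#' Trapezoidal evaluation of the Foerster overlap integral on the donor
#' wavelength grid restricted to the region where the two spectra overlap; the
#' acceptor spectrum is linearly interpolated onto that grid.
#'
#' @param donor_em Donor emission spectrum: tibble with `wavelength` (nm,
#'   strictly increasing) and `value` (a.u.).
#' @param acceptor_abs Acceptor absorption spectrum: tibble with `wavelength`
#'   (nm) and `value` (molar absorptivity, M^-1 cm^-1).
#' @return Overlap integral J in M^-1 cm^-1 nm^4 (0, with a warning, for
#'   disjoint spectra). The donor normalization uses the full donor band.
#' @export
overlap_integral <- function(donor_em, acceptor_abs) {
  donor_em <- validate_spectrum(as_tibble(donor_em))
  acceptor_abs <- validate_spectrum(as_tibble(acceptor_abs))
  lo <- max(min(donor_em$wavelength), min(acceptor_abs$wavelength))
  hi <- min(max(donor_em$wavelength), max(acceptor_abs$wavelength))
  denom <- pracma::trapz(donor_em$wavelength, donor_em$value)
  if (denom <= 0) abort("donor emission spectrum has zero integral")
  if (lo >= hi) {
    warn("donor and acceptor spectra do not overlap; J = 0")
    return(0)
  }
  keep <- donor_em$wavelength >= lo & donor_em$wavelength <= hi
  wl <- donor_em$wavelength[keep]
  if (length(wl) < 2) {
    warn("fewer than two donor grid points in the overlap region; J = 0")
    return(0)
  }
  eps <- approx(acceptor_abs$wavelength, acceptor_abs$value, xout = wl)$y
  num <- pracma::trapz(wl, donor_em$value[keep] * eps * wl^4)
  num / denom
}

#' Foerster radius from the overlap integral
#'
#' `R0 = (8.79e-5 kappa2 n^-4 phi_D J)^(1/6)` angstrom, returned in nm, for J
#' in M^-1 cm^-1 nm^4.
#'
#' @param J Overlap integral, M^-1 cm^-1 nm^4 (>= 0).
#' @param phi_D Donor fluorescence quantum yield (0, 1].
#' @param kappa2 Orientation factor; default 2/3 (isotropic dynamic averaging).
#' @param n_refr Refractive index of the intervening medium; default 1.326
#'   (methanol).
#' @return R0 in nm (0 iff J = 0).
#' @export
forster_radius <- function(J, phi_D, kappa2 = 2 / 3, n_refr = 1.326) {
  stopifnot_scalar_number(J, "J", lower = 0)
  stopifnot_scalar_number(phi_D, "phi_D", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(kappa2, "kappa2", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(n_refr, "n_refr", lower = 0, strict_lower = TRUE)
  (R0_CONSTANT_NM6 * kappa2 * n_refr^-4 * phi_D * J)^(1 / 6)
}

#' Foerster radius from spectra
#'
#' Chains [overlap_integral()] and [forster_radius()] and echoes the inputs.
#'
#' @inheritParams overlap_integral
#' @inheritParams forster_radius
#' @return A one-row tibble: `J` (M^-1 cm^-1 nm^4), `R0` (nm), `phi_D`,
#'   `kappa2`, `n_refr`.
#' @export
fret_r0 <- function(donor_em, acceptor_abs, phi_D = 0.32, kappa2 = 2 / 3,
                    n_refr = 1.326) {
  J <- overlap_integral(donor_em, acceptor_abs)
  tibble(J = J, R0 = forster_radius(J, phi_D, kappa2, n_refr),
         phi_D = phi_D, kappa2 = kappa2, n_refr = n_refr)
}

#' Convert an overlap integral between nm- and cm-based conventions
#'
#' @param J Overlap integral.
#' @param from,to `"M-1 cm-1 nm4"` or `"M-1 cm3"` (the cm-based convention,
#'   1 nm^4 M^-1 cm^-1 = 1e-28 cm^3 M^-1... i.e. J(cm) = J(nm) * 1e-28).
#' @return The converted value.
#' @export
convert_overlap_units <- function(J, from = "M-1 cm-1 nm4", to = "M-1 cm3") {
  units <- c("M-1 cm-1 nm4" = 1, "M-1 cm3" = 1e-28)
  if (!from %in% names(units) || !to %in% names(units)) {
    abort("unknown overlap-integral unit")
  }
  J * units[[to]] / units[[from]]
}
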