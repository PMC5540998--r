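#' Virtual wavelength of asymmetric two-photon excitation
#'
#' When two synchronized pulsed lasers overlap in space and time, a
#' fluorophore can absorb one photon from each beam. The process is
#' equivalent to degenerate two-photon excitation at the harmonic mean of
#' the two laser wavelengths, `2 / (1/lambda1 + 1/lambda2)` — e.g. 850 nm
#' (Ti:Sa) mixed with 1230 nm (OPO) excites virtually at 1005 nm. The raw
#' value is returned; round to the nearest nanometre for display.
#'
#' @param lambda1,lambda2 Laser wavelengths in nm (both > 0).
#' @return Virtual wavelength in nm (unrounded).
#' @examples
#' round(virtual_wavelength(850, 1230))  # 1005
#' @export
virtual_wavelength <- function(lambda1, lambda2) {
  if (!is.numeric(lambda1) || !is.numeric(lambda2) ||
      length(lambda1) != 1L || length(lambda2) != 1L ||
      !is.finite(lambda1) || !is.finite(lambda2) ||
      lambda1 <= 0 || lambda2 <= 0)
    stop("wavelengths must be positive finite scalars (nm)")
  2 / (1 / lambda1 + 1 / lambda2)
}

#' Total photon flux at the sample
#'
#' Photon fluxes of simultaneously applied excitation beams add
#' arithmetically; the sample experiences their sum regardless of the
#' individual wavelengths.
#'
#' @param fluxes Numeric vector of per-laser peak photon fluxes
#'   (photons cm^-2 s^-1), all nonnegative, at least one value.
#' @return The summed flux, same units.
#' @examples
#' total_photon_flux(c(2.34e28, 2.47e28))  # 4.81e28
#' @export
total_photon_flux <- function(fluxes) {
  fluxes <- as.numeric(fluxes)
  if (!length(fluxes)) stop("at least one flux value is required")
  if (anyNA(fluxes) || any(fluxes < 0))
    stop("fluxes must be nonnegative")
  sum(fluxes)
}
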