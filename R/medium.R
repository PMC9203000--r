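#' Tissue layer description
#'
#' Bundles the absorption side (chromophore concentrations) and the
#' scattering side (power law) of one layer of a turbid medium.
#'
#' @param total_hb Total hemoglobin, uM.
#' @param sat Hemoglobin oxygen saturation, fraction.
#' @param water,lipid Volume fractions.
#' @param musp830 Reduced scattering coefficient at 830 nm, 1/mm.
#' @param b Scattering power-law exponent.
#' @return Object of class `dos_layer`.
#' @export
tissue_layer <- function(total_hb, sat, water, lipid, musp830, b) {
  structure(list(
    chromophores = chromophores(total_hb, sat, water, lipid),
    scattering = scattering_law(musp830, b)
  ), class = "dos_layer")
}

#' @export
print.dos_layer <- function(x, ...) {
  print(x$chromophores)
  print(x$scattering)
  invisible(x)
}

#' Two-layer turbid medium
#'
#' A top layer of finite thickness over a semi-infinite bottom layer. The
#' 13 forward-model parameters are the four chromophore concentrations and
#' two scattering parameters per layer plus the top-layer thickness; the
#' refractive index is identical in both layers.
#'
#' @param top,bottom [tissue_layer()] objects.
#' @param z_top_mm Top-layer thickness, mm (> 0).
#' @param n Refractive index of both layers (default 1.4).
#' @return Object of class `dos_medium`.
#' @export
two_layer_medium <- function(top, bottom, z_top_mm = 5, n = 1.4) {
  stopifnot(inherits(top, "dos_layer"), inherits(bottom, "dos_layer"))
  if (!is.finite(z_top_mm) || z_top_mm <= 0) stop("z_top_mm must be > 0")
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  structure(list(top = top, bottom = bottom, z_top_mm = z_top_mm, n = n),
            class = "dos_medium")
}

#' @export
print.dos_medium <- function(x, ...) {
  cat("Two-layer turbid medium (n =", format(x$n), ")\n")
  cat(sprintf("  top (%.3g mm):    ", x$z_top_mm)); print(x$top$chromophores)
  cat("                    "); print(x$top$scattering)
  cat("  bottom (semi-inf): "); print(x$bottom$chromophores)
  cat("                    "); print(x$bottom$scattering)
  invisible(x)
}

#' Simulated instrument description
#'
#' Broadband continuous-wave (CW) grid plus a two-wavelength
#' frequency-domain (FD) channel, measured at two source-detector
#' distances. Defaults reproduce a dual-distance broadband tissue
#' spectrometer: CW 650-1024 nm in 0.5 nm steps (749 wavelengths), FD at
#' 690 and 830 nm modulated at 140.625 MHz, distances 25 and 35 mm,
#' assumed refractive index 1.4.
#'
#' @param cw_wavelengths CW wavelength grid, nm.
#' @param fd_wavelengths FD wavelength pair, nm.
#' @param distances Source-detector distance pair, mm.
#' @param mod_freq_hz FD modulation frequency, Hz.
#' @param n_assumed Refractive index assumed by the inversion.
#' @return Object of class `dos_instrument`.
#' @export
instrument_spec <- function(cw_wavelengths = seq(650, 1024, by = 0.5),
                            fd_wavelengths = c(690, 830),
                            distances = c(25, 35),
                            mod_freq_hz = 140.625e6,
                            n_assumed = 1.4) {
  stopifnot(length(fd_wavelengths) == 2, length(distances) == 2,
            all(distances > 0), mod_freq_hz > 0)
  structure(list(cw_wavelengths = as.numeric(cw_wavelengths),
                 fd_wavelengths = as.numeric(fd_wavelengths),
                 distances = as.numeric(distances),
                 mod_freq_hz = mod_freq_hz,
                 n_assumed = n_assumed),
            class = "dos_instrument")
}

#' @export
print.dos_instrument <- function(x, ...) {
  cat(sprintf(
    "DOS instrument: CW %d wavelengths (%.1f-%.1f nm), FD %g/%g nm @ %.4g MHz,\n  distances %g/%g mm, n = %g\n",
    length(x$cw_wavelengths), min(x$cw_wavelengths), max(x$cw_wavelengths),
    x$fd_wavelengths[1], x$fd_wavelengths[2], x$mod_freq_hz / 1e6,
    x$distances[1], x$distances[2], x$n_assumed))
  invisible(x)
}

# angular modulation frequency, rad/s
omega_of <- function(instrument) 2 * pi * instrument$mod_freq_hz

# per-layer optical property spectra on a wavelength grid
layer_optics <- function(layer, grid, extinction) {
  basis <- build_extinction_matrix(grid, extinction)
  list(mua = absorption_spectrum(layer$chromophores, basis),
       musp = reduced_scattering_spectrum(layer$scattering, grid))
}
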