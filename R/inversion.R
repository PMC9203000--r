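# Decode a trial effective attenuation into the (mua, musp) pair the
# homogeneous model needs. CW: musp is assumed known (extrapolated) and
# mua follows from mueff^2 = 3 mua (mua + musp). FD: the complex mueff
# determines both via its real/imaginary parts.
decode_mueff <- function(mueff, omega, n, musp = NULL) {
  if (omega == 0) {
    mua <- sqrt(musp^2 / 4 + mueff^2 / 3) - musp / 2
    list(mua = mua, musp = musp)
  } else {
    mut <- -2 * C_MM_S * Re(mueff) * Im(mueff) / (3 * n * omega)
    mua <- (Re(mueff)^2 - Im(mueff)^2) / (3 * mut)
    list(mua = mua, musp = mut - mua)
  }
}

# two-distance slope of the linearized reflectance ln(rho^2 R)
linearized_slope <- function(R1, R2, rho) {
  (log(R2 / R1) + 2 * log(rho[2] / rho[1])) / (rho[2] - rho[1])
}

#' Fit the effective attenuation coefficient from two-distance reflectance
#'
#' Iterative linear fit of the linearized reflectance `ln(rho^2 R)` versus
#' source-detector distance: the asymptotic two-distance slope provides the
#' initial estimate of the effective attenuation, which is then corrected
#' using the full semi-infinite homogeneous model (secant iteration on the
#' mismatch between measured and model slope) until convergence. For CW
#' data (`omega = 0`) the fit returns the real broadband effective
#' attenuation given an assumed reduced scattering; for FD data it returns
#' the complex effective attenuation, from which absorption and reduced
#' scattering follow via [fd_optical_properties()].
#'
#' @param R Reflectance at the two distances: a length-2 vector (or a
#'   2-column matrix for many wavelengths at once). Complex for FD.
#' @param distances The two source-detector distances, mm.
#' @param omega Angular modulation frequency, rad/s (0 for CW).
#' @param musp Assumed reduced scattering (1/mm), required for CW;
#'   recycled across wavelengths. Ignored for FD.
#' @param n Refractive index assumed by the model.
#' @param tol Relative convergence tolerance on the attenuation update.
#' @param max_iter Maximum number of secant iterations.
#' @return Effective attenuation (1/mm), one value per wavelength; complex
#'   when `omega > 0`.
#' @export
fit_effective_attenuation <- function(R, distances, omega = 0, musp = NULL,
                                      n = 1.4, tol = 1e-9, max_iter = 200) {
  if (is.matrix(R)) {
    R1 <- R[, 1]; R2 <- R[, 2]
  } else {
    stopifnot(length(R) == 2)
    R1 <- R[1]; R2 <- R[2]
  }
  stopifnot(length(distances) == 2, distances[1] != distances[2])
  if (omega == 0) {
    stopifnot(!is.null(musp), all(musp > 0), all(R1 > 0), all(R2 > 0))
    musp <- rep_len(musp, length(R1))
  } else if (any(R1 == 0 | R2 == 0)) {
    stop("FD reflectance phasors must be nonzero")
  }
  # order-independent: sort by distance
  if (distances[1] > distances[2]) {
    tmp <- R1; R1 <- R2; R2 <- tmp
    distances <- rev(distances)
  }
  m_meas <- linearized_slope(R1, R2, distances)

  model_slope <- function(mueff) {
    p <- decode_mueff(mueff, omega, n, musp)
    Rm1 <- homogeneous_reflectance(p$mua, p$musp, distances[1], n, omega)
    Rm2 <- homogeneous_reflectance(p$mua, p$musp, distances[2], n, omega)
    linearized_slope(Rm1, Rm2, distances)
  }

  x0 <- -m_meas
  g0 <- suppressWarnings(model_slope(x0)) - m_meas
  x1 <- x0 + g0          # first corrected estimate (slope derivative ~ -1)
  done <- abs(x1 - x0) <= tol * abs(x1)
  for (it in seq_len(max_iter)) {
    if (all(done)) break
    g1 <- suppressWarnings(model_slope(x1)) - m_meas
    step <- g1 * (x1 - x0) / (g1 - g0)
    step[done | !is.finite(step)] <- 0
    x0 <- x1; g0 <- g1
    x1 <- x1 - step
    done <- done | abs(step) <= tol * abs(x1)
  }
  if (!all(done))
    stop(sprintf(
      "effective-attenuation fit did not converge in %d iterations (last iterates %s, %s)",
      max_iter, format(x0[!done][1]), format(x1[!done][1])))
  x1
}

#' Optical properties from the complex FD effective attenuation
#'
#' Algebraic inversion of the complex effective attenuation measured at one
#' FD wavelength into absorption and reduced scattering:
#' `mut' = -2 c Re(mueff) Im(mueff) / (3 n omega)`,
#' `mua = (Re^2 - Im^2) / (3 mut')`, `musp = mut' - mua`.
#'
#' @param mueff Complex effective attenuation, 1/mm.
#' @param omega Angular modulation frequency, rad/s (> 0).
#' @param n Refractive index.
#' @return List with `mua`, `musp`, `mut` (all 1/mm).
#' @export
fd_optical_properties <- function(mueff, omega, n = 1.4) {
  stopifnot(omega > 0)
  if (any(Im(mueff) == 0))
    stop("degenerate FD input: Im(mueff) = 0 carries no phase information")
  p <- decode_mueff(mueff, omega, n)
  mut <- p$mua + p$musp
  if (any(mut <= 0) || any(p$musp <= 0) || any(p$mua < 0))
    stop(sprintf(
      "nonphysical FD recovery: mua = %s, musp = %s 1/mm",
      format(p$mua[1]), format(p$musp[1])))
  list(mua = p$mua, musp = p$musp, mut = mut)
}

#' Extrapolate reduced scattering across the CW band
#'
#' From reduced scattering recovered at the two FD wavelengths, computes
#' the recovered power-law exponent
#' `b = ln(musp(830)/musp(690)) / ln(690/830)` and evaluates the power law
#' anchored at 830 nm across a wavelength grid.
#'
#' @param musp690,musp830 Reduced scattering at 690 and 830 nm, 1/mm (> 0).
#' @param grid Wavelengths (nm) for the extrapolated spectrum.
#' @return List with `b` and `musp` (spectrum on `grid`).
#' @export
scattering_extrapolation <- function(musp690, musp830, grid) {
  if (musp690 <= 0 || musp830 <= 0) stop("reduced scattering must be > 0")
  b <- log(musp830 / musp690) / log(690 / 830)
  list(b = b,
       musp = reduced_scattering_spectrum(scattering_law(musp830, b), grid))
}

#' Broadband absorption from effective attenuation and reduced scattering
#'
#' Pointwise algebraic inversion
#' `mua = sqrt(musp^2/4 + mueff^2/3) - musp/2`, the exact inverse of
#' `mueff = sqrt(3 mua (mua + musp))`.
#'
#' @param mueff Real effective attenuation spectrum, 1/mm (>= 0).
#' @param musp Reduced scattering spectrum on the same grid, 1/mm (> 0).
#' @return Absorption spectrum, 1/mm.
#' @export
broadband_absorption <- function(mueff, musp) {
  stopifnot(length(mueff) == length(musp), all(musp > 0), all(mueff >= 0))
  sqrt(musp^2 / 4 + mueff^2 / 3) - musp / 2
}

#' Unmix chromophore concentrations from an absorption spectrum
#'
#' Unconstrained linear least-squares solution of `mua = E %*% c(O,D,W,L)`
#' via QR factorization of the (tall) basis matrix; oxy/deoxy are mapped
#' back to total hemoglobin `T = O + D` and saturation `S = O/T`. Recovered
#' values are reported as-is, never clipped to physical ranges.
#'
#' @param mua Absorption spectrum, 1/mm.
#' @param basis Basis matrix from [build_extinction_matrix()] on the same
#'   wavelength grid.
#' @return A [chromophores()] object (unvalidated, `sat = NA` when T = 0).
#' @export
unmix_chromophores <- function(mua, basis) {
  stopifnot(length(mua) == nrow(basis), ncol(basis) == 4)
  if (qr(basis)$rank < 4)
    stop("extinction basis is rank-deficient; cannot unmix four chromophores")
  x <- qr.solve(basis, mua)
  total <- x[1] + x[2]
  chromophores(total_hb = unname(total),
               sat = if (total == 0) NA_real_ else unname(x[1] / total),
               water = unname(x[3]), lipid = unname(x[4]),
               validate = FALSE)
}

#' Recover effective homogeneous properties from a reflectance set
#'
#' The full inverse pipeline applied to a simulated (or measured)
#' two-distance broadband data set, treating the medium as homogeneous:
#'
#' 1. fit the complex effective attenuation at each FD wavelength and
#'    convert it to absorption and reduced scattering
#'    ([fit_effective_attenuation()], [fd_optical_properties()]);
#' 2. extrapolate reduced scattering across the CW band through the
#'    recovered power law ([scattering_extrapolation()]);
#' 3. fit the real effective attenuation at every CW wavelength and
#'    convert to a broadband absorption spectrum
#'    ([broadband_absorption()]);
#' 4. unmix the four chromophores by unconstrained least squares
#'    ([unmix_chromophores()]).
#'
#' FD data enter only through the reduced scattering; absorption and
#' chromophores derive from the CW data alone.
#'
#' @param data A `dos_reflectance` from [simulate_instrument()].
#' @param extinction Extinction table for the unmixing basis.
#' @param scattering Optional list with elements `musp830` and `b`: when
#'   supplied, the FD stage is skipped and the reduced scattering spectrum
#'   is pinned to this power law (used by the sensitivity analysis, where
#'   scattering is fixed at its baseline recovered value).
#' @param tol,max_iter Convergence control for the attenuation fits.
#' @return Object of class `dos_fit` with the recovered scattering
#'   (`musp_fd`, `mua_fd`, `b`, `musp_cw`), the broadband spectra
#'   (`mueff_cw`, `mua_cw`), and the recovered `chromophores`.
#' @examples
#' \donttest{
#' med <- baseline_medium()
#' fit <- dos_fit(simulate_instrument(med))
#' coef(fit)
#' }
#' @export
dos_fit <- function(data, extinction = dos_extinction(), scattering = NULL,
                    tol = 1e-9, max_iter = 200) {
  stopifnot(inherits(data, "dos_reflectance"))
  ins <- data$instrument
  omega <- omega_of(ins)
  n <- ins$n_assumed

  if (is.null(scattering)) {
    mueff_fd <- fit_effective_attenuation(data$fd, ins$distances,
                                          omega = omega, n = n,
                                          tol = tol, max_iter = max_iter)
    fdp <- fd_optical_properties(mueff_fd, omega, n)
    names(fdp$mua) <- names(fdp$musp) <- format(ins$fd_wavelengths)
    i690 <- which(ins$fd_wavelengths == 690)
    i830 <- which(ins$fd_wavelengths == 830)
    stopifnot(length(i690) == 1, length(i830) == 1)
    ext_sc <- scattering_extrapolation(unname(fdp$musp[i690]),
                                       unname(fdp$musp[i830]),
                                       ins$cw_wavelengths)
    musp830 <- unname(fdp$musp[i830])
  } else {
    stopifnot(is.numeric(scattering$musp830), is.numeric(scattering$b))
    mueff_fd <- NULL
    fdp <- NULL
    musp830 <- scattering$musp830
    ext_sc <- list(
      b = scattering$b,
      musp = reduced_scattering_spectrum(
        scattering_law(scattering$musp830, scattering$b),
        ins$cw_wavelengths))
  }

  mueff_cw <- fit_effective_attenuation(data$cw, ins$distances, omega = 0,
                                        musp = ext_sc$musp, n = n,
                                        tol = tol, max_iter = max_iter)
  mua_cw <- broadband_absorption(mueff_cw, ext_sc$musp)
  basis <- build_extinction_matrix(ins$cw_wavelengths, extinction)
  conc <- unmix_chromophores(mua_cw, basis)

  structure(list(
    chromophores = conc,
    musp830 = musp830,
    b = ext_sc$b,
    mueff_fd = mueff_fd,
    mua_fd = fdp$mua,
    musp_fd = fdp$musp,
    musp_cw = ext_sc$musp,
    mueff_cw = mueff_cw,
    mua_cw = mua_cw,
    basis = basis,
    instrument = ins,
    scattering_pinned = !is.null(scattering)
  ), class = "dos_fit")
}

#' @export
print.dos_fit <- function(x, digits = 3, ...) {
  cat("Effective homogeneous properties (semi-infinite inverse model)\n")
  cat("  chromophores: "); print(x$chromophores)
  cat(sprintf("  scattering:   musp'(830 nm) = %.2f 1/mm, b = %.2g%s\n",
              x$musp830, x$b,
              if (x$scattering_pinned) " [pinned]" else ""))
  invisible(x)
}

#' @export
coef.dos_fit <- function(object, ...) {
  c(total_hb = object$chromophores$total_hb,
    sat = object$chromophores$sat,
    water = object$chromophores$water,
    lipid = object$chromophores$lipid,
    musp830 = object$musp830,
    b = object$b)
}

#' @export
fitted.dos_fit <- function(object, ...) {
  drop(object$basis %*% conc_vector(object$chromophores))
}

#' @export
residuals.dos_fit <- function(object, ...) {
  object$mua_cw - fitted(object)
}

#' Predicted absorption spectrum of the fitted chromophore mixture
#'
#' @param object A `dos_fit`.
#' @param wavelengths Wavelengths (nm); defaults to the CW grid.
#' @param extinction Extinction table for the basis.
#' @param ... Unused.
#' @return Absorption spectrum, 1/mm.
#' @export
predict.dos_fit <- function(object, wavelengths = NULL,
                            extinction = dos_extinction(), ...) {
  if (is.null(wavelengths)) return(fitted(object))
  basis <- build_extinction_matrix(wavelengths, extinction)
  drop(basis %*% conc_vector(object$chromophores))
}

#' @export
summary.dos_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 coef = coef(object),
                 rmse_mua = sqrt(mean(res^2)),
                 max_abs_resid = max(abs(res))),
            class = "summary.dos_fit")
}

#' @export
print.summary.dos_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  chromophore fit residuals: rmse = %.3g, max |.| = %.3g 1/mm\n",
              x$rmse_mua, x$max_abs_resid))
  invisible(x)
}

#' Plot the recovered absorption spectrum and chromophore fit
#'
#' @param x A `dos_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dos_fit <- function(x, ...) {
  wl <- x$instrument$cw_wavelengths
  graphics::plot(wl, x$mua_cw, type = "l", xlab = "wavelength (nm)",
                 ylab = "mua (1/mm)",
                 main = "Recovered broadband absorption", ...)
  graphics::lines(wl, fitted(x), col = 2, lty = 2)
  graphics::legend("topleft", c("recovered", "chromophore fit"),
                   col = c(1, 2), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Serialize a fit to a spectrum data frame
#'
#' @param x A `dos_fit`.
#' @param ... Unused.
#' @return Data frame with `wavelength_nm`, `musp_extrap`, `mueff`, `mua`.
#' @export
as.data.frame.dos_fit <- function(x, ...) {
  data.frame(wavelength_nm = x$instrument$cw_wavelengths,
             musp_extrap = x$musp_cw,
             mueff = x$mueff_cw,
             mua = x$mua_cw)
}
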