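# speed of light in vacuum, mm/s
C_MM_S <- 2.99792458e11

# effective reflection coefficient of the n = 1.4 tissue/air boundary;
# extrapolation length z_b = 2 D (1 + R_eff)/(1 - R_eff)
R_EFF_DEFAULT <- 0.493

extrapolation_length <- function(D, r_eff = R_EFF_DEFAULT) {
  2 * D * (1 + r_eff) / (1 - r_eff)
}

# complex absorption carrying the FD modulation; reduces to mua at omega = 0
complex_mua <- function(mua, omega, n) {
  if (identical(omega, 0) || all(omega == 0)) return(mua)
  mua - 1i * omega * n / C_MM_S
}

#' Semi-infinite homogeneous diffuse reflectance
#'
#' Diffusion-theory reflectance of a homogeneous semi-infinite medium with
#' the extrapolated-boundary condition: isotropic point source at depth
#' `z0 = 1/(mua + musp)`, zero-fluence plane at `-z_b` with
#' `z_b = 2 D (1 + R_eff)/(1 - R_eff)` and `R_eff = 0.493` for n = 1.4.
#' The measurand is the boundary flux `D * dphi/dz` at the surface, which
#' has the closed two-dipole form. With a nonzero angular modulation
#' frequency the absorption acquires the imaginary part `-i omega n / c`
#' and the returned reflectance is a complex phasor; at `omega = 0` it is
#' the real CW reflectance.
#'
#' @param mua Absorption coefficient(s), 1/mm (>= 0). Vectorized.
#' @param musp Reduced scattering coefficient(s), 1/mm (> 0).
#' @param rho Source-detector distance, mm (scalar, > 0).
#' @param n Refractive index.
#' @param omega Angular modulation frequency, rad/s (0 for CW).
#' @return Reflectance (1/mm^2); complex when `omega > 0`.
#' @export
homogeneous_reflectance <- function(mua, musp, rho, n = 1.4, omega = 0) {
  stopifnot(all(mua >= 0), all(musp > 0), length(rho) == 1, rho > 0)
  mut <- mua + musp
  if (any(rho < 1 / mut))
    warning("rho is inside one transport mean free path; ",
            "diffusion theory is unreliable here")
  D <- 1 / (3 * mut)
  z0 <- 1 / mut
  zb <- extrapolation_length(D)
  k <- sqrt(3 * mut * complex_mua(mua, omega, n))
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  (z0 * (k + 1 / r1) * exp(-k * r1) / r1^2 +
     (z0 + 2 * zb) * (k + 1 / r2) * exp(-k * r2) / r2^2) / (4 * pi)
}

# Gauss-Legendre nodes/weights on [0, 1] (order 6), mapped per panel
gl6 <- local({
  g <- pracma::gaussLegendre(6, 0, 1)
  list(x = g$x, w = g$w)
})

# Composite quadrature grid for the inverse Hankel transform: panels of
# width pi/rho (half a J0 oscillation) out to s_max.
hankel_grid <- function(rho, s_max, nodes_per_half = 6) {
  if (nodes_per_half == 6) {
    gx <- gl6$x; gw <- gl6$w
  } else {
    g <- pracma::gaussLegendre(nodes_per_half, 0, 1)
    gx <- g$x; gw <- g$w
  }
  h <- pi / rho
  n_panel <- ceiling(s_max / h)
  starts <- (seq_len(n_panel) - 1) * h
  s <- rep(starts, each = nodes_per_half) + rep(gx, n_panel) * h
  w <- rep(gw, n_panel) * h
  list(s = s, w = w)
}

# Hankel-space surface flux D1 * dphi/dz|_{z=0} of the two-layer medium.
# Stable exponential forms; source either in the top layer (z0 <= l) or,
# for thin tops, in the bottom layer at the depth where cumulative
# transport depth reaches one (z0 continuous across the crossover).
# s: vector of spatial frequencies; layer properties: vectors over
# wavelength (possibly complex mua). Returns matrix [s x wavelength].
tl_flux_kernel <- function(s, mua1c, mut1, mua2c, mut2, l, zb) {
  D1 <- 1 / (3 * mut1)
  D2 <- 1 / (3 * mut2)
  k1sq <- 3 * mut1 * mua1c
  k2sq <- 3 * mut2 * mua2c
  s2 <- s^2
  a1 <- sqrt(outer(s2, k1sq, `+`))
  a2 <- sqrt(outer(s2, k2sq, `+`))
  D1a1 <- sweep(a1, 2, D1, `*`)
  D2a2 <- sweep(a2, 2, D2, `*`)
  bycol <- function(v) matrix(v, nrow = length(s), ncol = length(v),
                              byrow = TRUE)
  zbm <- bycol(zb)
  E_lb <- exp(-2 * a1 * (l + zbm))
  den <- D1a1 * (1 + E_lb) + D2a2 * (1 - E_lb)

  z0_top <- 1 / mut1
  deep <- z0_top > l   # source falls below the interface
  z0 <- ifelse(deep, l + (1 - l * mut1) / mut2, z0_top)
  z0m <- bycol(z0)

  F <- a1 # placeholder, overwritten below (keeps complex type)
  if (any(!deep)) {
    j <- which(!deep)
    a1j <- a1[, j, drop = FALSE]
    z0j <- z0m[, j, drop = FALSE]
    zbj <- zbm[, j, drop = FALSE]
    denj <- den[, j, drop = FALSE]
    # source in the top layer
    t1 <- (exp(-a1j * (2 * l - z0j)) + exp(-a1j * (2 * l + 2 * zbj - z0j))) *
      (D1a1[, j, drop = FALSE] - D2a2[, j, drop = FALSE]) / denj / 2
    H <- (D1a1[, j, drop = FALSE] * (1 - exp(-2 * a1j * l)) +
          D2a2[, j, drop = FALSE] * (1 + exp(-2 * a1j * l))) / denj
    F[, j] <- t1 + exp(-a1j * z0j) / 2 +
      exp(-a1j * (z0j + 2 * zbj)) * H / 2
  }
  if (any(deep)) {
    j <- which(deep)
    a1j <- a1[, j, drop = FALSE]
    # source in the bottom layer
    F[, j] <- D1a1[, j, drop = FALSE] *
      (1 + exp(-2 * a1j * zbm[, j, drop = FALSE])) *
      exp(-a1j * l - a2[, j, drop = FALSE] *
            (z0m[, j, drop = FALSE] - l)) /
      den[, j, drop = FALSE]
  }
  F
}

# Two-layer reflectance from per-layer property spectra (internal engine).
# Returns a vector over wavelengths for one rho.
tl_reflectance_engine <- function(mua1, musp1, mua2, musp2, l, n, rho,
                                  omega = 0, nodes_per_half = 8,
                                  s_decay = 40) {
  mut1 <- Re(mua1) + musp1
  mut2 <- Re(mua2) + musp2
  D1 <- 1 / (3 * mut1)
  zb <- extrapolation_length(D1)
  # F(s) decays like exp(-s * z0); truncate where it is ~exp(-s_decay)
  z0_top <- 1 / mut1
  z0 <- ifelse(z0_top > l, l + (1 - l * mut1) / mut2, z0_top)
  s_max <- s_decay / min(z0)
  g <- hankel_grid(rho, s_max, nodes_per_half)
  mua1c <- complex_mua(mua1, omega, n)
  mua2c <- complex_mua(mua2, omega, n)
  F <- tl_flux_kernel(g$s, mua1c, mut1, mua2c, mut2, l, zb)
  v <- g$w * besselJ(g$s * rho, 0) * g$s
  colSums(F * v) / (2 * pi)
}

#' Two-layer diffuse reflectance
#'
#' Reflectance of a two-layer turbid medium from diffusion theory: the
#' layered Green's function is assembled in the spatial-frequency domain
#' (order-zero Hankel transform of the boundary flux, with the same
#' extrapolated-boundary treatment and measurand as
#' [homogeneous_reflectance()]) and inverted numerically by composite
#' Gauss-Legendre quadrature resolved against the Bessel oscillation.
#' When the two layers share identical properties the result matches the
#' homogeneous closed form to quadrature accuracy.
#'
#' @param medium A [two_layer_medium()].
#' @param wavelengths Wavelengths, nm.
#' @param rho Source-detector distance, mm (scalar).
#' @param omega Angular modulation frequency, rad/s (0 for CW).
#' @param extinction Extinction table used to build per-layer spectra.
#' @param nodes_per_half Quadrature nodes per half Bessel period.
#' @param s_decay Dimensionless truncation depth of the spatial-frequency
#'   integral (upper limit `s_decay / z0`).
#' @param check_convergence If `TRUE`, re-evaluate with doubled node
#'   density and error if the relative change exceeds `conv_tol`.
#' @param conv_tol Convergence tolerance for the optional check.
#' @return Reflectance vector over `wavelengths` (complex if `omega > 0`).
#' @export
two_layer_reflectance <- function(medium, wavelengths, rho, omega = 0,
                                  extinction = dos_extinction(),
                                  nodes_per_half = 8, s_decay = 40,
                                  check_convergence = FALSE,
                                  conv_tol = 1e-6) {
  stopifnot(inherits(medium, "dos_medium"), length(rho) == 1, rho > 0)
  top <- layer_optics(medium$top, wavelengths, extinction)
  bot <- layer_optics(medium$bottom, wavelengths, extinction)
  val <- tl_reflectance_engine(top$mua, top$musp, bot$mua, bot$musp,
                               medium$z_top_mm, medium$n, rho, omega,
                               nodes_per_half, s_decay)
  if (check_convergence) {
    ref <- tl_reflectance_engine(top$mua, top$musp, bot$mua, bot$musp,
                                 medium$z_top_mm, medium$n, rho, omega,
                                 2 * nodes_per_half, 2 * s_decay)
    err <- max(abs(val - ref) / abs(ref))
    if (err > conv_tol)
      stop(sprintf(
        "Hankel quadrature not converged: achieved %.3g, requested %.3g",
        err, conv_tol))
  }
  val
}

#' Simulate the broadband CW + FD instrument on a two-layer medium
#'
#' Evaluates the two-layer forward model on the full instrument grid:
#' real CW reflectance at every CW wavelength and distance (omega = 0) and
#' complex FD reflectance phasors at the FD wavelengths and distances.
#'
#' @param medium A [two_layer_medium()].
#' @param instrument An [instrument_spec()].
#' @param extinction Extinction table.
#' @param ... Passed to [two_layer_reflectance()] (quadrature control).
#' @return Object of class `dos_reflectance`: list with `cw`
#'   (wavelength x distance matrix), `fd` (complex wavelength x distance
#'   matrix), and the `instrument` used.
#' @export
simulate_instrument <- function(medium, instrument = instrument_spec(),
                                extinction = dos_extinction(), ...) {
  stopifnot(inherits(medium, "dos_medium"),
            inherits(instrument, "dos_instrument"))
  omega <- omega_of(instrument)
  cw <- sapply(instrument$distances, function(r)
    Re(two_layer_reflectance(medium, instrument$cw_wavelengths, r,
                             omega = 0, extinction = extinction, ...)))
  fd <- sapply(instrument$distances, function(r)
    two_layer_reflectance(medium, instrument$fd_wavelengths, r,
                          omega = omega, extinction = extinction, ...))
  dimnames(cw) <- list(format(instrument$cw_wavelengths, trim = TRUE),
                       format(instrument$distances, trim = TRUE))
  dimnames(fd) <- list(format(instrument$fd_wavelengths, trim = TRUE),
                       format(instrument$distances, trim = TRUE))
  structure(list(cw = cw, fd = fd, instrument = instrument),
            class = "dos_reflectance")
}

#' @export
print.dos_reflectance <- function(x, ...) {
  cat(sprintf(
    "Simulated reflectance set: CW %d x %d, FD %d x %d (distances %s mm)\n",
    nrow(x$cw), ncol(x$cw), nrow(x$fd), ncol(x$fd),
    paste(x$instrument$distances, collapse = "/")))
  invisible(x)
}

#' Simulate reflectance data from a two-layer medium
#'
#' `simulate()` method for [two_layer_medium()] objects; the study is
#' noise-free so `nsim`/`seed` only replicate the deterministic output.
#'
#' @param object A `dos_medium`.
#' @param nsim Number of (identical, noise-free) replicates.
#' @param seed Ignored (kept for the generic's signature).
#' @param instrument,extinction,... Passed to [simulate_instrument()].
#' @return A `dos_reflectance` (or a list of them when `nsim > 1`).
#' @export
simulate.dos_medium <- function(object, nsim = 1, seed = NULL,
                                instrument = instrument_spec(),
                                extinction = dos_extinction(), ...) {
  one <- simulate_instrument(object, instrument, extinction, ...)
  if (nsim == 1) one else replicate(nsim, one, simplify = FALSE)
}

#' Long-format data frame of a simulated reflectance set
#'
#' @param x A `dos_reflectance`.
#' @param ... Unused.
#' @return Data frame with columns `wavelength_nm`, `rho_mm`, `domain`
#'   (`cw`/`fd`), `value_real`, `value_imag`.
#' @export
as.data.frame.dos_reflectance <- function(x, ...) {
  ins <- x$instrument
  cw <- data.frame(
    wavelength_nm = rep(ins$cw_wavelengths, times = 2),
    rho_mm = rep(ins$distances, each = length(ins$cw_wavelengths)),
    domain = "cw",
    value_real = as.vector(x$cw),
    value_imag = 0)
  fd <- data.frame(
    wavelength_nm = rep(ins$fd_wavelengths, times = 2),
    rho_mm = rep(ins$distances, each = length(ins$fd_wavelengths)),
    domain = "fd",
    value_real = as.vector(Re(x$fd)),
    value_imag = as.vector(Im(x$fd)))
  rbind(cw, fd)
}
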