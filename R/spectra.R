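#' Load a chromophore extinction table
#'
#' Reads the bundled (or user-supplied) specific-absorption spectra of the
#' four near-infrared tissue chromophores -- oxyhemoglobin, deoxyhemoglobin,
#' water, and lipid -- and converts them to the working units used
#' throughout the package: natural-log absorption per mm, per micromolar
#' for the hemoglobins and at unit volume fraction for water and lipid.
#'
#' Hemoglobin input tables are decadic molar extinction coefficients in
#' 1/(cm*M) and are converted once at load time by the factor
#' `log(10) * 1e-7`; the water table is in 1/cm (factor 0.1); the lipid
#' table is already in 1/mm.
#'
#' @param hemoglobin,water,lipid Paths to whitespace-delimited tables with a
#'   `#` comment header. Defaults to the tables bundled with the package.
#' @return An object of class `dos_extinction`: a list with components
#'   `wavelengths` (nm, strictly increasing), `eps_O`, `eps_D`
#'   (1/mm per uM), `mua_W`, `mua_L` (1/mm at unit volume fraction).
#' @examples
#' ext <- dos_extinction()
#' range(ext$wavelengths)
#' @export
dos_extinction <- function(hemoglobin = NULL, water = NULL, lipid = NULL) {
  pkg_file <- function(f) system.file("extdata", f, package = "tldos",
                                      mustWork = TRUE)
  if (is.null(hemoglobin)) hemoglobin <- pkg_file("hemoglobin_extinction.tsv")
  if (is.null(water)) water <- pkg_file("water_absorption.tsv")
  if (is.null(lipid)) lipid <- pkg_file("lipid_absorption.tsv")

  hb <- utils::read.table(hemoglobin, header = TRUE, comment.char = "#")
  wa <- utils::read.table(water, header = TRUE, comment.char = "#")
  li <- utils::read.table(lipid, header = TRUE, comment.char = "#")

  wl <- hb$wavelength_nm
  lo <- max(min(wl), min(wa$wavelength_nm), min(li$wavelength_nm))
  hi <- min(max(wl), max(wa$wavelength_nm), max(li$wavelength_nm))
  grid <- wl[wl >= lo & wl <= hi]

  interp <- function(x, y, at) stats::approx(x, y, xout = at)$y
  # decadic 1/(cm*M) -> natural 1/(mm*uM)
  hb_scale <- log(10) * 1e-7
  out <- structure(list(
    wavelengths = grid,
    eps_O = interp(wl, hb$eps_HbO2, grid) * hb_scale,
    eps_D = interp(wl, hb$eps_Hb, grid) * hb_scale,
    mua_W = interp(wa$wavelength_nm, wa$mua_water, grid) * 0.1,
    mua_L = interp(li$wavelength_nm, li$mua_lipid, grid)
  ), class = "dos_extinction")
  validate_extinction(out)
  out
}

validate_extinction <- function(x) {
  stopifnot(inherits(x, "dos_extinction"))
  if (any(diff(x$wavelengths) <= 0))
    stop("extinction table wavelengths must be strictly increasing")
  for (f in c("eps_O", "eps_D", "mua_W", "mua_L")) {
    v <- x[[f]]
    if (length(v) != length(x$wavelengths) || any(!is.finite(v)) || any(v < 0))
      stop("extinction table column '", f, "' must be finite and >= 0")
  }
  invisible(x)
}

#' @export
print.dos_extinction <- function(x, ...) {
  cat("Chromophore extinction table\n")
  cat(sprintf("  wavelengths: %.1f-%.1f nm (%d knots)\n",
              min(x$wavelengths), max(x$wavelengths), length(x$wavelengths)))
  cat("  columns: eps_O, eps_D [1/mm/uM]; mua_W, mua_L [1/mm]\n")
  invisible(x)
}

#' Assemble the chromophore basis matrix
#'
#' Interpolates the extinction table onto a wavelength grid and returns the
#' basis matrix `E` of the linear absorption model `mua = E %*% c(O, D, W, L)`,
#' one row per wavelength and columns ordered oxyhemoglobin,
#' deoxyhemoglobin, water, lipid. Interpolation is linear in wavelength.
#'
#' @param grid Wavelengths (nm) at which to evaluate the basis.
#' @param table An extinction table from [dos_extinction()].
#' @return Numeric matrix, `length(grid)` x 4, columns `O`, `D`, `W`, `L`.
#' @export
build_extinction_matrix <- function(grid, table = dos_extinction()) {
  validate_extinction(table)
  wl <- table$wavelengths
  bad <- grid < min(wl) | grid > max(wl)
  if (any(bad))
    stop(sprintf(
      "wavelength(s) outside extinction table range [%.1f, %.1f] nm: %s",
      min(wl), max(wl), paste(utils::head(grid[bad], 5), collapse = ", ")))
  E <- cbind(
    O = stats::approx(wl, table$eps_O, xout = grid)$y,
    D = stats::approx(wl, table$eps_D, xout = grid)$y,
    W = stats::approx(wl, table$mua_W, xout = grid)$y,
    L = stats::approx(wl, table$mua_L, xout = grid)$y
  )
  rownames(E) <- format(grid, trim = TRUE)
  attr(E, "wavelengths") <- as.numeric(grid)
  E
}

#' Chromophore concentrations
#'
#' Container for the absorption side of a tissue layer: total hemoglobin
#' `T = O + D` (uM), hemoglobin oxygen saturation `S = O/T` (fraction),
#' and water and lipid volume fractions. Forward-model (actual) inputs must
#' satisfy the physical ranges; recovered concentrations from the
#' unconstrained linear inversion are exempt and may fall outside them.
#'
#' @param total_hb Total hemoglobin concentration, uM.
#' @param sat Hemoglobin oxygen saturation, fraction in `[0, 1]`.
#' @param water,lipid Volume fractions in `[0, 1]`.
#' @param validate Enforce the forward-model range invariants.
#' @return Object of class `dos_chromophores`.
#' @export
chromophores <- function(total_hb, sat, water, lipid, validate = TRUE) {
  x <- structure(list(total_hb = total_hb, sat = sat,
                      water = water, lipid = lipid),
                 class = "dos_chromophores")
  if (validate) {
    if (!is.finite(total_hb) || total_hb < 0) stop("total_hb must be >= 0")
    for (f in c("sat", "water", "lipid")) {
      v <- x[[f]]
      if (!is.finite(v) && !is.na(v) || (!is.na(v) && (v < 0 || v > 1)))
        stop("'", f, "' must be a fraction in [0, 1]")
    }
  }
  x
}

#' @export
print.dos_chromophores <- function(x, ...) {
  cat(sprintf("T = %.4g uM, S = %.4g%%, W = %.4g%%, L = %.4g%%\n",
              x$total_hb, 100 * x$sat, 100 * x$water, 100 * x$lipid))
  invisible(x)
}

# (O, D, W, L) concentration vector matching the basis column order
conc_vector <- function(c) {
  c(c$sat * c$total_hb, (1 - c$sat) * c$total_hb, c$water, c$lipid)
}

#' Absorption spectrum of a chromophore mixture
#'
#' Evaluates `mua(lambda) = eps_O*S*T + eps_D*(1-S)*T + mua_W*W + mua_L*L`
#' on the wavelength grid of a prebuilt basis matrix.
#'
#' @param conc A [chromophores()] object.
#' @param basis Basis matrix from [build_extinction_matrix()].
#' @return Numeric vector of absorption coefficients, 1/mm.
#' @export
absorption_spectrum <- function(conc, basis) {
  stopifnot(inherits(conc, "dos_chromophores"), ncol(basis) == 4)
  drop(basis %*% conc_vector(conc))
}

#' Scattering power law
#'
#' @param musp830 Reduced scattering coefficient at 830 nm, 1/mm (> 0).
#' @param b Scattering power-law exponent (dimensionless).
#' @return Object of class `dos_scattering`.
#' @export
scattering_law <- function(musp830, b) {
  if (!is.finite(musp830) || musp830 <= 0) stop("musp830 must be > 0")
  structure(list(musp830 = musp830, b = b), class = "dos_scattering")
}

#' @export
print.dos_scattering <- function(x, ...) {
  cat(sprintf("musp'(830 nm) = %.4g 1/mm, b = %.4g\n", x$musp830, x$b))
  invisible(x)
}

#' Reduced scattering spectrum from the power law
#'
#' Evaluates `musp(lambda) = musp830 * (lambda / 830)^(-b)` exactly.
#'
#' @param law A [scattering_law()] object.
#' @param grid Wavelengths, nm (> 0).
#' @return Numeric vector of reduced scattering coefficients, 1/mm.
#' @export
reduced_scattering_spectrum <- function(law, grid) {
  stopifnot(inherits(law, "dos_scattering"))
  if (any(grid <= 0)) stop("wavelengths must be > 0")
  law$musp830 * (grid / 830)^(-law$b)
}
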