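#' Baseline two-layer study medium
#'
#' The reference medium of the simulation study: a lipid-rich, weakly
#' absorbing 5 mm top layer (adipose-like: T = 12 uM, S = 83%, W = 5%,
#' L = 70%, musp'(830) = 0.60 1/mm, b = 0.1) over a blood- and water-rich
#' semi-infinite bottom layer (muscle-like: T = 120 uM, S = 67%, W = 90%,
#' L = 20%, musp'(830) = 0.40 1/mm, b = 1.5), refractive index 1.4.
#'
#' @param z_top_mm Top-layer thickness, mm.
#' @return A [two_layer_medium()].
#' @export
baseline_medium <- function(z_top_mm = 5) {
  two_layer_medium(
    top = tissue_layer(total_hb = 12, sat = 0.83, water = 0.05,
                       lipid = 0.70, musp830 = 0.60, b = 0.1),
    bottom = tissue_layer(total_hb = 120, sat = 0.67, water = 0.90,
                          lipid = 0.20, musp830 = 0.40, b = 1.5),
    z_top_mm = z_top_mm, n = 1.4)
}

mua_at <- function(layer, wavelengths, extinction) {
  absorption_spectrum(layer$chromophores,
                      build_extinction_matrix(wavelengths, extinction))
}

#' Baseline study: actual vs recovered tables and sensitivities
#'
#' Runs the complete baseline analysis: simulates the instrument on the
#' baseline medium, recovers effective homogeneous properties, and
#' computes the full 8 x 4 sensitivity matrix. Returns the four summary
#' tables of the study (absorption parameters, scattering parameters,
#' co-sensitivities, full sensitivities) and writes them as CSV when an
#' output directory is given.
#'
#' @param medium Baseline medium (defaults to [baseline_medium()]).
#' @param instrument,extinction Shared study configuration.
#' @param out_dir Optional directory for CSV output.
#' @param sensitivities Compute the sensitivity tables (17 pipeline runs);
#'   set `FALSE` for the absorption/scattering tables only.
#' @return List with data frames `absorption`, `scattering`,
#'   `co_sensitivity`, `sensitivity`, plus the baseline `fit` and
#'   `sensitivity_matrix` objects.
#' @export
baseline_study <- function(medium = baseline_medium(),
                           instrument = instrument_spec(),
                           extinction = dos_extinction(),
                           out_dir = NULL,
                           sensitivities = TRUE) {
  data <- simulate_instrument(medium, instrument, extinction)
  fit <- dos_fit(data, extinction)
  mua_wl <- c(650, 775, 900, 1024)

  row_of <- function(cc, mua) {
    data.frame(total_hb_uM = cc$total_hb, sat_pct = 100 * cc$sat,
               water_pct = 100 * cc$water, lipid_pct = 100 * cc$lipid,
               mua_650 = mua[1], mua_775 = mua[2], mua_900 = mua[3],
               mua_1024 = mua[4])
  }
  absorption <- rbind(
    top_actual = row_of(medium$top$chromophores,
                        mua_at(medium$top, mua_wl, extinction)),
    bottom_actual = row_of(medium$bottom$chromophores,
                           mua_at(medium$bottom, mua_wl, extinction)),
    recovered = row_of(fit$chromophores,
                       fit$mua_cw[match(mua_wl, instrument$cw_wavelengths)]))

  musp690 <- function(law) reduced_scattering_spectrum(law, 690)
  scattering <- rbind(
    top_actual = data.frame(musp830 = medium$top$scattering$musp830,
                            b = medium$top$scattering$b,
                            musp690 = musp690(medium$top$scattering)),
    bottom_actual = data.frame(musp830 = medium$bottom$scattering$musp830,
                               b = medium$bottom$scattering$b,
                               musp690 = musp690(medium$bottom$scattering)),
    recovered = data.frame(musp830 = fit$musp830, b = fit$b,
                           musp690 = unname(fit$musp_fd[1])))

  sens <- NULL; co <- NULL; sens_df <- NULL; co_df <- NULL
  if (sensitivities) {
    sens <- sensitivity_matrix(medium, instrument = instrument,
                               extinction = extinction, baseline_fit = fit)
    co <- co_sensitivities(sens)
    co_df <- data.frame(layer = rownames(co), co, row.names = NULL,
                        check.names = FALSE)
    sens_df <- as.data.frame(sens)
  }

  out <- list(absorption = absorption, scattering = scattering,
              co_sensitivity = co_df, sensitivity = sens_df,
              fit = fit, sensitivity_matrix = sens)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(absorption,
                     file.path(out_dir, "baseline_absorption.csv"))
    utils::write.csv(scattering,
                     file.path(out_dir, "baseline_scattering.csv"))
    if (sensitivities) {
      utils::write.csv(co_df,
                       file.path(out_dir, "baseline_co_sensitivity.csv"),
                       row.names = FALSE)
      utils::write.csv(sens_df,
                       file.path(out_dir, "baseline_sensitivity.csv"),
                       row.names = FALSE)
    }
  }
  out
}

# the 13 sweepable medium parameters
sweep_target <- function(medium, parameter, layer, value) {
  if (parameter == "z_top")
    return(two_layer_medium(medium$top, medium$bottom, z_top_mm = value,
                            n = medium$n))
  stopifnot(layer %in% c("top", "bottom"))
  if (parameter %in% SENS_PARAMS) {
    cc <- medium[[layer]]$chromophores
    cc[[parameter]] <- value
    medium[[layer]]$chromophores <-
      chromophores(cc$total_hb, cc$sat, cc$water, cc$lipid)
  } else if (parameter %in% c("musp830", "b")) {
    sc <- medium[[layer]]$scattering
    sc[[parameter]] <- value
    medium[[layer]]$scattering <- scattering_law(sc$musp830, sc$b)
  } else {
    stop("unknown sweep parameter: ", parameter)
  }
  medium
}

default_sweep_values <- function(medium, parameter, layer, n_points = 15) {
  if (parameter == "z_top") return(seq(1, 15, length.out = n_points))
  if (parameter %in% c("sat", "water", "lipid"))
    return(seq(0, 1, length.out = n_points))
  if (parameter == "b") return(seq(0, 2.5, length.out = n_points))
  base <- if (parameter == "total_hb")
    medium[[layer]]$chromophores$total_hb
  else medium[[layer]]$scattering$musp830
  seq(0.2 * base, 1.8 * base, length.out = n_points)
}

#' One-parameter sweep of absolute recovery
#'
#' Varies a single medium parameter over a grid (all other parameters held
#' at the baseline) and records the recovered effective homogeneous
#' parameters at each grid point, mirroring the study's
#' recovered-versus-actual curves. Per-point failures are recorded as `NA`
#' rows and the sweep continues.
#'
#' @param parameter One of `"total_hb"`, `"sat"`, `"water"`, `"lipid"`,
#'   `"musp830"`, `"b"` (with `layer`), or `"z_top"`.
#' @param layer `"top"` or `"bottom"` (ignored for `"z_top"`).
#' @param values Grid of parameter values; defaults to 15 points spanning
#'   the physical range (fractions, b) or +/-80% of baseline
#'   (concentrations, scattering amplitude), 1-15 mm for thickness.
#' @param baseline Baseline medium.
#' @param instrument,extinction Shared study configuration.
#' @return Data frame with the varied `value`, recovered `total_hb`,
#'   `sat`, `water`, `lipid`, `musp830`, `b`, `musp690`, and the actual
#'   top/bottom values of the varied parameter (reference lines).
#' @export
absolute_sweep <- function(parameter, layer = NULL, values = NULL,
                           baseline = baseline_medium(),
                           instrument = instrument_spec(),
                           extinction = dos_extinction()) {
  if (is.null(values))
    values <- default_sweep_values(baseline, parameter, layer)
  rows <- lapply(values, function(v) {
    res <- try({
      med <- sweep_target(baseline, parameter, layer, v)
      fit <- dos_fit(simulate_instrument(med, instrument, extinction),
                     extinction)
      data.frame(value = v, total_hb = fit$chromophores$total_hb,
                 sat = fit$chromophores$sat,
                 water = fit$chromophores$water,
                 lipid = fit$chromophores$lipid,
                 musp830 = fit$musp830, b = fit$b,
                 musp690 = unname(fit$musp_fd[1]))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      data.frame(value = v, total_hb = NA, sat = NA, water = NA,
                 lipid = NA, musp830 = NA, b = NA, musp690 = NA)
    else res
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "layer") <- layer
  attr(out, "baseline") <- baseline
  out
}

#' One-parameter sweep of co-sensitivities
#'
#' Recomputes the eight co-sensitivities (like-parameter dynamic
#' sensitivities, top and bottom) at each point of a one-parameter sweep
#' of the baseline medium, quantifying how the dynamic-sensitivity
#' structure depends on the absolute values of the layer parameters.
#'
#' @inheritParams absolute_sweep
#' @return Data frame with `value` and the eight co-sensitivities
#'   (`total_hb_top`, ..., `lipid_bottom`).
#' @export
sensitivity_sweep <- function(parameter, layer = NULL, values = NULL,
                              baseline = baseline_medium(),
                              instrument = instrument_spec(),
                              extinction = dos_extinction()) {
  if (is.null(values))
    values <- default_sweep_values(baseline, parameter, layer)
  rows <- lapply(values, function(v) {
    res <- try({
      med <- sweep_target(baseline, parameter, layer, v)
      S <- sensitivity_matrix(med, instrument = instrument,
                              extinction = extinction)
      co <- co_sensitivities(S)
      data.frame(value = v,
                 total_hb_top = co["top", "total_hb"],
                 sat_top = co["top", "sat"],
                 water_top = co["top", "water"],
                 lipid_top = co["top", "lipid"],
                 total_hb_bottom = co["bottom", "total_hb"],
                 sat_bottom = co["bottom", "sat"],
                 water_bottom = co["bottom", "water"],
                 lipid_bottom = co["bottom", "lipid"])
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      na <- as.data.frame(as.list(stats::setNames(rep(NA_real_, 8),
        c("total_hb_top", "sat_top", "water_top", "lipid_top",
          "total_hb_bottom", "sat_bottom", "water_bottom",
          "lipid_bottom"))))
      cbind(data.frame(value = v), na)
    } else res
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "layer") <- layer
  attr(out, "baseline") <- baseline
  out
}
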