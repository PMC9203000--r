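# the eight absorption parameters of the sensitivity analysis
SENS_PARAMS <- c("total_hb", "sat", "water", "lipid")

# modify one absorption parameter of one layer
perturb_medium <- function(medium, parameter, layer, delta) {
  stopifnot(parameter %in% SENS_PARAMS, layer %in% c("top", "bottom"))
  m <- medium
  cc <- m[[layer]]$chromophores
  cc[[parameter]] <- cc[[parameter]] + delta
  m[[layer]]$chromophores <- chromophores(cc$total_hb, cc$sat, cc$water,
                                          cc$lipid, validate = FALSE)
  m
}

param_valid <- function(medium, parameter, layer) {
  v <- medium[[layer]]$chromophores[[parameter]]
  if (parameter == "total_hb") v >= 0 else v >= 0 && v <= 1
}

#' Recover chromophores from a perturbed medium with scattering pinned
#'
#' Re-simulates the CW data for a medium in which one absorption parameter
#' of one layer is changed by a small step, and re-inverts it with the
#' reduced scattering (and its power-law exponent) pinned to the baseline
#' recovered values: only CW data are re-simulated, mimicking an
#' experiment in which a single FD calibration precedes CW monitoring of
#' absorption dynamics. If the step would push the parameter outside its
#' physical range its sign is reversed (with a message).
#'
#' @param baseline A [two_layer_medium()].
#' @param parameter One of `"total_hb"`, `"sat"`, `"water"`, `"lipid"`.
#' @param layer `"top"` or `"bottom"`.
#' @param step Signed perturbation (uM for `total_hb`, absolute fraction
#'   otherwise); must be nonzero.
#' @param baseline_fit `dos_fit` of the unperturbed medium (supplies the
#'   pinned scattering).
#' @param instrument,extinction Shared study configuration.
#' @return List with the recovered `chromophores`, the `step` actually
#'   used, and the perturbed `fit`.
#' @export
perturbed_recovery <- function(baseline, parameter, layer, step,
                               baseline_fit,
                               instrument = instrument_spec(),
                               extinction = dos_extinction()) {
  stopifnot(step != 0, inherits(baseline_fit, "dos_fit"))
  pert <- perturb_medium(baseline, parameter, layer, step)
  if (!param_valid(pert, parameter, layer)) {
    message("perturbation of ", parameter, " (", layer,
            ") leaves the physical range; reversing step sign")
    step <- -step
    pert <- perturb_medium(baseline, parameter, layer, step)
    if (!param_valid(pert, parameter, layer))
      stop("no valid perturbation of ", parameter, " (", layer, ")")
  }
  cw <- sapply(instrument$distances, function(r)
    Re(two_layer_reflectance(pert, instrument$cw_wavelengths, r,
                             omega = 0, extinction = extinction)))
  # FD data are not re-simulated: scattering is pinned below
  data <- structure(list(cw = cw, fd = NULL, instrument = instrument),
                    class = "dos_reflectance")
  fit <- dos_fit(data, extinction,
                 scattering = list(musp830 = baseline_fit$musp830,
                                   b = baseline_fit$b))
  list(chromophores = fit$chromophores, step = step, fit = fit)
}

#' Sensitivity matrix of recovered to actual layer absorption parameters
#'
#' Central finite differences of the four recovered chromophore parameters
#' with respect to each of the eight layer absorption parameters (four per
#' layer), all evaluated at a baseline medium with reduced scattering
#' pinned to its baseline recovered value. Diagonal entries of the two
#' layer blocks are co-sensitivities (like parameter over like parameter);
#' off-diagonal entries are cross-sensitivities, i.e. cross-talk between
#' chromophores. Entries between unlike units carry the ratio's units
#' (e.g. per-uM for a saturation response to total hemoglobin).
#'
#' Default steps: +/-0.5% relative for total hemoglobin and +/-0.5
#' absolute percentage points for saturation, water, and lipid -- inside
#' the linear regime but far above solver tolerance. One-sided differences
#' are used automatically at physical-range boundaries.
#'
#' @param baseline A [two_layer_medium()].
#' @param steps Named list of absolute step sizes for `total_hb` (uM,
#'   `NULL` means 0.5% of the layer value), `sat`, `water`, `lipid`.
#' @param instrument,extinction Shared study configuration.
#' @param baseline_fit Optional precomputed baseline `dos_fit`.
#' @return Object of class `dos_sensitivity`: an 8 x 4 matrix (rows:
#'   parameter x layer; columns: recovered T, S, W, L) with attributes
#'   `steps` and `baseline_fit`.
#' @export
sensitivity_matrix <- function(baseline,
                               steps = list(total_hb = NULL, sat = 0.005,
                                            water = 0.005, lipid = 0.005),
                               instrument = instrument_spec(),
                               extinction = dos_extinction(),
                               baseline_fit = NULL) {
  if (is.null(baseline_fit)) {
    data <- simulate_instrument(baseline, instrument, extinction)
    baseline_fit <- dos_fit(data, extinction)
  }
  rows <- expand.grid(parameter = SENS_PARAMS, layer = c("top", "bottom"),
                      stringsAsFactors = FALSE)
  out <- matrix(NA_real_, nrow = nrow(rows), ncol = 4,
                dimnames = list(paste0(rows$parameter, "_", rows$layer),
                                c("total_hb", "sat", "water", "lipid")))
  used_steps <- numeric(nrow(rows))
  base_cc <- unlist(dos_fit_conc(baseline_fit))
  for (i in seq_len(nrow(rows))) {
    p <- rows$parameter[i]; lay <- rows$layer[i]
    h <- if (p == "total_hb") {
      if (is.null(steps$total_hb))
        0.005 * baseline[[lay]]$chromophores$total_hb
      else steps$total_hb
    } else steps[[p]]
    up_ok <- param_valid(perturb_medium(baseline, p, lay, h), p, lay)
    dn_ok <- param_valid(perturb_medium(baseline, p, lay, -h), p, lay)
    if (up_ok && dn_ok) {
      plus <- perturbed_recovery(baseline, p, lay, h, baseline_fit,
                                 instrument, extinction)
      minus <- perturbed_recovery(baseline, p, lay, -h, baseline_fit,
                                  instrument, extinction)
      out[i, ] <- (unlist(dos_fit_conc(plus$fit)) -
                     unlist(dos_fit_conc(minus$fit))) / (2 * h)
    } else if (up_ok || dn_ok) {
      hh <- if (up_ok) h else -h
      one <- perturbed_recovery(baseline, p, lay, hh, baseline_fit,
                                instrument, extinction)
      out[i, ] <- (unlist(dos_fit_conc(one$fit)) - base_cc) / hh
    } else {
      stop("parameter ", p, " (", lay, ") admits no valid perturbation")
    }
    used_steps[i] <- h
  }
  structure(out, steps = stats::setNames(used_steps, rownames(out)),
            baseline_fit = baseline_fit, class = "dos_sensitivity")
}

dos_fit_conc <- function(fit) {
  cc <- fit$chromophores
  list(total_hb = cc$total_hb, sat = cc$sat, water = cc$water,
       lipid = cc$lipid)
}

#' Co-sensitivities (diagonal blocks) of a sensitivity matrix
#'
#' @param x A `dos_sensitivity`.
#' @return 2 x 4 matrix (top/bottom rows) of like-parameter sensitivities.
#' @export
co_sensitivities <- function(x) {
  stopifnot(inherits(x, "dos_sensitivity"))
  m <- rbind(
    top = diag(unclass(x)[1:4, ]),
    bottom = diag(unclass(x)[5:8, ]))
  colnames(m) <- colnames(x)
  m
}

#' @export
print.dos_sensitivity <- function(x, digits = 2, ...) {
  cat("Sensitivities of recovered to actual layer absorption parameters\n")
  cat("(rows: perturbed parameter; columns: recovered parameter; fractions)\n")
  print(signif(unclass(x), digits))
  invisible(x)
}

#' @export
as.data.frame.dos_sensitivity <- function(x, ...) {
  data.frame(parameter = sub("_(top|bottom)$", "", rownames(x)),
             layer = sub("^.*_", "", rownames(x)),
             unclass(x), check.names = FALSE, row.names = NULL)
}
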