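#' Study configuration
#'
#' A complete, serializable description of one simulation study: the
#' 13-parameter two-layer medium (plus refractive index), instrument
#' overrides, optional extinction-table paths, sweep definition,
#' sensitivity steps, and solver tolerances. All physical keys carry unit
#' suffixes to prevent unit drift. Defaults reproduce the baseline study.
#'
#' @param medium A [two_layer_medium()].
#' @param instrument An [instrument_spec()].
#' @param extinction_paths Named list (`hemoglobin`, `water`, `lipid`) of
#'   table paths, or `NULL` for the bundled tables.
#' @param sweep `NULL` or list with `parameter`, `layer`, `values`.
#' @param sensitivity_steps Named list of step sizes (see
#'   [sensitivity_matrix()]).
#' @param tol,max_iter Attenuation-fit convergence control.
#' @return Object of class `dos_config`.
#' @export
study_config <- function(medium = baseline_medium(),
                         instrument = instrument_spec(),
                         extinction_paths = NULL,
                         sweep = NULL,
                         sensitivity_steps = list(total_hb = NULL,
                                                  sat = 0.005,
                                                  water = 0.005,
                                                  lipid = 0.005),
                         tol = 1e-9, max_iter = 200) {
  structure(list(medium = medium, instrument = instrument,
                 extinction_paths = extinction_paths, sweep = sweep,
                 sensitivity_steps = sensitivity_steps,
                 tol = tol, max_iter = max_iter),
            class = "dos_config")
}

layer_to_list <- function(layer) {
  list(total_hb_uM = layer$chromophores$total_hb,
       sat_frac = layer$chromophores$sat,
       water_frac = layer$chromophores$water,
       lipid_frac = layer$chromophores$lipid,
       musp830_per_mm = layer$scattering$musp830,
       b = layer$scattering$b)
}

layer_from_list <- function(x) {
  tissue_layer(x$total_hb_uM, x$sat_frac, x$water_frac, x$lipid_frac,
               x$musp830_per_mm, x$b)
}

#' Write a study configuration to a YAML file
#'
#' @param config A [study_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "dos_config"))
  x <- list(
    medium = list(top = layer_to_list(config$medium$top),
                  bottom = layer_to_list(config$medium$bottom),
                  z_top_mm = config$medium$z_top_mm,
                  n = config$medium$n),
    instrument = list(
      cw_nm = list(from = min(config$instrument$cw_wavelengths),
                   to = max(config$instrument$cw_wavelengths),
                   by = if (length(config$instrument$cw_wavelengths) > 1)
                     diff(config$instrument$cw_wavelengths[1:2]) else 1),
      fd_nm = config$instrument$fd_wavelengths,
      distances_mm = config$instrument$distances,
      mod_freq_hz = config$instrument$mod_freq_hz,
      n_assumed = config$instrument$n_assumed),
    extinction_paths = config$extinction_paths,
    sweep = config$sweep,
    sensitivity_steps = config$sensitivity_steps,
    tol = config$tol,
    max_iter = config$max_iter)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a study configuration from a YAML file
#'
#' Validates fields and reports offending keys by name; round-trips with
#' [write_study_config()].
#'
#' @param path YAML file written by [write_study_config()] (or edited by
#'   hand with the same keys).
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  med <- x$medium
  if (is.null(med$z_top_mm) || med$z_top_mm <= 0)
    stop("config field medium$z_top_mm must be > 0")
  for (lay in c("top", "bottom")) {
    l <- med[[lay]]
    if (is.null(l)) stop("config field medium$", lay, " is missing")
    if (is.null(l$musp830_per_mm) || l$musp830_per_mm <= 0)
      stop("config field medium$", lay, "$musp830_per_mm must be > 0")
    for (f in c("sat_frac", "water_frac", "lipid_frac"))
      if (is.null(l[[f]]) || l[[f]] < 0 || l[[f]] > 1)
        stop("config field medium$", lay, "$", f, " must be in [0, 1]")
    if (is.null(l$total_hb_uM) || l$total_hb_uM < 0)
      stop("config field medium$", lay, "$total_hb_uM must be >= 0")
  }
  ins <- x$instrument
  medium <- two_layer_medium(layer_from_list(med$top),
                             layer_from_list(med$bottom),
                             z_top_mm = med$z_top_mm, n = med$n)
  instrument <- instrument_spec(
    cw_wavelengths = seq(ins$cw_nm$from, ins$cw_nm$to, by = ins$cw_nm$by),
    fd_wavelengths = unlist(ins$fd_nm),
    distances = unlist(ins$distances_mm),
    mod_freq_hz = ins$mod_freq_hz,
    n_assumed = ins$n_assumed)
  study_config(medium = medium, instrument = instrument,
               extinction_paths = x$extinction_paths,
               sweep = x$sweep,
               sensitivity_steps = x$sensitivity_steps,
               tol = x$tol, max_iter = x$max_iter)
}

config_extinction <- function(config) {
  p <- config$extinction_paths
  if (is.null(p)) dos_extinction()
  else dos_extinction(hemoglobin = p$hemoglobin, water = p$water,
                      lipid = p$lipid)
}

#' Run a study command and write its outputs
#'
#' Executes one of the study's experiments from a configuration and
#' writes CSV outputs plus a JSON manifest (configuration echo, solver
#' settings, file list) to the output directory. Deterministic: identical
#' configurations produce identical outputs.
#'
#' @param config A [study_config()] (or a path to a YAML config).
#' @param command One of `"baseline"`, `"sweep"`, `"sensitivity"`,
#'   `"simulate"`.
#' @param out_dir Output directory (created if needed).
#' @return Invisible character vector of files written.
#' @export
run_study <- function(config = study_config(),
                      command = c("baseline", "sweep", "sensitivity",
                                  "simulate"),
                      out_dir = "tldos-out") {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "dos_config"))
  command <- match.arg(command)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- config_extinction(config)
  files <- character()

  if (command == "baseline") {
    baseline_study(config$medium, config$instrument, ext, out_dir = out_dir)
    files <- c("baseline_absorption.csv", "baseline_scattering.csv",
               "baseline_co_sensitivity.csv", "baseline_sensitivity.csv")
  } else if (command == "simulate") {
    data <- simulate_instrument(config$medium, config$instrument, ext)
    f <- file.path(out_dir, "reflectance.csv")
    utils::write.csv(as.data.frame(data), f, row.names = FALSE)
    files <- "reflectance.csv"
  } else {
    sw <- config$sweep
    if (is.null(sw$parameter))
      stop("config field sweep$parameter is required for command '",
           command, "'")
    tab <- if (command == "sweep")
      absolute_sweep(sw$parameter, sw$layer, unlist(sw$values),
                     baseline = config$medium,
                     instrument = config$instrument, extinction = ext)
    else
      sensitivity_sweep(sw$parameter, sw$layer, unlist(sw$values),
                        baseline = config$medium,
                        instrument = config$instrument, extinction = ext)
    f <- sprintf("%s_%s%s.csv", command, sw$parameter,
                 if (is.null(sw$layer)) "" else paste0("_", sw$layer))
    utils::write.csv(tab, file.path(out_dir, f), row.names = FALSE)
    files <- f
  }

  manifest <- list(
    command = command,
    files = files,
    settings = list(tol = config$tol, max_iter = config$max_iter,
                    sensitivity_steps = config$sensitivity_steps),
    config_yaml = "config.yml")
  write_study_config(config, file.path(out_dir, "config.yml"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(c(files, "config.yml", "manifest.json"))
}
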