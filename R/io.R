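# Configuration loading (YAML with an explicit units block), fluorophore
# presets, and CSV/JSON serialization of series, reports, and sweep tables.
# Display units (nm, um, mPa*s) are converted to SI here and nowhere else.

#' Fluorophore material presets
#'
#' Properties of the fluorescein (donor) / TAMRA (acceptor) pair commonly
#' used for FRET: excitation/emission wavelengths, extinction coefficient,
#' quantum yield, and fluorescence lifetime. The pair preset
#' `"fluorescein-tamra"` additionally carries the pair's Forster distance,
#' about 5.5 nm.
#'
#' @param name One of `"fluorescein"`, `"tamra"`, `"fluorescein-tamra"`.
#' @return A list of material properties (wavelengths in nm, extinction in
#'   M^-1 cm^-1, lifetime in ns; `R0` in metres for the pair preset).
#' @export
material_preset <- function(name) {
  presets <- list(
    fluorescein = list(
      name = "fluorescein", role = "donor",
      excitation_wavelength = 500, emission_wavelength = 515,
      extinction_coeff = 7e4, quantum_yield = 0.95,
      fluorescence_lifetime = 4),
    tamra = list(
      name = "tamra", role = "acceptor",
      excitation_wavelength = 550, emission_wavelength = 577,
      extinction_coeff = 9e4, quantum_yield = 0.68,
      fluorescence_lifetime = 5),
    `fluorescein-tamra` = list(
      name = "fluorescein-tamra", role = "pair",
      donor = "fluorescein", acceptor = "tamra",
      R0 = 5.5e-9))
  key <- tolower(name)
  if (!key %in% names(presets))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  presets[[key]]
}

# display-unit -> SI conversion factors for the config file
.unit_factors <- list(
  nm = 1e-9, um = 1e-6, mm = 1e-3, m = 1,
  `mPa.s` = 1e-3, `Pa.s` = 1,
  us = 1e-6, ms = 1e-3, s = 1)

.convert_unit <- function(value, unit, field) {
  f <- .unit_factors[[unit]]
  if (is.null(f))
    stop(sprintf("field '%s': unknown unit '%s'", field, unit), call. = FALSE)
  value * f
}

#' Load an experiment configuration from a YAML file
#'
#' The file may set any subset of the [experiment_config()] and
#' [estimation_protocol()] fields; omitted fields take the baseline
#' defaults. An optional `units:` block declares display units per field
#' (`nm`, `um`, `mPa.s`, `us`, ...); values are converted to SI at load.
#' A `preset: fluorescein-tamra` entry loads that pair's Forster distance.
#' Unknown keys and out-of-range values are hard errors naming the field.
#'
#' @param path Path to the YAML configuration file.
#' @return A validated [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  cfg_keys <- c("rho_f", "c_f", "P_f", "f0", "d_p", "m_p", "rho_p",
                "R0", "kA", "delta_t", "alpha", "mu_list", "snr_list",
                "f0_list", "Pf_list", "dp_list", "NMC", "master_seed",
                "scaled")
  prot_keys <- c("NT", "Nm", "E_min", "Nmin_fraction", "d0_min", "d0_max",
                 "d0_initial", "mu_initial")
  meta_keys <- c("units", "preset")
  unknown <- setdiff(names(raw), c(cfg_keys, prot_keys, meta_keys))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)

  units <- raw$units %||% list()
  bad_units <- setdiff(names(units), c(cfg_keys, prot_keys))
  if (length(bad_units))
    stop(sprintf("units given for unknown field(s): %s",
                 paste(bad_units, collapse = ", ")), call. = FALSE)
  vals <- raw[setdiff(names(raw), meta_keys)]
  for (f in names(units))
    if (!is.null(vals[[f]]))
      vals[[f]] <- .convert_unit(vals[[f]], units[[f]], f)

  if (!is.null(raw$preset)) {
    p <- material_preset(raw$preset)
    if (!is.null(p$R0) && is.null(vals$R0)) vals$R0 <- p$R0
  }

  cfg_args <- vals[intersect(names(vals), cfg_keys)]
  prot_args <- vals[intersect(names(vals), prot_keys)]
  protocol <- do.call(estimation_protocol, c(
    prot_args,
    if (is.null(prot_args$NT) && !isFALSE(vals$scaled %||% TRUE)) list(NT = 200),
    if (is.null(prot_args$Nm) && !isFALSE(vals$scaled %||% TRUE)) list(Nm = 5)))
  do.call(experiment_config, c(cfg_args, list(protocol = protocol)))
}

#' Write / read a measurement series (CSV + JSON sidecar)
#'
#' The time series goes to `<prefix>.csv` (columns `t_s`, `counts`); the
#' truth snapshot, flags, and seed go to `<prefix>.json`. The round trip is
#' lossless to full double precision.
#'
#' @param series A [simulate_series()] result.
#' @param prefix Output path prefix (no extension).
#' @return `write_series` returns the two paths invisibly; `read_series`
#'   returns a `vfret_series`.
#' @export
write_series <- function(series, prefix) {
  stopifnot(inherits(series, "vfret_series"))
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  utils::write.csv(data.frame(t_s = series$t, counts = series$counts),
                   csv, row.names = FALSE)
  meta <- series[setdiff(names(series), c("t", "counts"))]
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' @rdname write_series
#' @export
read_series <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  if (!file.exists(csv) || !file.exists(json))
    stop(sprintf("series files '%s(.csv/.json)' not found", prefix),
         call. = FALSE)
  tab <- utils::read.csv(csv)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  out <- c(list(t = tab$t_s, counts = tab$counts), meta)
  out$S <- as.integer(out$S)
  out$seed <- as.integer(out$seed)
  structure(out, class = "vfret_series")
}

#' Write / read an estimate report (JSON + flat CSV)
#'
#' `<prefix>.json` holds the full report; `<prefix>.csv` is flat, one row
#' per measurement plus one summary row (`measurement = 0`).
#'
#' @param report A `vfret_report` from [aggregate_estimates()].
#' @param prefix Output path prefix (no extension).
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "vfret_report"))
  json <- paste0(prefix, ".json")
  csv <- paste0(prefix, ".csv")
  jsonlite::write_json(list(
    d0_hat_final = report$d0_hat_final,
    mu_hat_final = report$mu_hat_final,
    n_used = report$n_used, n_rejected = report$n_rejected,
    per_measurement = report$per_measurement),
    json, auto_unbox = TRUE, digits = NA)
  summary_row <- data.frame(
    measurement = 0L, verdict = "summary", reason = NA_character_,
    d0_hat = report$d0_hat_final, mu_hat = report$mu_hat_final,
    converged = TRUE, residual_norm = NA_real_,
    n_samples_used = NA_integer_, stringsAsFactors = FALSE)
  utils::write.csv(rbind(report$per_measurement, summary_row), csv,
                   row.names = FALSE)
  invisible(c(json = json, csv = csv))
}

#' @rdname write_report
#' @export
read_report <- function(prefix) {
  json <- paste0(prefix, ".json")
  if (!file.exists(json))
    stop(sprintf("report file '%s' not found", json), call. = FALSE)
  r <- jsonlite::read_json(json, simplifyVector = TRUE)
  structure(list(per_measurement = r$per_measurement,
                 d0_hat_final = r$d0_hat_final,
                 mu_hat_final = r$mu_hat_final,
                 n_used = r$n_used, n_rejected = r$n_rejected),
            class = "vfret_report")
}
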