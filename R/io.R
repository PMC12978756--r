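# Plain-text import/export: CSV traces with fixed headers, legacy VTK
# structured points for gridded fields, YAML pipeline configuration and
# JSON condition reports.

write_csv_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export helpers with fixed CSV headers
#'
#' Write the standard traces with their conventional headers:
#' `shear_rate_s-1,mu_eff_Pa_s` for viscosity curves, `t_s,v_m_per_s` for
#' waveform traces, `t_s,P_Pa,Pc_Pa,Q_m3_per_s` for Windkessel pressure
#' traces, and `t_s,r_m,u_m_per_s` for radial profile series.
#'
#' @param curve,trace,pressure,profiles The corresponding tibbles.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_viscosity_curve <- function(curve, path) {
  write_csv_header(curve[c("shear_rate", "mu_eff")], path,
                   "shear_rate_s-1,mu_eff_Pa_s")
}

#' @rdname export_viscosity_curve
#' @export
export_waveform_trace <- function(trace, path) {
  write_csv_header(trace[c("t", "v")], path, "t_s,v_m_per_s")
}

#' @rdname export_viscosity_curve
#' @export
export_pressure_trace <- function(pressure, path) {
  write_csv_header(pressure[c("t", "P", "Pc", "Q")], path,
                   "t_s,P_Pa,Pc_Pa,Q_m3_per_s")
}

#' @rdname export_viscosity_curve
#' @export
export_profiles <- function(profiles, path) {
  write_csv_header(profiles[c("t", "r", "u")], path, "t_s,r_m,u_m_per_s")
}

#' Write / read a gridded field as legacy VTK structured points
#'
#' ASCII legacy VTK (`STRUCTURED_POINTS`) with the velocity as a `VECTORS`
#' attribute and optional pressure as `SCALARS`, readable by ParaView and
#' by [read_gridded_vtk()].
#'
#' @param field A [gridded_field()].
#' @param path Output path.
#' @return `write_gridded_vtk`: the path, invisibly.
#'   `read_gridded_vtk`: the reconstructed [gridded_field()] (periodicity
#'   is not stored in VTK and defaults to `FALSE`).
#' @export
write_gridded_vtk <- function(field, path) {
  if (!inherits(field, "gridded_field")) {
    abort_invalid("`field` must be a gridded_field.")
  }
  d <- field$dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pulsarch gridded field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.17g %.17g %.17g", field$spacing[1],
                       field$spacing[2], field$spacing[3]),
               sprintf("POINT_DATA %d", prod(d)),
               "VECTORS velocity double"), con)
  vec <- cbind(as.double(field$u), as.double(field$v), as.double(field$w))
  utils::write.table(format(vec, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(field$p)) {
    writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(as.double(field$p), digits = 17, scientific = TRUE,
                      trim = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_gridded_vtk
#' @export
read_gridded_vtk <- function(path) {
  lines <- readLines(path)
  get_line <- function(prefix) {
    hit <- grep(paste0("^", prefix), lines, value = TRUE)
    if (length(hit) == 0) abort_invalid(sprintf("VTK file lacks %s.", prefix))
    hit[1]
  }
  d <- as.integer(strsplit(get_line("DIMENSIONS"), "\\s+")[[1]][-1])
  spacing <- as.double(strsplit(get_line("SPACING"), "\\s+")[[1]][-1])
  iv <- grep("^VECTORS", lines)
  n <- prod(d)
  vec_lines <- lines[(iv + 1):(iv + n)]
  vals <- matrix(as.double(unlist(strsplit(trimws(vec_lines), "\\s+"))),
                 ncol = 3, byrow = TRUE)
  p <- NULL
  is <- grep("^SCALARS pressure", lines)
  if (length(is) == 1) {
    p <- array(as.double(lines[(is + 2):(is + 1 + n)]), dim = d)
  }
  gridded_field(u = array(vals[, 1], d), v = array(vals[, 2], d),
                w = array(vals[, 3], d), spacing = spacing, p = p)
}

#' Pipeline configuration (YAML)
#'
#' The configuration file gathers the waveform, network, Windkessel,
#' numerics and (optionally) custom rheology blocks. `default_config()`
#' returns the defaults as a plain list; `write_pipeline_config()` /
#' `read_pipeline_config()` round-trip it through YAML; and
#' `config_inputs()` converts a configuration into the argument objects of
#' [run_condition()].
#'
#' @param config A configuration list (as from `default_config()` or
#'   `read_pipeline_config()`).
#' @param path File path of the YAML configuration.
#' @return See each function's description.
#' @export
default_config <- function() {
  br <- .default_branches()
  list(
    waveform = list(period = 0.5, systole_end = 0.218, amplitude = 0.5,
                    diastolic_level = 0.1, phase_offset = 0.016),
    network = list(inlet_radius = 0.0125, mean_pressure = 13332, tau = 1.0,
                   branches = purrr::pmap(
                     br[c("name", "label", "radius", "flow_fraction", "length")],
                     function(name, label, radius, flow_fraction, length) {
                       list(name = name, label = label, radius = radius,
                            flow_fraction = flow_fraction, length = length)
                     })),
    numerics = list(nr = 101, steps_per_cycle = 1000, n_cycles = 8,
                    picard_tol = 1e-8, max_iter = 50),
    rheology = NULL
  )
}

#' @rdname default_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname default_config
#' @export
config_inputs <- function(config) {
  wfc <- config$waveform %||% list()
  waveform <- do.call(waveform_params, wfc)
  netc <- config$network %||% list()
  branches <- if (is.null(netc$branches)) .default_branches() else {
    dplyr::bind_rows(purrr::map(netc$branches, tibble::as_tibble))
  }
  network <- arch_network(
    inlet_radius = netc$inlet_radius %||% 0.0125, branches = branches,
    mean_pressure = netc$mean_pressure %||% 13332,
    tau = netc$tau %||% 1.0, waveform = waveform)
  numerics <- do.call(pipeline_numerics, config$numerics %||% list())
  conditions <- NULL
  if (!is.null(config$rheology)) {
    conditions <- purrr::imap(config$rheology, function(p, nm) {
      rheology_params(nm, k = p$k, lambda = p$lambda, mu0 = p$mu0,
                      mu_inf = p$mu_inf,
                      hematocrit = p$hematocrit %||% NA_real_,
                      density = p$density %||% 1060)
    })
  }
  list(waveform = waveform, network = network, numerics = numerics,
       conditions = conditions)
}

#' Write a condition report as JSON
#'
#' Serializes the summaries, severity classification (with the thresholds
#' used, flagged as illustrative), periodicity and mass-conservation
#' diagnostics of an [run_condition()] report.
#'
#' @param report An `arch_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "arch_report")) {
    abort_invalid("`report` must be an arch_report.")
  }
  sev <- tibble::as_tibble(report$severity)
  payload <- list(
    condition = report$condition,
    rheology = report$rheology[c("k", "lambda", "mu0", "mu_inf",
                                 "hematocrit", "density")],
    summaries = report$summaries,
    severity = list(
      note = "bands are illustrative configuration defaults",
      classification = sev,
      bands = report$bands),
    periodicity = report$periodicity,
    mass_conservation_error = report$mass_error)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
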