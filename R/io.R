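# Delimited-text I/O. Layout: comma-separated, '.' decimal, UTF-8, one
# header row, '#' comment lines ignored. Observation files carry molar
# concentrations; a mass-units option converts glucose and biomass g/L
# columns on input.

OBS_FILE_COLUMNS <- c("time_h", "glucose_mol_L", "acetate_mol_L",
                      "lactate_mol_L", "biomass_molcell_L", "h2aq_mol_L",
                      "co2aq_mol_L", "h2_gas_frac", "co2_gas_frac",
                      "cum_h2_mol_per_L")

read_delimited <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data in ", path)
  content <- lines[keep]
  header <- strsplit(content[1], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  missing <- setdiff(required, header)
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  nfield <- lengths(strsplit(content[-1], ",", fixed = TRUE))
  # a trailing empty cell is legal; more fields than the header is not
  bad <- which(nfield > length(header))
  if (length(bad)) {
    lineno <- which(keep)[1 + bad[1]]
    stop("malformed row at line ", lineno, " of ", path, ": ",
         nfield[bad[1]], " fields for ", length(header), " columns")
  }
  df <- read.csv(text = paste(content, collapse = "\n"),
                 stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))
  for (nm in setdiff(names(df), character(0))) {
    if (!is.numeric(df[[nm]])) {
      suppressWarnings(v <- as.numeric(df[[nm]]))
      if (any(is.na(v) & !is.na(df[[nm]]) & nzchar(trimws(df[[nm]]))))
        stop("non-numeric value in column '", nm, "' of ", path)
      df[[nm]] <- v
    }
  }
  df
}

#' Read a batch observation file
#'
#' Reads the delimited observation layout (see the package vignette);
#' missing observables may be absent columns or empty cells. With
#' `mass_units = TRUE`, `glucose_g_L` and `biomass_g_L` columns are
#' converted to molar using 180.16 g/mol (glucose) and 24.7 g/mol
#' (cell carbon-mole).
#'
#' @param path file path.
#' @param mass_units convert mass-based glucose/biomass columns.
#' @return An `observation_set` data frame.
#' @export
read_observations <- function(path, mass_units = FALSE) {
  df <- read_delimited(path, required = "time_h")
  if (mass_units) {
    if ("glucose_g_L" %in% names(df)) {
      df$glucose_mol_L <- df$glucose_g_L / GLUCOSE_G_MOL
      df$glucose_g_L <- NULL
    }
    if ("biomass_g_L" %in% names(df)) {
      df$biomass_molcell_L <- df$biomass_g_L / BIOMASS_G_MOL
      df$biomass_g_L <- NULL
    }
  }
  unknown <- setdiff(names(df), OBS_FILE_COLUMNS)
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  if (is.unsorted(df$time_h))
    stop("time_h must be non-decreasing in ", path)
  for (nm in setdiff(names(df), "time_h"))
    if (any(df[[nm]] < 0, na.rm = TRUE))
      stop("negative values in column '", nm, "' of ", path)
  structure(df, class = c("observation_set", class(df)))
}

#' Write a batch observation file
#'
#' @param obs an `observation_set` (or plain data frame with `time_h`).
#' @param path output path.
#' @param comment optional comment lines written at the top (prefixed '#').
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path, comment = NULL) {
  if (!"time_h" %in% names(obs)) stop("observations must contain time_h")
  write_with_comments(as.data.frame(obs), path, comment)
}

#' Write a simulated time course
#'
#' Exports the state and rate columns of a [simulate_batch()] result as
#' delimited text (15 significant digits, so that a write/read round trip
#' preserves at least 12).
#'
#' @param tc a `batch_timecourse`.
#' @param path output path.
#' @param comment optional comment lines.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path, comment = NULL) {
  write_with_comments(as.data.frame(tc), path, comment)
}

#' Read back an exported time course
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_timecourse <- function(path) {
  read_delimited(path, required = "time")
}

write_with_comments <- function(df, path, comment) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  writeLines(paste(names(df), collapse = ","), con)
  rows <- do.call(paste, c(lapply(df, function(v) {
    out <- vapply(v, function(x) {
      if (is.na(x)) "" else format(x, digits = 15, scientific = NA)
    }, character(1))
    out
  }), sep = ","))
  writeLines(rows, con)
  invisible(path)
}

RUN_CONFIG_KEYS <- c("scenario", "glucose_g_L", "stripping_L_h", "mu_max",
                     "horizon_h", "X0", "seed", "rtol", "atol", "grid",
                     "parameters", "reactor", "output_dir")

#' Read a YAML run configuration
#'
#' Schema-validated configuration for a simulation or generation run:
#' either a preset `scenario` number (1-8) or explicit
#' `glucose_g_L`/`stripping_L_h`/`mu_max`/`horizon_h`, optional `parameters`
#' and `reactor` blocks overriding [kinetic_parameters()] /
#' [reactor_config()] fields, plus `seed`, solver tolerances and an output
#' directory. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A list with `scenario` (named list), `parameters`
#'   (`kinetic_parameters`), `reactor` (`reactor_config`), `seed`, `rtol`,
#'   `atol`, `grid`, `X0`, `output_dir`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("run configuration must be a YAML mapping")
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  presets <- table1_scenarios()
  if (!is.null(raw$scenario)) {
    if (!raw$scenario %in% presets$experiment)
      stop("scenario must be one of ", paste(presets$experiment, collapse = ", "))
    scn <- as.list(presets[presets$experiment == raw$scenario, ])
  } else {
    scn <- list(glucose_g_L = raw$glucose_g_L %||% 5,
                stripping_L_h = raw$stripping_L_h %||% 6,
                mu_max = raw$mu_max %||% 0.28,
                horizon_h = raw$horizon_h %||% 40)
  }
  for (ov in c("glucose_g_L", "stripping_L_h", "mu_max", "horizon_h"))
    if (!is.null(raw[[ov]])) scn[[ov]] <- raw[[ov]]
  p <- do.call(kinetic_parameters, as.list(raw$parameters %||% list()))
  cfg <- do.call(reactor_config, as.list(raw$reactor %||% list()))
  cfg <- update_params(cfg, F_in_N2 = scn$stripping_L_h)
  list(scenario = scn, parameters = p, reactor = cfg,
       seed = raw$seed %||% 0, rtol = raw$rtol %||% 1e-8,
       atol = raw$atol %||% 1e-10, grid = raw$grid %||% 0.25,
       X0 = raw$X0 %||% 1e-4, output_dir = raw$output_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an estimation report
#'
#' Exports the estimates, standard errors and 95% confidence bounds of an
#' `estimation_result` as delimited text, with the residual sum of squares
#' and convergence status in the header comments.
#'
#' @param result an `estimation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_estimation_report <- function(result, path) {
  stopifnot(inherits(result, "estimation_result"))
  tab <- confidence_intervals(result)
  write_with_comments(tab, path,
                      comment = c(sprintf("LSQ %.10g over %d residuals",
                                          result$lsq, result$n_residuals),
                                  sprintf("convergence: %s", result$message)))
}
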