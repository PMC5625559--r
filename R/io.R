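# CSV and YAML input handling. All exchange formats are plain UTF-8
# comma-delimited CSV with a mandatory header row; open-ended age groups may
# be written as "80+", "+" or "Inf" in the age_high column.

parse_age_high <- function(x) {
  x <- as.character(x)
  open <- x %in% c("+", "", "Inf") | grepl("\\+$", x)
  out <- suppressWarnings(as.numeric(sub("\\+$", "", x)))
  out[open] <- Inf
  if (anyNA(out)) stop_io("unparseable age_high value(s): %s",
                          paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

read_table_csv <- function(path, required, what) {
  if (!file.exists(path)) stop_io("%s file not found: %s", what, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_io("%s file %s is missing column(s): %s", what, path,
            paste(missing_cols, collapse = ", "))
  }
  if ("age_high" %in% names(df)) df$age_high <- parse_age_high(df$age_high)
  df
}

#' Read pipeline input tables from CSV
#'
#' `read_exposure_csv()` expects columns `sex`, `age_low`, `age_high`,
#' `mean_g_day`, `sd_g_day` and optionally `family` (default `"gamma"`);
#' `read_incidence_csv()` expects `sex`, `age_low`, `age_high`,
#' `rate_per_100k`; `read_population_csv()` expects `sex`, `age_low`,
#' `age_high`, `count`. `age_high` accepts `"80+"`, `"+"` or `Inf` for
#' open-ended groups.
#'
#' @param path CSV file path.
#' @return a validated data.frame in the pipeline's table layout.
#' @name input_csv
#' @export
read_exposure_csv <- function(path) {
  df <- read_table_csv(path, c("sex", "age_low", "age_high", "mean_g_day",
                               "sd_g_day"), "exposure")
  if (!"family" %in% names(df)) df$family <- "gamma"
  validate_strat_table(df, "mean_g_day", "exposure")
}

#' @rdname input_csv
#' @export
read_incidence_csv <- function(path) {
  validate_strat_table(
    read_table_csv(path, c("sex", "age_low", "age_high", "rate_per_100k"),
                   "incidence"),
    "rate_per_100k", "incidence")
}

#' @rdname input_csv
#' @export
read_population_csv <- function(path) {
  validate_strat_table(
    read_table_csv(path, c("sex", "age_low", "age_high", "count"),
                   "population"),
    "count", "population")
}

write_table_csv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Read and validate a YAML run configuration
#'
#' The run configuration names the input CSVs, the risk-factor relative
#' risks, and the scenario. Relative input paths are resolved against the
#' configuration file's directory.
#'
#' @param path YAML file path.
#' @return a validated list of class `run_config` with elements `spec`
#'   ([rr_spec()]), `step`, `scenario` ([scenario()]), `exposure_csv`,
#'   `incidence_csv`, `population_csv`, `standard` (a standard-population
#'   data.frame) and `output_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rfb <- cfg$risk_factor
  if (is.null(rfb) || is.null(rfb$name) || is.null(rfb$rr_central)) {
    stop_config("config must contain a risk_factor block with name and rr_central")
  }
  spec <- withCallingHandlers(
    rr_spec(rfb$name, rfb$rr_central,
            rr_lower = rfb$rr_lower %||% rfb$rr_central,
            rr_upper = rfb$rr_upper %||% rfb$rr_central,
            reference_dose = rfb$reference_dose_g_per_day %||% 100),
    pafsim_domain_error = function(e) {
      stop_config("invalid risk_factor block: %s", conditionMessage(e))
    })
  scn_block <- cfg$scenario %||% list()
  scn <- scenario(name = scn_block$name %||% scn_block$transform %||% "zero",
                  transform = scn_block$transform %||% "zero",
                  scale_factor = scn_block$scale_factor,
                  year = scn_block$year %||% 2010,
                  latency_years = scn_block$latency_years %||% 0)
  inputs <- cfg$inputs
  if (is.null(inputs)) stop_config("config must contain an inputs block")
  resolve <- function(p, what) {
    if (is.null(p)) stop_config("inputs block is missing %s", what)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }
  std_name <- cfg$standard_population %||% "segi"
  standard <- if (identical(std_name, "segi")) {
    segi_standard()
  } else if (file.exists(file.path(base, std_name)) ||
             file.exists(std_name)) {
    p <- if (file.exists(std_name)) std_name else file.path(base, std_name)
    read_table_csv(p, c("age_low", "age_high", "weight"),
                   "standard population")
  } else {
    stop_config("unknown standard_population '%s' (use 'segi' or a CSV path)",
                std_name)
  }
  structure(
    list(spec = spec,
         has_bounds = !is.null(rfb$rr_lower) && !is.null(rfb$rr_upper),
         step = rfb$step_g_per_day %||% 20,
         scenario = scn,
         exposure_csv = resolve(inputs$exposure_csv, "exposure_csv"),
         incidence_csv = resolve(inputs$incidence_csv, "incidence_csv"),
         population_csv = resolve(inputs$population_csv, "population_csv"),
         standard = standard,
         standard_name = std_name,
         output_dir = cfg$output_dir %||% ".",
         config_path = normalizePath(path)),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
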