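# Field-observable crop water stress index (CWSI).
#
# The classical CWSI needs the wet (T_wet) and dry (T_dry) reference leaf
# temperatures of a fully transpiring / non-transpiring canopy, which are
# rarely measurable on working farms. Here T_dry is a fixed site constant
# (default 34 degC, the hottest leaf observed on the study plots) and T_wet
# is estimated from air temperature via an empirical correction coefficient
# delta driven by soil moisture deviation from its optimum and by relative
# humidity:
#
#   delta = min(cap, base + soil_coeff * |VWC - VWC_opt| + rh_coeff * (1 - RH/100))
#   T_wet = T_a - delta
#   CWSI  = clip(|T_c - T_wet| / (T_dry - T_wet), floor, ceiling)
#
# The absolute-value numerator makes both unusually hot (droughted) and
# unusually cool (waterlogged) canopies register as stressed.

#' Weather observation
#'
#' A single field weather record: air temperature and relative humidity, the
#' two meteorological inputs the wet-reference estimate depends on.
#'
#' @param air_temp_c Air temperature in degrees Celsius.
#' @param rel_humidity_pct Relative humidity in percent (0--100).
#' @return An object of class `weather_observation`.
#' @export
weather_observation <- function(air_temp_c, rel_humidity_pct) {
  check_finite(air_temp_c, "air_temp_c")
  check_range(rel_humidity_pct, 0, 100, "rel_humidity_pct")
  structure(list(air_temp_c = air_temp_c,
                 rel_humidity_pct = rel_humidity_pct),
            class = "weather_observation")
}

#' Soil moisture reading
#'
#' @param vwc_pct Volumetric water content in percent (0--100).
#' @param depth_cm Optional measurement depth in cm (metadata only).
#' @return An object of class `soil_moisture_reading`.
#' @export
soil_moisture_reading <- function(vwc_pct, depth_cm = NULL) {
  check_range(vwc_pct, 0, 100, "vwc_pct")
  if (!is.null(depth_cm)) check_finite(depth_cm, "depth_cm")
  structure(list(vwc_pct = vwc_pct, depth_cm = depth_cm),
            class = "soil_moisture_reading")
}

#' CWSI parameters
#'
#' Parameters of the field-observable CWSI. Defaults reproduce the published
#' calibration: a dry reference fixed at 34 degC, a correction coefficient
#' with base 2, soil term 0.1 per percent VWC away from a 30% optimum, a
#' humidity term scaled by 2, a cap of 6 on the summed coefficient, and
#' index clipping to [0.05, 1].
#'
#' @param t_dry_c Dry-reference canopy temperature, degC. Site-specific; the
#'   default is the highest leaf temperature observed on the calibration
#'   plots.
#' @param delta_base Base value of the correction coefficient.
#' @param soil_coeff Weight on `|vwc - soil_optimum|`, per percent VWC.
#' @param soil_optimum_pct Optimal volumetric water content, percent.
#' @param rh_coeff Weight on the transpiration term `(1 - RH/100)`.
#' @param delta_cap Upper cap applied to the summed coefficient.
#' @param cwsi_floor,cwsi_ceiling Clipping bounds of the reported index.
#' @param numerator `"abs"` (default) uses `|T_c - T_wet|` so both hot and
#'   cool canopies register as stressed; `"signed"` uses `T_c - T_wet`.
#' @return An object of class `cwsi_parameters`.
#' @export
cwsi_parameters <- function(t_dry_c = 34, delta_base = 2, soil_coeff = 0.1,
                            soil_optimum_pct = 30, rh_coeff = 2,
                            delta_cap = 6, cwsi_floor = 0.05,
                            cwsi_ceiling = 1.0,
                            numerator = c("abs", "signed")) {
  numerator <- match.arg(numerator)
  for (nm in c("t_dry_c", "delta_base", "soil_coeff", "soil_optimum_pct",
               "rh_coeff", "delta_cap", "cwsi_floor", "cwsi_ceiling")) {
    check_finite(get(nm), nm)
  }
  if (delta_cap < delta_base) {
    stop_invalid("delta_cap (", delta_cap, ") must be >= delta_base (",
                 delta_base, ")")
  }
  if (!(cwsi_floor > 0 && cwsi_floor < cwsi_ceiling && cwsi_ceiling <= 1)) {
    stop_invalid("need 0 < cwsi_floor < cwsi_ceiling <= 1 (got ",
                 cwsi_floor, ", ", cwsi_ceiling, ")")
  }
  structure(list(t_dry_c = t_dry_c, delta_base = delta_base,
                 soil_coeff = soil_coeff,
                 soil_optimum_pct = soil_optimum_pct, rh_coeff = rh_coeff,
                 delta_cap = delta_cap, cwsi_floor = cwsi_floor,
                 cwsi_ceiling = cwsi_ceiling, numerator = numerator),
            class = "cwsi_parameters")
}

#' Load CWSI parameters from a YAML config
#'
#' Reads a YAML mapping whose keys are any subset of the
#' [cwsi_parameters()] arguments; unspecified keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cwsi_parameters` object.
#' @export
cwsi_parameters_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(cwsi_parameters))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop_invalid("unknown CWSI parameter(s) in ", path, ": ",
                 paste(unknown, collapse = ", "))
  }
  do.call(cwsi_parameters, cfg)
}

#' Water stress correction coefficient
#'
#' Computes the correction coefficient `delta` subtracted from air
#' temperature to estimate the wet reference: the sum of a base value, a
#' soil-moisture adjustment proportional to the absolute deviation of VWC
#' from its optimum, and a transpiration term that grows as humidity falls.
#' The sum is capped (default at 6); the cap applies to the sum, never to
#' individual terms.
#'
#' @param soil A [soil_moisture_reading()] (or a bare VWC percentage).
#' @param weather A [weather_observation()].
#' @param params A [cwsi_parameters()] object.
#' @return List with elements `delta` and logical `capped`.
#' @examples
#' compute_delta(soil_moisture_reading(30), weather_observation(25, 100))
#' @export
compute_delta <- function(soil, weather, params = cwsi_parameters()) {
  if (is.numeric(soil)) soil <- soil_moisture_reading(soil)
  stopifnot(inherits(soil, "soil_moisture_reading"),
            inherits(weather, "weather_observation"),
            inherits(params, "cwsi_parameters"))
  raw <- params$delta_base +
    params$soil_coeff * abs(soil$vwc_pct - params$soil_optimum_pct) +
    params$rh_coeff * (1 - weather$rel_humidity_pct / 100)
  capped <- raw > params$delta_cap
  list(delta = pmin(raw, params$delta_cap), capped = capped)
}

#' Wet reference temperature
#'
#' Estimates the fully transpiring ("wet") canopy temperature by subtracting
#' the correction coefficient from air temperature.
#'
#' @param weather A [weather_observation()].
#' @param delta Non-negative correction coefficient.
#' @return Temperature in degC.
#' @export
compute_t_wet <- function(weather, delta) {
  stopifnot(inherits(weather, "weather_observation"))
  check_finite(delta, "delta")
  if (any(delta < 0)) stop_invalid("delta must be >= 0 (got ", delta, ")")
  weather$air_temp_c - delta
}

#' Field-observable crop water stress index
#'
#' Computes the CWSI of a canopy from its leaf temperature, local weather
#' and soil moisture. The raw index is the (by default absolute) deviation
#' of leaf temperature from the estimated wet reference, normalized by the
#' wet--dry reference span, then clipped to `[cwsi_floor, cwsi_ceiling]`.
#' The floor (default 0.05) absorbs sensor error near the unstressed limit.
#'
#' @inheritParams compute_delta
#' @param leaf_temp_c Canopy/leaf temperature in degC (from thermal imagery).
#' @return An object of class `cwsi_result`: list with `delta`, `t_wet_c`,
#'   `cwsi_raw`, `cwsi`, and flags `clipped_low`, `clipped_high`,
#'   `delta_capped`.
#' @examples
#' r <- compute_cwsi(28.5, weather_observation(25, 100),
#'                   soil_moisture_reading(30))
#' r$cwsi  # 0.5
#' @export
compute_cwsi <- function(leaf_temp_c, weather, soil,
                         params = cwsi_parameters()) {
  check_finite(leaf_temp_c, "leaf_temp_c")
  if (is.numeric(soil)) soil <- soil_moisture_reading(soil)
  d <- compute_delta(soil, weather, params)
  t_wet <- compute_t_wet(weather, d$delta)
  denom <- params$t_dry_c - t_wet
  if (any(denom <= 0)) {
    stop_invalid("degenerate CWSI denominator: t_dry_c (", params$t_dry_c,
                 " degC) must exceed t_wet_c (",
                 paste(signif(t_wet[denom <= 0], 6), collapse = ", "),
                 " degC)")
  }
  num <- leaf_temp_c - t_wet
  if (params$numerator == "abs") num <- abs(num)
  raw <- num / denom
  clipped_low <- raw < params$cwsi_floor
  clipped_high <- raw > params$cwsi_ceiling
  structure(list(
    delta = d$delta, t_wet_c = t_wet, cwsi_raw = raw,
    cwsi = pmin(pmax(raw, params$cwsi_floor), params$cwsi_ceiling),
    clipped_low = clipped_low, clipped_high = clipped_high,
    delta_capped = d$capped
  ), class = "cwsi_result")
}

#' CWSI over a table of records
#'
#' Vectorized CWSI: appends `delta`, `t_wet_c` and `cwsi` columns to a data
#' frame holding one record per row. Row values are identical to calling
#' [compute_cwsi()] on each row.
#'
#' @param records Data frame with columns `leaf_temp_c`, `air_temp_c`,
#'   `rel_humidity_pct`, `vwc_pct` (extra columns pass through).
#' @param params A [cwsi_parameters()] object.
#' @return `records` with `delta`, `t_wet_c`, `cwsi` columns appended.
#' @export
compute_cwsi_table <- function(records, params = cwsi_parameters()) {
  check_columns(records, c("leaf_temp_c", "air_temp_c",
                           "rel_humidity_pct", "vwc_pct"))
  if (nrow(records) == 0) {
    records$delta <- numeric(0)
    records$t_wet_c <- numeric(0)
    records$cwsi <- numeric(0)
    return(records)
  }
  res <- compute_cwsi(records$leaf_temp_c,
                      weather_observation(records$air_temp_c,
                                          records$rel_humidity_pct),
                      soil_moisture_reading(records$vwc_pct),
                      params)
  records$delta <- res$delta
  records$t_wet_c <- res$t_wet_c
  records$cwsi <- res$cwsi
  records
}

#' Read / write CWSI record tables
#'
#' Thin CSV wrappers around the tabular schema used throughout the package
#' (`plot_id`, `timestamp`, `leaf_temp_c`, `air_temp_c`, `rel_humidity_pct`,
#' `vwc_pct`, plus appended index columns).
#'
#' @param path CSV file path.
#' @return `read_cwsi_table()` returns a data frame.
#' @export
read_cwsi_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("leaf_temp_c", "air_temp_c", "rel_humidity_pct",
                      "vwc_pct"))
  df
}

#' @rdname read_cwsi_table
#' @param records Data frame to write.
#' @export
write_cwsi_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
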