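#' Crop water stress index (CWSI)
#'
#' Normalizes canopy temperature by the temperatures of a wet (maximally
#' transpiring) and a dry (non-transpiring) reference surface imaged in the
#' same frame:
#' \deqn{CWSI = (T_{canopy} - T_{wet}) / (T_{dry} - T_{wet})}
#' A value of 0 corresponds to a fully transpiring canopy, 1 to a
#' non-transpiring one. Values outside \[0, 1\] can occur when the canopy is
#' cooler than the wet reference or warmer than the dry one; they are
#' retained (clipping would bias downstream models) and flagged with a
#' warning.
#'
#' @param t_canopy,t_wet,t_dry temperatures in degrees Celsius; vectors are
#'   recycled to a common length.
#' @param warn_out_of_range warn when a computed index falls outside
#'   \[0, 1\]? Default `TRUE`.
#' @return numeric vector of dimensionless index values.
#' @seealso [ig()] for the stomatal conductance index computed from the
#'   same temperatures.
#' @export
#' @examples
#' cwsi(30, 25, 35)        # 0.5
#' cwsi(25, 25, 35)        # 0: canopy at the wet reference
cwsi <- function(t_canopy, t_wet, t_dry, warn_out_of_range = TRUE) {
  stopifnot(is.numeric(t_canopy), is.numeric(t_wet), is.numeric(t_dry))
  if (any(!is.finite(t_canopy) | !is.finite(t_wet) | !is.finite(t_dry)))
    stop("non-finite temperature input")
  if (any(t_dry <= t_wet))
    stop("reference inversion: t_dry must be strictly greater than t_wet")
  out <- (t_canopy - t_wet) / (t_dry - t_wet)
  if (warn_out_of_range && any(out < 0 | out > 1))
    warning(sprintf("%d CWSI value(s) outside [0, 1] (canopy beyond references)",
                    sum(out < 0 | out > 1)))
  out
}

#' Stomatal conductance index (Ig)
#'
#' \deqn{I_g = (T_{dry} - T_{canopy}) / (T_{canopy} - T_{wet})}
#' Ig is linearly related to stomatal conductance: higher values indicate a
#' cooler, more freely transpiring canopy. Wherever both indices are
#' defined, \eqn{I_g = (1 - CWSI)/CWSI}.
#'
#' @inheritParams cwsi
#' @return numeric vector of dimensionless index values.
#' @export
#' @examples
#' ig(30, 25, 35)   # 1 at the midpoint
#' ig(35, 25, 35)   # 0 at the dry reference
ig <- function(t_canopy, t_wet, t_dry) {
  stopifnot(is.numeric(t_canopy), is.numeric(t_wet), is.numeric(t_dry))
  if (any(!is.finite(t_canopy) | !is.finite(t_wet) | !is.finite(t_dry)))
    stop("non-finite temperature input")
  if (any(t_canopy <= t_wet))
    stop("denominator nonpositive: t_canopy must be strictly greater than t_wet")
  (t_dry - t_canopy) / (t_canopy - t_wet)
}

#' Vapor pressure deficit (FAO-56 form)
#'
#' Saturation vapor pressure from the Tetens-type expression
#' \eqn{e_s = 0.6108 \exp(17.27 T / (T + 237.3))} (kPa), actual vapor
#' pressure \eqn{e_a = (RH/100) e_s}; the deficit is \eqn{e_s - e_a}.
#'
#' @param air_temp air temperature, degrees Celsius.
#' @param rh relative humidity, percent, in (0, 100].
#' @return vapor pressure deficit in kPa; zero at 100% relative humidity.
#' @export
#' @examples
#' vpd(20, 50)   # about 1.169 kPa
vpd <- function(air_temp, rh) {
  stopifnot(is.numeric(air_temp), is.numeric(rh))
  if (any(!is.finite(air_temp) | !is.finite(rh)))
    stop("non-finite input")
  if (any(rh <= 0 | rh > 100))
    stop("rh must be in (0, 100]")
  es <- 0.6108 * exp(17.27 * air_temp / (air_temp + 237.3))
  es - (rh / 100) * es
}

#' Percent soil water deficit from pot weights
#'
#' Depletion of plant-available water relative to field capacity:
#' \deqn{PSWD = (W_{fc} - W_{actual}) / W_{water,fc}}
#' where \eqn{W_{fc}} is the pot weight at field capacity, \eqn{W_{actual}}
#' the current pot weight and \eqn{W_{water,fc}} the absolute water content
#' at field capacity (for the peat substrate used here, 40% of pot weight
#' at a 10 kPa soil-water matrix potential). The result is a
#' deficit-positive fraction: 0 at field capacity, 1 when all
#' plant-available water at field capacity has been depleted, negative for
#' over-saturated pots.
#'
#' @param weight_actual current pot weight, g.
#' @param weight_field_capacity pot weight at field capacity, g.
#' @param water_content_fc absolute water content at field capacity, g; by
#'   default 40% of `weight_field_capacity`.
#' @return deficit fraction (multiply by 100 for percent).
#' @export
pswd <- function(weight_actual, weight_field_capacity,
                 water_content_fc = 0.4 * weight_field_capacity) {
  stopifnot(is.numeric(weight_actual), is.numeric(weight_field_capacity))
  if (any(weight_actual <= 0) || any(weight_field_capacity <= 0))
    stop("pot weights must be positive")
  if (any(water_content_fc <= 0))
    stop("water_content_fc must be positive")
  if (any(water_content_fc > weight_field_capacity))
    stop("water content at field capacity cannot exceed the pot weight")
  (weight_field_capacity - weight_actual) / water_content_fc
}

#' Summarize irrigation volumes per treatment
#'
#' Cumulative irrigation totals over the treatment window and the
#' drought-to-control percentage (rounded to the nearest integer), the
#' figure used to characterise the severity of a reduced-watering
#' treatment.
#'
#' @param control_ml,drought_ml cumulative irrigation volume per individual
#'   over the treatment window, ml.
#' @return list with `control_ml`, `drought_ml`, and `drought_pct_of_control`.
#' @export
#' @examples
#' irrigation_summary(3050, 725)$drought_pct_of_control   # 24
irrigation_summary <- function(control_ml, drought_ml) {
  stopifnot(is.numeric(control_ml), is.numeric(drought_ml),
            length(control_ml) == 1, length(drought_ml) == 1)
  if (control_ml < 0 || drought_ml < 0) stop("volumes must be nonnegative")
  if (control_ml == 0) stop("control total is zero; ratio undefined")
  list(control_ml = control_ml,
       drought_ml = drought_ml,
       drought_pct_of_control = as.integer(round(100 * drought_ml / control_ml)))
}

#' Length of a date window in days, inclusive of both endpoints
#'
#' @param start,end `Date`s or strings coercible by [as.Date()].
#' @return integer number of days.
#' @export
#' @examples
#' window_length_days("2013-07-11", "2013-08-21")  # 42
window_length_days <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end precedes start")
  as.integer(end - start) + 1L
}
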