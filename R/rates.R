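#' Classify an administration technique
#'
#' An administration whose start time equals its end time is a bolus;
#' otherwise it is a continuous intravenous administration.
#'
#' @param start_time,end_time POSIXct vectors.
#' @return Character vector, `"bolus"` or `"continuous"`.
#' @export
classify_technique <- function(start_time, end_time) {
  if (any(end_time < start_time, na.rm = TRUE)) {
    rlang::abort("end_time must not precede start_time.")
  }
  ifelse(as.numeric(end_time) == as.numeric(start_time), "bolus", "continuous")
}

# Normalize a rate to a canonical per-hour value.
# Returns list(dimension, value) with value in ml/h, mg/h or mg/kg/h;
# dimension NA when the unit is unknown.
normalize_rate <- function(value, unit, units_table, weight_kg = NA_real_) {
  hit <- match(unit, units_table$unit)
  if (is.na(hit)) return(list(dimension = NA_character_, value = NA_real_))
  dim <- units_table$dimension[hit]
  val <- value * units_table$factor[hit]
  if (identical(dim, "mass_rate_per_kg") && !is.na(weight_kg)) {
    # with a body weight per-kg rates become absolute mass rates;
    # without one they remain comparable only among themselves
    dim <- "mass_rate"
    val <- val * weight_kg
  }
  list(dimension = dim, value = val)
}

normalize_conc <- function(value, unit, units_table) {
  hit <- match(unit, units_table$unit)
  if (is.na(hit) || units_table$dimension[hit] != "concentration") return(NA_real_)
  value * units_table$factor[hit]
}

# Dose per time in mg/h for one episode; NA when it cannot be derived.
dose_per_time <- function(rate, rate_unit, conc, conc_unit, units_table,
                          weight_kg = NA_real_) {
  r <- normalize_rate(rate, rate_unit, units_table, weight_kg)
  if (is.na(r$dimension) || is.na(r$value)) return(NA_real_)
  if (r$dimension == "mass_rate_per_kg") return(NA_real_)
  if (r$dimension == "mass_rate") return(r$value)
  cm <- normalize_conc(conc, conc_unit, units_table)
  if (is.na(cm)) return(NA_real_)
  r$value * cm
}

#' Compare the rates of two continuous administrations
#'
#' Rates are directly comparable when they share a unit dimension (after
#' unit conversion) and the same concentration. When the concentrations
#' differ (for example propofol supplied at 10 mg/mL and at 20 mg/mL), the
#' administered doses per time (rate times concentration) are compared
#' instead. Per-kilogram rates need a body weight. When neither route gives
#' a common scale the result is `"incomparable"` and no rate-dependent rule
#' fires.
#'
#' @param rate_a,rate_b Numeric rates.
#' @param unit_a,unit_b Rate unit strings (see the shipped `units.csv`).
#' @param conc_a,conc_b Optional concentrations.
#' @param conc_unit_a,conc_unit_b Concentration units.
#' @param mappings An `alarm_mappings` object (for the unit table).
#' @param weight_kg Optional body weight for per-kg rates.
#' @return One of `"greater"`, `"less"`, `"equal"`, `"incomparable"`
#'   (comparison of a against b).
#' @export
#' @examples
#' m <- default_mappings()
#' comparable_rate(10, "ml/h", 6, "ml/h",
#'                 conc_a = 10, conc_unit_a = "mg/ml",
#'                 conc_b = 20, conc_unit_b = "mg/ml", mappings = m)
comparable_rate <- function(rate_a, unit_a, rate_b, unit_b,
                            conc_a = NA_real_, conc_unit_a = NA_character_,
                            conc_b = NA_real_, conc_unit_b = NA_character_,
                            mappings, weight_kg = NA_real_) {
  ut <- mappings$units
  a <- normalize_rate(rate_a, unit_a, ut, weight_kg)
  b <- normalize_rate(rate_b, unit_b, ut, weight_kg)
  same_conc <- (is.na(conc_a) && is.na(conc_b)) ||
    (!is.na(conc_a) && !is.na(conc_b) &&
       isTRUE(all.equal(normalize_conc(conc_a, conc_unit_a, ut),
                        normalize_conc(conc_b, conc_unit_b, ut))))
  va <- vb <- NA_real_
  if (!is.na(a$dimension) && !is.na(b$dimension) &&
      a$dimension == b$dimension && same_conc) {
    va <- a$value; vb <- b$value
  } else {
    va <- dose_per_time(rate_a, unit_a, conc_a, conc_unit_a, ut, weight_kg)
    vb <- dose_per_time(rate_b, unit_b, conc_b, conc_unit_b, ut, weight_kg)
  }
  if (is.na(va) || is.na(vb)) return("incomparable")
  if (isTRUE(all.equal(va, vb))) return("equal")
  if (va > vb) "greater" else "less"
}

#' Carrier or therapy role of an intravenous fluid
#'
#' Only for active ingredients classified as fluids for intravenous
#' administration: a fluid running strictly below the threshold rate (or,
#' for boluses, below the threshold amount per hour) is a carrier or
#' diluent and is ignored by every medication rule; at or above the
#' threshold it is a fluid therapy. With neither a rate nor an amount the
#' fluid is conservatively treated as a carrier, with a warning.
#'
#' @param rate Numeric rate (or `NA`).
#' @param rate_unit Rate unit.
#' @param amount Numeric amount (or `NA`), used when no rate is documented.
#' @param amount_unit Amount unit (`"ml"`/`"l"`).
#' @param mappings An `alarm_mappings` object.
#' @param threshold_ml_h Carrier/therapy threshold, mL/h (default 500).
#' @return `"carrier"` or `"therapy"`.
#' @export
fluid_role <- function(rate = NA_real_, rate_unit = NA_character_,
                       amount = NA_real_, amount_unit = NA_character_,
                       mappings, threshold_ml_h = 500) {
  ut <- mappings$units
  if (!is.na(rate) && !is.na(rate_unit)) {
    r <- normalize_rate(rate, rate_unit, ut)
    if (identical(r$dimension, "volume_rate") && !is.na(r$value)) {
      return(if (r$value < threshold_ml_h) "carrier" else "therapy")
    }
  }
  if (!is.na(amount) && !is.na(amount_unit)) {
    hit <- match(amount_unit, ut$unit)
    if (!is.na(hit) && ut$dimension[hit] == "volume_amount") {
      ml <- amount * ut$factor[hit]
      return(if (ml < threshold_ml_h) "carrier" else "therapy")
    }
  }
  rlang::warn("Fluid without rate or amount; treated as carrier.")
  "carrier"
}
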