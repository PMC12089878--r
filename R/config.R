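#' Annotation configuration
#'
#' Bundles every tunable constant of the annotation method. Defaults are the
#' method's published operating points: a 30-minute post-alarm window for
#' respiratory interventions, 15 minutes for medication interventions, a
#' 5-minute adjacency gap for chained start/stop comparisons, a 1-minute
#' tolerance for airway-device removals documented shortly after the
#' replacement, a 5-minute round-down granularity of PDMS medication
#' timestamps, and a 500 mL/h threshold separating carrier fluids from fluid
#' therapy.
#'
#' @param resp_window_min Post-alarm window for respiratory rules, minutes.
#' @param med_window_min Post-alarm window for medication rules, minutes.
#' @param med_adjacency_gap_min Gap linking an ending and a starting
#'   administration of the same ingredient (closed interval), minutes.
#' @param ad_removal_tolerance_min A new airway device documented up to this
#'   long before the previous one's removal still counts as a single change,
#'   minutes.
#' @param rounding_granularity_min Grid to which PDMS medication timestamps
#'   are rounded down, minutes.
#' @param fluid_carrier_threshold_ml_h Fluids running strictly below this
#'   rate (or amount per hour) are carriers, not therapy; at or above it they
#'   are therapy. mL/h.
#' @param rounding_compensation If `TRUE` (default) a medication timestamp on
#'   the rounding grid is treated as the uncertainty interval
#'   `[t, t + granularity)` when testing window membership, compensating the
#'   round-down documented in PDMS front ends.
#' @param range_bound Which bounds of the physiological range table remove
#'   implausible values: `"compatible"` (range compatible with life, default)
#'   or `"outlier"` (acceptable-outlier bounds).
#' @param planned_match_tolerance_min An administration within this long of a
#'   prescription's scheduled time (same order) counts as planned, minutes.
#' @return An object of class `alarm_config` (a named list).
#' @export
#' @examples
#' annotation_config()
annotation_config <- function(resp_window_min = 30,
                              med_window_min = 15,
                              med_adjacency_gap_min = 5,
                              ad_removal_tolerance_min = 1,
                              rounding_granularity_min = 5,
                              fluid_carrier_threshold_ml_h = 500,
                              rounding_compensation = TRUE,
                              range_bound = c("compatible", "outlier"),
                              planned_match_tolerance_min = 30) {
  range_bound <- match.arg(range_bound)
  durs <- c(
    resp_window_min = resp_window_min,
    med_window_min = med_window_min,
    med_adjacency_gap_min = med_adjacency_gap_min,
    ad_removal_tolerance_min = ad_removal_tolerance_min,
    rounding_granularity_min = rounding_granularity_min,
    fluid_carrier_threshold_ml_h = fluid_carrier_threshold_ml_h,
    planned_match_tolerance_min = planned_match_tolerance_min
  )
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    rlang::abort("All windows, tolerances and thresholds must be positive numbers.")
  }
  structure(
    list(
      resp_window_min = resp_window_min,
      med_window_min = med_window_min,
      med_adjacency_gap_min = med_adjacency_gap_min,
      ad_removal_tolerance_min = ad_removal_tolerance_min,
      rounding_granularity_min = rounding_granularity_min,
      fluid_carrier_threshold_ml_h = fluid_carrier_threshold_ml_h,
      rounding_compensation = isTRUE(rounding_compensation),
      range_bound = range_bound,
      planned_match_tolerance_min = planned_match_tolerance_min
    ),
    class = "alarm_config"
  )
}

#' @export
print.alarm_config <- function(x, ...) {
  cat("<alarm_config>\n")
  for (nm in names(x)) cat("  ", nm, ": ", as.character(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Read an annotation configuration from a key=value file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Unknown keys are an error. Values are coerced to the type of the matching
#' [annotation_config()] argument.
#'
#' @param path Path to the configuration file.
#' @return An `alarm_config` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(annotation_config())
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    rlang::abort(paste0("Malformed config line(s): ", paste(lines[bad], collapse = "; ")))
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  allowed <- names(formals(annotation_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) {
    rlang::abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "range_bound") return(vals[i])
    if (keys[i] == "rounding_compensation") return(toupper(vals[i]) %in% c("TRUE", "T", "1", "YES"))
    as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(annotation_config, args)
}
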