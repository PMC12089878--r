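#' Physiological range table
#'
#' Per-variable bounds used to remove implausible documented values before
#' annotation: the physiological range, the range compatible with life, and
#' the minimum/maximum acceptable outliers (physiological within
#' compatible-with-life within outlier bounds). The bundled table covers the
#' six settable ventilation parameters.
#'
#' @param path Optional path to a custom `range_table.csv`.
#' @return A tibble with columns `variable`, `phys_low`, `phys_high`,
#'   `life_low`, `life_high`, `outlier_low`, `outlier_high`.
#' @export
default_range_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "range_table.csv", package = "icualarms")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ok <- tab$life_low <= tab$phys_low & tab$phys_high <= tab$life_high &
    tab$outlier_low <= tab$life_low & tab$life_high <= tab$outlier_high
  if (!all(ok)) {
    rlang::abort(paste0("Range nesting violated for: ",
                        paste(tab$variable[!ok], collapse = ", ")))
  }
  tab
}

#' Link alarms to ICU stays via bed and timestamp
#'
#' Alarm logs carry only bed labels; interventions are documented per stay.
#' Each alarm is assigned the stay whose admission/discharge interval
#' (half-open, `[admit, discharge)`) covers its start time on the same bed.
#' Alarms falling in a gap stay unlinked and are excluded from annotation
#' statistics. Overlapping stays on one bed are a validation error.
#'
#' @param alarms Tibble with `alarm_id`, `bed_id`, `start_time`.
#' @param stays Tibble with `stay_ref`, `bed_id`, `admit_time`,
#'   `discharge_time`.
#' @return `alarms` with a `stay_ref` column (`NA` when unlinked).
#' @export
link_alarms_to_stays <- function(alarms, stays) {
  if (nrow(stays)) {
    by_bed <- split(stays, stays$bed_id)
    for (s in by_bed) {
      s <- s[order(s$admit_time), ]
      if (nrow(s) > 1 &&
          any(utils::head(s$discharge_time, -1) > utils::tail(s$admit_time, -1))) {
        rlang::abort(paste0("Overlapping stays on bed ", s$bed_id[1], "."))
      }
    }
  }
  ref <- rep(NA_character_, nrow(alarms))
  if (nrow(alarms) && nrow(stays)) {
    for (i in seq_len(nrow(alarms))) {
      hit <- which(stays$bed_id == alarms$bed_id[i] &
                     stays$admit_time <= alarms$start_time[i] &
                     alarms$start_time[i] < stays$discharge_time)
      if (length(hit) == 1) ref[i] <- stays$stay_ref[hit]
    }
  }
  dplyr::mutate(alarms, stay_ref = ref)
}

#' Remove documented values not compatible with life
#'
#' Filters a ventilation-parameter stream against the range table, dropping
#' values outside the chosen bounds (`"compatible"`: range compatible with
#' life; `"outlier"`: acceptable-outlier bounds). Variables absent from the
#' range table pass unfiltered with a warning. Surviving rows keep their
#' original order.
#'
#' @param params Tibble with at least `parameter` and `value`.
#' @param range_table See [default_range_table()].
#' @param bound `"compatible"` or `"outlier"`.
#' @return List with `kept` (filtered tibble) and `removed` (the removal
#'   log, same columns plus `reason`).
#' @export
filter_incompatible_values <- function(params,
                                       range_table = default_range_table(),
                                       bound = c("compatible", "outlier")) {
  bound <- match.arg(bound)
  lo_col <- if (bound == "compatible") "life_low" else "outlier_low"
  hi_col <- if (bound == "compatible") "life_high" else "outlier_high"
  idx <- match(params$parameter, range_table$variable)
  unknown <- is.na(idx)
  if (any(unknown)) {
    rlang::warn(paste0("No range bounds for: ",
                       paste(unique(params$parameter[unknown]), collapse = ", "),
                       "; values pass unfiltered."))
  }
  lo <- range_table[[lo_col]][idx]
  hi <- range_table[[hi_col]][idx]
  bad <- !unknown & (params$value < lo | params$value > hi)
  removed <- params[bad, , drop = FALSE]
  if (nrow(removed)) removed$reason <- paste0("outside ", bound, " range")
  list(kept = params[!bad, , drop = FALSE], removed = removed)
}

#' Exclude regular planned interventions
#'
#' Administrations executed as prescribed in advance (planned medication,
#' prophylactic respiratory support) are not reactions to an alarm and are
#' excluded before annotation: an administration is planned when a
#' prescription with the same order id is scheduled within the match
#' tolerance of its start.
#'
#' @param administrations Tibble with `order_id` and `start_time`.
#' @param prescriptions Tibble with `order_id` and `scheduled_time`; `NULL`
#'   disables the exclusion.
#' @param tolerance_min Match tolerance, minutes.
#' @return List with `kept` and `excluded` tibbles.
#' @export
exclude_planned <- function(administrations, prescriptions = NULL,
                            tolerance_min = 30) {
  if (is.null(prescriptions) || !nrow(administrations) || !nrow(prescriptions)) {
    return(list(kept = administrations,
                excluded = administrations[0, , drop = FALSE]))
  }
  planned <- vapply(seq_len(nrow(administrations)), function(i) {
    sched <- prescriptions$scheduled_time[
      prescriptions$order_id == administrations$order_id[i]]
    length(sched) > 0 &&
      any(abs(as.numeric(difftime(administrations$start_time[i], sched,
                                  units = "mins"))) <= tolerance_min)
  }, logical(1))
  list(kept = administrations[!planned, , drop = FALSE],
       excluded = administrations[planned, , drop = FALSE])
}

#' Round-down uncertainty interval of a documented timestamp
#'
#' PDMS front ends round a large share of medication timestamps down to the
#' nearest grid point (5 minutes by default). A timestamp sitting exactly on
#' the grid may therefore stand for any instant in `[ts, ts + granularity)`;
#' an off-grid timestamp is taken at face value (degenerate interval).
#'
#' @param ts POSIXct vector.
#' @param granularity_min Grid size, minutes.
#' @return A tibble with columns `lower` and `upper` (POSIXct).
#' @export
#' @examples
#' t <- as.POSIXct("2021-03-01 12:05:00", tz = "UTC")
#' timestamp_uncertainty(t, 5)
timestamp_uncertainty <- function(ts, granularity_min = 5) {
  if (granularity_min <= 0) rlang::abort("granularity must be positive")
  g <- granularity_min * 60
  on_grid <- (as.numeric(ts) %% g) == 0
  upper <- ts + ifelse(on_grid, g, 0)
  tibble::tibble(lower = ts, upper = upper)
}

#' Drop duplicated documentation rows
#'
#' Identical rows (all columns equal) are documentation duplicates; the
#' first is kept.
#'
#' @param tbl A tibble.
#' @return List with `kept` and `removed`.
#' @export
dedupe_rows <- function(tbl) {
  dup <- duplicated(tbl)
  list(kept = tbl[!dup, , drop = FALSE], removed = tbl[dup, , drop = FALSE])
}
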