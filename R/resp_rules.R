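#' Last documented value at or before a time point
#'
#' @param times POSIXct vector (any order).
#' @param values Vector parallel to `times`.
#' @param t Reference time; the latest event with `time <= t` wins.
#' @return A list with `value` and `time` (`NULL` value when no event
#'   qualifies).
#' @export
last_before <- function(times, values, t) {
  keep <- which(times <= t)
  if (!length(keep)) return(list(value = NULL, time = NULL))
  i <- keep[which.max(as.numeric(times[keep]))]
  list(value = values[i], time = times[i])
}

#' Peak documented value in a post-alarm window
#'
#' Several setting changes can follow one alarm; the rules compare against
#' the peak value in the half-open window `[t, t + w)`.
#'
#' @param times POSIXct vector.
#' @param values Numeric vector parallel to `times`.
#' @param t Window start (the alarm start).
#' @param w_min Window length, minutes.
#' @return A list with `value` and `time` of the maximum (`NULL` when the
#'   window is empty).
#' @export
max_in_window <- function(times, values, t, w_min) {
  keep <- which(times >= t & times < t + w_min * 60)
  if (!length(keep)) return(list(value = NULL, time = NULL))
  i <- keep[which.max(values[keep])]
  list(value = values[i], time = times[i])
}

# RST categories whose documented level survives an active standby
standby_exempt_categories <- function() {
  c("spontaneous_breathing", "oxygen_therapy")
}

# Current airway device at time t: the latest mapped record documented at or
# before t; removed (removal at or before t) means level 1 / no AD.
# Returns list(level, category); level 1 when nothing is documented.
current_ad <- function(ad_records, t, mappings) {
  if (!nrow(ad_records)) return(list(level = 1, category = "no_ad"))
  res <- resolve_ad_level(ad_records$entry_text, mappings)
  keep <- which(res$status == "mapped" & ad_records$insert_time <= t)
  if (!length(keep)) return(list(level = 1, category = "no_ad"))
  i <- keep[which.max(as.numeric(ad_records$insert_time[keep]))]
  removed <- !is.na(ad_records$removal_time[i]) && ad_records$removal_time[i] <= t
  if (removed) return(list(level = 1, category = "no_ad"))
  list(level = res$ad_level[i], category = res$ad_category[i])
}

# Resolve the vent-state rows to categories/levels once, with the airway
# device documented at each state's time deciding ambiguous VD-VM pairs.
resolve_states <- function(vent_states, ad_records, mappings) {
  if (!nrow(vent_states)) {
    return(cbind(vent_states,
                 tibble::tibble(rst_category = character(0),
                                rst_level = numeric(0),
                                status = character(0))))
  }
  ad_cat <- vapply(seq_len(nrow(vent_states)), function(i) {
    current_ad(ad_records, vent_states$time[i], mappings)$category
  }, character(1))
  r <- resolve_rst(vent_states$vd_text, vent_states$vm_text, ad_cat, mappings)
  vent_states$rst_category <- r$rst_category
  vent_states$rst_level <- r$rst_level
  vent_states$status <- r$status
  vent_states
}

#' Effective respiratory-support-therapy level at a time point
#'
#' The level of the last documented ventilation state at or before `t`,
#' with standby semantics: while the ventilator is in standby the
#' documented settings do not reflect delivered therapy, so the level is 0 -
#' except for spontaneous breathing and oxygen therapy, where standby is
#' allowed and the mapped level is kept. Level 0 exists only for this
#' purpose and never appears in the mapping itself. With no state documented
#' the patient is taken to breathe spontaneously (level 1); an unmapped
#' device/mode pair yields `NA` (unknown - rules using it do not fire).
#'
#' @param t Time point (POSIXct).
#' @param vent_states Tibble with `time`, `vd_text`, `vm_text`, `standby`.
#' @param ad_records Airway-device records (context for ambiguous pairs).
#' @param mappings An `alarm_mappings` object.
#' @return A single numeric level in 0-7, or `NA`.
#' @export
effective_rst_level <- function(t, vent_states, ad_records = NULL, mappings) {
  if (is.null(ad_records)) {
    ad_records <- tibble::tibble(entry_text = character(0),
                                 insert_time = as.POSIXct(character(0)),
                                 removal_time = as.POSIXct(character(0)))
  }
  st <- resolve_states(vent_states, ad_records, mappings)
  effective_level_of_last(st, t)
}

# effective level of the last resolved state at or before t (resolved via
# resolve_states); 1 when no state exists
effective_level_of_last <- function(resolved_states, t) {
  keep <- which(resolved_states$time <= t)
  if (!length(keep)) return(1)
  i <- keep[which.max(as.numeric(resolved_states$time[keep]))]
  effective_level_of_row(resolved_states, i)
}

effective_level_of_row <- function(resolved_states, i) {
  if (resolved_states$status[i] != "mapped") return(NA_real_)
  if (isTRUE(resolved_states$standby[i]) &&
      !(resolved_states$rst_category[i] %in% standby_exempt_categories())) {
    return(0)
  }
  resolved_states$rst_level[i]
}

no_match <- function() {
  list(fired = FALSE, matched_ref = NA_character_,
       matched_time = as.POSIXct(NA))
}

#' Airway-device change rule
#'
#' For a low-saturation alarm: fires when the peak airway-device level
#' documented in the post-alarm window exceeds the level at the alarm start
#' and no removal of the escalated device is logged within that window. A
#' device whose removal is documented inside the window did not stay in
#' place and does not count.
#'
#' @param alarm_time Alarm start (POSIXct).
#' @param ad_records Tibble with `entry_text`, `insert_time`,
#'   `removal_time`.
#' @param mappings An `alarm_mappings` object.
#' @param config An [annotation_config()].
#' @return List with `fired`, `matched_ref`, `matched_time`.
#' @export
rule_ad_change <- function(alarm_time, ad_records, mappings,
                           config = annotation_config()) {
  if (!nrow(ad_records)) return(no_match())
  w_end <- alarm_time + config$resp_window_min * 60
  last_level <- current_ad(ad_records, alarm_time, mappings)$level
  res <- resolve_ad_level(ad_records$entry_text, mappings)
  cand <- which(res$status == "mapped" &
                  ad_records$insert_time >= alarm_time &
                  ad_records$insert_time < w_end &
                  res$ad_level > last_level)
  if (!length(cand)) return(no_match())
  removed_in_window <- !is.na(ad_records$removal_time[cand]) &
    ad_records$removal_time[cand] >= alarm_time &
    ad_records$removal_time[cand] < w_end
  cand <- cand[!removed_in_window]
  if (!length(cand)) return(no_match())
  i <- cand[which.max(res$ad_level[cand])]
  list(fired = TRUE,
       matched_ref = paste0("ad:", ad_records$entry_text[i]),
       matched_time = ad_records$insert_time[i])
}

#' Respiratory-support-therapy change rule
#'
#' For a low-saturation alarm: fires when the peak effective therapy level
#' in the post-alarm window exceeds the effective level at the alarm start.
#' Effective levels apply standby semantics ([effective_rst_level()]), so a
#' change documented while standby is active contributes level 0 and never
#' fires the rule, while a ventilator in standby at the alarm (level 0)
#' makes any subsequent non-standby therapy an escalation.
#'
#' @inheritParams rule_ad_change
#' @param vent_states Tibble with `time`, `vd_text`, `vm_text`, `standby`.
#' @return List with `fired`, `matched_ref`, `matched_time`.
#' @export
rule_rst_change <- function(alarm_time, vent_states, ad_records = NULL,
                            mappings, config = annotation_config()) {
  if (is.null(ad_records)) {
    ad_records <- tibble::tibble(entry_text = character(0),
                                 insert_time = as.POSIXct(character(0)),
                                 removal_time = as.POSIXct(character(0)))
  }
  if (!nrow(vent_states)) return(no_match())
  st <- resolve_states(vent_states, ad_records, mappings)
  last_eff <- effective_level_of_last(st, alarm_time)
  if (is.na(last_eff)) return(no_match())
  w_end <- alarm_time + config$resp_window_min * 60
  win <- which(st$time >= alarm_time & st$time < w_end)
  if (!length(win)) return(no_match())
  eff <- vapply(win, function(i) effective_level_of_row(st, i), numeric(1))
  ok <- which(!is.na(eff) & eff > last_eff)
  if (!length(ok)) return(no_match())
  i <- win[ok[which.max(eff[ok])]]
  list(fired = TRUE,
       matched_ref = paste0("rst:", st$vd_text[i], "/", st$vm_text[i]),
       matched_time = st$time[i])
}

# Adjusted parameter value at a setting: 0 while standby is active at that
# time (except oxygen flow during oxygen therapy), 0 when the parameter
# cannot be set under the therapy level in force at that time.
adjusted_param_value <- function(value, at_time, parameter, resolved_states,
                                 mappings) {
  keep <- which(resolved_states$time <= at_time)
  if (!length(keep)) {
    lvl <- 1
    standby <- FALSE
    cat <- "spontaneous_breathing"
  } else {
    i <- keep[which.max(as.numeric(resolved_states$time[keep]))]
    if (resolved_states$status[i] != "mapped") return(0)
    lvl <- resolved_states$rst_level[i]
    standby <- isTRUE(resolved_states$standby[i])
    cat <- resolved_states$rst_category[i]
  }
  if (standby && !(cat %in% standby_exempt_categories()) &&
      !(parameter == "o2_flow" && cat == "oxygen_therapy")) {
    return(0)
  }
  if (!is_settable(lvl, parameter, mappings)) return(0)
  value
}

#' Ventilation-parameter increase rule
#'
#' For a low-saturation alarm and one settable parameter (oxygen flow rate,
#' FiO2, PEEP, pressure support, inspiratory pressure, or set rate): fires
#' when the last value before the alarm is strictly below the peak value set
#' in the post-alarm window. Values documented while the parameter cannot be
#' set under the therapy in force at the setting's time (or while the
#' ventilator is in standby, oxygen flow during oxygen therapy excepted)
#' count as 0 - a PEEP entry during oxygen therapy, for instance, is a
#' documentation artifact. With no prior setting the last value is 0.
#'
#' @inheritParams rule_rst_change
#' @param parameter One of [vent_parameters()].
#' @param vent_params Tibble with `time`, `parameter`, `value`.
#' @return List with `fired`, `matched_ref`, `matched_time`.
#' @export
rule_param_increase <- function(alarm_time, parameter, vent_params,
                                vent_states, ad_records = NULL, mappings,
                                config = annotation_config()) {
  stopifnot(parameter %in% vent_parameters())
  if (is.null(ad_records)) {
    ad_records <- tibble::tibble(entry_text = character(0),
                                 insert_time = as.POSIXct(character(0)),
                                 removal_time = as.POSIXct(character(0)))
  }
  series <- vent_params[vent_params$parameter == parameter, , drop = FALSE]
  if (!nrow(series)) return(no_match())
  st <- resolve_states(vent_states, ad_records, mappings)
  w_end <- alarm_time + config$resp_window_min * 60

  lb <- last_before(series$time, series$value, alarm_time)
  last_val <- if (is.null(lb$value)) 0 else {
    adjusted_param_value(lb$value, alarm_time, parameter, st, mappings)
  }

  win <- which(series$time >= alarm_time & series$time < w_end)
  if (!length(win)) return(no_match())
  adj <- vapply(win, function(i) {
    adjusted_param_value(series$value[i], series$time[i], parameter, st,
                         mappings)
  }, numeric(1))
  i <- win[which.max(adj)]
  if (max(adj) <= last_val) return(no_match())
  list(fired = TRUE,
       matched_ref = paste0("param:", parameter, "=", series$value[i]),
       matched_time = series$time[i])
}
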