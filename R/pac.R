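#' Physiological alarm conditions (PACs)
#'
#' The annotation method evaluates monitor alarms grouped into five
#' physiological alarm conditions, each tied to one vital sign (pulse
#' oximetry, electrocardiogram heart rate, or invasive blood pressure) and a
#' threshold direction. Only the low-saturation condition is eligible for the
#' respiratory rules; all five are eligible for the medication rules.
#'
#' @return A tibble with one row per PAC and columns `pac_id`, `vital_sign`
#'   and `direction`.
#' @export
#' @examples
#' pac_table()
pac_table <- function() {
  tibble::tibble(
    pac_id     = c("SpO2_low", "HR_low", "HR_high", "IBP_low", "IBP_high"),
    vital_sign = c("SpO2", "HR", "HR", "invasive BP", "invasive BP"),
    direction  = c("low", "low", "high", "low", "high")
  )
}

#' Monitor alarm labels and their PAC assignment
#'
#' The 14 alarm labels emitted by the bedside monitors, as they appear in the
#' alarm logs (German vendor spellings included), together with the PAC each
#' one resolves to. Labels whose vital sign can alarm in both directions
#' (`HF`, `ABPs`, `ARTs`, `ABPm`, `ARTm`) carry `NA` here and need a
#' threshold direction at classification time.
#'
#' @return A tibble with columns `alarm_label` and `pac_id` (`NA` for
#'   direction-dependent labels).
#' @export
alarm_label_table <- function() {
  tibble::tibble(
    alarm_label = c(
      "Desat", "SpO2", "SpO2l", "SpO2r", "SpO2po", "SpO2pr",
      "Asystolie", "xBrady", "xTachy", "HF",
      "ABPs", "ARTs", "ABPm", "ARTm"
    ),
    vital_sign = c(
      rep("SpO2", 6),
      rep("HR", 4),
      rep("invasive BP", 4)
    ),
    pac_id = c(
      rep("SpO2_low", 6),
      "HR_low", "HR_low", "HR_high", NA,
      NA, NA, NA, NA
    )
  )
}

#' @rdname alarm_label_table
#' @export
alarm_labels <- function() alarm_label_table()$alarm_label

#' Classify a monitor alarm label into its PAC
#'
#' Resolves each of the 14 monitor alarm labels to one of the five PACs.
#' Saturation labels always map to `SpO2_low`; `Asystolie` and `xBrady` to
#' `HR_low`; `xTachy` to `HR_high`. The generic heart-rate label `HF` and the
#' invasive-pressure labels (`ABPs`, `ARTs`, `ABPm`, `ARTm`) alarm on either
#' threshold, so the crossed direction (`"low"` or `"high"`, normally taken
#' from the threshold column of the alarm log) must be supplied for them.
#'
#' @param alarm_label Character vector of monitor labels.
#' @param direction Optional character vector (recycled) of threshold
#'   directions, `"low"` or `"high"`; ignored for labels with a fixed PAC.
#' @return Character vector of PAC ids (see [pac_table()]).
#' @export
#' @examples
#' classify_pac("Desat")
#' classify_pac("ABPs", direction = "high")
classify_pac <- function(alarm_label, direction = NULL) {
  tab <- alarm_label_table()
  idx <- match(alarm_label, tab$alarm_label)
  if (anyNA(idx)) {
    bad <- unique(alarm_label[is.na(idx)])
    rlang::abort(paste0(
      "Unknown alarm label(s): ", paste(bad, collapse = ", "),
      ". Expected one of the 14 monitor labels; see alarm_labels()."
    ))
  }
  pac <- tab$pac_id[idx]
  needs_dir <- is.na(pac)
  if (any(needs_dir)) {
    if (is.null(direction)) {
      rlang::abort(paste0(
        "Labels ", paste(unique(alarm_label[needs_dir]), collapse = ", "),
        " alarm on both thresholds; supply `direction` (\"low\"/\"high\")."
      ))
    }
    dir <- rep_len(as.character(direction), length(alarm_label))
    if (!all(dir[needs_dir] %in% c("low", "high"))) {
      rlang::abort("`direction` must be \"low\" or \"high\" for HF/ABP/ART labels.")
    }
    vs <- tab$vital_sign[idx]
    pac[needs_dir] <- ifelse(
      vs[needs_dir] == "HR",
      ifelse(dir[needs_dir] == "low", "HR_low", "HR_high"),
      ifelse(dir[needs_dir] == "low", "IBP_low", "IBP_high")
    )
  }
  pac
}

#' Intervention taxonomy
#'
#' The thirteen airway- and medication-management actions the rule set can
#' recognise: the airway-device change, the respiratory-support-therapy
#' change, an increase in each of the six settable ventilation parameters,
#' and the five medication actions.
#'
#' @return A tibble with columns `intervention_id`, `group` and `rule_id`
#'   (the rule that detects the intervention).
#' @export
intervention_types <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      intervention_id = c("ad_change", "rst_change"),
      group = "respiratory",
      rule_id = c("ad_change", "rst_change")
    ),
    tibble::tibble(
      intervention_id = paste0("param_increase_", vent_parameters()),
      group = "respiratory",
      rule_id = "param_increase"
    ),
    tibble::tibble(
      intervention_id = c("med_bolus", "med_start", "med_increase",
                          "med_stop", "med_decrease"),
      group = "medication",
      rule_id = c("med_bolus", "med_start", "med_increase",
                  "med_stop", "med_decrease")
    )
  )
}

#' Settable ventilation parameters evaluated by the parameter-increase rule
#'
#' Oxygen flow is one logical parameter here; whether it is read from the
#' flowmeter column or the ventilator column of the compatibility table is
#' decided by the respiratory-support-therapy level at the time of the
#' setting (level 2 means flowmeter oxygen therapy).
#'
#' @return Character vector of the six parameter ids.
#' @export
vent_parameters <- function() {
  c("o2_flow", "fio2", "peep", "psupp", "pinsp", "set_rate")
}
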