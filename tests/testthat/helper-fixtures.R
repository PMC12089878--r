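# shared fixtures: the bundled mapping is loaded once per test run
MAPS <- default_mappings()
CFG <- annotation_config()

ts <- function(x) as.POSIXct(x, tz = "UTC")
T0 <- ts("2021-03-01 10:00:07")

ad_tbl <- function(entry, insert_min, removal_min = NA_real_,
                   stay = "S1") {
  tibble::tibble(
    stay_ref = stay, entry_text = entry,
    insert_time = T0 + insert_min * 60,
    removal_time = T0 + ifelse(is.na(removal_min), NA, removal_min) * 60
  )
}

vs_tbl <- function(vd, vm, at_min, standby = FALSE, stay = "S1") {
  tibble::tibble(stay_ref = stay, time = T0 + at_min * 60,
                 vd_text = vd, vm_text = vm, standby = standby)
}

vp_tbl <- function(parameter, value, at_min, stay = "S1") {
  tibble::tibble(stay_ref = stay, time = T0 + at_min * 60,
                 parameter = parameter, value = value)
}

med_tbl <- function(drug, start_min, end_min, rate = NA_real_,
                    rate_unit = NA_character_, conc = NA_real_,
                    conc_unit = NA_character_, amount = NA_real_,
                    amount_unit = NA_character_, order = NULL,
                    stay = "S1") {
  n <- max(length(drug), length(start_min))
  tibble::tibble(
    stay_ref = stay,
    order_id = if (is.null(order)) paste0("O", seq_len(n)) else order,
    drug_id = drug,
    start_time = T0 + start_min * 60, end_time = T0 + end_min * 60,
    rate = rate, rate_unit = rate_unit,
    concentration = conc, conc_unit = conc_unit,
    amount = amount, amount_unit = amount_unit,
    route_text = "i.v."
  )
}

empty_ad <- function() ad_tbl(character(0), numeric(0))
empty_vs <- function() vs_tbl(character(0), character(0), numeric(0),
                              logical(0))
empty_vp <- function() vp_tbl(character(0), numeric(0), numeric(0))
empty_med <- function() med_tbl(character(0), numeric(0), numeric(0))

recovery_rate <- function(bundle, mappings = MAPS, config = CFG) {
  ann <- annotate_alarms(bundle$alarms, bundle$stays, bundle$ad_records,
                         bundle$vent_states, bundle$vent_params,
                         bundle$medications, bundle$prescriptions,
                         mappings = mappings, config = config)
  res <- dplyr::distinct(ann$results, alarm_id, label)
  cmp <- dplyr::left_join(bundle$ledger, res, by = "alarm_id")
  list(all = mean(cmp$true_label == cmp$label),
       actionable = mean(cmp$label[cmp$true_label == "actionable"] ==
                           "actionable"),
       cmp = cmp, ann = ann)
}
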