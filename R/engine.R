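#' The rule registry
#'
#' The eight general annotation rules: three respiratory rules, applicable
#' only to the low-saturation condition and evaluated over the 30-minute
#' window, and five medication rules evaluated over the 15-minute window
#' (stop and decrease never apply to the low-saturation condition).
#'
#' @return A tibble with columns `rule_id`, `group`, `applicable_pacs`
#'   (comma-separated PAC ids) and `window` (`"resp"` or `"med"`).
#' @export
rule_registry <- function() {
  pacs <- pac_table()$pac_id
  all_pacs <- paste(pacs, collapse = ",")
  not_spo2 <- paste(setdiff(pacs, "SpO2_low"), collapse = ",")
  tibble::tibble(
    rule_id = c("ad_change", "rst_change", "param_increase",
                "med_bolus", "med_start", "med_increase",
                "med_stop", "med_decrease"),
    group = c(rep("respiratory", 3), rep("medication", 5)),
    applicable_pacs = c(rep("SpO2_low", 3), all_pacs, all_pacs, all_pacs,
                        not_spo2, not_spo2),
    window = c(rep("resp", 3), rep("med", 5))
  )
}

rules_for_pac <- function(pac) {
  reg <- rule_registry()
  reg$rule_id[vapply(strsplit(reg$applicable_pacs, ","),
                     function(p) pac %in% p, logical(1))]
}

empty_table <- function(kind) {
  t0 <- as.POSIXct(character(0), tz = "UTC")
  switch(kind,
    ad = tibble::tibble(stay_ref = character(0), entry_text = character(0),
                        insert_time = t0, removal_time = t0),
    vent_states = tibble::tibble(stay_ref = character(0), time = t0,
                                 vd_text = character(0),
                                 vm_text = character(0), standby = logical(0)),
    vent_params = tibble::tibble(stay_ref = character(0), time = t0,
                                 parameter = character(0), value = numeric(0)),
    medications = tibble::tibble(stay_ref = character(0),
                                 order_id = character(0),
                                 drug_id = character(0),
                                 start_time = t0, end_time = t0,
                                 rate = numeric(0), rate_unit = character(0),
                                 concentration = numeric(0),
                                 conc_unit = character(0),
                                 amount = numeric(0),
                                 amount_unit = character(0),
                                 route_text = character(0))
  )
}

require_cols <- function(tbl, cols, name) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    rlang::abort(paste0("Table '", name, "' lacks required column(s): ",
                        paste(missing, collapse = ", ")))
  }
}

#' Annotate one alarm
#'
#' Evaluates every rule applicable to the alarm's PAC against the stay's
#' intervention records and labels the alarm actionable iff at least one
#' rule fires.
#'
#' @param alarm_time Alarm start (POSIXct).
#' @param pac PAC id.
#' @param ad_records,vent_states,vent_params One stay's respiratory
#'   documentation (may be empty tibbles).
#' @param episodes One stay's medication episodes ([build_episodes()]).
#' @param mappings An `alarm_mappings` object.
#' @param config An [annotation_config()].
#' @return A tibble with one row per fired rule (`rule_id`, `matched_ref`,
#'   `matched_time`); zero rows mean nonactionable.
#' @export
annotate_alarm <- function(alarm_time, pac, ad_records, vent_states,
                           vent_params, episodes, mappings,
                           config = annotation_config()) {
  fired <- list()
  if (pac == "SpO2_low") {
    r <- rule_ad_change(alarm_time, ad_records, mappings, config)
    if (r$fired) {
      fired[[length(fired) + 1]] <- tibble::tibble(
        rule_id = "ad_change", matched_ref = r$matched_ref,
        matched_time = r$matched_time)
    }
    r <- rule_rst_change(alarm_time, vent_states, ad_records, mappings, config)
    if (r$fired) {
      fired[[length(fired) + 1]] <- tibble::tibble(
        rule_id = "rst_change", matched_ref = r$matched_ref,
        matched_time = r$matched_time)
    }
    for (p in unique(vent_params$parameter)) {
      if (!p %in% vent_parameters()) next
      r <- rule_param_increase(alarm_time, p, vent_params, vent_states,
                               ad_records, mappings, config)
      if (r$fired) {
        fired[[length(fired) + 1]] <- tibble::tibble(
          rule_id = "param_increase", matched_ref = r$matched_ref,
          matched_time = r$matched_time)
      }
    }
  }
  med <- evaluate_medication_rules(alarm_time, pac, episodes, mappings, config)
  if (nrow(med)) fired[[length(fired) + 1]] <- med
  if (!length(fired)) {
    return(tibble::tibble(rule_id = character(0), matched_ref = character(0),
                          matched_time = as.POSIXct(character(0))))
  }
  dplyr::bind_rows(fired)
}

#' Annotate a full alarm dataset
#'
#' Runs the whole method: PAC classification, stay linkage, preprocessing
#' (deduplication, removal of values not compatible with life, exclusion of
#' planned administrations), and per-alarm rule evaluation. Each alarm is
#' annotated individually; co-occurring alarms share matched interventions.
#'
#' @param alarms Tibble with `alarm_id`, `bed_id`, `start_time` and either
#'   `pac` or `alarm_label` (plus `threshold_direction` for labels alarming
#'   on both thresholds).
#' @param stays Tibble with `stay_ref`, `bed_id`, `admit_time`,
#'   `discharge_time`. May be `NULL` when `alarms` already carries
#'   `stay_ref`.
#' @param ad_records,vent_states,vent_params,medications,prescriptions
#'   PDMS-style documentation tibbles (any may be `NULL`).
#' @param mappings An `alarm_mappings` object; defaults to the bundled
#'   synthetic mapping.
#' @param config An [annotation_config()].
#' @return An object of class `alarm_annotation` with components `results`
#'   (long tibble, one row per fired rule plus one row per
#'   nonactionable/unlinked alarm), `summary`, `log` (preprocessing counts)
#'   and `config`.
#' @export
#' @examples
#' bundle <- simulate_bundle(n_stays = 2, seed = 7)
#' ann <- annotate_alarms(bundle$alarms, bundle$stays, bundle$ad_records,
#'                        bundle$vent_states, bundle$vent_params,
#'                        bundle$medications, bundle$prescriptions)
#' glance(ann)
annotate_alarms <- function(alarms, stays = NULL, ad_records = NULL,
                            vent_states = NULL, vent_params = NULL,
                            medications = NULL, prescriptions = NULL,
                            mappings = default_mappings(),
                            config = annotation_config()) {
  require_cols(alarms, c("alarm_id", "start_time"), "alarms")
  if (is.null(ad_records)) ad_records <- empty_table("ad")
  if (is.null(vent_states)) vent_states <- empty_table("vent_states")
  if (is.null(vent_params)) vent_params <- empty_table("vent_params")
  if (is.null(medications)) medications <- empty_table("medications")
  require_cols(ad_records, c("stay_ref", "entry_text", "insert_time"),
               "ad_records")
  require_cols(vent_states, c("stay_ref", "time", "vd_text", "vm_text",
                              "standby"), "vent_states")
  require_cols(vent_params, c("stay_ref", "time", "parameter", "value"),
               "vent_params")
  require_cols(medications, c("stay_ref", "order_id", "drug_id",
                              "start_time", "end_time"), "medications")

  log <- list()
  if (!"pac" %in% names(alarms)) {
    require_cols(alarms, "alarm_label", "alarms")
    dir <- if ("threshold_direction" %in% names(alarms)) {
      alarms$threshold_direction
    } else NULL
    alarms$pac <- classify_pac(alarms$alarm_label, dir)
  }
  if (!"stay_ref" %in% names(alarms)) {
    if (is.null(stays)) {
      rlang::abort("Provide `stays` or a `stay_ref` column on `alarms`.")
    }
    require_cols(alarms, "bed_id", "alarms")
    alarms <- link_alarms_to_stays(alarms, stays)
  }
  log$alarms_in <- nrow(alarms)
  log$alarms_unlinked <- sum(is.na(alarms$stay_ref))

  for (nm in c("ad_records", "vent_states", "vent_params", "medications")) {
    dd <- dedupe_rows(get(nm))
    assign(nm, dd$kept)
    log[[paste0(nm, "_deduped")]] <- nrow(dd$removed)
  }
  fl <- filter_incompatible_values(vent_params, bound = config$range_bound)
  vent_params <- fl$kept
  log$vent_params_removed <- nrow(fl$removed)
  ex <- exclude_planned(medications, prescriptions,
                        tolerance_min = config$planned_match_tolerance_min)
  medications <- ex$kept
  log$medications_planned_excluded <- nrow(ex$excluded)

  episodes <- build_episodes(medications, mappings, config)
  log$episodes_unmapped <- sum(episodes$status == "unmapped")

  ord <- function(tbl, col) tbl[order(tbl$stay_ref, tbl[[col]]), , drop = FALSE]
  ad_by <- split(ord(ad_records, "insert_time"), ad_records$stay_ref[order(ad_records$stay_ref, ad_records$insert_time)])
  vs_by <- split(ord(vent_states, "time"), vent_states$stay_ref[order(vent_states$stay_ref, vent_states$time)])
  vp_by <- split(ord(vent_params, "time"), vent_params$stay_ref[order(vent_params$stay_ref, vent_params$time)])
  ep_by <- split(ord(episodes, "start_time"), episodes$stay_ref[order(episodes$stay_ref, episodes$start_time)])
  get_or_empty <- function(lst, ref, kind) {
    x <- lst[[ref]]
    if (is.null(x)) empty_table(kind) else x
  }

  res <- vector("list", nrow(alarms))
  for (i in seq_len(nrow(alarms))) {
    aid <- alarms$alarm_id[i]
    pac <- alarms$pac[i]
    t0 <- alarms$start_time[i]
    ref <- alarms$stay_ref[i]
    base <- tibble::tibble(
      alarm_id = aid, pac = pac, start_time = t0, stay_ref = ref,
      window_resp_end = t0 + config$resp_window_min * 60,
      window_med_end = t0 + config$med_window_min * 60
    )
    if (is.na(ref)) {
      res[[i]] <- dplyr::mutate(base, label = "unlinked",
                                rule_id = NA_character_,
                                matched_ref = NA_character_,
                                matched_time = as.POSIXct(NA))
      next
    }
    fired <- annotate_alarm(
      t0, pac,
      get_or_empty(ad_by, ref, "ad"),
      get_or_empty(vs_by, ref, "vent_states"),
      get_or_empty(vp_by, ref, "vent_params"),
      if (is.null(ep_by[[ref]])) episodes[0, , drop = FALSE] else ep_by[[ref]],
      mappings, config
    )
    if (nrow(fired)) {
      res[[i]] <- dplyr::mutate(
        dplyr::cross_join(base, fired), label = "actionable",
        .before = "rule_id")
    } else {
      res[[i]] <- dplyr::mutate(base, label = "nonactionable",
                                rule_id = NA_character_,
                                matched_ref = NA_character_,
                                matched_time = as.POSIXct(NA))
    }
  }
  results <- dplyr::bind_rows(res)
  if (!nrow(results)) {
    results <- tibble::tibble(
      alarm_id = character(0), pac = character(0),
      start_time = as.POSIXct(character(0), tz = "UTC"),
      stay_ref = character(0),
      window_resp_end = as.POSIXct(character(0), tz = "UTC"),
      window_med_end = as.POSIXct(character(0), tz = "UTC"),
      label = character(0), rule_id = character(0),
      matched_ref = character(0),
      matched_time = as.POSIXct(character(0), tz = "UTC")
    )
  }
  per_alarm <- results %>%
    dplyr::distinct(.data$alarm_id, .data$pac, .data$label)
  summary <- per_alarm %>%
    dplyr::count(.data$pac, .data$label, name = "n_alarms")
  structure(
    list(results = results, summary = summary,
         log = tibble::as_tibble(log), config = config),
    class = "alarm_annotation"
  )
}

#' @export
print.alarm_annotation <- function(x, ...) {
  g <- glance(x)
  cat("<alarm_annotation> ", g$n_alarms, " alarms: ",
      g$n_actionable, " actionable, ", g$n_nonactionable,
      " nonactionable, ", g$n_unlinked, " unlinked\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy an annotation result
#'
#' One row per fired rule, plus one row (empty `rule_id`) per
#' nonactionable or unlinked alarm.
#'
#' @param x An `alarm_annotation` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.alarm_annotation <- function(x, ...) x$results

#' One-row summary of an annotation run
#'
#' @param x An `alarm_annotation` object.
#' @param ... Unused.
#' @return A one-row tibble with alarm and rule-firing counts.
#' @exportS3Method generics::glance
glance.alarm_annotation <- function(x, ...) {
  per_alarm <- x$results %>%
    dplyr::distinct(.data$alarm_id, .data$label)
  tibble::tibble(
    n_alarms = nrow(per_alarm),
    n_actionable = sum(per_alarm$label == "actionable"),
    n_nonactionable = sum(per_alarm$label == "nonactionable"),
    n_unlinked = sum(per_alarm$label == "unlinked"),
    n_rules_fired = sum(!is.na(x$results$rule_id))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an annotation result
#'
#' Stacked bar chart of alarm labels per PAC.
#'
#' @param object An `alarm_annotation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.alarm_annotation <- function(object, ...) {
  per_alarm <- object$results %>%
    dplyr::distinct(.data$alarm_id, .data$pac, .data$label)
  ggplot2::ggplot(per_alarm,
                  ggplot2::aes(x = .data$pac, fill = .data$label)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "physiological alarm condition", y = "alarms",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of fired rules
#'
#' @param object An `alarm_annotation` object.
#' @return A ggplot object.
#' @export
plot_rule_counts <- function(object) {
  fired <- object$results %>% dplyr::filter(!is.na(.data$rule_id))
  ggplot2::ggplot(fired, ggplot2::aes(x = .data$rule_id)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "rule", y = "times fired") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
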