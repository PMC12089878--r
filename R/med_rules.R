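#' Build administration episodes from raw medication rows
#'
#' Resolves each documented administration against the medication mapping:
#' the drug id yields the active ingredient (or, for multi-ingredient
#' products, the sorted ingredient set treated as one unit via the mixture
#' mapping), the technique follows from the timestamps (bolus iff start
#' equals end), and intravenous fluids running below the carrier threshold
#' are dropped as carriers/diluents. Episodes of unmapped drug ids are kept
#' with status `"unmapped"` so batches never halt, but no rule fires on
#' them.
#'
#' @param medications Tibble with `order_id`, `drug_id`, `start_time`,
#'   `end_time` and optional `rate`, `rate_unit`, `concentration`,
#'   `conc_unit`, `amount`, `amount_unit`, `route_text`.
#' @param mappings An `alarm_mappings` object.
#' @param config An [annotation_config()].
#' @return A tibble of episodes with `ingredient_key`, `is_mixture`,
#'   `technique`, `status`, `fluid` and per-PAC relevance columns.
#' @export
build_episodes <- function(medications, mappings,
                           config = annotation_config()) {
  n <- nrow(medications)
  med <- medications
  for (col in c("rate", "concentration", "amount")) {
    if (is.null(med[[col]])) med[[col]] <- NA_real_
  }
  for (col in c("rate_unit", "conc_unit", "amount_unit")) {
    if (is.null(med[[col]])) med[[col]] <- NA_character_
  }
  map <- mappings$medication
  by_drug <- split(map, map$drug_id)
  key <- character(n); is_mix <- logical(n); status <- character(n)
  is_fluid <- logical(n)
  for (i in seq_len(n)) {
    rows <- by_drug[[as.character(med$drug_id[i])]]
    if (is.null(rows)) {
      key[i] <- NA_character_; is_mix[i] <- FALSE; status[i] <- "unmapped"
      next
    }
    ing <- sort(unique(rows$active_ingredient))
    key[i] <- paste(ing, collapse = "+")
    is_mix[i] <- length(ing) > 1
    status[i] <- "mapped"
    is_fluid[i] <- length(ing) == 1 && any(rows$is_iv_fluid)
  }
  med$ingredient_key <- key
  med$is_mixture <- is_mix
  med$status <- status
  med$technique <- classify_technique(med$start_time, med$end_time)

  med$fluid <- NA_character_
  fl <- which(is_fluid)
  for (i in fl) {
    med$fluid[i] <- fluid_role(
      rate = med$rate[i], rate_unit = med$rate_unit[i],
      amount = med$amount[i], amount_unit = med$amount_unit[i],
      mappings = mappings,
      threshold_ml_h = config$fluid_carrier_threshold_ml_h
    )
  }
  med <- med[is.na(med$fluid) | med$fluid != "carrier", , drop = FALSE]

  rel <- relevance_table(mappings)
  idx <- match(med$ingredient_key, rel$ingredient_key)
  for (col in grep("^rel_", names(rel), value = TRUE)) {
    med[[col]] <- !is.na(idx) & rel[[col]][idx]
  }
  med$episode_id <- paste0("ep", seq_len(nrow(med)))
  tibble::as_tibble(med)
}

# One relevance row per ingredient key (single ingredients from the
# medication mapping, sets from the mixture mapping).
relevance_table <- function(mappings) {
  rel_cols <- grep("^rel_", names(mappings$medication), value = TRUE)
  singles <- mappings$medication %>%
    dplyr::group_by(ingredient_key = .data$active_ingredient) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(rel_cols), any),
                     .groups = "drop")
  mixes <- mappings$mixture %>%
    dplyr::rename(ingredient_key = "ingredient_set")
  dplyr::bind_rows(singles, mixes[, c("ingredient_key", rel_cols)]) %>%
    dplyr::distinct(.data$ingredient_key, .keep_all = TRUE)
}

# TRUE when a documented timestamp may fall inside [w_start, w_end) once its
# round-down uncertainty is taken into account (degenerate off-grid).
in_window_ts <- function(ts, w_start, w_end, config) {
  if (config$rounding_compensation) {
    u <- timestamp_uncertainty(ts, config$rounding_granularity_min)
    u$upper > w_start & u$lower < w_end
  } else {
    ts >= w_start & ts < w_end
  }
}

compare_episode_rates <- function(a, b, mappings) {
  comparable_rate(
    a$rate, a$rate_unit, b$rate, b$rate_unit,
    conc_a = a$concentration, conc_unit_a = a$conc_unit,
    conc_b = b$concentration, conc_unit_b = b$conc_unit,
    mappings = mappings
  )
}

#' Evaluate the five medication rules for one alarm
#'
#' All rules work on one active ingredient (or relevant mixture) at a time
#' over the 15-minute post-alarm window. "Administration or increase in
#' dosage" (bolus, start, increase) applies to every PAC;
#' "administration stopped or reduction in dosage" (stop, decrease) applies
#' to every PAC except the low-saturation condition. Start falls back to
#' the increase check when a same-ingredient administration ended within
#' the 5-minute adjacency gap or runs in parallel; stop falls back to the
#' decrease check symmetrically. Rates are compared per
#' [comparable_rate()]; incomparable rates never fire a rate-dependent
#' rule.
#'
#' @param alarm_time Alarm start (POSIXct).
#' @param pac The alarm's PAC id.
#' @param episodes Episodes from [build_episodes()] (one stay's worth).
#' @param mappings An `alarm_mappings` object.
#' @param config An [annotation_config()].
#' @return A tibble with one row per fired rule: `rule_id`, `matched_ref`,
#'   `matched_time`.
#' @export
evaluate_medication_rules <- function(alarm_time, pac, episodes, mappings,
                                      config = annotation_config()) {
  out <- list()
  emit <- function(rule_id, ref, time) {
    out[[length(out) + 1]] <<- tibble::tibble(
      rule_id = rule_id, matched_ref = ref, matched_time = time
    )
  }
  w_start <- alarm_time
  w_end <- alarm_time + config$med_window_min * 60
  gap <- config$med_adjacency_gap_min * 60
  ep <- episodes[episodes$status == "mapped", , drop = FALSE]
  ep <- ep[order(ep$start_time, ep$end_time, ep$order_id), , drop = FALSE]

  give <- ep[ep[[paste0("rel_give_", pac)]], , drop = FALSE]
  if (nrow(give)) {
    b <- give[give$technique == "bolus" &
                in_window_ts(give$start_time, w_start, w_end, config), ,
              drop = FALSE]
    for (i in seq_len(min(nrow(b), 1))) {
      emit("med_bolus", paste0("med:", b$ingredient_key[i], ":", b$order_id[i]),
           b$start_time[i])
    }
    cont <- give[give$technique == "continuous", , drop = FALSE]
    starters <- cont[in_window_ts(cont$start_time, w_start, w_end, config), ,
                     drop = FALSE]
    start_hit <- incr_hit <- NULL
    for (i in seq_len(nrow(starters))) {
      e <- starters[i, ]
      same <- cont[cont$ingredient_key == e$ingredient_key &
                     cont$episode_id != e$episode_id, , drop = FALSE]
      prev <- same[same$end_time <= e$start_time &
                     same$end_time >= e$start_time - gap, , drop = FALSE]
      parallel <- any(same$start_time <= e$start_time &
                        same$end_time > e$start_time)
      if (!nrow(prev) && !parallel) {
        if (is.null(start_hit)) start_hit <- e
      } else if (nrow(prev)) {
        p <- prev[which.max(as.numeric(prev$end_time)), ]
        if (compare_episode_rates(e, p, mappings) == "greater" &&
            is.null(incr_hit)) {
          incr_hit <- e
        }
      }
    }
    if (!is.null(start_hit)) {
      emit("med_start",
           paste0("med:", start_hit$ingredient_key, ":", start_hit$order_id),
           start_hit$start_time)
    }
    if (!is.null(incr_hit)) {
      emit("med_increase",
           paste0("med:", incr_hit$ingredient_key, ":", incr_hit$order_id),
           incr_hit$start_time)
    }
  }

  if (pac != "SpO2_low") {
    stopd <- ep[ep[[paste0("rel_stop_", pac)]], , drop = FALSE]
    cont <- stopd[stopd$technique == "continuous", , drop = FALSE]
    enders <- cont[in_window_ts(cont$end_time, w_start, w_end, config), ,
                   drop = FALSE]
    stop_hit <- decr_hit <- NULL
    for (i in seq_len(nrow(enders))) {
      e <- enders[i, ]
      same <- cont[cont$ingredient_key == e$ingredient_key &
                     cont$episode_id != e$episode_id, , drop = FALSE]
      succ <- same[same$start_time >= e$end_time &
                     same$start_time <= e$end_time + gap, , drop = FALSE]
      parallel <- any(same$start_time <= e$end_time &
                        same$end_time > e$end_time)
      if (!nrow(succ) && !parallel) {
        if (is.null(stop_hit)) stop_hit <- e
      } else if (nrow(succ)) {
        s <- succ[which.min(as.numeric(succ$start_time)), ]
        if (compare_episode_rates(e, s, mappings) == "greater" &&
            is.null(decr_hit)) {
          decr_hit <- e
        }
      }
    }
    if (!is.null(stop_hit)) {
      emit("med_stop",
           paste0("med:", stop_hit$ingredient_key, ":", stop_hit$order_id),
           stop_hit$end_time)
    }
    if (!is.null(decr_hit)) {
      emit("med_decrease",
           paste0("med:", decr_hit$ingredient_key, ":", decr_hit$order_id),
           decr_hit$end_time)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(rule_id = character(0),
                          matched_ref = character(0),
                          matched_time = as.POSIXct(character(0))))
  }
  dplyr::bind_rows(out)
}
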