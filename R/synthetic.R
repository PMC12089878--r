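#' Error-injection parameters
#'
#' Documentation-error processes observed in real PDMS data, used by
#' [inject_errors()]: in 9.0% of documented airway-device changes the
#' removal of the preceding device is missing; a substantial share of
#' ventilation changes at therapy levels 3 and up (53,875 of 230,711
#' observed changes, about 23.4%) are documented while the ventilator is in
#' standby, with the standby deactivated after a delay whose median is 7
#' minutes and whose 75th percentile is 20 minutes (modeled log-normal);
#' and nearly 60% of medication timestamps are rounded down to the nearest
#' 5 minutes by the PDMS input dialog.
#'
#' @param missing_removal_rate Fraction of airway-device changes whose
#'   predecessor removal is deleted.
#' @param standby_error_rate Fraction of eligible ventilation changes
#'   marked as documented under standby.
#' @param standby_delay_meanlog,standby_delay_sdlog Log-normal parameters
#'   of the deactivation delay in minutes (defaults solve median 7 /
#'   75th percentile 20).
#' @param rounding_fraction Fraction of distinct medication timestamps
#'   floored to the rounding grid.
#' @param rounding_granularity_min The grid, minutes.
#' @return A named list of class `error_params`.
#' @export
error_injection_params <- function(missing_removal_rate = 0.090,
                                   standby_error_rate = 53875 / 230711,
                                   standby_delay_meanlog = log(7),
                                   standby_delay_sdlog =
                                     (log(20) - log(7)) / stats::qnorm(0.75),
                                   rounding_fraction = 0.60,
                                   rounding_granularity_min = 5) {
  fr <- c(missing_removal_rate, standby_error_rate, rounding_fraction)
  if (any(fr < 0 | fr > 1)) rlang::abort("Rates must lie in [0, 1].")
  if (stats::qlnorm(0.5, standby_delay_meanlog, standby_delay_sdlog) >
      stats::qlnorm(0.75, standby_delay_meanlog, standby_delay_sdlog)) {
    rlang::abort("Delay quantiles must be ordered.")
  }
  structure(list(
    missing_removal_rate = missing_removal_rate,
    standby_error_rate = standby_error_rate,
    standby_delay_meanlog = standby_delay_meanlog,
    standby_delay_sdlog = standby_delay_sdlog,
    rounding_fraction = rounding_fraction,
    rounding_granularity_min = rounding_granularity_min
  ), class = "error_params")
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

mins <- function(x) x * 60

# nudge timestamps off the 5-minute grid so that a grid-aligned timestamp
# unambiguously signals PDMS round-down
off_grid <- function(ts, granularity_s = 300) {
  on <- (as.numeric(ts) %% granularity_s) == 0
  ts + ifelse(on, 1, 0)
}

pac_alarm_label <- function(pac, u) {
  pool <- switch(pac,
    SpO2_low = c("Desat", "SpO2", "SpO2l", "SpO2r", "SpO2po", "SpO2pr"),
    HR_low = c("Asystolie", "xBrady", "HF"),
    HR_high = c("xTachy", "HF"),
    IBP_low = c("ABPs", "ARTs", "ABPm", "ARTm"),
    IBP_high = c("ABPs", "ARTs", "ABPm", "ARTm")
  )
  pool[1 + floor(u * length(pool)) %% length(pool)]
}

# scenario catalogue: every registry rule has at least one positive and one
# negative variant; negatives violate exactly one condition
scenario_catalog <- function() {
  tibble::tribble(
    ~rule_id, ~variant, ~positive, ~pac_constraint,
    "ad_change", "escalation", TRUE, "SpO2_low",
    "ad_change", "removed_in_window", FALSE, "SpO2_low",
    "ad_change", "no_change", FALSE, "SpO2_low",
    "rst_change", "escalation", TRUE, "SpO2_low",
    "rst_change", "from_standby", TRUE, "SpO2_low",
    "rst_change", "change_under_standby", FALSE, "SpO2_low",
    "rst_change", "deescalation", FALSE, "SpO2_low",
    "param_increase", "fio2_up", TRUE, "SpO2_low",
    "param_increase", "o2_flow_up", TRUE, "SpO2_low",
    "param_increase", "equal_value", FALSE, "SpO2_low",
    "param_increase", "peep_during_o2", FALSE, "SpO2_low",
    "param_increase", "implausible_value", FALSE, "SpO2_low",
    "med_bolus", "bolus", TRUE, "any",
    "med_bolus", "outside_window", FALSE, "any",
    "med_bolus", "planned", FALSE, "any",
    "med_start", "start", TRUE, "any",
    "med_start", "fluid_therapy", TRUE, "IBP_low",
    "med_start", "mixture", TRUE, "hi_pac",
    "med_start", "parallel_running", FALSE, "any",
    "med_start", "irrelevant_mixture", FALSE, "any",
    "med_start", "carrier_fluid", FALSE, "IBP_low",
    "med_increase", "rate_up", TRUE, "any",
    "med_increase", "conc_switch", TRUE, "hi_pac",
    "med_increase", "equal_rate", FALSE, "any",
    "med_stop", "stop", TRUE, "not_SpO2_low",
    "med_stop", "restart_equal", FALSE, "not_SpO2_low",
    "med_decrease", "rate_down", TRUE, "not_SpO2_low",
    "med_decrease", "rate_up_not_down", FALSE, "not_SpO2_low"
  )
}

sample_pac <- function(constraint, u) {
  pool <- switch(constraint,
    SpO2_low = "SpO2_low",
    not_SpO2_low = c("HR_low", "HR_high", "IBP_low", "IBP_high"),
    IBP_low = "IBP_low",
    hi_pac = c("HR_high", "IBP_high"),
    any = pac_table()$pac_id
  )
  pool[1 + floor(u * length(pool)) %% length(pool)]
}

# drug pools per PAC; give pools and stop pools are disjoint per PAC and
# chosen so give-pool drugs are never stop-relevant for the same PAC (and
# vice versa), keeping planted scenarios from firing the opposite rule set
med_pools <- function() {
  list(
    bolus = list(SpO2_low = "D016", HR_low = "D012", HR_high = "D013",
                 IBP_low = "D015", IBP_high = "D014"),
    give = list(SpO2_low = c("D017", "D018"), HR_low = c("D001", "D002"),
                HR_high = c("D005", "D010"), IBP_low = c("D001", "D003"),
                IBP_high = c("D004", "D005")),
    stop = list(HR_low = c("D005", "D010"), HR_high = c("D001", "D002"),
                IBP_low = c("D004", "D005"), IBP_high = c("D001", "D003"))
  )
}

drug_conc <- function(drug_id) {
  conc <- c(D001 = 0.1, D002 = 0.1, D003 = 5, D004 = 1, D005 = 0.03,
            D010 = 10, D011 = 20, D017 = 0.01, D018 = 0.01)
  unname(conc[drug_id])
}

pick <- function(pool_list, pac, u) {
  p <- pool_list[[pac]]
  p[1 + floor(u * length(p)) %% length(p)]
}

empty_fragments <- function() {
  list(
    ad = empty_table("ad"),
    vs = empty_table("vent_states"),
    vp = empty_table("vent_params"),
    med = empty_table("medications"),
    rx = tibble::tibble(order_id = character(0),
                        scheduled_time = as.POSIXct(character(0), tz = "UTC"))
  )
}

med_rows <- function(stay_ref, order_id, drug_id, start, end,
                     rate = NA_real_, rate_unit = NA_character_,
                     conc = NA_real_, conc_unit = NA_character_,
                     amount = NA_real_, amount_unit = NA_character_) {
  tibble::tibble(
    stay_ref = stay_ref, order_id = order_id, drug_id = drug_id,
    start_time = start, end_time = end,
    rate = rate, rate_unit = rate_unit,
    concentration = conc, conc_unit = conc_unit,
    amount = amount, amount_unit = amount_unit,
    route_text = "i.v."
  )
}

plant_ad_change <- function(df) {
  f <- empty_fragments()
  base <- tibble::tibble(
    stay_ref = df$stay_ref, entry_text = "Larynxmaske",
    insert_time = df$t - mins(35), removal_time = as.POSIXct(NA)
  )
  has_new <- df$variant != "no_change"
  newrec <- tibble::tibble(
    stay_ref = df$stay_ref[has_new], entry_text = "Tubus",
    insert_time = df$t[has_new] + mins(df$o1[has_new]),
    removal_time = dplyr::if_else(
      df$variant[has_new] == "removed_in_window",
      df$t[has_new] + mins(df$o1[has_new] + 2), as.POSIXct(NA))
  )
  f$ad <- dplyr::bind_rows(base, newrec)
  f
}

plant_rst_change <- function(df) {
  f <- empty_fragments()
  base_vd <- ifelse(df$variant %in% c("from_standby"), "ventilator",
                    ifelse(df$variant == "deescalation", "ventilator", "none"))
  base_vm <- ifelse(df$variant == "from_standby", "bipap",
                    ifelse(df$variant == "deescalation", "pcv", "spontaneous"))
  base_sb <- df$variant == "from_standby"
  base <- tibble::tibble(
    stay_ref = df$stay_ref, time = df$t - mins(35),
    vd_text = base_vd, vm_text = base_vm, standby = base_sb
  )
  newrec <- tibble::tibble(
    stay_ref = df$stay_ref, time = df$t + mins(df$o1),
    vd_text = "ventilator", vm_text = "bipap",
    standby = df$variant == "change_under_standby"
  )
  f$vs <- dplyr::bind_rows(base, newrec)
  f
}

plant_param_increase <- function(df) {
  f <- empty_fragments()
  o2ctx <- df$variant %in% c("o2_flow_up", "peep_during_o2")
  f$vs <- tibble::tibble(
    stay_ref = df$stay_ref, time = df$t - mins(35),
    vd_text = ifelse(o2ctx, "flowmeter", "ventilator"),
    vm_text = ifelse(o2ctx, "o2 flow", "bipap"),
    standby = FALSE
  )
  par <- dplyr::case_when(
    df$variant == "o2_flow_up" ~ "o2_flow",
    df$variant == "peep_during_o2" ~ "peep",
    TRUE ~ "fio2"
  )
  base_val <- dplyr::case_when(
    df$variant == "o2_flow_up" ~ 2,
    TRUE ~ 0.4
  )
  win_val <- dplyr::case_when(
    df$variant == "fio2_up" ~ 0.4 + 0.1 + round(df$o2, 2) * 0.1,
    df$variant == "o2_flow_up" ~ 2 + 2 + round(df$o2, 1),
    df$variant == "equal_value" ~ 0.4,
    df$variant == "peep_during_o2" ~ 5,
    df$variant == "implausible_value" ~ 1.5
  )
  has_base <- df$variant != "peep_during_o2"
  baserow <- tibble::tibble(
    stay_ref = df$stay_ref[has_base], time = df$t[has_base] - mins(34),
    parameter = par[has_base], value = base_val[has_base]
  )
  winrow <- tibble::tibble(
    stay_ref = df$stay_ref, time = df$t + mins(df$o1),
    parameter = par, value = win_val
  )
  f$vp <- dplyr::bind_rows(baserow, winrow)
  f
}

plant_med_bolus <- function(df) {
  f <- empty_fragments()
  pools <- med_pools()
  drug <- mapply(pick, pac = df$pac, u = df$u1,
                 MoreArgs = list(pool_list = pools$bolus))
  o <- ifelse(df$variant == "outside_window", 21 + df$o1 / 4, df$o1)
  ts <- df$t + mins(o)
  f$med <- med_rows(df$stay_ref, paste0("O", df$alarm_id), drug, ts, ts,
                    amount = 1, amount_unit = "mg")
  planned <- df$variant == "planned"
  f$rx <- tibble::tibble(order_id = paste0("O", df$alarm_id[planned]),
                         scheduled_time = ts[planned])
  f
}

plant_med_start <- function(df) {
  f <- empty_fragments()
  pools <- med_pools()
  drug <- dplyr::case_when(
    df$variant %in% c("fluid_therapy", "carrier_fluid") ~ "D020",
    df$variant == "mixture" ~ "D030",
    df$variant == "irrelevant_mixture" ~ "D031",
    TRUE ~ mapply(pick, pac = df$pac, u = df$u1,
                  MoreArgs = list(pool_list = pools$give))
  )
  rate <- dplyr::case_when(
    df$variant == "fluid_therapy" ~ 600,
    df$variant == "carrier_fluid" ~ 100,
    TRUE ~ 5 + round(df$o2, 1)
  )
  start <- df$t + mins(df$o1)
  new <- med_rows(df$stay_ref, paste0("O", df$alarm_id, "a"), drug,
                  start, start + mins(40), rate = rate, rate_unit = "ml/h",
                  conc = drug_conc(drug), conc_unit = "mg/ml")
  par <- df$variant == "parallel_running"
  running <- med_rows(
    df$stay_ref[par], paste0("O", df$alarm_id[par], "b"), drug[par],
    df$t[par] - mins(25), df$t[par] + mins(30),
    rate = rate[par], rate_unit = "ml/h",
    conc = drug_conc(drug[par]), conc_unit = "mg/ml"
  )
  f$med <- dplyr::bind_rows(new, running)
  f
}

plant_med_rate_change <- function(df) {
  # increase and decrease pairs: previous episode ends at the change
  # instant, the new one starts there (one PDMS dialog, one timestamp)
  f <- empty_fragments()
  pools <- med_pools()
  incr <- df$rule_id == "med_increase"
  drug_prev <- ifelse(df$variant == "conc_switch", "D010",
                      vapply(seq_len(nrow(df)), function(i) {
                        pick(pools$give, df$pac[i], df$u1[i])
                      }, character(1)))
  drug_prev[!incr] <- vapply(which(!incr), function(i) {
    pick(pools$stop, df$pac[i], df$u1[i])
  }, character(1))
  drug_new <- ifelse(df$variant == "conc_switch", "D011", drug_prev)
  r1 <- 5 + round(df$o2, 1)
  r2 <- dplyr::case_when(
    df$variant == "conc_switch" ~ 6 + round(df$o2, 1),  # 20 mg/ml: dose up
    df$variant == "equal_rate" ~ r1,
    df$variant == "rate_up_not_down" ~ r1 + 2 + round(df$o2, 1),
    incr ~ r1 + 2 + round(df$o2, 1),
    TRUE ~ pmax(r1 - 2 - round(df$o2, 1), 0.5)          # decrease
  )
  change <- df$t + mins(df$o1)
  prev <- med_rows(df$stay_ref, paste0("O", df$alarm_id, "a"), drug_prev,
                   df$t - mins(25), change, rate = r1, rate_unit = "ml/h",
                   conc = drug_conc(drug_prev), conc_unit = "mg/ml")
  new <- med_rows(df$stay_ref, paste0("O", df$alarm_id, "b"), drug_new,
                  change, change + mins(40), rate = r2, rate_unit = "ml/h",
                  conc = drug_conc(drug_new), conc_unit = "mg/ml")
  f$med <- dplyr::bind_rows(prev, new)
  f
}

plant_med_stop <- function(df) {
  f <- empty_fragments()
  pools <- med_pools()
  drug <- mapply(pick, pac = df$pac, u = df$u1,
                 MoreArgs = list(pool_list = pools$stop))
  r1 <- 5 + round(df$o2, 1)
  endt <- df$t + mins(df$o1)
  prev <- med_rows(df$stay_ref, paste0("O", df$alarm_id, "a"), drug,
                   df$t - mins(25), endt, rate = r1, rate_unit = "ml/h",
                   conc = drug_conc(drug), conc_unit = "mg/ml")
  re <- df$variant == "restart_equal"
  succ <- med_rows(df$stay_ref[re], paste0("O", df$alarm_id[re], "b"),
                   drug[re], endt[re], endt[re] + mins(40),
                   rate = r1[re], rate_unit = "ml/h",
                   conc = drug_conc(drug[re]), conc_unit = "mg/ml")
  f$med <- dplyr::bind_rows(prev, succ)
  f
}

plant_scenarios <- function(slots) {
  frags <- list(empty_fragments())
  planters <- list(
    ad_change = plant_ad_change,
    rst_change = plant_rst_change,
    param_increase = plant_param_increase,
    med_bolus = plant_med_bolus,
    med_start = plant_med_start,
    med_increase = plant_med_rate_change,
    med_decrease = plant_med_rate_change,
    med_stop = plant_med_stop
  )
  for (rid in names(planters)) {
    df <- slots[!is.na(slots$rule_id) & slots$rule_id == rid, , drop = FALSE]
    if (nrow(df)) frags[[length(frags) + 1]] <- planters[[rid]](df)
  }
  out <- empty_fragments()
  for (nm in names(out)) {
    out[[nm]] <- dplyr::bind_rows(lapply(frags, `[[`, nm))
  }
  # event times stay off the rounding grid so that grid alignment encodes
  # injected round-down, not chance
  out$vs$time <- off_grid(out$vs$time)
  out$vp$time <- off_grid(out$vp$time)
  out$ad$insert_time <- off_grid(out$ad$insert_time)
  out$ad$removal_time <- off_grid(out$ad$removal_time)
  out$med$start_time <- off_grid(out$med$start_time)
  out$med$end_time <- off_grid(out$med$end_time)
  out$rx$scheduled_time <- off_grid(out$rx$scheduled_time)
  out
}

# complete the airway-device documentation at stay level: when a new device
# is documented, the predecessor's removal is logged just after the change
# unless the scenario already logged one in time
close_ad_removals <- function(ad_records, tolerance_min = 1) {
  if (nrow(ad_records) < 2) return(ad_records)
  ad_records <- ad_records[order(ad_records$stay_ref, ad_records$insert_time), ]
  for (ref in unique(ad_records$stay_ref)) {
    idx <- which(ad_records$stay_ref == ref)
    if (length(idx) < 2) next
    for (j in seq_len(length(idx) - 1)) {
      i <- idx[j]; nx <- idx[j + 1]
      lim <- ad_records$insert_time[nx] + mins(tolerance_min)
      if (is.na(ad_records$removal_time[i]) ||
          ad_records$removal_time[i] > lim) {
        ad_records$removal_time[i] <- ad_records$insert_time[nx] + 20
      }
    }
  }
  ad_records
}

#' Simulate an annotated ICU data bundle with known ground truth
#'
#' Generates alarm logs and PDMS-style documentation for a set of ICU
#' stays. Alarms are placed on an 80-minute slot grid with per-alarm jitter
#' so that each alarm's post-alarm windows (30 min respiratory, 15 min
#' medication) and its pre-alarm baseline documentation are isolated from
#' neighbouring alarms; each alarm is then assigned a scenario - a planted
#' intervention firing exactly one targeted rule, or a negative scenario
#' violating exactly one rule condition - and the implied true label is
#' recorded in the ground-truth ledger. All randomness derives from `seed`.
#'
#' @param n_stays Number of ICU stays.
#' @param stay_duration_h Stay duration, hours.
#' @param alarms_per_hour Mean alarm rate per stay (Poisson; capped by the
#'   slot grid).
#' @param p_actionable Probability that an alarm receives a planted
#'   intervention (true label actionable).
#' @param p_unlinked Fraction of additional alarms emitted from a bed with
#'   no admitted patient (true label unlinked).
#' @param rules Optional character vector restricting the scenario pool to
#'   a subset of registry rule ids.
#' @param seed Integer seed; identical seeds give identical bundles.
#' @return An object of class `alarm_bundle`: a list of tibbles `alarms`,
#'   `stays`, `ad_records`, `vent_states`, `vent_params`, `medications`,
#'   `prescriptions` and the ground-truth `ledger` (`alarm_id`, `pac`,
#'   `rule_id`, `variant`, `true_label`).
#' @export
#' @examples
#' b <- simulate_bundle(n_stays = 2, seed = 42)
#' b$ledger
simulate_bundle <- function(n_stays = 10, stay_duration_h = 24,
                            alarms_per_hour = 0.75, p_actionable = 0.6,
                            p_unlinked = 0.02, rules = NULL, seed = 1) {
  reg <- rule_registry()
  if (is.null(rules)) rules <- reg$rule_id
  if (!all(rules %in% reg$rule_id)) {
    rlang::abort(paste0("Unknown rule id(s): ",
                        paste(setdiff(rules, reg$rule_id), collapse = ", ")))
  }
  with_local_seed(seed, {
    origin <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
    stays <- tibble::tibble(
      stay_ref = sprintf("S%03d", seq_len(n_stays)),
      bed_id = sprintf("B%03d", seq_len(n_stays)),
      admit_time = origin + (seq_len(n_stays) - 1) * 3600,
      discharge_time = origin + (seq_len(n_stays) - 1) * 3600 +
        stay_duration_h * 3600
    )
    n_slots <- max(floor((stay_duration_h * 60 - 60) / 80), 0)
    slot_list <- vector("list", n_stays)
    for (i in seq_len(n_stays)) {
      n_i <- min(stats::rpois(1, alarms_per_hour * stay_duration_h), n_slots)
      if (n_i == 0) next
      tt <- stays$admit_time[i] + mins(60) + (seq_len(n_i) - 1) * mins(80) +
        sample(0:299, n_i, replace = TRUE)
      slot_list[[i]] <- tibble::tibble(
        stay_ref = stays$stay_ref[i], bed_id = stays$bed_id[i],
        t = off_grid(tt)
      )
    }
    slots <- dplyr::bind_rows(slot_list)
    n <- nrow(slots)
    alarms0 <- tibble::tibble(alarm_id = character(0), bed_id = character(0),
                              start_time = as.POSIXct(character(0), tz = "UTC"),
                              alarm_label = character(0),
                              threshold_direction = character(0))
    if (n == 0) {
      return(structure(list(
        alarms = alarms0, stays = stays,
        ad_records = empty_table("ad"),
        vent_states = empty_table("vent_states"),
        vent_params = empty_table("vent_params"),
        medications = empty_table("medications"),
        prescriptions = tibble::tibble(order_id = character(0),
                                       scheduled_time = as.POSIXct(character(0), tz = "UTC")),
        ledger = tibble::tibble(alarm_id = character(0), stay_ref = character(0),
                                pac = character(0), rule_id = character(0),
                                variant = character(0), true_label = character(0))
      ), class = "alarm_bundle"))
    }
    slots$alarm_id <- sprintf("A%05d", seq_len(n))
    cat <- scenario_catalog()
    cat <- cat[cat$rule_id %in% rules, , drop = FALSE]
    pos_cat <- cat[cat$positive, , drop = FALSE]
    neg_cat <- cat[!cat$positive, , drop = FALSE]
    slots$positive <- runif(n) < p_actionable

    rule_id <- variant <- pac <- character(n)
    for (i in seq_len(n)) {
      tab <- if (slots$positive[i]) pos_cat else neg_cat
      if (!slots$positive[i] && (runif(1) < 0.3 || nrow(tab) == 0)) {
        rule_id[i] <- NA_character_
        variant[i] <- "none"
        pac[i] <- sample_pac("any", runif(1))
        next
      }
      k <- sample.int(nrow(tab), 1)
      rule_id[i] <- tab$rule_id[k]
      variant[i] <- tab$variant[k]
      pac[i] <- sample_pac(tab$pac_constraint[k], runif(1))
    }
    slots$rule_id <- rule_id
    slots$variant <- variant
    slots$pac <- pac
    slots$o1 <- runif(n, 3, 12)
    slots$o2 <- runif(n, 0.5, 3)
    slots$u1 <- runif(n)

    frags <- plant_scenarios(slots)
    frags$ad <- close_ad_removals(frags$ad)

    dirs <- setNames(pac_table()$direction, pac_table()$pac_id)
    alarms <- tibble::tibble(
      alarm_id = slots$alarm_id, bed_id = slots$bed_id,
      start_time = slots$t,
      alarm_label = unname(mapply(pac_alarm_label, slots$pac, runif(n))),
      threshold_direction = unname(dirs[slots$pac])
    )
    ledger <- tibble::tibble(
      alarm_id = slots$alarm_id, stay_ref = slots$stay_ref, pac = slots$pac,
      rule_id = slots$rule_id, variant = slots$variant,
      true_label = ifelse(slots$positive, "actionable", "nonactionable")
    )

    n_unl <- stats::rbinom(1, n, p_unlinked)
    if (n_unl > 0) {
      upac <- vapply(runif(n_unl), function(u) sample_pac("any", u), "")
      unl <- tibble::tibble(
        alarm_id = sprintf("U%05d", seq_len(n_unl)),
        bed_id = "B999",
        start_time = off_grid(origin + mins(60) + seq_len(n_unl) * mins(17) +
                                sample(0:299, n_unl, replace = TRUE)),
        alarm_label = unname(mapply(pac_alarm_label, upac, runif(n_unl))),
        threshold_direction = unname(dirs[upac])
      )
      alarms <- dplyr::bind_rows(alarms, unl)
      ledger <- dplyr::bind_rows(ledger, tibble::tibble(
        alarm_id = unl$alarm_id, stay_ref = NA_character_, pac = upac,
        rule_id = NA_character_, variant = "unlinked",
        true_label = "unlinked"
      ))
    }
    structure(list(
      alarms = alarms, stays = stays,
      ad_records = frags$ad[order(frags$ad$stay_ref, frags$ad$insert_time), ],
      vent_states = frags$vs[order(frags$vs$stay_ref, frags$vs$time), ],
      vent_params = frags$vp[order(frags$vp$stay_ref, frags$vp$time), ],
      medications = frags$med[order(frags$med$stay_ref, frags$med$start_time), ],
      prescriptions = frags$rx,
      ledger = ledger
    ), class = "alarm_bundle")
  })
}

#' @export
print.alarm_bundle <- function(x, ...) {
  cat("<alarm_bundle> ", nrow(x$alarms), " alarms over ", nrow(x$stays),
      " stays\n", sep = "")
  invisible(x)
}

#' Simulate a minimal fixture for one rule
#'
#' One stay, one alarm, and exactly the documentation the chosen scenario
#' needs: positive fixtures exercise the targeted rule; negative fixtures
#' violate exactly one of its conditions. Combinations the rule set forbids
#' (respiratory rules outside the low-saturation condition; stop/decrease
#' for the low-saturation condition) are refused.
#'
#' @param rule_id A registry rule id.
#' @param positive Generate a positive (`TRUE`) or negative fixture.
#' @param variant Optional scenario variant name (see the catalogue in the
#'   package sources); defaults to the first matching variant.
#' @param pac Optional PAC id; defaults to one compatible with the rule.
#' @param seed Integer seed.
#' @return An `alarm_bundle` with a one-row ledger.
#' @export
simulate_scenario <- function(rule_id, positive = TRUE, variant = NULL,
                              pac = NULL, seed = 1) {
  cat <- scenario_catalog()
  reg <- rule_registry()
  if (!rule_id %in% reg$rule_id) {
    rlang::abort(paste0("Unknown rule id: ", rule_id))
  }
  sub <- cat[cat$rule_id == rule_id & cat$positive == positive, , drop = FALSE]
  if (!is.null(variant)) sub <- sub[sub$variant == variant, , drop = FALSE]
  if (!nrow(sub)) rlang::abort("No scenario variant matches this request.")
  sub <- sub[1, ]
  applicable <- strsplit(reg$applicable_pacs[reg$rule_id == rule_id], ",")[[1]]
  if (is.null(pac)) {
    pac <- sample_pac(sub$pac_constraint, with_local_seed(seed, runif(1)))
  }
  if (!pac %in% applicable) {
    rlang::abort(paste0("Rule ", rule_id, " is not applicable to PAC ", pac,
                        "."))
  }
  pool <- switch(sub$pac_constraint,
                 SpO2_low = "SpO2_low",
                 not_SpO2_low = c("HR_low", "HR_high", "IBP_low", "IBP_high"),
                 IBP_low = "IBP_low",
                 hi_pac = c("HR_high", "IBP_high"),
                 any = pac_table()$pac_id)
  if (!pac %in% pool) {
    rlang::abort(paste0("Variant ", sub$variant, " requires PAC in ",
                        paste(pool, collapse = "/"), "."))
  }
  with_local_seed(seed, {
    origin <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
    stays <- tibble::tibble(stay_ref = "S001", bed_id = "B001",
                            admit_time = origin,
                            discharge_time = origin + 24 * 3600)
    t0 <- off_grid(origin + mins(120) + sample(0:299, 1))
    slots <- tibble::tibble(
      stay_ref = "S001", bed_id = "B001", t = t0, alarm_id = "A00001",
      positive = positive, rule_id = rule_id, variant = sub$variant,
      pac = pac, o1 = runif(1, 3, 12), o2 = runif(1, 0.5, 3), u1 = runif(1)
    )
    frags <- plant_scenarios(slots)
    frags$ad <- close_ad_removals(frags$ad)
    dirs <- setNames(pac_table()$direction, pac_table()$pac_id)
    structure(list(
      alarms = tibble::tibble(
        alarm_id = "A00001", bed_id = "B001", start_time = t0,
        alarm_label = pac_alarm_label(pac, runif(1)),
        threshold_direction = unname(dirs[pac])
      ),
      stays = stays, ad_records = frags$ad, vent_states = frags$vs,
      vent_params = frags$vp, medications = frags$med,
      prescriptions = frags$rx,
      ledger = tibble::tibble(
        alarm_id = "A00001", stay_ref = "S001", pac = pac,
        rule_id = rule_id, variant = sub$variant,
        true_label = ifelse(positive, "actionable", "nonactionable")
      )
    ), class = "alarm_bundle")
  })
}

#' Documented airway-device changes and their predecessor removals
#'
#' A change is a new airway-device record following a previous one within
#' the same stay. The predecessor's removal counts as logged when its
#' removal timestamp exists and does not lag the new device's insertion by
#' more than the tolerance (a new device is routinely documented up to a
#' minute before the previous one's removal).
#'
#' @param ad_records Airway-device records.
#' @param tolerance_min Tolerance, minutes.
#' @return A tibble with one row per change: `stay_ref`, `prev_row`,
#'   `new_row`, `change_time`, `removal_logged`.
#' @export
count_ad_changes <- function(ad_records, tolerance_min = 1) {
  out <- list()
  ord <- order(ad_records$stay_ref, ad_records$insert_time)
  ad <- ad_records[ord, , drop = FALSE]
  for (ref in unique(ad$stay_ref)) {
    idx <- which(ad$stay_ref == ref)
    if (length(idx) < 2) next
    prev <- idx[-length(idx)]
    nxt <- idx[-1]
    out[[length(out) + 1]] <- tibble::tibble(
      stay_ref = ref,
      prev_row = ord[prev], new_row = ord[nxt],
      change_time = ad$insert_time[nxt],
      removal_logged = !is.na(ad$removal_time[prev]) &
        ad$removal_time[prev] <= ad$insert_time[nxt] + mins(tolerance_min)
    )
  }
  if (!length(out)) {
    return(tibble::tibble(stay_ref = character(0), prev_row = integer(0),
                          new_row = integer(0),
                          change_time = as.POSIXct(character(0), tz = "UTC"),
                          removal_logged = logical(0)))
  }
  dplyr::bind_rows(out)
}

#' Inject documentation errors into a bundle
#'
#' Applies the three observed PDMS documentation-error processes to a clean
#' bundle: (1) deletes the predecessor removal of a random fraction of
#' airway-device changes; (2) marks a random fraction of ventilation
#' changes at therapy levels 3 and up as documented while the ventilator
#' was in standby and appends the delayed standby deactivation (log-normal
#' delay); (3) floors a random fraction of distinct medication timestamps
#' to the 5-minute grid - a rate change documented through one input dialog
#' carries one timestamp, so every occurrence of a selected instant is
#' floored together. Every corruption is recorded.
#'
#' @param bundle An `alarm_bundle`.
#' @param params [error_injection_params()].
#' @param seed Integer seed.
#' @param mappings Mapping bundle used to find standby-eligible changes.
#' @return The corrupted `alarm_bundle`, with a `corruptions` tibble
#'   (`type`, `stay_ref`, `time`) appended.
#' @export
inject_errors <- function(bundle, params = error_injection_params(), seed = 1,
                          mappings = default_mappings()) {
  stopifnot(inherits(bundle, "alarm_bundle"))
  with_local_seed(seed, {
    corr <- list()

    changes <- count_ad_changes(bundle$ad_records)
    if (nrow(changes)) {
      hit <- runif(nrow(changes)) < params$missing_removal_rate
      rows <- changes$prev_row[hit]
      bundle$ad_records$removal_time[rows] <- as.POSIXct(NA)
      if (any(hit)) {
        corr[[length(corr) + 1]] <- tibble::tibble(
          type = "missing_removal",
          stay_ref = changes$stay_ref[hit],
          time = changes$change_time[hit]
        )
      }
    }

    vs <- bundle$vent_states
    if (nrow(vs)) {
      r <- resolve_rst(vs$vd_text, vs$vm_text, NULL, mappings)
      eligible <- which(r$status == "mapped" & r$rst_level >= 3 & !vs$standby)
      hit <- eligible[runif(length(eligible)) < params$standby_error_rate]
      if (length(hit)) {
        bundle$vent_states$standby[hit] <- TRUE
        delay <- stats::rlnorm(length(hit), params$standby_delay_meanlog,
                               params$standby_delay_sdlog)
        deact <- bundle$vent_states[hit, , drop = FALSE]
        deact$time <- off_grid(deact$time + mins(delay))
        deact$standby <- FALSE
        bundle$vent_states <- dplyr::bind_rows(bundle$vent_states, deact)
        bundle$vent_states <- bundle$vent_states[
          order(bundle$vent_states$stay_ref, bundle$vent_states$time), ]
        corr[[length(corr) + 1]] <- tibble::tibble(
          type = "standby_misdocumented", stay_ref = deact$stay_ref,
          time = deact$time
        )
      }
    }

    med <- bundle$medications
    if (nrow(med)) {
      g <- params$rounding_granularity_min * 60
      all_ts <- unique(c(as.numeric(med$start_time), as.numeric(med$end_time)))
      sel <- all_ts[runif(length(all_ts)) < params$rounding_fraction]
      if (length(sel)) {
        floor_map <- function(x) {
          num <- as.numeric(x)
          hitv <- num %in% sel
          num[hitv] <- num[hitv] - (num[hitv] %% g)
          as.POSIXct(num, origin = "1970-01-01", tz = "UTC")
        }
        bundle$medications$start_time <- floor_map(med$start_time)
        bundle$medications$end_time <- floor_map(med$end_time)
        corr[[length(corr) + 1]] <- tibble::tibble(
          type = "timestamp_rounded", stay_ref = NA_character_,
          time = as.POSIXct(sel, origin = "1970-01-01", tz = "UTC")
        )
      }
    }

    bundle$corruptions <- if (length(corr)) dplyr::bind_rows(corr) else {
      tibble::tibble(type = character(0), stay_ref = character(0),
                     time = as.POSIXct(character(0), tz = "UTC"))
    }
    bundle
  })
}
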