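# Brute-force reference annotator: plain loops over every record, written
# against the documented rule semantics and sharing only the mapping DATA
# (never the package's resolver or rule functions) with the engine.

o_flagged_level <- function(text, m) {
  for (i in seq_len(nrow(m$ad))) {
    if (m$ad$raw_text[i] == text && m$ad$annotation_flag[i]) {
      lv <- m$ad$ad_level[i]
      return(list(level = if (lv >= 1) lv else NA_real_,
                  category = m$ad$ad_category[i],
                  mapped = lv >= 1))
    }
  }
  list(level = NA_real_, category = NA_character_, mapped = FALSE)
}

o_current_ad <- function(ad, t, m) {
  best_i <- NULL
  best_t <- NULL
  for (i in seq_len(nrow(ad))) {
    r <- o_flagged_level(ad$entry_text[i], m)
    if (!r$mapped) next
    if (ad$insert_time[i] <= t &&
        (is.null(best_t) || ad$insert_time[i] > best_t)) {
      best_i <- i
      best_t <- ad$insert_time[i]
    }
  }
  if (is.null(best_i)) return(list(level = 1, category = "no_ad"))
  if (!is.na(ad$removal_time[best_i]) && ad$removal_time[best_i] <= t) {
    return(list(level = 1, category = "no_ad"))
  }
  o_flagged_level(ad$entry_text[best_i], m)
}

o_rst_lookup <- function(vd, vm, adcat, m) {
  tab <- m$rst
  for (i in seq_len(nrow(tab))) {
    if (tab$vd_text[i] == vd && tab$vm_text[i] == vm &&
        tab$ad_category[i] == adcat) {
      return(list(cat = tab$rst_category[i], level = tab$rst_level[i],
                  mapped = TRUE))
    }
  }
  for (i in seq_len(nrow(tab))) {
    if (tab$vd_text[i] == vd && tab$vm_text[i] == vm &&
        tab$ad_category[i] == "") {
      return(list(cat = tab$rst_category[i], level = tab$rst_level[i],
                  mapped = TRUE))
    }
  }
  list(cat = NA_character_, level = NA_real_, mapped = FALSE)
}

o_state_at <- function(vs, t) {
  best <- NULL
  for (i in seq_len(nrow(vs))) {
    if (vs$time[i] <= t && (is.null(best) || vs$time[i] > vs$time[best])) {
      best <- i
    }
  }
  best
}

o_state_eff <- function(vs, i, ad, m) {
  adcat <- o_current_ad(ad, vs$time[i], m)$category
  r <- o_rst_lookup(vs$vd_text[i], vs$vm_text[i], adcat, m)
  if (!r$mapped) return(NA_real_)
  if (vs$standby[i] &&
      !(r$cat %in% c("spontaneous_breathing", "oxygen_therapy"))) return(0)
  r$level
}

o_settable <- function(level, param, m) {
  if (!level %in% 1:7) return(FALSE)
  col <- if (param == "o2_flow") {
    if (level == 2) "o2_flow_flowmeter" else "o2_flow_not_flowmeter"
  } else param
  isTRUE(m$compatibility[[col]][m$compatibility$rst_level == level])
}

o_resp_rules <- function(t, ad, vs, vp, m, cfg) {
  fired <- character(0)
  w_end <- t + cfg$resp_window_min * 60

  # airway-device change
  last_lvl <- o_current_ad(ad, t, m)$level
  for (i in seq_len(nrow(ad))) {
    r <- o_flagged_level(ad$entry_text[i], m)
    if (!r$mapped) next
    if (ad$insert_time[i] >= t && ad$insert_time[i] < w_end &&
        r$level > last_lvl) {
      removed <- !is.na(ad$removal_time[i]) &&
        ad$removal_time[i] >= t && ad$removal_time[i] < w_end
      if (!removed) {
        fired <- c(fired, "ad_change")
        break
      }
    }
  }

  # therapy change
  li <- o_state_at(vs, t)
  last_eff <- if (is.null(li)) 1 else o_state_eff(vs, li, ad, m)
  if (!is.na(last_eff)) {
    for (i in seq_len(nrow(vs))) {
      if (vs$time[i] >= t && vs$time[i] < w_end) {
        eff <- o_state_eff(vs, i, ad, m)
        if (!is.na(eff) && eff > last_eff) {
          fired <- c(fired, "rst_change")
          break
        }
      }
    }
  }

  # parameter increase
  adjust <- function(v, at, param) {
    si <- o_state_at(vs, at)
    if (is.null(si)) {
      lvl <- 1; sb <- FALSE; cat <- "spontaneous_breathing"
    } else {
      adcat <- o_current_ad(ad, vs$time[si], m)$category
      r <- o_rst_lookup(vs$vd_text[si], vs$vm_text[si], adcat, m)
      if (!r$mapped) return(0)
      lvl <- r$level; sb <- vs$standby[si]; cat <- r$cat
    }
    exempt <- cat %in% c("spontaneous_breathing", "oxygen_therapy")
    if (sb && !exempt && !(param == "o2_flow" && cat == "oxygen_therapy")) {
      return(0)
    }
    if (!o_settable(lvl, param, m)) return(0)
    v
  }
  for (param in intersect(unique(vp$parameter), vent_parameters())) {
    rows <- which(vp$parameter == param)
    last_v <- 0
    last_t <- NULL
    for (i in rows) {
      if (vp$time[i] <= t && (is.null(last_t) || vp$time[i] > last_t)) {
        last_t <- vp$time[i]
        last_v <- adjust(vp$value[i], t, param)
      }
    }
    win_max <- NULL
    for (i in rows) {
      if (vp$time[i] >= t && vp$time[i] < w_end) {
        v <- adjust(vp$value[i], vp$time[i], param)
        if (is.null(win_max) || v > win_max) win_max <- v
      }
    }
    if (!is.null(win_max) && win_max > last_v) {
      fired <- c(fired, "param_increase")
      break
    }
  }
  fired
}

o_rate_per_h <- function(rate, unit, m) {
  for (i in seq_len(nrow(m$units))) {
    if (!is.na(unit) && m$units$unit[i] == unit) {
      return(list(dim = m$units$dimension[i],
                  val = rate * m$units$factor[i]))
    }
  }
  list(dim = NA_character_, val = NA_real_)
}

o_conc_mg_ml <- function(conc, unit, m) {
  if (is.na(conc) || is.na(unit)) return(NA_real_)
  for (i in seq_len(nrow(m$units))) {
    if (m$units$unit[i] == unit && m$units$dimension[i] == "concentration") {
      return(conc * m$units$factor[i])
    }
  }
  NA_real_
}

o_compare <- function(a, b, m) {
  ra <- o_rate_per_h(a$rate, a$rate_unit, m)
  rb <- o_rate_per_h(b$rate, b$rate_unit, m)
  ca <- o_conc_mg_ml(a$concentration, a$conc_unit, m)
  cb <- o_conc_mg_ml(b$concentration, b$conc_unit, m)
  same_conc <- (is.na(ca) && is.na(cb)) ||
    (!is.na(ca) && !is.na(cb) && isTRUE(all.equal(ca, cb)))
  if (!is.na(ra$dim) && !is.na(rb$dim) && ra$dim == rb$dim && same_conc) {
    va <- ra$val; vb <- rb$val
  } else {
    va <- if (identical(ra$dim, "mass_rate")) ra$val else ra$val * ca
    vb <- if (identical(rb$dim, "mass_rate")) rb$val else rb$val * cb
    if (identical(ra$dim, "mass_rate_per_kg")) va <- NA_real_
    if (identical(rb$dim, "mass_rate_per_kg")) vb <- NA_real_
  }
  if (is.na(va) || is.na(vb)) return("incomparable")
  if (isTRUE(all.equal(va, vb))) return("equal")
  if (va > vb) "greater" else "less"
}

o_ingredients <- function(drug, m) {
  ing <- character(0)
  fluid <- logical(0)
  for (i in seq_len(nrow(m$medication))) {
    if (m$medication$drug_id[i] == drug) {
      ing <- c(ing, m$medication$active_ingredient[i])
      fluid <- c(fluid, m$medication$is_iv_fluid[i])
    }
  }
  list(set = sort(unique(ing)), fluid = length(ing) == 1 && any(fluid))
}

o_relevant <- function(ingredients, pac, type, m) {
  col <- paste0(ifelse(type == "give", "rel_give_", "rel_stop_"), pac)
  if (length(ingredients) == 1) {
    any(m$medication[[col]][m$medication$active_ingredient == ingredients])
  } else {
    key <- paste(ingredients, collapse = "+")
    isTRUE(m$mixture[[col]][m$mixture$ingredient_set == key])
  }
}

o_in_window <- function(tstamp, w0, w1, cfg) {
  if (cfg$rounding_compensation) {
    g <- cfg$rounding_granularity_min * 60
    up <- if ((as.numeric(tstamp) %% g) == 0) tstamp + g else tstamp
    up > w0 && tstamp < w1
  } else {
    tstamp >= w0 && tstamp < w1
  }
}

o_med_rules <- function(t, pac, med, m, cfg) {
  w0 <- t
  w1 <- t + cfg$med_window_min * 60
  gap <- cfg$med_adjacency_gap_min * 60
  n <- nrow(med)
  keep <- rep(TRUE, n)
  key <- character(n)
  for (i in seq_len(n)) {
    r <- o_ingredients(med$drug_id[i], m)
    if (!length(r$set)) { keep[i] <- FALSE; next }
    key[i] <- paste(r$set, collapse = "+")
    if (r$fluid) {
      rt <- if (!is.na(med$rate[i]) && !is.na(med$rate_unit[i])) {
        o_rate_per_h(med$rate[i], med$rate_unit[i], m)
      } else list(dim = NA, val = NA_real_)
      ml_h <- if (identical(rt$dim, "volume_rate")) rt$val else {
        if (!is.na(med$amount[i]) && !is.na(med$amount_unit[i]) &&
            med$amount_unit[i] %in% c("ml", "l")) {
          med$amount[i] * ifelse(med$amount_unit[i] == "l", 1000, 1)
        } else NA_real_
      }
      if (is.na(ml_h) || ml_h < cfg$fluid_carrier_threshold_ml_h) {
        keep[i] <- FALSE
      }
    }
  }
  bolus <- as.numeric(med$start_time) == as.numeric(med$end_time)
  ingset <- function(i) strsplit(key[i], "+", fixed = TRUE)[[1]]

  fired <- character(0)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (!o_relevant(ingset(i), pac, "give", m)) next
    if (bolus[i] && o_in_window(med$start_time[i], w0, w1, cfg)) {
      fired <- c(fired, "med_bolus")
      break
    }
  }
  for (i in seq_len(n)) {
    if (!keep[i] || bolus[i]) next
    if (!o_relevant(ingset(i), pac, "give", m)) next
    if (!o_in_window(med$start_time[i], w0, w1, cfg)) next
    prev_best <- NULL
    parallel <- FALSE
    for (j in seq_len(n)) {
      if (j == i || !keep[j] || bolus[j] || key[j] != key[i]) next
      if (med$end_time[j] <= med$start_time[i] &&
          med$end_time[j] >= med$start_time[i] - gap) {
        if (is.null(prev_best) ||
            med$end_time[j] > med$end_time[prev_best]) prev_best <- j
      }
      if (med$start_time[j] <= med$start_time[i] &&
          med$end_time[j] > med$start_time[i]) parallel <- TRUE
    }
    if (is.null(prev_best) && !parallel) {
      fired <- union(fired, "med_start")
    } else if (!is.null(prev_best)) {
      if (o_compare(med[i, ], med[prev_best, ], m) == "greater") {
        fired <- union(fired, "med_increase")
      }
    }
  }
  if (pac != "SpO2_low") {
    for (i in seq_len(n)) {
      if (!keep[i] || bolus[i]) next
      if (!o_relevant(ingset(i), pac, "stop", m)) next
      if (!o_in_window(med$end_time[i], w0, w1, cfg)) next
      succ_best <- NULL
      parallel <- FALSE
      for (j in seq_len(n)) {
        if (j == i || !keep[j] || bolus[j] || key[j] != key[i]) next
        if (med$start_time[j] >= med$end_time[i] &&
            med$start_time[j] <= med$end_time[i] + gap) {
          if (is.null(succ_best) ||
              med$start_time[j] < med$start_time[succ_best]) succ_best <- j
        }
        if (med$start_time[j] <= med$end_time[i] &&
            med$end_time[j] > med$end_time[i]) parallel <- TRUE
      }
      if (is.null(succ_best) && !parallel) {
        fired <- union(fired, "med_stop")
      } else if (!is.null(succ_best)) {
        if (o_compare(med[i, ], med[succ_best, ], m) == "greater") {
          fired <- union(fired, "med_decrease")
        }
      }
    }
  }
  fired
}

oracle_fired <- function(t, pac, ad, vs, vp, med, m, cfg) {
  fired <- character(0)
  if (pac == "SpO2_low") fired <- o_resp_rules(t, ad, vs, vp, m, cfg)
  union(fired, o_med_rules(t, pac, med, m, cfg))
}

# random small instance: arbitrary record soup around 1-3 alarms
random_instance <- function(seed) {
  set.seed(seed)
  n_alarm <- sample(1:3, 1)
  pacs <- sample(pac_table()$pac_id, n_alarm, replace = TRUE)
  t_alarms <- T0 + sample(0:5, n_alarm) * 3600 +
    sample(1:3500, n_alarm)

  rmin <- function(lo, hi) runif(1, lo, hi) * 60
  near <- function() t_alarms[sample(n_alarm, 1)] + rmin(-40, 40)

  n_ad <- sample(0:4, 1)
  ad <- do.call(rbind, lapply(seq_len(n_ad), function(i) {
    ins <- near()
    tibble::tibble(
      stay_ref = "S1",
      entry_text = sample(c("Larynxmaske", "Tubus", "Maske", "Guedel",
                            "Befeuchter", "Unknown123"), 1),
      insert_time = ins,
      removal_time = if (runif(1) < 0.4) ins + rmin(0.5, 30) else
        as.POSIXct(NA)
    )
  }))
  if (is.null(ad)) ad <- empty_ad()

  n_vs <- sample(0:5, 1)
  pairs <- list(c("none", "spontaneous"), c("flowmeter", "o2 flow"),
                c("ventilator", "cpap"), c("ventilator", "cpap/asb"),
                c("ventilator", "bipap"), c("ventilator", "pcv"),
                c("weird", "mode"))
  vs <- do.call(rbind, lapply(seq_len(n_vs), function(i) {
    p <- pairs[[sample(length(pairs), 1)]]
    tibble::tibble(stay_ref = "S1", time = near(), vd_text = p[1],
                   vm_text = p[2], standby = runif(1) < 0.25)
  }))
  if (is.null(vs)) vs <- empty_vs()

  n_vp <- sample(0:6, 1)
  vp <- do.call(rbind, lapply(seq_len(n_vp), function(i) {
    tibble::tibble(stay_ref = "S1", time = near(),
                   parameter = sample(c(vent_parameters(), "junk"), 1),
                   value = round(runif(1, 0, 12), 2))
  }))
  if (is.null(vp)) vp <- empty_vp()

  n_med <- sample(0:6, 1)
  med <- do.call(rbind, lapply(seq_len(n_med), function(i) {
    drug <- sample(c("D001", "D005", "D010", "D011", "D016", "D020",
                     "D030", "DXXX"), 1)
    s <- near()
    if (runif(1) < 0.5) s <- s - (as.numeric(s) %% 300)  # grid-aligned
    e <- if (runif(1) < 0.3) s else s + rmin(1, 30)
    tibble::tibble(
      stay_ref = "S1", order_id = paste0("O", i), drug_id = drug,
      start_time = s, end_time = e,
      rate = if (runif(1) < 0.8) round(runif(1, 1, 700), 1) else NA_real_,
      rate_unit = sample(c("ml/h", "ml/min", "mg/h"), 1),
      concentration = if (runif(1) < 0.6) sample(c(0.1, 10, 20), 1) else
        NA_real_,
      conc_unit = "mg/ml",
      amount = NA_real_, amount_unit = NA_character_, route_text = "i.v."
    )
  }))
  if (is.null(med)) med <- empty_med()

  list(t_alarms = t_alarms, pacs = pacs, ad = ad, vs = vs, vp = vp,
       med = med)
}
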