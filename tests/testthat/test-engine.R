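test_that("the registry holds eight rules with respiratory ones restricted to SpO2_low", {
  reg <- rule_registry()
  expect_equal(nrow(reg), 8)
  expect_equal(sum(reg$group == "respiratory"), 3)
  expect_true(all(reg$applicable_pacs[reg$group == "respiratory"] ==
                    "SpO2_low"))
  expect_false(any(grepl("SpO2_low",
                         reg$applicable_pacs[reg$rule_id %in%
                                               c("med_stop", "med_decrease")])))
})

make_dataset <- function() {
  stays <- tibble::tibble(stay_ref = "S1", bed_id = "B1",
                          admit_time = T0 - 6 * 3600,
                          discharge_time = T0 + 6 * 3600)
  alarms <- tibble::tibble(
    alarm_id = c("A1", "A2", "A3", "A4"),
    bed_id = c("B1", "B1", "B1", "B9"),
    start_time = c(T0, T0 + 90 * 60, T0 + 180 * 60, T0),
    alarm_label = c("Desat", "ABPs", "xTachy", "Desat"),
    threshold_direction = c("low", "high", "high", "low")
  )
  vs <- vs_tbl("ventilator", "bipap", -40)
  vp <- rbind(vp_tbl("fio2", 0.4, -30), vp_tbl("fio2", 0.6, 10))
  med <- med_tbl("D014", 94, 94, amount = 1, amount_unit = "mg")
  list(alarms = alarms, stays = stays, vs = vs, vp = vp, med = med)
}

test_that("annotate_alarms labels each alarm individually with fired-rule detail", {
  d <- make_dataset()
  ann <- annotate_alarms(d$alarms, d$stays, vent_states = d$vs,
                         vent_params = d$vp, medications = d$med,
                         mappings = MAPS)
  res <- tidy(ann)
  lab <- dplyr::distinct(res, alarm_id, label)
  expect_equal(lab$label[lab$alarm_id == "A1"], "actionable")   # FiO2 up
  expect_equal(lab$label[lab$alarm_id == "A2"], "actionable")   # urapidil bolus
  expect_equal(lab$label[lab$alarm_id == "A3"], "nonactionable")
  expect_equal(lab$label[lab$alarm_id == "A4"], "unlinked")     # unknown bed
  expect_equal(res$rule_id[res$alarm_id == "A1" & !is.na(res$rule_id)],
               "param_increase")
  expect_equal(res$rule_id[res$alarm_id == "A2" & !is.na(res$rule_id)],
               "med_bolus")
  # actionable exactly when at least one rule row exists
  per <- res %>% dplyr::group_by(alarm_id) %>%
    dplyr::summarise(lab = label[1], nfired = sum(!is.na(rule_id)))
  expect_equal(per$lab == "actionable", per$nfired > 0)
  # fired rules stay within the PAC's applicable set
  reg <- rule_registry()
  fired <- res[!is.na(res$rule_id), ]
  ok <- vapply(seq_len(nrow(fired)), function(i) {
    grepl(fired$pac[i],
          reg$applicable_pacs[reg$rule_id == fired$rule_id[i]], fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("glance counts reconcile with tidy output and autoplot returns a ggplot", {
  d <- make_dataset()
  ann <- annotate_alarms(d$alarms, d$stays, vent_states = d$vs,
                         vent_params = d$vp, medications = d$med,
                         mappings = MAPS)
  g <- glance(ann)
  expect_equal(g$n_alarms, 4)
  expect_equal(g$n_actionable + g$n_nonactionable + g$n_unlinked, 4)
  expect_equal(sum(ann$summary$n_alarms), 4)
  expect_s3_class(autoplot(ann), "ggplot")
  expect_s3_class(plot_rule_counts(ann), "ggplot")
})

test_that("an empty alarm table yields an empty result", {
  ann <- annotate_alarms(
    tibble::tibble(alarm_id = character(0), bed_id = character(0),
                   start_time = as.POSIXct(character(0), tz = "UTC"),
                   alarm_label = character(0)),
    tibble::tibble(stay_ref = character(0), bed_id = character(0),
                   admit_time = as.POSIXct(character(0), tz = "UTC"),
                   discharge_time = as.POSIXct(character(0), tz = "UTC")),
    mappings = MAPS
  )
  expect_equal(nrow(tidy(ann)), 0)
  expect_equal(glance(ann)$n_alarms, 0)
})

test_that("permuting input rows does not change the annotation", {
  b <- simulate_bundle(n_stays = 3, seed = 77)
  ann1 <- annotate_alarms(b$alarms, b$stays, b$ad_records, b$vent_states,
                          b$vent_params, b$medications, b$prescriptions,
                          mappings = MAPS)
  set.seed(1)
  perm <- function(x) x[sample(nrow(x)), , drop = FALSE]
  ann2 <- annotate_alarms(perm(b$alarms), perm(b$stays), perm(b$ad_records),
                          perm(b$vent_states), perm(b$vent_params),
                          perm(b$medications), b$prescriptions,
                          mappings = MAPS)
  r1 <- dplyr::arrange(tidy(ann1), alarm_id, rule_id)
  r2 <- dplyr::arrange(tidy(ann2), alarm_id, rule_id)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("schema violations are reported with the offending column", {
  alarms <- tibble::tibble(alarm_id = "A1", start_time = T0)
  expect_error(annotate_alarms(alarms, mappings = MAPS), "alarm_label")
  bad_med <- tibble::tibble(stay_ref = "S1", drug_id = "D1")
  al <- tibble::tibble(alarm_id = "A1", bed_id = "B1", start_time = T0,
                       alarm_label = "Desat", stay_ref = "S1")
  expect_error(annotate_alarms(al, medications = bad_med, mappings = MAPS),
               "order_id")
})
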