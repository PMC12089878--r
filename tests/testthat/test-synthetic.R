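test_that("identical seeds reproduce identical bundles; seeds do not leak", {
  set.seed(1); invisible(runif(1))  # materialise the global RNG state
  b1 <- simulate_bundle(n_stays = 3, seed = 99)
  rng_before <- get(".Random.seed", envir = globalenv())
  b2 <- simulate_bundle(n_stays = 3, seed = 99)
  expect_identical(rng_before, get(".Random.seed", envir = globalenv()))
  for (nm in c("alarms", "ad_records", "vent_states", "vent_params",
               "medications", "ledger")) {
    expect_equal(as.data.frame(b1[[nm]]), as.data.frame(b2[[nm]]), info = nm)
  }
  b3 <- simulate_bundle(n_stays = 3, seed = 100)
  expect_false(identical(as.data.frame(b1$alarms), as.data.frame(b3$alarms)))
})

test_that("a zero alarm rate yields an empty ledger", {
  b <- simulate_bundle(n_stays = 3, alarms_per_hour = 0, p_unlinked = 0,
                       seed = 2)
  expect_equal(nrow(b$alarms), 0)
  expect_equal(nrow(b$ledger), 0)
})

test_that("with propensity 1 every linked alarm is planted actionable and recovered", {
  b <- simulate_bundle(n_stays = 4, p_actionable = 1, p_unlinked = 0,
                       seed = 13)
  expect_true(all(b$ledger$true_label == "actionable"))
  r <- recovery_rate(b)
  expect_equal(r$actionable, 1)
})

test_that("scenario fixtures exercise exactly the targeted rule", {
  cat <- icualarms:::scenario_catalog()
  reg <- rule_registry()
  # every registry rule has at least one positive and one negative variant
  for (rid in reg$rule_id) {
    expect_true(any(cat$rule_id == rid & cat$positive), info = rid)
    expect_true(any(cat$rule_id == rid & !cat$positive), info = rid)
  }
  for (i in seq_len(nrow(cat))) {
    s <- simulate_scenario(cat$rule_id[i], positive = cat$positive[i],
                           variant = cat$variant[i], seed = 300 + i)
    ep <- build_episodes(s$medications, MAPS, CFG)
    pd <- exclude_planned(s$medications, s$prescriptions)
    ep <- build_episodes(pd$kept, MAPS, CFG)
    vp <- filter_incompatible_values(s$vent_params)$kept
    fired <- annotate_alarm(s$alarms$start_time[1], s$ledger$pac[1],
                            s$ad_records, s$vent_states, vp, ep, MAPS, CFG)
    if (cat$positive[i]) {
      expect_equal(unique(fired$rule_id), cat$rule_id[i],
                   info = paste(cat$rule_id[i], cat$variant[i]))
    } else {
      expect_equal(nrow(fired), 0,
                   info = paste(cat$rule_id[i], cat$variant[i]))
    }
  }
})

test_that("the generator refuses rule/PAC combinations the rule set forbids", {
  expect_error(simulate_scenario("med_stop", pac = "SpO2_low"),
               "not applicable")
  expect_error(simulate_scenario("ad_change", pac = "IBP_low"),
               "not applicable")
  expect_error(simulate_scenario("no_such_rule"), "Unknown rule")
})

test_that("error injection reproduces its configured rates", {
  b <- simulate_bundle(n_stays = 60, rules = "ad_change", p_actionable = 1,
                       p_unlinked = 0, alarms_per_hour = 10, seed = 21)
  ch0 <- count_ad_changes(b$ad_records)
  expect_gt(nrow(ch0), 1000)
  expect_equal(mean(ch0$removal_logged), 1)

  # full deletion
  all_del <- inject_errors(b, error_injection_params(
    missing_removal_rate = 1, standby_error_rate = 0, rounding_fraction = 0
  ), seed = 5)
  ch1 <- count_ad_changes(all_del$ad_records)
  expect_equal(mean(ch1$removal_logged), 0)

  # binomial tolerance around 9%
  some <- inject_errors(b, error_injection_params(
    missing_removal_rate = 0.09, standby_error_rate = 0,
    rounding_fraction = 0
  ), seed = 6)
  ch2 <- count_ad_changes(some$ad_records)
  p_hat <- mean(!ch2$removal_logged)
  se <- sqrt(0.09 * 0.91 / nrow(ch2))
  expect_lt(abs(p_hat - 0.09), 3 * se)
})

test_that("the 1-minute tolerance recovers removals documented just after a change", {
  # predecessor removal 40 s after the new device: one change, removal logged
  ad <- rbind(ad_tbl("Larynxmaske", -60, 10 + 40 / 60),
              ad_tbl("Tubus", 10))
  ch <- count_ad_changes(ad, tolerance_min = 1)
  expect_equal(nrow(ch), 1)
  expect_true(ch$removal_logged)
  # without the tolerance the same documentation counts as missing
  ch0 <- count_ad_changes(ad, tolerance_min = 0)
  expect_false(ch0$removal_logged)
})

test_that("timestamp rounding floors about the configured fraction of timestamps", {
  b <- simulate_bundle(n_stays = 25, seed = 42)
  bc <- inject_errors(b, error_injection_params(
    missing_removal_rate = 0, standby_error_rate = 0, rounding_fraction = 0.6
  ), seed = 7)
  on_grid <- (as.numeric(bc$medications$start_time) %% 300) == 0
  n <- length(on_grid)
  expect_gt(n, 100)
  se <- sqrt(0.6 * 0.4 / n)
  expect_lt(abs(mean(on_grid) - 0.6), 4 * se)
  expect_error(error_injection_params(rounding_fraction = 1.5), "0, 1")
})

test_that("standby mis-documentation delays follow the fitted log-normal", {
  p <- error_injection_params()
  expect_equal(stats::qlnorm(0.5, p$standby_delay_meanlog,
                             p$standby_delay_sdlog), 7, tolerance = 1e-8)
  expect_equal(stats::qlnorm(0.75, p$standby_delay_meanlog,
                             p$standby_delay_sdlog), 20, tolerance = 1e-8)
  b <- simulate_bundle(n_stays = 10, rules = "rst_change", p_actionable = 1,
                       p_unlinked = 0, seed = 3)
  bc <- inject_errors(b, error_injection_params(
    missing_removal_rate = 0, rounding_fraction = 0, standby_error_rate = 1
  ), seed = 8)
  extra <- nrow(bc$vent_states) - nrow(b$vent_states)
  expect_gt(extra, 0)   # delayed deactivations appended
  expect_equal(sum(bc$corruptions$type == "standby_misdocumented"), extra)
})

test_that("corruption with compensation on recovers at least as much as off", {
  b <- simulate_bundle(n_stays = 12, seed = 55)
  bc <- inject_errors(b, error_injection_params(
    missing_removal_rate = 0, standby_error_rate = 0, rounding_fraction = 0.6
  ), seed = 9)
  on <- recovery_rate(bc, config = annotation_config())$actionable
  off <- recovery_rate(
    bc, config = annotation_config(rounding_compensation = FALSE)
  )$actionable
  expect_gte(on, off)
})
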