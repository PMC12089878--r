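eval_med <- function(pac, med, config = CFG) {
  ep <- build_episodes(med, MAPS, config)
  evaluate_medication_rules(T0, pac, ep, MAPS, config)$rule_id
}

test_that("a relevant bolus inside the window fires the bolus rule", {
  # cafedrine/theodrenaline bolus 7 min after a low-pressure alarm
  med <- med_tbl("D015", 7, 7, amount = 1, amount_unit = "mg")
  expect_equal(eval_med("IBP_low", med), "med_bolus")
  expect_length(eval_med("IBP_low", med_tbl("D015", 21.5, 21.5)), 0)
  expect_length(eval_med("HR_high", med), 0)  # not relevant for this PAC
})

test_that("start, increase and the ELSE chain behave per the rule table", {
  fresh <- med_tbl("D001", 10, 50, rate = 8, rate_unit = "ml/h",
                   conc = 0.1, conc_unit = "mg/ml")
  expect_equal(eval_med("IBP_low", fresh), "med_start")

  chain <- med_tbl(c("D001", "D001"), c(-120, 10), c(7, 50),
                   rate = c(5, 8), rate_unit = "ml/h",
                   conc = 0.1, conc_unit = "mg/ml")
  # predecessor ended 3 min before the new start: increase, not start
  expect_equal(eval_med("IBP_low", chain), "med_increase")

  equal_chain <- med_tbl(c("D001", "D001"), c(-120, 10), c(7, 50),
                         rate = c(8, 8), rate_unit = "ml/h",
                         conc = 0.1, conc_unit = "mg/ml")
  expect_length(eval_med("IBP_low", equal_chain), 0)

  parallel <- med_tbl(c("D001", "D001"), c(-60, 10), c(60, 50),
                      rate = c(5, 8), rate_unit = "ml/h",
                      conc = 0.1, conc_unit = "mg/ml")
  expect_length(eval_med("IBP_low", parallel), 0)
})

test_that("stop and decrease fire for eligible PACs only", {
  stopped <- med_tbl("D004", -120, 5, rate = 5, rate_unit = "ml/h",
                     conc = 1, conc_unit = "mg/ml")
  expect_equal(eval_med("IBP_low", stopped), "med_stop")

  dec <- med_tbl(c("D004", "D004"), c(-120, 5), c(5, 60),
                 rate = c(8, 3), rate_unit = "ml/h",
                 conc = 1, conc_unit = "mg/ml")
  expect_equal(eval_med("IBP_low", dec), "med_decrease")

  restart_equal <- med_tbl(c("D004", "D004"), c(-120, 5), c(5, 60),
                           rate = c(8, 8), rate_unit = "ml/h",
                           conc = 1, conc_unit = "mg/ml")
  expect_length(eval_med("IBP_low", restart_equal), 0)
})

test_that("stop and decrease never fire for the low-saturation condition", {
  stopped <- med_tbl("D017", -120, 5, rate = 5, rate_unit = "ml/h",
                     conc = 0.01, conc_unit = "mg/ml")
  expect_length(eval_med("SpO2_low", stopped), 0)
  dec <- med_tbl(c("D017", "D017"), c(-120, 5), c(5, 60),
                 rate = c(8, 3), rate_unit = "ml/h",
                 conc = 0.01, conc_unit = "mg/ml")
  expect_length(eval_med("SpO2_low", dec), 0)
})

test_that("start and increase are mutually exclusive for an episode pair, as are stop and decrease", {
  set.seed(5)
  for (k in 1:25) {
    o <- runif(1, 1, 14)
    gap_end <- o - runif(1, 0, 8)          # predecessor end near the start
    r <- round(runif(2, 2, 12), 1)
    med <- med_tbl(c("D004", "D004"), c(-120, o), c(gap_end, o + 40),
                   rate = r, rate_unit = "ml/h", conc = 1,
                   conc_unit = "mg/ml")
    fired_give <- eval_med("IBP_high", med)   # nitroglycerin: give side
    fired_stop <- eval_med("IBP_low", med)    # nitroglycerin: stop side
    expect_false(all(c("med_start", "med_increase") %in% fired_give))
    expect_false(all(c("med_stop", "med_decrease") %in% fired_stop))
  }
})

test_that("mixtures are assessed as one unit via the mixture mapping", {
  mix <- med_tbl("D030", 5, 60, rate = 5, rate_unit = "ml/h")
  expect_equal(eval_med("HR_high", mix), "med_start")
  expect_length(eval_med("HR_low", mix), 0)   # give not relevant there
  irrelevant <- med_tbl("D031", 5, 60, rate = 50, rate_unit = "ml/h")
  expect_length(eval_med("IBP_low", irrelevant), 0)
})

test_that("carrier fluids are invisible to the rules, fluid therapy is not", {
  carrier <- med_tbl("D020", 5, 60, rate = 100, rate_unit = "ml/h")
  expect_length(eval_med("IBP_low", carrier), 0)
  therapy <- med_tbl("D020", 5, 60, rate = 600, rate_unit = "ml/h")
  expect_equal(eval_med("IBP_low", therapy), "med_start")
})

test_that("incomparable rates keep rate-dependent rules silent", {
  chain <- med_tbl(c("D001", "D001"), c(-120, 10), c(9, 50),
                   rate = c(5, 8), rate_unit = c("mg/h", "ml/h"),
                   conc = NA_real_, conc_unit = NA_character_)
  expect_length(eval_med("IBP_low", chain), 0)
})

test_that("round-down compensation recovers administrations floored past the alarm", {
  # alarm at T0 (07 s past the minute); bolus 2 min later, documented
  # floored to the previous grid point, i.e. before the alarm
  floored <- T0 + 120
  floored <- floored - (as.numeric(floored) %% 300)
  med <- med_tbl("D015", 0, 0)
  med$start_time <- med$end_time <- floored
  expect_length(eval_med("IBP_low", med,
                         annotation_config(rounding_compensation = FALSE)), 0)
  expect_equal(eval_med("IBP_low", med, CFG), "med_bolus")
})

test_that("unmapped drug ids never fire a rule and are reported", {
  med <- med_tbl("D999", 5, 5)
  ep <- build_episodes(med, MAPS, CFG)
  expect_equal(ep$status, "unmapped")
  expect_length(eval_med("IBP_low", med), 0)
})
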