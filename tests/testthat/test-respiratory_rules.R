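test_that("last_before and max_in_window follow the documented boundaries", {
  times <- T0 + c(-30, -10, 5, 12, 40) * 60
  vals <- c(0.3, 0.4, 0.4, 0.6, 0.9)
  lb <- last_before(times, vals, T0)
  expect_equal(lb$value, 0.4)
  expect_null(last_before(times[0], vals[0], T0)$value)
  # event exactly at the reference instant counts as "last"
  at <- last_before(times, vals, T0 + 5 * 60)
  expect_equal(at$value, 0.4)
  expect_equal(at$time, T0 + 5 * 60)

  mw <- max_in_window(times, vals, T0, 30)
  expect_equal(mw$value, 0.6)
  expect_null(max_in_window(times, vals, T0 + 120 * 60, 30)$value)
  # brute-force oracle scan
  set.seed(7)
  for (k in 1:20) {
    tt <- T0 + runif(15, -60, 60) * 60
    vv <- runif(15)
    got <- max_in_window(tt, vv, T0, 30)$value
    keep <- vv[tt >= T0 & tt < T0 + 1800]
    expect_equal(got, if (length(keep)) max(keep) else NULL)
  }
})

test_that("effective therapy level applies standby semantics", {
  vs6 <- vs_tbl("ventilator", "bipap", -20, standby = TRUE)
  expect_equal(effective_rst_level(T0, vs6, mappings = MAPS), 0)
  vs2 <- vs_tbl("flowmeter", "o2 flow", -20, standby = TRUE)
  expect_equal(effective_rst_level(T0, vs2, mappings = MAPS), 2)
  vs_plain <- vs_tbl("ventilator", "pcv", -20)
  expect_equal(effective_rst_level(T0, vs_plain, mappings = MAPS), 7)
  expect_equal(effective_rst_level(T0, empty_vs(), mappings = MAPS), 1)
  unk <- vs_tbl("gizmo", "??", -20)
  expect_true(is.na(effective_rst_level(T0, unk, mappings = MAPS)))
})

test_that("airway-device change fires on escalation without in-window removal", {
  esc <- rbind(ad_tbl("no AD documented", -60), ad_tbl("Tubus", 10))
  expect_true(rule_ad_change(T0, esc, MAPS)$fired)
  high <- ad_tbl("Tubus", -60)
  expect_false(rule_ad_change(T0, high, MAPS)$fired)
  removed <- rbind(ad_tbl("no AD documented", -60), ad_tbl("Tubus", 10, 12))
  expect_false(rule_ad_change(T0, removed, MAPS)$fired)
  # removal after the window does not cancel the change
  late_removed <- rbind(ad_tbl("no AD documented", -60),
                        ad_tbl("Tubus", 10, 45))
  expect_true(rule_ad_change(T0, late_removed, MAPS)$fired)
  # a device whose removal predates the alarm leaves level 1 behind
  gone <- rbind(ad_tbl("Tubus", -60, -30), ad_tbl("Larynxmaske", 8))
  expect_true(rule_ad_change(T0, gone, MAPS)$fired)
})

test_that("therapy change fires on escalation but not under standby", {
  esc <- rbind(vs_tbl("none", "spontaneous", -30),
               vs_tbl("ventilator", "bipap", 8))
  expect_true(rule_rst_change(T0, esc, mappings = MAPS)$fired)

  standby_doc <- rbind(vs_tbl("none", "spontaneous", -30),
                       vs_tbl("ventilator", "bipap", 8, standby = TRUE))
  expect_false(rule_rst_change(T0, standby_doc, mappings = MAPS)$fired)

  from_standby <- rbind(vs_tbl("ventilator", "bipap", -30, standby = TRUE),
                        vs_tbl("ventilator", "bipap", 8))
  expect_true(rule_rst_change(T0, from_standby, mappings = MAPS)$fired)

  deesc <- rbind(vs_tbl("ventilator", "pcv", -30),
                 vs_tbl("ventilator", "bipap", 8))
  expect_false(rule_rst_change(T0, deesc, mappings = MAPS)$fired)
})

test_that("parameter increase respects settability and standby", {
  st6 <- vs_tbl("ventilator", "bipap", -30)
  up <- rbind(vp_tbl("fio2", 0.4, -25), vp_tbl("fio2", 0.6, 10))
  expect_true(rule_param_increase(T0, "fio2", up, st6, mappings = MAPS)$fired)

  flat <- rbind(vp_tbl("fio2", 0.6, -25), vp_tbl("fio2", 0.6, 10))
  expect_false(rule_param_increase(T0, "fio2", flat, st6,
                                   mappings = MAPS)$fired)

  # PEEP documented during oxygen therapy is an artifact, value counts as 0
  st2 <- vs_tbl("flowmeter", "o2 flow", -30)
  peep <- vp_tbl("peep", 5, 10)
  expect_false(rule_param_increase(T0, "peep", peep, st2,
                                   mappings = MAPS)$fired)

  # oxygen flow may still be raised during oxygen therapy
  o2 <- rbind(vp_tbl("o2_flow", 2, -25), vp_tbl("o2_flow", 6, 10))
  expect_true(rule_param_increase(T0, "o2_flow", o2, st2,
                                  mappings = MAPS)$fired)

  # settings written while the ventilator is in standby count as 0
  st_sb <- vs_tbl("ventilator", "bipap", -30, standby = TRUE)
  expect_false(rule_param_increase(T0, "fio2", up, st_sb,
                                   mappings = MAPS)$fired)
})

test_that("parameter increase is monotone in the window length", {
  set.seed(11)
  for (k in 1:15) {
    n <- sample(2:8, 1)
    vp <- vp_tbl("fio2", round(runif(n), 2), runif(n, -40, 50))
    st <- vs_tbl("ventilator", "bipap", -45)
    fired <- vapply(c(10, 20, 30, 45), function(w) {
      rule_param_increase(T0, "fio2", vp, st, mappings = MAPS,
                          config = annotation_config(resp_window_min = w))$fired
    }, logical(1))
    expect_true(all(diff(as.integer(fired)) >= 0))
  }
})

test_that("respiratory rules are invariant to input row order", {
  set.seed(23)
  for (k in 1:10) {
    ad <- rbind(ad_tbl("Larynxmaske", -40), ad_tbl("Tubus", runif(1, 3, 25)))
    vs <- rbind(vs_tbl("none", "spontaneous", -30),
                vs_tbl("ventilator", "bipap", runif(1, 3, 25)))
    vp <- vp_tbl("fio2", runif(3), runif(3, -30, 29))
    perm_ad <- ad[sample(nrow(ad)), ]
    perm_vs <- vs[sample(nrow(vs)), ]
    perm_vp <- vp[sample(nrow(vp)), ]
    expect_equal(rule_ad_change(T0, perm_ad, MAPS)$fired,
                 rule_ad_change(T0, ad, MAPS)$fired)
    expect_equal(rule_rst_change(T0, perm_vs, mappings = MAPS)$fired,
                 rule_rst_change(T0, vs, mappings = MAPS)$fired)
    expect_equal(
      rule_param_increase(T0, "fio2", perm_vp, perm_vs, mappings = MAPS)$fired,
      rule_param_increase(T0, "fio2", vp, vs, mappings = MAPS)$fired
    )
  }
})
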