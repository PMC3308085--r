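ep_etn <- toy_episode("etanercept")
etn_fills <- do.call(rbind, lapply(seq(0L, 359L, 28L), function(d) {
  toy_fill("etanercept", d, 28, 50, 4)
}))

test_that("biologic switch-or-add fires only on new initiations in-window", {
  # adalimumab started at month 5
  f <- rbind(etn_fills, toy_fill("adalimumab", 150L, 28, 40, 2))
  expect_true(check_biologic_switch_or_add(ep_etn, f, empty_infusions()))
  # refills of the index biologic alone never flag
  expect_false(check_biologic_switch_or_add(ep_etn, etn_fills,
                                            empty_infusions()))
  # a second biologic used continuously since before the index date is not
  # a new initiation
  cont <- do.call(rbind, lapply(seq(-90L, 359L, 28L), function(d) {
    toy_fill("adalimumab", d, 28, 40, 2)
  }))
  expect_false(check_biologic_switch_or_add(ep_etn, rbind(etn_fills, cont),
                                            empty_infusions()))
})

test_that("new-DMARD rule honours the 6-month 'already taking' window", {
  f <- rbind(etn_fills, toy_fill("methotrexate", 120L, 30, 2.5, 120, "oral"))
  expect_true(check_new_dmard(ep_etn, f))
  # continued from before the index date
  f <- rbind(etn_fills,
             toy_fill("hydroxychloroquine", -60L, 30, 200, 60, "oral"),
             toy_fill("hydroxychloroquine", 30L, 30, 200, 60, "oral"))
  expect_false(check_new_dmard(ep_etn, f))
  # a fill on the index date itself counts as already taking
  f <- rbind(etn_fills, toy_fill("sulfasalazine", 0L, 30, 500, 120, "oral"))
  expect_false(check_new_dmard(ep_etn, f))
  # a DMARD last filled 7 months before the index is no longer 'taking'
  f <- rbind(etn_fills,
             toy_fill("leflunomide", -210L, 30, 20, 30, "oral"),
             toy_fill("leflunomide", 100L, 30, 20, 30, "oral"))
  expect_true(check_new_dmard(ep_etn, f))
})

test_that("dose escalation uses round-up arithmetic and schedule limits", {
  ifx_days <- c(0L, 14L, 42L, 98L, 154L, 210L, 266L, 322L)
  ep <- toy_episode("infliximab")
  # 300 -> 500 mg escalates (both round up to different 100 mg bins)
  inf <- toy_infusion("infliximab", ifx_days, c(rep(300, 7), 500))
  expect_true(check_dose_escalation(ep, empty_fills(), inf))
  # 290 -> 300 mg rounds to the same bin
  inf <- toy_infusion("infliximab", ifx_days, c(290, rep(300, 7)))
  expect_false(check_dose_escalation(ep, empty_fills(), inf))
  # more than 120% of the expected number of infusions
  inf <- toy_infusion("infliximab",
                      c(0L, 14L, 42L, 98L, 126L, 154L, 182L, 210L, 238L,
                        266L, 294L, 322L), rep(300, 12))
  expect_true(check_dose_escalation(ep, empty_fills(), inf))

  # abatacept uses the raw difference
  ep <- toy_episode("abatacept")
  inf <- toy_infusion("abatacept", seq(0L, 330L, 30L), rep(750, 12))
  expect_false(check_dose_escalation(ep, empty_fills(), inf))
  inf$dose_mg[12] <- 850
  expect_true(check_dose_escalation(ep, empty_fills(), inf))

  # etanercept 100 mg/week exceeds the 75 mg ceiling; 50 mg/week does not
  esc <- etn_fills
  esc$quantity <- 8
  expect_true(check_dose_escalation(ep_etn, esc, empty_infusions()))
  expect_false(check_dose_escalation(ep_etn, etn_fills, empty_infusions()))

  expect_error(check_dose_escalation(toy_episode("methotrexate", "dmard"),
                                     empty_fills(), empty_infusions()),
               "biologics only")
})

test_that("injection rule counts unique days from index + 90", {
  mk <- function(days) {
    data.frame(patient_id = "T1",
               date = as.Date("2005-01-15") + days,
               kind = "glucocorticoid_injection")
  }
  expect_true(check_injections(ep_etn, mk(c(150L, 240L))))
  expect_false(check_injections(ep_etn, mk(c(150L, 150L, 150L))))
  expect_false(check_injections(ep_etn, mk(c(30L, 60L))))
  # boundary: day 90 counts, day 89 does not
  expect_true(check_injections(ep_etn, mk(c(90L, 240L))))
  expect_false(check_injections(ep_etn, mk(c(89L, 240L))))
})

test_that("oral glucocorticoid rule branches on pre-index exposure", {
  gc <- function(day, supply, strength, qty) {
    toy_fill("oral_glucocorticoid", day, supply, strength, qty, "oral")
  }
  # naive: 40 days of supply after month 3 flags initiation
  f <- rbind(etn_fills, gc(120L, 20, 5, 20), gc(200L, 20, 5, 20))
  expect_equal(check_oral_glucocorticoid(ep_etn, f), "gc_initiation")
  # naive: exactly 30 days passes
  f <- rbind(etn_fills, gc(150L, 30, 5, 30))
  expect_length(check_oral_glucocorticoid(ep_etn, f), 0)
  # prevalent at exactly 120% passes, one milligram more fails
  f <- rbind(etn_fills, gc(-100L, 90, 5, 180), gc(250L, 90, 5, 216))
  expect_length(check_oral_glucocorticoid(ep_etn, f), 0)
  f <- rbind(etn_fills, gc(-100L, 90, 5, 180), gc(250L, 90, 1, 1081))
  expect_equal(check_oral_glucocorticoid(ep_etn, f), "gc_dose_increase")
  # a prevalent user with zero recorded milligrams is treated as naive
  f <- rbind(etn_fills, gc(-100L, 0, 5, 0), gc(150L, 10, 5, 10))
  expect_length(check_oral_glucocorticoid(ep_etn, f), 0)
})

test_that("classification is deterministic, monotone, and window-contained", {
  fx <- fixture_cohort()
  r1 <- classify_episodes(fx$episodes, fx$fills, fx$infusions, fx$procedures)
  r2 <- classify_episodes(fx$episodes, fx$fills, fx$infusions, fx$procedures)
  expect_identical(r1, r2)

  # adding a prohibited event can only remove effectiveness
  extra <- rbind(fx$fills,
                 toy_fill("methotrexate", 120L, 30, 2.5, 120, "oral",
                          pid = "F01"))
  r3 <- classify_episodes(fx$episodes, extra, fx$infusions, fx$procedures)
  expect_true(all(r3$effective <= r1$effective))
  expect_false(r3$effective[r3$patient_id == "F01"])

  # events outside (index, outcome] leave flags unchanged (other than the
  # pre-index exposure sets): injection after outcome, DMARD after outcome
  after <- rbind(
    fx$fills,
    toy_fill("methotrexate", 400L, 30, 2.5, 120, "oral", pid = "F01"))
  procs_after <- rbind(
    fx$procedures,
    data.frame(patient_id = "F01", date = as.Date("2005-01-15") + c(380L, 400L),
               kind = "glucocorticoid_injection"))
  r4 <- classify_episodes(fx$episodes, after, fx$infusions, procs_after)
  expect_identical(r4$flags, r1$flags)
})

test_that("overlapping reasons are all recorded", {
  fx <- fixture_cohort()
  res <- classify_episodes(fx$episodes, fx$fills, fx$infusions,
                           fx$procedures)
  multi <- res[res$patient_id == "F30", ]
  expect_false(multi$effective)
  expect_true(multi$nonadherent_or_switch && multi$new_dmard_added &&
                multi$excess_joint_injections)
  # rituximab with no prohibited events is effective despite no claims
  expect_true(res$effective[res$patient_id == "F15"])
})
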