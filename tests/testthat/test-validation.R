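test_that("confusion matrix tallies match a brute-force count", {
  res <- big_cohort_results()
  cm <- confusion_matrix(res$alg, res$gold)
  a <- res$alg$effective
  g <- res$gold$effective
  expect_equal(as.integer(cm),
               c(sum(a & g), sum(a & !g), sum(!a & g), sum(!a & !g)))
  expect_equal(sum(cm), nrow(res$alg))

  # all-concordant-positive toy case
  toy <- data.frame(patient_id = c("A", "B", "C"), index_drug = "etanercept",
                    index_date = as.Date("2005-01-01"), effective = TRUE)
  expect_equal(as.integer(confusion_matrix(toy, toy)), c(3L, 0L, 0L, 0L))

  # mismatched episode sets are an error
  expect_error(confusion_matrix(toy, toy[1:2, ]), "same episodes")
  other <- toy
  other$patient_id[1] <- "Z"
  expect_error(confusion_matrix(toy, other), "same episodes")
})

test_that("performance metrics reproduce the published 2x2 tables", {
  pm <- performance_metrics(as_confusion(42, 14, 14, 127))
  expect_equal(pm$ppv$estimate, 42 / 56)
  expect_equal(pm$npv$estimate, 127 / 141)
  expect_equal(round(100 * c(pm$ppv$estimate, pm$npv$estimate,
                             pm$se$estimate, pm$sp$estimate)),
               c(75, 90, 75, 90))
  pm <- performance_metrics(as_confusion(60, 19, 23, 203))
  expect_equal(round(100 * c(pm$ppv$estimate, pm$npv$estimate,
                             pm$se$estimate, pm$sp$estimate)),
               c(76, 90, 72, 91))
  # perfect classifier
  pm <- performance_metrics(as_confusion(10, 0, 0, 10))
  expect_equal(vapply(pm[c("ppv", "npv", "se", "sp")], `[[`, 1, "estimate"),
               c(ppv = 1, npv = 1, se = 1, sp = 1))
  # zero denominator is reported as missing, with a warning
  expect_warning(pm <- performance_metrics(as_confusion(0, 0, 5, 5)),
                 "denominator")
  expect_true(is.na(pm$ppv$estimate))
})

test_that("binomial confidence intervals contain the estimate within [0,1]", {
  set.seed(30)
  for (method in c("clopper_pearson", "wald", "wald_pooled_n")) {
    for (rep in 1:20) {
      cm <- as_confusion(sample(1:50, 1), sample(1:50, 1), sample(1:50, 1),
                         sample(1:50, 1))
      pm <- performance_metrics(cm, method)
      for (m in pm[c("ppv", "npv", "se", "sp")]) {
        expect_lte(m$lower, m$estimate)
        expect_gte(m$upper, m$estimate)
        expect_gte(m$lower, 0)
        expect_lte(m$upper, 1)
      }
    }
  }
})

test_that("the pooled-n Wald variant reproduces the reported PPV/Se widths", {
  # the published PPV and Se intervals correspond to a Wald interval on the
  # total episode count; the reported NPV/Sp widths fit no single-denominator
  # binomial convention and are not asserted
  pm <- performance_metrics(as_confusion(60, 19, 23, 203), "wald_pooled_n")
  expect_equal(round(100 * c(pm$ppv$lower, pm$ppv$upper)), c(71, 81))
  expect_equal(round(100 * c(pm$se$lower, pm$se$upper)), c(67, 77))
})

test_that("(Se, Sp, prevalence) and (PPV, NPV, positivity) are Bayes-consistent", {
  set.seed(31)
  for (rep in 1:20) {
    cm <- as_confusion(sample(1:80, 1), sample(1:80, 1), sample(1:80, 1),
                       sample(1:80, 1))
    pm <- performance_metrics(cm)
    n <- sum(cm)
    prev <- (cm[["tp"]] + cm[["fn"]]) / n
    pos <- (cm[["tp"]] + cm[["fp"]]) / n
    se <- pm$se$estimate
    sp <- pm$sp$estimate
    expect_equal(pm$ppv$estimate,
                 se * prev / (se * prev + (1 - sp) * (1 - prev)),
                 tolerance = 1e-12)
    expect_equal(pm$npv$estimate,
                 sp * (1 - prev) / (sp * (1 - prev) + (1 - se) * prev),
                 tolerance = 1e-12)
    expect_equal(pos, se * prev + (1 - sp) * (1 - prev), tolerance = 1e-12)
  }
})

test_that("bias analysis is linear with the predictive values as endpoints", {
  b <- bias_analysis(c(0.30, 0.50), ppv = 0.76, npv = 0.90)
  expect_equal(b$true_rate, c(0.298, 0.430), tolerance = 1e-12)
  expect_equal(round(100 * b$relative_bias), c(1, 16))
  expect_lt(b$relative_bias[1], 0.01)
  # endpoints: 1 - NPV at observed 0, PPV at observed 1
  ends <- bias_analysis(c(0, 1), ppv = 0.76, npv = 0.90)
  expect_equal(ends$true_rate, c(0.10, 0.76))
  # perfect test: no bias at any observed rate
  perfect <- bias_analysis(c(0.2, 0.5, 0.9), 1, 1)
  expect_equal(perfect$relative_bias, c(0, 0, 0))
  # linearity in the observed rate
  grid <- bias_analysis(seq(0, 1, 0.1), 0.76, 0.90)
  expect_equal(diff(grid$true_rate), rep(0.1 * (0.76 - 0.10), 10),
               tolerance = 1e-12)
  expect_error(bias_analysis(0, ppv = 0.5, npv = 1), "undefined")
})

test_that("discordance report tallies the flags behind false negatives", {
  fx <- fixture_cohort()
  alg <- classify_episodes(fx$episodes, fx$fills, fx$infusions,
                           fx$procedures)
  gold <- evaluate_gold_standard(fx$episodes, fx$visits, alg,
                                 "primary_das28")
  rep <- discordance_report(alg, gold)
  # fixture outcome visits all reach LDA, so gold follows adherence and
  # discordance is exactly the adherent-but-flagged episodes
  expect_equal(nrow(rep$false_positives), 0L)
  fn_expect <- sum(!alg$effective & !alg$nonadherent_or_switch)
  expect_equal(nrow(rep$false_negatives), fn_expect)
  expect_gte(rep$fn_flag_tally[["gc_dose_increase"]], 1)
  expect_gte(rep$fn_flag_tally[["biologic_dose_escalation"]], 1)

  # concordant sets give an empty report
  rep0 <- discordance_report(alg[alg$effective, ], gold[gold$effective, ])
  expect_equal(nrow(rep0$false_positives) + nrow(rep0$false_negatives), 0L)
})

test_that("comorbidity exclusion removes all episodes of flagged patients", {
  fx <- fixture_cohort()
  com <- data.frame(patient_id = c("F01", "F02", "F03"),
                    condition = c("fibromyalgia", "depression", "ptsd"),
                    flag = c(TRUE, FALSE, TRUE))
  out <- comorbidity_exclusion(fx$episodes, com)
  expect_equal(nrow(out), nrow(fx$episodes) - 2L)
  expect_false(any(out$patient_id %in% c("F01", "F03")))
  expect_true("F02" %in% out$patient_id)
  # no flags: identity; all flagged: empty
  expect_equal(comorbidity_exclusion(fx$episodes, com[com$flag == FALSE, ]),
               fx$episodes)
  allcom <- data.frame(patient_id = fx$episodes$patient_id,
                       condition = "depression", flag = TRUE)
  expect_equal(nrow(comorbidity_exclusion(fx$episodes, allcom)), 0L)
})
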