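idx <- as.Date("2005-06-01")

test_that("initiation requires a 6-month same-drug washout", {
  # prior fill 90 days before the candidate date blocks the initiation
  f <- rbind(toy_fill("etanercept", -90L, 28, index = idx),
             toy_fill("etanercept", 0L, 28, index = idx))
  inits <- find_initiations(f, NULL, "etanercept")
  expect_equal(inits$index_date, idx - 90L)

  # first-ever fill is an initiation
  inits <- find_initiations(toy_fill("etanercept", 0L, 28, index = idx),
                            NULL, "etanercept")
  expect_equal(inits$index_date, idx)

  # two fills 200 days apart with nothing between: both initiate
  f <- rbind(toy_fill("adalimumab", 0L, 28, index = idx),
             toy_fill("adalimumab", 200L, 28, index = idx))
  inits <- find_initiations(f, NULL, "adalimumab")
  expect_equal(nrow(inits), 2L)

  expect_error(find_initiations(f, NULL, "aspirin"), "unknown drug")
})

test_that("initiation count is monotone non-increasing in the lookback", {
  co <- generate_cohort(sim_config(n_patients = 60L), seed = 3L)
  counts <- vapply(c(30L, 90L, 183L, 365L), function(lb) {
    sum(vapply(ra_biologics(), function(d) {
      nrow(find_initiations(co$fills, co$infusions, d, lb))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("episode eligibility windows are enforced", {
  mk_visits <- function(days) {
    data.frame(patient_id = "T1", date = idx + days, tjc28 = 5, sjc28 = 4,
               esr_mm_hr = 20, patient_global = 40, physician_global = 40)
  }
  inits <- data.frame(patient_id = "T1", index_drug = "etanercept",
                      index_date = idx)
  oral <- toy_fill("other_oral", -240L, 30, 10, 30, "oral", index = idx)

  # baseline same day, outcome at 13 months, prior oral fill at month -8
  ep <- build_episodes(inits, oral, mk_visits(c(0L, 395L)))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$outcome_date, idx + 395L)

  # no outcome visit -> excluded
  ep <- build_episodes(inits, oral, mk_visits(0L))
  expect_equal(nrow(ep), 0L)
  expect_equal(attr(ep, "exclusions")[["no_outcome_visit"]], 1L)

  # outcome visit at 9 months only -> outside [10, 14] months
  ep <- build_episodes(inits, oral, mk_visits(c(0L, 274L)))
  expect_equal(nrow(ep), 0L)

  # no baseline visit -> excluded unless the requirement is dropped
  ep <- build_episodes(inits, oral, mk_visits(365L))
  expect_equal(nrow(ep), 0L)
  ep <- build_episodes(inits, oral, mk_visits(365L), require_baseline = FALSE)
  expect_equal(nrow(ep), 1L)

  # no oral fill in the 6-12 month pre-index window -> excluded
  late_oral <- toy_fill("other_oral", -100L, 30, 10, 30, "oral", index = idx)
  ep <- build_episodes(inits, late_oral, mk_visits(c(0L, 365L)))
  expect_equal(nrow(ep), 0L)
  expect_equal(attr(ep, "exclusions")[["no_prior_oral_fill"]], 1L)

  # two candidate outcome visits: nearest to 12 months wins
  ep <- build_episodes(inits, oral, mk_visits(c(0L, 320L, 370L)))
  expect_equal(ep$outcome_date, idx + 370L)
})

test_that("DMARD episodes require methotrexate history and never index MTX", {
  visits <- data.frame(patient_id = "T1", date = idx + c(0L, 365L),
                       tjc28 = 5, sjc28 = 4, esr_mm_hr = 20,
                       patient_global = 40, physician_global = 40)
  hcq <- toy_fill("hydroxychloroquine", 0L, 30, 200, 60, "oral", index = idx)
  mtx_old <- toy_fill("methotrexate", -730L, 30, 2.5, 120, "oral", index = idx)
  oral <- toy_fill("other_oral", -240L, 30, 10, 30, "oral", index = idx)

  # HCQ start with MTX two years prior qualifies
  ep <- find_dmard_episodes(rbind(hcq, mtx_old, oral), visits)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$index_drug, "hydroxychloroquine")

  # no MTX ever -> no episode
  ep <- find_dmard_episodes(rbind(hcq, oral), visits)
  expect_equal(nrow(ep), 0L)

  # a lone MTX start is never an episode
  mtx_new <- toy_fill("methotrexate", 0L, 30, 2.5, 120, "oral", index = idx)
  ep <- find_dmard_episodes(rbind(mtx_new, oral), visits)
  expect_equal(nrow(ep), 0L)
})

test_that("one episode per patient keeps the earliest and dedupes ids", {
  eps <- data.frame(
    patient_id = c("A", "A", "B"),
    index_drug = c("etanercept", "adalimumab", "rituximab"),
    index_date = as.Date(c("2005-03-01", "2004-06-01", "2006-01-01")),
    episode_class = "biologic",
    baseline_date = as.Date("2005-01-01"),
    outcome_date = as.Date("2006-01-01"))
  out <- one_episode_per_patient(eps)
  expect_equal(nrow(out), 2L)
  expect_equal(out$index_drug[out$patient_id == "A"], "adalimumab")
  expect_false(anyDuplicated(out$patient_id) > 0)

  # date tie broken by drug name
  eps$index_date[2] <- eps$index_date[1]
  out <- one_episode_per_patient(eps)
  expect_equal(out$index_drug[out$patient_id == "A"], "adalimumab")

  expect_equal(nrow(one_episode_per_patient(eps[0, ])), 0L)
})

test_that("every generated patient is recovered as exactly one episode", {
  co <- generate_cohort(sim_config(n_patients = 400L), seed = 9L)
  ep <- rbind(find_biologic_episodes(co$fills, co$infusions, co$visits),
              find_dmard_episodes(co$fills, co$visits))
  expect_equal(nrow(ep), 400L)
  expect_setequal(ep$patient_id, co$truth$patient_id)
  key <- function(x) paste(x$patient_id, x$index_drug, x$index_date)
  expect_setequal(key(ep), key(co$truth))
  # retained episodes satisfy the eligibility predicates directly
  lo <- vapply(seq_len(nrow(ep)), function(k)
    as.numeric(ep$outcome_date[k] - ep$index_date[k]), numeric(1))
  expect_true(all(lo >= 304 & lo <= 427))
  expect_true(all(abs(as.numeric(ep$baseline_date - ep$index_date)) <= 31))
})
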