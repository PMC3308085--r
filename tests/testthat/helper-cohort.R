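# Shared fixtures, built once per test run. The large cohort backs both the
# law-of-large-numbers properties and the parameter-recovery checks.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

big_cohort <- function() {
  cached("big_cohort", function() {
    generate_cohort(sim_config(n_patients = 5000L), seed = 1L)
  })
}

big_cohort_results <- function() {
  cached("big_results", function() {
    co <- big_cohort()
    alg <- classify_episodes(co$episodes, co$fills, co$infusions,
                             co$procedures)
    gold <- evaluate_gold_standard(co$episodes, co$visits, alg,
                                   "primary_das28")
    list(alg = alg, gold = gold)
  })
}

fixture_cohort <- function() {
  cached("fixture", boundary_cohort)
}

# minimal single-episode scaffold for unit tests of individual rule checks
toy_episode <- function(drug = "etanercept", class = "biologic",
                        index = as.Date("2005-01-15"), days = 360L) {
  data.frame(patient_id = "T1", index_drug = drug, index_date = index,
             episode_class = class, baseline_date = index,
             outcome_date = index + days)
}

toy_fill <- function(drug, day, supply, strength = 50, qty = 4,
                     route = "subcutaneous", pid = "T1",
                     index = as.Date("2005-01-15")) {
  data.frame(patient_id = pid, drug = drug, fill_date = index + day,
             days_supply = supply, strength_mg = strength, quantity = qty,
             route = route)
}

toy_infusion <- function(drug, days, doses, pid = "T1",
                         index = as.Date("2005-01-15")) {
  data.frame(patient_id = pid, drug = drug, date = index + days,
             dose_mg = doses)
}

empty_fills <- function() {
  data.frame(patient_id = character(), drug = character(),
             fill_date = as.Date(character()), days_supply = numeric(),
             strength_mg = numeric(), quantity = numeric(),
             route = character())
}

empty_infusions <- function() {
  data.frame(patient_id = character(), drug = character(),
             date = as.Date(character()), dose_mg = numeric())
}

empty_procedures <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
             kind = character())
}
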