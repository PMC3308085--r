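# Deterministic 30-episode cohort exercising every algorithm component at
# its decision boundary, with hand-audited expected classifications. Built
# entirely in code; no stored data files.

#' Boundary-case test cohort with hand-audited expectations
#'
#' A deterministic cohort of 30 single-episode patients, one per boundary of
#' the rule set: medication possession ratio exactly at 0.80 vs just below,
#' glucocorticoid cumulative dose at exactly 120% vs 120% + 1 mg, the
#' infliximab round-up edge (290 vs 300 mg round to the same 100 mg bin),
#' one vs two unique injection days (and injections before day 90), the
#' abatacept one-missed-infusion allowance vs two missed, weekly-dose
#' escalation for etanercept and adalimumab, switching, new-DMARD addition,
#' the glucocorticoid-naive 30-day supply cap, a zero-milligram prevalent
#' glucocorticoid user (treated as naive), and a multi-flag episode. Every
#' episode satisfies the eligibility rules (baseline visit on the index
#' date, an oral fill 8 months before, outcome visit at day 360).
#'
#' @return A list of class `ra_cohort`: `fills`, `infusions`, `procedures`,
#'   `visits`, `episodes`, and `expected` -- a frame with the case label and
#'   the hand-derived `effective` / `flags` per episode.
#' @examples
#' fx <- boundary_cohort()
#' res <- classify_episodes(fx$episodes, fx$fills, fx$infusions,
#'                          fx$procedures)
#' all(res$flags == fx$expected$flags)
#' @export
boundary_cohort <- function() {
  index <- as.Date("2005-01-15")
  W <- 360L
  outcome <- index + W

  fills <- list()
  infs <- list()
  procs <- list()
  eps <- list()
  expd <- list()

  fill <- function(pid, drug, day, supply, strength, qty,
                   route = if (drug %in% c("etanercept", "adalimumab"))
                     "subcutaneous" else "oral") {
    fills[[length(fills) + 1]] <<- data.frame(
      patient_id = pid, drug = drug, fill_date = index + day,
      days_supply = supply, strength_mg = strength, quantity = qty,
      route = route)
  }
  infuse <- function(pid, drug, days, doses) {
    infs[[length(infs) + 1]] <<- data.frame(
      patient_id = pid, drug = drug, date = index + days, dose_mg = doses)
  }
  inject <- function(pid, days) {
    procs[[length(procs) + 1]] <<- data.frame(
      patient_id = pid, date = index + days,
      kind = "glucocorticoid_injection")
  }
  episode <- function(pid, case, drug, class, flags) {
    fill(pid, "other_oral", -240L, 30, 10, 30, "oral")  # eligibility fill
    eps[[length(eps) + 1]] <<- data.frame(
      patient_id = pid, index_drug = drug, index_date = index,
      episode_class = class, baseline_date = index, outcome_date = outcome)
    expd[[length(expd) + 1]] <<- data.frame(
      patient_id = pid, case = case,
      effective = !nzchar(flags), flags = flags)
  }
  # adherent 50 mg/week etanercept backbone used by several cases
  etn_backbone <- function(pid) {
    for (day in seq(0L, W - 1L, by = 28L)) fill(pid, "etanercept", day, 28, 50, 4)
  }
  ifx_days <- c(0L, 14L, 42L, 98L, 154L, 210L, 266L, 322L)

  # --- adherence boundaries -------------------------------------------------
  p <- "F01"; episode(p, "etn_clean", "etanercept", "biologic", "")
  etn_backbone(p)

  p <- "F02"; episode(p, "mpr_080", "etanercept", "biologic", "")
  for (day in c(0L, 72L, 144L, 216L)) fill(p, "etanercept", day, 72, 50, 10)

  p <- "F03"; episode(p, "mpr_079", "etanercept", "biologic",
                      "nonadherent_or_switch")
  for (day in c(0L, 95L, 190L)) fill(p, "etanercept", day, 95, 50, 13)

  p <- "F04"; episode(p, "ada_clean", "adalimumab", "biologic", "")
  for (day in seq(0L, W - 1L, by = 28L)) fill(p, "adalimumab", day, 28, 40, 2)

  # --- weekly-dose escalation ----------------------------------------------
  p <- "F05"; episode(p, "ada_escal_weekly", "adalimumab", "biologic",
                      "biologic_dose_escalation")
  for (day in seq(0L, W - 1L, by = 28L)) fill(p, "adalimumab", day, 28, 40, 4)

  p <- "F06"; episode(p, "etn_escal_twice_weekly", "etanercept", "biologic",
                      "biologic_dose_escalation")
  for (day in seq(0L, W - 1L, by = 28L)) fill(p, "etanercept", day, 28, 50, 8)

  # --- infliximab schedule and round-up edge -------------------------------
  p <- "F07"; episode(p, "ifx_clean", "infliximab", "biologic", "")
  infuse(p, "infliximab", ifx_days, rep(300, 8))

  p <- "F08"; episode(p, "ifx_roundup_290_300", "infliximab", "biologic", "")
  infuse(p, "infliximab", ifx_days, c(290, rep(300, 7)))

  p <- "F09"; episode(p, "ifx_escal_300_500", "infliximab", "biologic",
                      "biologic_dose_escalation")
  infuse(p, "infliximab", ifx_days, c(rep(300, 7), 500))

  p <- "F10"; episode(p, "ifx_missed_infusion", "infliximab", "biologic",
                      "nonadherent_or_switch")
  infuse(p, "infliximab", ifx_days[1:7], rep(300, 7))

  p <- "F11"; episode(p, "ifx_too_many_infusions", "infliximab", "biologic",
                      "biologic_dose_escalation")
  infuse(p, "infliximab",
         c(0L, 14L, 42L, 98L, 126L, 154L, 182L, 210L, 238L, 266L, 294L, 322L),
         rep(300, 12))

  # --- abatacept one-missed-infusion allowance -----------------------------
  p <- "F12"; episode(p, "aba_miss_one", "abatacept", "biologic", "")
  infuse(p, "abatacept", seq(0L, 330L, by = 30L), rep(750, 12))

  p <- "F13"; episode(p, "aba_miss_two", "abatacept", "biologic",
                      "nonadherent_or_switch")
  infuse(p, "abatacept", seq(0L, 300L, by = 30L), rep(750, 11))

  p <- "F14"; episode(p, "aba_escal_100mg", "abatacept", "biologic",
                      "biologic_dose_escalation")
  infuse(p, "abatacept", seq(0L, 330L, by = 30L), c(rep(750, 11), 850))

  # --- rituximab: adherence not applicable ---------------------------------
  p <- "F15"; episode(p, "ritux_clean", "rituximab", "biologic", "")
  infuse(p, "rituximab", c(0L, 14L), c(1000, 1000))

  p <- "F16"; episode(p, "ritux_switch", "rituximab", "biologic",
                      "biologic_switch_or_add")
  infuse(p, "rituximab", c(0L, 14L), c(1000, 1000))
  for (day in c(150L, 178L)) fill(p, "etanercept", day, 28, 50, 4)

  # --- switch / new DMARD ---------------------------------------------------
  p <- "F17"; episode(p, "etn_switch_to_ada", "etanercept", "biologic",
                      "biologic_switch_or_add")
  etn_backbone(p)
  for (day in c(150L, 178L)) fill(p, "adalimumab", day, 28, 40, 2)

  p <- "F18"; episode(p, "new_dmard_mtx", "etanercept", "biologic",
                      "new_dmard_added")
  etn_backbone(p)
  for (day in c(120L, 150L)) fill(p, "methotrexate", day, 30, 2.5, 120)

  p <- "F19"; episode(p, "dmard_continued_hcq", "etanercept", "biologic", "")
  etn_backbone(p)
  for (day in c(-60L, 30L)) fill(p, "hydroxychloroquine", day, 30, 200, 60)

  # --- glucocorticoid injections -------------------------------------------
  p <- "F20"; episode(p, "inject_one_day_thrice", "etanercept", "biologic", "")
  etn_backbone(p)
  inject(p, c(150L, 150L, 150L))

  p <- "F21"; episode(p, "inject_two_days", "etanercept", "biologic",
                      "excess_joint_injections")
  etn_backbone(p)
  inject(p, c(150L, 240L))

  p <- "F22"; episode(p, "inject_before_day90", "etanercept", "biologic", "")
  etn_backbone(p)
  inject(p, c(30L, 60L))

  # --- oral glucocorticoids -------------------------------------------------
  p <- "F23"; episode(p, "gc_naive_30_days", "etanercept", "biologic", "")
  etn_backbone(p)
  fill(p, "oral_glucocorticoid", 150L, 30, 5, 30)

  p <- "F24"; episode(p, "gc_naive_40_days", "etanercept", "biologic",
                      "gc_initiation")
  etn_backbone(p)
  for (day in c(120L, 200L)) fill(p, "oral_glucocorticoid", day, 20, 5, 20)

  p <- "F25"; episode(p, "gc_exactly_120pct", "etanercept", "biologic", "")
  etn_backbone(p)
  fill(p, "oral_glucocorticoid", -100L, 90, 5, 180)  # 900 mg pre-index
  fill(p, "oral_glucocorticoid", 250L, 90, 5, 216)   # 1080 mg = 120%

  p <- "F26"; episode(p, "gc_121pct", "etanercept", "biologic",
                      "gc_dose_increase")
  etn_backbone(p)
  fill(p, "oral_glucocorticoid", -100L, 90, 5, 180)  # 900 mg pre-index
  fill(p, "oral_glucocorticoid", 250L, 90, 1, 1081)  # 1081 mg > 120%

  p <- "F27"; episode(p, "gc_zero_mg_prevalent", "etanercept", "biologic", "")
  etn_backbone(p)
  fill(p, "oral_glucocorticoid", -100L, 0, 5, 0)     # degenerate: 0 mg
  fill(p, "oral_glucocorticoid", 150L, 10, 5, 10)    # 10 days, under the cap

  # --- DMARD-class episodes -------------------------------------------------
  p <- "F28"; episode(p, "hcq_dmard_clean", "hydroxychloroquine", "dmard", "")
  fill(p, "methotrexate", -240L, 30, 2.5, 120)       # anchor-drug history
  for (day in seq(0L, 330L, by = 30L)) fill(p, "hydroxychloroquine", day, 30, 200, 60)

  p <- "F29"; episode(p, "hcq_new_ssz", "hydroxychloroquine", "dmard",
                      "new_dmard_added")
  fill(p, "methotrexate", -240L, 30, 2.5, 120)
  for (day in seq(0L, 330L, by = 30L)) fill(p, "hydroxychloroquine", day, 30, 200, 60)
  for (day in c(120L, 150L)) fill(p, "sulfasalazine", day, 30, 500, 120)

  # --- overlapping reasons --------------------------------------------------
  p <- "F30"; episode(p, "multi_flag", "etanercept", "biologic",
                      paste("nonadherent_or_switch", "new_dmard_added",
                            "excess_joint_injections", sep = "|"))
  for (day in c(0L, 95L)) fill(p, "etanercept", day, 95, 50, 13)
  for (day in c(120L, 150L)) fill(p, "methotrexate", day, 30, 2.5, 120)
  inject(p, c(150L, 240L))

  # outcome DAS28 2.73 (low disease activity), baseline 6.05
  episodes <- do.call(rbind, eps)
  visits <- do.call(rbind, lapply(episodes$patient_id, function(pid) {
    data.frame(patient_id = pid, date = c(index, outcome),
               tjc28 = c(12, 1), sjc28 = c(10, 1), esr_mm_hr = c(30, 10),
               patient_global = c(60, 20), physician_global = c(55, 20))
  }))
  out <- list(
    fills = do.call(rbind, fills),
    infusions = do.call(rbind, infs),
    procedures = do.call(rbind, procs),
    visits = visits,
    episodes = episodes,
    expected = do.call(rbind, expd)
  )
  for (nm in names(out)) rownames(out[[nm]]) <- NULL
  class(out) <- "ra_cohort"
  out
}
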