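# Drug vocabularies. Biologics are the injected/infused targeted agents;
# the nonbiologic DMARDs are the four conventional oral agents tracked by the
# new-DMARD rule. `other_oral` covers any oral fill used only for the
# active-user eligibility check.

#' Drug name vocabularies
#'
#' Character vectors naming the drug classes the algorithm knows about.
#' `ra_biologics()` are the five biologic agents eligible as index drugs;
#' `ra_dmards()` are the four nonbiologic DMARDs covered by the new-DMARD
#' rule; `ra_infused()` are the biologics administered by infusion (events in
#' the infusion stream rather than pharmacy fills); `ra_drugs()` is the full
#' pharmacy-fill vocabulary.
#'
#' @return A character vector of lower-case drug names.
#' @export
ra_biologics <- function() {
  c("abatacept", "adalimumab", "etanercept", "infliximab", "rituximab")
}

#' @rdname ra_biologics
#' @export
ra_dmards <- function() {
  c("methotrexate", "sulfasalazine", "leflunomide", "hydroxychloroquine")
}

#' @rdname ra_biologics
#' @export
ra_infused <- function() {
  c("infliximab", "abatacept", "rituximab")
}

#' @rdname ra_biologics
#' @export
ra_drugs <- function() {
  c(ra_biologics(), ra_dmards(), "oral_glucocorticoid", "other_oral")
}

# Reason flags an episode can accumulate; effective == no flags.
ra_flags <- function() {
  c("nonadherent_or_switch", "new_dmard_added", "biologic_dose_escalation",
    "excess_joint_injections", "gc_initiation", "gc_dose_increase",
    "biologic_switch_or_add")
}

#' Algorithm configuration with rule-set defaults
#'
#' All window constants and thresholds of the effectiveness rule set live in
#' one list so any sensitivity analysis is a one-argument change. Day-count
#' windows use fixed day equivalents (6 months = 183 days, 3 months = 90
#' days, 1 month = 31 days); only the outcome-visit window is specified in
#' calendar months.
#'
#' @param ... Named overrides of any default listed below.
#'
#' @return A list of class `ra_config`:
#' \describe{
#'   \item{lookback_days}{New-user washout: no use of the index drug in the
#'     prior 183 days.}
#'   \item{active_user_window_days}{`c(365, 183)`: at least one oral fill of
#'     any drug between 12 and 6 months before the index date.}
#'   \item{baseline_window_days}{Baseline registry visit within +/-31 days of
#'     the index date (nearest wins).}
#'   \item{outcome_window_months}{`c(10, 14)`: outcome visit at 12 +/- 2
#'     calendar months after the index date (nearest to 12 months wins).}
#'   \item{mpr_threshold}{High adherence means medication possession ratio
#'     >= 0.80.}
#'   \item{mpr_truncate}{If `TRUE`, days supplied are truncated at the window
#'     end before summing (alternate MPR convention); default `FALSE`.}
#'   \item{injection_offset_days}{Glucocorticoid injections are counted from
#'     index + 90 days through the outcome date.}
#'   \item{max_injection_days}{More than this many unique injection days is a
#'     failure (default 1).}
#'   \item{gc_naive_max_days}{Glucocorticoid-naive patients fail on more than
#'     30 days of oral glucocorticoid supply in the counting window.}
#'   \item{gc_ratio}{Prevalent glucocorticoid users fail when the cumulative
#'     prednisone-equivalent dose in the 6 months before the outcome visit
#'     exceeds 120% of the 6 months before the index date (strictly > 1.2).}
#'   \item{infusion_ratio}{Infliximab infusion count must stay within 120% of
#'     the loading + every-8-weeks schedule expectation.}
#'   \item{dose_roundup_mg}{Infliximab first/last doses are rounded up to the
#'     nearest 100 mg; a difference >= 100 mg is an escalation.}
#'   \item{abatacept_dose_diff_mg}{Abatacept last - first dose >= 100 mg is an
#'     escalation.}
#'   \item{etanercept_weekly_max_mg, adalimumab_weekly_max_mg}{Mean weekly
#'     dose ceilings (75 and 30 mg) over any `dose_window_days` sliding
#'     window; these operationalise "50 mg twice weekly" and "40 mg once
#'     weekly" from dispensed strength x quantity / days supply.}
#'   \item{dose_window_days}{Sliding-window length for the weekly-dose
#'     escalation check (60 days).}
#'   \item{lda_das28}{DAS28 low-disease-activity cut, <= 3.2.}
#'   \item{das28_improvement}{Meaningful DAS28 improvement, strictly > 1.2.}
#'   \item{lda_cdai}{CDAI low-disease-activity cut, strictly < 11.}
#'   \item{keep_episode}{Which episode the one-per-patient restriction keeps
#'     (`"earliest"`; ties broken by drug name).}
#' }
#' @examples
#' cfg <- ra_config(mpr_threshold = 0.9)
#' cfg$mpr_threshold
#' @export
ra_config <- function(...) {
  cfg <- list(
    lookback_days = 183L,
    active_user_window_days = c(365L, 183L),
    baseline_window_days = 31L,
    outcome_window_months = c(10L, 14L),
    mpr_threshold = 0.80,
    mpr_truncate = FALSE,
    injection_offset_days = 90L,
    max_injection_days = 1L,
    gc_naive_max_days = 30,
    gc_ratio = 1.2,
    infusion_ratio = 1.2,
    dose_roundup_mg = 100,
    abatacept_dose_diff_mg = 100,
    etanercept_weekly_max_mg = 75,
    adalimumab_weekly_max_mg = 30,
    dose_window_days = 60L,
    lda_das28 = 3.2,
    das28_improvement = 1.2,
    lda_cdai = 11,
    keep_episode = "earliest"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$mpr_threshold > 0, cfg$gc_ratio > 0, cfg$infusion_ratio > 0,
            cfg$lookback_days > 0,
            cfg$outcome_window_months[1] < cfg$outcome_window_months[2])
  structure(cfg, class = "ra_config")
}

# Add whole calendar months to a Date, clamping to the last day of the target
# month (so Jan 31 + 1 month = Feb 28/29, not Mar 2/3).
add_months <- function(date, n) {
  lt <- as.POSIXlt(date)
  day <- lt$mday
  lt$mday <- 1L
  lt$mon <- lt$mon + n
  first <- as.Date(lt)
  nxt <- as.POSIXlt(first)
  nxt$mon <- nxt$mon + 1L
  last_day <- as.integer(format(as.Date(nxt) - 1L, "%d"))
  first + pmin(day, last_day) - 1L
}

# round-half-up to match conventional clinical-journal presentation
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
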