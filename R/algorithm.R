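# The claims-based effectiveness rule set. An episode is classified
# effective only when every condition holds; each violated condition is
# recorded as a reason flag (flags are not mutually exclusive).

#' Individual rule checks
#'
#' Each `check_*()` function evaluates one prohibition for a single episode
#' and returns `TRUE` when the rule is violated (the reason flag fires).
#' They are exported for auditing single components; [classify_episodes()]
#' runs them all.
#'
#' * `check_biologic_switch_or_add()`: a biologic other than the index drug
#'   is newly initiated (6-month washout rule) between the index date
#'   (exclusive) and the outcome date (inclusive).
#' * `check_new_dmard()`: a nonbiologic DMARD (methotrexate, sulfasalazine,
#'   leflunomide, hydroxychloroquine) with no fill in the 6 months up to and
#'   including the index date is filled after the index date.
#' * `check_dose_escalation()`: etanercept mean weekly dose above 75 mg or
#'   adalimumab above 30 mg over any 60-day sliding window (operationalising
#'   the prohibited 50 mg twice-weekly / 40 mg weekly regimens from dispensed
#'   strength x quantity / days supply); infliximab ending dose at least
#'   100 mg above the starting dose after rounding each up to the nearest
#'   100 mg, or more infusions than 120% of the loading + every-8-weeks
#'   schedule expectation; abatacept ending minus starting dose >= 100 mg;
#'   rituximab is never flagged.
#' * `check_injections()`: glucocorticoid injections on more than one unique
#'   calendar day between index + 90 days and the outcome date, inclusive.
#' * `check_oral_glucocorticoid()`: for glucocorticoid-naive patients (no
#'   oral glucocorticoid fill in the 6 months before the index date), more
#'   than 30 days of oral glucocorticoid supply between index + 90 days and
#'   the outcome date (`"gc_initiation"`); for prevalent users, a cumulative
#'   prednisone-equivalent dose in the 6 months before the outcome visit
#'   exceeding 120% of the 6 months before the index date
#'   (`"gc_dose_increase"`). A prevalent user with zero recorded milligrams
#'   is treated as naive (degenerate denominator). Returns a character flag
#'   or `character(0)`.
#'
#' @param episode One episode row.
#' @param fills,infusions,procedures Claim streams (rows for other patients
#'   are ignored).
#' @param config An [ra_config()] list.
#' @return Logical flag (or for the glucocorticoid check, a character flag
#'   name or `character(0)`).
#' @name rule_checks
NULL

#' @rdname rule_checks
#' @export
check_biologic_switch_or_add <- function(episode, fills, infusions,
                                         config = ra_config()) {
  pf <- fills[fills$patient_id == episode$patient_id, , drop = FALSE]
  pi <- infusions[infusions$patient_id == episode$patient_id, , drop = FALSE]
  for (b in setdiff(ra_biologics(), episode$index_drug)) {
    inits <- find_initiations(pf, pi, b, config$lookback_days)
    if (any(inits$index_date > episode$index_date &
              inits$index_date <= episode$outcome_date)) {
      return(TRUE)
    }
  }
  FALSE
}

#' @rdname rule_checks
#' @export
check_new_dmard <- function(episode, fills, config = ra_config()) {
  idx <- episode$index_date
  out <- episode$outcome_date
  pf <- fills[fills$patient_id == episode$patient_id, , drop = FALSE]
  for (d in ra_dmards()) {
    dd <- pf$fill_date[pf$drug == d]
    if (!length(dd)) next
    already <- any(dd >= idx - config$lookback_days & dd <= idx)
    started <- any(dd > idx & dd <= out)
    if (!already && started) return(TRUE)
  }
  FALSE
}

# daily prednisone-free dose profile of one drug over (index, outcome],
# spreading each fill's strength*quantity evenly over its days of supply
daily_dose_profile <- function(fills, index_date, outcome_date) {
  len <- as.numeric(outcome_date - index_date)
  dose <- numeric(len)  # dose[t] = dose on day index_date + t
  for (k in seq_len(nrow(fills))) {
    s <- fills$days_supply[k]
    if (is.na(s) || s <= 0) next
    per_day <- fills$strength_mg[k] * fills$quantity[k] / s
    start_t <- as.numeric(fills$fill_date[k] - index_date)
    days <- seq(start_t, start_t + s - 1)
    days <- days[days >= 1 & days <= len]
    if (length(days)) dose[days] <- dose[days] + per_day
  }
  dose
}

# max mean weekly dose over sliding windows of `window` days
max_weekly_dose <- function(dose, window) {
  n <- length(dose)
  if (!n) return(0)
  w <- min(window, n)
  cs <- cumsum(c(0, dose))
  sums <- cs[(w + 1):(n + 1)] - cs[1:(n + 1 - w)]
  7 * max(sums) / w
}

#' @rdname rule_checks
#' @export
check_dose_escalation <- function(episode, fills, infusions,
                                  config = ra_config()) {
  drug <- episode$index_drug
  if (!drug %in% ra_biologics()) {
    stop("dose-escalation rule applies to biologics only, got: ", drug)
  }
  if (drug == "rituximab") return(FALSE)
  idx <- episode$index_date
  out <- episode$outcome_date
  if (drug %in% c("etanercept", "adalimumab")) {
    pf <- fills[fills$patient_id == episode$patient_id & fills$drug == drug, ,
                drop = FALSE]
    if (!nrow(pf)) return(FALSE)
    prof <- daily_dose_profile(pf, idx, out)
    lim <- if (drug == "etanercept") config$etanercept_weekly_max_mg else
      config$adalimumab_weekly_max_mg
    return(max_weekly_dose(prof, config$dose_window_days) > lim)
  }
  pin <- infusions[infusions$patient_id == episode$patient_id &
                     infusions$drug == drug &
                     infusions$date >= idx & infusions$date <= out, ,
                   drop = FALSE]
  if (!nrow(pin)) return(FALSE)
  pin <- pin[order(pin$date), , drop = FALSE]
  first <- pin$dose_mg[1]
  last <- pin$dose_mg[nrow(pin)]
  if (drug == "infliximab") {
    r <- config$dose_roundup_mg
    dose_up <- ceiling(last / r) * r - ceiling(first / r) * r >= r
    expn <- expected_infusion_count("infliximab", idx, out, "escalation")
    too_many <- nrow(pin) > config$infusion_ratio * expn
    return(dose_up || too_many)
  }
  # abatacept: raw dose difference, no rounding
  last - first >= config$abatacept_dose_diff_mg
}

#' @rdname rule_checks
#' @export
check_injections <- function(episode, procedures, config = ra_config()) {
  lo <- episode$index_date + config$injection_offset_days
  pp <- procedures[procedures$patient_id == episode$patient_id &
                     procedures$kind == "glucocorticoid_injection" &
                     procedures$date >= lo &
                     procedures$date <= episode$outcome_date, , drop = FALSE]
  length(unique(pp$date)) > config$max_injection_days
}

#' @rdname rule_checks
#' @export
check_oral_glucocorticoid <- function(episode, fills, config = ra_config()) {
  idx <- episode$index_date
  out <- episode$outcome_date
  gc <- fills[fills$patient_id == episode$patient_id &
                fills$drug == "oral_glucocorticoid", , drop = FALSE]
  pre <- gc[gc$fill_date >= idx - config$lookback_days & gc$fill_date < idx, ,
            drop = FALSE]
  pre_mg <- sum(pre$strength_mg * pre$quantity)
  if (!nrow(pre) || pre_mg == 0) {
    # glucocorticoid-naive: cap total days of supply after month 3
    win <- gc[gc$fill_date >= idx + config$injection_offset_days &
                gc$fill_date <= out, , drop = FALSE]
    if (sum(win$days_supply) > config$gc_naive_max_days) {
      return("gc_initiation")
    }
    return(character(0))
  }
  # prevalent user: cumulative-dose comparison over the two 6-month windows
  pre_cmp <- gc[gc$fill_date >= idx - config$lookback_days &
                  gc$fill_date <= idx, , drop = FALSE]
  post <- gc[gc$fill_date >= out - config$lookback_days & gc$fill_date <= out, ,
             drop = FALSE]
  if (sum(post$strength_mg * post$quantity) >
        config$gc_ratio * sum(pre_cmp$strength_mg * pre_cmp$quantity)) {
    return("gc_dose_increase")
  }
  character(0)
}

#' Classify treatment episodes with the claims-based effectiveness algorithm
#'
#' Runs the adherence requirement and every prohibition of the rule set on
#' each episode. An episode is effective if and only if no reason flag
#' fires; all violated flags are recorded, so the per-flag tallies mirror
#' overlapping failure reasons.
#'
#' @param episodes Episode frame from [find_biologic_episodes()],
#'   [find_dmard_episodes()], or [read_stream()].
#' @param fills,infusions,procedures Claim streams covering the episodes'
#'   patients.
#' @param config An [ra_config()] list.
#' @return A data.frame of class `ra_results`: the episode key columns, one
#'   logical column per reason flag, `effective`, a `|`-joined `flags`
#'   string, and the adherence detail (`mpr`, `expected_infusions`,
#'   `observed_infusions`).
#' @export
classify_episodes <- function(episodes, fills, infusions = NULL,
                              procedures = NULL, config = ra_config()) {
  empty_fills <- data.frame(patient_id = character(), drug = character(),
                            fill_date = as.Date(character()),
                            days_supply = numeric(), strength_mg = numeric(),
                            quantity = numeric(), route = character())
  if (is.null(infusions)) {
    infusions <- data.frame(patient_id = character(), drug = character(),
                            date = as.Date(character()), dose_mg = numeric())
  }
  if (is.null(procedures)) {
    procedures <- data.frame(patient_id = character(),
                             date = as.Date(character()), kind = character())
  }
  if (is.null(fills)) fills <- empty_fills

  # pre-split by patient so per-episode work stays proportional to one
  # patient's records
  split_by <- function(df) split(df, df$patient_id)
  fset <- split_by(fills)
  iset <- split_by(infusions)
  pset <- split_by(procedures)
  grab <- function(set, pid, empty) {
    x <- set[[pid]]
    if (is.null(x)) empty else x
  }
  empty_inf <- infusions[0, , drop = FALSE]
  empty_proc <- procedures[0, , drop = FALSE]
  empty_fill <- fills[0, , drop = FALSE]

  n <- nrow(episodes)
  flag_names <- ra_flags()
  flag_mat <- matrix(FALSE, n, length(flag_names),
                     dimnames = list(NULL, flag_names))
  mpr <- expn <- obs <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    ep <- episodes[k, , drop = FALSE]
    pid <- ep$patient_id
    pf <- grab(fset, pid, empty_fill)
    pinf <- grab(iset, pid, empty_inf)
    pproc <- grab(pset, pid, empty_proc)

    adh <- assess_adherence(ep, pf, pinf, config)
    mpr[k] <- adh$mpr
    expn[k] <- adh$expected_infusions
    obs[k] <- adh$observed_infusions
    flag_mat[k, "nonadherent_or_switch"] <- !adh$adherent
    flag_mat[k, "biologic_switch_or_add"] <-
      check_biologic_switch_or_add(ep, pf, pinf, config)
    flag_mat[k, "new_dmard_added"] <- check_new_dmard(ep, pf, config)
    if (ep$episode_class == "biologic") {
      flag_mat[k, "biologic_dose_escalation"] <-
        check_dose_escalation(ep, pf, pinf, config)
    }
    flag_mat[k, "excess_joint_injections"] <-
      check_injections(ep, pproc, config)
    gc_flag <- check_oral_glucocorticoid(ep, pf, config)
    if (length(gc_flag)) flag_mat[k, gc_flag] <- TRUE
  }
  effective <- rowSums(flag_mat) == 0
  flags <- apply(flag_mat, 1, function(r) {
    paste(flag_names[r], collapse = "|")
  })
  out <- cbind(
    episodes[c("patient_id", "index_drug", "index_date", "episode_class",
               "outcome_date")],
    as.data.frame(flag_mat),
    data.frame(effective = effective, flags = flags, mpr = mpr,
               expected_infusions = expn, observed_infusions = obs)
  )
  rownames(out) <- NULL
  class(out) <- c("ra_results", "data.frame")
  out
}

#' @export
print.ra_results <- function(x, ...) {
  cat("Claims-based effectiveness classification:", nrow(x), "episodes\n")
  cat(sprintf("  effective: %d (%s%%)\n", sum(x$effective),
              format(round_half_up(100 * mean(x$effective)))))
  tallies <- colSums(as.data.frame(x)[ra_flags()])
  tallies <- tallies[tallies > 0]
  if (length(tallies)) {
    cat("  reason flags (not mutually exclusive):\n")
    for (nm in names(sort(tallies, decreasing = TRUE))) {
      cat(sprintf("    %-25s %d\n", nm, tallies[[nm]]))
    }
  }
  invisible(x)
}
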