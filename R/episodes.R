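# New-user treatment-episode construction. An episode is an index drug plus
# index date, anchored by an outcome registry visit at 12 +/- 2 calendar
# months (and usually a baseline visit within a month of the index date).

#' Find new-user initiations of a drug
#'
#' An initiation is a fill or infusion of `drug` with no same-drug event in
#' the preceding `lookback_days` (exclusive window `(date - lookback, date)`).
#' A patient can contribute several initiations of the same drug when use
#' gaps exceed the lookback.
#'
#' @param fills Pharmacy-fill frame (see [read_stream()] schema `"fills"`).
#' @param infusions Infusion frame, or `NULL` if the drug is never infused.
#' @param drug A single drug name from [ra_drugs()].
#' @param lookback_days Washout length in days; default 183 (6 months).
#' @return A data.frame with columns `patient_id`, `index_drug`, `index_date`,
#'   one row per initiation, sorted by patient then date.
#' @export
find_initiations <- function(fills, infusions = NULL, drug,
                             lookback_days = 183L) {
  if (!drug %in% ra_drugs()) stop("unknown drug: ", drug)
  dates <- data.frame(patient_id = character(), date = as.Date(character()))
  if (!is.null(fills) && nrow(fills)) {
    f <- fills[fills$drug == drug, , drop = FALSE]
    if (nrow(f)) {
      dates <- rbind(dates, data.frame(patient_id = f$patient_id,
                                       date = f$fill_date))
    }
  }
  if (!is.null(infusions) && nrow(infusions)) {
    i <- infusions[infusions$drug == drug, , drop = FALSE]
    if (nrow(i)) {
      dates <- rbind(dates, data.frame(patient_id = i$patient_id,
                                       date = i$date))
    }
  }
  if (!nrow(dates)) {
    return(data.frame(patient_id = character(), index_drug = character(),
                      index_date = as.Date(character())))
  }
  dates <- unique(dates)
  dates <- dates[order(dates$patient_id, dates$date), , drop = FALSE]
  keep <- unlist(lapply(split(dates$date, dates$patient_id), function(d) {
    d <- sort(d)
    gap <- c(Inf, as.numeric(diff(d)))
    gap >= lookback_days
  }), use.names = FALSE)
  out <- dates[order(dates$patient_id, dates$date), , drop = FALSE][keep, ,
                                                                    drop = FALSE]
  data.frame(patient_id = out$patient_id, index_drug = drug,
             index_date = out$date, row.names = NULL)
}

# nearest date to `target` among `cands`; ties -> earliest
nearest_date <- function(cands, target) {
  d <- abs(as.numeric(cands - target))
  cands[order(d, cands)][1]
}

#' Build eligible treatment episodes from initiations
#'
#' Applies the three eligibility predicates to each candidate initiation:
#' (a) optionally, a baseline registry visit within +/-31 days of the index
#' date (nearest wins); (b) at least one oral-medication fill of any duration
#' 6 to 12 months before the index date (confirms the patient fills through
#' the observed pharmacy); (c) an outcome registry visit 10 to 14 calendar
#' months after the index date (nearest to 12 months wins). Initiations with
#' no outcome visit are dropped -- without it there is no clinical outcome to
#' classify against.
#'
#' @param initiations Frame from [find_initiations()] (or rows with
#'   `patient_id`, `index_drug`, `index_date`).
#' @param fills Pharmacy-fill frame.
#' @param visits Registry-visit frame.
#' @param episode_class `"biologic"` or `"dmard"`.
#' @param require_baseline Require the baseline visit (drop it for
#'   sensitivity analyses with LDA-only gold standards).
#' @param config An [ra_config()] list.
#' @return A data.frame of episodes (`patient_id`, `index_drug`,
#'   `index_date`, `episode_class`, `baseline_date`, `outcome_date`) with an
#'   `"exclusions"` attribute tallying why candidates were dropped.
#' @export
build_episodes <- function(initiations, fills, visits,
                           episode_class = "biologic",
                           require_baseline = TRUE, config = ra_config()) {
  excl <- c(no_baseline_visit = 0L, no_prior_oral_fill = 0L,
            no_outcome_visit = 0L)
  rows <- vector("list", nrow(initiations))
  oral <- fills[fills$route == "oral" | fills$drug %in%
                  c(ra_dmards(), "oral_glucocorticoid", "other_oral"), ,
                drop = FALSE]
  for (k in seq_len(nrow(initiations))) {
    pid <- initiations$patient_id[k]
    idx <- initiations$index_date[k]
    pv <- visits[visits$patient_id == pid, , drop = FALSE]

    baseline <- as.Date(NA)
    bl_ok <- !require_baseline
    cand <- pv$date[abs(as.numeric(pv$date - idx)) <= config$baseline_window_days]
    if (length(cand)) baseline <- nearest_date(cand, idx)
    if (require_baseline && !is.na(baseline)) bl_ok <- TRUE
    if (!bl_ok) {
      excl["no_baseline_visit"] <- excl["no_baseline_visit"] + 1L
      next
    }

    po <- oral[oral$patient_id == pid, , drop = FALSE]
    w <- config$active_user_window_days
    active <- any(po$fill_date >= idx - w[1] & po$fill_date <= idx - w[2])
    if (!active) {
      excl["no_prior_oral_fill"] <- excl["no_prior_oral_fill"] + 1L
      next
    }

    lo <- add_months(idx, config$outcome_window_months[1])
    hi <- add_months(idx, config$outcome_window_months[2])
    cand <- pv$date[pv$date >= lo & pv$date <= hi]
    if (!length(cand)) {
      excl["no_outcome_visit"] <- excl["no_outcome_visit"] + 1L
      next
    }
    outcome <- nearest_date(cand, add_months(idx, 12L))

    rows[[k]] <- data.frame(patient_id = pid,
                            index_drug = initiations$index_drug[k],
                            index_date = idx, episode_class = episode_class,
                            baseline_date = baseline, outcome_date = outcome)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), index_drug = character(),
                      index_date = as.Date(character()),
                      episode_class = character(),
                      baseline_date = as.Date(character()),
                      outcome_date = as.Date(character()))
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Build biologic new-user episodes
#'
#' Convenience wrapper: finds initiations of each of the five biologics and
#' applies [build_episodes()].
#'
#' @inheritParams build_episodes
#' @param infusions Infusion frame.
#' @return Episode frame as from [build_episodes()].
#' @export
find_biologic_episodes <- function(fills, infusions, visits,
                                   require_baseline = TRUE,
                                   config = ra_config()) {
  inits <- do.call(rbind, lapply(ra_biologics(), function(d) {
    find_initiations(fills, infusions, d, config$lookback_days)
  }))
  out <- build_episodes(inits, fills, visits, "biologic", require_baseline,
                        config)
  out[order(out$patient_id, out$index_date, out$index_drug), , drop = FALSE]
}

#' Build nonbiologic DMARD new-user episodes
#'
#' Episodes are initiations of leflunomide, sulfasalazine, or
#' hydroxychloroquine in patients with any methotrexate fill on or before
#' the index date. Methotrexate initiations themselves never form episodes:
#' it is the anchor drug and is typically continued even when the response is
#' suboptimal.
#'
#' @inheritParams build_episodes
#' @return Episode frame with `episode_class == "dmard"`.
#' @export
find_dmard_episodes <- function(fills, visits, require_baseline = TRUE,
                                config = ra_config()) {
  drugs <- c("leflunomide", "sulfasalazine", "hydroxychloroquine")
  inits <- do.call(rbind, lapply(drugs, function(d) {
    find_initiations(fills, NULL, d, config$lookback_days)
  }))
  if (nrow(inits)) {
    mtx <- fills[fills$drug == "methotrexate", , drop = FALSE]
    ok <- vapply(seq_len(nrow(inits)), function(k) {
      any(mtx$patient_id == inits$patient_id[k] &
            mtx$fill_date <= inits$index_date[k])
    }, logical(1))
    inits <- inits[ok, , drop = FALSE]
  }
  out <- build_episodes(inits, fills, visits, "dmard", require_baseline,
                        config)
  out[order(out$patient_id, out$index_date, out$index_drug), , drop = FALSE]
}

#' Restrict to one treatment episode per patient
#'
#' For the conservative analysis where each patient contributes a single
#' episode, keeps the earliest episode by index date (ties broken by drug
#' name, alphabetically).
#'
#' @param episodes Episode frame.
#' @param keep `"earliest"` (default) or `"latest"`.
#' @return Episode frame with unique `patient_id`s.
#' @export
one_episode_per_patient <- function(episodes, keep = c("earliest", "latest")) {
  keep <- match.arg(keep)
  if (!nrow(episodes)) return(episodes)
  ord <- order(episodes$patient_id, episodes$index_date, episodes$index_drug)
  if (keep == "latest") {
    ord <- order(episodes$patient_id, -as.numeric(episodes$index_date),
                 episodes$index_drug)
  }
  ep <- episodes[ord, , drop = FALSE]
  out <- ep[!duplicated(ep$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
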