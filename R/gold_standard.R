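# Clinical gold standard: disease-activity indices computed from registry
# visits, combined with the adherence requirement.

#' Disease Activity Score over 28 joints (4-variable, ESR)
#'
#' `0.56 * sqrt(TJC28) + 0.28 * sqrt(SJC28) + 0.70 * ln(ESR) + 0.014 * GH`,
#' where GH is the patient global health assessment on a 0-100 scale. ESR is
#' floored at 1 mm/h so the logarithm stays defined (affects only the
#' degenerate zero-ESR input).
#'
#' @param tjc28,sjc28 Tender / swollen joint counts in `[0, 28]`.
#' @param esr_mm_hr Erythrocyte sedimentation rate, mm/h, >= 0.
#' @param patient_global Patient global assessment, 0-100.
#' @return DAS28-ESR value (vectorised). Low disease activity is <= 3.2.
#' @examples
#' das28_esr(4, 2, 20, 50)  # 4.313
#' @export
das28_esr <- function(tjc28, sjc28, esr_mm_hr, patient_global) {
  if (any(tjc28 < 0 | tjc28 > 28 | sjc28 < 0 | sjc28 > 28)) {
    stop("joint counts must be in [0, 28]")
  }
  if (any(esr_mm_hr < 0)) stop("esr_mm_hr must be >= 0")
  if (any(patient_global < 0 | patient_global > 100)) {
    stop("patient_global must be in [0, 100]")
  }
  0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28) +
    0.70 * log(pmax(esr_mm_hr, 1)) + 0.014 * patient_global
}

#' Clinical Disease Activity Index
#'
#' Sum of the 28-joint tender and swollen counts and the patient and
#' physician global assessments on 0-10 scales. The registry records globals
#' on 0-100 visual-analogue scales, so they are divided by 10. Range 0-76;
#' low disease activity is strictly below 11.
#'
#' @param tjc28,sjc28 Joint counts in `[0, 28]`.
#' @param patient_global,physician_global Globals on the recorded 0-100
#'   scale.
#' @return CDAI value in `[0, 76]` (vectorised).
#' @examples
#' cdai(10, 8, 60, 50)  # 29
#' @export
cdai <- function(tjc28, sjc28, patient_global, physician_global) {
  if (any(tjc28 < 0 | tjc28 > 28 | sjc28 < 0 | sjc28 > 28)) {
    stop("joint counts must be in [0, 28]")
  }
  if (any(patient_global < 0 | patient_global > 100 |
            physician_global < 0 | physician_global > 100)) {
    stop("globals must be in [0, 100]")
  }
  tjc28 + sjc28 + patient_global / 10 + physician_global / 10
}

#' Evaluate the clinical effectiveness gold standard
#'
#' Primary definition: effective when the outcome-visit DAS28 is at or below
#' the low-disease-activity cut (3.2) *or* the DAS28 improved by strictly
#' more than 1.2 units from baseline, *and* the patient was highly adherent
#' to the index drug. Two sensitivity variants drop the improvement
#' criterion: `"lda_only_das28"` (DAS28 <= 3.2 with adherence; no baseline
#' visit needed) and `"lda_only_cdai"` (CDAI < 11 with adherence).
#'
#' @param episodes Episode frame; `baseline_date` must be present for the
#'   primary mode.
#' @param visits Registry-visit frame.
#' @param adherence Result frame with one row per episode and a logical
#'   `adherent` column (e.g. the output of [classify_episodes()], whose
#'   `nonadherent_or_switch` column is inverted, or a frame built from
#'   [assess_adherence()]).
#' @param mode Gold-standard definition.
#' @param config An [ra_config()] list.
#' @return A data.frame of class `ra_gold`: episode keys, `das28_baseline`,
#'   `das28_outcome`, `cdai_outcome`, `reached_lda`, `improved_gt_1_2`,
#'   `adherent`, `effective`.
#' @export
evaluate_gold_standard <- function(episodes, visits, adherence,
                                   mode = c("primary_das28",
                                            "lda_only_das28",
                                            "lda_only_cdai"),
                                   config = ra_config()) {
  mode <- match.arg(mode)
  stopifnot(nrow(adherence) == nrow(episodes))
  adherent <- if (!is.null(adherence$adherent)) {
    adherence$adherent
  } else {
    !adherence$nonadherent_or_switch
  }
  visit_at <- function(pid, date) {
    v <- visits[visits$patient_id == pid & visits$date == date, , drop = FALSE]
    if (!nrow(v)) stop("no registry visit for patient ", pid, " on ", date)
    v[1, , drop = FALSE]
  }
  n <- nrow(episodes)
  das_b <- das_o <- cdai_o <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    ov <- visit_at(episodes$patient_id[k], episodes$outcome_date[k])
    das_o[k] <- das28_esr(ov$tjc28, ov$sjc28, ov$esr_mm_hr, ov$patient_global)
    cdai_o[k] <- cdai(ov$tjc28, ov$sjc28, ov$patient_global,
                      ov$physician_global)
    if (mode == "primary_das28") {
      if (is.na(episodes$baseline_date[k])) {
        stop("primary gold standard needs a baseline visit (patient ",
             episodes$patient_id[k], ")")
      }
      bv <- visit_at(episodes$patient_id[k], episodes$baseline_date[k])
      das_b[k] <- das28_esr(bv$tjc28, bv$sjc28, bv$esr_mm_hr,
                            bv$patient_global)
    }
  }
  reached_lda <- das_o <= config$lda_das28
  improved <- !is.na(das_b) & (das_b - das_o > config$das28_improvement)
  effective <- switch(mode,
    primary_das28 = (reached_lda | improved) & adherent,
    lda_only_das28 = reached_lda & adherent,
    lda_only_cdai = (cdai_o < config$lda_cdai) & adherent
  )
  out <- cbind(
    episodes[c("patient_id", "index_drug", "index_date", "episode_class",
               "outcome_date")],
    data.frame(das28_baseline = das_b, das28_outcome = das_o,
               cdai_outcome = cdai_o, reached_lda = reached_lda,
               improved_gt_1_2 = improved, adherent = adherent,
               effective = effective)
  )
  rownames(out) <- NULL
  class(out) <- c("ra_gold", "data.frame")
  out
}

#' @export
print.ra_gold <- function(x, ...) {
  cat("Clinical gold standard:", nrow(x), "episodes\n")
  cat(sprintf("  effective: %d (%s%%)\n", sum(x$effective),
              format(round_half_up(100 * mean(x$effective)))))
  cat(sprintf("  reached LDA: %d; improved > 1.2: %d; adherent: %d\n",
              sum(x$reached_lda), sum(x$improved_gt_1_2), sum(x$adherent)))
  invisible(x)
}
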