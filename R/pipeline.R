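# End-to-end pipeline: read streams, build episodes, classify, evaluate the
# gold standard, validate, and write every artifact.

#' Run the full validation pipeline
#'
#' Chains episode construction, the claims-based classification, the
#' clinical gold standard, and the validation step, writing `episodes.csv`,
#' `algorithm_results.csv`, `gold_standard.csv`, `metrics.json`,
#' `discordance.csv`, and `bias.csv` to `out_dir`. Exclusion tallies and
#' per-flag counts are reported via `message()` (counts only, no
#' patient-level data). Re-running on identical inputs overwrites with
#' identical artifacts.
#'
#' @param fills,infusions,procedures,visits Input streams: data.frames or
#'   paths to CSV files in the [read_stream()] schemas.
#' @param comorbidities Optional comorbidity-flag frame or CSV path; when
#'   given, flagged patients' episodes are excluded before validation.
#' @param out_dir Output directory, created if needed.
#' @param episode_class `"biologic"`, `"dmard"`, or `"both"`.
#' @param mode Gold-standard definition (see [evaluate_gold_standard()]).
#' @param one_per_patient Restrict each patient to the earliest episode.
#' @param ci_method Confidence-interval method (see
#'   [performance_metrics()]).
#' @param bias_observed_rates Observed response rates for the bias table.
#' @param require_baseline Require a baseline visit (disable for the
#'   LDA-only sensitivity modes).
#' @param config An [ra_config()] list.
#' @return Invisibly, a list with `episodes`, `algorithm`, `gold`,
#'   `confusion`, `metrics`, `discordance`, and `bias`.
#' @export
run_pipeline <- function(fills, infusions = NULL, procedures = NULL, visits,
                         comorbidities = NULL, out_dir,
                         episode_class = c("both", "biologic", "dmard"),
                         mode = "primary_das28", one_per_patient = FALSE,
                         ci_method = "clopper_pearson",
                         bias_observed_rates = c(0.30, 0.40, 0.50, 0.60),
                         require_baseline = mode == "primary_das28",
                         config = ra_config()) {
  episode_class <- match.arg(episode_class)
  load <- function(x, schema) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) read_stream(x, schema) else x
  }
  fills <- load(fills, "fills")
  infusions <- load(infusions, "infusions")
  procedures <- load(procedures, "procedures")
  visits <- load(visits, "visits")
  comorbidities <- load(comorbidities, "comorbidities")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  episodes <- NULL
  if (episode_class %in% c("both", "biologic")) {
    episodes <- find_biologic_episodes(fills, infusions, visits,
                                       require_baseline, config)
    message("biologic episodes: ", nrow(episodes), " (excluded: ",
            paste(names(attr(episodes, "exclusions")),
                  attr(episodes, "exclusions"), sep = "=", collapse = ", "),
            ")")
  }
  if (episode_class %in% c("both", "dmard")) {
    dm <- find_dmard_episodes(fills, visits, require_baseline, config)
    message("dmard episodes: ", nrow(dm))
    episodes <- if (is.null(episodes)) dm else rbind(episodes, dm)
  }
  if (!is.null(comorbidities)) {
    before <- nrow(episodes)
    episodes <- comorbidity_exclusion(episodes, comorbidities)
    message("comorbidity exclusion removed ", before - nrow(episodes),
            " episodes")
  }
  if (one_per_patient) {
    episodes <- one_episode_per_patient(episodes, config$keep_episode)
  }
  if (!nrow(episodes)) stop("no eligible treatment episodes")
  write_stream(episodes, file.path(out_dir, "episodes.csv"))

  alg <- classify_episodes(episodes, fills, infusions, procedures, config)
  for (fl in ra_flags()) {
    n <- sum(alg[[fl]])
    if (n) message("flag ", fl, ": ", n)
  }
  write_results(alg, file.path(out_dir, "algorithm_results.csv"))

  gold <- evaluate_gold_standard(episodes, visits, alg, mode, config)
  write_results(gold, file.path(out_dir, "gold_standard.csv"))

  cm <- confusion_matrix(alg, gold)
  pm <- performance_metrics(cm, ci_method)
  disc <- discordance_report(alg, gold)
  bias <- bias_analysis(bias_observed_rates, pm$ppv$estimate,
                        pm$npv$estimate)

  metrics <- list(
    n_episodes = sum(cm),
    confusion = as.list(setNames(as.integer(cm), names(cm))),
    ci_method = ci_method
  )
  s <- summary(pm)
  metrics$metrics <- setNames(
    lapply(seq_len(nrow(s)), function(k) {
      list(estimate = s$estimate[k], lower = s$lower[k], upper = s$upper[k],
           numerator = s$x[k], denominator = s$n[k])
    }), s$metric)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  disc_df <- rbind(
    if (nrow(disc$false_positives)) {
      cbind(kind = "false_positive", as.data.frame(disc$false_positives))
    },
    if (nrow(disc$false_negatives)) {
      cbind(kind = "false_negative", as.data.frame(disc$false_negatives))
    })
  if (is.null(disc_df)) {
    disc_df <- data.frame(kind = character(), patient_id = character())
  }
  write_results(disc_df, file.path(out_dir, "discordance.csv"))
  write_stream(as.data.frame(bias), file.path(out_dir, "bias.csv"))

  invisible(list(episodes = episodes, algorithm = alg, gold = gold,
                 confusion = cm, metrics = pm, discordance = disc,
                 bias = bias))
}
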