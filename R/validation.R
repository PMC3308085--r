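# Validation of the claims algorithm against the clinical gold standard:
# confusion matrix, PPV/NPV/Se/Sp with binomial confidence intervals,
# misclassification-bias analysis, and the discordance report.

episode_key <- function(x) {
  paste(x$patient_id, format(x$index_date, "%Y-%m-%d"), x$index_drug,
        sep = "::")
}

#' Confusion matrix of algorithm vs gold standard
#'
#' Cross-tabulates the binary classifications for the same set of episodes.
#' "Positive" means classified effective. Both inputs must cover exactly the
#' same episodes (matched on patient, index date, and index drug).
#'
#' @param algorithm_results Frame from [classify_episodes()] (or any frame
#'   with the episode keys and a logical `effective`).
#' @param gold_results Frame from [evaluate_gold_standard()].
#' @return An object of class `ra_confusion`: named integer vector
#'   `c(tp, fp, fn, tn)`.
#' @export
confusion_matrix <- function(algorithm_results, gold_results) {
  ka <- episode_key(algorithm_results)
  kg <- episode_key(gold_results)
  if (length(ka) != length(kg) || !setequal(ka, kg) || anyDuplicated(ka)) {
    stop("algorithm and gold-standard results must cover the same episodes")
  }
  g <- gold_results$effective[match(ka, kg)]
  a <- algorithm_results$effective
  cm <- c(tp = sum(a & g), fp = sum(a & !g), fn = sum(!a & g),
          tn = sum(!a & !g))
  structure(as.integer(cm), names = names(cm), class = "ra_confusion")
}

#' Build a confusion matrix from the four cell counts
#'
#' @param tp,fp,fn,tn Non-negative cell counts (algorithm vs gold standard).
#' @return An `ra_confusion` object.
#' @examples
#' performance_metrics(as_confusion(60, 19, 23, 203))
#' @export
as_confusion <- function(tp, fp, fn, tn) {
  cm <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cm < 0) || any(cm != round(cm))) {
    stop("cell counts must be non-negative integers")
  }
  structure(as.integer(cm), names = names(cm), class = "ra_confusion")
}

#' @export
print.ra_confusion <- function(x, ...) {
  m <- matrix(c(x["tp"], x["fn"], x["fp"], x["tn"]), 2, 2,
              dimnames = list(algorithm = c("effective", "not effective"),
                              gold = c("effective", "not effective")))
  cat("Algorithm vs gold standard (n =", sum(x), ")\n")
  print(m)
  invisible(x)
}

binomial_ci <- function(x, n, method, conf_level = 0.95, pooled_n = NULL) {
  if (n == 0) return(c(NA_real_, NA_real_))
  p <- x / n
  if (method == "clopper_pearson") {
    ci <- binom.test(x, n, conf.level = conf_level)$conf.int
    return(as.numeric(ci))
  }
  nn <- if (method == "wald_pooled_n") pooled_n else n
  z <- qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(p * (1 - p) / nn)
  c(max(0, p - half), min(1, p + half))
}

#' Performance characteristics of the algorithm
#'
#' Positive predictive value, negative predictive value, sensitivity, and
#' specificity with 95% binomial confidence intervals. The default interval
#' is the exact Clopper-Pearson interval on each metric's own denominator;
#' `"wald"` gives the normal approximation, and `"wald_pooled_n"` a normal
#' approximation computed on the total episode count (reproducing reports
#' whose interval widths were based on the overall n).
#'
#' @param cm An `ra_confusion` object ([confusion_matrix()] or
#'   [as_confusion()]).
#' @param ci_method `"clopper_pearson"` (default), `"wald"`, or
#'   `"wald_pooled_n"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `ra_performance`: a list with elements `ppv`,
#'   `npv`, `se`, `sp` (each `list(estimate, lower, upper, x, n)`), the
#'   confusion matrix, and the CI method. A metric with a zero denominator
#'   is reported as `NA` with a warning.
#' @examples
#' performance_metrics(as_confusion(42, 14, 14, 127))
#' @export
performance_metrics <- function(cm,
                                ci_method = c("clopper_pearson", "wald",
                                              "wald_pooled_n"),
                                conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(cm, "ra_confusion"))
  total <- sum(cm)
  cells <- list(
    ppv = c(cm[["tp"]], cm[["tp"]] + cm[["fp"]]),
    npv = c(cm[["tn"]], cm[["tn"]] + cm[["fn"]]),
    se  = c(cm[["tp"]], cm[["tp"]] + cm[["fn"]]),
    sp  = c(cm[["tn"]], cm[["tn"]] + cm[["fp"]])
  )
  out <- lapply(names(cells), function(nm) {
    x <- cells[[nm]][1]
    n <- cells[[nm]][2]
    if (n == 0) {
      warning("denominator of ", nm, " is zero; metric undefined")
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  x = x, n = n))
    }
    ci <- binomial_ci(x, n, ci_method, conf_level, pooled_n = total)
    list(estimate = x / n, lower = ci[1], upper = ci[2], x = x, n = n)
  })
  names(out) <- names(cells)
  out$confusion <- cm
  out$ci_method <- ci_method
  out$conf_level <- conf_level
  class(out) <- "ra_performance"
  out
}

#' @export
print.ra_performance <- function(x, digits = 0, ...) {
  cat(sprintf("Performance of the effectiveness algorithm (n = %d, %s %d%% CI)\n",
              sum(x$confusion), x$ci_method, round(100 * x$conf_level)))
  lab <- c(ppv = "PPV", npv = "NPV", se = "Sensitivity", sp = "Specificity")
  for (nm in names(lab)) {
    m <- x[[nm]]
    if (is.na(m$estimate)) {
      cat(sprintf("  %-12s undefined (denominator 0)\n", lab[[nm]]))
    } else {
      cat(sprintf("  %-12s %3s%% (%s to %s)  [%d/%d]\n", lab[[nm]],
                  format(round_half_up(100 * m$estimate, digits)),
                  format(round_half_up(100 * m$lower, digits)),
                  format(round_half_up(100 * m$upper, digits)), m$x, m$n))
    }
  }
  invisible(x)
}

#' Summarise performance metrics as a data.frame
#'
#' @param object An `ra_performance` object.
#' @param ... Unused.
#' @return A data.frame with one row per metric (`metric`, `estimate`,
#'   `lower`, `upper`, `x`, `n`).
#' @export
summary.ra_performance <- function(object, ...) {
  do.call(rbind, lapply(c("ppv", "npv", "se", "sp"), function(nm) {
    m <- object[[nm]]
    data.frame(metric = nm, estimate = m$estimate, lower = m$lower,
               upper = m$upper, x = m$x, n = m$n)
  }))
}

#' Outcome-misclassification bias analysis
#'
#' Given an observed (algorithm-measured) response rate and the algorithm's
#' predictive values, recovers the implied true response rate
#' `true = obs * PPV + (1 - obs) * (1 - NPV)` and the relative bias
#' `(obs - true) / true`. Because the relation is linear in the observed
#' rate, the true rate runs from `1 - NPV` at `obs = 0` to `PPV` at
#' `obs = 1`.
#'
#' @param observed_rate Observed response rate(s) in `[0, 1]` (vectorised).
#' @param ppv,npv Positive and negative predictive values in `[0, 1]`.
#' @return A data.frame of class `ra_bias` with columns `observed_rate`,
#'   `true_rate`, `relative_bias` (as a proportion; multiply by 100 for
#'   percent).
#' @examples
#' bias_analysis(c(0.3, 0.4, 0.5, 0.6), ppv = 0.76, npv = 0.90)
#' @export
bias_analysis <- function(observed_rate, ppv, npv) {
  stopifnot(all(observed_rate >= 0 & observed_rate <= 1),
            ppv >= 0, ppv <= 1, npv >= 0, npv <= 1)
  true_rate <- observed_rate * ppv + (1 - observed_rate) * (1 - npv)
  if (any(true_rate == 0)) stop("true rate is zero; relative bias undefined")
  out <- data.frame(observed_rate = observed_rate, true_rate = true_rate,
                    relative_bias = (observed_rate - true_rate) / true_rate)
  class(out) <- c("ra_bias", "data.frame")
  out
}

#' @export
print.ra_bias <- function(x, ...) {
  cat("Misclassification bias (true = obs*PPV + (1-obs)*(1-NPV))\n")
  df <- data.frame(
    observed = sprintf("%s%%", format(round_half_up(100 * x$observed_rate))),
    true = sprintf("%s%%", format(round_half_up(100 * x$true_rate))),
    bias = sprintf("%s%%", format(round_half_up(100 * x$relative_bias))))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Discordance report between algorithm and gold standard
#'
#' Lists the false-positive episodes (algorithm effective, gold standard
#' not) and false-negative episodes (algorithm not effective, gold standard
#' effective), and tallies which algorithm reason flags fired among the
#' false negatives -- the machine-readable side of a discordance review.
#'
#' @inheritParams confusion_matrix
#' @return A list of class `ra_discordance`: `false_positives` and
#'   `false_negatives` (episode frames) and `fn_flag_tally` (named integer
#'   vector over the reason flags).
#' @export
discordance_report <- function(algorithm_results, gold_results) {
  ka <- episode_key(algorithm_results)
  kg <- episode_key(gold_results)
  g <- gold_results$effective[match(ka, kg)]
  a <- algorithm_results$effective
  fp <- algorithm_results[a & !g, , drop = FALSE]
  fn <- algorithm_results[!a & g, , drop = FALSE]
  tally <- if (nrow(fn)) {
    colSums(as.data.frame(fn)[ra_flags()])
  } else {
    setNames(integer(length(ra_flags())), ra_flags())
  }
  structure(list(false_positives = fp, false_negatives = fn,
                 fn_flag_tally = tally),
            class = "ra_discordance")
}

#' @export
print.ra_discordance <- function(x, ...) {
  cat("Discordant episodes: ", nrow(x$false_positives), " false-positive, ",
      nrow(x$false_negatives), " false-negative\n", sep = "")
  t <- x$fn_flag_tally[x$fn_flag_tally > 0]
  if (length(t)) {
    cat("Algorithm components not met among false negatives:\n")
    for (nm in names(sort(t, decreasing = TRUE))) {
      cat(sprintf("  %-25s %d\n", nm, t[[nm]]))
    }
  }
  invisible(x)
}

#' Exclude episodes of patients with confounding comorbidities
#'
#' Drops all episodes of patients flagged for any comorbidity expected to
#' inflate patient global scores independently of joint disease (e.g.
#' post-traumatic stress disorder, low-back pain, fibromyalgia, hepatitis C,
#' depression). Flags arrive pre-computed as booleans keyed by patient.
#'
#' @param episodes Episode frame.
#' @param comorbidities Frame with `patient_id`, `condition`, logical `flag`.
#' @return The episode frame restricted to unflagged patients.
#' @export
comorbidity_exclusion <- function(episodes, comorbidities) {
  if (is.null(comorbidities) || !nrow(comorbidities)) return(episodes)
  flagged <- unique(comorbidities$patient_id[comorbidities$flag])
  out <- episodes[!(episodes$patient_id %in% flagged), , drop = FALSE]
  rownames(out) <- NULL
  out
}
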