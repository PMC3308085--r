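# Calibrate the generator's component-failure probabilities so the
# simulated algorithm attains target sensitivity and specificity.

# Se depends only on the responders' non-adherence-independent components;
# Sp only on the non-responders' probabilities. Each is monotone in a single
# multiplier, so two bisections against the closed-form implied performance
# suffice; a seeded simulation then verifies the tolerance empirically.

scale_probs <- function(p, comps, mult, cap = 0.99) {
  p[comps] <- pmin(cap, p[comps] * mult)
  p
}

bisect_mult <- function(f, target, lo = 0, hi = 64, tol = 1e-6) {
  # f monotone (either direction) in the multiplier
  flo <- f(lo)
  fhi <- f(hi)
  if ((target - flo) * (target - fhi) > 0) {
    stop("infeasible target: attainable range is [",
         format(round(min(flo, fhi), 4)), ", ",
         format(round(max(flo, fhi), 4)), "]")
  }
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target) < tol) return(mid)
    if ((target - flo) * (target - fm) <= 0) {
      hi <- mid
    } else {
      lo <- mid
      flo <- fm
    }
  }
  (lo + hi) / 2
}

#' Calibrate component-failure probabilities to target Se/Sp
#'
#' Rescales the responder failure probabilities (the components other than
#' adherence, which defines the gold-standard denominator) until the implied
#' sensitivity matches `target_se`, and the non-responder probabilities
#' until the implied specificity matches `target_sp`, by bisection on the
#' closed-form [implied_performance()]. A seeded cohort of `verify_n`
#' patients is then generated and classified to confirm the empirical Se/Sp
#' land within `tol` of the targets; infeasible targets (outside the range
#' any multiplier can reach) raise an error.
#'
#' @param config Starting [sim_config()].
#' @param target_se,target_sp Targets in `(0, 1)`.
#' @param tol Verification tolerance on the empirical metrics, default 0.03.
#' @param verify_n Cohort size for the simulation check, default 3000.
#' @param seed Seed for the verification cohort.
#' @return The calibrated `ra_sim_config`, with attributes `implied` (the
#'   closed-form performance) and `empirical` (Se/Sp measured on the
#'   verification cohort).
#' @export
calibrate_misclassification <- function(config, target_se, target_sp,
                                        tol = 0.03, verify_n = 3000L,
                                        seed = config$seed) {
  stopifnot(target_se > 0, target_se < 1, target_sp > 0, target_sp < 1)
  se_comps <- c("new_dmard", "escalation", "injections", "gc")
  a <- bisect_mult(function(m) {
    cfg <- config
    cfg$responder_fail <- scale_probs(cfg$responder_fail, se_comps, m)
    implied_performance(cfg)$se
  }, target_se)
  config$responder_fail <- scale_probs(config$responder_fail, se_comps, a)

  sp_comps <- names(config$nonresponder_fail)
  b <- bisect_mult(function(m) {
    cfg <- config
    cfg$nonresponder_fail <- scale_probs(cfg$nonresponder_fail, sp_comps, m)
    implied_performance(cfg)$sp
  }, target_sp)
  config$nonresponder_fail <- scale_probs(config$nonresponder_fail, sp_comps, b)

  implied <- implied_performance(config)
  vcfg <- config
  vcfg$n_patients <- as.integer(verify_n)
  cohort <- generate_cohort(vcfg, seed = seed)
  res <- classify_episodes(cohort$episodes, cohort$fills, cohort$infusions,
                           cohort$procedures)
  gold <- evaluate_gold_standard(cohort$episodes, cohort$visits, res,
                                 mode = "primary_das28")
  pm <- performance_metrics(confusion_matrix(res, gold))
  empirical <- c(se = pm$se$estimate, sp = pm$sp$estimate)
  if (abs(empirical[["se"]] - target_se) > tol ||
        abs(empirical[["sp"]] - target_sp) > tol) {
    warning(sprintf(
      "verification cohort missed tolerance: Se %.3f vs %.3f, Sp %.3f vs %.3f",
      empirical[["se"]], target_se, empirical[["sp"]], target_sp))
  }
  attr(config, "implied") <- implied
  attr(config, "empirical") <- empirical
  config
}
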