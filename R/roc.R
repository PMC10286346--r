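# Screening performance of the merged referral scale: score subjects,
# sweep integer cutoffs, ROC/AUC with Hanley-McNeil (or DeLong)
# confidence intervals, operating-point Se/Sp/PPV/NPV.

#' Score subjects on the merged scale
#'
#' The score is the count of positive responses among the scale's
#' items; a subject is referred when the score reaches the scale's
#' cutoff.
#'
#' @param cohort a `spa_cohort`.
#' @param scale a `spa_merged_scale` (or a list with `items` and
#'   `cutoff`).
#' @return data.frame (`subject_id`, `group`, `score`, `referred`).
#' @export
score_subjects <- function(cohort, scale) {
  missing <- setdiff(scale$items, cohort$items$item_id)
  if (length(missing))
    stop("scale items absent from cohort: ",
         paste(missing, collapse = ", "))
  X <- cohort$subjects[, scale$items, drop = FALSE]
  score <- as.integer(rowSums(X))
  data.frame(subject_id = cohort$subjects$subject_id,
             group = cohort$subjects$group, score = score,
             referred = score >= scale$cutoff,
             stringsAsFactors = FALSE)
}

#' ROC curve over integer cutoffs
#'
#' Sweeps the decision rule `score >= k` over `k = 0 .. max_score + 1`
#' and records sensitivity and specificity at each cutoff.  The AUC is
#' the trapezoidal integral of the curve, which equals the
#' Mann-Whitney concordance probability (ties counted 1/2).
#'
#' @param case_scores,control_scores integer score vectors (both
#'   non-empty).
#' @param max_score maximum attainable score (default: observed max).
#' @return list with `points` (data.frame `cutoff`, `sensitivity`,
#'   `specificity`) and `auc`.
#' @export
roc_curve <- function(case_scores, control_scores,
                      max_score = max(case_scores, control_scores)) {
  if (length(case_scores) == 0 || length(control_scores) == 0)
    stop("both score vectors must be non-empty")
  ks <- 0:(max_score + 1)
  se <- vapply(ks, function(k) mean(case_scores >= k), 1)
  sp <- vapply(ks, function(k) mean(control_scores < k), 1)
  fpr <- 1 - sp
  o <- order(fpr, se)   # cutoff descending: (1,1) -> (0,0)
  auc <- -sum(diff(fpr[o]) * (se[o][-1] + se[o][-length(se)]) / 2)
  auc <- abs(auc)
  list(points = data.frame(cutoff = ks, sensitivity = se,
                           specificity = sp),
       auc = auc)
}

# Mann-Whitney concordance probability (independent check / DeLong).
mw_concordance <- function(case_scores, control_scores) {
  cmp <- outer(case_scores, control_scores,
               function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal 95% interval with the Hanley-McNeil standard error
#' (`Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`), truncated to `[0, 1]`.  A
#' degenerate AUC of exactly 0 or 1 returns a zero-width interval with
#' `degenerate = TRUE`.
#'
#' @param auc area under the curve.
#' @param n_cases,n_controls class sizes (each at least 2).
#' @param level confidence level (default 0.95).
#' @return list with `lower`, `upper`, `se`, `degenerate`.
#' @export
auc_confidence_interval <- function(auc, n_cases, n_controls,
                                    level = 0.95) {
  if (n_cases < 2 || n_controls < 2) stop("need at least 2 per class")
  if (auc <= 0 || auc >= 1)
    return(list(lower = auc, upper = auc, se = 0, degenerate = TRUE))
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_cases - 1) * (q1 - auc^2) +
                (n_controls - 1) * (q2 - auc^2)) / (n_cases * n_controls))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lower = max(0, auc - z * se), upper = min(1, auc + z * se),
       se = se, degenerate = FALSE)
}

# DeLong variance-based CI (optional alternative to Hanley-McNeil).
delong_interval <- function(case_scores, control_scores, level = 0.95) {
  m <- length(case_scores); n <- length(control_scores)
  auc <- mw_concordance(case_scores, control_scores)
  v10 <- vapply(case_scores, function(x)
    mean((x > control_scores) + 0.5 * (x == control_scores)), 1)
  v01 <- vapply(control_scores, function(y)
    mean((case_scores > y) + 0.5 * (case_scores == y)), 1)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  if (se == 0)
    return(list(lower = auc, upper = auc, se = 0, degenerate = TRUE))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lower = max(0, auc - z * se), upper = min(1, auc + z * se),
       se = se, degenerate = FALSE)
}

#' Operating point of the referral rule
#'
#' Se, Sp, PPV and NPV of the rule `score >= cutoff`, with predictive
#' values at the sample's case:control composition.  A zero
#' denominator (no referred, or no non-referred subject) yields `NA`
#' with a flag rather than an error.
#'
#' @param case_scores,control_scores integer score vectors.
#' @param cutoff referral cutoff.
#' @return list with `cutoff`, `se`, `sp`, `ppv`, `npv`, `flags`.
#' @export
operating_point <- function(case_scores, control_scores, cutoff) {
  tp <- sum(case_scores >= cutoff); fn <- length(case_scores) - tp
  fp <- sum(control_scores >= cutoff); tn <- length(control_scores) - fp
  flags <- character(0)
  ppv <- if (tp + fp == 0) { flags <- c(flags, "no_referred"); NA_real_
  } else tp / (tp + fp)
  npv <- if (tn + fn == 0) { flags <- c(flags, "no_nonreferred"); NA_real_
  } else tn / (tn + fn)
  list(cutoff = cutoff, se = tp / length(case_scores),
       sp = tn / length(control_scores), ppv = ppv, npv = npv,
       flags = flags)
}

#' Evaluate screening performance against every control group
#'
#' Runs the ROC analysis of the merged-scale score for cases versus
#' the diseased controls, versus the healthy controls, and versus both
#' control groups pooled (each comparison only when its groups are
#' present), all at the scale's shared operating cutoff.
#'
#' @param cohort a `spa_cohort`.
#' @param scale a `spa_merged_scale`.
#' @param ci_method `"hanley_mcneil"` (default) or `"delong"`.
#' @return object of class `spa_roc_set`: named list of analyses
#'   (`vs_diseased`, `vs_healthy`, `vs_pooled`), each with `points`,
#'   `auc`, `auc_ci`, `operating`, `n_cases`, `n_controls`.
#' @export
evaluate_all <- function(cohort, scale,
                         ci_method = c("hanley_mcneil", "delong")) {
  ci_method <- match.arg(ci_method)
  sc <- score_subjects(cohort, scale)
  cases <- sc$score[sc$group == "case"]
  if (length(cases) == 0) stop("no case group in cohort")
  controls <- list(
    vs_diseased = sc$score[sc$group == "diseased_control"],
    vs_healthy = sc$score[sc$group == "healthy_control"],
    vs_pooled = sc$score[sc$group %in% c("diseased_control",
                                         "healthy_control")])
  if (length(controls$vs_diseased) == 0 || length(controls$vs_healthy) == 0)
    controls$vs_pooled <- NULL
  controls <- Filter(length, controls)
  if (length(controls) == 0) stop("no control group in cohort")

  out <- lapply(names(controls), function(nm) {
    ctl <- controls[[nm]]
    roc <- roc_curve(cases, ctl, max_score = scale$max_score)
    ci <- if (ci_method == "hanley_mcneil")
      auc_confidence_interval(roc$auc, length(cases), length(ctl))
    else delong_interval(cases, ctl)
    list(comparison = nm, points = roc$points, auc = roc$auc,
         auc_ci = ci,
         operating = operating_point(cases, ctl, scale$cutoff),
         n_cases = length(cases), n_controls = length(ctl))
  })
  names(out) <- names(controls)
  structure(out, class = "spa_roc_set", ci_method = ci_method)
}

#' @export
print.spa_roc_set <- function(x, ...) {
  for (nm in names(x)) {
    a <- x[[nm]]
    cat(sprintf(
      "%-12s AUC %.3f (%.3f-%.3f)  cutoff %d: Se %.1f%% Sp %.1f%% PPV %s NPV %s\n",
      nm, a$auc, a$auc_ci$lower, a$auc_ci$upper, a$operating$cutoff,
      100 * a$operating$se, 100 * a$operating$sp,
      fmt_pct(a$operating$ppv), fmt_pct(a$operating$npv)))
  }
  invisible(x)
}

fmt_pct <- function(x) if (is.na(x)) "NA" else sprintf("%.1f%%", 100 * x)

#' Write ROC analyses
#'
#' One TSV of curve points per comparison plus a JSON summary of AUCs,
#' intervals and operating points.
#'
#' @param roc_set a `spa_roc_set`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the JSON path, invisibly.
#' @export
write_roc_report <- function(roc_set, dir, prefix = "roc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- lapply(roc_set, function(a) {
    utils::write.table(a$points,
                       file.path(dir, paste0(prefix, "_", a$comparison,
                                             ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(auc = a$auc, auc_lower = a$auc_ci$lower,
         auc_upper = a$auc_ci$upper, cutoff = a$operating$cutoff,
         se_pct = round(100 * a$operating$se, 1),
         sp_pct = round(100 * a$operating$sp, 1),
         ppv_pct = round(100 * a$operating$ppv, 1),
         npv_pct = round(100 * a$operating$npv, 1),
         n_cases = a$n_cases, n_controls = a$n_controls)
  })
  jp <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(summ, jp, auto_unbox = TRUE, digits = NA)
  invisible(jp)
}
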