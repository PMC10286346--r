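# Per-item case-control screening: 2x2 tables, Pearson chi-square /
# Fisher exact selection by Cochran's rule, demographic t-tests.

#' Build a 2x2 contingency table for one item and two groups
#'
#' Cell layout: `a` = group-a positives, `b` = group-a negatives,
#' `c` = group-b positives, `d` = group-b negatives.
#'
#' @param cohort a `spa_cohort`.
#' @param item item column id (e.g. `"q05"`) or text key.
#' @param group_a,group_b group labels present in the cohort.
#' @return object of class `spa_table2x2` with fields `a`,`b`,`c`,`d`
#'   and the two group labels.
#' @export
make_table <- function(cohort, item, group_a, group_b) {
  items <- cohort$items
  if (item %in% items$text_key)
    item <- items$item_id[match(item, items$text_key)]
  if (!item %in% items$item_id) stop("unknown item: ", item)
  subj <- cohort$subjects
  if (!all(c(group_a, group_b) %in% subj$group))
    stop("group not present in cohort: ",
         paste(setdiff(c(group_a, group_b), subj$group), collapse = ", "))
  ya <- subj[[item]][subj$group == group_a]
  yb <- subj[[item]][subj$group == group_b]
  table2x2(sum(ya == 1), sum(ya == 0), sum(yb == 1), sum(yb == 0),
           labels = c(group_a, group_b), item = item)
}

#' @rdname make_table
#' @param a,b,c,d non-negative cell counts.
#' @param labels length-2 character vector of group labels.
#' @export
table2x2 <- function(a, b, c, d, labels = c("group_a", "group_b"),
                     item = NA_character_) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  structure(list(a = a, b = b, c = c, d = d, labels = labels,
                 item = item),
            class = "spa_table2x2")
}

as_matrix2x2 <- function(tab)
  matrix(c(tab$a, tab$c, tab$b, tab$d), 2, 2,
         dimnames = list(group = tab$labels, response = c("yes", "no")))

test_result <- function(method, p, statistic = NA_real_, df = NA_real_,
                        note = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p, note = note),
            class = "spa_test")
}

#' @export
print.spa_test <- function(x, ...) {
  cat(x$method,
      if (!is.na(x$statistic)) sprintf(" statistic=%.4g df=%g",
                                       x$statistic, x$df),
      sprintf(" p=%.4g\n", x$p_value), sep = "")
  invisible(x)
}

expected_counts <- function(tab) {
  n <- tab$a + tab$b + tab$c + tab$d
  r <- c(tab$a + tab$b, tab$c + tab$d)   # row margins
  k <- c(tab$a + tab$c, tab$b + tab$d)   # column margins
  outer(r, k) / n
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom.
#' Rejects when any margin is zero (the exact test applies there).
#'
#' @param tab a `spa_table2x2`.
#' @return a `spa_test` with statistic, df and p-value.
#' @export
pearson_chi2 <- function(tab) {
  stopifnot(inherits(tab, "spa_table2x2"))
  n <- tab$a + tab$b + tab$c + tab$d
  margins <- c(tab$a + tab$b, tab$c + tab$d, tab$a + tab$c, tab$b + tab$d)
  if (any(margins == 0))
    stop("zero margin: Pearson chi-square undefined, use fisher_exact()")
  stat <- n * (tab$a * tab$d - tab$b * tab$c)^2 / prod(margins)
  test_result("pearson_chi2", stats::pchisq(stat, 1, lower.tail = FALSE),
              statistic = stat, df = 1)
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed
#' that of the observed table (relative tolerance 1e-7 on ties), as
#' implemented by [stats::fisher.test()].
#'
#' @param tab a `spa_table2x2`.
#' @return a `spa_test` (no statistic or df).
#' @export
fisher_exact <- function(tab) {
  stopifnot(inherits(tab, "spa_table2x2"))
  p <- stats::fisher.test(as_matrix2x2(tab))$p.value
  test_result("fisher_exact", min(p, 1))
}

#' Select the proportion test for a 2x2 table
#'
#' Cochran's rule: the exact test whenever any expected cell count is
#' below 5, otherwise the uncorrected Pearson chi-square.
#'
#' @param tab a `spa_table2x2`.
#' @return `"fisher_exact"` or `"pearson_chi2"`.
#' @export
choose_test <- function(tab) {
  stopifnot(inherits(tab, "spa_table2x2"))
  n <- tab$a + tab$b + tab$c + tab$d
  if (n == 0) return("fisher_exact")
  if (min(expected_counts(tab)) < 5) "fisher_exact" else "pearson_chi2"
}

run_test <- function(tab, method = choose_test(tab)) {
  # Items with no positive (or no negative) response in either compared
  # group carry no information; the exact test returns p = 1 there.
  switch(method,
         pearson_chi2 = pearson_chi2(tab),
         fisher_exact = fisher_exact(tab),
         stop("unknown method: ", method))
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's t with `df = n1 + n2 - 2` using the pooled variance; the
#' summary form agrees exactly with a `var.equal` t-test on raw data
#' realising the same summaries.  [two_sample_t_raw()] accepts raw
#' vectors.
#'
#' @param mean1,sd1,n1 first sample summary.
#' @param mean2,sd2,n2 second sample summary.
#' @return a `spa_test` with method `"student_t"`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  test_result("student_t", 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              statistic = t, df = df)
}

#' @rdname two_sample_t
#' @param x,y raw numeric vectors (NAs dropped).
#' @export
two_sample_t_raw <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  two_sample_t(mean(x), stats::sd(x), length(x),
               mean(y), stats::sd(y), length(y))
}

#' Screen all items against each control group
#'
#' Reproduces the item-screening stage: every item is compared between
#' cases and each control group with the test selected by
#' [choose_test()]; an item is *discriminating* when it is significant
#' versus at least one control group at level `alpha`.  Demographic
#' comparisons (age always; age at onset where both groups report it)
#' use the pooled t-test.  A Bonferroni-adjusted p-value column is
#' carried as supplementary information only; significance flags use
#' the unadjusted p-values, as no multiplicity correction is applied.
#'
#' @param cohort a `spa_cohort` containing the `case` group and at
#'   least one control group.
#' @param alpha two-sided significance level (default 0.05).
#' @param case_group,control_groups group labels.
#' @return object of class `spa_item_screen`: list with `results` (one
#'   row per item x control group), `demographics`, `summary`
#'   (`n_items`, `n_discriminating`, `alpha`) and `discriminating`
#'   (item ids).
#' @export
screen_items <- function(cohort, alpha = 0.05, case_group = "case",
                         control_groups = c("diseased_control",
                                            "healthy_control")) {
  subj <- cohort$subjects
  control_groups <- intersect(control_groups, unique(subj$group))
  if (!case_group %in% subj$group || length(control_groups) == 0)
    stop("cohort must contain the case group and at least one control group")

  rows <- list()
  for (q in cohort$items$item_id) {
    for (g in control_groups) {
      tab <- make_table(cohort, q, case_group, g)
      res <- run_test(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        item = q,
        text_key = cohort$items$text_key[match(q, cohort$items$item_id)],
        control_group = g, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        method = res$method, statistic = res$statistic, df = res$df,
        p = res$p_value, significant = res$p_value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  results$p_bonferroni <- pmin(1, stats::p.adjust(results$p, "bonferroni"))

  sig_by_item <- tapply(results$significant, results$item, any)
  discriminating <- names(sig_by_item)[sig_by_item]
  # keep item order
  discriminating <- cohort$items$item_id[cohort$items$item_id %in%
                                           discriminating]

  demo <- list()
  safe_t <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2 ||
        stats::sd(x) == 0 || stats::sd(y) == 0) NULL
    else two_sample_t_raw(x, y)
  }
  for (g in control_groups) {
    cx <- subj[subj$group == case_group, ]
    gx <- subj[subj$group == g, ]
    demo[[paste0("age_vs_", g)]] <- safe_t(cx$age, gx$age)
    demo[[paste0("onset_vs_", g)]] <- safe_t(cx$age_at_onset,
                                             gx$age_at_onset)
  }
  demo <- Filter(Negate(is.null), demo)

  structure(list(results = results, demographics = demo,
                 discriminating = discriminating,
                 summary = list(n_items = nrow(cohort$items),
                                n_discriminating = length(discriminating),
                                alpha = alpha)),
            class = "spa_item_screen")
}

#' @export
print.spa_item_screen <- function(x, ...) {
  cat("Item screening:", x$summary$n_discriminating, "of",
      x$summary$n_items, "items discriminating at alpha =",
      x$summary$alpha, "\n")
  invisible(x)
}

#' Write an item-screen report
#'
#' Writes the per-comparison table as TSV and the summary as JSON.
#'
#' @param screen a `spa_item_screen`.
#' @param tsv_path,json_path output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_screen_report <- function(screen, tsv_path, json_path = NULL) {
  utils::write.table(screen$results, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(screen$summary, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(tsv_path)
}
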