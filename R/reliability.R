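# Reliability- and validity-based item reduction: Cronbach's alpha,
# multitrait scaling success, the 0.70 retention rule, merged scale
# and referral cutoff.

#' Cronbach's alpha
#'
#' `alpha = p/(p-1) * (1 - sum(item variances) / variance(total))`,
#' with `n-1` denominators, over all subjects in the dataset.  The
#' standardized variant replaces variances by the mean inter-item
#' correlation (Spearman-Brown form).
#'
#' @param dataset a `spa_cohort`, or a numeric matrix/data.frame of
#'   item scores (subjects x items).
#' @param items item column ids to include (required for a cohort;
#'   default all columns for a matrix).
#' @param standardized if `TRUE` return the standardized alpha.
#' @return scalar alpha (can be negative; at most 1).
#' @export
cronbach_alpha <- function(dataset, items = NULL, standardized = FALSE) {
  X <- score_matrix(dataset, items)
  p <- ncol(X)
  if (p < 2) stop("Cronbach's alpha needs at least 2 items")
  if (nrow(X) < 2) stop("Cronbach's alpha needs at least 2 subjects")
  if (standardized) {
    R <- stats::cor(X)
    rbar <- mean(R[upper.tri(R)])
    return(p * rbar / (1 + (p - 1) * rbar))
  }
  tv <- stats::var(rowSums(X))
  if (tv == 0) stop("total-score variance is zero")
  p / (p - 1) * (1 - sum(apply(X, 2, stats::var)) / tv)
}

score_matrix <- function(dataset, items = NULL) {
  if (inherits(dataset, "spa_cohort")) {
    if (is.null(items)) items <- dataset$items$item_id
    as.matrix(dataset$subjects[, items, drop = FALSE])
  } else {
    X <- as.matrix(dataset)
    if (!is.null(items)) X <- X[, items, drop = FALSE]
    X
  }
}

#' Item-scale correlations
#'
#' Correlation of every assigned item with every component's scale
#' score (the sum of that component's items).  Own-scale correlations
#' are corrected for overlap: the item is removed from its own scale's
#' total before correlating.  Zero-variance scales (or items) yield a
#' correlation of 0 and are flagged.
#'
#' @param cohort a `spa_cohort`.
#' @param assignment a `spa_assignment` with at least one assigned item.
#' @return matrix (assigned items x components) with attribute
#'   `"degenerate"` listing flagged item/scale pairs.
#' @export
item_scale_correlations <- function(cohort, assignment) {
  stopifnot(inherits(assignment, "spa_assignment"))
  amap <- assignment$assignment
  if (nrow(amap) == 0) stop("assignment is empty")
  comps <- names(Filter(length, assignment$component_items))
  X <- response_matrix(cohort)
  totals <- vapply(comps, function(cl)
    rowSums(X[, assignment$component_items[[cl]], drop = FALSE]),
    numeric(nrow(X)))
  out <- matrix(NA_real_, nrow(amap), length(comps),
                dimnames = list(amap$item, comps))
  flagged <- character(0)
  for (i in seq_len(nrow(amap))) {
    item <- amap$item[i]
    y <- X[, item]
    for (cl in comps) {
      sc <- totals[, cl]
      if (cl == amap$component[i]) sc <- sc - y   # overlap correction
      if (stats::var(y) == 0 || stats::var(sc) == 0) {
        out[i, cl] <- 0
        flagged <- c(flagged, paste(item, cl, sep = ":"))
      } else out[i, cl] <- stats::cor(y, sc)
    }
  }
  attr(out, "degenerate") <- flagged
  out
}

#' Multitrait scaling success
#'
#' Convergent validity of a component: the fraction of its items whose
#' corrected own-scale correlation reaches `convergence_floor`
#' (default 0.40).  Discriminative validity: the fraction of
#' (item, other-scale) comparisons in which the corrected own-scale
#' correlation strictly exceeds the item's correlation with the other
#' scale.  With a single component, discriminative validity is not
#' applicable (`NA`).
#'
#' @param correlations matrix from [item_scale_correlations()].
#' @param assignment the matching `spa_assignment`.
#' @param convergence_floor minimum own-scale correlation counted as a
#'   convergence success (default 0.40).
#' @return data.frame (`component`, `convergent`, `discriminative`).
#' @export
scaling_success <- function(correlations, assignment,
                            convergence_floor = 0.40) {
  amap <- assignment$assignment
  comps <- colnames(correlations)
  res <- lapply(comps, function(cl) {
    its <- amap$item[amap$component == cl]
    if (length(its) == 0)
      return(data.frame(component = cl, convergent = NA_real_,
                        discriminative = NA_real_))
    own <- correlations[its, cl]
    conv <- mean(own >= convergence_floor)
    others <- setdiff(comps, cl)
    disc <- if (length(others) == 0) NA_real_ else
      mean(outer(seq_along(its), seq_along(others),
                 Vectorize(function(i, j)
                   own[i] > correlations[its[i], others[j]])))
    data.frame(component = cl, convergent = conv, discriminative = disc)
  })
  do.call(rbind, res)
}

#' Component reliability and validity report
#'
#' Builds the per-component report used for item reduction: number of
#' items, scale-score mean and SD, Cronbach's alpha, convergent and
#' discriminative scaling success, and the retention flag (every
#' criterion at or above `reliability_floor`).  Components with fewer
#' than two items get `NA` alpha and are never retained.
#'
#' @param cohort a `spa_cohort`.
#' @param assignment a `spa_assignment`.
#' @param reliability_floor retention floor for alpha and the validity
#'   proportions (default 0.70).
#' @param convergence_floor see [scaling_success()].
#' @return data.frame of class `spa_reliability` with one row per
#'   component (`component`, `n_items`, `mean`, `sd`, `alpha`,
#'   `convergent`, `discriminative`, `retained`).
#' @export
reliability_report <- function(cohort, assignment,
                               reliability_floor = 0.70,
                               convergence_floor = 0.40) {
  comps <- names(Filter(length, assignment$component_items))
  if (length(comps) == 0) stop("no component has any assigned item")
  corr <- item_scale_correlations(cohort, assignment)
  succ <- scaling_success(corr, assignment, convergence_floor)
  X <- response_matrix(cohort)
  rows <- lapply(comps, function(cl) {
    its <- assignment$component_items[[cl]]
    sc <- rowSums(X[, its, drop = FALSE])
    a <- if (length(its) >= 2 && stats::var(sc) > 0)
      cronbach_alpha(X, its) else NA_real_
    data.frame(component = cl, n_items = length(its),
               mean = mean(sc), sd = stats::sd(sc), alpha = a,
               convergent = succ$convergent[succ$component == cl],
               discriminative = succ$discriminative[succ$component == cl],
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$retained <- rep$component %in%
    retention_filter(rep, floor = reliability_floor)
  class(rep) <- c("spa_reliability", "data.frame")
  attr(rep, "reliability_floor") <- reliability_floor
  attr(rep, "convergence_floor") <- convergence_floor
  rep
}

#' Retention rule
#'
#' A component is retained iff its alpha, convergent validity and
#' discriminative validity all reach the floor (boundary inclusive);
#' failing any one criterion excludes it.  A missing alpha or
#' convergent value fails; a missing discriminative value (single
#' component: not applicable) is ignored.
#'
#' @param report a data.frame with columns `component`, `alpha`,
#'   `convergent`, `discriminative`.
#' @param floor the retention floor (default 0.70).
#' @return character vector of retained component labels.
#' @export
retention_filter <- function(report, floor = 0.70) {
  if (nrow(report) == 0) return(character(0))
  ok <- !is.na(report$alpha) & report$alpha >= floor &
    !is.na(report$convergent) & report$convergent >= floor &
    (is.na(report$discriminative) | report$discriminative >= floor)
  report$component[ok]
}

#' Referral cutoff from the global reliability fraction
#'
#' The minimum number of positive responses that flags a subject is
#' the global alpha expressed as a fraction of the maximum score:
#' `floor(global_alpha * max_score)` (the default rounding), or
#' `ceiling` as the documented alternative.
#'
#' @param global_alpha Cronbach's alpha of the merged scale, in `[0, 1]`.
#' @param max_score number of items in the merged scale.
#' @param rule `"floor"` (default) or `"ceiling"`.
#' @return integer cutoff in `[0, max_score]`.
#' @export
referral_cutoff <- function(global_alpha, max_score,
                            rule = c("floor", "ceiling")) {
  rule <- match.arg(rule)
  if (global_alpha < 0 || global_alpha > 1)
    stop("global_alpha must lie in [0, 1]")
  f <- if (rule == "floor") floor else ceiling
  as.integer(min(max_score, max(0, f(global_alpha * max_score))))
}

#' Merge retained components into the referral scale
#'
#' Pools the items of the retained components (in component order,
#' then assignment order within a component), computes the merged
#' scale's global Cronbach's alpha (plus the standardized variant for
#' reference), and derives the referral cutoff via [referral_cutoff()].
#'
#' @param cohort a `spa_cohort`.
#' @param assignment a `spa_assignment`.
#' @param retained character vector of retained component labels, e.g.
#'   from [retention_filter()].
#' @param rounding_rule `"floor"` (default) or `"ceiling"`.
#' @return object of class `spa_merged_scale`: `items`, `components`,
#'   `global_alpha`, `global_alpha_standardized`, `max_score`,
#'   `cutoff`, `rounding_rule`.
#' @export
merge_scale <- function(cohort, assignment, retained,
                        rounding_rule = c("floor", "ceiling")) {
  rounding_rule <- match.arg(rounding_rule)
  if (length(retained) == 0) stop("no retained component to merge")
  items <- unlist(assignment$component_items[retained], use.names = FALSE)
  if (length(items) < 2) stop("merged scale needs at least 2 items")
  ga <- cronbach_alpha(cohort, items)
  gs <- cronbach_alpha(cohort, items, standardized = TRUE)
  ms <- length(items)
  structure(list(items = items, components = retained,
                 global_alpha = ga, global_alpha_standardized = gs,
                 max_score = ms,
                 cutoff = referral_cutoff(max(0, min(1, ga)), ms,
                                          rounding_rule),
                 rounding_rule = rounding_rule),
            class = "spa_merged_scale")
}

#' @export
print.spa_merged_scale <- function(x, ...) {
  cat(sprintf("Merged referral scale: %d items (%s), alpha = %.3f\n",
              x$max_score, paste(x$components, collapse = "+"),
              x$global_alpha))
  cat(sprintf("  refer when score >= %d of %d (%s rounding)\n",
              x$cutoff, x$max_score, x$rounding_rule))
  invisible(x)
}

#' Write the reliability report and merged scale
#'
#' @param report a `spa_reliability`.
#' @param scale a `spa_merged_scale` (or `NULL`).
#' @param tsv_path,json_path output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_reliability_report <- function(report, scale = NULL,
                                     tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(report), tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(json_path) && !is.null(scale))
    jsonlite::write_json(unclass(scale), json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(tsv_path)
}
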