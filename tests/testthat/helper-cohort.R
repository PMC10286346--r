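# Construct small cohorts directly from response matrices so unit
# tests can pin exact counts without going through the generator.

# responses_by_group: named list group -> 0/1 matrix (subjects x items).
toy_cohort <- function(responses_by_group,
                       item_ids = NULL) {
  p <- ncol(responses_by_group[[1]])
  if (is.null(item_ids)) item_ids <- sprintf("q%02d", seq_len(p))
  items <- item_specs(item_id = item_ids,
                      text_key = item_ids,
                      factor = rep("none", p),
                      loading = rep(0, p),
                      prev_case = rep(0.5, p),
                      prev_diseased = rep(0.5, p),
                      prev_healthy = rep(0.5, p))
  parts <- lapply(names(responses_by_group), function(g) {
    X <- responses_by_group[[g]]
    colnames(X) <- item_ids
    cbind(data.frame(group = g, age = 40, sex = "M",
                     age_at_onset = NA_real_,
                     stringsAsFactors = FALSE),
          as.data.frame(X))
  })
  subjects <- do.call(rbind, parts)
  subjects <- cbind(data.frame(
    subject_id = sprintf("T%04d", seq_len(nrow(subjects))),
    stringsAsFactors = FALSE), subjects)
  rownames(subjects) <- NULL
  structure(list(subjects = subjects, items = items,
                 provenance = list(origin = "toy")),
            class = "spa_cohort")
}

# A group column of n subjects with exactly k positive responses.
count_col <- function(n, k) c(rep(1L, k), rep(0L, n - k))

# Two-group cohort realising exact 2x2 cell counts for one item.
toy_table_cohort <- function(a, b, c, d,
                             groups = c("case", "diseased_control")) {
  rs <- list(matrix(count_col(a + b, a), ncol = 1),
             matrix(count_col(c + d, c), ncol = 1))
  names(rs) <- groups
  toy_cohort(rs, item_ids = "q01")
}

# Multivariate normal with compound-symmetric correlation r.
rmvn_cs <- function(n, p, r) {
  z <- matrix(stats::rnorm(n * p), n, p)
  common <- stats::rnorm(n)
  sqrt(r) * common + sqrt(1 - r) * z
}
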