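# Synthetic cohort generator: threshold calibration, marginal
# matching, planted structure, determinism, CSV round trip.

test_that("threshold calibration matches normal quantiles", {
  expect_equal(calibrate_threshold(0.5, 0, 0), 0)
  expect_equal(calibrate_threshold(0.975, 0, 0), qnorm(0.025))
  expect_error(calibrate_threshold(0), "strictly inside")
  expect_error(calibrate_threshold(1), "strictly inside")
})

test_that("calibrated threshold reproduces the target marginal by Monte Carlo", {
  # target 0.84, loading 0.7, shift 1: draw the latent model directly
  thr <- calibrate_threshold(0.84, 0.7, 1)
  set.seed(1)
  z1 <- rnorm(1e5); z2 <- rnorm(1e5)
  prev <- mean(0.7 * (1 + z1) + sqrt(1 - 0.49) * z2 > thr)
  expect_lt(abs(prev - 0.84), 0.01)
})

test_that("default specs encode the three-group design", {
  sp <- default_specs()
  expect_equal(sum(sp$groups$n), 400L)
  expect_equal(sp$groups$n, c(50L, 150L, 200L))
  bp <- sp$items[sp$items$text_key == "back_pain", ]
  expect_equal(unname(unlist(
    bp[c("prev_case", "prev_diseased", "prev_healthy")])),
    c(0.84, 0.487, 0.205))
  ur <- sp$items[sp$items$text_key == "urethritis", ]
  expect_equal(unname(unlist(
    ur[c("prev_case", "prev_diseased", "prev_healthy")])),
    c(0.18, 0, 0.005))
  expect_equal(sum(sp$items$factor == "axial"), 8L)
  expect_equal(sum(sp$items$factor == "peripheral"), 3L)
  expect_true(all(sp$items$loading[sp$items$factor == "none"] == 0))
})

test_that("generated cohort has the declared sizes and valid fields", {
  sp <- default_specs()
  co <- generate_cohort(sp$groups, sp$items, seed = 7)
  expect_s3_class(co, "spa_cohort")
  expect_equal(nrow(co$subjects), 400L)
  expect_equal(as.integer(table(co$subjects$group)[c(
    "case", "diseased_control", "healthy_control")]), c(50L, 150L, 200L))
  expect_false(anyDuplicated(co$subjects$subject_id) > 0)
  expect_true(all(co$subjects$age >= 18 & co$subjects$age <= 95))
  expect_true(all(co$subjects$sex %in% c("M", "F")))
  onset <- co$subjects$age_at_onset
  expect_true(all(is.na(onset[co$subjects$group == "healthy_control"])))
  ok <- !is.na(onset)
  expect_true(all(onset[ok] <= co$subjects$age[ok]))
  X <- response_mat <- as.matrix(co$subjects[, sp$items$item_id])
  expect_true(all(X %in% c(0L, 1L)))
})

test_that("degenerate prevalence is clamped, not fatal", {
  g <- group_specs("case", n = 200L, age_mean = 40, age_sd = 10,
                   male_fraction = 0.5)
  it <- item_specs("q01", "always_yes", "none", 0, 1, 1, 1)
  co <- generate_cohort(g, it, seed = 3)
  expect_gte(sum(co$subjects$q01), 190)   # Bin(200, 0.995) tail
})

test_that("generation is deterministic in the seed and varies across seeds", {
  sp <- default_specs()
  a <- generate_cohort(sp$groups, sp$items, seed = 11)
  b <- generate_cohort(sp$groups, sp$items, seed = 11)
  expect_identical(a$subjects, b$subjects)
  differs <- vapply(1:10, function(s) {
    x <- generate_cohort(sp$groups, sp$items, seed = s)
    y <- generate_cohort(sp$groups, sp$items, seed = s + 1000)
    !identical(x$subjects[, sp$items$item_id],
               y$subjects[, sp$items$item_id])
  }, TRUE)
  expect_true(all(differs))
})

test_that("generator does not disturb the global RNG stream", {
  set.seed(42); before <- rnorm(1)
  set.seed(42)
  sp <- default_specs()
  invisible(generate_cohort(sp$groups, sp$items, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("generated prevalences match their targets within binomial noise", {
  sp <- default_specs()
  floor <- 0.005
  within <- c()
  for (s in 1:100) {
    co <- generate_cohort(sp$groups, sp$items, seed = 2000 + s)
    for (g in c("diseased_control", "healthy_control")) {   # n >= 150
      n <- sp$groups$n[sp$groups$group == g]
      prev_col <- c(diseased_control = "prev_diseased",
                    healthy_control = "prev_healthy")[[g]]
      targ <- pmin(pmax(sp$items[[prev_col]], floor), 1 - floor)
      got <- colMeans(co$subjects[co$subjects$group == g,
                                  sp$items$item_id])
      tol <- 3 * sqrt(targ * (1 - targ) / n)
      within <- c(within, abs(got - targ) <= tol)
    }
  }
  expect_gte(mean(within), 0.99)
})

test_that("planted axial block is more correlated than axial-none pairs", {
  sp <- default_specs()
  ax <- sp$items$item_id[sp$items$factor == "axial"]
  no <- sp$items$item_id[sp$items$factor == "none"]
  diffs <- vapply(1:20, function(s) {
    co <- generate_cohort(sp$groups, sp$items, seed = s)
    R <- correlation_matrix(co)$R   # zero-variance items -> 0 entries
    within <- mean(R[ax, ax][upper.tri(R[ax, ax])])
    across <- mean(R[ax, no])
    within - across
  }, 1)
  expect_true(all(diffs > 0))
})

test_that("cohort CSV round-trips and rejects malformed files", {
  sp <- default_specs()
  co <- generate_cohort(sp$groups, sp$items, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, items = sp$items)
  expect_equal(back$subjects, co$subjects)

  # corrupt one response cell
  lines <- readLines(path)
  row3 <- strsplit(lines[4], ",")[[1]]
  qcol <- which(strsplit(lines[1], ",")[[1]] == "q05")
  row3[qcol] <- "2"
  lines[4] <- paste(row3, collapse = ",")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, bad)
  expect_error(read_cohort(bad, items = sp$items), "row 3, column q05")

  # drop a required column
  df <- utils::read.csv(path)
  df$q20 <- NULL
  bad2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad2, row.names = FALSE, na = "")
  expect_error(read_cohort(bad2, items = sp$items), "q20")
})
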