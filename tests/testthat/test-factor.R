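# Factorability diagnostics, component extraction, varimax rotation
# and item assignment, checked against independent oracles.

test_that("phi correlation matrix handles exact and degenerate cases", {
  dup <- cbind(count_col(40, 10), count_col(40, 10))
  anti <- cbind(count_col(40, 10), 1L - count_col(40, 10))
  co <- toy_cohort(list(case = cbind(dup, anti)))
  cm <- correlation_matrix(co)
  expect_equal(cm$R["q01", "q02"], 1)
  expect_equal(cm$R["q03", "q04"], -1)

  co$subjects$q01 <- 1L
  cm2 <- correlation_matrix(co)
  expect_equal(cm2$degenerate, "q01")
  expect_true(all(cm2$R["q01", -1] == 0))
})

test_that("independent items decorrelate as n grows", {
  set.seed(11)
  n <- 4000
  X <- matrix(rbinom(n * 2, 1, 0.4), n, 2)
  co <- toy_cohort(list(case = X))
  r <- correlation_matrix(co)$R[1, 2]
  expect_lt(abs(r), 3 / sqrt(n))
})

test_that("tetrachoric estimate recovers a known latent correlation", {
  set.seed(21)
  n <- 3000
  z1 <- rnorm(n); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  X <- cbind(as.integer(z1 > 0.5), as.integer(z2 > -0.3))
  co <- toy_cohort(list(case = X))
  r <- correlation_matrix(co, method = "tetrachoric")$R[1, 2]
  expect_lt(abs(r - 0.6), 0.08)
  # and phi is attenuated below the latent correlation
  expect_lt(correlation_matrix(co)$R[1, 2], r)
})

test_that("KMO matches the regression-residual partial-correlation oracle", {
  R3 <- matrix(c(1, 0.5, 0.3,
                 0.5, 1, 0.4,
                 0.3, 0.4, 1), 3, 3)
  expect_equal(kmo_index(R3), oracle_kmo(R3), tolerance = 1e-8)

  set.seed(19)
  for (i in 1:20) {
    p <- sample(4:6, 1)
    L <- matrix(rnorm(p), ncol = 1)
    R <- tcrossprod(L) + diag(runif(p, 0.5, 2))
    R <- cov2cor(R)
    expect_equal(kmo_index(R), oracle_kmo(R), tolerance = 1e-8)
  }

  one_factor <- matrix(0.5, 6, 6); diag(one_factor) <- 1
  expect_gt(kmo_index(one_factor), 0.7)
  expect_error(kmo_index(diag(4)), "KMO undefined")
})

test_that("Bartlett sphericity matches its closed form", {
  id <- diag(5)
  res <- bartlett_sphericity(id, n = 100)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 10)

  R2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(bartlett_sphericity(R2, n = 101)$chi2,
               -(100 - 9 / 6) * log(0.75))

  # chi2 grows with |r| at fixed n, p
  chis <- vapply(c(0.1, 0.3, 0.5, 0.7), function(r)
    bartlett_sphericity(matrix(c(1, r, r, 1), 2), n = 50)$chi2, 1)
  expect_true(all(diff(chis) > 0))
  expect_error(bartlett_sphericity(matrix(c(1, 1, 1, 1), 2), n = 10),
               "positive-definite")
})

test_that("component extraction preserves trace and best rank-k fit", {
  blk <- matrix(0.6, 3, 3); diag(blk) <- 1
  R <- as.matrix(Matrix::bdiag(blk, blk))
  dimnames(R) <- list(paste0("v", 1:6), paste0("v", 1:6))
  sol <- extract_components(R)
  expect_equal(sol$n_components, 2L)
  expect_equal(sol$variance_shares, c(0.5, 0.5))
  expect_equal(sum(sol$eigenvalues), 6)

  set.seed(3)
  L <- matrix(rnorm(12), 6, 2)
  Rr <- cov2cor(tcrossprod(L) + diag(runif(6, 0.3, 1)))
  dimnames(Rr) <- list(paste0("v", 1:6), paste0("v", 1:6))
  s2 <- extract_components(Rr, "fixed_k", k = 2)
  approx_pkg <- tcrossprod(s2$loadings)
  sv <- svd(Rr)
  approx_svd <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  expect_equal(norm(Rr - approx_pkg, "F"), norm(Rr - approx_svd, "F"),
               tolerance = 1e-8)
})

test_that("varimax leaves trivial cases alone and preserves communalities", {
  L1 <- matrix(c(0.8, 0.6, 0.7), ncol = 1)
  expect_equal(varimax_rotate(L1)$loadings, L1)

  simple <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.7), c(0, 0.6))
  rot <- varimax_rotate(simple)
  expect_equal(sort(abs(rot$loadings[rot$loadings != 0])),
               sort(c(0.6, 0.7, 0.8, 0.9)), tolerance = 1e-10)

  set.seed(41)
  L <- matrix(rnorm(24), 8, 3)
  rot3 <- varimax_rotate(L)
  expect_equal(rowSums(rot3$loadings^2), rowSums(L^2), tolerance = 1e-8)
  expect_equal(crossprod(rot3$rotation), diag(3), tolerance = 1e-10)
  expect_equal(L %*% rot3$rotation, rot3$loadings, tolerance = 1e-10)
  # sign convention: every column's largest-magnitude entry positive
  expect_true(all(apply(rot3$loadings, 2,
                        function(x) x[which.max(abs(x))] > 0)))
})

test_that("varimax attains the grid-search optimum for k = 2", {
  set.seed(6)
  for (i in 1:5) {
    L <- matrix(rnorm(12), 6, 2)
    rot <- varimax_rotate(L)
    best <- oracle_varimax_best_k2(L)
    expect_equal(varimax_criterion(rot$loadings), best,
                 tolerance = 1e-6)
    expect_gte(varimax_criterion(rot$loadings) + 1e-12,
               varimax_criterion(L))
  }
})

test_that("varimax agrees with the reference implementation", {
  set.seed(23)
  L <- matrix(rnorm(40), 10, 4)
  ours <- varimax_rotate(L, tol = 1e-10)
  ref <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
  expect_equal(varimax_criterion(ours$loadings),
               varimax_criterion(unclass(ref$loadings)),
               tolerance = 1e-6)
})

test_that("item assignment follows max loading with threshold and ties", {
  L <- rbind(q1 = c(0.9, 0.2), q2 = c(0.1, 0.85), q3 = c(0.2, 0.1))
  sol <- structure(list(loadings = L, variance_shares = c(0.6, 0.4),
                        n_components = 2L, rotated = TRUE,
                        eigenvalues = c(2, 1)),
                   class = "spa_factor_solution")
  asg <- assign_items(sol)
  expect_equal(asg$assignment$component[asg$assignment$item == "q1"], "C1")
  expect_equal(asg$assignment$component[asg$assignment$item == "q2"], "C2")
  expect_equal(asg$unassigned, "q3")

  low <- sol; low$loadings <- L / 10
  expect_equal(nrow(assign_items(low)$assignment), 0L)
  expect_equal(assign_items(low)$unassigned, c("q1", "q2", "q3"))

  # variance-share ordering relabels components
  swapped <- sol; swapped$variance_shares <- c(0.4, 0.6)
  asg2 <- assign_items(swapped)
  expect_equal(asg2$assignment$component[asg2$assignment$item == "q2"],
               "C1")
})

test_that("pipeline recovers a planted two-block structure at moderate prevalence", {
  # moderate marginals, well inside the phi ceiling: the model class can
  # express this structure, so recovery should be near certain
  groups <- group_specs(c("case", "diseased_control", "healthy_control"),
                        n = c(100L, 150L, 150L),
                        age_mean = c(40, 55, 35), age_sd = c(10, 10, 10),
                        male_fraction = c(0.5, 0.4, 0.5),
                        axial_shift = c(1, 0, 0),
                        peripheral_shift = c(1, 0, 0))
  items <- item_specs(sprintf("q%02d", 1:10), sprintf("q%02d", 1:10),
                      factor = c(rep("axial", 4), rep("peripheral", 3),
                                 rep("none", 3)),
                      loading = c(rep(0.8, 7), rep(0, 3)),
                      prev_case = c(rep(0.7, 7), rep(0.3, 3)),
                      prev_diseased = c(rep(0.35, 4), rep(0.55, 3),
                                        rep(0.3, 3)),
                      prev_healthy = c(rep(0.25, 7), rep(0.3, 3)))
  hits <- vapply(1:10, function(s) {
    co <- generate_cohort(groups, items, seed = 100 + s)
    sol <- varimax_rotate(extract_components(correlation_matrix(co)))
    asg <- assign_items(sol)
    am <- asg$assignment
    axc <- unique(am$component[am$item %in% sprintf("q%02d", 1:4)])
    pec <- unique(am$component[am$item %in% sprintf("q%02d", 5:7)])
    sum(am$item %in% sprintf("q%02d", 1:4)) == 4 &&
      sum(am$item %in% sprintf("q%02d", 5:7)) == 3 &&
      length(axc) == 1 && length(pec) == 1 && axc != pec
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
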