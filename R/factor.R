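# Factorability diagnostics and principal-component extraction with
# varimax rotation for the binary item battery.

#' Inter-item correlation matrix
#'
#' Pairwise correlations of the 0/1 item responses over the selected
#' subjects.  The default is the Pearson product-moment correlation on
#' the binary codes (the phi coefficient), matching the conventional
#' SPSS-style workflow; a maximum-likelihood tetrachoric estimate is
#' available for sensitivity analyses.  Items with zero variance get
#' zero off-diagonal entries and are listed as degenerate.
#'
#' @param cohort a `spa_cohort`.
#' @param groups optional subset of group labels; default pools all
#'   subjects.
#' @param method `"pearson_phi"` (default) or `"tetrachoric"`.
#' @return object of class `spa_cormat`: list with `R` (p x p matrix),
#'   `n` (subjects used), `method`, `degenerate` (zero-variance items).
#' @export
correlation_matrix <- function(cohort, groups = NULL,
                               method = c("pearson_phi", "tetrachoric")) {
  method <- match.arg(method)
  X <- response_matrix(cohort, groups)
  if (nrow(X) < 2) stop("need at least 2 subjects after filtering")
  v <- apply(X, 2, stats::var)
  degenerate <- colnames(X)[v == 0]
  if (length(degenerate) == ncol(X))
    stop("all items are constant in the selected subjects")
  R <- diag(ncol(X))
  dimnames(R) <- list(colnames(X), colnames(X))
  live <- which(v > 0)
  if (method == "pearson_phi") {
    R[live, live] <- stats::cor(X[, live, drop = FALSE])
  } else {
    for (i in live) for (j in live) if (i < j) {
      r <- tetrachoric_r(X[, i], X[, j])
      R[i, j] <- R[j, i] <- r
    }
  }
  structure(list(R = R, n = nrow(X), method = method,
                 degenerate = degenerate),
            class = "spa_cormat")
}

# Standard bivariate normal upper-quadrant probability, by integrating
# dnorm(x) * P(Y > k | X = x) over x > h.
pbvn_upper <- function(h, k, rho) {
  if (abs(rho) < 1e-12)
    return(stats::pnorm(h, lower.tail = FALSE) *
             stats::pnorm(k, lower.tail = FALSE))
  f <- function(x)
    stats::dnorm(x) *
      stats::pnorm((k - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
  stats::integrate(f, h, Inf, rel.tol = 1e-10)$value
}

# ML tetrachoric correlation for two binary vectors (profile likelihood
# in rho with thresholds fixed at the marginal normal quantiles).
tetrachoric_r <- function(x, y) {
  n <- length(x)
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  c <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  if (min(a + b, c + d, a + c, b + d) == 0) return(0)
  h <- stats::qnorm(1 - (a + b) / n)   # threshold for x
  k <- stats::qnorm(1 - (a + c) / n)   # threshold for y
  nll <- function(rho) {
    p11 <- pbvn_upper(h, k, rho)
    p1x <- (a + b) / n; px1 <- (a + c) / n
    p10 <- p1x - p11; p01 <- px1 - p11; p00 <- 1 - p1x - px1 + p11
    pr <- pmax(c(p11, p10, p01, p00), 1e-12)
    -sum(c(a, b, c, d) * log(pr))
  }
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}

#' Kaiser-Meyer-Olkin sampling-adequacy index
#'
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal
#' pairs, where `q_ij` are the anti-image partial correlations obtained
#' from the inverse correlation matrix:
#' `q_ij = -s_ij / sqrt(s_ii s_jj)` with `S = R^-1`.
#'
#' @param R a `spa_cormat` or plain correlation matrix.
#' @param max_condition reject `R` when its condition number exceeds
#'   this value (near-singular matrix).
#' @return the scalar KMO index in `[0, 1]`.
#' @export
kmo_index <- function(R, max_condition = 1e10) {
  R <- cormat_of(R)
  cond <- kappa(R, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition)
    stop(sprintf("correlation matrix is (near-)singular: condition number %.3g",
                 cond))
  S <- solve(R)
  Q <- -S / sqrt(outer(diag(S), diag(S)))
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(Q[off]^2)
  if (r2 + q2 == 0)
    stop("KMO undefined: no off-diagonal correlation (identity matrix)")
  r2 / (r2 + q2)
}

#' Bartlett's test of sphericity
#'
#' Tests that the correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det R` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param R a `spa_cormat` or correlation matrix.
#' @param n number of subjects (taken from a `spa_cormat` when absent).
#' @return a list with `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(R, n = NULL) {
  if (inherits(R, "spa_cormat") && is.null(n)) n <- R$n
  R <- cormat_of(R)
  p <- ncol(R)
  if (is.null(n)) stop("n is required")
  if (n <= p) stop("Bartlett's test needs n > p")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("correlation matrix is not positive-definite")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * sum(log(ev))
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

cormat_of <- function(R) {
  if (inherits(R, "spa_cormat")) R <- R$R
  R <- as.matrix(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-12)))
    stop("correlation matrix must be symmetric")
  R
}

#' Principal-component extraction from a correlation matrix
#'
#' Eigendecomposition of `R`; retained components have eigenvalue > 1
#' (Kaiser rule, default) or a requested fixed number.  Unrotated
#' loadings are eigenvectors scaled by the square root of their
#' eigenvalues; communalities are row sums of squared retained
#' loadings; variance shares are the retained eigenvalues as a fraction
#' of their own sum (the "common variance" convention, so shares sum
#' to 1).
#'
#' @param R a `spa_cormat` or correlation matrix.
#' @param retention `"kaiser"` or `"fixed_k"`.
#' @param k number of components when `retention = "fixed_k"`.
#' @return object of class `spa_factor_solution`: `eigenvalues`,
#'   `n_components`, `loadings` (p x k), `communalities`,
#'   `variance_shares`, `rotated` flag.
#' @export
extract_components <- function(R, retention = c("kaiser", "fixed_k"),
                               k = NULL) {
  retention <- match.arg(retention)
  R <- cormat_of(R)
  e <- eigen(R, symmetric = TRUE)
  ev <- e$values
  nk <- if (retention == "kaiser") sum(ev > 1) else {
    if (is.null(k)) stop("k required for fixed_k retention")
    as.integer(k)
  }
  if (nk < 1) stop("no component retained")
  L <- e$vectors[, seq_len(nk), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(nk)]), nk)
  dimnames(L) <- list(rownames(R), paste0("PC", seq_len(nk)))
  structure(list(eigenvalues = ev, n_components = nk, loadings = L,
                 communalities = rowSums(L^2),
                 variance_shares = ev[seq_len(nk)] / sum(ev[seq_len(nk)]),
                 rotated = FALSE),
            class = "spa_factor_solution")
}

#' @export
print.spa_factor_solution <- function(x, ...) {
  cat(if (x$rotated) "Rotated" else "Unrotated",
      "component solution:", x$n_components, "components\n")
  cat("  variance shares:",
      paste(sprintf("%.1f%%", 100 * x$variance_shares), collapse = " "),
      "\n")
  invisible(x)
}

#' Varimax criterion of a loading matrix
#'
#' Sum over components of the variance of the squared (optionally
#' Kaiser-normalized) loadings.
#'
#' @param L p x k loading matrix.
#' @param kaiser_normalize divide each row by its communality's square
#'   root before evaluating.
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(L, kaiser_normalize = TRUE) {
  if (kaiser_normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  sq <- L^2
  sum(apply(sq, 2, function(col) mean((col - mean(col))^2)))
}

#' Varimax rotation
#'
#' Orthogonal rotation maximizing the varimax criterion by iterative
#' pairwise planar rotations, with Kaiser row normalization by default.
#' Each column of the result is sign-flipped so its largest-magnitude
#' loading is positive.  Communalities are invariant under the
#' rotation.
#'
#' @param L p x k loading matrix (or a `spa_factor_solution`).
#' @param kaiser_normalize normalize rows by communalities first
#'   (default `TRUE`).
#' @param tol stop when a full sweep improves the criterion by less
#'   than `tol` relatively (default 1e-6).
#' @param max_iter maximum number of sweeps (default 100); hitting it
#'   returns the best iterate with `converged = FALSE` and a warning.
#' @return for a matrix input, a list with `loadings`, `rotation`
#'   (k x k orthogonal matrix), `iterations`, `converged`, `criterion`;
#'   for a solution input, the updated `spa_factor_solution` (variance
#'   shares recomputed from the rotated loadings).
#' @export
varimax_rotate <- function(L, kaiser_normalize = TRUE, tol = 1e-6,
                           max_iter = 100) {
  if (inherits(L, "spa_factor_solution")) {
    rot <- varimax_rotate(L$loadings, kaiser_normalize, tol, max_iter)
    L$loadings <- rot$loadings
    L$rotation <- rot$rotation
    L$converged <- rot$converged
    ss <- colSums(rot$loadings^2)
    L$variance_shares <- ss / sum(ss)
    L$rotated <- TRUE
    return(L)
  }
  L <- as.matrix(L)
  k <- ncol(L)
  rot <- diag(k)
  if (k < 2)
    return(list(loadings = flip_signs(L), rotation = rot, iterations = 0L,
                converged = TRUE,
                criterion = varimax_criterion(L, kaiser_normalize)))

  h <- sqrt(rowSums(L^2))
  h[h == 0] <- 1
  W <- if (kaiser_normalize) L / h else L
  p <- nrow(W)
  crit <- varimax_criterion(W, kaiser_normalize = FALSE)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      x <- W[, i]; y <- W[, j]
      u <- x^2 - y^2; v <- 2 * x * y
      A <- sum(u); B <- sum(v)
      C <- sum(u^2 - v^2); D <- sum(2 * u * v)
      num <- D - 2 * A * B / p
      den <- C - (A^2 - B^2) / p
      phi <- atan2(num, den) / 4
      if (abs(phi) > .Machine$double.eps) {
        co <- cos(phi); si <- sin(phi)
        W[, i] <- co * x + si * y
        W[, j] <- -si * x + co * y
        rc <- rot[, i]
        rot[, i] <- co * rc + si * rot[, j]
        rot[, j] <- -si * rc + co * rot[, j]
      }
    }
    new_crit <- varimax_criterion(W, kaiser_normalize = FALSE)
    if (new_crit - crit <= tol * max(crit, .Machine$double.eps)) {
      crit <- new_crit
      converged <- TRUE
      break
    }
    crit <- new_crit
  }
  if (!converged)
    warning("varimax rotation did not converge in ", max_iter, " sweeps")
  out <- if (kaiser_normalize) W * h else W
  dimnames(out) <- dimnames(L)
  res <- flip_signs(out, rotation = rot)
  list(loadings = res$L, rotation = res$rot, iterations = iter,
       converged = converged,
       criterion = varimax_criterion(res$L, kaiser_normalize))
}

# Flip each column so its largest-magnitude entry is positive.
flip_signs <- function(L, rotation = NULL) {
  s <- apply(L, 2, function(col) {
    v <- col[which.max(abs(col))]
    if (v < 0) -1 else 1
  })
  L <- sweep(L, 2, s, `*`)
  if (is.null(rotation)) return(L)
  list(L = L, rot = sweep(rotation, 2, s, `*`))
}

#' Assign items to components
#'
#' Each item goes to the component of its maximum absolute rotated
#' loading, provided that loading reaches `loading_threshold`
#' (default 0.36); otherwise the item is unassigned.  Ties within 1e-9
#' break toward the lower component index.  Components are reported in
#' descending variance-share order and relabelled `C1..Ck`.
#'
#' @param solution a rotated `spa_factor_solution`.
#' @param loading_threshold minimum absolute loading (default 0.36).
#' @return object of class `spa_assignment`: `assignment` data.frame
#'   (`item`, `component`, `loading`), `unassigned`,
#'   `loading_threshold`, `components` (labels in order),
#'   `component_items` (list of item vectors per component label).
#' @export
assign_items <- function(solution, loading_threshold = 0.36) {
  stopifnot(inherits(solution, "spa_factor_solution"))
  L <- solution$loadings
  ord <- order(solution$variance_shares, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  labels <- paste0("C", seq_len(ncol(L)))
  colnames(L) <- labels

  items <- rownames(L)
  pick <- integer(nrow(L)); load <- numeric(nrow(L))
  for (i in seq_len(nrow(L))) {
    a <- abs(L[i, ])
    best <- which(a >= max(a) - 1e-9)[1]   # tie toward lower index
    pick[i] <- best
    load[i] <- L[i, best]
  }
  assigned <- abs(load) >= loading_threshold
  assignment <- data.frame(item = items[assigned],
                           component = labels[pick[assigned]],
                           loading = load[assigned],
                           stringsAsFactors = FALSE)
  component_items <- lapply(labels, function(cl)
    assignment$item[assignment$component == cl])
  names(component_items) <- labels
  structure(list(assignment = assignment,
                 unassigned = items[!assigned],
                 loading_threshold = loading_threshold,
                 components = labels,
                 component_items = component_items,
                 loadings = L,
                 variance_shares = sort(solution$variance_shares,
                                        decreasing = TRUE)),
            class = "spa_assignment")
}

#' @export
print.spa_assignment <- function(x, ...) {
  sizes <- vapply(x$component_items, length, 1L)
  cat("Item assignment (|loading| >=", x$loading_threshold, "):",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  if (length(x$unassigned))
    cat("  unassigned:", paste(x$unassigned, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a factor solution and assignment
#'
#' Writes the solution (eigenvalues, rotated loadings, variance shares,
#' assignment map) as JSON and the loading table as TSV.
#'
#' @param solution a `spa_factor_solution`.
#' @param assignment a `spa_assignment`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @param factorability optional list from [kmo_index()] /
#'   [bartlett_sphericity()] to embed.
#' @return `json_path`, invisibly.
#' @export
write_factor_report <- function(solution, assignment, json_path = NULL,
                                tsv_path = NULL, factorability = NULL) {
  if (!is.null(json_path)) {
    amap <- stats::setNames(as.list(assignment$assignment$component),
                            assignment$assignment$item)
    jsonlite::write_json(
      list(eigenvalues = solution$eigenvalues,
           n_components = solution$n_components,
           variance_shares = assignment$variance_shares,
           loading_threshold = assignment$loading_threshold,
           items = rownames(assignment$loadings),
           loadings = apply(assignment$loadings, 1, as.numeric,
                            simplify = FALSE),
           assignment = amap,
           unassigned = assignment$unassigned,
           factorability = factorability),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    tab <- data.frame(item = rownames(assignment$loadings),
                      round(assignment$loadings, 4),
                      check.names = FALSE)
    utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(json_path)
}
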