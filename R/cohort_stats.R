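# Group-comparison statistics for lesion cohorts: multivariate permutation
# tests on mean vectors and variance-covariance matrices, Euclidean distance
# profiles with Mann-Whitney comparison, and Pearson correlation.

.check_groups <- function(X, labels) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("feature matrix contains missing values")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (any(table(labels) == 0)) stop("both groups must be non-empty")
  list(X = X, labels = labels)
}

# permutation engine shared by the two multivariate tests; the p-value uses
# the add-one correction so that p is in (0, 1] and never exactly zero
.perm_test <- function(X, labels, stat_fun, n_perm, seed, exhaustive = FALSE) {
  obs <- stat_fun(X, labels)
  n <- length(labels)
  g1 <- levels(labels)[1]
  n1 <- sum(labels == g1)
  if (exhaustive) {
    combs <- utils::combn(n, n1)
    null <- apply(combs, 2, function(ix) {
      lab <- factor(ifelse(seq_len(n) %in% ix, g1, levels(labels)[2]),
                    levels = levels(labels))
      stat_fun(X, lab)
    })
    # the observed split is one of the enumerated ones: exact p
    p <- mean(null >= obs - 1e-12 * abs(obs))
    return(structure(list(statistic = obs, p_value = p,
                          n_permutations = ncol(combs), seed = NA_integer_,
                          exhaustive = TRUE, null = null),
                     class = "perm_test"))
  }
  null <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_fun(X, sample(labels))
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs - 1e-12 * abs(obs))) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 exhaustive = FALSE, null = null),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: statistic = %.5g, p = %.4g (%s%d permutations)\n",
              x$statistic, x$p_value, if (x$exhaustive) "exhaustive, " else "",
              x$n_permutations))
  invisible(x)
}

#' Multivariate permutation test on group mean vectors
#'
#' Two-sample nonparametric test of equality of the multivariate means. The
#' statistic is the squared Euclidean norm of the difference between the two
#' group mean vectors; its null distribution is built by permuting group
#' labels. The p-value uses the add-one correction
#' `p = (1 + #(null >= obs)) / (1 + n_perm)`.
#'
#' @param X Numeric matrix, rows = lesions, columns = features (e.g. the five
#'   composition differences, or the seven absorption differences).
#' @param labels Two-level factor (e.g. malignant / benign).
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed Integer seed (results are reproducible when given).
#' @param exhaustive Enumerate all label splits instead of sampling (exact
#'   test; feasible for small n).
#' @return A `perm_test` object: `statistic`, `p_value`, `n_permutations`,
#'   `seed`, `null`.
#' @export
permutation_mean_test <- function(X, labels, n_perm = 9999, seed = NULL,
                                  exhaustive = FALSE) {
  g <- .check_groups(X, labels)
  if (!exhaustive && n_perm < 99) stop("n_perm must be >= 99")
  stat <- function(X, lab) {
    d <- colMeans(X[lab == levels(lab)[1], , drop = FALSE]) -
         colMeans(X[lab == levels(lab)[2], , drop = FALSE])
    sum(d^2)
  }
  .perm_test(g$X, g$labels, stat, n_perm, seed, exhaustive)
}

#' Permutation (Mantel-type) test on variance-covariance matrices
#'
#' Compares the two group variance-covariance matrices with a label
#' permutation test. The statistic is the Frobenius norm of the difference
#' between the two sample covariance matrices.
#'
#' @inheritParams permutation_mean_test
#' @return A `perm_test` object.
#' @export
covariance_permutation_test <- function(X, labels, n_perm = 9999, seed = NULL,
                                        exhaustive = FALSE) {
  g <- .check_groups(X, labels)
  if (!exhaustive && n_perm < 99) stop("n_perm must be >= 99")
  tab <- table(g$labels)
  if (any(tab <= ncol(g$X)))
    warning("a group has no more observations than features; covariance estimates are unstable")
  stat <- function(X, lab) {
    S1 <- cov(X[lab == levels(lab)[1], , drop = FALSE])
    S2 <- cov(X[lab == levels(lab)[2], , drop = FALSE])
    sqrt(sum((S1 - S2)^2))
  }
  .perm_test(g$X, g$labels, stat, n_perm, seed, exhaustive)
}

#' Euclidean distance of each lesion to its own group mean
#'
#' Straight-line distances in feature space (R^5 for composition, R^7 for
#' absorption) between each lesion vector and the mean vector of its group.
#' Features should be on comparable scales; a warning is raised when the
#' ratio of the largest to smallest column IQR exceeds 10.
#'
#' @inheritParams permutation_mean_test
#' @return Data frame with `label` and `distance` per lesion.
#' @export
distance_profile <- function(X, labels) {
  g <- .check_groups(X, labels)
  iqrs <- apply(g$X, 2, function(x) diff(quantile(x, c(0.25, 0.75))))
  pos <- iqrs[iqrs > 0]
  if (length(pos) && max(pos) / min(pos) > 10)
    warning("feature interquartile ranges differ by more than a factor 10; consider rescaling")
  d <- numeric(nrow(g$X))
  for (lv in levels(g$labels)) {
    sel <- g$labels == lv
    mu <- colMeans(g$X[sel, , drop = FALSE])
    d[sel] <- sqrt(rowSums(sweep(g$X[sel, , drop = FALSE], 2, mu)^2))
  }
  data.frame(label = g$labels, distance = d)
}

#' Mann-Whitney two-sample test
#'
#' Rank-sum comparison of two samples. The U statistic counts pairs
#' `x_i > y_j`, scoring 0.5 for ties. The p-value is exact (full enumeration
#' of label splits, tie-safe) when the combined sample size is at most 20,
#' and uses the normal approximation with tie correction and continuity
#' correction otherwise.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact Force (`TRUE`)/suppress (`FALSE`) exact enumeration; default
#'   decides by combined size <= 20.
#' @return List of class `mw_test`: `U`, `U_prime` (`= n_x n_y - U`),
#'   `p_value` (two-sided), `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p_value  # exactly 1/3
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  ustat <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
  }
  U <- ustat(x, y)
  if (is.null(exact)) exact <- (nx + ny) <= 20
  if (exact) {
    z <- c(x, y)
    combs <- utils::combn(nx + ny, nx)
    null <- apply(combs, 2, function(ix) ustat(z[ix], z[-ix]))
    mu <- nx * ny / 2
    # two-sided: double the smaller tail, capped at 1
    p <- min(1, 2 * min(mean(null <= U + 1e-9), mean(null >= U - 1e-9)))
    method <- "exact enumeration"
  } else {
    z <- c(x, y)
    ties <- table(z)
    n <- nx + ny
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    zval <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(zval))
    method <- "normal approximation with tie and continuity correction"
  }
  structure(list(U = U, U_prime = nx * ny - U, p_value = min(p, 1),
                 n_x = nx, n_y = ny, method = method),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %.1f (n = %d + %d), two-sided p = %.4g [%s]\n",
              x$U, x$n_x, x$n_y, x$p_value, x$method))
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation between two variables (e.g. collagen and lipid
#' content), with the two-sided t-test p-value.
#'
#' @param x,y Numeric vectors, length >= 3, non-degenerate.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired samples of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
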