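#' Permutation test for a difference in group means
#'
#' The statistic is mean(group A) minus mean(group B).  Group labels
#' are permuted uniformly at random \code{B} times and the two-sided
#' p-value uses the add-one correction
#' \eqn{p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\}) / (B + 1)}; ties count
#' as exceedances, so constant data give p = 1.
#'
#' @param values numeric vector.
#' @param labels two-level vector (factor, character or logical) of the
#'   same length; the first level is group A.
#' @param B number of permutations (>= 1).
#' @param seed integer seed.
#' @return a \code{perm_test}: \code{statistic}, \code{p}, \code{B},
#'   \code{seed}.
#' @export
permutation_test <- function(values, labels, B = 10000, seed = NULL) {
  if (B < 1) stop("B must be at least 1")
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must have exactly two levels")
  if (any(table(labels) == 0)) stop("both groups must be nonempty")
  if (length(values) != length(labels))
    stop("values and labels differ in length")
  a <- labels == levels(labels)[1]
  n <- length(values); na <- sum(a)
  obs <- mean(values[a]) - mean(values[!a])
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, na)
      tb <- mean(values[idx]) - (sum(values) - sum(values[idx])) / (n - na)
      if (abs(tb) >= abs(obs) - 1e-12) exceed <- exceed + 1L
    }
    structure(list(statistic = obs, p = (1 + exceed) / (B + 1),
                   B = B, seed = seed),
              class = "perm_test")
  })
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test: difference of means = %.4g, p = %.4g (B = %d)\n",
    x$statistic, x$p, x$B))
  invisible(x)
}

#' Cramer's V for a contingency table
#'
#' \deqn{V = \sqrt{\chi^2 / (n\,(\min(r, c) - 1))}} with the Pearson
#' chi-squared statistic, no continuity correction.  For 2 x 2 tables V
#' equals the absolute phi coefficient.
#'
#' @param table matrix of nonnegative integer counts, at least 2 x 2.
#' @return V in [0, 1].
#' @export
cramers_v <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal row or column")
  n <- sum(table)
  if (n == 0) stop("empty table")
  chi2 <- suppressWarnings(
    stats::chisq.test(table, correct = FALSE)$statistic)
  as.numeric(sqrt(chi2 / (n * (min(dim(table)) - 1))))
}
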