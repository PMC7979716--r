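#' @title Cohort statistics layer
#' @description
#' The rank-based tests used for all density, location, proliferation and
#' sTIL comparisons, with exact enumeration p-values at small sample
#' sizes and standard large-sample approximations otherwise; t-based
#' paired-difference confidence intervals; and univariate logistic odds
#' ratios for pathological complete response. All tests are two-sided.
#' @name cohort-stats
NULL

test_result <- function(method, statistic, p_value, n, exact_flag,
                        note = NA_character_) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         n = n, exact_flag = exact_flag, note = note),
    class = "ngi_test_result"
  )
}

#' @export
print.ngi_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = "+"),
              if (isTRUE(x$exact_flag)) ", exact" else ""))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# all permutations of 1..n as an n! x n matrix (n <= 8)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation test
#'
#' Rho from midranks. Two-sided p by full permutation enumeration when
#' n <= 8 and neither vector has ties, else the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df. Missing pairs are
#' dropped.
#'
#' @param x,y numeric vectors of equal length (n >= 3 after NA removal).
#' @return an `ngi_test_result`; `statistic` is rho.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(test_result("spearman", NA_real_, NA_real_, n, FALSE,
                       note = "constant input: rho undefined"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 8 && !ties) {
    perms <- all_permutations(n)
    # rho for each permutation of the y-ranks against fixed x-ranks
    rhos <- as.numeric(stats::cor(rx, t(matrix(ry[perms], nrow(perms), n))))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(test_result("spearman", rho, p, n, TRUE))
  }
  tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
  p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
  test_result("spearman", rho, p, n, FALSE)
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences `y - x`; zero differences are dropped. Signed-rank
#' statistic V = sum of midranks of positive differences. Exact two-sided
#' p by sign-flip enumeration when the effective n <= 12 (valid under
#' ties, conditioning on the observed ranks), else normal approximation
#' with continuity correction and the tie-aware variance.
#'
#' @param x,y paired numeric vectors.
#' @return an `ngi_test_result`; `statistic` is V; `n` the effective
#'   number of non-zero differences.
#' @export
paired_wilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  d <- y[ok] - x[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(test_result("paired_wilcoxon", NA_real_, NA_real_, 0L, FALSE,
                       note = "all differences zero: test degenerate"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= 12) {
    signs <- matrix(bitwAnd(rep(0:(2^n - 1), each = n),
                            bitwShiftL(1L, 0:(n - 1))) > 0, ncol = n,
                    byrow = TRUE)
    w <- as.numeric(signs %*% r)
    p <- mean(abs(w - mu) >= abs(v - mu) - 1e-12)
    return(test_result("paired_wilcoxon", v, p, n, TRUE))
  }
  # tie-aware variance: sum of squared ranks / 4
  sigma <- sqrt(sum(r^2) / 4)
  z <- (abs(v - mu) - 0.5) / sigma
  p <- min(1, 2 * stats::pnorm(-z))
  test_result("paired_wilcoxon", v, p, n, FALSE)
}

#' Rank test across groups (Mann-Whitney / Kruskal-Wallis)
#'
#' Two groups: Mann-Whitney U, exact by enumeration of all labellings when
#' n1 + n2 <= 12, else normal approximation with the tie-corrected
#' variance (no continuity correction, making the two-group case
#' algebraically identical to Kruskal-Wallis). More than two groups:
#' Kruskal-Wallis chi-square approximation (via [stats::kruskal.test()]).
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return an `ngi_test_result`; `statistic` is U (2 groups) or the KW
#'   chi-square; `n` the group sizes.
#' @export
rank_group_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("empty group")
  if (length(groups) > 2) {
    kw <- stats::kruskal.test(groups)
    return(test_result("kruskal_wallis",
                       unname(kw$statistic), unname(kw$p.value),
                       sizes, FALSE))
  }
  x <- groups[[1]]; y <- groups[[2]]
  n1 <- sizes[1]; n2 <- sizes[2]; n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= 12) {
    labelings <- utils::combn(n, n1)
    usum <- colSums(matrix(r[labelings], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(usum - mu) >= abs(u - mu) - 1e-12)
    return(test_result("mann_whitney", u, p, sizes, TRUE))
  }
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0)
    return(test_result("mann_whitney", u, NA_real_, sizes, FALSE,
                       note = "all values tied"))
  z <- (u - mu) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result("mann_whitney", u, p, sizes, FALSE)
}

#' Paired mean difference with t-interval
#'
#' Mean of `y - x` with a t-distribution confidence interval, paired with
#' the nonparametric p-value from [paired_wilcoxon()] (mean differences
#' with rank-test p-values, as cohort TIL-shift tables are reported).
#'
#' @param x,y paired numeric vectors (missing pairs dropped, >= 2 needed).
#' @param level confidence level (default 0.95).
#' @return object of class `paired_difference`: `n_pairs`,
#'   `mean_difference`, `ci_low`, `ci_high`, `p_value`, `level`.
#' @export
paired_mean_difference_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), level > 0, level < 1)
  ok <- !is.na(x) & !is.na(y)
  d <- y[ok] - x[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  m <- mean(d)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(d) / sqrt(n)
  p <- paired_wilcoxon(x[ok], y[ok])$p_value
  structure(
    list(n_pairs = n, mean_difference = m, ci_low = m - half,
         ci_high = m + half, p_value = p, level = level),
    class = "paired_difference"
  )
}

#' @export
print.paired_difference <- function(x, ...) {
  cat(sprintf("paired difference: n = %d, mean %+.3g [%0.3g, %0.3g], p = %.4g\n",
              x$n_pairs, x$mean_difference, x$ci_low, x$ci_high,
              x$p_value))
  invisible(x)
}

#' Univariate logistic odds ratio for pCR
#'
#' Maximum-likelihood univariate logistic regression of a binary response
#' on one predictor; the odds ratio is reported per `unit_scale` units of
#' the predictor (e.g. 10 sTIL points, or 1000 cells/mm^2 of density)
#' with a Wald confidence interval on the same scale.
#'
#' @param outcome logical (or 0/1) response vector with both classes.
#' @param predictor numeric, non-constant.
#' @param unit_scale predictor units per reported OR (default 1).
#' @param level confidence level.
#' @return object of class `odds_ratio`: `or_per_unit`, `ci_low`,
#'   `ci_high`, `unit_scale`, `n`, `converged` (FALSE under separation or
#'   non-convergence).
#' @export
logistic_or_pcr <- function(outcome, predictor, unit_scale = 1,
                            level = 0.95) {
  ok <- !is.na(outcome) & !is.na(predictor)
  outcome <- as.logical(outcome)[ok]
  predictor <- predictor[ok]
  if (length(unique(outcome)) < 2) stop("outcome has a single class")
  if (stats::sd(predictor) == 0) stop("constant predictor")
  fit <- suppressWarnings(
    stats::glm(outcome ~ predictor, family = stats::binomial()))
  beta <- stats::coef(fit)[["predictor"]]
  se <- sqrt(stats::vcov(fit)["predictor", "predictor"])
  # separation shows as exploding |beta| and SE
  converged <- isTRUE(fit$converged) && is.finite(se) && se < 100 &&
    abs(beta * unit_scale) < 50
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(or_per_unit = exp(beta * unit_scale),
         ci_low = exp((beta - zq * se) * unit_scale),
         ci_high = exp((beta + zq * se) * unit_scale),
         unit_scale = unit_scale, n = length(outcome),
         converged = converged),
    class = "odds_ratio"
  )
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf("OR per %g units: %.3g [%0.3g, %0.3g] (n = %d%s)\n",
              x$unit_scale, x$or_per_unit, x$ci_low, x$ci_high, x$n,
              if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}
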