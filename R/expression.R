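#' Housekeeping genes of the expression panel
#'
#' The five reference genes used to normalise the nCounter-style count
#' matrix.
#'
#' @return character vector.
#' @export
housekeeping_genes <- function()
  c("ACTB", "MRPL19", "PSMC4", "RPLP0", "SF3A1")

#' Log2 + housekeeping normalisation of a count matrix
#'
#' Counts are log2(count + 1) transformed (pseudo-count so zeros stay
#' finite), then each sample is shifted so its housekeeping mean equals
#' the grand housekeeping mean: offset_s = grand_mean(HK log2) -
#' sample_mean_s(HK log2), added to every gene of sample s.
#'
#' @param raw_counts gene x sample numeric matrix with gene rownames.
#' @param housekeeping gene names used as the reference set (all must be
#'   present).
#' @return object of class `expression_matrix`: list with `log2` (the
#'   normalised gene x sample matrix), `housekeeping`, `offsets` (per
#'   sample).
#' @export
normalize_expression <- function(raw_counts,
                                 housekeeping = housekeeping_genes()) {
  stopifnot(is.matrix(raw_counts), !is.null(rownames(raw_counts)))
  missing <- setdiff(housekeeping, rownames(raw_counts))
  if (length(missing) > 0)
    stop("missing housekeeping gene(s): ", paste(missing, collapse = ", "))
  if (any(raw_counts < 0)) stop("negative counts")
  lg <- log2(raw_counts + 1)
  hk_means <- colMeans(lg[housekeeping, , drop = FALSE])
  grand <- mean(hk_means)
  offsets <- grand - hk_means
  out <- sweep(lg, 2L, offsets, `+`)
  structure(
    list(log2 = out, housekeeping = housekeeping, offsets = offsets),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (log2, HK-normalised)\n",
              nrow(x$log2), ncol(x$log2)))
  invisible(x)
}

# per-gene least-squares slope of expression on z plus its SE, vectorised;
# x: genes x n, z: length n (or n x B matrix of centred regressors)
gene_slopes <- function(xc, zc, sxx, ssy, n) {
  slope <- (xc %*% zc) / sxx                       # genes x B
  rss <- pmax(ssy - slope^2 * sxx, 0)
  se <- sqrt(rss / (n - 2)) / sqrt(sxx)
  list(slope = slope, se = se)
}

# Tusher-style fudge factor: candidate s0 = percentiles of se; pick the
# one minimising the coefficient of variation of window-wise MADs of d
choose_s0 <- function(slope, se) {
  cands <- unique(stats::quantile(se, seq(0, 1, by = 0.05), names = FALSE))
  qs <- stats::quantile(se, seq(0, 1, by = 0.01), names = FALSE)
  bins <- cut(se, breaks = unique(qs), include.lowest = TRUE)
  cv <- vapply(cands, function(s0) {
    d <- slope / (se + s0)
    mads <- tapply(d, bins, stats::mad)
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2 || mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  cands[which.min(cv)]
}

#' Quantitative SAM for gene-sTIL association
#'
#' Significance analysis with a continuous response: for each gene,
#' d_i = r_i / (s_i + s0) where r_i is the least-squares slope of
#' (log2, normalised) expression on the sTIL score, s_i its standard
#' error, and s0 a fudge factor chosen over the percentiles of the s_i to
#' minimise the coefficient of variation of d across the range of s.
#' The null distribution comes from seeded permutations of the sTIL
#' vector; the q-value of a gene is the median number of null
#' exceedances of |d| across permutations divided by the observed number
#' of genes at or above that |d| (capped at 1 and made monotone
#' non-increasing in |d|). The significant set is q < `fdr_threshold`.
#'
#' @param expr an [normalize_expression()] result, or a gene x sample
#'   matrix of normalised log2 values with gene rownames.
#' @param stils numeric sTIL score per sample (same order as columns).
#' @param fdr_threshold FDR cut (default 0.01, i.e. < 1%).
#' @param n_permutations number of permutations (>= 50; default 1000).
#' @param seed integer seed for the permutations.
#' @return object of class `sam_result`: data frame `genes` (gene, slope,
#'   se, d, q, significant) ordered by decreasing |d|, plus `s0`,
#'   `n_permutations`, `fdr_threshold`, `n_significant`.
#' @export
sam_til_association <- function(expr, stils, fdr_threshold = 0.01,
                                n_permutations = 1000, seed = 1) {
  if (inherits(expr, "expression_matrix")) expr <- expr$log2
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  n <- ncol(expr)
  if (length(stils) != n) stop("sample counts differ")
  if (n_permutations < 50) stop("n_permutations must be >= 50")
  if (stats::sd(stils) == 0) stop("constant sTILs")
  zc <- stils - mean(stils)
  sxx <- sum(zc^2)
  xc <- expr - rowMeans(expr)
  ssy <- rowSums(xc^2)
  obs <- gene_slopes(xc, zc, sxx, ssy, n)
  slope <- as.numeric(obs$slope)
  se <- as.numeric(obs$se)
  s0 <- choose_s0(slope, se)
  safe_d <- function(num, den) ifelse(den > 0, num / den, 0)
  d <- safe_d(slope, se + s0)
  # permutation null (sxx is permutation-invariant)
  perm_z <- local({
    set.seed(seed)
    vapply(seq_len(n_permutations), function(b) sample(zc), numeric(n))
  })
  pm <- gene_slopes(xc, perm_z, sxx, ssy, n)
  d_null <- safe_d(pm$slope, pm$se + s0)           # genes x B
  abs_null <- abs(d_null)
  abs_d <- abs(d)
  ord <- order(abs_d, decreasing = TRUE)
  thr <- abs_d[ord]
  # per permutation, count of null |d| >= threshold, for every threshold
  exceed <- apply(abs_null, 2, function(col)
    length(col) - findInterval(thr - 1e-12, sort(col)))
  false_calls <- apply(exceed, 1, stats::median)
  called <- seq_along(thr)
  q_sorted <- pmin(1, false_calls / called)
  q_sorted <- cummax(q_sorted)  # monotone non-increasing in |d|
  q <- numeric(length(d))
  q[ord] <- q_sorted
  genes <- data.frame(
    gene = rownames(expr), slope = slope, se = se, d = d, q = q,
    significant = q < fdr_threshold, row.names = NULL
  )[ord, ]
  rownames(genes) <- NULL
  structure(
    list(genes = genes, s0 = s0, n_permutations = n_permutations,
         fdr_threshold = fdr_threshold,
         n_significant = sum(genes$significant)),
    class = "sam_result"
  )
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf(
    "quantitative SAM: %d genes, s0 = %.4g, %d permutations, %d significant at FDR < %g\n",
    nrow(x$genes), x$s0, x$n_permutations, x$n_significant,
    x$fdr_threshold))
  if (x$n_significant > 0)
    print(utils::head(x$genes[x$genes$significant, ], 10))
  invisible(x)
}
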