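# Internal rank-sum machinery shared by marker ranking and differential
# expression. The large-sample path is a two-sided Wilcoxon rank-sum with
# midranks, tie-corrected variance and continuity correction; the
# small-sample path (n1 + n2 <= 20) enumerates every rank assignment.

# log2 fold change of pseudocounted de-logged group means (group1 vs group2)
.log2fc <- function(x, idx1, idx2) {
  m1 <- rowMeans(expm1(x[, idx1, drop = FALSE]))
  m2 <- rowMeans(expm1(x[, idx2, drop = FALSE]))
  log2((m1 + 1) / (m2 + 1))
}

# vectorized normal-approximation p-values, one gene per row of x
.ranksum_p_approx <- function(x, idx1, idx2, correct = TRUE) {
  n1 <- length(idx1); n2 <- length(idx2); N <- n1 + n2
  xs <- x[, c(idx1, idx2), drop = FALSE]
  r <- matrixStats::rowRanks(xs, ties.method = "average")
  W <- rowSums(r[, seq_len(n1), drop = FALSE])
  mu <- n1 * (N + 1) / 2
  tie_term <- apply(r, 1, function(rr) {
    t <- rle(sort(rr))$lengths
    sum(t^3 - t)
  })
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  cc <- if (correct) 0.5 else 0
  z <- pmax(abs(W - mu) - cc, 0) / sqrt(pmax(sig2, 0))
  p <- 2 * stats::pnorm(-z)
  p[sig2 <= 0] <- 1            # every value tied
  pmin(p, 1)
}

# exact two-sided p by enumeration of all C(N, n1) rank assignments
.ranksum_p_exact <- function(v1, v2) {
  n1 <- length(v1); N <- n1 + length(v2)
  r <- rank(c(v1, v2))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  combos <- utils::combn(N, n1)
  Wall <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
}

# per-gene table of effect sizes, detection fractions and approximate p
.ranksum_table <- function(x, idx1, idx2) {
  data.frame(gene = rownames(x),
             log2fc = .log2fc(x, idx1, idx2),
             p_raw = .ranksum_p_approx(x, idx1, idx2),
             pct1 = rowMeans(x[, idx1, drop = FALSE] > 0),
             pct2 = rowMeans(x[, idx2, drop = FALSE] > 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Significance stars for printed p-value thresholds
#'
#' The study's star scheme: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.00001; `"ns"` otherwise.
#'
#' @param p a p-value (vectorized).
#' @return character vector of star labels.
#' @export
p_stars <- function(p) {
  ifelse(p < 1e-5, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}
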