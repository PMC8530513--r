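# Rank-based two-group statistics shared by the dependency and enrichment
# modules: Mann-Whitney U with midrank tie handling, the matching
# rank-biserial effect size, and a vectorized form for genome-wide scans.

#' Rank-biserial correlation for a two-group comparison
#'
#' `rb = 2U / (n1 n2) - 1`, where `U` counts pairs in which the first group
#' exceeds the second (ties count one half). `-1` when every first-group
#' value lies below every second-group value, `+1` for the reverse, ~0 for
#' interleaved distributions.
#'
#' @param x First-group values (e.g. mutant samples).
#' @param y Second-group values (e.g. wild-type samples).
#' @return A number in \[-1, 1\].
#' @export
rank_biserial <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  2 * u / (n1 * n2) - 1
}

#' Vectorized two-sided Mann-Whitney U scan
#'
#' Tests every column of `x` for a location difference between the two
#' groups in `labels`, using the normal approximation with midrank tie
#' correction and continuity correction (matching
#' `wilcox.test(exact = FALSE, correct = TRUE)`), which is accurate at the
#' cohort sizes of genome-wide scans. Missing values are masked per column;
#' columns with fewer than `min_per_group` observations in either group are
#' returned as `NA`.
#'
#' @param x Numeric matrix, samples x features.
#' @param labels Logical vector over samples; `TRUE` marks the first group.
#' @param min_per_group Minimum group size per column (default 2).
#' @return Data frame with one row per column: `feature`, `n1`, `n2`, `U`
#'   (first group), `effect` (rank-biserial), `p` (two-sided).
#' @export
mwu_matrix <- function(x, labels, min_per_group = 2L) {
  x <- as.matrix(x)
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(x))
  feats <- if (is.null(colnames(x))) as.character(seq_len(ncol(x))) else colnames(x)
  res <- matrix(NA_real_, nrow = ncol(x), ncol = 5)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ok <- !is.na(v)
    g <- labels[ok]
    n1 <- sum(g); n2 <- sum(!g)
    if (n1 < min_per_group || n2 < min_per_group) next
    vv <- v[ok]
    r <- rank(vv)
    u <- sum(r[g]) - n1 * (n1 + 1) / 2
    n <- n1 + n2
    tie_term <- if (anyDuplicated(vv)) {
      runs <- rle(sort(vv))$lengths
      sum(runs^3 - runs)
    } else 0
    sigma <- sqrt((n1 * n2 / 12) *
                    ((n + 1) - tie_term / (n * (n - 1))))
    z <- u - n1 * n2 / 2
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (z - sign(z) * 0.5) / sigma
      p <- min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
    }
    res[j, ] <- c(n1, n2, u, 2 * u / (n1 * n2) - 1, p)
  }
  data.frame(feature = feats, n1 = res[, 1], n2 = res[, 2], U = res[, 3],
             effect = res[, 4], p = res[, 5], stringsAsFactors = FALSE)
}
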