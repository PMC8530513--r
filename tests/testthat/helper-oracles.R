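# Independent oracles used across the suite. Each is deliberately naive
# (brute force / closed form) and shares no code with the implementation.

# Non-overlapping left-to-right motif count by explicit character scanning.
oracle_count_motifs <- function(sequence, motif = "TTAGGG") {
  s <- toupper(sequence)
  m <- nchar(motif)
  i <- 1L
  n <- 0L
  while (i + m - 1L <= nchar(s)) {
    if (substr(s, i, i + m - 1L) == motif) {
      n <- n + 1L
      i <- i + m
    } else {
      i <- i + 1L
    }
  }
  n
}

# Phi coefficient with 0.5 pseudocounts in exact integer arithmetic:
# doubling each pseudocounted cell gives integers A = 2mm + 1 etc., and
# Phi = (AD - BC) / sqrt((A+B)(C+D)(A+C)(B+D)) exactly (the factors of 2
# cancel). All intermediate products stay far below 2^53 for the tested
# grid, so the only rounding is the final sqrt and division.
oracle_phi <- function(mm, mu, um, uu, clip = TRUE) {
  a <- 2 * mm + 1; b <- 2 * mu + 1; c <- 2 * um + 1; d <- 2 * uu + 1
  val <- (a * d - b * c) / sqrt((a + b) * (c + d) * (a + c) * (b + d))
  if (clip) val <- pmax(val, 0)
  val
}

# Brute-force mutual-top-k expansion: enumerate all mutual-top-k pairs
# directly from the r^2 matrix, then grow the seed set iteratively.
oracle_codependency <- function(dep, seed_genes, top_k = 5L, iterations = 4L) {
  r2 <- stats::cor(t(dep))^2
  diag(r2) <- -Inf
  genes <- rownames(dep)
  in_top_k <- function(x, y) {
    kth <- sort(r2[x, ], decreasing = TRUE)[top_k]
    r2[x, y] >= kth
  }
  mutual <- matrix(FALSE, length(genes), length(genes),
                   dimnames = list(genes, genes))
  for (x in genes) for (y in genes) {
    if (x != y) mutual[x, y] <- in_top_k(x, y) && in_top_k(y, x)
  }
  current <- seed_genes
  for (i in seq_len(iterations)) {
    # y joins if mutual with any current member
    adds <- setdiff(genes[apply(mutual[, current, drop = FALSE], 1, any)], current)
    if (length(adds) == 0L) break
    current <- c(current, adds)
  }
  current
}

# Hand-applied Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}
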