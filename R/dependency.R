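# Gene-dependency association machinery: Pearson correlation of dependency
# profiles against a telomere-content vector, recursive mutual-top-k
# codependency expansion, mutation-dependency tests (rank-biserial +
# Mann-Whitney U), signed -log10(q) ranking, and Ward clustering of
# codependency submatrices. Dependency matrices are genes x samples; more
# negative scores mean stronger dependence on the gene.

#' Correlate gene dependencies with a sample-level target
#'
#' Pearson correlation per gene, on pairwise-complete samples, with the
#' two-tailed p-value from the exact t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param dep Numeric matrix, genes x samples (missing entries allowed).
#' @param target Named numeric vector over (a superset of) the matrix's
#'   samples, e.g. merged telomere content.
#' @param min_n Minimum pairwise-complete sample count per gene (default 3);
#'   genes below it are reported with `NA` statistics.
#' @return Data frame with columns `gene`, `effect` (Pearson r), `p`, `n`.
#'   Zero-variance genes (or target subsets) yield `NA` with a warning.
#' @export
correlate_dependencies <- function(dep, target, min_n = 3L) {
  dep <- as.matrix(dep)
  common <- intersect(colnames(dep), names(target))
  if (length(common) < min_n) stop("fewer than `min_n` samples shared with the target")
  dep <- dep[, common, drop = FALSE]
  tgt <- target[common]
  res <- lapply(rownames(dep), function(g) {
    v <- dep[g, ]
    ok <- !is.na(v) & !is.na(tgt)
    n <- sum(ok)
    if (n < min_n) {
      return(data.frame(gene = g, effect = NA_real_, p = NA_real_, n = n))
    }
    if (stats::sd(v[ok]) == 0 || stats::sd(tgt[ok]) == 0) {
      warning("zero variance for gene ", g, "; correlation undefined")
      return(data.frame(gene = g, effect = NA_real_, p = NA_real_, n = n))
    }
    r <- stats::cor(v[ok], tgt[ok])
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    data.frame(gene = g, effect = r, p = p, n = n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# squared pairwise correlation with self excluded (-Inf on the diagonal)
.r2_matrix <- function(dep) {
  r2 <- stats::cor(t(dep), use = "pairwise.complete.obs")^2
  diag(r2) <- -Inf
  r2[is.na(r2)] <- -Inf
  r2
}

# genes whose r2 against `gene` ranks in the top k (ties at the k-th value
# are all admitted)
.top_k_set <- function(r2, gene, k) {
  v <- r2[gene, ]
  kth <- sort(v, decreasing = TRUE)[min(k, sum(is.finite(v)))]
  names(v)[v >= kth & is.finite(v)]
}

#' Recursive mutual-top-k codependency expansion
#'
#' Starting from a seed gene set, a candidate gene y joins the set when for
#' some current member x the squared Pearson correlation r2(x, y) ranks
#' among the top `top_k` of x against all other genes *and* among the top
#' `top_k` of y against all other genes (rankings always taken over the full
#' gene universe; self excluded; ties at the k-th rank all admitted). The
#' rule is applied `iterations` times; the set grows monotonically.
#'
#' @param dep Numeric matrix, genes x samples.
#' @param seed_genes Character vector of starting genes (e.g. the CST
#'   complex members); all must be rows of `dep`.
#' @param top_k Rank cutoff (default 5).
#' @param iterations Number of expansion rounds (default 4).
#' @return Character vector: the expanded gene set (seed order first, then
#'   joiners in discovery order).
#' @export
codependency_expand <- function(dep, seed_genes, top_k = 5L, iterations = 4L) {
  dep <- as.matrix(dep)
  missing <- setdiff(seed_genes, rownames(dep))
  if (length(missing) > 0L) {
    stop("seed gene(s) absent from dependency matrix: ",
         paste(missing, collapse = ", "))
  }
  if (iterations == 0L) return(seed_genes)
  r2 <- .r2_matrix(dep)
  top <- lapply(rownames(dep), function(g) .top_k_set(r2, g, top_k))
  names(top) <- rownames(dep)
  current <- seed_genes
  for (iter in seq_len(iterations)) {
    candidates <- setdiff(unique(unlist(top[current])), current)
    joins <- candidates[vapply(candidates, function(y) {
      any(current %in% top[[y]]) && any(vapply(current, function(x) y %in% top[[x]], logical(1)))
    }, logical(1))]
    if (length(joins) == 0L) break
    current <- c(current, joins)
  }
  current
}

#' Mutation-dependency association for one gene pair
#'
#' Compares dependency scores between mutant and wild-type samples with a
#' two-sided Mann-Whitney U test (midrank ties) and the rank-biserial
#' effect size (negative = mutants more dependent). Genes with fewer than
#' `min_mutants` mutants, or with no wild-type samples, are excluded
#' (`NA` statistics, `excluded = TRUE`).
#'
#' @param dep_row Numeric vector of dependency scores over samples.
#' @param mut_row Binary/logical vector over the same samples; `TRUE`/1 =
#'   mutant.
#' @param min_mutants Minimum mutant count (default 5).
#' @return One-row data frame: `effect` (rank-biserial), `p`, `n`,
#'   `n_mutant`, `excluded`.
#' @export
mutation_association <- function(dep_row, mut_row, min_mutants = 5L) {
  ok <- !is.na(dep_row) & !is.na(mut_row)
  dep_row <- dep_row[ok]
  mut <- as.logical(mut_row[ok])
  n_mut <- sum(mut)
  if (n_mut < min_mutants || n_mut == length(mut)) {
    return(data.frame(effect = NA_real_, p = NA_real_, n = length(mut),
                      n_mutant = n_mut, excluded = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(dep_row[mut], dep_row[!mut],
                                            alternative = "two.sided"))
  data.frame(effect = rank_biserial(dep_row[mut], dep_row[!mut]),
             p = wt$p.value, n = length(mut), n_mutant = n_mut,
             excluded = FALSE)
}

#' Genome-wide mutation-dependency scan
#'
#' Tests every row of `dep` against one binary mutation profile using the
#' vectorized normal-approximation Mann-Whitney machinery
#' ([mwu_matrix()]); suitable for thousands of genes.
#'
#' @param dep Numeric matrix, genes x samples.
#' @param mut_row Binary/logical mutation profile over the same samples.
#' @param min_mutants Minimum mutant count (default 5); fewer mutants
#'   (after per-gene missing-value masking) yields `NA` statistics.
#' @return Data frame with columns `gene`, `effect` (rank-biserial,
#'   mutant-vs-wild-type), `p`, `n`, `n_mutant`.
#' @export
mutation_associations <- function(dep, mut_row, min_mutants = 5L) {
  dep <- as.matrix(dep)
  mut <- as.logical(mut_row)
  stopifnot(length(mut) == ncol(dep))
  res <- mwu_matrix(t(dep), mut, min_per_group = 1L)
  too_few <- !is.na(res$n1) & res$n1 < min_mutants
  res$effect[too_few] <- NA_real_
  res$p[too_few] <- NA_real_
  data.frame(gene = rownames(dep), effect = res$effect, p = res$p,
             n = res$n1 + res$n2, n_mutant = res$n1,
             stringsAsFactors = FALSE)
}

#' Signed -log10 FDR ranking
#'
#' Benjamini-Hochberg adjustment over the tested family, then
#' `signed_q = sign(effect) * (-log10 q)`, the quantity used to rank
#' associations by both strength and direction. Rows with missing p-values
#' are carried through with `NA` and excluded from the adjustment family.
#'
#' @param results Data frame with columns `effect` and `p`.
#' @return The input with added columns `q` and `signed_q`, ordered by
#'   decreasing `|signed_q|`.
#' @export
signed_q <- function(results) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) stop("empty result family")
  q <- rep(NA_real_, nrow(results))
  ok <- !is.na(results$p)
  q[ok] <- stats::p.adjust(results$p[ok], method = "BH")
  results$q <- q
  results$signed_q <- sign(results$effect) * (-log10(q))
  results[order(-abs(results$signed_q)), , drop = FALSE]
}

#' Cluster a codependency submatrix
#'
#' Pairwise Pearson correlations on pairwise-complete samples for the given
#' genes, hierarchically clustered with Ward linkage on `1 - r` distances.
#' Undefined correlations are imputed as 0 with a warning.
#'
#' @param dep Numeric matrix, genes x samples.
#' @param genes Character vector of at least 3 genes to cluster.
#' @return List with `correlation` (genes x genes matrix), `hclust` (the
#'   dendrogram object), and `leaf_order` (gene names in dendrogram order).
#' @export
cluster_codependency <- function(dep, genes) {
  if (length(genes) < 3L) stop("need at least 3 genes to cluster")
  dep <- as.matrix(dep)[genes, , drop = FALSE]
  r <- stats::cor(t(dep), use = "pairwise.complete.obs")
  if (anyNA(r)) {
    warning("undefined correlation(s) imputed as 0")
    r[is.na(r)] <- 0
  }
  hc <- stats::hclust(stats::as.dist(1 - r), method = "ward.D2")
  list(correlation = r[hc$order, hc$order], hclust = hc,
       leaf_order = rownames(r)[hc$order])
}

#' Variance and missingness filters for marker feature tables
#'
#' Standard pre-association cleanup for the three marker classes:
#' expression tables are `log2(TPM + 1)` transformed and rows with standard
#' deviation below `sd_min` dropped; exon-inclusion tables drop rows missing
#' in more than `max_missing` samples or with SD below their `sd_min`;
#' methylation tables drop rows with SD below their `sd_min`. Defaults
#' follow common practice for these data types (0.25, 800/0.1, 0.05).
#'
#' @param x Numeric matrix, features x samples.
#' @param type One of `"expression"`, `"exon"`, `"methylation"`.
#' @param sd_min SD threshold; default depends on `type`.
#' @param max_missing Maximum missing sample count (exon tables only;
#'   default 800).
#' @param log_transform Apply `log2(x + 1)` first (expression tables only;
#'   default `TRUE`).
#' @return The filtered (and possibly transformed) matrix.
#' @export
feature_filters <- function(x, type = c("expression", "exon", "methylation"),
                            sd_min = NULL, max_missing = 800L,
                            log_transform = TRUE) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (is.null(sd_min)) {
    sd_min <- switch(type, expression = 0.25, exon = 0.1, methylation = 0.05)
  }
  if (type == "expression" && log_transform) x <- log2(x + 1)
  if (type == "exon") {
    n_missing <- rowSums(is.na(x))
    x <- x[n_missing <= max_missing, , drop = FALSE]
  }
  sds <- apply(x, 1, stats::sd, na.rm = TRUE)
  x[!is.na(sds) & sds >= sd_min, , drop = FALSE]
}
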