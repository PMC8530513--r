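# Cross-dataset harmonization of telomere-content estimates: z-scored log
# transformation per source, k-means batch detection on motif-frequency
# features, mean recentering of the minority batch, and merging of sources
# into one content value per cell line.

#' Z-scored log transform
#'
#' Log-transforms positive raw lengths and standardizes to mean 0 / SD 1.
#' Zero or negative values are excluded with a warning (returned as `NA`);
#' the standardization uses the remaining finite values.
#'
#' @param values Numeric vector of raw content estimates (kb).
#' @param log_base Logarithm base (default 2).
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1).
#' @return Numeric vector aligned with the input; excluded entries are `NA`.
#'   Attributes `log_base` and `sd_type` record the convention used.
#' @examples
#' log_z(c(1, 4))  # c(-1, 1)
#' @export
log_z <- function(values, log_base = 2, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  ok <- is.finite(values) & values > 0
  if (any(is.finite(values) & values <= 0)) {
    warning(sprintf("excluding %d non-positive value(s) from log transform",
                    sum(is.finite(values) & values <= 0)))
  }
  if (sum(ok) < 2L) stop("need at least 2 positive finite values")
  lg <- log(values[ok], base = log_base)
  s <- if (sd_type == "population") sqrt(mean((lg - mean(lg))^2)) else stats::sd(lg)
  if (s == 0) stop("zero variance after log transform; z-scores undefined")
  out <- rep(NA_real_, length(values))
  out[ok] <- (lg - mean(lg)) / s
  attr(out, "log_base") <- log_base
  attr(out, "sd_type") <- sd_type
  out
}

#' Detect library batches from motif-frequency features
#'
#' k-means clustering (multiple restarts, fixed seed) on the per-sample
#' frequencies of reads with exactly 4, 5 and 6 telomeric motifs. Labels are
#' renumbered so that cluster 0 is the largest cluster, which downstream
#' recentering treats as the reference.
#'
#' @param features Matrix or data frame, samples x features (typically the
#'   three motif frequencies), raw and unscaled.
#' @param k Number of clusters (default 2).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of random restarts (default 10).
#' @return Integer vector of 0-based batch labels (0 = largest cluster).
#' @export
detect_batches <- function(features, k = 2L, seed = 1L, nstart = 10L) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("`features` must be numeric")
  if (k == 1L) return(rep(0L, nrow(x)))
  if (nrow(x) < 2L * k) stop("need at least 2k samples for batch detection")
  if (nrow(unique(x)) == 1L) {
    stop("all feature vectors identical; batch structure undefined")
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart)
  sizes <- tabulate(km$cluster, nbins = k)
  # largest cluster first; ties broken by original cluster index
  new_order <- order(-sizes, seq_len(k))
  relabel <- integer(k)
  relabel[new_order] <- seq_len(k) - 1L
  relabel[km$cluster]
}

#' Recenter the non-reference batch
#'
#' Shifts every non-reference-cluster value by the difference between the
#' reference-cluster mean and its own mean, so that cluster means coincide.
#' Within-cluster ordering is preserved exactly (a pure location shift).
#'
#' @param values Numeric vector (typically z-scored log content).
#' @param batch_labels Integer labels from [detect_batches()]; label 0 is the
#'   reference cluster left untouched.
#' @return Numeric vector of corrected values.
#' @export
recenter <- function(values, batch_labels) {
  labs <- unique(batch_labels[!is.na(batch_labels)])
  if (length(labs) != 2L) stop("recentering requires exactly two batch labels")
  if (!0L %in% labs) stop("reference cluster (label 0) not present")
  other <- setdiff(labs, 0L)
  if (min(table(batch_labels)) < 2L) {
    warning("a batch has fewer than 2 members; its mean is still used for the shift")
  }
  shift <- mean(values[batch_labels == 0L], na.rm = TRUE) -
    mean(values[batch_labels == other], na.rm = TRUE)
  out <- values
  out[batch_labels == other] <- out[batch_labels == other] + shift
  out
}

#' Merge content tables from two sources
#'
#' Samples present in both sources receive the arithmetic mean of the two
#' z-values; samples present in one keep that value. Source provenance is
#' recorded per sample.
#'
#' @param z_a,z_b Data frames with columns `sample` and `z` (and optionally
#'   `source`).
#' @param replicate_policy How to treat duplicate samples within one source:
#'   `"error"` (default) or `"mean"`.
#' @return Data frame with columns `sample`, `content` (merged z), `sources`.
#' @export
merge_content <- function(z_a, z_b, replicate_policy = c("error", "mean")) {
  replicate_policy <- match.arg(replicate_policy)
  collapse <- function(tab, which) {
    if (anyDuplicated(tab$sample)) {
      if (replicate_policy == "error") {
        dups <- unique(tab$sample[duplicated(tab$sample)])
        stop("duplicate sample(s) within source ", which, ": ",
             paste(dups, collapse = ", "))
      }
      tab <- stats::aggregate(z ~ sample, data = tab, FUN = mean)
    }
    tab[, c("sample", "z")]
  }
  a <- collapse(as.data.frame(z_a), "a")
  b <- collapse(as.data.frame(z_b), "b")
  all_samples <- union(a$sample, b$sample)
  za <- a$z[match(all_samples, a$sample)]
  zb <- b$z[match(all_samples, b$sample)]
  content <- rowMeans(cbind(za, zb), na.rm = TRUE)
  sources <- ifelse(!is.na(za) & !is.na(zb), "a+b", ifelse(!is.na(za), "a", "b"))
  data.frame(sample = all_samples, content = content, sources = sources,
             stringsAsFactors = FALSE)
}

#' Group comparison of content values
#'
#' Kruskal-Wallis H across all groups, plus a two-sided Mann-Whitney U test
#' of each group (or a designated focus group) against the rest. Ties are
#' handled by midranks.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @param focus Optional single group to test against the rest; by default
#'   every group is tested in turn.
#' @return List with `kruskal` (`H`, `p`) and `pairwise` (data frame with
#'   `group`, `U`, `p`).
#' @export
group_compare <- function(values, groups, focus = NULL) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  tab <- table(groups)
  if (any(tab < 2L)) {
    drop <- names(tab)[tab < 2L]
    warning("excluding group(s) with < 2 values: ", paste(drop, collapse = ", "))
    keep <- !groups %in% drop
    values <- values[keep]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2L) stop("need at least two groups with >= 2 members")
  kw <- stats::kruskal.test(values, factor(groups))
  targets <- if (is.null(focus)) sort(unique(groups)) else focus
  pw <- do.call(rbind, lapply(targets, function(g) {
    x <- values[groups == g]
    y <- values[groups != g]
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    data.frame(group = g, U = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(kruskal = list(H = unname(kw$statistic), p = kw$p.value), pairwise = pw)
}
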