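# Region-set enrichment of differentially methylated CpG islands: rank
# islands by group-wise methylation difference, take the top-n
# hypomethylated islands as the interest set, and test overlap against
# annotated region sets (and against telomere proximity) with Fisher's
# exact test over interest/rest x overlap/no-overlap.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by point-probability summation over the hypergeometric support
#' (every table with point probability at most that of the observed table,
#' up to the standard 1e-7 relative tolerance, contributes). The odds ratio
#' is the sample odds ratio `a d / (b c)`, with 0.5 added to every cell
#' only when a zero cell occurs (flagged).
#'
#' @param a,b,c,d Contingency counts: interest-and-overlap, interest-only,
#'   rest-and-overlap, rest-only.
#' @return List with `p`, `odds_ratio`, `continuity` (whether the 0.5
#'   correction was applied).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m1 <- a + b          # interest size
  m2 <- c + d          # rest size
  k <- a + c           # total overlapping
  lo <- max(0L, k - m2)
  hi <- min(k, m1)
  support <- lo:hi
  dens <- stats::dhyper(support, m1, m2, k)
  d_obs <- stats::dhyper(a, m1, m2, k)
  p <- min(sum(dens[dens <= d_obs * (1 + 1e-7)]), 1)
  continuity <- any(c(a, b, c, d) == 0)
  or <- if (continuity) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  list(p = p, odds_ratio = or, continuity = continuity)
}

#' Rank CpG islands by group-wise methylation difference
#'
#' Per island, a two-sided Mann-Whitney U test of the first group (e.g.
#' TERT-promoter mutants) against the rest, with the rank-biserial effect
#' size giving the direction. Islands are then ordered by ascending p among
#' those changed in the requested direction (default: hypomethylated in the
#' first group, i.e. negative effect). Islands where either group has fewer
#' than 2 non-missing values are excluded.
#'
#' @param meth Numeric matrix, samples x islands, of mean island
#'   methylation (beta values).
#' @param groups Logical vector over samples; `TRUE` marks the group whose
#'   methylation change is ranked (e.g. mutants).
#' @param direction `"hypo"` (default) ranks islands with lower methylation
#'   in the `TRUE` group; `"hyper"` the opposite tail.
#' @return Data frame ordered by ascending p, columns `cgi`, `effect`
#'   (rank-biserial), `p`; only islands in the requested direction are
#'   retained.
#' @export
rank_differential_cgis <- function(meth, groups, direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  res <- mwu_matrix(meth, groups, min_per_group = 2L)
  names(res)[names(res) == "feature"] <- "cgi"
  res <- res[!is.na(res$p), c("cgi", "effect", "p")]
  res <- if (direction == "hypo") res[res$effect < 0, , drop = FALSE]
         else res[res$effect > 0, , drop = FALSE]
  res[order(res$p, res$cgi), , drop = FALSE]
}

#' Select the interest set from a ranked list
#'
#' The first `n` entries of the ranking; when fewer are available, all are
#' taken with a warning.
#'
#' @param ranked Data frame from [rank_differential_cgis()] (or any ranked
#'   table with a first identifier column).
#' @param n Interest-set size (default 1000).
#' @return Character vector of selected identifiers.
#' @export
select_interest <- function(ranked, n = 1000L) {
  if (n <= 0L) stop("interest-set size must be positive")
  ids <- if (is.data.frame(ranked)) as.character(ranked[[1]]) else as.character(ranked)
  if (length(ids) < n) {
    warning(sprintf("only %d ranked regions available; taking all", length(ids)))
    return(ids)
  }
  ids[seq_len(n)]
}

# count regions of `query` overlapping `annotated` by >= 1 bp
.n_overlapping <- function(query, annotated) {
  sum(GenomicRanges::countOverlaps(query, annotated) > 0L)
}

.region_key <- function(gr) {
  paste0(as.character(GenomicRanges::seqnames(gr)), ":",
         GenomicRanges::start(gr), "-", GenomicRanges::end(gr))
}

#' Overlap enrichment of an interest set within a universe
#'
#' Builds the 2x2 table (interest vs universe-rest) x (overlaps the
#' annotated set by >= 1 bp vs not) and applies the two-sided Fisher's
#' exact test. The interest set must be a proper subset of the universe.
#'
#' @param interest,universe,annotated [GenomicRanges::GRanges] region sets
#'   (1-based inclusive internally; see [read_regions()] for BED ingest).
#' @param name Label recorded in the result (default `"annotated"`).
#' @return One-row data frame: `region_set`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`.
#' @export
overlap_enrichment <- function(interest, universe, annotated, name = "annotated") {
  if (!all(.region_key(interest) %in% .region_key(universe))) {
    stop("interest set is not a subset of the universe")
  }
  rest <- universe[!.region_key(universe) %in% .region_key(interest)]
  if (length(rest) == 0L) {
    stop("interest set equals the universe; enrichment undefined")
  }
  a <- .n_overlapping(interest, annotated)
  b <- length(interest) - a
  cc <- .n_overlapping(rest, annotated)
  d <- length(rest) - cc
  ft <- fisher_exact_2x2(a, b, cc, d)
  data.frame(region_set = name, a = a, b = b, c = cc, d = d,
             odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
}

#' Enrichment against a database of region sets
#'
#' Runs [overlap_enrichment()] for each annotated set and adjusts the
#' p-values as one Benjamini-Hochberg family.
#'
#' @param interest,universe [GenomicRanges::GRanges].
#' @param annotated_sets Named list of [GenomicRanges::GRanges].
#' @return Data frame, one row per set, with added column `q`, ordered by
#'   ascending `q` then `p`.
#' @export
region_set_enrichment <- function(interest, universe, annotated_sets) {
  stopifnot(length(annotated_sets) >= 1L)
  if (is.null(names(annotated_sets))) {
    names(annotated_sets) <- paste0("set_", seq_along(annotated_sets))
  }
  out <- do.call(rbind, lapply(names(annotated_sets), function(nm) {
    overlap_enrichment(interest, universe, annotated_sets[[nm]], name = nm)
  }))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$q, out$p), , drop = FALSE]
}

#' Telomere-proximity enrichment
#'
#' A region is telomere-proximal when it starts within `window` bp of its
#' chromosome's start or ends within `window` bp of its chromosome's end.
#' The same interest-vs-rest Fisher machinery as [overlap_enrichment()] is
#' applied to the proximal/non-proximal split. Regions on chromosomes
#' absent from `chrom_sizes` are excluded with a warning.
#'
#' @param interest,universe [GenomicRanges::GRanges].
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param window Proximity window in bp (default 1e7, i.e. 10 Mb).
#' @return One-row data frame as in [overlap_enrichment()].
#' @export
telomere_proximity_enrichment <- function(interest, universe, chrom_sizes,
                                          window = 1e7) {
  drop_missing <- function(gr, label) {
    chr <- as.character(GenomicRanges::seqnames(gr))
    missing <- !chr %in% names(chrom_sizes)
    if (any(missing)) {
      warning(sprintf("excluding %d %s region(s) on chromosomes without sizes",
                      sum(missing), label))
    }
    gr[!missing]
  }
  interest <- drop_missing(interest, "interest")
  universe <- drop_missing(universe, "universe")
  proximal <- function(gr) {
    chr <- as.character(GenomicRanges::seqnames(gr))
    size <- chrom_sizes[chr]
    GenomicRanges::start(gr) < window | GenomicRanges::end(gr) > size - window
  }
  if (!all(.region_key(interest) %in% .region_key(universe))) {
    stop("interest set is not a subset of the universe")
  }
  rest <- universe[!.region_key(universe) %in% .region_key(interest)]
  pi_int <- proximal(interest)
  pi_rest <- proximal(rest)
  a <- sum(pi_int); b <- sum(!pi_int)
  cc <- sum(pi_rest); d <- sum(!pi_rest)
  ft <- fisher_exact_2x2(a, b, cc, d)
  data.frame(region_set = sprintf("telomere_%dMb", as.integer(window / 1e6)),
             a = a, b = b, c = cc, d = d,
             odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
}
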