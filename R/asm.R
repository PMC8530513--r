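# Allele-specific methylation (ASM) from joint methylation states of
# adjacent CpG pairs on the same bisulfite read. With allele-specific
# methylation, reads concentrate in the concordant states (both methylated,
# mm, or both unmethylated, uu); without it, semi-methylated pairs spread
# over the discordant states (mu, um). The imbalance is scored per pair with
# the mean square contingency coefficient Phi on the pseudocounted 2x2 table
# and aggregated over genomic regions.

#' Mean square contingency coefficient (Phi) of a CpG-pair state table
#'
#' With a pseudocount of 0.5 added to each of the four joint-state counts,
#' `Phi = (mm.uu - mu.um) / sqrt((mm+mu)(um+uu)(mm+um)(mu+uu))` (all terms
#' pseudocounted). Positive values indicate ASM; negative raw values are
#' rounded to 0 by default (discordant excess carries no ASM signal).
#'
#' @param mm,mu,um,uu Non-negative counts of the four joint methylation
#'   states (methylated/unmethylated at the first/second CpG); vectorized.
#' @param clip Round negative raw values to 0 (default `TRUE`).
#' @return Numeric vector; in \[0, 1\] when `clip = TRUE`.
#' @examples
#' phi(10, 0, 0, 10)  # 110/121, strong ASM
#' phi(5, 5, 5, 5)    # 0, balanced
#' @export
phi <- function(mm, mu, um, uu, clip = TRUE) {
  mm <- mm + 0.5; mu <- mu + 0.5; um <- um + 0.5; uu <- uu + 0.5
  val <- (mm * uu - mu * um) /
    sqrt((mm + mu) * (um + uu) * (mm + um) * (mu + uu))
  if (clip) val <- pmax(val, 0)
  val
}

#' Validity filters for CpG-pair observations
#'
#' A pair-sample observation is valid when (in order): coverage
#' `mm + mu + um + uu >= min_coverage`; the pair reaches that coverage in at
#' least `min_prevalence` of all cohort samples; and the per-CpG methylation
#' levels derived from the pair's own marginals,
#' `m_a = (mm + mu)/cov` and `m_b = (mm + um)/cov`, both lie inside
#' `bounds` (pairs outside are likely fully methylated or fully
#' unmethylated, hence uninformative for allelic imbalance).
#'
#' @param pairs Data frame with columns `sample`, `chrom`, `pos_a`, `pos_b`,
#'   `mm`, `mu`, `um`, `uu`, covering the whole cohort.
#' @param min_coverage Minimum read coverage per observation (default 8).
#' @param min_prevalence Minimum fraction of cohort samples in which the
#'   pair is observed at `min_coverage` (default 0.05).
#' @param bounds Inclusive per-CpG methylation bounds (default
#'   `c(0.1, 0.9)`).
#' @return The input with added columns `coverage`, `m_a`, `m_b`, `valid`.
#' @export
pair_filters <- function(pairs, min_coverage = 8L, min_prevalence = 0.05,
                         bounds = c(0.1, 0.9)) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(pairs$pos_a < pairs$pos_b))
  cov <- pairs$mm + pairs$mu + pairs$um + pairs$uu
  covered <- cov >= min_coverage
  key <- paste(pairs$chrom, pairs$pos_a, pairs$pos_b, sep = ":")
  n_samples <- length(unique(pairs$sample))
  covered_samples <- tapply(pairs$sample[covered], key[covered],
                            function(s) length(unique(s)))
  prevalence <- rep(0, nrow(pairs))
  hit <- match(key, names(covered_samples))
  prevalence[!is.na(hit)] <- covered_samples[hit[!is.na(hit)]] / n_samples
  m_a <- ifelse(cov > 0, (pairs$mm + pairs$mu) / cov, NA_real_)
  m_b <- ifelse(cov > 0, (pairs$mm + pairs$um) / cov, NA_real_)
  in_bounds <- !is.na(m_a) & !is.na(m_b) &
    m_a >= bounds[1] & m_a <= bounds[2] &
    m_b >= bounds[1] & m_b <= bounds[2]
  pairs$coverage <- cov
  pairs$m_a <- m_a
  pairs$m_b <- m_b
  pairs$valid <- covered & prevalence >= min_prevalence & in_bounds
  pairs
}

#' Score CpG pairs with Phi after filtering
#'
#' Convenience wrapper: applies [pair_filters()] then [phi()]; `phi` is `NA`
#' for invalid observations.
#'
#' @inheritParams pair_filters
#' @return The filtered data frame with an added `phi` column.
#' @export
score_pairs <- function(pairs, min_coverage = 8L, min_prevalence = 0.05,
                        bounds = c(0.1, 0.9)) {
  out <- pair_filters(pairs, min_coverage = min_coverage,
                      min_prevalence = min_prevalence, bounds = bounds)
  out$phi <- ifelse(out$valid, phi(out$mm, out$mu, out$um, out$uu), NA_real_)
  out
}

#' TERT locus regions (GRCh37)
#'
#' The five subregions used for regional ASM aggregation around TERT:
#' promoter, three sections of the first-exon CpG island complex, and the
#' remaining gene body. Coordinates are 1-based inclusive on chr5.
#'
#' @return A named [GenomicRanges::GRanges] of five non-overlapping regions.
#' @export
tert_locus_regions <- function() {
  gr <- GenomicRanges::GRanges(
    seqnames = "chr5",
    ranges = IRanges::IRanges(
      start = c(1295246L, 1294872L, 1291374L, 1289695L, 1249661L),
      end   = c(1298643L, 1295134L, 1294439L, 1291090L, 1289359L)
    )
  )
  names(gr) <- c("promoter", "CGI_1", "CGI_2", "CGI_3", "gene_body")
  gr
}

#' Regional ASM aggregation
#'
#' Mean of valid per-pair Phi values within each region, per sample. A pair
#' belongs to a region when its *first* CpG lies inside it (avoids double
#' counting across adjacent regions). Pairs with fewer than
#' `min_valid_frac` valid observations across the cohort are excluded
#' before averaging. Cells with no contributing pair are `NA`.
#'
#' @param scores Data frame from [score_pairs()] (columns `sample`, `chrom`,
#'   `pos_a`, `pos_b`, `phi`, `valid`).
#' @param regions Named [GenomicRanges::GRanges] of target regions.
#' @param min_valid_frac Minimum fraction of cohort samples with a valid
#'   estimate for a pair to be retained (default 0.25).
#' @return Numeric matrix, samples x regions.
#' @export
region_asm <- function(scores, regions, min_valid_frac = 0.25) {
  scores <- as.data.frame(scores)
  samples <- sort(unique(scores$sample))
  key <- paste(scores$chrom, scores$pos_a, scores$pos_b, sep = ":")
  n_samples <- length(samples)
  valid_frac <- tapply(scores$valid, key, sum) / n_samples
  keep_pair <- valid_frac[key] >= min_valid_frac
  scores <- scores[keep_pair & scores$valid & !is.na(scores$phi), , drop = FALSE]

  pair_gr <- GenomicRanges::GRanges(
    seqnames = scores$chrom,
    ranges = IRanges::IRanges(start = scores$pos_a, width = 1L))
  hits <- GenomicRanges::findOverlaps(pair_gr, regions)
  region_names <- if (is.null(names(regions))) as.character(seq_along(regions))
                  else names(regions)
  out <- matrix(NA_real_, nrow = length(samples), ncol = length(regions),
                dimnames = list(samples, region_names))
  if (length(hits) > 0L) {
    df <- data.frame(sample = scores$sample[S4Vectors::queryHits(hits)],
                     region = region_names[S4Vectors::subjectHits(hits)],
                     phi = scores$phi[S4Vectors::queryHits(hits)])
    agg <- stats::aggregate(phi ~ sample + region, data = df, FUN = mean)
    out[cbind(match(agg$sample, samples), match(agg$region, region_names))] <- agg$phi
  }
  out
}

#' Mean CpG-island methylation
#'
#' Mean beta value over the CpGs profiled inside each island, per sample;
#' islands with fewer than `min_cpgs` profiled CpGs in a sample are `NA`.
#' The minimum defaults to 8 for RRBS-style input; array-style input
#' conventionally uses 4.
#'
#' @param cpg_betas Data frame with columns `sample`, `chrom`, `pos`,
#'   `beta`.
#' @param islands Named [GenomicRanges::GRanges] of CpG islands.
#' @param min_cpgs Minimum profiled CpGs per island (default 8).
#' @return Numeric matrix, samples x islands.
#' @export
cgi_methylation <- function(cpg_betas, islands, min_cpgs = 8L) {
  cpg_betas <- as.data.frame(cpg_betas)
  samples <- sort(unique(cpg_betas$sample))
  island_names <- if (is.null(names(islands))) as.character(seq_along(islands))
                  else names(islands)
  cpg_gr <- GenomicRanges::GRanges(
    seqnames = cpg_betas$chrom,
    ranges = IRanges::IRanges(start = cpg_betas$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(cpg_gr, islands)
  out <- matrix(NA_real_, nrow = length(samples), ncol = length(islands),
                dimnames = list(samples, island_names))
  if (length(hits) > 0L) {
    df <- data.frame(sample = cpg_betas$sample[S4Vectors::queryHits(hits)],
                     island = island_names[S4Vectors::subjectHits(hits)],
                     beta = cpg_betas$beta[S4Vectors::queryHits(hits)])
    df <- df[!is.na(df$beta), , drop = FALSE]
    n <- stats::aggregate(beta ~ sample + island, data = df, FUN = length)
    m <- stats::aggregate(beta ~ sample + island, data = df, FUN = mean)
    ok <- n$beta >= min_cpgs
    out[cbind(match(m$sample[ok], samples),
              match(m$island[ok], island_names))] <- m$beta[ok]
  }
  out
}
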