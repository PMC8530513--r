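# Allele-specific expression (ASE) calling from paired DNA/RNA allele
# counts at heterozygous SNPs. A gene is called monoallelically expressed
# (MAE) in a sample when the RNA allele balance is strongly skewed relative
# to the DNA balance, quantified by a pseudocounted odds ratio anchored on
# the RNA-major allele.

#' Filter allele-count records
#'
#' Keeps records with at least `min_reads` DNA reads supporting *both* the
#' reference and the alternate allele, a passing upstream caller filter, and
#' RNA depth of at least `min_rna_depth`. Bounds are inclusive ("at least
#' eight").
#'
#' @param records Data frame with columns `dna_ref`, `dna_alt`, `rna_ref`,
#'   `rna_alt` and a logical `passed_caller_filter` (or a character `filter`
#'   column where `"PASS"` passes).
#' @param min_reads Minimum DNA support per allele (default 8).
#' @param min_rna_depth Minimum total RNA depth (default 8).
#' @return The surviving rows (possibly zero).
#' @export
filter_snps <- function(records, min_reads = 8L, min_rna_depth = 8L) {
  records <- as.data.frame(records)
  passed <- if ("passed_caller_filter" %in% names(records)) {
    as.logical(records$passed_caller_filter)
  } else if ("filter" %in% names(records)) {
    records$filter == "PASS"
  } else {
    rep(TRUE, nrow(records))
  }
  keep <- records$dna_ref >= min_reads & records$dna_alt >= min_reads &
    passed & (records$rna_ref + records$rna_alt) >= min_rna_depth
  records[keep & !is.na(keep), , drop = FALSE]
}

#' Allele-specific expression odds ratio
#'
#' From the 2x2 table of context (DNA vs RNA) by allele (ref vs alt), with a
#' pseudocount of 0.5 added to every cell. The RNA-major allele M anchors
#' both ratios:
#' `OR = (dna_minor / dna_major) / (rna_minor / rna_major)`,
#' so allelic skew in RNA relative to DNA inflates the OR above 1. Ties in
#' RNA counts are broken by the larger DNA count; the result is invariant
#' under exchanging the ref/alt labels.
#'
#' @param dna_ref,dna_alt,rna_ref,rna_alt Non-negative read counts
#'   (vectorized).
#' @return Positive numeric vector of odds ratios (always finite thanks to
#'   the pseudocounts).
#' @examples
#' ase_odds_ratio(10, 10, 50, 0)   # 101: strong monoallelic skew
#' ase_odds_ratio(10, 10, 20, 20)  # 1: balanced
#' @export
ase_odds_ratio <- function(dna_ref, dna_alt, rna_ref, rna_alt) {
  major_is_ref <- rna_ref > rna_alt | (rna_ref == rna_alt & dna_ref >= dna_alt)
  dna_major <- ifelse(major_is_ref, dna_ref, dna_alt) + 0.5
  dna_minor <- ifelse(major_is_ref, dna_alt, dna_ref) + 0.5
  rna_major <- ifelse(major_is_ref, rna_ref, rna_alt) + 0.5
  rna_minor <- ifelse(major_is_ref, rna_alt, rna_ref) + 0.5
  (dna_minor / dna_major) / (rna_minor / rna_major)
}

#' Classify an odds ratio as MAE or BAE
#'
#' Monoallelic expression is called when the odds ratio strictly exceeds the
#' threshold (default 5); otherwise biallelic.
#'
#' @param odds_ratio Numeric vector from [ase_odds_ratio()].
#' @param threshold Strict MAE cutoff (default 5).
#' @return Character vector, `"MAE"` or `"BAE"`.
#' @export
classify_ase <- function(odds_ratio, threshold = 5) {
  ifelse(odds_ratio > threshold, "MAE", "BAE")
}

#' Select the most informative SNP record per sample and gene
#'
#' When the same SNP is observed from multiple DNA sources (e.g. WGS and
#' WES), the source with the greatest DNA coverage wins first; among the
#' remaining SNPs the one with the greatest total RNA depth is chosen. Ties
#' are broken by lexicographic `snp_id`, then source tag.
#'
#' @param records Filtered records for one sample and gene, with columns
#'   `snp_id`, `dna_source`, `dna_ref`, `dna_alt`, `rna_ref`, `rna_alt`.
#' @return A single-row data frame, or `NULL` when `records` is empty.
#' @export
select_informative <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) return(NULL)
  if (!"dna_source" %in% names(records)) records$dna_source <- "unknown"
  dna_depth <- records$dna_ref + records$dna_alt
  # per SNP: keep the deepest DNA source
  ord <- order(records$snp_id, -dna_depth, records$dna_source)
  records <- records[ord, , drop = FALSE]
  records <- records[!duplicated(records$snp_id), , drop = FALSE]
  rna_depth <- records$rna_ref + records$rna_alt
  records[order(-rna_depth, records$snp_id, records$dna_source)[1L], , drop = FALSE]
}

#' Call allele-specific expression per sample and gene
#'
#' Runs the full calling pipeline: caller/coverage filters, most-informative
#' SNP selection, pseudocounted odds ratio, and MAE/BAE classification.
#' Sample-gene pairs whose records all fail the filters are reported as
#' `unassessable`.
#'
#' @param records Data frame of allele counts with columns `sample`, `gene`,
#'   `snp_id`, `dna_source`, `dna_ref`, `dna_alt`, `rna_ref`, `rna_alt`,
#'   and a caller filter column (see [filter_snps()]).
#' @param or_threshold Strict MAE odds-ratio cutoff (default 5).
#' @param min_reads,min_rna_depth Filter thresholds, see [filter_snps()].
#' @return Data frame with columns `sample`, `gene`, `status`
#'   (`MAE`/`BAE`/`unassessable`), `odds_ratio`, `chosen_snp`.
#' @export
call_ase <- function(records, or_threshold = 5, min_reads = 8L,
                     min_rna_depth = 8L) {
  records <- as.data.frame(records)
  filtered <- filter_snps(records, min_reads = min_reads,
                          min_rna_depth = min_rna_depth)
  groups <- unique(records[, c("sample", "gene")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    smp <- groups$sample[i]; gene <- groups$gene[i]
    rec <- select_informative(
      filtered[filtered$sample == smp & filtered$gene == gene, , drop = FALSE])
    if (is.null(rec)) {
      return(data.frame(sample = smp, gene = gene, status = "unassessable",
                        odds_ratio = NA_real_, chosen_snp = NA_character_,
                        stringsAsFactors = FALSE))
    }
    or <- ase_odds_ratio(rec$dna_ref, rec$dna_alt, rec$rna_ref, rec$rna_alt)
    data.frame(sample = smp, gene = gene,
               status = classify_ase(or, or_threshold),
               odds_ratio = or, chosen_snp = rec$snp_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
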