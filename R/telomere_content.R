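# Telomere content estimation from raw sequencing reads.
#
# A read is "telomeric" when it carries at least `threshold` non-overlapping
# copies of the canonical human telomeric repeat TTAGGG. The count of
# telomeric reads is normalized by coverage in a narrow GC band matching the
# repeat's base composition, scaled by the genome length in that band and the
# number of chromosome ends, yielding a per-sample content estimate in
# kilobases (a content proxy, not a physical length: interstitial and
# extrachromosomal repeats are counted too).

TELOMERE_MOTIF <- "TTAGGG"

# Genome length (bp) inside the default GC band [0.48, 0.52] for GRCh37,
# used to scale GC-band coverage to a per-chromosome-end length. Overridable
# in every entry point for other builds or custom GC profiles.
GRCH37_GC_BAND_LENGTH <- 332720800
N_CHROMOSOME_ENDS <- 46L

#' Count non-overlapping motif occurrences in reads
#'
#' Scans each sequence left to right and counts exact, non-overlapping
#' occurrences of `motif`. Sequences are uppercased on ingest; `N` never
#' matches.
#'
#' @param sequences Character vector of read sequences over \{A,C,G,T,N\}.
#' @param motif Single non-empty motif string (default the canonical
#'   telomeric repeat `TTAGGG`).
#' @return Integer vector of occurrence counts, one per read.
#' @examples
#' count_motifs(strrep("TTAGGG", 6))        # 6
#' count_motifs("TTAGGGTTAGGGTTAGG")        # 2 (third copy truncated)
#' @export
count_motifs <- function(sequences, motif = TELOMERE_MOTIF) {
  if (length(motif) != 1L || is.na(motif) || !nzchar(motif)) {
    stop("`motif` must be a single non-empty string")
  }
  stringi::stri_count_fixed(toupper(sequences), toupper(motif))
}

#' Flag telomeric reads
#'
#' A read is telomeric when it contains at least `threshold` non-overlapping
#' copies of the motif. With `rc_scan = TRUE` the reverse complement
#' (`CCCTAA` for the canonical motif) is also scanned and the larger count is
#' used, for inputs whose read orientation is not normalized.
#'
#' @param sequences Character vector of read sequences.
#' @param threshold Minimum motif count (default 6).
#' @param motif Motif string.
#' @param rc_scan Also scan the reverse complement (default `FALSE`).
#' @return Logical vector.
#' @export
is_telomeric <- function(sequences, threshold = 6L, motif = TELOMERE_MOTIF,
                         rc_scan = FALSE) {
  if (threshold < 1L) stop("`threshold` must be >= 1")
  n <- count_motifs(sequences, motif)
  if (rc_scan) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    n <- pmax(n, count_motifs(sequences, rc))
  }
  n >= threshold
}

#' Per-read GC fraction
#'
#' (#G + #C) / (#A + #C + #G + #T); `N` bases are excluded from both
#' numerator and denominator. All-N reads return `NA`.
#'
#' @param sequences Character vector of read sequences.
#' @return Numeric vector in \[0, 1\], `NA` where no called base exists.
#' @export
gc_fraction <- function(sequences) {
  s <- toupper(sequences)
  if (any(!nzchar(s))) stop("empty sequence")
  gc <- stringi::stri_count_regex(s, "[GC]")
  acgt <- stringi::stri_count_regex(s, "[ACGT]")
  out <- gc / acgt
  out[acgt == 0L] <- NA_real_
  out
}

#' Motif-count profile of a read set
#'
#' Tabulates how many reads contain exactly k non-overlapping motif copies,
#' for k = 0 .. max observed. The exact-4/5/6 frequencies are the features
#' used for batch detection (see [batch_features()]).
#'
#' @param sequences Character vector of read sequences.
#' @param motif Motif string.
#' @return Data frame with columns `k` and `n_reads`; `sum(n_reads)` equals
#'   `length(sequences)`.
#' @export
motif_profile <- function(sequences, motif = TELOMERE_MOTIF) {
  counts <- count_motifs(sequences, motif)
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  data.frame(k = seq_along(tab) - 1L, n_reads = tab)
}

#' Batch-detection feature vector
#'
#' Frequencies of reads containing exactly 4, 5 and 6 motif copies, each
#' divided by the total read count. These three frequencies separate
#' library-preparation batches that global normalization does not.
#'
#' @param sequences Character vector of read sequences.
#' @param motif Motif string.
#' @return Named numeric vector `c(freq4, freq5, freq6)`.
#' @export
batch_features <- function(sequences, motif = TELOMERE_MOTIF) {
  counts <- count_motifs(sequences, motif)
  n <- length(counts)
  c(freq4 = sum(counts == 4L) / n,
    freq5 = sum(counts == 5L) / n,
    freq6 = sum(counts == 6L) / n)
}

#' Estimate telomere content for one sample
#'
#' Counts telomeric reads (T) and GC-band reads (S) and converts their ratio
#' to a per-chromosome-end length:
#' `raw_length_kb = (T / S) * (L_gc / n_ends) / 1000`.
#' When `reads` carries a `read_group` column with more than one group, each
#' group is estimated separately and combined with
#' [aggregate_read_groups()], weighting by per-group read counts.
#'
#' @param reads Character vector of sequences, or a data frame with columns
#'   `sequence` and optionally `read_group`.
#' @param sample Sample identifier recorded in the output.
#' @param motif_threshold Minimum motif copies for a telomeric read.
#' @param gc_low,gc_high GC band bounds (inclusive).
#' @param l_gc Genome length (bp) within the GC band.
#' @param n_ends Number of chromosome ends (46 for a diploid human genome).
#' @param rc_scan Also scan the reverse complement motif.
#' @param source Dataset tag recorded in the output.
#' @return One-row data frame: `sample`, `source`, `read_groups`,
#'   `total_reads`, `telomeric_reads`, `gc_band_reads`, `raw_length_kb`.
#'   `raw_length_kb` is `NA` (with a warning) when no read falls in the GC
#'   band.
#' @export
estimate_content <- function(reads, sample = "sample",
                             motif_threshold = 6L,
                             gc_low = 0.48, gc_high = 0.52,
                             l_gc = GRCH37_GC_BAND_LENGTH,
                             n_ends = N_CHROMOSOME_ENDS,
                             rc_scan = FALSE,
                             source = NA_character_) {
  if (is.data.frame(reads)) {
    groups <- if ("read_group" %in% names(reads)) as.character(reads$read_group)
              else rep("rg1", nrow(reads))
    sequences <- as.character(reads$sequence)
  } else {
    sequences <- as.character(reads)
    groups <- rep("rg1", length(sequences))
  }
  if (length(sequences) == 0L) stop("no reads supplied")

  per_group <- lapply(split(sequences, groups), function(seqs) {
    t_count <- sum(is_telomeric(seqs, threshold = motif_threshold,
                                rc_scan = rc_scan))
    gc <- gc_fraction(seqs)
    s_count <- sum(!is.na(gc) & gc >= gc_low & gc <= gc_high)
    raw_kb <- if (s_count > 0L) (t_count / s_count) * (l_gc / n_ends) / 1000
              else NA_real_
    data.frame(total_reads = length(seqs), telomeric_reads = t_count,
               gc_band_reads = s_count, raw_length_kb = raw_kb)
  })
  est <- do.call(rbind, per_group)
  est$read_group <- names(per_group)

  if (any(est$gc_band_reads == 0L)) {
    warning(sprintf("sample %s: %d read group(s) with no reads in GC band [%g, %g]; estimate non-finite",
                    sample, sum(est$gc_band_reads == 0L), gc_low, gc_high))
  }
  agg <- aggregate_read_groups(est$raw_length_kb, est$total_reads)
  data.frame(sample = sample, source = source,
             read_groups = nrow(est),
             total_reads = sum(est$total_reads),
             telomeric_reads = sum(est$telomeric_reads),
             gc_band_reads = sum(est$gc_band_reads),
             raw_length_kb = agg,
             stringsAsFactors = FALSE)
}

#' Combine per-read-group estimates into a sample estimate
#'
#' Weighted mean of per-group length estimates, weighted by the total read
#' count of each group. Groups with a non-finite estimate are dropped with a
#' warning (they contribute no information about content).
#'
#' @param lengths Numeric vector of per-group length estimates (kb).
#' @param read_counts Positive weights, the per-group total read counts.
#' @return Single numeric estimate; `NA` if no group had a finite estimate.
#' @export
aggregate_read_groups <- function(lengths, read_counts) {
  if (length(lengths) == 0L) stop("no read-group estimates supplied")
  if (length(lengths) != length(read_counts)) {
    stop("`lengths` and `read_counts` must have equal length")
  }
  if (any(read_counts <= 0)) stop("read-group weights must be > 0")
  ok <- is.finite(lengths)
  if (!any(ok)) return(NA_real_)
  if (!all(ok)) warning(sprintf("dropping %d read group(s) with non-finite estimates", sum(!ok)))
  sum(lengths[ok] * read_counts[ok]) / sum(read_counts[ok])
}

#' Read sequencing reads from FASTQ or BAM
#'
#' FASTQ (plain or gzip) is read with Biostrings; BAM (aligned or unaligned)
#' with Rsamtools, taking the read group from the per-read `RG` tag when
#' present. Sequences are uppercased on ingest.
#'
#' @param path Path to a `.fastq`/`.fq` (optionally `.gz`) or `.bam` file.
#' @param sample Sample identifier attached to every read.
#' @return Data frame with columns `sequence`, `read_group`, `sample`.
#' @export
read_sequencing_reads <- function(path, sample = "sample") {
  if (!file.exists(path)) stop("input file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.bam$", lower)) {
    param <- Rsamtools::ScanBamParam(what = "seq", tag = "RG")
    res <- Rsamtools::scanBam(path, param = param)[[1]]
    seqs <- toupper(as.character(res$seq))
    rg <- res$tag$RG
    if (is.null(rg)) rg <- rep("rg1", length(seqs))
    rg[is.na(rg)] <- "rg1"
  } else if (grepl("\\.(fastq|fq)(\\.gz)?$", lower)) {
    seqs <- toupper(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
    rg <- rep("rg1", length(seqs))
  } else {
    stop("unrecognized read file extension (expect .fastq/.fq[.gz] or .bam): ", path)
  }
  data.frame(sequence = unname(seqs), read_group = rg, sample = sample,
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' Minimal plain-text FASTQ writer used by the simulators (constant quality
#' `I`, i.e. Q40).
#'
#' @param sequences Character vector of read sequences.
#' @param path Output path (plain text).
#' @param ids Optional read identifiers; defaults to `read_1 .. read_n`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sequences, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read_", seq_along(sequences))
  qual <- strrep("I", nchar(sequences))
  lines <- as.vector(rbind(paste0("@", ids), sequences, "+", qual))
  writeLines(lines, path)
  invisible(path)
}
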