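# Seeded synthetic-data generators with planted ground truth for every
# pipeline stage. One global seed drives independent per-stage substreams
# (derived by a stable string hash of the stage name), so adding a stage
# never perturbs another stage's draws. Every generator returns both the
# data in the format the pipeline consumes and a machine-readable truth
# object.

#' Derive a per-stage RNG seed from a global seed
#'
#' Stable polynomial hash of the stage name combined with the global seed,
#' reduced modulo 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character).
#' @return A single integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h) %% 2147483646 + 1)
}

# random sequences at a target GC content, as a character vector
.random_sequences <- function(n, len, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  mat <- matrix(sample(names(probs), n * len, replace = TRUE, prob = probs),
                nrow = n)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Simulate sequencing reads with a planted telomeric fraction
#'
#' Each read is telomeric with probability `telomere_fraction`: a tandem
#' TTAGGG repeat at a random phase offset (0-5 nt), guaranteeing at least
#' `floor((read_length - 5)/6)` complete motifs. Background reads are
#' random sequence at the target GC composition.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in nt (must allow >= 6 motifs, i.e.
#'   >= 41 nt).
#' @param telomere_fraction Probability a read is telomeric, in \[0, 1\].
#' @param gc_target Background GC content (default 0.5).
#' @param seed Integer seed.
#' @return List: `reads` (data frame `sequence`, `read_group`, `sample`),
#'   `truth` (per-read telomeric flag plus `n_reads`, `telomere_fraction`,
#'   `expected_telomeric`).
#' @export
simulate_reads <- function(n_reads, read_length = 100L, telomere_fraction = 0.001,
                           gc_target = 0.5, seed = 1L) {
  stopifnot(telomere_fraction >= 0, telomere_fraction <= 1)
  if (read_length < 6L * 6L + 5L) {
    stop("read_length too short to hold 6 telomeric motifs at any phase")
  }
  set.seed(stage_seed(seed, "reads"))
  telomeric <- stats::runif(n_reads) < telomere_fraction
  seqs <- character(n_reads)
  n_tel <- sum(telomeric)
  if (n_tel > 0L) {
    offset <- sample(0:5, n_tel, replace = TRUE)
    tandem <- strrep(TELOMERE_MOTIF, ceiling((read_length + 5) / 6) + 1L)
    seqs[telomeric] <- substring(tandem, offset + 1L, offset + read_length)
  }
  if (n_tel < n_reads) {
    seqs[!telomeric] <- .random_sequences(n_reads - n_tel, read_length, gc_target)
  }
  list(reads = data.frame(sequence = seqs, read_group = "rg1",
                          sample = "sim_sample", stringsAsFactors = FALSE),
       truth = list(telomeric = telomeric, n_reads = n_reads,
                    telomere_fraction = telomere_fraction,
                    expected_telomeric = n_reads * telomere_fraction))
}

#' Simulate two content tables with a planted batch effect
#'
#' Every sample has a latent log2 content drawn from N(`log2_mean`,
#' `log2_sd`); samples in batch 1 are shifted by `delta` in log2 space.
#' Motif-frequency features (exact-4/5/6 read fractions) are drawn around
#' batch-specific centers well separated relative to their spread, so the
#' batch is recoverable by clustering.
#'
#' @param n_per_batch Samples per batch (default 200).
#' @param delta Planted batch shift in log2 units (default 1.5).
#' @param log2_mean,log2_sd Latent content distribution (defaults 3 and 1,
#'   i.e. ~8 kb median).
#' @param seed Integer seed.
#' @return List: `content` (data frame `sample`, `raw_length_kb`, `freq4`,
#'   `freq5`, `freq6`, `source`), `truth` (`batch` 0/1, `latent_log2`,
#'   `delta`).
#' @export
simulate_batched_content <- function(n_per_batch = 200L, delta = 1.5,
                                     log2_mean = 3, log2_sd = 1, seed = 1L) {
  stopifnot(delta >= 0)
  set.seed(stage_seed(seed, "batched_content"))
  n <- 2L * n_per_batch
  batch <- rep(c(0L, 1L), each = n_per_batch)
  latent <- stats::rnorm(n, log2_mean, log2_sd)
  raw <- 2^(latent + delta * batch)
  centers <- rbind(c(3e-3, 2e-3, 1e-3),
                   c(4.5e-3, 3e-3, 2.2e-3))
  feats <- centers[batch + 1L, ] + matrix(stats::rnorm(n * 3, 0, 1e-4), n, 3)
  feats <- pmax(feats, 0)
  content <- data.frame(sample = sprintf("S%03d", seq_len(n)),
                        raw_length_kb = raw,
                        freq4 = feats[, 1], freq5 = feats[, 2], freq6 = feats[, 3],
                        source = "sim_wes", stringsAsFactors = FALSE)
  list(content = content,
       truth = list(batch = batch, latent_log2 = latent, delta = delta))
}

#' Simulate DNA/RNA allele counts with planted mono-/biallelic states
#'
#' DNA counts are binomial(depth, 0.5) at heterozygous SNPs. RNA counts are
#' binomial(depth, 0.5) for biallelic genes and binomial(depth,
#' `error_rate`) (expression almost entirely from one allele) for
#' monoallelic genes, with the expressed allele chosen at random.
#'
#' @param n Number of sample-gene records (default 1000).
#' @param depth_range Inclusive range of DNA and RNA depths (default
#'   30-100).
#' @param error_rate Minor-allele expression rate under MAE (default 0.01).
#' @param mae_fraction Fraction of records with planted MAE (default 0.5).
#' @param seed Integer seed.
#' @return List: `counts` (ASE input data frame), `truth` (data frame
#'   `sample`, `gene`, `status`).
#' @export
simulate_allele_counts <- function(n = 1000L, depth_range = c(30L, 100L),
                                   error_rate = 0.01, mae_fraction = 0.5,
                                   seed = 1L) {
  stopifnot(depth_range[1] >= 1L)
  set.seed(stage_seed(seed, "allele_counts"))
  mae <- stats::runif(n) < mae_fraction
  dna_depth <- sample(depth_range[1]:depth_range[2], n, replace = TRUE)
  rna_depth <- sample(depth_range[1]:depth_range[2], n, replace = TRUE)
  dna_ref <- stats::rbinom(n, dna_depth, 0.5)
  expressed_ref <- stats::runif(n) < 0.5
  p_ref <- ifelse(mae, ifelse(expressed_ref, 1 - error_rate, error_rate), 0.5)
  rna_ref <- stats::rbinom(n, rna_depth, p_ref)
  samples <- sprintf("S%04d", seq_len(n))
  counts <- data.frame(sample = samples, gene = "GENE",
                       snp_id = sprintf("rs%06d", seq_len(n)),
                       chrom = "chr5", pos = seq_len(n) + 1250000L,
                       dna_source = "WGS",
                       dna_ref = dna_ref, dna_alt = dna_depth - dna_ref,
                       rna_ref = rna_ref, rna_alt = rna_depth - rna_ref,
                       filter = "PASS", stringsAsFactors = FALSE)
  truth <- data.frame(sample = samples, gene = "GENE",
                      status = ifelse(mae, "MAE", "BAE"),
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Simulate CpG-pair methylation-state counts with planted ASM
#'
#' Each read comes from one of two alleles (chosen fairly); for an
#' ASM-positive pair one allele is methylated and the other unmethylated,
#' and each CpG on a read reflects its allele's state with probability
#' `purity`. Null pairs draw the two CpG states independently at
#' probability 0.5, giving no joint-state concordance.
#'
#' @param n_pairs CpG pairs per sample (default 50).
#' @param n_samples Cohort size (default 40).
#' @param coverage Reads per pair observation (default 20).
#' @param purity Per-CpG allele-state concordance for ASM pairs, in
#'   \[0.5, 1\] (default 0.95).
#' @param asm_fraction Fraction of pairs with planted ASM (default 0.5).
#' @param seed Integer seed.
#' @return List: `pairs` (data frame `sample`, `chrom`, `pos_a`, `pos_b`,
#'   `mm`, `mu`, `um`, `uu`), `truth` (per-pair `asm` flag and `purity`).
#' @export
simulate_cpg_pairs <- function(n_pairs = 50L, n_samples = 40L, coverage = 20L,
                               purity = 0.95, asm_fraction = 0.5, seed = 1L) {
  stopifnot(coverage >= 1L, purity >= 0.5, purity <= 1)
  set.seed(stage_seed(seed, "cpg_pairs"))
  asm <- stats::runif(n_pairs) < asm_fraction
  pos_a <- sort(sample(seq(1e5, 2e6, by = 50L), n_pairs))
  pos_b <- pos_a + 25L
  rows <- vector("list", n_pairs * n_samples)
  idx <- 1L
  for (s in seq_len(n_samples)) {
    for (p in seq_len(n_pairs)) {
      if (asm[p]) {
        allele_meth <- stats::runif(coverage) < 0.5   # TRUE = methylated allele
        target <- matrix(allele_meth, coverage, 2)
        flip <- matrix(stats::runif(coverage * 2) >= purity, coverage, 2)
        states <- xor(target, flip)
      } else {
        states <- matrix(stats::runif(coverage * 2) < 0.5, coverage, 2)
      }
      mm <- sum(states[, 1] & states[, 2])
      mu <- sum(states[, 1] & !states[, 2])
      um <- sum(!states[, 1] & states[, 2])
      uu <- sum(!states[, 1] & !states[, 2])
      rows[[idx]] <- c(s, p, mm, mu, um, uu)
      idx <- idx + 1L
    }
  }
  mat <- do.call(rbind, rows)
  pairs <- data.frame(sample = sprintf("S%03d", mat[, 1]), chrom = "chr5",
                      pos_a = pos_a[mat[, 2]], pos_b = pos_b[mat[, 2]],
                      mm = mat[, 3], mu = mat[, 4], um = mat[, 5], uu = mat[, 6],
                      stringsAsFactors = FALSE)
  truth <- data.frame(chrom = "chr5", pos_a = pos_a, pos_b = pos_b,
                      asm = asm, purity = ifelse(asm, purity, NA_real_),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth)
}

#' Simulate a dependency screen with a planted codependent module and a
#' planted mutation effect
#'
#' The module is planted with an *exact* correlation structure: pairwise
#' sample correlations are constructed (via a Cholesky factor applied to
#' exactly orthonormal residual directions) to equal `module_r` plus a
#' small ring-graded offset (nearest ring neighbors slightly above the
#' target, distant ones slightly below, all within `module_r` +/- 0.02).
#' Planting exact correlations rather than sampling an equicorrelated
#' factor model keeps the planted truth well defined under rank-based
#' mutual-top-k recovery: a sampled equicorrelated module leaves its
#' weakest member without any reciprocal top-k edge in a substantial
#' fraction of replicates, so "module membership" would not be ground
#' truth. Remaining genes are independent standard normal noise. One
#' non-module gene carries a planted mutation effect: its dependency in
#' mutant samples is shifted by `mutation_effect` standard deviations.
#'
#' @param n_genes Total genes (default 50).
#' @param n_samples Cell lines (default 200).
#' @param module_size Planted module size (default 9).
#' @param module_r Target pairwise correlation within the module (default
#'   0.9); 0 plants no module.
#' @param n_mutants Mutant samples for the planted mutation (default 20).
#' @param mutation_effect Shift in dependency SD units for mutants (default
#'   -1).
#' @param seed Integer seed.
#' @return List: `dep` (genes x samples matrix), `mut` (binary vector over
#'   samples), `truth` (`module_genes`, `effect_gene`, `mutant_samples`,
#'   `mutation_effect`).
#' @export
simulate_dependency_screen <- function(n_genes = 50L, n_samples = 200L,
                                       module_size = 9L, module_r = 0.9,
                                       n_mutants = 20L, mutation_effect = -1,
                                       seed = 1L) {
  stopifnot(module_size <= n_genes, n_mutants <= n_samples,
            module_r >= 0, module_r < 1)
  set.seed(stage_seed(seed, "dependency"))
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- sprintf("CL%03d", seq_len(n_samples))
  dep <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(genes, samples))
  module_genes <- genes[seq_len(module_size)]
  if (module_r > 0 && module_size > 1L) {
    m <- module_size
    if (n_samples < m + 2L) stop("n_samples too small for the planted module")
    # exact target correlation matrix: ring-graded around module_r
    idx <- seq_len(m)
    ring_d <- outer(idx, idx, function(i, j) pmin(abs(i - j), m - abs(i - j)))
    delta <- min(0.01, (1 - module_r) / 4)
    cmat <- module_r + (2 - ring_d) * delta
    diag(cmat) <- 1
    # orthonormal centered directions -> sample correlations equal cmat exactly
    q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n_samples * m), n_samples, m))))
    z <- t(q[, 2L:(m + 1L), drop = FALSE])
    dep[module_genes, ] <- (t(chol(cmat)) %*% z) * sqrt(n_samples - 1)
  }
  effect_gene <- genes[module_size + 1L]
  mutants <- sample(samples, n_mutants)
  mut <- as.integer(samples %in% mutants)
  names(mut) <- samples
  dep[effect_gene, mutants] <- dep[effect_gene, mutants] + mutation_effect
  list(dep = dep, mut = mut,
       truth = list(module_genes = module_genes, effect_gene = effect_gene,
                    mutant_samples = mutants, mutation_effect = mutation_effect))
}

#' Simulate a CGI methylation cohort with planted group-specific
#' hypomethylation concentrated in one region set
#'
#' CpG islands are placed on synthetic chromosomes; one annotated region
#' set coincides with a chosen CGI subset, and "mutant" samples are
#' hypomethylated by `effect` beta units only at those CGIs. Decoy sets
#' are random CGI subsets of the same size. The universe is the union of
#' all placed CGIs.
#'
#' @param n_cgis Number of CGIs (default 10000).
#' @param n_mut,n_wt Mutant and wild-type sample counts (defaults 40, 160).
#' @param effect Hypomethylation effect in beta units (default 0.3).
#' @param n_planted CGIs overlapped by the planted set (default 300).
#' @param n_decoys Number of decoy sets (default 20).
#' @param noise_sd Per-observation beta noise SD (default 0.08).
#' @param n_chroms Synthetic chromosomes (default 20).
#' @param chrom_size Length of each synthetic chromosome in bp (default
#'   15e6).
#' @param seed Integer seed.
#' @return List: `meth` (samples x CGIs beta matrix), `groups` (logical,
#'   `TRUE` = mutant), `universe` (GRanges of all CGIs), `sets` (named list
#'   of GRanges; `"planted"` first), `chrom_sizes`, `truth`
#'   (`planted_cgis`).
#' @export
simulate_methylation_cohort <- function(n_cgis = 10000L, n_mut = 40L,
                                        n_wt = 160L, effect = 0.3,
                                        n_planted = 300L, n_decoys = 20L,
                                        noise_sd = 0.08, n_chroms = 20L,
                                        chrom_size = 15e6, seed = 1L) {
  stopifnot(n_decoys >= 1L, n_planted <= n_cgis)
  set.seed(stage_seed(seed, "methylation_cohort"))
  chroms <- sample(sprintf("chr%d", seq_len(n_chroms)), n_cgis, replace = TRUE)
  starts <- sample.int(as.integer(chrom_size - 5e3), n_cgis, replace = TRUE)
  widths <- sample(500:2000, n_cgis, replace = TRUE)
  cgi_names <- sprintf("CGI%05d", seq_len(n_cgis))
  universe <- GenomicRanges::GRanges(chroms,
                                     IRanges::IRanges(start = starts,
                                                      width = widths))
  names(universe) <- cgi_names
  universe <- GenomicRanges::sort(universe, ignore.strand = TRUE)
  cgi_names <- names(universe)

  planted_cgis <- sample(cgi_names, n_planted)
  sets <- c(list(planted = universe[planted_cgis]),
            stats::setNames(lapply(seq_len(n_decoys), function(i) {
              universe[sample(cgi_names, n_planted)]
            }), sprintf("decoy_%02d", seq_len(n_decoys))))

  n_samples <- n_mut + n_wt
  groups <- rep(c(TRUE, FALSE), c(n_mut, n_wt))
  baseline <- stats::runif(n_cgis, 0.4, 0.8)
  meth <- matrix(baseline, n_samples, n_cgis, byrow = TRUE) +
    matrix(stats::rnorm(n_samples * n_cgis, 0, noise_sd), n_samples, n_cgis)
  planted_idx <- match(planted_cgis, cgi_names)
  meth[groups, planted_idx] <- meth[groups, planted_idx] - effect
  meth <- pmin(pmax(meth, 0), 1)
  dimnames(meth) <- list(sprintf("S%03d", seq_len(n_samples)), cgi_names)

  chrom_sizes <- stats::setNames(rep(chrom_size, n_chroms),
                                 sprintf("chr%d", seq_len(n_chroms)))
  list(meth = meth, groups = groups, universe = universe, sets = sets,
       chrom_sizes = chrom_sizes, truth = list(planted_cgis = planted_cgis))
}
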