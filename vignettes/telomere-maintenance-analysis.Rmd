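---
title: "Methods: telomere content, allele-specific regulation and dependency associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: telomere content, allele-specific regulation and dependency associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomaint)
```

telomaint implements the computational stages of a telomere-maintenance
analysis of cancer cell lines: telomere content estimated directly from
sequencing reads, harmonized across datasets; allele-specific expression
(ASE) and allele-specific methylation (ASM) at and around *TERT*;
associations between telomere content or mutations and genome-wide
gene-dependency screens; and region-set enrichment of differentially
methylated CpG islands. Every stage has a seeded synthetic-data generator
with planted ground truth, so the full pipeline is exercised end to end
without any external download. This vignette is the package's own account
of the models, the tunable parameters, the numerical choices, and what the
synthetic tests do and do not establish.

## Telomere content from raw reads

A read is *telomeric* when it carries at least `motif_threshold` (default
6) non-overlapping copies of the canonical human telomeric repeat
`TTAGGG`, scanned left to right with exact matching (`N` never matches).
The per-sample estimate is

$$\mathrm{raw\_length} = \frac{T}{S}\cdot\frac{L_{GC}}{n_\mathrm{ends}}$$

where $T$ is the telomeric-read count, $S$ the number of reads whose GC
fraction falls in a narrow band matching the repeat's composition (default
$[0.48, 0.52]$, inclusive; `N` bases excluded from the GC computation),
$L_{GC}$ the genome length within that band (bundled GRCh37 default
332,720,800 bp), and $n_\mathrm{ends} = 46$ the number of chromosome ends
of a diploid human genome. The result is reported in kilobases per
chromosome end. All four constants are arguments. Reads shorter than six
motif lengths can never qualify as telomeric but still count toward totals
and the GC band. When a sample has several read groups, each group is
estimated separately and combined as a mean weighted by per-group total
read counts — read groups often differ in library preparation, and the
weighting keeps the estimate proportional to evidence.

This is a *content* measure, not a physical telomere length: interstitial
and extrachromosomal repeats contribute, and no attempt is made to
distinguish terminal repeats. An optional reverse-complement scan
(`CCCTAA`) covers inputs whose read orientation has not been normalized;
it is off by default so that results are comparable with the common
single-orientation convention.

```{r content-example}
sim <- simulate_reads(5e4, 100, telomere_fraction = 1e-3, seed = 7)
estimate_content(sim$reads, sample = "demo", l_gc = 3e8)
```

## Cross-dataset harmonization

Raw estimates from different datasets are not directly comparable, so each
source is log-transformed (base 2 by default) and z-scored. Z-scores use
the population SD convention (divide by $n$); both the base and the SD
convention are arguments, recorded as attributes on the output. Zero or
negative raw values cannot be log-transformed and are excluded with a
warning rather than silently clamped.

Exome datasets can carry a library-preparation batch effect that shifts
the motif-count spectrum. The frequencies of reads containing *exactly* 4,
5 and 6 motifs are a compact fingerprint of that shift: `detect_batches()`
runs k-means (k = 2, 10 restarts, fixed seed) on the raw three-dimensional
frequency vectors. Frequencies, not absolute counts, are used so that
sequencing depth does not masquerade as batch; no further feature scaling
is applied because the three frequencies share a scale. Labels are
renumbered so the *larger* cluster is the reference (label 0) — a
deterministic convention matching the intuition that the minority batch is
the one to adjust. `recenter()` then shifts the non-reference cluster by
the difference of cluster means, a pure location shift that preserves
within-cluster ordering exactly. No covariate batch model (ComBat-style)
is attempted: the observed artifact is a two-cluster location shift, and
the correction is matched to it.

Sources are merged per cell line: samples present in both sources get the
arithmetic mean of the two z-values, samples in one source keep theirs,
and provenance is recorded. Merging is symmetric and self-merge is the
identity. Duplicate samples within a source are an error unless a
replicate policy (mean) is configured.

## Allele-specific expression

At a heterozygous SNP, monoallelic expression (MAE) shows as a skewed RNA
allele balance relative to the DNA balance. Records are filtered to at
least 8 DNA reads supporting *each* allele (inclusive — "at least eight"),
a passing upstream caller filter, and RNA depth of at least 8. Upstream
caller thresholds (base and mapping quality) are the count producer's
responsibility and are treated as metadata.

With a pseudocount of 0.5 in every cell of the context-by-allele table,
the odds ratio anchored on the RNA-major allele $M$ is

$$\mathrm{OR} = \frac{\mathrm{dna}_{m}/\mathrm{dna}_{M}}{\mathrm{rna}_{m}/\mathrm{rna}_{M}},$$

with $m$ the minor allele. Anchoring both ratios on the RNA-major allele
makes MAE detection one-sided — allelic skew in RNA relative to DNA always
inflates the OR above 1 — which is what a single strict cutoff requires:
MAE is called when OR > 5, else biallelic (BAE). The convention is
interpretive (an OR can be oriented either way) and is therefore stated
here and in the function documentation rather than silently assumed. The
OR is invariant under exchanging the ref/alt labels; RNA ties are broken
by the larger DNA count, which preserves that invariance. When several
SNPs are informative for one sample and gene, the SNP with the greatest
total RNA depth is used; when the same SNP is seen from several DNA
sources, the deepest source wins first. Sample-gene pairs with no
surviving record are reported `unassessable`, not dropped.

## Allele-specific methylation

For two adjacent CpGs covered by the same bisulfite reads, the four joint
methylation states (mm, mu, um, uu) form a 2×2 table. Without ASM, a
semi-methylated pair spreads over the discordant states; with ASM, reads
concentrate in mm and uu. With 0.5 pseudocounts,

$$\Phi = \frac{\dot{mm}\,\dot{uu} - \dot{mu}\,\dot{um}}
{\sqrt{(\dot{mm}+\dot{mu})(\dot{um}+\dot{uu})(\dot{mm}+\dot{um})(\dot{mu}+\dot{uu})}}$$

Negative values (discordant excess) carry no ASM signal and are rounded to
0. The pseudocounts make the statistic defined for every table; the
implementation is checked against an exact-integer oracle over the full
grid of cell counts 0–12 (28,561 tables) to 1e-12.

Filters, in order: coverage ≥ 8 reads; pair observed at that coverage in
at least 5% of cohort samples; per-CpG methylation (from the pair's own
marginals — self-contained, no external methylation track needed) within
[0.1, 0.9] on both CpGs, removing fully methylated or unmethylated pairs
that cannot show imbalance. Regional ASM is the unweighted mean of valid
Φ over pairs whose *first* CpG lies in the region (no double counting at
region boundaries), after excluding pairs with valid estimates in fewer
than 25% of cohort samples. The 25% rule is applied per pair (a per-CpG
variant is the natural alternative; per-pair is self-consistent with the
pair being the unit of scoring). The five *TERT*-locus regions (promoter,
three CpG-island segments, remaining gene body; GRCh37 chr5 coordinates,
1-based inclusive) are bundled as `tert_locus_regions()`.

Absolute CpG-island methylation is the mean beta over profiled CpGs in the
island, requiring at least 8 CpGs for sequencing-based input (4 is the
customary minimum for array input; the minimum is an argument).

## Dependency associations

Dependency matrices are genes × samples, more negative meaning stronger
dependence. Per-gene association with a sample-level target (merged
telomere content) is the Pearson correlation on pairwise-complete samples
with the exact two-tailed t-based p-value.

Codependency expansion starts from a seed set (e.g. the CST complex) and
admits gene $y$ when, for some current member $x$, $r^2(x,y)$ ranks in the
top 5 of $x$ against all other genes *and* in the top 5 of $y$ — both
rankings always over the full gene universe, self excluded, ties at the
k-th rank all admitted (deterministic without arbitrary ordering). The
rule is applied four times; the set grows monotonically. Full-universe
re-ranking is the literal reading of a mutual "top five vs. all other
genes" criterion and is what the brute-force oracle in the test suite
implements independently.

Mutation-dependency association compares mutant (damaging or hotspot,
treated as one class by default; channels can be tested separately)
against wild-type samples with a two-sided Mann-Whitney U test (midrank
ties) and the rank-biserial effect size ($-1$ when every mutant is more
dependent than every wild-type). Genes with fewer than 5 mutants are
excluded. Families of tests are Benjamini-Hochberg adjusted and ranked by
$\mathrm{sign}(\mathrm{effect})\cdot(-\log_{10} q)$. Genome-wide scans use
a vectorized normal-approximation U test with tie and continuity
corrections, matching `wilcox.test(exact = FALSE, correct = TRUE)` to
1e-12; single-pair calls use `wilcox.test()` itself, which is exact for
small untied samples. Codependency submatrices are clustered with Ward
linkage on $1 - r$ distances.

Marker feature tables are pre-filtered with the conventional thresholds:
expression as $\log_2(\mathrm{TPM}+1)$ dropping SD < 0.25; exon inclusion
dropping features missing in more than 800 samples or SD < 0.1;
methylation regions dropping SD < 0.05. All thresholds are arguments.

## Region-set enrichment

CpG islands are ranked by the significance of the methylation difference
between groups (e.g. *TERT*-promoter mutant vs wild type), two-sided
Mann-Whitney per island, keeping only islands changed in the
hypomethylated direction (the direction of interest for a
promoter-mutant signature; the opposite tail is available via a flag —
ranking within one direction keeps the interest set interpretable). The
top 1000 form the interest set; all tested islands are the universe.

For each annotated region set, the 2×2 table (interest vs universe-rest) ×
(overlap vs no overlap) is tested with a two-sided Fisher's exact test,
computed by point-probability summation over the hypergeometric support —
the standard exact definition, matching `fisher.test` and verifiable
against a direct hypergeometric oracle. Overlap is any 1-bp intersection
(a minimum-fraction option exists but defaults off); the odds ratio is the
sample OR, with a 0.5 continuity correction only when a zero cell occurs
(flagged). Region sets tested against one database are corrected as one BH
family. Telomere proximity uses the same machinery with "overlap" replaced
by "within `window` (default 10 Mb) of either chromosome end".

Coordinates are 1-based inclusive internally; BED input/output converts
from/to 0-based half-open at the boundary (via rtracklayer).

## Synthetic data and what the tests show

One global seed drives independent per-stage substreams derived by a
stable hash of the stage name, so adding a stage never perturbs another
stage's draws; identical seed and configuration reproduce outputs
byte-identically. Default generator settings are the study conditions used
throughout the test suite:

* **Reads** — 100-nt reads, telomeric with probability $f$ (tandem
  `TTAGGG` at a random phase, ≥ 15 complete motifs), background at a
  target GC of 0.5; $f$ spans $10^{-4}$–$10^{-2}$ at $2\times10^5$ reads.
* **Batches** — latent log2 content N(3, 1) (≈ 8 kb median), a 1.5-log2
  planted shift on one of two 200-sample batches, and motif-frequency
  features at batch-specific centers separated far beyond their spread.
* **ASE** — DNA binomial(depth, 0.5), RNA binomial(depth, 0.5) for BAE or
  binomial(depth, 0.01) for MAE, depths 30–100.
* **CpG pairs** — reads drawn from two alleles; for ASM pairs each CpG
  reflects its allele's state with probability `purity`, null pairs draw
  states independently.
* **Dependency screens** — 50 genes × 200 samples; the 9-gene module is
  planted with an *exact* correlation structure: a Cholesky factor of a
  ring-graded target matrix (pairwise $r$ within ±0.02 of the 0.9 target,
  nearest ring neighbors highest) applied to exactly orthonormal centered
  directions. A sampled equicorrelated module was deliberately rejected:
  its sample correlation matrix acquires a multiplicative
  estimated-loading structure under which the weakest member falls outside
  every peer's top-5 in roughly one replicate in six — independent of
  sample size — so "module membership" would not be a recoverable ground
  truth under the mutual-top-5 rule that defines codependency here.
  Planting exact correlations makes the planted truth well defined and
  recovery deterministic. One non-module gene carries a −1 SD dependency
  shift in 20 mutant samples.
* **Methylation cohorts** — 10,000 CGIs on 20 synthetic 15-Mb
  chromosomes, 40 mutant / 160 wild-type samples, baseline beta
  Uniform(0.4, 0.8) with 0.08 noise, a 0.3-beta hypomethylation planted
  only in the 300 CGIs of the planted set, 20 random decoy sets.

These generators emulate the *structure* of real inputs (planted
fractions, shifts, allelic states, modules, region-set signal), not their
marginal distributions: no read errors or quality scores, no realistic
GC-coverage coupling, no linkage between SNPs, no spatial autocorrelation
of methylation, no screen-specific noise. Passing tests therefore
establish that the statistics, filters and recovery machinery are
implemented correctly and are calibrated under their own assumptions —
they do not establish robustness to the failure modes of real sequencing
data.

Two calibration facts are worth stating plainly. First, under the null,
the genome-wide Mann-Whitney scan's raw p < 0.01 rate sits inside the
binomial 99% band of the nominal level, and BH at q < 0.01 makes
essentially no false calls. Second, the power to detect a 1-SD dependency
shift with 20 mutants among 200 samples at q < 0.01 is about 93% — high,
but detectably below certainty; rank tests pay a small efficiency price
relative to normal-theory tests at this effect size, so effects of this
magnitude are occasionally missed.

## Numerical and design choices

* Motif counting is non-overlapping, left-to-right, exact-match, stored
  orientation by default; the reverse-complement scan is opt-in.
* z-scores: population SD, log base 2 (both arguments).
* k-means: fixed seed, 10 restarts, raw frequencies; an all-identical
  feature matrix is a hard error (no batch structure to find).
* Φ: pseudocounts guarantee a finite value for every table; clipping at 0
  is applied after the exact computation.
* Degenerate inputs fail loudly: fewer than 2 positive values for
  standardization, zero-variance genes, interest = universe, empty result
  families, a GC band containing no reads.
* Tie-breaks are deterministic everywhere: lexicographic SNP/source for
  ASE selection, inclusive ties at the k-th codependency rank, larger
  cluster as batch reference.
* Problem sizes in the test suite are the generator defaults above; the
  acceptance script uses the same sizes with 25 enrichment replicates.

## Known limitations

* Telomere content is a genome-wide repeat abundance, not a length; no
  exome-capture-specific correction is applied beyond the two-cluster
  batch recentering.
* The ASE odds-ratio orientation is an interpretive choice (documented
  above); alternative orientations change the numeric OR but not the
  ordering of evidence for MAE.
* The vectorized Mann-Whitney scan is asymptotic; for very small groups
  use the single-pair functions, which switch to the exact distribution.
* Enrichment treats regions as exchangeable units; no correction for
  region length or CpG density beyond the universe construction.
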