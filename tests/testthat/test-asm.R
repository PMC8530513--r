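test_that("Phi matches the printed-formula hand computations", {
  expect_equal(phi(10, 0, 0, 10), 110 / 121)
  expect_equal(phi(5, 5, 5, 5), 0)
  expect_equal(phi(0, 10, 10, 0), 0)                 # negative raw, clipped
  expect_lt(phi(0, 10, 10, 0, clip = FALSE), 0)
})

test_that("Phi is invariant under simultaneous (mm,uu) and (mu,um) exchange", {
  set.seed(5)
  for (i in 1:100) {
    cts <- rpois(4, 6)
    expect_equal(phi(cts[1], cts[2], cts[3], cts[4]),
                 phi(cts[4], cts[3], cts[2], cts[1]))
  }
})

test_that("Phi agrees with the exact-integer oracle on a count grid", {
  g <- expand.grid(mm = 0:8, mu = 0:8, um = 0:8, uu = 0:8)
  diff <- abs(phi(g$mm, g$mu, g$um, g$uu) - oracle_phi(g$mm, g$mu, g$um, g$uu))
  expect_lt(max(diff), 1e-12)
})

test_that("pair filters apply coverage, cohort prevalence and boundary rules", {
  # cohort of 40 samples; pair P1 covered everywhere, P2 in 1 sample (2.5%)
  mk <- function(sample, pos_a, mm, mu, um, uu) {
    data.frame(sample = sample, chrom = "chr5", pos_a = pos_a,
               pos_b = pos_a + 30, mm = mm, mu = mu, um = um, uu = uu)
  }
  cohort <- do.call(rbind, lapply(sprintf("S%02d", 1:40), function(s) {
    mk(s, 100, 5, 5, 5, 5)
  }))
  rare <- mk("S01", 500, 5, 5, 5, 5)
  lowcov <- mk("S02", 100, 2, 2, 2, 1)       # coverage 7 < 8
  extreme <- mk("S03", 900, 19, 0, 1, 0)     # m_a = 0.95: fully methylated
  flt <- pair_filters(rbind(cohort, rare, lowcov, extreme))
  expect_true(all(flt$valid[flt$pos_a == 100 & flt$coverage >= 8]))
  expect_false(any(flt$valid[flt$pos_a == 500]))   # prevalence 1/40 < 5%
  expect_false(any(flt$valid[flt$coverage == 7]))
  expect_false(any(flt$valid[flt$pos_a == 900]))
})

test_that("planted ASM increases mean Phi monotonically with allelic purity", {
  means <- vapply(c(0.6, 0.8, 0.95), function(p) {
    sim <- simulate_cpg_pairs(n_pairs = 40, n_samples = 10, coverage = 30,
                              purity = p, asm_fraction = 1, seed = 21)
    mean(phi(sim$pairs$mm, sim$pairs$mu, sim$pairs$um, sim$pairs$uu))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # independent-state null: mean Phi small after clipping
  null <- simulate_cpg_pairs(n_pairs = 60, n_samples = 10, coverage = 30,
                             asm_fraction = 0, seed = 22)
  expect_lt(mean(phi(null$pairs$mm, null$pairs$mu, null$pairs$um,
                     null$pairs$uu)), 0.15)
})

test_that("TERT locus regions are the five printed non-overlapping chr5 intervals", {
  regs <- tert_locus_regions()
  expect_equal(length(regs), 5L)
  expect_true(all(as.character(GenomicRanges::seqnames(regs)) == "chr5"))
  expect_equal(GenomicRanges::width(regs["promoter"]), 3398L)
  ov <- GenomicRanges::findOverlaps(regs, regs)
  expect_equal(length(ov), 5L)   # self-hits only: mutually non-overlapping
  expect_setequal(names(regs),
                  c("promoter", "CGI_1", "CGI_2", "CGI_3", "gene_body"))
})

test_that("regional ASM averages valid pairs assigned by their first CpG", {
  regions <- GenomicRanges::GRanges("chr5",
                                    IRanges::IRanges(c(100, 1000), c(500, 2000)))
  names(regions) <- c("r1", "r2")
  scores <- data.frame(sample = "s1", chrom = "chr5",
                       pos_a = c(150, 400, 1500, 495),
                       pos_b = c(180, 430, 1530, 1010),
                       phi = c(0.2, 0.6, 0.9, 0.4),
                       valid = c(TRUE, TRUE, TRUE, TRUE))
  m <- region_asm(scores, regions, min_valid_frac = 0)
  expect_equal(m["s1", "r1"], mean(c(0.2, 0.6, 0.4)))  # 4th pair: first CpG in r1
  expect_equal(m["s1", "r2"], 0.9)
  # single valid pair and missing region
  single <- scores[1, ]
  m1 <- region_asm(single, regions, min_valid_frac = 0)
  expect_equal(m1["s1", "r1"], 0.2)
  expect_true(is.na(m1["s1", "r2"]))
  # the 25% cohort-validity rule drops mostly-invalid pairs
  two <- rbind(transform(scores, sample = "s1"),
               transform(scores, sample = "s2", valid = FALSE),
               transform(scores, sample = "s3", valid = FALSE),
               transform(scores, sample = "s4", valid = FALSE))
  m25 <- region_asm(two, regions, min_valid_frac = 0.5)
  expect_true(all(is.na(m25)))
})

test_that("CGI methylation averages profiled CpGs with a minimum count", {
  islands <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 1000))
  names(islands) <- "cgi1"
  betas8 <- data.frame(sample = "s1", chrom = "chr1",
                       pos = seq(110, 810, by = 100),
                       beta = c(0, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(cgi_methylation(betas8, islands)["s1", "cgi1"], 0.5)
  betas7 <- betas8[1:7, ]
  expect_true(is.na(cgi_methylation(betas7, islands)["s1", "cgi1"]))
  expect_equal(cgi_methylation(betas7, islands, min_cpgs = 4)["s1", "cgi1"],
               mean(betas7$beta))
  zero <- transform(betas8, beta = 0)
  expect_equal(unname(cgi_methylation(zero, islands)[, "cgi1"]), 0)
})
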