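test_that("dependency-target correlation matches the closed-form t oracle", {
  dep <- rbind(G1 = c(1, -1, 1, -1), G2 = c(1, 1, -1, -1),
               G3 = c(0.5, 1.5, 2.5, 3.5))
  colnames(dep) <- paste0("s", 1:4)
  target <- setNames(c(1, -1, 1, -1), paste0("s", 1:4))
  res <- correlate_dependencies(dep, target)
  expect_equal(res$effect[res$gene == "G1"], 1)
  expect_lt(res$p[res$gene == "G1"], 1e-10)
  expect_equal(res$effect[res$gene == "G2"], 0)

  set.seed(4)
  dep2 <- matrix(rnorm(5 * 30), 5, 30,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  tgt <- setNames(rnorm(30), paste0("s", 1:30))
  res2 <- correlate_dependencies(dep2, tgt)
  for (i in 1:5) {
    ct <- cor.test(dep2[i, ], tgt)
    expect_equal(res2$effect[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(res2$p[i], ct$p.value, tolerance = 1e-10)
  }
  flat <- matrix(1, 1, 30, dimnames = list("flat", paste0("s", 1:30)))
  expect_warning(res_flat <- correlate_dependencies(flat, tgt), "zero variance")
  expect_true(is.na(res_flat$effect))
})

test_that("codependency expansion recovers a planted module and matches the brute-force oracle", {
  for (s in c(1, 2, 3)) {
    sim <- simulate_dependency_screen(module_r = 0.9, seed = s)
    got <- codependency_expand(sim$dep, sim$truth$module_genes[1:3])
    expect_setequal(got, sim$truth$module_genes)
    oracle <- oracle_codependency(sim$dep, sim$truth$module_genes[1:3])
    expect_setequal(got, oracle)
  }
  # fixed points
  sim <- simulate_dependency_screen(module_r = 0, seed = 8)
  seed_set <- c("G001", "G030", "G045")
  expect_equal(codependency_expand(sim$dep, seed_set, iterations = 0), seed_set)
  expect_setequal(codependency_expand(sim$dep, seed_set),
                  oracle_codependency(sim$dep, seed_set))
  expect_error(codependency_expand(sim$dep, "NOPE"), "NOPE")
})

test_that("mutation association gives exact ranks, effects and exclusions", {
  dep <- c(1, 2, 3, 4, 5)
  mut <- c(1, 1, 0, 0, 0)
  res <- mutation_association(dep, mut, min_mutants = 2)
  expect_equal(res$effect, -1)          # complete separation, mutants lower
  expect_equal(res$p, 0.2)              # exact: 2 of 10 splits as extreme
  # below the mutant-count floor: excluded
  res5 <- mutation_association(dep, mut, min_mutants = 5)
  expect_true(res5$excluded && is.na(res5$p))
  # all mutant: excluded
  expect_true(mutation_association(dep, rep(1, 5), min_mutants = 2)$excluded)
  # identical distributions: effect near 0
  set.seed(6)
  x <- rep(1:10, 4)
  lab <- sample(rep(c(0, 1), 20))
  expect_lt(abs(mutation_association(x, lab, min_mutants = 5)$effect), 0.2)
})

test_that("the genome-wide mutation scan agrees with wilcox.test per gene", {
  set.seed(13)
  dep <- matrix(rnorm(20 * 60), 20, 60,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:60)))
  mut <- rbinom(60, 1, 0.3)
  res <- mutation_associations(dep, mut, min_mutants = 5)
  for (i in c(1, 7, 20)) {
    ref <- wilcox.test(dep[i, mut == 1], dep[i, mut == 0],
                       exact = FALSE, correct = TRUE)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(res$effect[i], rank_biserial(dep[i, mut == 1], dep[i, mut == 0]),
                 tolerance = 1e-12)
  }
})

test_that("signed q-values follow the BH step-up and carry the effect sign", {
  res <- data.frame(effect = c(-0.5, 0.3, 0.2, -0.1),
                    p = c(0.001, 0.02, 0.03, 0.9))
  out <- signed_q(res)
  expect_equal(sort(out$q), sort(c(0.004, 0.04, 0.04, 0.9)))
  expect_equal(out$q[order(out$p)], oracle_bh(sort(res$p)))
  expect_equal(sign(out$signed_q), sign(out$effect))
  expect_equal(out$signed_q[out$p == 0.001], log10(0.004))  # negative effect
  expect_equal(abs(out$signed_q), -log10(out$q))
  # q ordering preserves p ordering (BH monotone)
  expect_false(is.unsorted(out$q[order(out$p)]))
  # all p = 1: all signed q are 0
  flat <- signed_q(data.frame(effect = c(1, -1), p = c(1, 1)))
  expect_equal(flat$signed_q, c(0, 0))
  expect_error(signed_q(data.frame(effect = numeric(0), p = numeric(0))),
               "empty")
})

test_that("Ward clustering separates planted blocks and returns a symmetric matrix", {
  set.seed(17)
  f1 <- rnorm(80); f2 <- rnorm(80)
  dep <- rbind(
    t(sapply(1:4, function(i) 0.95 * f1 + 0.3 * rnorm(80))),
    t(sapply(1:4, function(i) 0.95 * f2 + 0.3 * rnorm(80))))
  rownames(dep) <- paste0("g", 1:8)
  res <- cluster_codependency(dep, rownames(dep))
  expect_equal(res$correlation, t(res$correlation))
  expect_equal(unname(diag(res$correlation)), rep(1, 8))
  top_split <- cutree(res$hclust, k = 2)
  expect_equal(length(unique(top_split[paste0("g", 1:4)])), 1L)
  expect_equal(length(unique(top_split[paste0("g", 5:8)])), 1L)
  expect_error(cluster_codependency(dep, c("g1", "g2")), "at least 3")
})

test_that("feature filters drop low-variance and high-missingness rows", {
  expr <- rbind(constant = rep(3, 10), variable = 2^(1:10))
  out <- feature_filters(expr, "expression")
  expect_equal(rownames(out), "variable")
  expect_equal(unname(feature_filters(matrix(0, 1, 3,
                                             dimnames = list("z", NULL)),
                                      "expression", sd_min = 0)[1, 1]),
               0)  # log2(0 + 1)
  exon <- rbind(sparse = c(rep(NA, 5), rnorm(5)), dense = rnorm(10))
  expect_equal(rownames(feature_filters(exon, "exon", max_missing = 4)), "dense")
  meth <- rbind(flat = rep(0.5, 10) + rnorm(10, 0, 0.001), var = runif(10))
  expect_equal(rownames(feature_filters(meth, "methylation")), "var")
})
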