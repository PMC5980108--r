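test_that("expressedUniverse keeps genes expressed in either condition", {
  counts <- rbind(g1 = c(12, 0), g2 = c(9, 9), g3 = c(0, 40))
  colnames(counts) <- c("norm_r1", "hyp_r1")
  cond <- c(norm_r1 = "normoxia", hyp_r1 = "hypoxia")
  u <- expressedUniverse(counts, cond, use = c("normoxia", "hypoxia"),
                        minReads = 10)
  expect_setequal(u, c("g1", "g3"))
  expect_setequal(expressedUniverse(counts, cond,
                                    use = c("normoxia", "hypoxia"),
                                    minReads = 0),
                  c("g1", "g2", "g3"))
  counts[1, 1] <- -1
  expect_error(expressedUniverse(counts), "non-negative")
})

test_that("selectRegulated applies strict FC and FDR cutoffs", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   log2fc = c(1.0, 0.3, -1.2),
                   fdr = c(0.001, 0.001, 0.001))
  up <- selectRegulated(de, "up", fcThreshold = 1.5, fdrThreshold = 0.05)
  expect_identical(up@geneIds, "a")           # log2(1.5) ~ 0.585
  down <- selectRegulated(de, "down", fcThreshold = 1.5, fdrThreshold = 0.05)
  expect_identical(down@geneIds, "c")
  # boundary values are excluded (strict inequalities)
  de2 <- data.frame(gene_id = c("x", "y"),
                    log2fc = c(log2(1.5), 1),
                    fdr = c(0.001, 0.05))
  expect_length(selectRegulated(de2, "up", 1.5, 0.05)@geneIds, 0L)
  # fdr threshold 0 selects nothing
  expect_length(selectRegulated(de, "up", 1.5, 0)@geneIds, 0L)
})

test_that("expandToIsoforms reports absent genes instead of dropping them", {
  db <- tinyDb()
  ex <- expandToIsoforms(c("g1", "g3"), db)
  expect_setequal(ex$transcript_ids, c("g1-t1", "g1-t2", "g3-t1"))
  expect_length(ex$missing_genes, 0L)
  ex2 <- expandToIsoforms(c("g1", "absent"), db)
  expect_identical(ex2$missing_genes, "absent")
  # duplicate input genes: set semantics, no double counting
  ex3 <- expandToIsoforms(c("g1", "g1"), db)
  expect_identical(sort(ex3$transcript_ids), sort(c("g1-t1", "g1-t2")))
})

test_that("sampleBackground is reproducible from its seed", {
  u <- sprintf("g%03d", 1:50)
  b1 <- sampleBackground(u, nGenes = 10, seed = 1)
  b2 <- sampleBackground(u, nGenes = 10, seed = 1)
  b3 <- sampleBackground(u, nGenes = 10, seed = 2)
  expect_identical(b1@geneIds, b2@geneIds)
  expect_false(identical(b1@geneIds, b3@geneIds))
  expect_length(unique(b1@geneIds), 10L)      # without replacement
  expect_true(all(b1@geneIds %in% u))
  # exhaustive case and infeasible request
  expect_setequal(sampleBackground(u, nGenes = 50, seed = 3)@geneIds, u)
  expect_error(sampleBackground(u, nGenes = 51, seed = 3), "cannot draw")
  # drawing does not disturb the global RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sampleBackground(u, nGenes = 5, seed = 7))
  expect_identical(runif(1), before)
})

test_that("ecdfTable yields a right-continuous step ending at 1", {
  e <- ecdfTable(c(1, 2, 3))
  expect_equal(e$value, c(1, 2, 3))
  expect_equal(e$cumfrac, c(1, 2, 3) / 3)
  # ties pooled into one step
  e2 <- ecdfTable(c(5, 5, 5))
  expect_identical(nrow(e2), 1L)
  expect_equal(e2$cumfrac, 1)
  expect_error(ecdfTable(numeric(0)), "non-empty")
  set.seed(71)
  for (i in 1:20) {
    e <- ecdfTable(round(rnorm(sample(1:100, 1)), 1))
    expect_true(all(diff(e$value) > 0))
    expect_true(all(diff(e$cumfrac) > 0))
    expect_equal(e$cumfrac[nrow(e)], 1)
  }
})

test_that("ksTwoSample matches ECDF geometry on edge cases", {
  x <- c(1, 2, 3, 4)
  same <- ksTwoSample(x, x)
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)
  disjoint <- ksTwoSample(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disjoint@statistic, 1)
  expect_error(ksTwoSample(numeric(0), x), "non-empty")
})

test_that("ksTwoSample is symmetric and monotone-transform invariant", {
  set.seed(81)
  for (i in 1:20) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), mean = 0.5)
    k1 <- ksTwoSample(a, b); k2 <- ksTwoSample(b, a)
    expect_equal(k1@statistic, k2@statistic)
    expect_equal(k1@pValue, k2@pValue)
    k3 <- ksTwoSample(exp(a), exp(b))   # strictly monotone transform
    expect_equal(k1@statistic, k3@statistic)
  }
})

test_that("exact permutation KS p agrees with the exact null distribution", {
  set.seed(91)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(4)
    pkg <- ksTwoSample(a, b, exact = TRUE)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = TRUE))
    expect_equal(pkg@statistic, unname(ref$statistic))
    expect_equal(pkg@pValue, ref$p.value, tolerance = 1e-12)
  }
  # n1 = n2 = 5 as well
  a <- c(0.1, 0.9, 1.4, 2.2, 3.3); b <- c(0.5, 1.1, 1.2, 2.8, 4.0)
  expect_equal(ksTwoSample(a, b, exact = TRUE)@pValue,
               suppressWarnings(stats::ks.test(a, b, exact = TRUE))$p.value)
})

test_that("dichotomizedEnrichment computes chi-squared on 2x2 ARE classes", {
  groups <- list(a = c(rep(0, 30), rep(3, 70)),
                 b = c(rep(0, 10), rep(3, 90)))
  d <- dichotomizedEnrichment(groups)
  expect_equal(d$chi2, 12.5)                  # hand computation: E = 20/80
  expect_equal(d$p_raw, 1 - pchisq(12.5, 1))
  # identical proportions give the null result exactly
  g2 <- list(a = c(rep(0, 30), rep(3, 70)), b = c(rep(0, 30), rep(3, 70)))
  d2 <- dichotomizedEnrichment(g2)
  expect_equal(d2$chi2, 0)
  expect_equal(d2$p_raw, 1)
})

test_that("chi-squared equals the squared two-proportion z statistic", {
  set.seed(101)
  for (i in 1:20) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    s1 <- rbinom(1, n1, runif(1, .1, .9)); s2 <- rbinom(1, n2, runif(1, .1, .9))
    g <- list(a = c(rep(0, n1 - s1), rep(9, s1)),
              b = c(rep(0, n2 - s2), rep(9, s2)))
    d <- dichotomizedEnrichment(g)
    p1 <- s1 / n1; p2 <- s2 / n2; pp <- (s1 + s2) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    if (is.finite(z)) expect_equal(d$chi2, z^2, tolerance = 1e-9)
  }
})

test_that("Bonferroni identity holds for every emitted comparison", {
  set.seed(111)
  groups <- lapply(setNames(1:4, paste0("grp", 1:4)), function(i)
    sample(c(0, 1, 3), 100, replace = TRUE))
  d <- dichotomizedEnrichment(groups)             # 6 pairwise comparisons
  expect_identical(nrow(d), 6L)
  expect_true(all(d$m == 6))
  expect_equal(d$p_adj, pmin(1, d$m * d$p_raw))
  # explicit capping example
  d2 <- dichotomizedEnrichment(groups[1:2], familySize = 6)
  expect_equal(d2$p_adj, min(1, 6 * d2$p_raw))
  expect_error(dichotomizedEnrichment(groups, familySize = 2), "at least")
  expect_error(dichotomizedEnrichment(list(a = numeric(0), b = 1)),
               "non-empty")
})
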