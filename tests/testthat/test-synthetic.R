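test_that("generateUTR realizes the planted pentamer architecture exactly", {
  # no pentamer, GC-only background
  s0 <- generateUTR(50, nPentamers = 0, auContextFraction = 0, seed = 1)
  expect_identical(nchar(s0), 50L)
  expect_false(grepl("[AU]", s0))
  expect_equal(computeAREScore(s0)@score, 0)
  # one pentamer in GC context scores exactly the pentamer weight
  s1 <- generateUTR(60, nPentamers = 1, auContextFraction = 0, seed = 2)
  expect_equal(computeAREScore(s1)@score, 1)
  # overlapping run: gap 4 chains pentamers through the shared A
  s3 <- generateUTR(80, nPentamers = 3, pentamerGap = 4, seed = 3)
  expect_identical(length(findPentamers(s3)), 3L)
  expect_equal(diff(pentamerStarts(findPentamers(s3))), c(4L, 4L))
})

test_that("generateUTR output always satisfies its planted contract", {
  set.seed(141)
  for (i in 1:40) {
    np <- sample(0:4, 1)
    gap <- sample(c(4, 6, 8, 12), 1)
    len <- sample(80:200, 1)
    au <- runif(1, 0, 0.6)
    s <- generateUTR(len, np, gap, au, seed = i)
    expect_identical(nchar(s), len)
    expect_identical(length(findPentamers(s)), as.integer(np))
  }
})

test_that("generateUTR is deterministic and validates its spec", {
  expect_identical(generateUTR(100, 2, seed = 5), generateUTR(100, 2, seed = 5))
  expect_false(identical(generateUTR(100, 2, seed = 5),
                         generateUTR(100, 2, seed = 6)))
  expect_error(generateUTR(10, 3, pentamerGap = 8, seed = 1), "do not fit")
  expect_error(generateUTR(100, 2, pentamerGap = 2, seed = 1),
               "self-contradictory")
})

test_that("scrambleSequence permutes composition and removes motifs", {
  asCounts <- function(s) table(strsplit(s, "")[[1]])
  scr <- scrambleSequence(ARE_PROBE, seed = 1)
  expect_identical(nchar(scr), 45L)
  expect_identical(asCounts(scr), asCounts(normalizeAlphabet(ARE_PROBE)))
  expect_length(findPentamers(scr), 0L)
  # composition preserved on random inputs too
  set.seed(151)
  for (i in 1:20) {
    s <- randomRNA(sample(10:60, 1), probs = c(A = .3, U = .3, G = .2, C = .2))
    p <- scrambleSequence(s, seed = i, forbidPentamers = FALSE)
    expect_identical(asCounts(p), asCounts(s))
  }
  # degenerate input: permutation is the identity
  expect_identical(scrambleSequence("AAAAA", seed = 1), "AAAAA")
  # exhausted resampling budget is a constraint error
  expect_error(scrambleSequence(strrep("AUUUA", 30), seed = 1,
                                maxAttempts = 2), "attempts")
})

test_that("generateTimecourse produces the planted decay law", {
  tc <- generateTimecourse(60, cv = 0, seed = 1)
  expect_equal(tc@normalized, 100 * exp(-log(2) * tc@times / 60))
  expect_equal(halfLife(fitOnePhaseDecay(tc)), 60, tolerance = 1e-8)
  # noisy series: pinned start, different seeds differ
  a <- generateTimecourse(60, cv = 0.15, seed = 1)
  b <- generateTimecourse(60, cv = 0.15, seed = 2)
  expect_equal(a@normalized[1], 100)
  expect_false(identical(a@normalized, b@normalized))
  expect_error(generateTimecourse(60, cv = -0.1, seed = 1), "cv")
  expect_error(generateTimecourse(-5, cv = 0, seed = 1), "tHalf")
})

test_that("generateExperiment plants structure the pipeline can recover", {
  sim <- generateExperiment(nGenes = 150, seed = 17)
  expect_identical(sort(unique(transcriptMap(sim$db)$gene_id)),
                   sim$truth$gene_id)
  expect_identical(ncol(sim$counts), 18L)     # 3 cond x 2 geno x 3 reps
  expect_true(all(sim$counts >= 0))
  # ARE identity is structural: scoring recovers the planted classes
  sc <- scoreTranscriptome(sim$db)
  gene_are <- setNames(sim$truth$are, sim$truth$gene_id)
  expect_identical(unname(gene_are[sc$gene_id]), sc$are_class)
  # genotype difference planted on ARE genes only
  expect_equal(mean(sim$truth$delta[sim$truth$are]), 1.5, tolerance = 0.15)
  expect_equal(mean(sim$truth$delta[!sim$truth$are]), 0, tolerance = 0.1)
  expect_error(generateExperiment(nGenes = 50, nReplicates = 0, seed = 1),
               "nReplicates")
})

test_that("generateExperiment is a pure function of its seed", {
  a <- generateExperiment(nGenes = 60, seed = 23)
  b <- generateExperiment(nGenes = 60, seed = 23)
  expect_identical(as.character(utrSequences(a$db)),
                   as.character(utrSequences(b$db)))
  expect_identical(a$counts, b$counts)
  expect_identical(a$de, b$de)
  c_ <- generateExperiment(nGenes = 60, seed = 24)
  expect_false(identical(a$counts, c_$counts))
})

test_that("planted repression effects average to their specification", {
  # mean delta (ko - ctrl) among ARE genes ~ repression_ko - repression_ctrl
  deltas <- vapply(1:3, function(s) {
    sim <- generateExperiment(nGenes = 120, seed = s,
                              reoxRepressionCtrl = -2,
                              reoxRepressionKo = -0.5)
    mean(sim$truth$delta[sim$truth$are])
  }, numeric(1))
  expect_equal(mean(deltas), 1.5, tolerance = 0.1)
})

test_that("generateScoreSample hits its ARE-positive fraction", {
  s <- generateScoreSample(5000, 0.4, seed = 31)
  expect_equal(mean(s >= 2), 0.4, tolerance = 0.03)
  expect_true(all(s >= 0))
  expect_identical(generateScoreSample(100, 0.2, seed = 1),
                   generateScoreSample(100, 0.2, seed = 1))
})
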