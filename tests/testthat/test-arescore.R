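test_that("findPentamers reports all occurrences, including overlaps", {
  expect_identical(pentamerStarts(findPentamers("AUUUA")), 0L)
  expect_identical(pentamerStarts(findPentamers("AUUUAUUUA")), c(0L, 4L))
  expect_length(findPentamers(""), 0L)
  expect_length(findPentamers("GCGC"), 0L)
  # printed ARE probe and its scrambled control
  expect_identical(pentamerStarts(findPentamers(ARE_PROBE)), c(24L, 28L))
  expect_length(findPentamers(SCRAMBLED_PROBE), 0L)
})

test_that("findPentamers agrees with the naive sliding-window oracle", {
  set.seed(31)
  for (i in 1:300) {
    s <- randomRNA(sample(5:120, 1),
                   probs = c(A = .3, U = .3, G = .2, C = .2))
    expect_identical(pentamerStarts(findPentamers(s)),
                     naivePentamerStarts(s))
  }
})

test_that("auFraction counts A+U over half-open windows", {
  expect_equal(auFraction("AUUUA", 0, 5), 1.0)
  expect_equal(auFraction("GCGCG", 0, 5), 0.0)
  expect_equal(auFraction("AUGCG", 0, 5), 0.4)
  expect_equal(auFraction("AUGCG", 2, 2), 0)     # empty window
  expect_error(auFraction("AUGCG", 0, 6), "out of range")
  expect_error(auFraction("AUGCG", -1, 3), "out of range")
})

test_that("detectAUBlocks finds maximal AU-rich intervals", {
  p <- AREScoreParams(auBlockMinLen = 20L, auBlockMinFraction = 0.9)
  run30 <- paste(rep(c("A", "U"), 15), collapse = "")
  b <- detectAUBlocks(run30, p)
  expect_identical(length(b), 1L)
  expect_identical(IRanges::start(b), 1L)
  expect_identical(IRanges::end(b), 30L)
  expect_length(detectAUBlocks(strrep("GC", 20), p), 0L)
})

test_that("block qualification follows the A+U fraction threshold", {
  # 25 nt, 22 A/U and G at 0-based 6, 12, 18: every window of length >= 20
  # contains all three Gs, so the best fraction is 17/20 = 0.88... < 0.9
  chars <- rep(c("A", "U"), length.out = 25)
  chars[c(7, 13, 19)] <- "G"
  s <- paste(chars, collapse = "")
  expect_equal(sum(strsplit(s, "")[[1]] %in% c("A", "U")), 22)
  strict <- AREScoreParams(auBlockMinLen = 20L, auBlockMinFraction = 0.9)
  loose <- AREScoreParams(auBlockMinLen = 20L, auBlockMinFraction = 0.85)
  expect_length(detectAUBlocks(s, strict), 0L)
  expect_identical(length(detectAUBlocks(s, loose)), 1L)
})

test_that("computeAREScore anchors: lone pentamer scores exactly 1", {
  r <- computeAREScore("GCGCAUUUAGCGC")
  expect_identical(r@score, 1.0)
  expect_identical(r@nPentamers, 1L)
  expect_identical(r@nClusterPairs, 0L)
  expect_identical(r@nAuBlocks, 0L)
  r0 <- computeAREScore("GCGCGCGC")
  expect_identical(r0@score, 0)
  expect_identical(r0@nPentamers, 0L)
})

test_that("clustered and AU-context pentamers score above the lone case", {
  p <- AREScoreParams()
  # two pentamers 4 nt apart: 2 * 1 + 1.5 cluster pair
  r2 <- computeAREScore(paste0(strrep("GC", 10), "AUUUAUUUA",
                               strrep("GC", 10)), p)
  expect_identical(r2@nPentamers, 2L)
  expect_identical(r2@nClusterPairs, 1L)
  expect_equal(r2@score, 2 + 1.5)
  # the printed probe: 2 pentamers + 1 cluster pair + 1 AU block
  rp <- computeAREScore(ARE_PROBE, p)
  expect_identical(rp@nPentamers, 2L)
  expect_identical(rp@nClusterPairs, 1L)
  expect_identical(rp@nAuBlocks, 1L)
  expect_equal(rp@score, 2 * 1 + 1.5 + 0.85)
})

test_that("decomposition identity holds against independent recounts", {
  set.seed(41)
  p <- AREScoreParams()
  for (i in 1:100) {
    s <- randomRNA(sample(30:200, 1),
                   probs = c(A = .3, U = .35, G = .2, C = .15))
    r <- computeAREScore(s, p)
    hits <- naivePentamerStarts(s)
    expect_identical(r@nPentamers, length(hits))
    pairs <- if (length(hits) > 1) sum(diff(hits) <= p@clusterMaxGap) else 0L
    expect_identical(r@nClusterPairs, as.integer(pairs))
    expect_equal(r@score,
                 r@nPentamers * p@pentamerWeight +
                   r@nClusterPairs * p@clusterBonus +
                   r@nAuBlocks * p@auBlockBonus)
    expect_identical(r@score == 0, r@nPentamers == 0L)
  }
})

test_that("inserting an extra pentamer never decreases the score", {
  set.seed(51)
  p <- AREScoreParams()
  for (i in 1:150) {
    s <- randomRNA(sample(30:150, 1),
                   probs = c(A = .28, U = .32, G = .22, C = .18))
    pos <- sample(0:nchar(s), 1)
    augmented <- paste0(substr(s, 1, pos), "AUUUA",
                        substr(s, pos + 1, nchar(s)))
    expect_gte(computeAREScore(augmented, p)@score,
               computeAREScore(s, p)@score)
  }
})

test_that("scoring is invariant to DNA-vs-RNA spelling", {
  set.seed(61)
  for (i in 1:25) {
    rna <- randomRNA(80, probs = c(A = .3, U = .3, G = .2, C = .2))
    dna <- tolower(chartr("U", "T", rna))
    expect_equal(computeAREScore(dna)@score, computeAREScore(rna)@score)
  }
})

test_that("classifyARE applies the boundary-inclusive threshold of 2", {
  expect_true(classifyARE(4.1))
  expect_false(classifyARE(1.9))
  expect_true(classifyARE(2.0))
  expect_identical(classifyARE(c(0, 1.99, 2, 5)),
                   c(FALSE, FALSE, TRUE, TRUE))
  r <- computeAREScore("GCGCAUUUAGCGC")
  expect_false(classifyARE(r))           # lone pentamer is not a functional ARE
})

test_that("scoreTranscriptome scores isoforms individually", {
  db <- tinyDb()
  tab <- scoreTranscriptome(db)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$transcript_id, names(utrSequences(db)))
  # two isoforms of g1 keep distinct scores (no per-gene collapsing)
  g1 <- tab[tab$gene_id == "g1", ]
  expect_identical(nrow(g1), 2L)
  expect_false(g1$score[1] == g1$score[2])
  # identical sequences under two ids score identically
  db2 <- TranscriptDb(c(a = "GCAUUUAGC", b = "GCAUUUAGC"),
                      data.frame(gene_id = c("gA", "gB"),
                                 transcript_id = c("a", "b")))
  tab2 <- scoreTranscriptome(db2)
  expect_identical(tab2$score[1], tab2$score[2])
  expect_identical(tab2$hit_starts[1], tab2$hit_starts[2])
})
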