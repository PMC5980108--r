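#' Generate a 3'UTR with a controlled pentamer architecture
#'
#' Builds a sequence of the requested length containing exactly
#' `nPentamers` AUUUA occurrences, planted at a fixed start-to-start
#' spacing, inside a random background whose A+U fraction is controlled.
#' The background is rejection-resampled until a rescan finds exactly the
#' planted hits, so the planted-motif contract is verified on every call;
#' the generator is a pure function of its arguments and seed. ARE
#' positivity of synthetic genes is therefore structural (real motifs),
#' not a label, and the scoring engine is genuinely exercised downstream.
#'
#' Overlapping architectures are supported where consistent: a gap of 4
#' chains pentamers through their shared A (AUUUAUUUA), while gaps of
#' 1-3 nt are contradictory and rejected.
#'
#' @param length Sequence length (nt).
#' @param nPentamers Number of AUUUA motifs to plant (>= 0).
#' @param pentamerGap Start-to-start spacing between consecutive planted
#'   motifs (default 8 nt).
#' @param auContextFraction A+U fraction of the background composition, in
#'   [0, 1] (A and U equiprobable; remainder split between G and C).
#' @param seed Integer seed.
#' @param offset 0-based start of the first planted motif (default centers
#'   the planted run).
#' @param maxAttempts Background resampling budget before giving up.
#' @return A normalized RNA character string.
#' @examples
#' s <- generateUTR(60, nPentamers = 1, auContextFraction = 0, seed = 1)
#' computeAREScore(s)@score  # exactly 1: one isolated pentamer
#' @export
generateUTR <- function(length, nPentamers, pentamerGap = 8L,
                        auContextFraction = 0.5, seed,
                        offset = NULL, maxAttempts = 1000L) {
  assertScalarNumber(length, "length", lower = 1)
  assertScalarNumber(nPentamers, "nPentamers", lower = 0)
  assertScalarNumber(auContextFraction, "auContextFraction", 0, 1)
  nPentamers <- as.integer(nPentamers)
  length <- as.integer(length)
  span <- if (nPentamers > 0L) (nPentamers - 1L) * pentamerGap + 5L else 0L
  if (span > length)
    stop("planted pentamers do not fit within the requested length",
         call. = FALSE)
  if (nPentamers > 1L && pentamerGap < 4L)
    stop("start-to-start gaps of 1-3 nt are self-contradictory for AUUUA",
         call. = FALSE)
  starts <- integer(0)
  template <- rep(NA_character_, length)
  if (nPentamers > 0L) {
    off <- offset %||% as.integer((length - span) %/% 2L)
    if (off < 0L || off + span > length)
      stop("offset places planted pentamers out of range", call. = FALSE)
    starts <- off + pentamerGap * (seq_len(nPentamers) - 1L)  # 0-based
    motif <- c("A", "U", "U", "U", "A")
    for (s in starts) {
      idx <- s + 1:5
      clash <- !is.na(template[idx]) & template[idx] != motif
      if (any(clash))
        stop("planted pentamers overlap inconsistently", call. = FALSE)
      template[idx] <- motif
    }
  }
  free <- which(is.na(template))
  p <- c(A = auContextFraction / 2, U = auContextFraction / 2,
         G = (1 - auContextFraction) / 2, C = (1 - auContextFraction) / 2)
  withSeed(seed, {
    for (attempt in seq_len(maxAttempts)) {
      cand <- template
      if (length(free))
        cand[free] <- sample(names(p), length(free), replace = TRUE, prob = p)
      seqchr <- paste(cand, collapse = "")
      found <- pentamerStarts(findPentamers(seqchr))
      if (identical(sort(found), sort(as.integer(starts))))
        return(seqchr)
    }
    stop(sprintf("could not realize the pentamer architecture in %d attempts",
                 maxAttempts), call. = FALSE)
  })
}

#' Scramble a sequence while preserving its composition
#'
#' Returns a random permutation of the input characters (identical length
#' and nucleotide multiset), optionally rejection-resampled until the
#' permutation carries no AUUUA pentamer -- the construction used for
#' scrambled control probes that retain base composition but lose the
#' destabilizing motif.
#'
#' @param seq Input sequence (any representation accepted by
#'   [findPentamers()]).
#' @param seed Integer seed.
#' @param forbidPentamers Require the output to scan motif-free
#'   (default TRUE).
#' @param maxAttempts Resampling budget; inputs for which a motif-free
#'   permutation is unreachable (e.g. poly-AU) raise an error.
#' @return A normalized RNA character string.
#' @export
scrambleSequence <- function(seq, seed, forbidPentamers = TRUE,
                             maxAttempts = 1000L) {
  s <- .asRnaChar(seq)
  if (!nchar(s)) stop("sequence must be non-empty", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  withSeed(seed, {
    for (attempt in seq_len(maxAttempts)) {
      perm <- paste(sample(chars), collapse = "")
      if (!forbidPentamers || length(findPentamers(perm)) == 0L)
        return(perm)
    }
    stop(sprintf("no pentamer-free permutation found in %d attempts",
                 maxAttempts), call. = FALSE)
  })
}

#' Generate a synthetic two-condition, two-genotype count experiment
#'
#' Emulates the design the enrichment and repression analyses consume:
#' biological replicates of control (CTRL) and decay-factor knockout (KO)
#' cells in normoxia, hypoxia and reoxygenation. A fraction `fracARE` of
#' genes carries structurally planted AREs in every isoform 3'UTR
#' (clustered pentamers; scored, not labelled); the remaining genes carry
#' at most a lone pentamer. ARE genes are induced in hypoxia more often
#' than non-ARE genes (`pInducedARE` vs `pInducedNonARE`), and upon
#' reoxygenation ARE genes are repressed more strongly in CTRL than in KO
#' (`reoxRepressionCtrl` vs `reoxRepressionKo`, log2 scale), while induced
#' non-ARE genes relax identically in both genotypes. Gene-level noise of
#' sd `noiseSd` perturbs each planted log2 effect; the KO repression is
#' generated as CTRL repression plus a per-gene delta, so `noiseSd` is the
#' sd of the genotype delta itself. Counts are drawn negative-binomially
#' around the condition means.
#'
#' Differential-expression tables for the three contrasts are computed by
#' a deliberately simple internal estimator (see [estimateDE()]); it only
#' has to provide well-formed inputs, upstream DE testing being outside
#' this package's scope.
#'
#' @param nGenes Number of genes (default 2000).
#' @param fracARE Fraction of genes with planted AREs (default 0.2).
#' @param isoformsPerGene Integer vector of possible isoform counts per
#'   gene, sampled uniformly (default `1:3`).
#' @param utrLength 3'UTR length in nt (default 200).
#' @param baselineMean Mean normoxic expression (counts; default 100).
#' @param dispersion Negative-binomial size parameter (default 10).
#' @param hypoxiaUpLog2fc Mean hypoxic induction of induced genes, log2
#'   (default 2).
#' @param pInducedARE,pInducedNonARE Probability that an ARE / non-ARE
#'   gene is hypoxia-induced (defaults 0.5 / 0.15).
#' @param pDownregulated Probability that a non-induced gene is
#'   hypoxia-downregulated, by -`hypoxiaUpLog2fc`, independent of ARE
#'   status (default 0.1).
#' @param reoxRepressionCtrl,reoxRepressionKo Mean reoxygenation log2 fold
#'   change of ARE genes in CTRL / KO (defaults -2 / -0.5).
#' @param noiseSd Gene-level sd of planted log2 effects (default 0.25).
#' @param nReplicates Replicates per condition x genotype (default 3).
#' @param seed Integer seed.
#' @return List with elements `db` ([TranscriptDb-class]), `counts`
#'   (gene x sample matrix), `samples` (sample annotation), `truth`
#'   (per-gene planted parameters), and `de` (list of data.frames:
#'   `hypoxia_vs_normoxia_ctrl`, `reox_vs_hypoxia_ctrl`,
#'   `reox_vs_hypoxia_ko`).
#' @export
generateExperiment <- function(nGenes = 2000, fracARE = 0.2,
                               isoformsPerGene = 1:3, utrLength = 200,
                               baselineMean = 100, dispersion = 10,
                               hypoxiaUpLog2fc = 2,
                               pInducedARE = 0.5, pInducedNonARE = 0.15,
                               pDownregulated = 0.1,
                               reoxRepressionCtrl = -2,
                               reoxRepressionKo = -0.5,
                               noiseSd = 0.25, nReplicates = 3, seed) {
  assertScalarNumber(nGenes, "nGenes", lower = 2)
  assertScalarNumber(fracARE, "fracARE", 0, 1)
  assertScalarNumber(baselineMean, "baselineMean", lower = 1e-9)
  assertScalarNumber(dispersion, "dispersion", lower = 1e-9)
  assertScalarNumber(noiseSd, "noiseSd", lower = 0)
  if (nReplicates < 1) stop("nReplicates must be >= 1", call. = FALSE)
  nGenes <- as.integer(nGenes)

  withSeed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(nGenes))
    are <- seq_len(nGenes) %in% sample(nGenes, round(fracARE * nGenes))
    induced <- runif(nGenes) < ifelse(are, pInducedARE, pInducedNonARE)
    downreg <- !induced & runif(nGenes) < pDownregulated

    # --- sequences: structural ARE identity -------------------------------
    iso_n <- sample(rep(isoformsPerGene, length.out = max(nGenes, 1)),
                    nGenes, replace = TRUE)
    tx_gene <- rep(gene_ids, iso_n)
    tx_ids <- paste0(tx_gene, "-t", unlist(lapply(iso_n, seq_len)))
    utr_seeds <- sample.int(.Machine$integer.max, length(tx_ids))
    seqs <- vapply(seq_along(tx_ids), function(i) {
      g <- match(tx_gene[i], gene_ids)
      if (are[g]) {
        generateUTR(utrLength, nPentamers = 3L, pentamerGap = 8L,
                    auContextFraction = 0.6, seed = utr_seeds[i])
      } else {
        generateUTR(utrLength, nPentamers = sample(0:1, 1L),
                    auContextFraction = 0.45, seed = utr_seeds[i])
      }
    }, character(1))
    names(seqs) <- tx_ids
    db <- TranscriptDb(seqs, data.frame(gene_id = tx_gene,
                                        transcript_id = tx_ids,
                                        stringsAsFactors = FALSE))

    # --- planted condition means ------------------------------------------
    base <- baselineMean * 2^rnorm(nGenes, 0, 1)      # expression spread
    fc_hyp <- ifelse(induced, hypoxiaUpLog2fc, 0) +
      ifelse(downreg, -hypoxiaUpLog2fc, 0) +
      ifelse(induced | downreg, rnorm(nGenes, 0, noiseSd), 0)
    fc_reox_ctrl <- ifelse(are, reoxRepressionCtrl,
                           ifelse(induced, -hypoxiaUpLog2fc, 0)) +
      rnorm(nGenes, 0, noiseSd)
    delta <- ifelse(are, reoxRepressionKo - reoxRepressionCtrl, 0) +
      rnorm(nGenes, 0, noiseSd)
    fc_reox_ko <- fc_reox_ctrl + delta

    mu <- list(
      normoxia_CTRL = base,
      hypoxia_CTRL = base * 2^fc_hyp,
      reox_CTRL = base * 2^(fc_hyp + fc_reox_ctrl),
      normoxia_KO = base,
      hypoxia_KO = base * 2^fc_hyp,
      reox_KO = base * 2^(fc_hyp + fc_reox_ko))

    samples <- expand.grid(rep = seq_len(nReplicates),
                           group = names(mu), stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_r%d", samples$group, samples$rep)
    counts <- vapply(seq_len(nrow(samples)), function(i) {
      rnbinom(nGenes, size = dispersion, mu = mu[[samples$group[i]]])
    }, numeric(nGenes))
    dimnames(counts) <- list(gene_ids, samples$sample)

    truth <- data.frame(gene_id = gene_ids, are = are, induced = induced,
                        downregulated = downreg,
                        baseline = base, log2fc_hypoxia = fc_hyp,
                        log2fc_reox_ctrl = fc_reox_ctrl,
                        log2fc_reox_ko = fc_reox_ko, delta = delta,
                        stringsAsFactors = FALSE)

    grp <- function(g) samples$sample[samples$group == g]
    de <- list(
      hypoxia_vs_normoxia_ctrl =
        estimateDE(counts, grp("normoxia_CTRL"), grp("hypoxia_CTRL")),
      reox_vs_hypoxia_ctrl =
        estimateDE(counts, grp("hypoxia_CTRL"), grp("reox_CTRL")),
      reox_vs_hypoxia_ko =
        estimateDE(counts, grp("hypoxia_KO"), grp("reox_KO")))

    list(db = db, counts = counts, samples = samples, truth = truth, de = de)
  })
}

#' Simple differential-expression estimator for synthetic data
#'
#' Per-gene log2 ratio of group means with a 0.5 pseudo-count, with a
#' pooled label-permutation p-value (the null statistics of all genes over
#' all distinct label splits form one pool, giving usable resolution at
#' small replicate numbers) and Benjamini-Hochberg FDR. This is a
#' deliberately plain estimator producing well-formed DE tables for the
#' pipeline; it is not a reimplementation of count-model DE testing.
#'
#' @param counts Gene x sample count matrix.
#' @param samplesA,samplesB Column names of the two groups (A is the
#'   denominator: positive log2fc means higher in B).
#' @param maxPerm Cap on the number of label splits used (default 100).
#' @return data.frame `gene_id`, `log2fc`, `fdr`, `mean_expr`.
#' @export
estimateDE <- function(counts, samplesA, samplesB, maxPerm = 100L) {
  stopifnot(all(c(samplesA, samplesB) %in% colnames(counts)))
  a <- counts[, samplesA, drop = FALSE]
  b <- counts[, samplesB, drop = FALSE]
  lfc <- log2((rowMeans(b) + 0.5) / (rowMeans(a) + 0.5))
  pooledCols <- cbind(a, b)
  nA <- length(samplesA); nTot <- nA + length(samplesB)
  splits <- combn(nTot, nA)
  # drop the observed labelling (and its mirror) from the null
  obs <- seq_len(nA)
  keep <- apply(splits, 2L, function(s)
    !identical(sort(s), obs) && !identical(sort(s), (nTot - nA + 1):nTot))
  splits <- splits[, keep, drop = FALSE]
  if (ncol(splits) > maxPerm) splits <- splits[, seq_len(maxPerm), drop = FALSE]
  nullStats <- abs(vapply(seq_len(ncol(splits)), function(j) {
    ia <- splits[, j]
    log2((rowMeans(pooledCols[, -ia, drop = FALSE]) + 0.5) /
           (rowMeans(pooledCols[, ia, drop = FALSE]) + 0.5))
  }, numeric(nrow(counts))))
  nullPool <- sort(as.numeric(nullStats))
  # pooled-null p: fraction of null statistics at least as extreme
  exceed <- length(nullPool) -
    findInterval(abs(lfc) - 1e-12, nullPool)
  p <- (1 + exceed) / (1 + length(nullPool))
  data.frame(gene_id = rownames(counts), log2fc = lfc,
             fdr = p.adjust(p, method = "BH"),
             mean_expr = log2(rowMeans(pooledCols) + 0.5),
             stringsAsFactors = FALSE)
}

#' Generate a noisy exponential decay time course
#'
#' Produces `100 * exp(-log(2) t / tHalf)` perturbed by multiplicative
#' lognormal noise of coefficient of variation `cv` (mean-1 noise;
#' signals are positive blot-type intensities), with the t = 0 value
#' re-pinned to 100.
#'
#' @param tHalf True half-life (minutes, > 0).
#' @param times Time points (minutes), starting at 0.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param seed Integer seed.
#' @return A [DecayTimecourse-class].
#' @export
generateTimecourse <- function(tHalf, times = c(0, 30, 60, 90, 120, 180),
                               cv = 0.15, seed) {
  assertScalarNumber(tHalf, "tHalf", lower = 1e-12)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  times <- as.numeric(times)
  expected <- 100 * exp(-log(2) * times / tHalf)
  noisy <- withSeed(seed, {
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      expected * rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else expected
  })
  noisy[1L] <- 100
  normalizeTimecourse(times, noisy, rep(1, length(times)))
}

#' Generate genotype fold-change pairs with planted sensitivity
#'
#' Reduced-form generator for the repression-contrast statistics: every
#' gene receives a control reoxygenation log2 fold change around
#' `repressionCtrl` (ARE genes) or 0 (non-ARE), and a per-gene genotype
#' delta of mean `delta` for the planted sensitive genes and 0 otherwise,
#' each with noise sd `noiseSd`; the KO fold change is the CTRL value plus
#' the delta. ARE genes receive scores >= 2, non-ARE genes scores < 2.
#'
#' @param nARE Number of ARE genes (default 250).
#' @param nPlanted Number of ARE genes with planted sensitivity
#'   (default 30).
#' @param nNonARE Number of non-ARE genes (default 750).
#' @param delta Planted mean of log2fc_ko - log2fc_ctrl (default 1).
#' @param repressionCtrl Mean CTRL log2 fold change of ARE genes
#'   (default -2).
#' @param noiseSd Noise sd on the CTRL fold change and on the delta
#'   (default 0.25).
#' @param seed Integer seed.
#' @return data.frame compatible with [rankSensitivity()] /
#'   [contrastFCDistributions()], with a logical `planted` truth column.
#' @export
generateGenotypePairs <- function(nARE = 250, nPlanted = 30, nNonARE = 750,
                                  delta = 1, repressionCtrl = -2,
                                  noiseSd = 0.25, seed) {
  stopifnot(nPlanted <= nARE)
  n <- nARE + nNonARE
  withSeed(seed, {
    are <- c(rep(TRUE, nARE), rep(FALSE, nNonARE))
    planted <- c(rep(TRUE, nPlanted), rep(FALSE, n - nPlanted))
    ctrl <- ifelse(are, repressionCtrl, 0) + rnorm(n, 0, noiseSd)
    d <- ifelse(planted, delta, 0) + rnorm(n, 0, noiseSd)
    score <- ifelse(are, 2 + round(rexp(n, rate = 0.5), 2),
                    sample(c(0, 1), n, replace = TRUE, prob = c(0.6, 0.4)))
    data.frame(id = sprintf("g%04d", seq_len(n)),
               log2fc_ctrl = ctrl, fdr_ctrl = 0.001,
               log2fc_ko = ctrl + d, fdr_ko = 0.001,
               score = score, are_class = score >= 2,
               planted = planted, stringsAsFactors = FALSE)
  })
}

#' Generate a score sample with a prescribed ARE-positive fraction
#'
#' Reduced-form generator for calibrating the dichotomized enrichment
#' test: a fraction `fracPos` of scores falls at or above the functional
#' threshold (2), the rest below it, with score magnitudes drawn from
#' simple positive distributions.
#'
#' @param n Sample size.
#' @param fracPos Probability that a score is >= 2.
#' @param seed Integer seed.
#' @return Numeric vector of `n` scores.
#' @export
generateScoreSample <- function(n, fracPos, seed) {
  assertScalarNumber(fracPos, "fracPos", 0, 1)
  withSeed(seed, {
    pos <- runif(n) < fracPos
    ifelse(pos, 2 + rexp(n, rate = 0.5),
           sample(c(0, 1), n, replace = TRUE, prob = c(0.6, 0.4)))
  })
}
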