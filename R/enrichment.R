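#' Define the expressed-gene universe from raw counts
#'
#' A gene counts as expressed when its read count reaches `minReads` in at
#' least one sample of any of the named conditions (e.g. expressed in
#' either normoxia or hypoxia).
#'
#' @param counts Non-negative integer matrix, genes x samples, with gene
#'   ids as rownames.
#' @param conditions Character/factor of length `ncol(counts)` assigning
#'   each sample to a condition.
#' @param use Conditions to consider (default: all).
#' @param minReads Minimal read count (default 10).
#' @return Character vector of expressed gene ids.
#' @export
expressedUniverse <- function(counts, conditions = NULL, use = NULL,
                              minReads = 10) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts))) stop("counts needs gene ids as rownames",
                                      call. = FALSE)
  keep_cols <- seq_len(ncol(counts))
  if (!is.null(conditions) && !is.null(use)) {
    keep_cols <- which(as.character(conditions) %in% use)
    if (!length(keep_cols)) stop("no sample matches the named conditions",
                                 call. = FALSE)
  }
  mx <- apply(counts[, keep_cols, drop = FALSE], 1L, max)
  rownames(counts)[mx >= minReads]
}

#' Select an up- or down-regulated gene set
#'
#' Applies the strict cutoffs |FC| > `fcThreshold` (linear scale, i.e.
#' |log2FC| > log2(fcThreshold)) and FDR < `fdrThreshold`; boundary values
#' are excluded.
#'
#' @param de data.frame of DE records as returned by [readDETable()].
#' @param direction "up" or "down".
#' @param fcThreshold Linear fold-change cutoff (> 1), default 1.5.
#' @param fdrThreshold FDR cutoff in (0, 1].
#' @param label Set label; defaults to the direction.
#' @return A [RegulatedSet-class] (transcript ids empty until
#'   [expandToIsoforms()]).
#' @export
selectRegulated <- function(de, direction = c("up", "down"),
                            fcThreshold = 1.5, fdrThreshold = 0.05,
                            label = NULL) {
  direction <- match.arg(direction)
  stopifnot(nrow(de) > 0L)
  assertScalarNumber(fcThreshold, "fcThreshold", lower = 1 + 1e-12)
  assertScalarNumber(fdrThreshold, "fdrThreshold", lower = 0, upper = 1)
  lfc <- log2(fcThreshold)
  keep <- de$fdr < fdrThreshold &
    if (direction == "up") de$log2fc > lfc else de$log2fc < -lfc
  new("RegulatedSet",
      label = label %||% paste0(direction, "_regulated"),
      geneIds = unique(de$gene_id[keep]),
      transcriptIds = character(),
      direction = direction,
      fcThreshold = as.numeric(fcThreshold),
      fdrThreshold = as.numeric(fdrThreshold))
}

#' Expand a gene set to all its transcript isoforms
#'
#' @param genes Character vector (or [RegulatedSet-class]) of gene ids.
#' @param db A [TranscriptDb-class].
#' @return For a character input, a list with `transcript_ids` (union of
#'   all isoforms) and `missing_genes` (input genes absent from the
#'   database, reported rather than silently dropped). For a
#'   `RegulatedSet`, the set with its `transcriptIds` slot filled
#'   (missing genes attached as attribute `"missing_genes"`).
#' @export
expandToIsoforms <- function(genes, db) {
  stopifnot(methods::is(db, "TranscriptDb"))
  if (methods::is(genes, "RegulatedSet")) {
    ex <- expandToIsoforms(genes@geneIds, db)
    genes@transcriptIds <- ex$transcript_ids
    attr(genes, "missing_genes") <- ex$missing_genes
    return(genes)
  }
  genes <- unique(as.character(genes))
  m <- transcriptMap(db)
  present <- genes %in% m$gene_id
  list(transcript_ids = m$transcript_id[m$gene_id %in% genes],
       missing_genes = genes[!present])
}

#' Draw a randomized background gene set
#'
#' Samples `nGenes` genes uniformly without replacement from the expressed
#' universe (mirroring randomized control lists drawn from all genes
#' detected as expressed), then expands them to all transcript isoforms.
#' Identical (universe, nGenes, seed) always reproduces the identical set;
#' the global RNG state is left untouched.
#'
#' @param universe Character vector of expressed gene ids.
#' @param nGenes Number of genes to draw (default 900).
#' @param seed Integer seed.
#' @param db Optional [TranscriptDb-class] for isoform expansion.
#' @param label Set label.
#' @return A [BackgroundSet-class].
#' @export
sampleBackground <- function(universe, nGenes = 900, seed, db = NULL,
                             label = sprintf("background_seed%d", seed)) {
  universe <- unique(as.character(universe))
  if (nGenes > length(universe))
    stop(sprintf("cannot draw %d genes from a universe of %d", nGenes,
                 length(universe)), call. = FALSE)
  picked <- withSeed(seed, sample(universe, size = nGenes, replace = FALSE))
  tx <- character()
  if (!is.null(db)) tx <- expandToIsoforms(picked, db)$transcript_ids
  new("BackgroundSet", label = label, seed = as.integer(seed),
      geneIds = picked, transcriptIds = tx)
}

#' Empirical cumulative distribution as a step table
#'
#' @param scores Non-empty numeric vector.
#' @return data.frame with one row per distinct value: `value` (ascending)
#'   and `cumfrac` (right-continuous cumulative fraction, ending at 1).
#' @examples
#' ecdfTable(c(1, 2, 2, 3))
#' @export
ecdfTable <- function(scores) {
  if (!length(scores)) stop("scores must be non-empty", call. = FALSE)
  stopifnot(all(is.finite(scores)))
  v <- sort(unique(scores))
  data.frame(value = v,
             cumfrac = cumsum(tabulate(match(sort(scores), v))) / length(scores))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two score distributions by the sup-distance between their
#' ECDFs. The default p-value is asymptotic (two-sided, effective sample
#' size n1*n2/(n1+n2)), appropriate for the hundreds-to-thousands of
#' transcripts per set in enrichment analyses. For very small samples an
#' exact permutation p-value can be requested: every assignment of the
#' pooled values into groups of sizes n1/n2 is enumerated and the fraction
#' with a sup-distance at least the observed one is reported.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact If TRUE, enumerate all `choose(n1+n2, n1)` label
#'   assignments (only sensible for n1, n2 <= 10).
#' @return A [KSResult-class].
#' @export
ksTwoSample <- function(a, b, exact = FALSE) {
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  stat <- .ksStatistic(a, b)
  if (exact) {
    n1 <- length(a); n2 <- length(b)
    if (choose(n1 + n2, n1) > 2e5)
      stop("exact enumeration infeasible for these sample sizes",
           call. = FALSE)
    pooled <- c(a, b)
    idx <- combn(n1 + n2, n1)
    stats <- apply(idx, 2L, function(i)
      .ksStatistic(pooled[i], pooled[-i]))
    p <- mean(stats >= stat - 1e-12)
    method <- "exact-permutation"
  } else {
    p <- suppressWarnings(
      stats::ks.test(a, b, exact = FALSE)$p.value)
    method <- "asymptotic"
  }
  new("KSResult", statistic = stat, pValue = p,
      n1 = length(a), n2 = length(b), method = method)
}

# Sup-distance between the ECDFs of two samples.
.ksStatistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

#' Dichotomized ARE-class enrichment tests
#'
#' For each requested pairwise comparison of score groups, builds the 2x2
#' table of counts below/at-or-above the ARE threshold and computes the
#' chi-squared test (1 df, no continuity correction; expected cells below
#' 1 are flagged, not silently re-tested). P-values receive a Bonferroni
#' correction `p_adj = min(1, m * p_raw)` with family size `m` defaulting
#' to the number of comparisons performed.
#'
#' @param groups Named list of non-empty numeric score vectors.
#' @param threshold Dichotomization threshold (default 2, inclusive above).
#' @param comparisons Two-column character matrix of group name pairs;
#'   default: all pairwise combinations.
#' @param familySize Bonferroni family size `m`; default
#'   `nrow(comparisons)`.
#' @return data.frame with one row per comparison: group names, the four
#'   table counts (`below_1`, `atLeast_1`, `below_2`, `atLeast_2`),
#'   `chi2`, `p_raw`, `p_adj`, `m`, and `small_expected`.
#' @export
dichotomizedEnrichment <- function(groups, threshold = 2, comparisons = NULL,
                                   familySize = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)),
            all(nzchar(names(groups))))
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("every group must be non-empty", call. = FALSE)
  if (is.null(comparisons)) {
    if (length(groups) < 2L)
      stop("need at least two groups", call. = FALSE)
    comparisons <- t(combn(names(groups), 2L))
  }
  comparisons <- matrix(as.character(comparisons), ncol = 2L)
  m <- familySize %||% nrow(comparisons)
  if (m < nrow(comparisons))
    stop("familySize must be at least the number of comparisons",
         call. = FALSE)
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    g1 <- comparisons[i, 1L]; g2 <- comparisons[i, 2L]
    s1 <- groups[[g1]]; s2 <- groups[[g2]]
    tab <- rbind(c(sum(s1 < threshold), sum(s1 >= threshold)),
                 c(sum(s2 < threshold), sum(s2 >= threshold)))
    ident <- identical(tab[1, ] * sum(tab[2, ]), tab[2, ] * sum(tab[1, ]))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(colSums(tab) == 0)) {
      chi2 <- 0; p <- 1  # degenerate: one class absent everywhere
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      chi2 <- unname(ct$statistic); p <- ct$p.value
      if (ident) { chi2 <- 0; p <- 1 }
    }
    data.frame(group1 = g1, group2 = g2,
               below_1 = tab[1, 1], atLeast_1 = tab[1, 2],
               below_2 = tab[2, 1], atLeast_2 = tab[2, 2],
               chi2 = chi2, p_raw = p,
               p_adj = min(1, m * p), m = m,
               small_expected = any(expected < 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
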