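#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

# ---------------------------------------------------------------------------
# AREScoreParams
# ---------------------------------------------------------------------------

#' Scoring parameters for ARE detection
#'
#' Bundle of tunable weights used by [computeAREScore()]. The score of a
#' 3'UTR is assembled additively from three components: one
#' `pentamerWeight` per AUUUA occurrence, one `clusterBonus` per pair of
#' consecutive pentamers whose start positions lie within `clusterMaxGap`
#' nucleotides, and one `auBlockBonus` per AU-rich block (length at least
#' `auBlockMinLen` nt with A+U fraction at least `auBlockMinFraction`)
#' lying within `auBlockMaxDist` nt of any pentamer.
#'
#' The defaults anchor the minimal configuration in which a single isolated
#' AUUUA in non-AU context scores exactly 1, the conventional baseline for
#' a lone pentamer, with the score rising for clustered pentamers and
#' AU-rich context as functional AREs require.
#'
#' @param pentamerWeight Score contributed by each AUUUA pentamer.
#' @param clusterBonus Extra score per consecutive pentamer pair within
#'   `clusterMaxGap` nt (start-to-start).
#' @param clusterMaxGap Maximum start-to-start distance (nt) for a pair of
#'   pentamers to count as clustered.
#' @param auBlockBonus Extra score per qualifying AU-rich block near a
#'   pentamer.
#' @param auBlockMinLen Minimum block length (nt).
#' @param auBlockMinFraction Minimum A+U fraction within a block, in [0,1].
#' @param auBlockMaxDist Maximum distance (nt) between a block and the
#'   nearest pentamer for the block to score.
#'
#' @return An `AREScoreParams` object.
#' @examples
#' AREScoreParams()
#' AREScoreParams(clusterMaxGap = 8L)
#' @export
AREScoreParams <- function(pentamerWeight = 1.0,
                           clusterBonus = 1.5,
                           clusterMaxGap = 10L,
                           auBlockBonus = 0.85,
                           auBlockMinLen = 20L,
                           auBlockMinFraction = 0.9,
                           auBlockMaxDist = 25L) {
  new("AREScoreParams",
      pentamerWeight = as.numeric(pentamerWeight),
      clusterBonus = as.numeric(clusterBonus),
      clusterMaxGap = as.integer(clusterMaxGap),
      auBlockBonus = as.numeric(auBlockBonus),
      auBlockMinLen = as.integer(auBlockMinLen),
      auBlockMinFraction = as.numeric(auBlockMinFraction),
      auBlockMaxDist = as.integer(auBlockMaxDist))
}

#' @rdname AREScoreParams
#' @export
setClass("AREScoreParams",
         slots = c(pentamerWeight = "numeric",
                   clusterBonus = "numeric",
                   clusterMaxGap = "integer",
                   auBlockBonus = "numeric",
                   auBlockMinLen = "integer",
                   auBlockMinFraction = "numeric",
                   auBlockMaxDist = "integer"))

setValidity("AREScoreParams", function(object) {
  msgs <- character()
  for (s in c("pentamerWeight", "clusterBonus", "auBlockBonus")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msgs <- c(msgs, sprintf("'%s' must be a single finite value >= 0", s))
  }
  for (s in c("clusterMaxGap", "auBlockMinLen", "auBlockMaxDist")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 1L)
      msgs <- c(msgs, sprintf("'%s' must be a positive integer", s))
  }
  f <- object@auBlockMinFraction
  if (length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    msgs <- c(msgs, "'auBlockMinFraction' must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AREScoreParams", function(object) {
  cat("AREScoreParams\n")
  cat("  pentamer weight   :", object@pentamerWeight, "\n")
  cat("  cluster bonus     :", object@clusterBonus,
      sprintf("(start-to-start gap <= %d nt)\n", object@clusterMaxGap))
  cat("  AU-block bonus    :", object@auBlockBonus,
      sprintf("(len >= %d nt, A+U >= %.2f, within %d nt of a pentamer)\n",
              object@auBlockMinLen, object@auBlockMinFraction,
              object@auBlockMaxDist))
})

# ---------------------------------------------------------------------------
# AREScoreResult
# ---------------------------------------------------------------------------

#' Result of scoring a single 3'UTR
#'
#' Holds the score with its exact additive decomposition: number of AUUUA
#' pentamers, number of clustered consecutive pentamer pairs, number of
#' AU-rich blocks near a pentamer, and the pentamer hit positions as an
#' [IRanges::IRanges] (1-based, width 5). Use [pentamerStarts()] for
#' 0-based start coordinates as written to tabular output.
#'
#' @slot transcriptId Sequence identifier.
#' @slot score Total score (non-negative).
#' @slot nPentamers Number of AUUUA occurrences.
#' @slot nClusterPairs Number of consecutive pentamer pairs within the
#'   cluster gap.
#' @slot nAuBlocks Number of qualifying AU-rich blocks near a pentamer.
#' @slot hits Pentamer hit positions (IRanges).
#' @slot params The `AREScoreParams` used.
#' @export
setClass("AREScoreResult",
         slots = c(transcriptId = "character",
                   score = "numeric",
                   nPentamers = "integer",
                   nClusterPairs = "integer",
                   nAuBlocks = "integer",
                   hits = "IRanges",
                   params = "AREScoreParams"))

setValidity("AREScoreResult", function(object) {
  msgs <- character()
  if (object@score < 0) msgs <- c(msgs, "score must be >= 0")
  if (object@nPentamers != length(object@hits))
    msgs <- c(msgs, "nPentamers must equal length(hits)")
  p <- object@params
  expected <- object@nPentamers * p@pentamerWeight +
    object@nClusterPairs * p@clusterBonus +
    object@nAuBlocks * p@auBlockBonus
  if (abs(object@score - expected) > 1e-9)
    msgs <- c(msgs, "score must equal its additive decomposition")
  if ((object@score == 0) != (object@nPentamers == 0L) && p@pentamerWeight > 0)
    msgs <- c(msgs, "score must be zero iff no pentamer was found")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AREScoreResult", function(object) {
  cat("AREScoreResult for", object@transcriptId, "\n")
  cat(sprintf("  score %.3g = %d pentamer(s) + %d cluster pair(s) + %d AU block(s)\n",
              object@score, object@nPentamers, object@nClusterPairs,
              object@nAuBlocks))
  if (object@nPentamers > 0L)
    cat("  hit starts (0-based):",
        paste(IRanges::start(object@hits) - 1L, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# TranscriptDb
# ---------------------------------------------------------------------------

#' Gene-to-isoform 3'UTR database
#'
#' Associates every transcript isoform with its gene and its normalized
#' 3'UTR sequence. Sequences are held in a [Biostrings::RNAStringSet]
#' named by transcript id; the gene/transcript mapping is an explicit
#' two-column table (the package never guesses gene identity from FASTA
#' headers).
#'
#' @slot sequences `RNAStringSet` named by transcript id.
#' @slot txMap data.frame with columns `gene_id`, `transcript_id`.
#' @export
setClass("TranscriptDb",
         slots = c(sequences = "RNAStringSet",
                   txMap = "data.frame"))

setValidity("TranscriptDb", function(object) {
  msgs <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msgs <- c(msgs, "all sequences must be named by transcript id")
  if (anyDuplicated(ids))
    msgs <- c(msgs, "transcript ids must be unique")
  m <- object@txMap
  if (!all(c("gene_id", "transcript_id") %in% colnames(m)))
    msgs <- c(msgs, "txMap must have columns 'gene_id' and 'transcript_id'")
  else {
    if (anyDuplicated(m$transcript_id))
      msgs <- c(msgs, "txMap transcript ids must be unique")
    if (!setequal(m$transcript_id, ids))
      msgs <- c(msgs, "txMap transcript ids must match sequence names")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TranscriptDb
#'
#' @param sequences A named [Biostrings::RNAStringSet] (or coercible
#'   character vector / `DNAStringSet`; sequences are normalized to the
#'   RNA alphabet).
#' @param txMap data.frame with columns `gene_id` and `transcript_id`
#'   covering exactly the sequence names.
#' @return A [TranscriptDb-class] object.
#' @examples
#' seqs <- c(tx1 = "AUUUAGC", tx2 = "GCGCGCG")
#' db <- TranscriptDb(seqs, data.frame(gene_id = c("g1", "g1"),
#'                                     transcript_id = c("tx1", "tx2")))
#' db
#' @export
TranscriptDb <- function(sequences, txMap) {
  if (is.character(sequences)) {
    sequences <- Biostrings::RNAStringSet(
      vapply(sequences, normalizeAlphabet, character(1)))
  } else if (!methods::is(sequences, "RNAStringSet")) {
    sequences <- Biostrings::RNAStringSet(
      vapply(as.character(sequences), normalizeAlphabet, character(1)))
  }
  txMap <- as.data.frame(txMap, stringsAsFactors = FALSE)
  txMap$gene_id <- as.character(txMap$gene_id)
  txMap$transcript_id <- as.character(txMap$transcript_id)
  new("TranscriptDb", sequences = sequences, txMap = txMap)
}

setMethod("show", "TranscriptDb", function(object) {
  cat("TranscriptDb:", length(object@sequences), "transcripts from",
      length(unique(object@txMap$gene_id)), "genes\n")
})

#' @describeIn TranscriptDb The UTR sequences (`RNAStringSet`).
#' @param db A `TranscriptDb`.
#' @export
utrSequences <- function(db) db@sequences

#' @describeIn TranscriptDb The gene/transcript mapping table.
#' @export
transcriptMap <- function(db) db@txMap

#' @describeIn TranscriptDb Unique gene identifiers.
#' @export
geneIds <- function(db) unique(db@txMap$gene_id)

# ---------------------------------------------------------------------------
# RegulatedSet / BackgroundSet
# ---------------------------------------------------------------------------

#' A differentially regulated gene set with its selection provenance
#'
#' @slot label Set label (e.g. "up_hypoxia").
#' @slot geneIds Selected gene ids.
#' @slot transcriptIds Isoform-expanded transcript ids (possibly empty
#'   until expansion).
#' @slot direction "up" or "down".
#' @slot fcThreshold Linear fold-change cutoff (strict).
#' @slot fdrThreshold FDR cutoff (strict).
#' @export
setClass("RegulatedSet",
         slots = c(label = "character",
                   geneIds = "character",
                   transcriptIds = "character",
                   direction = "character",
                   fcThreshold = "numeric",
                   fdrThreshold = "numeric"))

setValidity("RegulatedSet", function(object) {
  msgs <- character()
  if (!object@direction %in% c("up", "down"))
    msgs <- c(msgs, "direction must be 'up' or 'down'")
  if (object@fcThreshold <= 1)
    msgs <- c(msgs, "fcThreshold must exceed 1 (linear scale)")
  if (object@fdrThreshold < 0 || object@fdrThreshold > 1)
    msgs <- c(msgs, "fdrThreshold must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RegulatedSet", function(object) {
  cat(sprintf("RegulatedSet '%s': %d genes (%s, FC > %.3g, FDR < %.3g), %d transcripts\n",
              object@label, length(object@geneIds), object@direction,
              object@fcThreshold, object@fdrThreshold,
              length(object@transcriptIds)))
})

#' A randomized background gene set
#'
#' @slot label Set label.
#' @slot seed RNG seed that produced the draw.
#' @slot geneIds Sampled gene ids (without replacement).
#' @slot transcriptIds Isoform-expanded transcript ids.
#' @export
setClass("BackgroundSet",
         slots = c(label = "character",
                   seed = "integer",
                   geneIds = "character",
                   transcriptIds = "character"))

setMethod("show", "BackgroundSet", function(object) {
  cat(sprintf("BackgroundSet '%s' (seed %d): %d genes, %d transcripts\n",
              object@label, object@seed, length(object@geneIds),
              length(object@transcriptIds)))
})

# ---------------------------------------------------------------------------
# KSResult
# ---------------------------------------------------------------------------

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @slot statistic Sup-distance between the two ECDFs, in [0, 1].
#' @slot pValue Two-sided p-value.
#' @slot n1,n2 Sample sizes.
#' @slot method "asymptotic" or "exact-permutation".
#' @export
setClass("KSResult",
         slots = c(statistic = "numeric", pValue = "numeric",
                   n1 = "integer", n2 = "integer", method = "character"))

setMethod("show", "KSResult", function(object) {
  cat(sprintf("Two-sample KS (%s): D = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              object@method, object@statistic, object@pValue,
              object@n1, object@n2))
})

# ---------------------------------------------------------------------------
# DecayTimecourse / HalfLifeFit
# ---------------------------------------------------------------------------

#' A reference-normalized mRNA decay time course
#'
#' Target signal relative to a stable reference transcript, rescaled so
#' the value before transcription shut-off (t = 0) is 100.
#'
#' @slot times Minutes after transcription block, strictly increasing,
#'   starting at 0.
#' @slot target Raw target signal (> 0).
#' @slot reference Raw reference signal (> 0).
#' @slot normalized 100 * (target/reference) / (target/reference at t=0).
#' @export
setClass("DecayTimecourse",
         slots = c(times = "numeric", target = "numeric",
                   reference = "numeric", normalized = "numeric"))

setValidity("DecayTimecourse", function(object) {
  msgs <- character()
  n <- length(object@times)
  if (length(object@target) != n || length(object@reference) != n ||
      length(object@normalized) != n)
    msgs <- c(msgs, "times, target, reference, normalized must share length")
  if (n > 0L) {
    if (object@times[1L] != 0)
      msgs <- c(msgs, "first time point must be 0")
    if (n > 1L && any(diff(object@times) <= 0))
      msgs <- c(msgs, "times must be strictly increasing")
    if (any(object@target <= 0) || any(object@reference <= 0))
      msgs <- c(msgs, "signals must be strictly positive")
    if (abs(object@normalized[1L] - 100) > 1e-9)
      msgs <- c(msgs, "normalized value at t = 0 must be 100")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DecayTimecourse", function(object) {
  cat(sprintf("DecayTimecourse: %d points over %g min (normalized to 100 at t = 0)\n",
              length(object@times), max(object@times)))
})

#' One-phase exponential decay fit
#'
#' Fit of Y(t) = 100 * exp(-k t) (initial value pinned at 100, plateau at
#' 0) to a normalized decay time course; the decay rate `k` is the only
#' free parameter and `halfLife = log(2) / k`.
#'
#' @slot k Decay rate constant (1/min); 0 when the series is flagged
#'   non-decaying.
#' @slot halfLife Half-life in minutes; `Inf` when non-decaying.
#' @slot rss Residual sum of squares on the normalized scale.
#' @slot nPoints Number of time points fitted.
#' @slot unbounded TRUE when the least-squares optimum sits at k <= 0,
#'   i.e. the series shows no decay.
#' @export
setClass("HalfLifeFit",
         slots = c(k = "numeric", halfLife = "numeric", rss = "numeric",
                   nPoints = "integer", unbounded = "logical"))

setValidity("HalfLifeFit", function(object) {
  msgs <- character()
  if (object@rss < 0) msgs <- c(msgs, "rss must be >= 0")
  if (!object@unbounded) {
    if (object@k <= 0) msgs <- c(msgs, "k must be > 0 for a bounded fit")
    if (abs(object@halfLife * object@k - log(2)) > 1e-9 * log(2))
      msgs <- c(msgs, "halfLife * k must equal log(2)")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "HalfLifeFit", function(object) {
  if (object@unbounded) {
    cat("HalfLifeFit: no measurable decay (half-life unbounded)\n")
  } else {
    cat(sprintf("HalfLifeFit: t1/2 = %.4g min (k = %.4g /min, RSS = %.4g, n = %d)\n",
                object@halfLife, object@k, object@rss, object@nPoints))
  }
})

#' @describeIn HalfLifeFit Half-life in minutes (`Inf` if non-decaying).
#' @param fit A `HalfLifeFit`.
#' @export
halfLife <- function(fit) fit@halfLife

#' @describeIn HalfLifeFit Decay rate constant (1/min).
#' @export
decayRate <- function(fit) fit@k
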