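# Coerce any supported sequence representation to one normalized RNA string.
.asRnaChar <- function(seq) {
  if (methods::is(seq, "RNAString")) return(as.character(seq))
  if (methods::is(seq, "XStringSet")) {
    if (length(seq) != 1L)
      stop("expected a single sequence", call. = FALSE)
    return(normalizeAlphabet(as.character(seq)[[1L]]))
  }
  normalizeAlphabet(seq)
}

#' Locate AUUUA pentamers in a 3'UTR
#'
#' Scans the forward strand for every occurrence of the AUUUA destabilizing
#' pentamer. Overlapping occurrences are each reported (AUUUAUUUA yields
#' two hits). Ambiguity letters never match.
#'
#' @param seq A sequence: character string, `RNAString`, or single-element
#'   `RNAStringSet` (normalized on the fly).
#' @return An [IRanges::IRanges] of hits in ascending order (1-based,
#'   width 5); use [pentamerStarts()] for the 0-based starts.
#' @examples
#' findPentamers("GCAUUUAGC")
#' pentamerStarts(findPentamers("AUUUAUUUA"))  # 0 and 4
#' @export
findPentamers <- function(seq) {
  s <- .asRnaChar(seq)
  if (nchar(s) < 5L) return(IRanges::IRanges())
  m <- Biostrings::matchPattern(Biostrings::RNAString("AUUUA"),
                                Biostrings::RNAString(s))
  methods::as(m, "IRanges")
}

#' 0-based start positions of pentamer hits
#'
#' Converts hit ranges (or a scoring result) to the 0-based, half-open
#' start coordinates used in tabular outputs.
#'
#' @param x An `IRanges` of hits or an [AREScoreResult-class].
#' @return Integer vector of 0-based starts.
#' @export
pentamerStarts <- function(x) {
  if (methods::is(x, "AREScoreResult")) x <- x@hits
  IRanges::start(x) - 1L
}

#' A+U fraction of a sequence window
#'
#' @param seq Sequence (any representation accepted by [findPentamers()]).
#' @param start,end 0-based half-open window bounds,
#'   `0 <= start <= end <= length`.
#' @return The fraction of A and U characters in the window; an empty
#'   window is defined as 0.
#' @examples
#' auFraction("AUGCG", 0, 5)  # 0.4
#' @export
auFraction <- function(seq, start, end) {
  s <- .asRnaChar(seq)
  n <- nchar(s)
  if (start < 0 || end < start || end > n)
    stop(sprintf("window [%d, %d) out of range for length %d", start, end, n),
         call. = FALSE)
  if (end == start) return(0)
  win <- strsplit(substr(s, start + 1L, end), "", fixed = TRUE)[[1L]]
  sum(win %in% c("A", "U")) / (end - start)
}

#' Detect AU-rich blocks
#'
#' Finds the maximal non-overlapping intervals obtained by merging every
#' window of length `auBlockMinLen` whose A+U fraction is at least
#' `auBlockMinFraction`. These AU-rich blocks provide the sequence context
#' that strengthens the destabilizing potential of nearby pentamers.
#'
#' @param seq Sequence (any representation accepted by [findPentamers()]).
#' @param params An [AREScoreParams()] object.
#' @return An `IRanges` of blocks in ascending order (1-based).
#' @export
detectAUBlocks <- function(seq, params = AREScoreParams()) {
  s <- .asRnaChar(seq)
  n <- nchar(s)
  w <- params@auBlockMinLen
  if (n < w) return(IRanges::IRanges())
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  au <- cumsum(chars %in% c("A", "U"))
  starts <- seq_len(n - w + 1L)
  winsum <- au[starts + w - 1L] - c(0, au)[starts]
  ok <- starts[winsum / w >= params@auBlockMinFraction - 1e-12]
  if (!length(ok)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = ok, width = w))
}

#' Compute the ARE score of a 3'UTR
#'
#' Assembles the score additively: `pentamerWeight` per AUUUA hit, plus
#' `clusterBonus` per consecutive pair of hits whose start-to-start
#' distance is at most `clusterMaxGap`, plus `auBlockBonus` per AU-rich
#' block lying within `auBlockMaxDist` of any hit. The decomposition
#' identity (score = sum of the three weighted counts) holds exactly, and
#' a sequence with no pentamer always scores 0 (blocks alone never score).
#'
#' @param seq Sequence (any representation accepted by [findPentamers()]).
#' @param params An [AREScoreParams()] object.
#' @param id Identifier recorded in the result.
#' @return An [AREScoreResult-class].
#' @examples
#' computeAREScore("GCGCAUUUAGCGC")          # single isolated pentamer: 1
#' computeAREScore(strrep("AUUUA", 4))       # clustered, AU-rich: higher
#' @export
computeAREScore <- function(seq, params = AREScoreParams(), id = "seq") {
  s <- .asRnaChar(seq)
  hits <- findPentamers(s)
  nP <- length(hits)
  nPairs <- 0L
  nBlocks <- 0L
  if (nP > 0L) {
    starts <- IRanges::start(hits)
    if (nP > 1L)
      nPairs <- sum(diff(starts) <= params@clusterMaxGap)
    blocks <- detectAUBlocks(s, params)
    if (length(blocks)) {
      d <- .rangeDistance(blocks, hits)
      nBlocks <- sum(apply(d, 1L, min) <= params@auBlockMaxDist)
    }
  }
  score <- nP * params@pentamerWeight + nPairs * params@clusterBonus +
    nBlocks * params@auBlockBonus
  new("AREScoreResult", transcriptId = as.character(id), score = score,
      nPentamers = as.integer(nP), nClusterPairs = as.integer(nPairs),
      nAuBlocks = as.integer(nBlocks), hits = hits, params = params)
}

# Pairwise gap (nt) between two IRanges sets; 0 when overlapping/adjacent.
.rangeDistance <- function(a, b) {
  sa <- IRanges::start(a); ea <- IRanges::end(a)
  sb <- IRanges::start(b); eb <- IRanges::end(b)
  m <- matrix(0, nrow = length(a), ncol = length(b))
  for (i in seq_along(a)) {
    gap <- pmax(sb - ea[i] - 1L, sa[i] - eb - 1L)
    m[i, ] <- pmax(gap, 0L)
  }
  m
}

#' Classify a transcript as ARE-containing
#'
#' A score of at least `threshold` (default 2, boundary inclusive) marks a
#' functional ARE: a lone pentamer (score 1) is not sufficient for decay,
#' whereas clustered or AU-context-supported pentamers are.
#'
#' @param x An [AREScoreResult-class] or a numeric score (vectorized).
#' @param threshold Classification threshold (default 2).
#' @return Logical: TRUE when score >= threshold.
#' @export
classifyARE <- function(x, threshold = 2) {
  score <- if (methods::is(x, "AREScoreResult")) x@score else as.numeric(x)
  score >= threshold
}

#' Score every transcript of a database
#'
#' Applies [computeAREScore()] to each isoform 3'UTR; isoforms are scored
#' individually (no per-gene collapsing).
#'
#' @param db A [TranscriptDb-class].
#' @param params An [AREScoreParams()] object.
#' @param threshold ARE classification threshold passed to [classifyARE()].
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `score`, `n_pentamers`, `n_cluster_pairs`, `n_au_blocks`,
#'   `are_class`, and `hit_starts` (comma-joined 0-based starts).
#' @export
scoreTranscriptome <- function(db, params = AREScoreParams(), threshold = 2) {
  stopifnot(methods::is(db, "TranscriptDb"))
  seqs <- utrSequences(db)
  if (length(seqs) == 0L) stop("TranscriptDb is empty", call. = FALSE)
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("duplicate transcript ids in database", call. = FALSE)
  gene_of <- setNames(transcriptMap(db)$gene_id, transcriptMap(db)$transcript_id)
  res <- lapply(seq_along(seqs), function(i) {
    r <- computeAREScore(as.character(seqs[[i]]), params, id = ids[i])
    data.frame(transcript_id = ids[i],
               gene_id = unname(gene_of[ids[i]]),
               score = r@score,
               n_pentamers = r@nPentamers,
               n_cluster_pairs = r@nClusterPairs,
               n_au_blocks = r@nAuBlocks,
               are_class = classifyARE(r, threshold),
               hit_starts = paste(pentamerStarts(r), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
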