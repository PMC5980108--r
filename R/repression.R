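#' Join genotype-specific fold changes with ARE scores
#'
#' Inner-joins two differential-expression tables for the same contrast
#' (e.g. reoxygenation vs hypoxia) measured in control and knockout cells,
#' and annotates each id with its ARE score. Ids present in only one table
#' are reported in the `"dropped"` attribute, never silently discarded.
#'
#' @param deCtrl,deKo data.frames as returned by [readDETable()] (columns
#'   `gene_id`, `log2fc`, `fdr`).
#' @param scores Named numeric vector of scores by id, or a data.frame
#'   with columns `gene_id`/`transcript_id` and `score` (as from
#'   [scoreTranscriptome()]; per-gene score is the maximum over isoforms).
#' @param threshold ARE classification threshold (default 2).
#' @return data.frame with columns `id`, `log2fc_ctrl`, `fdr_ctrl`,
#'   `log2fc_ko`, `fdr_ko`, `score`, `are_class`; attribute `"dropped"`
#'   lists unmatched ids per table.
#' @export
joinGenotypes <- function(deCtrl, deKo, scores, threshold = 2) {
  for (nm in c("deCtrl", "deKo")) {
    de <- get(nm)
    if (anyDuplicated(de$gene_id))
      stop(sprintf("duplicate ids in %s table", nm), call. = FALSE)
  }
  score_of <- .scoreLookup(scores)
  common <- intersect(deCtrl$gene_id, deKo$gene_id)
  i <- match(common, deCtrl$gene_id)
  j <- match(common, deKo$gene_id)
  sc <- unname(score_of[common])
  sc[is.na(sc)] <- 0
  out <- data.frame(id = common,
                    log2fc_ctrl = deCtrl$log2fc[i],
                    fdr_ctrl = deCtrl$fdr[i],
                    log2fc_ko = deKo$log2fc[j],
                    fdr_ko = deKo$fdr[j],
                    score = sc,
                    are_class = classifyARE(sc, threshold),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- list(ctrl_only = setdiff(deCtrl$gene_id, common),
                               ko_only = setdiff(deKo$gene_id, common))
  out
}

.scoreLookup <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores))) return(scores)
  if (is.data.frame(scores) && "score" %in% colnames(scores)) {
    key <- if ("gene_id" %in% colnames(scores)) "gene_id" else "transcript_id"
    agg <- tapply(scores$score, scores[[key]], max)
    return(setNames(as.numeric(agg), names(agg)))
  }
  stop("scores must be a named numeric vector or a scoring data.frame",
       call. = FALSE)
}

#' Contrast repression fold-change distributions between genotypes
#'
#' Compares the control and knockout log2 fold-change distributions over a
#' restricted gene set by a two-sample KS test. The default restriction
#' mirrors the reoxygenation analysis: genes detected as downregulated in
#' control cells (FDR < `fdrThreshold`, FC < -`fcThreshold`) that carry a
#' functional ARE.
#'
#' @param pairs data.frame from [joinGenotypes()].
#' @param restrictToARE Keep only ARE-classified ids (default TRUE).
#' @param fcThreshold,fdrThreshold Control-downregulation cutoffs applied
#'   when `subset` is not given (strict inequalities; set
#'   `fdrThreshold = NULL` to skip the downregulation restriction).
#' @param subset Optional explicit logical vector overriding the
#'   downregulation rule (ARE restriction still applies).
#' @param exact Passed to [ksTwoSample()].
#' @return A [KSResult-class] comparing `log2fc_ctrl` vs `log2fc_ko`.
#' @export
contrastFCDistributions <- function(pairs, restrictToARE = TRUE,
                                    fcThreshold = 1.5, fdrThreshold = 0.05,
                                    subset = NULL, exact = FALSE) {
  keep <- rep(TRUE, nrow(pairs))
  if (!is.null(subset)) {
    stopifnot(length(subset) == nrow(pairs))
    keep <- keep & subset
  } else if (!is.null(fdrThreshold)) {
    keep <- keep & pairs$fdr_ctrl < fdrThreshold &
      pairs$log2fc_ctrl < -log2(fcThreshold)
  }
  if (restrictToARE) keep <- keep & pairs$are_class
  if (sum(keep) < 2L)
    stop("restriction leaves fewer than two pairs", call. = FALSE)
  ksTwoSample(pairs$log2fc_ctrl[keep], pairs$log2fc_ko[keep], exact = exact)
}

#' Rank genes by genotype sensitivity of their repression
#'
#' Filters to ARE-containing ids (score >= `minScore`) and ranks by
#' `delta = log2fc_ko - log2fc_ctrl`, descending: the top of the list is
#' repressed much more strongly in control than in knockout cells, i.e.
#' most dependent on the decay factor. Ties are broken by id so the
#' ranking is a deterministic, permutation-invariant function of the
#' input set.
#'
#' @param pairs data.frame from [joinGenotypes()].
#' @param topN Number of genes to return (default 30).
#' @param minScore Minimal ARE score (default 2).
#' @return data.frame `rank`, `id`, `score`, `log2fc_ctrl`, `log2fc_ko`,
#'   `delta`, at most `topN` rows.
#' @export
rankSensitivity <- function(pairs, topN = 30, minScore = 2) {
  qualifying <- pairs[pairs$score >= minScore, , drop = FALSE]
  if (nrow(qualifying) == 0L)
    stop("no pair reaches the minimal ARE score", call. = FALSE)
  delta <- qualifying$log2fc_ko - qualifying$log2fc_ctrl
  ord <- order(-delta, qualifying$id)
  keep <- head(ord, topN)
  data.frame(rank = seq_along(keep),
             id = qualifying$id[keep],
             score = qualifying$score[keep],
             log2fc_ctrl = qualifying$log2fc_ctrl[keep],
             log2fc_ko = qualifying$log2fc_ko[keep],
             delta = delta[keep],
             stringsAsFactors = FALSE)
}
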