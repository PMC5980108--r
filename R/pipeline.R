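# Run a pipeline stage with stage-tagged error propagation.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.logStage <- function(name, ...) {
  message(sprintf("[%s] %s", name, paste0(...)))
}

#' Read a run configuration
#'
#' @param path Path to a YAML configuration file.
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(path) {
  stopifnot(file.exists(path))
  yaml::read_yaml(path)
}

.resolveParams <- function(p) {
  if (is.null(p)) return(AREScoreParams())
  if (methods::is(p, "AREScoreParams")) return(p)
  do.call(AREScoreParams, p)
}

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.manifest <- function(config, inputs, outDir) {
  inputs <- inputs[vapply(inputs, function(p)
    is.character(p) && length(p) == 1L && file.exists(p), logical(1))]
  list(config = config,
       package_version = as.character(packageVersion("AREmd")),
       input_md5 = as.list(vapply(inputs, function(p) unname(md5sum(p)),
                                  character(1))),
       timestamp = format(Sys.time(), tz = "UTC"))
}

.ksAsList <- function(ks) {
  list(statistic = ks@statistic, p_value = ks@pValue,
       n1 = ks@n1, n2 = ks@n2, method = ks@method)
}

#' Run the hypoxia ARE-enrichment analysis
#'
#' End-to-end orchestration of the first analysis: score every isoform
#' 3'UTR, select the hypoxia up- and down-regulated gene sets from the DE
#' table, expand them to transcripts, draw seeded randomized background
#' sets from the expressed-gene universe, and compare the score
#' distributions (ECDF + two-sample KS) and the dichotomized ARE classes
#' (chi-squared with Bonferroni correction over all pairwise group
#' comparisons). Every random draw flows from the seeds recorded in the
#' configuration; reruns are reproducible from the emitted manifest.
#'
#' @param config Named list (or path to a YAML file readable by
#'   [readRunConfig()]) with entries: `fasta`, `tx_map`, `de_table`,
#'   `counts`, `normoxia_samples`, `hypoxia_samples`, `out_dir`; optional
#'   `de_schema`, `min_reads` (10), `fc_threshold` (1.5), `fdr_threshold`
#'   (0.01), `n_background` (900), `background_seeds` (1, 2),
#'   `are_threshold` (2), `params` (AREScoreParams fields).
#' @return Invisibly, a list with `scores`, `groups`, `ecdfs`, `ks`,
#'   `dichotomy`, `sets`; files `scores.tsv`, `report.json` and
#'   `manifest.json` are written under `out_dir`.
#' @export
runHypoxiaEnrichment <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- config$out_dir %||% stop("config needs 'out_dir'", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  params <- .resolveParams(config$params)
  fc <- config$fc_threshold %||% 1.5
  fdr <- config$fdr_threshold %||% 0.01
  areThr <- config$are_threshold %||% 2
  nBg <- config$n_background %||% 900
  seeds <- as.integer(config$background_seeds %||% c(1L, 2L))

  .logStage("score", "reading sequences and scoring transcripts")
  db <- .stage("score", {
    seqs <- readUtrFasta(config$fasta)
    TranscriptDb(seqs, readTranscriptMap(config$tx_map))
  })
  scores <- .stage("score", scoreTranscriptome(db, params, areThr))
  scoreOf <- setNames(scores$score, scores$transcript_id)

  .logStage("select", "selecting regulated sets")
  de <- .stage("select", {
    schema <- config$de_schema
    if (is.null(schema)) readDETable(config$de_table)
    else readDETable(config$de_table, schema = unlist(schema))
  })
  up <- .stage("select", expandToIsoforms(
    selectRegulated(de, "up", fc, fdr, label = "up_hypoxia"), db))
  down <- .stage("select", expandToIsoforms(
    selectRegulated(de, "down", fc, fdr, label = "down_hypoxia"), db))

  .logStage("background", "sampling randomized backgrounds")
  universe <- .stage("background", {
    counts <- read.delim(config$counts, check.names = FALSE)
    rn <- counts[[1L]]
    counts <- as.matrix(counts[, -1L, drop = FALSE])
    rownames(counts) <- rn
    cond <- c(setNames(rep("normoxia", length(config$normoxia_samples)),
                       config$normoxia_samples),
              setNames(rep("hypoxia", length(config$hypoxia_samples)),
                       config$hypoxia_samples))
    use <- colnames(counts)[colnames(counts) %in% names(cond)]
    expressedUniverse(counts[, use, drop = FALSE], conditions = cond[use],
                      use = c("normoxia", "hypoxia"),
                      minReads = config$min_reads %||% 10)
  })
  backgrounds <- .stage("background", lapply(seeds, function(s)
    sampleBackground(universe, nGenes = nBg, seed = s, db = db)))

  .logStage("enrich", "ECDF/KS and dichotomized tests")
  groups <- c(list(up_hypoxia = unname(scoreOf[up@transcriptIds]),
                   down_hypoxia = unname(scoreOf[down@transcriptIds])),
              setNames(lapply(backgrounds, function(b)
                unname(scoreOf[b@transcriptIds])),
                paste0("random", seq_along(backgrounds))))
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty))
    .logStage("enrich", "empty set(s) skipped: ",
              paste(empty, collapse = ", "))
  groups <- groups[lengths(groups) > 0L]
  report <- .stage("enrich", {
    ecdfs <- lapply(groups, ecdfTable)
    bgNames <- intersect(paste0("random", seq_along(backgrounds)),
                         names(groups))
    ks <- list()
    for (set in intersect(c("up_hypoxia", "down_hypoxia"), names(groups)))
      for (bg in bgNames)
        ks[[paste(set, "vs", bg)]] <-
          .ksAsList(ksTwoSample(groups[[set]], groups[[bg]]))
    dich <- dichotomizedEnrichment(groups, threshold = areThr)
    list(ecdfs = ecdfs, ks = ks, dichotomy = dich,
         provenance = list(
           fc_threshold = fc, fdr_threshold = fdr,
           are_threshold = areThr, n_background = nBg,
           background_seeds = seeds,
           ks_variant = "two-sided asymptotic",
           set_sizes = lapply(groups, length),
           empty_sets = empty,
           missing_genes = list(
             up = attr(up, "missing_genes"),
             down = attr(down, "missing_genes"))))
  })

  .stage("write", {
    .writeTsv(scores, file.path(outDir, "scores.tsv"))
    .writeJson(report, file.path(outDir, "report.json"))
    .writeJson(.manifest(config,
                         config[c("fasta", "tx_map", "de_table", "counts")],
                         outDir),
               file.path(outDir, "manifest.json"))
  })
  invisible(list(scores = scores, groups = groups, ecdfs = report$ecdfs,
                 ks = report$ks, dichotomy = report$dichotomy,
                 sets = list(up = up, down = down,
                             backgrounds = backgrounds)))
}

#' Run the reoxygenation genotype-contrast analysis
#'
#' End-to-end orchestration of the second analysis: join the control and
#' knockout reoxygenation DE tables, restrict to control-downregulated
#' ARE-containing genes, compare the two fold-change distributions by KS,
#' and rank the genes whose repression is most genotype-sensitive
#' (largest log2fc_ko - log2fc_ctrl).
#'
#' @param config Named list (or YAML path) with entries: `de_ctrl`,
#'   `de_ko`, `out_dir`, and either `scores` (a scores.tsv as written by
#'   [runHypoxiaEnrichment()]) or `fasta` + `tx_map` to score on the fly;
#'   optional `de_schema`, `top_n` (30), `fc_threshold` (1.5),
#'   `fdr_threshold` (0.05), `are_threshold` (2), `params`.
#' @return Invisibly, a list with `pairs`, `ks`, `ranking`; files
#'   `ranking.tsv`, `ks.json` and `manifest.json` are written under
#'   `out_dir`.
#' @export
runReoxygenationContrast <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- config$out_dir %||% stop("config needs 'out_dir'", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  topN <- config$top_n %||% 30
  fc <- config$fc_threshold %||% 1.5
  fdr <- config$fdr_threshold %||% 0.05
  areThr <- config$are_threshold %||% 2

  .logStage("score", "resolving ARE scores")
  scores <- .stage("score", {
    if (!is.null(config$scores)) {
      read.delim(config$scores, stringsAsFactors = FALSE)
    } else {
      db <- TranscriptDb(readUtrFasta(config$fasta),
                         readTranscriptMap(config$tx_map))
      scoreTranscriptome(db, .resolveParams(config$params), areThr)
    }
  })

  .logStage("join", "joining genotype DE tables")
  readDe <- function(p) {
    schema <- config$de_schema
    if (is.null(schema)) readDETable(p)
    else readDETable(p, schema = unlist(schema))
  }
  pairs <- .stage("join", joinGenotypes(readDe(config$de_ctrl),
                                        readDe(config$de_ko),
                                        scores, threshold = areThr))

  .logStage("contrast", "KS contrast and sensitivity ranking")
  ks <- .stage("contrast", contrastFCDistributions(
    pairs, restrictToARE = TRUE, fcThreshold = fc, fdrThreshold = fdr))
  ranking <- .stage("contrast", rankSensitivity(pairs, topN = topN,
                                                minScore = areThr))

  .stage("write", {
    .writeTsv(ranking, file.path(outDir, "ranking.tsv"))
    .writeJson(list(ks = .ksAsList(ks),
                    provenance = list(
                      restriction = "CTRL-downregulated ARE transcripts",
                      fc_threshold = fc, fdr_threshold = fdr,
                      are_threshold = areThr, top_n = topN,
                      delta_definition = "log2fc_ko - log2fc_ctrl",
                      dropped = attr(pairs, "dropped"))),
               file.path(outDir, "ks.json"))
    .writeJson(.manifest(config,
                         config[c("de_ctrl", "de_ko", "scores",
                                  "fasta", "tx_map")],
                         outDir),
               file.path(outDir, "manifest.json"))
  })
  invisible(list(pairs = pairs, ks = ks, ranking = ranking))
}
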