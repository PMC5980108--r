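# Shared fixtures and independent oracles, built in code at test time.

# Printed RNA probe with two overlapping-cluster pentamers (starts 24, 28)
# and its scrambled, motif-free control of identical composition.
ARE_PROBE <- "uguuuauuuuuaguccaccucucaauuuauuuauuauuuuuauga"
SCRAMBLED_PROBE <- "auucuauuguuucuucuuauauauuguuauucuucacauaauguu"

# Naive O(n*5) sliding-window pentamer oracle: 0-based starts.
naivePentamerStarts <- function(s) {
  s <- toupper(chartr("t", "u", chartr("T", "U", s)))
  n <- nchar(s)
  if (n < 5L) return(integer(0))
  starts <- seq_len(n - 4L)
  starts[substring(s, starts, starts + 4L) == "AUUUA"] - 1L
}

# Random RNA string with given A/U/G/C probabilities.
randomRNA <- function(n, probs = c(A = .25, U = .25, G = .25, C = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# Closed-form log-linear-through-origin decay-rate oracle (noiseless data).
loglinearK <- function(t, y) {
  keep <- t > 0
  -sum(t[keep] * log(y[keep] / 100)) / sum(t[keep]^2)
}

# A tiny transcript database: g1 has two isoforms with different 3'UTRs,
# g2 and g3 one each.
tinyDb <- function() {
  seqs <- c(
    "g1-t1" = "GCGCAUUUAGCGCGCGCGCG",
    "g1-t2" = paste0("GCGC", strrep("AUUUA", 3), "GCGCGC"),
    "g2-t1" = "GCGCGCGCGCGCGCGCGCGC",
    "g3-t1" = "AUAUAUAUGCGCGCGCGCAU")
  TranscriptDb(seqs, data.frame(
    gene_id = c("g1", "g1", "g2", "g3"),
    transcript_id = names(seqs), stringsAsFactors = FALSE))
}

# Write a simulated experiment bundle to disk for pipeline tests; returns
# the file paths.
writeSimBundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta = file.path(dir, "utrs.fa"),
    tx_map = file.path(dir, "map.tsv"),
    counts = file.path(dir, "counts.tsv"),
    de_hyp = file.path(dir, "de_hyp.tsv"),
    de_ctrl = file.path(dir, "de_reox_ctrl.tsv"),
    de_ko = file.path(dir, "de_reox_ko.tsv"))
  writeUtrFasta(utrSequences(sim$db), paths$fasta)
  wt <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(transcriptMap(sim$db), paths$tx_map)
  wt(data.frame(gene_id = rownames(sim$counts), sim$counts,
                check.names = FALSE), paths$counts)
  wt(sim$de$hypoxia_vs_normoxia_ctrl, paths$de_hyp)
  wt(sim$de$reox_vs_hypoxia_ctrl, paths$de_ctrl)
  wt(sim$de$reox_vs_hypoxia_ko, paths$de_ko)
  paths
}
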