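# IUPAC nucleotide letters accepted on input (T converted to U).
.IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

#' Normalize a nucleotide string to the canonical RNA alphabet
#'
#' Upper-cases the input and converts every T to U, so DNA-spelled and
#' RNA-spelled sequences score identically downstream. IUPAC ambiguity
#' letters are preserved; they can never match inside an AUUUA pentamer or
#' count towards AU content (the scorer never invents a motif).
#'
#' @param raw A single nucleotide string (case-insensitive IUPAC letters).
#' @return The normalized upper-case RNA string, same length as the input.
#' @examples
#' normalizeAlphabet("atttA")  # "AUUUA"
#' @export
normalizeAlphabet <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  up <- toupper(raw)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% .IUPAC))
  if (length(bad)) {
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad[1L]],
                 bad[1L]), call. = FALSE)
  }
  chartr("T", "U", up)
}

#' Read 3'UTR sequences from a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file and returns the
#' records in file order as a normalized [Biostrings::RNAStringSet]
#' (upper-case, U-based). Records with an empty header or empty sequence
#' are rejected with their record index.
#'
#' @param path Path to a FASTA file.
#' @return An `RNAStringSet` named by record id; empty file gives an empty
#'   set.
#' @seealso [writeUtrFasta()], [normalizeAlphabet()]
#' @export
readUtrFasta <- function(path) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) return(Biostrings::RNAStringSet())
  ids <- sub("\\s.*$", "", names(raw))
  empty_id <- which(is.na(ids) | ids == "")
  if (length(empty_id))
    stop(sprintf("FASTA record %d has an empty header", empty_id[1L]),
         call. = FALSE)
  seqs <- as.character(raw)
  empty_seq <- which(nchar(seqs) == 0L)
  if (length(empty_seq))
    stop(sprintf("FASTA record %d ('%s') has an empty sequence",
                 empty_seq[1L], ids[empty_seq[1L]]), call. = FALSE)
  norm <- vapply(seqs, normalizeAlphabet, character(1), USE.NAMES = FALSE)
  out <- Biostrings::RNAStringSet(norm)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x A named `RNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeUtrFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::RNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Reads a delimited text table produced by upstream differential-expression
#' testing and maps its columns onto the canonical record layout
#' (`gene_id`, `log2fc`, `fdr`, `mean_expr`, optional `transcript_ids`).
#' Rows whose numeric fields fail to parse, whose FDR falls outside [0, 1],
#' or whose log2 fold change is non-finite are dropped with a warning
#' naming the offending row numbers.
#'
#' @param path Path to the table.
#' @param schema Named character vector mapping canonical names to column
#'   names in the file, e.g. `c(gene_id = "gene", log2fc = "logFC",
#'   fdr = "FDR", mean_expr = "logCPM")`. `gene_id`, `log2fc` and `fdr`
#'   are required; `mean_expr` and `transcript_ids` are optional.
#' @param sep Field delimiter (default tab).
#' @return data.frame with canonical columns; attribute `"rejected_rows"`
#'   lists dropped row numbers.
#' @export
readDETable <- function(path,
                        schema = c(gene_id = "gene_id", log2fc = "log2fc",
                                   fdr = "fdr", mean_expr = "mean_expr"),
                        sep = "\t") {
  stopifnot(file.exists(path))
  required <- c("gene_id", "log2fc", "fdr")
  if (!all(required %in% names(schema)))
    stop("schema must map at least 'gene_id', 'log2fc' and 'fdr'",
         call. = FALSE)
  tab <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  missing_cols <- setdiff(unname(schema), colnames(tab))
  if (length(missing_cols))
    stop(sprintf("mapped column(s) not found in '%s': %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  out <- data.frame(gene_id = as.character(tab[[schema[["gene_id"]]]]),
                    log2fc = suppressWarnings(as.numeric(tab[[schema[["log2fc"]]]])),
                    fdr = suppressWarnings(as.numeric(tab[[schema[["fdr"]]]])),
                    stringsAsFactors = FALSE)
  out$mean_expr <- if ("mean_expr" %in% names(schema))
    suppressWarnings(as.numeric(tab[[schema[["mean_expr"]]]])) else NA_real_
  out$transcript_ids <- if ("transcript_ids" %in% names(schema))
    as.character(tab[[schema[["transcript_ids"]]]]) else NA_character_
  bad <- which(!is.finite(out$log2fc) | is.na(out$fdr) |
                 out$fdr < 0 | out$fdr > 1)
  if (length(bad)) {
    warning(sprintf("dropped %d row(s) with invalid numerics: %s",
                    length(bad), paste(bad, collapse = ", ")), call. = FALSE)
    out <- out[-bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "rejected_rows") <- bad
  out
}

#' Read a gene-to-transcript mapping table
#'
#' Two-column delimited text (header `gene_id`, `transcript_id`); the
#' explicit mapping file is required rather than inferring gene identity
#' from FASTA header conventions.
#'
#' @param path Path to the mapping table.
#' @param sep Field delimiter.
#' @return data.frame with columns `gene_id`, `transcript_id`.
#' @export
readTranscriptMap <- function(path, sep = "\t") {
  stopifnot(file.exists(path))
  tab <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "transcript_id") %in% colnames(tab)))
    stop("mapping file must have columns 'gene_id' and 'transcript_id'",
         call. = FALSE)
  tab[, c("gene_id", "transcript_id")]
}
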