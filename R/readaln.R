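HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Import BLAST tabular (outfmt 6) alignment hits
#'
#' Reads the standard 12-column tabular dialect, or a 13-column variant
#' with query length (`qlen`) appended.  12-column input requires the
#' query FASTA so read lengths can be attached (the coverage filter needs
#' them).
#'
#' @param path TSV path.
#' @param query optional query FASTA path (or named sequences) supplying
#'   `qlen` for 12-column input.
#' @return data frame of hits with columns `qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore qlen`.
#' @export
import_hits <- function(path, query = NULL) {
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character", quote = "", comment.char = "#"),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), 13),
                                  c(HIT_COLS, "qlen")))
    for (cc in c(HIT_COLS[-(1:2)], "qlen")) out[[cc]] <- numeric(0)
    return(out)
  }
  if (!ncol(raw) %in% c(12, 13))
    stopf("expected 12 or 13 tab-separated columns, found %d", ncol(raw))
  names(raw) <- c(HIT_COLS, if (ncol(raw) == 13) "qlen")
  num_cols <- setdiff(names(raw), c("qseqid", "sseqid"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    if (anyNA(v)) {
      line <- which(is.na(v))[1]
      stopf("non-numeric value '%s' in column %s, line %d",
            raw[[cc]][line], cc, line)
    }
    raw[[cc]] <- v
  }
  if (!"qlen" %in% names(raw)) {
    if (is.null(query))
      stopf("query lengths unavailable: 12-column input needs a query FASTA")
    qs <- as_named_seqs(query, "query")
    miss <- setdiff(unique(raw$qseqid), names(qs))
    if (length(miss))
      stopf("query '%s' absent from the supplied FASTA", miss[1])
    raw$qlen <- unname(nchar(qs)[raw$qseqid])
  }
  raw
}

#' Write hits in BLAST outfmt-6 tabular form (13th column: qlen)
#' @param hits hit data frame.
#' @param path output TSV path.
#' @export
write_hits <- function(hits, path) {
  cols <- c(HIT_COLS, "qlen")
  out <- hits[, cols]
  out$evalue <- formatC(out$evalue, format = "e", digits = 2)
  out$pident <- formatC(out$pident, format = "f", digits = 3)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Alignment scoring scheme for the built-in aligner
#'
#' Linear gap costs (every gap column costs `|gap|`); the default is the
#' megablast-like +1/-2/-2.5 scheme.  Bitscores are the raw score rescaled
#' as `(lambda * S - ln K) / ln 2` with lambda = 1.28, K = 0.46; exact
#' parity with BLAST statistics is not promised.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap per-gap-column penalty (< 0).
#' @param lambda,K bitscore rescaling constants.
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap = -2.5,
                          lambda = 1.28, K = 0.46) {
  if (match <= 0 || mismatch >= 0 || gap >= 0)
    stopf("need match > 0, mismatch < 0, gap < 0")
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 lambda = lambda, K = K),
            class = "align_scoring")
}

#' Convert a bitscore to an e-value
#'
#' `E = qlen * db_size * 2^(-bitscore)`: the expected number of chance
#' hits of at least that score in a search space of query length times
#' database size.
#'
#' @param bitscore bitscore(s).
#' @param qlen query length (bp).
#' @param db_size total database size (bp).
#' @return e-value(s); monotone decreasing in bitscore.
#' @export
#' @examples
#' score_to_evalue(50, qlen = 100, db_size = 1e6)  # ~8.9e-08
score_to_evalue <- function(bitscore, qlen, db_size) {
  if (any(qlen <= 0) || any(db_size <= 0))
    stopf("qlen and db_size must be positive")
  qlen * db_size * 2^(-bitscore)
}

raw_to_bitscore <- function(score, scoring) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

#' Align reads against a reference database
#'
#' Seed-and-extend local alignment (exact 11-mer seeds, gapped
#' dynamic-programming extension in a window of half-width `band` around
#' seeded diagonals) of every read, on both strands, against every genome
#' of the database.  Subject coordinates are 1-based inclusive on the
#' concatenated genome sequence; `sstart > send` marks minus-strand hits
#' (BLAST convention).
#'
#' @param reads FASTA path, `DNAStringSet`, or named character.
#' @param db a `genome_db` from [build_db()].
#' @param scoring an [align_scoring()].
#' @param seed_len exact seed length (bp).
#' @param band window margin around seeded diagonals (bp).
#' @param best_per_genome keep only the single best hit per (read, genome)
#'   pair.
#' @param max_evalue report only hits with e-value below this.
#' @return Hit data frame as in [import_hits()].
#' @export
local_align <- function(reads, db, scoring = align_scoring(),
                        seed_len = 11, band = 15,
                        best_per_genome = FALSE, max_evalue = 10) {
  stopifnot(inherits(db, "genome_db"), inherits(scoring, "align_scoring"))
  if (length(db$genomes) == 0) stopf("empty reference database")
  reads <- as_named_seqs(reads, "reads")
  subj <- db_sequences(db)
  hits <- cpp_local_align(unname(reads), names(reads),
                          unname(subj), names(subj),
                          scoring$match, scoring$mismatch, scoring$gap,
                          as.integer(seed_len), as.integer(band),
                          best_per_genome)
  hits$bitscore <- raw_to_bitscore(hits$score, scoring)
  hits$evalue <- score_to_evalue(hits$bitscore, hits$qlen, sum(db_sizes(db)))
  hits <- hits[hits$evalue < max_evalue, , drop = FALSE]
  hits$score <- NULL
  rownames(hits) <- NULL
  hits[, c(HIT_COLS, "qlen")]
}
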