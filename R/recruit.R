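#' Filter thresholds for the recruitment cascade
#'
#' The defaults mirror the conventional fragment-recruitment settings: a
#' hit survives when its e-value is strictly below `max_evalue`, its
#' percent identity strictly above `min_pident`, and the aligned span on
#' the read (`|qend - qstart| + 1`) covers at least `min_qcov` of the read
#' length (inclusive).
#'
#' @param max_evalue e-value ceiling (strict), default 1e-6.
#' @param min_pident identity floor in percent (strict), default 70.
#' @param min_qcov minimum query coverage fraction (inclusive), default 0.9.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(max_evalue = 1e-6, min_pident = 70,
                          min_qcov = 0.9) {
  if (min_qcov <= 0 || min_qcov > 1) stopf("min_qcov must be in (0, 1]")
  if (min_pident < 0 || min_pident > 100)
    stopf("min_pident must be in [0, 100]")
  structure(list(max_evalue = max_evalue, min_pident = min_pident,
                 min_qcov = min_qcov),
            class = "filter_params")
}

#' Threshold filter: e-value, identity and read coverage
#'
#' @param hits hit data frame (needs a `qlen` column).
#' @param params a [filter_params()].
#' @return The surviving hits, input order preserved.
#' @export
filter_hits <- function(hits, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  if (nrow(hits) == 0) return(hits)
  if (!"qlen" %in% names(hits) || anyNA(hits$qlen))
    stopf("hits are missing query lengths (qlen)")
  qcov <- (abs(hits$qend - hits$qstart) + 1) / hits$qlen
  keep <- hits$evalue < params$max_evalue &
    hits$pident > params$min_pident &
    qcov >= params$min_qcov
  hits[keep, , drop = FALSE]
}

#' Remove duplicated reads within each genome
#'
#' Keeps at most one hit per (read, genome) pair: the hit with the highest
#' bitscore, ties broken by larger alignment length, then smaller
#' strand-normalized subject start (deterministic).
#'
#' @param hits hit data frame.
#' @return Deduplicated hits.
#' @export
dedup_within_genome <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  sstart0 <- pmin(hits$sstart, hits$send)
  o <- order(hits$qseqid, hits$sseqid, -hits$bitscore, -hits$length, sstart0)
  h <- hits[o, , drop = FALSE]
  keep <- !duplicated(paste(h$qseqid, h$sseqid, sep = "\r"))
  h[keep, , drop = FALSE]
}

#' Mask hits overlapping ribosomal-operon intervals
#'
#' Removes every hit whose strand-normalized subject interval overlaps a
#' mask interval of its genome by at least one base.  The ribosomal operon
#' does not follow the species-delimiting recruitment pattern of the rest
#' of the genome, so keeping it would overestimate recruitment.
#'
#' @param hits hit data frame (subject coordinates 1-based inclusive on
#'   the concatenated genome).
#' @param db a `genome_db` carrying mask intervals.
#' @return Hits outside all masks.
#' @export
mask_ribosomal <- function(hits, db) {
  stopifnot(inherits(db, "genome_db"))
  if (nrow(hits) == 0) return(hits)
  lo <- pmin(hits$sstart, hits$send) - 1   # 0-based half-open
  hi <- pmax(hits$sstart, hits$send)
  drop <- rep(FALSE, nrow(hits))
  for (id in names(db$genomes)) {
    m <- db$genomes[[id]]$masks
    if (nrow(m) == 0) next
    sel <- which(hits$sseqid == id)
    for (k in seq_len(nrow(m)))
      drop[sel] <- drop[sel] |
        (pmin(hi[sel], m[k, 2]) - pmax(lo[sel], m[k, 1]) > 0)
  }
  hits[!drop, , drop = FALSE]
}

#' Competitive best-genome assignment
#'
#' For each read keeps the single best hit across all genomes of the
#' shared database (max bitscore; ties by higher pident, then
#' lexicographically smaller genome id), so every read is claimed by
#' exactly one genome.  Subject coordinates are converted here -- the one
#' conversion point -- to 0-based half-open, strand-normalized
#' (`start < end`) intervals.
#'
#' @param hits filtered, deduplicated, masked hit data frame.
#' @return data frame of class `recruited_reads`: `qseqid, genome, pident,
#'   start, end, bitscore`.
#' @export
competitive_assign <- function(hits) {
  if (nrow(hits) == 0) {
    out <- data.frame(qseqid = character(0), genome = character(0),
                      pident = numeric(0), start = numeric(0),
                      end = numeric(0), bitscore = numeric(0))
    class(out) <- c("recruited_reads", "data.frame")
    return(out)
  }
  o <- order(hits$qseqid, -hits$bitscore, -hits$pident, hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  out <- data.frame(qseqid = h$qseqid, genome = h$sseqid,
                    pident = h$pident,
                    start = pmin(h$sstart, h$send) - 1,
                    end = pmax(h$sstart, h$send),
                    bitscore = h$bitscore)
  rownames(out) <- NULL
  class(out) <- c("recruited_reads", "data.frame")
  out
}

#' Run the full recruitment cascade
#'
#' Applies, in order: threshold filtering ([filter_hits()]),
#' within-genome deduplication ([dedup_within_genome()]), ribosomal-operon
#' masking ([mask_ribosomal()]) and competitive assignment
#' ([competitive_assign()]), then labels identity bins
#' ([bin_identity()]).
#'
#' @param hits hit data frame ([import_hits()] or [local_align()]).
#' @param db a `genome_db`.
#' @param params a [filter_params()].
#' @param edges identity-bin edges, see [bin_identity()].
#' @return `recruited_reads` data frame with a `bin` column.
#' @export
recruit <- function(hits, db, params = filter_params(),
                    edges = c(70, 95, 100)) {
  rec <- competitive_assign(
    mask_ribosomal(dedup_within_genome(filter_hits(hits, params)), db))
  bin_identity(rec, edges)
}

#' Read / write recruited-read tables
#' @param rec `recruited_reads` data frame.
#' @param path TSV path.
#' @export
write_recruited <- function(rec, path) {
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recruited
#' @export
read_recruited <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("recruited_reads", "data.frame")
  out
}
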