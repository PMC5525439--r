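#' Specify a simulated read set
#'
#' @param genome_id id of the source genome (bookkeeping only).
#' @param n_reads number of reads to draw.
#' @param length_mean,length_sd read length distribution (bp); lengths are
#'   normal draws rounded and clamped to at least 30 bp.
#' @param identity target per-read identity `p` (matches over alignment
#'   columns of the true read-to-source alignment), 0.5--1.
#' @param indel_frac share of error events that are indels (the rest are
#'   substitutions); indel events have geometric length, mean 1.5.
#' @param seed integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(genome_id = "genome", n_reads = 1000L,
                          length_mean = 150, length_sd = 20,
                          identity = 0.95, indel_frac = 0.1, seed = 1L) {
  if (n_reads < 0) stopf("n_reads must be >= 0")
  if (identity < 0.5 || identity > 1)
    stopf("target identity must be within [0.5, 1]")
  if (indel_frac < 0 || indel_frac > 1)
    stopf("indel_frac must be within [0, 1]")
  if (length_mean < 30) stopf("length_mean must be >= 30")
  structure(list(genome_id = genome_id, n_reads = as.integer(n_reads),
                 length_mean = length_mean, length_sd = length_sd,
                 identity = identity, indel_frac = indel_frac,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

## emit one read of `target_len` bases starting at 0-based `start`;
## the edit script is generated column-wise so that a column is a match
## with probability q_m, solved so E[matches / columns] equals `p`
sim_one_read <- function(gchars, start, target_len, p, indel_frac) {
  L <- length(gchars)
  bases <- c("A", "C", "G", "T")
  r <- 1 + 0.5 * indel_frac          # mean columns per error event / 1
  q_m <- p * r / (1 - p + p * r)     # event-level match probability
  out <- character(target_len)
  nout <- 0L
  gpos <- start                       # 0-based, next genome base to consume
  matches <- 0L; columns <- 0L
  while (nout < target_len && gpos < L) {
    u <- runif(1)
    if (u < q_m) {
      nout <- nout + 1L; out[nout] <- gchars[gpos + 1L]
      gpos <- gpos + 1L; matches <- matches + 1L; columns <- columns + 1L
    } else if (u < q_m + (1 - q_m) * (1 - indel_frac)) {
      nout <- nout + 1L
      out[nout] <- sample(setdiff(bases, gchars[gpos + 1L]), 1)
      gpos <- gpos + 1L; columns <- columns + 1L
    } else {
      g <- rgeom(1, 1 / INDEL_MEAN_LEN) + 1L
      if (runif(1) < 0.5) {           # deletion: consume genome only
        g <- min(g, L - gpos)
        gpos <- gpos + g; columns <- columns + g
      } else {                        # insertion: emit random bases
        g <- min(g, target_len - nout)
        if (g > 0) {
          out[nout + seq_len(g)] <- sample(bases, g, replace = TRUE)
          nout <- nout + g; columns <- columns + g
        }
      }
    }
  }
  list(seq = paste(out[seq_len(nout)], collapse = ""),
       span = c(start, gpos), identity = matches / columns)
}

#' Simulate reads from a genome with a ground-truth table
#'
#' Reads are drawn uniformly from the (concatenated) genome on either
#' strand; errors are placed i.i.d. over alignment columns and split
#' between substitutions and indels according to the spec, so the realized
#' identity recorded in the truth table is directly comparable to aligner
#' percent identity (matches / alignment columns).
#'
#' @param genome a single sequence: character string, `DNAString`, or a
#'   [gen_community()] object together with `genome_id` in `spec`.
#' @param spec a [read_sim_spec()].
#' @param masks optional data frame (`start`, `end`, 0-based half-open) of
#'   rRNA-operon intervals used to set the truth `overlaps_rrna` flag; when
#'   `genome` is a community the spec'd genome's masks are used.
#' @param out optional directory for `reads.fasta` + `truth.tsv`.
#' @return list of class `read_sim` with `reads` (named character) and
#'   `truth` (data frame: read, genome, start, end, strand, identity,
#'   overlaps_rrna).
#' @export
sim_reads <- function(genome, spec, masks = NULL, out = NULL) {
  stopifnot(inherits(spec, "read_sim_spec"))
  if (inherits(genome, "community")) {
    com <- genome
    if (!spec$genome_id %in% names(com$sequences))
      stopf("genome '%s' not in community", spec$genome_id)
    if (is.null(masks) && nrow(com$masks))
      masks <- com$masks[com$masks$genome == spec$genome_id,
                         c("start", "end"), drop = FALSE]
    genome <- com$sequences[[spec$genome_id]]
  }
  if (methods::is(genome, "XString")) genome <- as.character(genome)
  L <- nchar(genome)
  if (spec$n_reads > 0 && L == 0) stopf("cannot simulate reads from an empty genome")
  if (L < spec$length_mean)
    stopf("genome shorter than the mean read length")
  gchars <- strsplit(genome, "", fixed = TRUE)[[1]]
  with_seed(spec$seed, {
    n <- spec$n_reads
    reads <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      len <- max(30L, round(rnorm(1, spec$length_mean, spec$length_sd)))
      len <- min(len, L)
      start <- sample.int(L - len + 1L, 1) - 1L
      r <- sim_one_read(gchars, start, len, spec$identity, spec$indel_frac)
      minus <- runif(1) < 0.5
      reads[i] <- if (minus) revcomp_chr(r$seq) else r$seq
      ov <- FALSE
      if (!is.null(masks) && nrow(masks))
        ov <- any(pmin(masks$end, r$span[2]) - pmax(masks$start, r$span[1]) > 0)
      truth[[i]] <- data.frame(
        read = sprintf("%s_read%05d", spec$genome_id, i),
        genome = spec$genome_id, start = r$span[1], end = r$span[2],
        strand = if (minus) "-" else "+", identity = r$identity,
        overlaps_rrna = ov)
    }
    truth <- if (n) do.call(rbind, truth) else
      data.frame(read = character(0), genome = character(0),
                 start = numeric(0), end = numeric(0), strand = character(0),
                 identity = numeric(0), overlaps_rrna = logical(0))
    names(reads) <- truth$read[seq_len(n)]
    res <- structure(list(reads = reads, truth = truth, spec = spec),
                     class = "read_sim")
    if (!is.null(out)) {
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_fasta(as.list(reads), file.path(out, "reads.fasta"))
      write.table(truth, file.path(out, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    res
  })
}

#' @export
print.read_sim <- function(x, ...) {
  cat(sprintf("Simulated read set: %d reads from '%s' (target identity %.3f)\n",
              length(x$reads), x$spec$genome_id, x$spec$identity))
  if (length(x$reads))
    cat(sprintf("  mean realized identity %.4f, mean length %.1f bp\n",
                mean(x$truth$identity), mean(nchar(x$reads))))
  invisible(x)
}
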