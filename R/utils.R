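stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state so the
#' generators are reproducible without disturbing the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stopf("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## uniform random DNA with a given GC fraction
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Coerce sequence input to a named character vector
#'
#' Accepts a FASTA file path, a `Biostrings` `XStringSet`, or a named
#' character vector; FASTA headers keep their first whitespace-delimited
#' token; unnamed entries are named `seq1`, `seq2`, ...
#'
#' @param x sequence input.
#' @param what label used in error messages.
#' @return named character vector of sequences.
#' @export
as_named_seqs <- function(x, what = "sequences") {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- Biostrings::readBStringSet(x)
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x)) stopf("cannot interpret %s input", what)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    names(x) <- paste0("seq", seq_along(x))
  ## FASTA headers: keep first whitespace-delimited token
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line-wrap width.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  set <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

## merge possibly overlapping [start, end) intervals (matrix, 2 columns)
merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(matrix(numeric(0), ncol = 2))
  ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1] + 1, end = m[, 2]))
  cbind(IRanges::start(ir) - 1, IRanges::end(ir))
}
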