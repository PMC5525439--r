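#' Generate a synthetic marker-gene family with known polymorphic sites
#'
#' A random root sequence is copied `n_seqs` times and exactly
#' `n_polymorphic_sites` positions receive a variant base in a proper,
#' non-empty subset of the copies, so each listed position is truly
#' polymorphic across the family (requires `n_seqs >= 2`; a family of one
#' carries no polymorphism and the truth set is empty).
#'
#' @param n_seqs number of family members.
#' @param length sequence length (bp).
#' @param n_polymorphic_sites number of polymorphic columns.
#' @param seed integer seed.
#' @param marker marker name label (e.g. "16S").
#' @param id_prefix sequence name prefix.
#' @return list of class `marker_family`: `sequences` (named character),
#'   `root`, `marker`, and `truth` (data frame: position (1-based), ref,
#'   alt, carriers).
#' @export
gen_marker_family <- function(n_seqs, length, n_polymorphic_sites = 0L,
                              seed = 1L, marker = "16S",
                              id_prefix = marker) {
  if (n_polymorphic_sites > length)
    stopf("n_polymorphic_sites must be <= length")
  if (n_seqs < 1) stopf("n_seqs must be >= 1")
  with_seed(seed, {
    root <- random_dna(length, 0.5)
    seqs <- rep(root, n_seqs)
    names(seqs) <- sprintf("%s_%02d", id_prefix, seq_len(n_seqs))
    truth <- data.frame(position = integer(0), ref = character(0),
                        alt = character(0), carriers = character(0))
    if (n_polymorphic_sites > 0 && n_seqs >= 2) {
      pos <- sort(sample.int(length, n_polymorphic_sites))
      rootc <- strsplit(root, "", fixed = TRUE)[[1]]
      mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
      for (p in pos) {
        alt <- sample(setdiff(c("A", "C", "G", "T"), rootc[p]), 1)
        k <- sample.int(n_seqs - 1L, 1)          # proper non-empty subset
        carriers <- sample.int(n_seqs, k)
        mat[carriers, p] <- alt
        truth <- rbind(truth, data.frame(
          position = p, ref = rootc[p], alt = alt,
          carriers = paste(names(seqs)[sort(carriers)], collapse = ",")))
      }
      seqs <- setNames(apply(mat, 1, paste, collapse = ""), names(seqs))
    } else if (n_polymorphic_sites > 0) {
      warning("a family of one cannot be polymorphic; truth set is empty")
    }
    structure(list(sequences = seqs, root = root, marker = marker,
                   truth = truth),
              class = "marker_family")
  })
}

#' @export
print.marker_family <- function(x, ...) {
  cat(sprintf("Synthetic %s family: %d sequence(s) of %d bp, %d polymorphic site(s)\n",
              x$marker, length(x$sequences), nchar(x$root), nrow(x$truth)))
  invisible(x)
}
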