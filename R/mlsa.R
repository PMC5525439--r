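guess_alphabet <- function(x) {
  chars <- unique(strsplit(toupper(gsub("-", "", x)), "", fixed = TRUE)[[1]])
  if (all(chars %in% c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W",
                       "K", "M", "B", "D", "H", "V")))
    "nucleotide" else "amino-acid"
}

## end-gap-free ("overlap") pairwise alignment; returns the two aligned
## strings over the non-terminal-gap region
overlap_align <- function(a, b, alphabet) {
  if (alphabet == "nucleotide") {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                   baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = sm, gapOpening = 0, gapExtension = 2,
      type = "overlap")
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "overlap")
  }
  list(pattern = as.character(Biostrings::alignedPattern(pa)),
       subject = as.character(Biostrings::alignedSubject(pa)))
}

#' End-gap-free pairwise identity and coverage
#'
#' Global alignment with unpenalized terminal gaps; percent identity is
#' matches over aligned columns (terminal-gap columns excluded) and
#' coverage is the aligned span of `a` over its length.  This suits
#' comparisons of a full-length gene against partial database sequences,
#' where both an identity and a coverage are reported.  Nucleotide scoring
#' is match +1 / mismatch -1 / gap -2; protein alignments are
#' BLOSUM62-scored with identity (not similarity) counted.
#'
#' @param a,b sequences (character, `DNAString` or `AAString`); both must
#'   be the same alphabet.
#' @return list of class `identity_result`: `pident` and `coverage`
#'   (percent).
#' @export
#' @examples
#' pairwise_identity("ACGTACGTAC", "ACGTACGTAC")
pairwise_identity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  al_a <- guess_alphabet(a); al_b <- guess_alphabet(b)
  if (al_a != al_b)
    stopf("alphabet mismatch: '%s' vs '%s'", al_a, al_b)
  al <- overlap_align(a, b, al_a)
  p <- strsplit(al$pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(al$subject, "", fixed = TRUE)[[1]]
  cols <- length(p)
  matches <- sum(p == s & p != "-")
  pident <- if (cols == 0) 0 else 100 * matches / cols
  coverage <- 100 * sum(p != "-") / nchar(a)
  structure(list(pident = pident, coverage = coverage),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("identity %.1f%%, coverage %.1f%%\n", x$pident, x$coverage))
  invisible(x)
}

#' Merge two overlapping amplicons into one sequence
#'
#' Finds the best suffix--prefix overlap of at least `min_overlap` bases
#' with a mismatch fraction at most `max_mismatch_frac`, considering both
#' input orders and the reverse complement of `b`, and returns the merged
#' consensus (at conflicting positions the base with fewer ambiguities
#' wins; ties go to the earlier sequence).  Used, e.g., to assemble a
#' complete 16S rRNA gene from two partially overlapping amplicons.
#'
#' @param a,b nucleotide sequences.
#' @param min_overlap minimum overlap length (>= 20).
#' @param max_mismatch_frac maximum mismatch fraction inside the overlap.
#' @return Merged character sequence.
#' @export
merge_amplicons <- function(a, b, min_overlap = 30,
                            max_mismatch_frac = 0.02) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (min_overlap < 20) stopf("min_overlap must be >= 20")
  if (guess_alphabet(a) != "nucleotide" || guess_alphabet(b) != "nucleotide")
    stopf("merge_amplicons expects nucleotide sequences")
  best <- NULL
  for (y in unique(c(b, revcomp_chr(b)))) {
    for (ord in 1:2) {
      x1 <- if (ord == 1) a else y
      y1 <- if (ord == 1) y else a
      m <- best_overlap(x1, y1, min_overlap, max_mismatch_frac)
      if (!is.null(m) && (is.null(best) || m$o > best$o))
        best <- c(m, list(x = x1, y = y1))
    }
  }
  if (is.null(best)) stopf("no overlap")
  x <- best$x; y <- best$y; o <- best$o
  xs <- strsplit(substring(x, nchar(x) - o + 1), "", fixed = TRUE)[[1]]
  ys <- strsplit(substring(y, 1, o), "", fixed = TRUE)[[1]]
  amb <- !(xs %in% c("A", "C", "G", "T")) & ys %in% c("A", "C", "G", "T")
  cons <- ifelse(amb, ys, xs)
  paste0(substring(x, 1, nchar(x) - o), paste(cons, collapse = ""),
         substring(y, o + 1))
}

## largest qualifying suffix(x)-prefix(y) overlap, or NULL
best_overlap <- function(x, y, min_overlap, max_mismatch_frac) {
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  ys <- strsplit(y, "", fixed = TRUE)[[1]]
  for (o in seq(min(length(xs), length(ys)), min_overlap)) {
    mm <- sum(xs[seq(length(xs) - o + 1, length(xs))] != ys[seq_len(o)])
    if (mm / o <= max_mismatch_frac) return(list(o = o, mismatches = mm))
  }
  NULL
}

#' Haplotype census of a marker-sequence family
#'
#' Counts distinct sequences (haplotypes) and locates polymorphic
#' columns.  Identical-length families are compared column-wise directly;
#' mixed-length families are first projected onto the coordinates of the
#' longest member via pairwise end-gap-free alignment (positions are then
#' reported in that reference frame).
#'
#' @param seqs named character vector of sequences, or a
#'   [gen_marker_family()] object.
#' @param marker optional vector of marker names (one per sequence); mixed
#'   markers are an error.
#' @return list of class `haplotype_census`: `n_sequences`,
#'   `n_haplotypes`, `all_identical`, `polymorphic_positions` (1-based).
#' @export
haplotype_census <- function(seqs, marker = NULL) {
  if (inherits(seqs, "marker_family")) seqs <- seqs$sequences
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 1) stopf("need at least one sequence")
  if (!is.null(marker) && length(unique(marker)) > 1)
    stopf("mixed markers in one census")
  if (length(unique(nchar(seqs))) > 1) {
    ref_i <- which.max(nchar(seqs))
    al <- guess_alphabet(seqs[ref_i])
    proj <- vapply(seqs, function(s) {
      if (identical(s, seqs[ref_i])) return(s)
      pa <- overlap_align(seqs[ref_i], s, al)
      r <- strsplit(pa$pattern, "", fixed = TRUE)[[1]]
      q <- strsplit(pa$subject, "", fixed = TRUE)[[1]]
      out <- rep("-", nchar(seqs[ref_i]))
      out[cumsum(r != "-")[r != "-"]] <- q[r != "-"]
      paste(out, collapse = "")
    }, character(1))
    seqs_cmp <- proj
  } else seqs_cmp <- seqs
  mat <- do.call(rbind, strsplit(seqs_cmp, "", fixed = TRUE))
  poly <- which(apply(mat, 2, function(col) length(unique(col)) > 1))
  structure(list(n_sequences = length(seqs),
                 n_haplotypes = length(unique(seqs_cmp)),
                 all_identical = length(unique(seqs_cmp)) == 1,
                 polymorphic_positions = as.integer(poly)),
            class = "haplotype_census")
}

#' @export
print.haplotype_census <- function(x, ...) {
  cat(sprintf("%d sequence(s), %d haplotype(s)%s\n", x$n_sequences,
              x$n_haplotypes,
              if (x$all_identical) " (all identical)" else ""))
  if (length(x$polymorphic_positions))
    cat("  polymorphic positions:",
        paste(x$polymorphic_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Screen sequences against a reference at an identity threshold
#'
#' Partitions `seqs` by strict pairwise identity to `ref`
#' (`pident > min_pident`), the conventional ">99% similarity" selection
#' step when picking members of a target population.
#'
#' @param seqs named character vector.
#' @param ref reference sequence.
#' @param min_pident strict identity threshold in percent, in (0, 100].
#' @return list with `selected`, `rejected` (named character vectors) and
#'   `pident` (named numeric).
#' @export
screen_by_reference <- function(seqs, ref, min_pident = 99) {
  if (min_pident <= 0 || min_pident > 100)
    stopf("min_pident must be in (0, 100]")
  seqs <- as_named_seqs(seqs, "sequences")
  pid <- vapply(seqs, function(s) pairwise_identity(s, ref)$pident,
                numeric(1))
  sel <- pid > min_pident
  list(selected = seqs[sel], rejected = seqs[!sel], pident = pid)
}
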