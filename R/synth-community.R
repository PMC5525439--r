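#' Specify a synthetic multi-genome community
#'
#' Describes a set of reference genomes, optional relatives derived from
#' them at a controlled average nucleotide identity (ANI), and optional
#' rRNA-operon intervals, for [gen_community()].
#'
#' @param genomes data frame with columns `id`, `length` (bp), `gc`
#'   (fraction), `n_contigs`.
#' @param relatives optional data frame with columns `parent`, `id`,
#'   `ani` (target ANI fraction, 0.7--1) and `indel_rate` (indel events
#'   per site).
#' @param rrna_operons optional data frame with columns `genome`, `start`,
#'   `end` giving rRNA-operon intervals, 0-based half-open on the
#'   concatenated genome sequence.
#' @param seed integer seed; identical specs and seeds give byte-identical
#'   output.
#' @return An object of class `community_spec`.
#' @export
#' @examples
#' spec <- community_spec(
#'   genomes = data.frame(id = "gA", length = 10000, gc = 0.5, n_contigs = 1),
#'   seed = 1)
community_spec <- function(genomes, relatives = NULL, rrna_operons = NULL,
                           seed = 1L) {
  genomes <- as.data.frame(genomes)
  need <- c("id", "length", "gc", "n_contigs")
  if (!all(need %in% names(genomes)))
    stopf("`genomes` needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(genomes$id)) stopf("duplicate genome id in spec")
  if (any(genomes$length <= 0)) stopf("genome lengths must be > 0")
  if (any(genomes$gc <= 0 | genomes$gc >= 1)) stopf("gc must be in (0, 1)")
  if (any(genomes$n_contigs < 1)) stopf("n_contigs must be >= 1")
  if (!is.null(relatives)) {
    relatives <- as.data.frame(relatives)
    if (!"id" %in% names(relatives))
      relatives$id <- paste0(relatives$parent, "_rel", seq_len(nrow(relatives)))
    if (!all(c("parent", "ani", "indel_rate") %in% names(relatives)))
      stopf("`relatives` needs columns parent, ani, indel_rate")
    if (any(!relatives$parent %in% genomes$id))
      stopf("relative parent not among genome ids")
    if (any(relatives$ani < 0.7 | relatives$ani > 1))
      stopf("target ANI must be within [0.7, 1]")
    if (any(relatives$indel_rate < 0)) stopf("indel_rate must be >= 0")
  }
  if (!is.null(rrna_operons)) {
    rrna_operons <- as.data.frame(rrna_operons)
    if (!all(c("genome", "start", "end") %in% names(rrna_operons)))
      stopf("`rrna_operons` needs columns genome, start, end")
    len <- setNames(genomes$length, genomes$id)
    if (any(!rrna_operons$genome %in% genomes$id))
      stopf("rRNA operon genome id not in spec")
    bad <- rrna_operons$start < 0 | rrna_operons$end <= rrna_operons$start |
      rrna_operons$end > len[rrna_operons$genome]
    if (any(bad)) stopf("rRNA operon interval outside genome bounds")
  }
  structure(list(genomes = genomes, relatives = relatives,
                 rrna_operons = rrna_operons, seed = as.integer(seed)),
            class = "community_spec")
}

## mean indel-event length (geometric) used throughout the generators
INDEL_MEAN_LEN <- 1.5

## derive a child from `parent` at target alignment identity `ani` with
## indel events at `indel_rate` per site; returns the child string plus the
## realized identity implied by the edit script
mutate_to_ani <- function(parent, ani, indel_rate) {
  L <- nchar(parent)
  if (indel_rate * INDEL_MEAN_LEN > 0.10)
    stopf("indel rate %.3g implies net length change > 10%%; rejected",
          indel_rate)
  ## expected gap columns: half the events delete, half insert
  exp_del <- L * indel_rate / 2 * INDEL_MEAN_LEN
  exp_ins <- exp_del
  sub_rate <- 1 - ani * (L + exp_ins) / (L - exp_del)
  if (sub_rate < 0)
    stopf("target ANI %.3f unreachable with indel rate %.3g", ani, indel_rate)
  bases <- c("A", "C", "G", "T")
  p <- strsplit(parent, "", fixed = TRUE)[[1]]
  out <- character(0)
  matches <- 0L; columns <- 0L
  i <- 1L
  while (i <= L) {
    u <- runif(1)
    if (u < indel_rate) {
      g <- rgeom(1, 1 / INDEL_MEAN_LEN) + 1L
      if (runif(1) < 0.5) {                       # deletion
        g <- min(g, L - i + 1L)
        columns <- columns + g
        i <- i + g
      } else {                                    # insertion
        out <- c(out, sample(bases, g, replace = TRUE))
        columns <- columns + g
      }
    } else if (u < indel_rate + sub_rate) {       # substitution
      out <- c(out, sample(setdiff(bases, p[i]), 1))
      columns <- columns + 1L
      i <- i + 1L
    } else {                                      # match
      out <- c(out, p[i])
      matches <- matches + 1L
      columns <- columns + 1L
      i <- i + 1L
    }
  }
  list(seq = paste(out, collapse = ""), identity = matches / columns)
}

split_contigs <- function(seq, n_contigs, id) {
  L <- nchar(seq)
  n_contigs <- min(n_contigs, L)
  cuts <- floor(seq(0, L, length.out = n_contigs + 1))
  contigs <- substring(seq, cuts[-length(cuts)] + 1, cuts[-1])
  setNames(contigs, paste0(id, "_c", seq_len(n_contigs)))
}

#' Generate a synthetic genome community with ground truth
#'
#' Emits one multi-contig genome per spec entry, relatives mutated from
#' their parents to a target ANI (substitutions plus geometric-length
#' indels), rRNA-operon mask intervals, and a truth table of realized
#' identities.
#'
#' @param spec a [community_spec()].
#' @param out optional directory; when given, one FASTA per genome, a
#'   `masks.bed` (contig coordinates) and `truth.tsv` are written there.
#' @return A list of class `community` with elements `contigs` (named list
#'   of per-genome named contig vectors), `sequences` (named character,
#'   concatenated per genome), `masks` (data frame, concatenated 0-based
#'   half-open coordinates), `truth` (data frame of relatives with target
#'   and realized identity) and `spec`.
#' @export
gen_community <- function(spec, out = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    seqs <- list()
    for (k in seq_len(nrow(spec$genomes))) {
      g <- spec$genomes[k, ]
      seqs[[g$id]] <- random_dna(g$length, g$gc)
    }
    truth <- NULL
    if (!is.null(spec$relatives)) {
      for (k in seq_len(nrow(spec$relatives))) {
        r <- spec$relatives[k, ]
        mut <- mutate_to_ani(seqs[[r$parent]], r$ani, r$indel_rate)
        seqs[[r$id]] <- mut$seq
        truth <- rbind(truth, data.frame(
          parent = r$parent, child = r$id, target_ani = r$ani,
          realized_identity = mut$identity))
      }
    }
    ncontig <- setNames(spec$genomes$n_contigs, spec$genomes$id)
    contigs <- lapply(names(seqs), function(id) {
      n <- if (id %in% names(ncontig)) ncontig[[id]] else 1L
      split_contigs(seqs[[id]], n, id)
    })
    names(contigs) <- names(seqs)
    masks <- if (is.null(spec$rrna_operons))
      data.frame(genome = character(0), start = numeric(0), end = numeric(0))
    else spec$rrna_operons
    out_obj <- structure(list(contigs = contigs, sequences = unlist(seqs),
                              masks = masks, truth = truth, spec = spec),
                         class = "community")
    if (!is.null(out)) write_community(out_obj, out)
    out_obj
  })
}

## masks in contig-local BED rows (lift concatenated -> contig coordinates)
community_mask_bed <- function(com) {
  if (nrow(com$masks) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  rows <- NULL
  for (k in seq_len(nrow(com$masks))) {
    m <- com$masks[k, ]
    ctg <- com$contigs[[m$genome]]
    offs <- cumsum(c(0, nchar(ctg)))
    for (j in seq_along(ctg)) {
      lo <- max(m$start, offs[j]); hi <- min(m$end, offs[j + 1])
      if (hi > lo)
        rows <- rbind(rows, data.frame(chrom = names(ctg)[j],
                                       start = lo - offs[j],
                                       end = hi - offs[j]))
    }
  }
  rows
}

write_community <- function(com, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(com$contigs))
    write_fasta(com$contigs[[id]], file.path(dir, paste0(id, ".fasta")))
  bed <- community_mask_bed(com)
  write.table(bed, file.path(dir, "masks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(com$truth))
    write.table(com$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.community <- function(x, ...) {
  cat("Synthetic community:", length(x$contigs), "genome(s)\n")
  for (id in names(x$contigs))
    cat(sprintf("  %s: %d bp in %d contig(s)\n", id,
                nchar(x$sequences[[id]]), length(x$contigs[[id]])))
  if (nrow(x$masks)) cat("  rRNA operon masks:", nrow(x$masks), "\n")
  invisible(x)
}
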