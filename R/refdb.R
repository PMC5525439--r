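#' Build a competitive multi-genome reference database
#'
#' Concatenates each genome's contigs (file order, no spacer) into a
#' single sequence, records contig offsets for coordinate lifting, and
#' lifts optional rRNA-operon mask intervals into concatenated 0-based
#' half-open coordinates (overlapping masks are merged).  The genome
#' length `L_g` used for recruitment-rate normalization always includes
#' masked bases: masking removes reads, not genome.
#'
#' @param genomes one of: character vector of FASTA paths (genome id =
#'   file name without extension; all records in a file are that genome's
#'   contigs), a named list of named contig vectors, or a
#'   [gen_community()] object.
#' @param masks optional masks: a BED path or data frame
#'   (`chrom`, `start`, `end`, 0-based half-open).  `chrom` may name a
#'   contig (coordinates are lifted) or a genome id (coordinates are taken
#'   as already concatenated).
#' @return An object of class `genome_db`.
#' @export
#' @examples
#' com <- gen_community(community_spec(
#'   genomes = data.frame(id = "gA", length = 3000, gc = 0.45, n_contigs = 2),
#'   seed = 7))
#' db <- build_db(com)
#' db_sizes(db)
build_db <- function(genomes, masks = NULL) {
  if (inherits(genomes, "community")) {
    if (is.null(masks)) masks <- community_mask_bed(genomes)
    genomes <- genomes$contigs
  }
  if (is.character(genomes)) {
    paths <- genomes
    ids <- tools::file_path_sans_ext(basename(paths))
    genomes <- lapply(paths, function(p) as_named_seqs(p, "genome FASTA"))
    names(genomes) <- ids
  }
  if (!is.list(genomes)) stopf("cannot interpret `genomes` input")
  ids <- names(genomes)
  if (is.null(ids) || anyDuplicated(ids))
    stopf("duplicate or missing genome id")
  db <- list()
  for (id in ids) {
    ctg <- genomes[[id]]
    if (methods::is(ctg, "XStringSet")) ctg <- as_named_seqs(ctg)
    lens <- nchar(ctg)
    offs <- cumsum(c(0, lens))[seq_along(lens)]
    db[[id]] <- list(id = id, contigs = setNames(as.integer(lens), names(ctg)),
                     offsets = setNames(as.integer(offs), names(ctg)),
                     seq = paste(ctg, collapse = ""),
                     L = sum(lens),
                     masks = matrix(numeric(0), ncol = 2))
  }
  obj <- structure(list(genomes = db), class = "genome_db")
  if (!is.null(masks)) obj <- db_add_masks(obj, masks)
  obj
}

db_add_masks <- function(db, masks) {
  if (is.character(masks) && length(masks) == 1) {
    masks <- read.table(masks, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)[, 1:3]
    names(masks) <- c("chrom", "start", "end")
  }
  masks <- as.data.frame(masks)
  if (!all(c("chrom", "start", "end") %in% names(masks)))
    stopf("masks need columns chrom, start, end")
  contig2genome <- list()
  for (id in names(db$genomes))
    for (ctg in names(db$genomes[[id]]$contigs))
      contig2genome[[ctg]] <- id
  for (k in seq_len(nrow(masks))) {
    m <- masks[k, ]
    if (!is.null(contig2genome[[m$chrom]])) {
      id <- contig2genome[[m$chrom]]
      g <- db$genomes[[id]]
      clen <- g$contigs[[m$chrom]]
      if (m$start < 0 || m$end > clen || m$end <= m$start)
        stopf("mask row %d: interval [%s, %s) outside contig '%s' (length %d)",
              k, format(m$start), format(m$end), m$chrom, clen)
      off <- g$offsets[[m$chrom]]
      iv <- c(off + m$start, off + m$end)
    } else if (m$chrom %in% names(db$genomes)) {
      g <- db$genomes[[m$chrom]]
      if (m$start < 0 || m$end > g$L || m$end <= m$start)
        stopf("mask row %d: interval outside genome '%s'", k, m$chrom)
      id <- m$chrom
      iv <- c(m$start, m$end)
    } else stopf("mask row %d: unknown contig or genome '%s'", k, m$chrom)
    db$genomes[[id]]$masks <- rbind(db$genomes[[id]]$masks, iv)
  }
  for (id in names(db$genomes))
    db$genomes[[id]]$masks <- merge_intervals(db$genomes[[id]]$masks)
  db
}

#' Genome sizes of a reference database
#' @param db a `genome_db`.
#' @return Named integer vector of concatenated genome lengths (bp).
#' @export
db_sizes <- function(db) {
  stopifnot(inherits(db, "genome_db"))
  vapply(db$genomes, function(g) as.integer(g$L), integer(1))
}

db_sequences <- function(db) {
  vapply(db$genomes, function(g) g$seq, character(1))
}

#' Lift a contig-local position to the concatenated coordinate
#'
#' @param db a `genome_db`.
#' @param genome genome id.
#' @param contig contig name.
#' @param pos 0-based position on the contig.
#' @return 0-based position on the concatenated genome sequence.
#' @export
lift_coord <- function(db, genome, contig, pos) {
  stopifnot(inherits(db, "genome_db"))
  g <- db$genomes[[genome]]
  if (is.null(g)) stopf("unknown genome '%s'", genome)
  if (!contig %in% names(g$contigs)) stopf("unknown contig '%s'", contig)
  if (any(pos < 0) || any(pos >= g$contigs[[contig]]))
    stopf("position outside contig '%s'", contig)
  unname(g$offsets[[contig]] + pos)
}

#' Invert a concatenated coordinate back to (contig, position)
#'
#' @inheritParams lift_coord
#' @param pos 0-based position on the concatenated sequence.
#' @return data frame with columns `contig` and `pos` (0-based).
#' @export
locate_coord <- function(db, genome, pos) {
  stopifnot(inherits(db, "genome_db"))
  g <- db$genomes[[genome]]
  if (is.null(g)) stopf("unknown genome '%s'", genome)
  if (any(pos < 0) || any(pos >= g$L)) stopf("position outside genome")
  idx <- findInterval(pos, g$offsets)
  data.frame(contig = names(g$contigs)[idx], pos = pos - g$offsets[idx])
}

#' Write / read a reference database directory
#'
#' The directory holds `concatenated.fasta` (one record per genome),
#' `contigs.tsv` (genome, contig, length, offset) and `masks.bed`
#' (concatenated coordinates, chrom = genome id).
#'
#' @param db a `genome_db`.
#' @param dir directory path.
#' @return `write_db` the directory (invisibly); `read_db` a `genome_db`.
#' @export
write_db <- function(db, dir) {
  stopifnot(inherits(db, "genome_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(as.list(db_sequences(db)), file.path(dir, "concatenated.fasta"))
  tab <- do.call(rbind, lapply(db$genomes, function(g)
    data.frame(genome = g$id, contig = names(g$contigs),
               length = unname(g$contigs), offset = unname(g$offsets))))
  write.table(tab, file.path(dir, "contigs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  beds <- do.call(rbind, lapply(db$genomes, function(g) {
    if (nrow(g$masks) == 0) return(NULL)
    data.frame(chrom = g$id, start = g$masks[, 1], end = g$masks[, 2])
  }))
  if (is.null(beds))
    beds <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  write.table(beds, file.path(dir, "masks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_db
#' @export
read_db <- function(dir) {
  seqs <- as_named_seqs(file.path(dir, "concatenated.fasta"))
  tab <- read.table(file.path(dir, "contigs.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  genomes <- lapply(unique(tab$genome), function(id) {
    rows <- tab[tab$genome == id, , drop = FALSE]
    full <- seqs[[id]]
    setNames(substring(full, rows$offset + 1, rows$offset + rows$length),
             rows$contig)
  })
  names(genomes) <- unique(tab$genome)
  db <- build_db(genomes)
  bedp <- file.path(dir, "masks.bed")
  if (file.exists(bedp) && file.size(bedp) > 0) {
    bed <- read.table(bedp, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[, 1:3]
    names(bed) <- c("chrom", "start", "end")
    db <- db_add_masks(db, bed)
  }
  db
}

#' @export
print.genome_db <- function(x, ...) {
  cat("Competitive reference database:", length(x$genomes),
      "genome(s)\n")
  for (g in x$genomes)
    cat(sprintf("  %s: %d bp, %d contig(s), %d mask interval(s)\n",
                g$id, g$L, length(g$contigs), nrow(g$masks)))
  invisible(x)
}
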