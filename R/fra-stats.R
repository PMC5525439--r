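#' Label recruited reads with identity bins
#'
#' Default bins follow the two recruitment strata used with the 95% ANI
#' species threshold: a closed upper bin `[95,100]` ("same species"
#' signal) and `[70,95)` (related but distinct populations).  Custom
#' `edges` must be strictly increasing; every bin is left-closed and the
#' last bin is closed on both sides.  Values are compared at full float
#' precision (a displayed "94.9" upper edge is a display convention, not
#' a gap).
#'
#' @param rec `recruited_reads` data frame (or any data frame with
#'   `pident`).
#' @param edges numeric vector of bin edges, default `c(70, 95, 100)`.
#' @return `rec` with a `bin` factor column.
#' @export
#' @examples
#' bin_identity(data.frame(pident = c(94.9, 95, 100)))$bin
bin_identity <- function(rec, edges = c(70, 95, 100)) {
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stopf("bin edges must be strictly increasing (non-overlapping bins)")
  labs <- identity_bin_labels(edges)
  idx <- findInterval(rec$pident, edges, rightmost.closed = TRUE)
  if (nrow(rec) && (any(idx < 1) || any(idx > length(labs))))
    stopf("pident outside the binning range [%g, %g]",
          edges[1], edges[length(edges)])
  rec$bin <- factor(labs[idx], levels = labs)
  rec
}

identity_bin_labels <- function(edges) {
  n <- length(edges) - 1
  labs <- sprintf("[%g,%g)", edges[-(n + 1)], edges[-1])
  labs[n] <- sprintf("[%g,%g]", edges[n], edges[n + 1])
  labs
}

#' Per-sample metadata table
#'
#' @param x data frame or TSV path with columns `sample_id`, `total_reads`
#'   (the sample's merged-read sequencing depth `D_s`), and optionally
#'   `fraction`, `depth_m`, `location`.
#' @return validated data frame of class `sample_meta`.
#' @export
sample_meta <- function(x) {
  if (is.character(x) && length(x) == 1)
    x <- read.table(x, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  x <- as.data.frame(x)
  if (!all(c("sample_id", "total_reads") %in% names(x)))
    stopf("sample metadata needs columns sample_id, total_reads")
  if (any(x$total_reads <= 0)) stopf("total_reads must be > 0")
  if (anyDuplicated(x$sample_id)) stopf("duplicate sample_id")
  class(x) <- c("sample_meta", "data.frame")
  x
}

#' Normalized recruitment rate
#'
#' The canonical recruitment quantity: percent of a sample's reads
#' recruited per genomic megabase,
#' `R = 100 * (r / D_s) * (1e6 / L_g)`.
#' The chain normalizes by reference genome size (reads per genomic bp),
#' upscales to 1 Mb, and divides by sequencing depth; expressing depth as
#' the fraction `r / D_s` makes any common smallest-depth factor cancel.
#'
#' @param r recruited read count.
#' @param L_g reference genome size (bp).
#' @param D_s sample sequencing depth (read count).
#' @return Recruitment rate R (percent reads per genomic Mbp).
#' @export
#' @examples
#' recruitment_rate(5100, L_g = 1e6, D_s = 1e6)  # 0.51
recruitment_rate <- function(r, L_g, D_s) {
  if (any(L_g <= 0) || any(D_s <= 0)) stopf("L_g and D_s must be positive")
  100 * (r / D_s) * (1e6 / L_g)
}

#' Build the sample x genome x identity-bin recruitment matrix
#'
#' Dense long-format matrix with one row per cell, carrying the raw count
#' `r`, the count rescaled to the smallest sequencing depth
#' `r_norm = r * D_min / D_s`, and the normalized rate `R` from
#' [recruitment_rate()].
#'
#' @param recruited named list of `recruited_reads` (one per sample, names
#'   are sample ids); reads must carry a `bin` column ([bin_identity()]).
#' @param meta a [sample_meta()] covering every sample in `recruited`.
#' @param db a `genome_db` (supplies genome sizes and the genome axis).
#' @param edges identity-bin edges (used to re-bin if `bin` is absent).
#' @return data frame of class `recruitment_matrix` with columns
#'   `sample, genome, bin, r, r_norm, R`.
#' @export
build_matrix <- function(recruited, meta, db, edges = c(70, 95, 100)) {
  stopifnot(inherits(db, "genome_db"))
  meta <- sample_meta(meta)
  miss <- setdiff(names(recruited), meta$sample_id)
  if (length(miss))
    stopf("recruited reads reference unknown sample '%s'", miss[1])
  labs <- identity_bin_labels(edges)
  genomes <- names(db$genomes)
  Ds <- setNames(meta$total_reads, meta$sample_id)
  Dmin <- min(Ds[names(recruited)])
  grid <- expand.grid(sample = names(recruited), genome = genomes,
                      bin = labs, stringsAsFactors = FALSE)
  grid$r <- 0
  for (s in names(recruited)) {
    rec <- recruited[[s]]
    if (!"bin" %in% names(rec)) rec <- bin_identity(rec, edges)
    if (nrow(rec) > Ds[[s]])
      stopf("sample '%s': more recruited reads than total_reads", s)
    tab <- table(rec$genome, rec$bin)
    for (g in rownames(tab)) for (b in colnames(tab)) {
      i <- grid$sample == s & grid$genome == g & grid$bin == b
      if (!any(i)) stopf("recruited read in unknown genome/bin %s/%s", g, b)
      grid$r[i] <- tab[g, b]
    }
  }
  Lg <- db_sizes(db)
  grid$r_norm <- grid$r * Dmin / Ds[grid$sample]
  grid$R <- recruitment_rate(grid$r, Lg[grid$genome], Ds[grid$sample])
  grid <- grid[order(grid$sample, grid$genome, grid$bin), ]
  rownames(grid) <- NULL
  attr(grid, "edges") <- edges
  attr(grid, "D_min") <- Dmin
  class(grid) <- c("recruitment_matrix", "data.frame")
  grid
}

#' Write / read a recruitment matrix
#' @param mat `recruitment_matrix`.
#' @param path TSV path.
#' @export
write_matrix <- function(mat, path) {
  write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("recruitment_matrix", "data.frame")
  out
}

#' Detect low-recruitment regions along a genome
#'
#' Tiles the concatenated genome into non-overlapping windows, counts
#' recruited read starts per window, and reports maximal runs of
#' consecutive windows whose density falls below `min_density` as merged
#' intervals (0-based half-open).
#'
#' @param rec `recruited_reads` for one genome.
#' @param db a `genome_db`.
#' @param genome genome id.
#' @param window window size (bp), default 5000.
#' @param min_density reads-per-window threshold; default 25% of the
#'   genome-wide mean density.
#' @return data frame `start`, `end`, `n_windows`, `mean_reads`.
#' @export
low_recruitment_regions <- function(rec, db, genome, window = 5000,
                                    min_density = NULL) {
  stopifnot(inherits(db, "genome_db"))
  if (window <= 0) stopf("window must be > 0")
  g <- db$genomes[[genome]]
  if (is.null(g)) stopf("unknown genome '%s'", genome)
  rec <- rec[rec$genome == genome, , drop = FALSE]
  n_win <- max(1L, ceiling(g$L / window))
  counts <- tabulate(pmin(floor(rec$start / window) + 1L, n_win), n_win)
  if (is.null(min_density)) min_density <- 0.25 * mean(counts)
  low <- counts < min_density
  if (!any(low))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_windows = integer(0), mean_reads = numeric(0)))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  data.frame(start = (starts[sel] - 1) * window,
             end = pmin(ends[sel] * window, g$L),
             n_windows = r$lengths[sel],
             mean_reads = vapply(sel, function(k)
               mean(counts[starts[k]:ends[k]]), numeric(1)))
}
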