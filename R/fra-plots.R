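#' Recruitment-plot profile for one genome
#'
#' One point per recruited read (x = midpoint of the strand-normalized
#' subject interval, y = percent identity) plus a marginal histogram of
#' identities over 1-percentage-point bins on [70, 100] (left-closed; 100
#' falls in the top bin).  Duplicates and rRNA-operon reads are absent by
#' construction when the profile is built from [recruit()] output.
#'
#' @param rec `recruited_reads` data frame.
#' @param db a `genome_db`.
#' @param genome genome id.
#' @param ani_line identity percent for the species-threshold line
#'   (default 95, the conventional ANI species boundary).
#' @return list of class `recruitment_profile`: `genome`, `points`
#'   (data frame x, y), `histogram` (data frame bin_lo, bin_hi, count),
#'   `ani_line`, `L`.
#' @export
profile_recruitment <- function(rec, db, genome, ani_line = 95) {
  stopifnot(inherits(db, "genome_db"))
  g <- db$genomes[[genome]]
  if (is.null(g)) stopf("unknown genome '%s'", genome)
  bad <- rec$genome != genome
  if (any(bad)) stopf("recruited reads do not all belong to '%s'", genome)
  pts <- data.frame(x = (rec$start + rec$end) / 2, y = rec$pident)
  lo <- 70:99
  cnt <- vapply(lo, function(b) {
    hi <- b + 1
    sum(pts$y >= b & (if (hi == 100) pts$y <= 100 else pts$y < hi))
  }, numeric(1))
  structure(list(genome = genome, points = pts,
                 histogram = data.frame(bin_lo = lo, bin_hi = lo + 1,
                                        count = cnt),
                 ani_line = ani_line, L = g$L),
            class = "recruitment_profile")
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat(sprintf("Recruitment profile of '%s': %d reads over %d bp\n",
              x$genome, nrow(x$points), x$L))
  invisible(x)
}

write_sidecar <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a recruitment plot (identity vs genome coordinate)
#'
#' Scatter of read identity against genome position with the marginal
#' identity histogram on the right and a gray horizontal line at the ANI
#' species threshold.  Plot-data sidecar TSVs (`*_points.tsv`,
#' `*_hist.tsv`) are written next to the image; the image is a pure
#' function of the sidecar content.
#'
#' @param profile a [profile_recruitment()] object.
#' @param file output image path (`.png` or `.svg`).
#' @param width,height device size in pixels (png) or inches (svg).
#' @return Invisibly, the sidecar paths.
#' @export
plot_recruitment <- function(profile, file, width = 900, height = 450) {
  stopifnot(inherits(profile, "recruitment_profile"))
  base <- tools::file_path_sans_ext(file)
  side <- c(points = paste0(base, "_points.tsv"),
            hist = paste0(base, "_hist.tsv"))
  write_sidecar(profile$points, side[["points"]])
  write_sidecar(profile$histogram, side[["hist"]])
  open_device(file, width, height)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(c(1, 2), 1, 2), widths = c(4, 1))
  op <- graphics::par(mar = c(4, 4, 2, 0.5))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  plot(profile$points$x, profile$points$y, pch = 16, cex = 0.3,
       col = grDevices::rgb(0, 0, 0.55, 0.5),
       xlim = c(0, profile$L), ylim = c(70, 100),
       xlab = "genome coordinate (bp)", ylab = "identity (%)",
       main = profile$genome)
  graphics::abline(h = profile$ani_line, col = "gray50", lwd = 2)
  graphics::par(mar = c(4, 0.5, 2, 1))
  graphics::barplot(profile$histogram$count, horiz = TRUE, space = 0,
                    axes = FALSE, col = "gray30", border = NA)
  graphics::axis(1)
  invisible(side)
}

#' Render the identity-binned recruitment heatmap
#'
#' Genome-by-sample grid colored by log10 of the recruitment rate R, with
#' one row group per identity bin (upper bin rows on top, as in the
#' conventional two-stratum display).  A sidecar TSV holding the plotted
#' matrix is written next to the image.
#'
#' @param mat a [build_matrix()] result.
#' @param file output image path (`.png` or `.svg`).
#' @param width,height device size.
#' @return Invisibly, the sidecar path.
#' @export
plot_heatmap <- function(mat, file, width = 800, height = 600) {
  stopifnot(inherits(mat, "recruitment_matrix"))
  base <- tools::file_path_sans_ext(file)
  side <- paste0(base, "_matrix.tsv")
  bins <- rev(unique(as.character(mat$bin)))   # upper bin first
  genomes <- unique(mat$genome)
  samples <- unique(mat$sample)
  rows <- expand.grid(genome = genomes, bin = bins,
                      stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$bin, bins)), ]
  z <- matrix(NA_real_, nrow(rows), length(samples),
              dimnames = list(paste(rows$bin, rows$genome, sep = " "),
                              samples))
  for (k in seq_len(nrow(mat)))
    z[paste(as.character(mat$bin[k]), mat$genome[k], sep = " "),
      mat$sample[k]] <- mat$R[k]
  out <- data.frame(row = rownames(z), z, check.names = FALSE)
  write_sidecar(out, side)
  open_device(file, width, height)
  on.exit(grDevices::dev.off())
  lz <- log10(z + 1e-9)
  op <- graphics::par(mar = c(7, 12, 2, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  graphics::image(seq_along(samples), seq_len(nrow(z)),
                  t(lz[rev(seq_len(nrow(z))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "recruitment rate (% reads per genomic Mbp, log10)")
  graphics::axis(1, seq_along(samples), samples, las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(z)), rev(rownames(z)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(side)
}

open_device <- function(file, width, height) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") grDevices::png(file, width = width, height = height)
  else if (ext == "svg") grDevices::svg(file, width = width / 100,
                                        height = height / 100)
  else stopf("unsupported image format '%s' (use png or svg)", ext)
}
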