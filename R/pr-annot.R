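## Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Classify the proteorhodopsin spectral-tuning residue
#'
#' Methionine (M) and leucine (L) at the tuning position lead to an
#' absorption maximum in green light (518--535 nm); glutamine (Q) sets a
#' blue absorption maximum (~490 nm, recorded as the point value 490).
#' Any other standard residue is classified `unknown`.
#'
#' @param residue single amino-acid letter.
#' @return list: `class` ("green", "blue" or "unknown") and
#'   `wavelength_nm` (numeric range c(lower, upper); empty for unknown).
#' @export
#' @examples
#' classify_tuning("M")  # green, 518-535 nm
#' classify_tuning("Q")  # blue, 490 nm
classify_tuning <- function(residue) {
  if (!is.character(residue) || length(residue) != 1 ||
      nchar(residue) != 1 || !toupper(residue) %in% names(KD_SCALE))
    stopf("'%s' is not a standard amino-acid letter", as.character(residue))
  residue <- toupper(residue)
  if (residue %in% c("M", "L"))
    list(class = "green", wavelength_nm = c(518, 535))
  else if (residue == "Q")
    list(class = "blue", wavelength_nm = c(490, 490))
  else list(class = "unknown", wavelength_nm = numeric(0))
}

#' Predict transmembrane helices by sliding-window hydropathy
#'
#' Kyte--Doolittle mean hydropathy over a sliding window; maximal runs of
#' window centers above `cutoff` are merged when separated by fewer than
#' 3 positions, expanded by half a window on each side (clipped to the
#' sequence, and clipped back at the midpoint between adjacent runs so the
#' reported intervals stay disjoint), and intervals shorter than 15
#' residues are discarded.
#'
#' @param seq protein sequence.
#' @param window odd window size >= 7 (default 19, the classic
#'   transmembrane setting).
#' @param cutoff mean-hydropathy threshold (default 1.6).
#' @return data frame `start`, `end` (1-based inclusive), disjoint and
#'   sorted; empty (with a warning) when the sequence is shorter than the
#'   window.
#' @export
predict_tm <- function(seq, window = 19, cutoff = 1.6) {
  if (window %% 2 == 0 || window < 7) stopf("window must be odd and >= 7")
  s <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  n <- length(s)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < window) {
    warning("sequence shorter than the hydropathy window; no prediction")
    return(empty)
  }
  h <- unname(KD_SCALE[s])
  h[is.na(h)] <- 0
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  half <- (window - 1) / 2
  centers <- which(!is.na(means) & means > cutoff)
  if (!length(centers)) return(empty)
  ## group centers, merging gaps < 3
  grp <- cumsum(c(1, diff(centers) >= 3))
  iv <- do.call(rbind, lapply(split(centers, grp), function(cs)
    c(max(1, min(cs) - half), min(n, max(cs) + half))))
  if (nrow(iv) > 1) for (k in seq_len(nrow(iv) - 1)) {
    if (iv[k, 2] >= iv[k + 1, 1]) {      # keep expansions disjoint
      mid <- (iv[k, 2] + iv[k + 1, 1]) %/% 2
      iv[k, 2] <- mid
      iv[k + 1, 1] <- mid + 1
    }
  }
  iv <- iv[iv[, 2] - iv[, 1] + 1 >= 15, , drop = FALSE]
  data.frame(start = as.integer(iv[, 1]), end = as.integer(iv[, 2]))
}

## map reference positions to query positions through an end-gap-free
## alignment; NA where the position is gapped or outside the aligned span
map_positions <- function(query, reference, positions) {
  al <- overlap_align(reference, query, "amino-acid")
  r <- strsplit(al$pattern, "", fixed = TRUE)[[1]]
  q <- strsplit(al$subject, "", fixed = TRUE)[[1]]
  rpos <- cumsum(r != "-")
  qpos <- cumsum(q != "-")
  ## offsets of trimmed leading ends (overlap alignment trims terminal gaps)
  roff <- ref_lead_offset(reference, al$pattern)
  qoff <- ref_lead_offset(query, al$subject)
  p <- length(r)
  matches <- sum(r == q & r != "-")
  out <- vapply(positions, function(pos) {
    k <- which(rpos + roff == pos & r != "-")
    if (!length(k) || q[k[1]] == "-") return(NA_integer_)
    as.integer(qpos[k[1]] + qoff)
  }, integer(1))
  list(positions = out, aligned_identity = 100 * matches / p,
       aligned_columns = p)
}

## how many residues of `full` precede the aligned region
ref_lead_offset <- function(full, aligned) {
  core <- gsub("-", "", aligned)
  off <- regexpr(core, full, fixed = TRUE)[1] - 1
  if (off < 0) 0L else as.integer(off)
}

#' Map proteorhodopsin feature positions onto a query
#'
#' Aligns the query (end-gap-free, BLOSUM62) to the bundled synthetic
#' reference scaffold in the eBAC31A08 numbering convention (proton
#' acceptor Asp97, proton donor Glu108, tuning position 105,
#' retinal-binding Lys231) and maps each feature position to a query
#' position, or marks it absent when outside the aligned span or gapped.
#' Queries diverging too far from the reference frame (aligned identity
#' below 40%, or fewer than 50 aligned columns) are reported as
#' unmappable rather than guessed.
#'
#' @param query protein sequence, >= 50 residues.
#' @param reference reference sequence with a `features` attribute;
#'   default [pr_reference()].
#' @return list: `features` data frame (feature, ref_pos, query_pos,
#'   observed, expected, present), `aligned_identity`, `mappable`.
#' @export
map_features <- function(query, reference = pr_reference()) {
  query <- as.character(query)
  if (nchar(query) < 50) stopf("fragment too short")
  feats <- attr(reference, "features")
  if (is.null(feats)) feats <- PR_LAYOUT$features
  mp <- map_positions(query, as.character(reference), unname(feats))
  qc <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  ## a meaningful mapping needs both sequence agreement and a substantial
  ## aligned span; end-gap-free alignment of an unrelated protein can trim
  ## down to a tiny high-identity segment, which must not count
  mappable <- mp$aligned_identity >= 40 && mp$aligned_columns >= 50
  qpos <- if (mappable) mp$positions else rep(NA_integer_, length(feats))
  observed <- ifelse(is.na(qpos), NA_character_, qc[qpos])
  expected <- vapply(names(feats), function(f)
    paste(PR_LAYOUT$expected[[f]], collapse = "/"), character(1))
  present <- !is.na(observed) & mapply(function(o, f)
    o %in% PR_LAYOUT$expected[[f]], observed, names(feats))
  list(features = data.frame(feature = names(feats),
                             ref_pos = unname(feats),
                             query_pos = qpos, observed = observed,
                             expected = expected,
                             present = unname(present),
                             row.names = NULL),
       aligned_identity = mp$aligned_identity, mappable = mappable)
}

#' Annotate a proteorhodopsin protein sequence
#'
#' Combines feature mapping ([map_features()]), spectral-tuning
#' classification ([classify_tuning()]) and transmembrane-helix
#' prediction ([predict_tm()]) into one annotation record.
#'
#' @param query protein sequence (character, named character or FASTA
#'   path with one record).
#' @param reference see [map_features()].
#' @param window,cutoff see [predict_tm()].
#' @return object of class `rhodopsin_annotation`: `features`,
#'   `spectral_class`, `wavelength_nm` (with a note that the blue value is
#'   approximate), `tm_helices`, `n_helices`, `aligned_identity`,
#'   `mappable`.
#' @export
annotate_rhodopsin <- function(query, reference = pr_reference(),
                               window = 19, cutoff = 1.6) {
  if (is.character(query) && length(query) == 1 && file.exists(query))
    query <- as_named_seqs(query, "protein")[[1]]
  query <- as.character(query)[1]
  mf <- map_features(query, reference)
  tun <- mf$features[mf$features$feature == "tuning", ]
  spec <- if (!is.na(tun$observed)) classify_tuning(tun$observed)
  else list(class = "unknown", wavelength_nm = numeric(0))
  tm <- predict_tm(query, window, cutoff)
  structure(list(features = mf$features,
                 spectral_class = spec$class,
                 wavelength_nm = spec$wavelength_nm,
                 wavelength_note = if (spec$class == "blue")
                   "approximate (~490 nm)" else NA_character_,
                 tm_helices = tm, n_helices = nrow(tm),
                 aligned_identity = mf$aligned_identity,
                 mappable = mf$mappable),
            class = "rhodopsin_annotation")
}

#' @export
print.rhodopsin_annotation <- function(x, ...) {
  cat("Proteorhodopsin annotation\n")
  if (!x$mappable) {
    cat("  query unmappable to the reference frame (aligned identity",
        sprintf("%.1f%%)\n", x$aligned_identity))
    return(invisible(x))
  }
  print(x$features, row.names = FALSE)
  wl <- if (length(x$wavelength_nm))
    sprintf(" (%g-%g nm)", x$wavelength_nm[1], x$wavelength_nm[2]) else ""
  cat(sprintf("  spectral class: %s%s\n", x$spectral_class, wl))
  cat(sprintf("  transmembrane helices: %d\n", x$n_helices))
  invisible(x)
}

#' Write a rhodopsin annotation report (TSV + JSON)
#' @param ann a `rhodopsin_annotation`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_annotation <- function(ann, dir) {
  stopifnot(inherits(ann, "rhodopsin_annotation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(ann$features, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ann$tm_helices, file.path(dir, "tm_helices.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(spectral_class = ann$spectral_class,
         wavelength_nm = ann$wavelength_nm,
         wavelength_note = ann$wavelength_note,
         n_helices = ann$n_helices,
         aligned_identity = ann$aligned_identity,
         mappable = ann$mappable),
    file.path(dir, "annotation.json"), auto_unbox = TRUE, digits = NA,
    null = "null", na = "null")
  invisible(dir)
}
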