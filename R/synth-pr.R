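## Proteorhodopsin scaffold shared by the generator and the bundled
## reference.  Numbering follows the SAR86 eBAC31A08 community convention:
## proton acceptor Asp97, proton donor Glu108, spectral tuning position
## 105, retinal-binding Lys231; seven transmembrane helices.
PR_LAYOUT <- list(
  length = 249,
  ## inter-helix loops are >= 9 residues so the 19-residue hydropathy
  ## window resolves all seven helices as separate intervals
  helices = cbind(start = c(23, 55, 90, 124, 157, 190, 223),
                  end   = c(45, 77, 112, 146, 179, 212, 245)),
  features = c(proton_acceptor = 97L, tuning = 105L,
               proton_donor = 108L, retinal_lysine = 231L),
  expected = list(proton_acceptor = "D", tuning = c("M", "L", "Q"),
                  proton_donor = "E", retinal_lysine = "K"))

PR_HYDROPHOBIC <- c("I", "L", "V", "F")
PR_POLAR <- c("D", "E", "K", "R", "S", "N", "Q", "G", "T", "P")

.pr_cache <- new.env(parent = emptyenv())

## deterministic synthetic template in the layout above (built once)
pr_template <- function() {
  if (!is.null(.pr_cache$template)) return(.pr_cache$template)
  tpl <- with_seed(20170725L, {
    lay <- PR_LAYOUT
    s <- character(lay$length)
    in_helix <- rep(FALSE, lay$length)
    for (h in seq_len(nrow(lay$helices)))
      in_helix[lay$helices[h, 1]:lay$helices[h, 2]] <- TRUE
    s[in_helix] <- sample(PR_HYDROPHOBIC, sum(in_helix), replace = TRUE)
    s[!in_helix] <- sample(PR_POLAR, sum(!in_helix), replace = TRUE)
    s[lay$features["proton_acceptor"]] <- "D"
    s[lay$features["proton_donor"]] <- "E"
    s[lay$features["retinal_lysine"]] <- "K"
    s[lay$features["tuning"]] <- "L"
    paste(s, collapse = "")
  })
  .pr_cache$template <- tpl
  tpl
}

#' Bundled synthetic proteorhodopsin reference
#'
#' A synthetic 249-residue proteorhodopsin-like reference sequence (it is a
#' constructed scaffold, not a database record) laid out in the SAR86
#' eBAC31A08 numbering convention: proton acceptor Asp97, proton donor
#' Glu108, spectral-tuning position 105, retinal-binding Lys231, and seven
#' hydrophobic transmembrane stretches.  It anchors feature mapping in
#' [map_features()].
#'
#' @return Named character of length 1 (`"PR_reference_synthetic"`), with
#'   attribute `features` giving the four 1-based feature positions.
#' @export
pr_reference <- function() {
  structure(setNames(pr_template(), "PR_reference_synthetic"),
            features = PR_LAYOUT$features)
}

#' Generate a rhodopsin-like protein with chosen functional residues
#'
#' Derives a protein from the bundled synthetic reference scaffold: the
#' spectral-tuning residue is set as requested, the three catalytic
#' residues (D97, E108, K231) are kept, and a fraction of the remaining
#' positions is substituted at random (hydrophobic positions stay
#' hydrophobic, loop positions stay polar, so helix prediction is
#' preserved).
#'
#' @param tuning_residue single amino-acid letter placed at the tuning
#'   position (105).
#' @param seed integer seed.
#' @param divergence fraction of non-feature positions substituted.
#' @return Named character protein sequence with attribute `features`
#'   (named 1-based positions of proton_acceptor, tuning, proton_donor,
#'   retinal_lysine).
#' @export
#' @examples
#' p <- gen_pr_protein("M", seed = 1)
#' substring(p, attr(p, "features")["tuning"], attr(p, "features")["tuning"])
gen_pr_protein <- function(tuning_residue, seed = 1L, divergence = 0.05) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!is.character(tuning_residue) || nchar(tuning_residue) != 1 ||
      !toupper(tuning_residue) %in% aa20)
    stopf("tuning_residue must be a standard amino-acid letter")
  tuning_residue <- toupper(tuning_residue)
  with_seed(seed, {
    lay <- PR_LAYOUT
    s <- strsplit(pr_template(), "", fixed = TRUE)[[1]]
    in_helix <- rep(FALSE, lay$length)
    for (h in seq_len(nrow(lay$helices)))
      in_helix[lay$helices[h, 1]:lay$helices[h, 2]] <- TRUE
    free <- setdiff(seq_len(lay$length), lay$features)
    nmut <- round(divergence * length(free))
    if (nmut > 0) {
      at <- sample(free, nmut)
      for (p in at) {
        pool <- if (in_helix[p]) PR_HYDROPHOBIC else PR_POLAR
        s[p] <- sample(setdiff(pool, s[p]), 1)
      }
    }
    s[lay$features["tuning"]] <- tuning_residue
    structure(setNames(paste(s, collapse = ""),
                       sprintf("PR_synthetic_%s_seed%d", tuning_residue,
                               as.integer(seed))),
              features = lay$features)
  })
}
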