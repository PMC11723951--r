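#' Reference table for disordered-linker conformational classes
#'
#' Pairs the five-member reference series of designed disordered linkers
#' (40-residue chains spanning compact globules through self-avoiding random
#' coils) with the fraction-of-charged-residues (FCR) levels used to assign
#' conformational classes and the corresponding functional lengths in
#' Angstroms. The functional lengths are literature constants for that
#' series; the FCR levels are this package's calibration and the table is
#' intended to be edited or replaced via the `reference` argument of
#' [linker_features()].
#'
#' @return Tibble with columns `idr`, `category`, `conformational_class`,
#'   `fcr` and `functional_length_A`.
#' @export
idr_reference <- function() {
  tibble(
    idr = paste0("IDR", 1:5),
    category = c(1L, 2L, 3L, 3L, 4L),
    conformational_class = c("compact_globule", "intermediate",
                             "Flory_random_coil", "Flory_random_coil",
                             "self_avoiding_random_coil"),
    fcr = c(0.00, 0.15, 0.30, 0.40, 0.50),
    functional_length_A = c(13, 22.5, 34.3, 53.9, 66.6)
  )
}

#' Physicochemical features of a disordered linker segment
#'
#' Computes the per-residue sequence parameters governing disordered-chain
#' compaction: net charge per residue `NCPR = (#K + #R - #D - #E) / L`,
#' fraction of charged residues `FCR = (#K + #R + #D + #E) / L` (histidine
#' treated as uncharged), the fraction of disorder-promoting residues, a
#' window-1 per-residue charge profile (+1 for K/R, -1 for D/E, 0
#' otherwise), the 20-residue composition vector, and a conformational-class
#' assignment with its reference functional length (nearest FCR level in the
#' reference table).
#'
#' @param segment Non-empty protein segment (string).
#' @param dp_set Disorder-promoting residue set.
#' @param reference Conformational-class reference table, see
#'   [idr_reference()].
#' @return One-row tibble with columns `length`, `ncpr`, `fcr`,
#'   `dp_fraction`, `conformational_class`, `functional_length_A`, and
#'   list-columns `charge_profile` and `composition`.
#' @export
linker_features <- function(segment, dp_set = DP_SET,
                            reference = idr_reference()) {
  stopifnot(is.character(segment), length(segment) == 1)
  if (nchar(segment) == 0) {
    abort("empty segment.", class = "hrdquant_empty_segment")
  }
  res <- strsplit(toupper(segment), "")[[1]]
  bad <- setdiff(res, c(AA20, "X"))
  if (length(bad)) {
    abort(sprintf("illegal residue character(s): %s", paste(unique(bad), collapse = ", ")),
          class = "hrdquant_bad_sequence")
  }
  L <- length(res)
  charge <- ifelse(res %in% c("K", "R"), 1, ifelse(res %in% c("D", "E"), -1, 0))
  ncpr <- sum(charge) / L
  fcr <- sum(charge != 0) / L
  dp_fraction <- mean(res %in% dp_set)
  composition <- vapply(AA20, function(a) mean(res == a), numeric(1))

  row <- reference[which.min(abs(reference$fcr - fcr)), ]
  tibble(
    length = L, ncpr = ncpr, fcr = fcr, dp_fraction = dp_fraction,
    conformational_class = row$conformational_class,
    functional_length_A = row$functional_length_A,
    charge_profile = list(charge), composition = list(composition)
  )
}

#' Column-z-scored amino-acid composition matrix for labelled segments
#'
#' Builds the segment-by-residue fraction matrix used for linker composition
#' heatmaps, z-scored per residue column (columns with zero variance get
#' z-scores of 0), with the disorder-promoting columns flagged.
#'
#' @param segments Named character vector of two or more segments.
#' @param dp_set Disorder-promoting residue set used for the column flags.
#' @return Numeric matrix (segments x 20 residues) of column z-scores, with
#'   attributes `fractions` (the raw composition matrix) and `dp_columns`.
#' @export
composition_matrix <- function(segments, dp_set = DP_SET) {
  if (length(segments) < 2) {
    abort("at least two segments are required to z-score compositions.",
          class = "hrdquant_too_few_segments")
  }
  if (is.null(names(segments))) names(segments) <- paste0("segment", seq_along(segments))
  frac <- t(vapply(segments, function(s) {
    res <- strsplit(toupper(s), "")[[1]]
    vapply(AA20, function(a) mean(res == a), numeric(1))
  }, numeric(length(AA20))))
  z <- apply(frac, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  rownames(z) <- names(segments)
  structure(z, fractions = frac, dp_columns = AA20 %in% dp_set)
}

#' Fraction of invariant columns in a gapless protein alignment
#'
#' A column is invariant when every sequence carries the same residue and no
#' sequence has a gap there. Identity is reported over all aligned columns,
#' as a percentage.
#'
#' @param alignment Character vector of equal-length aligned sequences
#'   (gaps as `-`).
#' @return One-row tibble with `n_columns`, `n_invariant` and
#'   `pct_identity`.
#' @export
alignment_identity <- function(alignment) {
  stopifnot(is.character(alignment), length(alignment) >= 2)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1) {
    abort("aligned sequences must have equal length.",
          class = "hrdquant_ragged_alignment")
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  invariant <- apply(mat, 2, function(col) length(unique(col)) == 1 && col[1] != "-")
  tibble(
    n_columns = ncol(mat),
    n_invariant = sum(invariant),
    pct_identity = 100 * sum(invariant) / ncol(mat)
  )
}
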