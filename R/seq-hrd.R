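#' Call the bipartite retention-domain architecture from motif hits
#'
#' Selects a phi1 -> His-Cys -> phi2 chain whose inter-motif gaps (residues
#' strictly between one motif's end and the next motif's start) match the
#' spacing constraints -- the default gaps of 0 and 1 residue are the
#' invariant spacings of the mammalian architecture -- then attaches the
#' nearest downstream phi3 whose linker length falls within bounds.
#' Ambiguity is resolved by minimal total span, then leftmost start.
#' Incomplete annotations (missing motifs or no constraint-satisfying chain)
#' are legal outputs with `complete = FALSE` and whatever partial spans
#' could be anchored.
#'
#' @param sequence Protein sequence string.
#' @param hits Motif hits from [scan_motifs()] on the same sequence;
#'   computed if `NULL`.
#' @param gap_phi1_hiscys Allowed gap(s) between phi1 and His-Cys.
#' @param gap_hiscys_phi2 Allowed gap(s) between His-Cys and phi2.
#' @param linker_range Allowed linker length range (residues strictly
#'   between phi2 and phi3).
#' @param hiscys_classes His-Cys grammar variants to accept.
#' @return One-row tibble of class `hrd_annotation` with CR1/linker/CR2
#'   spans, the realized gaps, `linker_length` and `complete`; alternative
#'   phi3 placements (if any) are attached as attribute `alternatives`.
#' @export
call_hrd <- function(sequence, hits = NULL,
                     gap_phi1_hiscys = 0L, gap_hiscys_phi2 = 1L,
                     linker_range = c(1L, 400L),
                     hiscys_classes = c("hiscys", "hiscys_amphibian")) {
  if (is.null(hits)) {
    hits <- scan_motifs(sequence, classes = unique(c("phi1", hiscys_classes,
                                                     "phi2", "phi3")))
  }
  hits <- dplyr::arrange(as_tibble(hits), .data$start, .data$end)
  pick <- function(cls) hits[hits$motif_class %in% cls, , drop = FALSE]
  p1 <- pick("phi1"); hc <- pick(hiscys_classes)
  p2 <- pick("phi2"); p3 <- pick("phi3")

  empty <- tibble(
    cr1_start = NA_integer_, cr1_end = NA_integer_,
    linker_start = NA_integer_, linker_end = NA_integer_,
    cr2_start = NA_integer_, cr2_end = NA_integer_,
    gap_phi1_hiscys = NA_integer_, gap_hiscys_phi2 = NA_integer_,
    linker_length = NA_integer_, complete = FALSE
  )

  # enumerate CR1 chains satisfying both gap constraints
  chains <- NULL
  if (nrow(p1) && nrow(hc) && nrow(p2)) {
    chains <- tidyr::expand_grid(i1 = seq_len(nrow(p1)), ih = seq_len(nrow(hc)),
                                 i2 = seq_len(nrow(p2)))
    chains$g1 <- hc$start[chains$ih] - p1$end[chains$i1] - 1L
    chains$g2 <- p2$start[chains$i2] - hc$end[chains$ih] - 1L
    chains <- chains[chains$g1 %in% gap_phi1_hiscys &
                       chains$g2 %in% gap_hiscys_phi2, , drop = FALSE]
  }
  if (is.null(chains) || nrow(chains) == 0) {
    out <- empty
    # anchor whatever partial CR1 evidence exists, leftmost-first
    if (nrow(p1)) {
      out$cr1_start <- p1$start[1]
      out$cr1_end <- p1$end[1]
    }
    class(out) <- c("hrd_annotation", class(out))
    attr(out, "alternatives") <- empty[0, ]
    return(out)
  }

  candidates <- purrr::pmap(chains, function(i1, ih, i2, g1, g2) {
    cr1_start <- p1$start[i1]; cr1_end <- p2$end[i2]
    down <- p3[p3$start > cr1_end, , drop = FALSE]
    down$linker_length <- down$start - cr1_end - 1L
    down <- down[down$linker_length >= linker_range[1] &
                   down$linker_length <= linker_range[2], , drop = FALSE]
    base <- tibble(
      cr1_start = cr1_start, cr1_end = cr1_end,
      gap_phi1_hiscys = g1, gap_hiscys_phi2 = g2
    )
    if (!nrow(down)) {
      return(dplyr::mutate(base, linker_start = NA_integer_,
                           linker_end = NA_integer_, cr2_start = NA_integer_,
                           cr2_end = NA_integer_, linker_length = NA_integer_,
                           complete = FALSE))
    }
    down <- dplyr::arrange(down, .data$linker_length)
    dplyr::mutate(base,
                  linker_start = cr1_end + 1L, linker_end = down$start[1] - 1L,
                  cr2_start = down$start[1], cr2_end = down$end[1],
                  linker_length = down$linker_length[1], complete = TRUE,
                  n_phi3_alternatives = nrow(down) - 1L)
  })
  candidates <- dplyr::bind_rows(candidates)

  complete <- candidates[candidates$complete, , drop = FALSE]
  pool <- if (nrow(complete)) complete else candidates
  pool$span <- dplyr::coalesce(pool$cr2_end, pool$cr1_end) - pool$cr1_start + 1L
  pool <- dplyr::arrange(pool, .data$span, .data$cr1_start)
  best <- pool[1, setdiff(names(pool), "span"), drop = FALSE]
  alternatives <- pool[-1, setdiff(names(pool), "span"), drop = FALSE]

  class(best) <- c("hrd_annotation", class(best))
  attr(best, "alternatives") <- alternatives
  best
}
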