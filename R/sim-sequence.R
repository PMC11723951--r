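#' Specification for a synthetic HRD-like protein sequence
#'
#' Describes the bipartite retention-domain architecture: a first conserved
#' region (hydrophobic motif phi1, then the His-Cys motif, then hydrophobic
#' motif phi2, with fixed short spacings), a disordered linker of controlled
#' length and charge composition, and a second conserved region (hydrophobic
#' motif phi3).
#'
#' @param gap_phi1_hiscys Residues strictly between phi1 and His-Cys
#'   (default 0: abutting).
#' @param gap_hiscys_phi2 Residues strictly between His-Cys and phi2
#'   (default 1).
#' @param linker_length Linker length in residues (default 21, the
#'   placental-mammal value).
#' @param ncpr,fcr,dp_fraction Target linker composition: net charge per
#'   residue, fraction of charged residues, fraction of disorder-promoting
#'   residues. Must satisfy `|ncpr| <= fcr <= 1`.
#' @param flank_length Length of the uniform flanks added on both sides.
#' @param seed Integer seed.
#' @return A list of class `hrd_sequence_spec`.
#' @export
hrd_sequence_spec <- function(gap_phi1_hiscys = 0L, gap_hiscys_phi2 = 1L,
                              linker_length = 21L, ncpr = 0.05, fcr = 0.15,
                              dp_fraction = 0.7, flank_length = 8L, seed = 1L) {
  if (abs(ncpr) > fcr || fcr > 1) {
    abort("infeasible linker composition: need |ncpr| <= fcr <= 1.",
          class = "hrdquant_infeasible_composition")
  }
  stopifnot(gap_phi1_hiscys >= 0, gap_hiscys_phi2 >= 0, linker_length >= 1)
  structure(
    list(gap_phi1_hiscys = as.integer(gap_phi1_hiscys),
         gap_hiscys_phi2 = as.integer(gap_hiscys_phi2),
         linker_length = as.integer(linker_length),
         ncpr = ncpr, fcr = fcr, dp_fraction = dp_fraction,
         flank_length = as.integer(flank_length), seed = as.integer(seed)),
    class = "hrd_sequence_spec"
  )
}

# Residues that do not seed any of the motif grammars (no V/I/L/H/C/P) and
# carry no charge; used for wildcard positions inside motifs and flanks.
SAFE_NEUTRAL <- c("A", "G", "S", "T", "N", "Q", "M", "F", "Y", "W")
# Disorder-promoting uncharged residues outside the motif alphabet.
SAFE_DP <- c("A", "G", "Q", "S")
SAFE_NONDP <- c("T", "N", "M", "F", "Y", "W")

sample_motif_instance <- function(class) {
  x <- function(n) paste(sample(SAFE_NEUTRAL, n, replace = TRUE), collapse = "")
  switch(class,
    phi1 = paste0(sample(c("V", "I"), 1), x(1), "L"),
    hiscys = paste0("H", x(4), "C", x(sample(3:4, 1)), "C"),
    phi2 = paste0("L", x(6), "V", x(1), "L"),
    phi3 = paste0("L", x(5), "V", x(1), "L"),
    abort(sprintf("no sampler for motif class '%s'.", class))
  )
}

# Integer charged-residue counts best matching the NCPR/FCR targets.
linker_charge_counts <- function(L, ncpr, fcr) {
  grid <- expand.grid(pos = 0:L, neg = 0:L)
  grid <- grid[grid$pos + grid$neg <= L, ]
  err <- abs((grid$pos - grid$neg) / L - ncpr) + abs((grid$pos + grid$neg) / L - fcr)
  grid[which.min(err), ]
}

build_linker <- function(spec) {
  L <- spec$linker_length
  cnt <- linker_charge_counts(L, spec$ncpr, spec$fcr)
  pos <- sample(c("K", "R"), cnt$pos, replace = TRUE)
  neg <- sample(c("E", "D"), cnt$neg, replace = TRUE)
  n_unch <- L - cnt$pos - cnt$neg
  # K, R, E count toward the disorder-promoting fraction; D does not
  dp_from_charged <- sum(pos %in% DP_SET) + sum(neg %in% DP_SET)
  n_dp <- max(0, min(n_unch, round(spec$dp_fraction * L) - dp_from_charged))
  unch <- c(sample(SAFE_DP, n_dp, replace = TRUE),
            sample(SAFE_NONDP, n_unch - n_dp, replace = TRUE))
  paste(sample(c(pos, neg, unch)), collapse = "")
}

#' Generate a synthetic HRD-like protein sequence with planted motifs
#'
#' Assembles flank + phi1 + gap + His-Cys + gap + phi2 + linker + phi3 +
#' flank from the motif grammars, with the linker drawn by constrained
#' residue sampling so its realized net charge per residue, fraction of
#' charged residues and disorder-promoting fraction land within 0.05 of the
#' targets. Candidate sequences are rejected and resampled until the motif
#' scanner recovers exactly the planted architecture (no spurious motif hits
#' and no alternative motif chain), so generator and scanner round-trip by
#' construction.
#'
#' @param spec An [hrd_sequence_spec()].
#' @param max_tries Resampling budget for the rejection step.
#' @return A list of class `hrd_sequence`: `sequence` (string), `planted`
#'   (tibble of planted motif spans), `linker` (string) and `spec`.
#' @export
make_hrd_sequence <- function(spec = hrd_sequence_spec(), max_tries = 200L) {
  stopifnot(inherits(spec, "hrd_sequence_spec"))
  set.seed(spec$seed)
  x <- function(n) paste(sample(SAFE_NEUTRAL, n, replace = TRUE), collapse = "")

  for (try in seq_len(max_tries)) {
    motifs <- list(
      phi1 = sample_motif_instance("phi1"),
      hiscys = sample_motif_instance("hiscys"),
      phi2 = sample_motif_instance("phi2"),
      phi3 = sample_motif_instance("phi3")
    )
    linker <- build_linker(spec)
    parts <- c(x(spec$flank_length), motifs$phi1, x(spec$gap_phi1_hiscys),
               motifs$hiscys, x(spec$gap_hiscys_phi2), motifs$phi2,
               linker, motifs$phi3, x(spec$flank_length))
    seqstr <- paste(parts, collapse = "")

    starts <- cumsum(c(1L, nchar(parts)))[seq_along(parts)]
    planted <- tibble(
      motif_class = c("phi1", "hiscys", "phi2", "phi3"),
      start = starts[c(2, 4, 6, 8)],
      end = starts[c(2, 4, 6, 8)] + nchar(unlist(motifs)) - 1L,
      matched = unlist(motifs, use.names = FALSE)
    )

    hits <- scan_motifs(seqstr, classes = c("phi1", "hiscys", "phi2", "phi3"))
    planted_ok <- all(purrr::pmap_lgl(planted, function(motif_class, start, end, ...) {
      any(hits$motif_class == motif_class & hits$start == start & hits$end == end)
    }))
    # The grammar family is nested: every phi2/phi3 instance ends in V-x-L,
    # which is itself a legal phi1 match, and a phi3 instance is a legal
    # phi2 match. These derived sub-motifs are unavoidable consequences of
    # planting, so they are tolerated; anything else is spurious and
    # triggers resampling.
    p23 <- planted[planted$motif_class %in% c("phi2", "phi3"), ]
    derived <- dplyr::bind_rows(
      dplyr::mutate(planted[planted$motif_class == "phi3", ], motif_class = "phi2"),
      tibble(motif_class = "phi1", start = p23$end - 2L, end = p23$end,
             matched = substring(seqstr, p23$end - 2L, p23$end))
    )
    extra <- dplyr::anti_join(
      hits, dplyr::bind_rows(planted, derived),
      by = c("motif_class", "start", "end")
    )
    if (!planted_ok || nrow(extra) > 0) next

    ann <- call_hrd(seqstr, hits,
                    gap_phi1_hiscys = spec$gap_phi1_hiscys,
                    gap_hiscys_phi2 = spec$gap_hiscys_phi2)
    if (!isTRUE(ann$complete) || ann$linker_length != spec$linker_length) next

    return(structure(
      list(sequence = seqstr, planted = planted, linker = linker, spec = spec),
      class = "hrd_sequence"
    ))
  }
  abort("failed to generate a clean sequence within `max_tries` resamples.")
}

#' Synthetic ortholog alignment with a fixed number of invariant columns
#'
#' Builds a gapless multiple alignment of HRD-architecture sequences with an
#' exactly specified number of invariant columns, emulating the sparse
#' cross-species conservation of a retention domain: motif-constrained
#' positions are held fixed while the remaining columns are forced to vary.
#' The default geometry (57 columns) corresponds to flank(1) + phi1(3) +
#' His-Cys(11) + spacer(1) + phi2(10) + linker(21) + phi3(9) + flank(1).
#'
#' @param n_seq Number of sequences (>= 2).
#' @param n_columns Alignment width.
#' @param n_invariant Number of invariant columns.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences (no gaps), one
#'   element per synthetic ortholog.
#' @export
make_hrd_alignment <- function(n_seq = 8L, n_columns = 57L, n_invariant = 17L,
                               seed = 1L) {
  stopifnot(n_seq >= 2, n_invariant >= 0, n_invariant <= n_columns)
  set.seed(seed)
  consensus <- sample(AA20, n_columns, replace = TRUE)
  inv_pos <- sort(sample.int(n_columns, n_invariant))
  seqs <- matrix(rep(consensus, n_seq), nrow = n_seq, byrow = TRUE)
  for (j in setdiff(seq_len(n_columns), inv_pos)) {
    # force at least two residue states in every variable column
    alt <- sample(setdiff(AA20, consensus[j]), 1)
    carriers <- sample.int(n_seq, size = sample(seq_len(n_seq - 1), 1))
    seqs[carriers, j] <- alt
  }
  out <- apply(seqs, 1, paste, collapse = "")
  names(out) <- sprintf("synthetic_ortholog_%02d", seq_len(n_seq))
  out
}
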