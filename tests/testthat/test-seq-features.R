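test_that("scanner reproduces hand-checked motif hits", {
  hits <- scan_motifs("LAAAAAVAL", classes = "phi3")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 9L)
  expect_equal(hits$matched, "LAAAAAVAL")
  expect_equal(hits$core_zero_pos, 7L)   # the V of the ...V-x-L core

  pent <- scan_motifs("PAVAL", classes = "pxvxl")
  expect_equal(nrow(pent), 1)
  expect_equal(c(pent$start, pent$end), c(1L, 5L))

  expect_equal(nrow(scan_motifs("", classes = "phi1")), 0)
  expect_error(scan_motifs("LAZAL"), class = "hrdquant_bad_sequence")
  expect_error(scan_motifs("PAVAL", classes = "pxvl"),
               class = "hrdquant_unknown_motif_class")
  # X never satisfies a constrained position, but wildcards accept it
  expect_equal(nrow(scan_motifs("XALVXL", classes = "phi1")), 1) # VXL matches
  expect_equal(nrow(scan_motifs("XAL", classes = "phi1")), 0)
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  classes <- c("phi1", "hiscys", "hiscys_amphibian", "phi2", "phi3", "pxvxl")
  set.seed(7)
  for (i in 1:150) {
    n <- sample(30:120, 1)
    s <- paste(sample(AA, n, replace = TRUE), collapse = "")
    got <- as.data.frame(scan_motifs(s, classes)[, c("motif_class", "start",
                                                     "end", "matched")])
    ref <- brute_force_scan(s, classes)
    rownames(got) <- rownames(ref) <- NULL
    expect_identical(got, ref, info = paste("seed seq", i))
  }
})

test_that("matched strings re-extract by coordinates for every hit", {
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(AA, 150, replace = TRUE), collapse = "")
    hits <- scan_motifs(s)
    if (nrow(hits)) {
      expect_identical(hits$matched, substring(s, hits$start, hits$end))
      expect_identical(hits$end - hits$start + 1L, nchar(hits$matched))
    }
  }
})

test_that("generated sequences round-trip through scanner and architecture caller", {
  for (seed in 1:100) {
    sq <- make_hrd_sequence(hrd_sequence_spec(seed = seed))
    hits <- scan_motifs(sq$sequence, classes = c("phi1", "hiscys", "phi2", "phi3"))
    found <- purrr::pmap_lgl(sq$planted, function(motif_class, start, end, ...) {
      any(hits$motif_class == motif_class & hits$start == start & hits$end == end)
    })
    expect_true(all(found), info = paste("seed", seed))

    ann <- call_hrd(sq$sequence, hits)
    expect_true(ann$complete)
    expect_equal(ann$gap_phi1_hiscys, 0L)
    expect_equal(ann$gap_hiscys_phi2, 1L)
    expect_equal(ann$linker_length, 21L)
  }
})

test_that("generated linkers hit their composition targets within 0.05", {
  for (seed in c(3, 14, 59)) {
    spec <- hrd_sequence_spec(ncpr = 0.05, fcr = 0.15, dp_fraction = 0.7,
                              seed = seed)
    sq <- make_hrd_sequence(spec)
    lf <- linker_features(sq$linker)
    expect_lt(abs(lf$ncpr - spec$ncpr), 0.05)
    expect_lt(abs(lf$fcr - spec$fcr), 0.05)
    expect_lt(abs(lf$dp_fraction - spec$dp_fraction), 0.05)
  }
  # zero-charge targets draw only uncharged residues
  sq0 <- make_hrd_sequence(hrd_sequence_spec(ncpr = 0, fcr = 0, seed = 2))
  expect_false(grepl("[KRDE]", sq0$linker))
  expect_error(hrd_sequence_spec(ncpr = 0.3, fcr = 0.1),
               class = "hrdquant_infeasible_composition")
})

test_that("architecture calling handles missing and ambiguous phi3 sites", {
  base <- make_hrd_sequence(hrd_sequence_spec(seed = 4))
  ann <- call_hrd(base$sequence)
  # truncate before phi3: incomplete annotation, CR1 still anchored
  cut <- substr(base$sequence, 1, ann$cr2_start - 1)
  ann_cut <- call_hrd(cut)
  expect_false(ann_cut$complete)
  expect_true(is.na(ann_cut$cr2_start))
  expect_equal(ann_cut$cr1_start, ann$cr1_start)

  # append a second phi3 farther downstream: nearest one wins, alternative counted
  two <- paste0(base$sequence, "GGGG", "LAAAAAVAL")
  ann_two <- call_hrd(two)
  expect_equal(ann_two$cr2_start, ann$cr2_start)
  expect_gte(ann_two$n_phi3_alternatives, 1L)

  # permutation invariance of the hit list order
  hits <- scan_motifs(two, classes = c("phi1", "hiscys", "phi2", "phi3"))
  set.seed(1)
  shuffled <- hits[sample(nrow(hits)), ]
  expect_equal(as.data.frame(call_hrd(two, hits)),
               as.data.frame(call_hrd(two, shuffled)))
})

test_that("linker features match hand counts and invariants", {
  polyg <- linker_features(strrep("G", 21))
  expect_equal(polyg$ncpr, 0)
  expect_equal(polyg$fcr, 0)
  expect_equal(polyg$conformational_class, "compact_globule")
  expect_equal(polyg$functional_length_A, 13)

  ek <- linker_features("EKEKEKEKEK")
  expect_equal(ek$ncpr, 0)
  expect_equal(ek$fcr, 1)

  a <- linker_features("KKKDDE")
  expect_equal(a$ncpr, 0)
  expect_equal(a$fcr, 1)
  b <- linker_features("KKKKDE")
  expect_equal(b$ncpr, 2 / 6)
  expect_equal(b$fcr, 1)

  expect_equal(sum(a$composition[[1]]), 1)
  expect_equal(a$charge_profile[[1]], c(1, 1, 1, -1, -1, -1))
  expect_error(linker_features(""), class = "hrdquant_empty_segment")
})

test_that("per-residue features are invariant under self-concatenation and |NCPR| <= FCR", {
  set.seed(21)
  for (i in 1:25) {
    s <- paste(sample(AA, sample(10:60, 1), replace = TRUE), collapse = "")
    f1 <- linker_features(s)
    f2 <- linker_features(paste0(s, s))
    expect_equal(f1$ncpr, f2$ncpr)
    expect_equal(f1$fcr, f2$fcr)
    expect_equal(f1$dp_fraction, f2$dp_fraction)
    expect_lte(abs(f1$ncpr), f1$fcr)
    expect_lte(f1$fcr, 1)
  }
})

test_that("composition matrices are column z-scores with flagged disorder columns", {
  two_same <- c(a = "GGGSSSPPP", b = "GGGSSSPPP")
  z <- composition_matrix(two_same)
  expect_true(all(z == 0))

  graded <- c(l1 = strrep("G", 20),
              l2 = paste0(strrep("G", 15), strrep("K", 5)),
              l3 = paste0(strrep("G", 10), strrep("K", 10)))
  zg <- composition_matrix(graded)
  expect_true(all(diff(zg[, "K"]) > 0))
  dp <- attr(zg, "dp_columns")
  expect_true(dp[match("K", colnames(zg))])
  expect_false(dp[match("L", colnames(zg))])

  expect_error(composition_matrix(c(a = "GGG")),
               class = "hrdquant_too_few_segments")
})

test_that("alignment identity counts invariant columns over aligned length", {
  al <- c("ACDEF", "ACDGF", "ACDHF")
  out <- alignment_identity(al)
  expect_equal(out$n_columns, 5L)
  expect_equal(out$n_invariant, 4L)
  expect_equal(out$pct_identity, 80)

  gapped <- c("AC-EF", "AC-EF")
  out2 <- alignment_identity(gapped)
  expect_equal(out2$n_invariant, 4L)   # the gap column never counts

  expect_error(alignment_identity(c("AC", "ACD")),
               class = "hrdquant_ragged_alignment")

  # the synthetic ortholog generator plants the invariant count exactly
  for (seed in 1:5) {
    al3 <- make_hrd_alignment(n_seq = 6, n_columns = 57, n_invariant = 17,
                              seed = seed)
    out3 <- alignment_identity(al3)
    expect_equal(out3$n_invariant, 17L)
    expect_equal(out3$n_columns, 57L)
  }
})
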