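#' Three-class intensity segmentation of a nucleus image
#'
#' Deterministic replacement for interactive pixel classification: pixel
#' intensities are clustered into three classes (background, nucleoplasm,
#' chromocenter, in increasing intensity order) by k-means initialized at
#' the 5th/50th/95th intensity percentiles, followed by small-object
#' removal on the chromocenter mask. For proteins with minimal chromocenter
#' partitioning the protein channel carries no contrast, so
#' `mode = "counterstain"` segments the DNA channel instead and transfers
#' the labels to the protein channel.
#'
#' @param field An `imaging_field` (see [make_nucleus_field()]) or a plain
#'   numeric matrix.
#' @param mode `"protein"` or `"counterstain"`.
#' @param min_size Chromocenter components smaller than this (pixels) are
#'   reassigned to nucleoplasm.
#' @return Integer label matrix of class `label_masks` (0 = background,
#'   1 = nucleoplasm, 2 = chromocenter) with attribute `source`.
#' @export
segment_nucleus <- function(field, mode = c("protein", "counterstain"),
                            min_size = 9L) {
  mode <- match.arg(mode)
  if (is.matrix(field)) field <- list(protein = field, counterstain = NULL)
  img <- switch(mode, protein = field$protein, counterstain = field$counterstain)
  if (is.null(img)) {
    abort(sprintf("no %s channel available.", mode),
          class = "hrdquant_missing_channel")
  }
  v <- as.vector(img)
  if (length(unique(v)) < 3) {
    abort("degenerate intensity histogram: fewer than 3 intensity levels.",
          class = "hrdquant_degenerate_histogram")
  }
  centers <- matrix(quantile(v, c(0.05, 0.5, 0.95)), ncol = 1)
  if (any(duplicated(centers))) {
    centers <- matrix(sort(unique(v))[round(seq(1, length(unique(v)), length.out = 3))],
                      ncol = 1)
  }
  km <- kmeans(v, centers = centers)
  ord <- order(km$centers)
  lab <- matrix(match(km$cluster, ord) - 1L, nrow(img), ncol(img))

  # drop speckle chromocenters
  comp <- cc_label(lab == 2L)
  if (max(comp) > 0) {
    sizes <- tabulate(comp[comp > 0])
    drop <- which(sizes < min_size)
    if (length(drop)) lab[comp %in% drop] <- 1L
  }

  structure(lab, source = paste0(mode, "_channel"),
            class = c("label_masks", "matrix"))
}

#' Partition coefficient of one nucleus
#'
#' Applies the partition-coefficient formula to the class means of a
#' segmented nucleus:
#' `PC = (mean chromocenter - mean background) / (mean nucleoplasm - mean background)`.
#' The whole-nucleus mean is computed over chromocenter plus nucleoplasm
#' pixels. Cells whose background-corrected nucleoplasm signal sits within
#' the noise floor (below `noise_floor_k` background standard deviations)
#' are flagged so they can be excluded from downstream averaging.
#'
#' @param field An `imaging_field` or numeric matrix (protein channel).
#' @param masks A `label_masks` matrix (from [segment_nucleus()] or a
#'   ground-truth mask).
#' @param construct_id,cell_id,experiment_id Optional labels carried into
#'   the record.
#' @param noise_floor_k Multiple of the background standard deviation used
#'   for the low-contrast flag.
#' @return One-row tibble (a partition record) with the class means,
#'   `mean_nuclear`, `pc` and `flag_low_contrast`.
#' @export
partition_coefficient <- function(field, masks, construct_id = NA_character_,
                                  cell_id = NA_character_,
                                  experiment_id = NA_character_,
                                  noise_floor_k = 3) {
  img <- if (is.matrix(field)) field else field$protein
  stopifnot(all(dim(img) == dim(masks)))
  if (!any(masks == 2L)) {
    abort("empty chromocenter mask; consider mode = 'counterstain' segmentation.",
          class = "hrdquant_empty_class")
  }
  if (!any(masks == 1L) || !any(masks == 0L)) {
    abort("all three classes must be non-empty.", class = "hrdquant_empty_class")
  }
  mean_cc <- mean(img[masks == 2L])
  mean_np <- mean(img[masks == 1L])
  mean_bg <- mean(img[masks == 0L])
  sd_bg <- sd(img[masks == 0L])
  if (mean_np <= mean_bg) {
    abort("nucleoplasm mean does not exceed background: partition coefficient undefined.",
          class = "hrdquant_degenerate_field")
  }
  tibble(
    construct_id = construct_id, cell_id = cell_id,
    experiment_id = experiment_id,
    mean_cc = mean_cc, mean_np = mean_np, mean_bg = mean_bg,
    mean_nuclear = mean(img[masks >= 1L]),
    pc = (mean_cc - mean_bg) / (mean_np - mean_bg),
    flag_low_contrast = is.finite(sd_bg) && sd_bg > 0 &&
      (mean_np - mean_bg) < noise_floor_k * sd_bg
  )
}

#' Normalized chromocenter-versus-nucleoplasm scatter
#'
#' For each construct, background-corrected chromocenter and nucleoplasm
#' means are divided by their construct-wise maxima, producing the
#' normalized intensity scatter in which non-partitioned proteins fall on
#' the y = x diagonal and retained proteins rise above it as expression
#' increases.
#'
#' @param records Tibble of partition records (rows from
#'   [partition_coefficient()]), at least 2 per construct.
#' @return Tibble with `construct_id`, `cell_id`, `cc_norm`, `np_norm`,
#'   `nuclear_intensity`; the normalization rule and the diagonal reference
#'   are recorded in attributes `normalization` and `reference_line`.
#' @export
normalized_scatter <- function(records) {
  records <- as_tibble(records)
  counts <- dplyr::count(records, .data$construct_id)
  if (any(counts$n < 2)) {
    abort("need at least 2 records per construct to normalize.",
          class = "hrdquant_too_few_records")
  }
  out <- records |>
    dplyr::group_by(.data$construct_id) |>
    dplyr::mutate(
      cc_corr = .data$mean_cc - .data$mean_bg,
      np_corr = .data$mean_np - .data$mean_bg,
      max_cc = max(.data$cc_corr), max_np = max(.data$np_corr)
    ) |>
    dplyr::ungroup()
  if (any(out$max_cc <= 0) || any(out$max_np <= 0)) {
    abort("construct-wise maximum is zero: cannot normalize.",
          class = "hrdquant_degenerate_field")
  }
  out <- out |>
    dplyr::transmute(
      construct_id = .data$construct_id, cell_id = .data$cell_id,
      cc_norm = .data$cc_corr / .data$max_cc,
      np_norm = .data$np_corr / .data$max_np,
      nuclear_intensity = .data$mean_nuclear
    )
  structure(out, normalization = "construct_max",
            reference_line = "y = x (equivalent intensities, PC = 1)")
}

#' Expression-saturation binning of partition and recovery data
#'
#' Groups partition records into nuclear-intensity bins (e.g. low / medium
#' / high expression) at the supplied cutpoints and reports per-bin
#' descriptive statistics, optionally joined with FRAP recovery values per
#' cell.
#'
#' @param records Tibble of partition records.
#' @param bounds Strictly increasing nuclear-intensity cutpoints; `n`
#'   cutpoints define `n + 1` bins.
#' @param recovery Optional tibble with `cell_id` and `recovery_100s`.
#' @return Tibble with one row per bin: `bin`, `n`, `mean_nuclear`,
#'   `mean_pc`, `median_pc`, `mean_recovery_100s`. Empty bins are reported
#'   with `n = 0` and no statistics.
#' @export
saturation_bins <- function(records, bounds, recovery = NULL) {
  if (is.unsorted(bounds, strictly = TRUE)) {
    abort("`bounds` must be strictly increasing.", class = "hrdquant_bad_bounds")
  }
  records <- as_tibble(records)
  if (!is.null(recovery)) {
    records <- dplyr::left_join(records, recovery, by = "cell_id")
  } else {
    records$recovery_100s <- NA_real_
  }
  breaks <- c(-Inf, bounds, Inf)
  labels <- if (length(bounds) == 2) c("low", "medium", "high") else
    paste0("bin", seq_len(length(bounds) + 1))
  records$bin <- cut(records$mean_nuclear, breaks = breaks, labels = labels)

  records |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_nuclear = if (dplyr::n() > 0) mean(.data$mean_nuclear) else NA_real_,
      mean_pc = if (dplyr::n() > 0) mean(.data$pc) else NA_real_,
      median_pc = if (dplyr::n() > 0) median(.data$pc) else NA_real_,
      mean_recovery_100s = if (dplyr::n() > 0) mean(.data$recovery_100s) else NA_real_,
      .groups = "drop"
    )
}
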