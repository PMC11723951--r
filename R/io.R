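#' Write a FRAP series as CSV plus JSON sidecar
#'
#' The CSV carries columns `time_s`, `roi_id`, `mean_intensity`; the
#' sidecar (same path with extension `.json`) records the ROI roles, the
#' bleach-frame index and the bleach geometry so the series round-trips
#' losslessly.
#'
#' @param series A [frap_series()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_frap_series <- function(series, path) {
  stopifnot(inherits(series, "frap_series"))
  readr::write_csv(
    dplyr::transmute(series, time_s = .data$time_s, roi_id = .data$roi,
                     mean_intensity = .data$intensity),
    path
  )
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(
      roles = list(bleach = "bleach", nucleus = "nucleus",
                   background = "background"),
      bleach_index = bleach_index(series),
      roi_kind = attr(series, "roi_kind")
    ),
    sidecar, auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a FRAP series from CSV (with sidecar)
#'
#' Validates the trace (monotone times, all roles present) and reports
#' malformed rows by line number.
#'
#' @param path CSV path with columns `time_s`, `roi_id`, `mean_intensity`.
#' @param sidecar Sidecar JSON path; defaults to `path` with a `.json`
#'   extension. Must name the ROI roles and the bleach-frame index.
#' @return A [frap_series()].
#' @export
read_frap_series <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) {
    abort(sprintf("missing sidecar '%s': supply roles and bleach index.", sidecar),
          class = "hrdquant_missing_sidecar")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$roles) || is.null(meta$bleach_index)) {
    abort("sidecar must contain `roles` and `bleach_index`.",
          class = "hrdquant_missing_sidecar")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "roi_id", "mean_intensity")
  if (!all(need %in% names(df))) {
    abort(sprintf("CSV must have columns %s.", paste(need, collapse = ", ")))
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$mean_intensity))
  if (length(bad)) {
    abort(sprintf("malformed rows (non-finite values) at line(s): %s",
                  paste(head(bad + 1L, 10), collapse = ", ")),
          class = "hrdquant_malformed_rows")
  }
  roles <- unlist(meta$roles)
  df$roi <- names(roles)[match(df$roi_id, roles)]
  if (any(is.na(df$roi))) {
    abort("ROI ids in the CSV do not match the sidecar roles; add the missing role assignments.",
          class = "hrdquant_missing_role")
  }
  per_roi <- split(df$time_s, df$roi)
  if (any(vapply(per_roi, function(t) any(diff(t) <= 0), logical(1)))) {
    abort("times must be strictly increasing within each ROI.",
          class = "hrdquant_nonmonotone_times")
  }
  frap_series(
    tibble(time_s = df$time_s, roi = df$roi, intensity = df$mean_intensity),
    bleach_index = meta$bleach_index,
    roi_kind = meta$roi_kind %||% "total"
  )
}

#' Write protein sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are rescaled to the 16-bit range jointly (preserving relative
#' intensities) and written as one multi-page TIFF; the sidecar records the
#' intensity scale, pixel size and frame times.
#'
#' @param frames List of matrices (e.g. from [simulate_frap()]).
#' @param path TIFF output path.
#' @param pixel_size Pixel size recorded in the sidecar, micrometres.
#' @return `path`, invisibly.
#' @export
write_field_stack <- function(frames, path, pixel_size = NA_real_) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF stacks.")
  }
  top <- max(vapply(frames, max, numeric(1)))
  scaled <- lapply(frames, function(m) m / top)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(intensity_scale = top, pixel_size_um = pixel_size,
         times_s = attr(frames, "times"), n_frames = length(frames)),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
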