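#' Kymograph (position x time) from a frame stack
#'
#' Extracts the width-averaged intensity profile along a line segment from
#' every frame of a time series, including pre-bleach frames; each column of
#' the result is one frame. Sampling is at unit-pixel spacing along the
#' segment with bilinear interpolation, averaging over `width` parallel
#' offsets perpendicular to the line.
#'
#' @param frames List of image matrices (e.g. `frames` from
#'   [simulate_frap()] with `store_frames = TRUE`), optionally carrying a
#'   `times` attribute.
#' @param from,to Segment endpoints, `c(row, col)` in pixels.
#' @param width Averaging width in pixels (odd).
#' @return A numeric matrix (positions x frames) of class `kymograph` with
#'   attributes `positions` (distance along the line, pixels) and `times`.
#' @export
kymograph <- function(frames, from, to, width = 1L) {
  if (inherits(frames, "frap_sim")) frames <- frames$frames
  stopifnot(is.list(frames), length(frames) >= 1, width >= 1)
  d <- c(to[1] - from[1], to[2] - from[2])
  len <- sqrt(sum(d^2))
  if (len == 0) abort("zero-length line.", class = "hrdquant_bad_line")
  u <- d / len
  perp <- c(-u[2], u[1])
  n_pos <- floor(len) + 1L
  s <- seq(0, len, length.out = n_pos)
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = width)

  img0 <- frames[[1]]
  bilinear <- function(img, r, c) {
    r <- pmin(pmax(r, 1), nrow(img)); c <- pmin(pmax(c, 1), ncol(img))
    r0 <- floor(r); c0 <- floor(c)
    r1 <- pmin(r0 + 1, nrow(img)); c1 <- pmin(c0 + 1, ncol(img))
    fr <- r - r0; fc <- c - c0
    img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      img[cbind(r1, c0)] * fr * (1 - fc) +
      img[cbind(r0, c1)] * (1 - fr) * fc +
      img[cbind(r1, c1)] * fr * fc
  }

  rr <- outer(s, offsets, function(si, oi) from[1] + si * u[1] + oi * perp[1])
  cc <- outer(s, offsets, function(si, oi) from[2] + si * u[2] + oi * perp[2])
  if (any(rr < 1 | rr > nrow(img0) | cc < 1 | cc > ncol(img0))) {
    abort("line (with width) extends beyond the image bounds.",
          class = "hrdquant_bad_line")
  }

  mat <- vapply(frames, function(img) {
    rowMeans(matrix(bilinear(img, as.vector(rr), as.vector(cc)), n_pos, width))
  }, numeric(n_pos))

  structure(mat,
            positions = s,
            times = attr(frames, "times") %||% seq_along(frames),
            class = c("kymograph", "matrix"))
}
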