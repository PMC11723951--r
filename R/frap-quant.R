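#' Subtract per-frame background from every ROI trace
#'
#' First step of FRAP quantification: the background ROI's per-frame mean is
#' subtracted from each ROI at the same frame, after which the background
#' trace is identically zero.
#'
#' @param series A [frap_series()] containing a `"background"` ROI.
#' @return The background-corrected `frap_series`.
#' @export
background_correct <- function(series) {
  stopifnot(inherits(series, "frap_series"))
  bg <- roi_trace(series, "background")
  if (is.null(bg)) {
    abort("no background ROI in series.", class = "hrdquant_missing_roi")
  }
  out <- dplyr::left_join(series, dplyr::rename(bg, bg = "intensity"),
                          by = "time_s", suffix = c("", ".bg"))
  out$intensity <- out$intensity - out$bg
  out$bg <- NULL
  out$roi.bg <- NULL
  frap_series(out[, c("time_s", "roi", "intensity")],
              bleach_index = bleach_index(series),
              roi_kind = attr(series, "roi_kind"))
}

#' Correct acquisition photobleaching using the whole-nucleus trace
#'
#' Rescales the measured ROI frame-wise by the whole-nucleus ratio anchored
#' at the first post-bleach frame:
#' `NormI(t_n) = I(t_1)_nucleus / I(t_n)_nucleus * I(t_n)_roi`.
#' The correction factor is exactly 1 at the anchor frame. Frames where the
#' whole-nucleus trace is non-positive are rejected with a diagnostic.
#'
#' @param series A background-corrected [frap_series()].
#' @param anchor `"post"` (default: first post-bleach frame, the standard
#'   reading) or `"pre"` (last pre-bleach frame).
#' @return The scanning-normalized `frap_series`.
#' @export
normalize_scanning <- function(series, anchor = c("post", "pre")) {
  stopifnot(inherits(series, "frap_series"))
  anchor <- match.arg(anchor)
  nuc <- roi_trace(series, "nucleus")
  if (is.null(nuc)) {
    abort("no whole-nucleus ROI in series.", class = "hrdquant_missing_roi")
  }
  bi <- bleach_index(series)
  idx <- if (anchor == "post") bi else bi - 1L
  ref <- nuc$intensity[idx]
  bad <- which(nuc$intensity <= 0)
  if (length(bad)) {
    abort(
      sprintf("whole-nucleus intensity non-positive at frame(s) %s; cannot normalize.",
              paste(head(bad, 5), collapse = ", ")),
      class = "hrdquant_bad_nucleus_trace"
    )
  }
  fac <- tibble(time_s = nuc$time_s, fac = ref / nuc$intensity)
  out <- dplyr::left_join(series, fac, by = "time_s")
  out$intensity <- ifelse(out$roi == "bleach", out$intensity * out$fac,
                          out$intensity)
  out$fac <- NULL
  frap_series(out, bleach_index = bi, roi_kind = attr(series, "roi_kind"))
}

#' Relative fluorescence curve
#'
#' Divides the (corrected, normalized) measured-ROI trace by its pre-bleach
#' value, so the curve equals 1 at the pre-bleach reference timepoint.
#'
#' @param series A [frap_series()] (normally after [background_correct()]
#'   and [normalize_scanning()]).
#' @param reference `"last_prebleach"` (default) or `"mean_prebleach"`.
#' @return A `frap_curve`: tibble with `time_s` and `rel_fluor`, carrying
#'   `bleach_index` and the bleach-frame time as attributes.
#' @export
relative_fluorescence <- function(series,
                                  reference = c("last_prebleach", "mean_prebleach")) {
  stopifnot(inherits(series, "frap_series"))
  reference <- match.arg(reference)
  bi <- bleach_index(series)
  tr <- roi_trace(series, "bleach")
  if (bi <= 1 || bi > nrow(tr)) {
    abort("no pre-bleach frame available.", class = "hrdquant_no_prebleach")
  }
  ref <- if (reference == "last_prebleach") tr$intensity[bi - 1L] else
    mean(tr$intensity[seq_len(bi - 1L)])
  if (ref <= 0) abort("non-positive pre-bleach reference intensity.")
  structure(
    tibble(time_s = tr$time_s, rel_fluor = tr$intensity / ref),
    bleach_index = bi,
    bleach_time = tr$time_s[bi],
    roi_kind = attr(series, "roi_kind"),
    class = c("frap_curve", class(tibble()))
  )
}

#' Full normalization pipeline from raw series to relative fluorescence
#'
#' Convenience chain: [background_correct()], [normalize_scanning()],
#' [relative_fluorescence()].
#'
#' @inheritParams background_correct
#' @inheritParams normalize_scanning
#' @inheritParams relative_fluorescence
#' @return A `frap_curve`.
#' @export
frap_curve <- function(series, anchor = "post", reference = "last_prebleach") {
  relative_fluorescence(
    normalize_scanning(background_correct(series), anchor = anchor),
    reference = reference
  )
}

post_bleach <- function(curve) {
  bi <- attr(curve, "bleach_index")
  tibble(
    t = curve$time_s[bi:nrow(curve)] - curve$time_s[bi],
    y = curve$rel_fluor[bi:nrow(curve)]
  )
}

#' Double-term exponential fit of a FRAP recovery curve
#'
#' Least-squares fit of
#' `F(t) = F0 + a1 * (1 - exp(-t / tau1)) + a2 * (1 - exp(-t / tau2))`
#' on the post-bleach frames (time re-zeroed at the bleach frame), with
#' bounded positive parameters (`a_i` in `[0, 1.5]`, `tau` in
#' `[1e-3, 1e4]` s) and 8 multi-starts on a log-spaced tau grid; the start
#' with the lowest residual sum of squares wins. If no double-exponential
#' start converges, a single-exponential fallback is returned flagged as
#' degraded. The mobile fraction is `(plateau - F0) / (1 - F0)` with
#' `plateau = F0 + a1 + a2`.
#'
#' @param curve A `frap_curve` with at least 8 post-bleach frames.
#' @param n_starts Number of multi-start tau pairs.
#' @return An object of class `frap_fit` with components `a1`, `a2`,
#'   `tau1`, `tau2` (`tau1 <= tau2`), `F0`, `mobile_fraction`,
#'   `recovery_5s`, `recovery_100s`, `fit_rss`, `degraded`, and the fitted
#'   post-bleach data.
#' @export
fit_frap <- function(curve, n_starts = 8L) {
  stopifnot(inherits(curve, "frap_curve"))
  pb <- post_bleach(curve)
  if (nrow(pb) < 8) abort("need at least 8 post-bleach frames to fit.")
  if (any(!is.finite(pb$y))) abort("non-finite curve values.")

  f0_start <- pb$y[1]
  amp <- max(pb$y) - f0_start
  tau_grid <- exp(seq(log(max(pb$t[2], 1e-2)), log(max(pb$t)), length.out = n_starts))

  lower <- c(F0 = 0, a1 = 0, a2 = 0, tau1 = 1e-3, tau2 = 1e-3)
  upper <- c(F0 = 1.2, a1 = 1.5, a2 = 1.5, tau1 = 1e4, tau2 = 1e4)

  best <- NULL
  for (i in seq_len(n_starts)) {
    t1 <- tau_grid[max(1, i - 2)]
    t2 <- tau_grid[min(n_starts, i + 2)]
    start <- list(F0 = max(f0_start, 1e-6), a1 = max(amp * 0.6, 1e-3),
                  a2 = max(amp * 0.4, 1e-3), tau1 = t1, tau2 = max(t2, t1 * 3))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ F0 + a1 * (1 - exp(-t / tau1)) + a2 * (1 - exp(-t / tau2)),
        data = pb, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  degraded <- FALSE
  if (is.null(best)) {
    degraded <- TRUE
    single <- NULL
    for (tau0 in c(pb$t[2], median(pb$t), max(pb$t))) {
      single <- tryCatch(
        minpack.lm::nlsLM(
          y ~ F0 + a1 * (1 - exp(-t / tau1)), data = pb,
          start = list(F0 = max(f0_start, 1e-6), a1 = max(amp, 1e-3),
                       tau1 = max(tau0, 1e-2)),
          lower = lower[c("F0", "a1", "tau1")],
          upper = upper[c("F0", "a1", "tau1")],
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (!is.null(single)) break
    }
    if (!is.null(single)) {
      cf <- coef(single)
      cf <- c(cf["F0"], a1 = unname(cf["a1"]), a2 = 0,
              tau1 = unname(cf["tau1"]), tau2 = unname(cf["tau1"]))
      rss <- sum(residuals(single)^2)
    } else {
      # step-like or flat record: describe it as an immediate jump from the
      # first post-bleach value to the mean of the settled tail
      tail_mean <- mean(pb$y[pb$t > min(pb$t)])
      if (!is.finite(tail_mean)) tail_mean <- f0_start
      a1 <- max(tail_mean - f0_start, 0)
      cf <- c(F0 = f0_start, a1 = a1, a2 = 0,
              tau1 = max(pb$t[2] / 10, 1e-3), tau2 = max(pb$t[2] / 10, 1e-3))
      rss <- sum((pb$y - (f0_start + a1 * (1 - exp(-pb$t / cf[["tau1"]]))))^2)
    }
  } else {
    cf <- coef(best$fit)
    rss <- best$rss
  }
  # ordering convention: tau1 <= tau2
  if (cf[["tau1"]] > cf[["tau2"]]) {
    cf[c("a1", "a2")] <- cf[c("a2", "a1")]
    cf[c("tau1", "tau2")] <- cf[c("tau2", "tau1")]
  }
  F0 <- cf[["F0"]]
  plateau <- F0 + cf[["a1"]] + cf[["a2"]]
  mobile <- if (F0 < 1) (plateau - F0) / (1 - F0) else NA_real_

  rec <- function(t) {
    if (t > max(pb$t)) return(NA_real_)
    recovery_at(curve, t)
  }

  structure(
    list(a1 = cf[["a1"]], a2 = cf[["a2"]], tau1 = cf[["tau1"]],
         tau2 = cf[["tau2"]], F0 = F0, plateau = plateau,
         mobile_fraction = mobile,
         recovery_5s = rec(5), recovery_100s = rec(100),
         fit_rss = rss, degraded = degraded, data = pb),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit>%s a1=%.3f tau1=%.3gs  a2=%.3f tau2=%.3gs  F0=%.3f\n  mobile fraction=%.3f  RSS=%.3g\n",
    if (x$degraded) " [degraded: single-exponential fallback]" else "",
    x$a1, x$tau1, x$a2, x$tau2, x$F0, x$mobile_fraction, x$fit_rss))
  invisible(x)
}

#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("a1", "a2", "tau1", "tau2", "F0"),
    estimate = c(x$a1, x$a2, x$tau1, x$tau2, x$F0)
  )
}

#' @export
glance.frap_fit <- function(x, ...) {
  tibble(
    mobile_fraction = x$mobile_fraction, recovery_5s = x$recovery_5s,
    recovery_100s = x$recovery_100s, plateau = x$plateau,
    fit_rss = x$fit_rss, degraded = x$degraded
  )
}

#' Fractional recovery at a bleach-relative time
#'
#' Linearly interpolates the relative-fluorescence curve at time `t` after
#' the bleach and rescales to fractional recovery
#' `(value - post-bleach minimum) / (1 - post-bleach minimum)`, which is
#' comparable across constructs with different bleach depths. `type =
#' "raw"` returns the interpolated relative fluorescence itself.
#'
#' @param curve A `frap_curve`.
#' @param t Bleach-relative time, seconds (within the sampled range).
#' @param type `"fractional"` (default) or `"raw"`.
#' @return A single numeric value.
#' @export
recovery_at <- function(curve, t, type = c("fractional", "raw")) {
  stopifnot(inherits(curve, "frap_curve"))
  type <- match.arg(type)
  pb <- post_bleach(curve)
  if (t < 0 || t > max(pb$t)) {
    abort(sprintf("t = %g s is outside the sampled post-bleach range [0, %g].",
                  t, max(pb$t)), class = "hrdquant_time_out_of_range")
  }
  v <- approx(pb$t, pb$y, xout = t)$y
  if (type == "raw") return(v)
  m <- min(pb$y)
  if (m >= 1) return(0)
  max(0, (v - m) / (1 - m))
}
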