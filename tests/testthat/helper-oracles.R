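# Independent oracles used across the suite. These deliberately do not share
# code with the package: the brute-force scanner matches substrings position
# by position, the FRAP half-time comes from the closed-form uniform-disk
# solution, and the rank-sum reference enumerates all labelings.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# all fixed-length position-constraint templates per motif class,
# hand-written: NULL entries mean "any residue"
oracle_templates <- function(class) {
  gap <- function(n) rep(list(NULL), n)
  switch(class,
    phi1 = list(c(list(c("V", "I")), gap(1), list("L"))),
    hiscys = lapply(3:4, function(g2)
      c(list("H"), gap(4), list("C"), gap(g2), list("C"))),
    hiscys_amphibian = unlist(lapply(3:4, function(g1)
      lapply(13:14, function(g2)
        c(list("H"), gap(g1), list("C"), gap(g2), list("C")))),
      recursive = FALSE),
    phi2 = lapply(5:6, function(g)
      c(list("L"), gap(g), list("V"), gap(1), list("L"))),
    phi3 = list(c(list("L"), gap(5), list("V"), gap(1), list("L"))),
    pxvxl = list(c(list("P"), gap(1), list("V"), gap(1), list("L")))
  )
}

brute_force_scan <- function(sequence, classes) {
  res <- strsplit(toupper(sequence), "")[[1]]
  out <- list()
  for (cls in classes) {
    for (tmpl in oracle_templates(cls)) {
      span <- length(tmpl)
      if (span > length(res)) next
      for (s in seq_len(length(res) - span + 1)) {
        ok <- TRUE
        for (k in seq_len(span)) {
          allowed <- tmpl[[k]]
          if (!is.null(allowed) && !(res[s + k - 1] %in% allowed)) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          out[[length(out) + 1]] <- data.frame(
            motif_class = cls, start = s, end = s + span - 1L,
            matched = paste(res[s:(s + span - 1)], collapse = ""),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif_class = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, out))
  df[order(df$start, match(df$motif_class, classes), df$end), , drop = FALSE]
}

# Closed-form uniform-disk FRAP recovery (Soumpasis): f(t) =
# exp(-2 tauD / t) * (I0 + I1)(2 tauD / t), tauD = w^2 / (4 D).
soumpasis_curve <- function(t, w, D) {
  tauD <- w^2 / (4 * D)
  x <- 2 * tauD / t
  # exp(-x) * (I0(x) + I1(x)), via the exponentially scaled Bessel functions
  besselI(x, 0, expon.scaled = TRUE) + besselI(x, 1, expon.scaled = TRUE)
}

soumpasis_half_time <- function(w, D) {
  uniroot(function(t) soumpasis_curve(t, w, D) - 0.5,
          interval = c(1e-6, 1e4 * w^2 / D))$root
}

# Exact two-sample rank-sum reference by exhaustive enumeration of all
# C(m+n, m) group labelings (Mann-Whitney U statistic for group x).
ranksum_enumerate <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_two <- mean(abs(u_all - m * length(y) / 2) >= abs(u_obs - m * length(y) / 2))
  list(statistic = u_obs, p_value = p_two, null = u_all)
}

# Adjusted Rand index from the contingency-table formula.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Quick synthetic FRAP series built directly from trace vectors.
make_series <- function(bleach, nucleus, background, bleach_index,
                        times = seq_along(bleach), roi_kind = "total") {
  frap_series(
    tibble::tibble(
      time_s = rep(times, 3),
      roi = rep(c("bleach", "nucleus", "background"), each = length(times)),
      intensity = c(bleach, nucleus, background)
    ),
    bleach_index = bleach_index, roi_kind = roi_kind
  )
}
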