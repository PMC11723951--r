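#' Assemble a per-construct feature panel
#'
#' Reduces per-cell partition records and FRAP summaries to per-construct
#' medians of the panel features (partition coefficient, fractional recovery
#' at 5 s and 100 s, mobile fraction), keeping cell counts as provenance.
#' Constructs missing one modality are retained with missing features and
#' `complete = FALSE` so they can be excluded from clustering.
#'
#' @param pc_records Tibble of partition records (needs `construct_id`,
#'   `pc`).
#' @param frap_summaries Tibble with `construct_id` and per-cell
#'   `recovery_5s`, `recovery_100s`, `mobile_fraction` (e.g. rows of
#'   `glance()` on [fit_frap()] objects).
#' @param construct_map Optional tibble mapping `construct_id` to motif
#'   status flags (columns such as `phi1`, `his`, `cys`, `phi2`, `linker`,
#'   `phi3`).
#' @return Tibble with one row per construct: features, `n_cells_pc`,
#'   `n_cells_frap`, `complete`, plus any construct-map columns.
#' @export
assemble_panel <- function(pc_records, frap_summaries, construct_map = NULL) {
  pc <- as_tibble(pc_records) |>
    dplyr::group_by(.data$construct_id) |>
    dplyr::summarise(pc = median(.data$pc), n_cells_pc = dplyr::n(),
                     .groups = "drop")
  fr <- as_tibble(frap_summaries) |>
    dplyr::group_by(.data$construct_id) |>
    dplyr::summarise(
      recovery_5s = median(.data$recovery_5s),
      recovery_100s = median(.data$recovery_100s),
      mobile_fraction = median(.data$mobile_fraction),
      n_cells_frap = dplyr::n(), .groups = "drop"
    )
  panel <- dplyr::full_join(pc, fr, by = "construct_id")
  panel$complete <- complete.cases(
    panel[, c("pc", "recovery_5s", "recovery_100s")]
  )
  if (!is.null(construct_map)) {
    panel <- dplyr::left_join(panel, as_tibble(construct_map), by = "construct_id")
  }
  panel
}

#' Hierarchically cluster a construct panel
#'
#' Z-scores the selected feature columns, clusters constructs by
#' agglomerative hierarchical clustering (Euclidean distance, average
#' linkage), cuts the tree at `k` groups, and relabels clusters
#' deterministically in order of decreasing mean partition coefficient
#' (cluster 1 = most retained). Tied rows keep input order and are flagged.
#'
#' @param panel Tibble from [assemble_panel()].
#' @param k Number of clusters (<= number of complete constructs).
#' @param features Feature columns to cluster on. The mobile fraction can
#'   be added as a fourth feature; the default clusters on the three
#'   panel metrics.
#' @param method Linkage method passed to [stats::hclust()].
#' @return List of class `panel_clustering`: `panel` (with `cluster`
#'   labels), `tree` (an `hclust`), `zscores`, `features`, `k`.
#' @export
cluster_panel <- function(panel, k,
                          features = c("pc", "recovery_5s", "recovery_100s"),
                          method = "average") {
  panel <- as_tibble(panel)
  usable <- panel[complete.cases(panel[, features]), , drop = FALSE]
  if (k > nrow(usable)) {
    abort(sprintf("k = %d exceeds the %d constructs with complete features.",
                  k, nrow(usable)), class = "hrdquant_k_too_large")
  }
  mat <- as.matrix(usable[, features])
  rownames(mat) <- usable$construct_id
  z <- apply(mat, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  rownames(z) <- usable$construct_id
  tree <- hclust(dist(z, method = "euclidean"), method = method)
  raw <- cutree(tree, k = k)

  # deterministic labels: decreasing mean pc
  mean_pc <- vapply(split(usable$pc, raw), mean, numeric(1))
  ord <- order(-mean_pc)
  relabel <- match(raw, as.integer(names(mean_pc))[ord])
  ties <- any(duplicated(round(mean_pc, 12)))
  if (ties) warn("tied cluster mean PCs: labels follow input order among ties.")

  usable$cluster <- relabel
  out <- dplyr::left_join(panel,
                          usable[, c("construct_id", "cluster")],
                          by = "construct_id")
  structure(
    list(panel = out, tree = tree, zscores = z, features = features, k = k,
         tied = ties),
    class = "panel_clustering"
  )
}

#' @export
print.panel_clustering <- function(x, ...) {
  cat("<panel_clustering>", nrow(x$zscores), "constructs,", x$k,
      "clusters on", paste(x$features, collapse = ", "), "\n")
  print(dplyr::count(x$panel, .data$cluster))
  invisible(x)
}

#' @export
tidy.panel_clustering <- function(x, ...) x$panel

#' Write a panel linkage tree as Newick
#'
#' @param x A `panel_clustering`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_panel_tree <- function(x, path) {
  stopifnot(inherits(x, "panel_clustering"))
  ape::write.tree(ape::as.phylo(x$tree), file = path)
  invisible(path)
}

#' Rank-based group comparison of partition coefficients
#'
#' Evaluates overall significance across constructs with the
#' Kruskal--Wallis one-way analysis, then performs pairwise Wilcoxon
#' rank-sum tests between constructs; Holm-adjusted p-values are reported
#' alongside the raw values.
#'
#' @param records Tibble with a grouping column and a value column.
#' @param group,value Column names (strings).
#' @return List of class `pc_tests`: `kruskal` (one-row tibble) and
#'   `pairwise` (one row per pair with `statistic`, `p_value`, `p_holm`).
#' @export
compare_pc <- function(records, group = "construct_id", value = "pc") {
  records <- as_tibble(records)
  g <- factor(records[[group]])
  v <- records[[value]]
  if (nlevels(g) < 2) abort("need at least 2 groups.")
  if (any(table(g) < 3)) abort("each group needs n >= 3.")

  all_tied <- length(unique(v)) == 1
  if (all_tied) {
    kr <- tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                 flag = "all_values_tied")
  } else {
    kt <- kruskal.test(v, g)
    kr <- tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, flag = "ok")
  }

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(p) {
    x <- v[g == p[1]]; y <- v[g == p[2]]
    if (length(unique(c(x, y))) == 1) {
      return(tibble(group1 = p[1], group2 = p[2],
                    statistic = length(x) * length(y) / 2, p_value = 1))
    }
    wt <- suppressWarnings(wilcox.test(x, y))
    tibble(group1 = p[1], group2 = p[2],
           statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  pw$p_holm <- p.adjust(pw$p_value, method = "holm")

  structure(list(kruskal = kr, pairwise = pw), class = "pc_tests")
}

#' @export
print.pc_tests <- function(x, ...) {
  cat(sprintf("<pc_tests> Kruskal-Wallis H = %.3g, df = %d, p = %.3g [%s]\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value,
              x$kruskal$flag))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.pc_tests <- function(x, ...) x$pairwise

#' @export
glance.pc_tests <- function(x, ...) x$kruskal
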