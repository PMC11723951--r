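#' Synthetic nucleus image with known partition ground truth
#'
#' Renders a two-channel nucleus image: a protein channel whose noiseless
#' mean intensities satisfy the partition-coefficient identity
#' `(chromocenter - background) / (nucleoplasm - background) = pc_target`,
#' and a DNA-counterstain channel that marks chromocenters independently of
#' `pc_target` (standing in for Hoechst/DAPI staining). Optional mixed
#' Poisson + Gaussian readout noise emulates confocal acquisition.
#'
#' @param params A [sim_params()] object (geometry is taken from it).
#' @param pc_target Target partition coefficient (>= 0).
#' @param mean_nuclear_intensity Area-weighted mean protein intensity over
#'   the nucleus (chromocenters plus nucleoplasm), arbitrary units.
#' @param bg_mean Mean background (extranuclear) intensity, a.u.
#' @param noise `NULL` for a noiseless field, or a list with elements
#'   `photons_at_np` (expected photon count at the nucleoplasm mean, so the
#'   nucleoplasm signal-to-noise ratio is `sqrt(photons_at_np)`), `read_sd`
#'   (Gaussian read noise, a.u.) and optionally `seed`.
#' @return A list with elements `field` (class `imaging_field`: protein and
#'   counterstain matrices plus pixel size) and `truth` (class
#'   `ground_truth`: label masks coded 0 = background, 1 = nucleoplasm,
#'   2 = chromocenter, together with `pc_true` and the noiseless class
#'   means).
#' @export
make_nucleus_field <- function(params, pc_target, mean_nuclear_intensity = 200,
                               bg_mean = 20, noise = NULL) {
  stopifnot(inherits(params, "sim_params"), pc_target >= 0)
  labels <- matrix(0L, params$grid_shape[1], params$grid_shape[2])
  labels[params$nucleus_mask] <- 1L
  labels[params$cc_mask > 0] <- 2L

  a_cc <- sum(labels == 2L) / sum(labels >= 1L)
  np <- (mean_nuclear_intensity - a_cc * bg_mean * (1 - pc_target)) /
    (1 + a_cc * (pc_target - 1))
  if (!is.finite(np) || np <= bg_mean) {
    abort(
      "requested pc_target leaves no nucleoplasm signal above background (undefined ratio).",
      class = "hrdquant_degenerate_field"
    )
  }
  cc <- bg_mean + pc_target * (np - bg_mean)

  protein <- matrix(bg_mean, params$grid_shape[1], params$grid_shape[2])
  protein[labels == 1L] <- np
  protein[labels == 2L] <- cc

  # counterstain: dense DNA in chromocenters regardless of protein level
  counterstain <- matrix(bg_mean, params$grid_shape[1], params$grid_shape[2])
  counterstain[labels == 1L] <- 4 * bg_mean
  counterstain[labels == 2L] <- 10 * bg_mean

  if (!is.null(noise)) {
    if (!is.null(noise$seed)) set.seed(noise$seed)
    q <- (noise$photons_at_np %||% 100) / np
    read_sd <- noise$read_sd %||% 0
    shot <- function(img) {
      out <- rpois(length(img), as.vector(img) * q) / q +
        rnorm(length(img), 0, read_sd)
      matrix(out, nrow(img), ncol(img))
    }
    protein <- shot(protein)
    counterstain <- shot(counterstain)
  }

  field <- structure(
    list(protein = protein, counterstain = counterstain,
         pixel_size = params$pixel_size),
    class = "imaging_field"
  )
  truth <- structure(
    list(masks = labels, pc_true = pc_target,
         means = c(chromocenter = cc, nucleoplasm = np, background = bg_mean),
         bound_fraction_true = NA_real_),
    class = "ground_truth"
  )
  list(field = field, truth = truth)
}

# Nonlinear mass-action steady state with finite sites. At a no-flux steady
# state the free concentration is spatially uniform, so conservation reduces
# to a scalar root find in the per-pixel free count cf:
#   N = cf * n_pixels + sum_x s(x) * cf / (cf + Kd),  Kd = k_off / k_on_per_site.
solve_binding_ss <- function(params, copies) {
  stopifnot(copies > 0)
  s <- params$site_map[params$nucleus_mask]
  n_px <- sum(params$nucleus_mask)
  if (params$k_on_per_site <= 0 || sum(s) == 0) {
    cf <- copies / n_px
    bound <- matrix(0, params$grid_shape[1], params$grid_shape[2])
    return(list(free_conc = cf, bound = bound,
                free_sites = params$site_map, total_sites = sum(s)))
  }
  Kd <- params$k_off / params$k_on_per_site
  f <- function(cf) cf * n_px + sum(s * cf / (cf + Kd)) - copies
  upper <- copies / n_px
  cf <- uniroot(f, c(1e-12 * upper, upper), tol = 1e-12 * upper)$root
  occ <- cf / (cf + Kd)
  bound <- params$site_map * occ
  list(free_conc = cf, bound = bound,
       free_sites = params$site_map * (1 - occ), total_sites = sum(s))
}

#' Steady-state expression series over a range of copy numbers
#'
#' Emulates imaging an expression gradient: for each copy number the
#' mass-action steady state with finite chromocenter binding sites is solved
#' exactly, and a synthetic two-channel image is rendered at the resulting
#' chromocenter/nucleoplasm concentration ratio. Once copies exceed the
#' total site count, chromocenter concentration grows sub-linearly and the
#' partition coefficient decreases toward a plateau just above 1.
#'
#' @param params A [sim_params()] object whose site map defines the finite
#'   binding-site pool.
#' @param copy_numbers Positive molecule counts, ideally spanning below and
#'   above `sum(site_map)`.
#' @param seed Integer seed for the per-field readout noise.
#' @param gain Intensity units per molecule per pixel for rendering.
#' @param bg_mean Background intensity, a.u.
#' @param noise Per-field noise specification passed to
#'   [make_nucleus_field()]; `NULL` for noiseless fields.
#' @return A list of class `expression_series`: `fields` (list of
#'   field/truth pairs as from [make_nucleus_field()]) and `summary`
#'   (tibble with `copies`, `pc_true`, `cc_conc`, `np_conc`,
#'   `bound_fraction`, `mean_nuclear`).
#' @export
make_expression_series <- function(params, copy_numbers, seed = params$seed,
                                   gain = 1, bg_mean = 20, noise = NULL) {
  stopifnot(inherits(params, "sim_params"), all(copy_numbers > 0))
  rows <- purrr::map(copy_numbers, function(n) {
    ss <- solve_binding_ss(params, n)
    cc_px <- params$cc_mask > 0
    np_px <- params$nucleus_mask & !cc_px
    cc_conc <- ss$free_conc + mean(ss$bound[cc_px])
    np_conc <- ss$free_conc + mean(ss$bound[np_px])
    tibble(
      copies = n, pc_true = cc_conc / np_conc,
      cc_conc = cc_conc, np_conc = np_conc,
      bound_fraction = sum(ss$bound) / n,
      mean_nuclear = gain * n / sum(params$nucleus_mask) + bg_mean,
      total_sites = ss$total_sites
    )
  })
  summary <- dplyr::bind_rows(rows)

  fields <- purrr::imap(copy_numbers, function(n, i) {
    fld_noise <- noise
    if (!is.null(fld_noise)) fld_noise$seed <- seed + i
    make_nucleus_field(
      params, pc_target = summary$pc_true[i],
      mean_nuclear_intensity = summary$mean_nuclear[i],
      bg_mean = bg_mean, noise = fld_noise
    )
  })
  structure(list(fields = fields, summary = summary),
            class = "expression_series")
}
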