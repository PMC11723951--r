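test_that("noiseless well-separated fields segment exactly to the ground truth", {
  p <- sim_params(seed = 5)
  f <- make_nucleus_field(p, pc_target = 5)
  masks <- segment_nucleus(f$field, mode = "protein")
  expect_identical(unclass(masks)[, ], unclass(f$truth$masks)[, ])
})

test_that("counterstain segmentation recovers chromocenters for non-partitioned proteins", {
  p <- sim_params(seed = 6)
  f <- make_nucleus_field(p, pc_target = 1,
                          noise = list(photons_at_np = 400, read_sd = 1,
                                       seed = 11))
  expect_error(segment_nucleus(matrix(1, 4, 4), mode = "counterstain"),
               class = "hrdquant_missing_channel")
  masks <- segment_nucleus(f$field, mode = "counterstain")
  truth <- f$truth$masks
  jaccard <- sum(masks == 2 & truth == 2) / sum(masks == 2 | truth == 2)
  expect_gte(jaccard, 0.9)
})

test_that("segmentation accuracy at SNR ~ 10 is at least 95% per pixel", {
  p <- sim_params(seed = 7)
  f <- make_nucleus_field(p, pc_target = 8,
                          noise = list(photons_at_np = 100, read_sd = 1,
                                       seed = 12))
  masks <- segment_nucleus(f$field, mode = "protein")
  acc <- mean(masks == f$truth$masks)
  expect_gte(acc, 0.95)
})

test_that("the partition-coefficient formula is exact on constructed means", {
  masks <- structure(matrix(c(rep(0L, 20), rep(1L, 20), rep(2L, 10)), 5, 10),
                     class = c("label_masks", "matrix"))
  img <- matrix(0, 5, 10)
  img[masks == 0L] <- 10
  img[masks == 1L] <- 20
  img[masks == 2L] <- 60
  rec <- partition_coefficient(img, masks)
  expect_identical(rec$pc, 5)
  expect_equal(rec$mean_nuclear, mean(img[masks >= 1L]))

  img_flat <- img
  img_flat[masks == 1L] <- 10   # nucleoplasm equals background
  expect_error(partition_coefficient(img_flat, masks),
               class = "hrdquant_degenerate_field")

  no_cc <- structure(matrix(c(rep(0L, 25), rep(1L, 25)), 5, 10),
                     class = c("label_masks", "matrix"))
  expect_error(partition_coefficient(img, no_cc),
               class = "hrdquant_empty_class")
})

test_that("mean recovered PC converges to the target as noise shrinks and cells grow", {
  p <- sim_params(seed = 8)
  run <- function(photons, n, seed0) {
    pcs <- vapply(seq_len(n), function(i) {
      f <- make_nucleus_field(p, pc_target = 6,
                              noise = list(photons_at_np = photons,
                                           read_sd = 1, seed = seed0 + i))
      partition_coefficient(f$field, f$truth$masks)$pc
    }, numeric(1))
    mean(pcs)
  }
  err_noisy <- abs(run(25, 10, 100) - 6) / 6
  err_clean <- abs(run(2500, 20, 200) - 6) / 6
  expect_lt(err_clean, 0.01)
  expect_lt(err_noisy, 0.15)
  expect_lt(err_clean, err_noisy)
})

test_that("segmented and ground-truth-mask PC agree within 5% at SNR ~ 10", {
  p <- sim_params(seed = 9)
  f <- make_nucleus_field(p, pc_target = 8,
                          noise = list(photons_at_np = 100, read_sd = 1,
                                       seed = 33))
  pc_truth <- partition_coefficient(f$field, f$truth$masks)$pc
  pc_seg <- partition_coefficient(f$field, segment_nucleus(f$field))$pc
  expect_lt(abs(pc_seg - pc_truth) / pc_truth, 0.05)
})

test_that("normalized scatter puts non-partitioned cells on the diagonal", {
  p <- sim_params(seed = 10)
  recs <- purrr::map_dfr(1:4, function(i) {
    f <- make_nucleus_field(p, pc_target = 1,
                            mean_nuclear_intensity = 100 + 40 * i)
    partition_coefficient(f$field, f$truth$masks, construct_id = "flat",
                          cell_id = paste0("c", i))
  })
  sc <- normalized_scatter(recs)
  expect_equal(sc$cc_norm, sc$np_norm, tolerance = 1e-12)

  expect_error(normalized_scatter(recs[1, ]),
               class = "hrdquant_too_few_records")
})

test_that("saturation bins summarize records and flag empty bins", {
  one <- tibble::tibble(construct_id = "wt", cell_id = "c1",
                        mean_cc = 60, mean_np = 20, mean_bg = 10,
                        mean_nuclear = 90, pc = 5,
                        flag_low_contrast = FALSE)
  out <- saturation_bins(one, bounds = c(150, 300))
  expect_equal(nrow(out), 3)
  expect_equal(out$n, c(1L, 0L, 0L))
  expect_equal(out$mean_pc[1], 5)
  expect_true(all(is.na(out$mean_pc[2:3])))
  expect_error(saturation_bins(one, bounds = c(300, 150)),
               class = "hrdquant_bad_bounds")
})

test_that("expression-series records show non-increasing PC across expression bins", {
  p <- sim_preset("retentive")
  sites <- sum(p$site_map)
  copies <- sites * c(0.05, 0.05, 1.5, 1.5, 8, 8)
  es <- make_expression_series(p, copies, gain = 100 / (sites / sum(p$nucleus_mask)))
  recs <- purrr::imap_dfr(es$fields, function(fw, i) {
    partition_coefficient(fw$field, fw$truth$masks, construct_id = "wt",
                          cell_id = paste0("c", i))
  })
  bounds <- quantile(recs$mean_nuclear, c(0.34, 0.67))
  out <- saturation_bins(recs, bounds = unname(bounds))
  occupied <- out[out$n > 0, ]
  expect_true(all(diff(occupied$mean_pc) <= 0))
})
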