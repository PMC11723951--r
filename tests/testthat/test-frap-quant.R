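test_that("background correction subtracts per-frame background exactly", {
  s <- make_series(bleach = c(12, 5, 6, 7), nucleus = c(22, 15, 16, 17),
                   background = rep(2, 4), bleach_index = 2)
  out <- background_correct(s)
  expect_equal(roi_trace(out, "bleach")$intensity, c(10, 3, 4, 5))
  expect_equal(roi_trace(out, "background")$intensity, rep(0, 4))

  s0 <- make_series(bleach = c(12, 5, 6, 7), nucleus = c(22, 15, 16, 17),
                    background = rep(0, 4), bleach_index = 2)
  expect_equal(roi_trace(background_correct(s0), "bleach")$intensity,
               roi_trace(s0, "bleach")$intensity)

  no_bg <- frap_series(
    tibble::tibble(time_s = rep(1:4, 2),
                   roi = rep(c("bleach", "nucleus"), each = 4),
                   intensity = rep(1, 8)),
    bleach_index = 2
  )
  expect_error(background_correct(no_bg), class = "hrdquant_missing_roi")
})

test_that("scanning normalization undoes a shared per-frame decay", {
  # whole nucleus decays 1% per frame, true ROI1 signal constant
  n <- 12
  decay <- 0.99^(0:(n - 1))
  s <- make_series(bleach = 50 * decay, nucleus = 200 * decay,
                   background = rep(0, n), bleach_index = 3)
  out <- normalize_scanning(s)
  expect_equal(roi_trace(out, "bleach")$intensity, rep(50 * decay[3], n))

  # constant whole-nucleus trace: identity on ROI1
  s2 <- make_series(bleach = c(5, 2, 3, 4), nucleus = rep(100, 4),
                    background = rep(0, 4), bleach_index = 2)
  expect_equal(roi_trace(normalize_scanning(s2), "bleach")$intensity,
               c(5, 2, 3, 4))

  # the correction factor is exactly 1 at the post-bleach anchor frame
  out3 <- normalize_scanning(s)
  expect_equal(roi_trace(out3, "bleach")$intensity[3],
               roi_trace(s, "bleach")$intensity[3])
})

test_that("simulated acquisition bleaching is corrected to within 1% of the clean run", {
  p <- sim_preset("exchanging")
  clean <- simulate_frap(p, bleach = "total", t_end = 30, frame_interval = 1)
  dirty <- simulate_frap(p, bleach = "total", t_end = 30, frame_interval = 1,
                         acq_bleach_per_frame = 0.005)
  c_clean <- frap_curve(clean$series)
  c_dirty <- frap_curve(dirty$series)
  expect_lt(max(abs(c_clean$rel_fluor - c_dirty$rel_fluor)), 0.01)
})

test_that("relative fluorescence anchors at 1 pre-bleach and tracks bleach depth", {
  # unbleached ROI: curve identically 1
  s <- make_series(bleach = rep(80, 6), nucleus = rep(200, 6),
                   background = rep(0, 6), bleach_index = 3)
  expect_true(all(frap_curve(s)$rel_fluor == 1))

  # bleach to 30% with no dynamics: post-bleach values all 0.3
  s2 <- make_series(bleach = c(80, 80, 24, 24, 24, 24),
                    nucleus = rep(200, 6), background = rep(0, 6),
                    bleach_index = 3)
  cur <- frap_curve(s2)
  expect_equal(cur$rel_fluor[1:2], c(1, 1))
  expect_equal(cur$rel_fluor[3:6], rep(0.3, 4), tolerance = 1e-12)
})

test_that("the normalization pipeline is the identity up to the pre-bleach scale", {
  # zero background, constant nuclear trace: curve = trace / pre-bleach value
  tr <- c(60, 60, 20, 30, 40, 45)
  s <- make_series(bleach = tr, nucleus = rep(150, 6),
                   background = rep(0, 6), bleach_index = 3)
  cur <- frap_curve(s)
  expect_equal(cur$rel_fluor, tr / 60)
})

test_that("double-exponential fit recovers planted parameters on noiseless curves", {
  t <- seq(0, 120, by = 0.5)
  y <- 0.2 + 0.5 * (1 - exp(-t / 3)) + 0.3 * (1 - exp(-t / 40))
  s <- make_series(bleach = c(1, 1, y), nucleus = rep(1, length(y) + 2),
                   background = rep(0, length(y) + 2), bleach_index = 3,
                   times = c(-2, -1, t))
  fit <- fit_frap(frap_curve(s))
  expect_false(fit$degraded)
  expect_lt(fit$fit_rss, 1e-10)
  expect_equal(fit$a1, 0.5, tolerance = 0.01)
  expect_equal(fit$tau1, 3, tolerance = 0.01)
  expect_equal(fit$a2, 0.3, tolerance = 0.01)
  expect_equal(fit$tau2, 40, tolerance = 0.01)
  expect_lte(fit$tau1, fit$tau2)
})

test_that("mobile fraction hits its limiting values", {
  t <- seq(0, 60, by = 0.5)
  flat <- make_series(bleach = c(1, rep(0.25, length(t))),
                      nucleus = rep(1, length(t) + 1),
                      background = rep(0, length(t) + 1), bleach_index = 2,
                      times = c(-1, t))
  fit_flat <- fit_frap(frap_curve(flat))
  expect_equal(fit_flat$mobile_fraction, 0, tolerance = 1e-6)

  full <- 0.2 + 0.8 * (1 - exp(-t / 5))
  s_full <- make_series(bleach = c(1, full), nucleus = rep(1, length(t) + 1),
                        background = rep(0, length(t) + 1), bleach_index = 2,
                        times = c(-1, t))
  fit_full <- fit_frap(frap_curve(s_full))
  expect_equal(fit_full$mobile_fraction, 1, tolerance = 0.02)
})

test_that("fractional recovery interpolates and clamps sensibly", {
  t <- seq(0, 50, by = 1)
  y <- 0.2 + 0.6 * (1 - exp(-t / 10))
  s <- make_series(bleach = c(1, y), nucleus = rep(1, length(t) + 1),
                   background = rep(0, length(t) + 1), bleach_index = 2,
                   times = c(-1, t))
  cur <- frap_curve(s)
  expect_equal(recovery_at(cur, 0), 0)
  expect_error(recovery_at(cur, 51), class = "hrdquant_time_out_of_range")

  flat <- make_series(bleach = c(1, rep(0.3, length(t))),
                      nucleus = rep(1, length(t) + 1),
                      background = rep(0, length(t) + 1), bleach_index = 2,
                      times = c(-1, t))
  cflat <- frap_curve(flat)
  expect_equal(recovery_at(cflat, 10), 0)
  expect_equal(recovery_at(cflat, 40), 0)
})

test_that("internal equilibration time matches the closed-form 3-tau rule", {
  t <- seq(0, 60, by = 0.25)
  y <- 0.2 + 0.7 * (1 - exp(-t / 7))
  s <- make_series(bleach = c(1, y), nucleus = rep(1, length(t) + 1),
                   background = rep(0, length(t) + 1), bleach_index = 2,
                   times = c(-1, t))
  tin <- internal_equilibration_time(frap_curve(s), threshold = 0.95)
  expect_equal(as.numeric(tin), -7 * log(0.05), tolerance = 0.03)

  # step to plateau: first post-step time
  step <- make_series(bleach = c(1, 0.2, rep(0.8, 10)),
                      nucleus = rep(1, 12), background = rep(0, 12),
                      bleach_index = 2, times = 0:11)
  tin2 <- internal_equilibration_time(frap_curve(step))
  pb_first <- 0  # bleach-relative time of the step completion frame
  expect_lte(as.numeric(tin2), 2)

  # plateau never reached within the record
  slow <- 0.2 + 0.7 * (1 - exp(-t / 500))
  s_slow <- make_series(bleach = c(1, slow), nucleus = rep(1, length(t) + 1),
                        background = rep(0, length(t) + 1), bleach_index = 2,
                        times = c(-1, t))
  expect_error(internal_equilibration_time(frap_curve(s_slow)),
               class = "hrdquant_plateau_not_reached")
})

test_that("efflux-rate arithmetic reproduces the turnover and ratio identities", {
  t <- seq(0, 30 * 60, by = 30)             # 30 min, seconds
  y <- 1 - 0.007 / 60 * t                   # 0.7% per minute decay
  s <- make_series(bleach = c(1, y), nucleus = rep(1, length(t) + 1),
                   background = rep(0, length(t) + 1), bleach_index = 2,
                   times = c(-30, t), roi_kind = "inverse")
  res <- ifrap_efflux(frap_curve(s), window_min = 30, internal_time_s = 30)
  expect_equal(res$efflux_rate, 0.7, tolerance = 1e-9)
  # turnover * rate = 100 exactly (in minutes)
  expect_equal(res$turnover_time_h * 60 * res$efflux_rate, 100,
               tolerance = 1e-9)
  expect_equal(round(res$turnover_time_h, 1), 2.4)
  expect_equal(signif(res$equilibration_ratio, 2), 290)
  expect_equal(res$equilibration_ratio,
               res$turnover_time_h * 3600 / res$internal_time_s)

  # constant curve: rate 0, turnover not defined, flagged
  s_const <- make_series(bleach = rep(1, 10), nucleus = rep(1, 10),
                         background = rep(0, 10), bleach_index = 2,
                         roi_kind = "inverse")
  res0 <- ifrap_efflux(frap_curve(s_const))
  expect_equal(res0$efflux_rate, 0)
  expect_true(is.nan(res0$turnover_time_h))
  expect_equal(res0$flag, "no_efflux")

  # apparent influx: warned and zeroed
  s_up <- make_series(bleach = c(1, 1, seq(1, 1.2, length.out = 8)),
                      nucleus = rep(1, 10), background = rep(0, 10),
                      bleach_index = 3, roi_kind = "inverse")
  expect_warning(res_up <- ifrap_efflux(frap_curve(s_up)), "influx")
  expect_equal(res_up$efflux_rate, 0)
})
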