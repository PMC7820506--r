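# spot image on a blank frame, pixel units, via the package's own renderer
spot_frame <- function(x_px, y_px, photons, bg = 0, nrow = 32, ncol = 32,
                       sigma_px = 1.05, noisy = FALSE, seed = 1) {
  set.seed(seed)
  xg <- matrix(rep(seq_len(ncol) - 0.5, each = nrow), nrow, ncol)
  yg <- matrix(rep(seq_len(nrow) - 0.5, times = ncol), nrow, ncol)
  img <- bg + photons / (2 * pi * sigma_px^2) *
    exp(-((xg - x_px)^2 + (yg - y_px)^2) / (2 * sigma_px^2))
  if (noisy) img <- matrix(stats::rpois(length(img), img), nrow, ncol)
  img
}

test_that("blank noise frames rarely produce candidates at 5 sigma", {
  cfg <- detection_config(snr_threshold = 5, roi_half_size = 4)
  set.seed(42)
  n_cand <- vapply(seq_len(1000), function(i) {
    frame <- matrix(stats::rpois(32 * 32, 20), 32, 32)
    nrow(detect_spots(frame, cfg))
  }, numeric(1))
  expect_gte(mean(n_cand == 0), 0.99)
})

test_that("bright emitters are detected at their positions", {
  cfg <- detection_config(snr_threshold = 5, roi_half_size = 4)
  one <- detect_spots(spot_frame(16.5, 12.5, 5000), cfg)
  expect_identical(nrow(one), 1L)
  expect_lt(abs(one$col - 0.5 - 16.5), 1)
  expect_lt(abs(one$row - 0.5 - 12.5), 1)
  # two emitters 10 px apart resolve into two candidates
  two_img <- spot_frame(10.5, 16.5, 4000) + spot_frame(20.5, 16.5, 4000)
  two <- detect_spots(two_img, cfg)
  expect_identical(nrow(two), 2L)
})

test_that("noiseless Gaussian spots are fit to sub-millipixel accuracy", {
  roi <- spot_frame(5.3, 6.1, 4000, bg = 2, nrow = 11, ncol = 11)
  fit <- fit_gaussian2d(roi)
  expect_true(fit$converged)
  expect_lt(abs(fit$x_px - 5.3), 1e-3)
  expect_lt(abs(fit$y_px - 6.1), 1e-3)
  expect_lt(abs(fit$photons - 4000) / 4000, 0.01)
  expect_lt(abs(fit$bg - 2), 0.05)
})

test_that("precision estimate scales as 1/sqrt(photons)", {
  med_prec <- function(photons) {
    p <- vapply(seq_len(40), function(i) {
      roi <- spot_frame(5.5, 5.5, photons, bg = 5, nrow = 11, ncol = 11,
                        noisy = TRUE, seed = 100 + i)
      fit_gaussian2d(roi)$precision_px
    }, numeric(1))
    stats::median(p, na.rm = TRUE)
  }
  p1 <- med_prec(1000)
  p4 <- med_prec(4000)
  expect_lt(abs(p1 / p4 - 2), 0.4)  # quadrupling photons halves precision
})

test_that("higher background strictly worsens the precision estimate", {
  med_prec_bg <- function(bg) {
    p <- vapply(seq_len(40), function(i) {
      roi <- spot_frame(5.5, 5.5, 2000, bg = bg, nrow = 11, ncol = 11,
                        noisy = TRUE, seed = 200 + i)
      fit_gaussian2d(roi)$precision_px
    }, numeric(1))
    stats::median(p, na.rm = TRUE)
  }
  bgs <- c(2, 20, 80)
  prec <- vapply(bgs, med_prec_bg, numeric(1))
  expect_true(all(diff(prec) > 0))
})

test_that("reported precision is calibrated against the true error", {
  # repeated noisy fits of a known emitter: RMSE within 1.5x of the median
  # reported precision (and vice versa)
  err <- prec <- numeric(60)
  for (i in seq_len(60)) {
    roi <- spot_frame(5.5, 5.5, 3000, bg = 10, nrow = 11, ncol = 11,
                      noisy = TRUE, seed = 300 + i)
    fit <- fit_gaussian2d(roi)
    err[i] <- sqrt(mean(c(fit$x_px - 5.5, fit$y_px - 5.5)^2))
    prec[i] <- fit$precision_px
  }
  rmse <- sqrt(mean(err^2))
  ratio <- rmse / stats::median(prec)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("linking groups per-frame localizations into events", {
  cfg <- detection_config(link_radius = 50, link_max_gap = 1)
  tab <- data.frame(frame = c(3:7, 20, 21),
                    x_nm = c(rep(500, 5), 500, 502),
                    y_nm = 500, sigma_nm = 110, photons = 2000, bg = 5,
                    precision_nm = 5)
  ev <- link_events(tab, cfg)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$n_locs[1], 5L)
  expect_identical(ev$start_frame[1], 3)
  expect_identical(ev$end_frame[1], 7)
  # a gap larger than link_max_gap splits events
  tab2 <- data.frame(frame = c(1, 2, 6, 7), x_nm = 100, y_nm = 100,
                     sigma_nm = 110, photons = 1000, bg = 1,
                     precision_nm = 5)
  expect_identical(nrow(link_events(tab2, cfg)), 2L)
  # simultaneous localizations far apart stay separate events
  tab3 <- data.frame(frame = c(1, 1, 2, 2), x_nm = c(100, 900, 100, 900),
                     y_nm = 100, sigma_nm = 110, photons = 1000, bg = 1,
                     precision_nm = 5)
  expect_identical(nrow(link_events(tab3, cfg)), 2L)
})

test_that("end-to-end recall and precision reach 95% for isolated events", {
  set.seed(17)
  # 30 temporally isolated events of >= 2000 photons on a 12-site layout,
  # tissue-scale diffuse background
  n_ev <- 30
  pos <- cbind(x = stats::runif(n_ev, 500, 2900),
               y = stats::runif(n_ev, 500, 2900))
  t0 <- (seq_len(n_ev) - 1) * 1.0 + 0.12
  em <- data.frame(x_nm = pos[, "x"], y_nm = pos[, "y"], t_start = t0,
                   t_end = t0 + 0.35)
  noise <- noise_model(photon_rate = 20000, offset = 30, read_noise_sd = 1)
  stack <- render_fixture(em, duration = n_ev, noise = noise, seed = 18)
  tab <- localize_stack(stack, detection_config(snr_threshold = 5))
  ev <- link_events(tab, detection_config(link_radius = 150, link_max_gap = 1))
  # match recovered events to ground truth within 100 nm and 1 s
  matched <- logical(n_ev)
  false_pos <- 0L
  for (i in seq_len(nrow(ev))) {
    d <- sqrt((ev$x_nm[i] - em$x_nm)^2 + (ev$y_nm[i] - em$y_nm)^2)
    j <- which.min(d)
    tmatch <- abs(ev$start_frame[i] * 0.1 - em$t_start[j]) < 1
    if (d[j] < 100 && tmatch) matched[j] <- TRUE else false_pos <- false_pos + 1L
  }
  recall <- mean(matched)
  precision <- 1 - false_pos / nrow(ev)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # recovered event count within 5% of ground truth at this low density
  expect_lte(abs(nrow(ev) - n_ev) / n_ev, 0.05)
})

test_that("localization tables round-trip through CSV", {
  tab <- localization_table(
    data.frame(frame = c(2L, 0L), x_nm = c(1, 2), y_nm = c(3, 4),
               sigma_nm = 110, photons = c(1000, 2000), bg = 5,
               precision_nm = c(4, 6)),
    frame_time = 0.1, pixel_size = 108)
  expect_identical(tab$frame, c(0L, 2L))  # sorted on construction
  path <- tempfile(fileext = ".csv")
  write_localizations_csv(tab, path)
  back <- read_localizations_csv(path, frame_time = 0.1, pixel_size = 108)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  unlink(path)
})
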