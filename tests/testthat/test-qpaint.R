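test_that("dark times are the frame gaps between merged events", {
  ev <- data.frame(start_frame = c(10, 30), end_frame = c(20, 40))
  d <- extract_dark_times(ev)
  expect_equal(d$dark_frames, 10)
  expect_identical(d$n_events, 2L)
  # single event: empty, flagged
  one <- extract_dark_times(data.frame(start_frame = 1, end_frame = 5))
  expect_length(one$dark_frames, 0)
  expect_true(one$flagged)
  # continuous-time input is discretized on the frame grid
  evt <- data.frame(t_start = c(1.0, 3.0), t_end = c(2.0, 4.0))
  expect_equal(extract_dark_times(evt, frame_time = 0.1)$dark_frames, 10)
  # overlapping events merge into one bright period
  ov <- data.frame(t_start = c(1, 1.5, 10), t_end = c(2, 3, 11))
  expect_equal(extract_dark_times(ov, frame_time = 0.1)$dark_frames, 70)
})

test_that("single-site mean dark time approaches 1 / (k_on [I])", {
  im <- default_imager()
  conc <- 5e-9
  darks <- tile_trace_darks(1, 1, conc, duration = 3e4, imager = im)
  sec <- darks$dark_frames * 0.1
  theo <- 1 / (im$k_on * conc)
  se <- stats::sd(sec) / sqrt(length(sec))
  # discretization to whole frames biases each gap by about half a frame
  expect_lt(abs(mean(sec) - theo), 3 * se + 0.1)
})

test_that("pure-exponential dark times give tau_D within 5% and small alpha", {
  set.seed(61)
  tau <- 200
  d <- stats::rexp(5000, 1 / tau)
  fit <- fit_dark_cdf(d)
  expect_lt(abs(fit$tau_d - tau) / tau, 0.05)
  expect_lt(fit$alpha * fit$tau_b, 5)  # fast component carries little mass
})

test_that("the two-exponential mixture is recovered across seeds", {
  errs <- vapply(1:20, function(s) {
    set.seed(700 + s)
    d <- c(stats::rexp(1500, 1 / 3), stats::rexp(3500, 1 / 300))
    fit <- fit_dark_cdf(d)
    abs(fit$tau_d - 300) / 300
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
  expect_lt(max(errs), 0.10)
})

test_that("tau_B constraint binds under misspecification without hurting tau_D", {
  fits <- lapply(1:5, function(s) {
    set.seed(70 + s)
    fit_dark_cdf(c(stats::rexp(1500, 1 / 12), stats::rexp(3500, 1 / 300)))
  })
  tau_b <- vapply(fits, function(f) f$tau_b, numeric(1))
  expect_true(all(tau_b > 7.5))  # pushed to the 8-frame bound
  errs <- vapply(fits, function(f) abs(f$tau_d - 300) / 300, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("few dark times are flagged and too few are an error", {
  set.seed(3)
  fit <- fit_dark_cdf(stats::rexp(10, 1 / 50))
  expect_true(fit$flagged)
  expect_error(fit_dark_cdf(numeric(0)), "at least 2")
})

test_that("qPAINT index is the inverse dark time and superposes", {
  expect_equal(qpaint_index(100), 0.01)
  fit <- structure(list(tau_d = 250), class = "cdf_fit")
  expect_equal(qpaint_index(fit), 1 / 250)
  # merging two identical site traces doubles the index
  im <- default_imager()
  idx_for <- function(n_sites_tile, seed) {
    set.seed(seed)
    darks <- tile_trace_darks(n_sites_tile, 1, 5e-9, duration = 2e4,
                              imager = im)
    qpaint_index(fit_dark_cdf(darks))
  }
  i1 <- stats::median(vapply(1:6, function(s) idx_for(1, s), numeric(1)))
  i2 <- stats::median(vapply(1:6, function(s) idx_for(2, 50 + s), numeric(1)))
  expect_lt(abs(i2 / i1 - 2), 0.2)
  # index is proportional to [I] at a fixed site count
  idx_conc <- function(conc, seed) {
    set.seed(seed)
    darks <- tile_trace_darks(1, 1, conc, duration = 4e4, imager = im)
    qpaint_index(fit_dark_cdf(darks))
  }
  ia <- stats::median(vapply(1:6, function(s) idx_conc(2e-9, 80 + s), numeric(1)))
  ib <- stats::median(vapply(1:6, function(s) idx_conc(4e-9, 90 + s), numeric(1)))
  expect_lt(abs(ib / ia - 2), 0.25)
})

test_that("6-site calibration returns the Gaussian center per site", {
  expect_error(calibrate_6site(rep(0.01, 5)), "at least 10")
  # all-identical indices: center equals that value
  cal <- calibrate_6site(rep(0.012, 30))
  expect_equal(cal$gaussian_center, 0.012)
  expect_equal(cal$index_per_unit, 0.002)
  # symmetric data: center within 2 SE of the sample mean
  set.seed(81)
  idx <- stats::rnorm(200, 0.012, 0.002)
  cal2 <- calibrate_6site(idx)
  se <- stats::sd(idx) / sqrt(length(idx))
  expect_lt(abs(cal2$gaussian_center - mean(idx)), 2 * se)
  # applying the calibration to its own set returns ~6 sites
  est <- count_sites(idx, cal2, n_boot = 200)
  expect_lt(abs(est$median - 6), 0.2)
})

test_that("site-count estimates scale inversely with dark times", {
  set.seed(91)
  idx <- stats::rnorm(50, 0.012, 0.001)
  cal <- calibrate_6site(idx)
  est <- count_sites(idx, cal, n_boot = 100)
  half <- count_sites(idx / 2, cal, n_boot = 100)  # doubled dark times
  expect_equal(half$median, est$median / 2)
  expect_error(count_sites(numeric(0), cal), "empty")
})

test_that("tau_D recovery stays within 5% median error for n >= 2000", {
  errs <- vapply(1:50, function(s) {
    set.seed(900 + s)
    d <- c(stats::rexp(400, 1 / 2), stats::rexp(2000, 1 / 400))
    abs(fit_dark_cdf(d)$tau_d - 400) / 400
  }, numeric(1))
  expect_lte(stats::median(errs), 0.05)
})

test_that("estimated site counts are linear in true site counts (slope 1)", {
  im <- default_imager()
  conc <- 1e-9
  # per-tile index from pooled traces for 1..8 sites; calibrate at 6
  mean_idx <- vapply(1:8, function(ns) {
    idx <- vapply(1:10, function(r) {
      set.seed(4000 + 97 * ns + r)
      darks <- tile_trace_darks(ns, 10, conc / 10, duration = 4e4,
                                imager = im)
      qpaint_index(fit_dark_cdf(darks))
    }, numeric(1))
    mean(idx)
  }, numeric(1))
  ipu <- mean_idx[6] / 6
  est <- mean_idx / ipu
  fit <- stats::lm(est ~ I(1:8))
  expect_lt(abs(stats::coef(fit)[[2]] - 1), 0.05)
})
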