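#' Extract dark times from an event trace
#'
#' Dark times are the gaps between consecutive detected binding events of one
#' target region, in camera frames. Events are first merged when they overlap
#' in time (two sites of the same target bound simultaneously appear as one
#' bright period), so `n_dark = n_merged_events - 1`.
#'
#' @param events Data frame of events for one target, either continuous-time
#'   (`t_start`, `t_end` seconds) or frame-based (`start_frame`, `end_frame`).
#' @param frame_time Seconds per frame (for continuous-time input).
#' @return An object of class `dark_time_set`: list with `dark_frames`
#'   (positive gaps in frames), `n_events`, `frame_time`, and a `flagged`
#'   field set when fewer than 2 events were available.
#' @export
extract_dark_times <- function(events, frame_time = 0.1) {
  stopifnot(is.data.frame(events))
  if ("start_frame" %in% names(events)) {
    f0 <- events$start_frame; f1 <- events$end_frame
  } else {
    stopifnot(all(c("t_start", "t_end") %in% names(events)), frame_time > 0)
    f0 <- floor(events$t_start / frame_time)
    f1 <- floor(events$t_end / frame_time)
  }
  ord <- order(f0)
  f0 <- f0[ord]; f1 <- f1[ord]
  # merge events overlapping on the frame grid into single bright periods
  m0 <- integer(0); m1 <- integer(0)
  for (i in seq_along(f0)) {
    k <- length(m1)
    if (k > 0L && f0[i] <= m1[k] + 1L) {
      m1[k] <- max(m1[k], f1[i])
    } else {
      m0 <- c(m0, f0[i]); m1 <- c(m1, f1[i])
    }
  }
  n_ev <- length(m0)
  darks <- if (n_ev >= 2L) (m0[-1] - m1[-n_ev]) else numeric(0)
  darks <- darks[darks > 0]
  structure(list(dark_frames = as.numeric(darks), n_events = n_ev,
                 frame_time = frame_time, flagged = n_ev < 2L),
            class = "dark_time_set")
}

dark_cdf_model <- function(t, alpha, tau_b, tau_d) {
  alpha * (1 - exp(-t / tau_b)) + (1 - alpha) * (1 - exp(-t / tau_d))
}

#' Fit the two-exponential mixture CDF to dark times
#'
#' Least-squares fit of
#' `CDF(t) = alpha (1 - exp(-t/tau_B)) + (1 - alpha)(1 - exp(-t/tau_D))`
#' to the empirical CDF evaluated at the sorted unique dark times. The fast
#' component (`tau_B`, constrained below 8 frames) absorbs dye blinking and
#' detection dropouts; `tau_D` is the binding dark time used for qPAINT.
#' Three multistart initializations are tried and the best-residual fit kept.
#'
#' @param darks A `dark_time_set` (or numeric vector of dark times, frames).
#' @param tau_b_max Upper constraint on the fast component, frames.
#' @return An object of class `cdf_fit`: list with `alpha`, `tau_b`, `tau_d`
#'   (frames), `residual` (sum of squares), `n_dark`, `flagged`
#'   (`TRUE` when n < 20 dark times), `convergence`.
#' @export
fit_dark_cdf <- function(darks, tau_b_max = 8) {
  d <- if (inherits(darks, "dark_time_set")) darks$dark_frames else as.numeric(darks)
  stopifnot(all(d > 0))
  n <- length(d)
  if (n < 2L) stop("need at least 2 dark times to fit the CDF")
  tgrid <- sort(unique(d))
  emp <- stats::ecdf(d)(tgrid)
  m <- mean(d)
  obj <- function(p) {
    sum((dark_cdf_model(tgrid, p[1], p[2], p[3]) - emp)^2)
  }
  lower <- c(1e-4, 1e-3, 1e-2)
  upper <- c(1 - 1e-4, tau_b_max * (1 - 1e-9), Inf)
  starts <- list(c(0.1, 2, m), c(0.3, tau_b_max / 2, 2 * m),
                 c(0.5, 1, stats::median(d) / log(2)))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), c(upper[1:2], max(s[3], 1)))
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("dark-time CDF optimization failed")
  p <- best$par
  # keep tau_d as the slow component
  if (p[3] < p[2]) p <- c(1 - p[1], p[3], p[2])
  structure(list(alpha = p[1], tau_b = p[2], tau_d = p[3],
                 residual = best$value, n_dark = n, flagged = n < 20L,
                 convergence = best$convergence),
            class = "cdf_fit")
}

#' @export
print.cdf_fit <- function(x, ...) {
  cat(sprintf("<cdf_fit> alpha = %.3f, tau_B = %.2f fr, tau_D = %.1f fr (n = %d%s)\n",
              x$alpha, x$tau_b, x$tau_d, x$n_dark,
              if (x$flagged) ", flagged: few dark times" else ""))
  invisible(x)
}

#' qPAINT index
#'
#' The uncalibrated qPAINT index is the inverse of the fitted dark time,
#' `1 / tau_D` (per frame). It is proportional to the number of available
#' binding sites in the region and to the imager concentration.
#'
#' @param fit A `cdf_fit`, or a numeric `tau_D` in frames.
#' @return Index in 1/frames.
#' @export
qpaint_index <- function(fit) {
  tau_d <- if (inherits(fit, "cdf_fit")) fit$tau_d else as.numeric(fit)
  stopifnot(tau_d > 0)
  1 / tau_d
}

# Gaussian fit to a histogram of indices; falls back to moments
gaussian_hist_fit <- function(x) {
  nb <- max(8L, ceiling(sqrt(length(x)) * 1.5))
  h <- graphics::hist(x, breaks = nb, plot = FALSE)
  df <- data.frame(mid = h$mids, cnt = h$counts)
  st <- list(A = max(h$counts), mu = mean(x), s = stats::sd(x))
  fit <- tryCatch(
    stats::nls(cnt ~ A * exp(-(mid - mu)^2 / (2 * s^2)), data = df,
               start = st,
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    list(center = mean(x), sd = stats::sd(x), from_fallback = TRUE)
  } else {
    cf <- stats::coef(fit)
    ctr <- cf[["mu"]]
    # reject pathological fits (center outside data range)
    if (ctr < min(x) || ctr > max(x))
      list(center = mean(x), sd = stats::sd(x), from_fallback = TRUE)
    else
      list(center = ctr, sd = abs(cf[["s"]]), from_fallback = FALSE)
  }
}

#' Calibrate the qPAINT index on tiles with a known site count
#'
#' The histogram of qPAINT indices of the calibration tiles (six detectable
#' sites each) is fit with a Gaussian; the center divided by the known site
#' count gives the calibrated index per site.
#'
#' @param indices Numeric vector of per-tile qPAINT indices (1/frames).
#' @param n_sites Known number of sites per calibration tile.
#' @return An object of class `qpaint_calibration`: list with
#'   `index_per_unit`, `gaussian_center`, `gaussian_sd`, `n_tiles`.
#' @export
calibrate_6site <- function(indices, n_sites = 6) {
  stopifnot(is.numeric(indices), n_sites >= 1)
  if (length(indices) < 10L) stop("need at least 10 calibration tiles")
  if (stats::sd(indices) == 0) {
    g <- list(center = indices[1], sd = 0, from_fallback = TRUE)
  } else {
    g <- gaussian_hist_fit(indices)
  }
  if (g$center <= 0) stop("calibration produced a non-positive index")
  structure(list(index_per_unit = g$center / n_sites,
                 gaussian_center = g$center, gaussian_sd = g$sd,
                 n_tiles = length(indices),
                 from_fallback = isTRUE(g$from_fallback)),
            class = "qpaint_calibration")
}

#' qPAINT site-count estimates
#'
#' Applies a calibration to per-tile qPAINT indices and summarizes the
#' distribution by its median with a bootstrap standard error
#' (1000 resamples).
#'
#' @param indices Numeric vector of per-tile indices (1/frames).
#' @param calibration A [calibrate_6site()] result.
#' @param n_boot Bootstrap resamples for the SE of the median.
#' @return List with `sites_est` (per-tile estimates), `median`, `se_median`.
#' @export
count_sites <- function(indices, calibration, n_boot = 1000L) {
  stopifnot(inherits(calibration, "qpaint_calibration"))
  if (length(indices) == 0L) stop("empty index list")
  est <- indices / calibration$index_per_unit
  meds <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(est, replace = TRUE)), numeric(1))
  list(sites_est = est, median = stats::median(est),
       se_median = stats::sd(meds))
}

#' Write per-tile qPAINT results as CSV
#'
#' @param tiles Data frame with columns `target_id`, `n_events`, `alpha`,
#'   `tau_b`, `tau_d`, `index`, `sites_est`.
#' @param path Output path.
#' @export
write_qpaint_csv <- function(tiles, path) {
  cols <- c("target_id", "n_events", "alpha", "tau_b", "tau_d", "index",
            "sites_est")
  stopifnot(all(cols %in% names(tiles)))
  utils::write.csv(tiles[, cols], path, row.names = FALSE)
  invisible(path)
}
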