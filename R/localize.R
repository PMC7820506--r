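#' Spot detection and event-linking configuration
#'
#' The detection threshold is signal-to-noise-ratio relative (a multiple of
#' the frame noise SD above background), so events of equal photon yield are
#' detected equally at different diffuse background levels.
#'
#' @param snr_threshold Detection threshold in multiples of the local noise SD.
#' @param roi_half_size Half-size of the square fitting ROI in pixels (>= 2).
#' @param link_radius Maximum distance (nm) between localizations merged into
#'   one binding event.
#' @param link_max_gap Maximum number of dark frames bridged inside one event.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(snr_threshold = 5, roi_half_size = 5,
                             link_radius = 200, link_max_gap = 1) {
  stopifnot(snr_threshold > 0, roi_half_size >= 2, link_radius > 0,
            link_max_gap >= 0)
  structure(list(snr_threshold = snr_threshold,
                 roi_half_size = as.integer(roi_half_size),
                 link_radius = link_radius,
                 link_max_gap = as.integer(link_max_gap)),
            class = "detection_config")
}

# separable Gaussian smoothing, reflected edges
gauss_smooth <- function(img, sigma = 1) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
    padded <- m[pmin(pmax(idx, 1), n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (s in seq_along(k))
      out <- out + k[s] * padded[s:(s + n - 1), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(img))))
}

#' Detect candidate spots in one frame
#'
#' Candidates are local maxima of the Gaussian-smoothed frame exceeding
#' `background + snr_threshold * noise_SD`, where background and noise SD are
#' robust (median / MAD) estimates from the smoothed frame. Candidates closer
#' than the ROI size are reduced to the brighter one, and candidates whose ROI
#' would leave the frame are dropped.
#'
#' @param frame Numeric matrix of pixel counts.
#' @param config A [detection_config()].
#' @return Data frame with 1-based pixel coordinates `row`, `col` and the
#'   smoothed intensity `value`, ordered by decreasing `value`.
#' @export
detect_spots <- function(frame, config) {
  stopifnot(is.matrix(frame), inherits(config, "detection_config"))
  sm <- gauss_smooth(frame, sigma = 1)
  bg <- stats::median(sm)
  noise_sd <- stats::mad(sm)
  if (noise_sd == 0) noise_sd <- sqrt(max(bg, 1))  # noiseless synthetic frames
  thr <- bg + config$snr_threshold * noise_sd
  nr <- nrow(sm); nc <- ncol(sm)
  h <- config$roi_half_size
  cand <- which(sm > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; cl <- cand[i, 2]
    if (r <= h || r > nr - h || cl <= h || cl > nc - h) next
    nb <- sm[(r - 1):(r + 1), (cl - 1):(cl + 1)]
    keep[i] <- sm[r, cl] >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  val <- sm[cand]
  ord <- order(val, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; val <- val[ord]
  # enforce separation >= ROI size, keeping the brighter candidate
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(sel) == 0L ||
        all(pmax(abs(cand[sel, 1] - cand[i, 1]),
                 abs(cand[sel, 2] - cand[i, 2])) >= 2 * h)) {
      sel <- c(sel, i)
    }
  }
  data.frame(row = as.integer(cand[sel, 1]), col = as.integer(cand[sel, 2]),
             value = val[sel])
}

# model and weighted residuals for the 2D Gaussian spot fit
gauss2d_model <- function(par, xg, yg) {
  par["b"] + par["A"] * exp(-((xg - par["x0"])^2 + (yg - par["y0"])^2) /
                              (2 * par["sigma"]^2))
}

#' Fit a 2D Gaussian model to a spot ROI
#'
#' Weighted least squares with weights from the Poisson variance estimate
#' (`w = 1 / max(counts, 1)`), via Levenberg-Marquardt. Free parameters:
#' amplitude, center x/y, width sigma, constant background. The per-axis
#' precision estimate is the square root of the position diagonal of the
#' parameter covariance `(J' W J)^-1` at convergence.
#'
#' @param roi Numeric matrix of pixel counts (the fitting region).
#' @param initial Optional named list with starting values `x0`, `y0` (px,
#'   ROI coordinates, 0-based pixel centers), `sigma` (px).
#' @param pixel_size Pixel size in nm (used only to convert the output).
#' @return A one-row data frame: `x_px`, `y_px` (ROI pixel coordinates),
#'   `sigma_px`, `photons` (integrated), `bg` (photons/px), `precision_px`,
#'   `converged`. Positions are pixel-center based: the center of pixel (i, j)
#'   is at (j - 0.5, i - 0.5) in 0-based half-open pixel coordinates.
#' @export
fit_gaussian2d <- function(roi, initial = NULL, pixel_size = 1) {
  stopifnot(is.matrix(roi), all(is.finite(roi)))
  nr <- nrow(roi); nc <- ncol(roi)
  xg <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  yg <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
  b0 <- stats::median(roi)
  peak <- which(roi == max(roi), arr.ind = TRUE)[1, ]
  start <- c(A = max(roi) - b0,
             x0 = if (!is.null(initial$x0)) initial$x0 else peak[["col"]] - 0.5,
             y0 = if (!is.null(initial$y0)) initial$y0 else peak[["row"]] - 0.5,
             sigma = if (!is.null(initial$sigma)) initial$sigma else 1.3,
             b = b0)
  w <- 1 / pmax(roi, 1)
  sw <- sqrt(w)
  resid_fn <- function(par) as.vector(sw * (roi - gauss2d_model(par, xg, yg)))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = c(A = 0, x0 = -1, y0 = -1, sigma = 0.3, b = 0),
                       upper = c(A = Inf, x0 = nc + 1, y0 = nr + 1,
                                 sigma = max(nr, nc), b = Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fail <- data.frame(x_px = NA_real_, y_px = NA_real_, sigma_px = NA_real_,
                     photons = NA_real_, bg = NA_real_,
                     precision_px = NA_real_, converged = FALSE)
  if (is.null(fit) || fit$info %in% c(0, 5, 9)) return(fail)
  par <- fit$par
  # covariance of the weighted LS estimate; hessian = J'WJ at convergence
  cov <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0))
    return(fail)
  prec <- sqrt(mean(diag(cov)[c("x0", "y0")]))
  data.frame(x_px = par[["x0"]], y_px = par[["y0"]],
             sigma_px = par[["sigma"]],
             photons = 2 * pi * par[["A"]] * par[["sigma"]]^2,
             bg = par[["b"]], precision_px = prec, converged = TRUE)
}

#' Localize all blinks in a frame stack
#'
#' Runs [detect_spots()] and [fit_gaussian2d()] on every frame and assembles a
#' localization table in nm. Non-converged fits are dropped (counted in the
#' `n_failed` attribute).
#'
#' @param stack A `frame_stack`.
#' @param config A [detection_config()].
#' @return A `localization_table`: data frame with columns `frame` (0-based),
#'   `x_nm`, `y_nm`, `sigma_nm`, `photons`, `bg`, `precision_nm`, sorted by
#'   frame, with attributes `frame_time` and `pixel_size`.
#' @export
localize_stack <- function(stack, config = detection_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  h <- config$roi_half_size
  p <- stack$pixel_size
  n_frames <- dim(stack$pixels)[1]
  rows <- vector("list", n_frames)
  n_failed <- 0L
  for (f in seq_len(n_frames)) {
    frame <- stack$pixels[f, , ]
    spots <- detect_spots(frame, config)
    if (nrow(spots) == 0L) next
    fits <- vector("list", nrow(spots))
    for (s in seq_len(nrow(spots))) {
      r <- spots$row[s]; cl <- spots$col[s]
      roi <- frame[(r - h):(r + h), (cl - h):(cl + h)]
      fit <- fit_gaussian2d(roi)
      if (!fit$converged || fit$photons <= 0 || fit$precision_px <= 0) {
        n_failed <- n_failed + 1L
        next
      }
      fits[[s]] <- data.frame(
        frame = f - 1L,
        x_nm = (cl - 1L - h + fit$x_px) * p,
        y_nm = (r - 1L - h + fit$y_px) * p,
        sigma_nm = fit$sigma_px * p,
        photons = fit$photons, bg = fit$bg,
        precision_nm = fit$precision_px * p)
    }
    rows[[f]] <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab))
    tab <- data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                      sigma_nm = numeric(0), photons = numeric(0),
                      bg = numeric(0), precision_nm = numeric(0))
  rownames(tab) <- NULL
  localization_table(tab, frame_time = stack$frame_time, pixel_size = p,
                     n_failed = n_failed)
}

#' Construct a localization table
#'
#' @param tab Data frame with columns `frame`, `x_nm`, `y_nm`, `sigma_nm`,
#'   `photons`, `bg`, `precision_nm`.
#' @param frame_time Seconds per frame.
#' @param pixel_size Camera pixel size in nm.
#' @param n_failed Number of dropped (non-converged) fits.
#' @return The table, sorted by frame, with class `localization_table`.
#' @export
localization_table <- function(tab, frame_time = NA_real_,
                               pixel_size = NA_real_, n_failed = 0L) {
  need <- c("frame", "x_nm", "y_nm", "sigma_nm", "photons", "bg",
            "precision_nm")
  stopifnot(all(need %in% names(tab)))
  tab <- tab[order(tab$frame), need, drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, frame_time = frame_time, pixel_size = pixel_size,
            n_failed = n_failed,
            class = c("localization_table", "data.frame"))
}

#' Link per-frame localizations into binding events
#'
#' Localizations in consecutive frames (allowing up to `link_max_gap` missed
#' frames) within `link_radius` of an open event are merged into that event.
#' Every localization belongs to exactly one event.
#'
#' @param table A `localization_table`.
#' @param config A [detection_config()].
#' @return Data frame with one row per event: `event_id`, `start_frame`,
#'   `end_frame`, `x_nm`, `y_nm` (mean position), `n_locs`, `photons`
#'   (total), `precision_nm` (mean).
#' @export
link_events <- function(table, config = detection_config()) {
  stopifnot(is.data.frame(table))
  n <- nrow(table)
  if (n == 0L)
    return(data.frame(event_id = integer(0), start_frame = integer(0),
                      end_frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), n_locs = integer(0),
                      photons = numeric(0), precision_nm = numeric(0)))
  ord <- order(table$frame)
  fr <- table$frame[ord]; x <- table$x_nm[ord]; y <- table$y_nm[ord]
  ph <- table$photons[ord]; pr <- table$precision_nm[ord]
  ev_id <- integer(n)
  open_id <- integer(0); open_last <- integer(0)
  open_x <- numeric(0); open_y <- numeric(0)
  next_id <- 0L
  for (i in seq_len(n)) {
    live <- fr[i] - open_last <= config$link_max_gap + 1L & open_last < fr[i]
    assigned <- FALSE
    if (any(live)) {
      cand <- which(live)
      d2 <- (open_x[cand] - x[i])^2 + (open_y[cand] - y[i])^2
      j <- cand[which.min(d2)]
      if (d2[which.min(d2)] <= config$link_radius^2) {
        ev_id[i] <- open_id[j]
        open_last[j] <- fr[i]; open_x[j] <- x[i]; open_y[j] <- y[i]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      next_id <- next_id + 1L
      ev_id[i] <- next_id
      open_id <- c(open_id, next_id); open_last <- c(open_last, fr[i])
      open_x <- c(open_x, x[i]); open_y <- c(open_y, y[i])
    }
    # drop events that can no longer be extended
    stale <- fr[i] - open_last > config$link_max_gap + 1L
    if (any(stale)) {
      open_id <- open_id[!stale]; open_last <- open_last[!stale]
      open_x <- open_x[!stale]; open_y <- open_y[!stale]
    }
  }
  grp <- factor(ev_id, levels = sort(unique(ev_id)))
  agg <- function(v, f) as.vector(tapply(v, grp, f))
  out <- data.frame(event_id = sort(unique(ev_id)),
                    start_frame = agg(fr, min), end_frame = agg(fr, max),
                    x_nm = agg(x, mean), y_nm = agg(y, mean),
                    n_locs = agg(rep(1L, n), sum), photons = agg(ph, sum),
                    precision_nm = agg(pr, mean))
  out[order(out$start_frame), , drop = FALSE]
}

#' Write / read localization tables as CSV
#'
#' Fixed header: `frame,x_nm,y_nm,sigma_nm,photons,bg,precision_nm`.
#'
#' @param table A `localization_table`.
#' @param path File path.
#' @param frame_time,pixel_size Metadata restored on read.
#' @return `read_localizations_csv` returns a `localization_table`.
#' @export
write_localizations_csv <- function(table, path) {
  cols <- c("frame", "x_nm", "y_nm", "sigma_nm", "photons", "bg",
            "precision_nm")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations_csv
#' @export
read_localizations_csv <- function(path, frame_time = NA_real_,
                                   pixel_size = NA_real_) {
  localization_table(utils::read.csv(path), frame_time = frame_time,
                     pixel_size = pixel_size)
}
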