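#' Fourier Ring Correlation configuration
#'
#' @param block_size Frames per alternating block when splitting a series
#'   into two statistically independent halves.
#' @param render_pixel Rendering pixel size in nm.
#' @param threshold Fixed FRC threshold (resolution read at the crossing).
#' @param tile_size Tile edge length in nm for resolution maps.
#' @param render_sigma Fallback rendering Gaussian SD in nm, used when the
#'   table carries no per-localization precision or `use_precision = FALSE`.
#' @param use_precision Render each localization with its own precision
#'   estimate as Gaussian SD when available.
#' @param min_locs Minimum localizations per tile; tiles below are flagged.
#' @return An object of class `frc_config`.
#' @export
frc_config <- function(block_size = 100L, render_pixel = 5, threshold = 1 / 7,
                       tile_size = 2000, render_sigma = 5,
                       use_precision = TRUE, min_locs = 50L) {
  stopifnot(block_size >= 1, render_pixel > 0, threshold > 0, threshold < 1,
            tile_size > 0, render_sigma > 0, min_locs >= 1)
  structure(list(block_size = as.integer(block_size),
                 render_pixel = render_pixel, threshold = threshold,
                 tile_size = tile_size, render_sigma = render_sigma,
                 use_precision = use_precision,
                 min_locs = as.integer(min_locs)),
            class = "frc_config")
}

#' Split a localization table into alternating frame blocks
#'
#' Localizations whose block index `floor(frame / block_size)` is even go to
#' half A, odd to half B; every localization lands in exactly one half.
#'
#' @param table Localization table (needs a `frame` column).
#' @param block_size Frames per block.
#' @return List with data frames `A` and `B`.
#' @export
split_alternating <- function(table, block_size = 100L) {
  stopifnot(is.data.frame(table), block_size >= 1)
  parity <- (floor(table$frame / block_size)) %% 2
  list(A = table[parity == 0, , drop = FALSE],
       B = table[parity == 1, , drop = FALSE])
}

gaussian_kernel_1d <- function(sigma_px, half) {
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k / sum(k)
}

#' Render localizations as a Gaussian-blurred image
#'
#' Each localization contributes a unit-integral 2D Gaussian. The SD is the
#' per-localization precision estimate when present and
#' `use_precision = TRUE`, else the fixed `sigma`. The image integral equals
#' the number of rendered localizations (up to < 0.1% kernel truncation).
#'
#' @param table Data frame with `x_nm`, `y_nm` (and optionally
#'   `precision_nm`).
#' @param pixel Rendering pixel size, nm.
#' @param sigma Fixed rendering SD, nm.
#' @param extent Numeric length-4 `c(x0, x1, y0, y1)` in nm; localizations
#'   outside are dropped. Defaults to the data bounding box padded by 5
#'   sigma.
#' @param use_precision See [frc_config()].
#' @return Numeric matrix (rows = y, cols = x) with attributes `pixel` and
#'   `extent`; flagged with attribute `empty = TRUE` for an empty table.
#' @export
render_gaussian <- function(table, pixel = 5, sigma = 5, extent = NULL,
                            use_precision = TRUE) {
  stopifnot(pixel > 0, sigma > 0)
  sig <- rep(sigma, nrow(table))
  if (use_precision && "precision_nm" %in% names(table)) {
    ok <- is.finite(table$precision_nm) & table$precision_nm > 0
    sig[ok] <- table$precision_nm[ok]
  }
  if (is.null(extent)) {
    if (nrow(table) == 0L) extent <- c(0, pixel, 0, pixel)
    else {
      pad <- 5 * max(sig, 1)
      extent <- c(min(table$x_nm) - pad, max(table$x_nm) + pad,
                  min(table$y_nm) - pad, max(table$y_nm) + pad)
    }
  }
  nc <- max(1L, ceiling((extent[2] - extent[1]) / pixel))
  nr <- max(1L, ceiling((extent[4] - extent[3]) / pixel))
  img <- matrix(0, nr, nc)
  if (nrow(table) == 0L) {
    attr(img, "empty") <- TRUE
    attr(img, "pixel") <- pixel
    attr(img, "extent") <- extent
    return(img)
  }
  inx <- table$x_nm >= extent[1] & table$x_nm < extent[2] &
    table$y_nm >= extent[3] & table$y_nm < extent[4]
  x <- (table$x_nm[inx] - extent[1]) / pixel
  y <- (table$y_nm[inx] - extent[3]) / pixel
  s <- sig[inx] / pixel
  for (i in seq_along(x)) {
    half <- max(2L, ceiling(4 * s[i]))
    j0 <- floor(x[i]) - half; j1 <- floor(x[i]) + half
    i0 <- floor(y[i]) - half; i1 <- floor(y[i]) + half
    jj <- max(0L, j0):min(nc - 1L, j1)
    ii <- max(0L, i0):min(nr - 1L, i1)
    if (length(jj) == 0L || length(ii) == 0L) next
    fx <- stats::pnorm(jj + 1, x[i], s[i]) - stats::pnorm(jj, x[i], s[i])
    fy <- stats::pnorm(ii + 1, y[i], s[i]) - stats::pnorm(ii, y[i], s[i])
    img[ii + 1L, jj + 1L] <- img[ii + 1L, jj + 1L] + outer(fy, fx)
  }
  attr(img, "pixel") <- pixel
  attr(img, "extent") <- extent
  attr(img, "n_locs") <- sum(inx)
  img
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Fourier Ring Correlation curve of two images
#'
#' Correlation per spatial-frequency ring of the discrete Fourier transforms:
#' `Re <F_A conj(F_B)>_ring / sqrt(<|F_A|^2>_ring <|F_B|^2>_ring)`, with rings
#' one frequency sample wide. Images are zero-padded to a common
#' power-of-two square before the transform.
#'
#' @param img_a,img_b Equal-shape numeric matrices rendered on the same grid.
#' @param pixel Pixel size in nm (taken from `img_a`'s attribute when absent).
#' @return An object of class `frc_curve`: data frame with `freq` (1/nm,
#'   ascending) and `frc` (clamped to \[-1, 1\]).
#' @export
frc_curve <- function(img_a, img_b, pixel = NULL) {
  if (!all(dim(img_a) == dim(img_b)))
    stop("image shapes differ: ", paste(dim(img_a), collapse = "x"), " vs ",
         paste(dim(img_b), collapse = "x"))
  if (is.null(pixel)) pixel <- attr(img_a, "pixel")
  stopifnot(is.numeric(pixel), pixel > 0)
  n <- next_pow2(max(dim(img_a)))
  pad <- function(m) {
    out <- matrix(0, n, n)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  fa <- stats::fft(pad(img_a))
  fb <- stats::fft(pad(img_b))
  kx <- c(0:(n / 2), -((n / 2 - 1):1))
  ring <- round(sqrt(outer(kx^2, kx^2, "+")))
  rmax <- n %/% 2
  idx <- ring <= rmax
  rf <- factor(ring[idx], levels = 0:rmax)
  num <- as.vector(tapply(Re(fa[idx] * Conj(fb[idx])), rf, sum))
  da <- as.vector(tapply(Mod(fa[idx])^2, rf, sum))
  db <- as.vector(tapply(Mod(fb[idx])^2, rf, sum))
  den <- sqrt(da * db)
  corr <- ifelse(den > 0, num / den, 0)
  corr <- pmin(1, pmax(-1, corr))
  structure(data.frame(freq = (0:rmax) / (n * pixel), frc = corr),
            class = c("frc_curve", "data.frame"),
            pixel = pixel, n_fft = n)
}

#' FRC resolution at the fixed-threshold crossing
#'
#' The resolution is the inverse of the spatial frequency where the curve
#' first drops below the threshold (default 1/7), with linear interpolation
#' between frequency samples. Returns at least twice the rendering pixel
#' (Nyquist); `NA` with attribute `unresolved = TRUE` when the curve never
#' crosses.
#'
#' @param curve An [frc_curve()] result.
#' @param threshold Crossing threshold.
#' @return Resolution in nm, or `NA` (unresolved).
#' @export
frc_resolution <- function(curve, threshold = 1 / 7) {
  stopifnot(inherits(curve, "frc_curve"), threshold > 0, threshold < 1)
  fr <- curve$frc; fq <- curve$freq
  below <- which(fr < threshold & seq_along(fr) > 1L)
  if (length(below) == 0L) {
    out <- NA_real_
    attr(out, "unresolved") <- TRUE
    return(out)
  }
  i <- below[1]
  f0 <- fq[i - 1]; f1 <- fq[i]
  c0 <- fr[i - 1]; c1 <- fr[i]
  fc <- if (c0 == c1) f1 else f0 + (c0 - threshold) * (f1 - f0) / (c0 - c1)
  max(1 / fc, 2 * attr(curve, "pixel"))
}

#' Tiled FRC resolution map
#'
#' Splits the field into square tiles, renders the two half-datasets per
#' tile, and reports the per-tile FRC resolution. Tiles with fewer than
#' `min_locs` localizations are flagged (`NA` resolution).
#'
#' @param table Localization table.
#' @param config An [frc_config()].
#' @param extent Optional field extent `c(x0, x1, y0, y1)` in nm.
#' @return An object of class `frc_map`: list with `tiles` (data frame
#'   `tile_x`, `tile_y`, `resolution_nm`, `n_locs`), `mean_resolution`,
#'   `sem_resolution`.
#' @export
frc_map <- function(table, config = frc_config(), extent = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(extent))
    extent <- c(min(table$x_nm), max(table$x_nm),
                min(table$y_nm), max(table$y_nm))
  ts <- config$tile_size
  nx <- max(1L, ceiling((extent[2] - extent[1]) / ts))
  ny <- max(1L, ceiling((extent[4] - extent[3]) / ts))
  rows <- list()
  for (iy in seq_len(ny) - 1L) {
    for (ix in seq_len(nx) - 1L) {
      x0 <- extent[1] + ix * ts; y0 <- extent[3] + iy * ts
      sub <- table[table$x_nm >= x0 & table$x_nm < x0 + ts &
                     table$y_nm >= y0 & table$y_nm < y0 + ts, , drop = FALSE]
      res <- NA_real_
      if (nrow(sub) >= config$min_locs) {
        halves <- split_alternating(sub, config$block_size)
        te <- c(x0, x0 + ts, y0, y0 + ts)
        img_a <- render_gaussian(halves$A, config$render_pixel,
                                 config$render_sigma, te, config$use_precision)
        img_b <- render_gaussian(halves$B, config$render_pixel,
                                 config$render_sigma, te, config$use_precision)
        res <- frc_resolution(frc_curve(img_a, img_b), config$threshold)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(tile_x = ix, tile_y = iy, resolution_nm = as.numeric(res),
                   n_locs = nrow(sub))
    }
  }
  tiles <- do.call(rbind, rows)
  ok <- is.finite(tiles$resolution_nm)
  structure(list(tiles = tiles,
                 mean_resolution = if (any(ok)) mean(tiles$resolution_nm[ok]) else NA_real_,
                 sem_resolution = if (sum(ok) > 1)
                   stats::sd(tiles$resolution_nm[ok]) / sqrt(sum(ok)) else NA_real_),
            class = "frc_map")
}

#' @export
print.frc_map <- function(x, ...) {
  cat(sprintf("<frc_map> %d tiles, mean resolution %.1f +/- %.1f nm (SEM)\n",
              nrow(x$tiles), x$mean_resolution, x$sem_resolution))
  invisible(x)
}

#' Write an FRC map as CSV
#'
#' @param map An `frc_map`.
#' @param path Output CSV path.
#' @export
write_frc_map_csv <- function(map, path) {
  stopifnot(inherits(map, "frc_map"))
  utils::write.csv(map$tiles, path, row.names = FALSE)
  invisible(path)
}
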