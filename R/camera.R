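#' Microscope optics model
#'
#' @param wavelength Emission wavelength in nm.
#' @param numerical_aperture Objective NA (0 < NA < 2).
#' @param pixel_size Camera pixel size in sample space, nm. The default
#'   108 nm corresponds to a 60x objective with a 6.5 um camera pixel.
#' @param psf_kind `"airy"` (diffraction-limited Airy disk) or `"gaussian"`
#'   (Gaussian of matched FWHM).
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(wavelength = 700, numerical_aperture = 1.45,
                         pixel_size = 108, psf_kind = c("airy", "gaussian")) {
  psf_kind <- match.arg(psf_kind)
  stopifnot(wavelength > 0, pixel_size > 0)
  if (!(numerical_aperture > 0 && numerical_aperture < 2))
    stop("numerical aperture must lie in (0, 2)")
  structure(list(wavelength = wavelength,
                 numerical_aperture = numerical_aperture,
                 pixel_size = pixel_size, psf_kind = psf_kind),
            class = "optics_model")
}

#' Camera noise and background model
#'
#' Pixel values are in photons (unit gain). The mean diffuse background per
#' pixel per frame is `offset + bg_coeff * [I] + oof_coeff * site_rate_density`:
#' the free-imager term grows linearly with imager concentration while the
#' out-of-focus term is proportional to the specific event rate per area and
#' is therefore invariant when an N-repeat motif is imaged at `[I] / N`.
#'
#' @param photon_rate Detected photons per second from one bound dye.
#' @param bg_coeff Free-imager background coefficient `beta`,
#'   photons/pixel/frame per molar.
#' @param oof_coeff Out-of-focus background coefficient `kappa`,
#'   photons/pixel/frame per (specific events/s/um^2).
#' @param offset Constant camera offset, photons/pixel/frame.
#' @param read_noise_sd Gaussian read noise SD, photons.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_rate = 30000, bg_coeff = 0, oof_coeff = 0,
                        offset = 0, read_noise_sd = 0) {
  stopifnot(photon_rate >= 0, bg_coeff >= 0, oof_coeff >= 0, offset >= 0,
            read_noise_sd >= 0)
  structure(list(photon_rate = photon_rate, bg_coeff = bg_coeff,
                 oof_coeff = oof_coeff, offset = offset,
                 read_noise_sd = read_noise_sd),
            class = "noise_model")
}

#' Radial point-spread-function profile
#'
#' For the Airy kind the normalized intensity is `(2 J1(v) / v)^2` with
#' `v = (2 pi / lambda) * NA * r`; the profile is normalized to unit total
#' intensity over the plane. The FWHM (~0.51 lambda/NA) and the radius of the
#' first minimum (~0.61 lambda/NA, first zero of J1 at v = 3.8317) are located
#' numerically from the profile. The Gaussian kind matches the Airy FWHM and
#' has no first minimum (`first_minimum = NA`).
#'
#' @param optics An [optics_model()].
#' @return Object of class `psf_profile` with fields `intensity` (a function
#'   of radius in nm returning the areal density, 1/nm^2), `fwhm`,
#'   `first_minimum` (nm, `NA` for the Gaussian kind), `kind`, `wavelength`,
#'   `numerical_aperture`.
#' @examples
#' psf <- psf_profile(optics_model(700, 1.45))
#' psf$fwhm          # ~248 nm
#' psf$first_minimum # ~294 nm
#' @export
psf_profile <- function(optics) {
  stopifnot(inherits(optics, "optics_model"))
  lam <- optics$wavelength
  na <- optics$numerical_aperture
  k <- 2 * pi * na / lam
  if (optics$psf_kind == "airy") {
    shape <- function(r) {
      v <- k * r
      out <- rep(1, length(v))
      nz <- v != 0
      out[nz] <- (2 * besselJ(v[nz], 1) / v[nz])^2
      out
    }
    # integral of (2 J1(v)/v)^2 over the plane is 4*pi/k^2
    norm <- k^2 / (4 * pi)
    # half maximum and first zero of J1 by root finding on the shape
    r_half <- stats::uniroot(function(r) shape(r) - 0.5,
                             c(1e-9, 0.5 * lam / na), tol = 1e-12)$root
    v1 <- stats::uniroot(function(v) besselJ(v, 1),
                         c(3, 4.5), tol = 1e-12)$root
    first_min <- v1 / k
    fwhm <- 2 * r_half
    intensity <- function(r) norm * shape(r)
  } else {
    airy <- psf_profile(optics_model(lam, na, optics$pixel_size, "airy"))
    fwhm <- airy$fwhm
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    intensity <- function(r) exp(-r^2 / (2 * sigma^2)) / (2 * pi * sigma^2)
    first_min <- NA_real_
  }
  structure(list(kind = optics$psf_kind, wavelength = lam,
                 numerical_aperture = na, intensity = intensity,
                 fwhm = fwhm, first_minimum = first_min),
            class = "psf_profile")
}

#' @export
print.psf_profile <- function(x, ...) {
  cat(sprintf("<psf_profile> %s, lambda = %g nm, NA = %g, FWHM = %.2f nm, first minimum = %s\n",
              x$kind, x$wavelength, x$numerical_aperture, x$fwhm,
              if (is.na(x$first_minimum)) "absent" else sprintf("%.2f nm", x$first_minimum)))
  invisible(x)
}

# Gaussian sigma (px) matching the optics' PSF FWHM, for pixel-integrated
# rendering and as the initial width guess in fitting.
psf_sigma_px <- function(optics) {
  psf_profile(optics)$fwhm / (2 * sqrt(2 * log(2))) / optics$pixel_size
}

# expected photon pattern of one emitter: pixel-integrated over the patch
# [rows x cols], positions in px units (0-based, half-open pixel convention)
emitter_patch <- function(x_px, y_px, sigma_px, photons, nrow, ncol,
                          radius_px) {
  i0 <- max(0L, floor(y_px - radius_px)); i1 <- min(nrow - 1L, ceiling(y_px + radius_px))
  j0 <- max(0L, floor(x_px - radius_px)); j1 <- min(ncol - 1L, ceiling(x_px + radius_px))
  if (i0 > i1 || j0 > j1) return(NULL)
  jj <- j0:j1; ii <- i0:i1
  fx <- stats::pnorm(jj + 1, x_px, sigma_px) - stats::pnorm(jj, x_px, sigma_px)
  fy <- stats::pnorm(ii + 1, y_px, sigma_px) - stats::pnorm(ii, y_px, sigma_px)
  list(rows = ii + 1L, cols = jj + 1L, patch = photons * outer(fy, fx))
}

#' Render binding events into a noisy camera movie
#'
#' Forward model: an event contributes `photon_rate * overlap` expected
#' photons to each frame it overlaps (pro-rata across frame boundaries, no
#' blinking within an event), distributed over pixels by integrating a
#' Gaussian PSF of the optics' FWHM over pixel areas. The mean background is
#' `offset + bg_coeff * [I] + oof_coeff * site_rate_density`. Pixel values are
#' `Poisson(signal + background) + Normal(0, read_noise_sd)`, rounded and
#' clipped at zero. Events outside the field of view are clipped silently and
#' counted in the metadata.
#'
#' @param events Event data frame ([simulate_specific()] format).
#' @param optics An [optics_model()].
#' @param noise A [noise_model()].
#' @param config A [kinetic_config()] (duration, frame time, `[I]`).
#' @param field_px Integer length-2, field size in pixels (rows, cols).
#' @param site_rate_density Specific event rate per area (events/s/um^2)
#'   driving the out-of-focus background term.
#' @return An object of class `frame_stack`: list with `pixels`
#'   (frames x rows x cols array of counts), `frame_time`, `pixel_size`,
#'   `metadata`.
#' @export
render_frames <- function(events, optics, noise, config,
                          field_px = c(64L, 64L), site_rate_density = 0) {
  stopifnot(inherits(optics, "optics_model"), inherits(noise, "noise_model"),
            inherits(config, "kinetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ft <- config$frame_time
  n_frames <- as.integer(ceiling(config$duration / ft))
  nr <- as.integer(field_px[1]); nc <- as.integer(field_px[2])
  p <- optics$pixel_size
  bg <- noise$offset + noise$bg_coeff * config$imager_conc +
    noise$oof_coeff * site_rate_density
  mean_img <- array(bg, dim = c(n_frames, nr, nc))
  sigma_px <- psf_sigma_px(optics)
  radius_px <- ceiling(5 * sigma_px)
  n_clipped <- 0L
  if (nrow(events) > 0) {
    for (e in seq_len(nrow(events))) {
      x_px <- events$x_nm[e] / p
      y_px <- events$y_nm[e] / p
      if (x_px < -radius_px || x_px > nc + radius_px ||
          y_px < -radius_px || y_px > nr + radius_px) {
        n_clipped <- n_clipped + 1L
        next
      }
      f0 <- max(0L, floor(events$t_start[e] / ft))
      f1 <- min(n_frames - 1L, floor(min(events$t_end[e], config$duration - 1e-12) / ft))
      if (f0 > f1) next
      for (f in f0:f1) {
        overlap <- min(events$t_end[e], (f + 1) * ft) -
          max(events$t_start[e], f * ft)
        if (overlap <= 0) next
        pat <- emitter_patch(x_px, y_px, sigma_px,
                             noise$photon_rate * overlap, nr, nc, radius_px)
        if (!is.null(pat))
          mean_img[f + 1L, pat$rows, pat$cols] <-
            mean_img[f + 1L, pat$rows, pat$cols] + pat$patch
      }
    }
  }
  counts <- stats::rpois(length(mean_img), mean_img)
  if (noise$read_noise_sd > 0)
    counts <- counts + stats::rnorm(length(counts), 0, noise$read_noise_sd)
  pixels <- array(pmax(0, round(counts)), dim = dim(mean_img))
  structure(list(pixels = pixels, frame_time = ft, pixel_size = p,
                 metadata = list(seed = config$seed,
                                 imager_conc = config$imager_conc,
                                 duration = config$duration,
                                 field_px = c(nr, nc),
                                 background_mean = bg,
                                 n_events = nrow(events),
                                 n_clipped = n_clipped)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame_stack> %d frames of %dx%d px, %.0f nm/px, %.3g s/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_time))
  invisible(x)
}

#' Write / read a frame stack as multi-page 16-bit TIFF
#'
#' Pixel data round-trips bit-exactly; frame time, pixel size and provenance
#' metadata are stored in a JSON sidecar file (`<path>.json`).
#'
#' @param stack A `frame_stack`.
#' @param path Output TIFF path.
#' @return `read_tiff_stack` returns the reconstructed `frame_stack`.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$pixels)
  if (is.null(d) || d[1] == 0L) stop("refusing to write an empty frame stack")
  if (any(stack$pixels < 0) || any(stack$pixels > 65535))
    stop("pixel values outside the 16-bit range [0, 65535]; not writing")
  pages <- lapply(seq_len(d[1]), function(f)
    matrix(stack$pixels[f, , ] / 65535, nrow = d[2], ncol = d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(stack$metadata,
            list(frame_time = stack$frame_time, pixel_size = stack$pixel_size,
                 n_frames = d[1]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("malformed TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (length(pages) == 0L) stop("TIFF '", path, "' contains no frames")
  for (f in seq_along(pages)) {
    if (!is.matrix(pages[[f]]))
      stop("malformed TIFF '", path, "': frame ", f, " is not a single plane")
  }
  d <- dim(pages[[1]])
  pixels <- array(0, dim = c(length(pages), d[1], d[2]))
  for (f in seq_along(pages)) pixels[f, , ] <- round(pages[[f]] * 65535)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(list(pixels = pixels,
                 frame_time = meta$frame_time %||% NA_real_,
                 pixel_size = meta$pixel_size %||% NA_real_,
                 metadata = meta),
            class = "frame_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
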