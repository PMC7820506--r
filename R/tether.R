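#' Tether geometry of an imager bound to an N-repeat docking motif
#'
#' Coarse polymer surrogate for the docking-imager complex: the unhybridized
#' repeat domains between the surface anchor and the bound domain form a
#' freely jointed chain (FJC) of single-stranded DNA, the bound domain plus
#' imager form a rigid 9-bp duplex rod, and the fluorophore sits at the rod
#' end distal to the anchor. Domains distal to the bound one dangle beyond
#' the fluorophore and are ignored.
#'
#' @param n_domains Number of repeat domains N of the motif.
#' @param bound_domain 0-based index of the domain the imager occupies
#'   (0 = proximal to the anchor, `n_domains - 1` = most distal).
#' @param nt_per_domain Nucleotides per repeat domain.
#' @param ss_contour_per_nt ssDNA contour length per nucleotide, nm.
#' @param ss_kuhn ssDNA Kuhn length, nm.
#' @param ds_rise_per_bp dsDNA rise per base pair, nm (rod length =
#'   `nt_per_domain * ds_rise_per_bp`).
#' @return An object of class `tether_geometry`.
#' @export
tether_geometry <- function(n_domains, bound_domain, nt_per_domain = 9L,
                            ss_contour_per_nt = 0.63, ss_kuhn = 1.8,
                            ds_rise_per_bp = 0.34) {
  stopifnot(n_domains >= 1, bound_domain >= 0, bound_domain < n_domains,
            nt_per_domain >= 1, ss_contour_per_nt > 0, ss_kuhn > 0,
            ds_rise_per_bp > 0)
  structure(list(n_domains = as.integer(n_domains),
                 bound_domain = as.integer(bound_domain),
                 nt_per_domain = as.integer(nt_per_domain),
                 ss_contour_per_nt = ss_contour_per_nt, ss_kuhn = ss_kuhn,
                 ds_rise_per_bp = ds_rise_per_bp),
            class = "tether_geometry")
}

uniform_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Sample fluorophore positions under the tether model
#'
#' Builds the chain from the anchor at the origin: the flexible part
#' (`bound_domain * nt_per_domain` nucleotides) as FJC links of the Kuhn
#' length (a shorter final link carries the remaining contour), then the
#' rigid duplex rod with uniform random orientation. The coverslip surface is
#' modeled as a reflecting half-space at z = 0 (`z -> |z|`), which leaves the
#' x-y projection — the quantity imaged by the microscope — unchanged.
#'
#' @param geometry A [tether_geometry()].
#' @param n_samples Number of configurations (warning below 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @param half_space Apply the reflecting surface at z = 0 (set `FALSE` for
#'   free-chain checks against the FJC closed form).
#' @return `n_samples x 3` matrix of fluorophore positions in nm, with the
#'   flexible-chain endpoint positions in attribute `chain_end`.
#' @export
sample_fluorophore <- function(geometry, n_samples = 1e5, seed = NULL,
                               half_space = TRUE) {
  stopifnot(inherits(geometry, "tether_geometry"), n_samples >= 1)
  if (n_samples < 1e3) warning("fewer than 1000 samples: distributions will be noisy")
  if (!is.null(seed)) set.seed(seed)
  n_nt <- geometry$bound_domain * geometry$nt_per_domain
  contour <- n_nt * geometry$ss_contour_per_nt
  b <- geometry$ss_kuhn
  n_links <- floor(contour / b)
  partial <- contour - n_links * b
  end <- matrix(0, n_samples, 3)
  for (i in seq_len(n_links)) end <- end + b * uniform_directions(n_samples)
  if (partial > 1e-12) end <- end + partial * uniform_directions(n_samples)
  rod <- geometry$nt_per_domain * geometry$ds_rise_per_bp
  fluor <- end + rod * uniform_directions(n_samples)
  if (half_space) fluor[, 3] <- abs(fluor[, 3])
  attr(fluor, "chain_end") <- end
  attr(fluor, "rod_length") <- rod
  fluor
}

#' Radially averaged 2D distribution of sampled positions
#'
#' Projects positions onto the x-y (focal) plane and radially averages. Two
#' densities are reported: the areal density `density` (1/nm^2, normalized so
#' that its integral against `2 pi r dr` is 1) and the radial probability
#' density `radial_density` (= `2 pi r * density`, 1/nm, integrating to 1 in
#' `dr`) whose mode is the "peak" of the distribution.
#'
#' @param positions Matrix with x, y in the first two columns.
#' @param bin_width Radial bin width in nm.
#' @param r_max Outer radius; defaults to the maximum sample radius.
#' @return An object of class `radial_distribution`: data frame with `r`
#'   (bin centers), `density`, `radial_density`, `counts`; attributes
#'   `n_samples`, `bin_width`.
#' @export
radial_distribution <- function(positions, bin_width = 0.25, r_max = NULL) {
  stopifnot(is.matrix(positions), ncol(positions) >= 2, bin_width > 0)
  r <- sqrt(positions[, 1]^2 + positions[, 2]^2)
  n <- length(r)
  if (is.null(r_max)) r_max <- max(r) + bin_width
  breaks <- seq(0, r_max + bin_width, by = bin_width)
  cnt <- graphics::hist(pmin(r, r_max), breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  area <- pi * (breaks[-1]^2 - breaks[-length(breaks)]^2)
  dens <- cnt / (n * area)
  structure(data.frame(r = mids, density = dens,
                       radial_density = cnt / (n * bin_width),
                       counts = cnt),
            class = c("radial_distribution", "data.frame"),
            n_samples = n, bin_width = bin_width)
}

#' Peak radius of a radial distribution
#'
#' Bin center of maximum radial probability density (the mode of the
#' distribution of projected radial distances).
#'
#' @param dist A [radial_distribution()].
#' @return Radius in nm.
#' @export
radial_peak <- function(dist) {
  stopifnot(inherits(dist, "radial_distribution"))
  dist$r[which.max(dist$radial_density)]
}

# build a radially symmetric square image from an areal density function of r
radial_image <- function(dens_fun, grid_nm, half_extent) {
  ax <- seq(-half_extent, half_extent, by = grid_nm)
  r <- sqrt(outer(ax^2, ax^2, "+"))
  img <- dens_fun(r)
  dim(img) <- c(length(ax), length(ax))
  img
}

radial_average_image <- function(img, grid_nm, bin_width = NULL) {
  if (is.null(bin_width)) bin_width <- grid_nm
  n <- nrow(img)
  c0 <- (n + 1) / 2
  ax <- (seq_len(n) - c0) * grid_nm
  r <- sqrt(outer(ax^2, ax^2, "+"))
  bins <- floor(r / bin_width)
  keep <- bins <= max(bins[, c0])  # stay inside the inscribed circle
  f <- factor(bins[keep])
  val <- as.vector(tapply(img[keep], f, mean))
  data.frame(r = (as.numeric(levels(f)) + 0.5) * bin_width, density = val)
}

#' Convolve a radial fluorophore distribution with the PSF
#'
#' 2D convolution of the radially symmetric fluorophore distribution with the
#' radially symmetric PSF, carried out on a square grid via FFT; the
#' convolved image is radially averaged back to a profile. Grid sampling must
#' be at most 2 nm to resolve the nanometre-scale tether distributions.
#'
#' @param dist A [radial_distribution()].
#' @param psf A [psf_profile()].
#' @param grid_nm Grid sampling in nm (<= 2).
#' @param half_extent Half-width of the convolution grid in nm; defaults to
#'   1.6x the PSF first minimum (or 2x FWHM for the Gaussian kind).
#' @return An object of class `blink_profile`: data frame with `r` (nm) and
#'   `density` (1/nm^2 areal density of detected photons), with the PSF's
#'   matching discrete profile in attribute `psf_profile_grid`.
#' @export
convolve_with_psf <- function(dist, psf, grid_nm = 1, half_extent = NULL) {
  stopifnot(inherits(dist, "radial_distribution"), inherits(psf, "psf_profile"))
  if (grid_nm > 2) stop("grid sampling above 2 nm under-resolves the distribution")
  if (is.null(half_extent)) {
    half_extent <- if (!is.na(psf$first_minimum)) 1.6 * psf$first_minimum
    else 2 * psf$fwhm
  }
  dist_fun <- function(r) {
    out <- stats::approx(dist$r, dist$density, xout = r, rule = 2)$y
    out[r > max(dist$r)] <- 0
    out
  }
  img_d <- radial_image(dist_fun, grid_nm, half_extent)
  img_p <- radial_image(psf$intensity, grid_nm, half_extent)
  # normalize the discrete distribution to unit mass; keep the PSF's own
  # discrete mass so normalization preservation can be checked downstream
  img_d <- img_d / (sum(img_d) * grid_nm^2)
  n <- nrow(img_d)
  m <- next_pow2(2 * n)
  pad <- function(x) { out <- matrix(0, m, m); out[1:n, 1:n] <- x; out }
  conv <- Re(stats::fft(stats::fft(pad(img_d)) * stats::fft(pad(img_p)),
                        inverse = TRUE)) / m^2
  conv <- conv * grid_nm^2  # discrete sum -> integral
  total_mass <- sum(conv) * grid_nm^2
  # the convolution center sits at twice the image center offset
  c0 <- (n + 1) / 2
  ctr <- 2 * (c0 - 1) + 1
  half_px <- floor((n - 1) / 2)
  sel <- (ctr - half_px):(ctr + half_px)
  conv_c <- conv[sel, sel]
  prof <- radial_average_image(conv_c, grid_nm)
  psf_prof <- radial_average_image(img_p, grid_nm)
  structure(prof, class = c("blink_profile", "data.frame"),
            psf_profile_grid = psf_prof, grid_nm = grid_nm,
            mass = total_mass,
            psf_mass = sum(img_p) * grid_nm^2)
}

# parabolic interpolation of the minimum near r0 of a discrete profile
profile_minimum <- function(r, v, r0, window = 0.25) {
  sel <- which(r > (1 - window) * r0 & r < (1 + window) * r0)
  if (length(sel) < 3) stop("profile does not cover the minimum region")
  i <- sel[which.min(v[sel])]
  if (i <= 1 || i >= length(r)) stop("minimum at profile edge")
  y0 <- v[i - 1]; y1 <- v[i]; y2 <- v[i + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (denom == 0) 0 else 0.5 * (y0 - y2) / denom
  r[i] + delta * (r[i + 1] - r[i])
}

#' Shift of the first Airy minimum caused by tether blurring
#'
#' Locates the first radial minimum of the convolved blink profile and of the
#' PSF profile discretized on the same grid (so discretization bias cancels),
#' both by parabolic interpolation around the discrete minimum near
#' 0.61 lambda / NA, and reports the relative shift in percent.
#'
#' @param profile A [convolve_with_psf()] result.
#' @param psf The [psf_profile()] used for the convolution (must be Airy).
#' @return Percent shift `100 * (r_conv - r_psf) / r_psf`.
#' @export
first_minimum_shift <- function(profile, psf) {
  stopifnot(inherits(profile, "blink_profile"), inherits(psf, "psf_profile"))
  if (is.na(psf$first_minimum))
    stop("the Gaussian PSF has no first minimum")
  r0 <- psf$first_minimum
  pg <- attr(profile, "psf_profile_grid")
  r_psf <- profile_minimum(pg$r, pg$density, r0)
  r_conv <- profile_minimum(profile$r, profile$density, r0)
  100 * (r_conv - r_psf) / r_psf
}

#' Write a radial distribution or blink profile as CSV
#'
#' Two columns: `r_nm`, `density`.
#'
#' @param x A `radial_distribution` or `blink_profile`.
#' @param path Output path.
#' @export
write_radial_csv <- function(x, path) {
  d <- data.frame(r_nm = x$r,
                  density = if ("radial_density" %in% names(x))
                    x$radial_density else x$density)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
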