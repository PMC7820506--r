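#' Default study kinetics
#'
#' Shared defaults for the scenario drivers: a 9-nt imager with
#' `k_on = 2e6 /M/s` and `tau_bright = 0.5 s` (typical published DNA-PAINT
#' values; the dissociation constant follows as 1 uM), 100 ms frames.
#'
#' @return An [imager_spec()].
#' @export
default_imager <- function() imager_spec("P1", k_on = 2e6, tau_bright = 0.5)

# lay out n sites on a square grid with the given spacing (nm)
site_grid <- function(n, n_domains, spacing = 500, origin = c(500, 500)) {
  side <- ceiling(sqrt(n))
  lapply(seq_len(n), function(i) {
    gx <- (i - 1) %% side
    gy <- (i - 1) %/% side
    docking_site(i, origin + spacing * c(gx, gy), n_domains)
  })
}

site_targets <- function(sites) {
  data.frame(target_id = vapply(sites, function(s) s$site_id, integer(1)),
             x_nm = vapply(sites, function(s) s$position[1], numeric(1)),
             y_nm = vapply(sites, function(s) s$position[2], numeric(1)))
}

#' Event-rate scaling with repeat number (microsphere-style experiment)
#'
#' Simulates targets carrying 1x, 3x and 6x repeat motifs at fixed imager
#' concentration, measures per-target event rates, and fits rate versus N.
#'
#' @param n_targets Targets per condition.
#' @param conc Imager concentration, M.
#' @param duration Acquisition, s.
#' @param motifs_per_target Docking-motif copies per target: a functionalized
#'   microsphere carries many identical motifs, so its event rate is
#'   `copies * N * k_on * [I]`.
#' @param imager An [imager_spec()].
#' @param seed RNG seed.
#' @return List with `rates` (data frame `N`, `mean_rate`, `sd_rate`),
#'   `fit` (lm of mean rate on N), `intercept_se`, `r_squared`.
#' @export
scenario_rate_vs_n <- function(n_targets = 60, conc = 50e-12, duration = 500,
                               motifs_per_target = 200,
                               imager = default_imager(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(c(1, 3, 6), function(N) {
    sites <- site_grid(n_targets, N * motifs_per_target)
    cfg <- kinetic_config(conc, duration)
    sim <- simulate_specific(sites, imager, cfg)
    asg <- assign_events(sim$events, site_targets(sites), radius = 50)
    r <- event_rate_per_target(asg, duration)
    data.frame(N = N, mean_rate = r$mean_rate, sd_rate = r$sd_rate,
               per_target = I(list(r$per_target$rate)))
  })
  rates <- do.call(rbind, out)
  fit <- stats::lm(mean_rate ~ N, data = rates)
  sm <- summary(fit)
  list(rates = rates[, c("N", "mean_rate", "sd_rate")],
       per_target = rates$per_target,
       fit = fit,
       intercept = stats::coef(fit)[["(Intercept)"]],
       intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
       r_squared = sm$r.squared)
}

#' Rate invariance under N-fold repeat with N-fold diluted imager
#'
#' Compares per-target event rates of single-domain motifs at `[I]` against
#' 10x repeat motifs at `[I] / 10`.
#'
#' @param n_targets Targets (origami tiles) per condition.
#' @param conc Imager concentration for the 1x condition, M.
#' @param duration Acquisition, s.
#' @param motifs_per_target Anchor overhangs per tile, each carrying one
#'   docking motif.
#' @param imager An [imager_spec()].
#' @param seed RNG seed.
#' @return List with `rate_1x`, `rate_10x`, `ratio`, and the per-target
#'   rates of each condition.
#' @export
scenario_n_conc_invariance <- function(n_targets = 60, conc = 0.4e-9,
                                       duration = 4000,
                                       motifs_per_target = 6,
                                       imager = default_imager(),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run <- function(N, c_i) {
    sites <- site_grid(n_targets, N * motifs_per_target)
    sim <- simulate_specific(sites, imager, kinetic_config(c_i, duration))
    asg <- assign_events(sim$events, site_targets(sites), radius = 50)
    event_rate_per_target(asg, duration)
  }
  r1 <- run(1, conc)
  r10 <- run(10, conc / 10)
  list(rate_1x = r1$mean_rate, rate_10x = r10$mean_rate,
       ratio = r10$mean_rate / r1$mean_rate,
       per_target_1x = r1$per_target$rate,
       per_target_10x = r10$per_target$rate)
}

#' Non-specific contamination prediction (analytic + simulated)
#'
#' Calibrates the non-specific rate coefficient so that the single-repeat
#' condition at `conc` carries `calib_fraction` non-specific events, then
#' predicts the contamination for a 10x repeat motif at `conc / 10` with
#' unchanged specific event rate. Optionally verifies both fractions by
#' simulating the two event streams and classifying events against the known
#' site positions.
#'
#' @param conc Reference (1x) imager concentration, M.
#' @param calib_fraction Calibration contamination at the 1x condition.
#' @param specific_rate Total specific event rate over the field, events/s.
#' @param area Field area, um^2.
#' @param simulate Also run the paired simulation check.
#' @param duration Simulated acquisition, s.
#' @param n_sites Number of specific sites carrying the rate.
#' @param seed RNG seed.
#' @return List with `gamma`, `fraction_1x`, `fraction_10x` (analytic,
#'   as fractions), and when simulated, `measured_1x`, `measured_10x`.
#' @export
scenario_nonspecific <- function(conc = 0.4e-9, calib_fraction = 0.08,
                                 specific_rate = 0.5, area = 100,
                                 simulate = TRUE, duration = 4000,
                                 n_sites = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gamma <- calibrate_nonspecific(calib_fraction, specific_rate, conc, area)
  f1 <- nonspecific_fraction(specific_rate, gamma, conc, area)
  f10 <- nonspecific_fraction(specific_rate, gamma, conc / 10, area)
  out <- list(gamma = gamma, fraction_1x = f1, fraction_10x = f10)
  if (simulate) {
    imager <- default_imager()
    measure <- function(c_i, N) {
      # per-site rate chosen so the field's total specific rate is preserved
      k_eff <- specific_rate / (n_sites * N * c_i)
      im <- imager_spec(imager$name, k_eff, imager$tau_bright)
      side_nm <- sqrt(area) * 1000
      sites <- site_grid(n_sites, N, spacing = side_nm / ceiling(sqrt(n_sites)),
                         origin = c(400, 400))
      cfg <- kinetic_config(c_i, duration,
                            nonspecific_rate_coeff = gamma,
                            nonspecific_tau = 0.15)
      ev_s <- simulate_specific(sites, imager = im, config = cfg)$events
      ev_n <- simulate_nonspecific(area, cfg)
      ev <- rbind(ev_s, ev_n)
      mean(!ev$specific)
    }
    out$measured_1x <- measure(conc, 1)
    out$measured_10x <- measure(conc / 10, 10)
  }
  out
}

#' Photoinduced site-loss experiment on origami-style tiles
#'
#' Simulates tiles of `sites_per_tile` docking sites imaged for two
#' consecutive frame windows, with per-event domain inactivation, and
#' reports the percentage of detectable sites lost between the windows.
#' The 1x condition runs at `conc`; the 10x condition runs ten 10-fold
#' slower domains at `conc / 10`, preserving the total per-site event rate.
#'
#' @param q Per-event inactivation probability (see
#'   [calibrate_inactivation()]).
#' @param n_repeats Domains per site (1 or 10).
#' @param conc Imager concentration for this condition, M.
#' @param n_tiles Number of tiles.
#' @param sites_per_tile Sites per tile.
#' @param n_frames Total frames (two equal windows).
#' @param frame_time Seconds per frame.
#' @param min_events Detection rule per window.
#' @param imager An [imager_spec()].
#' @param seed RNG seed.
#' @return A `site_loss_report` with the simulated events in attribute.
#' @export
scenario_site_loss <- function(q, n_repeats, conc, n_tiles = 300,
                               sites_per_tile = 6, n_frames = 40000,
                               frame_time = 0.1, min_events = 1,
                               imager = default_imager(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_sites <- n_tiles * sites_per_tile
  sites <- site_grid(n_sites, n_repeats, spacing = 300)
  duration <- n_frames * frame_time
  cfg <- kinetic_config(conc, duration, frame_time = frame_time,
                        inactivation_prob = q)
  sim <- simulate_specific(sites, imager, cfg)
  asg <- assign_events(sim$events, site_targets(sites), radius = 50)
  half <- n_frames / 2
  rep <- site_loss_percent(asg, list(c(0, half), c(half, n_frames)),
                           min_events = min_events, frame_time = frame_time)
  attr(rep, "events") <- sim$events
  rep
}

# discretize one tile's merged event stream and fit the dark-time CDF
tile_qpaint_index <- function(events, frame_time) {
  darks <- extract_dark_times(events, frame_time)
  fit <- fit_dark_cdf(darks)
  list(index = qpaint_index(fit), fit = fit, n_events = darks$n_events)
}

#' qPAINT counting experiment: 6-site calibration, 5-site estimation
#'
#' Simulates origami-style tiles whose sites each carry a 10x repeat motif,
#' pools each tile's binding events into one time trace, extracts dark
#' times, fits the two-exponential CDF, and computes qPAINT indices. The
#' 6-site tiles calibrate the index per site; the calibrated index
#' distribution of the 5-site tiles is summarized by its median.
#'
#' @param n_tiles_6,n_tiles_5 Number of calibration / test tiles.
#' @param sites_6,sites_5 Sites per tile in the two sets.
#' @param n_repeats Repeat domains per site.
#' @param conc Imager concentration, M.
#' @param n_frames Frames at `frame_time` each.
#' @param frame_time Seconds per frame.
#' @param imager An [imager_spec()].
#' @param seed RNG seed.
#' @return List with `calibration`, `counts` (the [count_sites()] result for
#'   the 5-site set), `indices_6`, `indices_5`, `tiles` (per-tile records).
#' @export
scenario_qpaint <- function(n_tiles_6 = 50, n_tiles_5 = 80, sites_6 = 6,
                            sites_5 = 5, n_repeats = 10, conc = 0.2e-9,
                            n_frames = 40000, frame_time = 0.1,
                            imager = default_imager(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  duration <- n_frames * frame_time
  cfg <- kinetic_config(conc, duration, frame_time = frame_time)
  run_set <- function(n_tiles, n_sites) {
    idx <- numeric(n_tiles)
    recs <- vector("list", n_tiles)
    for (tile in seq_len(n_tiles)) {
      sites <- site_grid(n_sites, n_repeats, spacing = 20,
                         origin = c(100, 100))
      sim <- simulate_specific(sites, imager, cfg)
      res <- tile_qpaint_index(sim$events, frame_time)
      idx[tile] <- res$index
      recs[[tile]] <- data.frame(target_id = tile, n_events = res$n_events,
                                 alpha = res$fit$alpha, tau_b = res$fit$tau_b,
                                 tau_d = res$fit$tau_d, index = res$index)
    }
    list(indices = idx, recs = do.call(rbind, recs))
  }
  set6 <- run_set(n_tiles_6, sites_6)
  set5 <- run_set(n_tiles_5, sites_5)
  calib <- calibrate_6site(set6$indices, n_sites = sites_6)
  counts <- count_sites(set5$indices, calib)
  tiles <- rbind(cbind(set6$recs, set = "6site"),
                 cbind(set5$recs, set = "5site"))
  tiles$sites_est <- tiles$index / calib$index_per_unit
  list(calibration = calib, counts = counts,
       indices_6 = set6$indices, indices_5 = set5$indices, tiles = tiles)
}

#' Tether-blurring analysis over all domains of 1x/3x/6x motifs
#'
#' Samples fluorophore positions for an imager bound to every domain of the
#' three motifs, radially averages, convolves with the Airy PSF, and
#' measures the first-minimum shift per case.
#'
#' @param n_samples Samples per bound-domain case.
#' @param optics An [optics_model()] (Airy kind required).
#' @param grid_nm Convolution grid sampling, nm.
#' @param seed RNG seed.
#' @return List with `cases` (data frame `n_domains`, `bound_domain`,
#'   `peak_nm`, `shift_percent`), `max_shift_percent`,
#'   `distal_6x_peak_nm`.
#' @export
scenario_tether_blur <- function(n_samples = 1e5,
                                 optics = optics_model(700, 1.45),
                                 grid_nm = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  psf <- psf_profile(optics)
  rows <- list()
  for (N in c(1, 3, 6)) {
    for (d in 0:(N - 1)) {
      geo <- tether_geometry(N, d)
      pos <- sample_fluorophore(geo, n_samples)
      dist <- radial_distribution(pos, bin_width = 0.25)
      prof <- convolve_with_psf(dist, psf, grid_nm = grid_nm)
      rows[[length(rows) + 1L]] <- data.frame(
        n_domains = N, bound_domain = d, peak_nm = radial_peak(dist),
        shift_percent = first_minimum_shift(prof, psf))
    }
  }
  cases <- do.call(rbind, rows)
  distal <- cases$n_domains == 6 & cases$bound_domain == 5
  list(cases = cases, max_shift_percent = max(cases$shift_percent),
       distal_6x_peak_nm = cases$peak_nm[distal])
}

#' Background-to-resolution chain (tissue-style comparison)
#'
#' Renders the same site structure under two imaging conditions with equal
#' specific event statistics but 10-fold different imager concentration
#' (1x RD at `[I]` versus 10x RD at `[I] / 10`), localizes both movies, and
#' compares FRC resolutions. The diffuse background scales with `[I]`, so
#' the low-concentration condition localizes better and resolves finer
#' detail.
#'
#' @param conc Imager concentration of the 1x condition, M.
#' @param n_frames Frames per condition.
#' @param frame_time Seconds per frame.
#' @param n_sites Number of sites on a grid.
#' @param bg_coeff Free-imager background coefficient, photons/px/frame/M.
#' @param seed RNG seed.
#' @return List with per-condition localization tables, FRC resolutions and
#'   mean background levels.
#' @export
scenario_background_frc <- function(conc = 0.4e-9, n_frames = 2500,
                                    frame_time = 0.1, n_sites = 48,
                                    bg_coeff = 3e11, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  optics <- optics_model()
  # boost k_on so the small field produces enough events in a short movie
  imager <- imager_spec("P1", k_on = 5e7, tau_bright = 0.5)
  noise_for <- function(c_i) noise_model(photon_rate = 20000,
                                         bg_coeff = bg_coeff, offset = 4,
                                         read_noise_sd = 1)
  # scattered sites: a broadband structure, unlike a periodic grid whose
  # spectrum is empty between lattice harmonics and breaks ring correlation
  pos <- cbind(stats::runif(n_sites, 1000, 5000),
               stats::runif(n_sites, 1000, 5000))
  bg_mean <- function(c_i) 4 + bg_coeff * c_i
  run <- function(N, c_i, snr_threshold) {
    sites <- lapply(seq_len(n_sites),
                    function(i) docking_site(i, pos[i, ], N))
    cfg <- kinetic_config(c_i, n_frames * frame_time, frame_time)
    sim <- simulate_specific(sites, imager, cfg)
    stack <- render_frames(sim$events, optics, noise_for(c_i), cfg,
                           field_px = c(56L, 56L))
    tab <- localize_stack(stack, detection_config(snr_threshold))
    halves <- split_alternating(tab, 100L)
    ext <- c(600, 5400, 600, 5400)
    fc <- frc_config(render_pixel = 2.5)
    img_a <- render_gaussian(halves$A, fc$render_pixel, fc$render_sigma, ext)
    img_b <- render_gaussian(halves$B, fc$render_pixel, fc$render_sigma, ext)
    list(table = tab,
         resolution = frc_resolution(frc_curve(img_a, img_b)),
         background = stack$metadata$background_mean,
         median_precision = stats::median(tab$precision_nm))
  }
  # the SNR-relative threshold is raised for the low-background condition so
  # both conditions detect events at the same absolute photon yield (the
  # standard adjustment when comparing across background levels)
  thr_hi <- 4
  thr_lo <- thr_hi * sqrt(bg_mean(conc) / bg_mean(conc / 10))
  hi <- run(1, conc, thr_hi)
  lo <- run(10, conc / 10, thr_lo)
  list(high_bg = hi, low_bg = lo)
}

#' Run a named end-to-end scenario
#'
#' Dispatcher over the end-to-end synthetic experiments, so every analysis
#' is reproducible from a name and a seed.
#'
#' @param name One of `"rate_vs_n"`, `"rate_invariance"`, `"background_frc"`,
#'   `"nonspecific"`, `"site_loss"`, `"tether_blur"`, `"qpaint"`.
#' @param seed RNG seed (default 1).
#' @param ... Passed to the scenario function.
#' @return The scenario result (see the individual `scenario_*` functions).
#' @export
run_scenario <- function(name, seed = 1, ...) {
  scenarios <- list(
    rate_vs_n = scenario_rate_vs_n,
    rate_invariance = scenario_n_conc_invariance,
    background_frc = scenario_background_frc,
    nonspecific = scenario_nonspecific,
    site_loss = function(seed = NULL, ...) {
      lambda <- default_imager()$k_on * 0.4e-9
      q <- calibrate_inactivation(0.121, lambda, 2000)
      list(q = q,
           loss_1x = scenario_site_loss(q, 1, 0.4e-9, seed = seed, ...),
           loss_10x = scenario_site_loss(q, 10, 0.04e-9, seed = NULL, ...))
    },
    tether_blur = scenario_tether_blur,
    qpaint = scenario_qpaint)
  if (!name %in% names(scenarios))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(scenarios), collapse = ", "))
  scenarios[[name]](seed = seed, ...)
}
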