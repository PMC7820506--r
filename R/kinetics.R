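#' Imager strand specification
#'
#' Describes the binding kinetics of a dye-labeled imager oligonucleotide to a
#' single docking domain. The dissociation constant is derived from the
#' association rate and the mean bound (bright) time,
#' `K_d = 1 / (k_on * tau_bright)`.
#'
#' @param name Imager name (e.g. `"P1"` for the standard 9-nt imager,
#'   `"P1s"` for the short 8-nt imager used in accelerated acquisition).
#' @param k_on Association rate constant per docking domain, in 1/(M s).
#' @param tau_bright Mean bound (bright) duration in seconds.
#' @return An object of class `imager_spec` with fields `name`, `k_on`,
#'   `tau_bright` and the derived `K_d` (in M).
#' @examples
#' p1 <- imager_spec("P1", k_on = 2e6, tau_bright = 0.5)
#' p1$K_d  # 1e-6 M
#' @export
imager_spec <- function(name = "P1", k_on = 2e6, tau_bright = 0.5) {
  stopifnot(is.numeric(k_on), length(k_on) == 1L, k_on > 0)
  stopifnot(is.numeric(tau_bright), length(tau_bright) == 1L, tau_bright > 0)
  structure(
    list(name = as.character(name), k_on = k_on, tau_bright = tau_bright,
         K_d = 1 / (k_on * tau_bright)),
    class = "imager_spec")
}

#' @export
print.imager_spec <- function(x, ...) {
  cat(sprintf("<imager_spec> %s: k_on = %.3g /M/s, tau_bright = %.3g s, K_d = %.3g M\n",
              x$name, x$k_on, x$tau_bright, x$K_d))
  invisible(x)
}

#' Docking site with N repeat domains
#'
#' A docking site is one target-anchored docking motif carrying `n_domains`
#' identical imager-binding repeat domains (an Nx RD motif). All domains of a
#' motif share the site position: the physical extent of the motif (< 10 nm)
#' is far below the width of the point-spread function, so intra-motif
#' geometry only matters for the tether model (see [tether_geometry()]).
#'
#' @param site_id Integer site identifier.
#' @param position Numeric length-2, (x, y) position in nm.
#' @param n_domains Number of repeat domains N (>= 1).
#' @param domain_active Logical vector of per-domain activity states; domains
#'   inactivated by photoinduced damage are permanently `FALSE`.
#' @return An object of class `docking_site`.
#' @export
docking_site <- function(site_id, position = c(0, 0), n_domains = 1L,
                         domain_active = rep(TRUE, n_domains)) {
  n_domains <- as.integer(n_domains)
  stopifnot(n_domains >= 1L, length(position) == 2L, is.numeric(position))
  stopifnot(is.logical(domain_active), length(domain_active) == n_domains)
  structure(
    list(site_id = as.integer(site_id), position = as.numeric(position),
         n_domains = n_domains, domain_active = domain_active),
    class = "docking_site")
}

#' Kinetic simulation configuration
#'
#' @param imager_conc Imager concentration \[I\] in molar.
#' @param duration Acquisition duration in seconds.
#' @param frame_time Camera integration time per frame, seconds.
#' @param inactivation_prob Probability `q` that a docking domain is
#'   permanently inactivated after each completed binding event (photoinduced
#'   site damage by the bound, photo-excited dye).
#' @param nonspecific_rate_coeff Non-specific binding coefficient `gamma`, in
#'   events per um^2 per second per molar; the non-specific event rate over an
#'   area A is `gamma * [I] * A`.
#' @param nonspecific_tau Mean duration of non-specific events, seconds.
#' @param seed Optional integer seed; when non-`NULL` the simulators call
#'   `set.seed(seed)` so a run is bit-reproducible. Leave `NULL` to draw from
#'   the current RNG stream (e.g. inside a larger seeded scenario).
#' @return An object of class `kinetic_config`.
#' @export
kinetic_config <- function(imager_conc, duration, frame_time = 0.1,
                           inactivation_prob = 0,
                           nonspecific_rate_coeff = 0,
                           nonspecific_tau = 0.15, seed = NULL) {
  stopifnot(is.numeric(imager_conc), imager_conc >= 0)
  stopifnot(is.numeric(duration), duration > 0)
  stopifnot(frame_time > 0)
  stopifnot(inactivation_prob >= 0, inactivation_prob <= 1)
  stopifnot(nonspecific_rate_coeff >= 0, nonspecific_tau > 0)
  structure(
    list(imager_conc = imager_conc, duration = duration,
         frame_time = frame_time, inactivation_prob = inactivation_prob,
         nonspecific_rate_coeff = nonspecific_rate_coeff,
         nonspecific_tau = nonspecific_tau,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "kinetic_config")
}

empty_events <- function() {
  data.frame(site_id = integer(0), domain_index = integer(0),
             t_start = numeric(0), t_end = numeric(0),
             x_nm = numeric(0), y_nm = numeric(0), specific = logical(0))
}

#' Expected specific event rate of a docking site
#'
#' Closed-form per-site event rate in the low-occupancy imaging regime:
#' `rate = N_active * k_on * conc`, where `N_active` is the number of active
#' repeat domains. The rate is linear in both the repeat number N and the
#' imager concentration, so an N-fold repeat motif at concentration `conc / N`
#' yields the same event rate as a single domain at `conc`.
#'
#' @param site A [docking_site()].
#' @param imager An [imager_spec()].
#' @param conc Imager concentration in molar (>= 0).
#' @return Expected events per second for this site.
#' @export
expected_event_rate <- function(site, imager, conc) {
  stopifnot(inherits(site, "docking_site"), inherits(imager, "imager_spec"))
  if (!is.numeric(conc) || length(conc) != 1L || is.na(conc) || conc < 0)
    stop("imager concentration must be a single non-negative number")
  sum(site$domain_active) * imager$k_on * conc
}

#' Simulate specific binding events on docking sites
#'
#' Continuous-time kinetic Monte Carlo of imager binding. Each active repeat
#' domain is an independent two-state (free/bound) process: while free, the
#' waiting time to the next binding is Exponential with rate `k_on * [I]`;
#' bound durations are Exponential with mean `tau_bright`. After each
#' completed binding event the domain is permanently inactivated with
#' probability `inactivation_prob` (photoinduced site damage). Time is
#' continuous; discretization to camera frames happens at the rendering stage.
#'
#' @param sites A list of [docking_site()] objects.
#' @param imager An [imager_spec()].
#' @param config A [kinetic_config()].
#' @return A list with components:
#'   * `events`: data frame with columns `site_id`, `domain_index`, `t_start`,
#'     `t_end`, `x_nm`, `y_nm`, `specific` (all `TRUE`), sorted by `t_start`.
#'     `t_end` may exceed `config$duration` when a binding outlasts the run.
#'   * `sites`: the input sites with final `domain_active` states.
#' @export
simulate_specific <- function(sites, imager, config) {
  stopifnot(is.list(sites), inherits(imager, "imager_spec"),
            inherits(config, "kinetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rate <- imager$k_on * config$imager_conc
  out <- list(events = empty_events(), sites = sites)
  if (length(sites) == 0L) return(out)

  # flatten (site, domain) pairs so the event loop is vectorised over domains
  ns <- vapply(sites, function(s) s$n_domains, integer(1))
  dom_site <- rep(seq_along(sites), ns)
  dom_index <- unlist(lapply(ns, seq_len), use.names = FALSE)
  alive <- unlist(lapply(sites, function(s) s$domain_active), use.names = FALSE)
  if (rate == 0 || !any(alive)) return(out)

  T_end <- config$duration
  q <- config$inactivation_prob
  t_cur <- ifelse(alive, 0, Inf)
  ev_site <- list(); ev_dom <- list(); ev_t0 <- list(); ev_t1 <- list()
  k <- 0L
  repeat {
    idx <- which(alive & t_cur < T_end)
    if (length(idx) == 0L) break
    t0 <- t_cur[idx] + stats::rexp(length(idx), rate)
    t1 <- t0 + stats::rexp(length(idx), 1 / imager$tau_bright)
    ok <- t0 < T_end
    if (any(ok)) {
      k <- k + 1L
      ev_site[[k]] <- dom_site[idx[ok]]
      ev_dom[[k]] <- dom_index[idx[ok]]
      ev_t0[[k]] <- t0[ok]
      ev_t1[[k]] <- t1[ok]
      if (q > 0) {
        # inactivation is tied to completed binding events
        died <- ok & (stats::runif(length(idx)) < q)
        alive[idx[died]] <- FALSE
      }
    }
    t_cur[idx] <- ifelse(ok, t1, Inf)
  }
  if (k == 0L) {
    ev <- empty_events()
  } else {
    s_id <- vapply(sites, function(s) s$site_id, integer(1))
    pos <- t(vapply(sites, function(s) s$position, numeric(2)))
    si <- unlist(ev_site); di <- unlist(ev_dom)
    ev <- data.frame(site_id = s_id[si], domain_index = di,
                     t_start = unlist(ev_t0), t_end = unlist(ev_t1),
                     x_nm = pos[si, 1], y_nm = pos[si, 2], specific = TRUE)
    ev <- ev[order(ev$t_start), , drop = FALSE]
    rownames(ev) <- NULL
  }
  # write final domain states back
  for (j in seq_along(sites))
    sites[[j]]$domain_active <- alive[dom_site == j]
  list(events = ev, sites = sites)
}

#' Simulate non-specific binding events
#'
#' Non-specific imager attachments occur homogeneously over the field with
#' total rate `gamma * [I] * area` (linear in imager concentration), uniform
#' positions, and Exponential durations with mean `nonspecific_tau`.
#'
#' @param area Field area in um^2. Events are placed uniformly over a square
#'   of side `sqrt(area)` um anchored at `origin`.
#' @param config A [kinetic_config()] supplying `[I]`, `gamma`, duration and
#'   the mean non-specific duration.
#' @param origin Numeric length-2 field corner in nm (default `c(0, 0)`).
#' @return Event data frame as in [simulate_specific()], with `site_id` and
#'   `domain_index` `NA` and `specific = FALSE`.
#' @export
simulate_nonspecific <- function(area, config, origin = c(0, 0)) {
  stopifnot(inherits(config, "kinetic_config"), is.numeric(area), area >= 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  lambda <- config$nonspecific_rate_coeff * config$imager_conc * area
  n <- stats::rpois(1L, lambda * config$duration)
  if (n == 0L) return(empty_events())
  side_nm <- sqrt(area) * 1000
  t0 <- sort(stats::runif(n, 0, config$duration))
  data.frame(site_id = NA_integer_, domain_index = NA_integer_,
             t_start = t0,
             t_end = t0 + stats::rexp(n, 1 / config$nonspecific_tau),
             x_nm = origin[1] + stats::runif(n, 0, side_nm),
             y_nm = origin[2] + stats::runif(n, 0, side_nm),
             specific = FALSE)
}

#' Predicted non-specific event fraction
#'
#' Fraction of all events that are non-specific, `ns / (ns + s)` with
#' `ns = gamma * conc * area`. Because the specific rate of an N-repeat motif
#' is preserved when `[I]` is reduced N-fold while the non-specific rate drops
#' linearly with `[I]`, repeat motifs suppress the non-specific fraction
#' nearly N-fold.
#'
#' @param specific_rate Total specific event rate over the area, events/s.
#' @param gamma Non-specific rate coefficient, events/um^2/s/M.
#' @param conc Imager concentration, M.
#' @param area Area in um^2.
#' @return Non-specific fraction in \[0, 1\].
#' @export
nonspecific_fraction <- function(specific_rate, gamma, conc, area) {
  stopifnot(specific_rate >= 0, gamma >= 0, conc >= 0, area >= 0)
  ns <- gamma * conc * area
  if (ns + specific_rate <= 0)
    stop("both specific and non-specific rates are zero: fraction undefined")
  ns / (ns + specific_rate)
}

#' Calibrate the non-specific coefficient to a target contamination
#'
#' Solves `gamma * conc * area / (s + gamma * conc * area) = target` for
#' `gamma`, i.e. finds the non-specific rate coefficient that produces the
#' given contamination fraction at a reference condition.
#'
#' @param target Target non-specific fraction (0 < target < 1).
#' @param specific_rate Specific event rate over the area, events/s.
#' @param conc Reference imager concentration, M.
#' @param area Area in um^2.
#' @return The coefficient `gamma` in events/um^2/s/M.
#' @export
calibrate_nonspecific <- function(target, specific_rate, conc, area) {
  stopifnot(target > 0, target < 1, specific_rate > 0, conc > 0, area > 0)
  specific_rate * target / (1 - target) / (conc * area)
}

#' Expected fraction of sites surviving photoinduced damage
#'
#' Under per-event inactivation with probability `q`, lethal events on a
#' domain binding at rate `lambda_d = k_on * [I]` form a thinned Poisson
#' process of rate `q * lambda_d`, so a domain is still active at time `T`
#' with probability `exp(-q * lambda_d * T)`. A site with N independent
#' domains survives (retains at least one active domain) with probability
#' `1 - (1 - exp(-q * lambda_d * T))^N`.
#'
#' @param imager An [imager_spec()].
#' @param config A [kinetic_config()] (uses `imager_conc`, `inactivation_prob`).
#' @param N Number of repeat domains per site.
#' @param T_end Elapsed time in seconds.
#' @return Probability that a site has >= 1 active domain at `T_end`.
#' @export
expected_site_survival <- function(imager, config, N, T_end) {
  stopifnot(inherits(imager, "imager_spec"), inherits(config, "kinetic_config"),
            N >= 1, T_end >= 0)
  lambda_d <- imager$k_on * config$imager_conc
  p_dead <- -expm1(-config$inactivation_prob * lambda_d * T_end)
  1 - p_dead^N
}

#' Expected probability of detecting a site in a time window
#'
#' Probability that a domain binding at rate `lambda_d` with per-event
#' inactivation `q` produces at least one event inside the window
#' \[`a`, `b`\] before dying. Conditioning on the number of events before `a`
#' gives `exp(-q * lambda_d * a) * (1 - exp(-lambda_d * (b - a)))` for a
#' single domain; a site with `N` independent domains is detected when any
#' domain fires.
#'
#' @param lambda_site Total per-site binding rate (summed over domains), 1/s.
#' @param N Repeat domains per site (each binds at `lambda_site / N`).
#' @param q Per-event inactivation probability.
#' @param window Numeric length-2 time window in seconds.
#' @return Detection probability.
#' @export
expected_detection_prob <- function(lambda_site, N, q, window) {
  stopifnot(length(window) == 2L, window[2] > window[1], window[1] >= 0)
  ld <- lambda_site / N
  p_dom <- exp(-q * ld * window[1]) * (-expm1(-ld * (window[2] - window[1])))
  1 - (1 - p_dom)^N
}

#' Expected site loss between two windows (closed form)
#'
#' Relative drop in the expected number of detected sites between two equal
#' observation windows, for the minimal detection rule (>= 1 event in the
#' window). For a single-domain site this reduces to
#' `1 - exp(-q * lambda * t1)` where `t1` is the start of the second window.
#'
#' @inheritParams expected_detection_prob
#' @param window1,window2 The two observation windows (seconds).
#' @return Expected loss as a fraction in \[0, 1\].
#' @export
expected_site_loss <- function(lambda_site, N, q, window1, window2) {
  p1 <- expected_detection_prob(lambda_site, N, q, window1)
  p2 <- expected_detection_prob(lambda_site, N, q, window2)
  (p1 - p2) / p1
}

#' Calibrate the per-event inactivation probability
#'
#' Finds `q` such that single-domain (1x RD) sites binding at rate `lambda`
#' lose `target_loss` of detected sites between two consecutive windows of
#' length `t1` (detection rule: >= 1 event per window). Closed form:
#' `q = -log(1 - target_loss) / (lambda * t1)`.
#'
#' @param target_loss Target fractional loss (e.g. 0.121).
#' @param lambda Per-site (single-domain) binding rate, 1/s.
#' @param t1 Window length in seconds (second window starts at `t1`).
#' @return Inactivation probability `q`.
#' @export
calibrate_inactivation <- function(target_loss, lambda, t1) {
  stopifnot(target_loss > 0, target_loss < 1, lambda > 0, t1 > 0)
  q <- -log1p(-target_loss) / (lambda * t1)
  if (q > 1) stop("target loss unreachable: required q exceeds 1")
  q
}

#' Write / read binding-event streams as CSV
#'
#' Columns: `site_id`, `domain_index`, `t_start`, `t_end`, `x_nm`, `y_nm`,
#' `specific`.
#'
#' @param events Event data frame.
#' @param path File path.
#' @return `read_events_csv` returns the event data frame.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("site_id", "domain_index", "t_start", "t_end", "x_nm", "y_nm",
            "specific")
  stopifnot(all(cols %in% names(events)))
  utils::write.csv(events[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path)
  ev$specific <- as.logical(ev$specific)
  ev
}
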