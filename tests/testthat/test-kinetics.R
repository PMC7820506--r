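test_that("expected event rate follows N_active * k_on * [I]", {
  im <- imager_spec("P1", k_on = 2e6, tau_bright = 0.5)
  expect_equal(im$K_d, 1 / (2e6 * 0.5))
  s1 <- docking_site(1, c(0, 0), 1)
  expect_identical(expected_event_rate(s1, im, 0), 0)
  expect_error(expected_event_rate(s1, im, -1e-9), "non-negative")
  # linear in N: doubling N doubles the rate at fixed concentration
  for (N in c(1, 3, 5)) {
    rN <- expected_event_rate(docking_site(1, c(0, 0), N), im, 1e-9)
    r2N <- expected_event_rate(docking_site(1, c(0, 0), 2 * N), im, 1e-9)
    expect_equal(r2N, 2 * rN)
  }
  # N repeats at conc/N equals one domain at conc
  expect_equal(expected_event_rate(docking_site(1, c(0, 0), 10), im, 1e-10),
               expected_event_rate(s1, im, 1e-9))
  # inactive domains do not bind
  s_half <- docking_site(1, c(0, 0), 4, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(expected_event_rate(s_half, im, 1e-9),
               2 * im$k_on * 1e-9)
})

test_that("closed-form rate matches the Monte-Carlo event frequency", {
  im <- default_imager()
  conc <- 2e-9
  sites <- n_sites(1, N = 3)
  rate <- expected_event_rate(sites[[1]], im, conc)
  sim <- simulate_specific(sites, im, kinetic_config(conc, 1e4, seed = 101))
  n <- nrow(sim$events)
  se <- sqrt(rate * 1e4)
  expect_lt(abs(n - rate * 1e4), 3 * se)
})

test_that("specific simulator honors basic contracts", {
  im <- default_imager()
  # no imager, no events
  sim0 <- simulate_specific(n_sites(5), im, kinetic_config(0, 100, seed = 1))
  expect_identical(nrow(sim0$events), 0L)
  # bit-exact reproducibility under the same seed
  cfg <- kinetic_config(5e-9, 500, seed = 7)
  a <- simulate_specific(n_sites(10, N = 2), im, cfg)
  b <- simulate_specific(n_sites(10, N = 2), im, cfg)
  expect_identical(a$events, b$events)
  # sorted by start time, no overlapping events within one domain
  ev <- a$events
  expect_true(!is.unsorted(ev$t_start))
  for (sid in unique(ev$site_id)) {
    for (d in unique(ev$domain_index[ev$site_id == sid])) {
      e <- ev[ev$site_id == sid & ev$domain_index == d, ]
      if (nrow(e) > 1)
        expect_true(all(e$t_start[-1] >= e$t_end[-nrow(e)]))
    }
  }
})

test_that("two-state occupancy converges to [I] / ([I] + K_d)", {
  im <- default_imager()
  conc <- im$K_d  # expected occupancy 1/2
  T_end <- 300
  nd <- 120
  sim <- simulate_specific(n_sites(nd), im,
                           kinetic_config(conc, T_end, seed = 11))
  occ <- vapply(seq_len(nd), function(i) {
    e <- sim$events[sim$events$site_id == i, ]
    sum(pmin(e$t_end, T_end) - e$t_start) / T_end
  }, numeric(1))
  theo <- conc / (conc + im$K_d)
  se <- stats::sd(occ) / sqrt(nd)
  expect_lt(abs(mean(occ) - theo), 3 * se)
})

test_that("low-occupancy event counts are Poisson with mean N k_on [I] T", {
  im <- default_imager()
  conc <- 1e-10  # occupancy ~1e-4
  sites <- n_sites(50, N = 4)
  T_end <- 2000
  sim <- simulate_specific(sites, im, kinetic_config(conc, T_end, seed = 3))
  lambda <- 50 * 4 * im$k_on * conc * T_end
  expect_lt(abs(nrow(sim$events) - lambda), 3 * sqrt(lambda))
})

test_that("event rate is linear in N and [I] over two decades (log-log slope 1)", {
  im <- default_imager()
  concs <- 10^seq(-10, -8, length.out = 5)
  counts <- vapply(seq_along(concs), function(i) {
    sim <- simulate_specific(n_sites(200, N = 2), im,
                             kinetic_config(concs[i], 1000, seed = 20 + i))
    nrow(sim$events)
  }, numeric(1))
  expect_gt(sum(counts), 1e4)
  fit <- stats::lm(log(counts) ~ log(concs))
  expect_lt(abs(stats::coef(fit)[[2]] - 1), 0.05)
  # and in N at fixed [I]
  Ns <- c(1, 2, 4, 8, 16)
  countsN <- vapply(seq_along(Ns), function(i) {
    sim <- simulate_specific(n_sites(60, N = Ns[i]), im,
                             kinetic_config(2e-9, 2000, seed = 40 + i))
    nrow(sim$events)
  }, numeric(1))
  expect_gt(sum(countsN), 1e4)
  fitN <- stats::lm(log(countsN) ~ log(Ns))
  expect_lt(abs(stats::coef(fitN)[[2]] - 1), 0.05)
})

test_that("(N=10, [I]/10) and (N=1, [I]) event-count distributions agree", {
  im <- default_imager()
  n_t <- 80
  sim1 <- simulate_specific(n_sites(n_t, N = 1), im,
                            kinetic_config(5e-9, 2000, seed = 5))
  sim10 <- simulate_specific(n_sites(n_t, N = 10), im,
                             kinetic_config(5e-10, 2000, seed = 6))
  c1 <- tabulate(sim1$events$site_id, n_t)
  c10 <- tabulate(sim10$events$site_id, n_t)
  p <- suppressWarnings(stats::wilcox.test(c1, c10))$p.value
  expect_gt(p, 0.01)
})

test_that("inactivation suppresses counts permanently", {
  im <- default_imager()
  cfg0 <- kinetic_config(2e-8, 2000, inactivation_prob = 0, seed = 9)
  cfgq <- kinetic_config(2e-8, 2000, inactivation_prob = 0.3, seed = 9)
  s0 <- simulate_specific(n_sites(60), im, cfg0)
  sq <- simulate_specific(n_sites(60), im, cfgq)
  expect_lt(nrow(sq$events), nrow(s0$events))
  # inactivated domains host no events after their last (lethal) one:
  # with q = 1 every domain has at most one event
  s1 <- simulate_specific(n_sites(60), im,
                          kinetic_config(2e-8, 2000, inactivation_prob = 1,
                                         seed = 10))
  expect_true(all(tabulate(s1$events$site_id, 60) <= 1))
  expect_true(all(!unlist(lapply(s1$sites[tabulate(s1$events$site_id, 60) == 1],
                                 function(s) s$domain_active))))
})

test_that("non-specific events are Poisson, uniform and linear in [I]", {
  cfg0 <- kinetic_config(1e-9, 1000, nonspecific_rate_coeff = 0, seed = 1)
  expect_identical(nrow(simulate_nonspecific(100, cfg0)), 0L)
  # count over 100 seeded replicates within 3 SD of the Poisson mean
  gamma <- 0.002
  lam <- gamma * 1e-9 * 1e9 * 100 * 50   # gamma * [I] * area * T (conc 1 nM)
  tot <- 0
  for (s in 1:100) {
    cfg <- kinetic_config(1e-9, 50, nonspecific_rate_coeff = gamma * 1e9,
                          seed = 1000 + s)
    tot <- tot + nrow(simulate_nonspecific(100, cfg))
  }
  expect_lt(abs(tot - 100 * lam), 3 * sqrt(100 * lam))
  # halving [I] halves the expected count
  tot_half <- 0
  for (s in 1:100) {
    cfg <- kinetic_config(0.5e-9, 50, nonspecific_rate_coeff = gamma * 1e9,
                          seed = 2000 + s)
    tot_half <- tot_half + nrow(simulate_nonspecific(100, cfg))
  }
  expect_lt(abs(tot_half - 50 * lam), 3 * sqrt(50 * lam))
  # positions uniform over the field
  cfg <- kinetic_config(1e-8, 500, nonspecific_rate_coeff = 2e9, seed = 77)
  ev <- simulate_nonspecific(100, cfg)
  expect_true(all(!ev$specific))
  expect_true(all(ev$x_nm >= 0 & ev$x_nm <= 1e4))
  expect_gt(suppressWarnings(stats::ks.test(ev$x_nm / 1e4, "punif"))$p.value,
            0.01)
})

test_that("non-specific fraction: algebra and simulation agree", {
  expect_identical(nonspecific_fraction(1, 0, 1e-9, 100), 0)
  expect_error(nonspecific_fraction(0, 0, 1e-9, 100), "undefined")
  # the calibration scenario: 8% at [I] becomes ~0.86% at [I]/10
  g <- calibrate_nonspecific(0.08, specific_rate = 1, conc = 0.4e-9,
                             area = 100)
  expect_equal(nonspecific_fraction(1, g, 0.4e-9, 100), 0.08)
  f10 <- nonspecific_fraction(1, g, 0.04e-9, 100)
  expect_equal(f10, 0.08 / (10 * 0.92 + 0.08), tolerance = 1e-12)
  expect_lt(abs(f10 - 0.009), 0.001)
  # against the two simulators
  res <- scenario_nonspecific(seed = 31, simulate = TRUE)
  n_ev <- 0.5 * 4000 / (1 - 0.08)
  se <- sqrt(0.08 * 0.92 / n_ev)
  expect_lt(abs(res$measured_1x - res$fraction_1x), 3 * se)
})

test_that("site survival closed form matches simulation and is monotone in N", {
  im <- default_imager()
  cfg <- kinetic_config(1e-8, 2000, inactivation_prob = 0)
  expect_identical(expected_site_survival(im, cfg, 5, 2000), 1)
  # fixed total site rate: survival non-decreasing in N
  lam_tot <- 0.02
  surv <- vapply(1:12, function(N) {
    cfgN <- kinetic_config(lam_tot / (N * im$k_on), 1000,
                           inactivation_prob = 0.1)
    expected_site_survival(im, cfgN, N, 1000)
  }, numeric(1))
  expect_true(all(diff(surv) >= -1e-12))
  # Monte-Carlo check at N = 1 and N = 10
  for (N in c(1, 10)) {
    n_t <- 300
    cfgN <- kinetic_config(2e-9 / N, 2000, inactivation_prob = 0.15,
                           seed = 50 + N)
    sim <- simulate_specific(n_sites(n_t, N = N), im, cfgN)
    alive <- vapply(sim$sites, function(s) any(s$domain_active), logical(1))
    p <- expected_site_survival(im, cfgN, N, 2000)
    se <- sqrt(p * (1 - p) / n_t)
    expect_lt(abs(mean(alive) - p), 3 * se + 1e-9)
  }
})

test_that("inactivation calibration closed form hits its target loss", {
  lambda <- 8e-4
  q <- calibrate_inactivation(0.121, lambda, 2000)
  expect_equal(expected_site_loss(lambda, 1, q, c(0, 2000), c(2000, 4000)),
               0.121, tolerance = 1e-12)
  # same q on a 10-domain site with identical total rate loses far less
  loss10 <- expected_site_loss(lambda, 10, q, c(0, 2000), c(2000, 4000))
  expect_lt(loss10, 0.022)
})

test_that("event streams round-trip through CSV", {
  im <- default_imager()
  sim <- simulate_specific(n_sites(5, N = 2, pos = c(12.5, -3)), im,
                           kinetic_config(1e-8, 300, seed = 4))
  ns <- simulate_nonspecific(25, kinetic_config(1e-8, 300,
                                                nonspecific_rate_coeff = 1e9,
                                                seed = 5))
  ev <- rbind(sim$events, ns)
  path <- tempfile(fileext = ".csv")
  write_events_csv(ev, path)
  back <- read_events_csv(path)
  expect_equal(back$t_start, ev$t_start)
  expect_equal(back$x_nm, ev$x_nm)
  expect_identical(back$specific, ev$specific)
  unlink(path)
})
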