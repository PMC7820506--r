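# linear ramp up to a barrier, then downhill to the target state
barrier_energy <- function(barrier, n = 12, peak = 9) {
  E <- numeric(n)
  E[3:peak] <- barrier * ((3:peak) - 2) / (peak - 2)
  if (peak < n) E[(peak + 1):n] <- barrier - 2 * (((peak + 1):n) - peak)
  E
}

test_that("the toy chain satisfies detailed balance", {
  E <- barrier_energy(5)
  P <- attr(bd_model(E), "transition_matrix")
  pi_ <- exp(-E) / sum(exp(-E))
  flows <- outer(pi_, rep(1, length(E))) * P
  expect_equal(flows, t(flows), tolerance = 1e-12)
  expect_equal(rowSums(P), rep(1, length(E)))
})

test_that("exact MFPT oracle matches the flat-chain closed form", {
  # symmetric lazy walk, reflecting at 1: MFPT(1 -> n) = n (n - 1)
  for (n in c(4, 7, 10)) {
    m <- bd_model(rep(0, n))
    ex <- exact_rate_bd(m, 1, n)
    expect_equal(ex$mfpt, n * (n - 1), tolerance = 1e-9)
  }
  # higher barriers give lower rates
  r <- vapply(c(2, 5, 8), function(b)
    exact_rate_bd(bd_model(barrier_energy(b)), 1, 12)$rate, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("flux matches the analytic crossing rate of a flat chain", {
  # flat 3-state chain, q_min = 1, q0 = 2: crossings out of state 1 occur at
  # rate pi(1) * P(1 -> 2) = (1/3) * (1/2) per step
  m <- bd_model(rep(0, 3))
  sch <- interface_scheme(1, 2, 99)  # unreachable target: pure free dynamics
  fl <- estimate_flux(m, sch, sampling_steps = 4e4, seed = 3)
  k <- 1 / 6
  se <- sqrt(fl$n_transitions) / fl$sampling_time
  expect_lt(abs(fl$flux - k), 3 * se)
  # doubling the sampling time roughly doubles the transition count
  fl2 <- estimate_flux(m, sch, sampling_steps = 8e4, seed = 3)
  expect_lt(abs(fl2$n_transitions - 2 * fl$n_transitions),
            3 * sqrt(2 * fl$n_transitions))
})

test_that("an unreachable first interface is flagged", {
  m <- bd_model(rep(0, 5), Q = function(s) s)
  sch <- interface_scheme(1, 10, 12)
  fl <- estimate_flux(m, sch, sampling_steps = 5000, seed = 1)
  expect_identical(fl$n_transitions, 0L)
  expect_true(fl$flagged)
  rate <- ffs_rate(fl, list())
  expect_true(is.na(rate$rate))
})

test_that("stage probabilities reduce to trivial limits", {
  m <- bd_model(barrier_energy(5))
  sch <- interface_scheme(1, 3, 12)
  configs <- list(4L, 4L)
  # target already reached by the stored configs
  st <- run_stage(m, configs, target_q = 4, scheme = sch, n_trials = 50,
                  seed = 2)
  expect_equal(st$p, 1)
  # barrier-free downhill chain crosses with probability ~1
  down <- bd_model(-2 * (1:10))
  std <- run_stage(down, list(3L), target_q = 6,
                   scheme = interface_scheme(1, 2, 10), n_trials = 200,
                   seed = 3)
  expect_gt(std$p, 0.97)
  expect_error(run_stage(m, list(), 4, sch), "no stored")
})

test_that("stage success probabilities match the exact committor", {
  # 20-state chain with a gentle ramp; p(reach 8 before 1 | start 5)
  E <- 0.25 * (0:19)
  m <- bd_model(E)
  q <- committor_bd(m, a = 1, b = 8)
  sch <- interface_scheme(1, 5, 20)
  st <- run_stage(m, list(5L), target_q = 8, scheme = sch, n_trials = 2000,
                  seed = 7)
  se <- sqrt(q[5] * (1 - q[5]) / 2000)
  expect_lt(abs(st$p - q[5]), 3 * se)
})

test_that("rate composition follows Eq-style product structure", {
  fl <- structure(list(n_transitions = 50L, sampling_time = 1000,
                       flux = 0.05, configs = list(1), flagged = FALSE),
                  class = "flux_estimate")
  mk_stage <- function(p) structure(
    list(target_q = 1, n_trials = 100, n_successes = round(100 * p), p = p,
         se = sqrt(p * (1 - p) / 100), configs = list(1)),
    class = "stage_result")
  r1 <- ffs_rate(fl, list(mk_stage(1), mk_stage(1)))
  expect_equal(r1$rate, fl$flux)
  r0 <- ffs_rate(fl, list(mk_stage(0.5), mk_stage(0)))
  expect_equal(r0$rate, 0)
  expect_true(r0$flagged)
})

test_that("FFS reproduces exact rates within 15% across 3 decades", {
  for (barrier in c(4, 7, 10)) {
    m <- bd_model(barrier_energy(barrier))
    ex <- exact_rate_bd(m, 1, 12)$rate
    rates <- vapply(1:5, function(s)
      run_ffs(m, interface_scheme(1, 3, 12), sampling_steps = 1e5,
              n_trials = 1000, seed = 100 + s)$rate$rate, numeric(1))
    expect_lt(abs(mean(rates) / ex - 1), 0.15)
  }
})

test_that("merging two adjacent interfaces changes the rate within noise", {
  m <- bd_model(barrier_energy(6))
  sch <- interface_scheme(1, 3, 12)
  set.seed(11)
  fl <- estimate_flux(m, sch, sampling_steps = 1e5)
  run_chain <- function(targets, seed) {
    set.seed(seed)
    configs <- fl$configs
    stages <- list()
    for (tq in targets) {
      st <- run_stage(m, configs, tq, sch, n_trials = 2000)
      stages[[length(stages) + 1]] <- st
      configs <- st$configs
    }
    ffs_rate(fl, stages)
  }
  fine <- run_chain(4:12, seed = 12)
  merged <- run_chain(c(4, 5, 7:12), seed = 13)  # interfaces 6 merged into 7
  se <- fine$rate * sqrt(fine$rel_se^2 + merged$rel_se^2)
  expect_lt(abs(fine$rate - merged$rate), 2 * se)
})

test_that("the terminal-state classifier resolves which basin was reached", {
  # double-funnel chain: basin in the middle, targets at both ends
  n <- 21
  E <- -0.4 * abs((1:n) - 11)
  Qf <- function(s) abs(s - 11L)
  m <- bd_model(E, Q = Qf)
  m$init_state <- 11L
  sch <- interface_scheme(0, 2, 10)
  res <- run_ffs(m, sch, sampling_steps = 2e4, n_trials = 1500, seed = 9,
                 classify = function(s) if (s < 11) "left" else "right")
  lab <- res$stages[[length(res$stages)]]$labels
  expect_setequal(names(lab), c("left", "right"))
  frac <- lab[["left"]] / sum(lab)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(lab)))
})

test_that("run records serialize to JSON", {
  m <- bd_model(barrier_energy(5))
  run <- run_ffs(m, interface_scheme(1, 3, 12), sampling_steps = 2e4,
                 n_trials = 300, seed = 21)
  path <- tempfile(fileext = ".json")
  write_ffs_json(run, path)
  rec <- jsonlite::read_json(path)
  expect_equal(rec$rate, run$rate$rate)
  expect_length(rec$stages, length(run$stages))
  unlink(path)
})
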