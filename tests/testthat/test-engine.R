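test_that("donor excitation has the at-least-one truncated-binomial law", {
  set.seed(1)
  # P = 1: everyone is excited, in some order
  expect_setequal(excite_donors(8, 1), 1:8)
  # a single donor is always the one excited
  expect_identical(excite_donors(1, 1e-6), 1L)

  # mean excited per cycle matches the binomial conditioned on >= 1
  n <- 50; p <- 0.02; cycles <- 4000
  k <- vapply(seq_len(cycles), function(i) length(excite_donors(n, p)), 0L)
  m_expect <- n * p / (1 - (1 - p)^n)
  expect_lt(abs(mean(k) - m_expect), 3 * stats::sd(k) / sqrt(cycles))

  # the compiled engine draws from the same law: donor-only scene, cycle
  # count implies the mean excited per cycle via total excitations
  sc <- fixed_pair_scene(numeric(0), n_donor_only = 50)
  pp <- default_params(P_excitation = 0.02)
  h <- run_simulation(sc, pp, sim_config(photon_threshold = 300, seed = 3))
  m_engine <- h$excitations / h$cycles
  expect_lt(abs(m_engine - m_expect), 4 * stats::sd(k) / sqrt(h$cycles))
})

test_that("acceptor recovery is exponential with the acceptor lifetime", {
  expect_identical(step_acceptors(integer(0), 3.9, 0.05)$excited, integer(0))
  set.seed(2)
  # dt/tau = ln 2: each excited acceptor relaxes with probability 1/2
  out <- step_acceptors(1:100000, tau_A0 = 1, dt = log(2))
  frac <- length(out$deactivated) / 1e5
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_setequal(c(out$excited, out$deactivated), 1:100000)

  # one step at the default grid: fraction 1 - exp(-dt/tau) within 3 sigma
  p <- 1 - exp(-(50 / 1024) / 3.9)
  out <- step_acceptors(1:100000, 3.9, 50 / 1024)
  expect_lt(abs(length(out$deactivated) / 1e5 - p),
            3 * sqrt(p * (1 - p) / 1e5))
})

test_that("donor stepping picks channels in proportion to the rates", {
  p <- default_params()
  set.seed(3)
  # no acceptors, dt much longer than the lifetime: the donor deactivates
  # and emits with probability phi_D
  rs <- donor_rate_set(p)
  out <- replicate(4000, step_donor(rs, dt = 1000)$channel)
  expect_true(all(out %in% c("emission", "nonradiative")))
  f <- mean(out == "emission")
  expect_lt(abs(f - 0.6), 3 * sqrt(0.6 * 0.4 / 4000))

  # one acceptor at R0: conditional on deactivation, FRET happens half of
  # the time
  rs1 <- donor_rate_set(p, p$R0)
  ch <- replicate(4000, step_donor(rs1, dt = 1000)$channel)
  f <- mean(ch == "fret")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 4000))

  # two acceptors at R0 and 2 R0: FRET events split 64:1
  rs2 <- donor_rate_set(p, c(p$R0, 2 * p$R0))
  acc <- replicate(6000, step_donor(rs2, dt = 1000)$acceptor)
  acc <- acc[!is.na(acc)]
  f <- mean(acc == 1)
  expect_lt(abs(f - 64 / 65), 3 * sqrt((64 / 65) * (1 / 65) / length(acc)))
})

test_that("runs are bitwise reproducible given the seed", {
  sc <- pair_scene_at(5)
  pp <- default_params(P_excitation = 1, linker_D = 0.5, linker_A = 0.5)
  cfg <- sim_config(photon_threshold = 100, seed = 77)
  h1 <- run_simulation(sc, pp, cfg)
  h2 <- run_simulation(sc, pp, cfg)
  expect_identical(h1$counts, h2$counts)
  expect_identical(h1$cycles, h2$cycles)
})

test_that("count bookkeeping is conserved", {
  set.seed(8)
  fib <- fibril_scene(fibril_model(n_monomers = 200))
  pp <- default_params(R0 = 4.7, P_excitation = 0.05)
  h <- run_simulation(fib, pp, sim_config(photon_threshold = 100, seed = 4,
                                          track_acceptor_decay = TRUE))
  deact <- sum(h$counts[, c("emission", "nonradiative", "fret")])
  # every deactivation belongs to an excited donor
  expect_lte(deact, h$excitations)
  # all counts are non-negative integers
  expect_true(all(h$counts >= 0))
  expect_equal(h$counts, round(h$counts))
  # FRET transfers equal acceptor excitations and bound the deactivations
  expect_equal(sum(h$counts[, "fret"]), h$fret_total)
  expect_identical(h$acceptor_excitations, h$fret_total)
  expect_equal(sum(h$counts[, "acceptor_deactivation"]),
               h$acceptor_deactivations_total)
  expect_lte(h$acceptor_deactivations_total, h$fret_total)
  # threshold reached on the emission peak
  expect_gte(max(h$counts[, "emission"]), 100)
})

test_that("a donor-only run recovers the donor lifetime within 2%", {
  sc <- fixed_pair_scene(numeric(0), n_donor_only = 20)
  pp <- default_params(P_excitation = 1)
  h <- run_simulation(sc, pp, sim_config(photon_threshold = 10000, seed = 5))
  y <- h$counts[, "emission"]
  use <- y >= 50
  fit <- stats::lm(log(y[use]) ~ h$time[use], weights = y[use])
  tau_fit <- -1 / coef(fit)[2]
  expect_lt(abs(tau_fit - pp$tau_D0) / pp$tau_D0, 0.02)
})

test_that("an isolated pair at R0 transfers half of all deactivations", {
  sc <- pair_scene_at(5.4)
  pp <- default_params(P_excitation = 1)
  h <- run_simulation(sc, pp, sim_config(photon_threshold = 1000, seed = 6))
  deact <- sum(h$counts[, c("emission", "nonradiative", "fret")])
  frac <- h$fret_total / deact
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / deact))
})

test_that("the engine matches a continuous-time event-driven oracle", {
  # fixed small scene: one donor with acceptors at 4 and 5 nm
  pp <- default_params(P_excitation = 1)
  for (n_channels in c(1024L, 4096L)) {
    cfg <- sim_config(n_channels = n_channels, photon_threshold = 2000,
                      seed = 9, resample_positions = FALSE)
    sc <- fret_scene(c(30, 10, 10), donor_sites = c(10, 5, 5),
                     acceptor_sites = rbind(c(14, 5, 5), c(10, 10, 5)))
    h <- run_simulation(sc, pp, cfg)
    set.seed(1e4 + n_channels)
    oracle <- event_oracle_emission(c(4, 5), pp, cfg, n_draws = 3e5)
    p <- chisq_two_sample(h$counts[, "emission"], oracle)
    expect_gt(p, 0.01)
  }
})

test_that("adding an acceptor within 2 R0 never brightens the donor", {
  pp <- default_params(P_excitation = 1)
  cfg <- sim_config(photon_threshold = 600, seed = 10)
  yield <- function(sc) {
    h <- run_simulation(sc, pp, cfg)
    c(total_photons(h) / h$excitations, h$excitations)
  }
  y0 <- yield(fixed_pair_scene(numeric(0), n_donor_only = 5))
  y5 <- yield(pair_scene_at(5, n_pairs = 5))
  y4 <- yield(pair_scene_at(4, n_pairs = 5))
  # expected yields: phi_D times (1 - efficiency)
  se <- function(y) sqrt(y[1] * (1 - y[1]) / y[2])
  expect_lt(y5[1] + 3 * se(y5), y0[1])
  expect_lt(y4[1] + 3 * se(y4), y5[1])
})

test_that("warnings flag unreachable thresholds", {
  sc <- fixed_pair_scene(numeric(0), n_donor_only = 2)
  expect_error(
    run_simulation(fret_scene(c(10, 10, 10), acceptor_sites = c(1, 1, 1)),
                   default_params(), sim_config()),
    "no donors")
  pp_dark <- default_params(phi_D = 0)
  expect_warning(
    expect_warning(
      run_simulation(sc, pp_dark,
                     sim_config(photon_threshold = 10, max_cycles = 5,
                                seed = 1)),
      "unreachable"),
    "not reached")
})
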