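test_that("IRF convolution is an identity for a delta response", {
  dt <- 50 / 1024
  counts <- 1000 * exp(-(0:1023) * dt / 4.1)
  # delta at t = 0
  d0 <- irf(c(0, dt), c(1, 0))
  expect_equal(convolve_irf(counts, d0, dt = dt), counts, tolerance = 1e-12)
  # delta at channel k shifts the curve by k channels (zero samples on
  # the neighbouring channels so the interpolated response is a spike)
  k <- 12
  dk <- irf(c(0, (k - 1) * dt, k * dt, (k + 1) * dt), c(0, 0, 1, 0))
  out <- convolve_irf(counts, dk, dt = dt)
  expect_equal(out[(k + 1):1024], counts[1:(1024 - k)], tolerance = 1e-12)
  expect_equal(out[1:k], rep(0, k))
})

test_that("a normalised IRF conserves the photon count", {
  dt <- 50 / 1024
  counts <- 500 * exp(-(0:1023) * dt / 2)
  # broad early response; the decay has negligible mass near the window
  # end so truncation losses are tiny
  tgrid <- seq(0, 3, by = 0.02)
  resp <- irf(tgrid, exp(-(tgrid - 1)^2 / 0.1))
  out <- convolve_irf(counts, resp, dt = dt)
  expect_equal(sum(out), sum(counts), tolerance = 1e-3)
  expect_true(all(out >= 0))
  # an IRF entirely outside the window is rejected
  expect_error(convolve_irf(counts, irf(c(100, 101), c(1, 1)), dt = dt),
               "window")
})

test_that("IRF input validates and reads from two-column text", {
  expect_error(irf(c(0, 1), c(-1, 2)), ">= 0")
  expect_error(irf(c(1, 0), c(1, 2)), "increase")
  expect_error(irf(c(0, 1), c(0, 0)), "zero total")
  path <- tempfile()
  writeLines(c("# measured response", "0\t0.0", "0.1\t2.5", "0.2\t1.0"),
             path)
  r <- read_irf(path)
  expect_s3_class(r, "irf")
  expect_equal(r$intensity, c(0, 2.5, 1))
})

test_that("residuals are zero on perfect agreement and track departures", {
  expected <- 100 * exp(-(0:199) / 40)
  rep0 <- decay_residuals(expected, expected, scale = "none")
  use <- !is.na(rep0$residuals)
  expect_true(all(rep0$residuals[use] == 0))
  expect_equal(rep0$mean_early_signed, 0)
  expect_equal(rep0$max_early_abs, 0)

  # a 30% excess in one channel appears as residual +0.3 there
  sim <- expected
  sim[7] <- 1.3 * expected[7]
  rep1 <- decay_residuals(sim, expected, scale = "none")
  expect_equal(rep1$residuals[7], 0.3, tolerance = 1e-12)

  # channels with expectation below the floor are excluded (NA)
  expect_true(all(is.na(rep0$residuals[expected < 10])))

  # grids must match
  expect_error(decay_residuals(sim[1:10], expected), "length")
})

test_that("histograms round-trip through the TSV format", {
  sc <- pair_scene_at(5)
  pp <- default_params(P_excitation = 1)
  h <- run_simulation(sc, pp, sim_config(photon_threshold = 200, seed = 31))
  path <- tempfile(fileext = ".tsv")
  write_histogram(h, path)
  back <- read_histogram(path)
  expect_equal(back$counts, h$counts)
  expect_equal(back$time, h$time, tolerance = 1e-9)
  expect_equal(back$cycles, h$cycles)
  expect_equal(back$fret_total, h$fret_total)
})

test_that("early deviations shrink with the photon threshold", {
  fib <- donor_only_fibril()
  pp <- default_params(R0 = 4.7)
  st <- threshold_study(fib, pp, sim_config(), thresholds = c(100, 10000),
                        seeds = 1:8)
  m <- tapply(st$max_early_abs, st$threshold, mean)
  # statistical ordering: low-threshold runs deviate far more ...
  expect_gt(m[["100"]], m[["10000"]])
  # ... and roughly like counting error, i.e. by about sqrt(100) = 10
  expect_gt(m[["100"]] / m[["10000"]], 3)

  # single (threshold, seed) combination gives a one-row table
  st1 <- threshold_study(fib, pp, sim_config(), thresholds = 500, seeds = 7)
  expect_equal(nrow(st1), 1L)
  expect_s3_class(st1, "threshold_study")
})

test_that("the excitation probability does not distort dilute decays", {
  # dense fibril with donors and acceptors: at low excitation probability
  # the decay is invariant, far above it donor competition for shared
  # acceptors slows the apparent decay
  set.seed(33)
  fib <- fibril_scene(fibril_model(n_monomers = 300))
  cfg <- sim_config(photon_threshold = 400)
  mean_arrival <- function(p_exc, seed) {
    cfg$seed <- seed
    h <- run_simulation(fib, default_params(R0 = 4.7,
                                            P_excitation = p_exc), cfg)
    y <- h$counts[, "emission"]
    m <- sum(h$time * y) / sum(y)
    # standard error of the mean arrival time
    c(m, sqrt(sum((h$time - m)^2 * y)) / sum(y), sum(y))
  }
  lo1 <- mean_arrival(0.002, 34)
  lo2 <- mean_arrival(0.01, 35)
  hi <- mean_arrival(0.5, 36)
  # the two dilute settings agree within counting error
  se12 <- sqrt(lo1[2]^2 + lo2[2]^2)
  expect_lt(abs(lo1[1] - lo2[1]), 4 * se12)
  # strong excitation visibly lengthens the decay (acceptor blocking)
  se_hi <- sqrt(lo2[2]^2 + hi[2]^2)
  expect_gt(hi[1] - lo2[1], 4 * se_hi)
})

test_that("flexible linkers brighten isolated pairs and quench fibrils", {
  # isolated pairs at 3 and 6 nm: the mean dye separation grows with the
  # linker radius ...
  sc_pair <- fixed_pair_scene(c(3, 6), pair_counts = 5, spacing = 32,
                              R0 = 5.4)
  mean_sep <- function(L) {
    set.seed(40)
    mean(replicate(400, {
      cfg <- resample_dye_positions(sc_pair, L, L)
      mean(vapply(seq_len(nrow(cfg$donor_positions)), function(i) {
        minimum_image_distance(cfg$donor_positions[i, ],
                               cfg$acceptor_positions[i, ],
                               sc_pair$box, sc_pair$periodic)
      }, 0))
    }))
  }
  seps <- vapply(c(0, 0.5, 1), mean_sep, 0)
  expect_true(all(diff(seps) > 0))

  # ... and so does the photon yield (less quenching)
  yield <- function(scene, params, seed, threshold = 500) {
    h <- run_simulation(scene, params,
                        sim_config(photon_threshold = threshold,
                                   seed = seed))
    c(total_photons(h) / h$excitations, h$excitations)
  }
  y0 <- yield(sc_pair, default_params(P_excitation = 1), 41)
  y1 <- yield(sc_pair, default_params(P_excitation = 1, linker_D = 1,
                                      linker_A = 1), 42)
  se <- sqrt(y0[1] * (1 - y0[1]) / y0[2] + y1[1] * (1 - y1[1]) / y1[2])
  expect_gt(y1[1] - y0[1], 3 * se)

  # dense multi-acceptor fibril lattice with label distances in the
  # FRET-sensitive band just above R0 (acceptors every 12 nm on two
  # protofilaments, donors midway, nearest acceptors at 6-6.5 nm for
  # R0 = 4.7): a small isotropic displacement increases quenching,
  # because above R0 the spherical average of the transfer efficiency
  # grows with displacement (r^-6 convexity beats the mean-distance
  # growth; below R0 the sign flips and a lattice behaves like isolated
  # pairs -- see the vignette)
  nrep <- 20; sp <- 12
  xa <- sp * (0:(nrep - 1)); xd <- xa + sp / 2
  mk <- function(x, y) cbind(x + 10, y + 10, 10)
  lattice <- fret_scene(c(2 * 10 + sp * nrep, 20, 20),
                        donor_sites = rbind(mk(xd, 1.25), mk(xd, -1.25)),
                        acceptor_sites = rbind(mk(xa, 1.25),
                                               mk(xa, -1.25)))
  f0 <- yield(lattice, default_params(R0 = 4.7, P_excitation = 0.2), 60,
              threshold = 1000)
  f1 <- yield(lattice, default_params(R0 = 4.7, P_excitation = 0.2,
                                      linker_D = 1, linker_A = 1), 70,
              threshold = 1000)
  se_f <- sqrt(f0[1] * (1 - f0[1]) / f0[2] + f1[1] * (1 - f1[1]) / f1[2])
  expect_lt(f1[1] - f0[1], -3 * se_f)
})
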