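test_that("filter magnitude responses match the analytic curves", {
  fs <- 20000
  t <- seq(0, 2, by = 1 / fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  amp <- function(f) {
    y <- filter_trace(sin(2 * pi * f * t), fs)
    sqrt(2) * sqrt(mean(y[mid]^2))
  }
  # zero-phase filtering applies |H|^2: analytic Butterworth magnitudes
  hp_mag <- function(f, fc = 100, n = 2) (f / fc)^n / sqrt(1 + (f / fc)^(2 * n))
  lp_mag <- function(f, fc = 3500, n = 4) 1 / sqrt(1 + (f / fc)^(2 * n))

  a10 <- amp(10)
  expect_lt(a10, 10^(-20 / 20))                         # > 20 dB down
  expect_equal(a10, hp_mag(10)^2, tolerance = 0.2)      # tracks analytic curve

  a50 <- amp(50)
  expect_lt(a50, 10^(-20 / 20))                         # notch center > 20 dB

  a1k <- amp(1000)
  expect_equal(a1k, 1, tolerance = 0.05)                # passband within 5%
  expect_equal(a1k, (hp_mag(1000) * lp_mag(1000))^2, tolerance = 0.05)

  expect_error(filter_trace(t, fs_hz = 6000),
               class = "axonsynkit_invalid_argument")
})

test_that("false positives on pure noise match the 5-SD Gaussian tail", {
  withr::with_seed(31, {
    x <- stats::rnorm(60 * 20000)
    spk <- detect_spikes(x, 20000)
    # two-sided 5-SD tail: 2 * N * (1 - pnorm(5)) ~ 0.7 expected events
    expected <- 2 * length(x) * (1 - stats::pnorm(5))
    expect_lt(length(spk), expected + 8)
  })
})

test_that("embedded high-SNR spikes are recovered through the full chain", {
  fs <- 20000
  withr::with_seed(32, {
    x <- stats::rnorm(60 * fs, 0, 3)
    tmpl <- axonsynkit:::spike_template(fs) * 30      # 10x noise SD
    at <- round(seq(0.5, 59.5, length.out = 100) * fs)
    for (i in at) x[i:(i + length(tmpl) - 1)] <- x[i:(i + length(tmpl) - 1)] + tmpl
    spk <- detect_spikes(filter_trace(x, fs), fs)
    hits <- vapply(at / fs, function(t0) any(abs(spk - t0) < 0.002), logical(1))
    expect_gte(sum(hits), 99)
  })
  expect_warning(out <- detect_spikes(rep(0, 1000), 20000))
  expect_length(out, 0)
})

test_that("active electrodes require strictly more than 10 spikes/min", {
  rec <- structure(list(
    well_id = "w", div = 21, fs_hz = 20000, duration_s = 600, n_electrodes = 12,
    spikes = tibble::tibble(
      electrode_id = rep(1:2, c(101, 100)),
      t_s = c(seq(0, 599, length.out = 101), seq(0, 599, length.out = 100)))),
    class = "mea_recording")
  expect_equal(active_electrodes(rec), 1L)   # 10.1/min in, 10.0/min out
  silent <- rec; silent$spikes <- silent$spikes[0, ]
  expect_length(active_electrodes(silent), 0)
})

test_that("mean firing rate averages active electrodes only", {
  rec <- structure(list(
    well_id = "w", div = 21, fs_hz = 20000, duration_s = 600, n_electrodes = 12,
    spikes = tibble::tibble(
      electrode_id = rep(1:3, c(600, 1800, 3)),
      t_s = c(seq(0, 599.9, length.out = 600), seq(0, 599.9, length.out = 1800),
              c(1, 2, 3)))),
    class = "mea_recording")
  expect_equal(mean_firing_rate(rec), 2.0)   # (1 + 3)/2 Hz; electrode 3 inactive
  silent <- rec; silent$spikes <- silent$spikes[0, ]
  expect_warning(mfr0 <- mean_firing_rate(silent))
  expect_equal(mfr0, 0)
})

test_that("burst detection follows the 50/100 ms rule on worked examples", {
  b1 <- detect_bursts(c(0, 0.03, 0.06, 0.09, 0.5))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$t_start, 0); expect_equal(b1$t_end, 0.09)
  expect_equal(b1$n_spikes, 4L)

  expect_equal(nrow(detect_bursts(seq(0, 2, by = 0.2))), 0)

  # a gap of 0.08 s inside a seeded burst continues it
  b3 <- detect_bursts(c(0, 0.03, 0.11, 0.14, 0.17))
  expect_equal(b3$n_spikes, 5L)

  # a (0.05, 0.1] gap before seeding does not extend the burst backwards
  b4 <- detect_bursts(c(0, 0.08, 0.11, 0.14, 0.17))
  expect_equal(b4$t_start, 0.08)
  expect_equal(b4$n_spikes, 4L)
})

test_that("burst detector equals the exhaustive interval-scan oracle", {
  withr::with_seed(41, {
    for (i in 1:300) {
      n <- sample(0:50, 1)
      t <- sort(stats::runif(n, 0, 3))
      t <- t[c(TRUE, diff(t) > 1e-4)]
      got <- detect_bursts(t)
      want <- burst_scan_oracle(t)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(nrow(got), nrow(want))
        expect_equal(got$t_start, want$t_start)
        expect_equal(got$t_end, want$t_end)
        expect_equal(got$n_spikes, as.integer(want$n_spikes))
      }
    }
  })
})

test_that("bursts are disjoint and spikes belong to at most one burst", {
  withr::with_seed(42, {
    for (i in 1:30) {
      t <- sort(stats::runif(80, 0, 4))
      b <- detect_bursts(t)
      if (nrow(b) < 2) next
      b <- b[order(b$t_start), ]
      expect_true(all(b$t_start[-1] > b$t_end[-nrow(b)]))
    }
  })
})

test_that("network bursts need simultaneous bursting on >= 4 electrodes", {
  mk <- function(e, s, f) tibble::tibble(electrode_id = e, t_start = s, t_end = f)
  four <- dplyr::bind_rows(lapply(1:4, function(e) mk(e, 0.10, 0.20)))
  nb <- detect_network_bursts(four)
  expect_equal(nrow(nb), 1)
  expect_equal(nb$duration_s, 0.10)
  expect_setequal(nb$electrodes[[1]], 1:4)

  three <- dplyr::bind_rows(lapply(1:3, function(e) mk(e, 0.10, 0.20)))
  expect_equal(nrow(detect_network_bursts(three)), 0)

  # monotone non-increasing in the electrode requirement
  withr::with_seed(43, {
    many <- dplyr::bind_rows(lapply(1:12, function(e) {
      s <- sort(stats::runif(10, 0, 10))
      mk(e, s, s + 0.12)
    }))
    counts <- vapply(2:8, function(m) nrow(detect_network_bursts(many, m)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("generated network events are recovered by the detector", {
  p <- genotype_params("WT", mfr_base = 0.2, burst_rate = 0.5, netburst_rate = 6)
  truth <- 0; found <- 0
  for (i in 1:12) {
    rec <- gen_mea_recording(p, duration_s = 120, seed = 500 + i)
    bursts <- detect_well_bursts(rec)
    nb <- detect_network_bursts(bursts)
    truth <- truth + nrow(rec$truth$network)
    found <- found + nrow(nb)
  }
  expect_lt(abs(found - truth) / truth, 0.1)
})

test_that("well summaries assemble the per-well parameters", {
  p <- genotype_params("WT", mfr_base = 0, burst_rate = 0, netburst_rate = 0)
  silent <- gen_mea_recording(p, duration_s = 60, seed = 51)
  expect_equal(nrow(silent$spikes), 0)
  s <- suppressWarnings(summarize_well(silent))
  expect_equal(s$n_active, 0); expect_equal(s$mfr, 0); expect_equal(s$nb_freq, 0)

  # single active electrode with 2 bursts in 600 s -> 0.2 bursts/min
  spk <- sort(c(seq(0, 599, length.out = 200),
                5 + c(0, 0.02, 0.04, 0.06), 300 + c(0, 0.02, 0.04, 0.06)))
  rec <- structure(list(well_id = "w", div = 21, fs_hz = 20000,
                        duration_s = 600, n_electrodes = 12,
                        spikes = tibble::tibble(electrode_id = 1L, t_s = spk)),
                   class = "mea_recording")
  s2 <- summarize_well(rec)
  expect_equal(s2$n_active, 1)
  expect_equal(s2$burst_freq, 0.2)
})

test_that("spike counts follow the configured Poisson rate", {
  p <- genotype_params("WT", mfr_base = 1, burst_rate = 0, netburst_rate = 0)
  n <- vapply(1:3, function(i) {
    nrow(gen_mea_recording(p, duration_s = 600, seed = 60 + i)$spikes)
  }, numeric(1))
  # 12 electrodes x 600 s x 1 Hz = 7200 expected per well
  expect_lt(abs(mean(n) - 7200) / 7200, 0.05)
})

test_that("MFR is invariant to electrode relabeling", {
  p <- coculture_params(genotype_params("WT"))
  rec <- gen_mea_recording(p, duration_s = 60, seed = 71)
  base <- mean_firing_rate(rec)
  perm <- rec
  map <- sample(1:12)
  perm$spikes$electrode_id <- map[perm$spikes$electrode_id]
  expect_equal(mean_firing_rate(perm), base)
})
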