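#' Generate a synthetic MEA well recording
#'
#' Simulates one multi-electrode-array well (12 electrodes by default):
#' per electrode, background spikes are Poisson at `mfr_base` with burst
#' epochs superimposed (burst onsets Poisson at `burst_rate`/min; burst
#' size 3 + Geometric; within-burst inter-spike intervals Exponential
#' with 20 ms mean).  Network events at `netburst_rate`/min trigger
#' near-simultaneous bursts (onset jitter <= 20 ms) on a random subset of
#' at least 4 electrodes.  With `with_traces = TRUE` every spike is also
#' rendered as a biphasic 1 ms waveform (peak 10x the noise SD) on
#' Gaussian noise sampled at `fs_hz`, so the full voltage pipeline
#' (filtering, thresholding) can be exercised end to end.
#'
#' @param params a [genotype_params()] row (see [coculture_params()] for
#'   the astrocyte co-culture variant).
#' @param div days in vitro label carried into summaries.
#' @param duration_s recording length (default 600 s, the 10-minute
#'   session).
#' @param seed integer seed.
#' @param with_traces render raw voltage traces as well as spike times.
#' @param fs_hz sampling rate (default 20 kHz).
#' @param n_electrodes electrodes per well (default 12).
#' @param noise_sd_uv trace noise SD in uV.
#' @param well_id identifier carried into summaries.
#'
#' @return Object of class `mea_recording`: list with `well_id`, `div`,
#'   `fs_hz`, `duration_s`, `n_electrodes`, `spikes` (tibble
#'   `electrode_id`, `t_s`), optional `traces` (samples x electrodes
#'   matrix, uV) and `truth` (ground-truth burst and network-event
#'   tables).
#' @examples
#' rec <- gen_mea_recording(genotype_params("WT"), duration_s = 60, seed = 1)
#' summarize_well(rec)
#' @export
gen_mea_recording <- function(params, div = 21, duration_s = 600, seed = NULL,
                              with_traces = FALSE, fs_hz = 20000,
                              n_electrodes = 12, noise_sd_uv = 3,
                              well_id = "well1") {
  check_positive(duration_s, "duration_s")
  local_seed_if(seed)

  ele_spikes <- vector("list", n_electrodes)
  truth_bursts <- list()

  # electrode-level background + bursts
  for (e in seq_len(n_electrodes)) {
    bg <- stats::runif(stats::rpois(1, params$mfr_base * duration_s), 0, duration_s)
    n_b <- stats::rpois(1, params$burst_rate * duration_s / 60)
    bt <- if (n_b) stats::runif(n_b, 0, duration_s) else numeric(0)
    bspk <- lapply(bt, function(t0) t0 + cumsum(c(0, stats::rexp(2 + stats::rgeom(1, 0.35), 1 / 0.02))))
    if (n_b) {
      truth_bursts[[e]] <- tibble::tibble(
        electrode_id = e,
        t_start = vapply(bspk, min, 1), t_end = vapply(bspk, max, 1),
        n_spikes = lengths(bspk))
    }
    ele_spikes[[e]] <- c(bg, unlist(bspk))
  }

  # network events
  n_net <- stats::rpois(1, params$netburst_rate * duration_s / 60)
  truth_net <- NULL
  if (n_net) {
    t_net <- sort(stats::runif(n_net, 0, max(1e-3, duration_s - 0.5)))
    net_rows <- list()
    for (i in seq_len(n_net)) {
      size <- sample(4:n_electrodes, 1)
      elecs <- sample(seq_len(n_electrodes), size)
      for (e in elecs) {
        on <- t_net[i] + stats::runif(1, 0, 0.02)
        spk <- on + cumsum(c(0, stats::rexp(3 + stats::rgeom(1, 0.3), 1 / 0.02)))
        ele_spikes[[e]] <- c(ele_spikes[[e]], spk)
      }
      net_rows[[i]] <- tibble::tibble(event_id = i, t_s = t_net[i],
                                      n_electrodes = size,
                                      electrodes = list(sort(elecs)))
    }
    truth_net <- dplyr::bind_rows(net_rows)
  }

  spikes <- purrr::imap(ele_spikes, function(t, e) {
    t <- sort(t[t >= 0 & t < duration_s])
    if (length(t) > 1) t <- t[c(TRUE, diff(t) >= 0.0015)]  # resolvable separation
    tibble::tibble(electrode_id = as.integer(e), t_s = t)
  }) |> dplyr::bind_rows()

  traces <- NULL
  if (with_traces) {
    n_smp <- round(duration_s * fs_hz)
    tmpl <- spike_template(fs_hz) * 10 * noise_sd_uv
    traces <- matrix(stats::rnorm(n_smp * n_electrodes, 0, noise_sd_uv),
                     n_smp, n_electrodes)
    for (e in seq_len(n_electrodes)) {
      st <- spikes$t_s[spikes$electrode_id == e]
      for (t0 in st) {
        i0 <- floor(t0 * fs_hz) + 1L
        idx <- i0:(i0 + length(tmpl) - 1L)
        ok <- idx <= n_smp
        traces[idx[ok], e] <- traces[idx[ok], e] + tmpl[ok]
      }
    }
  }

  structure(
    list(well_id = well_id, div = div, fs_hz = fs_hz, duration_s = duration_s,
         n_electrodes = n_electrodes, spikes = spikes, traces = traces,
         truth = list(bursts = dplyr::bind_rows(truth_bursts),
                      network = truth_net)),
    class = "mea_recording")
}

# biphasic 1 ms extracellular spike template, unit negative peak first
spike_template <- function(fs_hz) {
  n <- max(4L, round(fs_hz * 0.001))
  -sin(2 * pi * seq_len(n) / n)
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %s DIV%s | %d electrodes, %.0f s, %d spikes%s\n",
              x$well_id, x$div, x$n_electrodes, x$duration_s, nrow(x$spikes),
              if (is.null(x$traces)) "" else sprintf(" | traces @ %d Hz", x$fs_hz)))
  invisible(x)
}

#' Band-limit an extracellular voltage trace
#'
#' Cascade of a 2nd-order 100 Hz high-pass Butterworth, a 4th-order
#' 3500 Hz low-pass Butterworth, and a 50 Hz notch (biquad, Q = 30), each
#' applied zero-phase (forward-backward) so spike timing is preserved.
#'
#' @param trace numeric voltage series.
#' @param fs_hz sampling rate; must exceed twice the 3500 Hz low-pass
#'   corner.
#' @return Filtered series, same length.
#' @examples
#' x <- sin(2 * pi * 1000 * seq(0, 0.1, by = 1 / 20000))
#' y <- filter_trace(x, 20000)
#' @export
filter_trace <- function(trace, fs_hz) {
  if (fs_hz <= 2 * 3500) abort_bad_arg("`fs_hz` must exceed 7000 Hz")
  hp <- signal::butter(2, 100 / (fs_hz / 2), type = "high")
  lp <- signal::butter(4, 3500 / (fs_hz / 2), type = "low")
  nf <- notch_biquad(50, fs_hz, q = 30)
  x <- signal::filtfilt(hp, trace)
  x <- signal::filtfilt(lp, x)
  signal::filtfilt(nf, x)
}

# RBJ audio-EQ-cookbook notch biquad
notch_biquad <- function(f0, fs_hz, q = 30) {
  w0 <- 2 * pi * f0 / fs_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Threshold spike detection
#'
#' Baseline noise SD is estimated robustly as `median(|x|) / 0.6745`
#' (insensitive to the spikes themselves); samples exceeding
#' `k_sd` SD in either polarity are grouped into events separated by at
#' least the refractory dead time, and each event is stamped at its
#' extremum sample.
#'
#' @param trace filtered voltage series.
#' @param fs_hz sampling rate.
#' @param k_sd detection threshold in baseline SDs (default 5).
#' @param refractory_s dead time between events (default 1 ms).
#' @return Numeric vector of spike times (s).
#' @export
detect_spikes <- function(trace, fs_hz, k_sd = 5, refractory_s = 0.001) {
  sd0 <- stats::median(abs(trace)) / 0.6745
  if (sd0 == 0) {
    warning("flat trace: zero baseline SD, no spikes detected")
    return(numeric(0))
  }
  idx <- which(abs(trace) > k_sd * sd0)
  if (!length(idx)) return(numeric(0))
  gap <- round(refractory_s * fs_hz)
  grp <- cumsum(c(1L, as.integer(diff(idx) > gap)))
  peaks <- vapply(split(idx, grp), function(ii) ii[which.max(abs(trace[ii]))], 1)
  unname((peaks - 0.5) / fs_hz)
}

#' Re-detect spikes of a recording from its raw traces
#'
#' Runs [filter_trace()] and [detect_spikes()] on every electrode trace
#' and replaces the recording's spike table with the detected times.
#'
#' @param well an `mea_recording` with traces.
#' @inheritParams detect_spikes
#' @return The recording with `spikes` replaced by detected times.
#' @export
detect_mea_spikes <- function(well, k_sd = 5) {
  if (is.null(well$traces)) abort_bad_arg("recording carries no raw traces")
  spk <- purrr::map(seq_len(well$n_electrodes), function(e) {
    f <- filter_trace(well$traces[, e], well$fs_hz)
    tibble::tibble(electrode_id = as.integer(e),
                   t_s = detect_spikes(f, well$fs_hz, k_sd))
  })
  well$spikes <- dplyr::bind_rows(spk)
  well
}

#' Active electrodes of a well
#'
#' Electrodes whose firing rate strictly exceeds `min_rate_per_min`
#' (default: more than 10 spikes per minute).
#'
#' @param well an `mea_recording`.
#' @param min_rate_per_min activity bound, spikes/min.
#' @return Integer vector of active electrode ids.
#' @export
active_electrodes <- function(well, min_rate_per_min = 10) {
  counts <- table(factor(well$spikes$electrode_id, levels = seq_len(well$n_electrodes)))
  rate <- as.numeric(counts) / (well$duration_s / 60)
  which(rate > min_rate_per_min)
}

#' Well mean firing rate
#'
#' Mean of per-electrode firing rates over active electrodes only; 0
#' (with a warning) when no electrode is active.
#'
#' @inheritParams active_electrodes
#' @return Spikes per second.
#' @export
mean_firing_rate <- function(well, min_rate_per_min = 10) {
  act <- active_electrodes(well, min_rate_per_min)
  if (!length(act)) {
    warning("no active electrodes; mean firing rate reported as 0")
    return(0)
  }
  counts <- table(factor(well$spikes$electrode_id, levels = seq_len(well$n_electrodes)))
  mean(as.numeric(counts[act]) / well$duration_s)
}

#' Burst detection on one spike train
#'
#' A burst is seeded by two spikes with inter-spike interval at most
#' `isi_join_s` (50 ms); once seeded it continues through gaps up to
#' `quiet_s` (100 ms) and terminates at the first gap longer than
#' `quiet_s`.  A leading gap in (`isi_join_s`, `quiet_s`] does not extend
#' a burst backwards.  Candidates with fewer than `min_spikes` spikes are
#' dropped.  Bursts on one electrode never overlap and each spike belongs
#' to at most one burst.
#'
#' @param spike_times sorted numeric spike times (s).
#' @param isi_join_s seeding inter-spike interval (default 0.05 s).
#' @param quiet_s terminating quiet period (default 0.1 s).
#' @param min_spikes minimum spikes per burst (default 3).
#' @return Tibble `t_start`, `t_end`, `n_spikes`, one row per burst.
#' @examples
#' detect_bursts(c(0, 0.03, 0.11, 0.14, 0.17, 1))
#' @export
detect_bursts <- function(spike_times, isi_join_s = 0.05, quiet_s = 0.1,
                          min_spikes = 3) {
  n <- length(spike_times)
  empty <- tibble::tibble(t_start = double(), t_end = double(), n_spikes = integer())
  if (n < 2) return(empty)
  if (is.unsorted(spike_times)) abort_bad_arg("spike times must be sorted")
  gaps <- diff(spike_times)

  # maximal runs of gaps <= quiet_s; within each, the burst starts at the
  # first gap <= isi_join_s and runs to the end of the block
  in_block <- gaps <= quiet_s
  r <- rle(in_block)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- list()
  for (b in which(r$values)) {
    g <- starts[b]:ends[b]                       # gap indices of the block
    seed <- g[gaps[g] <= isi_join_s][1]
    if (is.na(seed)) next
    first_spike <- seed                          # gap i joins spikes i, i+1
    last_spike <- ends[b] + 1
    n_spk <- last_spike - first_spike + 1
    if (n_spk >= min_spikes) {
      out[[length(out) + 1]] <- tibble::tibble(
        t_start = spike_times[first_spike], t_end = spike_times[last_spike],
        n_spikes = as.integer(n_spk))
    }
  }
  if (!length(out)) empty else dplyr::bind_rows(out)
}

#' Burst detection across a well
#'
#' @param well an `mea_recording`.
#' @param electrodes electrode ids to scan (default: all).
#' @inheritParams detect_bursts
#' @return Tibble `electrode_id`, `t_start`, `t_end`, `n_spikes`.
#' @export
detect_well_bursts <- function(well, electrodes = seq_len(well$n_electrodes),
                               isi_join_s = 0.05, quiet_s = 0.1, min_spikes = 3) {
  purrr::map(electrodes, function(e) {
    b <- detect_bursts(well$spikes$t_s[well$spikes$electrode_id == e],
                       isi_join_s, quiet_s, min_spikes)
    if (nrow(b)) dplyr::mutate(b, electrode_id = as.integer(e), .before = 1) else NULL
  }) |> dplyr::bind_rows()
}

#' Network-burst detection
#'
#' Sweeps the union of per-electrode burst intervals and reports the
#' maximal time spans during which at least `min_electrodes` electrodes
#' are simultaneously within a burst.
#'
#' @param bursts tibble `electrode_id`, `t_start`, `t_end` (from
#'   [detect_well_bursts()]).
#' @param min_electrodes simultaneity requirement (default 4).
#' @return Tibble `nb_id`, `t_start`, `t_end`, `duration_s`,
#'   `n_electrodes`, `electrodes` (list-column of participating ids).
#' @export
detect_network_bursts <- function(bursts, min_electrodes = 4) {
  empty <- tibble::tibble(nb_id = integer(), t_start = double(), t_end = double(),
                          duration_s = double(), n_electrodes = integer(),
                          electrodes = list())
  if (is.null(bursts) || !nrow(bursts)) return(empty)
  ev_t <- c(bursts$t_start, bursts$t_end)
  ev_d <- rep(c(1L, -1L), each = nrow(bursts))
  o <- order(ev_t, -ev_d)                      # starts before ends at ties
  depth <- cumsum(ev_d[o])
  t_sorted <- ev_t[o]

  above <- depth >= min_electrodes
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1
  spans <- which(r$values)
  out <- purrr::imap(spans, function(b, i) {
    t0 <- t_sorted[starts_i[b]]
    # the span closes at the event that drops the count below the bound
    t1 <- if (ends_i[b] < length(t_sorted)) t_sorted[ends_i[b] + 1] else t_sorted[ends_i[b]]
    part <- sort(unique(bursts$electrode_id[bursts$t_start <= t1 & bursts$t_end >= t0]))
    tibble::tibble(nb_id = i, t_start = t0, t_end = t1,
                   duration_s = t1 - t0,
                   n_electrodes = length(part), electrodes = list(part))
  })
  dplyr::bind_rows(out)
}

#' Per-well activity summary
#'
#' Assembles the well-level MEA parameters: active electrode count, mean
#' firing rate over active electrodes, burst frequency (total bursts on
#' active electrodes per minute) and mean burst duration, and
#' network-burst frequency and mean duration.
#'
#' @param well an `mea_recording`.
#' @param from_traces detect spikes from raw voltage first (requires
#'   traces).
#' @inheritParams detect_bursts
#' @param min_electrodes network-burst simultaneity requirement.
#' @param min_rate_per_min active-electrode bound, spikes/min.
#' @return One-row tibble: `well_id`, `div`, `n_active`, `mfr`,
#'   `burst_freq`, `burst_dur_mean`, `nb_freq`, `nb_dur_mean`.
#' @export
summarize_well <- function(well, from_traces = FALSE, min_rate_per_min = 10,
                           isi_join_s = 0.05, quiet_s = 0.1, min_spikes = 3,
                           min_electrodes = 4) {
  if (from_traces) well <- detect_mea_spikes(well)
  act <- active_electrodes(well, min_rate_per_min)
  mfr <- if (length(act)) suppressWarnings(mean_firing_rate(well, min_rate_per_min)) else 0
  mins <- well$duration_s / 60

  bursts <- if (length(act)) {
    detect_well_bursts(well, act, isi_join_s, quiet_s, min_spikes)
  } else NULL
  nb <- detect_network_bursts(bursts %||% tibble::tibble(), min_electrodes)

  tibble::tibble(
    well_id = well$well_id, div = well$div,
    n_active = length(act), mfr = mfr,
    burst_freq = if (is.null(bursts)) 0 else nrow(bursts) / mins,
    burst_dur_mean = if (is.null(bursts) || !nrow(bursts)) NA_real_ else mean(bursts$t_end - bursts$t_start),
    nb_freq = nrow(nb) / mins,
    nb_dur_mean = if (nrow(nb)) mean(nb$duration_s) else NA_real_
  )
}
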