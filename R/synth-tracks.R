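#' Generate ground-truth SVP transport tracks
#'
#' Simulates motile synaptic-vesicle-precursor (SVP) cargo along a set of
#' axons as piecewise-constant-velocity polylines, the same representation a
#' manual kymograph tracer records (one coordinate per inflection point).
#' Per axon, anterograde and retrograde track counts are Poisson with means
#' `antero_flux * duration_s / 60` and `retro_flux * duration_s / 60`.
#'
#' Segment speeds follow a "fast run" model: in each axon and direction,
#' five designated run segments have speeds drawn from
#' `Normal(vmax_mean, 0.03 * vmax_mean)` while all other moving segments
#' cruise at `vmax_mean * Uniform(0.4, 0.85)`, so the mean of the five
#' fastest segment speeds per axon — the "maximum velocity" statistic —
#' equals the preset `antero_vmax_mean` / `retro_vmax_mean` in expectation
#' by construction.  Pause segments (speed < 0.1 um/s) occur with
#' probability 0.3 per segment and are excluded from that statistic
#' downstream.  Track brightness is LogNormal, scaled by
#' `intensity_scale`.
#'
#' @param params a [genotype_params()] row.
#' @param n_axons number of axons to simulate.
#' @param duration_s movie duration in seconds (default 300 s, i.e. the
#'   5-minute live-imaging session).
#' @param length_um axon segment length in micrometres (default 100).
#' @param seed integer seed; identical seeds give identical output.
#'
#' @return A tibble of inflection points, one row per point, columns:
#'   `axon_id`, `track_id`, `direction` (ground truth, `"anterograde"` or
#'   `"retrograde"`), `intensity` (AU), `origin` (`"generated"`),
#'   `fast_run` (ground-truth flag of the segment *starting* at this
#'   point), `t_s`, `x_um`.  Times are strictly increasing within a track.
#'
#' @examples
#' trk <- gen_svp_tracks(genotype_params("WT"), n_axons = 2, seed = 1)
#' dplyr::count(trk, axon_id, track_id)
#' @export
gen_svp_tracks <- function(params, n_axons, duration_s = 300,
                           length_um = 100, seed = NULL) {
  check_positive(duration_s, "duration_s")
  check_positive(length_um, "length_um")
  check_positive(n_axons, "n_axons")
  local_seed_if(seed)

  out <- purrr::map(seq_len(n_axons), function(ax) {
    axon_tracks(params, ax, duration_s, length_um)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out)) out$intensity <- out$intensity * params$intensity_scale
  out
}

# One axon: Poisson counts per direction, skeletons, fast-run assignment.
axon_tracks <- function(params, axon_id, duration_s, length_um) {
  n_a <- stats::rpois(1, params$antero_flux * duration_s / 60)
  n_r <- stats::rpois(1, params$retro_flux * duration_s / 60)
  dirs <- rep(c("anterograde", "retrograde"), c(n_a, n_r))
  if (!length(dirs)) return(NULL)

  tracks <- purrr::imap(dirs, function(dir, i) {
    track_skeleton(i, dir)
  })
  segs <- dplyr::bind_rows(tracks)

  # fast-run assignment: five designated run segments per direction
  for (dir in c("anterograde", "retrograde")) {
    mov <- which(segs$direction == dir & !segs$pause)
    if (!length(mov)) next
    vmax <- if (dir == "anterograde") params$antero_vmax_mean else params$retro_vmax_mean
    fast <- if (length(mov) <= 5) mov else sample(mov, 5)
    segs$fast_run[fast] <- TRUE
    segs$speed[fast] <- pmax(0.15, stats::rnorm(length(fast), vmax, 0.03 * vmax))
    cruise <- setdiff(mov, fast)
    segs$speed[cruise] <- vmax * stats::runif(length(cruise), 0.4, 0.85)
  }
  segs$speed[segs$pause] <- stats::runif(sum(segs$pause), 0, 0.08)

  pts <- segs |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(g, key) {
      track_points(g, key$track_id, duration_s, length_um)
    }) |>
    dplyr::bind_rows()
  pts$axon_id <- axon_id
  dplyr::relocate(pts, "axon_id")
}

# Segment skeleton for one track: count, pause flags, durations.
track_skeleton <- function(track_id, direction) {
  n_seg <- sample(3:5, 1)
  pause <- stats::runif(n_seg) < 0.3
  if (all(pause)) pause[1] <- FALSE
  dur <- ifelse(pause, stats::runif(n_seg, 1, 3), stats::runif(n_seg, 2, 6))
  tibble::tibble(
    track_id = track_id, direction = direction, seg = seq_len(n_seg),
    pause = pause, dur = dur, speed = NA_real_, fast_run = FALSE
  )
}

# Geometry for one track once speeds are fixed: pick start time/position,
# guarantee net displacement >= 15 um (well clear of the 10 um motile
# classification bound), truncate at the axon boundary if need be.
track_points <- function(g, track_id, duration_s, length_um) {
  sgn <- if (g$direction[1] == "anterograde") 1 else -1
  # drift direction of pauses is random, magnitude ~0
  drift_sgn <- ifelse(g$pause, sample(c(-1, 1), nrow(g), replace = TRUE), sgn)
  disp <- g$speed * g$dur * drift_sgn
  net <- sum(disp)

  if (abs(net) < 15) {  # extend the longest run so the track is clearly motile
    i <- which(!g$pause)[which.max(g$dur[!g$pause] * g$speed[!g$pause])]
    need <- (15 + stats::runif(1, 0, 5) - abs(net)) / g$speed[i]
    g$dur[i] <- g$dur[i] + need
    disp[i] <- disp[i] + sgn * need * g$speed[i]
    net <- sum(disp)
  }

  total <- sum(g$dur)
  if (total > 0.9 * duration_s) {            # short-movie fallback
    f <- 0.9 * duration_s / total
    g$dur <- g$dur * f
    disp <- disp * f
    net <- sum(disp)
    total <- sum(g$dur)
  }
  t0 <- stats::runif(1, 0, duration_s - total)

  span <- abs(net)
  # 0.5 um margin keeps pause drift from nudging the path out of bounds
  if (sgn > 0) {
    x0 <- if (span < length_um - 1) stats::runif(1, 0.5, length_um - span - 0.5) else 0
  } else {
    x0 <- if (span < length_um - 1) stats::runif(1, span + 0.5, length_um - 0.5) else length_um
  }

  t <- t0 + cumsum(c(0, g$dur))
  x <- x0 + cumsum(c(0, disp))

  # truncate where the path leaves [0, length_um] (only when span >= length)
  out_of <- x < 0 | x > length_um
  if (any(out_of)) {
    k <- which(out_of)[1]
    bound <- if (x[k] < 0) 0 else length_um
    frac <- (bound - x[k - 1]) / (x[k] - x[k - 1])
    t <- c(t[seq_len(k - 1)], t[k - 1] + frac * (t[k] - t[k - 1]))
    x <- c(x[seq_len(k - 1)], bound)
    g <- g[seq_len(k - 1), , drop = FALSE]
  }

  tibble::tibble(
    track_id = track_id,
    direction = g$direction[1],
    intensity = stats::rlnorm(1, log(400), 0.3),
    origin = "generated",
    fast_run = c(g$fast_run, FALSE),
    t_s = t, x_um = x
  )
}
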