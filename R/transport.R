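#' Classify tracks by net displacement
#'
#' A track is anterograde if its net displacement (last minus first
#' position) strictly exceeds `min_net_um` in the anterograde direction
#' (increasing coordinate), retrograde if it strictly exceeds `min_net_um`
#' the other way, and non-motile otherwise.  A net displacement of exactly
#' `min_net_um` is non-motile (strict inequality).
#'
#' @param tracks track point tibble (`track_id`, `t_s`, `x_um`, optionally
#'   `axon_id`); coordinates must increase anterogradely (flip upstream if
#'   your acquisition is oriented the other way).
#' @param min_net_um motility bound, default 10 um.
#' @return One row per track: `axon_id`, `track_id`, `net_um`, `class`
#'   (`"anterograde"`, `"retrograde"` or `"non_motile"`).
#' @examples
#' trk <- gen_svp_tracks(genotype_params("WT"), 1, seed = 3)
#' classify_tracks(trk)
#' @export
classify_tracks <- function(tracks, min_net_um = 10) {
  tracks <- ensure_axon_id(tracks)
  tracks |>
    dplyr::group_by(.data$axon_id, .data$track_id) |>
    dplyr::arrange(.data$t_s, .by_group = TRUE) |>
    dplyr::summarise(net_um = dplyr::last(.data$x_um) - dplyr::first(.data$x_um),
                     .groups = "drop") |>
    dplyr::mutate(class = dplyr::case_when(
      .data$net_um >  min_net_um ~ "anterograde",
      .data$net_um < -min_net_um ~ "retrograde",
      TRUE ~ "non_motile"
    ))
}

ensure_axon_id <- function(tracks) {
  if (!"axon_id" %in% names(tracks)) tracks$axon_id <- 1L
  tracks
}

#' Instantaneous segment velocities of one track
#'
#' Speeds between consecutive inflection points, |dx|/dt; the signed
#' velocity is kept alongside.
#'
#' @param track point tibble for a single track (`t_s`, `x_um`).
#' @return One row per inter-inflection segment: `t_s` (segment start),
#'   `dt_s`, `dx_um`, `velocity` (signed um/s) and `speed` (um/s).
#' @examples
#' segment_velocities(tibble::tibble(t_s = c(0, 5), x_um = c(0, 20)))
#' @export
segment_velocities <- function(track) {
  track <- track[order(track$t_s), ]
  if (nrow(track) < 2) abort_bad_arg("a track needs at least 2 points")
  dt <- diff(track$t_s)
  if (any(dt == 0)) abort_bad_arg("repeated timestamps in track")
  dx <- diff(track$x_um)
  tibble::tibble(t_s = track$t_s[-nrow(track)], dt_s = dt, dx_um = dx,
                 velocity = dx / dt, speed = abs(dx) / dt)
}

# all segments of a track collection, carrying grouping ids
all_segments <- function(tracks) {
  tracks <- ensure_axon_id(tracks)
  tracks |>
    dplyr::group_by(.data$axon_id, .data$track_id) |>
    dplyr::group_modify(~ segment_velocities(.x)) |>
    dplyr::ungroup()
}

#' Per-axon "maximum velocity": mean of the k fastest segment speeds
#'
#' Pools the instantaneous segment speeds of all tracks of the requested
#' direction within each axon, drops pause segments (speed below
#' `min_speed`), and averages the `k` fastest.  When fewer than `k`
#' segments are available the mean of all of them is returned and the row
#' is flagged.  Axons with no motile track in the requested direction are
#' absent from the output (the statistic is undefined, not zero).
#'
#' @param tracks track point tibble.
#' @param direction `"anterograde"` or `"retrograde"`.
#' @param k number of fastest speeds averaged (default 5).
#' @param min_speed pause-exclusion bound, um/s (default 0.1).
#' @param min_dur_s minimum segment duration entering the pool (default
#'   1 s): instantaneous velocities come from sustained
#'   inflection-to-inflection runs, and sub-second kinks in automated
#'   traces are linking artifacts, not movement.
#' @param min_net_um motility bound passed to [classify_tracks()].
#' @return One row per axon: `axon_id`, `vmax_um_s`, `n_segments`,
#'   `flagged`.
#' @examples
#' trk <- gen_svp_tracks(genotype_params("WT"), 2, seed = 4)
#' max_velocity(trk, "anterograde")
#' @export
max_velocity <- function(tracks, direction = c("anterograde", "retrograde"),
                         k = 5, min_speed = 0.1, min_net_um = 10,
                         min_dur_s = 1) {
  direction <- match.arg(direction)
  tracks <- ensure_axon_id(tracks)
  cls <- classify_tracks(tracks, min_net_um)
  keep <- cls[cls$class == direction, c("axon_id", "track_id")]
  if (!nrow(keep)) {
    return(tibble::tibble(axon_id = integer(), vmax_um_s = double(),
                          n_segments = integer(), flagged = logical()))
  }
  segs <- all_segments(dplyr::semi_join(tracks, keep, by = c("axon_id", "track_id")))
  segs |>
    dplyr::filter(.data$speed >= min_speed, .data$dt_s >= min_dur_s) |>
    dplyr::group_by(.data$axon_id) |>
    dplyr::summarise(
      vmax_um_s = mean(sort(.data$speed, decreasing = TRUE)[seq_len(min(k, dplyr::n()))]),
      n_segments = dplyr::n(),
      flagged = dplyr::n() < k,
      .groups = "drop"
    )
}

#' Directional SVP flux
#'
#' Number of tracks classified in the given direction per minute of
#' imaging; each track is counted once.
#'
#' @inheritParams max_velocity
#' @param duration_s imaging duration (s).
#' @param axon_ids optional vector of all imaged axon ids, so axons with
#'   zero motile tracks contribute explicit zero rows.
#' @return One row per axon: `axon_id`, `n_tracks`, `flux_per_min`.
#' @examples
#' trk <- gen_svp_tracks(genotype_params("WT"), 2, seed = 5)
#' flux(trk, "anterograde", duration_s = 300)
#' @export
flux <- function(tracks, direction = c("anterograde", "retrograde"),
                 duration_s, min_net_um = 10, axon_ids = NULL) {
  direction <- match.arg(direction)
  check_positive(duration_s, "duration_s")
  cls <- classify_tracks(tracks, min_net_um)
  out <- cls |>
    dplyr::group_by(.data$axon_id) |>
    dplyr::summarise(n_tracks = sum(.data$class == direction), .groups = "drop")
  if (!is.null(axon_ids)) {
    out <- dplyr::left_join(tibble::tibble(axon_id = axon_ids), out, by = "axon_id") |>
      dplyr::mutate(n_tracks = dplyr::coalesce(.data$n_tracks, 0L))
  }
  dplyr::mutate(out, flux_per_min = .data$n_tracks / (duration_s / 60))
}

#' Retrograde/anterograde flux ratio
#'
#' @param summary a per-axon transport summary with `antero_flux` and
#'   `retro_flux` columns (see [summarize_transport()]).
#' @return The summary with `flux_ratio` (NA and flagged where the
#'   anterograde flux is zero).
#' @export
flux_ratio <- function(summary) {
  summary |>
    dplyr::mutate(
      flux_ratio = dplyr::if_else(.data$antero_flux > 0,
                                  .data$retro_flux / .data$antero_flux,
                                  NA_real_),
      ratio_flagged = .data$antero_flux == 0
    )
}

#' Motile-cargo entry intensity
#'
#' Maximum pixel value in a 3x3 window at a track's first point, minus the
#' local background (median of that time row, excluding pixels near any
#' supplied track position), mirroring an intensity measurement taken as a
#' moving SVP enters the field.
#'
#' @param kymo a [kymograph()].
#' @param track point tibble of the track measured.
#' @param all_tracks optional point tibble of every traced track, used to
#'   exclude occupied pixels from the background estimate (defaults to
#'   `track`).
#' @return Background-subtracted intensity (AU).
#' @export
motile_intensity <- function(kymo, track, all_tracks = NULL) {
  track <- track[order(track$t_s), ]
  r <- round(track$t_s[1] / kymo$dt_s + 0.5)
  c0 <- round(track$x_um[1] / kymo$px_um + 0.5)
  n_row <- nrow(kymo$values); n_col <- ncol(kymo$values)
  if (r < 1 || r > n_row || c0 < 1 || c0 > n_col) {
    abort_bad_arg("track first point lies outside the kymograph grid")
  }
  rows <- pmax(1, r - 1):pmin(n_row, r + 1)
  cols <- pmax(1, c0 - 1):pmin(n_col, c0 + 1)
  peak <- max(kymo$values[rows, cols])

  occupied <- all_tracks %||% track
  row_t <- (r - 0.5) * kymo$dt_s
  occ_cols <- unique(unlist(lapply(
    split(occupied, occupied$track_id %||% 1L),
    function(tr) {
      tr <- tr[order(tr$t_s), ]
      if (row_t < tr$t_s[1] || row_t > tr$t_s[nrow(tr)]) return(integer(0))
      xc <- stats::approx(tr$t_s, tr$x_um, xout = row_t)$y
      cc <- round(xc / kymo$px_um + 0.5)
      (cc - 5):(cc + 5)
    })))
  bg_cols <- setdiff(seq_len(n_col), occ_cols)
  if (!length(bg_cols)) bg_cols <- seq_len(n_col)
  peak - stats::median(kymo$values[r, bg_cols])
}

#' Per-axon transport summary
#'
#' Assembles the per-axon SVP transport metrics: anterograde and
#' retrograde flux, their ratio, and the top-`k` "maximum velocity" in
#' both directions.
#'
#' @inheritParams flux
#' @param k fastest-speed pool size for [max_velocity()].
#' @return One row per axon with columns `axon_id`, `antero_flux`,
#'   `retro_flux`, `flux_ratio`, `ratio_flagged`, `antero_vmax`,
#'   `retro_vmax`.
#' @examples
#' trk <- gen_svp_tracks(genotype_params("WT"), 3, seed = 6)
#' summarize_transport(trk, duration_s = 300)
#' @export
summarize_transport <- function(tracks, duration_s, k = 5, min_net_um = 10,
                                axon_ids = NULL) {
  axon_ids <- axon_ids %||% sort(unique(ensure_axon_id(tracks)$axon_id))
  fa <- flux(tracks, "anterograde", duration_s, min_net_um, axon_ids)
  fr <- flux(tracks, "retrograde", duration_s, min_net_um, axon_ids)
  va <- max_velocity(tracks, "anterograde", k, min_net_um = min_net_um)
  vr <- max_velocity(tracks, "retrograde", k, min_net_um = min_net_um)
  tibble::tibble(axon_id = axon_ids) |>
    dplyr::left_join(dplyr::select(fa, "axon_id", antero_flux = "flux_per_min"), by = "axon_id") |>
    dplyr::left_join(dplyr::select(fr, "axon_id", retro_flux = "flux_per_min"), by = "axon_id") |>
    flux_ratio() |>
    dplyr::left_join(dplyr::select(va, "axon_id", antero_vmax = "vmax_um_s"), by = "axon_id") |>
    dplyr::left_join(dplyr::select(vr, "axon_id", retro_vmax = "vmax_um_s"), by = "axon_id")
}
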