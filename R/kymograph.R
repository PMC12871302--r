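#' Kymograph container
#'
#' A kymograph is a space-time intensity grid for one axon: rows are time
#' samples, columns are positions along the axon.  Moving cargo appears as
#' sloped streaks, stationary accumulations as vertical bands.
#'
#' @param values numeric matrix, rows = time, columns = space.
#' @param px_um micrometres per spatial pixel (> 0).
#' @param dt_s seconds per time row (> 0).
#' @return An object of class `kymograph`: a list with `values`, `px_um`,
#'   `dt_s`, `length_um` and `duration_s`.
#' @examples
#' k <- kymograph(matrix(0, 10, 20), px_um = 0.16, dt_s = 0.2)
#' dim(k$values)
#' @export
kymograph <- function(values, px_um, dt_s) {
  check_positive(px_um, "px_um")
  check_positive(dt_s, "dt_s")
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_bad_arg("`values` must be a numeric matrix (time x space).")
  }
  structure(
    list(values = values, px_um = px_um, dt_s = dt_s,
         length_um = ncol(values) * px_um,
         duration_s = nrow(values) * dt_s),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d rows x %d cols | %.1f um @ %.3g um/px | %.1f s @ %.3g s/row\n",
              nrow(x$values), ncol(x$values), x$length_um, x$px_um,
              x$duration_s, x$dt_s))
  invisible(x)
}

#' Render tracks and stationary sites into a synthetic kymograph
#'
#' Paints each track as a 3-pixel-wide anti-aliased streak (Gaussian
#' cross-section, unit peak) of its brightness over a constant background
#' with Gaussian read noise, emulating a photobleached-background
#' live-imaging acquisition.  Stationary SVP+ sites are painted as
#' vertical bands spanning the whole recording.
#'
#' @param tracks track point tibble ([gen_svp_tracks()] format) or `NULL`.
#' @param sites site tibble (`centroid_um`, `extent_um`, `mean_intensity`)
#'   or `NULL`.
#' @param length_um,duration_s physical span of the grid.
#' @param px_um,dt_s calibration (defaults 0.16 um/px and 0.2 s/row, the
#'   5 frames/s SVP acquisition; use `dt_s = 1` for comet-mode movies).
#' @param bg constant background level (AU).
#' @param noise_sd Gaussian read-noise SD (AU); 0 gives a noise-free
#'   render.
#' @param seed integer seed for the noise field.
#' @return A [kymograph()].
#' @examples
#' trk <- gen_svp_tracks(genotype_params("WT"), 1, seed = 1)
#' k <- render_kymograph(trk, length_um = 100, duration_s = 300, seed = 1)
#' @export
render_kymograph <- function(tracks = NULL, sites = NULL,
                             length_um = 100, duration_s = 300,
                             px_um = 0.16, dt_s = 0.2,
                             bg = 100, noise_sd = 10, seed = NULL) {
  check_positive(px_um, "px_um")
  check_positive(dt_s, "dt_s")
  check_positive(length_um, "length_um")
  check_positive(duration_s, "duration_s")
  local_seed_if(seed)

  n_row <- round(duration_s / dt_s)
  n_col <- round(length_um / px_um)
  v <- matrix(bg, n_row, n_col)
  if (noise_sd > 0) v <- v + matrix(stats::rnorm(n_row * n_col, 0, noise_sd), n_row, n_col)

  if (!is.null(tracks) && nrow(tracks)) {
    clipped <- FALSE
    for (tr in split(tracks, interaction(tracks$axon_id %||% 1, tracks$track_id, drop = TRUE))) {
      res <- paint_track(v, tr, px_um, dt_s, n_row, n_col)
      v <- res$v
      clipped <- clipped || res$clipped
    }
    if (clipped) warning("some track points fell outside the spatial span and were clipped")
  }

  if (!is.null(sites) && nrow(sites)) {
    col_centers <- (seq_len(n_col) - 0.5) * px_um
    for (i in seq_len(nrow(sites))) {
      d <- abs(col_centers - sites$centroid_um[i])
      w <- pmin(1, pmax(0, (sites$extent_um[i] / 2 + px_um / 2 - d) / px_um))
      hit <- which(w > 0)
      if (length(hit)) {
        v[, hit] <- v[, hit] + rep(w[hit] * sites$mean_intensity[i], each = n_row)
      }
    }
  }

  kymograph(v, px_um, dt_s)
}

# Paint one track polyline: per time row crossed by the track, a Gaussian
# profile (sigma 0.65 px, ~3 px wide, peak = track intensity).
paint_track <- function(v, tr, px_um, dt_s, n_row, n_col) {
  tr <- tr[order(tr$t_s), ]
  rows <- seq(ceiling(tr$t_s[1] / dt_s + 0.5), floor(tr$t_s[nrow(tr)] / dt_s + 0.5))
  rows <- rows[rows >= 1 & rows <= n_row]
  clipped <- FALSE
  if (!length(rows)) return(list(v = v, clipped = clipped))
  t_row <- (rows - 0.5) * dt_s
  x <- stats::approx(tr$t_s, tr$x_um, xout = t_row, rule = 2)$y
  inside <- x >= 0 & x <= n_col * px_um
  if (any(!inside)) clipped <- TRUE
  rows <- rows[inside]; x <- x[inside]
  if (!length(rows)) return(list(v = v, clipped = clipped))

  x_px <- x / px_um + 0.5           # continuous column coordinate
  cc <- round(x_px)
  for (off in -2:2) {
    col <- cc + off
    ok <- col >= 1 & col <= n_col
    if (!any(ok)) next
    d <- col[ok] - x_px[ok]
    w <- exp(-d^2 / (2 * 0.65^2))
    idx <- cbind(rows[ok], col[ok])
    v[idx] <- v[idx] + w * tr$intensity[1]
  }
  list(v = v, clipped = clipped)
}
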