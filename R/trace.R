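#' Trace motile tracks from a kymograph
#'
#' Automated replacement for manual kymograph tracing.  Per time row,
#' particles are detected as local intensity maxima above a robust
#' background threshold (global median + 3 MAD).  Detections are linked
#' row-to-row by nearest neighbour against a constant-velocity prediction
#' (maximum per-step displacement `max_step_um`, gap closing up to
#' `max_gap_rows` missed rows), and each linked path is simplified to its
#' inflection points by Douglas-Peucker with a 1-pixel tolerance — the
#' same representation a manual tracer records.  Paths shorter than
#' `min_len_um` of total travelled distance are discarded.
#'
#' @param kymo a [kymograph()].
#' @param min_len_um minimum total travelled distance (um) to keep a
#'   track; the default 5 um drops noise blips and stationary bands while
#'   keeping everything close to the 10 um motility bound.
#' @param max_step_um hard cap on the displacement between consecutive
#'   detections of one track, um (default 6: covers > 4 um/s at 5
#'   frames/s with margin).
#' @param max_gap_rows number of consecutive rows a track may go
#'   undetected before it is closed (default 4, i.e. 0.8 s at 5
#'   frames/s, enough to ride out a crossing where two particles merge
#'   into one detection).
#' @param max_speed_um_s physical speed bound used to scale the matching
#'   gate with elapsed time (default 6.5 um/s, above the fastest cargo);
#'   links implying faster movement are never made, which keeps isolated
#'   noise detections from chaining into spurious fast "tracks".
#' @param min_rows minimum number of detections per kept track (default
#'   5, i.e. one second of continuous detection at 5 frames/s).
#' @param dp_tol_px Douglas-Peucker simplification tolerance in pixels.
#'
#' @return A track point tibble (`track_id`, `origin = "traced"`, `t_s`,
#'   `x_um`), one row per inflection point.
#'
#' @examples
#' trk <- gen_svp_tracks(genotype_params("WT"), 1, seed = 2)
#' k <- render_kymograph(trk, noise_sd = 0)
#' traced <- trace_tracks(k)
#' @export
trace_tracks <- function(kymo, min_len_um = 5, max_step_um = 6,
                         max_gap_rows = 4, max_speed_um_s = 6.5,
                         min_rows = 5, dp_tol_px = 1) {
  if (!inherits(kymo, "kymograph")) {
    abort_bad_arg("`kymo` must be a calibrated `kymograph` object.")
  }
  v <- kymo$values
  n_row <- nrow(v); n_col <- ncol(v)
  thr <- stats::median(v) + 3 * robust_sd(v)

  # vectorised per-row local maxima above threshold
  left  <- cbind(-Inf, v[, -n_col, drop = FALSE])
  right <- cbind(v[, -1, drop = FALSE], -Inf)
  mask <- v > thr & v >= left & v > right
  hits <- which(mask, arr.ind = TRUE)
  if (!nrow(hits)) return(empty_tracks())
  det_by_row <- split((hits[, 2] - 0.5) * kymo$px_um, hits[, 1])

  paths <- link_detections(det_by_row, n_row, kymo$dt_s,
                           max_step_um, max_gap_rows, max_speed_um_s)

  out <- purrr::imap(paths, function(p, i) {
    if (length(p$row) < min_rows) return(NULL)
    x_f <- if (length(p$x) >= 5) stats::runmed(p$x, 5) else p$x
    keep <- dp_simplify(p$row, x_f / kymo$px_um, dp_tol_px)
    x <- x_f[keep]
    if (sum(abs(diff(x))) < min_len_um) return(NULL)
    tibble::tibble(
      track_id = as.integer(i), origin = "traced",
      t_s = (p$row[keep] - 0.5) * kymo$dt_s, x_um = x
    )
  })
  dplyr::bind_rows(out)
}

empty_tracks <- function() {
  tibble::tibble(track_id = integer(), origin = character(),
                 t_s = double(), x_um = double())
}

# Row-by-row greedy linking with constant-velocity prediction.
link_detections <- function(det_by_row, n_row, dt_s, max_step_um, max_gap_rows,
                            max_speed_um_s = 6.5) {
  finished <- list()
  act_x <- act_row <- act_vel <- act_x0 <- numeric(0)
  act_path <- list()

  close_track <- function(p) {
    if (length(p$row) >= 2) finished[[length(finished) + 1]] <<- p
  }

  for (r in as.integer(names(det_by_row))) {
    xs <- det_by_row[[as.character(r)]]
    n_act <- length(act_x)

    # close tracks whose gap has grown too large
    if (n_act) {
      stale <- (r - act_row) > (max_gap_rows + 1L)
      if (any(stale)) {
        for (i in which(stale)) close_track(act_path[[i]])
        keep <- !stale
        act_x <- act_x[keep]; act_row <- act_row[keep]; act_vel <- act_vel[keep]
        act_x0 <- act_x0[keep]; act_path <- act_path[keep]
        n_act <- length(act_x)
      }
    }

    assigned_det <- rep(FALSE, length(xs))
    if (n_act) {
      elapsed <- (r - act_row) * dt_s
      pred <- act_x + act_vel * elapsed
      # established tracks must match their constant-velocity prediction
      # closely even across a gap (a particle re-emerging from an
      # occlusion has kept its speed); only young tracks, whose velocity
      # is still unknown, get the wide speed-scaled gate
      n_pts <- lengths(lapply(act_path, `[[`, "row"))
      gate <- ifelse(n_pts >= 3,
                     pmin(max_step_um, 0.8 + 1.0 * elapsed),
                     pmin(max_step_um, max_speed_um_s * elapsed + 0.5))
      d <- abs(outer(pred, xs, "-"))
      d[d > gate] <- Inf
      # direction-consistency veto: a track with an established net
      # direction does not reverse abruptly into fast movement the other
      # way (prevents identity swaps where opposite-direction tracks
      # cross; resuming after a pause keeps the net direction and is
      # unaffected)
      net <- act_x - act_x0
      imp_v <- (matrix(xs, n_act, length(xs), byrow = TRUE) - act_x) / elapsed
      veto <- (abs(net) > 3) & (sign(imp_v) != sign(net)) & (abs(imp_v) > 0.8)
      d[veto] <- Inf
      repeat {
        m <- which.min(d)
        if (!length(m) || !is.finite(d[m])) break
        i <- (m - 1) %% n_act + 1
        j <- (m - 1) %/% n_act + 1
        v_new <- (xs[j] - act_x[i]) / ((r - act_row[i]) * dt_s)
        act_vel[i] <- if (length(act_path[[i]]$row) == 1L) v_new else 0.5 * act_vel[i] + 0.5 * v_new
        act_x[i] <- xs[j]; act_row[i] <- r
        act_path[[i]]$row <- c(act_path[[i]]$row, r)
        act_path[[i]]$x <- c(act_path[[i]]$x, xs[j])
        assigned_det[j] <- TRUE
        d[i, ] <- Inf; d[, j] <- Inf
      }
    }

    for (j in which(!assigned_det)) {  # new tracks
      act_x <- c(act_x, xs[j]); act_row <- c(act_row, r); act_vel <- c(act_vel, 0)
      act_x0 <- c(act_x0, xs[j])
      act_path[[length(act_path) + 1]] <- list(row = r, x = xs[j])
    }
  }
  for (p in act_path) close_track(p)
  finished
}

# Douglas-Peucker on x(t) using vertical deviation; returns indices kept.
dp_simplify <- function(t, x, tol) {
  n <- length(t)
  if (n <= 2) return(seq_len(n))
  keep <- logical(n); keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    a <- rng[1]; b <- rng[2]
    if (b - a < 2) next
    idx <- (a + 1):(b - 1)
    x_hat <- x[a] + (x[b] - x[a]) * (t[idx] - t[a]) / (t[b] - t[a])
    dev <- abs(x[idx] - x_hat)
    k <- which.max(dev)
    if (dev[k] > tol) {
      split_at <- idx[k]
      keep[split_at] <- TRUE
      stack <- c(stack, list(c(a, split_at)), list(c(split_at, b)))
    }
  }
  which(keep)
}
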