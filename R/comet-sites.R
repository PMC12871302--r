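#' Generate ground-truth SVP+ sites and microtubule comet events
#'
#' Emulates a comet-mode acquisition (plus-end marker plus stationary SVP
#' label, 1 frame/s): per axon, the number of stable SVP+ sites is Poisson
#' with mean `site_density * length_um / 10` and the number of comets is
#' Poisson with mean `comet_rate * length_um * duration_s / 60`.  A
#' fraction `assoc_prob` of comets initiates within 10 um of a site
#' centroid; the remainder initiate uniformly along the axon (when the
#' axon happens to carry no site, all comets fall back to uniform
#' placement).  Comet growth speeds are Normal(0.1, 0.02) um/s truncated
#' positive.  Site centroids follow a minimum-separation (3 um hard-core)
#' process so that distinct ground-truth sites stay resolvable.
#'
#' @param params a [genotype_params()] row.
#' @param n_axons number of axons.
#' @param length_um axon span (default 100 um).
#' @param duration_s movie duration (default 300 s).
#' @param seed integer seed.
#' @return A list with tibbles `sites` (`axon_id`, `site_id`,
#'   `centroid_um`, `extent_um`, `mean_intensity`) and `comets`
#'   (`axon_id`, `comet_id`, `t_start_s`, `x_start_um`, `t_end_s`,
#'   `x_end_um`, `velocity_um_s`, `assoc_truth`).
#' @examples
#' ax <- gen_comet_site_axon(genotype_params("WT"), n_axons = 2, seed = 1)
#' ax$sites
#' @export
gen_comet_site_axon <- function(params, n_axons = 1, length_um = 100,
                                duration_s = 300, seed = NULL) {
  check_positive(length_um, "length_um")
  check_positive(duration_s, "duration_s")
  local_seed_if(seed)

  sites <- list(); comets <- list()
  for (ax in seq_len(n_axons)) {
    s <- gen_sites_one(params, ax, length_um)
    k <- gen_comets_one(params, ax, s, length_um, duration_s)
    sites[[ax]] <- s; comets[[ax]] <- k
  }
  list(sites = dplyr::bind_rows(sites), comets = dplyr::bind_rows(comets))
}

gen_sites_one <- function(params, axon_id, length_um, min_sep = 3) {
  n <- stats::rpois(1, params$site_density * length_um / 10)
  cent <- numeric(0)
  tries <- 0
  while (length(cent) < n && tries < 200 * max(n, 1)) {
    cand <- stats::runif(1, 2, length_um - 2)
    if (!length(cent) || min(abs(cent - cand)) >= min_sep) cent <- c(cent, cand)
    tries <- tries + 1
  }
  n <- length(cent)
  tibble::tibble(
    axon_id = axon_id, site_id = seq_len(n),
    centroid_um = sort(cent),
    extent_um = stats::runif(n, 1, 3),
    mean_intensity = stats::rlnorm(n, log(300), 0.25)
  )
}

gen_comets_one <- function(params, axon_id, sites, length_um, duration_s) {
  n <- stats::rpois(1, params$comet_rate * length_um * duration_s / 60)
  if (!n) {
    return(tibble::tibble(axon_id = integer(), comet_id = integer(),
                          t_start_s = double(), x_start_um = double(),
                          t_end_s = double(), x_end_um = double(),
                          velocity_um_s = double(), assoc_truth = logical()))
  }
  has_sites <- nrow(sites) > 0
  assoc <- has_sites & stats::runif(n) < params$assoc_prob
  x0 <- stats::runif(n, 0, length_um)
  if (any(assoc)) {
    anchor <- sample(sites$centroid_um, sum(assoc), replace = TRUE)
    x0[assoc] <- pmin(length_um, pmax(0, anchor + stats::runif(sum(assoc), -10, 10)))
  }
  speed <- pmax(0.01, stats::rnorm(n, 0.1, 0.02))
  life <- stats::runif(n, 10, 60)
  dir <- ifelse(stats::runif(n) < 0.9, 1, -1)
  t0 <- stats::runif(n, 0, pmax(1e-3, duration_s - life))
  x1 <- x0 + dir * speed * life
  # truncate lifetimes at the axon boundary
  over <- x1 > length_um | x1 < 0
  bound <- ifelse(x1 > length_um, length_um, 0)
  life[over] <- (abs(bound - x0) / speed)[over]
  x1[over] <- bound[over]
  tibble::tibble(
    axon_id = axon_id, comet_id = seq_len(n),
    t_start_s = t0, x_start_um = x0,
    t_end_s = t0 + life, x_end_um = x1,
    velocity_um_s = dir * speed, assoc_truth = assoc
  )
}

#' Convert comet events to track polylines (for rendering)
#'
#' @param comets comet tibble from [gen_comet_site_axon()].
#' @param intensity painted streak brightness (AU).
#' @return A track point tibble usable by [render_kymograph()].
#' @export
comets_to_tracks <- function(comets, intensity = 300) {
  if (!nrow(comets)) return(empty_tracks())
  dplyr::bind_rows(
    dplyr::transmute(comets, axon_id = .data$axon_id, track_id = .data$comet_id,
                     intensity = intensity, t_s = .data$t_start_s, x_um = .data$x_start_um),
    dplyr::transmute(comets, axon_id = .data$axon_id, track_id = .data$comet_id,
                     intensity = intensity, t_s = .data$t_end_s, x_um = .data$x_end_um)
  ) |> dplyr::arrange(.data$axon_id, .data$track_id, .data$t_s)
}

#' Detect stable SVP+ sites in a comet-mode kymograph
#'
#' A site is a run of columns whose intensity stays above background
#' (global median + 3 MAD) in at least `min_frac_above` of the time rows —
#' the operational form of "stationary signal consistently above
#' background for the entire recording".  Runs separated by less than
#' `merge_gap_um` merge (the 3-pixel line width blurs band edges).
#'
#' @param kymo a [kymograph()] (1 s/row comet-mode render).
#' @param min_frac_above persistence fraction (default 0.95).
#' @param merge_gap_um merge distance for adjacent bright runs (um).
#' @return Site tibble: `site_id`, `centroid_um` (intensity-weighted),
#'   `extent_um`, `mean_intensity` (background-subtracted).
#' @examples
#' ax <- gen_comet_site_axon(genotype_params("WT"), seed = 2)
#' k <- render_kymograph(sites = ax$sites, dt_s = 1, seed = 2)
#' detect_svp_sites(k)
#' @export
detect_svp_sites <- function(kymo, min_frac_above = 0.95, merge_gap_um = 1) {
  v <- kymo$values
  bg <- stats::median(v)
  thr <- bg + 3 * robust_sd(v)
  frac <- colMeans(v > thr)
  flag <- frac >= min_frac_above

  # close sub-merge_gap gaps between flagged runs
  r <- rle(flag)
  gap_px <- merge_gap_um / kymo$px_um
  if (length(r$lengths) > 2) {
    inner <- 2:(length(r$lengths) - 1)
    fill <- inner[!r$values[inner] & r$lengths[inner] < gap_px]
    r$values[fill] <- TRUE
  }
  flag <- inverse.rle(r)

  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  if (!length(keep)) {
    return(tibble::tibble(site_id = integer(), centroid_um = double(),
                          extent_um = double(), mean_intensity = double()))
  }
  col_centers <- (seq_len(ncol(v)) - 0.5) * kymo$px_um
  col_mean <- colMeans(v)
  out <- purrr::map(seq_along(keep), function(i) {
    cols <- starts[keep[i]]:ends[keep[i]]
    w <- pmax(0, col_mean[cols] - bg)
    if (!sum(w)) w <- rep(1, length(cols))
    tibble::tibble(
      site_id = i,
      centroid_um = sum(col_centers[cols] * w) / sum(w),
      extent_um = length(cols) * kymo$px_um,
      mean_intensity = mean(col_mean[cols]) - bg
    )
  })
  dplyr::bind_rows(out)
}

#' Site density per 10 um
#'
#' @param sites site tibble (one axon).
#' @param length_um axon span.
#' @return Sites per 10 um of axon.
#' @export
site_density <- function(sites, length_um) {
  check_positive(length_um, "length_um")
  nrow(sites) / (length_um / 10)
}

#' Comet density
#'
#' Comet count normalized to kymograph length and time,
#' comets/um/min.
#'
#' @param comets comet tibble (one axon).
#' @param length_um axon span (um).
#' @param duration_s movie duration (s).
#' @export
comet_density <- function(comets, length_um, duration_s) {
  check_positive(length_um, "length_um")
  check_positive(duration_s, "duration_s")
  nrow(comets) / (length_um * duration_s / 60)
}

#' Flag comets associated with SVP+ sites
#'
#' A comet is associated when any point of its spatial span lies within
#' `window_um` of any site centroid (set `mode = "start"` to score only
#' the initiation point).
#'
#' @param comets comet tibble (one axon).
#' @param sites site tibble (same axon).
#' @param window_um association window, default 10 um.
#' @param mode `"span"` (default) or `"start"`.
#' @return `comets` with a logical `associated` column.
#' @export
associate_comets <- function(comets, sites, window_um = 10,
                             mode = c("span", "start")) {
  mode <- match.arg(mode)
  if (!nrow(comets)) return(dplyr::mutate(comets, associated = logical(0)))
  if (!nrow(sites)) return(dplyr::mutate(comets, associated = FALSE))
  lo <- pmin(comets$x_start_um, comets$x_end_um)
  hi <- pmax(comets$x_start_um, comets$x_end_um)
  if (mode == "start") {
    lo <- hi <- comets$x_start_um
  }
  assoc <- vapply(seq_len(nrow(comets)), function(i) {
    d <- pmax(0, pmax(lo[i] - sites$centroid_um, sites$centroid_um - hi[i]))
    any(d <= window_um)
  }, logical(1))
  dplyr::mutate(comets, associated = assoc)
}

#' Fraction of SVP+ sites visited by at least one comet
#'
#' A site counts as active when at least one comet starts, ends, or
#' passes through its spatial extent (centroid +/- half extent).
#'
#' @inheritParams associate_comets
#' @return A single fraction in \[0, 1\]; `NA` (with a warning) when
#'   there are no sites.
#' @export
sites_with_comets <- function(sites, comets) {
  if (!nrow(sites)) {
    warning("no sites on axon; fraction undefined")
    return(NA_real_)
  }
  if (!nrow(comets)) return(0)
  lo <- pmin(comets$x_start_um, comets$x_end_um)
  hi <- pmax(comets$x_start_um, comets$x_end_um)
  active <- vapply(seq_len(nrow(sites)), function(i) {
    s_lo <- sites$centroid_um[i] - sites$extent_um[i] / 2
    s_hi <- sites$centroid_um[i] + sites$extent_um[i] / 2
    any(hi >= s_lo & lo <= s_hi)
  }, logical(1))
  mean(active)
}

#' Regression of SVP+ site density on comet activity
#'
#' Ordinary least squares of per-axon site density against comet density,
#' the relationship used to ask whether presynaptic cargo accumulation
#' tracks local microtubule plus-end growth.
#'
#' @param per_axon tibble with columns `comet_density` and `site_density`
#'   (one row per axon, n >= 3).
#' @return Object of class `density_regression` with elements `slope`,
#'   `intercept`, `r_squared`, `n`, `flagged` and the underlying `lm`
#'   fit.  `tidy()` and `glance()` methods are provided.
#' @examples
#' df <- tibble::tibble(comet_density = c(0, 1, 2, 3),
#'                      site_density = c(0, 1, 2, 2))
#' glance(density_regression(df))
#' @export
density_regression <- function(per_axon) {
  if (nrow(per_axon) < 3) abort_bad_arg("need at least 3 axons for the regression")
  flagged <- stats::var(per_axon$comet_density) == 0
  if (flagged) {
    fit <- NULL; slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
    warning("zero variance in comet density; regression undefined")
  } else {
    fit <- stats::lm(site_density ~ comet_density, data = per_axon)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n = nrow(per_axon), flagged = flagged, fit = fit),
            class = "density_regression")
}

#' @export
print.density_regression <- function(x, ...) {
  cat(sprintf("<density_regression> slope %.3f, intercept %.3f, R^2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @rdname density_regression
#' @param x a `density_regression` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.density_regression <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "comet_density"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname density_regression
#' @exportS3Method generics::glance
glance.density_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n, flagged = x$flagged)
}
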