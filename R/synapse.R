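#' Generate a ground-truth synapse puncta field
#'
#' Lays out `n_pre` presynaptic puncta in a 3-D imaging field (uniform
#' positions with pairwise spacing above `3 * max_gap_um`, so greedy
#' matching is provably optimal on the ground truth), gives a fixed
#' fraction `apposed_frac` of them a postsynaptic partner within
#' `max_gap_um` of the centroid (deterministic rounding:
#' `floor(apposed_frac * n_pre)` pairs), and scatters the remaining
#' postsynaptic puncta far (> 3 * `max_gap_um`) from every presynaptic
#' punctum.  Sizes are uniform within the channel windows used for
#' detection (pre 0.2-2.5 um, post 0.06-2 um equivalent diameter).
#'
#' @param n_pre number of presynaptic puncta.
#' @param apposed_frac fraction of pre puncta with a partner, in \[0, 1\].
#' @param map2_area_um2 MAP2-positive (somatodendritic) area of the field.
#' @param max_gap_um apposition distance bound (um).
#' @param field_um field extents `c(x, y, z)` in um.
#' @param n_extra_post lone postsynaptic puncta (default `0.25 * n_pre`).
#' @param seed integer seed.
#' @return List with tibbles `pre` (`punctum_id`, `x_um`, `y_um`, `z_um`,
#'   `diameter_um`, `matched_truth`, `partner_id`) and `post`, plus
#'   `map2_area_um2` and `max_gap_um`.
#' @examples
#' f <- gen_synapse_field(50, 0.5, seed = 1)
#' sum(f$pre$matched_truth)
#' @export
gen_synapse_field <- function(n_pre, apposed_frac, map2_area_um2 = 2000,
                              max_gap_um = 0.5, field_um = c(60, 60, 4),
                              n_extra_post = round(0.25 * n_pre), seed = NULL) {
  check_fraction(apposed_frac, "apposed_frac")
  check_positive(n_pre, "n_pre")
  local_seed_if(seed)

  min_sep <- 3 * max_gap_um
  pre_xyz <- place_points(n_pre, field_um, min_sep)
  n_match <- floor(apposed_frac * n_pre)
  matched <- sort(sample(n_pre, n_match))

  pre <- tibble::tibble(
    punctum_id = seq_len(n_pre),
    x_um = pre_xyz[, 1], y_um = pre_xyz[, 2], z_um = pre_xyz[, 3],
    diameter_um = stats::runif(n_pre, 0.2, 2.5),
    matched_truth = seq_len(n_pre) %in% matched,
    partner_id = NA_integer_
  )

  # partners: random 3-D offset at gap <= max_gap_um
  gap <- stats::runif(n_match, 0.1 * max_gap_um, 0.9 * max_gap_um)
  u <- matrix(stats::rnorm(3 * n_match), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  partner_xyz <- pre_xyz[matched, , drop = FALSE] + u * gap
  pre$partner_id[matched] <- seq_len(n_match)

  # lone post puncta far from every pre punctum
  lone <- matrix(numeric(0), 0, 3)
  while (nrow(lone) < n_extra_post) {
    cand <- matrix(stats::runif(3, 0, 1), 1) %*% diag(field_um)
    d <- sqrt(rowSums((pre_xyz - cand[rep(1, n_pre), ])^2))
    if (min(d) > 3 * max_gap_um) lone <- rbind(lone, cand)
  }
  post_xyz <- rbind(partner_xyz, lone)
  n_post <- nrow(post_xyz)
  post <- tibble::tibble(
    punctum_id = seq_len(n_post),
    x_um = post_xyz[, 1], y_um = post_xyz[, 2], z_um = post_xyz[, 3],
    diameter_um = stats::runif(n_post, 0.06, 2),
    partner_of = c(matched, rep(NA_integer_, nrow(lone)))
  )
  list(pre = pre, post = post, map2_area_um2 = map2_area_um2,
       max_gap_um = max_gap_um)
}

# uniform placement with minimum pairwise separation (sequential rejection)
place_points <- function(n, field_um, min_sep) {
  pts <- matrix(NA_real_, n, 3)
  k <- 0; tries <- 0
  while (k < n && tries < 5000 * n) {
    cand <- stats::runif(3) * field_um
    ok <- k == 0 ||
      min(sqrt(rowSums((pts[seq_len(k), , drop = FALSE] -
                          matrix(cand, k, 3, byrow = TRUE))^2))) >= min_sep
    if (ok) { k <- k + 1; pts[k, ] <- cand }
    tries <- tries + 1
  }
  if (k < n) abort_bad_arg("field too crowded for the requested spacing")
  pts
}

#' Rasterize a puncta table into a 3-D image stack
#'
#' Paints each punctum as a solid ball of its equivalent diameter (at
#' least one voxel), used to exercise [detect_puncta()] against ground
#' truth.
#'
#' @param puncta tibble with `x_um`, `y_um`, `z_um`, `diameter_um`.
#' @param field_um field extents `c(x, y, z)` in um.
#' @param px_um lateral voxel size; `z_um` axial step.
#' @param z_um axial voxel size.
#' @param intensity voxel value inside puncta.
#' @param bg background value.
#' @return Numeric 3-D array (y, x, z).
#' @export
render_puncta_stack <- function(puncta, field_um = c(60, 60, 4), px_um = 0.1,
                                z_um = 0.3, intensity = 200, bg = 0) {
  nx <- round(field_um[1] / px_um); ny <- round(field_um[2] / px_um)
  nz <- max(1L, round(field_um[3] / z_um))
  arr <- array(bg, c(ny, nx, nz))
  xs <- (seq_len(nx) - 0.5) * px_um
  ys <- (seq_len(ny) - 0.5) * px_um
  zs <- (seq_len(nz) - 0.5) * z_um
  for (i in seq_len(nrow(puncta))) {
    r <- puncta$diameter_um[i] / 2
    ix <- which(abs(xs - puncta$x_um[i]) <= max(r, px_um / 2))
    iy <- which(abs(ys - puncta$y_um[i]) <= max(r, px_um / 2))
    iz <- which(abs(zs - puncta$z_um[i]) <= max(r, z_um / 2))
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - puncta$x_um[i])^2
    dy2 <- (ys[iy] - puncta$y_um[i])^2
    dz2 <- (zs[iz] - puncta$z_um[i])^2
    d2 <- outer(outer(dy2, dx2, "+"), dz2, "+")
    inside <- d2 <= max(r, px_um * 0.75)^2
    sub <- arr[iy, ix, iz, drop = FALSE]
    sub[inside] <- intensity
    arr[iy, ix, iz] <- sub
  }
  arr
}

#' Detect puncta in a 3-D stack
#'
#' Two-pass segmentation following the described synapse-counting
#' settings: a provisional Otsu threshold seeds connected components,
#' the mean intensity of those provisional puncta sets the final
#' threshold at two-thirds of that mean, and components re-segmented at
#' the final threshold are filtered to the channel's equivalent-diameter
#' window (pre 0.2-2.5 um, post 0.06-2 um).
#'
#' Connected components are 3-D: slices are labelled in 2-D (EBImage) and
#' labels overlapping across adjacent slices are merged (igraph).
#'
#' @param stack numeric 3-D array (y, x, z) or matrix.
#' @param channel `"pre"` or `"post"` (selects the size window).
#' @param px_um lateral voxel size (um); `z_um` axial size.
#' @param z_um axial voxel size.
#' @param size_window override `c(min, max)` equivalent diameter (um).
#' @return Tibble `punctum_id`, `channel`, `x_um`, `y_um`, `z_um`
#'   (intensity-weighted centroid), `equiv_diameter_um`,
#'   `mean_intensity`, `n_voxels`.
#' @export
detect_puncta <- function(stack, channel = c("pre", "post"), px_um = 0.1,
                          z_um = 0.3, size_window = NULL) {
  channel <- match.arg(channel)
  if (!requireNamespace("EBImage", quietly = TRUE) ||
      !requireNamespace("igraph", quietly = TRUE)) {
    abort_bad_arg("detect_puncta() needs the EBImage and igraph packages")
  }
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  win <- size_window %||% if (channel == "pre") c(0.2, 2.5) else c(0.06, 2)
  empty <- tibble::tibble(punctum_id = integer(), channel = character(),
                          x_um = double(), y_um = double(), z_um = double(),
                          equiv_diameter_um = double(), mean_intensity = double(),
                          n_voxels = integer())
  rng <- range(stack)
  if (diff(rng) == 0) return(empty)

  norm <- (stack - rng[1]) / diff(rng)
  thr0 <- rng[1] + EBImage::otsu(norm, range = c(0, 1)) * diff(rng)
  if (!any(stack > thr0)) return(empty)
  mean_punct <- mean(stack[stack > thr0])
  thr <- (2 / 3) * mean_punct

  lab <- label_3d(stack > thr)
  if (!length(lab$ids)) return(empty)

  vox_vol <- px_um^2 * z_um
  comp <- tibble::tibble(
    comp = lab$comp, y = lab$y, x = lab$x, z = lab$z,
    val = stack[cbind(lab$y, lab$x, lab$z)]
  ) |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(
      x_um = sum(.data$x * .data$val) / sum(.data$val) * px_um - px_um / 2,
      y_um = sum(.data$y * .data$val) / sum(.data$val) * px_um - px_um / 2,
      z_um = sum(.data$z * .data$val) / sum(.data$val) * z_um - z_um / 2,
      mean_intensity = mean(.data$val),
      n_voxels = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(equiv_diameter_um = 2 * (3 * .data$n_voxels * vox_vol / (4 * pi))^(1 / 3)) |>
    dplyr::filter(.data$equiv_diameter_um >= win[1], .data$equiv_diameter_um <= win[2]) |>
    dplyr::arrange(.data$x_um, .data$y_um)
  dplyr::mutate(comp,
                punctum_id = dplyr::row_number(), channel = channel,
                .before = 1) |>
    dplyr::select("punctum_id", "channel", "x_um", "y_um", "z_um",
                  "equiv_diameter_um", "mean_intensity", "n_voxels")
}

# 3-D connected components: 2-D labels per slice, merged across slices
# where labels share a voxel footprint.
label_3d <- function(mask) {
  nz <- dim(mask)[3]
  labs <- vector("list", nz)
  offset <- 0
  n_per <- integer(nz)
  for (k in seq_len(nz)) {
    l <- EBImage::bwlabel(mask[, , k] * 1)
    n_per[k] <- max(l)
    l[l > 0] <- l[l > 0] + offset
    labs[[k]] <- l
    offset <- offset + n_per[k]
  }
  total <- offset
  if (!total) return(list(ids = integer(0)))
  edges <- list()
  for (k in seq_len(nz - 1)) {
    a <- labs[[k]]; b <- labs[[k + 1]]
    both <- a > 0 & b > 0
    if (any(both)) {
      edges[[length(edges) + 1]] <- unique(cbind(a[both], b[both]))
    }
  }
  g <- igraph::make_empty_graph(n = total, directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  comp_of <- igraph::components(g)$membership

  idx <- lapply(seq_len(nz), function(k) {
    w <- which(labs[[k]] > 0, arr.ind = TRUE)
    if (!nrow(w)) return(NULL)
    cbind(w, k, comp_of[labs[[k]][w]])
  })
  idx <- do.call(rbind, idx)
  list(ids = unique(idx[, 4]), y = idx[, 1], x = idx[, 2], z = idx[, 3],
       comp = idx[, 4])
}

#' Match apposed pre- and postsynaptic puncta
#'
#' Greedy nearest-neighbour one-to-one matching: candidate pairs with
#' centroid gap at most `max_gap_um` are taken in order of increasing
#' distance (ties broken by lower pre then post index); each punctum is
#' used at most once.
#'
#' @param pre,post puncta tibbles with `x_um`, `y_um` and optionally
#'   `z_um` columns and a `punctum_id`.
#' @param max_gap_um maximum centroid gap (default 0.5 um).
#' @return Tibble `pre_id`, `post_id`, `gap_um`, one row per matched
#'   pair.
#' @examples
#' f <- gen_synapse_field(20, 0.5, seed = 2)
#' nrow(match_appositions(f$pre, f$post))
#' @export
match_appositions <- function(pre, post, max_gap_um = 0.5) {
  empty <- tibble::tibble(pre_id = integer(), post_id = integer(), gap_um = double())
  if (!nrow(pre) || !nrow(post)) return(empty)
  zc <- function(d) if ("z_um" %in% names(d)) d$z_um else 0
  d <- sqrt(outer(pre$x_um, post$x_um, "-")^2 +
              outer(pre$y_um, post$y_um, "-")^2 +
              outer(zc(pre), zc(post), "-")^2)
  cand <- which(d <= max_gap_um, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  ord <- order(d[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_pre <- logical(nrow(pre)); used_post <- logical(nrow(post))
  out <- list()
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]; b <- cand[i, 2]
    if (used_pre[a] || used_post[b]) next
    used_pre[a] <- TRUE; used_post[b] <- TRUE
    out[[length(out) + 1]] <- c(a, b, d[a, b])
  }
  m <- do.call(rbind, out)
  tibble::tibble(pre_id = pre$punctum_id[m[, 1]],
                 post_id = post$punctum_id[m[, 2]],
                 gap_um = m[, 3])
}

#' Synapse counts, density and apposed fraction for one field
#'
#' @param pre,post puncta tibbles.
#' @param matches matched pairs from [match_appositions()].
#' @param map2_area_um2 MAP2-positive area of the field (um^2).
#' @return One-row tibble: `n_pre`, `n_post`, `n_matched`,
#'   `map2_area_um2`, `density_per_um2`, `apposed_pct`.
#' @export
synapse_table <- function(pre, post, matches, map2_area_um2) {
  tibble::tibble(
    n_pre = nrow(pre), n_post = nrow(post), n_matched = nrow(matches),
    map2_area_um2 = map2_area_um2,
    density_per_um2 = synapse_density(nrow(matches), map2_area_um2),
    apposed_pct = if (nrow(pre)) 100 * nrow(matches) / nrow(pre) else NA_real_
  )
}

#' Synapse density
#'
#' Matched pairs per MAP2-positive area; `NA` with a warning when the
#' area is zero.
#'
#' @param n_matched matched pair count.
#' @param map2_area_um2 MAP2-positive area (um^2).
#' @return Synapses per um^2.
#' @export
synapse_density <- function(n_matched, map2_area_um2) {
  if (map2_area_um2 <= 0) {
    warning("zero MAP2 area; density undefined")
    return(NA_real_)
  }
  n_matched / map2_area_um2
}

#' Chi-square test of independence on apposition counts
#'
#' Pearson chi-square (no continuity correction) on a 2 x k contingency
#' table of apposed vs lone presynaptic puncta across genotypes.
#'
#' @param counts 2 x k numeric matrix (rows: apposed, lone; columns:
#'   genotypes).
#' @return Tibble `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_independence(matrix(c(10, 20, 20, 10), 2))
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort_bad_arg("contingency table has a zero margin")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ht$expected <= 0)) abort_bad_arg("expected counts must be positive")
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' Mean intensity within a top-percent mask
#'
#' Builds a mask of the pixels above the (100 - `pct`)th intensity
#' percentile of a 2-D projection (3% and 2% masks are used for
#' synaptophysin and synaptobrevin-2 signals respectively) and returns
#' the mean original intensity within the mask.  A constant image yields
#' a whole-image mask with a warning.
#'
#' @param image 2-D numeric matrix (maximum projection).
#' @param pct mask percentage in (0, 100).
#' @return Mean intensity (AU) within the mask.
#' @export
top_percent_mask_intensity <- function(image, pct) {
  if (pct <= 0 || pct >= 100) abort_bad_arg("`pct` must be in (0, 100)")
  thr <- stats::quantile(image, 1 - pct / 100, names = FALSE)
  mask <- image > thr
  if (!any(mask)) {
    warning("constant image: mask covers the whole image")
    mask[] <- TRUE
  }
  mean(image[mask])
}

#' Mean intensity inside a polygonal ROI
#'
#' @param sum_projection 2-D numeric matrix (sum projection).
#' @param roi two-column matrix/data frame of polygon vertices in pixel
#'   coordinates (x = column, y = row); the polygon is closed
#'   automatically.
#' @return Mean of the pixel values whose centers fall inside the ROI.
#' @export
roi_mean_intensity <- function(sum_projection, roi) {
  roi <- as.matrix(roi)
  if (!nrow(roi) || nrow(roi) < 3) abort_bad_arg("`roi` must be a polygon (>= 3 vertices)")
  bnd <- rbind(roi, roi[1, ])
  nr <- nrow(sum_projection); nc <- ncol(sum_projection)
  centers <- cbind(rep(seq_len(nc) - 0.5, each = nr),
                   rep(seq_len(nr) - 0.5, nc))
  inside <- mgcv::in.out(bnd, centers)
  if (!any(inside)) abort_bad_arg("ROI contains no pixel centers")
  mean(sum_projection[inside])
}
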