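test_that("generated fields have exact apposition counts and far lone puncta", {
  f <- gen_synapse_field(100, 0.5, seed = 1)
  expect_equal(sum(f$pre$matched_truth), 50)        # floor(0.5 * 100)
  expect_equal(sum(!is.na(f$post$partner_of)), 50)
  # partners within the gap, lone post puncta far from every pre
  for (i in which(f$pre$matched_truth)) {
    j <- f$pre$partner_id[i]
    d <- sqrt((f$pre$x_um[i] - f$post$x_um[j])^2 +
                (f$pre$y_um[i] - f$post$y_um[j])^2 +
                (f$pre$z_um[i] - f$post$z_um[j])^2)
    expect_lte(d, f$max_gap_um)
  }
  lone <- f$post[is.na(f$post$partner_of), ]
  dmin <- vapply(seq_len(nrow(lone)), function(j) {
    min(sqrt((f$pre$x_um - lone$x_um[j])^2 + (f$pre$y_um - lone$y_um[j])^2 +
               (f$pre$z_um - lone$z_um[j])^2))
  }, numeric(1))
  expect_true(all(dmin > 3 * f$max_gap_um))

  f0 <- gen_synapse_field(40, 0, seed = 2)
  expect_equal(sum(f0$pre$matched_truth), 0)
  f1 <- gen_synapse_field(40, 1, seed = 3)
  expect_equal(sum(f1$pre$matched_truth), 40)
})

test_that("greedy matching recovers ground-truth pairs and respects the gap", {
  f <- gen_synapse_field(100, 0.5, seed = 4)
  m <- match_appositions(f$pre, f$post, f$max_gap_um)
  expect_equal(nrow(m), 50)
  expect_equal(anyDuplicated(m$pre_id), 0)          # one-to-one
  expect_equal(anyDuplicated(m$post_id), 0)

  one_pre <- tibble::tibble(punctum_id = 1L, x_um = 0, y_um = 0, z_um = 0)
  near <- tibble::tibble(punctum_id = 1L, x_um = 0.3, y_um = 0, z_um = 0)
  far <- tibble::tibble(punctum_id = 1L, x_um = 0.6, y_um = 0, z_um = 0)
  expect_equal(nrow(match_appositions(one_pre, near)), 1)
  expect_equal(nrow(match_appositions(one_pre, far)), 0)
})

test_that("match count is monotone in the gap and greedy is optimal when spaced", {
  f <- gen_synapse_field(80, 0.6, seed = 5)
  counts <- vapply(c(0.1, 0.3, 0.5, 1), function(g) {
    nrow(match_appositions(f$pre, f$post, g))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # with inter-pair spacing > 2 * gap the greedy count equals the truth,
  # which is the optimal bipartite matching size
  expect_equal(counts[3], sum(f$pre$matched_truth))
})

test_that("apposed fraction recovery within 5 points at n_pre = 200", {
  f <- gen_synapse_field(200, 0.35, seed = 6)
  m <- match_appositions(f$pre, f$post, f$max_gap_um)
  tab <- synapse_table(f$pre, f$post, m, f$map2_area_um2)
  expect_lt(abs(tab$apposed_pct - 35), 5)
  expect_true(tab$apposed_pct >= 0 && tab$apposed_pct <= 100)
  expect_equal(tab$density_per_um2, tab$n_matched / f$map2_area_um2)
})

test_that("synapse density scales inversely with area and flags zero area", {
  expect_equal(synapse_density(50, 1000), 0.05)
  expect_equal(synapse_density(0, 1000), 0)
  expect_equal(synapse_density(50, 2000), synapse_density(50, 1000) / 2)
  expect_warning(d <- synapse_density(10, 0))
  expect_true(is.na(d))
})

test_that("puncta detection round-trips a rendered field", {
  skip_if_not_installed("EBImage")
  skip_if_not_installed("igraph")
  f <- gen_synapse_field(40, 0.5, field_um = c(30, 30, 3), seed = 7)
  pre <- f$pre
  # resolvable at 0.1 um/px and small enough that neighbouring spheres
  # (centroid spacing >= 1.5 um in this field) never touch
  pre$diameter_um <- pmin(pmax(pre$diameter_um, 0.5), 1.2)
  stack <- render_puncta_stack(pre, field_um = c(30, 30, 3))
  det <- detect_puncta(stack, "pre")
  expect_equal(nrow(det), 40)
  # centroids recovered
  ord <- vapply(seq_len(nrow(pre)), function(i) {
    which.min((det$x_um - pre$x_um[i])^2 + (det$y_um - pre$y_um[i])^2)
  }, integer(1))
  expect_lt(max(abs(det$x_um[ord] - pre$x_um)), 0.2)
  expect_lt(max(abs(det$y_um[ord] - pre$y_um)), 0.2)
})

test_that("size windows reject out-of-range blobs and blank stacks give none", {
  skip_if_not_installed("EBImage")
  skip_if_not_installed("igraph")
  big <- tibble::tibble(punctum_id = 1L, x_um = 10, y_um = 10, z_um = 1.5,
                        diameter_um = 3)            # exceeds the 2.5 um pre window
  stack <- render_puncta_stack(big, field_um = c(20, 20, 3))
  expect_equal(nrow(detect_puncta(stack, "pre")), 0)
  expect_equal(nrow(detect_puncta(array(0, c(50, 50, 3)), "pre")), 0)
})

test_that("chi-square matches the hand formula and its symmetries", {
  m <- matrix(c(10, 20, 20, 10), 2)
  got <- chi_square_independence(m)
  o <- chisq_oracle(m)
  expect_equal(got$statistic, o$statistic, tolerance = 1e-12)
  expect_equal(got$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(got$df, 1)

  same <- matrix(c(10, 20, 20, 40, 5, 10), 2)       # identical proportions
  g2 <- chi_square_independence(same)
  expect_equal(g2$statistic, 0, tolerance = 1e-12)
  expect_equal(g2$p_value, 1)

  perm <- m[, 2:1]
  expect_equal(chi_square_independence(perm)$statistic, got$statistic)
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2)),
               class = "axonsynkit_invalid_argument")
})

test_that("top-percent masks return the right means", {
  img <- matrix(0, 100, 100)
  img[1:300] <- 1000                                  # exactly 3% bright
  expect_equal(top_percent_mask_intensity(img, 3), 1000)
  expect_warning(u <- top_percent_mask_intensity(matrix(7, 10, 10), 3))
  expect_equal(u, 7)
  # linear ramp: mean of the top q fraction of Uniform(0, 1) is 1 - q/2
  ramp <- matrix(seq(0, 1, length.out = 1e4), 100)
  expect_equal(top_percent_mask_intensity(ramp, 2), 1 - 0.02 / 2, tolerance = 0.01)
  expect_error(top_percent_mask_intensity(ramp, 0),
               class = "axonsynkit_invalid_argument")
})

test_that("ROI means are exact on constructed grids", {
  uni <- matrix(7, 20, 20)
  roi <- cbind(x = c(2, 18, 18, 2), y = c(2, 2, 18, 18))
  expect_equal(roi_mean_intensity(uni, roi), 7)

  half <- rbind(matrix(0, 10, 20), matrix(10, 10, 20))
  expect_equal(roi_mean_intensity(half, cbind(c(0, 20, 20, 0), c(0, 0, 20, 20))), 5)
  expect_error(roi_mean_intensity(uni, roi[1:2, ]),
               class = "axonsynkit_invalid_argument")
})
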