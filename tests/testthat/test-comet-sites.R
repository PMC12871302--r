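wt <- genotype_params("WT")

test_that("site and comet counts follow the configured densities", {
  field <- gen_comet_site_axon(wt, n_axons = 150, seed = 1)
  mean_sites <- nrow(field$sites) / 150
  expect_equal(mean_sites, 6, tolerance = 0.1)          # 0.6/10um x 100um
  dens_per_axon <- comet_density(field$comets, 100, 300) / 150
  expect_equal(dens_per_axon, wt$comet_rate, tolerance = 0.1)
})

test_that("assoc_prob = 1 puts every comet within 10 um of a site", {
  p <- genotype_params("WT", assoc_prob = 1, comet_rate = 0.2)
  field <- gen_comet_site_axon(p, n_axons = 10, seed = 2)
  for (ax in 1:10) {
    s <- field$sites[field$sites$axon_id == ax, ]
    k <- field$comets[field$comets$axon_id == ax, ]
    if (!nrow(s) || !nrow(k)) next
    d <- vapply(k$x_start_um, function(x) min(abs(s$centroid_um - x)), numeric(1))
    expect_true(all(d <= 10))
    expect_true(all(k$assoc_truth))
  }
})

test_that("no sites means uniform comet placement (documented fallback)", {
  p <- genotype_params("WT", site_density = 0, assoc_prob = 1, comet_rate = 0.2)
  field <- gen_comet_site_axon(p, n_axons = 5, seed = 3)
  expect_equal(nrow(field$sites), 0)
  expect_true(all(!field$comets$assoc_truth))
  expect_gt(nrow(field$comets), 0)
})

test_that("site detection recovers rendered bands and rejects transients", {
  sites <- tibble::tibble(centroid_um = c(10, 25, 40, 60, 75, 90),
                          extent_um = 2, mean_intensity = 300)
  k <- render_kymograph(sites = sites, length_um = 100, duration_s = 300,
                        dt_s = 1, noise_sd = 8, seed = 4)
  det <- detect_svp_sites(k)
  expect_equal(nrow(det), 6)
  expect_equal(site_density(det, 100), 0.6)
  expect_true(all(abs(sort(det$centroid_um) - sites$centroid_um) < 0.5))

  blank <- render_kymograph(length_um = 100, duration_s = 300, dt_s = 1,
                            noise_sd = 8, seed = 5)
  expect_equal(nrow(detect_svp_sites(blank)), 0)

  # a band present for only half the movie fails the persistence rule
  half <- render_kymograph(length_um = 100, duration_s = 300, dt_s = 1,
                           noise_sd = 8, seed = 6)
  cols <- 180:195
  half$values[1:150, cols] <- half$values[1:150, cols] + 300
  expect_equal(nrow(detect_svp_sites(half)), 0)
})

test_that("comet density is count over length x minutes", {
  k30 <- tibble::tibble(comet_id = 1:30)
  expect_equal(comet_density(k30, 100, 300), 0.06)
  expect_equal(comet_density(k30[0, ], 100, 300), 0)
})

test_that("association uses any point of the comet span, 10 um window", {
  sites <- tibble::tibble(site_id = 1, centroid_um = 50, extent_um = 2)
  mk <- function(x0, x1) tibble::tibble(comet_id = 1, x_start_um = x0,
                                        x_end_um = x1, t_start_s = 0, t_end_s = 10)
  expect_true(associate_comets(mk(41, 45), sites)$associated)     # start 9 um away
  expect_false(associate_comets(mk(61.5, 70), sites)$associated)  # wholly 11+ um
  expect_true(associate_comets(mk(70, 55), sites)$associated)     # span reaches in
  # start-only mode scores just the initiation point
  expect_false(associate_comets(mk(70, 55), sites, mode = "start")$associated)
  none <- associate_comets(mk(41, 45), sites[0, ])
  expect_false(none$associated)
})

test_that("associated fraction is monotone in the window and counts sum", {
  field <- gen_comet_site_axon(wt, n_axons = 1, seed = 7,
                               duration_s = 3000)  # plenty of comets
  s <- field$sites; k <- field$comets
  fr <- vapply(c(2, 5, 10, 20), function(w) {
    a <- associate_comets(k, s, window_um = w)
    expect_equal(sum(a$associated) + sum(!a$associated), nrow(k))
    mean(a$associated)
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("fraction of sites with comets hits its limits", {
  sites <- tibble::tibble(site_id = 1, centroid_um = 50, extent_um = 2)
  crossing <- tibble::tibble(comet_id = 1, x_start_um = 45, x_end_um = 55,
                             t_start_s = 0, t_end_s = 50)
  elsewhere <- tibble::tibble(comet_id = 1, x_start_um = 80, x_end_um = 90,
                              t_start_s = 0, t_end_s = 50)
  expect_equal(sites_with_comets(sites, crossing), 1)
  expect_equal(sites_with_comets(sites, elsewhere), 0)
  expect_warning(out <- sites_with_comets(sites[0, ], crossing))
  expect_true(is.na(out))

  # saturation: dense comets with assoc_prob 1 visit every site
  p <- genotype_params("WT", assoc_prob = 1, comet_rate = 1)
  f <- gen_comet_site_axon(p, n_axons = 1, seed = 8)
  expect_equal(sites_with_comets(f$sites, f$comets), 1)
})

test_that("density regression matches the closed-form oracle to 1e-10", {
  df <- tibble::tibble(comet_density = c(0, 1, 2, 3),
                       site_density = c(0, 1, 2, 2))
  fit <- density_regression(df)
  o <- ols_oracle(df$comet_density, df$site_density)
  expect_equal(fit$slope, o$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-10)

  withr::with_seed(12, {
    for (i in 1:10) {
      x <- stats::rnorm(20); y <- 0.5 * x + stats::rnorm(20)
      f2 <- density_regression(tibble::tibble(comet_density = x, site_density = y))
      o2 <- ols_oracle(x, y)
      expect_equal(f2$slope, o2$slope, tolerance = 1e-10)
      expect_equal(f2$r_squared, o2$r_squared, tolerance = 1e-10)
    }
  })
})

test_that("regression limits: collinear gives R2 = 1, shuffled ~ 0", {
  col <- tibble::tibble(comet_density = 1:10, site_density = 2 * (1:10) + 1)
  fit_col <- suppressWarnings(density_regression(col))  # perfect-fit lm warning
  expect_equal(fit_col$r_squared, 1, tolerance = 1e-12)
  withr::with_seed(13, {
    big <- tibble::tibble(comet_density = stats::rnorm(4000),
                          site_density = sample(stats::rnorm(4000)))
    expect_lt(density_regression(big)$r_squared, 0.01)
  })
  flat <- tibble::tibble(comet_density = rep(1, 5), site_density = 1:5)
  expect_warning(f <- density_regression(flat))
  expect_true(f$flagged && is.na(f$r_squared))
  expect_error(density_regression(col[1:2, ]),
               class = "axonsynkit_invalid_argument")
})

test_that("tidy and glance expose the fit", {
  df <- tibble::tibble(comet_density = c(0, 1, 2, 3),
                       site_density = c(0.1, 1, 1.9, 3.2))
  fit <- density_regression(df)
  expect_equal(nrow(tidy(fit)), 2)
  expect_equal(glance(fit)$n, 4)
})

test_that("detected site density separates R350G from WT at n = 15", {
  d_wt <- detected_site_run("WT", 15, seed0 = 7700)
  d_mut <- detected_site_run("R350G", 15, seed0 = 7700)
  expect_gt(mean(d_wt), mean(d_mut))
})
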