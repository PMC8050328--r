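# Synthetic-data generator: seeded Poisson placement, concentration-
# dependent intensities, disk time series, image rendering, and closure
# of the generative model with the quantification pipeline.

test_that("cell sampling is seed-deterministic and honours the density", {
  expect_equal(nrow(sample_cells(uniform_density(0), seed = 1)), 0)

  a <- sample_cells(uniform_density(1e-4), seed = 42)
  b <- sample_cells(uniform_density(1e-4), seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- sample_cells(uniform_density(1e-4), seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))

  # all cells live on the annulus
  r <- sqrt(a$x_um^2 + a$y_um^2)
  expect_true(all(r >= 350 & r <= 6000))
})

test_that("constant-density counts match the Poisson expectation", {
  rho <- 1e-5
  expected <- rho * pi * (6000^2 - 350^2)
  counts <- vapply(1:200, function(s)
    nrow(sample_cells(uniform_density(rho), seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected))
})

test_that("radius-dependent densities thin the proposal correctly", {
  # density zero inside 2000 um, constant outside: no cell below 2000
  dp <- density_profile(c(0, 1999, 2000, 6000), c(0, 0, 1e-4, 1e-4))
  cells <- sample_cells(dp, seed = 5)
  r <- sqrt(cells$x_um^2 + cells$y_um^2)
  expect_true(all(r >= 1999))
  expect_gt(nrow(cells), 0)
})

test_that("intensity assignment follows the response monotonically", {
  ss <- o2_steady_base()
  cells <- sample_cells(uniform_density(2e-4), seed = 8)
  noiseless <- intensity_model("hypoxia", noise_sigma = 0)

  # uniform concentration -> identical intensities
  grid <- ss$profile$grid
  uni <- concentration_profile(grid, rep(100, length(grid$nodes)),
                               c_ref = 171)
  ci <- assign_intensities(cells, uni, noiseless, seed = 9)
  expect_equal(diff(range(ci$reporter)), 0)

  # hypoxia response: intensity non-increasing with local oxygen
  cs <- assign_intensities(cells, ss$profile, noiseless, seed = 9)
  r <- sqrt(cs$x_um^2 + cs$y_um^2)
  ord <- order(r)
  expect_true(all(diff(cs$reporter[ord]) >= -1e-9))

  # cells outside the profile domain are rejected
  tiny <- radial_grid(chamber_geometry(r_outer = 3000), spacing = 50)
  short <- concentration_profile(tiny, rep(100, length(tiny$nodes)),
                                 c_ref = 171)
  expect_error(assign_intensities(cells, short, noiseless, seed = 9),
               "domain")
})

test_that("binned synthetic intensities recover the generative response", {
  # the binned MFI estimates E[response(C) e^eps] = response(C) e^(s^2/2);
  # with 1e4 cells the estimate must sit within 2 SEM of that expectation
  # in at least 90% of occupied bins, across seeds
  ss <- o2_steady_base()
  model <- intensity_model("hypoxia", noise_sigma = 0.2)
  lognormal_bias <- exp(0.2^2 / 2)
  hit_rates <- vapply(1:20, function(s) {
    cells <- sample_cells(uniform_density(9e-5), seed = derive_seed(s, 1))
    cells <- assign_intensities(cells, ss$profile, model,
                                seed = derive_seed(s, 2))
    p <- bin_cells(cells, "reporter")
    ok <- which(p$n >= 5)
    expect_gt(length(ok), 50)
    Cmid <- approx(ss$profile$grid$nodes, ss$profile$C,
                   xout = p$bin_centers[ok], rule = 2)$y
    want <- expected_intensity(model, Cmid) * lognormal_bias
    mean(abs(p$mfi[ok] - want) <= 2 * pmax(p$sem[ok], 1e-9))
  }, numeric(1))
  expect_gte(mean(hit_rates >= 0.9), 0.9)
})

test_that("disk series interpolates from uniform seeding to a tight disk", {
  series <- make_disk_series(times_h = c(0, 96, 192), disk_radius = 1500,
                             seed = 21)
  expect_length(series, 3)
  expect_equal(attr(series[[1]], "time_h"), 0)

  r0 <- sqrt(series[[1]]$x_um^2 + series[[1]]$y_um^2)
  rT <- sqrt(series[[3]]$x_um^2 + series[[3]]$y_um^2)

  # initial table is uniform over the annulus: occupied radius ~ wall
  expect_gt(max(r0), 5800)
  # occupied radius (95th percentile) shrinks monotonically
  q95 <- vapply(series, function(s)
    unname(quantile(sqrt(s$x_um^2 + s$y_um^2), 0.95)), numeric(1))
  expect_true(all(diff(q95) < 0))
  # final disk: at least 95% of cells within 1.1x the target radius
  expect_gte(mean(rT <= 1.1 * 1500), 0.95)

  expect_error(make_disk_series(disk_radius = 7000, seed = 1), "chamber")
})

test_that("density-thresholded masks of the disk series shrink in area", {
  series <- make_disk_series(times_h = c(0, 192), disk_radius = 1500,
                             seed = 22)
  mask_of <- function(cells) {
    px <- 200  # um per mask pixel
    sz <- ceiling(12000 / px)
    ix <- pmin(pmax(floor((cells$x_um + 6000) / px) + 1, 1), sz)
    iy <- pmin(pmax(floor((cells$y_um + 6000) / px) + 1, 1), sz)
    counts <- matrix(0, sz, sz)
    for (k in seq_along(ix)) counts[iy[k], ix[k]] <- counts[iy[k], ix[k]] + 1
    disk_mask(counts >= 0.5 * 2e-3 * px^2, scale = px)
  }
  change <- disk_area_change(mask_of(series[[1]]), mask_of(series[[2]]))
  expect_lt(change, 0)
})

test_that("rendered images integrate to the summed cell intensity", {
  empty <- cell_table(data.frame(cell_id = integer(0), x_um = numeric(0),
                                 y_um = numeric(0)))
  img0 <- render_image(empty, channel = character(0), background = 7)
  expect_true(all(img0 == 7))

  set.seed(14)
  n <- 50
  df <- data.frame(cell_id = 1:n, x_um = runif(n, -300, 300),
                   y_um = runif(n, -300, 300), ch = runif(n, 50, 200))
  cells <- cell_table(df)
  img <- render_image(cells, "ch", scale = 2, psf_sigma = 5, size = 501)
  expect_lt(abs(sum(img) - sum(df$ch)) / sum(df$ch), 0.01)

  # tile modulation leaves the image non-negative and seed-stable
  t1 <- render_image(cells, "ch", scale = 2, size = 501,
                     tile_amplitude = 0.3, tile_period = 100,
                     shot_noise = TRUE, seed = 3)
  t2 <- render_image(cells, "ch", scale = 2, size = 501,
                     tile_amplitude = 0.3, tile_period = 100,
                     shot_noise = TRUE, seed = 3)
  expect_identical(t1, t2)
  expect_true(all(t1 >= 0))
})

test_that("pixel profiles of rendered images agree with cell binning", {
  ss <- o2_steady_base()
  cells <- sample_cells(uniform_density(3e-4), seed = 31)
  cells <- assign_intensities(cells, ss$profile,
                              intensity_model("hypoxia", noise_sigma = 0.1),
                              seed = 32)
  img <- render_image(cells, "reporter", scale = 10, psf_sigma = 5)
  ctr <- (ncol(img) + 1) / 2
  pix <- pixel_radial_profile(img, center = c(ctr, ctr), scale = 10)
  cel <- bin_cells(cells, "reporter")
  nb <- min(length(pix$mfi), length(cel$mfi))
  ok <- which(!is.na(pix$mfi[1:nb]) & !is.na(cel$mfi[1:nb]) &
                cel$n[1:nb] >= 5)
  # uniform density: pixel fluorescence per area tracks per-cell MFI
  expect_gt(cor(pix$mfi[ok], cel$mfi[ok]), 0.9)
})

test_that("the full pipeline recovers the model front within one bin", {
  ss <- o2_steady_base()
  thr <- matched_threshold(ss, 0.9)
  model_front <- front_from_concentration(ss$profile, thr) + 350
  for (s in 1:5) {
    rec <- recover_front(ss, seed = s)
    expect_lt(abs(rec - model_front), 50)
  }
})
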