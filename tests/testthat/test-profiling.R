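# Quantification pipeline: annulus binning, pixel profiles,
# normalization, smoothing, front detection, area change, correlation,
# replicate aggregation.  Expected values are hand computations on tiny
# constructed inputs.

toy_cells <- function(r, I, channel = "ch") {
  df <- data.frame(cell_id = seq_along(r), x_um = r, y_um = 0)
  df[[channel]] <- I
  cell_table(df)
}

test_that("cells are binned into 50-um annuli with per-bin MFI and SEM", {
  # single cell at r = 75: lands in [50, 100)
  p1 <- bin_cells(toy_cells(75, 10), "ch")
  expect_equal(as.data.frame(p1)$mfi, c(NA, 10))
  expect_equal(as.data.frame(p1)$n, c(0L, 1L))

  # identical intensities: every occupied bin has that mean, SEM 0
  pc <- bin_cells(toy_cells(c(10, 20, 60, 110, 120), rep(7, 5)), "ch")
  expect_equal(pc$mfi, c(7, 7, 7))
  expect_equal(pc$sem, c(0, NA, 0))

  # hand computation: r = 20 (I=2), 60 (4), 80 (6), 120 (10)
  ph <- bin_cells(toy_cells(c(20, 60, 80, 120), c(2, 4, 6, 10)), "ch")
  expect_equal(ph$mfi, c(2, 5, 10))
  # SEM: single-cell bins undefined, the two-cell bin sd/sqrt(2) = 1
  expect_equal(ph$sem, c(NA, 1, NA))
  expect_equal(ph$n, c(1L, 2L, 1L))
})

test_that("binning conserves counts and respects the exclusion radius", {
  set.seed(7)
  n <- 500
  r <- runif(n, 0, 800)
  cells <- toy_cells(r, runif(n))
  p <- bin_cells(cells, "ch")
  expect_equal(sum(p$n), sum(r < max(p$bin_edges)))
  expect_message(p2 <- bin_cells(cells, "ch", max_radius = 400), "excluded")
  expect_equal(sum(p2$n), sum(r <= 400))
  expect_error(bin_cells(cells, "nope"), "unknown channel")
})

test_that("pixel radial profile averages pixels by radius", {
  # constant image: every bin is that constant
  img <- matrix(3.5, 21, 21)
  p <- pixel_radial_profile(img, center = c(11, 11), scale = 1,
                            bin_width = 5)
  expect_true(all(abs(p$mfi[!is.na(p$mfi)] - 3.5) < 1e-12))

  # 5x5 image, ones everywhere except centre = 5: bin [0,1) holds only
  # the centre pixel, bin [1,2) the 8 neighbours (radii 1 and sqrt(2))
  img5 <- matrix(1, 5, 5)
  img5[3, 3] <- 5
  p5 <- pixel_radial_profile(img5, center = c(3, 3), scale = 1,
                             bin_width = 1)
  expect_equal(p5$mfi[1], 5)
  expect_equal(p5$mfi[2], 1)
  expect_equal(p5$n[2], 8L)

  # image whose value is its own radius: bin means must match the mean
  # radius of member pixels computed by brute force
  sz <- 41
  ctr <- c(21, 21)
  rr <- sqrt((col(matrix(0, sz, sz)) - ctr[1])^2 +
               (row(matrix(0, sz, sz)) - ctr[2])^2) * 2   # scale 2 um/px
  pr <- pixel_radial_profile(rr, center = ctr, scale = 2, bin_width = 4)
  brute <- tapply(as.vector(rr), findInterval(as.vector(rr),
                                              pr$bin_edges), mean)
  expect_equal(unname(pr$mfi[as.integer(names(brute))]),
               as.vector(unname(brute)))
  # bin means sit within half a pixel spacing of the bin centres
  ok <- !is.na(pr$mfi) & pr$n > 20
  expect_true(all(abs(pr$mfi[ok] - pr$bin_centers[ok]) <= 1))

  expect_error(pixel_radial_profile(img5, center = c(9, 3)), "inside")
})

test_that("normalization modes rescale intensity and distance as documented", {
  p <- radial_profile(seq(0, 200, 50), c(4, 2, NA, 1), n = c(5, 5, 0, 5))

  pf <- normalize_profile(p, intensity_mode = "first_point")
  expect_equal(pf$mfi, c(1, 0.5, NA, 0.25))
  expect_equal(pf$normalization$reference, 4)

  pm <- normalize_profile(p, intensity_mode = "max")
  expect_equal(max(pm$mfi, na.rm = TRUE), 1)
  expect_true(all(pm$mfi <= 1, na.rm = TRUE))

  # external reference equal to the first point reproduces first_point
  pe <- normalize_profile(p, intensity_mode = "external_reference",
                          reference = 4)
  expect_equal(pe$mfi, pf$mfi)

  pd <- normalize_profile(p, distance_mode = "relative_to_disk_radius",
                          disk_radius = 200)
  expect_equal(max(pd$bin_edges), 1)

  zero <- radial_profile(seq(0, 100, 50), c(0, 1), n = c(1, 1))
  expect_error(normalize_profile(zero, intensity_mode = "first_point"),
               "reference")
})

test_that("normalized profiles and fronts are invariant to intensity scale", {
  set.seed(3)
  r <- runif(2000, 0, 2000)
  I <- pmin(1, (r / 1500)^2) * 100 + runif(2000)
  a <- smooth_profile(normalize_profile(bin_cells(toy_cells(r, I), "ch"),
                                        intensity_mode = "max"))
  b <- smooth_profile(normalize_profile(bin_cells(toy_cells(r, 37 * I),
                                                  "ch"),
                                        intensity_mode = "max"))
  expect_equal(a$mfi, b$mfi)
  expect_equal(hypoxic_front(a)$distance, hypoxic_front(b)$distance)
})

test_that("moving-average smoothing truncates at the edges", {
  mk <- function(v) radial_profile(seq(0, 50 * length(v), 50), v,
                                   n = rep(2L, length(v)))
  # spike: hand-computed truncated 5-point means
  sp <- smooth_profile(mk(c(0, 0, 0, 10, 0, 0, 0)))
  expect_equal(sp$mfi, c(0, 2.5, 2, 2, 2, 2.5, 0))

  const <- mk(rep(4, 12))
  expect_equal(smooth_profile(const)$mfi, rep(4, 12))

  v <- runif(9)
  expect_equal(smooth_profile(mk(v), window = 1)$mfi, v)
  expect_error(smooth_profile(mk(v), window = 4), "odd")
})

test_that("smoothing preserves the interior mean of long profiles", {
  set.seed(9)
  v <- runif(60, 5, 10)
  p <- radial_profile(seq(0, 3000, 50), v, n = rep(3L, 60))
  sm <- smooth_profile(p, 5)
  interior <- 3:58
  expect_lt(abs(mean(sm$mfi[interior]) - mean(v[interior])) /
              mean(v[interior]), 0.01)
})

test_that("hypoxic front finds the first 90% crossing with interpolation", {
  mk <- function(d, v) {
    w <- d[2] - d[1]
    radial_profile(c(d - w / 2, d[length(d)] + w / 2), v,
                   n = rep(2L, length(v)))
  }
  # linear ramp 0 -> 100 over 0 -> 1000 um: 90% of max at 900 um
  d <- seq(0, 1000, 100)
  fr <- hypoxic_front(mk(d, d / 10))
  expect_equal(fr$distance, 900)
  expect_equal(fr$max_value, 100)

  # already above threshold at the first bin
  flat_hi <- hypoxic_front(mk(d, c(95, 96, rep(100, 9))))
  expect_equal(flat_hi$distance, 0)
  expect_equal(flat_hi$crossing_bin, 1L)

  # ramp to max at 500, plateau, later dip: first crossing wins at 450
  d2 <- seq(0, 1000, 50)
  v2 <- c(seq(0, 100, 10), rep(100, 6), 80, 80, 100, 100)
  expect_equal(hypoxic_front(mk(d2, v2))$distance, 450)

  expect_error(hypoxic_front(mk(d, rep(5, 11))), "flat")
})

test_that("front distance is monotone in the defining fraction", {
  d <- seq(0, 2000, 50)
  v <- 100 / (1 + exp(-(d - 900) / 150))
  p <- radial_profile(c(d - 25, 2025), v, n = rep(2L, length(v)))
  fronts <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95), function(f)
    hypoxic_front(p, f)$distance, numeric(1))
  expect_true(all(diff(fronts) >= 0))
})

test_that("front fold change is the treated/control ratio", {
  expect_equal(front_fold_change(800, 800), 1)
  expect_equal(front_fold_change(1600, 800), 2)
  expect_equal(front_fold_change(1600 * 3.2, 800 * 3.2), 2)  # scale invariant
  expect_error(front_fold_change(100, 0), "> 0")
})

test_that("disk area change follows pixel counts and the circle formula", {
  m <- rasterize_circle(50)
  d0 <- disk_mask(m, scale = 2)
  expect_equal(disk_area_change(d0, d0), 0)

  # radius * sqrt(2) doubles the area
  expect_equal(disk_area_change(disk_mask(radius = 100),
                                disk_mask(radius = 100 * sqrt(2))), 100)

  # rasterized 100 px -> 90 px circle: -19% by the circle formula,
  # within rasterization error
  big <- disk_mask(rasterize_circle(100, 221), scale = 1)
  small <- disk_mask(rasterize_circle(90, 221), scale = 1)
  expect_equal(disk_area_change(big, small), -19, tolerance = 0.05)

  expect_error(disk_area_change(disk_mask(matrix(FALSE, 5, 5), scale = 2),
                                d0), "empty")
  expect_error(disk_area_change(d0, disk_mask(m, scale = 3)), "scale")
})

test_that("channel correlation is Pearson r over paired bins", {
  mk <- function(v) radial_profile(seq(0, 50 * length(v), 50), v,
                                   n = rep(2L, length(v)))
  p <- mk(c(1, 3, 2, 5, 4))
  expect_equal(correlate_channels(p, p), 1)
  neg <- mk(10 - c(1, 3, 2, 5, 4))
  expect_equal(correlate_channels(p, neg), -1)

  # textbook hand computation
  expect_equal(correlate_channels(mk(c(1, 2, 3)), mk(c(1, 2, 4))),
               3 / (sqrt(2) * sqrt(14 / 3)), tolerance = 1e-12)
  expect_equal(correlate_channels(mk(c(1, 2, 3)), mk(c(1, 2, 4))),
               0.98198, tolerance = 1e-4)

  expect_error(correlate_channels(p, mk(rep(2, 5))), "variance")
  expect_error(correlate_channels(p, mk(c(1, 2, 3))), "bin structure")
})

test_that("replicate aggregation pools per bin with SEM and gap skipping", {
  mk <- function(v, norm = "none") {
    p <- radial_profile(seq(0, 50 * length(v), 50), v,
                        n = rep(2L, length(v)))
    if (norm != "none") p <- normalize_profile(p, intensity_mode = norm)
    p
  }
  # hand computation: bins [1,3] and [2,4] -> means [2,3], SEM [1,1]
  agg <- aggregate_replicates(list(mk(c(1, 2)), mk(c(3, 4))))
  expect_equal(agg$mfi, c(2, 3))
  expect_equal(agg$sem, c(1, 1))
  expect_equal(agg$n, c(2L, 2L))

  single <- aggregate_replicates(list(mk(c(5, 6))))
  expect_equal(single$mfi, c(5, 6))
  expect_true(all(is.na(single$sem)))

  twin <- aggregate_replicates(list(mk(c(5, 6)), mk(c(5, 6))))
  expect_equal(twin$sem, c(0, 0))

  # gaps are skipped, not imputed
  ga <- aggregate_replicates(list(mk(c(1, NA)), mk(c(3, 7))))
  expect_equal(ga$mfi, c(2, 7))
  expect_equal(ga$n, c(2L, 1L))
  expect_true(is.na(ga$sem[2]))

  expect_error(aggregate_replicates(list(mk(c(1, 2), "max"), mk(c(3, 4)))),
               "normalization")
})

test_that("cell tables validate structure and round-trip through CSV", {
  df <- data.frame(cell_id = 1:3, x_um = c(10, 20, 30), y_um = 0,
                   green = c(1.5, 2, 0))
  ct <- cell_table(df)
  expect_equal(channels(ct), "green")
  expect_error(cell_table(df[-1]), "cell_id")
  expect_error(cell_table(transform(df, green = -1)), "green")
  dup <- df
  dup$cell_id <- c(1, 1, 2)
  expect_error(cell_table(dup), "unique")

  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(ct, path)
  back <- read_cell_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ct))

  # malformed rows are reported with their line number
  writeLines(c("cell_id,x_um,y_um,green", "1,10,0,2", "2,oops,0,3"), path)
  expect_error(read_cell_table(path), "line 3")
})
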