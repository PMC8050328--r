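#' Radial cell-density profile
#'
#' Expected cell density (cells/um^2) as a function of radial distance
#' from the opening centre, interpolated linearly between the supplied
#' points and held constant beyond them.
#'
#' @param distance Distances, um (strictly increasing).
#' @param density Expected densities, cells/um^2 (non-negative, finite).
#' @return An object of class `density_profile`, callable via
#'   [density_at()].
#' @export
density_profile <- function(distance, density) {
  if (length(distance) != length(density) || length(distance) < 1L)
    stop_reec("'distance' and 'density' must have equal positive length")
  if (is.unsorted(distance, strictly = TRUE))
    stop_reec("'distance' must be strictly increasing")
  if (any(!is.finite(density)) || any(density < 0))
    stop_reec("densities must be finite and >= 0")
  structure(list(distance = distance, density = density),
            class = "density_profile")
}

#' Spatially uniform density profile
#' @param density Cells/um^2.  The default 2e-3 /um^2 equals the
#'   reference plating density of 2e5 cells/cm^2.
#' @return A [density_profile()].
#' @export
uniform_density <- function(density = 2e-3) {
  density_profile(c(0, 1), c(density, density))
}

#' Evaluate a density profile
#' @param density A [density_profile()].
#' @param r Distances, um.
#' @return Densities at `r`, cells/um^2.
#' @export
density_at <- function(density, r) {
  stopifnot(inherits(density, "density_profile"))
  if (length(density$distance) == 1L)
    return(rep(density$density, length(r)))
  stats::approx(density$distance, density$density, xout = r,
                rule = 2)$y
}

#' Sample synthetic cell positions on the chamber annulus
#'
#' Draws cells from an inhomogeneous spatial Poisson process over the
#' annulus `[r_inner, r_outer]` with the given radial intensity
#' (cells/um^2), uniform in angle, by thinning a homogeneous proposal at
#' the peak density.  Identical seeds give identical tables.
#'
#' @param density A [density_profile()].
#' @param geom A [chamber_geometry()].
#' @param seed Integer seed (required: fixtures must be reproducible).
#' @return A [cell_table()] with columns `cell_id`, `x_um`, `y_um`,
#'   centred on the opening.
#' @export
sample_cells <- function(density, geom = chamber_geometry(), seed) {
  stopifnot(inherits(density, "density_profile"),
            inherits(geom, "chamber_geometry"))
  if (missing(seed)) stop_reec("'seed' is required")
  r1 <- geom$r_inner
  r2 <- geom$r_outer
  rho_max <- max(density_at(density, seq(r1, r2, length.out = 2048L)))
  with_seed(seed, {
    if (rho_max <= 0) {
      df <- data.frame(cell_id = integer(0), x_um = numeric(0),
                       y_um = numeric(0))
      return(cell_table(df))
    }
    n_prop <- stats::rpois(1, rho_max * pi * (r2^2 - r1^2))
    r <- sqrt(stats::runif(n_prop, r1^2, r2^2))   # uniform over the annulus
    keep <- stats::runif(n_prop) < density_at(density, r) / rho_max
    r <- r[keep]
    theta <- stats::runif(length(r), 0, 2 * pi)
    df <- data.frame(cell_id = seq_along(r),
                     x_um = r * cos(theta),
                     y_um = r * sin(theta))
    cell_table(df)
  })
}

#' Reporter response model
#'
#' Maps local concentration to expected per-cell fluorescence.
#' `"hypoxia"` is the default linear hypoxia-reporter convention,
#' `I = I_max * (1 - C/C_ref)` clipped at 0, signal rising as oxygen
#' falls.  `"hypoxia_sigmoid"` is a thresholded alternative,
#' `I = I_max / (1 + exp((C - C_thresh)/width))`, reflecting that
#' reporter chemistry activates below a threshold oxygen tension (the
#' default threshold, 44.5 uM, is the 5%-O2 equivalent of 178 uM at
#' ~20% incubator O2).  `"direct"` is an affine response
#' `I = gain0 + gain1 * C` for reporters that rise with concentration.
#' Per-cell noise is multiplicative log-normal with standard deviation
#' `noise_sigma` on the log scale, plus an additive background.
#'
#' @param response One of `"hypoxia"`, `"hypoxia_sigmoid"`, `"direct"`.
#' @param I_max Maximum expected intensity (arbitrary units).
#' @param C_ref Reference concentration for the linear hypoxia response,
#'   uM.
#' @param C_thresh,width Sigmoid midpoint and steepness, uM.
#' @param gain0,gain1 Affine response coefficients.
#' @param noise_sigma Log-normal sigma (default 0.2).
#' @param background Additive offset.
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(response = c("hypoxia", "hypoxia_sigmoid",
                                         "direct"),
                            I_max = 1000, C_ref = 171,
                            C_thresh = 44.5, width = 5,
                            gain0 = 0, gain1 = 1,
                            noise_sigma = 0.2, background = 0) {
  response <- match.arg(response)
  check_scalar(I_max, "I_max", allow_zero = TRUE)
  check_scalar(noise_sigma, "noise_sigma", allow_zero = TRUE)
  check_scalar(background, "background", allow_zero = TRUE)
  if (gain1 < 0) stop_reec("'gain1' must be >= 0")
  fn <- switch(response,
    hypoxia = function(C) I_max * pmax(1 - C / C_ref, 0),
    hypoxia_sigmoid = function(C) I_max / (1 + exp((C - C_thresh) / width)),
    direct = function(C) gain0 + gain1 * C)
  structure(list(response = response, fn = fn, I_max = I_max, C_ref = C_ref,
                 C_thresh = C_thresh, width = width, gain0 = gain0,
                 gain1 = gain1, noise_sigma = noise_sigma,
                 background = background),
            class = "intensity_model")
}

#' Expected reporter intensity at given concentrations
#' @param model An [intensity_model()].
#' @param C Concentrations, uM.
#' @return Expected intensities (noise-free, background included).
#' @export
expected_intensity <- function(model, C) {
  stopifnot(inherits(model, "intensity_model"))
  model$fn(C) + model$background
}

#' Assign concentration-dependent intensities to cells
#'
#' Looks up the local concentration at each cell's radius on a
#' concentration profile (linear interpolation between nodes) and draws
#' the per-cell intensity `response(C) * exp(eps) + background`,
#' `eps ~ N(0, noise_sigma^2)`.  Every cell must lie inside the profile
#' domain.
#'
#' @param cells A [cell_table()].
#' @param profile A [concentration_profile()].
#' @param model An [intensity_model()].
#' @param seed Integer seed.
#' @param channel Name of the intensity column to create.
#' @return The cell table with the new channel column.
#' @export
assign_intensities <- function(cells, profile, model, seed,
                               channel = "reporter") {
  stopifnot(inherits(cells, "cell_table"),
            inherits(profile, "concentration_profile"),
            inherits(model, "intensity_model"))
  if (missing(seed)) stop_reec("'seed' is required")
  r <- cell_radii(cells)
  nodes <- profile$grid$nodes
  tol <- 1e-9 * max(nodes)
  if (nrow(cells) > 0 &&
      (min(r) < min(nodes) - tol || max(r) > max(nodes) + tol))
    stop_reec("cell radii outside the concentration-profile domain [",
              min(nodes), ", ", max(nodes), "] um")
  C <- stats::approx(nodes, profile$C, xout = pmin(pmax(r, min(nodes)),
                                                  max(nodes)))$y
  base <- model$fn(C)
  out <- with_seed(seed, {
    eps <- stats::rnorm(length(base), 0, model$noise_sigma)
    base * exp(eps) + model$background
  })
  df <- as.data.frame(cells)
  df[[channel]] <- out
  cell_table(df, center = attr(cells, "center"))
}

#' Synthetic disk-formation time series
#'
#' Phenomenological emulation of disk formation: the radial density
#' interpolates from the uniform plating density towards a disk-shaped
#' profile with a logistic edge at the target radius (cells densify near
#' the opening and are lost distally), so the occupied radius shrinks
#' monotonically across time points.  No mechanistic migration,
#' proliferation or death dynamics are modelled.
#'
#' @param geom A [chamber_geometry()].
#' @param times_h Time stamps, hours; the first is the uniform state and
#'   the last the fully formed disk.
#' @param initial_density Uniform plating density, cells/um^2.
#' @param disk_radius Target disk radius, um; must not exceed the chamber
#'   radius.
#' @param densification Fold increase of density inside the final disk.
#' @param edge_width Logistic edge width, um.
#' @param seed Master seed; each time point draws from a derived
#'   sub-seed.
#' @return A list of [cell_table()]s, one per time point, each with a
#'   `time_h` attribute.
#' @export
make_disk_series <- function(geom = chamber_geometry(),
                             times_h = c(0, 48, 96, 192),
                             initial_density = 2e-3,
                             disk_radius = 1500,
                             densification = 3,
                             edge_width = 100,
                             seed) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (missing(seed)) stop_reec("'seed' is required")
  check_scalar(initial_density, "initial_density", allow_zero = TRUE)
  check_scalar(disk_radius, "disk_radius")
  if (disk_radius > geom$r_outer)
    stop_reec("'disk_radius' exceeds the chamber radius")
  if (is.unsorted(times_h, strictly = TRUE))
    stop_reec("'times_h' must be strictly increasing")
  rgrid <- seq(geom$r_inner, geom$r_outer, length.out = 256L)
  w_all <- (times_h - times_h[1]) / diff(range(times_h))
  lapply(seq_along(times_h), function(i) {
    w <- w_all[i]
    disk_shape <- 1 / (1 + exp((rgrid - disk_radius) / edge_width))
    rho <- initial_density * ((1 - w) + w * densification * disk_shape)
    tab <- sample_cells(density_profile(rgrid, rho), geom,
                        seed = derive_seed(seed, i))
    attr(tab, "time_h") <- times_h[i]
    tab
  })
}

#' Render a synthetic fluorescence image from a cell table
#'
#' Sums isotropic Gaussian spots (integral equal to the cell's intensity)
#' at the cell positions onto a square 16-bit canvas centred on the
#' opening, optionally modulated by a periodic tile pattern emulating the
#' checkerboard artifact of stitched mosaics, optionally with Poisson
#' shot noise.
#'
#' @param cells A [cell_table()] with the channel to render.
#' @param channel Channel name.
#' @param scale um per pixel (default 10).
#' @param psf_sigma Gaussian spot sigma, um (default 5).
#' @param size Image side, pixels; defaults to the smallest square
#'   containing every cell.
#' @param background Additive background level.
#' @param tile_amplitude,tile_period Relative amplitude and period (um)
#'   of the multiplicative tile modulation; amplitude 0 disables it.
#' @param shot_noise If `TRUE`, replace each pixel by a Poisson draw.
#' @param seed Seed (required when `shot_noise`).
#' @param max_value Saturation level (default 65535, 16-bit).
#' @param saturation_warn_frac Warn when more than this fraction of
#'   pixels saturate.
#' @return A `size x size` numeric matrix with attribute `scale`
#'   (um/pixel); values clipped to `[0, max_value]`.
#' @export
render_image <- function(cells, channel, scale = 10, psf_sigma = 5,
                         size = NULL, background = 0,
                         tile_amplitude = 0, tile_period = 500,
                         shot_noise = FALSE, seed = NULL,
                         max_value = 65535, saturation_warn_frac = 0.01) {
  stopifnot(inherits(cells, "cell_table"))
  if (nrow(cells) > 0 && !isTRUE(channel %in% channels(cells)))
    stop_reec("unknown channel '", channel, "'")
  check_scalar(scale, "scale")
  check_scalar(psf_sigma, "psf_sigma")
  ctr <- attr(cells, "center")
  x <- cells$x_um - ctr[1]
  y <- cells$y_um - ctr[2]
  if (is.null(size)) {
    extent <- if (nrow(cells)) max(abs(c(x, y))) + 4 * psf_sigma else
      10 * scale
    size <- 2L * ceiling(extent / scale) + 1L
  }
  c0 <- (size + 1) / 2                       # centre pixel
  px <- x / scale + c0
  py <- y / scale + c0
  if (nrow(cells) && (min(px, py) < 1 || max(px, py) > size))
    stop_reec("cells fall outside the ", size, "x", size, " px field")
  img <- matrix(0, size, size)
  if (nrow(cells)) {
    s_px <- psf_sigma / scale
    halo <- max(1L, ceiling(4 * s_px))
    amp <- cells[[channel]] / (2 * pi * s_px^2)   # integral = intensity
    for (i in seq_len(nrow(cells))) {
      ix <- max(1L, floor(px[i]) - halo):min(size, ceiling(px[i]) + halo)
      iy <- max(1L, floor(py[i]) - halo):min(size, ceiling(py[i]) + halo)
      gx <- exp(-(ix - px[i])^2 / (2 * s_px^2))
      gy <- exp(-(iy - py[i])^2 / (2 * s_px^2))
      img[iy, ix] <- img[iy, ix] + amp[i] * outer(gy, gx)
    }
  }
  img <- img + background
  if (tile_amplitude > 0) {
    check_scalar(tile_period, "tile_period")
    ax <- sin(2 * pi * ((seq_len(size) - c0) * scale) / tile_period)
    img <- img * (1 + tile_amplitude * outer(ax, ax))
  }
  if (shot_noise) {
    if (is.null(seed)) stop_reec("'seed' is required with shot noise")
    img <- with_seed(seed,
      matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img)))
  }
  sat <- img > max_value
  if (mean(sat) > saturation_warn_frac)
    warning(sprintf("%.1f%% of pixels saturate at %g",
                    100 * mean(sat), max_value))
  img[sat] <- max_value
  img[img < 0] <- 0
  structure(img, scale = scale)
}

#' Write a 16-bit TIFF
#' @param img Matrix from [render_image()] (values in `[0, 65535]`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image16 <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img / 65535, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}
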