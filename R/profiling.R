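#' Per-cell table
#'
#' A table of segmented cells: positions in um and one intensity column
#' per fluorescence channel, plus the coordinates of the chamber opening
#' centre against which radial distances are measured.  This is the form
#' in which segmentation output (cell id, centroid, per-channel mean
#' intensity) enters the quantification pipeline.
#'
#' @param df A data frame with columns `cell_id`, `x_um`, `y_um` and at
#'   least one intensity column.
#' @param center Opening centre `c(x, y)` in um (default origin).
#' @return A `cell_table` (a data frame with a `center` attribute).
#' @export
cell_table <- function(df, center = c(0, 0)) {
  if (!is.data.frame(df)) stop_reec("'df' must be a data frame")
  req <- c("cell_id", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_reec("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop_reec("'cell_id' values must be unique")
  if (!is.numeric(center) || length(center) != 2L || any(!is.finite(center)))
    stop_reec("'center' must be two finite coordinates (um)")
  chans <- setdiff(names(df), req)
  for (ch in chans) {
    v <- df[[ch]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop_reec("intensity column '", ch, "' must be finite and >= 0")
  }
  structure(df, center = center, class = c("cell_table", class(df)))
}

#' Channels available in a cell table
#' @param cells A [cell_table()].
#' @return Character vector of channel column names.
#' @export
channels <- function(cells) {
  setdiff(names(cells), c("cell_id", "x_um", "y_um"))
}

# radial distance of every cell from the opening centre
cell_radii <- function(cells) {
  ctr <- attr(cells, "center")
  sqrt((cells$x_um - ctr[1])^2 + (cells$y_um - ctr[2])^2)
}

#' Read / write a cell table as CSV
#'
#' The CSV dialect is comma-separated, UTF-8, `.` decimal separator, with
#' header `cell_id,x_um,y_um,<channel>,...`.  Malformed numeric fields are
#' reported with their line number.
#'
#' @param path File path.
#' @param center Opening centre, um.
#' @return A [cell_table()] (for `read_cell_table`); the path, invisibly
#'   (for `write_cell_table`).
#' @export
read_cell_table <- function(path, center = c(0, 0)) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  req <- c("cell_id", "x_um", "y_um")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop_reec("'", path, "' is missing column(s): ",
              paste(miss, collapse = ", "))
  num_cols <- setdiff(names(raw), "cell_id")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]) & nzchar(raw[[cl]]))
    if (length(bad) == 0) bad <- which(is.na(v))
    if (length(bad))
      stop_reec("malformed value in column '", cl, "' at line ",
                bad[1] + 1L, " of '", path, "'")
    raw[[cl]] <- v
  }
  raw$cell_id <- utils::type.convert(raw$cell_id, as.is = TRUE)
  cell_table(raw, center = center)
}

#' @rdname read_cell_table
#' @param cells A [cell_table()].
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Radial intensity profile
#'
#' Per-bin summary of intensity against radial distance: contiguous
#' half-open bins `[lo, hi)` of constant width starting at the opening
#' centre, the mean intensity (MFI) in each bin, its standard error, and
#' the number of cells (or pixels) contributing.  Empty bins carry `NA`
#' (a gap), never zero; the SEM of a single-observation bin is `NA`
#' (undefined), which is distinct from an observed SEM of 0.
#'
#' @param bin_edges Bin edges, length one more than the number of bins.
#' @param mfi Mean intensity per bin (`NA` for empty bins).
#' @param sem Standard error per bin.
#' @param n Observations per bin.
#' @param normalization A list recording the normalization state:
#'   `distance` mode, `intensity` mode, and the `reference` value used.
#' @return An object of class `radial_profile`.
#' @export
radial_profile <- function(bin_edges, mfi, sem = rep(NA_real_, length(mfi)),
                           n = rep(NA_integer_, length(mfi)),
                           normalization = list(distance = "absolute",
                                                intensity = "none",
                                                reference = NA_real_)) {
  if (length(bin_edges) != length(mfi) + 1L)
    stop_reec("'bin_edges' must be one longer than 'mfi'")
  w <- diff(bin_edges)
  if (any(w <= 0) || diff(range(w)) > 1e-8 * mean(w))
    stop_reec("bins must be contiguous with constant positive width")
  structure(list(bin_edges = as.numeric(bin_edges),
                 bin_centers = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
                 mfi = as.numeric(mfi), sem = as.numeric(sem),
                 n = as.integer(n), normalization = normalization),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  nb <- length(x$mfi)
  cat(sprintf("radial profile: %d bins of width %g (%s distance), %d non-empty\n",
              nb, x$bin_edges[2] - x$bin_edges[1],
              x$normalization$distance, sum(!is.na(x$mfi))))
  cat(sprintf("intensity normalization: %s\n", x$normalization$intensity))
  invisible(x)
}

#' @export
as.data.frame.radial_profile <- function(x, ...) {
  data.frame(bin_lo_um = x$bin_edges[-length(x$bin_edges)],
             bin_hi_um = x$bin_edges[-1],
             mfi = x$mfi, sem = x$sem, n = x$n)
}

#' @export
plot.radial_profile <- function(x, ...) {
  graphics::plot(x$bin_centers, x$mfi, type = "b", pch = 16,
                 xlab = "distance", ylab = "MFI", ...)
  ok <- !is.na(x$sem)
  if (any(ok))
    graphics::arrows(x$bin_centers[ok], x$mfi[ok] - x$sem[ok],
                     x$bin_centers[ok], x$mfi[ok] + x$sem[ok],
                     angle = 90, code = 3, length = 0.02)
  invisible(x)
}

# shared binning of values by radius
bin_by_radius <- function(r, values, bin_width, max_edge = NULL) {
  if (is.null(max_edge)) max_edge <- ceiling(max(r) / bin_width) * bin_width
  if (max_edge <= 0) max_edge <- bin_width
  edges <- seq(0, max_edge, by = bin_width)
  nb <- length(edges) - 1L
  idx <- findInterval(r, edges, rightmost.closed = FALSE)  # [lo, hi)
  keep <- idx >= 1L & idx <= nb
  idx <- idx[keep]
  values <- values[keep]
  n <- tabulate(idx, nbins = nb)
  group_sum <- function(v) {
    out <- numeric(nb)
    if (length(v)) {
      s <- rowsum(v, idx)
      out[as.integer(rownames(s))] <- s
    }
    out
  }
  sums <- group_sum(values)
  mfi <- ifelse(n > 0, sums / n, NA_real_)
  sq <- group_sum(values^2)
  sd <- ifelse(n > 1, sqrt(pmax(sq - n * mfi^2, 0) / (n - 1)), NA_real_)
  sem <- ifelse(n > 1, sd / sqrt(n), NA_real_)
  list(edges = edges, mfi = mfi, sem = sem, n = n)
}

#' Bin per-cell intensities into radial annuli
#'
#' Cells are binned into annuli of constant width (default 50 um) from
#' the opening centre and the mean fluorescence intensity (MFI) per cell
#' in each bin is computed, with SEM = sd/sqrt(n).  Cells beyond
#' `max_radius` (e.g. detections outside the chamber in stitched mosaics)
#' are excluded with a message rather than an error.
#'
#' @param cells A [cell_table()].
#' @param channel Channel (intensity column) to profile.
#' @param bin_width Annulus width, um (default 50).
#' @param max_radius Optional exclusion radius, um.
#' @return A [radial_profile()].
#' @export
bin_cells <- function(cells, channel, bin_width = 50, max_radius = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  check_scalar(bin_width, "bin_width")
  if (!channel %in% channels(cells))
    stop_reec("unknown channel '", channel, "'; available: ",
              paste(channels(cells), collapse = ", "))
  r <- cell_radii(cells)
  v <- cells[[channel]]
  if (!is.null(max_radius)) {
    out <- r > max_radius
    if (any(out))
      message(sum(out), " cell(s) beyond ", max_radius, " um excluded")
    r <- r[!out]
    v <- v[!out]
  }
  if (length(r) == 0) stop_reec("no cells inside the binning range")
  b <- bin_by_radius(r, v, bin_width)
  radial_profile(b$edges, b$mfi, b$sem, b$n)
}

#' Radial profile of pixel intensities
#'
#' Bins every pixel of a single-channel raster by its radial distance
#' from a fixed point and averages the intensities, the raster analog of
#' [bin_cells()] for disks that cannot be segmented.  Pixel positions are
#' taken at pixel centres; the image `x` is indexed `[row, col]` and the
#' centre is given as `c(col, row)` in pixel units.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param center Centre `c(x = col, y = row)` in pixel coordinates; must
#'   lie inside the image.
#' @param scale Pixel size, um per pixel.
#' @param bin_width Bin width, um (default 50).
#' @return A [radial_profile()] (here `n` counts pixels, and SEM is the
#'   per-bin pixel standard error).
#' @export
pixel_radial_profile <- function(image, center, scale = 1, bin_width = 50) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_reec("'image' must be a numeric matrix")
  check_scalar(scale, "scale")
  check_scalar(bin_width, "bin_width")
  if (length(center) != 2L || center[1] < 1 || center[1] > ncol(image) ||
      center[2] < 1 || center[2] > nrow(image))
    stop_reec("'center' must lie inside the image (pixel coordinates)")
  xs <- (col(image) - center[1]) * scale
  ys <- (row(image) - center[2]) * scale
  r <- sqrt(xs^2 + ys^2)
  b <- bin_by_radius(as.vector(r), as.vector(image), bin_width)
  radial_profile(b$edges, b$mfi, b$sem, b$n)
}

#' Normalize a radial profile
#'
#' Applies the normalization conventions used when pooling disks:
#' intensities divided by the MFI of the first non-empty bin (the value
#' at the opening), by the profile maximum, or by an externally supplied
#' reference (e.g. the first-bin value of a control-group disk); and
#' distances divided by the disk radius, or by the maximum depth (so 0 is
#' the surface and 1 the deepest point, the spheroid convention).  SEMs
#' are scaled by the same intensity reference.
#'
#' @param profile A [radial_profile()].
#' @param intensity_mode One of `"none"`, `"first_point"`, `"max"`,
#'   `"external_reference"`.
#' @param distance_mode One of `"absolute"`, `"relative_to_disk_radius"`,
#'   `"relative_depth"`.
#' @param reference Reference intensity for `"external_reference"`.
#' @param disk_radius Disk radius, um, for `"relative_to_disk_radius"`.
#' @param max_depth Maximum depth, um, for `"relative_depth"`.
#' @return The normalized [radial_profile()]; its `normalization` field
#'   records the modes and reference used.
#' @export
normalize_profile <- function(profile,
                              intensity_mode = c("none", "first_point", "max",
                                                 "external_reference"),
                              distance_mode = c("absolute",
                                                "relative_to_disk_radius",
                                                "relative_depth"),
                              reference = NULL, disk_radius = NULL,
                              max_depth = NULL) {
  stopifnot(inherits(profile, "radial_profile"))
  intensity_mode <- match.arg(intensity_mode)
  distance_mode <- match.arg(distance_mode)

  ref <- switch(intensity_mode,
    none = NA_real_,
    first_point = profile$mfi[which(!is.na(profile$mfi))[1]],
    max = max(profile$mfi, na.rm = TRUE),
    external_reference = {
      if (is.null(reference))
        stop_reec("'reference' is required for external_reference mode")
      reference
    })
  if (intensity_mode != "none") {
    if (!is.finite(ref) || ref <= 0)
      stop_reec("normalization reference must be a positive finite value ",
                "(got ", format(ref), ")")
    profile$mfi <- profile$mfi / ref
    profile$sem <- profile$sem / ref
  }

  dref <- switch(distance_mode,
    absolute = NA_real_,
    relative_to_disk_radius = {
      if (is.null(disk_radius))
        stop_reec("'disk_radius' is required for relative_to_disk_radius mode")
      check_scalar(disk_radius, "disk_radius")
    },
    relative_depth = {
      if (is.null(max_depth))
        stop_reec("'max_depth' is required for relative_depth mode")
      check_scalar(max_depth, "max_depth")
    })
  if (distance_mode != "absolute") {
    profile$bin_edges <- profile$bin_edges / dref
    profile$bin_centers <- profile$bin_centers / dref
  }

  profile$normalization <- list(distance = distance_mode,
                                intensity = intensity_mode,
                                reference = if (intensity_mode == "none")
                                  NA_real_ else ref)
  profile
}

#' Smooth a radial profile with a centred moving average
#'
#' A centred moving average of odd window length (default 5 points), the
#' filter used to suppress the periodic intensity oscillation that
#' tile-stitched mosaics imprint on radial profiles.  At the profile ends
#' the window truncates to the available points.  Gaps (`NA` bins) do not
#' contribute to neighbouring windows and remain gaps.  SEMs are carried
#' through unchanged (the filter does not propagate uncertainty).
#'
#' @param profile A [radial_profile()].
#' @param window Odd window length in bins (default 5); 1 is the identity.
#' @return The smoothed [radial_profile()].
#' @export
smooth_profile <- function(profile, window = 5) {
  stopifnot(inherits(profile, "radial_profile"))
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 != 1)
    stop_reec("'window' must be an odd positive integer")
  v <- profile$mfi
  n <- length(v)
  k <- (window - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    if (is.na(v[i])) return(NA_real_)
    win <- v[max(1, i - k):min(n, i + k)]
    mean(win, na.rm = TRUE)
  }, numeric(1))
  profile$mfi <- sm
  profile
}

#' Hypoxic front of a reporter profile
#'
#' The distance at which a hypoxia-reporter signal first reaches a given
#' fraction (default 90%) of its maximum, scanning outward from the
#' opening centre, with linear interpolation between adjacent bin
#' centres.  Exact ties resolve to the smaller distance; a profile
#' already at or above the threshold in its first bin fronts at the
#' first bin centre.
#'
#' @param profile A [radial_profile()] of a signal that increases with
#'   hypoxia (e.g. a fluorogenic hypoxia reporter).
#' @param fraction Fraction of the maximum defining the front
#'   (default 0.9).
#' @return An object of class `front_estimate`: `distance` (same units as
#'   the profile distances), `fraction`, `max_value` and `crossing_bin`
#'   (index of the first bin at or above threshold).
#' @export
hypoxic_front <- function(profile, fraction = 0.9) {
  stopifnot(inherits(profile, "radial_profile"))
  check_scalar(fraction, "fraction")
  if (fraction > 1) stop_reec("'fraction' must be in (0, 1]")
  ok <- which(!is.na(profile$mfi))
  if (length(ok) < 2L)
    stop_reec("need at least two non-empty bins to locate a front")
  v <- profile$mfi[ok]
  d <- profile$bin_centers[ok]
  if (diff(range(v)) == 0)
    stop_reec("flat profile: front undefined")
  m <- max(v)
  target <- fraction * m
  i <- which(v >= target)[1]
  dist <- if (i == 1L) d[1] else
    d[i - 1] + (target - v[i - 1]) / (v[i] - v[i - 1]) * (d[i] - d[i - 1])
  structure(list(distance = dist, fraction = fraction, max_value = m,
                 crossing_bin = ok[i]),
            class = "front_estimate")
}

#' @export
print.front_estimate <- function(x, ...) {
  cat(sprintf("front at %.4g (%.0f%% of max %.4g), crossing bin %d\n",
              x$distance, 100 * x$fraction, x$max_value, x$crossing_bin))
  invisible(x)
}

#' Fold change between two front distances
#'
#' Treated front distance divided by control front distance (the
#' normalized-to-control convention used when comparing stimulated to
#' unstimulated consumers).  Invariant under a common rescaling of both
#' distances.
#'
#' @param front_treated,front_control [hypoxic_front()] estimates or bare
#'   distances.
#' @return The ratio.
#' @export
front_fold_change <- function(front_treated, front_control) {
  d1 <- if (inherits(front_treated, "front_estimate"))
    front_treated$distance else front_treated
  d0 <- if (inherits(front_control, "front_estimate"))
    front_control$distance else front_control
  check_scalar(d1, "front_treated", allow_zero = TRUE)
  if (!is.numeric(d0) || length(d0) != 1L || !is.finite(d0) || d0 <= 0)
    stop_reec("control front distance must be > 0")
  d1 / d0
}

#' Disk mask
#'
#' A cell-disk footprint, either as a binary raster with a um-per-pixel
#' scale or as an equivalent circle radius.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param scale um per pixel (required with `mask`).
#' @param radius Disk radius, um (alternative to `mask`).
#' @return An object of class `disk_mask`.
#' @export
disk_mask <- function(mask = NULL, scale = NULL, radius = NULL) {
  if (is.null(mask) == is.null(radius))
    stop_reec("give exactly one of 'mask' or 'radius'")
  if (!is.null(mask)) {
    if (!is.matrix(mask)) stop_reec("'mask' must be a matrix")
    if (is.null(scale)) stop_reec("'scale' (um/pixel) is required with a mask")
    check_scalar(scale, "scale")
    mask <- mask > 0
  } else {
    check_scalar(radius, "radius", allow_zero = TRUE)
  }
  structure(list(mask = mask, scale = scale, radius = radius),
            class = "disk_mask")
}

disk_area_um2 <- function(m) {
  if (!is.null(m$mask)) sum(m$mask) * m$scale^2 else pi * m$radius^2
}

#' Percent change in disk area
#'
#' `100 * (A1 - A0) / A0`, where areas come from mask pixel counts times
#' pixel area, or from `pi r^2` for radius-specified masks.  Raster masks
#' must share a scale.
#'
#' @param mask_t0,mask_t1 [disk_mask()] objects at the two time points.
#' @return Percent area change (negative for shrinkage).
#' @export
disk_area_change <- function(mask_t0, mask_t1) {
  stopifnot(inherits(mask_t0, "disk_mask"), inherits(mask_t1, "disk_mask"))
  if (!is.null(mask_t0$mask) && !is.null(mask_t1$mask) &&
      !isTRUE(all.equal(mask_t0$scale, mask_t1$scale)))
    stop_reec("masks must share the same um/pixel scale")
  a0 <- disk_area_um2(mask_t0)
  a1 <- disk_area_um2(mask_t1)
  if (a0 <= 0) stop_reec("empty reference mask: area change undefined")
  100 * (a1 - a0) / a0
}

#' Pearson correlation between two channel profiles
#'
#' Pearson correlation over paired per-bin means of two radial profiles
#' sharing the same bin structure (e.g. a glucose-uptake channel against
#' a mitochondrial-potential channel).  Bins empty in either profile are
#' dropped pairwise.
#'
#' @param profile_a,profile_b [radial_profile()] objects on identical
#'   bins.
#' @return Pearson r.
#' @export
correlate_channels <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "radial_profile"),
            inherits(profile_b, "radial_profile"))
  if (!isTRUE(all.equal(profile_a$bin_edges, profile_b$bin_edges)))
    stop_reec("profiles must share the same bin structure")
  ok <- !is.na(profile_a$mfi) & !is.na(profile_b$mfi)
  if (sum(ok) < 3L)
    stop_reec("need at least 3 paired non-empty bins")
  a <- profile_a$mfi[ok]
  b <- profile_b$mfi[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_reec("zero variance: correlation undefined")
  stats::cor(a, b, method = "pearson")
}

#' Aggregate replicate profiles into a mean +/- SEM profile
#'
#' Per-bin mean and standard error across replicate disks, the `mean +/-
#' SEM, N disks` summary used for pooled profiles.  All replicates must
#' share bin structure and normalization state (pool after normalizing,
#' not before).  Gaps are skipped per bin, never imputed as zeros; the
#' `n` field reports how many replicates contributed to each bin, and a
#' bin covered by a single replicate has an undefined (`NA`) SEM.
#'
#' @param profiles A list of [radial_profile()] objects.
#' @return A [radial_profile()] of the replicate means.
#' @export
aggregate_replicates <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0 ||
      !all(vapply(profiles, inherits, logical(1), "radial_profile")))
    stop_reec("'profiles' must be a non-empty list of radial profiles")
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!isTRUE(all.equal(p$bin_edges, ref$bin_edges)))
      stop_reec("replicates must share the same bin structure")
    if (!identical(p$normalization[c("distance", "intensity")],
                   ref$normalization[c("distance", "intensity")]))
      stop_reec("replicates have mixed normalization states")
  }
  m <- do.call(rbind, lapply(profiles, `[[`, "mfi"))
  n_rep <- colSums(!is.na(m))
  mean_v <- ifelse(n_rep > 0, colMeans(m, na.rm = TRUE), NA_real_)
  sd_v <- apply(m, 2, stats::sd, na.rm = TRUE)
  sem <- ifelse(n_rep > 1, sd_v / sqrt(n_rep), NA_real_)
  radial_profile(ref$bin_edges, mean_v, sem, n_rep,
                 normalization = ref$normalization)
}

#' Read / write a radial profile as CSV
#'
#' Header: `bin_lo_um,bin_hi_um,mfi,sem,n`.
#'
#' @param profile A [radial_profile()].
#' @param path File path.
#' @return The path, invisibly (write); a [radial_profile()] (read).
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path)
  radial_profile(c(df$bin_lo_um, df$bin_hi_um[nrow(df)]), df$mfi, df$sem,
                 df$n)
}
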