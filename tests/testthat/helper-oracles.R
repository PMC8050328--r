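# Independent oracles used to cross-check the package's solvers, plus a
# small cache so expensive reference solutions are computed once per run.

.oracle_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .oracle_cache))
    assign(key, force(expr), envir = .oracle_cache)
  get(key, envir = .oracle_cache)
}

# Independent steady-state two-point BVP solver: damped Newton iteration on
# a node-centred finite-difference discretization of
#   (1/r) d/dr (r D dC/dr) = nk * f(C),  C(r1) = Cb,  C'(r2) = 0
# with f(C) = Cb*C/(C+Km) (or f(C) = C in linear mode).  This is a direct
# steady solve, deliberately a different algorithm from the package's
# time-marching method-of-lines integration.
oracle_bvp_steady <- function(r, D, nk, Cb, Km = Cb, linear = FALSE) {
  N <- length(r)
  h <- diff(r)
  C <- rep(Cb, N)
  fcons <- function(C) if (linear) nk * C else nk * Cb * C / (C + Km)
  dfcons <- function(C) if (linear) rep(nk, length(C)) else
    nk * Cb * Km / (C + Km)^2
  for (it in 1:200) {
    G <- numeric(N)
    J <- matrix(0, N, N)
    G[1] <- C[1] - Cb
    J[1, 1] <- 1
    for (i in 2:(N - 1)) {
      rp <- (r[i] + r[i + 1]) / 2
      rm <- (r[i] + r[i - 1]) / 2
      ap <- rp * D / h[i]
      am <- rm * D / h[i - 1]
      vol <- r[i] * (h[i] + h[i - 1]) / 2
      G[i] <- (ap * (C[i + 1] - C[i]) - am * (C[i] - C[i - 1])) / vol -
        fcons(C[i])
      J[i, i + 1] <- ap / vol
      J[i, i - 1] <- am / vol
      J[i, i] <- -(ap + am) / vol - dfcons(C[i])
    }
    rm <- (r[N] + r[N - 1]) / 2
    am <- rm * D / h[N - 1]
    vol <- r[N] * h[N - 1] / 2
    G[N] <- -am * (C[N] - C[N - 1]) / vol - fcons(C[N])
    J[N, N - 1] <- am / vol
    J[N, N] <- -am / vol - dfcons(C[N])
    dC <- solve(J, -G)
    C <- pmax(C + dC, 0)
    if (max(abs(dC)) < 1e-11 * Cb) break
  }
  C
}

# Independent 1-D finite-difference steady column: D C'' = 0 on (0, L),
# C(L) = C_top, flux at the bottom equals the monolayer consumption
# (D dC/dx at x = 0 equals J).  Solved as a dense linear system.
oracle_column_fd <- function(L, D, J, C_top, N = 201) {
  x <- seq(0, L, length.out = N)
  h <- x[2] - x[1]
  A <- matrix(0, N, N)
  b <- numeric(N)
  A[1, 1:3] <- c(-3, 4, -1) / (2 * h)   # one-sided derivative at the bottom
  b[1] <- J / D
  for (i in 2:(N - 1)) A[i, (i - 1):(i + 1)] <- c(1, -2, 1)
  A[N, N] <- 1
  b[N] <- C_top
  solve(A, b)[1]
}

# reference oxygen steady states reused across test files
o2_steady_base <- function() cache_get("o2_base", {
  solve_steady_state(oxygen_params(), consumer_field())
})

o2_steady_low_ocr <- function() cache_get("o2_low", {
  sp <- oxygen_params()
  solve_steady_state(transport_params("oxygen", sp$D, sp$A_max / 4,
                                      sp$C_bulk),
                     consumer_field())
})

# binary raster of a filled circle (pixel-centre inclusion), used as an
# independent rasterization for the disk-area oracle
rasterize_circle <- function(radius_px, size = 2 * radius_px + 21) {
  c0 <- (size + 1) / 2
  d2 <- (row(matrix(0, size, size)) - c0)^2 +
    (col(matrix(0, size, size)) - c0)^2
  d2 <= radius_px^2
}

# recovered-front pipeline for one seed: sample cells at the reference
# plating density, assign hypoxia-reporter intensities, bin, smooth,
# detect the 90% front; returns distance from the chamber centre (um)
recover_front <- function(steady, seed, noise_sigma = 0.2,
                          density = 2e-3, bin_width = 50, window = 5,
                          fraction = 0.9) {
  cells <- sample_cells(uniform_density(density), seed = derive_seed(seed, 1))
  model <- intensity_model("hypoxia", C_ref = steady$profile$c_ref,
                           noise_sigma = noise_sigma)
  cells <- assign_intensities(cells, steady$profile, model,
                              seed = derive_seed(seed, 2))
  prof <- smooth_profile(bin_cells(cells, "reporter", bin_width = bin_width),
                         window = window)
  hypoxic_front(prof, fraction = fraction)$distance
}

# matched concentration threshold for a reporter front at `fraction` of max
matched_threshold <- function(steady, fraction = 0.9) {
  Cb <- steady$profile$c_ref
  Cmin <- min(steady$profile$C)
  Cb - fraction * (Cb - Cmin)
}
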