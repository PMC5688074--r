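# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own kernels: plain R loops over the defining formulas.

# Triple-loop weighted temporal average / variance.
bf_wta <- function(a, w) apply(a, 1:3, function(ts) sum(w * ts))
bf_wtv <- function(a, w) apply(a, 1:3, function(ts) {
  m <- sum(w * ts)
  sqrt(sum(w * (m - ts)^2))
})

# Histogram parameters of a raw value vector, mirroring the documented
# binning contract (local [min,max] range, lowest-bin tie-break, population
# std) but computed independently of the C++ kernel.
bf_hist_params <- function(vals, n_bins = 32, eps = 1e-4) {
  n <- length(vals)
  m <- mean(vals)
  s <- sqrt(sum((vals - m)^2) / n)
  vmin <- min(vals); vmax <- max(vals)
  if (vmax == vmin) {
    return(list(mean = m, sd = s, mode = vmin, entropy = -log2(1 + eps)))
  }
  bw <- (vmax - vmin) / n_bins
  bins <- pmin(floor((vals - vmin) / bw), n_bins - 1)
  counts <- tabulate(bins + 1, nbins = n_bins)
  p <- counts[counts > 0] / n
  list(mean = m, sd = s,
       mode = vmin + (which.max(counts) - 0.5) * bw,
       entropy = -sum(p * log2(p + eps)))
}

# Boundary voxels (foreground with a background 6-neighbor, out-of-bounds
# background) as an n x 3 index matrix.
bf_boundary <- function(m) {
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  keep <- apply(idx, 1, function(v) {
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- v; nb[ax] <- nb[ax] + s
      if (nb[ax] < 1 || nb[ax] > d[ax]) return(TRUE)
      if (!m[nb[1], nb[2], nb[3]]) return(TRUE)
    }
    FALSE
  })
  idx[keep, , drop = FALSE]
}

# Exhaustive directed boundary distance sets in physical mm.
bf_surface_sets <- function(ma, mb, spacing) {
  pa <- sweep(bf_boundary(ma), 2, spacing, `*`)
  pb <- sweep(bf_boundary(mb), 2, spacing, `*`)
  dmin <- function(p, q) apply(p, 1, function(v)
    sqrt(min(colSums((t(q) - v)^2))))
  list(a_to_b = dmin(pa, pb), b_to_a = dmin(pb, pa))
}

# Random structured mask: union of a few random balls plus salt voxels.
rand_mask <- function(dims = c(16L, 16L, 16L), n_balls = 2, salt = 3) {
  m <- array(FALSE, dims)
  centers <- matrix(runif(3 * n_balls, 3, dims - 2), ncol = 3)
  radii <- runif(n_balls, 1.5, 4)
  coords <- as.matrix(expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3]))
  for (b in seq_len(n_balls)) {
    d2 <- colSums((t(coords) - centers[b, ])^2)
    m[coords[d2 <= radii[b]^2, , drop = FALSE]] <- TRUE
  }
  m[sample(prod(dims), salt)] <- TRUE
  m
}

# A tiny, fast phantom spec for unit tests (not the study conditions of the
# acceptance suite, which uses the defaults).
tiny_spec <- function(noise_sd = 5) {
  extent <- c(32, 32, 32) * c(0.43, 0.43, 0.5)
  phantom_spec(
    shape = c(32L, 32L, 32L),
    noise_sd = noise_sd,
    vessels = list(
      list(points = rbind(c(extent[1] / 2, extent[2] / 2, 0.15 * extent[3]),
                          c(extent[1] / 2, extent[2] / 2, 0.85 * extent[3])),
           radius_mm = 1.5, peak_hu = 400, delay_s = 7, width_s = 6),
      list(points = rbind(c(extent[1] / 2, extent[2] / 2, extent[3] / 2),
                          c(0.25 * extent[1], 0.3 * extent[2], 0.6 * extent[3])),
           radius_mm = 1.0, peak_hu = 300, delay_s = 12, width_s = 8)
    )
  )
}
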