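#' Exposure-derived temporal weights
#'
#' The volumes of a dynamic CT protocol are acquired at different tube
#' exposures, so their quantum-noise levels differ. Assuming quantum noise
#' dominates, weighting each time point by its exposure maximizes the
#' signal-to-noise ratio of temporal averages: `w_i = E_i / sum(E)`.
#'
#' @param protocol an [acquisition_protocol], or a numeric vector of
#'   positive exposures (mAs).
#' @return numeric vector of weights summing to 1.
#' @examples
#' compute_weights(c(200, rep(100, 13), rep(75, 5)))[1]  # 200/1875
#' @export
compute_weights <- function(protocol) {
  e <- if (inherits(protocol, "acquisition_protocol")) protocol$exposures
       else as.numeric(protocol)
  if (length(e) < 1L) stop("empty exposure list")
  if (any(!is.finite(e)) || any(e <= 0)) stop("exposures must be positive")
  e / sum(e)
}

#' Weighted temporal average (WTA) and variance (WTV)
#'
#' The WTA is the per-voxel exposure-weighted mean over time,
#' `WTA = sum_i w_i * I_i`. The WTV is the exposure-weighted standard
#' deviation about the WTA, `WTV = sqrt(sum_i w_i * (WTA - I_i)^2)`: large
#' where contrast agent changes the attenuation over time (vessels), near
#' the noise floor in static tissue. The WTV is parameter-free and
#' independent of the temporal sampling pattern, which makes it the
#' workhorse map for candidate selection and most downstream features.
#'
#' @param vol a [volume4d].
#' @param weights temporal weights from [compute_weights()]; length must
#'   equal the number of time points.
#' @return A [volume3d] on the spatial grid of `vol`.
#' @export
weighted_temporal_average <- function(vol, weights) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  if (length(weights) != d[4])
    stop("weights length must equal the number of time points")
  flat <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  wta <- as.vector(flat %*% weights)
  volume3d(array(wta, d[1:3]), vol$spacing)
}

#' @rdname weighted_temporal_average
#' @export
weighted_temporal_variance <- function(vol, weights) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  if (length(weights) != d[4])
    stop("weights length must equal the number of time points")
  flat <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  wta <- as.vector(flat %*% weights)
  wtv <- sqrt(as.vector((flat - wta)^2 %*% weights))
  volume3d(array(wtv, d[1:3]), vol$spacing)
}

#' Local intensity-histogram features
#'
#' For each voxel, the values of the WTV map within a cubic neighborhood
#' are summarized by four parameters: mean, standard deviation (population
#' convention), mode and entropy. Mode and entropy come from a histogram of
#' `n_bins` bins spanning the neighborhood's own value range, so the
#' features compare a voxel to its immediate surroundings rather than to a
#' global threshold; mean and std are computed from the raw values. The
#' entropy is `E = -sum_i p_i * log2(p_i + eps)` over occupied bins with
#' `eps = 1e-4` guarding the zero logarithm; a flat neighborhood therefore
#' scores `-log2(1 + eps)` and a uniformly spread one close to
#' `log2(n_bins)`. Image borders are replicate-padded.
#'
#' @param wtv a [volume3d] (typically the WTV map).
#' @param neighborhood_edge odd cube edge in voxels (5 and 9 by default in
#'   the pipeline).
#' @param n_bins number of histogram bins (>= 2).
#' @param eps epsilon inside the entropy logarithm.
#' @return list of four [volume3d] maps: `mean`, `sd`, `mode`, `entropy`.
#' @export
local_histogram_params <- function(wtv, neighborhood_edge, n_bins = 32L,
                                   eps = 1e-4) {
  stopifnot(inherits(wtv, "volume3d"))
  res <- local_hist_cpp(wtv$data, dim(wtv$data), as.integer(neighborhood_edge),
                        as.integer(n_bins), eps)
  lapply(res, volume3d, spacing = wtv$spacing)
}

#' Signed distance to the intracranial cavity
#'
#' Euclidean distance (mm, anisotropic spacing respected) from each voxel
#' to the border of the intracranial-cavity mask, negative inside the
#' cavity and positive outside. The border is the set of cavity voxels with
#' at least one background 6-neighbor. Unlike a binary cavity feature, the
#' signed distance lets the classifier keep vessels that run just outside
#' the cavity (internal carotids, jugular veins).
#'
#' @param cavity a [binary_mask]; must be neither empty nor full (the
#'   border would be undefined).
#' @return A [volume3d] of signed distances in mm.
#' @export
signed_cavity_distance <- function(cavity) {
  stopifnot(inherits(cavity, "binary_mask"))
  n_fg <- sum(cavity$data)
  if (n_fg == 0L) stop("cavity mask is empty: border undefined")
  if (n_fg == length(cavity$data)) stop("cavity mask is full: border undefined")
  border <- boundary6_cpp(cavity$data, dim(cavity$data))
  d <- edt_cpp(border, dim(cavity$data), cavity$spacing)
  d[cavity$data] <- -d[cavity$data]
  volume3d(d, cavity$spacing)
}

#' Multi-scale Hessian eigenvalues
#'
#' Gaussian-derivative Hessian of a 3D map at each requested scale
#' (sigma in mm, converted per axis to voxels and gamma-normalized by
#' sigma^2), eigen-decomposed per voxel. The three eigenvalues are sorted
#' by ascending absolute value: at the center of a bright tube the
#' smallest-|lambda| eigenvalue is near zero and the other two are negative
#' and of similar magnitude, the classical tubular signature.
#'
#' @param wtv a [volume3d] (typically the WTV map).
#' @param scales_mm positive Gaussian scales in mm (default evenly spaced
#'   0.5 to 2.0 mm).
#' @return Named list: for each scale, a list of three [volume3d] maps
#'   `l1`, `l2`, `l3` (ascending |lambda|).
#' @export
hessian_eigenvalues <- function(wtv, scales_mm = c(0.5, 1.0, 1.5, 2.0)) {
  stopifnot(inherits(wtv, "volume3d"))
  if (any(scales_mm <= 0)) stop("scales must be positive")
  dims <- dim(wtv$data)
  sp <- wtv$spacing
  out <- list()
  for (s in scales_mm) {
    sig_vox <- s / sp
    if (any(sig_vox < 0.5))
      warning(sprintf("scale %.3g mm is below half the voxel spacing", s))
    k0 <- lapply(sig_vox, gauss_kernel, order = 0)
    k1 <- lapply(sig_vox, gauss_kernel, order = 1)
    k2 <- lapply(sig_vox, gauss_kernel, order = 2)
    sconv <- function(kx, ky, kz) {
      a <- conv_axis_cpp(wtv$data, dims, kx, 0L)
      a <- conv_axis_cpp(a, dims, ky, 1L)
      conv_axis_cpp(a, dims, kz, 2L)
    }
    # second derivatives in physical units (voxel derivative / spacing^2),
    # gamma-normalized by sigma^2
    hxx <- sconv(k2[[1]], k0[[2]], k0[[3]]) / sp[1]^2 * s^2
    hyy <- sconv(k0[[1]], k2[[2]], k0[[3]]) / sp[2]^2 * s^2
    hzz <- sconv(k0[[1]], k0[[2]], k2[[3]]) / sp[3]^2 * s^2
    hxy <- sconv(k1[[1]], k1[[2]], k0[[3]]) / (sp[1] * sp[2]) * s^2
    hxz <- sconv(k1[[1]], k0[[2]], k1[[3]]) / (sp[1] * sp[3]) * s^2
    hyz <- sconv(k0[[1]], k1[[2]], k1[[3]]) / (sp[2] * sp[3]) * s^2
    ev <- eig3x3_cpp(hxx, hyy, hzz, hxy, hxz, hyz)
    out[[sprintf("s%g", s)]] <- lapply(ev, volume3d, spacing = sp)
  }
  out
}

# Sampled Gaussian (order 0) or its first/second derivative, in voxel
# units, DC-corrected so constants map to (1, 0, 0) respectively.
gauss_kernel <- function(sigma, order = 0) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) {
    k <- -x / sigma^2 * g
    k <- k - mean(k)              # zero response to constants
    # normalize so the response to a unit ramp is exactly 1
    k / sum(k * x)
  } else if (order == 2) {
    k <- (x^2 - sigma^2) / sigma^4 * g
    k <- k - mean(k)
    # normalize so the response to x^2/2 is exactly 1
    k / (sum(k * x^2) / 2)
  } else stop("order must be 0, 1 or 2")
}

#' First time point (baseline tissue map)
#'
#' The first acquisition of the dynamic series carries minimal contrast
#' agent and represents baseline tissue attenuation; it is used as a
#' feature alongside the temporal statistics.
#'
#' @param vol a [volume4d].
#' @return A [volume3d] equal to time point 1.
#' @export
extract_t0 <- function(vol) {
  stopifnot(inherits(vol, "volume4d"))
  volume3d(vol$data[, , , 1, drop = TRUE], vol$spacing)
}

#' Assemble the per-voxel feature matrix
#'
#' Computes every feature map and collects, for each candidate voxel, the
#' 24-dimensional feature vector used by the classifier: WTA, WTV, T0,
#' signed cavity distance, four local-histogram parameters at each of two
#' neighborhood sizes, and three Hessian eigenvalues at each of four
#' scales. Column order is fixed and recorded in the `features` attribute
#' so a trained model can refuse mismatched inputs.
#'
#' @param vol a [volume4d].
#' @param cavity intracranial-cavity [binary_mask] on the same grid.
#' @param candidates [binary_mask] of voxels to featurize (normally from
#'   [select_candidates()]; any nonempty mask is accepted, e.g. annotation
#'   subvolumes at training time).
#' @param config pipeline configuration, see [default_config()].
#' @return Object of class `feature_matrix`: list with `index` (1-based
#'   linear voxel indices), `x` (numeric matrix, one row per candidate),
#'   `names` (column manifest), `dims` and `spacing`.
#' @export
assemble_features <- function(vol, cavity, candidates,
                              config = default_config()) {
  stopifnot(inherits(vol, "volume4d"))
  stopifnot_same_grid(list(data = vol$data[, , , 1, drop = TRUE],
                           spacing = vol$spacing), cavity)
  stopifnot_same_grid(cavity, candidates)
  idx <- which(candidates$data)
  if (length(idx) == 0L) stop("empty candidate set")
  w <- compute_weights(vol$exposures)
  wta <- weighted_temporal_average(vol, w)
  wtv <- weighted_temporal_variance(vol, w)
  t0 <- extract_t0(vol)
  cdist <- signed_cavity_distance(cavity)

  cols <- list(wta = wta$data[idx], wtv = wtv$data[idx], t0 = t0$data[idx],
               cavity_dist = cdist$data[idx])
  for (edge in config$hist_edges) {
    hp <- local_histogram_params(wtv, edge, config$hist_bins,
                                 config$entropy_eps)
    for (p in names(hp))
      cols[[sprintf("hist%d_%s", edge, p)]] <- hp[[p]]$data[idx]
  }
  hev <- hessian_eigenvalues(wtv, config$hessian_scales)
  for (s in names(hev))
    for (l in names(hev[[s]]))
      cols[[sprintf("hess_%s_%s", s, l)]] <- hev[[s]][[l]]$data[idx]

  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  if (anyNA(x) || any(!is.finite(x)))
    stop("feature matrix contains NaN/Inf")
  structure(list(index = idx, x = x, names = colnames(x),
                 dims = dim(cavity$data), spacing = cavity$spacing),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d voxels x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Write a feature matrix as a columnar table
#'
#' CSV with a leading `index` column (1-based linear voxel index) and one
#' column per feature, in manifest order.
#'
#' @param fm a `feature_matrix` from [assemble_features()].
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(index = fm$index, fm$x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
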