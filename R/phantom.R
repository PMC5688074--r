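#' Default dynamic acquisition protocol
#'
#' Nineteen whole-brain acquisitions: one high-dose scan at 200 mAs five
#' seconds after contrast injection, thirteen scans every 2 s at 100 mAs,
#' then five scans every 5 s at 75 mAs.
#'
#' @return An [acquisition_protocol] with 19 exposures and scan times.
#' @export
ct_protocol <- function() {
  acquisition_protocol(
    exposures = c(200, rep(100, 13), rep(75, 5)),
    times = c(5, seq(7, 31, by = 2), seq(36, 56, by = 5))
  )
}

#' Parametric 4D vascular phantom specification
#'
#' Describes a synthetic dynamic CT acquisition with known vessel ground
#' truth: tubular vessels (polylines with radius, peak enhancement and a
#' gamma-variate arrival curve), a static soft-tissue background, a static
#' high-intensity skull shell around an ellipsoidal intracranial cavity,
#' and per-time-point Gaussian noise whose standard deviation scales with
#' the inverse square root of the exposure (the quantum-noise law).
#' Defaults emulate the clinical protocol at desk scale: a 64^3 grid at
#' 0.43 x 0.43 x 0.5 mm, 19 time points, 30 HU background, 10 HU noise at
#' the 100 mAs reference, and five vessels with arterial (early, narrow)
#' and venous (late, broad) enhancement so the temporal features are
#' exercised on both.
#'
#' @param shape integer length-3 grid size in voxels.
#' @param spacing voxel size in mm.
#' @param protocol an [acquisition_protocol] with scan times.
#' @param background_hu soft-tissue attenuation inside the cavity (HU).
#' @param skull_hu skull-shell attenuation (HU).
#' @param skull_thickness_mm thickness of the skull shell.
#' @param noise_sd noise standard deviation (HU) at `noise_ref_exposure`.
#' @param noise_ref_exposure reference exposure (mAs) for `noise_sd`.
#' @param vessels list of vessels; each a list with `points` (n x 3 matrix
#'   of polyline coordinates in mm), `radius_mm`, `peak_hu`, `delay_s`,
#'   `width_s`. `NULL` gives the default five-vessel layout.
#' @param cavity_axes_frac semi-axes of the cavity ellipsoid as a fraction
#'   of the half-extent per axis.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         spacing = c(0.43, 0.43, 0.5),
                         protocol = ct_protocol(),
                         background_hu = 30,
                         skull_hu = 1000,
                         skull_thickness_mm = 1.5,
                         noise_sd = 10,
                         noise_ref_exposure = 100,
                         vessels = NULL,
                         cavity_axes_frac = c(0.82, 0.82, 0.88)) {
  check_spacing(spacing)
  if (is.null(protocol$times)) stop("phantom protocol needs scan times")
  extent <- shape * spacing
  if (is.null(vessels)) vessels <- default_vessels(extent)
  for (v in vessels) {
    if (v$radius_mm <= 0) stop("vessel radius must be positive")
    if (v$peak_hu <= 0) stop("vessel peak enhancement must be positive")
    if (any(v$points < 0) || any(t(v$points) > extent))
      stop("vessel polyline outside grid")
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 protocol = protocol, background_hu = background_hu,
                 skull_hu = skull_hu, skull_thickness_mm = skull_thickness_mm,
                 noise_sd = noise_sd, noise_ref_exposure = noise_ref_exposure,
                 vessels = vessels, cavity_axes_frac = cavity_axes_frac),
            class = "phantom_spec")
}

# Five vessels spread over the cavity: a central artery, two lateral
# arteries, a frontal artery and a posterior draining vein (late, broad
# enhancement). Coordinates in mm within the grid extent.
default_vessels <- function(extent) {
  cx <- extent / 2
  list(
    list(points = rbind(c(cx[1], cx[2], 0.12 * extent[3]),
                        c(cx[1], cx[2], 0.88 * extent[3])),
         radius_mm = 1.8, peak_hu = 400, delay_s = 7, width_s = 6),
    list(points = rbind(c(cx[1], cx[2], 0.5 * extent[3]),
                        c(0.22 * extent[1], 0.35 * extent[2], 0.72 * extent[3])),
         radius_mm = 1.1, peak_hu = 350, delay_s = 8, width_s = 6),
    list(points = rbind(c(cx[1], cx[2], 0.5 * extent[3]),
                        c(0.78 * extent[1], 0.35 * extent[2], 0.72 * extent[3])),
         radius_mm = 1.1, peak_hu = 350, delay_s = 8.5, width_s = 6),
    list(points = rbind(c(cx[1], 0.30 * extent[2], 0.30 * extent[3]),
                        c(cx[1], 0.20 * extent[2], 0.70 * extent[3])),
         radius_mm = 0.9, peak_hu = 300, delay_s = 9, width_s = 7),
    list(points = rbind(c(0.25 * extent[1], 0.78 * extent[2], 0.35 * extent[3]),
                        c(0.75 * extent[1], 0.78 * extent[2], 0.35 * extent[3])),
         radius_mm = 1.5, peak_hu = 300, delay_s = 14, width_s = 10)
  )
}

#' Gamma-variate contrast enhancement curve
#'
#' The standard parametric model of a contrast bolus time-attenuation
#' curve: zero before arrival, rising to `peak` at `delay + width`
#' seconds, then decaying. Normalized so the maximum equals `peak`.
#'
#' @param t time in seconds (vectorized).
#' @param delay bolus arrival time (s).
#' @param width time from arrival to peak (s, > 0).
#' @param peak peak enhancement (HU).
#' @param alpha shape exponent of the gamma-variate (default 3).
#' @return HU offset at `t` (nonnegative).
#' @export
enhancement_curve <- function(t, delay, width, peak, alpha = 3) {
  if (width <= 0) stop("width must be positive")
  u <- (t - delay) / width
  y <- ifelse(u <= 0, 0, peak * u^alpha * exp(alpha * (1 - u)))
  pmax(y, 0)
}

#' Rasterize the vessel set
#'
#' A voxel belongs to the truth mask when its center lies within the
#' radius of any vessel polyline. A per-vessel enhancement-scaling field
#' models partial-volume voxels: 1 deep inside the lumen, falling
#' linearly to 0 across a one-voxel rim around the radius.
#'
#' @param spec a [phantom_spec].
#' @return list with `truth` (a [binary_mask]) and `scaling` (list of 3D
#'   arrays, one per vessel, values in `[0, 1]`).
#' @export
rasterize_vessels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$shape
  sp <- spec$spacing
  xs <- (seq_len(dims[1]) - 0.5) * sp[1]
  ys <- (seq_len(dims[2]) - 0.5) * sp[2]
  zs <- (seq_len(dims[3]) - 0.5) * sp[3]
  h <- mean(sp) / 2  # partial-volume rim half-width
  truth <- array(FALSE, dims)
  scaling <- vector("list", length(spec$vessels))
  for (vi in seq_along(spec$vessels)) {
    v <- spec$vessels[[vi]]
    dmin <- array(Inf, dims)
    for (s in seq_len(nrow(v$points) - 1)) {
      dseg <- dist_to_segment(xs, ys, zs, v$points[s, ], v$points[s + 1, ],
                              v$radius_mm + 2 * h)
      dmin <- pmin(dmin, dseg)
    }
    truth <- truth | (dmin <= v$radius_mm)
    frac <- pmin(1, pmax(0, (v$radius_mm + h - dmin) / (2 * h)))
    scaling[[vi]] <- frac
  }
  list(truth = binary_mask(truth, sp), scaling = scaling)
}

# Distance from every voxel center to segment p-q, computed only inside
# the segment's bounding box padded by `pad` mm (Inf elsewhere).
dist_to_segment <- function(xs, ys, zs, p, q, pad) {
  dims <- c(length(xs), length(ys), length(zs))
  lo <- pmin(p, q) - pad
  hi <- pmax(p, q) + pad
  ix <- which(xs >= lo[1] & xs <= hi[1])
  iy <- which(ys >= lo[2] & ys <= hi[2])
  iz <- which(zs >= lo[3] & zs <= hi[3])
  out <- array(Inf, dims)
  if (!length(ix) || !length(iy) || !length(iz)) return(out)
  g <- expand.grid(x = xs[ix], y = ys[iy], z = zs[iz])
  d <- q - p
  len2 <- sum(d^2)
  if (len2 == 0) {
    dd <- sqrt((g$x - p[1])^2 + (g$y - p[2])^2 + (g$z - p[3])^2)
  } else {
    t <- ((g$x - p[1]) * d[1] + (g$y - p[2]) * d[2] + (g$z - p[3]) * d[3]) / len2
    t <- pmin(1, pmax(0, t))
    dd <- sqrt((p[1] + t * d[1] - g$x)^2 + (p[2] + t * d[2] - g$y)^2 +
               (p[3] + t * d[3] - g$z)^2)
  }
  out[ix, iy, iz] <- array(dd, c(length(ix), length(iy), length(iz)))
  out
}

#' Generate a synthetic 4D case with ground truth
#'
#' Builds the full dynamic volume: per time point,
#' `background + skull + sum_v scaling_v * curve_v(t_i) + noise_i`, with
#' noise standard deviation `noise_sd * sqrt(ref_exposure / E_i)`. Also
#' returns the vessel truth mask, the ellipsoidal intracranial-cavity
#' mask, and five annotation subvolumes, one per vessel. Identical seed
#' and spec reproduce the case bit-for-bit.
#'
#' @param spec a [phantom_spec].
#' @param seed integer seed.
#' @return Object of class `phantom_case`: list with `volume`
#'   ([volume4d]), `truth`, `cavity` ([binary_mask]), `subvolumes` (list
#'   of [subvolume_box]), `seed`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$shape
  sp <- spec$spacing
  extent <- dims * sp
  xs <- (seq_len(dims[1]) - 0.5) * sp[1]
  ys <- (seq_len(dims[2]) - 0.5) * sp[2]
  zs <- (seq_len(dims[3]) - 0.5) * sp[3]
  cx <- extent / 2
  ax <- spec$cavity_axes_frac * extent / 2
  r2 <- outer(outer(((xs - cx[1]) / ax[1])^2, ((ys - cx[2]) / ax[2])^2, "+"),
              ((zs - cx[3]) / ax[3])^2, "+")
  cavity <- r2 <= 1
  ax_out <- ax + spec$skull_thickness_mm
  r2_out <- outer(outer(((xs - cx[1]) / ax_out[1])^2,
                        ((ys - cx[2]) / ax_out[2])^2, "+"),
                  ((zs - cx[3]) / ax_out[3])^2, "+")
  skull <- (r2_out <= 1) & !cavity

  rast <- rasterize_vessels(spec)
  base <- array(0, dims)
  base[r2_out <= 1] <- spec$background_hu
  base[skull] <- spec$skull_hu

  times <- spec$protocol$times
  expos <- spec$protocol$exposures
  nt <- length(expos)
  set.seed(seed)
  data <- array(0, c(dims, nt))
  for (i in seq_len(nt)) {
    enh <- array(0, dims)
    for (vi in seq_along(spec$vessels)) {
      v <- spec$vessels[[vi]]
      c_t <- enhancement_curve(times[i], v$delay_s, v$width_s, v$peak_hu)
      if (c_t > 0) enh <- pmax(enh, rast$scaling[[vi]] * c_t)
    }
    sd_i <- spec$noise_sd * sqrt(spec$noise_ref_exposure / expos[i])
    noise <- if (spec$noise_sd > 0) array(rnorm(prod(dims), 0, sd_i), dims)
             else array(0, dims)
    data[, , , i] <- base + enh + noise
  }
  structure(list(
    volume = volume4d(data, sp, expos),
    truth = rast$truth,
    cavity = binary_mask(cavity, sp),
    subvolumes = default_subvolumes(spec, rast$truth),
    seed = seed, spec = spec
  ), class = "phantom_case")
}

# One annotation box per vessel, centered on the vessel's voxels,
# clipped to the grid; emulates restricted annotation subvolumes.
default_subvolumes <- function(spec, truth) {
  dims <- spec$shape
  sp <- spec$spacing
  half <- pmax(4L, as.integer(round(4 / sp)))  # ~8 mm boxes
  lapply(spec$vessels, function(v) {
    mid <- (v$points[1, ] + v$points[nrow(v$points), ]) / 2
    c_vox <- pmin(pmax(as.integer(round(mid / sp)), 1L), dims)
    subvolume_box(pmax(c_vox - half, 1L), pmin(c_vox + half, dims))
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> seed %d, %s grid, %d time points, %d vessel voxels\n",
              x$seed, paste(dim(x$truth$data), collapse = "x"),
              length(x$volume$exposures), sum(x$truth$data)))
  invisible(x)
}

#' Inject a motion artifact
#'
#' Translates selected time points by an integer voxel shift (circular,
#' so a reversed shift restores the original data exactly). The truth
#' mask is left unchanged: motion is an acquisition corruption, and
#' shifted time points inflate the temporal variance over broad tissue
#' regions — the characteristic failure mode of motion-degraded cases.
#'
#' @param case a `phantom_case`.
#' @param time_indices time points to shift (1-based).
#' @param shift_voxels integer length-3 shift in voxels.
#' @return The modified `phantom_case`.
#' @export
inject_motion <- function(case, time_indices, shift_voxels) {
  stopifnot(inherits(case, "phantom_case"))
  dims <- dim(case$volume$data)
  shift_voxels <- as.integer(shift_voxels)
  if (any(abs(shift_voxels) >= dims[1:3]))
    stop("shift out of bounds")
  roll <- function(n, s) ((seq_len(n) - 1 - s) %% n) + 1
  ix <- roll(dims[1], shift_voxels[1])
  iy <- roll(dims[2], shift_voxels[2])
  iz <- roll(dims[3], shift_voxels[3])
  for (i in time_indices) {
    if (i < 1 || i > dims[4]) stop("time index out of range")
    case$volume$data[, , , i] <- case$volume$data[ix, iy, iz, i]
  }
  case
}
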