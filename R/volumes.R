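#' Spatial containers for the 4D CT pipeline
#'
#' Lightweight S3 containers shared by every stage of the pipeline:
#' `volume4d` holds the registered dynamic acquisition `I[x, y, z, i]` with
#' voxel spacing in mm and one tube exposure (mAs) per time point;
#' `volume3d` carries derived scalar maps (WTA, WTV, feature maps);
#' `binary_mask` holds candidate/segmentation/annotation/cavity masks on the
#' same grid. Voxel indices are 1-based (R convention) and the time axis is
#' the last array axis.
#'
#' @param data numeric array (3D for `volume3d`, 4D for `volume4d`) or a
#'   logical/0-1 array for `binary_mask`.
#' @param spacing numeric length-3, voxel size in mm along (x, y, z); all
#'   components must be positive.
#' @param exposures numeric length-T, tube current-time product (mAs) per
#'   time point; all must be positive.
#' @return An object of class `volume4d`, `volume3d` or `binary_mask`: a
#'   list with elements `data` and `spacing` (plus `exposures` for
#'   `volume4d`).
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing = c(0.43, 0.43, 0.5))
#' dim(v$data)
#' @name containers
NULL

#' @rdname containers
#' @export
volume4d <- function(data, spacing, exposures = NULL) {
  if (length(dim(data)) != 4L) stop("volume4d data must be a 4D array")
  check_spacing(spacing)
  nt <- dim(data)[4]
  if (is.null(exposures)) exposures <- rep(1, nt)
  if (length(exposures) != nt) stop("length(exposures) must equal T")
  if (any(!is.finite(exposures)) || any(exposures <= 0))
    stop("all exposures must be positive and finite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 exposures = as.numeric(exposures)),
            class = "volume4d")
}

#' @rdname containers
#' @export
volume3d <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("volume3d data must be a 3D array")
  check_spacing(spacing)
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "volume3d")
}

#' @rdname containers
#' @export
binary_mask <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  check_spacing(spacing)
  d <- dim(data)
  data <- as.logical(data)
  if (anyNA(data)) stop("mask contains NA")
  dim(data) <- d
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "binary_mask")
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  invisible(TRUE)
}

#' Rectangular subvolume in voxel indices
#'
#' An axis-aligned box on the voxel grid, used for restricted annotation,
#' training sampling and per-subvolume evaluation. Bounds are 1-based and
#' inclusive on both ends, matching R array subsetting.
#'
#' @param lower,upper integer length-3 voxel indices of the box corners
#'   (inclusive); `upper >= lower` componentwise.
#' @return Object of class `subvolume_box` with elements `lower`, `upper`.
#' @export
subvolume_box <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (length(lower) != 3L || length(upper) != 3L)
    stop("box corners must have 3 components")
  if (any(lower < 1L)) stop("box lower corner must be >= 1")
  if (any(upper < lower)) stop("box must be nonempty (upper >= lower)")
  structure(list(lower = lower, upper = upper), class = "subvolume_box")
}

box_in_grid <- function(box, dims) {
  all(box$upper <= dims[1:3])
}

# logical 3D array: TRUE inside the box
box_to_mask <- function(box, dims) {
  if (!box_in_grid(box, dims)) stop("subvolume box outside grid")
  m <- array(FALSE, dims)
  m[box$lower[1]:box$upper[1], box$lower[2]:box$upper[2],
    box$lower[3]:box$upper[3]] <- TRUE
  m
}

crop_to_box <- function(arr, box) {
  arr[box$lower[1]:box$upper[1], box$lower[2]:box$upper[2],
      box$lower[3]:box$upper[3], drop = FALSE]
}

stopifnot_same_grid <- function(a, b) {
  da <- dim(a$data)[1:3]; db <- dim(b$data)[1:3]
  if (!identical(da, db)) stop("inputs do not share the same voxel grid")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("inputs do not share the same voxel spacing")
  invisible(TRUE)
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d x %d, spacing %s mm, exposures %s mAs\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$spacing, 3), collapse = "x"),
              paste(range(x$exposures), collapse = "-")))
  invisible(x)
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Acquisition protocol
#'
#' Per-time-point tube exposures (mAs) and optional acquisition times
#' (seconds) of a dynamic CT protocol. The exposures drive the temporal
#' weights of the weighted temporal average/variance; the times are used by
#' the phantom generator to sample contrast enhancement curves.
#'
#' @param exposures numeric, one positive mAs value per time point.
#' @param times optional numeric acquisition times in seconds (same length).
#' @return Object of class `acquisition_protocol`.
#' @seealso [ct_protocol()] for the default 19-time-point protocol.
#' @export
acquisition_protocol <- function(exposures, times = NULL) {
  exposures <- as.numeric(exposures)
  if (length(exposures) < 1L || any(!is.finite(exposures)) || any(exposures <= 0))
    stop("all exposures must be positive")
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != length(exposures))
      stop("times must match exposures in length")
    if (is.unsorted(times)) stop("times must be non-decreasing")
  }
  structure(list(exposures = exposures, times = times),
            class = "acquisition_protocol")
}
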