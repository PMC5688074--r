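#' Dice similarity coefficient
#'
#' Overlap between two masks on the same grid: `2|A n B| / (|A| + |B|)`.
#' Defined as 1 when both masks are empty.
#'
#' @param a,b [binary_mask] objects on the same grid.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot_same_grid(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}

#' Directed boundary-to-boundary distances
#'
#' Shared kernel of the Hausdorff-family metrics: for every boundary voxel
#' of A (foreground voxel with a background 6-neighbor), the physical
#' distance in mm to the nearest boundary voxel of B, and vice versa.
#' Distances are voxel-center to voxel-center with anisotropic spacing.
#'
#' @param a,b nonempty [binary_mask] objects on the same grid.
#' @return list with numeric vectors `a_to_b` and `b_to_a` (mm).
#' @export
surface_distances <- function(a, b) {
  stopifnot_same_grid(a, b)
  if (sum(a$data) == 0L || sum(b$data) == 0L)
    stop("surface distances undefined for an empty mask")
  dims <- dim(a$data)
  ba <- boundary6_cpp(a$data, dims)
  bb <- boundary6_cpp(b$data, dims)
  dist_to_bb <- edt_cpp(bb, dims, a$spacing)
  dist_to_ba <- edt_cpp(ba, dims, a$spacing)
  list(a_to_b = as.numeric(dist_to_bb[ba]),
       b_to_a = as.numeric(dist_to_ba[bb]))
}

#' Hausdorff-family boundary distance metrics
#'
#' * `hausdorff`: HD, the maximum over both directed maxima.
#' * `modified_hausdorff`: MHD, the maximum of the two directed mean
#'   distances.
#' * `hausdorff_percentile`: the q-th percentile (default 95) of the two
#'   directed distance sets pooled together.
#' * `contour_mean_distance`: CMD, the mean of the pooled directed
#'   distances.
#'
#' All distances are in mm and satisfy `MHD <= HD` and `HD95 <= HD`.
#'
#' @param a,b nonempty [binary_mask] objects on the same grid.
#' @param q percentile for `hausdorff_percentile`.
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b) {
  d <- surface_distances(a, b)
  max(max(d$a_to_b), max(d$b_to_a))
}

#' @rdname hausdorff
#' @export
modified_hausdorff <- function(a, b) {
  d <- surface_distances(a, b)
  max(mean(d$a_to_b), mean(d$b_to_a))
}

#' @rdname hausdorff
#' @export
hausdorff_percentile <- function(a, b, q = 95) {
  d <- surface_distances(a, b)
  as.numeric(quantile(c(d$a_to_b, d$b_to_a), q / 100, names = FALSE))
}

#' @rdname hausdorff
#' @export
contour_mean_distance <- function(a, b) {
  d <- surface_distances(a, b)
  mean(c(d$a_to_b, d$b_to_a))
}

#' Absolute volume difference
#'
#' `|V_seg - V_ref| / V_ref * 100`, volumes counted in voxels (spacing
#' cancels on a shared grid).
#'
#' @param seg,ref [binary_mask] objects on the same grid; `ref` nonempty.
#' @return AVD in percent.
#' @export
absolute_volume_difference <- function(seg, ref) {
  stopifnot_same_grid(seg, ref)
  v_ref <- sum(ref$data)
  if (v_ref == 0L) stop("reference mask is empty")
  abs(sum(seg$data) - v_ref) / v_ref * 100
}

#' Voxel-wise confusion statistics within a subvolume
#'
#' Sensitivity, specificity and accuracy computed voxel-by-voxel inside
#' the annotated subvolume. With `exclude_boundary = TRUE` the 1-voxel
#' boundary band of the reference — `dilate(ref, 3x3x3) \ ref` — is
#' removed from the evaluation domain: annotations mark high-confidence
#' vessel voxels, not exact lumen borders, so disagreement in that band is
#' not counted against the segmentation. Excluding the band can only raise
#' specificity; sensitivity is untouched because reference-positive voxels
#' are never excluded.
#'
#' @param seg,ref [binary_mask] objects on the same grid.
#' @param roi optional [subvolume_box] restricting the evaluation.
#' @param exclude_boundary exclude the 1-voxel dilation band of `ref`.
#' @return list with `sensitivity`, `specificity`, `accuracy` and counts
#'   `tp`, `fp`, `tn`, `fn`, `n_excluded`.
#' @export
confusion_stats <- function(seg, ref, roi = NULL, exclude_boundary = TRUE) {
  stopifnot_same_grid(seg, ref)
  dims <- dim(ref$data)
  domain <- if (is.null(roi)) array(TRUE, dims) else box_to_mask(roi, dims)
  n_excl <- 0L
  if (exclude_boundary) {
    dil <- ref$data | (neighbor_count_cpp(ref$data, dims, 1L) > 0L)
    band <- dil & !ref$data
    n_excl <- sum(band & domain)
    domain <- domain & !band
  }
  s <- seg$data[domain]; r <- ref$data[domain]
  tp <- sum(s & r); fp <- sum(s & !r); tn <- sum(!s & !r); fn <- sum(!s & r)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn, n_excluded = n_excl
  )
}

#' Combine per-subvolume distance statistics
#'
#' Annotations live in disconnected subvolumes, so the distance metrics
#' are computed per subvolume and then combined: the mean for CMD and the
#' maximum for HD, MHD and 95% HD.
#'
#' @param reports nonempty list of per-subvolume reports (lists or named
#'   vectors containing `hd`, `mhd`, `hd95`, `cmd`).
#' @return list with combined `hd`, `mhd`, `hd95`, `cmd`.
#' @export
combine_subvolumes <- function(reports) {
  if (length(reports) == 0L) stop("no reports to combine")
  g <- function(name) vapply(reports, function(r) as.numeric(r[[name]]), numeric(1))
  list(hd = max(g("hd")), mhd = max(g("mhd")), hd95 = max(g("hd95")),
       cmd = mean(g("cmd")))
}

#' Full evaluation of a segmentation against a reference
#'
#' Computes the complete metric suite inside the region of interest:
#' Dice, HD, MHD, 95% HD, CMD, absolute volume difference, and voxel-wise
#' sensitivity/specificity/accuracy. The 1-voxel boundary-band exclusion
#' is applied to the confusion statistics only; overlap and distance
#' metrics use the full annotation.
#'
#' @param seg,ref [binary_mask] objects on the same grid.
#' @param roi optional [subvolume_box]; metrics are computed on the
#'   cropped region.
#' @param exclude_boundary apply the boundary-band exclusion to the
#'   confusion statistics.
#' @return Object of class `evaluation_report`: list with `dsc`, `hd`,
#'   `mhd`, `hd95`, `cmd`, `avd`, `sensitivity`, `specificity`,
#'   `accuracy` and the confusion counts.
#' @export
evaluate_segmentation <- function(seg, ref, roi = NULL,
                                  exclude_boundary = TRUE) {
  stopifnot_same_grid(seg, ref)
  if (!is.null(roi)) {
    seg <- binary_mask(crop_to_box(seg$data, roi), seg$spacing)
    ref <- binary_mask(crop_to_box(ref$data, roi), ref$spacing)
  }
  if (sum(ref$data) == 0L) stop("reference is empty within the roi")
  conf <- confusion_stats(seg, ref, roi = NULL,
                          exclude_boundary = exclude_boundary)
  d <- surface_distances(seg, ref)
  pooled <- c(d$a_to_b, d$b_to_a)
  hd <- max(pooled)
  mhd <- max(mean(d$a_to_b), mean(d$b_to_a))
  hd95 <- as.numeric(quantile(pooled, 0.95, names = FALSE))
  cmd <- mean(pooled)
  structure(list(
    dsc = dice(seg, ref), hd = hd, mhd = mhd, hd95 = hd95, cmd = cmd,
    avd = absolute_volume_difference(seg, ref),
    sensitivity = conf$sensitivity, specificity = conf$specificity,
    accuracy = conf$accuracy,
    tp = conf$tp, fp = conf$fp, tn = conf$tn, fn = conf$fn,
    n_excluded = conf$n_excluded
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> DSC %.3f | HD %.2f mm | MHD %.3f mm | HD95 %.2f mm | CMD %.3f mm | AVD %.1f%%\n",
    x$dsc, x$hd, x$mhd, x$hd95, x$cmd, x$avd))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, accuracy %.3f (%d boundary voxels excluded)\n",
              x$sensitivity, x$specificity, x$accuracy, x$n_excluded))
  invisible(x)
}
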