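#' Read a 3D or 4D medical image volume
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`, via RNifti) or uncompressed MetaImage
#' (`.mha`, `.mhd` + raw) files. Returns the raw array and the voxel spacing
#' from the header; use [load_volume4d()] to obtain a [volume4d] with
#' exposures attached.
#'
#' @param path file path.
#' @return list with `data` (numeric array) and `spacing` (mm, per spatial
#'   axis).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (grepl("\\.(nii|nii\\.gz)$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    data <- array(as.numeric(img), dim(img))
    spacing <- as.numeric(RNifti::pixdim(img))[seq_len(min(3, length(dim(img))))]
    list(data = data, spacing = abs(spacing))
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    read_mha(path)
  } else {
    stop("unsupported volume format: ", path,
         " (expected .nii, .nii.gz, .mha or .mhd)")
  }
}

#' Load a dynamic (4D) acquisition
#'
#' Accepts either a single 4D file or an ordered series of T 3D files with
#' identical grids and spacings; both on-disk layouts yield the same
#' [volume4d]. Exposures (mAs per time point) come from `exposures` or from
#' a sidecar config (image headers carry no exposure field); when absent,
#' uniform exposures are assumed.
#'
#' @param paths one 4D file path, or a character vector of T 3D file paths
#'   in acquisition order.
#' @param exposures optional numeric, one mAs value per time point.
#' @return A [volume4d].
#' @export
load_volume4d <- function(paths, exposures = NULL) {
  if (length(paths) == 1L) {
    v <- read_volume(paths)
    if (length(dim(v$data)) != 4L)
      stop("expected a 4D volume in ", paths)
    data <- v$data
    spacing <- v$spacing[1:3]
  } else {
    vols <- lapply(paths, read_volume)
    dims <- lapply(vols, function(v) dim(v$data))
    if (any(vapply(dims, length, 1L) != 3L))
      stop("series entries must be 3D volumes")
    if (!all(vapply(dims, identical, TRUE, dims[[1]])))
      stop("time points have mismatched grids")
    sp <- vapply(vols, function(v) v$spacing[1:3], numeric(3))
    if (max(abs(sp - sp[, 1])) > 1e-6)
      stop("time points have mismatched spacings")
    data <- array(0, c(dims[[1]], length(vols)))
    for (i in seq_along(vols)) data[, , , i] <- vols[[i]]$data
    spacing <- vols[[1]]$spacing[1:3]
  }
  if (dim(data)[4] < 2L) stop("a dynamic acquisition needs T >= 2 time points")
  volume4d(data, spacing, exposures)
}

#' Save 3D volumes and binary masks
#'
#' Scalar maps are written at full floating-point precision; masks are
#' written as 8-bit labels in \{0, 1\}. Format is chosen from the file
#' extension (`.nii`/`.nii.gz`/`.mha`/`.mhd`). Volumes containing NaN are
#' refused.
#'
#' @param vol a [volume3d].
#' @param mask a [binary_mask].
#' @param path output file path (parent directory must exist).
#' @return Invisibly, the path written.
#' @export
save_volume3d <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (anyNA(vol$data) || any(!is.finite(vol$data)))
    stop("refusing to write volume containing NaN/Inf")
  write_image(vol$data, vol$spacing, path, type = "double")
  invisible(path)
}

#' @rdname save_volume3d
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  u <- array(as.integer(mask$data), d)
  write_image(u, mask$spacing, path, type = "uint8")
  invisible(path)
}

#' Load a binary mask from file
#'
#' @param path mask file (any nonzero voxel becomes TRUE).
#' @return A [binary_mask].
#' @export
load_mask <- function(path) {
  v <- read_volume(path)
  if (length(dim(v$data)) != 3L) stop("mask must be 3D: ", path)
  binary_mask(v$data != 0, v$spacing[1:3])
}

write_image <- function(data, spacing, path, type = c("double", "uint8")) {
  type <- match.arg(type)
  dirp <- dirname(path)
  if (!dir.exists(dirp)) stop("parent directory does not exist: ", dirp)
  if (grepl("\\.(nii|nii\\.gz)$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(data)
    pd <- RNifti::pixdim(img)
    pd[seq_len(min(3, length(pd)))] <- spacing[seq_len(min(3, length(pd)))]
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, path,
                       datatype = if (type == "uint8") "uint8" else "double")
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    write_mha(data, spacing, path,
              element_type = if (type == "uint8") "MET_UCHAR" else "MET_DOUBLE")
  } else {
    stop("unsupported output format: ", path)
  }
  invisible(path)
}

# ---- MetaImage (.mha/.mhd) ---------------------------------------------
# Minimal reader/writer for uncompressed MetaImage: text header of
# "Key = Value" lines followed by (or pointing at) little-endian raw data.

mha_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("unexpected end of MetaImage header")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != ndims) stop("DimSize does not match NDims")
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(1, ndims)
  if (!is.null(hdr$CompressedData) &&
      tolower(hdr$CompressedData) == "true")
    stop("compressed MetaImage not supported")
  if (!is.null(hdr$BinaryDataByteOrderMSB) &&
      tolower(hdr$BinaryDataByteOrderMSB) == "true")
    stop("big-endian MetaImage not supported")
  tinfo <- mha_types[[hdr$ElementType]]
  if (is.null(tinfo)) stop("unsupported ElementType: ", hdr$ElementType)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
    vals <- readBin(raw_con, what = tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stop("raw data file not found: ", raw_path)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, what = tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = "little")
  }
  if (length(vals) != n) stop("truncated MetaImage data in ", path)
  list(data = array(as.numeric(vals), dims), spacing = spacing)
}

write_mha <- function(data, spacing, path, element_type = "MET_DOUBLE") {
  dims <- dim(data)
  ndims <- length(dims)
  sp <- c(spacing, rep(1, ndims))[seq_len(ndims)]
  local_data <- grepl("\\.mha$", path, ignore.case = TRUE)
  raw_name <- paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    paste("NDims =", ndims),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementSpacing =", paste(sp, collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", if (local_data) "LOCAL" else raw_name)
  )
  tinfo <- mha_types[[element_type]]
  vals <- if (tinfo$what == "integer") as.integer(data) else as.numeric(data)
  if (local_data) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(vals, con, size = tinfo$size, endian = "little")
  } else {
    writeLines(hdr, path)
    rcon <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(rcon))
    writeBin(vals, rcon, size = tinfo$size, endian = "little")
  }
  invisible(path)
}

# ---- pipeline configuration --------------------------------------------

#' Pipeline configuration
#'
#' `default_config()` returns the full set of pipeline parameters with the
#' published defaults: the 19-point acquisition protocol (1 x 200, 13 x 100,
#' 5 x 75 mAs), candidate threshold multiplier 1.5, 5^3 and 9^3 histogram
#' neighborhoods with 32 bins and entropy epsilon 1e-4, four Hessian scales
#' evenly spaced from 0.5 to 2.0 mm, a 100-tree forest of maximum depth 30,
#' 10% positive sampling, probability threshold 0.5, 25-voxel minimum
#' component size and 10 iterations of 3x3x3 hole filling. `load_config()`
#' reads a YAML/JSON file and overlays it on the defaults; unknown keys and
#' invalid values are rejected.
#'
#' @param path path to a YAML (or JSON) configuration file; `NULL` gives
#'   the defaults.
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    exposures = c(200, rep(100, 13), rep(75, 5)),
    scan_times = c(5, seq(7, 31, by = 2), seq(36, 56, by = 5)),
    candidate_k = 1.5,
    hist_edges = c(5L, 9L),
    hist_bins = 32L,
    entropy_eps = 1e-4,
    hessian_scales = c(0.5, 1.0, 1.5, 2.0),
    n_trees = 100L,
    max_depth = 30L,
    sample_fraction = 0.1,
    prob_threshold = 0.5,
    min_component = 25L,
    hole_radius = 1L,
    hole_iterations = 10L,
    hole_vote = NULL,   # NULL = strict majority of the neighborhood
    seed = 1L
  )
}

#' @rdname default_config
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0)
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (any(cfg$exposures <= 0)) stop("exposures must be positive")
  if (cfg$candidate_k <= 0) stop("candidate_k must be positive")
  if (any(cfg$hist_edges %% 2 == 0)) stop("hist_edges must be odd")
  if (cfg$hist_bins < 2) stop("hist_bins must be >= 2")
  if (any(cfg$hessian_scales <= 0)) stop("hessian_scales must be positive")
  if (cfg$n_trees < 1 || cfg$max_depth < 1) stop("invalid forest settings")
  if (cfg$sample_fraction <= 0 || cfg$sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]")
  if (cfg$min_component < 1) stop("min_component must be >= 1")
  invisible(cfg)
}
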