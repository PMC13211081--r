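#' CT volume container
#'
#' A 3D Hounsfield-unit image with voxel spacing. Axis order is fixed to
#' (z, y, x): axis 1 is craniocaudal (z), axes 2-3 are in-plane (y =
#' antero-posterior, x = left-right). World coordinates are in mm.
#'
#' @param voxels 3D numeric array of HU values, (z, y, x) order.
#' @param spacing voxel spacing in mm per axis, (z, y, x) order.
#' @param origin world-space origin in mm, (z, y, x) order.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("each axis must have at least one voxel")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (z, y, x)")
  if (any(!is.finite(voxels))) stop("HU values must be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels (z,y,x), spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' The nine bilateral trunk muscle groups
#'
#' Group names in the fixed label order used throughout the package.
#' @export
muscle_groups <- function() {
  c("psoas", "quadratus_lumborum", "paraspinal", "latissimus_dorsi",
    "iliacus", "rectus_femoris", "rhomboid", "trapezius", "vastus")
}

#' Default label taxonomy: 18 side-specific labels
#'
#' Label 0 is background; labels 1-18 encode the nine bilateral muscle
#' groups as (group, side) pairs, left then right within each group.
#'
#' @return data.frame with columns `label`, `group`, `side`.
#' @export
default_taxonomy <- function() {
  g <- muscle_groups()
  data.frame(label = 1:18,
             group = rep(g, each = 2L),
             side  = rep(c("left", "right"), times = length(g)),
             stringsAsFactors = FALSE)
}

#' Label map container
#'
#' An integer mask volume aligned to a [ct_volume()], with a taxonomy
#' mapping each nonzero label to a (muscle group, side) pair.
#'
#' @param labels 3D integer array, same shape as the paired volume.
#' @param spacing voxel spacing in mm, (z, y, x).
#' @param taxonomy data.frame with columns label/group/side; defaults to
#'   [default_taxonomy()].
#' @param origin world-space origin in mm, (z, y, x).
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, spacing, taxonomy = default_taxonomy(),
                      origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (z, y, x)")
  present <- sort(unique(as.vector(labels)))
  unknown <- setdiff(present, c(0L, taxonomy$label))
  if (length(unknown) > 0L)
    stop("label map contains labels not in the taxonomy: ",
         paste(unknown, collapse = ", "))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 taxonomy = taxonomy, origin = as.numeric(origin)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  nz <- sum(x$labels != 0L)
  cat(sprintf("label_map: %d x %d x %d voxels, %d labeled (%d taxonomy labels)\n",
              d[1], d[2], d[3], nz, nrow(x$taxonomy)))
  invisible(x)
}

#' Read / write CT volumes and label maps (NIfTI-1)
#'
#' Round trips preserve voxel values exactly (volumes are stored as
#' float64, labels as int16) and spacing to float32 precision. NIfTI
#' stores data x-fastest; arrays are permuted to the package's (z, y, x)
#' convention at the boundary.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param vol a [ct_volume()].
#' @return `read_volume` returns a [ct_volume()]; `read_labels` a
#'   [label_map()]; the writers return the path invisibly.
#' @export
read_volume <- function(path) {
  x <- read_nifti(path)
  ct_volume(x$voxels, x$spacing, x$origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  write_nifti(vol$voxels, vol$spacing, vol$origin, path, datatype = 64L)
}

#' @rdname read_volume
#' @param taxonomy label taxonomy to validate against.
#' @export
read_labels <- function(path, taxonomy = default_taxonomy()) {
  x <- read_nifti(path)
  label_map(x$voxels, x$spacing, taxonomy, x$origin)
}

#' @rdname read_volume
#' @param lab a [label_map()].
#' @export
write_labels <- function(lab, path) {
  stopifnot(inherits(lab, "label_map"))
  write_nifti(lab$labels, lab$spacing, lab$origin, path, datatype = 4L)
}

#' Preprocessing specification
#'
#' Defaults follow the segmentation model's CT pipeline: resampling to
#' 2.5 x 0.871 x 0.871 mm (z, y, x) with cubic interpolation in-plane and
#' nearest-neighbor along z for images (nearest everywhere for labels),
#' intensity clipping to the soft-tissue window -95..+116 HU, then per-case
#' z-score normalization. The clipping bounds are fixed constants here (the
#' foreground-percentile derivation that produced them is out of scope).
#'
#' @param clip_low,clip_high clipping bounds in HU.
#' @param target_spacing target voxel spacing in mm, (z, y, x).
#' @return a `preprocess_spec` list.
#' @export
preprocess_spec <- function(clip_low = -95, clip_high = 116,
                            target_spacing = c(2.5, 0.871, 0.871)) {
  if (clip_low >= clip_high) stop("clip_low must be below clip_high")
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be three strictly positive numbers")
  structure(list(clip_low = clip_low, clip_high = clip_high,
                 target_spacing = as.numeric(target_spacing)),
            class = "preprocess_spec")
}

# Keys cubic convolution kernel, a = -0.5.
.keys_kernel <- function(s) {
  s <- abs(s)
  ifelse(s <= 1, 1.5 * s^3 - 2.5 * s^2 + 1,
         ifelse(s < 2, -0.5 * (s^3 - 5 * s^2 + 8 * s - 4), 0))
}

# Interpolation weight matrix (n_out x n_in) for one axis. Output voxel
# centers at (i + 0.5) * sp_out map to continuous input index
# t = ((i + 0.5) * sp_out) / sp_in - 0.5; borders replicate. Rows sum to 1,
# so constants are preserved and identity spacing reproduces the input
# exactly (the kernel interpolates: w(0) = 1, w(+-1) = w(+-2) = 0).
.resample_weights <- function(n_in, sp_in, n_out, sp_out, method) {
  t <- ((seq_len(n_out) - 0.5) * sp_out) / sp_in - 0.5
  W <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    idx <- pmin(pmax(floor(t + 0.5), 0), n_in - 1) + 1
    W[cbind(seq_len(n_out), idx)] <- 1
  } else {
    base <- floor(t)
    for (m in -1:2) {
      j <- pmin(pmax(base + m, 0), n_in - 1) + 1
      w <- .keys_kernel(t - (base + m))
      for (i in seq_len(n_out)) W[i, j[i]] <- W[i, j[i]] + w[i]
    }
  }
  W
}

# Apply a weight matrix along one axis of a (z,y,x) array.
.apply_axis <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(2, 3, 1), `2` = c(1, 3, 2), `3` = c(1, 2, 3))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- matrix(a, nrow = dp[1] * dp[2], ncol = dp[3]) %*% t(W)
  out <- array(m, dim = c(dp[1], dp[2], nrow(W)))
  aperm(out, order(perm))
}

#' Resample a CT volume or label map to a target spacing
#'
#' Images: cubic (Keys, a = -0.5) interpolation in-plane, nearest neighbor
#' along z. Labels: nearest neighbor on every axis, so no label absent from
#' the input can appear in the output. The output grid covers the input's
#' physical extent (`n_out = ceiling(n_in * sp_in / sp_out)`); resampling
#' to the input's own spacing is the identity.
#'
#' @param x a [ct_volume()] or [label_map()].
#' @param spec a [preprocess_spec()].
#' @return object of the same class as `x` on the target grid.
#' @export
resample <- function(x, spec = preprocess_spec()) {
  is_lab <- inherits(x, "label_map")
  if (!is_lab && !inherits(x, "ct_volume"))
    stop("x must be a ct_volume or label_map")
  arr <- if (is_lab) x$labels else x$voxels
  d <- dim(arr)
  if (any(d < 2L))
    stop("cannot resample a degenerate (single-voxel) axis")
  sp_in <- x$spacing
  sp_out <- spec$target_spacing
  n_out <- pmax(1L, as.integer(ceiling(d * sp_in / sp_out)))
  methods <- if (is_lab) rep("nearest", 3L) else c("nearest", "cubic", "cubic")
  out <- arr * 1.0
  for (ax in 1:3) {
    W <- .resample_weights(d[ax], sp_in[ax], n_out[ax], sp_out[ax],
                           methods[ax])
    out <- .apply_axis(out, W, ax)
  }
  if (is_lab) {
    storage.mode(out) <- "integer"
    label_map(out, sp_out, x$taxonomy, x$origin)
  } else {
    ct_volume(out, sp_out, x$origin)
  }
}

#' Clip and z-score-normalize a volume for the segmentation model
#'
#' Intensities are clipped to `[clip_low, clip_high]`, then z-scored with
#' the mean and population SD (denominator n) of the whole clipped volume.
#' This transform is for model input only: fat quantification always runs
#' on raw HU (clipping at -95 HU would censor fat attenuation).
#'
#' @param vol a [ct_volume()].
#' @param spec a [preprocess_spec()].
#' @return a [ct_volume()] with approximately zero mean and unit SD.
#' @export
preprocess_for_model <- function(vol, spec = preprocess_spec()) {
  stopifnot(inherits(vol, "ct_volume"))
  v <- pmin(pmax(vol$voxels, spec$clip_low), spec$clip_high)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (!is.finite(s) || s == 0)
    stop("zero intensity variance after clipping; cannot z-score")
  ct_volume((v - m) / s, vol$spacing, vol$origin)
}
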