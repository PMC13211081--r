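#' Fat quantification configuration
#'
#' Muscle-fat% is the percentage of voxels within a segmented muscle whose
#' attenuation is strictly below the threshold (default -20 HU; a voxel at
#' exactly -20 counts as muscle). Bilateral merging pools voxels from both
#' sides before dividing, which equals computing the ratio over the union
#' mask.
#'
#' @param fat_threshold_hu attenuation threshold in HU.
#' @param merge_bilateral pool left/right sides into one value per group?
#' @return a `fat_quant_config` list.
#' @export
fat_quant_config <- function(fat_threshold_hu = -20, merge_bilateral = TRUE) {
  stopifnot_scalar_num(fat_threshold_hu, "fat_threshold_hu")
  structure(list(fat_threshold_hu = fat_threshold_hu,
                 merge_bilateral = isTRUE(merge_bilateral)),
            class = "fat_quant_config")
}

#' Muscle-fat percentage within a mask
#'
#' @param vol a [ct_volume()] with raw HU values.
#' @param mask logical array of the same shape as `vol$voxels`.
#' @param cfg a [fat_quant_config()].
#' @return fat percentage in \[0, 100\]:
#'   `100 * #(HU < threshold within mask) / #mask`.
#' @export
muscle_fat_percent <- function(vol, mask, cfg = fat_quant_config()) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!identical(dim(mask), dim(vol$voxels)))
    stop("mask shape does not match volume shape")
  mask <- as.logical(mask)
  n <- sum(mask)
  if (n == 0L) stop("empty mask: fat percentage is undefined (not 0%)")
  hu <- vol$voxels[mask]
  100 * sum(hu < cfg$fat_threshold_hu) / n
}

#' Muscle volume of a mask in milliliters
#'
#' @param mask logical array.
#' @param spacing voxel spacing in mm, (z, y, x).
#' @return volume in mL: voxel count x voxel volume (mm^3) / 1000.
#' @export
muscle_volume <- function(mask, spacing) {
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  n <- sum(as.logical(mask))
  if (n == 0L) stop("empty mask: volume is undefined")
  n * prod(spacing) / 1000
}

#' Quantify fat% and volume for every muscle group in a label map
#'
#' One row per (group, side) or per group when `cfg$merge_bilateral` is
#' TRUE (sides pooled before division, not averaged after). Groups with no
#' voxels are reported with `present = FALSE` and NA metrics, never as 0%.
#'
#' @param vol a [ct_volume()] with raw HU.
#' @param labels a [label_map()] aligned to `vol`.
#' @param cfg a [fat_quant_config()].
#' @return data.frame with columns group (and side when unmerged),
#'   present, n_voxels, n_fat_voxels, fat_percent, volume_mL.
#' @export
quantify_all <- function(vol, labels, cfg = fat_quant_config()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(labels, "label_map"))
  if (!identical(dim(vol$voxels), dim(labels$labels)))
    stop("volume and label map shapes do not match")
  tax <- labels$taxonomy
  lab_vec <- as.vector(labels$labels)
  hu_vec <- as.vector(vol$voxels)
  fat_vec <- hu_vec < cfg$fat_threshold_hu
  cnt <- tabulate(lab_vec, nbins = max(tax$label))
  fat_cnt <- vapply(tax$label,
                    function(l) if (cnt[l] > 0L) sum(fat_vec[lab_vec == l]) else 0L,
                    numeric(1))
  per_label <- data.frame(group = tax$group, side = tax$side,
                          n_voxels = cnt[tax$label],
                          n_fat_voxels = fat_cnt,
                          stringsAsFactors = FALSE)
  if (cfg$merge_bilateral) {
    agg <- stats::aggregate(cbind(n_voxels, n_fat_voxels) ~ group,
                            data = per_label, FUN = sum)
    agg <- agg[match(unique(tax$group), agg$group), , drop = FALSE]
    per_label <- agg
  }
  vox_mm3 <- prod(vol$spacing)
  per_label$present <- per_label$n_voxels > 0L
  per_label$fat_percent <- ifelse(per_label$present,
                                  100 * per_label$n_fat_voxels / per_label$n_voxels,
                                  NA_real_)
  per_label$volume_mL <- ifelse(per_label$present,
                                per_label$n_voxels * vox_mm3 / 1000,
                                NA_real_)
  rownames(per_label) <- NULL
  cols <- c("group", if (!cfg$merge_bilateral) "side", "present",
            "n_voxels", "n_fat_voxels", "fat_percent", "volume_mL")
  per_label[, cols]
}
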