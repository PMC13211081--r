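#' Dice coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks give 1.0 with a
#' `both_empty` warning attribute (absent-muscle cases must not poison
#' macro-averages); exactly one empty mask gives 0.0.
#'
#' @param a,b logical/0-1 arrays of identical shape.
#' @return Dice in \[0, 1\] (attribute `both_empty` set when applicable).
#' @export
dice <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("mask shapes do not match")
  a <- as.logical(a); b <- as.logical(b)
  na <- sum(a); nb <- sum(b)
  if (na == 0L && nb == 0L) {
    warning("both masks empty; Dice defined as 1.0")
    return(structure(1.0, both_empty = TRUE))
  }
  2 * sum(a & b) / (na + nb)
}

#' Macro-average of per-muscle Dice values
#'
#' @param per_muscle nonempty numeric vector of per-muscle Dice values.
#' @param digits decimals for the reported value (3, matching convention);
#'   use NA to skip rounding.
#' @return arithmetic mean.
#' @export
macro_average <- function(per_muscle, digits = 3) {
  if (length(per_muscle) == 0L) stop("empty Dice list")
  m <- mean(per_muscle)
  if (is.na(digits)) m else round(m, digits)
}

#' Per-label Dice table between predicted and reference label maps
#'
#' Per-case Dice per muscle group (both sides of a group pooled into one
#' mask), plus the macro-average over groups.
#'
#' @param pred,truth [label_map()]s on the same grid and taxonomy.
#' @return data.frame with group, dice, both_empty; the macro-average is
#'   attached as attribute `macro_average`.
#' @export
dice_table <- function(pred, truth) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  if (!identical(dim(pred$labels), dim(truth$labels)))
    stop("label map shapes do not match")
  tax <- truth$taxonomy
  groups <- unique(tax$group)
  rows <- lapply(groups, function(g) {
    labs <- tax$label[tax$group == g]
    a <- pred$labels %in% labs
    b <- truth$labels %in% labs
    d <- withCallingHandlers(dice(a, b), warning = function(w)
      invokeRestart("muffleWarning"))
    data.frame(group = g, dice = as.numeric(d),
               both_empty = isTRUE(attr(d, "both_empty")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "macro_average") <- macro_average(out$dice)
  out
}

#' Compound soft-Dice + cross-entropy segmentation loss
#'
#' Reference implementation of the training objective
#' `L_total = L_Dice + L_CE` with
#' `L_Dice = 1 - (2*sum(p*g) + eps) / (sum(p^2) + sum(g^2) + eps)` and
#' `L_CE = mean over voxels of -sum_c g_c log(p_c)`.
#'
#' By default the soft-Dice sums run over classes and voxels jointly
#' (global soft Dice, the nnU-Net convention); `per_class = TRUE` instead
#' averages a per-class soft Dice, provided for comparison. The CE voxel
#' aggregation is the mean, so the loss scale is patch-size independent.
#' Probabilities are clipped at 1e-12 inside the log.
#'
#' @param p numeric matrix of predicted class probabilities, voxels x
#'   classes; rows must sum to 1 (within 1e-6).
#' @param g one-hot ground-truth matrix of the same shape.
#' @param epsilon numerical-stability constant of the Dice term.
#' @param per_class use the per-class-averaged soft Dice variant?
#' @return list with `total`, `dice`, `ce`.
#' @export
dice_ce_loss <- function(p, g, epsilon = 1e-5, per_class = FALSE) {
  p <- as.matrix(p); g <- as.matrix(g)
  if (!identical(dim(p), dim(g))) stop("p and g shapes do not match")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-6))
    stop("p must be per-voxel probability distributions (rows sum to 1)")
  if (any(g != 0 & g != 1) || any(rowSums(g) != 1))
    stop("g must be one-hot")
  if (per_class) {
    l_dice <- mean(vapply(seq_len(ncol(p)), function(c) {
      1 - (2 * sum(p[, c] * g[, c]) + epsilon) /
        (sum(p[, c]^2) + sum(g[, c]^2) + epsilon)
    }, numeric(1)))
  } else {
    l_dice <- 1 - (2 * sum(p * g) + epsilon) /
      (sum(p^2) + sum(g^2) + epsilon)
  }
  l_ce <- mean(-log(pmax(p[g == 1], 1e-12)))
  list(total = l_dice + l_ce, dice = l_dice, ce = l_ce)
}
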