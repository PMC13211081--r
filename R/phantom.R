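#' Synthetic CT phantom specification
#'
#' Describes a synthetic HU volume containing the nine bilateral trunk
#' muscle compartments (axis-aligned elliptic cylinders at anatomically
#' ordered craniocaudal stations, mirrored across the mid-sagittal plane)
#' with planted expected fat fractions, plus a stack of vertebral-body
#' solids following a circular arc in the mid-sagittal plane whose tangent
#' rotates by `planted_cobb` degrees between the T1-superior and
#' T12-inferior stations.
#'
#' The HU tissue model keeps both tissue distributions at least 4 SD away
#' from the -20 HU fat threshold on their own side, so threshold recovery
#' error is purely binomial (defaults: 7 SD).
#'
#' @param grid_shape voxels per axis, (z, y, x).
#' @param spacing mm per axis, (z, y, x).
#' @param per_group_fat_fraction named numeric in \[0, 1\], one entry per
#'   group of [muscle_groups()]; defaults are realistic cohort means
#'   (fractions of the per-muscle fat% means used by [cohort_spec()]).
#' @param hu_muscle_mean,hu_muscle_sd,hu_fat_mean,hu_fat_sd normal tissue
#'   HU models for muscle and fat voxels.
#' @param hu_background,hu_bone constant HU for air background and
#'   vertebral bodies.
#' @param planted_cobb ground-truth Cobb angle in degrees, in \[0, 90).
#' @param seed integer seed; all randomness in [generate_phantom()] derives
#'   from it.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         spacing = c(2.5, 0.871, 0.871),
                         per_group_fat_fraction = NULL,
                         hu_muscle_mean = 50, hu_muscle_sd = 10,
                         hu_fat_mean = -90, hu_fat_sd = 10,
                         hu_background = -1000, hu_bone = 700,
                         planted_cobb = 38.6,
                         seed = 1L) {
  groups <- muscle_groups()
  if (is.null(per_group_fat_fraction)) {
    per_group_fat_fraction <- c(psoas = 0.051, quadratus_lumborum = 0.14,
                                paraspinal = 0.15, latissimus_dorsi = 0.164,
                                iliacus = 0.045, rectus_femoris = 0.021,
                                rhomboid = 0.022, trapezius = 0.020,
                                vastus = 0.025)
  }
  if (length(per_group_fat_fraction) == 1L && is.null(names(per_group_fat_fraction)))
    per_group_fat_fraction <- stats::setNames(
      rep(per_group_fat_fraction, length(groups)), groups)
  if (!setequal(names(per_group_fat_fraction), groups))
    stop("per_group_fat_fraction must be named with the nine muscle groups")
  per_group_fat_fraction <- per_group_fat_fraction[groups]
  if (any(per_group_fat_fraction < 0 | per_group_fat_fraction > 1))
    stop("fat fractions must lie in [0, 1]")
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop("grid_shape must be three axis sizes of at least 8 voxels")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be strictly positive")
  if (!(hu_fat_mean + 4 * hu_fat_sd < -20))
    stop("fat HU distribution too close to the -20 threshold: need hu_fat_mean + 4*hu_fat_sd < -20")
  if (!(-20 < hu_muscle_mean - 4 * hu_muscle_sd))
    stop("muscle HU distribution too close to the -20 threshold: need hu_muscle_mean - 4*hu_muscle_sd > -20")
  if (planted_cobb < 0 || planted_cobb >= 90)
    stop("planted_cobb must lie in [0, 90)")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 muscle_groups = groups,
                 per_group_fat_fraction = per_group_fat_fraction,
                 hu_muscle_mean = hu_muscle_mean, hu_muscle_sd = hu_muscle_sd,
                 hu_fat_mean = hu_fat_mean, hu_fat_sd = hu_fat_sd,
                 hu_background = hu_background, hu_bone = hu_bone,
                 planted_cobb = planted_cobb,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Mid-sagittal spinal arc geometry shared by the volume rasterizer and the
# analytic endplate construction. Returns the arc center (z, y in mm),
# radius, and the half-angle; NULL radius encodes a straight spine.
.phantom_arc <- function(spec) {
  nz <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  sz <- spec$spacing[1]; sy <- spec$spacing[2]
  mz <- max(2L, round(0.03 * nz))
  slab <- (nz - 2L * mz) %/% 9L
  if (slab < 3L) stop("grid too small for nine craniocaudal stations")
  zs_mm <- mz * sz                    # T1 superior endplate station
  ze_mm <- (mz + 9L * slab) * sz      # T12 inferior endplate station
  y0_mm <- 0.30 * ny * sy             # spine column depth
  half <- spec$planted_cobb * pi / 180 / 2
  if (half < 1e-12) {
    return(list(straight = TRUE, zs = zs_mm, ze = ze_mm, y0 = y0_mm,
                mz = mz, slab = slab, half = 0))
  }
  L <- ze_mm - zs_mm
  R <- L / (2 * sin(half))
  Cz <- (zs_mm + ze_mm) / 2
  # center the bow so the sagittal excursion splits evenly about y0
  Cy <- y0_mm - R * (1 + cos(half)) / 2
  list(straight = FALSE, zs = zs_mm, ze = ze_mm, y0 = y0_mm, mz = mz,
       slab = slab, half = half, R = R, Cz = Cz, Cy = Cy)
}

# Analytic endplate lines at the two arc stations. For a straight spine
# both lines are parallel to the y axis.
.phantom_endplates <- function(spec, half_width_mm = 15) {
  arc <- .phantom_arc(spec)
  mk <- function(P, phi) {
    n <- c(sin(phi), cos(phi))   # endplate direction: normal to the tangent
    rbind(P - half_width_mm * n, P + half_width_mm * n)
  }
  if (arc$straight) {
    sup <- rbind(c(arc$zs, arc$y0 - half_width_mm),
                 c(arc$zs, arc$y0 + half_width_mm))
    inf <- rbind(c(arc$ze, arc$y0 - half_width_mm),
                 c(arc$ze, arc$y0 + half_width_mm))
  } else {
    sup <- mk(c(arc$Cz + arc$R * sin(-arc$half), arc$Cy + arc$R * cos(-arc$half)),
              -arc$half)
    inf <- mk(c(arc$Cz + arc$R * sin(arc$half), arc$Cy + arc$R * cos(arc$half)),
              arc$half)
  }
  endplate_pair(sup, inf)
}

#' Generate a synthetic CT phantom with known ground truth
#'
#' Builds the HU volume and label map described by a [phantom_spec()].
#' Within each muscle compartment every voxel is independently fat with the
#' group's planted probability (fat HU drawn from the fat distribution,
#' remaining voxels from the muscle distribution), so measured fat%
#' recovers the planted fraction up to binomial sampling error. Vertebral
#' bodies are rasterized along the spinal arc at `hu_bone`; background is
#' constant `hu_background`. The returned endplate pair is the exact
#' analytic pair of endplate lines in the mid-sagittal plane.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `ct_phantom` with `volume` ([ct_volume()]),
#'   `labels` ([label_map()]), `ground_truth` (data.frame: group,
#'   planted_fraction, n_voxels, n_fat_voxels, fat_percent, volume_mL) and
#'   `endplates` ([endplate_pair()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nx <- spec$grid_shape[3]
  sz <- spec$spacing[1]; sy <- spec$spacing[2]; sx <- spec$spacing[3]
  arc <- .phantom_arc(spec)
  tax <- default_taxonomy()
  groups <- spec$muscle_groups

  vol <- array(spec$hu_background, dim = c(nz, ny, nx))
  lab <- array(0L, dim = c(nz, ny, nx))

  ## vertebral bodies along the arc (HU only; not part of the label map)
  n_vert <- 12L
  rz_v <- 0.38 * (arc$ze - arc$zs) / n_vert
  ry_v <- 6; rx_v <- 6
  xc_mm <- (nx / 2) * sx
  zc_idx <- (seq_len(nz) - 0.5) * sz
  yc_idx <- (seq_len(ny) - 0.5) * sy
  xc_idx <- (seq_len(nx) - 0.5) * sx
  phis <- if (arc$straight) rep(0, n_vert) else
    seq(-arc$half, arc$half, length.out = n_vert)
  zc_v <- if (arc$straight) seq(arc$zs, arc$ze, length.out = n_vert) else
    arc$Cz + arc$R * sin(phis)
  yc_v <- if (arc$straight) rep(arc$y0, n_vert) else
    arc$Cy + arc$R * cos(phis)
  bone <- array(FALSE, dim = c(nz, ny, nx))
  for (j in seq_len(n_vert)) {
    if (yc_v[j] - ry_v < 0 || yc_v[j] + ry_v > ny * sy)
      stop("spinal arc leaves the grid (planted_cobb too large for this grid)")
    iz <- which(abs(zc_idx - zc_v[j]) <= rz_v)
    iy <- which(abs(yc_idx - yc_v[j]) <= ry_v)
    ix <- which(abs(xc_idx - xc_mm) <= rx_v)
    if (!length(iz) || !length(iy) || !length(ix)) next
    dz2 <- ((zc_idx[iz] - zc_v[j]) / rz_v)^2
    dy2 <- ((yc_idx[iy] - yc_v[j]) / ry_v)^2
    dx2 <- ((xc_idx[ix] - xc_mm) / rx_v)^2
    inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
    sub <- bone[iz, iy, ix, drop = FALSE]
    bone[iz, iy, ix] <- sub | inside
  }
  vol[bone] <- spec$hu_bone

  ## muscle compartments: elliptic cylinders, one z station per group,
  ## mirrored left/right
  ry <- 0.11 * ny; rx <- 0.085 * nx
  y_m <- 0.62 * ny
  dx_off <- 0.18 * nx
  if (dx_off <= rx)
    stop("grid too narrow: left/right compartments of group ", groups[1],
         " would overlap at the midline")
  comp_voxels <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    z_lo <- arc$mz + (g - 1L) * arc$slab + 1L
    z_hi <- arc$mz + g * arc$slab - 1L       # one-slice gap between stations
    iy <- which(abs(seq_len(ny) - 0.5 - y_m) <= ry)
    idx_side <- function(x_c) {
      ix <- which(abs(seq_len(nx) - 0.5 - x_c) <= rx)
      if (!length(ix) || !length(iy) || z_hi < z_lo)
        stop("compartment for group ", groups[g], " exceeds the grid")
      d2 <- outer(((iy - 0.5 - y_m) / ry)^2, ((ix - 0.5 - x_c) / rx)^2, `+`)
      sel <- which(d2 <= 1, arr.ind = TRUE)
      if (nrow(sel) == 0L)
        stop("compartment for group ", groups[g], " exceeds the grid")
      zz <- rep(z_lo:z_hi, each = nrow(sel))
      cbind(zz, rep(sel[, 1], times = z_hi - z_lo + 1L) + min(iy) - 1L,
            rep(sel[, 2], times = z_hi - z_lo + 1L) + min(ix) - 1L)
    }
    left  <- idx_side(nx / 2 - dx_off)
    right <- idx_side(nx / 2 + dx_off)
    lin_l <- left[, 1] + (left[, 2] - 1L) * nz + (left[, 3] - 1L) * nz * ny
    lin_r <- right[, 1] + (right[, 2] - 1L) * nz + (right[, 3] - 1L) * nz * ny
    if (any(lab[lin_l] != 0L) || any(lab[lin_r] != 0L) ||
        any(bone[lin_l]) || any(bone[lin_r]))
      stop("compartment for group ", groups[g],
           " overlaps another structure")
    lab[lin_l] <- tax$label[tax$group == groups[g] & tax$side == "left"]
    lab[lin_r] <- tax$label[tax$group == groups[g] & tax$side == "right"]
    comp_voxels[[g]] <- c(lin_l, lin_r)
  }

  ## plant fat voxels and draw HU
  gt <- with_seed(spec$seed, {
    rows <- lapply(seq_along(groups), function(g) {
      lin <- comp_voxels[[g]]
      f <- spec$per_group_fat_fraction[[groups[g]]]
      is_fat <- stats::runif(length(lin)) < f
      hu <- numeric(length(lin))
      hu[is_fat] <- stats::rnorm(sum(is_fat), spec$hu_fat_mean, spec$hu_fat_sd)
      hu[!is_fat] <- stats::rnorm(sum(!is_fat), spec$hu_muscle_mean,
                                  spec$hu_muscle_sd)
      vol[lin] <<- hu
      data.frame(group = groups[g], planted_fraction = f,
                 n_voxels = length(lin), n_fat_voxels = sum(is_fat),
                 fat_percent = 100 * sum(is_fat) / length(lin),
                 volume_mL = length(lin) * prod(spec$spacing) / 1000,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  structure(list(volume = ct_volume(vol, spec$spacing),
                 labels = label_map(lab, spec$spacing, tax),
                 ground_truth = gt,
                 endplates = .phantom_endplates(spec),
                 spec = spec),
            class = "ct_phantom")
}

#' Write a phantom to disk
#'
#' Writes `volume.nii.gz`, `labels.nii.gz`, `ground_truth.csv` and a
#' `spec.json` sidecar into `dir`.
#'
#' @param ph a `ct_phantom` from [generate_phantom()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  stopifnot(inherits(ph, "ct_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(ph$volume, file.path(dir, "volume.nii.gz"))
  write_labels(ph$labels, file.path(dir, "labels.nii.gz"))
  utils::write.csv(ph$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  sp <- ph$spec
  jsonlite::write_json(
    list(grid_shape = sp$grid_shape, spacing = sp$spacing,
         per_group_fat_fraction = as.list(sp$per_group_fat_fraction),
         hu_muscle_mean = sp$hu_muscle_mean, hu_muscle_sd = sp$hu_muscle_sd,
         hu_fat_mean = sp$hu_fat_mean, hu_fat_sd = sp$hu_fat_sd,
         hu_background = sp$hu_background, hu_bone = sp$hu_bone,
         planted_cobb = sp$planted_cobb, seed = sp$seed),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Synthetic cohort specification
#'
#' Describes a cohort whose kyphosis (Cobb angle) and per-muscle fat%
#' share a latent degeneration score: each case draws z ~ N(0, 1);
#' Cobb = `cobb_mean + cobb_sd * (cobb_loading * z + sqrt(1 - cobb_loading^2) * e0)`
#' and each muscle's fat% = `mean + sd * (lambda * z + sqrt(1 - lambda^2) * e)`,
#' floored at 0. With `cobb_loading = 1` the planted Cobb-fat% correlation
#' of a muscle equals its loading `lambda` (up to flooring attenuation).
#' Surgery-flagged cases have their Cobb replaced by an independent draw
#' (decoupling the biomechanical relationship); atrophy-flagged cases have
#' paraspinal fat% drawn uniformly in (50, 90]. Fracture, transitional and
#' sex flags are assigned independently of z.
#'
#' Defaults emulate the automated-cohort structure: n = 433, Cobb
#' 38.6 +/- 13.5 deg, per-muscle fat% means/SDs at realistic cohort values,
#' loadings equal to the adjusted per-muscle correlations the analysis is
#' designed to recover (paraspinal 0.42), 8 surgery and 4 atrophy cases
#' (12 confounded cases in all), 42 fracture and 20 transitional cases,
#' 56.7% male.
#'
#' @param n_cases number of cases.
#' @param cobb_mean,cobb_sd Cobb angle distribution (degrees).
#' @param cobb_loading loading of Cobb on the latent score, in \[-1, 1\].
#' @param per_muscle_fat_mean,per_muscle_fat_sd named per-muscle fat%
#'   moments (percent).
#' @param per_muscle_loading named per-muscle loadings in \[-1, 1\].
#' @param n_surgery,n_atrophy,n_fracture,n_transitional confounder counts.
#'   Surgery and atrophy sets are drawn disjoint so the union of the two
#'   exclusion rules has exactly `n_surgery + n_atrophy` cases.
#' @param sex_fraction_male expected fraction of male cases.
#' @param seed integer seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_cases = 433,
                        cobb_mean = 38.6, cobb_sd = 13.5, cobb_loading = 1,
                        per_muscle_fat_mean = NULL,
                        per_muscle_fat_sd = NULL,
                        per_muscle_loading = NULL,
                        n_surgery = 8, n_atrophy = 4,
                        n_fracture = 42, n_transitional = 20,
                        sex_fraction_male = 0.567,
                        seed = 1L) {
  groups <- muscle_groups()
  if (is.null(per_muscle_fat_mean))
    per_muscle_fat_mean <- c(psoas = 5.1, quadratus_lumborum = 14,
                             paraspinal = 15, latissimus_dorsi = 16.36,
                             iliacus = 4.48, rectus_femoris = 2.07,
                             rhomboid = 2.24, trapezius = 1.97,
                             vastus = 2.52)
  if (is.null(per_muscle_fat_sd))
    per_muscle_fat_sd <- c(psoas = 3.1, quadratus_lumborum = 9.3,
                           paraspinal = 11, latissimus_dorsi = 9.29,
                           iliacus = 2.39, rectus_femoris = 2.32,
                           rhomboid = 2.14, trapezius = 1.71,
                           vastus = 2.72)
  if (is.null(per_muscle_loading))
    per_muscle_loading <- c(psoas = 0.23, quadratus_lumborum = 0.33,
                            paraspinal = 0.42, latissimus_dorsi = 0.17,
                            iliacus = 0.22, rectus_femoris = 0.15,
                            rhomboid = 0.11, trapezius = 0.17,
                            vastus = 0.32)
  for (nm in c("per_muscle_fat_mean", "per_muscle_fat_sd",
               "per_muscle_loading")) {
    v <- get(nm)
    if (!setequal(names(v), groups))
      stop(nm, " must be named with the nine muscle groups")
    assign(nm, v[groups])
  }
  if (any(abs(per_muscle_loading) > 1) || abs(cobb_loading) > 1)
    stop("loadings must lie in [-1, 1]")
  if (any(per_muscle_fat_sd < 0) || cobb_sd < 0) stop("sd must be >= 0")
  if (n_surgery + n_atrophy > n_cases ||
      n_fracture > n_cases || n_transitional > n_cases)
    stop("counts of flagged cases exceed n_cases")
  structure(list(n_cases = as.integer(n_cases),
                 cobb_mean = cobb_mean, cobb_sd = cobb_sd,
                 cobb_loading = cobb_loading,
                 per_muscle_fat_mean = per_muscle_fat_mean,
                 per_muscle_fat_sd = per_muscle_fat_sd,
                 per_muscle_loading = per_muscle_loading,
                 n_surgery = as.integer(n_surgery),
                 n_atrophy = as.integer(n_atrophy),
                 n_fracture = as.integer(n_fracture),
                 n_transitional = as.integer(n_transitional),
                 sex_fraction_male = sex_fraction_male,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_spec()].
#' @return data.frame (one row per case) with case_id, cobb_mean,
#'   `fat_<group>` columns (percent, bilateral-merged), logical flags
#'   surgery/atrophy/fracture/transitional, sex ("M"/"F") and the hidden
#'   ground-truth latent score `latent_z` (retained for testing).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- muscle_groups()
  n <- spec$n_cases
  with_seed(spec$seed, {
    z <- stats::rnorm(n)
    rho <- spec$cobb_loading
    cobb <- spec$cobb_mean +
      spec$cobb_sd * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
    fat <- sapply(groups, function(g) {
      lam <- spec$per_muscle_loading[[g]]
      v <- spec$per_muscle_fat_mean[[g]] + spec$per_muscle_fat_sd[[g]] *
        (lam * z + sqrt(1 - lam^2) * stats::rnorm(n))
      pmin(pmax(v, 0), 100)
    })
    colnames(fat) <- paste0("fat_", groups)

    flagged <- sample.int(n, spec$n_surgery + spec$n_atrophy)
    surgery_id <- flagged[seq_len(spec$n_surgery)]
    atrophy_id <- setdiff(flagged, surgery_id)
    fracture_id <- sample.int(n, spec$n_fracture)
    transitional_id <- sample.int(n, spec$n_transitional)
    sex <- ifelse(stats::runif(n) < spec$sex_fraction_male, "M", "F")

    # surgery decouples Cobb from the latent score
    cobb[surgery_id] <- spec$cobb_mean +
      spec$cobb_sd * stats::rnorm(length(surgery_id))
    # atrophy: profound paraspinal fatty replacement in (50, 90]
    fat[atrophy_id, "fat_paraspinal"] <-
      90 - stats::runif(length(atrophy_id), 0, 40)
    # keep the >50% atrophy rule consistent with the planted flags: clamp
    # chance extremes of non-atrophy cases at the rule boundary
    non_atr <- setdiff(seq_len(n), atrophy_id)
    fat[non_atr, "fat_paraspinal"] <- pmin(fat[non_atr, "fat_paraspinal"], 50)

    out <- data.frame(case_id = seq_len(n), cobb_mean = cobb,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(fat))
    out$surgery <- seq_len(n) %in% surgery_id
    out$atrophy <- seq_len(n) %in% atrophy_id
    out$fracture <- seq_len(n) %in% fracture_id
    out$transitional <- seq_len(n) %in% transitional_id
    out$sex <- sex
    out$latent_z <- z
    attr(out, "cohort_spec") <- spec
    out
  })
}

#' Rater measurement-noise specification
#'
#' Entry (i, j) of a simulated rater matrix is
#' `true_i + bias_j + e_ij`, `e_ij ~ N(0, per_rating_error_sd^2)`. The
#' default error SD of 3.69 deg is chosen so the expected per-case 4-rater
#' sample SD is 3.4 deg (E\[S\] = sigma * c4(4), c4(4) ~ 0.9213).
#'
#' @param k_raters number of raters (>= 2).
#' @param per_rating_error_sd SD of a single rating's error, degrees.
#' @param per_rater_bias systematic bias per rater, degrees (length k).
#' @param seed integer seed.
#' @return a `rater_noise_spec` object.
#' @export
rater_noise_spec <- function(k_raters = 4, per_rating_error_sd = 3.69,
                             per_rater_bias = rep(0, k_raters), seed = 1L) {
  if (k_raters < 2) stop("k_raters must be at least 2")
  if (per_rating_error_sd < 0) stop("per_rating_error_sd must be >= 0")
  if (length(per_rater_bias) != k_raters)
    stop("per_rater_bias must have one entry per rater")
  structure(list(k_raters = as.integer(k_raters),
                 per_rating_error_sd = per_rating_error_sd,
                 per_rater_bias = as.numeric(per_rater_bias),
                 seed = as.integer(seed)),
            class = "rater_noise_spec")
}

#' Simulate a multi-rater measurement matrix
#'
#' @param true_angles numeric vector of true Cobb angles (degrees).
#' @param noise a [rater_noise_spec()].
#' @return n x k numeric matrix (cases x raters) with columns
#'   `rater_1..k`; reproducible for a fixed seed.
#' @export
simulate_raters <- function(true_angles, noise = rater_noise_spec()) {
  stopifnot(inherits(noise, "rater_noise_spec"))
  if (any(!is.finite(true_angles))) stop("true angles must be finite")
  n <- length(true_angles); k <- noise$k_raters
  m <- with_seed(noise$seed, {
    e <- matrix(stats::rnorm(n * k, 0, noise$per_rating_error_sd), n, k)
    matrix(true_angles, n, k) + matrix(noise$per_rater_bias, n, k,
                                       byrow = TRUE) + e
  })
  dimnames(m) <- list(as.character(seq_len(n)), paste0("rater_", seq_len(k)))
  m
}
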