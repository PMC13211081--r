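#' Endplate line pair for Cobb measurement
#'
#' Two lines in the mid-sagittal plane: one parallel to the superior
#' endplate of T1, one to the inferior endplate of T12/L1. Points are 2D
#' (z, y) = (craniocaudal mm, antero-posterior mm); lines are undirected.
#'
#' @param superior,inferior 2x2 numeric matrices, one point per row (z, y).
#' @param inferior_level which endplate the inferior line was drawn on
#'   ("T12_inferior" or "L1_superior"); recorded for provenance, the
#'   geometry is identical.
#' @return an `endplate_pair` object.
#' @export
endplate_pair <- function(superior, inferior,
                          inferior_level = c("T12_inferior", "L1_superior")) {
  chk <- function(m, name) {
    m <- matrix(as.numeric(m), ncol = 2)
    if (nrow(m) != 2L || any(!is.finite(m)))
      stop(name, " must be two finite 2D points")
    if (all(m[1, ] == m[2, ]))
      stop(name, " line has coincident points")
    m
  }
  structure(list(superior = chk(superior, "superior"),
                 inferior = chk(inferior, "inferior"),
                 inferior_level = match.arg(inferior_level),
                 plane_convention = "axis 1 = craniocaudal (z, mm), axis 2 = antero-posterior (y, mm)"),
            class = "endplate_pair")
}

# Inclination of an undirected line relative to the antero-posterior (y)
# axis, folded to (-90, 90] degrees. d = (dz, dy).
.line_inclination_deg <- function(p) {
  d <- p[2, ] - p[1, ]
  theta <- atan2(d[1], d[2]) * 180 / pi   # vs y axis
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  theta
}

#' Supine thoracic Cobb angle from an endplate pair
#'
#' The Cobb angle is the acute intersection angle of the two endplate
#' lines: the absolute difference of their inclinations (each measured
#' against the antero-posterior axis and folded to (-90, 90]), reflected to
#' \[0, 90\] when obtuse. Parallel lines give 0; the result is invariant
#' under common rotation and under rescaling of the point coordinates.
#'
#' @param pair an [endplate_pair()].
#' @return list of class `cobb_result` with `angle_deg`,
#'   `superior_inclination_deg`, `inferior_inclination_deg`.
#' @export
cobb_angle <- function(pair) {
  stopifnot(inherits(pair, "endplate_pair"))
  ts <- .line_inclination_deg(pair$superior)
  ti <- .line_inclination_deg(pair$inferior)
  a <- abs(ts - ti)
  if (a > 90) a <- 180 - a
  structure(list(angle_deg = a,
                 superior_inclination_deg = ts,
                 inferior_inclination_deg = ti),
            class = "cobb_result")
}

#' @export
print.cobb_result <- function(x, ...) {
  cat(sprintf("Cobb angle: %.2f deg (superior endplate %.2f, inferior %.2f)\n",
              x$angle_deg, x$superior_inclination_deg,
              x$inferior_inclination_deg))
  invisible(x)
}

#' Closed-form Cobb angle of a phantom's spinal arc
#'
#' The phantom spine follows a circular arc in the mid-sagittal plane; the
#' Cobb angle equals the rotation of the arc's tangent between the
#' T1-superior and T12-inferior stations, which is simply the arc's
#' subtended angle. Provides the generator-side closed form against which
#' the point-based [cobb_angle()] path is checked.
#'
#' @param spec a [phantom_spec()].
#' @return the planted Cobb angle in degrees.
#' @export
cobb_from_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  abs(spec$planted_cobb)
}

#' Read endplate annotations and compute Cobb angles
#'
#' Annotation schema (JSON): a list of objects
#' `{case_id, superior: [[z,y],[z,y]], inferior: [[z,y],[z,y]],
#' units: "mm", inferior_level}`.
#'
#' @param path JSON annotation file.
#' @return data.frame with case_id, angle_deg, superior/inferior
#'   inclinations.
#' @export
cobb_from_annotations <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(ann, function(a) {
    pts <- function(p) do.call(rbind, lapply(p, function(q) unlist(q)))
    res <- cobb_angle(endplate_pair(pts(a$superior), pts(a$inferior),
                                    a$inferior_level %||% "T12_inferior"))
    data.frame(case_id = a$case_id, angle_deg = res$angle_deg,
               superior_inclination_deg = res$superior_inclination_deg,
               inferior_inclination_deg = res$inferior_inclination_deg)
  })
  do.call(rbind, rows)
}
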