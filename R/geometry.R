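# Spherical 10-20 electrode placement and electrode-to-skull-defect
# distances. All coordinates are centimeters in a right-handed frame:
# +x toward the right tragus, +y toward the nasion, +z toward the vertex,
# origin at the sphere center.

# spherical linear interpolation midpoint, stays on the sphere
slerp_mid <- function(a, b) {
  m <- a + b
  m / sqrt(sum(m^2)) * sqrt(sum(a^2))
}

sph_point <- function(r, incl_deg, azim_deg) {
  # inclination from vertex (+z); azimuth from anterior midline (+y),
  # positive toward the left (-x)
  th <- incl_deg * pi / 180; ph <- azim_deg * pi / 180
  r * c(-sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
}

#' Spherical 10-20 electrode placement from fiducials
#'
#' Places the 21 electrodes of the 10-20 system on a sphere by the
#' proportional rules: the midline electrodes at 20%-steps along the
#' nasion-inion arc, the circumferential ring (Fp1/2, F7/8, T3/4, T5/6,
#' O1/2) at 10%-steps around the head ring, the parasagittal electrodes
#' (F3/4, C3/4, P3/4) at great-circle midpoints of their midline and
#' temporal neighbors, and the ear electrodes A1/A2 just below the
#' temporal ring. The four fiducials (nasion, inion, left/right tragus)
#' fix the frame; they must not be collinear.
#'
#' @param radius sphere radius in cm (default 9).
#' @param fiducials optional 4 x 3 matrix with rownames nasion, inion,
#'   tragus_left, tragus_right; defaults to the canonical positions on the
#'   sphere equator.
#' @return matrix 21 x 3 (cm) with electrode labels as rownames, plus
#'   attribute \code{fiducials}.
#' @export
place_electrodes_1020 <- function(radius = 9, fiducials = NULL) {
  if (is.null(fiducials)) {
    fiducials <- rbind(nasion = c(0, radius, 0), inion = c(0, -radius, 0),
                       tragus_left = c(-radius, 0, 0),
                       tragus_right = c(radius, 0, 0))
  }
  v1 <- fiducials["inion", ] - fiducials["nasion", ]
  v2 <- fiducials["tragus_right", ] - fiducials["tragus_left", ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(cr^2)) < 1e-9 * sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    stop("degenerate fiducials: nasion-inion and tragus axes are collinear")
  pos <- list()
  # midline: 10-20-20-20-20-10 percent along the 180-degree nasion-inion arc
  pos$Fz <- sph_point(radius, 90 - 54, 0)     # 30% from nasion
  pos$Cz <- sph_point(radius, 0, 0)
  pos$Pz <- sph_point(radius, 90 - 126, 0)    # 70% -> posterior
  # circumferential ring at 10% (18 deg) inclination steps, azimuth from front
  ring <- c(Fp1 = 18, F7 = 54, T3 = 90, T5 = 126, O1 = 162)
  for (nm in names(ring)) {
    pos[[nm]] <- sph_point(radius, 72, ring[[nm]])
    pos[[mirror_electrode(nm)]] <- sph_point(radius, 72, -ring[[nm]])
  }
  # parasagittal electrodes: on-sphere midpoints
  pos$F3 <- slerp_mid(pos$Fz, pos$F7); pos$F4 <- slerp_mid(pos$Fz, pos$F8)
  pos$C3 <- slerp_mid(pos$Cz, pos$T3); pos$C4 <- slerp_mid(pos$Cz, pos$T4)
  pos$P3 <- slerp_mid(pos$Pz, pos$T5); pos$P4 <- slerp_mid(pos$Pz, pos$T6)
  # ear electrodes below the temporal ring
  pos$A1 <- sph_point(radius, 108, 90); pos$A2 <- sph_point(radius, 108, -90)
  out <- do.call(rbind, pos[electrode_labels()])
  colnames(out) <- c("x", "y", "z")
  attr(out, "fiducials") <- fiducials
  out
}

#' Head model with a circular skull-defect patch
#'
#' Combines 10-20 electrode positions on a sphere with the boundary of a
#' circular craniotomy defect centered at a named electrode. The boundary
#' circle lies on the sphere at geodesic radius \code{defect_radius} from
#' the center electrode and is discretized to \code{n_boundary} points.
#'
#' @param defect_center_electrode electrode label at the defect center.
#' @param defect_radius defect radius in cm (> 0).
#' @param radius sphere radius in cm.
#' @param n_boundary number of boundary points (>= 64 by default).
#' @param fiducials see \code{\link{place_electrodes_1020}}.
#' @return list of class \code{head_model}: \code{electrodes} (21 x 3 cm),
#'   \code{fiducials}, \code{defect_boundary} (n x 3 cm), \code{radius}.
#' @export
head_model <- function(defect_center_electrode = "C3", defect_radius = 2,
                       radius = 9, n_boundary = 64L, fiducials = NULL) {
  if (defect_radius <= 0) stop("defect_radius must be > 0")
  el <- place_electrodes_1020(radius, fiducials)
  if (!defect_center_electrode %in% rownames(el))
    stop("unknown electrode label: ", defect_center_electrode)
  c0 <- el[defect_center_electrode, ]
  # orthonormal tangent basis at the center point
  n0 <- c0 / sqrt(sum(c0^2))
  ref <- if (abs(n0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * n0) * n0; u <- u / sqrt(sum(u^2))
  v <- c(n0[2] * u[3] - n0[3] * u[2], n0[3] * u[1] - n0[1] * u[3],
         n0[1] * u[2] - n0[2] * u[1])
  ang <- defect_radius / radius          # geodesic angle
  th <- seq(0, 2 * pi, length.out = n_boundary + 1L)[-(n_boundary + 1L)]
  boundary <- t(vapply(th, function(t)
    radius * (cos(ang) * n0 + sin(ang) * (cos(t) * u + sin(t) * v)),
    numeric(3)))
  colnames(boundary) <- c("x", "y", "z")
  structure(list(electrodes = el, fiducials = attr(el, "fiducials"),
                 defect_boundary = boundary, radius = radius,
                 defect_center_electrode = defect_center_electrode,
                 defect_radius = defect_radius),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("Spherical head model: radius %.1f cm, %d electrodes, defect at %s (radius %.1f cm, %d boundary points)\n",
              x$radius, nrow(x$electrodes), x$defect_center_electrode,
              x$defect_radius, nrow(x$defect_boundary)))
  invisible(x)
}

#' Electrode-to-defect-border distances
#'
#' Minimum Euclidean distance from each electrode to the discretized
#' defect boundary point set, in cm.
#'
#' @param head a \code{head_model}, or a list with \code{electrodes} and
#'   \code{defect_boundary} matrices.
#' @return named numeric vector of distances (cm).
#' @export
electrode_defect_distances <- function(head) {
  el <- head$electrodes; bd <- head$defect_boundary
  if (is.null(bd) || nrow(bd) == 0L) stop("empty defect boundary")
  d <- apply(el, 1, function(p)
    sqrt(min(colSums((t(bd) - p)^2))))
  d
}

#' Classify skull-defect electrodes
#'
#' Electrodes within \code{cutoff_cm} (inclusive) of the defect border.
#' Electrodes lying over the defect itself (inside the boundary patch)
#' count regardless of their distance to the border ring: an electrode over
#' the bone flap center is a defect electrode even though the border is
#' far. Interior membership is tested against the boundary's spherical
#' centroid (a point is inside when its angular distance to the centroid
#' does not exceed the boundary's smallest angular radius).
#'
#' @param head a \code{head_model}.
#' @param cutoff_cm distance cutoff in cm (default 1.0, as in the
#'   clinical rule).
#' @param include_interior count electrodes over the defect interior
#'   (default TRUE).
#' @return character vector of electrode labels.
#' @export
classify_defect_electrodes <- function(head, cutoff_cm = 1.0,
                                       include_interior = TRUE) {
  d <- electrode_defect_distances(head)
  hit <- d <= cutoff_cm
  if (include_interior) {
    bd <- head$defect_boundary
    ctr <- colMeans(bd)
    nc <- sqrt(sum(ctr^2))
    if (nc > 1e-9) {
      ctr <- ctr / nc
      ang_to <- function(p) acos(pmin(1, pmax(-1,
        sum(p * ctr) / sqrt(sum(p^2)))))
      theta_b <- min(apply(bd, 1, ang_to))
      hit <- hit | apply(head$electrodes, 1, ang_to) <= theta_b + 1e-9
    }
  }
  names(d)[hit]
}
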