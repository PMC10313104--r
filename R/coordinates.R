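# Normalized myocardial coordinates: radial (endocardium 0 -> epicardium 1),
# circumferential (anticlockwise from the LV-RV junction, periodic on [0,1)),
# long-axis (apex 0 -> base 1).

#' Radial coordinate field on one slice
#'
#' r = d_endo / (d_endo + d_epi) with unsigned Euclidean distances to the
#' endocardial and epicardial contours, so r is 0 on the endocardium, 1 on the
#' epicardium, and monotone across the wall regardless of contour
#' parameterization.
#'
#' @param myo_mask logical matrix of myocardial pixels (possibly oversampled).
#' @param endo_contour,epi_contour vertex matrices in the mask's own pixel
#'   frame.
#' @param px,py optional precomputed pixel-center coordinate matrices matching
#'   `myo_mask` (0-based).
#' @return numeric matrix, `NA` off the myocardium; pixels where both
#'   distances vanish (touching contours) are `NA`.
#' @export
radial_coordinate <- function(myo_mask, endo_contour, epi_contour,
                              px = NULL, py = NULL) {
  if (is.null(px) || is.null(py)) {
    g <- fine_grid_centers(dim(myo_mask), 1L)
    px <- g$x; py <- g$y
  }
  idx <- which(myo_mask)
  out <- matrix(NA_real_, nrow(myo_mask), ncol(myo_mask))
  if (!length(idx)) return(out)
  de <- dist_to_polyline(px[idx], py[idx], endo_contour)
  dp <- dist_to_polyline(px[idx], py[idx], epi_contour)
  den <- de + dp
  r <- ifelse(den > 0, de / den, NA_real_)
  out[idx] <- r
  out
}

#' Circumferential coordinate field on one slice
#'
#' Polar angle about the cavity center, measured anticlockwise in the displayed
#' image plane (y up, i.e. against the row index), zeroed on the junction ray:
#' c = ((theta - theta_junction) mod 2*pi) / (2*pi).
#'
#' @param myo_mask logical matrix.
#' @param junction_point numeric (x, y) LV-RV junction landmark.
#' @param cavity_center numeric (x, y), typically the endocardial centroid.
#' @param chirality `+1` for anticlockwise-with-y-up (default), `-1` to flip
#'   for mirrored acquisitions.
#' @inheritParams radial_coordinate
#' @return numeric matrix with values in [0, 1), `NA` off the myocardium.
#' @export
circumferential_coordinate <- function(myo_mask, junction_point, cavity_center,
                                       chirality = 1, px = NULL, py = NULL) {
  if (sqrt(sum((junction_point - cavity_center)^2)) < 1e-9) {
    rlang::abort("junction landmark coincides with the cavity center")
  }
  if (is.null(px) || is.null(py)) {
    g <- fine_grid_centers(dim(myo_mask), 1L)
    px <- g$x; py <- g$y
  }
  idx <- which(myo_mask)
  out <- matrix(NA_real_, nrow(myo_mask), ncol(myo_mask))
  if (!length(idx)) return(out)
  th <- atan2(-(py[idx] - cavity_center[2]), px[idx] - cavity_center[1])
  th0 <- atan2(-(junction_point[2] - cavity_center[2]),
               junction_point[1] - cavity_center[1])
  out[idx] <- circ_wrap(chirality * (th - th0) / (2 * pi))
  out
}

#' Long-axis coordinate of a slice
#'
#' z = (slice_index - apex_index) / (base_index - apex_index). Values outside
#' [0, 1] mark slices beyond the annotated apex/base that are excluded from
#' analysis.
#'
#' @param slice_index slice index (same 1-based axis as the annotations).
#' @param apex_index,base_index real-valued annotated indices (may lie outside
#'   the acquired stack when extrapolated).
#' @return numeric scalar (vectorized over `slice_index`).
#' @export
longaxis_coordinate <- function(slice_index, apex_index, base_index) {
  if (isTRUE(all.equal(apex_index, base_index))) {
    rlang::abort("apex_index and base_index must differ")
  }
  (slice_index - apex_index) / (base_index - apex_index)
}

#' Exclude the LV outflow tract wedge from a slice mask
#'
#' Removes pixels whose polar angle about the cavity center falls in the
#' shorter angular interval between the two LVOT landmark rays.
#'
#' @param myo_mask logical matrix.
#' @param lvot_pair 2x2 matrix, one landmark point (x, y) per row.
#' @param cavity_center numeric (x, y).
#' @param side for the ambiguous 180-degree case: `1` or `-1` selects the
#'   interval swept anticlockwise from the first or second landmark.
#' @inheritParams radial_coordinate
#' @return the mask with the wedge removed.
#' @export
exclude_lvot <- function(myo_mask, lvot_pair, cavity_center, side = NULL,
                         px = NULL, py = NULL) {
  stopifnot(is.matrix(lvot_pair), nrow(lvot_pair) == 2)
  if (sqrt(sum((lvot_pair[1, ] - lvot_pair[2, ])^2)) < 1e-9) {
    rlang::abort("LVOT landmarks are identical")
  }
  if (is.null(px) || is.null(py)) {
    g <- fine_grid_centers(dim(myo_mask), 1L)
    px <- g$x; py <- g$y
  }
  ang <- function(p) atan2(-(p[2] - cavity_center[2]), p[1] - cavity_center[1]) / (2 * pi)
  a1 <- circ_wrap(ang(lvot_pair[1, ]))
  a2 <- circ_wrap(ang(lvot_pair[2, ]))
  width <- circ_diff(a2, a1)   # signed, in (-0.5, 0.5]
  if (abs(abs(width) - 0.5) < 1e-9 && is.null(side)) {
    rlang::abort("LVOT landmarks are diametrically opposite; pass `side` to pick the wedge")
  }
  if (!is.null(side)) width <- 0.5 * sign(side)
  lo <- if (width >= 0) a1 else a2
  w <- abs(width)
  idx <- which(myo_mask)
  if (!length(idx)) return(myo_mask)
  pc <- circ_wrap(atan2(-(py[idx] - cavity_center[2]), px[idx] - cavity_center[1]) / (2 * pi))
  inside <- circ_wrap(pc - lo) <= w
  out <- myo_mask
  out[idx[inside]] <- FALSE
  out
}

#' Signed angular difference between two junction annotations
#'
#' Angle between the rays joining the cavity center to each annotation,
#' returned in degrees in (-180, 180].
#'
#' @param junction_a,junction_b numeric (x, y) annotation points.
#' @param cavity_center numeric (x, y).
#' @return degrees.
#' @export
junction_angle_difference <- function(junction_a, junction_b, cavity_center) {
  ra <- junction_a - cavity_center
  rb <- junction_b - cavity_center
  if (sqrt(sum(ra^2)) < 1e-12 || sqrt(sum(rb^2)) < 1e-12) {
    rlang::abort("annotation coincides with the cavity center")
  }
  # anticlockwise with y up
  tha <- atan2(-ra[2], ra[1])
  thb <- atan2(-rb[2], rb[1])
  d <- (tha - thb) * 180 / pi
  d <- d - 360 * floor(d / 360)
  if (d > 180) d <- d - 360
  d
}

#' Difference between two slice-index annotations
#' @param index_a,index_b annotated slice indices.
#' @return `index_a - index_b`.
#' @export
slice_annotation_difference <- function(index_a, index_b) index_a - index_b

# cavity center for one slice: endocardial polygon centroid when contours are
# available, otherwise the centroid of the enclosed cavity pixels.
.cavity_center <- function(endo_polygon = NULL, myo_fine = NULL, oversample = 1L) {
  if (!is.null(endo_polygon)) return(polygon_centroid(endo_polygon))
  filled <- .fill_hull(myo_fine)
  cav <- filled & !myo_fine
  if (!any(cav)) return(NULL)
  idx <- which(cav, arr.ind = TRUE)
  s <- as.numeric(oversample)
  c(mean((idx[, 2] - 0.5) / s - 0.5), mean((idx[, 1] - 0.5) / s - 0.5))
}

.fill_hull <- function(mask) {
  m <- EBImage::fillHull(EBImage::Image(mask * 1))
  as.matrix(m) > 0.5
}

# Euclidean distance-transform path used when no contours are stored with the
# study (e.g. after a bundle round trip). Distances are measured to the cavity
# (endocardial) and exterior (epicardial) regions, shifted by half a pixel so
# that boundary pixels sit at distance ~0.
.mask_wall_distances <- function(myo_fine) {
  filled <- .fill_hull(myo_fine)
  cav <- filled & !myo_fine
  d_endo <- as.matrix(EBImage::distmap(EBImage::Image((!cav) * 1))) - 0.5
  d_epi <- as.matrix(EBImage::distmap(EBImage::Image(filled * 1))) - 0.5
  list(d_endo = pmax(d_endo, 0), d_epi = pmax(d_epi, 0))
}

#' Compute normalized myocardial coordinates for a study
#'
#' Estimates per-pixel radial/circumferential/long-axis coordinates on a grid
#' oversampled in-plane by `oversample` (contours, when stored with the study,
#' are rasterized directly at the fine grid; otherwise masks are
#' nearest-neighbor upsampled and contour distances replaced by distance
#' transforms). The LVOT wedge is removed where landmark pairs are present,
#' and slices whose long-axis coordinate falls outside [0, 1] are excluded.
#'
#' @param study a validated `myo_study`.
#' @param oversample integer in-plane oversampling factor (>= 1).
#' @param chirality passed to [circumferential_coordinate()].
#' @return a `myo_coordmap`: fine-grid arrays `r`, `c` (per-pixel), per-slice
#'   `z`, logical `valid` array, `oversample`, per-slice cavity centers.
#' @export
compute_coordinates <- function(study, oversample = 4L, chirality = 1) {
  stopifnot(inherits(study, "myo_study"), oversample >= 1)
  s <- as.integer(oversample)
  d <- dim(study$labels)
  nr <- d[1] * s; nc <- d[2] * s; ns <- d[3]
  g <- fine_grid_centers(d[1:2], s)
  r_f <- array(NA_real_, c(nr, nc, ns))
  c_f <- array(NA_real_, c(nr, nc, ns))
  valid <- array(FALSE, c(nr, nc, ns))
  centers <- matrix(NA_real_, ns, 2)
  lm <- study$landmarks
  z <- longaxis_coordinate(seq_len(ns), lm$apex_index, lm$base_index)
  myo <- study_mask(study, "myocardium")
  has_contours <- !is.null(study$contours)
  for (k in seq_len(ns)) {
    if (!any(myo[, , k])) next
    if (anyNA(lm$junction[k, ])) {
      rlang::abort(sprintf("slice %d has myocardium but no junction landmark", k))
    }
    endo <- epi <- NULL
    if (has_contours) {
      rows <- study$contours[study$contours$slice == k, ]
      if (any(rows$role == "endocardium")) endo <- rows$xy[rows$role == "endocardium"][[1]]
      if (any(rows$role == "epicardium")) epi <- rows$xy[rows$role == "epicardium"][[1]]
    }
    if (!is.null(endo) && !is.null(epi)) {
      in_epi <- rasterize_polygon(epi, d[1:2], s)
      in_endo <- rasterize_polygon(endo, d[1:2], s)
      myo_fine <- in_epi & !in_endo
    } else {
      myo_fine <- myo[rep(seq_len(d[1]), each = s), rep(seq_len(d[2]), each = s), k]
      # rep over rows/cols gives block upsampling only if applied per dim:
      myo_fine <- matrix(myo_fine, nrow = d[1] * s)
    }
    if (sum(myo_fine) <= s * s) {
      rlang::warn(sprintf("slice %d: degenerate (near single-pixel) myocardium dropped", k))
      next
    }
    center <- .cavity_center(endo, myo_fine, s)
    if (is.null(center)) {
      rlang::warn(sprintf("slice %d: no enclosed cavity; slice dropped", k))
      next
    }
    centers[k, ] <- center
    mask_k <- myo_fine
    if (!is.null(lm$lvot[[k]])) {
      mask_k <- exclude_lvot(mask_k, lm$lvot[[k]], center, px = g$x, py = g$y)
    }
    if (!is.null(endo) && !is.null(epi)) {
      r_k <- radial_coordinate(mask_k, endo, epi, px = g$x, py = g$y)
    } else {
      dd <- .mask_wall_distances(myo_fine)
      den <- dd$d_endo + dd$d_epi
      r_k <- matrix(NA_real_, nr, nc)
      ok <- mask_k & (den > 0)
      r_k[ok] <- pmin(1, pmax(0, dd$d_endo[ok] / den[ok]))
    }
    c_k <- circumferential_coordinate(mask_k, lm$junction[k, ], center,
                                      chirality = chirality, px = g$x, py = g$y)
    v_k <- mask_k & !is.na(r_k) & !is.na(c_k)
    if (z[k] < 0 || z[k] > 1) v_k[] <- FALSE   # beyond annotated apex/base
    r_f[, , k] <- r_k
    c_f[, , k] <- c_k
    valid[, , k] <- v_k
  }
  structure(list(r = r_f, c = c_f, z = z, valid = valid,
                 oversample = s, cavity_centers = centers,
                 base_dim = d),
            class = "myo_coordmap")
}

#' @export
print.myo_coordmap <- function(x, ...) {
  cat(sprintf("<myo_coordmap> %dx%dx%d at oversample %d; %d valid pixels\n",
              dim(x$r)[1], dim(x$r)[2], dim(x$r)[3], x$oversample, sum(x$valid)))
  invisible(x)
}
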