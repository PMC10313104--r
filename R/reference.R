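# The common reference geometry: a semi-ellipsoid left ventricle sampled on a
# stack of square slices, with its own analytic coordinate map.

#' Build the common reference geometry
#'
#' A semi-ellipsoid whose per-slice endocardial/epicardial radii shrink from
#' the base (z = 1, maximal radii) toward the apex (z = 0) along an ellipse
#' quarter-arc: radius(z) = R_base * sqrt(1 - ((1 - z) * apex_taper)^2), with
#' `apex_taper < 1` so the apical slice keeps a small nonzero wall. Defaults
#' are the standard analysis geometry: maximal endo/epi radii 30/50 px on 21
#' slices of 80 x 80 px. With these defaults the outermost part of the basal
#' epicardial ring extends beyond the slice grid and is cropped, so the most
#' basal rings are radially incomplete (the usual dashed/incomplete basal
#' myocardium of polar displays); missing outer radial cells are handled by
#' the lattice resampler.
#'
#' @param endo_radius,epi_radius maximal (basal) radii in pixels.
#' @param n_slices number of reference slices (apex = slice 1, base = last).
#' @param grid side length of the square slice grid in pixels.
#' @param apex_taper ellipse eccentricity parameter in (0, 1) controlling how
#'   fast radii shrink toward the apex.
#' @param junction_angle image-plane angle (degrees, anticlockwise with y up)
#'   of the reference LV-RV junction ray.
#' @return a `myo_reference`: logical `mask` array `[grid, grid, n_slices]`,
#'   analytic coordinate arrays `r`, `c`, per-slice `z` and radii, grid center.
#' @export
build_reference_geometry <- function(endo_radius = 30, epi_radius = 50,
                                     n_slices = 21, grid = 80,
                                     apex_taper = 0.98, junction_angle = 90) {
  if (endo_radius >= epi_radius) {
    rlang::abort("endo_radius must be smaller than epi_radius")
  }
  if (n_slices < 2) rlang::abort("n_slices must be >= 2")
  if (grid < 2 * endo_radius) {
    rlang::abort("grid must be large enough to contain the endocardial cavity")
  }
  if (apex_taper <= 0 || apex_taper >= 1) rlang::abort("apex_taper must be in (0, 1)")
  z <- (seq_len(n_slices) - 1) / (n_slices - 1)
  shrink <- sqrt(1 - ((1 - z) * apex_taper)^2)
  endo_k <- endo_radius * shrink
  epi_k <- epi_radius * shrink
  center <- c((grid - 1) / 2, (grid - 1) / 2)
  g <- fine_grid_centers(c(grid, grid), 1L)
  rho <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  th <- atan2(-(g$y - center[2]), g$x - center[1])
  th0 <- junction_angle * pi / 180
  c_plane <- circ_wrap((th - th0) / (2 * pi))
  mask <- array(FALSE, c(grid, grid, n_slices))
  r_f <- array(NA_real_, c(grid, grid, n_slices))
  c_f <- array(NA_real_, c(grid, grid, n_slices))
  for (k in seq_len(n_slices)) {
    m <- rho >= endo_k[k] & rho <= epi_k[k]
    mask[, , k] <- m
    rk <- matrix(NA_real_, grid, grid)
    rk[m] <- (rho[m] - endo_k[k]) / (epi_k[k] - endo_k[k])
    r_f[, , k] <- rk
    ck <- matrix(NA_real_, grid, grid)
    ck[m] <- c_plane[m]
    c_f[, , k] <- ck
  }
  structure(list(mask = mask, r = r_f, c = c_f, z = z,
                 endo_radius = endo_radius, epi_radius = epi_radius,
                 n_slices = n_slices, grid = grid, apex_taper = apex_taper,
                 junction_angle = junction_angle,
                 slice_radii = tibble::tibble(slice = seq_len(n_slices), z = z,
                                              endo = endo_k, epi = epi_k),
                 center = center),
            class = "myo_reference")
}

#' @export
print.myo_reference <- function(x, ...) {
  cat(sprintf("<myo_reference> %d slices of %dx%d px; basal endo/epi radii %g/%g px\n",
              x$n_slices, x$grid, x$grid, x$endo_radius, x$epi_radius))
  invisible(x)
}
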