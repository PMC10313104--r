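# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# study made of identical circular annuli (optionally tapered toward the apex)
make_annulus_study <- function(n_slices = 9, grid = 64, r_endo = 10, r_epi = 20,
                               jun_angle_deg = 0, apex_index = 1,
                               base_index = n_slices, taper = NULL,
                               n_vertices = 96, subject_id = "annulus") {
  ctr <- c((grid - 1) / 2, (grid - 1) / 2)
  rows <- list()
  endo_k <- epi_k <- numeric(n_slices)
  for (k in seq_len(n_slices)) {
    sh <- if (is.null(taper)) 1 else {
      z <- (k - apex_index) / (base_index - apex_index)
      sqrt(max(0.05, 1 - ((1 - min(max(z, 0), 1)) * taper)^2))
    }
    endo_k[k] <- r_endo * sh
    epi_k[k] <- r_epi * sh
    rows[[length(rows) + 1]] <- tibble::tibble(
      slice = k, role = c("endocardium", "epicardium"),
      xy = list(myoatlas:::circle_polygon(ctr, endo_k[k], n_vertices),
                myoatlas:::circle_polygon(ctr, epi_k[k], n_vertices)))
  }
  a <- jun_angle_deg * pi / 180
  rmid <- (r_endo + r_epi) / 2
  jun <- matrix(rep(c(ctr[1] + rmid * cos(a), ctr[2] - rmid * sin(a)), n_slices),
                ncol = 2, byrow = TRUE)
  lm <- landmark_set(jun, NULL, apex_index = apex_index, base_index = base_index)
  st <- rasterize_study(dplyr::bind_rows(rows), lm, c(grid, grid),
                        subject_id = subject_id)
  st$anatomy_truth <- list(centers = matrix(rep(ctr, n_slices), ncol = 2, byrow = TRUE),
                           endo = endo_k, epi = epi_k,
                           junction_angle = rep(jun_angle_deg, n_slices),
                           apex_index = apex_index, base_index = base_index)
  st
}

# implant an analytic wedge lesion (optionally with MVO core) into an annulus
# study built by make_annulus_study: infarct where the circumferential
# distance to c_center is within extent/2, r <= depth and z inside the span
implant_wedge <- function(st, c_center = 0.25, extent = 0.25, depth = 1,
                          z_span = c(0, 1), mvo_rel = NULL) {
  at <- st$anatomy_truth
  d <- dim(st$labels)
  g <- myoatlas:::fine_grid_centers(d[1:2], 1L)
  for (k in seq_len(d[3])) {
    z <- (k - at$apex_index) / (at$base_index - at$apex_index)
    if (z < z_span[1] || z > z_span[2]) next
    myo <- bitwAnd(st$labels[, , k], 1L) > 0
    idx <- which(myo)
    dx <- g$x[idx] - at$centers[k, 1]
    dy <- g$y[idx] - at$centers[k, 2]
    rho <- sqrt(dx^2 + dy^2)
    rr <- (rho - at$endo[k]) / (at$epi[k] - at$endo[k])
    cc <- myoatlas:::circ_wrap(
      (atan2(-dy, dx) - at$junction_angle[k] * pi / 180) / (2 * pi))
    dc <- myoatlas:::circ_diff(cc, c_center)
    inf <- abs(dc) <= extent / 2 & rr <= depth
    sl <- st$labels[, , k]
    sl[idx[inf]] <- bitwOr(sl[idx[inf]], 2L)
    if (!is.null(mvo_rel)) {
      mv <- inf & abs(dc) <= extent * mvo_rel / 2 & rr <= depth * mvo_rel
      sl[idx[mv]] <- bitwOr(sl[idx[mv]], bitwOr(4L, 8L))
    }
    st$labels[, , k] <- sl
  }
  st
}

# compact cohort spec used for statistical simulations: small grids and
# oversampling keep runtimes reasonable without changing the data model
sim_spec <- function(..., anatomy = list(), seed = 1) {
  compact <- list(grid = 48L, endo_radius_mean = 11, endo_radius_sd = 0.8,
                  wall_mean = 5, wall_sd = 0.5,
                  n_slices_mean = 10, n_slices_sd = 1,
                  n_slices_range = c(8L, 12L), n_vertices = 48L,
                  contour_jitter_sd = 0.2)
  cohort_spec(anatomy = utils::modifyList(compact, anatomy), ..., seed = seed)
}

sim_config <- function(...) {
  run_config(oversample = 2L, ...)
}

expect_tibble_cols <- function(x, cols) {
  testthat::expect_s3_class(x, "tbl_df")
  testthat::expect_true(all(cols %in% names(x)))
}
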