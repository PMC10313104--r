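# Myocardial coordinate fields against closed-form annulus oracles.

# analytic oracle for circular annuli centered at ctr with junction angle a0
annulus_oracle <- function(grid, oversample, ctr, r_endo, r_epi, a0 = 0) {
  g <- myoatlas:::fine_grid_centers(c(grid, grid), oversample)
  rho <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
  th <- atan2(-(g$y - ctr[2]), g$x - ctr[1])
  list(r = (rho - r_endo) / (r_epi - r_endo),
       c = ((th - a0) / (2 * pi)) %% 1)
}

circ_absdiff <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

test_that("radial and circumferential fields match the analytic annulus", {
  st <- make_annulus_study(n_slices = 5, grid = 64, r_endo = 10, r_epi = 20,
                           jun_angle_deg = 90)
  cm <- compute_coordinates(st, oversample = 4)
  orc <- annulus_oracle(64, 4, c(31.5, 31.5), 10, 20, pi / 2)
  v <- cm$valid[, , 3]
  expect_lt(max(abs(cm$r[, , 3][v] - orc$r[v])), 0.02)
  expect_lt(max(circ_absdiff(cm$c[, , 3][v], orc$c[v])), 1 / 720)
  # r in [0,1] everywhere valid
  expect_true(all(cm$r[cm$valid] >= 0 & cm$r[cm$valid] <= 1))
  expect_true(all(cm$c[cm$valid] >= 0 & cm$c[cm$valid] < 1))
})

test_that("radial coordinate hits the boundary and midwall values", {
  endo <- myoatlas:::circle_polygon(c(15.5, 15.5), 6, 128)
  epi <- myoatlas:::circle_polygon(c(15.5, 15.5), 12, 128)
  mask <- matrix(TRUE, 32, 32)
  r <- radial_coordinate(mask, endo, epi)
  g <- myoatlas:::fine_grid_centers(c(32, 32), 1)
  rho <- sqrt((g$x - 15.5)^2 + (g$y - 15.5)^2)
  mid <- which(abs(rho - 9) < 0.05)
  expect_true(all(abs(r[mid] - 0.5) < 0.02))
  on_endo <- which(abs(rho - 6) < 0.02)
  expect_true(all(r[on_endo] < 0.01))
})

test_that("circumferential coordinate anchors at the junction and wraps once", {
  st <- make_annulus_study(n_slices = 3, grid = 64, r_endo = 10, r_epi = 20,
                           jun_angle_deg = 0)
  cm <- compute_coordinates(st, oversample = 2)
  ck <- cm$c[, , 2]; v <- cm$valid[, , 2]
  g <- myoatlas:::fine_grid_centers(c(64, 64), 2)
  # pixels on the junction ray (angle ~0): c near 0; diametrically opposite: 0.5
  th <- atan2(-(g$y - 31.5), g$x - 31.5)
  near0 <- v & abs(th) < 0.02
  expect_true(all(circ_absdiff(ck[near0], 0) < 0.01))
  opp <- v & abs(abs(th) - pi) < 0.02
  expect_true(all(abs(ck[opp] - 0.5) < 0.01))
  # periodicity: sorted c values have a single large gap-free cycle
  expect_true(all(diff(sort(ck[v])) < 0.01))
})

test_that("long-axis coordinate is the normalized slice position", {
  expect_equal(longaxis_coordinate(5, 5, 16), 0)
  expect_equal(longaxis_coordinate(7, -1, 15), 0.5)
  expect_equal(longaxis_coordinate(8, 0, 16), 0.5)
  expect_error(longaxis_coordinate(3, 4, 4), "differ")
  # the mid slice of a 17-slice stack with one extrapolated basal slice
  expect_equal(longaxis_coordinate(11, 1, 17), 0.625)
})

test_that("slices beyond the annotated apex/base are excluded", {
  st <- make_annulus_study(n_slices = 9, grid = 48, r_endo = 8, r_epi = 15,
                           apex_index = 3, base_index = 7)
  cm <- compute_coordinates(st, oversample = 1)
  valid_slices <- which(apply(cm$valid, 3, any))
  expect_equal(valid_slices, 3:7)
})

test_that("LVOT wedge exclusion removes the expected angular fraction", {
  st <- make_annulus_study(n_slices = 1, grid = 64, r_endo = 10, r_epi = 20,
                           base_index = 2)
  ctr <- c(31.5, 31.5)
  mask <- study_mask(st, "myocardium")[, , 1]
  ang <- function(a) c(ctr[1] + 25 * cos(a), ctr[2] - 25 * sin(a))
  pair <- rbind(ang(0.3), ang(0.3 + 30 * pi / 180))
  excl <- exclude_lvot(mask, pair, ctr)
  frac <- 1 - sum(excl) / sum(mask)
  expect_equal(frac, 30 / 360, tolerance = 0.01)
  # absent pair: unchanged; identical landmarks: error; 180 degrees: ambiguous
  expect_error(exclude_lvot(mask, rbind(ang(1), ang(1)), ctr), "identical")
  pair180 <- rbind(ang(0), ang(pi))
  expect_error(exclude_lvot(mask, pair180, ctr), "side")
  expect_silent(exclude_lvot(mask, pair180, ctr, side = 1))
})

test_that("junction angle differences match a direct atan2 oracle", {
  ctr <- c(10, 10)
  expect_equal(junction_angle_difference(c(15, 10), c(15, 10), ctr), 0)
  # rays at 10 and 350 degrees (y up): wrap-around gives -20
  a <- c(10 + cos(10 * pi / 180), 10 - sin(10 * pi / 180))
  b <- c(10 + cos(350 * pi / 180), 10 - sin(350 * pi / 180))
  expect_equal(junction_angle_difference(b, a, ctr), -20, tolerance = 1e-9)
  set.seed(31)
  for (i in 1:50) {
    p1 <- ctr + stats::rnorm(2); p2 <- ctr + stats::rnorm(2)
    got <- junction_angle_difference(p1, p2, ctr)
    th1 <- atan2(-(p1[2] - ctr[2]), p1[1] - ctr[1])
    th2 <- atan2(-(p2[2] - ctr[2]), p2[1] - ctr[1])
    want <- (th1 - th2) * 180 / pi
    want <- want - 360 * floor(want / 360)
    if (want > 180) want <- want - 360
    expect_equal(got, want, tolerance = 1e-9)
    expect_true(got > -180 && got <= 180)
  }
  expect_equal(slice_annotation_difference(5, 5), 0)
  expect_equal(slice_annotation_difference(5, 7), -2)
  expect_equal(slice_annotation_difference(-1, 0), -1)
})

test_that("coordinates are translation invariant and rotation equivariant", {
  base <- make_annulus_study(n_slices = 3, grid = 64, r_endo = 9, r_epi = 17,
                             jun_angle_deg = 40)
  cm0 <- compute_coordinates(base, oversample = 2)
  # translate anatomy and landmarks together by (3, -2) pixels
  shift <- c(3, -2)
  contours <- base$contours
  contours$xy <- lapply(contours$xy, function(m) sweep(m, 2, -shift))
  lm <- base$landmarks
  lm$junction <- sweep(lm$junction, 2, -shift)
  st_t <- rasterize_study(contours, lm, c(64, 64))
  cm1 <- compute_coordinates(st_t, oversample = 2)
  # an anatomical point at fine index (i, j) moves to (i + 2*dy, j + 2*dx)
  v0 <- which(cm0$valid[, , 2], arr.ind = TRUE)
  i1 <- v0[, 1] + 2 * shift[2]; j1 <- v0[, 2] + 2 * shift[1]
  r0 <- cm0$r[, , 2][v0]; r1 <- cm1$r[, , 2][cbind(i1, j1)]
  c0 <- cm0$c[, , 2][v0]; c1 <- cm1$c[, , 2][cbind(i1, j1)]
  expect_gt(sum(!is.na(r1)), 1000)
  ok <- !is.na(r1)
  expect_lt(max(abs(r0[ok] - r1[ok])), 1e-9)
  expect_lt(max(circ_absdiff(c0[ok], c1[ok])), 1e-9)

  # co-rotating the (circular) anatomy and the junction by 60 degrees shifts
  # the circumferential field by exactly -60/360 at fixed pixels, i.e. the
  # field is unchanged at material points
  st_r <- make_annulus_study(n_slices = 3, grid = 64, r_endo = 9, r_epi = 17,
                             jun_angle_deg = 40 + 60)
  cm2 <- compute_coordinates(st_r, oversample = 2)
  v <- cm0$valid[, , 2] & cm2$valid[, , 2]
  d <- (cm2$c[, , 2][v] - cm0$c[, , 2][v]) %% 1
  expect_lt(max(circ_absdiff(d, (-60 / 360) %% 1)), 1e-9)
  expect_lt(diff(range(myoatlas:::circ_diff(d, (-60 / 360) %% 1))), 1e-9)
})

test_that("oversampling reduces the scattered-sample reconstruction error on a thin wall", {
  # the oversampling exists to prevent artifacts when few pixels cover the
  # wall: measure how well the (c, r) samples of a 3-px-thick annulus
  # reconstruct the analytic radial field at dense query points
  recon_err <- function(os) {
    st <- make_annulus_study(n_slices = 3, grid = 48, r_endo = 9, r_epi = 12,
                             n_vertices = 192)
    cm <- compute_coordinates(st, oversample = os)
    idx <- which(cm$valid[, , 2])
    grid <- myoatlas:::.slice_value_grid(cm$r[, , 2][idx], cm$c[, , 2][idx],
                                         cm$r[, , 2][idx])
    set.seed(1)
    rq <- stats::runif(4000); cq <- stats::runif(4000)
    mean(abs(myoatlas:::.query_value_grid(grid, rq, cq) - rq))
  }
  e1 <- recon_err(1); e2 <- recon_err(2); e4 <- recon_err(4)
  expect_lt(e2, e1)
  expect_lt(e4, e2)
  expect_lt(e4, 0.03)
})

test_that("mask-only studies (bundle round trip) still yield usable coordinates", {
  st <- make_annulus_study(n_slices = 3, grid = 64, r_endo = 10, r_epi = 20)
  stem <- file.path(withr::local_tempdir(), "s1")
  write_bundle(st, stem)
  st2 <- read_bundle(stem)   # contours lost; distance-transform path
  cm <- compute_coordinates(st2, oversample = 2)
  orc <- annulus_oracle(64, 2, c(31.5, 31.5), 10, 20)
  v <- cm$valid[, , 2]
  expect_gt(sum(v), 1000)
  expect_lt(mean(abs(cm$r[, , 2][v] - orc$r[v])), 0.06)
  expect_lt(stats::quantile(circ_absdiff(cm$c[, , 2][v], orc$c[v]), 0.99), 0.02)
})
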