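# The synthetic cohort generator: determinism, validity, priors and
# ground-truth recovery.

test_that("cohorts are reproducible and per-subject streams are stable", {
  spec <- sim_spec(n_arms = c(immediate = 4, delayed = 3), seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_equal(length(a$studies), 7)
  expect_equal(sum(a$cohort$treatment == "immediate"), 4)
  for (i in seq_along(a$studies)) {
    expect_identical(a$studies[[i]]$labels, b$studies[[i]]$labels)
  }
  expect_equal(a$cohort, b$cohort)
  # extending the cohort never perturbs existing subjects
  spec2 <- sim_spec(n_arms = c(immediate = 6, delayed = 3), seed = 5)
  c2 <- generate_cohort(spec2)
  expect_identical(c2$studies[[3]]$labels, a$studies[[3]]$labels)
})

test_that("every generated study passes validation with zero violations", {
  co <- generate_cohort(sim_spec(n_arms = c(immediate = 5, delayed = 5), seed = 8))
  for (st in co$studies) {
    v <- validate_study(st)
    expect_true(v$pass)
    expect_equal(nrow(v$issues), 0)
  }
})

test_that("anatomy priors are respected", {
  # zero-variance priors give identical anatomies
  spec0 <- sim_spec(n_arms = c(immediate = 3, delayed = 0),
                    anatomy = list(endo_radius_sd = 0, wall_sd = 0,
                                   n_slices_sd = 0, extra_sd = 0, extend_prob = 0,
                                   junction_angle_sd = 0, junction_jitter_sd = 0,
                                   center_offset_sd = 0, center_drift_sd = 0,
                                   contour_jitter_sd = 0),
                    no_infarct_prob = 0, seed = 2)
  co0 <- generate_cohort(spec0)
  expect_identical(co0$studies[[1]]$labels > 0L, co0$studies[[2]]$labels > 0L)
  # slice-count prior: empirical mean near 17 over many draws (default prior)
  spec1 <- cohort_spec(n_arms = c(immediate = 100, delayed = 0), seed = 3)
  set.seed(3)
  ns <- replicate(200, {
    n <- round(stats::rnorm(1, spec1$anatomy$n_slices_mean, spec1$anatomy$n_slices_sd))
    min(max(n, spec1$anatomy$n_slices_range[1]), spec1$anatomy$n_slices_range[2])
  })
  expect_lt(abs(mean(ns) - 17), 0.5)
  n_obs <- vapply(generate_cohort(sim_spec(
    n_arms = c(immediate = 30, delayed = 0),
    anatomy = list(n_slices_mean = 17, n_slices_sd = 2,
                   n_slices_range = c(10L, 24L), grid = 64L,
                   endo_radius_mean = 13),
    seed = 4))$studies, function(s) dim(s$labels)[3], numeric(1))
  expect_lt(abs(mean(n_obs) - 17), 1.5)
  # coverage probability 0: apex/base always inside the acquired stack
  co_in <- generate_cohort(sim_spec(n_arms = c(immediate = 6, delayed = 0),
                                    anatomy = list(extend_prob = 0), seed = 6))
  for (st in co_in$studies) {
    expect_gte(st$landmarks$apex_index, 1)
    expect_lte(st$landmarks$base_index, dim(st$labels)[3])
  }
})

test_that("lesions honor their construction: wedge, depth and MVO nesting", {
  spec <- sim_spec(n_arms = c(immediate = 6, delayed = 0),
                   lesion = list(taper = "flat",
                                 mvo_prob_early = 1, mvo_prob_late = 1),
                   no_infarct_prob = 0, seed = 9)
  co <- generate_cohort(spec)
  for (st in co$studies) {
    inf <- study_mask(st, "infarct")
    myo <- study_mask(st, "myocardium")
    emvo <- study_mask(st, "early_mvo")
    expect_true(all(myo[inf]))
    expect_gt(sum(emvo), 0)                 # MVO probability 1
    expect_true(all(inf[emvo]))             # nested in the infarct
    expect_lt(sum(emvo), sum(inf))          # strictly smaller
  }
  expect_true(all(co$truth$has_early_mvo))
})

test_that("full-depth full-span wedges give transmurality 1 inside and 0 outside", {
  spec <- sim_spec(
    n_arms = c(immediate = 1, delayed = 0),
    territory_mix = c(RCA = 1),
    lesion = list(params = tibble::tibble(
      territory = "RCA", c_center = 0.5, c_center_sd = 0,
      extent_mean = 0.25, extent_sd = 0, depth_mean = 1, depth_sd = 0,
      z_lo = 0, z_hi = 1, z_sd = 0), taper = "flat",
      mvo_prob_early = 0, mvo_prob_late = 0),
    anatomy = list(contour_jitter_sd = 0, junction_jitter_sd = 0,
                   center_drift_sd = 0, extend_prob = 0),
    no_infarct_prob = 0, seed = 12)
  co <- generate_cohort(spec)
  cm <- compute_coordinates(co$studies[[1]], oversample = 2)
  lat <- native_lattice(co$studies[[1]], cm, "infarct")
  tm <- transmurality_map(lat)
  cc <- (seq_len(24) - 0.5) / 24
  # strictly interior / exterior columns (one full bin away from the edges,
  # which carry sub-pixel discretization jitter)
  inside <- abs(cc - 0.5) < 0.25 / 2 - 1 / 24
  outside <- abs(cc - 0.5) > 0.25 / 2 + 1 / 24
  expect_true(all(tm[inside, ] > 0.95, na.rm = TRUE))
  expect_true(all(tm[outside, ] < 0.05, na.rm = TRUE))
})

test_that("generated lesion parameters are recovered by the analysis pipeline", {
  # noiseless, flat-tapered wedge aligned to the lattice bins
  spec <- sim_spec(
    n_arms = c(immediate = 3, delayed = 0),
    territory_mix = c(LCX = 1),
    lesion = list(params = tibble::tibble(
      territory = "LCX", c_center = 10 / 24, c_center_sd = 0,
      extent_mean = 0.25, extent_sd = 0, depth_mean = 0.6, depth_sd = 0,
      z_lo = 0, z_hi = 1, z_sd = 0), taper = "flat",
      mvo_prob_early = 0, mvo_prob_late = 0),
    anatomy = list(contour_jitter_sd = 0, junction_jitter_sd = 0,
                   center_drift_sd = 0, extend_prob = 0),
    no_infarct_prob = 0, seed = 21)
  co <- generate_cohort(spec)
  for (i in seq_along(co$studies)) {
    st <- co$studies[[i]]
    cm <- compute_coordinates(st, oversample = 2)
    lat <- native_lattice(st, cm, "infarct")
    truth <- co$truth[i, ]
    # circumferential center within 1/48
    got_c <- infarct_center(lat)
    d <- abs(got_c - truth$c_center); d <- min(d, 1 - d)
    expect_lt(d, 1 / 48)
    # extent within 1/24: columns whose location value is substantial
    loc <- location_map(lat)
    ext <- sum(apply(loc > 0.5, 1, any, na.rm = TRUE)) / 24
    expect_lt(abs(ext - truth$extent), 1 / 24 + 1e-9)
    # transmurality within 0.05 of the drawn depth
    gl <- compute_globals(st, cmap = cm)
    expect_lt(abs(gl$transmurality_pct / 100 - truth$depth), 0.05)
  }
})

test_that("arm effects are injected exactly where configured", {
  eff <- list(arm = "delayed", depth_delta = 0.3,
              c_range = c(0.375, 0.625), z_range = c(0.2, 0.8))
  spec <- sim_spec(
    n_arms = c(immediate = 2, delayed = 2),
    territory_mix = c(RCA = 1),
    lesion = list(params = tibble::tibble(
      territory = "RCA", c_center = 0.5, c_center_sd = 0,
      extent_mean = 0.5, extent_sd = 0, depth_mean = 0.4, depth_sd = 0,
      z_lo = 0, z_hi = 1, z_sd = 0), taper = "flat",
      mvo_prob_early = 0, mvo_prob_late = 0),
    anatomy = list(contour_jitter_sd = 0, junction_jitter_sd = 0,
                   center_drift_sd = 0, extend_prob = 0, n_slices_sd = 0,
                   endo_radius_sd = 0, wall_sd = 0, junction_angle_sd = 0),
    effects = eff, no_infarct_prob = 0, seed = 30)
  co <- generate_cohort(spec)
  expect_equal(co$truth$effect_applied, co$truth$treatment == "delayed")
  lat_of <- function(st) {
    cm <- compute_coordinates(st, oversample = 2)
    native_lattice(st, cm, "infarct")
  }
  arm <- co$cohort$treatment
  tm_imm <- transmurality_map(lat_of(co$studies[[which(arm == "immediate")[1]]]))
  tm_del <- transmurality_map(lat_of(co$studies[[which(arm == "delayed")[1]]]))
  cc <- (seq_len(24) - 0.5) / 24
  in_eff <- cc > 0.375 + 1 / 48 & cc < 0.625 - 1 / 48
  out_wedge <- abs(cc - 0.5) < 0.5 / 2 - 1 / 24 & !in_eff
  mid_z <- 4:7
  expect_gt(mean(tm_del[in_eff, mid_z] - tm_imm[in_eff, mid_z], na.rm = TRUE), 0.2)
  expect_lt(abs(mean(tm_del[out_wedge, mid_z] - tm_imm[out_wedge, mid_z], na.rm = TRUE)), 0.1)
})
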