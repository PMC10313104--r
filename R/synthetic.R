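# Synthetic cohort generation: multi-slice annular anatomies with wedge-shaped
# territory lesions and optional MVO cores, with known ground truth for every
# downstream stage.

#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the study conditions of an acute STEMI imaging cohort:
#' two treatment arms of 65 and 58 subjects, four culprit territories, stacks
#' of about 17 +/- 2 short-axis slices at 1.5625 mm in-plane / 5 mm slice
#' spacing with about one slice of the ventricle lying outside the acquired
#' stack, and territory-specific wedge lesions with cosine-tapered transmural
#' depth and nested MVO cores. Override any component by passing a partial
#' list; it is merged over the defaults.
#'
#' @param n_arms named integer: subjects per treatment arm.
#' @param territory_mix named probabilities over `LAD_mid`, `LAD_prox`,
#'   `LCX`, `RCA`.
#' @param anatomy,lesion,effects,noise partial lists merged over the defaults
#'   (see the built object for the available fields).
#' @param no_infarct_prob probability of a subject without any infarct.
#' @param seed master seed; the same spec + seed reproduces the cohort
#'   bitwise, and each subject draws from an independent stream keyed by
#'   (seed, subject index) so extending the cohort never perturbs existing
#'   subjects.
#' @return a `myo_cohort_spec` list.
#' @export
cohort_spec <- function(n_arms = c(immediate = 65, delayed = 58),
                        territory_mix = c(LAD_mid = 0.20, LAD_prox = 0.16,
                                          LCX = 0.14, RCA = 0.50),
                        anatomy = list(), lesion = list(), effects = list(),
                        noise = list(), no_infarct_prob = 1 / 123, seed = 1L) {
  anatomy_def <- list(
    grid = 64L, spacing = c(inplane = 1.5625, slice = 5),
    endo_radius_mean = 15, endo_radius_sd = 1.2,
    wall_mean = 6.5, wall_sd = 0.7,
    n_slices_mean = 17, n_slices_sd = 2, n_slices_range = c(8L, 24L),
    extra_mean = 0.5, extra_sd = 0.7, extend_prob = 0.6,
    junction_angle_mean = 120, junction_angle_sd = 8, junction_jitter_sd = 3,
    center_offset_sd = 1, center_drift_sd = 0.3, contour_jitter_sd = 0.25,
    apex_taper = 0.95, n_vertices = 60L, oversample_hint = 4L
  )
  lesion_def <- list(
    # circumferential centers: anterior/lateral/inferior convention relative
    # to an anterior LV-RV junction
    params = tibble::tibble(
      territory = c("LAD_mid", "LAD_prox", "LCX", "RCA"),
      c_center = c(0.17, 0.17, 0.46, 0.79),
      c_center_sd = 0.03,
      extent_mean = c(0.28, 0.38, 0.24, 0.30),
      extent_sd = 0.05,
      depth_mean = c(0.62, 0.70, 0.62, 0.58),
      depth_sd = 0.12,
      z_lo = c(0.00, 0.00, 0.15, 0.10),
      z_hi = c(0.60, 0.85, 0.75, 0.80),
      z_sd = 0.05
    ),
    taper = "cosine",
    mvo_prob_early = 0.75, mvo_prob_late = 0.55,
    mvo_rel_extent = 0.45, mvo_rel_depth = 0.6
  )
  effects_def <- list(arm = NULL, depth_delta = 0, extent_delta = 0,
                      c_range = NULL, z_range = NULL, territories = NULL)
  noise_def <- list(label_flip_rate = 0)
  spec <- list(
    n_arms = n_arms,
    territory_mix = territory_mix / sum(territory_mix),
    anatomy = utils::modifyList(anatomy_def, anatomy),
    lesion = utils::modifyList(lesion_def, lesion),
    effects = utils::modifyList(effects_def, effects),
    noise = utils::modifyList(noise_def, noise),
    no_infarct_prob = no_infarct_prob,
    seed = as.integer(seed)
  )
  stopifnot(all(spec$territory_mix >= 0), spec$no_infarct_prob >= 0,
            spec$no_infarct_prob <= 1,
            all(spec$lesion$params$extent_mean > 0),
            all(spec$lesion$params$extent_mean <= 1),
            all(spec$lesion$params$depth_mean > 0),
            all(spec$lesion$params$depth_mean <= 1))
  structure(spec, class = "myo_cohort_spec")
}

.subject_seed <- function(master, i) {
  as.integer((as.numeric(master) * 100003 + i * 10007) %% 2147483629)
}

# smooth circular jitter for contour vertices
.smooth_circular_noise <- function(n, sd, window = 7L) {
  if (sd <= 0) return(numeric(n))
  e <- stats::rnorm(n, sd = sd)
  k <- rep(1 / window, window)
  e3 <- c(e, e, e)
  sm <- stats::filter(e3, k, circular = FALSE)[(n + 1):(2 * n)]
  as.numeric(sm) * sqrt(window)   # restore marginal sd after averaging
}

#' Sample one synthetic anatomy (myocardium + landmarks)
#'
#' Draws a stack of near-circular annuli tapering toward the apex, a junction
#' landmark on every slice and apex/base indices that may extend beyond the
#' acquired stack, then rasterizes the contours into a `myo_study` (lesion
#' channels empty). The per-slice circle parameters are stored in
#' `$anatomy_truth` for analytic checks.
#'
#' @param spec a [cohort_spec()].
#' @param subject_id identifier.
#' @param covariates covariate list stored with the study.
#' @return a `myo_study` with an `anatomy_truth` element attached.
#' @export
sample_anatomy <- function(spec, subject_id = "subject", covariates = list()) {
  a <- spec$anatomy
  for (attempt in 1:25) {
    endo_base <- stats::rnorm(1, a$endo_radius_mean, a$endo_radius_sd)
    wall <- stats::rnorm(1, a$wall_mean, a$wall_sd)
    if (endo_base > 3 && wall > 2 * a$contour_jitter_sd + 1.5 &&
        endo_base + wall < a$grid / 2 - 2) break
    if (attempt == 25) rlang::abort("infeasible anatomy priors (wall collapses)")
  }
  n_acq <- as.integer(round(stats::rnorm(1, a$n_slices_mean, a$n_slices_sd)))
  n_acq <- min(max(n_acq, a$n_slices_range[1]), a$n_slices_range[2])
  extra <- function() {
    if (stats::runif(1) < a$extend_prob) max(0, round(stats::rnorm(1, a$extra_mean / a$extend_prob, a$extra_sd))) else 0
  }
  apex_index <- 1 - extra()
  base_index <- n_acq + extra()
  jun_angle <- stats::rnorm(1, a$junction_angle_mean, a$junction_angle_sd)
  c0 <- (a$grid - 1) / 2 + stats::rnorm(2, 0, a$center_offset_sd)
  centers <- matrix(NA_real_, n_acq, 2)
  slice_rows <- list()
  junction <- matrix(NA_real_, n_acq, 2)
  endo_k <- epi_k <- jun_k <- numeric(n_acq)
  drift <- c(0, 0)
  for (k in seq_len(n_acq)) {
    z_k <- (k - apex_index) / (base_index - apex_index)
    shrink <- sqrt(pmax(0.02, 1 - ((1 - min(max(z_k, 0), 1)) * a$apex_taper)^2))
    endo_k[k] <- endo_base * shrink
    epi_k[k] <- endo_k[k] + wall
    drift <- drift + stats::rnorm(2, 0, a$center_drift_sd)
    centers[k, ] <- c0 + drift
    th <- seq(0, 2 * pi, length.out = a$n_vertices + 1L)[-(a$n_vertices + 1L)]
    je <- .smooth_circular_noise(a$n_vertices, a$contour_jitter_sd)
    jp <- .smooth_circular_noise(a$n_vertices, a$contour_jitter_sd)
    endo_xy <- cbind(centers[k, 1] + (endo_k[k] + je) * cos(th),
                     centers[k, 2] - (endo_k[k] + je) * sin(th))
    epi_xy <- cbind(centers[k, 1] + (epi_k[k] + jp) * cos(th),
                    centers[k, 2] - (epi_k[k] + jp) * sin(th))
    slice_rows[[length(slice_rows) + 1]] <-
      tibble::tibble(slice = k, role = c("endocardium", "epicardium"),
                     xy = list(endo_xy, epi_xy))
    jun_k[k] <- jun_angle + stats::rnorm(1, 0, a$junction_jitter_sd)
    rmid <- (endo_k[k] + epi_k[k]) / 2
    junction[k, ] <- c(centers[k, 1] + rmid * cos(jun_k[k] * pi / 180),
                       centers[k, 2] - rmid * sin(jun_k[k] * pi / 180))
  }
  contours <- dplyr::bind_rows(slice_rows)
  lm <- landmark_set(junction, NULL, apex_index, base_index)
  study <- rasterize_study(contours, lm, c(a$grid, a$grid), a$spacing,
                           subject_id = subject_id, covariates = covariates)
  study$anatomy_truth <- list(centers = centers, endo = endo_k, epi = epi_k,
                              junction_angle = jun_k, apex_index = apex_index,
                              base_index = base_index, wall = wall,
                              endo_base = endo_base)
  study
}

# cosine depth taper from wedge center to edges
.depth_taper <- function(dc, extent, kind) {
  if (kind == "flat") return(rep(1, length(dc)))
  pmax(0, cos(pi * dc / extent))^0.5
}

#' Implant a wedge lesion into a synthetic anatomy
#'
#' The infarct is the set of myocardial pixels whose circumferential
#' coordinate lies in the wedge, long-axis coordinate in the slice span, and
#' radial coordinate below the transmural depth (growing outward from the
#' endocardium; depth tapers toward the wedge edges unless `taper = "flat"`).
#' MVO cores are concentric sub-wedges nested inside the infarct by
#' construction.
#'
#' @param study a [sample_anatomy()] output (needs `anatomy_truth`).
#' @param params one-row lesion parameter list/tibble: `c_center`, `extent`,
#'   `depth`, `z_lo`, `z_hi`, optional `emvo`/`lmvo` logicals and
#'   `mvo_rel_extent`, `mvo_rel_depth`, `taper`.
#' @param effect optional effect list (`depth_delta`, `extent_delta`,
#'   `c_range`, `z_range`) applied to this subject.
#' @return the study with lesion bits set and `lesion_truth` attached.
#' @export
sample_lesion <- function(study, params, effect = NULL) {
  at <- study$anatomy_truth
  if (is.null(at)) rlang::abort("sample_lesion needs a synthetic anatomy with anatomy_truth")
  d <- dim(study$labels)
  g <- fine_grid_centers(d[1:2], 1L)
  extent <- params$extent + if (!is.null(effect)) effect$extent_delta else 0
  extent <- min(max(extent, 0.02), 1)
  taper <- if (!is.null(params$taper)) params$taper else "cosine"
  for (k in seq_len(d[3])) {
    z_k <- (k - at$apex_index) / (at$base_index - at$apex_index)
    if (z_k < params$z_lo || z_k > params$z_hi) next
    myo <- bitwAnd(study$labels[, , k], MYO_BIT) > 0
    idx <- which(myo)
    if (!length(idx)) next
    dx <- g$x[idx] - at$centers[k, 1]
    dy <- g$y[idx] - at$centers[k, 2]
    rho <- sqrt(dx^2 + dy^2)
    rr <- (rho - at$endo[k]) / (at$epi[k] - at$endo[k])
    th <- atan2(-dy, dx)
    cc <- circ_wrap((th - at$junction_angle[k] * pi / 180) / (2 * pi))
    dc <- circ_diff(cc, params$c_center)
    depth_eff <- params$depth * .depth_taper(dc, extent, taper)
    if (!is.null(effect) && effect$depth_delta != 0) {
      in_c <- if (is.null(effect$c_range)) TRUE else
        circ_wrap(cc - effect$c_range[1]) <= circ_wrap(effect$c_range[2] - effect$c_range[1])
      in_z <- if (is.null(effect$z_range)) TRUE else
        (z_k >= effect$z_range[1] & z_k <= effect$z_range[2])
      depth_eff <- pmin(1, depth_eff + effect$depth_delta * in_c * in_z)
    }
    inf <- abs(dc) <= extent / 2 & rr <= depth_eff
    sl <- study$labels[, , k]
    sl[idx[inf]] <- bitwOr(sl[idx[inf]], INF_BIT)
    for (ch in c("emvo", "lmvo")) {
      if (!isTRUE(params[[ch]])) next
      rel_e <- params$mvo_rel_extent
      rel_d <- params$mvo_rel_depth
      mv <- inf & abs(dc) <= extent * rel_e / 2 & rr <= depth_eff * rel_d &
        z_k >= params$z_lo + 0.05 & z_k <= params$z_hi - 0.05
      bit <- if (ch == "emvo") EMVO_BIT else LMVO_BIT
      sl[idx[mv]] <- bitwOr(sl[idx[mv]], bit)
    }
    study$labels[, , k] <- sl
  }
  study$lesion_truth <- list(c_center = params$c_center, extent = extent,
                             depth = params$depth, z_lo = params$z_lo,
                             z_hi = params$z_hi, taper = taper,
                             effect = effect)
  study
}

.apply_label_noise <- function(study, flip_rate) {
  if (flip_rate <= 0) return(study)
  myo <- study_mask(study, "myocardium")
  flips <- myo & (array(stats::runif(length(myo)), dim = dim(myo)) < flip_rate)
  study$labels[flips] <- bitwXor(study$labels[flips], INF_BIT)
  # restore nesting: MVO only inside infarct
  inf <- study_mask(study, "infarct")
  for (bit in c(EMVO_BIT, LMVO_BIT)) {
    mv <- bitwAnd(study$labels, bit) > 0
    drop <- mv & !inf
    study$labels[drop] <- bitwAnd(study$labels[drop], bitwNot(bit))
  }
  study
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws anatomies, territory assignments, lesions (with any configured arm
#' effects), covariates and label noise for every subject of the spec, each
#' from an independent random stream keyed by (master seed, subject index).
#'
#' @param spec a [cohort_spec()].
#' @return a `myo_cohort`: `studies` (list of `myo_study`), `cohort`
#'   (covariate tibble), `truth` (per-subject drawn lesion parameters),
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "myo_cohort_spec"))
  arms <- rep(names(spec$n_arms), spec$n_arms)
  n <- length(arms)
  terr_levels <- names(spec$territory_mix)
  studies <- vector("list", n)
  cohort_rows <- truth_rows <- vector("list", n)
  lp <- spec$lesion$params
  for (i in seq_len(n)) {
    set.seed(.subject_seed(spec$seed, i))
    sid <- sprintf("sub%03d", i)
    territory <- sample(terr_levels, 1, prob = spec$territory_mix)
    covs <- list(
      treatment = arms[i], territory = territory,
      age = round(stats::rnorm(1, 62, 12), 1),
      sex = sample(c("male", "female"), 1, prob = c(0.8, 0.2)),
      bmi = round(stats::rnorm(1, 26.4, 3.6), 1),
      lvef = round(stats::rnorm(1, 53, 9), 1),
      diabetes = stats::runif(1) < 0.15,
      smoking = stats::runif(1) < 0.45,
      delay_to_pci_h = round(stats::rlnorm(1, log(4), 0.5), 1)
    )
    study <- sample_anatomy(spec, subject_id = sid, covariates = covs)
    p <- lp[lp$territory == territory, ]
    draw <- list(
      c_center = circ_wrap(stats::rnorm(1, p$c_center, p$c_center_sd)),
      extent = min(max(stats::rnorm(1, p$extent_mean, p$extent_sd), 0.05), 1),
      depth = min(max(stats::rnorm(1, p$depth_mean, p$depth_sd), 0.05), 1),
      z_lo = max(0, p$z_lo + stats::rnorm(1, 0, p$z_sd)),
      z_hi = min(1, p$z_hi + stats::rnorm(1, 0, p$z_sd)),
      emvo = stats::runif(1) < spec$lesion$mvo_prob_early,
      lmvo = stats::runif(1) < spec$lesion$mvo_prob_late,
      mvo_rel_extent = spec$lesion$mvo_rel_extent,
      mvo_rel_depth = spec$lesion$mvo_rel_depth,
      taper = spec$lesion$taper
    )
    has_infarct <- stats::runif(1) >= spec$no_infarct_prob
    effect <- NULL
    eff <- spec$effects
    if (!is.null(eff$arm) && arms[i] == eff$arm &&
        (is.null(eff$territories) || territory %in% eff$territories)) {
      effect <- eff
    }
    if (has_infarct) {
      study <- sample_lesion(study, draw, effect = effect)
      study <- .apply_label_noise(study, spec$noise$label_flip_rate)
    }
    studies[[i]] <- study
    cohort_rows[[i]] <- tibble::as_tibble(c(list(subject_id = sid), covs))
    truth_rows[[i]] <- tibble::tibble(
      subject_id = sid, treatment = arms[i], territory = territory,
      has_infarct = has_infarct,
      c_center = draw$c_center, extent = draw$extent, depth = draw$depth,
      z_lo = draw$z_lo, z_hi = draw$z_hi,
      has_early_mvo = has_infarct && draw$emvo,
      has_late_mvo = has_infarct && draw$lmvo,
      effect_applied = !is.null(effect)
    )
  }
  structure(list(studies = studies,
                 cohort = dplyr::bind_rows(cohort_rows),
                 truth = dplyr::bind_rows(truth_rows),
                 spec = spec),
            class = "myo_cohort")
}

#' @export
print.myo_cohort <- function(x, ...) {
  cat(sprintf("<myo_cohort> %d subjects (%s)\n", length(x$studies),
              paste(sprintf("%s: %d", names(x$spec$n_arms), x$spec$n_arms),
                    collapse = ", ")))
  invisible(x)
}

#' Write a generated cohort to disk as study bundles + cohort CSV
#'
#' @param cohort a `myo_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in cohort$studies) {
    write_bundle(st, file.path(dir, st$subject_id))
  }
  write_cohort_table(cohort$cohort, file.path(dir, "cohort.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
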