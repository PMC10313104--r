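# Global lesion descriptors, computed identically in native and standardized
# geometry from a (c, z, r) analysis lattice with equal cell weights.

#' Global lesion descriptors
#'
#' Computes, for one subject and one lesion channel: area (% of the
#' myocardium), transmurality (%, averaged over infarct-bearing columns only,
#' i.e. excluding the preserved myocardium; missing when no lesion exists) and
#' endocardial surface area (% of columns whose innermost radial bin carries
#' lesion). Definitions are identical in native geometry (the subject's own
#' coordinates binned by [native_lattice()]) and standardized geometry (the
#' warped pattern binned by [resample_to_lattice()]); cells are weighted
#' equally. MVO areas are reported when the corresponding lattices are given.
#'
#' @param x a `myo_lattice`, a `myo_study` (native mode; coordinates computed
#'   on the fly unless `cmap` is given) or a `myo_pattern` (standardized mode,
#'   requires `ref`).
#' @param ... passed on to methods.
#' @return one-row tibble: `subject_id`, `geometry`, `infarct_area_pct`,
#'   `early_mvo_area_pct`, `late_mvo_area_pct`, `transmurality_pct`,
#'   `endocardial_surface_pct`.
#' @export
compute_globals <- function(x, ...) UseMethod("compute_globals")

# lesion presence threshold for "infarct-bearing" columns; warped channels are
# soft, so exact zero is too strict at lesion borders.
GLOBALS_EPS <- 0.05

.lattice_globals <- function(lat, eps = GLOBALS_EPS) {
  ok <- !is.na(lat)
  if (!any(ok)) rlang::abort("lattice is entirely missing (empty myocardium?)")
  area <- 100 * mean(lat[ok])
  trans_col <- transmurality_map(lat)            # [n_c, n_z]
  covered <- !is.na(trans_col)
  bearing <- covered & trans_col > eps
  trans <- if (any(bearing)) 100 * mean(trans_col[bearing]) else NA_real_
  # endocardial surface: mean of the innermost covered radial-bin value over
  # columns. For binary lattices this is the fraction of infarct-bearing
  # endocardial columns; for soft (warped) lattices it is the expected
  # subtended fraction, which keeps the estimator consistent across modes
  # instead of letting interpolation leak inflate a thresholded count.
  n_c <- dim(lat)[1]; n_z <- dim(lat)[2]; n_r <- dim(lat)[3]
  endo_val <- matrix(NA_real_, n_c, n_z)
  for (k in seq_len(n_z)) {
    for (j in seq_len(n_c)) {
      col <- lat[j, k, ]
      w <- which(!is.na(col))
      if (length(w)) endo_val[j, k] <- col[w[1]]
    }
  }
  endo <- 100 * mean(endo_val[covered])
  list(area = area, trans = trans, endo = endo)
}

#' @rdname compute_globals
#' @param mvo_lattices optional named list with `early_mvo`/`late_mvo`
#'   lattices whose areas are reported alongside.
#' @param subject_id,geometry identifiers recorded in the output row.
#' @param eps lesion-presence threshold for column-wise descriptors.
#' @export
compute_globals.myo_lattice <- function(x, subject_id = "subject",
                                        geometry = "native",
                                        mvo_lattices = NULL,
                                        eps = GLOBALS_EPS, ...) {
  g <- .lattice_globals(x, eps)
  emvo <- lmvo <- NA_real_
  if (!is.null(mvo_lattices$early_mvo)) {
    emvo <- .lattice_globals(mvo_lattices$early_mvo, eps)$area
  }
  if (!is.null(mvo_lattices$late_mvo)) {
    lmvo <- .lattice_globals(mvo_lattices$late_mvo, eps)$area
  }
  tibble::tibble(subject_id = subject_id, geometry = geometry,
                 infarct_area_pct = g$area,
                 early_mvo_area_pct = emvo,
                 late_mvo_area_pct = lmvo,
                 transmurality_pct = g$trans,
                 endocardial_surface_pct = g$endo)
}

#' @rdname compute_globals
#' @param cmap optional precomputed coordinate map.
#' @param oversample oversampling factor when coordinates must be computed.
#' @param n_c,n_z,n_r lattice dimensions.
#' @export
compute_globals.myo_study <- function(x, cmap = NULL, oversample = 4L,
                                      n_c = 24L, n_z = 21L, n_r = 20L,
                                      eps = GLOBALS_EPS, ...) {
  if (!any(study_mask(x, "myocardium"))) rlang::abort("study has empty myocardium")
  if (is.null(cmap)) cmap <- compute_coordinates(x, oversample = oversample)
  lat_inf <- native_lattice(x, cmap, "infarct", n_c, n_z, n_r)
  mvo <- list(
    early_mvo = native_lattice(x, cmap, "early_mvo", n_c, n_z, n_r),
    late_mvo = native_lattice(x, cmap, "late_mvo", n_c, n_z, n_r)
  )
  compute_globals.myo_lattice(lat_inf, subject_id = x$subject_id,
                              geometry = "native", mvo_lattices = mvo, eps = eps)
}

#' @rdname compute_globals
#' @param ref reference geometry the pattern lives on.
#' @export
compute_globals.myo_pattern <- function(x, ref, n_c = 24L, n_r = 20L,
                                        eps = GLOBALS_EPS, ...) {
  lat_inf <- resample_to_lattice(x, ref, "infarct", n_c, n_r)
  mvo <- list()
  for (ch in intersect(c("early_mvo", "late_mvo"), x$channels)) {
    mvo[[ch]] <- resample_to_lattice(x, ref, ch, n_c, n_r)
  }
  compute_globals.myo_lattice(lat_inf, subject_id = x$subject_id,
                              geometry = "standardized", mvo_lattices = mvo,
                              eps = eps)
}

#' Compare a descriptor between two groups
#'
#' Continuous descriptors: two-sided Mann-Whitney U test (normal approximation
#' with tie correction). Categorical descriptors: two-sided Fisher exact test
#' on the 2x2 table. Also returns the per-group summaries used in cohort
#' tables: median (IQR) or count (%).
#'
#' @param values_a,values_b numeric vectors (continuous) or logical/0-1
#'   vectors (categorical).
#' @param kind `"continuous"` or `"categorical"`.
#' @return one-row tibble with `p_value`, per-group summaries and `n`.
#' @export
compare_groups <- function(values_a, values_b, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0) rlang::abort("empty group")
  if (kind == "continuous") {
    if (length(values_a) < 2 || length(values_b) < 2) {
      rlang::abort("continuous comparison needs >= 2 samples per group")
    }
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              exact = FALSE, correct = TRUE))
    p <- wt$p.value
    if (is.nan(p)) p <- 1   # all observations tied: no evidence either way
    fmt <- function(v) sprintf("%.1f (%.1f-%.1f)", stats::median(v),
                               stats::quantile(v, 0.25), stats::quantile(v, 0.75))
    tibble::tibble(kind = kind, p_value = p,
                   summary_a = fmt(values_a), summary_b = fmt(values_b),
                   n_a = length(values_a), n_b = length(values_b))
  } else {
    ta <- c(sum(values_a %in% c(TRUE, 1)), sum(!values_a %in% c(TRUE, 1)))
    tb <- c(sum(values_b %in% c(TRUE, 1)), sum(!values_b %in% c(TRUE, 1)))
    ft <- stats::fisher.test(matrix(c(ta, tb), nrow = 2))
    fmt <- function(tab) sprintf("%d (%.1f%%)", tab[1], 100 * tab[1] / sum(tab))
    tibble::tibble(kind = kind, p_value = ft$p.value,
                   summary_a = fmt(ta), summary_b = fmt(tb),
                   n_a = sum(ta), n_b = sum(tb))
  }
}

#' Descriptor table stratified by territory and treatment arm
#'
#' Renders the cohort-level table of the five global descriptors per culprit
#' territory, treatment arm and geometry (native/standardized), with the
#' between-arm Mann-Whitney p-value per row and a significance flag at
#' p < 0.05. Strata with a single arm get empty p columns.
#'
#' @param globals tibble of per-subject [compute_globals()] rows (both
#'   geometries allowed).
#' @param cohort cohort table with `subject_id`, `treatment`, `territory`.
#' @param arms optional character(2) selecting/ordering the two arms.
#' @return tibble: descriptor x territory x geometry rows with per-arm
#'   median (IQR), `p_value`, `significant`.
#' @export
render_descriptor_table <- function(globals, cohort, arms = NULL) {
  descriptors <- c("infarct_area_pct", "early_mvo_area_pct", "late_mvo_area_pct",
                   "transmurality_pct", "endocardial_surface_pct")
  df <- dplyr::inner_join(globals, cohort, by = "subject_id")
  if (is.null(arms)) arms <- sort(unique(df$treatment))
  out <- list()
  for (geom in unique(df$geometry)) {
    for (terr in intersect(territory_levels, unique(df$territory))) {
      sub <- df[df$geometry == geom & df$territory == terr, ]
      for (desc in descriptors) {
        va <- sub[[desc]][sub$treatment == arms[1]]
        vb <- if (length(arms) > 1) sub[[desc]][sub$treatment == arms[2]] else numeric(0)
        row <- tibble::tibble(geometry = geom, territory = terr, descriptor = desc,
                              arm_a = NA_character_, arm_b = NA_character_,
                              p_value = NA_real_, significant = NA)
        fmt <- function(v) {
          v <- v[!is.na(v)]
          if (!length(v)) return(NA_character_)
          sprintf("%.1f (%.1f-%.1f)", stats::median(v),
                  stats::quantile(v, 0.25), stats::quantile(v, 0.75))
        }
        row$arm_a <- fmt(va)
        row$arm_b <- fmt(vb)
        if (sum(!is.na(va)) >= 2 && sum(!is.na(vb)) >= 2) {
          cmp <- compare_groups(va, vb, "continuous")
          row$p_value <- cmp$p_value
          row$significant <- cmp$p_value < 0.05
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  tab <- dplyr::bind_rows(out)
  # name the per-arm summary columns after the arms themselves
  names(tab)[names(tab) == "arm_a"] <- arms[1]
  if (length(arms) > 1) names(tab)[names(tab) == "arm_b"] <- arms[2]
  tab
}
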