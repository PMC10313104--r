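# Segmented studies: label volumes + landmarks + covariates.

# label bitmask layout
MYO_BIT  <- 1L
INF_BIT  <- 2L
EMVO_BIT <- 4L
LMVO_BIT <- 8L

channel_bits <- c(myocardium = MYO_BIT, infarct = INF_BIT,
                  early_mvo = EMVO_BIT, late_mvo = LMVO_BIT)

#' Landmark set for one study
#'
#' @param junction per-slice LV-RV junction points: an `n_slices x 2` matrix of
#'   (x, y) pixel coordinates, `NA` rows where not annotated.
#' @param lvot optional list (length `n_slices`) of 2x2 matrices (two points
#'   delimiting the LV outflow tract) or `NULL` entries.
#' @param apex_index,base_index real-valued slice indices (1-based axis) of the
#'   endocardial apex and the mitral level; may lie outside the acquired stack
#'   when extrapolated by the annotator.
#' @return a `myo_landmarks` list.
#' @export
landmark_set <- function(junction, lvot = NULL, apex_index, base_index) {
  junction <- as.matrix(junction)
  stopifnot(ncol(junction) == 2)
  n <- nrow(junction)
  if (is.null(lvot)) lvot <- vector("list", n)
  stopifnot(length(lvot) == n)
  if (isTRUE(all.equal(apex_index, base_index))) {
    rlang::abort("apex_index and base_index must differ")
  }
  structure(list(junction = junction, lvot = lvot,
                 apex_index = as.numeric(apex_index),
                 base_index = as.numeric(base_index)),
            class = "myo_landmarks")
}

#' Segmented study container
#'
#' @param labels 3D integer bitmask array `[row, col, slice]`: bit 1
#'   myocardium, bit 2 infarct, bit 4 early MVO, bit 8 late MVO.
#' @param spacing named numeric: `inplane` pixel size (mm) and `slice`
#'   spacing (mm).
#' @param landmarks a [landmark_set()].
#' @param subject_id subject identifier string.
#' @param covariates named list of clinical covariates (treatment, territory, ...).
#' @param contours optional contour-set tibble the labels were rasterized from
#'   (kept for contour-exact coordinate estimation).
#' @return a `myo_study` object.
#' @export
segmented_study <- function(labels, spacing = c(inplane = 1.5625, slice = 5),
                            landmarks, subject_id = "subject",
                            covariates = list(), contours = NULL) {
  stopifnot(length(dim(labels)) == 3, inherits(landmarks, "myo_landmarks"))
  if (nrow(landmarks$junction) != dim(labels)[3]) {
    rlang::abort("landmarks must have one junction row per acquired slice")
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing, landmarks = landmarks,
                 subject_id = subject_id, covariates = covariates,
                 contours = contours),
            class = "myo_study")
}

#' @export
print.myo_study <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<myo_study '%s'> %dx%d, %d slices; myocardium %d px, infarct %d px\n",
              x$subject_id, d[1], d[2], d[3],
              sum(bitwAnd(x$labels, MYO_BIT) > 0),
              sum(bitwAnd(x$labels, INF_BIT) > 0)))
  invisible(x)
}

#' Extract a binary channel mask from a study
#'
#' @param study a `myo_study`.
#' @param channel one of `"myocardium"`, `"infarct"`, `"early_mvo"`, `"late_mvo"`.
#' @return logical array with the study's dimensions.
#' @export
study_mask <- function(study, channel = "myocardium") {
  bit <- channel_bits[[match.arg(channel, names(channel_bits))]]
  array(bitwAnd(study$labels, bit) > 0, dim = dim(study$labels))
}

#' Rasterize contours into a segmented study
#'
#' Digitizes wall and lesion polygons into the label bitmask using the
#' pixel-center-in-polygon even-odd rule (centers on an edge are in).
#' Myocardium is the region inside the epicardium and outside the endocardium;
#' lesion bits are clipped to their parent (infarct to myocardium, MVO to
#' infarct) at construction.
#'
#' @param contours contour-set tibble.
#' @param landmarks a [landmark_set()].
#' @param grid_shape integer c(nrow, ncol) of the pixel grid.
#' @param spacing named numeric spacing (mm), see [segmented_study()].
#' @param subject_id,covariates passed to [segmented_study()].
#' @return a `myo_study`.
#' @export
rasterize_study <- function(contours, landmarks, grid_shape,
                            spacing = c(inplane = 1.5625, slice = 5),
                            subject_id = "subject", covariates = list()) {
  validate_contour_set(contours)
  n_slices <- nrow(landmarks$junction)
  labels <- array(0L, dim = c(grid_shape[1], grid_shape[2], n_slices))
  for (s in sort(unique(contours$slice))) {
    rows <- contours[contours$slice == s, ]
    endo <- rows$xy[rows$role == "endocardium"]
    epi  <- rows$xy[rows$role == "epicardium"]
    if (length(endo) == 0 || length(epi) == 0) next
    # nesting check: endocardial vertices must lie inside the epicardium
    for (e in endo) {
      if (!all(point_in_polygon(e[, 1], e[, 2], epi[[1]]))) {
        rlang::abort(sprintf("slice %d: endocardial contour not inside epicardial contour", s))
      }
    }
    in_epi <- Reduce(`|`, lapply(epi, rasterize_polygon, dim = grid_shape))
    in_endo <- Reduce(`|`, lapply(endo, rasterize_polygon, dim = grid_shape))
    myo <- in_epi & !in_endo
    sl <- matrix(0L, grid_shape[1], grid_shape[2])
    sl[myo] <- MYO_BIT
    for (role in lesion_roles) {
      polys <- rows$xy[rows$role == role]
      if (length(polys) == 0) next
      les <- Reduce(`|`, lapply(polys, rasterize_polygon, dim = grid_shape))
      parent <- if (role == "infarct") myo else (bitwAnd(sl, INF_BIT) > 0)
      kept <- les & parent
      if (any(les) && !any(kept)) {
        rlang::warn(sprintf("slice %d: %s contour lies entirely outside its parent region", s, role))
      }
      sl[kept] <- bitwOr(sl[kept], channel_bits[[role]])
    }
    labels[, , s] <- sl
  }
  segmented_study(labels, spacing, landmarks, subject_id, covariates,
                  contours = contours)
}

#' Validate a segmented study
#'
#' Always returns a report. Checks: nonempty myocardium; a junction landmark on
#' every myocardium-bearing slice; apex/base index sanity; lesion-nesting
#' violations (counted, then clipped in the returned study); empty-myocardium
#' and no-infarct conditions are noted without failing.
#'
#' @param study a `myo_study`.
#' @return a `myo_validation` list: `pass` flag, `issues` tibble
#'   (check, slice, count, detail), `notes`, and `study` (the nesting-clipped
#'   study).
#' @export
validate_study <- function(study) {
  issues <- list()
  notes <- character()
  add_issue <- function(check, slice = NA_integer_, count = NA_integer_, detail = "") {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      check = check, slice = slice, count = count, detail = detail)
  }
  labels <- study$labels
  myo <- array(bitwAnd(labels, MYO_BIT) > 0, dim = dim(labels))
  n_slices <- dim(labels)[3]
  myo_per_slice <- vapply(seq_len(n_slices), function(s) sum(myo[, , s]), integer(1))
  if (sum(myo_per_slice) == 0) add_issue("empty_study", detail = "no myocardium on any slice")
  for (s in which(myo_per_slice > 0)) {
    if (anyNA(study$landmarks$junction[s, ])) {
      add_issue("missing_junction", slice = s, detail = "myocardium-bearing slice without LV-RV junction")
    }
  }
  if (isTRUE(all.equal(study$landmarks$apex_index, study$landmarks$base_index))) {
    add_issue("apex_base", detail = "apex_index equals base_index")
  }
  if (any(myo_per_slice == 0)) {
    notes <- c(notes, sprintf("%d slice(s) without myocardium", sum(myo_per_slice == 0)))
  }
  # lesion nesting: infarct within myocardium, MVO within infarct
  inf <- bitwAnd(labels, INF_BIT) > 0
  n_inf_out <- sum(inf & !myo)
  if (n_inf_out > 0) add_issue("infarct_outside_myocardium", count = n_inf_out)
  clipped <- labels
  clipped[inf & !myo] <- bitwAnd(clipped[inf & !myo], bitwNot(INF_BIT))
  inf2 <- bitwAnd(clipped, INF_BIT) > 0
  for (role in c("early_mvo", "late_mvo")) {
    bit <- channel_bits[[role]]
    mv <- bitwAnd(clipped, bit) > 0
    n_out <- sum(mv & !inf2)
    if (n_out > 0) add_issue(paste0(role, "_outside_infarct"), count = n_out)
    clipped[mv & !inf2] <- bitwAnd(clipped[mv & !inf2], bitwNot(bit))
  }
  if (sum(inf) == 0) notes <- c(notes, "no infarct")
  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(check = character(), slice = integer(), count = integer(), detail = character())
  fail_checks <- c("empty_study", "missing_junction", "apex_base")
  pass <- !any(issues$check %in% fail_checks)
  out <- study
  out$labels <- clipped
  structure(list(pass = pass, issues = issues, notes = notes, study = out),
            class = "myo_validation")
}

#' @export
print.myo_validation <- function(x, ...) {
  cat(sprintf("<myo_validation> pass = %s; %d issue(s)\n", x$pass, nrow(x$issues)))
  if (nrow(x$issues)) print(x$issues)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
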