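# Study bundles: one NIfTI integer label volume + one JSON sidecar holding
# spacing, landmarks and covariates. Cohort tables are plain CSV.

BUNDLE_SCHEMA_VERSION <- "1.0"

#' Write a study bundle
#'
#' Persists a study as `<stem>.nii.gz` (label bitmask) plus `<stem>.json`
#' (schema version, spacing, junction/LVOT landmarks, apex/base indices,
#' covariates). The round trip through [read_bundle()] is lossless for labels,
#' spacing, landmarks and covariates (rasterization contours are not stored).
#'
#' @param study a `myo_study`.
#' @param stem output path stem (without extension).
#' @return `stem`, invisibly.
#' @export
write_bundle <- function(study, stem) {
  stopifnot(inherits(study, "myo_study"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(study$labels,
                         pixdim = c(study$spacing[["inplane"]],
                                    study$spacing[["inplane"]],
                                    study$spacing[["slice"]]))
  RNifti::writeNifti(img, paste0(stem, ".nii.gz"))
  lm <- study$landmarks
  sidecar <- list(
    schema_version = BUNDLE_SCHEMA_VERSION,
    subject_id = study$subject_id,
    spacing_mm = list(inplane = unname(study$spacing[["inplane"]]),
                      slice = unname(study$spacing[["slice"]])),
    junction = apply(lm$junction, 1, function(r) as.list(unname(r)), simplify = FALSE),
    lvot = lapply(lm$lvot, function(p) if (is.null(p)) NULL else as.list(as.numeric(t(p)))),
    apex_index = lm$apex_index,
    base_index = lm$base_index,
    covariates = study$covariates
  )
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(stem)
}

#' Read a study bundle
#'
#' @param stem path stem written by [write_bundle()].
#' @return a `myo_study`.
#' @export
read_bundle <- function(stem) {
  nii <- paste0(stem, ".nii.gz")
  side <- paste0(stem, ".json")
  if (!file.exists(nii)) rlang::abort(paste0("bundle is missing the label volume: ", nii))
  if (!file.exists(side)) rlang::abort(paste0("bundle is missing the landmark sidecar: ", side))
  meta <- jsonlite::read_json(side)
  if (!identical(meta$schema_version, BUNDLE_SCHEMA_VERSION)) {
    rlang::abort(sprintf("bundle schema version '%s' does not match supported version '%s'",
                         meta$schema_version, BUNDLE_SCHEMA_VERSION))
  }
  vol <- RNifti::readNifti(nii)
  labels <- array(as.integer(vol), dim = dim(vol))
  junction <- do.call(rbind, lapply(meta$junction, function(r) {
    vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
  }))
  lvot <- lapply(meta$lvot, function(p) {
    if (is.null(p) || length(p) == 0) NULL else matrix(as.numeric(unlist(p)), 2, 2, byrow = TRUE)
  })
  lm <- landmark_set(junction, lvot, meta$apex_index, meta$base_index)
  covs <- lapply(meta$covariates, function(v) if (is.null(v)) NA else v)
  segmented_study(labels,
                  spacing = c(inplane = meta$spacing_mm$inplane, slice = meta$spacing_mm$slice),
                  landmarks = lm, subject_id = meta$subject_id, covariates = covs)
}

#' Write / read a cohort covariate table
#'
#' One row per subject; `subject_id` must be unique and `territory`, when
#' present, must be one of `LAD_mid`, `LAD_prox`, `LCX`, `RCA`.
#'
#' @param cohort tibble with a `subject_id` column.
#' @param path CSV path.
#' @return the cohort tibble (invisibly for the writer).
#' @export
write_cohort_table <- function(cohort, path) {
  validate_cohort_table(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(cohort)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  cohort <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_cohort_table(cohort)
  cohort
}

territory_levels <- c("LAD_mid", "LAD_prox", "LCX", "RCA")

#' @rdname write_cohort_table
#' @export
validate_cohort_table <- function(cohort) {
  stopifnot(is.data.frame(cohort), "subject_id" %in% names(cohort))
  if (anyDuplicated(cohort$subject_id)) rlang::abort("subject_id values must be unique")
  if ("territory" %in% names(cohort)) {
    bad <- setdiff(unique(cohort$territory), territory_levels)
    if (length(bad)) {
      rlang::abort(paste0("unknown territory level(s): ", paste(bad, collapse = ", ")))
    }
  }
  invisible(cohort)
}
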