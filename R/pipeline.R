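# End-to-end orchestration: ingest -> validate -> coordinates -> warp ->
# lattice -> group statistics -> global descriptors -> embedding, with a run
# manifest and per-subject inclusion log.

#' Pipeline run configuration
#'
#' Defaults are the standard analysis constants: reference geometry of 21
#' slices of 80 x 80 px with basal endo/epi radii 30/50 px, a 24 x 21 x 20
#' analysis lattice, in-plane oversampling factor 4, significance threshold
#' 0.05, and t-SNE with 2 components, perplexity 10 and PCA initialization.
#'
#' @param ref_endo_radius,ref_epi_radius,ref_n_slices,ref_grid reference
#'   geometry parameters.
#' @param n_c,n_r lattice bins (slices are the long-axis bins).
#' @param oversample coordinate oversampling factor.
#' @param alpha significance threshold for p-value maps.
#' @param perplexity,n_components,tsne_init,tsne_max_iter embedding
#'   hyperparameters.
#' @param group_by covariate naming the two compared arms.
#' @param stratify_by covariate defining pattern subgroups (territories).
#' @param seed seed for the stochastic stages.
#' @param save_patterns write per-subject standardized patterns to the run
#'   directory.
#' @return a `myo_run_config` list.
#' @export
run_config <- function(ref_endo_radius = 30, ref_epi_radius = 50,
                       ref_n_slices = 21L, ref_grid = 80L,
                       n_c = 24L, n_r = 20L, oversample = 4L, alpha = 0.05,
                       perplexity = 10, n_components = 2L, tsne_init = "pca",
                       tsne_max_iter = 1000L,
                       group_by = "treatment", stratify_by = "territory",
                       seed = 1L, save_patterns = FALSE) {
  structure(list(ref_endo_radius = ref_endo_radius,
                 ref_epi_radius = ref_epi_radius,
                 ref_n_slices = as.integer(ref_n_slices),
                 ref_grid = as.integer(ref_grid),
                 n_c = as.integer(n_c), n_r = as.integer(n_r),
                 oversample = as.integer(oversample), alpha = alpha,
                 perplexity = perplexity, n_components = as.integer(n_components),
                 tsne_init = tsne_init, tsne_max_iter = as.integer(tsne_max_iter),
                 group_by = group_by, stratify_by = stratify_by,
                 seed = as.integer(seed), save_patterns = save_patterns),
            class = "myo_run_config")
}

.load_studies <- function(input) {
  if (inherits(input, "myo_cohort")) {
    return(list(studies = input$studies, cohort = input$cohort))
  }
  if (is.character(input) && dir.exists(input)) {
    cohort <- read_cohort_table(file.path(input, "cohort.csv"))
    studies <- lapply(cohort$subject_id, function(sid) {
      tryCatch(read_bundle(file.path(input, sid)), error = function(e) e)
    })
    return(list(studies = studies, cohort = cohort))
  }
  if (is.list(input)) {
    cohort <- dplyr::bind_rows(lapply(input, function(s) {
      tibble::as_tibble(c(list(subject_id = s$subject_id), s$covariates))
    }))
    return(list(studies = input, cohort = cohort))
  }
  rlang::abort("input must be a myo_cohort, a cohort directory, or a list of studies")
}

#' Run the full standardization and comparison pipeline
#'
#' Processes every readable study (per-subject failures are logged and
#' skipped, never aborting the cohort unless all subjects fail), computes
#' standardized patterns and lattices, per-subgroup average patterns and
#' Bull's eyes, per-location Hotelling p-value maps between the two arms per
#' subgroup, global descriptors before/after standardization, and the
#' realigned t-SNE embedding. All tables are written as CSV under `out_dir`
#' together with a JSON manifest (configuration, package version, seed,
#' per-subject inclusion log).
#'
#' @param input a `myo_cohort`, a cohort directory (bundles + cohort.csv), or
#'   a list of `myo_study` objects.
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return (invisibly) a list with the in-memory results: `lattices`,
#'   `patterns` (if saved), `pmaps`, `group_means`, `globals`,
#'   `descriptor_table`, `embedding`, `inclusion`, `manifest`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = tempfile("myoatlas_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loaded <- .load_studies(input)
  ref <- build_reference_geometry(config$ref_endo_radius, config$ref_epi_radius,
                                  config$ref_n_slices, config$ref_grid)
  n <- length(loaded$studies)
  inclusion <- tibble::tibble(subject_id = loaded$cohort$subject_id,
                              included = FALSE, reason = "")
  lattices <- list(); globals_rows <- list(); patterns <- list()
  for (i in seq_len(n)) {
    sid <- loaded$cohort$subject_id[i]
    res <- tryCatch({
      st <- loaded$studies[[i]]
      if (inherits(st, "error")) rlang::abort(conditionMessage(st))
      val <- validate_study(st)
      if (!val$pass) {
        rlang::abort(paste0("validation failed: ",
                            paste(unique(val$issues$check), collapse = ", ")))
      }
      st <- val$study
      cmap <- compute_coordinates(st, oversample = config$oversample)
      pat <- warp_to_reference(st, cmap, ref)
      lat <- resample_to_lattice(pat, ref, "infarct", config$n_c, config$n_r)
      gl_nat <- compute_globals(st, cmap = cmap, n_c = config$n_c,
                                n_z = config$ref_n_slices, n_r = config$n_r)
      gl_std <- compute_globals(pat, ref = ref, n_c = config$n_c, n_r = config$n_r)
      list(lat = lat, pat = pat, globals = dplyr::bind_rows(gl_nat, gl_std))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      inclusion$reason[i] <- conditionMessage(res)
      next
    }
    inclusion$included[i] <- TRUE
    lattices[[sid]] <- res$lat
    globals_rows[[sid]] <- res$globals
    if (config$save_patterns) patterns[[sid]] <- res$pat
  }
  if (!any(inclusion$included)) rlang::abort("no valid subjects in the cohort")
  cohort <- loaded$cohort[inclusion$included, ]
  globals <- dplyr::bind_rows(globals_rows)
  utils::write.csv(globals, file.path(out_dir, "globals.csv"), row.names = FALSE)
  desc_tab <- tryCatch(
    render_descriptor_table(globals, cohort),
    error = function(e) NULL)
  if (!is.null(desc_tab)) {
    utils::write.csv(desc_tab, file.path(out_dir, "descriptor_table.csv"),
                     row.names = FALSE)
  }
  arms <- sort(unique(cohort[[config$group_by]]))
  strata <- unique(cohort[[config$stratify_by]])
  group_means <- list(); pmaps <- list(); sig_rows <- list()
  for (terr in strata) {
    sel_t <- cohort[[config$stratify_by]] == terr
    for (arm in arms) {
      sel <- sel_t & cohort[[config$group_by]] == arm
      if (!any(sel)) next
      gs <- group_average(lattices[cohort$subject_id[sel]],
                          label = paste(terr, arm, sep = "/"))
      group_means[[paste(terr, arm, sep = "/")]] <- gs
      be <- bullseye_summarize(transmurality_map(gs$mean),
                               metric = "transmurality")
      utils::write.csv(unclass(be),
                       file.path(out_dir, sprintf("bullseye_transmurality_%s_%s.csv", terr, arm)),
                       row.names = FALSE)
    }
    if (length(arms) >= 2) {
      la <- lattices[cohort$subject_id[sel_t & cohort[[config$group_by]] == arms[1]]]
      lb <- lattices[cohort$subject_id[sel_t & cohort[[config$group_by]] == arms[2]]]
      if (length(la) >= 3 && length(lb) >= 3) {
        pm <- tryCatch(hotelling_map(la, lb), error = function(e) NULL)
        if (!is.null(pm)) {
          pmaps[[terr]] <- pm
          utils::write.csv(pm$p, file.path(out_dir, sprintf("pmap_%s.csv", terr)),
                           row.names = FALSE)
          sig_rows[[terr]] <- tibble::tibble(
            stratum = terr,
            significant_pct = significant_fraction(pm, config$alpha))
        }
      }
    }
  }
  if (length(sig_rows)) {
    utils::write.csv(dplyr::bind_rows(sig_rows),
                     file.path(out_dir, "significant_fractions.csv"), row.names = FALSE)
  }
  embedding <- NULL
  with_inf <- names(lattices)[vapply(lattices, function(l) sum(l, na.rm = TRUE) > 0, logical(1))]
  if (length(with_inf) >= 3 * config$perplexity) {
    terr_vec <- cohort[[config$stratify_by]][match(with_inf, cohort$subject_id)]
    embedding <- tryCatch({
      aligned <- if (any(grepl("^LAD", terr_vec))) {
        realign_to_lad(lattices[with_inf], terr_vec)$lattices
      } else {
        lattices[with_inf]   # single-territory cohort: nothing to realign to
      }
      embed_tsne(aligned, subject_ids = with_inf,
                 perplexity = config$perplexity,
                 n_components = config$n_components,
                 init = config$tsne_init, seed = config$seed,
                 max_iter = config$tsne_max_iter)
    }, error = function(e) {
      rlang::warn(paste0("embedding skipped: ", conditionMessage(e)))
      NULL
    })
    if (!is.null(embedding)) {
      utils::write.csv(embedding$points, file.path(out_dir, "embedding.csv"),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    package = "myoatlas",
    version = as.character(utils::packageVersion("myoatlas")),
    config = unclass(config),
    reference = list(endo_radius = ref$endo_radius, epi_radius = ref$epi_radius,
                     n_slices = ref$n_slices, grid = ref$grid),
    embedding = if (!is.null(embedding)) {
      list(perplexity = embedding$perplexity, n_components = embedding$n_components,
           init = embedding$init, seed = embedding$seed)
    },
    n_subjects = n, n_included = sum(inclusion$included),
    inclusion = inclusion,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, null = "null")
  invisible(list(lattices = lattices, patterns = patterns, pmaps = pmaps,
                 group_means = group_means, globals = globals,
                 descriptor_table = desc_tab, embedding = embedding,
                 inclusion = inclusion, manifest = manifest,
                 out_dir = out_dir, reference = ref))
}

#' Compare two annotation sets of the same cohort
#'
#' Reproducibility summary between two observers (or two readings): per-slice
#' junction angle differences about the cavity center and apex/base slice
#' index differences.
#'
#' @param studies_a,studies_b paired lists of `myo_study` objects (same
#'   subjects, different annotations).
#' @param oversample oversampling factor for cavity-center estimation.
#' @return tibble: per subject and slice, `angle_diff_deg`; plus per-subject
#'   `apex_diff`, `base_diff`.
#' @export
compare_annotations <- function(studies_a, studies_b, oversample = 1L) {
  stopifnot(length(studies_a) == length(studies_b))
  rows <- list()
  for (i in seq_along(studies_a)) {
    sa <- studies_a[[i]]; sb <- studies_b[[i]]
    cm <- compute_coordinates(sa, oversample = oversample)
    for (k in seq_len(dim(sa$labels)[3])) {
      if (anyNA(cm$cavity_centers[k, ])) next
      ja <- sa$landmarks$junction[k, ]; jb <- sb$landmarks$junction[k, ]
      if (anyNA(ja) || anyNA(jb)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sa$subject_id, slice = k,
        angle_diff_deg = junction_angle_difference(ja, jb, cm$cavity_centers[k, ]),
        apex_diff = slice_annotation_difference(sa$landmarks$apex_index,
                                                sb$landmarks$apex_index),
        base_diff = slice_annotation_difference(sa$landmarks$base_index,
                                                sb$landmarks$base_index))
    }
  }
  dplyr::bind_rows(rows)
}
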