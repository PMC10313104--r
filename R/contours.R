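#' Contour sets
#'
#' A contour set is a tibble with one row per polygon and columns
#' `slice` (1-based acquired slice index), `role` (one of `"endocardium"`,
#' `"epicardium"`, `"infarct"`, `"early_mvo"`, `"late_mvo"`) and `xy`
#' (list-column of two-column vertex matrices in continuous 0-based pixel
#' coordinates, x = column, y = row, open polygons).
#'
#' @param slice integer vector of slice indices.
#' @param role character vector of contour roles.
#' @param xy list of vertex matrices.
#' @return a validated contour-set tibble.
#' @export
contour_set <- function(slice, role, xy) {
  out <- tibble::tibble(slice = as.integer(slice), role = as.character(role), xy = xy)
  validate_contour_set(out)
}

contour_roles <- c("endocardium", "epicardium", "infarct", "early_mvo", "late_mvo")
lesion_roles <- c("infarct", "early_mvo", "late_mvo")

#' Validate a contour-set tibble
#'
#' Checks vertex counts, polygon simplicity, role names, and that every slice
#' carrying a lesion contour also carries endocardium and epicardium.
#'
#' @param contours contour-set tibble.
#' @return the input, invisibly validated (errors on violation).
#' @export
validate_contour_set <- function(contours) {
  stopifnot(is.data.frame(contours),
            all(c("slice", "role", "xy") %in% names(contours)))
  bad_role <- setdiff(unique(contours$role), contour_roles)
  if (length(bad_role)) {
    rlang::abort(paste0("unknown contour role(s): ", paste(bad_role, collapse = ", ")))
  }
  for (i in seq_len(nrow(contours))) {
    v <- contours$xy[[i]]
    if (!is.matrix(v) || ncol(v) != 2 || nrow(v) < 3) {
      rlang::abort(sprintf("polygon %d (%s, slice %d) must have >= 3 vertices",
                           i, contours$role[i], contours$slice[i]))
    }
    if (!polygon_is_simple(v)) {
      rlang::abort(sprintf("polygon %d (%s, slice %d) is self-intersecting",
                           i, contours$role[i], contours$slice[i]))
    }
  }
  lesion_slices <- unique(contours$slice[contours$role %in% lesion_roles])
  for (s in lesion_slices) {
    here <- contours$role[contours$slice == s]
    if (!all(c("endocardium", "epicardium") %in% here)) {
      rlang::abort(sprintf(
        "slice %d has a lesion contour but no myocardial wall (endocardium + epicardium required)", s))
    }
  }
  invisible(contours)
}

#' Default CVI42 contour-name mapping
#'
#' Maps the contour element names of CVI42 v.5.x workspaces onto package roles.
#' Pass a modified copy to [parse_cvi42_workspace()] to support other
#' versions or naming schemes (this is the parser's extension point).
#'
#' @export
cvi42_role_map <- c(
  saendocardialContour      = "endocardium",
  saepicardialContour       = "epicardium",
  saenhancementContour      = "infarct",
  saearlyEnhancementContour = "early_mvo",
  sanoReflowContour         = "late_mvo"
)

#' Parse a CVI42 workspace contour file
#'
#' Reads the hash/list layout of `.cvi42wsx` workspace exports: contours are
#' looked up by their CVI42 element key (see [cvi42_role_map]), grouped under
#' per-slice image states, with vertex coordinates stored at the workspace's
#' `SubpixelResolution`. Unrecognized contour keys are skipped with a warning;
#' files with no endocardial/epicardial contour anywhere are rejected.
#'
#' @param path path to the workspace XML file.
#' @param role_map named character vector mapping CVI42 contour keys to
#'   package roles.
#' @return a contour-set tibble (see [contour_set()]).
#' @export
parse_cvi42_workspace <- function(path, role_map = cvi42_role_map) {
  doc <- xml2::read_xml(path)
  slice_nodes <- xml2::xml_find_all(doc, "//*[starts-with(@Hash_key, 'slice:')]")
  if (length(slice_nodes) == 0) {
    rlang::abort("no per-slice image states found in workspace")
  }
  rows_slice <- integer(); rows_role <- character(); rows_xy <- list()
  skipped <- character()
  for (sn in slice_nodes) {
    slice <- as.integer(sub("^slice:", "", xml2::xml_attr(sn, "Hash_key")))
    cnodes <- xml2::xml_find_all(sn, ".//*[@Hash_key='Contours']/*[@Hash_key]")
    for (cn in cnodes) {
      key <- xml2::xml_attr(cn, "Hash_key")
      if (!key %in% names(role_map)) {
        skipped <- c(skipped, key)
        next
      }
      sub_node <- xml2::xml_find_first(cn, "./*[@Hash_key='SubpixelResolution']")
      subpix <- if (inherits(sub_node, "xml_missing")) 1 else as.numeric(xml2::xml_text(sub_node))
      pts <- xml2::xml_find_all(cn, "./*[@Hash_key='Points']/*")
      x <- as.numeric(xml2::xml_text(xml2::xml_find_all(pts, "./Point_x")))
      y <- as.numeric(xml2::xml_text(xml2::xml_find_all(pts, "./Point_y")))
      rows_slice <- c(rows_slice, slice)
      rows_role <- c(rows_role, unname(role_map[key]))
      rows_xy <- c(rows_xy, list(cbind(x, y) / subpix))
    }
  }
  if (length(skipped)) {
    rlang::warn(paste0("skipped unrecognized contour role(s): ",
                       paste(unique(skipped), collapse = ", ")))
  }
  if (!any(rows_role == "endocardium") || !any(rows_role == "epicardium")) {
    rlang::abort("workspace contains no myocardial wall contours (empty study)")
  }
  contour_set(rows_slice, rows_role, rows_xy)
}

#' Write a contour set as a CVI42-style workspace file
#'
#' Fixture/export writer producing the hash/list XML layout understood by
#' [parse_cvi42_workspace()]. Coordinates are written at full double precision
#' scaled by `subpixel_resolution`, so write-then-parse is vertex-identical.
#'
#' @param contours contour-set tibble.
#' @param path output path.
#' @param subpixel_resolution coordinate scaling factor stored in the file.
#' @param role_map named character vector mapping CVI42 contour keys to roles.
#' @return `path`, invisibly.
#' @export
write_cvi42_workspace <- function(contours, path, subpixel_resolution = 4,
                                  role_map = cvi42_role_map) {
  validate_contour_set(contours)
  inv_map <- stats::setNames(names(role_map), role_map)
  doc <- xml2::xml_new_root("Workspace", version = "5.1.0")
  states <- xml2::xml_add_child(doc, "Hash_item", Hash_key = "StudyMapStates")
  images <- xml2::xml_add_child(states, "Hash_item", Hash_key = "ImageStates")
  fmt <- function(v) sprintf("%.17g", v)
  for (s in sort(unique(contours$slice))) {
    sn <- xml2::xml_add_child(images, "Hash_item", Hash_key = paste0("slice:", s))
    cn <- xml2::xml_add_child(sn, "Hash_item", Hash_key = "Contours")
    rows <- which(contours$slice == s)
    for (i in rows) {
      key <- inv_map[[contours$role[i]]]
      node <- xml2::xml_add_child(cn, "Hash_item", Hash_key = key)
      pts <- xml2::xml_add_child(node, "Hash_item", Hash_key = "Points")
      v <- contours$xy[[i]] * subpixel_resolution
      for (k in seq_len(nrow(v))) {
        li <- xml2::xml_add_child(pts, "List_item")
        xml2::xml_add_child(li, "Point_x", fmt(v[k, 1]))
        xml2::xml_add_child(li, "Point_y", fmt(v[k, 2]))
      }
      xml2::xml_add_child(node, "Hash_item", fmt(subpixel_resolution),
                          Hash_key = "SubpixelResolution")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
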