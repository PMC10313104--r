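# Contour parsing, rasterization, validation and bundle round trips.

test_that("CVI42 workspace write-then-parse is vertex-identical and counts match", {
  set.seed(7)
  rows <- list()
  for (k in 1:12) {
    ctr <- c(31.5, 31.5)
    rows[[length(rows) + 1]] <- tibble::tibble(
      slice = k, role = c("endocardium", "epicardium"),
      xy = list(myoatlas:::circle_polygon(ctr, 9 + runif(1), 24),
                myoatlas:::circle_polygon(ctr, 18 + runif(1), 24)))
  }
  for (k in c(3, 5, 6, 9, 11)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      slice = k, role = "infarct",
      xy = list(myoatlas:::circle_polygon(c(38, 31.5), 5, 16)))
  }
  contours <- dplyr::bind_rows(rows)
  path <- withr::local_tempfile(fileext = ".cvi42wsx")
  write_cvi42_workspace(contours, path)
  parsed <- parse_cvi42_workspace(path)
  expect_equal(sum(parsed$role %in% c("endocardium", "epicardium")), 24)
  expect_equal(sum(parsed$role == "infarct"), 5)
  # vertex-identical round trip (order normalized by slice then role)
  key <- function(df) df[order(df$slice, df$role), ]
  a <- key(contours); b <- key(parsed)
  expect_equal(a$slice, b$slice)
  expect_equal(a$role, b$role)
  for (i in seq_len(nrow(a))) {
    expect_equal(unname(b$xy[[i]]), unname(a$xy[[i]]), tolerance = 1e-12)
  }
})

test_that("workspace with a lesion but no wall contours is rejected", {
  contours <- tibble::tibble(slice = 3L, role = "infarct",
                             xy = list(myoatlas:::circle_polygon(c(20, 20), 5, 12)))
  path <- withr::local_tempfile(fileext = ".cvi42wsx")
  # writer enforces the same invariant, so emit the raw XML directly
  doc <- xml2::xml_new_root("Workspace", version = "5.1.0")
  st <- xml2::xml_add_child(doc, "Hash_item", Hash_key = "StudyMapStates")
  im <- xml2::xml_add_child(st, "Hash_item", Hash_key = "ImageStates")
  sn <- xml2::xml_add_child(im, "Hash_item", Hash_key = "slice:3")
  cn <- xml2::xml_add_child(sn, "Hash_item", Hash_key = "Contours")
  nd <- xml2::xml_add_child(cn, "Hash_item", Hash_key = "saenhancementContour")
  pts <- xml2::xml_add_child(nd, "Hash_item", Hash_key = "Points")
  for (i in 1:3) {
    li <- xml2::xml_add_child(pts, "List_item")
    xml2::xml_add_child(li, "Point_x", as.character(10 * i))
    xml2::xml_add_child(li, "Point_y", as.character(5 * i + 3))
  }
  xml2::write_xml(doc, path)
  expect_error(parse_cvi42_workspace(path), "no myocardial wall")
})

test_that("unrecognized contour roles are skipped with a warning", {
  st <- make_annulus_study(n_slices = 2, grid = 32, r_endo = 5, r_epi = 10)
  path <- withr::local_tempfile(fileext = ".cvi42wsx")
  write_cvi42_workspace(st$contours, path)
  # inject an unknown contour element
  doc <- xml2::read_xml(path)
  cn <- xml2::xml_find_first(doc, "//*[@Hash_key='Contours']")
  nd <- xml2::xml_add_child(cn, "Hash_item", Hash_key = "saMysteryContour")
  pts <- xml2::xml_add_child(nd, "Hash_item", Hash_key = "Points")
  for (i in 1:3) {
    li <- xml2::xml_add_child(pts, "List_item")
    xml2::xml_add_child(li, "Point_x", "1")
    xml2::xml_add_child(li, "Point_y", as.character(i))
  }
  xml2::write_xml(doc, path)
  expect_warning(parsed <- parse_cvi42_workspace(path), "saMysteryContour")
  expect_false("saMysteryContour" %in% parsed$role)
})

test_that("rasterized annulus area approaches the analytic area and converges", {
  area_err <- function(grid, r_endo, r_epi) {
    st <- make_annulus_study(n_slices = 1, grid = grid, r_endo = r_endo,
                             r_epi = r_epi, base_index = 2, n_vertices = 256)
    measured <- sum(study_mask(st, "myocardium"))
    analytic <- pi * (r_epi^2 - r_endo^2)
    abs(measured - analytic) / analytic
  }
  expect_lt(area_err(64, 10, 20), 0.03)
  # halving the pixel size (doubling radii and grid) roughly halves the error
  e1 <- area_err(64, 8, 14)
  e2 <- area_err(128, 16, 28)
  expect_lt(e2, e1)
})

test_that("rasterization is deterministic and respects lesion nesting", {
  st1 <- make_annulus_study(n_slices = 3, grid = 48, r_endo = 8, r_epi = 16)
  st2 <- make_annulus_study(n_slices = 3, grid = 48, r_endo = 8, r_epi = 16)
  expect_identical(st1$labels, st2$labels)

  # infarct polygon fully outside the myocardium: zero bits, warning
  ctr <- c(23.5, 23.5)
  contours <- dplyr::bind_rows(
    st1$contours,
    tibble::tibble(slice = 2L, role = "infarct",
                   xy = list(myoatlas:::circle_polygon(c(2.5, 2.5), 2, 12))))
  lm <- st1$landmarks
  expect_warning(
    st3 <- rasterize_study(contours, lm, c(48, 48)),
    "outside its parent")
  expect_equal(sum(study_mask(st3, "infarct")), 0)

  # MVO straddling the infarct border is clipped to the infarct
  contours4 <- dplyr::bind_rows(
    st1$contours,
    tibble::tibble(slice = 2L, role = c("infarct", "early_mvo"),
                   xy = list(myoatlas:::circle_polygon(c(35, 23.5), 5, 24),
                             myoatlas:::circle_polygon(c(39, 23.5), 4, 24))))
  st4 <- rasterize_study(contours4, lm, c(48, 48))
  emvo <- study_mask(st4, "early_mvo")
  expect_gt(sum(emvo), 0)
  expect_true(all(study_mask(st4, "infarct")[emvo]))
})

test_that("endocardium outside epicardium raises a geometry error naming the slice", {
  ctr <- c(23.5, 23.5)
  contours <- tibble::tibble(
    slice = c(1L, 1L), role = c("endocardium", "epicardium"),
    xy = list(myoatlas:::circle_polygon(c(40, 23.5), 8, 24),
              myoatlas:::circle_polygon(ctr, 12, 24)))
  lm <- landmark_set(matrix(c(30, 23.5), 1, 2), NULL, 0.5, 1.5)
  expect_error(rasterize_study(contours, lm, c(48, 48)), "slice 1")
})

test_that("validation reports junction gaps, nesting violations and no-infarct note", {
  st <- make_annulus_study(n_slices = 5, grid = 48, r_endo = 8, r_epi = 16)
  v <- validate_study(st)
  expect_true(v$pass)
  expect_true(any(grepl("no infarct", v$notes)))

  st_bad <- st
  st_bad$landmarks$junction[3, ] <- NA
  v2 <- validate_study(st_bad)
  expect_false(v2$pass)
  expect_true(3L %in% v2$issues$slice[v2$issues$check == "missing_junction"])

  # infarct bits planted outside the myocardium are counted then clipped
  st_nest <- st
  outside <- which(!study_mask(st_nest, "myocardium"))[1:17]
  st_nest$labels[outside] <- bitwOr(st_nest$labels[outside], 2L)
  v3 <- validate_study(st_nest)
  row <- v3$issues[v3$issues$check == "infarct_outside_myocardium", ]
  expect_equal(row$count, 17L)
  expect_equal(sum(study_mask(v3$study, "infarct")), 0)
  expect_s3_class(tidy(v3), "tbl_df")
  expect_equal(glance(v3)$pass, v3$pass)
})

test_that("study bundles round trip losslessly and flag schema/missing parts", {
  st <- make_annulus_study(n_slices = 4, grid = 40, r_endo = 7, r_epi = 13)
  st <- implant_wedge(st, c_center = 0.2, extent = 0.3, depth = 0.7,
                      mvo_rel = 0.5)
  st$covariates <- list(treatment = "immediate", territory = "RCA", age = 61.5)
  st$landmarks$lvot[[2]] <- matrix(c(30, 10, 33, 12), 2, 2, byrow = TRUE)
  stem <- file.path(withr::local_tempdir(), "sub001")
  write_bundle(st, stem)
  st2 <- read_bundle(stem)
  expect_identical(st2$labels, st$labels)
  expect_equal(st2$landmarks$junction, st$landmarks$junction)
  expect_equal(st2$landmarks$lvot[[2]], st$landmarks$lvot[[2]])
  expect_equal(st2$landmarks$apex_index, st$landmarks$apex_index)
  expect_equal(st2$covariates$territory, "RCA")

  file.remove(paste0(stem, ".json"))
  expect_error(read_bundle(stem), "sidecar")

  # schema version mismatch
  stem2 <- file.path(withr::local_tempdir(), "sub002")
  write_bundle(st, stem2)
  meta <- jsonlite::read_json(paste0(stem2, ".json"))
  meta$schema_version <- "0.9"
  jsonlite::write_json(meta, paste0(stem2, ".json"), auto_unbox = TRUE, null = "null")
  expect_error(read_bundle(stem2), "schema version")
})

test_that("cohort tables round trip and reject duplicate ids / bad territories", {
  co <- tibble::tibble(subject_id = sprintf("s%02d", 1:6),
                       treatment = rep(c("immediate", "delayed"), 3),
                       territory = c("LAD_mid", "LAD_prox", "LCX", "RCA", "RCA", "LCX"),
                       age = round(rnorm(6, 60, 10), 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(co, path)
  co2 <- read_cohort_table(path)
  expect_equal(as.data.frame(co2), as.data.frame(co))
  expect_error(validate_cohort_table(dplyr::bind_rows(co, co[1, ])), "unique")
  co_bad <- co; co_bad$territory[2] <- "LMS"
  expect_error(validate_cohort_table(co_bad), "territory")
})
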