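# Transport of per-subject lesion channels onto the reference geometry by
# piecewise-linear interpolation in normalized (r, c, z) coordinate space.

# Build a regular (c, r) value grid for one subject slice by bin-averaging the
# slice's scattered coordinate samples; empty nodes are filled by iterative
# neighbor averaging (periodic in c). Averaging and the subsequent bilinear
# queries are convex, so interpolated values never leave the sample range.
.slice_value_grid <- function(r_s, c_s, v_s, n_c = 96L, n_r = 32L) {
  if (!any(v_s != 0)) return(matrix(0, n_r, n_c))   # empty channel shortcut
  ic <- (floor(c_s * n_c) %% n_c) + 1L
  ir <- pmin(n_r, pmax(1L, round(r_s * (n_r - 1)) + 1L))
  grid <- matrix(NA_real_, n_r, n_c)
  idx <- (ic - 1L) * n_r + ir
  sums <- tapply(v_s, idx, sum)
  cnts <- tapply(v_s, idx, length)
  pos <- as.integer(names(sums))
  grid[pos] <- as.numeric(sums) / as.numeric(cnts)
  # fill empty nodes from neighbors (vectorized NA-aware 4-neighbor mean)
  while (anyNA(grid)) {
    left  <- grid[, c(n_c, seq_len(n_c - 1L)), drop = FALSE]
    right <- grid[, c(2:n_c, 1L), drop = FALSE]
    up    <- grid[c(1L, seq_len(n_r - 1L)), , drop = FALSE]
    down  <- grid[c(2:n_r, n_r), , drop = FALSE]
    z <- function(m) { m[is.na(m)] <- 0; m }
    k <- function(m) !is.na(m)
    cnt <- k(left) + k(right) + k(up) + k(down)
    tot <- z(left) + z(right) + z(up) + z(down)
    means <- ifelse(cnt > 0, tot / cnt, NA_real_)
    fill <- is.na(grid) & !is.na(means)
    if (!any(fill)) break
    grid[fill] <- means[fill]
  }
  if (anyNA(grid)) grid[is.na(grid)] <- 0
  grid
}

# Bilinear query of a (n_r x n_c) grid at coordinates (r, c); c periodic,
# r clamped to [0, 1].
.query_value_grid <- function(grid, r_q, c_q) {
  n_r <- nrow(grid); n_c <- ncol(grid)
  r_q <- pmin(1, pmax(0, r_q))
  fr <- r_q * (n_r - 1)
  i0 <- pmin(n_r - 1L, floor(fr) + 1L); i1 <- i0 + 1L
  wr <- fr - (i0 - 1L)
  fc <- circ_wrap(c_q) * n_c
  j0 <- (floor(fc) %% n_c) + 1L
  j1 <- (j0 %% n_c) + 1L
  wc <- fc - floor(fc)
  v00 <- grid[cbind(i0, j0)]; v01 <- grid[cbind(i0, j1)]
  v10 <- grid[cbind(i1, j0)]; v11 <- grid[cbind(i1, j1)]
  (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
}

#' Warp a study's lesion channels onto the reference geometry
#'
#' For every reference myocardial pixel whose long-axis coordinate lies inside
#' the subject's acquired z-range, the channel value is linearly interpolated
#' from the subject's coordinate samples: bin-averaged per-slice (c, r) grids
#' (circumferentially periodic) queried bilinearly, then combined linearly in
#' z between the two bracketing subject slices. No extrapolation is performed
#' beyond the first and last acquired slices: reference pixels outside the
#' subject's z-range are flagged missing. Binary channels therefore become
#' soft values in [0, 1] on the reference.
#'
#' @param study a `myo_study`.
#' @param cmap the study's [compute_coordinates()] map.
#' @param ref a [build_reference_geometry()] object.
#' @param channels channels to transport.
#' @param n_cgrid,n_rgrid resolution of the intermediate per-slice coordinate
#'   grids.
#' @param rebinarize if `TRUE`, re-threshold warped channels at 0.5
#'   (sensitivity analysis; default keeps soft values).
#' @return a `myo_pattern`: named list of value arrays on the reference grid
#'   (`NA` outside coverage), logical `coverage` array, `z_range`, subject id.
#' @export
warp_to_reference <- function(study, cmap, ref,
                              channels = c("infarct", "early_mvo", "late_mvo"),
                              n_cgrid = 96L, n_rgrid = 32L, rebinarize = FALSE) {
  stopifnot(inherits(cmap, "myo_coordmap"), inherits(ref, "myo_reference"))
  s <- cmap$oversample
  ns <- dim(study$labels)[3]
  valid_slices <- which(vapply(seq_len(ns), function(k) any(cmap$valid[, , k]), logical(1)))
  if (length(valid_slices) < 2) {
    rlang::abort("subject has fewer than 2 valid slices; cannot interpolate along the long axis")
  }
  ord <- valid_slices[order(cmap$z[valid_slices])]
  zs <- cmap$z[ord]
  z_range <- range(zs)
  # per-slice sample extraction (shared across channels); samples are fine
  # pixels that are valid in the coordinate map AND myocardial on the base
  # grid, so channel values (defined on base pixels) are always sampled
  # inside their own support
  d <- cmap$base_dim
  up_rows <- rep(seq_len(d[1]), each = s)
  up_cols <- rep(seq_len(d[2]), each = s)
  myo_base <- study_mask(study, "myocardium")
  slice_samples <- lapply(ord, function(k) {
    idx <- which(cmap$valid[, , k] & myo_base[up_rows, up_cols, k])
    list(idx = idx, r = cmap$r[, , k][idx], c = cmap$c[, , k][idx])
  })
  grids <- lapply(channels, function(ch) {
    mask <- study_mask(study, ch)
    lapply(seq_along(ord), function(j) {
      k <- ord[j]
      fine <- mask[up_rows, up_cols, k]
      v <- as.numeric(fine[slice_samples[[j]]$idx])
      .slice_value_grid(slice_samples[[j]]$r, slice_samples[[j]]$c, v,
                        n_c = n_cgrid, n_r = n_rgrid)
    })
  })
  names(grids) <- channels
  ref_dim <- dim(ref$mask)
  coverage <- array(FALSE, ref_dim)
  values <- lapply(channels, function(ch) array(NA_real_, ref_dim))
  names(values) <- channels
  for (k in seq_len(ref$n_slices)) {
    zq <- ref$z[k]
    if (zq < z_range[1] || zq > z_range[2]) next
    m <- ref$mask[, , k]
    idx <- which(m)
    if (!length(idx)) next
    r_q <- ref$r[, , k][idx]
    c_q <- ref$c[, , k][idx]
    hi <- findInterval(zq, zs, rightmost.closed = TRUE)
    j0 <- max(1L, min(hi, length(zs) - 1L)); j1 <- j0 + 1L
    w <- if (zs[j1] > zs[j0]) (zq - zs[j0]) / (zs[j1] - zs[j0]) else 0
    coverage[, , k][idx] <- TRUE
    for (ch in channels) {
      v0 <- .query_value_grid(grids[[ch]][[j0]], r_q, c_q)
      v1 <- .query_value_grid(grids[[ch]][[j1]], r_q, c_q)
      vals <- (1 - w) * v0 + w * v1
      if (rebinarize) vals <- as.numeric(vals >= 0.5)
      sl <- values[[ch]][, , k]
      sl[idx] <- vals
      values[[ch]][, , k] <- sl
    }
  }
  structure(list(values = values, coverage = coverage, z_range = z_range,
                 subject_id = study$subject_id, channels = channels,
                 rebinarized = rebinarize),
            class = "myo_pattern")
}

#' @export
print.myo_pattern <- function(x, ...) {
  cat(sprintf("<myo_pattern '%s'> channels: %s; covered z in [%.2f, %.2f]\n",
              x$subject_id, paste(x$channels, collapse = ", "),
              x$z_range[1], x$z_range[2]))
  invisible(x)
}

#' Resample a standardized pattern onto the analysis lattice
#'
#' Averages a channel of the reference-geometry pattern within each
#' (circumferential bin, slice, radial bin) cell. Cells with no covered
#' reference pixels are missing; with `fill_radial = TRUE` (default) empty
#' cells inside a partially observed column (thin apical wall) are filled by
#' linear interpolation along the radial bins, so that only coverage gaps
#' remain missing.
#'
#' @param pattern a `myo_pattern` (or a `myo_reference` paired with a value
#'   array via `values`).
#' @param channel channel name.
#' @param ref the reference geometry the pattern lives on.
#' @param n_c,n_r circumferential and radial bin counts (slices are the
#'   long-axis bins).
#' @param fill_radial fill within-column empty cells by radial interpolation.
#' @return a `myo_lattice`: numeric array `[n_c, n_z, n_r]` with `NA` for
#'   missing cells; attributes record the bin geometry.
#' @export
resample_to_lattice <- function(pattern, ref, channel = "infarct",
                                n_c = 24L, n_r = 20L, fill_radial = TRUE) {
  stopifnot(inherits(pattern, "myo_pattern"), inherits(ref, "myo_reference"))
  vol <- pattern$values[[channel]]
  if (is.null(vol)) rlang::abort(paste0("pattern has no channel '", channel, "'"))
  n_z <- ref$n_slices
  lat <- array(NA_real_, c(n_c, n_z, n_r))
  for (k in seq_len(n_z)) {
    m <- ref$mask[, , k] & pattern$coverage[, , k]
    idx <- which(m)
    if (!length(idx)) next
    v <- vol[, , k][idx]
    ic <- (floor(ref$c[, , k][idx] * n_c) %% n_c) + 1L
    ir <- pmin(n_r, floor(ref$r[, , k][idx] * n_r) + 1L)
    cell <- (ir - 1L) * n_c + ic
    sums <- tapply(v, cell, sum)
    cnts <- tapply(v, cell, length)
    pos <- as.integer(names(sums))
    sl <- matrix(NA_real_, n_c, n_r)
    sl[pos] <- as.numeric(sums) / as.numeric(cnts)
    if (fill_radial) {
      for (j in seq_len(n_c)) {
        col <- sl[j, ]
        if (anyNA(col) && any(!is.na(col))) {
          known <- which(!is.na(col))
          sl[j, ] <- stats::approx(known, col[known], xout = seq_len(n_r),
                                   rule = 2)$y
        }
      }
    }
    lat[, k, ] <- sl
  }
  structure(lat, class = "myo_lattice", n_c = n_c, n_z = n_z, n_r = n_r,
            channel = channel)
}

#' Bin a subject's own coordinates into a native-geometry lattice
#'
#' The native-mode counterpart of [resample_to_lattice()]: each valid fine-grid
#' myocardial pixel contributes its channel value to the (c, z-bin, r) cell
#' given by its own coordinates, without warping. Long-axis bins are `n_z`
#' equal intervals of [0, 1].
#'
#' @param study a `myo_study`.
#' @param cmap the study's coordinate map.
#' @param channel channel name.
#' @param n_c,n_z,n_r lattice dimensions.
#' @inheritParams resample_to_lattice
#' @return a `myo_lattice` array `[n_c, n_z, n_r]`.
#' @export
native_lattice <- function(study, cmap, channel = "infarct",
                           n_c = 24L, n_z = 21L, n_r = 20L, fill_radial = TRUE) {
  stopifnot(inherits(cmap, "myo_coordmap"))
  s <- cmap$oversample
  d <- cmap$base_dim
  up_rows <- rep(seq_len(d[1]), each = s)
  up_cols <- rep(seq_len(d[2]), each = s)
  mask <- study_mask(study, channel)
  myo_base <- study_mask(study, "myocardium")
  lat <- array(NA_real_, c(n_c, n_z, n_r))
  sums <- array(0, c(n_c, n_z, n_r))
  cnts <- array(0L, c(n_c, n_z, n_r))
  for (k in seq_len(d[3])) {
    idx <- which(cmap$valid[, , k] & myo_base[up_rows, up_cols, k])
    if (!length(idx)) next
    v <- as.numeric(mask[up_rows, up_cols, k][idx])
    ic <- (floor(cmap$c[, , k][idx] * n_c) %% n_c) + 1L
    iz <- pmin(n_z, pmax(1L, floor(cmap$z[k] * n_z) + 1L))
    ir <- pmin(n_r, floor(pmin(1, pmax(0, cmap$r[, , k][idx])) * n_r) + 1L)
    lin <- (ir - 1L) * (n_c * n_z) + (iz - 1L) * n_c + ic
    gs <- tapply(v, lin, sum)
    gc <- tapply(v, lin, length)
    pos <- as.integer(names(gs))
    sums[pos] <- sums[pos] + as.numeric(gs)
    cnts[pos] <- cnts[pos] + as.integer(gc)
  }
  lat[cnts > 0] <- sums[cnts > 0] / cnts[cnts > 0]
  if (fill_radial) {
    for (k in seq_len(n_z)) {
      for (j in seq_len(n_c)) {
        col <- lat[j, k, ]
        if (anyNA(col) && any(!is.na(col))) {
          known <- which(!is.na(col))
          lat[j, k, ] <- stats::approx(known, col[known], xout = seq_len(n_r),
                                       rule = 2)$y
        }
      }
    }
  }
  structure(lat, class = "myo_lattice", n_c = n_c, n_z = n_z, n_r = n_r,
            channel = channel)
}
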