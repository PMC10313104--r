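# Group-level pattern estimation and per-location two-sample comparison on the
# analysis lattice, with Bull's eye summarization.

.lattice_stack <- function(lattices) {
  stopifnot(length(lattices) >= 1)
  dims <- dim(lattices[[1]])
  for (l in lattices) {
    if (!identical(dim(l), dims)) rlang::abort("lattices must share a common shape")
  }
  arr <- array(NA_real_, c(length(lattices), dims))
  for (i in seq_along(lattices)) arr[i, , , ] <- lattices[[i]]
  arr
}

#' Average a group of subject lattices
#'
#' Per-cell mean and sample standard deviation over the subjects with coverage
#' at that cell; cells covered in at most half of the subjects are flagged
#' missing.
#'
#' @param lattices list of `myo_lattice` arrays with identical shape.
#' @param label group label carried through to summaries.
#' @return a `myo_group_summary`: `mean`, `sd`, `n` arrays, `n_subjects`,
#'   `label`.
#' @export
group_average <- function(lattices, label = "group") {
  if (length(lattices) == 0) rlang::abort("empty group")
  arr <- .lattice_stack(lattices)
  n <- apply(!is.na(arr), c(2, 3, 4), sum)
  mu <- apply(arr, c(2, 3, 4), function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  sd_ <- apply(arr, c(2, 3, 4), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  })
  low <- n <= length(lattices) / 2
  mu[low] <- NA_real_
  sd_[low] <- NA_real_
  structure(list(mean = mu, sd = sd_, n = n, n_subjects = length(lattices),
                 label = label),
            class = "myo_group_summary")
}

#' Location map: radial maximum of a lattice
#'
#' Per-(circumferential, slice) maximum of the channel over the radial bins —
#' where the lesion touches, regardless of depth.
#'
#' @param lattice a `myo_lattice` array `[n_c, n_z, n_r]`.
#' @return numeric matrix `[n_c, n_z]` (`NA` where the whole column is missing).
#' @export
location_map <- function(lattice) {
  apply(lattice, c(1, 2), function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
}

#' Transmurality map: radial mean of a lattice
#'
#' Per-(circumferential, slice) average of the channel over the radial bins —
#' the fraction of the wall thickness occupied by the lesion.
#'
#' @inheritParams location_map
#' @return numeric matrix `[n_c, n_z]`.
#' @export
transmurality_map <- function(lattice) {
  apply(lattice, c(1, 2), function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
}

#' Two-sample Hotelling T-squared test
#'
#' Pooled-covariance T-squared with Moore-Penrose pseudo-inverse
#' regularization when the covariance is rank-deficient (singular values below
#' `tol` relative to the largest are dropped) and the F transformation using
#' the effective dimension q = rank: F = (n - q - 1) / ((n - 2) q) * T2 on
#' (q, n - q - 1) degrees of freedom. For q = 1 this reduces exactly to the
#' squared two-sample t statistic and its two-sided p-value.
#'
#' @param a,b numeric matrices (subjects x features).
#' @param tol relative singular-value tolerance for the pseudo-inverse.
#' @return list with `statistic`, `df1`, `df2`, `p_value`, `n_a`, `n_b`.
#' @export
hotelling_test <- function(a, b, tol = 1e-8) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- nrow(a); nb <- nrow(b); n <- na + nb
  if (na < 2 || nb < 2) rlang::abort("each group needs >= 2 subjects")
  d <- colMeans(a) - colMeans(b)
  S <- ((na - 1) * stats::cov(a) + (nb - 1) * stats::cov(b)) / (n - 2)
  sv <- svd(S)
  thr <- tol * max(sv$d[1], 0)
  keep <- sv$d > thr & sv$d > 0
  q <- sum(keep)
  q <- min(q, n - 2L)   # keep F denominator dof positive
  if (q == 0) {
    if (sqrt(sum(d^2)) <= sqrt(.Machine$double.eps)) {
      return(list(statistic = 0, df1 = 1L, df2 = n - 2L, p_value = 1,
                  n_a = na, n_b = nb))
    }
    # zero within-group variance but nonzero mean difference: perfect separation
    return(list(statistic = Inf, df1 = 1L, df2 = n - 2L, p_value = 1e-300,
                n_a = na, n_b = nb))
  }
  keep <- which(keep)[seq_len(q)]
  ginv_d <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% d) / sv$d[keep])
  t2 <- (na * nb / n) * sum(d * ginv_d)
  t2 <- max(t2, 0)
  f <- (n - q - 1) / ((n - 2) * q) * t2
  p <- stats::pf(f, q, n - q - 1, lower.tail = FALSE)
  list(statistic = t2, df1 = q, df2 = n - q - 1L,
       p_value = max(p, .Machine$double.xmin), n_a = na, n_b = nb)
}

#' Per-location Hotelling comparison of two groups
#'
#' At each (circumferential, slice) location the per-subject feature vector is
#' the radial profile of the lattice (multivariate mode, default) or the
#' scalar per-subject transmurality (univariate mode). Subjects without
#' coverage at a location are dropped there; locations with fewer than `min_n`
#' subjects in either group are missing.
#'
#' @param group_a,group_b lists of `myo_lattice` arrays.
#' @param mode `"profile"` (radial-profile vector) or `"transmurality"`
#'   (scalar).
#' @param min_n minimum subjects per group per location.
#' @param tol pseudo-inverse tolerance, see [hotelling_test()].
#' @return a `myo_pmap`: matrices `p`, `statistic`, `df1`, `df2`, `n_a`,
#'   `n_b` of shape `[n_c, n_z]`.
#' @export
hotelling_map <- function(group_a, group_b, mode = c("profile", "transmurality"),
                          min_n = 3L, tol = 1e-8) {
  mode <- match.arg(mode)
  arr_a <- .lattice_stack(group_a)
  arr_b <- .lattice_stack(group_b)
  stopifnot(identical(dim(arr_a)[-1], dim(arr_b)[-1]))
  n_c <- dim(arr_a)[2]; n_z <- dim(arr_a)[3]
  p <- stat <- df1 <- df2 <- na_m <- nb_m <- matrix(NA_real_, n_c, n_z)
  any_tested <- FALSE
  for (k in seq_len(n_z)) {
    for (j in seq_len(n_c)) {
      xa <- arr_a[, j, k, , drop = TRUE]
      xb <- arr_b[, j, k, , drop = TRUE]
      if (is.null(dim(xa))) xa <- matrix(xa, ncol = 1)
      if (is.null(dim(xb))) xb <- matrix(xb, ncol = 1)
      if (mode == "transmurality") {
        xa <- matrix(rowMeans(xa), ncol = 1)
        xb <- matrix(rowMeans(xb), ncol = 1)
      }
      oka <- stats::complete.cases(xa)
      okb <- stats::complete.cases(xb)
      if (sum(oka) < min_n || sum(okb) < min_n) next
      ht <- hotelling_test(xa[oka, , drop = FALSE], xb[okb, , drop = FALSE], tol = tol)
      p[j, k] <- ht$p_value
      stat[j, k] <- ht$statistic
      df1[j, k] <- ht$df1
      df2[j, k] <- ht$df2
      na_m[j, k] <- ht$n_a
      nb_m[j, k] <- ht$n_b
      any_tested <- TRUE
    }
  }
  if (!any_tested) {
    rlang::abort(sprintf("fewer than %d subjects per group at every location", min_n))
  }
  structure(list(p = p, statistic = stat, df1 = df1, df2 = df2,
                 n_a = na_m, n_b = nb_m, mode = mode),
            class = "myo_pmap")
}

#' @export
print.myo_pmap <- function(x, ...) {
  ok <- !is.na(x$p)
  cat(sprintf("<myo_pmap> %dx%d locations, %d tested, %.1f%% with p < 0.05\n",
              nrow(x$p), ncol(x$p), sum(ok),
              100 * mean(x$p[ok] < 0.05)))
  invisible(x)
}

#' Summarize a per-location map as a Bull's eye grid
#'
#' Transposes a `[n_c, n_z]` location map into the ring/segment polar layout:
#' ring 1 (innermost) is the apical slice, the outermost ring the basal slice;
#' segment 1 starts at the junction and proceeds anticlockwise.
#'
#' @param map2d numeric matrix `[n_c, n_z]` (or a `myo_pmap`, whose p-values
#'   are used).
#' @param metric display name of the summarized quantity.
#' @param log_scale flag the metric for logarithmic color display (the
#'   convention for p-values).
#' @return a `myo_bullseye`: numeric matrix `[n_z rings, n_c segments]` with
#'   attributes `metric` and `log_scale`.
#' @export
bullseye_summarize <- function(map2d, metric = "value", log_scale = FALSE) {
  if (inherits(map2d, "myo_pmap")) {
    if (missing(metric)) metric <- "p_value"
    if (missing(log_scale)) log_scale <- TRUE
    map2d <- map2d$p
  }
  if (!is.matrix(map2d)) rlang::abort("map2d must be a [n_c, n_z] matrix")
  structure(t(map2d), class = "myo_bullseye", metric = metric,
            log_scale = log_scale)
}

#' Fraction of myocardial locations with p below a threshold
#'
#' @param pmap a `myo_pmap` (or a p-value matrix).
#' @param alpha significance threshold.
#' @return percentage of non-missing locations with p < `alpha`.
#' @export
significant_fraction <- function(pmap, alpha = 0.05) {
  p <- if (inherits(pmap, "myo_pmap")) pmap$p else pmap
  ok <- !is.na(p)
  if (!any(ok)) rlang::abort("all locations are missing")
  100 * sum(p[ok] < alpha) / sum(ok)
}
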