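# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Bull's eye grid
#'
#' @param x a `myo_bullseye`.
#' @param ... unused.
#' @return tibble with `ring` (1 = apex), `segment` (1 starts at the
#'   junction), `value`.
#' @method tidy myo_bullseye
#' @export
tidy.myo_bullseye <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(ring = rep(seq_len(nrow(m)), times = ncol(m)),
                 segment = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.numeric(m))
}

#' Tidy a per-location p-value map
#'
#' @param x a `myo_pmap`.
#' @param ... unused.
#' @return tibble with one row per tested location: `c_bin`, `slice`,
#'   `statistic`, `df1`, `df2`, `n_a`, `n_b`, `p_value`.
#' @method tidy myo_pmap
#' @export
tidy.myo_pmap <- function(x, ...) {
  ok <- which(!is.na(x$p), arr.ind = TRUE)
  tibble::tibble(c_bin = ok[, 1], slice = ok[, 2],
                 statistic = x$statistic[ok], df1 = x$df1[ok], df2 = x$df2[ok],
                 n_a = x$n_a[ok], n_b = x$n_b[ok], p_value = x$p[ok])
}

#' @rdname tidy.myo_pmap
#' @param alpha threshold used for the significant-fraction summary.
#' @method glance myo_pmap
#' @export
glance.myo_pmap <- function(x, alpha = 0.05, ...) {
  ok <- !is.na(x$p)
  tibble::tibble(n_locations = length(x$p), n_tested = sum(ok),
                 significant_pct = significant_fraction(x, alpha),
                 min_p = min(x$p[ok]), mode = x$mode)
}

#' Tidy an embedding
#'
#' @param x a `myo_embedding`.
#' @param ... unused.
#' @return the per-subject coordinate tibble.
#' @method tidy myo_embedding
#' @export
tidy.myo_embedding <- function(x, ...) x$points

#' @rdname tidy.myo_embedding
#' @method glance myo_embedding
#' @export
glance.myo_embedding <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$points), perplexity = x$perplexity,
                 n_components = x$n_components, init = x$init, seed = x$seed,
                 stability = x$stability)
}

#' Tidy a group pattern summary
#'
#' @param x a `myo_group_summary`.
#' @param ... unused.
#' @return tibble with `c_bin`, `slice`, `r_bin`, `mean`, `sd`, `n`.
#' @method tidy myo_group_summary
#' @export
tidy.myo_group_summary <- function(x, ...) {
  d <- dim(x$mean)
  idx <- which(!is.na(x$mean), arr.ind = TRUE)
  tibble::tibble(c_bin = idx[, 1], slice = idx[, 2], r_bin = idx[, 3],
                 mean = x$mean[idx], sd = x$sd[idx], n = x$n[idx])
}

#' Tidy a validation report
#'
#' @param x a `myo_validation`.
#' @param ... unused.
#' @return the issues tibble.
#' @method tidy myo_validation
#' @export
tidy.myo_validation <- function(x, ...) x$issues

#' @rdname tidy.myo_validation
#' @method glance myo_validation
#' @export
glance.myo_validation <- function(x, ...) {
  tibble::tibble(pass = x$pass, n_issues = nrow(x$issues),
                 notes = paste(x$notes, collapse = "; "))
}
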