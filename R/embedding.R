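# Circumferential realignment of infarct patterns to the LAD territory and a
# two-dimensional t-SNE population embedding.

#' Intensity-weighted circumferential infarct center
#'
#' Circular mean of the circumferential coordinate over all lattice cells,
#' weighted by cell values (sum of unit phasors), returned in [0, 1).
#'
#' @param lattice a `myo_lattice` array `[n_c, n_z, n_r]`.
#' @return circumferential coordinate of the lesion's center of mass.
#' @export
infarct_center <- function(lattice) {
  n_c <- dim(lattice)[1]
  w <- apply(lattice, 1, function(v) sum(v, na.rm = TRUE))
  if (sum(w) <= 0) rlang::abort("lesion has zero mass; no circumferential center")
  ang <- 2 * pi * (seq_len(n_c) - 0.5) / n_c
  ph <- sum(w * exp(1i * ang))
  circ_wrap(Arg(ph) / (2 * pi))
}

# integer circumferential shift of a lattice (positive = toward higher c)
.rotate_lattice <- function(lattice, shift) {
  n_c <- dim(lattice)[1]
  shift <- ((shift %% n_c) + n_c) %% n_c
  if (shift == 0) return(lattice)
  idx <- c((n_c - shift + 1):n_c, 1:(n_c - shift))
  out <- lattice[idx, , , drop = FALSE]
  attributes(out) <- attributes(lattice)
  out
}

#' Realign infarct patterns to the LAD territory
#'
#' Rotates every pattern along the circumference so that the average infarct
#' center of its territory coincides with the average infarct center of the
#' LAD territory (LAD subgroups are left unrotated). Rotations are applied as
#' the integer lattice shift nearest to the circular difference of the
#' group-average centers, preserving each pattern's mass exactly. Subjects
#' with zero infarct mass keep their pattern and are flagged.
#'
#' @param lattices list of `myo_lattice` arrays.
#' @param territories character vector of territory labels per subject
#'   (`LAD_mid`/`LAD_prox` count as the LAD target).
#' @return list with `lattices` (rotated), `rotations` (tibble per territory:
#'   center, rotation in circumferential units and bins), `centers`
#'   (per-subject, `NA` where massless), `excluded` (indices with zero mass).
#' @export
realign_to_lad <- function(lattices, territories) {
  stopifnot(length(lattices) == length(territories))
  n_c <- dim(lattices[[1]])[1]
  centers <- vapply(lattices, function(l) {
    tryCatch(infarct_center(l), error = function(e) NA_real_)
  }, numeric(1))
  excluded <- which(is.na(centers))
  if (length(excluded)) {
    rlang::warn(sprintf("%d subject(s) with zero infarct mass left unrotated", length(excluded)))
  }
  is_lad <- grepl("^LAD", territories)
  if (!any(is_lad & !is.na(centers))) {
    rlang::abort("no LAD-territory subject with infarct; cannot define the realignment target")
  }
  circ_mean <- function(cc) {
    cc <- cc[!is.na(cc)]
    circ_wrap(Arg(sum(exp(2i * pi * cc))) / (2 * pi))
  }
  lad_center <- circ_mean(centers[is_lad])
  rot_rows <- list()
  out <- lattices
  for (terr in unique(territories)) {
    sel <- which(territories == terr)
    if (grepl("^LAD", terr)) {
      rot_rows[[terr]] <- tibble::tibble(territory = terr,
                                         center = circ_mean(centers[sel]),
                                         rotation = 0, shift_bins = 0L)
      next
    }
    tc <- centers[sel]
    if (all(is.na(tc)) ) {
      rlang::warn(sprintf("territory %s has zero total infarct; passed through unrotated", terr))
      rot_rows[[terr]] <- tibble::tibble(territory = terr, center = NA_real_,
                                         rotation = 0, shift_bins = 0L)
      next
    }
    t_center <- circ_mean(tc)
    delta <- circ_diff(lad_center, t_center)
    shift <- as.integer(round(delta * n_c))
    for (i in sel) out[[i]] <- .rotate_lattice(lattices[[i]], shift)
    rot_rows[[terr]] <- tibble::tibble(territory = terr, center = t_center,
                                       rotation = circ_wrap(delta),
                                       shift_bins = shift)
  }
  list(lattices = out, rotations = dplyr::bind_rows(rot_rows),
       centers = centers, excluded = excluded)
}

# ---- exact t-SNE -----------------------------------------------------------

# Conditional input probabilities at a fixed perplexity via per-point binary
# search on the Gaussian bandwidth.
.tsne_input_p <- function(D2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      ex <- exp(-di * beta)
      sumP <- sum(ex)
      if (sumP < .Machine$double.xmin) sumP <- .Machine$double.xmin
      H <- log(sumP) + beta * sum(di * ex) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    row <- ex / sumP
    P[i, -i] <- row
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# Standard exact t-SNE gradient descent (early exaggeration + momentum).
.tsne_core <- function(D2, n_components = 2L, perplexity = 10,
                       init, max_iter = 1000L, learning_rate = NULL,
                       exaggeration = 12, exaggeration_iters = 250L) {
  n <- nrow(D2)
  if (is.null(learning_rate)) {
    # the usual auto heuristic: n / (early exaggeration * 4), floored
    learning_rate <- max(50, n / (exaggeration * 4))
  }
  P <- .tsne_input_p(D2, perplexity)
  Y <- init
  inc <- matrix(0, n, n_components)
  gains <- matrix(1, n, n_components)
  Pe <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    Pu <- if (iter <= exaggeration_iters) Pe else P
    momentum <- if (iter <= exaggeration_iters) 0.5 else 0.8
    sum2 <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum2, sum2, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pu - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - learning_rate * gains * grad
    Y <- inc + Y
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Two-dimensional t-SNE embedding of lesion patterns
#'
#' Flattens the (typically realigned) lattices with missing cells imputed as 0
#' (absence of lesion), and embeds subjects with exact t-SNE using the
#' standard hyperparameters: 2 components, perplexity 10 and PCA
#' initialization for stability. Deterministic given `seed`. Optionally reruns
#' the embedding with `n_stability` extra seeds and reports the mean pairwise
#' Procrustes disparity between runs.
#'
#' @param patterns list of `myo_lattice` arrays (one per subject) or a numeric
#'   matrix subjects x features.
#' @param subject_ids identifiers carried into the result.
#' @param perplexity t-SNE perplexity; needs at least `3 * perplexity`
#'   subjects.
#' @param n_components embedding dimension.
#' @param init `"pca"` (default) or `"random"`.
#' @param seed integer random seed.
#' @param max_iter gradient-descent iterations.
#' @param n_stability number of extra seeded reruns for the stability report.
#' @return a `myo_embedding`: tibble `points` (subject_id, dim1, dim2),
#'   hyperparameters, and `stability` (mean pairwise Procrustes disparity, or
#'   `NA` when not assessed).
#' @export
embed_tsne <- function(patterns, subject_ids = NULL, perplexity = 10,
                       n_components = 2L, init = c("pca", "random"), seed = 1L,
                       max_iter = 1000L, n_stability = 0L) {
  init <- match.arg(init)
  X <- if (is.matrix(patterns)) patterns else
    do.call(rbind, lapply(patterns, function(l) {
      v <- as.numeric(l); v[is.na(v)] <- 0; v
    }))
  n <- nrow(X)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%03d", seq_len(n))
  if (n < 3 * perplexity) {
    rlang::abort(sprintf(
      "t-SNE with perplexity %g needs at least %d subjects (3 * perplexity), got %d",
      perplexity, ceiling(3 * perplexity), n))
  }
  D2 <- as.matrix(stats::dist(X))^2
  run_once <- function(sd) {
    set.seed(sd)
    Y0 <- if (init == "pca") {
      pc <- stats::prcomp(X, rank. = n_components)$x
      pc / stats::sd(pc[, 1]) * 1e-4
    } else {
      matrix(stats::rnorm(n * n_components, sd = 1e-4), n, n_components)
    }
    .tsne_core(D2, n_components, perplexity, Y0, max_iter = max_iter)
  }
  Y <- run_once(seed)
  stability <- NA_real_
  if (n_stability > 0) {
    runs <- c(list(Y), lapply(seq_len(n_stability), function(i) run_once(seed + i)))
    disp <- c()
    for (a in seq_along(runs)) {
      for (b in seq_along(runs)) {
        if (b <= a) next
        disp <- c(disp, .procrustes_disparity(runs[[a]], runs[[b]]))
      }
    }
    stability <- mean(disp)
  }
  structure(list(
    points = tibble::tibble(subject_id = subject_ids,
                            dim1 = Y[, 1], dim2 = Y[, 2]),
    perplexity = perplexity, n_components = n_components, init = init,
    seed = seed, max_iter = max_iter, stability = stability),
    class = "myo_embedding")
}

# symmetric Procrustes disparity (scaled, rotation/translation removed)
.procrustes_disparity <- function(A, B) {
  center <- function(M) sweep(M, 2, colMeans(M))
  A <- center(A); B <- center(B)
  A <- A / sqrt(sum(A^2)); B <- B / sqrt(sum(B^2))
  s <- svd(crossprod(A, B))
  1 - sum(s$d)^2
}

#' @export
print.myo_embedding <- function(x, ...) {
  cat(sprintf("<myo_embedding> %d subjects; perplexity %g, %d components, %s init, seed %d\n",
              nrow(x$points), x$perplexity, x$n_components, x$init, x$seed))
  if (!is.na(x$stability)) {
    cat(sprintf("  stability (mean pairwise Procrustes disparity): %.3f\n", x$stability))
  }
  invisible(x)
}
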