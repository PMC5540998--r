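#' Classify a single pixel against a fingerprint set
#'
#' The elementary similarity-unmixing step. The pixel's channel vector is
#' normalized to a unit-sum distribution `b` and scored against every
#' fingerprint `a_j` with the squared difference `sum((b - a_j)^2)`; the
#' fluorophore with the smallest score wins. Because the candidate set is
#' discrete, scores are evaluated exhaustively, which returns the global
#' minimum deterministically. Pixels whose total signal does not exceed
#' `threshold` are labeled 0 (background). Ties (second-best score within
#' `tie_eps` of the best) resolve to the lowest fluorophore index and raise
#' the ambiguity flag.
#'
#' @param s Numeric per-channel intensity vector of one pixel.
#' @param prints A [fingerprint_set()] with matching channel count.
#' @param threshold Total-signal background threshold (default 0).
#' @param tie_eps Ambiguity tolerance on the score (default 1e-9).
#' @return List with `label` (0 = background, else fluorophore index),
#'   `residual` (winning score, `NA` for background) and `ambiguous`.
#' @examples
#' fps <- fingerprint_set(list(fingerprint("A", c(0.9, 0.1)),
#'                             fingerprint("B", c(0.5, 0.5)),
#'                             fingerprint("C", c(0.1, 0.9))))
#' classify_pixel(c(20, 80), fps, threshold = 10)  # label 3 ("C")
#' @export
classify_pixel <- function(s, prints, threshold = 0, tie_eps = 1e-9) {
  stopifnot(inherits(prints, "fingerprint_set"))
  s <- as.numeric(s)
  if (length(s) != n_channels(prints))
    stop("dimension mismatch: pixel has ", length(s), " channels, fingerprints ",
         n_channels(prints))
  if (sum(s) <= threshold)
    return(list(label = 0L, residual = NA_real_, ambiguous = FALSE))
  b <- normalize_channel_vector(s)
  scores <- colSums((prints$weights - b)^2)
  j <- which.min(scores)
  second <- if (length(scores) > 1L) min(scores[-j]) else Inf
  list(label = as.integer(j), residual = scores[[j]],
       ambiguous = is.finite(second) && (second - scores[[j]] <= tie_eps))
}

# Otsu threshold on the total-signal image. Computed on square-root
# transformed counts (variance stabilization for Poisson-scale data, so the
# background/foreground split is not dragged upward by bright objects) and
# mapped back to the raw count scale.
otsu_threshold <- function(total) {
  hi <- max(total)
  if (hi <= 0) return(0)
  s <- sqrt(pmax(total, 0))
  EBImage::otsu(matrix(s / sqrt(hi)), range = c(0, 1), levels = 256L)^2 * hi
}

#' Similarity-unmix a multichannel image
#'
#' Applies [classify_pixel()] to every pixel (vectorized) and deposits each
#' foreground pixel's intensity into the output channel of its winning
#' fluorophore, yielding one image per fluorophore with exactly one nonzero
#' fluorophore channel per pixel. The method operates pixel-wise with no
#' spatial coupling and is valid under the one-fluorophore-per-cell
#' condition; it works equally in the underdetermined regime (more
#' fluorophores than detection channels), where linear unmixing has no
#' unique solution. Mixed-signal objects (e.g. phagocytes carrying engulfed
#' labeled material) are handled by adding an extra empirical fingerprint
#' class, not by fractional abundances.
#'
#' @param image A [multichannel_image()].
#' @param prints A [fingerprint_set()]; a warning is issued when the minimum
#'   pairwise fingerprint separation falls below 0.02.
#' @param threshold `"otsu"` (on the total-signal image, default) or an
#'   absolute total-signal value.
#' @param intensity Scalar written into the winning fluorophore channel:
#'   `"total"` (total cross-channel signal, conserves measured photons;
#'   default) or `"max"` (winning pixel's brightest channel).
#' @param tie_eps Ambiguity tolerance passed to the per-pixel rule.
#' @param median_filter Optional 3x3 modal/median smoothing of the label
#'   map; off by default, provided as an extension beyond the pixel-wise
#'   method.
#' @return Object of class `"unmix_result"`: list with `labels` (integer
#'   matrix, 0 = background), `fluor_channels` (`H x W x m` array),
#'   `residual` and `ambiguity` matrices, `threshold_used`,
#'   `fluorophore_names`, `intensity_mode`.
#' @export
unmix_image <- function(image, prints, threshold = "otsu",
                        intensity = c("total", "max"), tie_eps = 1e-9,
                        median_filter = FALSE) {
  intensity <- match.arg(intensity)
  stopifnot(inherits(image, "multichannel_image"),
            inherits(prints, "fingerprint_set"))
  d <- dim(image)
  if (d[3L] != n_channels(prints))
    stop("image has ", d[3L], " channels but fingerprints have ",
         n_channels(prints))
  if (n_fluorophores(prints) >= 2L) {
    sep <- min_pairwise_separation(prints)
    if (sep < 0.02)
      warning("minimum pairwise fingerprint separation is ", signif(sep, 3),
              "; classes this close are hard to distinguish under noise")
  }
  npix <- d[1L] * d[2L]
  m <- n_fluorophores(prints)
  P <- matrix(unclass(image), nrow = npix, ncol = d[3L])
  total <- rowSums(P)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(total) else {
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
      stop("threshold must be \"otsu\" or a nonnegative number")
    threshold
  }
  fg <- total > thr
  labels <- integer(npix)
  residual <- rep(NA_real_, npix)
  ambiguous <- logical(npix)
  if (any(fg)) {
    B <- P[fg, , drop = FALSE] / total[fg]
    A <- prints$weights
    # sum((b - a_j)^2) = |b|^2 - 2 b.a_j + |a_j|^2, evaluated for all j at once
    scores <- rowSums(B^2) - 2 * B %*% A +
      matrix(colSums(A^2), nrow = sum(fg), ncol = m, byrow = TRUE)
    win <- max.col(-scores, ties.method = "first")
    # recompute the winning score in direct form: the expanded form above
    # cancels catastrophically near zero, the direct difference does not
    best <- rowSums((B - t(A)[win, , drop = FALSE])^2)
    second <- if (m > 1L) {
      s2 <- scores
      s2[cbind(seq_len(nrow(scores)), win)] <- Inf
      apply(s2, 1L, min)
    } else rep(Inf, nrow(scores))
    labels[fg] <- win
    residual[fg] <- pmax(best, 0)
    ambiguous[fg] <- is.finite(second) & (second - best <= tie_eps)
  } else {
    warning("image is entirely background at the chosen threshold")
  }
  labels <- matrix(labels, d[1L], d[2L])
  if (median_filter) labels <- modal_filter3(labels)
  deposit <- switch(intensity,
                    total = total,
                    max = apply(P, 1L, max))
  lab_vec <- as.vector(labels)
  F <- matrix(0, npix, m)
  keep <- lab_vec > 0L
  F[cbind(which(keep), lab_vec[keep])] <- deposit[keep]
  structure(list(labels = labels,
                 fluor_channels = array(F, dim = c(d[1L], d[2L], m)),
                 residual = matrix(residual, d[1L], d[2L]),
                 ambiguity = matrix(ambiguous, d[1L], d[2L]),
                 threshold_used = thr,
                 fluorophore_names = fluorophore_names(prints),
                 intensity_mode = intensity),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:length(x$fluorophore_names),
                      labels = c("background", x$fluorophore_names)))
  cat("<unmix_result>", nrow(x$labels), "x", ncol(x$labels),
      "pixels, threshold", signif(x$threshold_used, 4),
      ", intensity mode:", x$intensity_mode, "\n")
  print(tab)
  invisible(x)
}

# 3x3 modal filter on a label map (most frequent label in the neighborhood,
# center-biased on ties); an optional smoothing extension, not part of the
# pixel-wise classifier.
modal_filter3 <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  out <- labels
  for (i in seq_len(h)) {
    ii <- max(1L, i - 1L):min(h, i + 1L)
    for (j in seq_len(w)) {
      jj <- max(1L, j - 1L):min(w, j + 1L)
      nb <- labels[ii, jj]
      tab <- tabulate(nb + 1L)
      best <- which(tab == max(tab)) - 1L
      out[i, j] <- if (labels[i, j] %in% best) labels[i, j] else best[1L]
    }
  }
  out
}

#' Similarity-unmix a stack of image planes
#'
#' Planes (z slices or time points) are processed independently — the
#' per-pixel method has no spatial or temporal coupling — so results are
#' deterministic and order-preserving.
#'
#' @param stack List of [multichannel_image()] planes with uniform geometry.
#' @param prints A [fingerprint_set()].
#' @param ... Passed to [unmix_image()].
#' @return List of `unmix_result`, one per plane, in input order.
#' @export
unmix_stack <- function(stack, prints, ...) {
  if (!length(stack) || !all(vapply(stack, inherits, TRUE, "multichannel_image")))
    stop("stack must be a non-empty list of multichannel images")
  dims <- vapply(stack, function(p) dim(p), integer(3L))
  if (length(unique(dims[3L, ])) != 1L)
    stop("inconsistent channel counts across planes")
  if (length(unique(dims[1L, ])) != 1L || length(unique(dims[2L, ])) != 1L)
    stop("inconsistent plane geometry across the stack")
  lapply(stack, unmix_image, prints = prints, ...)
}
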