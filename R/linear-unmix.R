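#' Build the mixing matrix from a fingerprint set
#'
#' The `n x m` matrix whose column `j` is fingerprint `j`'s unit-sum weight
#' vector: detected signal is modeled as `S = A %*% F` with `F` the
#' per-fluorophore contributions. With more fluorophores than channels the
#' matrix is flagged underdetermined (attribute `underdetermined`), in which
#' case the linear system has no unique solution and only similarity
#' matching applies.
#'
#' @param prints A [fingerprint_set()].
#' @return Numeric `n x m` matrix with fluorophore names as column names.
#' @export
build_mixing_matrix <- function(prints) {
  stopifnot(inherits(prints, "fingerprint_set"))
  A <- prints$weights
  structure(A, underdetermined = ncol(A) > nrow(A))
}

#' Solve one pixel by linear unmixing
#'
#' Minimizes `||S - A F||_2` over fluorophore contributions `F`, via a
#' QR-based least-squares solve (`"ols"`, may return negative contributions)
#' or non-negative least squares (`"nnls"`). Requires at least as many
#' channels as fluorophores: in the underdetermined case linear unmixing
#' fails by construction and the similarity classifier
#' ([classify_pixel()]) is the applicable method.
#'
#' @param s Numeric per-channel intensity vector.
#' @param A Mixing matrix from [build_mixing_matrix()] (n rows x m columns).
#' @param mode `"ols"` or `"nnls"`.
#' @return Numeric length-m abundance vector (named when `A` has column
#'   names).
#' @examples
#' A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)
#' solve_pixel(c(14, 16), A)  # c(10, 20)
#' @export
solve_pixel <- function(s, A, mode = c("ols", "nnls")) {
  mode <- match.arg(mode)
  s <- as.numeric(s)
  if (length(s) != nrow(A))
    stop("dimension mismatch: pixel has ", length(s), " channels, matrix has ",
         nrow(A), " rows")
  if (ncol(A) > nrow(A))
    stop("underdetermined system (", ncol(A), " fluorophores > ", nrow(A),
         " channels): linear unmixing fails here; use similarity unmixing (SIMI)")
  if (qr(A)$rank < ncol(A))
    stop("singular mixing matrix: fingerprints are linearly dependent")
  f <- if (mode == "ols") {
    qr.solve(A, s)
  } else {
    pracma::lsqnonneg(unclass(A), s)$x
  }
  stats::setNames(as.numeric(f), colnames(A))
}

#' Linear unmixing of a full image
#'
#' Per-pixel least-squares abundances under the linear detection model,
#' written as one abundance map per fluorophore. The OLS path is solved for
#' all pixels in one QR factorization; NNLS runs the active-set solver per
#' pixel.
#'
#' @param image A [multichannel_image()].
#' @param prints A [fingerprint_set()] with `m <= n`.
#' @param mode `"ols"` or `"nnls"`.
#' @return `H x W x m` abundance array (fluorophore names in `dimnames`).
#' @export
linear_unmix_image <- function(image, prints, mode = c("ols", "nnls")) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "multichannel_image"),
            inherits(prints, "fingerprint_set"))
  d <- dim(image)
  if (d[3L] != n_channels(prints))
    stop("image has ", d[3L], " channels but fingerprints have ",
         n_channels(prints))
  A <- build_mixing_matrix(prints)
  if (ncol(A) > nrow(A))
    stop("underdetermined system (", ncol(A), " fluorophores > ", nrow(A),
         " channels): linear unmixing fails here; use similarity unmixing (SIMI)")
  if (qr(A)$rank < ncol(A))
    stop("singular mixing matrix: fingerprints are linearly dependent")
  npix <- d[1L] * d[2L]
  P <- matrix(unclass(image), nrow = npix, ncol = d[3L])
  F <- if (mode == "ols") {
    t(qr.coef(qr(A), t(P)))
  } else {
    t(apply(P, 1L, function(s) pracma::lsqnonneg(unclass(A), s)$x))
  }
  array(F, dim = c(d[1L], d[2L], ncol(A)),
        dimnames = list(NULL, NULL, colnames(A)))
}
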