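#' Normalize a channel vector to unit sum
#'
#' Converts a vector of raw per-channel intensities into a relative intensity
#' distribution summing to one. This is the normalization applied to every
#' pixel before fingerprint matching: the normalization constant is the
#' pixel's total cross-channel signal, so proportions between channels are
#' preserved exactly.
#'
#' @param x Numeric vector of nonnegative per-channel intensities (length
#'   >= 2, ordered by ascending detection-channel center wavelength).
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' normalize_channel_vector(c(10, 30, 60))  # 0.1 0.3 0.6
#' @export
normalize_channel_vector <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L)
    stop("channel vector must have at least 2 channels")
  if (anyNA(x) || any(x < 0))
    stop("channel intensities must be nonnegative and finite")
  total <- sum(x)
  if (total <= 0)
    stop("degenerate channel vector: all entries are zero")
  x / total
}

#' Construct a fluorophore fingerprint
#'
#' A fingerprint is a fluorophore's normalized emission signature: the
#' relative intensity it deposits in each detection channel, summing to one.
#' Weights below `1e-12` (e.g. tiny negatives left by background subtraction
#' upstream) are clamped to zero before renormalization so the result is
#' always a valid probability vector.
#'
#' @param name Single character string identifying the fluorophore.
#' @param weights Numeric vector of nonnegative per-channel weights (length
#'   >= 2); normalized to unit sum.
#' @return Object of class `"fingerprint"`: list with `name` and `weights`.
#' @examples
#' fingerprint("eGFP", c(1, 3, 6))
#' @export
fingerprint <- function(name, weights) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("fingerprint name must be a non-empty string")
  w <- as.numeric(weights)
  if (length(w) < 2L)
    stop("fingerprint needs at least 2 channels")
  if (anyNA(w) || any(w < -1e-12))
    stop("fingerprint weights must be nonnegative")
  w[w < 1e-12] <- 0
  if (sum(w) <= 0)
    stop("degenerate fingerprint: all weights are zero")
  structure(list(name = name, weights = w / sum(w)), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint>", x$name, ":",
      paste(sprintf("%.4f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Construct a set of fingerprints
#'
#' Bundles `m` fingerprints measured on the same `n`-channel detection
#' system. Column `j` of [build_mixing_matrix()] is fingerprint `j`; the set
#' may hold more fingerprints than channels (the underdetermined regime in
#' which similarity matching, unlike linear unmixing, still operates).
#'
#' @param fingerprints List of [fingerprint()] objects with identical length
#'   and unique names.
#' @param channel_centers Optional numeric vector of per-channel center
#'   wavelengths (nm), ascending.
#' @param channel_bandwidths Optional numeric vector of full filter
#'   bandwidths (nm).
#' @return Object of class `"fingerprint_set"`.
#' @export
fingerprint_set <- function(fingerprints, channel_centers = NULL,
                            channel_bandwidths = NULL) {
  if (inherits(fingerprints, "fingerprint")) fingerprints <- list(fingerprints)
  if (!length(fingerprints) || !all(vapply(fingerprints, inherits, TRUE, "fingerprint")))
    stop("'fingerprints' must be a non-empty list of fingerprint objects")
  nms <- vapply(fingerprints, function(f) f$name, "")
  if (anyDuplicated(nms))
    stop("fingerprint names must be unique")
  lens <- vapply(fingerprints, function(f) length(f$weights), 0L)
  if (length(unique(lens)) != 1L)
    stop("all fingerprints must have the same number of channels")
  n <- lens[[1L]]
  if (!is.null(channel_centers) && length(channel_centers) != n)
    stop("channel_centers length must equal the number of channels")
  if (!is.null(channel_bandwidths) && length(channel_bandwidths) != n)
    stop("channel_bandwidths length must equal the number of channels")
  W <- vapply(fingerprints, function(f) f$weights, numeric(n))
  W <- matrix(W, nrow = n, dimnames = list(NULL, nms))
  structure(list(weights = W, channel_centers = channel_centers,
                 channel_bandwidths = channel_bandwidths),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("<fingerprint_set>", n_fluorophores(x), "fluorophores x",
      n_channels(x), "channels\n")
  print(round(t(x$weights), 4))
  invisible(x)
}

#' Number of detection channels in a fingerprint set
#' @param x A `fingerprint_set`.
#' @return Integer channel count `n`.
#' @export
n_channels <- function(x) nrow(x$weights)

#' Number of fluorophores in a fingerprint set
#' @param x A `fingerprint_set`.
#' @return Integer fluorophore count `m`.
#' @export
n_fluorophores <- function(x) ncol(x$weights)

#' Fluorophore names of a fingerprint set
#' @param x A `fingerprint_set`.
#' @return Character vector of names, in fingerprint order.
#' @export
fluorophore_names <- function(x) colnames(x$weights)

as_weight_vector <- function(a) {
  if (inherits(a, "fingerprint")) a$weights else as.numeric(a)
}

#' Squared-difference similarity score
#'
#' The matching score between a pixel's normalized signal distribution `b`
#' and a fingerprint `a`: `sum((b - a)^2)`. Zero iff the two distributions
#' are identical; its square root is the Euclidean distance, so the usual
#' metric properties hold. Both arguments must be unit-sum distributions of
#' equal length.
#'
#' @param b Numeric unit-sum vector (normalized pixel signal) or fingerprint.
#' @param a Fingerprint or numeric unit-sum vector.
#' @return Nonnegative scalar score.
#' @examples
#' similarity_score(c(0.5, 0.5), fingerprint("A", c(1, 0)))  # 0.5
#' @export
similarity_score <- function(b, a) {
  b <- as_weight_vector(b)
  a <- as_weight_vector(a)
  if (length(b) != length(a))
    stop("dimension mismatch: vectors have lengths ", length(b), " and ", length(a))
  if (abs(sum(b) - 1) > 1e-6 || abs(sum(a) - 1) > 1e-6)
    stop("similarity_score expects unit-sum distributions")
  sum((b - a)^2)
}

#' Minimum pairwise fingerprint separation
#'
#' The smallest squared-difference score over all unordered pairs in a
#' fingerprint set. Classification quality is governed by this margin:
#' fluorophores remain separable as long as their fingerprints differ, and
#' the count of separable fluorophores is not limited by the channel count
#' unless two fingerprints become (near-)identical.
#'
#' @param x A `fingerprint_set` with at least two fingerprints.
#' @return Smallest pairwise score (0 means two fingerprints coincide).
#' @export
min_pairwise_separation <- function(x) {
  m <- n_fluorophores(x)
  if (m < 2L)
    stop("pairwise separation needs at least 2 fingerprints")
  best <- Inf
  for (j in seq_len(m - 1L))
    for (k in seq.int(j + 1L, m)) {
      s <- sum((x$weights[, j] - x$weights[, k])^2)
      if (s < best) best <- s
    }
  best
}

#' Write fingerprints to CSV or JSON
#'
#' CSV layout: one row per fluorophore, first column `name`, remaining
#' columns the channel weights in wavelength order. JSON additionally stores
#' channel center wavelengths and bandwidths. Weights are serialized at full
#' double precision so a write/read cycle reproduces them to better than
#' 1e-12.
#'
#' @param x A `fingerprint_set`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(x, path) {
  stopifnot(inherits(x, "fingerprint_set"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    n <- n_channels(x)
    df <- data.frame(name = fluorophore_names(x),
                     matrix(sprintf("%.17g", t(x$weights)), ncol = n,
                            dimnames = list(NULL, paste0("ch", seq_len(n)))),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    obj <- list(
      fluorophores = lapply(fluorophore_names(x), function(nm)
        list(name = nm, weights = unname(x$weights[, nm]))),
      channel_centers = x$channel_centers,
      channel_bandwidths = x$channel_bandwidths)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else stop("unsupported fingerprint format: .", ext)
  invisible(path)
}

#' Read fingerprints from CSV or JSON
#'
#' @param path Path written by [write_fingerprints()] (format by extension).
#' @return A `fingerprint_set`.
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"name" %in% names(df) || ncol(df) < 3L)
      stop("fingerprint CSV needs a 'name' column plus >= 2 channel columns")
    fps <- lapply(seq_len(nrow(df)), function(i)
      fingerprint(df$name[i], as.numeric(df[i, -1L])))
    fingerprint_set(fps)
  } else if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    fps <- lapply(obj$fluorophores, function(f)
      fingerprint(f$name, as.numeric(f$weights)))
    fingerprint_set(fps,
                    channel_centers = if (length(obj$channel_centers)) as.numeric(obj$channel_centers),
                    channel_bandwidths = if (length(obj$channel_bandwidths)) as.numeric(obj$channel_bandwidths))
  } else stop("unsupported fingerprint format: .", ext)
}
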