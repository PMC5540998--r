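#' Estimate per-channel background offsets
#'
#' Detector offsets differ between PMTs, so background is estimated per
#' channel, never as a scalar. The default `darkest-percentile` method ranks
#' pixels by total cross-channel signal and returns, per channel, the mean
#' intensity of the dimmest `p` percent.
#'
#' @param image A [multichannel_image()].
#' @param method `"darkest-percentile"`, `"user-ROI"` (mean over `roi`
#'   pixels), or `"explicit"` (echo `offsets`).
#' @param p Percentile for the darkest-percentile method (default 5).
#' @param roi Logical pixel matrix for `"user-ROI"`.
#' @param offsets Numeric length-n vector for `"explicit"`.
#' @return Object of class `"background_estimate"`: list with
#'   `per_channel_offset` and `method`.
#' @export
estimate_background <- function(image,
                                method = c("darkest-percentile", "user-ROI", "explicit"),
                                p = 5, roi = NULL, offsets = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(image, "multichannel_image"))
  d <- dim(image)
  n <- d[3L]
  off <- switch(method,
    "darkest-percentile" = {
      if (p <= 0 || p > 100) stop("percentile p must be in (0, 100]")
      total <- apply(unclass(image), c(1L, 2L), sum)
      k <- max(1L, floor(length(total) * p / 100))
      idx <- order(total)[seq_len(k)]
      vapply(seq_len(n), function(j) mean(unclass(image)[, , j][idx]), 0)
    },
    "user-ROI" = {
      if (is.null(roi) || !is.logical(roi) || !identical(dim(roi), d[1:2]))
        stop("user-ROI method needs a logical 'roi' matrix matching the image")
      if (!any(roi)) stop("ROI is empty")
      vapply(seq_len(n), function(j) mean(unclass(image)[, , j][roi]), 0)
    },
    "explicit" = {
      if (is.null(offsets) || length(offsets) != n)
        stop("explicit method needs 'offsets' of length n")
      as.numeric(offsets)
    })
  if (any(off < 0)) stop("background offsets must be nonnegative")
  structure(list(per_channel_offset = off, method = method),
            class = "background_estimate")
}

#' Compute a foreground mask
#'
#' A pixel is foreground when its background-subtracted total signal exceeds
#' a threshold: either Otsu's threshold on the total-signal image (default)
#' or an absolute value.
#'
#' @param image A [multichannel_image()].
#' @param background Optional [estimate_background()] result (`NULL` = no
#'   subtraction).
#' @param threshold `"otsu"` or a nonnegative number (counts of total
#'   signal).
#' @param min_pixels Smallest acceptable foreground size (default 100);
#'   fewer surviving pixels is an error, as is an empty mask.
#' @return Object of class `"foreground_mask"`: logical matrix with
#'   attribute `pixel_count`.
#' @export
foreground_mask <- function(image, background = NULL, threshold = "otsu",
                            min_pixels = 100L) {
  stopifnot(inherits(image, "multichannel_image"))
  total <- apply(unclass(image), c(1L, 2L), sum)
  if (!is.null(background)) {
    stopifnot(inherits(background, "background_estimate"))
    if (length(background$per_channel_offset) != dim(image)[3L])
      stop("background length does not match channel count")
    total <- total - sum(background$per_channel_offset)
  }
  thr <- if (identical(threshold, "otsu")) {
    if (max(total) <= 0)
      stop("empty foreground mask: image has no signal above background")
    otsu_threshold(total)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
      stop("threshold must be \"otsu\" or a nonnegative number")
    threshold
  }
  mask <- total > thr
  if (!any(mask)) stop("empty foreground mask: no pixel exceeds the threshold")
  if (sum(mask) < min_pixels)
    stop("foreground mask has ", sum(mask), " pixels, fewer than min_pixels = ",
         min_pixels)
  structure(mask, class = "foreground_mask", pixel_count = sum(mask),
            threshold_used = thr)
}

#' Extract a fluorophore fingerprint from a single-color reference image
#'
#' The fingerprint is the normalized histogram of average signal intensities
#' across detection channels: per-channel mean over foreground pixels,
#' background-subtracted, negatives clamped to zero, normalized to unit sum.
#' A `"median"` statistic is offered for robustness against bright debris.
#'
#' @param image A [multichannel_image()] of a single-fluorophore sample.
#' @param background Optional [estimate_background()] result.
#' @param mask Optional [foreground_mask()]; defaults to Otsu on the total
#'   signal.
#' @param name Fluorophore name for the resulting fingerprint.
#' @param stat `"mean"` (default) or `"median"` per-channel statistic.
#' @return A [fingerprint()].
#' @export
extract_fingerprint <- function(image, background = NULL, mask = NULL,
                                name, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(inherits(image, "multichannel_image"))
  n <- dim(image)[3L]
  if (is.null(mask)) mask <- foreground_mask(image, background)
  if (!any(mask)) stop("foreground mask is empty")
  fun <- if (stat == "mean") mean else stats::median
  avg <- vapply(seq_len(n), function(j) fun(unclass(image)[, , j][mask]), 0)
  if (!is.null(background)) {
    stopifnot(inherits(background, "background_estimate"))
    avg <- avg - background$per_channel_offset
  }
  avg <- pmax(avg, 0)
  if (sum(avg) <= 0)
    stop("degenerate fingerprint: no signal left after background subtraction")
  fingerprint(name, avg)
}

#' Define an empirical fingerprint from a region of a mixed image
#'
#' For signals never recorded in isolation (e.g. macrophage autofluorescence
#' or an intravascular dye), a fingerprint can be read directly off a mixed
#' image from a user-drawn region known to contain only that signal. The
#' computation is identical to [extract_fingerprint()] restricted to the
#' region.
#'
#' @param mixed_image A [multichannel_image()].
#' @param region Logical pixel matrix marking the annotated region.
#' @param background Optional [estimate_background()] result.
#' @param name Fluorophore name.
#' @param stat `"mean"` or `"median"`.
#' @return A [fingerprint()].
#' @export
fingerprint_from_annotated_region <- function(mixed_image, region,
                                              background = NULL, name,
                                              stat = c("mean", "median")) {
  stopifnot(inherits(mixed_image, "multichannel_image"))
  if (!is.logical(region) || !identical(dim(region), dim(mixed_image)[1:2]))
    stop("region must be a logical matrix matching the image geometry")
  if (!any(region)) stop("annotated region is empty")
  mask <- structure(region, class = "foreground_mask", pixel_count = sum(region))
  extract_fingerprint(mixed_image, background = background, mask = mask,
                      name = name, stat = stat)
}
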