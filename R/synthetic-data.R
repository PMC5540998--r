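#' Noise model for synthetic scenes
#'
#' Emulates PMT detection noise on an expectation-scale count image:
#' per-pixel, per-channel independent Poisson shot noise, then additive
#' Gaussian read noise (clamped at zero), then a constant detector offset.
#'
#' @param poisson Apply Poisson shot noise (default `TRUE`).
#' @param gaussian_sigma Read-noise standard deviation in counts (>= 0).
#' @param offset Detector offset in counts, scalar or per channel.
#' @return Object of class `"noise_model"`.
#' @export
noise_model <- function(poisson = TRUE, gaussian_sigma = 0, offset = 0) {
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  if (any(offset < 0)) stop("offset must be >= 0")
  structure(list(poisson = isTRUE(poisson), gaussian_sigma = gaussian_sigma,
                 offset = offset), class = "noise_model")
}

#' Configuration of a synthetic one-fluorophore-per-cell scene
#'
#' Describes a scene of disk-shaped cells, each emitting with exactly one
#' fingerprint (the validity condition of similarity unmixing), with
#' per-object lognormal brightness variation, optional mixed-signature
#' "phagocyte" objects whose emission is a stated convex combination of two
#' fingerprints, a constant background, and a detection noise model.
#'
#' @param fingerprints A [fingerprint_set()]; one scene class per
#'   fingerprint.
#' @param image_size `c(H, W)` in pixels.
#' @param n_objects Number of cells to place.
#' @param radius_range `c(min, max)` disk radius in pixels.
#' @param mean_brightness Mean total counts per foreground pixel across
#'   objects.
#' @param brightness_sigma Lognormal spread factor (sdlog) of per-object
#'   brightness; 0 = uniform.
#' @param class_proportions Class sampling probabilities (default equal).
#' @param mixed_object_fraction Fraction of objects rendered as the mixed
#'   "phagocyte" class (label `m + 1`).
#' @param mixed_components Indices `c(j, k)` of the two fingerprints the
#'   mixed class combines.
#' @param mixed_weight Convex weight `w` of the first component.
#' @param background_level Background counts per channel (scalar or
#'   per-channel vector).
#' @param noise A [noise_model()].
#' @param ensure_all_classes Guarantee at least one object per pure class
#'   when `n_objects >= m` (default `TRUE`).
#' @param seed Mandatory integer seed; every stochastic choice derives from
#'   it.
#' @return Object of class `"scene_config"`.
#' @export
scene_config <- function(fingerprints, image_size = c(128L, 128L),
                         n_objects = 30L, radius_range = c(4, 9),
                         mean_brightness = 200, brightness_sigma = 0.25,
                         class_proportions = NULL,
                         mixed_object_fraction = 0,
                         mixed_components = c(1L, 2L), mixed_weight = 0.5,
                         background_level = 0.5,
                         noise = noise_model(poisson = TRUE, gaussian_sigma = 1),
                         ensure_all_classes = TRUE, seed) {
  stopifnot(inherits(fingerprints, "fingerprint_set"))
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("scene_config requires an explicit integer seed")
  m <- n_fluorophores(fingerprints)
  if (is.null(class_proportions)) class_proportions <- rep(1 / m, m)
  if (length(class_proportions) != m)
    stop("class_proportions must have one entry per fingerprint")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0)) stop("class_proportions must be nonnegative")
  if (mixed_object_fraction < 0 || mixed_object_fraction > 1)
    stop("mixed_object_fraction must lie in [0, 1]")
  if (mixed_object_fraction > 0) {
    if (m < 2L) stop("mixed objects need at least 2 fingerprints")
    if (length(mixed_components) != 2L ||
        any(mixed_components < 1L) || any(mixed_components > m) ||
        mixed_components[1L] == mixed_components[2L])
      stop("mixed_components must be two distinct fingerprint indices")
    if (mixed_weight < 0 || mixed_weight > 1)
      stop("mixed_weight must lie in [0, 1]")
  }
  if (mean_brightness <= 0 || brightness_sigma < 0)
    stop("brightness parameters must be positive (mean) and nonnegative (sigma)")
  if (any(background_level < 0)) stop("background_level must be >= 0")
  if (length(radius_range) != 2L || radius_range[1L] <= 0 ||
      radius_range[2L] < radius_range[1L])
    stop("radius_range must be c(min, max) with 0 < min <= max")
  stopifnot(inherits(noise, "noise_model"))
  structure(list(fingerprints = fingerprints,
                 image_size = as.integer(image_size),
                 n_objects = as.integer(n_objects),
                 radius_range = radius_range,
                 mean_brightness = mean_brightness,
                 brightness_sigma = brightness_sigma,
                 class_proportions = class_proportions,
                 mixed_object_fraction = mixed_object_fraction,
                 mixed_components = as.integer(mixed_components),
                 mixed_weight = mixed_weight,
                 background_level = background_level,
                 noise = noise,
                 ensure_all_classes = isTRUE(ensure_all_classes),
                 seed = as.integer(seed)),
            class = "scene_config")
}

disk_pixels <- function(cx, cy, r, h, w) {
  ii <- max(1L, floor(cx - r)):min(h, ceiling(cx + r))
  jj <- max(1L, floor(cy - r)):min(w, ceiling(cy + r))
  g <- expand.grid(i = ii, j = jj)
  g <- g[(g$i - cx)^2 + (g$j - cy)^2 <= r^2, , drop = FALSE]
  cbind(g$i, g$j)
}

#' Sample a ground-truth scene layout
#'
#' Places `n_objects` non-overlapping disks by dart throwing (bounded
#' retries), draws a class for each object according to the configured
#' proportions (guaranteeing, by default, that every pure class appears at
#' least once), and draws per-object brightness from the lognormal spread.
#' Fully deterministic given the configuration seed.
#'
#' @param config A [scene_config()].
#' @return Object of class `"ground_truth"`: list with `labels` (integer
#'   matrix: 0 background, `1..m` pure classes, `m + 1` the mixed class)
#'   and `objects` (data frame: id, class, cx, cy, radius, brightness).
#' @export
sample_layout <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$image_size[1L]; w <- config$image_size[2L]
  m <- n_fluorophores(config$fingerprints)
  nobj <- config$n_objects
  mean_r <- mean(config$radius_range)
  if (nobj * pi * mean_r^2 > 0.4 * h * w)
    stop("packing infeasible: expected object area exceeds 40% of the image")
  set.seed(config$seed)
  labels <- matrix(0L, h, w)
  if (nobj == 0L)
    return(structure(list(labels = labels,
                          objects = data.frame(id = integer(), class = integer(),
                                               cx = numeric(), cy = numeric(),
                                               radius = numeric(),
                                               brightness = numeric())),
                     class = "ground_truth"))
  n_mixed <- round(config$mixed_object_fraction * nobj)
  n_pure <- nobj - n_mixed
  classes <- sample.int(m, n_pure, replace = TRUE, prob = config$class_proportions)
  if (config$ensure_all_classes && n_pure >= m) {
    present <- config$class_proportions > 0
    need <- which(present & !(seq_len(m) %in% classes))
    if (length(need))
      classes[sample.int(n_pure, length(need))] <- need
  }
  classes <- c(classes, rep(m + 1L, n_mixed))
  classes <- classes[sample.int(nobj)]       # shuffle placement order
  cx <- cy <- rr <- numeric(nobj)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 400L * nobj
  while (placed < nobj && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- stats::runif(1L, config$radius_range[1L], config$radius_range[2L])
    x <- stats::runif(1L, r + 1, h - r)
    y <- stats::runif(1L, r + 1, w - r)
    if (placed > 0L) {
      sq <- (cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2
      if (any(sq < (rr[seq_len(placed)] + r + 1)^2)) next
    }
    placed <- placed + 1L
    cx[placed] <- x; cy[placed] <- y; rr[placed] <- r
  }
  if (placed < nobj)
    stop("packing infeasible: could not place ", nobj, " objects in ",
         max_attempts, " attempts")
  sdlog <- config$brightness_sigma
  brightness <- if (sdlog > 0)
    stats::rlnorm(nobj, meanlog = log(config$mean_brightness) - sdlog^2 / 2,
                  sdlog = sdlog)
  else rep(config$mean_brightness, nobj)
  for (k in seq_len(nobj)) {
    px <- disk_pixels(cx[k], cy[k], rr[k], h, w)
    labels[px] <- classes[k]
  }
  structure(list(labels = labels,
                 objects = data.frame(id = seq_len(nobj), class = classes,
                                      cx = cx, cy = cy, radius = rr,
                                      brightness = brightness)),
            class = "ground_truth")
}

scene_class_weights <- function(config) {
  A <- config$fingerprints$weights
  if (config$mixed_object_fraction > 0) {
    jk <- config$mixed_components
    wmix <- config$mixed_weight * A[, jk[1L]] +
      (1 - config$mixed_weight) * A[, jk[2L]]
    A <- cbind(A, mixed = wmix)
  }
  A
}

#' Render the noiseless expectation image of a scene
#'
#' Each foreground pixel of an object of class `j` receives
#' `brightness * a_j` counts per channel — the generative reading of the
#' linear detection model — and the constant background level is added
#' everywhere. Mixed-class objects use the stated convex combination of
#' their two component fingerprints.
#'
#' @param truth A [sample_layout()] result.
#' @param config The matching [scene_config()].
#' @return A noiseless [multichannel_image()] of expected counts.
#' @export
render_scene <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "scene_config"))
  h <- config$image_size[1L]; w <- config$image_size[2L]
  n <- n_channels(config$fingerprints)
  A <- scene_class_weights(config)
  if (nrow(truth$objects) && max(truth$objects$class) > ncol(A))
    stop("ground truth contains a class without a fingerprint")
  bg <- rep(config$background_level, length.out = n)
  img <- array(rep(bg, each = h * w), dim = c(h, w, n))
  for (k in seq_len(nrow(truth$objects))) {
    obj <- truth$objects[k, ]
    px <- disk_pixels(obj$cx, obj$cy, obj$radius, h, w)
    keep <- truth$labels[px] == obj$class   # guard against rare co-rounding
    px <- px[keep, , drop = FALSE]
    for (j in seq_len(n))
      img[cbind(px, j)] <- obj$brightness * A[j, obj$class] + bg[j]
  }
  cc <- tryCatch(default_filter_set(n)$center, error = function(e) NULL)
  multichannel_image(img, channel_centers = cc,
                     channel_names = if (!is.null(cc)) sprintf("ch%d", seq_len(n)))
}

#' Apply detection noise to an expectation image
#'
#' Per-pixel, per-channel independent draws: Poisson (when enabled) on the
#' expected counts, then additive Gaussian read noise clamped at zero, then
#' the detector offset. Deterministic for a given seed.
#'
#' @param image Expectation-scale [multichannel_image()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return A noisy [multichannel_image()].
#' @export
add_noise <- function(image, noise, seed) {
  stopifnot(inherits(image, "multichannel_image"), inherits(noise, "noise_model"))
  if (missing(seed)) stop("add_noise requires an explicit seed")
  d <- dim(image)
  v <- as.vector(unclass(image))
  set.seed(as.integer(seed))
  if (noise$poisson) v <- as.numeric(stats::rpois(length(v), v))
  if (noise$gaussian_sigma > 0)
    v <- pmax(v + stats::rnorm(length(v), 0, noise$gaussian_sigma), 0)
  a <- array(v, dim = d)
  off <- rep(noise$offset, length.out = d[3L])
  if (any(off > 0))
    a <- a + array(rep(off, each = d[1L] * d[2L]), dim = d)
  multichannel_image(a,
                     channel_centers = attr(image, "channel_centers"),
                     channel_bandwidths = attr(image, "channel_bandwidths"),
                     channel_names = attr(image, "channel_names"))
}

#' Simulate a complete scene
#'
#' Convenience pipeline: [sample_layout()], [render_scene()], then
#' [add_noise()] (noise seed derived from the configuration seed).
#'
#' @param config A [scene_config()].
#' @return List with `image` (noisy), `expectation` (noiseless), `truth`.
#' @export
simulate_scene <- function(config) {
  truth <- sample_layout(config)
  expectation <- render_scene(truth, config)
  image <- add_noise(expectation, config$noise, seed = config$seed + 1L)
  list(image = image, expectation = expectation, truth = truth)
}

dominant_channel_prints <- function(n, names = sprintf("F%d", seq_len(n))) {
  lapply(seq_len(n), function(j) {
    w <- exp(-((seq_len(n) - j)^2) / 1.8) + 0.02
    fingerprint(names[j], w)
  })
}

#' Preset simulation scenarios
#'
#' Ready-made channel/fluorophore configurations mirroring the regimes of
#' interest: a two-channel three-fluorophore underdetermined scene, a
#' six-channel determined scene, a six-channel seven-signal underdetermined
#' scene (six dominant-channel signatures plus one spectrally broad
#' autofluorescence-like signature), and a five-channel five-fluorophore
#' scene. The shipped fingerprints are synthetic constructions chosen for a
#' minimum pairwise separation of at least 0.02; they are not measured
#' emission signatures of any real fluorophore.
#'
#' @param name One of `"two_channel_three_class"`,
#'   `"six_channel_six_class"`, `"six_channel_seven_class"`,
#'   `"five_channel_five_class"`.
#' @param seed Scene seed (default 1).
#' @param ... Overrides passed to [scene_config()].
#' @return List with `config` (a [scene_config()]) and `fingerprints`.
#' @export
preset_scenario <- function(name, seed = 1L, ...) {
  presets <- c("two_channel_three_class", "six_channel_six_class",
               "six_channel_seven_class", "five_channel_five_class")
  if (!is.character(name) || length(name) != 1L || !name %in% presets)
    stop("unknown preset; available: ", paste(presets, collapse = ", "))
  fps <- switch(name,
    two_channel_three_class = fingerprint_set(list(
      fingerprint("F1", c(0.9, 0.1)),
      fingerprint("F2", c(0.5, 0.5)),
      fingerprint("F3", c(0.1, 0.9)))),
    six_channel_six_class = fingerprint_set(dominant_channel_prints(6L)),
    six_channel_seven_class = fingerprint_set(c(
      dominant_channel_prints(6L),
      list(fingerprint("autofluor", rep(1, 6L))))),
    five_channel_five_class = fingerprint_set(dominant_channel_prints(5L)))
  config <- scene_config(fingerprints = fps, seed = seed, ...)
  list(config = config, fingerprints = fps)
}
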