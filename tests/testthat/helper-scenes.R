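# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

three_prints_2ch <- function() {
  fingerprint_set(list(fingerprint("A", c(0.9, 0.1)),
                       fingerprint("B", c(0.5, 0.5)),
                       fingerprint("C", c(0.1, 0.9))))
}

# a uniform image where every pixel carries the same channel vector
constant_image <- function(values, h = 12L, w = 12L) {
  n <- length(values)
  multichannel_image(array(rep(values, each = h * w), dim = c(h, w, n)))
}

# noiseless image with one centered disk of the given channel vector on a
# constant background
disk_image <- function(values, bg = 0, h = 40L, w = 40L, radius = 10) {
  n <- length(values)
  a <- array(rep(rep(bg, length.out = n), each = h * w), dim = c(h, w, n))
  cx <- (h + 1) / 2; cy <- (w + 1) / 2
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((i - cx)^2 + (j - cy)^2 <= radius^2)
      a[i, j, ] <- values + rep(bg, length.out = n)
  multichannel_image(a)
}

disk_mask <- function(h = 40L, w = 40L, radius = 10) {
  cx <- (h + 1) / 2; cy <- (w + 1) / 2
  outer(seq_len(h), seq_len(w),
        function(i, j) (i - cx)^2 + (j - cy)^2 <= radius^2)
}

# independent per-pixel oracle: classify every pixel with a naive loop that
# reuses only the scalar primitives, never the vectorized image path
naive_unmix_labels <- function(image, prints, threshold = 0) {
  d <- dim(image)
  labels <- matrix(0L, d[1L], d[2L])
  resid <- matrix(NA_real_, d[1L], d[2L])
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    s <- unclass(image)[i, j, ]
    if (sum(s) <= threshold) next
    b <- s / sum(s)
    scores <- apply(prints$weights, 2L, function(a) sum((b - a)^2))
    labels[i, j] <- which.min(scores)
    resid[i, j] <- min(scores)
  }
  list(labels = labels, residual = resid)
}

# scene whose every foreground pixel is exactly proportional to one
# fingerprint (no noise, no brightness spread)
pure_scene <- function(prints, seed = 1L, ...) {
  cfg <- scene_config(prints, seed = seed, brightness_sigma = 0,
                      background_level = 0,
                      noise = noise_model(poisson = FALSE), ...)
  simulate_scene(cfg)
}

noisy_scene <- function(prints, seed, mean_brightness = 200, ...) {
  cfg <- scene_config(prints, seed = seed, mean_brightness = mean_brightness, ...)
  simulate_scene(cfg)
}
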