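test_that("pixel classification picks the closest fingerprint", {
  fps <- three_prints_2ch()
  # exact match: zero residual
  r <- classify_pixel(100 * fps$weights[, 2], fps)
  expect_equal(r$label, 2L)
  expect_equal(r$residual, 0)
  # scores 0.98 / 0.18 / 0.02 -> C
  r <- classify_pixel(c(20, 80), fps, threshold = 10)
  expect_equal(r$label, 3L)
  expect_equal(r$residual, 0.02)
  expect_false(r$ambiguous)
  # exact tie 0.08 / 0.08 between B and C -> lowest index, flagged
  r <- classify_pixel(c(30, 70), fps)
  expect_equal(r$label, 2L)
  expect_equal(r$residual, 0.08)
  expect_true(r$ambiguous)
  # sub-threshold -> background
  r <- classify_pixel(c(1, 1), fps, threshold = 10)
  expect_equal(r$label, 0L)
  expect_true(is.na(r$residual))
  expect_error(classify_pixel(c(1, 1, 1), fps), "dimension mismatch")
})

test_that("labels are invariant to rescaling the pixel above threshold", {
  fps <- three_prints_2ch()
  set.seed(5)
  for (i in 1:30) {
    s <- runif(2, 1, 100)
    k <- runif(1, 0.1, 1e3)
    expect_identical(classify_pixel(k * s, fps)$label, classify_pixel(s, fps)$label)
  }
})

test_that("noiseless scenes are recovered exactly, including more dyes than channels", {
  # determined: m = n = 3
  fps3 <- fingerprint_set(lapply(1:3, function(j)
    fingerprint(paste0("f", j), c(0.7, 0.2, 0.1)[c(j, j %% 3 + 1, (j + 1) %% 3 + 1)])))
  sc <- pure_scene(fps3, seed = 2)
  res <- unmix_image(sc$image, fps3, threshold = 1)
  fg <- sc$truth$labels > 0
  expect_true(all(res$labels[fg] == sc$truth$labels[fg]))
  expect_true(all(res$residual[fg] < 1e-18))
  # underdetermined: m = 3 > n = 2
  fps <- three_prints_2ch()
  sc2 <- pure_scene(fps, seed = 3)
  res2 <- unmix_image(sc2$image, fps, threshold = 1)
  fg2 <- sc2$truth$labels > 0
  expect_true(all(res2$labels[fg2] == sc2$truth$labels[fg2]))
})

test_that("vectorized unmixing agrees with the per-pixel oracle", {
  fps <- fingerprint_set(lapply(1:4, function(j) {
    set.seed(100 + j); fingerprint(paste0("f", j), runif(3) + 0.05)
  }))
  for (s in 1:4) {
    set.seed(s)
    img <- multichannel_image(array(runif(32 * 32 * 3, 0, 50), c(32, 32, 3)))
    # random prints may sit closer than the separability advisory threshold
    res <- suppressWarnings(unmix_image(img, fps, threshold = 5))
    oracle <- naive_unmix_labels(img, fps, threshold = 5)
    expect_identical(res$labels, oracle$labels)
    expect_equal(res$residual, oracle$residual, tolerance = 1e-10)
  }
})

test_that("deposited intensity conserves the measured foreground signal", {
  fps <- three_prints_2ch()
  sc <- noisy_scene(fps, seed = 8)
  res <- unmix_image(sc$image, fps, intensity = "total")
  total <- apply(unclass(sc$image), c(1, 2), sum)
  fg <- res$labels > 0
  expect_equal(sum(res$fluor_channels), sum(total[fg]))
  # exactly one nonzero fluorophore channel per foreground pixel
  nonzero <- apply(res$fluor_channels > 0, c(1, 2), sum)
  expect_true(all(nonzero[fg] == 1))
  expect_true(all(nonzero[!fg] == 0))
  # max mode deposits the brightest channel instead
  res_max <- unmix_image(sc$image, fps, intensity = "max")
  peak <- apply(unclass(sc$image), c(1, 2), max)
  expect_equal(sum(res_max$fluor_channels), sum(peak[fg]))
})

test_that("SIMI labels agree with the linear-unmixing argmax when m = n", {
  fps3 <- fingerprint_set(list(fingerprint("a", c(0.7, 0.2, 0.1)),
                               fingerprint("b", c(0.2, 0.6, 0.2)),
                               fingerprint("c", c(0.1, 0.2, 0.7))))
  sc <- pure_scene(fps3, seed = 4)
  res <- unmix_image(sc$image, fps3, threshold = 1)
  ab <- linear_unmix_image(sc$image, fps3)
  fg <- sc$truth$labels > 0
  lin_argmax <- apply(ab, c(1, 2), which.max)
  expect_true(all(res$labels[fg] == lin_argmax[fg]))
})

test_that("per-pixel accuracy under Poisson noise exceeds 0.95", {
  fps <- three_prints_2ch()
  accs <- vapply(1:10, function(s) {
    sc <- noisy_scene(fps, seed = s, mean_brightness = 200)
    res <- unmix_image(sc$image, fps)
    fg <- sc$truth$labels > 0
    mean(res$labels[fg] == sc$truth$labels[fg])
  }, 0)
  expect_true(all(accs > 0.95))
})

test_that("accuracy degrades monotonically as counts drop", {
  fps <- three_prints_2ch()
  acc_at <- function(counts) {
    mean(vapply(1:5, function(s) {
      sc <- noisy_scene(fps, seed = s, mean_brightness = counts)
      res <- unmix_image(sc$image, fps, threshold = max(2, counts / 20))
      fg <- sc$truth$labels > 0
      mean(res$labels[fg] == sc$truth$labels[fg])
    }, 0))
  }
  a500 <- acc_at(500); a50 <- acc_at(50); a10 <- acc_at(10)
  expect_gte(a500, a50)
  expect_gte(a50, a10)
  expect_lt(a10, a500)  # the gradient is real, not a chain of ties
})

test_that("stacks are processed plane-wise, independently and in order", {
  fps <- three_prints_2ch()
  sc <- noisy_scene(fps, seed = 6)
  plane <- sc$image
  stack <- list(plane, plane, plane)
  out <- unmix_stack(stack, fps, threshold = 10)
  expect_length(out, 3L)
  expect_identical(out[[1]]$labels, out[[2]]$labels)
  expect_identical(out[[2]]$labels, out[[3]]$labels)
  # permuted planes give identically permuted results
  sc2 <- noisy_scene(fps, seed = 7)
  two <- unmix_stack(list(sc$image, sc2$image), fps, threshold = 10)
  rev2 <- unmix_stack(list(sc2$image, sc$image), fps, threshold = 10)
  expect_identical(two[[1]]$labels, rev2[[2]]$labels)
  expect_identical(two[[2]]$labels, rev2[[1]]$labels)
  # inconsistent channel counts across planes are rejected
  bad <- multichannel_image(array(1, c(dim(plane)[1], dim(plane)[2], 3)))
  expect_error(unmix_stack(list(plane, bad), fps), "channel counts")
})

test_that("degenerate inputs warn: all-background image, near-identical prints", {
  fps <- three_prints_2ch()
  dark <- multichannel_image(array(0.01, c(8, 8, 2)))
  expect_warning(unmix_image(dark, fps, threshold = 10), "entirely background")
  close_fps <- fingerprint_set(list(fingerprint("a", c(0.5, 0.5)),
                                    fingerprint("b", c(0.501, 0.499))))
  img <- multichannel_image(array(runif(128, 10, 20), c(8, 8, 2)))
  expect_warning(unmix_image(img, close_fps, threshold = 1), "separation")
})
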