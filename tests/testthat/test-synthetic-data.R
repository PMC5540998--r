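test_that("scene layout is deterministic per seed and respects object count", {
  fps <- three_prints_2ch()
  cfg <- scene_config(fps, seed = 7)
  t1 <- sample_layout(cfg)
  t2 <- sample_layout(cfg)
  expect_identical(t1$labels, t2$labels)
  expect_identical(t1$objects, t2$objects)
  expect_equal(nrow(t1$objects), cfg$n_objects)
  # a different seed moves the objects
  t3 <- sample_layout(scene_config(fps, seed = 8))
  expect_false(identical(t1$labels, t3$labels))
  # empty scene
  t0 <- sample_layout(scene_config(fps, n_objects = 0L, seed = 1))
  expect_true(all(t0$labels == 0L))
  expect_equal(nrow(t0$objects), 0L)
})

test_that("objects never overlap and all classes appear", {
  fps <- three_prints_2ch()
  for (s in 1:5) {
    truth <- sample_layout(scene_config(fps, seed = s))
    obj <- truth$objects
    if (nrow(obj) > 1) {
      d2 <- as.matrix(dist(cbind(obj$cx, obj$cy)))^2
      rsum <- outer(obj$radius, obj$radius, "+")
      diag(d2) <- Inf
      expect_true(all(d2 > rsum^2))
    }
    expect_setequal(unique(obj$class), 1:3)
    # label image consistent with the object table
    expect_setequal(setdiff(unique(as.vector(truth$labels)), 0L),
                    unique(obj$class))
  }
})

test_that("class draws stay inside the multinomial 99% band", {
  fps2 <- fingerprint_set(list(fingerprint("a", c(0.9, 0.1)),
                               fingerprint("b", c(0.1, 0.9))))
  counts <- vapply(1:100, function(s) {
    truth <- sample_layout(scene_config(fps2, n_objects = 50L, seed = s,
                                        image_size = c(256L, 256L)))
    sum(truth$objects$class == 1L)
  }, 0)
  # Binomial(50, 0.5): 99% band approx 25 +/- 2.58 * sqrt(12.5) = [16, 34]
  expect_true(mean(counts >= 16 & counts <= 34) > 0.95)
  expect_gt(mean(counts), 22)
  expect_lt(mean(counts), 28)
})

test_that("infeasible packings are rejected", {
  fps <- three_prints_2ch()
  expect_error(scene_config(fps, seed = 1, radius_range = c(0, 3)), "radius_range")
  cfg <- scene_config(fps, n_objects = 500L, seed = 1)
  expect_error(sample_layout(cfg), "packing infeasible")
})

test_that("rendering follows the linear generative model exactly", {
  fps <- three_prints_2ch()
  cfg <- scene_config(fps, seed = 11, brightness_sigma = 0,
                      mean_brightness = 100, background_level = 0,
                      noise = noise_model(poisson = FALSE))
  truth <- sample_layout(cfg)
  img <- render_scene(truth, cfg)
  for (k in seq_len(nrow(truth$objects))) {
    cls <- truth$objects$class[k]
    px <- which(truth$labels == cls, arr.ind = TRUE)[1, ]
    expect_equal(unclass(img)[px[1], px[2], ], 100 * fps$weights[, cls],
                 tolerance = 1e-12)
  }
  # empty truth renders pure background
  cfg0 <- scene_config(fps, n_objects = 0L, seed = 1, background_level = 2.5)
  img0 <- render_scene(sample_layout(cfg0), cfg0)
  expect_true(all(unclass(img0) == 2.5))
})

test_that("mixed phagocyte-like objects emit the stated convex combination", {
  fps2 <- fingerprint_set(list(fingerprint("a", c(1, 0)),
                               fingerprint("b", c(0, 1))))
  cfg <- scene_config(fps2, seed = 5, n_objects = 10L,
                      brightness_sigma = 0, mean_brightness = 100,
                      background_level = 0,
                      mixed_object_fraction = 0.5, mixed_weight = 0.5,
                      noise = noise_model(poisson = FALSE))
  truth <- sample_layout(cfg)
  expect_equal(sum(truth$objects$class == 3L), 5L)  # label m+1 = 3
  img <- render_scene(truth, cfg)
  px <- which(truth$labels == 3L, arr.ind = TRUE)[1, ]
  expect_equal(unclass(img)[px[1], px[2], ], c(50, 50), tolerance = 1e-12)
})

test_that("noise application is seed-deterministic with correct moments", {
  img <- constant_image(c(100, 100), h = 100L, w = 100L)
  # identity when everything is off
  off <- add_noise(img, noise_model(poisson = FALSE, gaussian_sigma = 0), seed = 1)
  expect_equal(unclass(off), unclass(img))
  # Poisson: sample mean within the 3-sigma band of the expectation
  n1 <- add_noise(img, noise_model(poisson = TRUE), seed = 1)
  expect_lt(abs(mean(unclass(n1)) - 100), 3 * sqrt(100 / (100 * 100 * 2)))
  # same seed twice: identical; different seed: different
  n2 <- add_noise(img, noise_model(poisson = TRUE), seed = 1)
  expect_identical(unclass(n1), unclass(n2))
  n3 <- add_noise(img, noise_model(poisson = TRUE), seed = 2)
  expect_false(identical(unclass(n1), unclass(n3)))
  # offsets are added per channel after clamping
  n4 <- add_noise(img, noise_model(poisson = FALSE, offset = c(5, 10)), seed = 1)
  expect_equal(unclass(n4)[1, 1, ], c(105, 110))
})

test_that("presets reproduce the stated channel/fluorophore counts", {
  ps <- preset_scenario("two_channel_three_class", seed = 1)
  expect_equal(n_channels(ps$fingerprints), 2L)
  expect_equal(n_fluorophores(ps$fingerprints), 3L)
  expect_equal(unname(ps$fingerprints$weights),
               matrix(c(0.9, 0.1, 0.5, 0.5, 0.1, 0.9), 2))
  for (nm in c("six_channel_six_class", "six_channel_seven_class",
               "five_channel_five_class")) {
    ps <- preset_scenario(nm, seed = 1)
    expect_gte(min_pairwise_separation(ps$fingerprints), 0.02)
  }
  ps7 <- preset_scenario("six_channel_seven_class", seed = 1)
  expect_equal(n_channels(ps7$fingerprints), 6L)
  expect_equal(n_fluorophores(ps7$fingerprints), 7L)
  expect_error(preset_scenario("foo"), "two_channel_three_class")
})

test_that("noiseless rendering lies in the fingerprint span (zero residual)", {
  for (nm in c("two_channel_three_class", "six_channel_six_class",
               "six_channel_seven_class")) {
    ps <- preset_scenario(nm, seed = 2, brightness_sigma = 0,
                          background_level = 0,
                          noise = noise_model(poisson = FALSE))
    sc <- simulate_scene(ps$config)
    res <- unmix_image(sc$image, ps$fingerprints, threshold = 1)
    fg <- sc$truth$labels > 0
    expect_true(all(res$labels[fg] == sc$truth$labels[fg]))
    expect_true(all(res$residual[fg] < 1e-18))
  }
})

test_that("simulation is fully reproducible from config and seed", {
  ps <- preset_scenario("two_channel_three_class", seed = 42)
  s1 <- simulate_scene(ps$config)
  s2 <- simulate_scene(ps$config)
  expect_identical(unclass(s1$image), unclass(s2$image))
  expect_identical(s1$truth$labels, s2$truth$labels)
})
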