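# image fixtures are generated procedurally at test time; nothing binary
# ships with the package

test_that("the identity augmentation spec is a no-op", {
  man <- tiny_image_set()
  img <- read_image(man$path[1])
  out <- augment_image(img, augment_spec(preset = "identity"), seed = 3)
  expect_identical(as.array(out), as.array(img))
})

test_that("horizontal flip is an involution", {
  man <- tiny_image_set(seed = 5)
  img <- read_image(man$path[1])
  expect_identical(as.array(EBImage::flop(EBImage::flop(img))),
                   as.array(img))
  # a spec that always flips and does nothing else
  spec <- augment_spec(rotation = c(0, 0), hflip = c(1, 1), vshift = c(0, 0),
                       scale = c(0, 0))
  once <- augment_image(img, spec, seed = 1)
  twice <- augment_image(once, spec, seed = 1)
  expect_identical(as.array(twice), as.array(img))
})

test_that("sampled augmentation parameters respect the preset ranges", {
  spec <- augment_spec(preset = "validation")
  draws <- t(vapply(1:1000, function(s) {
    p <- draw_augment_params(spec, seed = s)
    c(p$rotation, p$hflip_prob, p$vshift, p$sx, p$sy)
  }, numeric(5)))
  expect_true(all(draws[, 1] >= 10 & draws[, 1] <= 20))
  expect_true(all(draws[, 2] >= 0.1 & draws[, 2] <= 0.5))
  expect_true(all(draws[, 3] >= 0 & draws[, 3] <= 0.1))
  expect_true(all(draws[, 4] >= 1.01 & draws[, 4] <= 1.10))
  expect_true(all(draws[, 5] >= 1.01 & draws[, 5] <= 1.10))
})

test_that("augmentation is deterministic given (image, spec, seed)", {
  man <- tiny_image_set(seed = 19)
  img <- read_image(man$path[1])
  spec <- augment_spec(preset = "validation")
  a1 <- augment_image(img, spec, seed = 42)
  a2 <- augment_image(img, spec, seed = 42)
  expect_identical(as.array(a1), as.array(a2))
  expect_identical(dim(a1), dim(img))
  a3 <- augment_image(img, spec, seed = 43)
  expect_false(identical(as.array(a1), as.array(a3)))
})

test_that("salt-and-pepper noise flips exactly the stated pixel count", {
  man <- tiny_image_set(seed = 23)
  img <- read_image(man$path[1])
  d <- dim(img)
  spec <- noise_spec(fraction = c(0.30, 0.30))
  noisy <- add_noise(img, spec, seed = 4)
  changed <- apply(abs(as.array(noisy) - as.array(img)) > 0, c(1, 2), any)
  expect_equal(sum(changed), round(0.30 * d[1] * d[2]))
  # changed pixels are pure black or white on every channel
  vals <- as.array(noisy)[cbind(rep(which(changed, arr.ind = TRUE)[, 1], 3),
                                rep(which(changed, arr.ind = TRUE)[, 2], 3),
                                rep(1:3, each = sum(changed)))]
  expect_true(all(vals %in% c(0, 1)))
  expect_identical(dim(noisy), d)
  # zero fraction is a no-op; same seed reproduces the same corruption
  expect_identical(as.array(add_noise(img, noise_spec(c(0, 0)), 1)),
                   as.array(img))
  expect_identical(as.array(add_noise(img, spec, 4)), as.array(noisy))
  expect_error(noise_spec(fraction = c(0.5, 1.2)), "sub-interval")
})

test_that("noise presets carry the challenge-set fraction bands", {
  expect_equal(noise_spec(preset = "td1")$fraction, c(0.25, 0.40))
  expect_equal(noise_spec(preset = "td2")$fraction, c(0.40, 0.50))
  man <- tiny_image_set(seed = 29)
  img <- read_image(man$path[1])
  d <- dim(img)
  for (s in 1:5) {
    noisy <- add_noise(img, noise_spec(preset = "td1"), seed = s)
    frac <- sum(apply(abs(as.array(noisy) - as.array(img)) > 0,
                      c(1, 2), any)) / (d[1] * d[2])
    expect_gte(frac, 0.25 - 1 / (d[1] * d[2]))
    expect_lte(frac, 0.40 + 1 / (d[1] * d[2]))
  }
})

test_that("occluder coverage lands within 20% relative of the target", {
  man <- tiny_image_set(seed = 37, size = 48)
  img <- read_image(man$path[1])
  for (s in 1:6) {
    occ <- add_occluders(img, occluder_spec(coverage = 0.15), seed = s)
    frac <- mean(occ$mask)
    expect_gte(frac, 0.12)
    expect_lte(frac, 0.18)
    expect_identical(dim(occ$image), dim(img))
  }
  expect_error(occluder_spec(coverage = 1), "< 1")
})

test_that("the occlusion mask is exactly the repainted pixel set for solid shapes", {
  man <- tiny_image_set(seed = 41, size = 48)
  img <- read_image(man$path[1])
  spec <- occluder_spec(shapes = c("leaf", "branch"), coverage = 0.15)
  occ <- add_occluders(img, spec, seed = 2)
  changed <- apply(abs(as.array(occ$image) - as.array(img)) > 0, c(1, 2), any)
  expect_identical(changed, occ$mask)
  # zero-shape spec leaves the image untouched with an empty mask
  none <- add_occluders(img, occluder_spec(coverage = 0.15, count = c(0, 0)),
                        seed = 2)
  expect_identical(as.array(none$image), as.array(img))
  expect_false(any(none$mask))
  # determinism
  occ2 <- add_occluders(img, spec, seed = 2)
  expect_identical(occ2$mask, occ$mask)
})

test_that("class balancing reaches the target while conserving originals", {
  man <- tiny_image_set(n_classes = 2, per_class = 4, seed = 43)
  cls_dir <- dirname(man$path[man$class == "species_01"][1])
  out1 <- tempfile("bal")
  bal <- balance_class(cls_dir, 11, augment_spec(preset = "validation"),
                       seed = 7, out_dir = out1)
  expect_equal(nrow(bal), 11)
  expect_equal(sum(bal$provenance == "original"), 4)
  expect_equal(sum(bal$provenance == "augmented"), 7)
  expect_true(all(file.exists(bal$path)))
  # every original is carried over byte-identically
  origs <- man$path[man$class == "species_01"]
  for (p in origs) {
    copied <- bal$path[basename(bal$path) == paste0("orig_", basename(p))]
    expect_length(copied, 1)
    expect_identical(readBin(copied, "raw", file.size(copied)),
                     readBin(p, "raw", file.size(p)))
  }
  # target equal to current count: originals only
  out2 <- tempfile("bal")
  bal2 <- balance_class(cls_dir, 4, augment_spec(preset = "validation"),
                        seed = 7, out_dir = out2)
  expect_equal(nrow(bal2), 4)
  expect_true(all(bal2$provenance == "original"))
  # same seed reproduces the same file set
  out3 <- tempfile("bal")
  bal3 <- balance_class(cls_dir, 11, augment_spec(preset = "validation"),
                        seed = 7, out_dir = out3)
  expect_identical(basename(bal3$path), basename(bal$path))
  expect_identical(readBin(bal$path[11], "raw", file.size(bal$path[11])),
                   readBin(bal3$path[11], "raw", file.size(bal3$path[11])))
  expect_error(balance_class(tempfile(), 5, augment_spec()), "empty|not found")
})

test_that("occluded subsets replace a seeded 10-15% fraction per class", {
  man <- tiny_image_set(n_classes = 2, per_class = 20, seed = 47, size = 24)
  out <- make_occluded_subset(man, c(0.10, 0.15),
                              occluder_spec(coverage = 0.12), seed = 3,
                              out_dir = tempfile("occ"))
  expect_equal(nrow(out), nrow(man))
  for (cls in unique(out$class)) {
    k <- sum(out$provenance == "occluded" & out$class == cls)
    expect_gte(k, 2)   # round(0.10 * 20)
    expect_lte(k, 3)   # round(0.15 * 20)
    # tags partition the class
    expect_equal(k + sum(out$provenance == "original" & out$class == cls), 20)
  }
  expect_true(all(file.exists(out$path)))
  # degenerate range keeps the manifest unchanged
  same <- make_occluded_subset(man, c(0, 0), occluder_spec(), seed = 3)
  expect_identical(same$path, man$path)
})

test_that("the procedural image generator is deterministic with distinct palettes", {
  man <- generate_synthetic_images(3, 5, seed = 7, dir = tempfile(), size = 24)
  expect_equal(nrow(man), 15)
  expect_equal(length(unique(man$class)), 3)
  validate_manifest(man)
  man2 <- generate_synthetic_images(3, 5, seed = 7, dir = tempfile(), size = 24)
  expect_identical(readBin(man$path[1], "raw", file.size(man$path[1])),
                   readBin(man2$path[1], "raw", file.size(man2$path[1])))
  pal <- attr(man, "palette")
  dists <- as.matrix(dist(pal))
  diag(dists) <- Inf
  expect_gt(min(dists), 0)
  expect_error(generate_synthetic_images(1, 5), ">= 2")
})

test_that("manifests round-trip through JSON", {
  man <- tiny_image_set(seed = 53, size = 16)
  path <- tempfile(fileext = ".json")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(back$path, man$path)
  expect_equal(back$class, man$class)
  scan <- scan_dataset(dirname(dirname(man$path[1])))
  expect_equal(sort(scan$path), sort(man$path))
})
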