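# Challenge-set machinery: seeded geometric/photometric augmentation, class
# balancing, salt-and-pepper / Gaussian noise injection (TD1/TD2 presets),
# synthetic occluder compositing (TD3), and a procedural bird-like image
# generator so the whole stage is testable without external datasets.
#
# Images are EBImage `Image` objects in [0, 1], colour mode Color, indexed
# [x, y, channel] (origin top-left). All randomized operations are pure
# functions of (input, spec, seed).

load_image_checked <- function(image) {
  if (!inherits(image, "Image")) stopf("`image` must be an EBImage Image")
  d <- dim(image)
  if (length(d) < 2L || d[1] < 8L || d[2] < 8L) {
    stopf("degenerate image: need >= 8 x 8 pixels")
  }
  image
}

#' Read / write a raster image
#'
#' Thin wrappers over EBImage I/O. PNG is preferred for bit-exact round
#' trips; JPEG is accepted on read only.
#'
#' @param path Image path.
#' @return `read_image`: an EBImage `Image` with values in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- EBImage::readImage(path)
  if (length(dim(img)) == 2L) {
    img <- EBImage::Image(array(rep(as.numeric(img), 3L), c(dim(img), 3L)),
                          colormode = "Color")
  }
  img
}

#' @rdname read_image
#' @param image An EBImage `Image`.
#' @export
write_image <- function(image, path) {
  if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    stopf("JPEG is accepted on read only; write PNG for exact round trips")
  }
  EBImage::writeImage(EBImage::Image(pmin(pmax(image, 0), 1),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Augmentation specification
#'
#' Ranges for the seeded geometric/photometric transforms. The `"validation"`
#' preset uses the statistical-validation protocol's ranges: rotation
#' 10-20 degrees, horizontal-flip probability 0.1-0.5, vertical shift
#' 0-0.1 of the height, per-axis scale 0.01-0.1. The flip entry is read as
#' a per-image flip probability drawn uniformly from its range (a flip has
#' no magnitude).
#'
#' @param rotation Rotation range in degrees, `c(lo, hi)`.
#' @param hflip Range for the horizontal-flip probability.
#' @param vshift Vertical shift range as a fraction of image height.
#' @param scale Zoom-in range per axis (factor `1 + s`).
#' @param vflip Range for the vertical-flip probability.
#' @param shear Horizontal shear range in degrees.
#' @param preset `"validation"` overrides the geometric ranges with the
#'   validation-protocol values; `"identity"` zeroes everything.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(rotation = c(10, 20), hflip = c(0.1, 0.5),
                         vshift = c(0, 0.1), scale = c(0.01, 0.1),
                         vflip = c(0, 0), shear = c(0, 0), preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("validation", "identity"))
    if (preset == "validation") {
      rotation <- c(10, 20); hflip <- c(0.1, 0.5); vshift <- c(0, 0.1)
      scale <- c(0.01, 0.1); vflip <- c(0, 0); shear <- c(0, 0)
    } else {
      rotation <- c(0, 0); hflip <- c(0, 0); vshift <- c(0, 0)
      scale <- c(0, 0); vflip <- c(0, 0); shear <- c(0, 0)
    }
  }
  for (r in list(rotation, hflip, vshift, scale, vflip, shear)) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stopf("ranges must be finite c(lo, hi) with lo <= hi")
    }
  }
  structure(list(rotation = rotation, hflip = hflip, vshift = vshift,
                 scale = scale, vflip = vflip, shear = shear),
            class = "augment_spec")
}

#' Sample one set of augmentation parameters
#'
#' Draws the transform magnitudes [augment_image()] will apply for a given
#' seed: rotation, the flip probabilities and the resulting flip decisions,
#' vertical shift, per-axis scale and shear. Exposed so the sampled values
#' can be audited against the spec ranges.
#'
#' @param spec An [augment_spec()].
#' @param seed Integer seed.
#' @return Named list of sampled parameters.
#' @export
draw_augment_params <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "augment_spec"))
  with_seed(seed, {
    rot <- runif_range(spec$rotation)
    flip_p <- runif_range(spec$hflip)
    do_hflip <- stats::runif(1) < flip_p
    vflip_p <- runif_range(spec$vflip)
    do_vflip <- stats::runif(1) < vflip_p
    shift <- runif_range(spec$vshift)
    sx <- 1 + runif_range(spec$scale)
    sy <- 1 + runif_range(spec$scale)
    sh <- runif_range(spec$shear)
    list(rotation = rot, hflip_prob = flip_p, do_hflip = do_hflip,
         vflip_prob = vflip_p, do_vflip = do_vflip, vshift = shift,
         sx = sx, sy = sy, shear = sh)
  })
}

#' Apply a seeded random augmentation
#'
#' Samples one parameter per transform from the spec ranges (see
#' [draw_augment_params()]) and applies, in order: zoom, shear, rotation,
#' vertical shift, horizontal flip, vertical flip. Transforms whose sampled
#' magnitude is zero are skipped, so the identity spec returns the input
#' unchanged. The same (image, spec, seed) always yields the same output.
#'
#' @param image An EBImage `Image` (>= 8 x 8 pixels).
#' @param spec An [augment_spec()].
#' @param seed Integer seed.
#' @return The augmented image, same dimensions as the input.
#' @export
augment_image <- function(image, spec, seed = 1) {
  image <- load_image_checked(image)
  stopifnot(inherits(spec, "augment_spec"))
  d <- dim(image)
  p <- draw_augment_params(spec, seed)
  rot <- p$rotation; do_hflip <- p$do_hflip; do_vflip <- p$do_vflip
  shift <- p$vshift; sx <- p$sx; sy <- p$sy; sh <- p$shear
  local({
    out <- image
    if (sx != 1 || sy != 1) {
      # zoom about the centre: scale then crop back to the original frame
      big <- EBImage::resize(out, w = max(round(d[1] * sx), d[1]),
                             h = max(round(d[2] * sy), d[2]))
      db <- dim(big)
      x0 <- floor((db[1] - d[1]) / 2); y0 <- floor((db[2] - d[2]) / 2)
      out <- big[x0 + seq_len(d[1]), y0 + seq_len(d[2]), , drop = FALSE]
    }
    if (sh != 0) {
      t <- tan(sh * pi / 180)
      m <- matrix(c(1, 0, t, 1, -t * d[2] / 2, 0), nrow = 3L, byrow = TRUE)
      out <- EBImage::affine(out, m, output.dim = d[1:2], bg.col = "black")
    }
    if (rot != 0) {
      out <- EBImage::rotate(out, rot, output.dim = d[1:2], bg.col = "black")
    }
    if (shift != 0) {
      out <- EBImage::translate(out, c(0, round(shift * d[2])),
                                bg.col = "black")
    }
    if (do_hflip) out <- EBImage::flop(out)
    if (do_vflip) out <- EBImage::flip(out)
    EBImage::Image(pmin(pmax(out, 0), 1), colormode = "Color")
  })
}

# ---- dataset manifest ------------------------------------------------------

new_manifest <- function(class, path, provenance) {
  data.frame(class = class, path = path, provenance = provenance,
             stringsAsFactors = FALSE)
}

#' Dataset manifest I/O and validation
#'
#' A manifest lists every image of a class-per-folder dataset with its
#' class and provenance tag (`original`, `augmented`, `occluded`,
#' `noised`). `validate_manifest()` checks that the listed files exist.
#'
#' @param manifest A manifest `data.frame` (`class`, `path`, `provenance`).
#' @param path JSON path.
#' @return `read_manifest` returns the manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
}

#' @rdname write_manifest
#' @export
validate_manifest <- function(manifest) {
  need <- c("class", "path", "provenance")
  if (!all(need %in% names(manifest))) {
    stopf("manifest needs columns %s", paste(need, collapse = ", "))
  }
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing) > 0L) stopf("manifest lists missing file: %s", missing[1L])
  invisible(manifest)
}

#' Scan a class-per-folder directory into a manifest
#'
#' @param root Directory whose sub-directories are class folders.
#' @param provenance Tag applied to every file found.
#' @return A manifest `data.frame`.
#' @export
scan_dataset <- function(root, provenance = "original") {
  classes <- list.dirs(root, recursive = FALSE)
  if (length(classes) == 0L) stopf("no class folders under %s", root)
  do.call(rbind, lapply(classes, function(d) {
    files <- list.files(d, pattern = "\\.(png|jpe?g)$", full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0L) return(NULL)
    new_manifest(basename(d), files, provenance)
  }))
}

#' Balance a class folder to a target count by augmentation
#'
#' Copies every original into `out_dir/<class>` and appends seeded
#' augmented variants (cycling over the originals) until exactly
#' `target_count` images exist. Deterministic given the seed; originals
#' are always conserved.
#'
#' @param class_dir Folder of one class's images (non-empty).
#' @param target_count Desired image count, >= the current count.
#' @param spec An [augment_spec()] for the generated variants.
#' @param seed Integer seed.
#' @param out_dir Output root; the class folder is created beneath it.
#' @return Manifest rows for the balanced class (tags `original` /
#'   `augmented`).
#' @export
balance_class <- function(class_dir, target_count, spec, seed = 1,
                          out_dir = tempfile("balanced")) {
  files <- list.files(class_dir, pattern = "\\.(png|jpe?g)$",
                      full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0L) stopf("empty class folder: %s", class_dir)
  if (target_count < length(files)) {
    stopf("target %d below current count %d", target_count, length(files))
  }
  cls <- basename(normalizePath(class_dir))
  dest <- file.path(out_dir, cls)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  orig_paths <- file.path(dest, paste0("orig_", basename(files)))
  ok <- file.copy(files, orig_paths, overwrite = TRUE)
  if (!all(ok)) stopf("failed to copy originals into %s", dest)
  n_aug <- target_count - length(files)
  aug_paths <- character(n_aug)
  for (i in seq_len(max(n_aug, 0L))) {
    src <- files[((i - 1L) %% length(files)) + 1L]
    img <- read_image(src)
    aug <- augment_image(img, spec, seed = seed + i)
    aug_paths[i] <- file.path(
      dest, sprintf("aug_%04d_%s.png", i,
                    tools::file_path_sans_ext(basename(src))))
    write_image(aug, aug_paths[i])
  }
  rbind(new_manifest(cls, orig_paths, "original"),
        if (n_aug > 0L) new_manifest(cls, aug_paths, "augmented"))
}

# ---- noise -----------------------------------------------------------------

#' Noise specification
#'
#' The corruption level is a fraction of pixels, drawn uniformly from
#' `fraction`. Presets follow the two noise challenge sets: `"td1"` =
#' 25-40%, `"td2"` = 40-50%. `kind = "salt_pepper"` (default) sets the
#' chosen pixels to pure black or white (50/50); `"gaussian"` adds zero-
#' mean Gaussian noise with standard deviation equal to the drawn fraction.
#'
#' @param fraction Sub-interval of \[0, 1\], `c(lo, hi)`.
#' @param kind `"salt_pepper"` or `"gaussian"`.
#' @param preset `"td1"` or `"td2"` overrides `fraction`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(fraction = c(0.25, 0.40),
                       kind = c("salt_pepper", "gaussian"), preset = NULL) {
  kind <- match.arg(kind)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("td1", "td2"))
    fraction <- if (preset == "td1") c(0.25, 0.40) else c(0.40, 0.50)
  }
  if (length(fraction) != 2L || any(fraction < 0) || any(fraction > 1) ||
      fraction[1] > fraction[2]) {
    stopf("`fraction` must be a sub-interval of [0, 1]")
  }
  structure(list(fraction = fraction, kind = kind), class = "noise_spec")
}

#' Inject seeded noise into an image
#'
#' Salt-and-pepper mode flips exactly `round(f * width * height)` distinct
#' pixel positions (all channels) to black or white with equal probability,
#' where `f` is drawn uniformly from the spec's fraction range; a pixel
#' already at the drawn extreme gets the opposite extreme, so the changed-
#' pixel count is exact. Dimensions and channel count are never altered.
#'
#' @param image An EBImage `Image`.
#' @param spec A [noise_spec()].
#' @param seed Integer seed.
#' @return The noised image.
#' @export
add_noise <- function(image, spec, seed = 1) {
  image <- load_image_checked(image)
  stopifnot(inherits(spec, "noise_spec"))
  d <- dim(image)
  npix <- d[1] * d[2]
  with_seed(seed, {
    f <- runif_range(spec$fraction)
    if (spec$kind == "gaussian") {
      if (f == 0) return(image)
      noisy <- image + stats::rnorm(length(image), sd = f)
      return(EBImage::Image(pmin(pmax(noisy, 0), 1), colormode = "Color"))
    }
    n_flip <- round(f * npix)
    if (n_flip == 0L) return(image)
    pos <- sample.int(npix, n_flip)
    val <- stats::rbinom(n_flip, 1L, 0.5)  # 1 = white, 0 = black
    arr <- as.array(image)
    xi <- ((pos - 1L) %% d[1]) + 1L
    yi <- ((pos - 1L) %/% d[1]) + 1L
    for (ch in seq_len(d[3])) {
      idx <- cbind(xi, yi, ch)
      cur <- arr[idx]
      tgt <- as.numeric(val)
      tgt[cur == tgt] <- 1 - tgt[cur == tgt]  # force a visible change
      arr[idx] <- tgt
    }
    EBImage::Image(arr, colormode = "Color")
  })
}

# ---- occluders -------------------------------------------------------------

#' Occluder specification
#'
#' Parametric foreground occluders composited over the frame: `leaf` =
#' filled rotated ellipse in a green-brown palette, `branch` = thick
#' polyline in bark tones, `shadow` = semi-transparent dark convex
#' polygon. `coverage` is the target fraction of image area the occlusion
#' mask should reach; the rendered mask lands within +/-20% relative of
#' it.
#'
#' @param shapes Subset of `c("leaf", "branch", "shadow")`.
#' @param coverage Target mask fraction, in (0, 1).
#' @param count Shape-count range `c(min, max)`; shapes are added until the
#'   coverage target is reached or `max` shapes are placed. `c(0, 0)`
#'   composites nothing and returns an empty mask.
#' @param opacity Shadow darkening factor in (0, 1\] (1 = opaque black).
#' @return An object of class `occluder_spec`.
#' @export
occluder_spec <- function(shapes = c("leaf", "branch", "shadow"),
                          coverage = 0.15, count = c(1, 400),
                          opacity = 0.55) {
  shapes <- match.arg(shapes, several.ok = TRUE)
  assert_scalar_number(coverage, "coverage", 0, 1)
  if (coverage >= 1) stopf("coverage must be < 1")
  if (coverage <= 0) stopf("coverage must be > 0")
  if (length(count) != 2L || any(count < 0) || count[1] > count[2]) {
    stopf("`count` must be c(min, max) with 0 <= min <= max")
  }
  assert_scalar_number(opacity, "opacity", 0, 1)
  structure(list(shapes = shapes, coverage = coverage,
                 count = round(count), opacity = opacity),
            class = "occluder_spec")
}

# pixel-centre coordinate grids for an image of dims d (x across, y down)
coord_grids <- function(d) {
  list(x = matrix(rep(seq_len(d[1]), d[2]), d[1], d[2]),
       y = matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2]))
}

ellipse_mask <- function(g, cx, cy, a, b, theta) {
  u <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
  v <- -(g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# thick segment: distance from (x, y) to segment p1-p2 below w
segment_mask <- function(g, p1, p2, w) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(pmax(((g$x - p1[1]) * vx + (g$y - p1[2]) * vy) / len2, 0), 1)
  dx <- g$x - (p1[1] + t * vx); dy <- g$y - (p1[2] + t * vy)
  dx^2 + dy^2 <= w^2
}

# convex polygon via half-plane tests (vertices in order)
polygon_mask <- function(g, xs, ys) {
  n <- length(xs)
  inside <- NULL
  sgn <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    cr <- (xs[j] - xs[i]) * (g$y - ys[i]) - (ys[j] - ys[i]) * (g$x - xs[i])
    if (sgn == 0) sgn <- sign(sum(cr))
    side <- if (sgn >= 0) cr >= 0 else cr <= 0
    inside <- if (is.null(inside)) side else inside & side
  }
  inside
}

leaf_palette <- matrix(c(
  0.24, 0.45, 0.15,
  0.33, 0.55, 0.20,
  0.48, 0.58, 0.18,
  0.45, 0.35, 0.16), ncol = 3, byrow = TRUE)

branch_palette <- matrix(c(
  0.36, 0.25, 0.14,
  0.45, 0.33, 0.20,
  0.28, 0.20, 0.12), ncol = 3, byrow = TRUE)

paint_solid <- function(arr, mask, col) {
  for (ch in 1:3) {
    plane <- arr[, , ch]
    # nudge when the paint colour coincides with the pixel, so every masked
    # pixel provably differs from the original
    hit <- mask & (abs(plane - col[ch]) < 1e-12)
    plane[mask] <- col[ch]
    plane[hit] <- min(max(col[ch] + 0.004, 0), 1)
    arr[, , ch] <- plane
  }
  arr
}

#' Composite seeded occluders onto an image
#'
#' Adds parametric occluder shapes until the occlusion mask reaches the
#' coverage target, and returns both the composited image and the boolean
#' mask. Each shape's nominal area is a fifth of the target, so the final
#' mask fraction lands within +/-20% relative of the target. For leaf and
#' branch shapes the mask is exactly the set of repainted pixels; shadow
#' regions are darkened in place (semi-transparent), still tracked by the
#' mask.
#'
#' @param image An EBImage `Image`.
#' @param spec An [occluder_spec()].
#' @param seed Integer seed.
#' @return List with `image` (composited) and `mask` (logical
#'   width x height matrix).
#' @export
add_occluders <- function(image, spec, seed = 1) {
  image <- load_image_checked(image)
  stopifnot(inherits(spec, "occluder_spec"))
  d <- dim(image)
  g <- coord_grids(d)
  area <- d[1] * d[2]
  target <- spec$coverage
  shape_area <- target * area / 5
  with_seed(seed, {
    arr <- as.array(image)
    mask <- matrix(FALSE, d[1], d[2])
    guard <- 0L
    while (guard < spec$count[2] &&
           (guard < spec$count[1] || sum(mask) < 0.97 * target * area)) {
      guard <- guard + 1L
      kind <- sample(spec$shapes, 1L)
      cx <- stats::runif(1, 0.15 * d[1], 0.85 * d[1])
      cy <- stats::runif(1, 0.15 * d[2], 0.85 * d[2])
      m <- switch(kind,
        leaf = {
          ar <- stats::runif(1, 1.6, 2.6)            # elongation
          b <- sqrt(shape_area / (pi * ar)); a <- ar * b
          ellipse_mask(g, cx, cy, a, b, stats::runif(1, 0, pi))
        },
        branch = {
          len <- sqrt(shape_area * 6)
          w <- shape_area / (2 * len)
          th <- stats::runif(1, 0, pi)
          p1 <- c(cx - cos(th) * len / 2, cy - sin(th) * len / 2)
          p2 <- c(cx + cos(th) * len / 2, cy + sin(th) * len / 2)
          segment_mask(g, p1, p2, w)
        },
        shadow = {
          r <- sqrt(shape_area / pi) * stats::runif(4, 0.8, 1.4)
          ang <- sort(stats::runif(4, 0, 2 * pi))
          polygon_mask(g, cx + r * cos(ang), cy + r * sin(ang))
        })
      if (!any(m)) next
      if (kind == "shadow") {
        fac <- 1 - spec$opacity
        for (ch in 1:3) {
          plane <- arr[, , ch]
          plane[m] <- plane[m] * fac
          arr[, , ch] <- plane
        }
      } else {
        pal <- if (kind == "leaf") leaf_palette else branch_palette
        col <- pal[sample.int(nrow(pal), 1L), ]
        arr <- paint_solid(arr, m, col)
      }
      mask <- mask | m
    }
    list(image = EBImage::Image(arr, colormode = "Color"), mask = mask)
  })
}

#' Replace a seeded fraction of each class with occluded variants
#'
#' Per class, a fraction `f` drawn uniformly from `fraction` (default
#' 10-15%) of the images is replaced by occluded variants written next to
#' the originals; provenance tags partition the class into `original` and
#' `occluded`.
#'
#' @param manifest A dataset manifest (see [scan_dataset()]).
#' @param fraction Range of the per-class occluded fraction.
#' @param spec An [occluder_spec()].
#' @param seed Integer seed.
#' @param out_dir Output root for the occluded copies.
#' @return The updated manifest.
#' @export
make_occluded_subset <- function(manifest, fraction = c(0.10, 0.15),
                                 spec = occluder_spec(), seed = 1,
                                 out_dir = tempfile("occluded")) {
  validate_manifest(manifest)
  if (length(fraction) != 2L || any(fraction < 0) || any(fraction > 1) ||
      fraction[1] > fraction[2]) {
    stopf("`fraction` must be a sub-interval of [0, 1]")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pieces <- lapply(unique(manifest$class), function(cls) {
    rows <- manifest[manifest$class == cls, , drop = FALSE]
    with_seed(seed + match(cls, unique(manifest$class)), {
      f <- runif_range(fraction)
      k <- round(f * nrow(rows))
      if (k == 0L) return(rows)
      pick <- sample.int(nrow(rows), k)
      dest <- file.path(out_dir, cls)
      dir.create(dest, recursive = TRUE, showWarnings = FALSE)
      for (idx in pick) {
        img <- read_image(rows$path[idx])
        occ <- add_occluders(img, spec, seed = seed + idx)
        newp <- file.path(dest, paste0(
          "occ_", tools::file_path_sans_ext(basename(rows$path[idx])), ".png"))
        write_image(occ$image, newp)
        rows$path[idx] <- newp
        rows$provenance[idx] <- "occluded"
      }
      rows
    })
  })
  do.call(rbind, pieces)
}

# ---- procedural fixture generator ------------------------------------------

#' Generate a procedural bird-like image dataset
#'
#' Writes `per_class` PNG images for each of `n_classes` classes into a
#' class-per-folder layout: a textured background, a class-coloured body
#' ellipse, a head disc and a beak triangle, with per-class palettes spread
#' around the hue circle so they are pairwise distinct. Deterministic per
#' seed. This is a synthetic stand-in for real photographic datasets, meant
#' to exercise the augmentation/occlusion pipeline.
#'
#' @param n_classes Number of classes (>= 2).
#' @param per_class Images per class (>= 1).
#' @param seed Integer seed.
#' @param dir Output root directory.
#' @param size Image side length in pixels (default 64).
#' @return A dataset manifest (provenance `original`), with the per-class
#'   body colours in its `"palette"` attribute.
#' @export
generate_synthetic_images <- function(n_classes, per_class, seed = 1,
                                      dir = tempfile("birds"), size = 64) {
  if (n_classes < 2) stopf("need >= 2 classes")
  if (per_class < 1) stopf("need >= 1 image per class")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  classes <- sprintf("species_%02d", seq_len(n_classes))
  hues <- (seq_len(n_classes) - 1) / n_classes
  palette <- t(grDevices::col2rgb(grDevices::hsv(hues, 0.75, 0.72)) / 255)
  g <- coord_grids(c(size, size))
  rows <- list()
  for (ci in seq_len(n_classes)) {
    cdir <- file.path(dir, classes[ci])
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(per_class)) {
      path <- file.path(cdir, sprintf("img_%03d.png", i))
      with_seed(seed + ci * 1000L + i, {
        # textured background: smooth low-frequency field plus grain
        fx <- stats::runif(2, 0.5, 2); ph <- stats::runif(2, 0, 2 * pi)
        base <- 0.45 + 0.15 * sin(2 * pi * fx[1] * g$x / size + ph[1]) *
          cos(2 * pi * fx[2] * g$y / size + ph[2])
        arr <- array(0, c(size, size, 3))
        sky <- c(0.55, 0.70, 0.85)
        for (ch in 1:3) {
          arr[, , ch] <- pmin(pmax(
            base * sky[ch] + stats::rnorm(size^2, sd = 0.02), 0), 1)
        }
        cx <- size * stats::runif(1, 0.40, 0.60)
        cy <- size * stats::runif(1, 0.45, 0.62)
        body <- ellipse_mask(g, cx, cy, size * 0.22, size * 0.14,
                             stats::runif(1, -0.3, 0.3))
        head <- ellipse_mask(g, cx + size * 0.20, cy - size * 0.14,
                             size * 0.08, size * 0.08, 0)
        beak <- polygon_mask(
          g,
          c(cx + size * 0.27, cx + size * 0.38, cx + size * 0.27),
          c(cy - size * 0.17, cy - size * 0.13, cy - size * 0.09))
        col <- palette[ci, ]
        for (ch in 1:3) {
          plane <- arr[, , ch]
          plane[body] <- col[ch]
          plane[head] <- pmin(col[ch] * 1.25, 1)
          plane[beak] <- c(0.9, 0.65, 0.1)[ch]
          arr[, , ch] <- plane
        }
        write_image(EBImage::Image(arr, colormode = "Color"), path)
      })
      rows[[length(rows) + 1L]] <- new_manifest(classes[ci], path, "original")
    }
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "palette") <- palette
  manifest
}
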