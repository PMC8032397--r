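# Seeded synthetic EM-like fixtures: textured cytoplasm with dark-membraned
# elliptical organelles, four kinds of uninformative frames, duplicate-rich
# volumes, labeled filter-training sets, and toy encoders. Every generator
# is a pure function of (config, seed).

#' Synthetic-corpus configuration
#'
#' Appearance and composition parameters of the generator. Intensities
#' follow a stylized EM convention: bright resin (~200), mid-gray textured
#' cytoplasm (~135), dark membranes (~40).
#'
#' @param patch_size patch side in pixels.
#' @param n_patches corpus size for [make_corpus()].
#' @param duplicate_fraction fraction of corpus patches that are planted
#'   near-duplicates of earlier patches.
#' @param uninformative_fraction fraction of base patches that are
#'   uninformative.
#' @param organelle_n_range number of organelles per informative patch.
#' @param organelle_axis_range semi-axis range in pixels.
#' @param texture_sd cytoplasm texture amplitude (intensity units).
#' @param noise_sd speckle noise sd (intensity units).
#' @param drift latent slice-to-slice drift in \[0, 1\] for
#'   [make_volume()]; 0 duplicates slices exactly, values below ~0.15 keep
#'   adjacent slices within difference-hash distance 12.
#' @param seed corpus seed.
#' @return named list of class `synth_config`.
#' @export
synth_config <- function(patch_size = 224L, n_patches = 5000L,
                         duplicate_fraction = 0.4,
                         uninformative_fraction = 0.3,
                         organelle_n_range = c(2L, 6L),
                         organelle_axis_range = c(15, 45),
                         texture_sd = 22, noise_sd = 7,
                         drift = 0.05, seed = 42L) {
  stopifnot(duplicate_fraction >= 0, duplicate_fraction <= 1,
            uninformative_fraction >= 0, uninformative_fraction <= 1,
            drift >= 0, drift <= 1, !is.null(seed))
  structure(list(patch_size = as.integer(patch_size),
                 n_patches = as.integer(n_patches),
                 duplicate_fraction = duplicate_fraction,
                 uninformative_fraction = uninformative_fraction,
                 organelle_n_range = organelle_n_range,
                 organelle_axis_range = organelle_axis_range,
                 texture_sd = texture_sd, noise_sd = noise_sd,
                 drift = drift, seed = as.integer(seed)),
            class = "synth_config")
}

# smooth zero-mean unit-sd random field (uses the current RNG stream)
smooth_field <- function(h, w, sigma = 6) {
  f <- gaussian_blur(matrix(rnorm(h * w), h, w), sigma)
  (f - mean(f)) / sd(as.numeric(f))
}

# squared-normalized elliptical radius over the pixel grid
ellipse_rho <- function(h, w, cy, cx, a, b, theta) {
  gy <- matrix(rep(seq_len(h), w), h) - cy
  gx <- matrix(rep(seq_len(w), each = h), h) - cx
  u <- (gx * cos(theta) + gy * sin(theta)) / a
  v <- (-gx * sin(theta) + gy * cos(theta)) / b
  sqrt(u^2 + v^2)
}

#' Generate an informative EM-like patch
#'
#' Textured cytoplasm background plus dark-membraned elliptical organelles
#' with distinct interiors, under speckle noise. The returned masks give
#' the organelle ground truth; the uniform-region mask is empty (the whole
#' frame is textured), so by construction the 80% uniform-area rule labels
#' these patches informative.
#'
#' @param cfg a [synth_config()].
#' @param seed patch seed.
#' @return list: `image` (8-bit matrix), `masks` (list with binary
#'   `organelle` and `uniform`), `artifact` (FALSE), `kind`, `label` (1).
#' @export
make_informative_patch <- function(cfg = synth_config(), seed = 1L) {
  s <- cfg$patch_size
  set.seed(seed)
  img <- 135 + cfg$texture_sd * smooth_field(s, s, sigma = 5)
  org_tex <- 0.6 * cfg$texture_sd * smooth_field(s, s, sigma = 3)
  org_mask <- matrix(FALSE, s, s)
  n_org <- sample(seq.int(cfg$organelle_n_range[1], cfg$organelle_n_range[2]), 1)
  for (i in seq_len(n_org)) {
    cy <- runif(1, 0.15 * s, 0.85 * s)
    cx <- runif(1, 0.15 * s, 0.85 * s)
    ab <- sort(runif(2, cfg$organelle_axis_range[1], cfg$organelle_axis_range[2]))
    th <- runif(1, 0, pi)
    rho <- ellipse_rho(s, s, cy, cx, ab[2], ab[1], th)
    interior <- rho < 0.82
    ring <- rho >= 0.82 & rho <= 1
    lum <- runif(1, 95, 170)
    img[interior] <- lum + org_tex[interior]
    img[ring] <- 40
    org_mask <- org_mask | (rho <= 1)
  }
  img <- img + matrix(rnorm(s * s, 0, cfg$noise_sd), s, s)
  list(image = as_uint8(round(clip255(img))),
       masks = list(organelle = org_mask, uniform = matrix(FALSE, s, s)),
       artifact = FALSE, kind = "informative", label = 1L)
}

#' Generate an uninformative patch
#'
#' Four kinds emulating the frames the curation filter removes: `resin`
#' (near-constant bright field), `low_contrast` (smooth texture below the
#' contrast floor), `padding` (a zero border occupying at least 80% of the
#' frame around a small textured block), and `artifact` (saturated
#' stitching-style stripes). Resin and padding kinds carry a uniform-region
#' mask covering at least 80% of the area; all kinds have ground-truth
#' label 0.
#'
#' @param cfg a [synth_config()].
#' @param seed patch seed.
#' @param kind one of resin, low_contrast, padding, artifact.
#' @return same structure as [make_informative_patch()], `label = 0`.
#' @export
make_uninformative_patch <- function(cfg = synth_config(), seed = 1L,
                                     kind = c("resin", "low_contrast",
                                              "padding", "artifact")) {
  kind <- match.arg(kind)
  s <- cfg$patch_size
  set.seed(seed)
  uniform <- matrix(TRUE, s, s)
  artifact <- FALSE
  if (kind == "resin") {
    # faint shared illumination gradient: keeps the frame uniform for the
    # 80% rule while making its perceptual hash stable rather than
    # noise-driven (uniform frames collapse into one duplicate group)
    grad <- matrix(rep(4 * seq_len(s) / s, each = s), s, byrow = FALSE)
    img <- 198 + grad + matrix(rnorm(s * s, 0, 2), s, s)
  } else if (kind == "low_contrast") {
    img <- 128 + 3 * smooth_field(s, s, sigma = 8) +
      matrix(rnorm(s * s, 0, 1), s, s)
  } else if (kind == "padding") {
    img <- matrix(0, s, s)
    blk <- as.integer(floor(sqrt(0.16) * s))   # content block: 16% of area
    corner <- sample.int(4L, 1L)
    y0 <- if (corner %in% c(1L, 2L)) 0L else s - blk
    x0 <- if (corner %in% c(1L, 3L)) 0L else s - blk
    content <- 135 + cfg$texture_sd * smooth_field(blk, blk, sigma = 4) +
      matrix(rnorm(blk * blk, 0, cfg$noise_sd), blk, blk)
    img[y0 + seq_len(blk), x0 + seq_len(blk)] <- content
    uniform <- matrix(TRUE, s, s)
    uniform[y0 + seq_len(blk), x0 + seq_len(blk)] <- FALSE
  } else {                                      # artifact: saturated stripes
    img <- 200 + matrix(rnorm(s * s, 0, 2), s, s)
    stripe <- ((seq_len(s) - 1L) %/% 8L) %% 2L == 0L
    img[stripe, seq_len(s %/% 2L)] <- 255
    img[!stripe, seq_len(s %/% 2L)] <- 0
    uniform <- matrix(FALSE, s, s)
    artifact <- TRUE
  }
  list(image = as_uint8(round(clip255(img))),
       masks = list(organelle = matrix(FALSE, s, s), uniform = uniform),
       artifact = artifact, kind = kind, label = 0L)
}

# near-duplicate of an existing patch: light speckle re-noise, which leaves
# the difference hash within a distance of a few bits
perturb_duplicate <- function(image, seed, sd = 3) {
  set.seed(seed)
  as_uint8(round(clip255(image + matrix(rnorm(length(image), 0, sd),
                                        nrow(image)))))
}

#' Generate a duplicate-rich synthetic volume
#'
#' Builds a 3D source whose adjacent xy slices are near-duplicates,
#' emulating high-resolution volume EM: a latent smooth structure field
#' evolves slice to slice as an AR(1) process with mixing weight `drift`.
#' With `drift = 0` all slices are byte-identical; for drift below roughly
#' 0.15 adjacent slices stay within difference-hash distance 12.
#'
#' @param cfg a [synth_config()] (uses `drift`, texture/noise levels).
#' @param depth number of slices (>= 2).
#' @param height,width slice extents.
#' @param seed volume seed.
#' @param spacing_nm optional `c(z, y, x)` spacing attached to the source.
#' @param source_id identifier of the generated source.
#' @return a [source_image()] of kind volume3d.
#' @export
make_volume <- function(cfg = synth_config(), depth = 8L, height = 448L,
                        width = 448L, seed = 1L, spacing_nm = c(10, 10, 10),
                        source_id = "synthvol") {
  stopifnot(depth >= 2L)
  d <- cfg$drift
  set.seed(seed)
  lat <- smooth_field(height, width, sigma = 8)
  ring <- ellipse_rho(height, width, height / 2, width / 2,
                      0.3 * width, 0.2 * height, pi / 6)
  vol <- array(0L, c(depth, height, width))
  base_noise <- matrix(rnorm(height * width, 0, cfg$noise_sd), height, width)
  for (k in seq_len(depth)) {
    if (k > 1L && d > 0) {
      set.seed(derive_seed(seed, paste0("slice", k)))
      lat <- sqrt(1 - d^2) * lat + d * smooth_field(height, width, sigma = 8)
      noise <- matrix(rnorm(height * width, 0, cfg$noise_sd), height, width)
    } else {
      noise <- base_noise
    }
    img <- 135 + cfg$texture_sd * lat
    img[ring >= 0.85 & ring <= 1] <- 40
    img <- img + noise
    vol[k, , ] <- as_uint8(round(clip255(img)))
  }
  source_image(vol, source_id, spacing_nm = spacing_nm)
}

#' Generate a labeled patch set for filter training
#'
#' Mixture of informative patches and the four uninformative kinds (cycled)
#' at the configured fraction, with ground-truth labels and a 75/25
#' train/test split.
#'
#' @param cfg a [synth_config()] (uses `uninformative_fraction`).
#' @param n total number of patches (>= 40).
#' @param seed set seed.
#' @return list: `patches` (a [patch_set()]), `labels` (0/1), `split`
#'   ("train"/"test"), `kinds`, `masks`, `artifact`.
#' @export
make_filter_dataset <- function(cfg = synth_config(), n = 2000L, seed = 7L) {
  if (n < 40L) stop("make_filter_dataset: n must be >= 40")
  n_unin <- as.integer(round(n * cfg$uninformative_fraction))
  kinds <- c(rep("informative", n - n_unin),
             rep(c("resin", "low_contrast", "padding", "artifact"),
                 length.out = n_unin))
  set.seed(seed)
  kinds <- sample(kinds)
  images <- vector("list", n)
  recs <- vector("list", n)
  labels <- integer(n)
  masks <- vector("list", n)
  artifact <- logical(n)
  for (i in seq_len(n)) {
    ps <- derive_seed(seed, paste0("patch", i))
    p <- if (kinds[i] == "informative") {
      make_informative_patch(cfg, ps)
    } else {
      make_uninformative_patch(cfg, ps, kinds[i])
    }
    pid <- sprintf("lab-%05d", i)
    images[[i]] <- p$image
    labels[i] <- p$label
    masks[[i]] <- p$masks
    artifact[i] <- p$artifact
    recs[[i]] <- data.frame(
      patch_id = pid, source_id = "labeled", plane = "xy",
      slice_index = 0L, y0 = 0L, x0 = 0L, edge_anchored = FALSE,
      padded = FALSE, stage = "raw", prob = NA_real_,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  names(images) <- records$patch_id
  set.seed(derive_seed(seed, "split"))
  split <- rep("train", n)
  split[sample.int(n, as.integer(round(0.25 * n)))] <- "test"
  list(patches = patch_set(images, records), labels = labels, split = split,
       kinds = kinds, masks = masks, artifact = artifact)
}

#' Generate a flat synthetic corpus with planted duplicates
#'
#' Base patches (informative/uninformative mixture per
#' `uninformative_fraction`) plus planted near-duplicates of randomly
#' chosen earlier patches per `duplicate_fraction`, all in one synthetic
#' source so deduplication sees every planted pair.
#'
#' @param cfg a [synth_config()] (uses `n_patches`, fractions, seed unless
#'   overridden).
#' @param seed corpus seed; defaults to `cfg$seed`.
#' @return list: `patches` (a [patch_set()]), `labels`, `kinds`,
#'   `is_duplicate` (logical), `duplicate_of` (patch id or `NA`).
#' @export
make_corpus <- function(cfg = synth_config(), seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  n <- cfg$n_patches
  n_dup <- as.integer(round(n * cfg$duplicate_fraction))
  n_base <- n - n_dup
  n_unin <- as.integer(round(n_base * cfg$uninformative_fraction))
  kinds <- c(rep("informative", n_base - n_unin),
             rep(c("resin", "low_contrast", "padding", "artifact"),
                 length.out = n_unin))
  set.seed(seed)
  kinds <- sample(kinds)
  images <- vector("list", n)
  labels <- integer(n)
  all_kinds <- character(n)
  is_dup <- logical(n)
  dup_of <- rep(NA_character_, n)
  ids <- sprintf("c-%05d", seq_len(n))
  for (i in seq_len(n_base)) {
    ps <- derive_seed(seed, paste0("base", i))
    p <- if (kinds[i] == "informative") make_informative_patch(cfg, ps)
         else make_uninformative_patch(cfg, ps, kinds[i])
    images[[i]] <- p$image
    labels[i] <- p$label
    all_kinds[i] <- p$kind
  }
  if (n_dup > 0L) {
    set.seed(derive_seed(seed, "dup"))
    parents <- sample.int(n_base, n_dup, replace = TRUE)
    for (k in seq_len(n_dup)) {
      i <- n_base + k
      images[[i]] <- perturb_duplicate(images[[parents[k]]],
                                       derive_seed(seed, paste0("dup", k)))
      labels[i] <- labels[parents[k]]
      all_kinds[i] <- all_kinds[parents[k]]
      is_dup[i] <- TRUE
      dup_of[i] <- ids[parents[k]]
    }
  }
  names(images) <- ids
  records <- data.frame(
    patch_id = ids, source_id = "synth-corpus", plane = "xy",
    slice_index = 0L, y0 = 0L, x0 = 0L, edge_anchored = FALSE,
    padded = FALSE, stage = "raw", prob = NA_real_,
    stringsAsFactors = FALSE)
  list(patches = patch_set(images, records), labels = labels,
       kinds = all_kinds, is_duplicate = is_dup, duplicate_of = dup_of)
}

#' Construct a toy encoder
#'
#' Deterministic test doubles satisfying the encoder contract:
#' `global_mean` (D = 1, pooled = mean pixel, one half-resolution feature
#' map), `corner_pixel` (D = 1, pooled = mean of the top-left 16x16
#' block), `planted_filter` (C = 8 maps at stride 2, channel 1 a smoothed
#' copy of a supplied truth mask, the rest seeded smooth noise; pooled =
#' per-channel means), `random_conv` (C = D = 16 seeded random separable
#' convolutions, half resolution).
#'
#' @param kind encoder kind.
#' @param seed seed for the random kinds.
#' @param truth_mask binary 224x224 mask, required for `planted_filter`.
#' @return a [new_encoder()].
#' @export
make_toy_encoder <- function(kind = c("global_mean", "corner_pixel",
                                      "planted_filter", "random_conv"),
                             seed = 1L, truth_mask = NULL) {
  kind <- match.arg(kind)
  if (kind == "global_mean") {
    return(new_encoder(
      pooled = function(image) mean(image), D = 1L,
      feature_maps = function(image) {
        list(area_resize(image, nrow(image) %/% 2L, ncol(image) %/% 2L))
      },
      C = 1L, stride = 2L, name = "global_mean"))
  }
  if (kind == "corner_pixel") {
    return(new_encoder(
      pooled = function(image) mean(image[1:16, 1:16]), D = 1L,
      name = "corner_pixel"))
  }
  if (kind == "planted_filter") {
    if (is.null(truth_mask)) {
      stop("make_toy_encoder: planted_filter requires a truth_mask")
    }
    s <- nrow(truth_mask)
    planted <- area_resize(gaussian_blur(truth_mask * 1, 1.5),
                           s %/% 2L, s %/% 2L)
    set.seed(seed)
    others <- lapply(seq_len(7L), function(i) {
      smooth_field(s %/% 2L, s %/% 2L, sigma = 10)
    })
    maps <- c(list(planted), others)
    return(new_encoder(
      pooled = function(image) vapply(maps, mean, numeric(1)), D = 8L,
      feature_maps = function(image) maps, C = 8L, stride = 2L,
      name = "planted_filter"))
  }
  # random_conv: separable random kernels, ReLU, half-resolution maps
  set.seed(seed)
  C <- 16L
  kernels <- lapply(seq_len(C), function(i) {
    list(u = rnorm(5), v = rnorm(5))
  })
  fmap <- function(image) {
    img <- (image - mean(image)) / max(sd(as.numeric(image)), 1e-8)
    lapply(kernels, function(k) {
      r <- conv_operator(nrow(img), k$u) %*% img %*%
        t(conv_operator(ncol(img), k$v))
      r[r < 0] <- 0
      area_resize(r, nrow(img) %/% 2L, ncol(img) %/% 2L)
    })
  }
  new_encoder(
    pooled = function(image) vapply(fmap(image), mean, numeric(1)),
    D = C, feature_maps = fmap, C = C, stride = 2L, name = "random_conv")
}
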