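# Standardization: intensity normalization, plane planning, byte-budget
# downsampling, slicing, tiling, and the composed per-source pipeline.

test_that("normalize_to_uint8 maps ranges affinely and passes 8-bit through", {
  m8 <- matrix(c(0L, 128L, 255L), 1)
  expect_identical(normalize_to_uint8(m8), m8)

  const <- matrix(500L, 3, 3)
  expect_true(all(normalize_to_uint8(const) == 0L))

  m16 <- matrix(c(0, 32768, 65535), 1)
  expect_equal(as.vector(normalize_to_uint8(m16)), c(0L, 127L, 255L))

  # affine min-max with floor rounding on an arbitrary range
  m <- matrix(c(-10, 0, 10), 1)
  expect_equal(as.vector(normalize_to_uint8(m)), c(0L, 127L, 255L))

  expect_error(normalize_to_uint8(matrix(c(1, NaN), 1), "srcA"), "srcA")
  expect_error(normalize_to_uint8(matrix(c(1, Inf), 1), "srcB"), "srcB")
})

test_that("normalize_to_uint8 is idempotent on its own output", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rnorm(400, 500, 300), 20)
    once <- normalize_to_uint8(m)
    expect_identical(normalize_to_uint8(once), once)
  }
})

test_that("plan_planes applies the 20% axial-deviation rule strictly", {
  expect_setequal(plan_planes(c(10, 10, 10))$planes, c("xy", "xz", "yz"))
  # deviation exactly 20%: excluded by the strict inequality
  expect_identical(plan_planes(c(24, 20, 20))$planes, "xy")
  # deviation 15%
  expect_setequal(plan_planes(c(23, 20, 20))$planes, c("xy", "xz", "yz"))
  expect_identical(plan_planes(NULL)$planes, "xy")
  expect_error(plan_planes(c(0, 10, 10)), "positive")
  # xy always included
  expect_true("xy" %in% plan_planes(c(100, 10, 10))$planes)
})

test_that("downsample_to_budget picks the smallest sufficient stride", {
  v <- array(0L, c(100, 100, 100))
  r <- downsample_to_budget(v, 1e9)
  expect_identical(r$factor, 1L)
  expect_identical(dim(r$volume), c(100L, 100L, 100L))

  v2 <- array(0L, c(200, 200, 200))
  r2 <- downsample_to_budget(v2, 1e6)
  expect_identical(r2$factor, 2L)          # 100^3 = 1e6 exactly passes
  expect_lte(prod(dim(r2$volume)), 1e6)

  # budget equal to the size: unchanged (inclusive boundary)
  r3 <- downsample_to_budget(v2, 8e6)
  expect_identical(r3$factor, 1L)

  expect_error(downsample_to_budget(v, 0), "max_bytes")
  expect_error(downsample_to_budget(matrix(0, 2, 2)), "3D")
})

test_that("slice_volume yields every section of each plane in axis order", {
  vol <- array(seq_len(3 * 4 * 5), c(3, 4, 5))
  xy <- slice_volume(vol, "xy")
  expect_length(xy, 3)
  expect_identical(dim(xy[[1]]$image), c(4L, 5L))
  expect_identical(xy[[2]]$slice_index, 1L)
  expect_equal(xy[[2]]$image, matrix(vol[2, , ], 4, 5))

  all3 <- slice_volume(vol, c("xy", "xz", "yz"))
  expect_length(all3, 3 + 4 + 5)
  planes <- vapply(all3, `[[`, character(1), "plane")
  expect_identical(as.vector(table(planes)[c("xy", "xz", "yz")]),
                   c(3L, 4L, 5L))
  # degenerate depth
  v1 <- array(seq_len(20), c(1, 4, 5))
  s1 <- slice_volume(v1, "xy")
  expect_length(s1, 1)
  expect_equal(s1[[1]]$image, matrix(v1[1, , ], 4, 5))
})

test_that("tile_image matches the window-enumeration oracle on key cases", {
  mk <- function(h, w) matrix(seq_len(h * w) %% 256L, h, w)
  cases <- list(c(448L, 448L), c(448L, 600L), c(448L, 559L), c(150L, 150L),
                c(100L, 100L), c(224L, 224L), c(336L, 336L), c(112L, 112L))
  expected_n <- c(4, 6, 4, 1, 0, 1, 4, 1)   # 336: 1 grid + edge-anchored rows/cols
  for (i in seq_along(cases)) {
    h <- cases[[i]][1]; w <- cases[[i]][2]
    tl <- tile_image(mk(h, w))
    expect_length(tl, expected_n[i])
    orc <- oracle_tile_windows(h, w)
    got <- if (length(tl)) {
      data.frame(y0 = vapply(tl, `[[`, integer(1), "y0"),
                 x0 = vapply(tl, `[[`, integer(1), "x0"),
                 edge = vapply(tl, `[[`, logical(1), "edge"),
                 pad = vapply(tl, `[[`, logical(1), "pad"))
    } else {
      data.frame(y0 = integer(0), x0 = integer(0),
                 edge = logical(0), pad = logical(0))
    }
    o1 <- orc[order(orc$y0, orc$x0), ]
    g1 <- got[order(got$y0, got$x0), ]
    rownames(o1) <- rownames(g1) <- NULL
    expect_identical(g1, o1, label = sprintf("windows for %dx%d", h, w))
  }
})

test_that("tile_image equals the oracle over random sizes and emits exact 224x224 crops", {
  set.seed(202)
  for (i in 1:120) {
    h <- sample(50:700, 1); w <- sample(50:700, 1)
    img <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    tl <- tile_image(img)
    orc <- oracle_tile_windows(h, w)
    expect_length(tl, nrow(orc))
    if (length(tl)) {
      got <- data.frame(y0 = vapply(tl, `[[`, integer(1), "y0"),
                        x0 = vapply(tl, `[[`, integer(1), "x0"))
      expect_setequal(paste(got$y0, got$x0), paste(orc$y0, orc$x0))
      for (t in tl) {
        expect_identical(dim(t$image), c(224L, 224L))
        # unpadded grid crops must reproduce the source pixels exactly
        if (!t$pad) {
          expect_identical(t$image,
                           img[t$y0 + 1:224, t$x0 + 1:224, drop = FALSE])
        }
      }
    }
  }
})

test_that("sample_random_patches is reproducible and respects bounds", {
  vol <- block_volume(10L, 448L, 448L)
  ps1 <- sample_random_patches(vol, n = 200, seed = 42, source_id = "v")
  ps2 <- sample_random_patches(vol, n = 200, seed = 42, source_id = "v")
  expect_identical(ps1$records, ps2$records)
  expect_identical(ps1$images, ps2$images)
  expect_true(all(ps1$records$y0 >= 0 & ps1$records$y0 <= 224))
  expect_true(all(ps1$records$x0 >= 0 & ps1$records$x0 <= 224))
  expect_true(all(ps1$records$slice_index >= 0 &
                  ps1$records$slice_index <= 9))
  expect_length(sample_random_patches(vol, n = 0, seed = 1), 0)
  expect_error(sample_random_patches(array(0L, c(3, 50, 50)), 10, 1),
               "minimum")
})

test_that("standardize_source composes the stages with full provenance", {
  # 2D: four clean grid patches
  img <- matrix(sample(0:255, 448 * 448, replace = TRUE), 448)
  src <- source_image(img, "flat2d")
  ps <- standardize_source(src)
  expect_length(ps, 4)
  expect_true(all(ps$records$plane == "xy"))
  expect_true(all(ps$records$slice_index == 0L))
  expect_true(all(vapply(ps$images, function(m)
    identical(dim(m), c(224L, 224L)), logical(1))))

  # isotropic volume: all three planes appear; anisotropic: xy only
  vol <- block_volume(300L, 448L, 448L)
  iso <- standardize_source(source_image(vol, "iso", spacing_nm = c(10, 10, 10)))
  expect_setequal(unique(iso$records$plane), c("xy", "xz", "yz"))
  n_xy <- sum(iso$records$plane == "xy")
  expect_identical(n_xy, 300L * 4L)         # 300 slices x 4 tiles

  aniso <- standardize_source(source_image(vol, "aniso",
                                           spacing_nm = c(50, 10, 10)))
  expect_identical(unique(aniso$records$plane), "xy")

  # provenance ids unique and parseable
  expect_false(anyDuplicated(iso$records$patch_id) > 0)
})

test_that("polarity inversion is applied only when requested", {
  img <- matrix(sample(0:255, 224 * 224, replace = TRUE), 224)
  src <- source_image(img, "inv", inverted = TRUE)
  cfg <- default_config()
  plain <- standardize_source(src, cfg)
  cfg$unify_polarity <- TRUE
  flipped <- standardize_source(src, cfg)
  expect_identical(flipped$images[[1]], 255L - plain$images[[1]])
})
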