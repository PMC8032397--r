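# Encoder probing: firing thresholds, Z selection, distortions, invariance
# curves, Point-Biserial selectivity, IoU, occlusion.

test_that("firing thresholds follow the encoder's response to uniform noise", {
  const1 <- new_encoder(function(img) 1, D = 1L, name = "one")
  expect_equal(firing_thresholds(const1, 200, seed = 1), 1)
  const0 <- new_encoder(function(img) 0, D = 1L, name = "zero")
  expect_equal(firing_thresholds(const0, 200, seed = 1), 0)
  # global pixel mean over 224^2 iid uniforms concentrates near 127.5
  gm <- make_toy_encoder("global_mean")
  th <- firing_thresholds(gm, 1000, seed = 5)
  expect_gt(th, 126.5)
  expect_lt(th, 128.5)
  expect_error(firing_thresholds(gm, 50, seed = 1), "100")
})

test_that("select_Z takes the top tenth with deterministic tie-breaking", {
  # encoder reading a single pixel gives distinct responses per image
  px <- new_encoder(function(img) img[1, 1], D = 1L, name = "px")
  images <- lapply(1:100, function(i) matrix(i, 4, 4))
  sel <- select_Z(px, images, thresholds = 0)
  expect_length(sel$Z[[1]], 10)
  expect_setequal(sel$Z[[1]], 91:100)
  expect_true(sel$selective[1])
  # dead neuron: responses 0 vs positive threshold -> not selective
  dead <- select_Z(new_encoder(function(img) 0, D = 1L), images,
                   thresholds = 0.5)
  expect_false(dead$selective[1])
  # constant responses: ties resolved to the first indices
  const <- select_Z(new_encoder(function(img) 3, D = 1L), images,
                    thresholds = 1)
  expect_identical(sort(const$Z[[1]]), 1:10)
  expect_error(select_Z(px, list(), 0), "empty")
})

test_that("distortions have exact identities and domain behaviour", {
  set.seed(8)
  img <- matrix(runif(224 * 224, 0, 255), 224)
  expect_identical(apply_distortion(img, "rotation", 0), img)
  expect_identical(apply_distortion(img, "blur", 0), img)
  expect_identical(apply_distortion(img, "noise", 0), img)
  expect_identical(apply_distortion(img, "brightness", 1), img)
  expect_identical(apply_distortion(img, "contrast", 1), img)
  expect_identical(apply_distortion(img, "scale", 1), img)
  # 90-degree rotations are exact permutations; 360 returns the input
  expect_identical(apply_distortion(img, "rotation", 360), img)
  r90 <- apply_distortion(img, "rotation", 90)
  expect_setequal(as.numeric(r90), as.numeric(img))
  expect_identical(apply_distortion(r90, "rotation", 270), img)
  # clipping keeps the range
  for (tr in c("noise", "brightness", "contrast")) {
    d <- apply_distortion(img, tr, if (tr == "noise") 50 else 3)
    expect_gte(min(d), 0)
    expect_lte(max(d), 255)
  }
  expect_identical(dim(apply_distortion(img, "scale", 1.7)), dim(img))
  expect_identical(dim(apply_distortion(img, "scale", 0.6)), dim(img))
  expect_error(apply_distortion(img, "shear", 1), "unknown")
})

test_that("mean firing rate is exactly 1 at identity and under exact invariances", {
  gm <- make_toy_encoder("global_mean")
  th <- firing_thresholds(gm, 500, seed = 5)
  probe <- mixed_probe_images(40)
  cur <- mean_firing_rate_curve(gm, probe, "rotation", c(0, 90, 180, 270),
                                thresholds = th)
  # global mean is exactly invariant under 90-degree permutations
  expect_identical(unname(cur$mean_firing_rate), c(1, 1, 1, 1))
  expect_gte(cur$n_selective, 1)

  cur_b <- mean_firing_rate_curve(gm, probe, "brightness", c(1, 0.5),
                                  thresholds = th)
  expect_identical(unname(cur_b$mean_firing_rate[1]), 1)
  # halving brightness halves the mean: responses fall below threshold
  expect_lt(cur_b$mean_firing_rate[2], 1)
})

test_that("a corner-reading encoder loses its stimulus under 180-degree rotation", {
  cp <- make_toy_encoder("corner_pixel")
  th <- firing_thresholds(cp, 500, seed = 5)
  probe <- lapply(1:60, corner_blob_patch)
  cur <- mean_firing_rate_curve(cp, probe, "rotation", c(0, 180),
                                thresholds = th)
  expect_identical(unname(cur$mean_firing_rate[1]), 1)
  expect_lt(cur$mean_firing_rate[2], cur$mean_firing_rate[1])
})

test_that("zero selective neurons is a diagnosed error", {
  never <- new_encoder(function(img) 0, D = 1L, name = "never")
  probe <- lapply(1:20, function(i) matrix(i, 8, 8))
  expect_error(
    mean_firing_rate_curve(never, probe, "blur", c(0, 1), thresholds = 1),
    "selective")
})

test_that("point_biserial equals the Pearson oracle and rejects degeneracy", {
  expect_equal(point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1)), 0.8944,
               tolerance = 1e-4)
  m <- matrix(c(0, 1, 0, 1), 2)
  expect_equal(point_biserial(m, m), 1.0)
  expect_error(point_biserial(matrix(1, 2, 2), matrix(c(0, 1, 0, 1), 2)),
               "variance")
  expect_error(point_biserial(1:4, rep(1, 4)), "single class")
  set.seed(41)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    x <- rnorm(n)
    g <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(g)) < 2) g[1:2] <- c(0, 1)
    expect_equal(point_biserial(x, g), cor(x, g), tolerance = 1e-10)
  }
})

test_that("iou counts mask overlap", {
  a <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(iou(a, a), 1.0)
  b <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(iou(a, b), 0.0)
  c2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(iou(a, c2), 0.5)
  expect_equal(iou(matrix(0, 2, 2), matrix(0, 2, 2)), 1.0)
  expect_error(iou(a, matrix(0, 3, 3)), "shape")
})

test_that("selectivity recovers a planted feature map", {
  p <- make_informative_patch(synth_config(), 11)
  img <- matrix(as.numeric(p$image), 224)
  enc <- make_toy_encoder("planted_filter", seed = 3,
                          truth_mask = p$masks$organelle)
  sel <- selectivity_map(enc, img, p$masks$organelle, k = 1)
  expect_identical(sel$top_channels[1], 1L)
  expect_gte(sel$iou_vs_truth, 0.9)
  expect_gte(min(sel$heatmap), 0)
  expect_lte(max(sel$heatmap), 1)
  # k = C: heatmap is the rescaled mean of all maps
  selC <- selectivity_map(enc, img, p$masks$organelle, k = enc$C)
  expect_equal(dim(selC$heatmap), c(224L, 224L))
  expect_error(selectivity_map(enc, img, p$masks$organelle, k = enc$C + 1L),
               "exceeds")
  expect_error(selectivity_map(enc, img, matrix(TRUE, 224, 224)),
               "single class")
})

test_that("occlusion grid follows the floor formula and localizes a planted landmark", {
  ide <- new_encoder(function(img) as.numeric(img), D = 224L * 224L,
                     name = "identity")
  img <- matrix(0, 224, 224)
  img[10:20, 10:20] <- 255        # blob inside the first window only
  oc <- occlusion_map(ide, img)
  expect_identical(dim(oc$grid), c(6L, 6L))
  expect_equal(oc$grid_norm[1, 1], 1.0)
  expect_true(all(oc$grid_norm[-1] == 0))
  expect_gte(min(oc$heatmap), 0)
  expect_lte(max(oc$heatmap), 1)
  # occluding an already-zero window changes nothing (raw importance 0)
  expect_equal(oc$grid[6, 6], 0)
  expect_error(occlusion_map(ide, img, window = 500L), "window")
  # alternative grid geometry
  oc2 <- occlusion_map(ide, img, window = 32L, stride = 32L)
  expect_identical(dim(oc2$grid), c(7L, 7L))
})
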