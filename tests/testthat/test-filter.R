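# Texture statistics, Random Forest informativeness filter, AUROC, and the
# labeling criteria.

test_that("feature extraction degenerate and textured cases behave as stated", {
  const <- matrix(100L, 224, 224)
  f <- extract_features(const)
  expect_identical(unname(f["lbp_std"]), 0)
  expect_lt(f["entropy_std"], 1e-10)
  expect_identical(unname(f["canny_mean"]), 0)
  expect_equal(unname(f["geomean_median"]), 100)

  set.seed(6)
  noise <- matrix(sample(0:255, 224 * 224, replace = TRUE), 224)
  fn <- extract_features(noise)
  expect_gt(fn["canny_mean"], 0)
  expect_gt(fn["entropy_std"], 0)

  expect_error(extract_features(array(0, c(2, 2, 2))), "2D")
})

test_that("canny edge fraction on a straight step edge matches a direct count", {
  # half-black / half-white vertical step: non-maximum suppression keeps a
  # one-pixel-wide vertical edge; border rows carry no edge. The oracle
  # count for a single straight boundary is therefore one edge pixel per
  # interior row: 224 - 2 = 222.
  # floating ties at the symmetric gradient peak may keep the odd pixel in
  # the adjoining column, so the count lies in [222, 2 * 222]
  img <- matrix(0L, 224, 224)
  img[, 113:224] <- 255L
  f <- extract_features(img)
  edge_pixels <- round(f[["canny_mean"]] * 224^2)
  expect_gte(edge_pixels, 222)
  expect_lte(edge_pixels, 444)
})

test_that("feature extraction is deterministic", {
  p <- make_informative_patch(synth_config(), 13)$image
  expect_identical(extract_features(p), extract_features(p))
})

test_that("evaluate_auroc equals the pairwise win-fraction oracle", {
  expect_equal(evaluate_auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(evaluate_auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(evaluate_auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(evaluate_auroc(1:4, rep(1, 4)), "both classes")

  oracle_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    wins <- 0
    for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
    wins / (length(pos) * length(neg))
  }
  set.seed(90)
  for (i in 1:60) {
    n <- sample(4:120, 1)
    s <- round(runif(n), 2)            # rounded scores force ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(evaluate_auroc(s, l), oracle_auc(s, l), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  s <- runif(300)
  l <- rbinom(300, 1, plogis(4 * s - 2))
  if (length(unique(l)) == 2) {
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(evaluate_auroc(s, l), ref, tolerance = 1e-10)
  }
})

test_that("training on separable features reaches perfect training AUROC and is deterministic", {
  cfg <- synth_config()
  ds <- make_filter_dataset(cfg, n = 120, seed = 21)
  m1 <- train_filter(ds, seed = 5, ntree = 200)
  m2 <- train_filter(ds, seed = 5, ntree = 200)
  sc1 <- predict_informative(ds$patches, m1)
  sc2 <- predict_informative(ds$patches, m2)
  expect_identical(sc1, sc2)
  train_idx <- ds$split == "train"
  expect_gte(evaluate_auroc(sc1$prob[train_idx], ds$labels[train_idx]), 0.999)

  # error paths
  one_class <- list(patches = ds$patches, labels = rep(1L, 120), split = NULL)
  expect_error(train_filter(one_class), "both classes")
  tiny <- list(patches = subset_patches(ds$patches,
                 ds$patches$records$patch_id[1:10]),
               labels = ds$labels[1:10], split = NULL)
  expect_error(train_filter(tiny), "20")
})

test_that("prediction applies the threshold with ties counting informative", {
  cfg <- synth_config()
  ds <- make_filter_dataset(cfg, n = 120, seed = 22)
  m <- train_filter(ds, seed = 5, ntree = 200)
  sc <- predict_informative(ds$patches, m)
  expect_identical(sc$is_informative, sc$prob >= m$threshold)
  # boundary: a probability exactly at threshold is informative
  m2 <- m
  m2$threshold <- sc$prob[1]
  sc2 <- predict_informative(ds$patches, m2)
  expect_true(sc2$is_informative[1])
  # feature-config mismatch is refused
  fc <- default_feature_config()
  fc$entropy_radius <- 5L
  expect_error(predict_informative(ds$patches, m, feature_config = fc),
               "feature_config")
})

test_that("raising the threshold never increases the retained count", {
  cfg <- synth_config()
  ds <- make_filter_dataset(cfg, n = 150, seed = 23)
  m <- train_filter(ds, seed = 5, ntree = 200)
  sc <- predict_informative(ds$patches, m)
  kept <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(th) sum(sc$prob >= th),
                 integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("label_with_criteria implements the 80% rule inclusively", {
  s <- 100L
  patch <- matrix(sample(0:255, s * s, replace = TRUE), s)
  exact80 <- matrix(FALSE, s, s)
  exact80[seq_len(80), ] <- TRUE        # exactly 80% uniform
  expect_identical(label_with_criteria(patch, list(uniform = exact80)), 0L)
  over <- matrix(TRUE, s, s)
  over[1:10, 1:10] <- FALSE             # 99% uniform
  expect_identical(label_with_criteria(patch, list(uniform = over)), 0L)
  under <- matrix(FALSE, s, s)
  under[seq_len(50), ] <- TRUE          # 50%
  expect_identical(label_with_criteria(patch, list(uniform = under)), 1L)
  # contrast floor and artifact flag
  flat <- matrix(128L, s, s)
  expect_identical(label_with_criteria(flat, NULL), 0L)
  expect_identical(label_with_criteria(patch, NULL, artifact = TRUE), 0L)
})

test_that("filter_corpus keeps informative patches and reports scores", {
  cfg <- synth_config()
  ds <- make_filter_dataset(cfg, n = 200, seed = 24)
  m <- train_filter(ds, seed = 5, ntree = 300)

  mk <- function(imgs, prefix) {
    recs <- do.call(rbind, lapply(seq_along(imgs), function(i) data.frame(
      patch_id = sprintf("%s-%03d", prefix, i), source_id = "x",
      plane = "xy", slice_index = 0L, y0 = 0L, x0 = 0L,
      edge_anchored = FALSE, padded = FALSE, stage = "dedup",
      prob = NA_real_, stringsAsFactors = FALSE)))
    names(imgs) <- recs$patch_id
    patch_set(imgs, recs)
  }
  resin <- mk(lapply(1:30, function(i)
    make_uninformative_patch(cfg, 500 + i, "resin")$image), "r")
  organ <- mk(lapply(1:30, function(i)
    make_informative_patch(cfg, 500 + i)$image), "o")

  fr <- filter_corpus(resin, m)
  fo <- filter_corpus(organ, m)
  expect_lte(length(fr$kept), 2)        # ~0 retained on all-resin
  expect_gte(length(fo$kept), 28)       # ~all retained on all-organelle
  expect_identical(nrow(fr$report$scores), 30L)
  expect_true(all(fo$kept$records$stage == "filtered"))
  expect_false(anyNA(fo$kept$records$prob))
})
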