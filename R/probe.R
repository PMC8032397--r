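# Encoder probing: invariance via neuron mean firing rates under image
# distortions, feature-map selectivity via Point-Biserial correlation, and
# spatial attribution via occlusion analysis. Encoders are pluggable and
# must satisfy the contract checked by new_encoder().

#' Construct an encoder object
#'
#' The probe contract: `pooled(image)` returns a length-`D` activation
#' vector (the global-average-pooled representation); `feature_maps(image)`
#' — optional, required only for selectivity — returns a list of `C` square
#' maps of side `224 / stride`. Both must be deterministic for fixed
#' weights.
#'
#' @param pooled function(image matrix) -> numeric vector of length `D`.
#' @param D pooled dimensionality.
#' @param feature_maps optional function(image) -> list of `C` matrices.
#' @param C number of feature maps.
#' @param stride output stride of the feature maps.
#' @param name label used in printing.
#' @return object of class `cem_encoder`.
#' @export
new_encoder <- function(pooled, D, feature_maps = NULL, C = NULL,
                        stride = NULL, name = "encoder") {
  stopifnot(is.function(pooled), D >= 1)
  structure(list(pooled = pooled, D = as.integer(D),
                 feature_maps = feature_maps,
                 C = if (is.null(C)) NULL else as.integer(C),
                 stride = stride, name = name),
            class = "cem_encoder")
}

#' @export
print.cem_encoder <- function(x, ...) {
  cat(sprintf("<encoder '%s': D=%d%s>\n", x$name, x$D,
              if (is.null(x$C)) "" else sprintf(", C=%d, stride=%s",
                                                x$C, x$stride)))
  invisible(x)
}

#' Per-neuron firing thresholds from random-noise inputs
#'
#' Passes `n_noise` images of iid uniform noise on \[0, 255\] through the
#' encoder and takes each neuron's 99th percentile response as its firing
#' threshold: activation above this level counts as "firing".
#'
#' @param encoder a [new_encoder()].
#' @param n_noise number of noise images (default 1000; below 100 is an
#'   error, the percentile is too unstable).
#' @param seed RNG seed.
#' @param size image side (default 224).
#' @return numeric vector of `D` thresholds.
#' @export
firing_thresholds <- function(encoder, n_noise = 1000L, seed = 42L,
                              size = 224L) {
  stopifnot(inherits(encoder, "cem_encoder"))
  if (n_noise < 100L) stop("firing_thresholds: n_noise must be >= 100")
  set.seed(seed)
  R <- matrix(NA_real_, n_noise, encoder$D)
  for (i in seq_len(n_noise)) {
    img <- matrix(runif(size * size, 0, 255), size, size)
    R[i, ] <- encoder$pooled(img)
  }
  apply(R, 2, quantile, probs = 0.99, names = FALSE)
}

#' Near-maximal image sets Z and neuron selectivity
#'
#' For each neuron, Z is the set of probe images activating it near
#' maximally: the top `ceiling(0.1 * n)` responses (the strict
#' 90th-percentile reading; ties are broken by response descending, then
#' image index). A neuron is selective iff every image in its Z activates
#' it above its firing threshold; non-selective neurons are ignored by the
#' invariance measure.
#'
#' @param encoder a [new_encoder()].
#' @param images list of probe images (matrices).
#' @param thresholds from [firing_thresholds()].
#' @return list with `Z` (list of image-index vectors per neuron),
#'   `selective` (logical per neuron), `responses` (n x D matrix).
#' @export
select_Z <- function(encoder, images, thresholds) {
  stopifnot(inherits(encoder, "cem_encoder"))
  n <- length(images)
  if (n == 0L) stop("select_Z: empty probe set")
  if (length(thresholds) != encoder$D) {
    stop("select_Z: thresholds length must equal D")
  }
  R <- t(vapply(images, encoder$pooled, numeric(encoder$D)))
  R <- matrix(R, n, encoder$D)
  m <- as.integer(ceiling(0.1 * n))
  Z <- vector("list", encoder$D)
  selective <- logical(encoder$D)
  for (j in seq_len(encoder$D)) {
    ord <- order(-R[, j], seq_len(n))
    Z[[j]] <- ord[seq_len(m)]
    selective[j] <- all(R[Z[[j]], j] > thresholds[j])
  }
  list(Z = Z, selective = selective, responses = R)
}

#' Apply a parametric distortion to an image
#'
#' The six probe transforms with their identity levels: `rotation`
#' (degrees about the centre, reflect padding; identity 0), `blur`
#' (Gaussian sigma; identity 0), `noise` (additive Gaussian sd, clipped;
#' identity 0), `brightness` (multiplicative factor, clipped; identity 1),
#' `contrast` (scaling about the image mean, clipped; identity 1), `scale`
#' (centre zoom factor, bilinear; identity 1). Identity levels return the
#' input unchanged; 90-degree rotation multiples are exact permutations.
#'
#' @param image numeric matrix on the 0-255 scale.
#' @param transform one of rotation, blur, noise, brightness, contrast,
#'   scale.
#' @param level distortion strength.
#' @param seed seed for the noise transform.
#' @return distorted image, same shape, values in \[0, 255\].
#' @export
apply_distortion <- function(image, transform, level, seed = 42L) {
  stopifnot(is.matrix(image))
  switch(transform,
    rotation = rotate_image(image, level),
    blur = gaussian_blur(image, level),
    noise = {
      if (level == 0) image else {
        set.seed(seed)
        clip255(image + matrix(rnorm(length(image), 0, level),
                               nrow(image)))
      }
    },
    brightness = if (level == 1) image else clip255(image * level),
    contrast = {
      if (level == 1) image else {
        mu <- mean(image)
        clip255((image - mu) * level + mu)
      }
    },
    scale = {
      if (level == 1) image else {
        h <- nrow(image); w <- ncol(image)
        nh <- max(2L, as.integer(round(h * level)))
        nw <- max(2L, as.integer(round(w * level)))
        z <- bilinear_resize(image, nh, nw)
        if (level > 1) {           # zoom in: centre crop
          y0 <- (nh - h) %/% 2L; x0 <- (nw - w) %/% 2L
          z[y0 + seq_len(h), x0 + seq_len(w), drop = FALSE]
        } else {                   # zoom out: reflect-pad back
          pt <- (h - nh) %/% 2L; pl <- (w - nw) %/% 2L
          reflect_pad(z, pt, h - nh - pt, pl, w - nw - pl)
        }
      }
    },
    stop(sprintf("apply_distortion: unknown transform '%s'", transform))
  )
}

#' Mean firing rate curve under a distortion
#'
#' For each selective neuron and each level, the firing rate is the
#' fraction of its near-maximal images Z whose distorted versions still
#' activate it above its firing threshold; the curve is the mean over
#' selective neurons. At the identity level the rate is exactly 1.
#'
#' @param encoder a [new_encoder()].
#' @param images probe images (list of matrices).
#' @param transform distortion name, see [apply_distortion()].
#' @param levels ordered distortion strengths.
#' @param thresholds from [firing_thresholds()]; computed when `NULL`.
#' @param seed RNG seed (noise transform and threshold computation).
#' @return list of class `invariance_curve`: `transform`, `levels`,
#'   `mean_firing_rate`, `n_selective`, `per_neuron` (rate matrix).
#' @export
mean_firing_rate_curve <- function(encoder, images, transform, levels,
                                   thresholds = NULL, seed = 42L) {
  if (is.null(thresholds)) {
    thresholds <- firing_thresholds(encoder, seed = derive_seed(seed, "noise"))
  }
  sel <- select_Z(encoder, images, thresholds)
  if (!any(sel$selective)) {
    stop(sprintf(
      "mean_firing_rate_curve: no selective neurons (max response %.3g, max threshold %.3g)",
      max(sel$responses), max(thresholds)))
  }
  js <- which(sel$selective)
  rates <- matrix(NA_real_, length(levels), length(js),
                  dimnames = list(NULL, paste0("n", js)))
  for (li in seq_along(levels)) {
    lev <- levels[li]
    Rd <- t(vapply(seq_along(images), function(i) {
      encoder$pooled(apply_distortion(images[[i]], transform, lev,
                                      seed = derive_seed(seed, paste0("d", i))))
    }, numeric(encoder$D)))
    Rd <- matrix(Rd, length(images), encoder$D)
    for (k in seq_along(js)) {
      j <- js[k]
      rates[li, k] <- mean(Rd[sel$Z[[j]], j] > thresholds[j])
    }
  }
  structure(list(transform = transform, levels = levels,
                 mean_firing_rate = rowMeans(rates),
                 n_selective = length(js), per_neuron = rates),
            class = "invariance_curve")
}

#' Point-Biserial correlation between a map and a binary mask
#'
#' `r_pb = ((M1 - M0) / s) * sqrt(n1 * n0 / n^2)` with `s` the population
#' standard deviation of the map; algebraically identical to the Pearson
#' correlation of the map against the 0/1 mask.
#'
#' @param map numeric matrix (or vector).
#' @param mask binary matrix (or vector), same length, both classes present.
#' @return correlation in \[-1, 1\].
#' @export
point_biserial <- function(map, mask) {
  x <- as.numeric(map); g <- as.numeric(mask)
  if (length(x) != length(g)) stop("point_biserial: shape mismatch")
  if (!all(g %in% c(0, 1))) stop("point_biserial: mask must be binary")
  n1 <- sum(g == 1); n0 <- sum(g == 0); n <- n1 + n0
  if (n1 == 0 || n0 == 0) stop("point_biserial: mask has a single class")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("point_biserial: map has zero variance")
  (mean(x[g == 1]) - mean(x[g == 0])) / s * sqrt(n1 * n0 / n^2)
}

#' Intersection-over-Union of two binary masks
#'
#' @param a,b binary matrices of the same shape.
#' @return `|a & b| / |a | b|`; 1 when both masks are empty.
#' @export
iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("iou: shape mismatch")
  a <- a != 0; b <- b != 0
  un <- sum(a | b)
  if (un == 0) return(1.0)
  sum(a & b) / un
}

# rescale to [0, 1]; degenerate (constant) input maps to all zeros
rescale01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(m * 0)
  (m - lo) / (hi - lo)
}

#' Feature-map selectivity for a ground-truth mask
#'
#' Bilinearly resizes each of the encoder's feature maps to the image size,
#' correlates each against the binary ground-truth mask by Point-Biserial
#' correlation, averages the `k` most correlated maps, rescales the mean
#' response to \[0, 1\], and thresholds it into a binary segmentation.
#'
#' @param encoder a [new_encoder()] exposing `feature_maps`.
#' @param image input image.
#' @param truth_mask binary 224x224 mask with both classes present.
#' @param k number of top maps to average (default 32).
#' @param threshold heatmap threshold for the binary mask (default 0.3).
#' @return list of class `selectivity_result`: `r_pb` (per-map, constant
#'   maps get `NA`), `top_channels` (indices, best first), `heatmap` in
#'   \[0, 1\], `mask` (binary), `iou_vs_truth`.
#' @export
selectivity_map <- function(encoder, image, truth_mask, k = 32L,
                            threshold = 0.3) {
  stopifnot(inherits(encoder, "cem_encoder"))
  if (is.null(encoder$feature_maps)) {
    stop("selectivity_map: encoder exposes no feature maps")
  }
  tm <- truth_mask != 0
  if (all(tm) || !any(tm)) stop("selectivity_map: truth mask has a single class")
  maps <- encoder$feature_maps(image)
  C <- length(maps)
  if (k > C) stop(sprintf("selectivity_map: k = %d exceeds C = %d", k, C))
  h <- nrow(image); w <- ncol(image)
  up <- lapply(maps, function(m) bilinear_resize(m, h, w))
  r_pb <- vapply(up, function(m) {
    tryCatch(point_biserial(m, tm), error = function(e) NA_real_)
  }, numeric(1))
  ord <- order(-r_pb, seq_len(C), na.last = TRUE)
  top <- ord[seq_len(k)]
  heat <- rescale01(Reduce(`+`, up[top]) / k)
  mask <- heat >= threshold
  structure(list(r_pb = r_pb, top_channels = top, heatmap = heat,
                 mask = mask, iou_vs_truth = iou(mask, tm)),
            class = "selectivity_result")
}

#' Occlusion-sensitivity map
#'
#' Measures each image region's importance to the encoder's match with a
#' reference view: windows of `window` pixels, spaced every `stride`
#' pixels, are zeroed out one at a time, and importance is the drop in
#' pooled-vector dot-product similarity `s_full - s_occluded`. The grid is
#' min-max normalized to \[0, 1\] and bilinearly upsampled for overlay.
#'
#' @param encoder a [new_encoder()].
#' @param image image to occlude.
#' @param reference reference view, same shape (defaults to `image`).
#' @param window occlusion window side (default 61).
#' @param stride window spacing (default 30).
#' @param fill occluded value (default 0).
#' @return list of class `occlusion_result`: `grid` (raw importance),
#'   `grid_norm` in \[0, 1\], `heatmap` (upsampled), `window`, `stride`.
#' @export
occlusion_map <- function(encoder, image, reference = image, window = 61L,
                          stride = 30L, fill = 0) {
  stopifnot(inherits(encoder, "cem_encoder"), is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  if (!identical(dim(image), dim(reference))) {
    stop("occlusion_map: image and reference must share a shape")
  }
  if (window > h || window > w) stop("occlusion_map: window exceeds image side")
  vref <- encoder$pooled(reference)
  s_full <- sum(encoder$pooled(image) * vref)
  gy <- floor((h - window) / stride) + 1L
  gx <- floor((w - window) / stride) + 1L
  grid <- matrix(NA_real_, gy, gx)
  for (a in seq_len(gy)) {
    for (b in seq_len(gx)) {
      y0 <- (a - 1L) * stride
      x0 <- (b - 1L) * stride
      occ <- image
      occ[y0 + seq_len(window), x0 + seq_len(window)] <- fill
      grid[a, b] <- s_full - sum(encoder$pooled(occ) * vref)
    }
  }
  gn <- rescale01(grid)
  structure(list(grid = grid, grid_norm = gn,
                 heatmap = bilinear_resize(gn, h, w),
                 window = window, stride = stride),
            class = "occlusion_result")
}
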