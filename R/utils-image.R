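# Low-level image helpers shared across modules.
#
# Images are plain R matrices indexed [row, col] = (y, x), 0-based offsets in
# all public records, values either 8-bit integers in [0, 255] or doubles on
# the same scale (distorted copies are kept as doubles to avoid cumulative
# quantization).

#' Reflect an index vector into [1, n] (mirror boundary, edge not duplicated)
#' @noRd
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  # period of the reflected sequence 1..n..2 is 2n - 2
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  ifelse(j < n, j + 1L, p - j + 1L)
}

#' Reflect-pad a matrix
#'
#' Mirrors rows/columns about the image edge (the edge pixel itself is not
#' duplicated), the convention used for whole-image padding of small frames
#' and for rotations.
#'
#' @param m numeric matrix.
#' @param top,bottom,left,right non-negative pad widths; each must be
#'   strictly smaller than the corresponding image extent.
#' @return padded matrix.
#' @export
reflect_pad <- function(m, top = 0L, bottom = 0L, left = 0L, right = 0L) {
  stopifnot(is.matrix(m))
  h <- nrow(m); w <- ncol(m)
  if (top >= h || bottom >= h || left >= w || right >= w) {
    stop("reflect_pad: pad width must be smaller than the image extent")
  }
  ri <- reflect_index(seq.int(1L - top, h + bottom), h)
  ci <- reflect_index(seq.int(1L - left, w + right), w)
  m[ri, ci, drop = FALSE]
}

#' 1-D convolution operator with mirror boundary, as a dense matrix
#'
#' Returns the n x n matrix K such that K %*% x convolves x with `kernel`
#' under reflected (mirror, no edge duplication) boundary handling. Used to
#' express separable filters as two small matrix products.
#' @noRd
conv_operator <- function(n, kernel) {
  k <- length(kernel)
  r <- (k - 1L) %/% 2L
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (t in seq_len(k)) {
    j <- reflect_index(idx + (t - 1L) - r, n)
    K[cbind(idx, j)] <- K[cbind(idx, j)] + kernel[t]
  }
  K
}

.op_cache <- new.env(parent = emptyenv())

gauss_operator <- function(n, sigma) {
  key <- sprintf("g:%d:%.6g", n, sigma)
  K <- .op_cache[[key]]
  if (is.null(K)) {
    r <- max(1L, as.integer(ceiling(3 * sigma)))
    x <- seq.int(-r, r)
    k <- exp(-x^2 / (2 * sigma^2))
    K <- conv_operator(n, k / sum(k))
    .op_cache[[key]] <- K
  }
  K
}

#' Gaussian blur (separable, mirror boundary)
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the input
#'   unchanged.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(m, sigma) {
  stopifnot(is.matrix(m))
  if (sigma <= 0) return(m)
  gauss_operator(nrow(m), sigma) %*% m %*% t(gauss_operator(ncol(m), sigma))
}

#' Box (moving-average) filter with mirror boundary
#' @noRd
box_filter <- function(m, size) {
  k <- rep(1 / size, size)
  conv_operator(nrow(m), k) %*% m %*% t(conv_operator(ncol(m), k))
}

#' Area-averaging resize
#'
#' Each output pixel is the exact area-weighted mean of the input pixels its
#' footprint covers (the kernel used to build difference hashes).
#'
#' @param m numeric matrix.
#' @param out_h,out_w output extents (positive integers).
#' @return `out_h` x `out_w` matrix.
#' @export
area_resize <- function(m, out_h, out_w) {
  stopifnot(is.matrix(m), out_h >= 1, out_w >= 1)
  m <- Wgt_area(nrow(m), out_h) %*% m %*% t(Wgt_area(ncol(m), out_w))
  m
}

# overlap-weight matrix mapping n input cells to out output cells
Wgt_area <- function(n, out) {
  W <- matrix(0, out, n)
  step <- n / out
  for (i in seq_len(out)) {
    a <- (i - 1) * step
    b <- i * step
    j0 <- floor(a) + 1L
    j1 <- min(n, ceiling(b))
    for (j in j0:j1) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) W[i, j] <- ov / step
    }
  }
  W
}

#' Bilinear resize (half-pixel centre alignment)
#'
#' @param m numeric matrix.
#' @param out_h,out_w output extents.
#' @return resized matrix.
#' @export
bilinear_resize <- function(m, out_h, out_w) {
  stopifnot(is.matrix(m), out_h >= 1, out_w >= 1)
  h <- nrow(m); w <- ncol(m)
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  bilinear_sample(m, matrix(rep(ys, out_w), out_h),
                  matrix(rep(xs, each = out_h), out_h))
}

# sample m at fractional (y, x) positions (same-shape matrices), clamping
# coordinates to the image; returns a matrix shaped like y
bilinear_sample <- function(m, y, x) {
  h <- nrow(m); w <- ncol(m)
  y <- pmin(pmax(y, 1), h)
  x <- pmin(pmax(x, 1), w)
  y0 <- pmin(floor(y), h - 1L); y0[h == 1L] <- 1
  x0 <- pmin(floor(x), w - 1L); x0[w == 1L] <- 1
  fy <- y - y0; fx <- x - x0
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  v <- (1 - fy) * (1 - fx) * m[cbind(c(y0), c(x0))] +
       (1 - fy) * fx       * m[cbind(c(y0), c(x1))] +
       fy       * (1 - fx) * m[cbind(c(y1), c(x0))] +
       fy       * fx       * m[cbind(c(y1), c(x1))]
  matrix(v, nrow(y), ncol(y))
}

#' Rotate an image about its centre
#'
#' Multiples of 90 degrees are exact index permutations; other angles use
#' bilinear interpolation over a reflect-padded copy so no background fill is
#' introduced.
#'
#' @param m numeric matrix (square for non-multiples of 90).
#' @param degrees rotation angle, counter-clockwise.
#' @return rotated matrix, same shape.
#' @export
rotate_image <- function(m, degrees) {
  stopifnot(is.matrix(m))
  d <- degrees %% 360
  if (d == 0) return(m)
  if (d %% 90 == 0) {
    k <- as.integer(d / 90)
    for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    return(m)
  }
  h <- nrow(m); w <- ncol(m)
  pad <- as.integer(ceiling(max(h, w) * (sqrt(2) - 1) / 2)) + 2L
  pad <- min(pad, h - 1L, w - 1L)
  mp <- reflect_pad(m, pad, pad, pad, pad)
  th <- d * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- matrix(rep(seq_len(h), w), h) - cy
  gx <- matrix(rep(seq_len(w), each = h), h) - cx
  # inverse map: rotate output coords by -theta into source space
  sy <-  cos(th) * gy + sin(th) * gx + cy + pad
  sx <- -sin(th) * gy + cos(th) * gx + cx + pad
  bilinear_sample(mp, sy, sx)
}

clip255 <- function(m) {
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

#' Derive a per-stage seed from a corpus-level seed
#'
#' One corpus seed fans out deterministically to independent stage seeds so
#' that every stage is reproducible in isolation. The label is hashed with
#' a base-31 polynomial rolling hash (order-sensitive) and combined with
#' the seed modulo `2^31 - 1`.
#'
#' @param seed integer corpus seed.
#' @param label character stage label.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  M <- 2147483647
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% M
  as.integer((abs(seed) %% M * 69621 + h) %% M)
}

as_uint8 <- function(m) {
  storage.mode(m) <- "integer"
  m
}

is_uint8 <- function(m) {
  is.matrix(m) && is.numeric(m) && !anyNA(m) &&
    all(m >= 0 & m <= 255) && all(m == floor(m))
}
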