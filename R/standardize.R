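# Standardization of heterogeneous 2D/3D EM data into 224x224 8-bit patches.
#
# Volumes are arrays dim = (z, y, x); the xy plane of slice k is vol[k, , ].
# All crop offsets in patch records are 0-based, (y0, x0) top-left, windows
# half-open [y0, y0 + 224).

PATCH_SIZE <- 224L
MIN_KEEP <- 112L

#' Construct a source image
#'
#' The unit of ingestion: one 2D image or one 3D volume, together with the
#' metadata the pipeline consults (voxel spacing for the anisotropy rule,
#' intensity polarity).
#'
#' @param pixels 2D matrix or 3D array of numeric pixel values.
#' @param source_id unique identifier within the corpus.
#' @param spacing_nm optional voxel spacing `c(z, y, x)` in nanometres; all
#'   values must be positive.
#' @param inverted logical; `TRUE` when the source has inverted intensity
#'   polarity (membranes bright).
#' @return an object of class `source_image`.
#' @export
source_image <- function(pixels, source_id, spacing_nm = NULL,
                         inverted = FALSE) {
  nd <- length(dim(pixels))
  if (is.null(dim(pixels)) || !nd %in% c(2L, 3L)) {
    stop("source_image: pixels must be a 2D matrix or 3D array")
  }
  if (!is.null(spacing_nm)) {
    if (length(spacing_nm) != 3L || any(!is.finite(spacing_nm)) ||
        any(spacing_nm <= 0)) {
      stop("source_image: spacing_nm must be a positive (z, y, x) triple")
    }
  }
  structure(
    list(source_id = as.character(source_id),
         kind = if (nd == 2L) "image2d" else "volume3d",
         pixels = pixels,
         spacing_nm = spacing_nm,
         inverted = isTRUE(inverted)),
    class = "source_image")
}

#' @export
print.source_image <- function(x, ...) {
  cat(sprintf("<source_image '%s' %s [%s]%s>\n", x$source_id, x$kind,
              paste(dim(x$pixels), collapse = "x"),
              if (is.null(x$spacing_nm)) "" else
                paste0(" spacing=", paste(x$spacing_nm, collapse = ","))))
  invisible(x)
}

#' Min-max normalize pixel data to 8-bit
#'
#' Affine global min-max mapping of the input range onto \[0, 255\] with
#' floor rounding. Inputs already holding 8-bit values pass through
#' unchanged; constant inputs map to all zeros.
#'
#' @param pixels numeric matrix or array.
#' @param source_id identifier used in error messages.
#' @return same-shape integer array with values in \[0, 255\].
#' @export
normalize_to_uint8 <- function(pixels, source_id = "<unnamed>") {
  if (!is.numeric(pixels)) stop("normalize_to_uint8: non-numeric input")
  if (any(!is.finite(pixels))) {
    stop(sprintf("normalize_to_uint8: non-finite values in source '%s'",
                 source_id))
  }
  lo <- min(pixels); hi <- max(pixels)
  if (lo >= 0 && hi <= 255 && all(pixels == floor(pixels))) {
    storage.mode(pixels) <- "integer"
    return(pixels)
  }
  if (hi == lo) {
    out <- array(0L, dim(pixels))
    return(out)
  }
  out <- floor(255 * (pixels - lo) / (hi - lo))
  out[out > 255] <- 255L
  storage.mode(out) <- "integer"
  out
}

#' Decide which orthogonal planes to slice from a volume
#'
#' Near-isotropic volumes are sliced along all three orthogonal planes;
#' volumes whose axial (z) spacing deviates from the lateral mean by 20% or
#' more — and volumes without spacing metadata — are sliced along xy only.
#' The deviation is `|z - mean(x, y)| / mean(x, y)`, compared strictly
#' against 0.2.
#'
#' @param spacing_nm optional `c(z, y, x)` spacing in nanometres.
#' @param max_rel_dev relative deviation bound (default 0.2).
#' @return a `slice_plan`: list with `planes` (subset of xy/xz/yz, xy always
#'   included) and `downsample_factors` (filled in by
#'   [downsample_to_budget()], identity here).
#' @export
plan_planes <- function(spacing_nm = NULL, max_rel_dev = 0.2) {
  if (is.null(spacing_nm)) {
    return(structure(list(planes = "xy", downsample_factors = c(1L, 1L, 1L)),
                     class = "slice_plan"))
  }
  if (length(spacing_nm) != 3L || any(spacing_nm <= 0)) {
    stop("plan_planes: spacing must be a positive (z, y, x) triple")
  }
  lat <- mean(spacing_nm[2:3])
  dev <- abs(spacing_nm[1] - lat) / lat
  planes <- if (dev < max_rel_dev) c("xy", "xz", "yz") else "xy"
  structure(list(planes = planes, downsample_factors = c(1L, 1L, 1L)),
            class = "slice_plan")
}

#' Downsample a volume to a byte budget by uniform stride subsampling
#'
#' Finds the smallest integer stride f = 1, 2, 3, ... applied to all three
#' axes such that the strided volume's byte size (1 byte per voxel after
#' 8-bit standardization) does not exceed `max_bytes`.
#'
#' @param volume 3D array.
#' @param max_bytes byte budget, default 5e9 (5 GB).
#' @return list with `volume` (possibly strided) and `factor` (the stride).
#' @export
downsample_to_budget <- function(volume, max_bytes = 5e9) {
  if (length(dim(volume)) != 3L) stop("downsample_to_budget: volume must be 3D")
  if (max_bytes < 1) stop("downsample_to_budget: max_bytes must be >= 1")
  d <- dim(volume)
  f <- 1L
  repeat {
    sz <- prod(ceiling(d / f))
    if (sz <= max_bytes) break
    f <- f + 1L
  }
  if (f > 1L) {
    volume <- volume[seq.int(1L, d[1], by = f),
                     seq.int(1L, d[2], by = f),
                     seq.int(1L, d[3], by = f), drop = FALSE]
  }
  list(volume = volume, factor = f)
}

#' Extract every cross-section of the planned planes from a volume
#'
#' Sections are yielded in axis order: all xy sections (one per z index),
#' then xz (one per y), then yz (one per x), for the planes present in the
#' plan. Section matrices are oriented with rows = the first remaining axis.
#'
#' @param volume 3D array, dim = (z, y, x).
#' @param plan a `slice_plan` (or character vector of planes).
#' @return list of lists `(plane, slice_index, image)` with 0-based
#'   `slice_index`.
#' @export
slice_volume <- function(volume, plan) {
  if (length(dim(volume)) != 3L) stop("slice_volume: volume must be 3D")
  planes <- if (inherits(plan, "slice_plan")) plan$planes else plan
  d <- dim(volume)
  out <- vector("list", sum(c(xy = d[1], xz = d[2], yz = d[3])[planes]))
  i <- 0L
  if ("xy" %in% planes) {
    for (k in seq_len(d[1])) {
      i <- i + 1L
      out[[i]] <- list(plane = "xy", slice_index = k - 1L,
                       image = matrix(volume[k, , ], d[2], d[3]))
    }
  }
  if ("xz" %in% planes) {
    for (k in seq_len(d[2])) {
      i <- i + 1L
      out[[i]] <- list(plane = "xz", slice_index = k - 1L,
                       image = matrix(volume[, k, ], d[1], d[3]))
    }
  }
  if ("yz" %in% planes) {
    for (k in seq_len(d[3])) {
      i <- i + 1L
      out[[i]] <- list(plane = "yz", slice_index = k - 1L,
                       image = matrix(volume[, , k], d[1], d[2]))
    }
  }
  out
}

# per-axis crop offsets under the 224/112 rules; returns a data.frame with
# 0-based offsets plus edge/pad flags, or zero rows when the axis is too small
axis_offsets <- function(n, patch = PATCH_SIZE, min_keep = MIN_KEEP) {
  if (n < min_keep) {
    return(data.frame(off = integer(0), edge = logical(0), pad = logical(0)))
  }
  if (n < patch) {
    return(data.frame(off = 0L, edge = FALSE, pad = TRUE))
  }
  k <- n %/% patch
  off <- (seq_len(k) - 1L) * patch
  edge <- rep(FALSE, k)
  r <- n - k * patch
  if (r >= min_keep) {
    off <- c(off, n - patch)
    edge <- c(edge, TRUE)
  }
  data.frame(off = off, edge = edge, pad = FALSE)
}

# reflect-pad an image up to `patch` on any axis smaller than it
pad_to_patch <- function(image, patch = PATCH_SIZE) {
  h <- nrow(image); w <- ncol(image)
  ptop <- pleft <- 0L
  if (h < patch) {
    p <- patch - h
    ptop <- p %/% 2L
    image <- reflect_pad(image, ptop, p - ptop, 0L, 0L)
  }
  if (w < patch) {
    p <- patch - w
    pleft <- p %/% 2L
    image <- reflect_pad(image, 0L, 0L, pleft, p - pleft)
  }
  image
}

#' Tile an image into non-overlapping 224x224 crops
#'
#' Emits the full grid of non-overlapping 224-pixel windows. A remainder
#' strip of width r with 112 <= r < 224 along an axis yields one extra
#' edge-anchored full window (offset `dim - 224`, flagged `edge`); strips
#' with r < 112 are discarded. An image smaller than 224 on an axis but at
#' least 112 is reflect-padded to 224 on that axis and emits a single crop
#' flagged `pad`; images below 112 on any axis emit nothing.
#'
#' @param image 2D matrix of 8-bit values.
#' @return list of lists `(y0, x0, image, edge, pad)` with 0-based offsets
#'   and exact 224x224 8-bit crops.
#' @export
tile_image <- function(image) {
  if (!is.matrix(image)) stop("tile_image: input must be a 2D matrix")
  ro <- axis_offsets(nrow(image))
  co <- axis_offsets(ncol(image))
  if (nrow(ro) == 0L || nrow(co) == 0L) return(list())
  padded <- any(ro$pad) || any(co$pad)
  if (padded) image <- pad_to_patch(image)
  out <- vector("list", nrow(ro) * nrow(co))
  i <- 0L
  for (a in seq_len(nrow(ro))) {
    for (b in seq_len(nrow(co))) {
      i <- i + 1L
      out[[i]] <- list(
        y0 = ro$off[a], x0 = co$off[b],
        image = image[ro$off[a] + seq_len(PATCH_SIZE),
                      co$off[b] + seq_len(PATCH_SIZE), drop = FALSE],
        edge = ro$edge[a] || co$edge[b],
        pad = ro$pad[a] || co$pad[b])
    }
  }
  out
}

#' Randomly sample xy-plane patches from a volume
#'
#' Uniformly samples slice indices and top-left offsets; slices narrower
#' than 224 on an axis (but at least 112) are reflect-padded first.
#'
#' @param volume 3D array, dim = (z, y, x), 8-bit values.
#' @param n number of patches (default 1000).
#' @param seed RNG seed.
#' @param source_id identifier recorded in the patch records.
#' @return a [patch_set()].
#' @export
sample_random_patches <- function(volume, n = 1000L, seed = 42L,
                                  source_id = "volume") {
  if (length(dim(volume)) != 3L) stop("sample_random_patches: volume must be 3D")
  d <- dim(volume)
  if (d[2] < MIN_KEEP || d[3] < MIN_KEEP) {
    stop("sample_random_patches: xy extent below the minimum keepable size")
  }
  if (n < 0) stop("sample_random_patches: n must be >= 0")
  if (n == 0) return(patch_set(list(), empty_records()))
  set.seed(seed)
  ks <- sample.int(d[1], n, replace = TRUE)
  ymax <- max(d[2] - PATCH_SIZE, 0L)
  xmax <- max(d[3] - PATCH_SIZE, 0L)
  y0s <- if (ymax > 0) sample.int(ymax + 1L, n, replace = TRUE) - 1L else rep(0L, n)
  x0s <- if (xmax > 0) sample.int(xmax + 1L, n, replace = TRUE) - 1L else rep(0L, n)
  images <- vector("list", n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    sl <- matrix(volume[ks[i], , ], d[2], d[3])
    pad <- d[2] < PATCH_SIZE || d[3] < PATCH_SIZE
    if (pad) sl <- pad_to_patch(sl)
    img <- sl[y0s[i] + seq_len(PATCH_SIZE), x0s[i] + seq_len(PATCH_SIZE),
              drop = FALSE]
    pid <- sprintf("%s-xy-%04d-%d-%d", source_id, ks[i] - 1L, y0s[i], x0s[i])
    images[[i]] <- as_uint8(img)
    recs[[i]] <- data.frame(
      patch_id = pid, source_id = source_id, plane = "xy",
      slice_index = ks[i] - 1L, y0 = y0s[i], x0 = x0s[i],
      edge_anchored = FALSE, padded = pad, stage = "raw",
      prob = NA_real_, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  # sampling with replacement can repeat a location; disambiguate ids
  records$patch_id <- make.unique(records$patch_id, sep = "#")
  names(images) <- records$patch_id
  patch_set(images, records)
}

#' Standardize one source into 224x224 8-bit patches
#'
#' Composition of the standardization steps: intensity normalization to
#' 8-bit, volume downsampling to the byte budget, plane planning by the
#' anisotropy rule, orthogonal slicing, and tiling. 2D sources skip the
#' volume steps. Optional intensity inversion unifies polarity when the
#' source is flagged inverted and `config$unify_polarity` is `TRUE`.
#'
#' @param src a [source_image()].
#' @param config pipeline configuration, see [default_config()].
#' @return a [patch_set()] with full provenance records.
#' @export
standardize_source <- function(src, config = default_config()) {
  stopifnot(inherits(src, "source_image"))
  px <- src$pixels
  if (!is.null(config$clip_percentiles)) {
    q <- quantile(px, config$clip_percentiles, names = FALSE)
    px[px < q[1]] <- q[1]
    px[px > q[2]] <- q[2]
  }
  px <- normalize_to_uint8(px, src$source_id)
  if (src$inverted && isTRUE(config$unify_polarity)) px <- 255L - px
  if (src$kind == "image2d") {
    sections <- list(list(plane = "xy", slice_index = 0L,
                          image = matrix(px, dim(px)[1], dim(px)[2])))
  } else {
    ds <- downsample_to_budget(px, config$max_source_bytes)
    plan <- plan_planes(src$spacing_nm, config$max_rel_spacing_dev)
    plan$downsample_factors <- rep(ds$factor, 3L)
    sections <- slice_volume(ds$volume, plan)
  }
  images <- list()
  recs <- list()
  for (sec in sections) {
    for (tl in tile_image(sec$image)) {
      pid <- sprintf("%s-%s-%04d-%d-%d", src$source_id, sec$plane,
                     sec$slice_index, tl$y0, tl$x0)
      images[[pid]] <- as_uint8(tl$image)
      recs[[pid]] <- data.frame(
        patch_id = pid, source_id = src$source_id, plane = sec$plane,
        slice_index = sec$slice_index, y0 = tl$y0, x0 = tl$x0,
        edge_anchored = tl$edge, padded = tl$pad, stage = "raw",
        prob = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) return(patch_set(list(), empty_records()))
  patch_set(images, do.call(rbind, recs))
}
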