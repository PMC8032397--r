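# Independent oracles and fixtures shared across tests. Oracles are written
# as direct enumerations, independent of the implementation paths they
# check.

# Brute-force tiling oracle: enumerate, for one axis, the offsets the
# 224/112 rules admit — full grid windows, one edge-anchored window for a
# keepable remainder, a single padded window for small axes — and cross the
# two axes.
oracle_axis_offsets <- function(n, patch = 224L, min_keep = 112L) {
  if (n < min_keep) return(NULL)
  if (n < patch) return(data.frame(off = 0L, edge = FALSE, pad = TRUE))
  offs <- seq.int(0L, n - patch, by = patch)
  edge <- rep(FALSE, length(offs))
  if (n %% patch >= min_keep && n %% patch > 0L) {
    offs <- c(offs, n - patch)
    edge <- c(edge, TRUE)
  }
  data.frame(off = offs, edge = edge, pad = FALSE)
}

oracle_tile_windows <- function(h, w, patch = 224L, min_keep = 112L) {
  ro <- oracle_axis_offsets(h, patch, min_keep)
  co <- oracle_axis_offsets(w, patch, min_keep)
  if (is.null(ro) || is.null(co)) {
    return(data.frame(y0 = integer(0), x0 = integer(0),
                      edge = logical(0), pad = logical(0)))
  }
  g <- expand.grid(a = seq_len(nrow(ro)), b = seq_len(nrow(co)))
  data.frame(y0 = ro$off[g$a], x0 = co$off[g$b],
             edge = ro$edge[g$a] | co$edge[g$b],
             pad = ro$pad[g$a] | co$pad[g$b])
}

# Brute-force connected components under Hamming distance < cutoff: O(n^2)
# pairwise distances + BFS, no graph library.
oracle_components <- function(B, cutoff) {
  n <- nrow(B)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      for (j in seq_len(n)) {
        if (is.na(comp[j]) && sum(B[i, ] != B[j, ]) < cutoff) {
          comp[j] <- cid
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# random 64-bit hash rows, some clustered around shared centroids so that
# non-trivial groups exist
random_hash_matrix <- function(n, n_centroids = max(1L, n %/% 5L),
                               flip = 3L) {
  centroids <- matrix(sample(0:1, n_centroids * 64, replace = TRUE),
                      n_centroids, 64)
  B <- matrix(0L, n, 64)
  for (i in seq_len(n)) {
    b <- centroids[sample.int(n_centroids, 1), ]
    nf <- sample.int(flip + 1L, 1) - 1L
    if (nf > 0) {
      at <- sample.int(64, nf)
      b[at] <- 1L - b[at]
    }
    B[i, ] <- b
  }
  rownames(B) <- sprintf("h%04d", seq_len(n))
  B
}

# probe fixture: dark frame with one bright block in a random corner; the
# corner moves under 180-degree rotation, so a corner-reading encoder loses
# its stimulus
corner_blob_patch <- function(seed, size = 224L) {
  set.seed(seed)
  img <- matrix(60 + rnorm(size * size, 0, 5), size)
  corner <- sample.int(4L, 1L)
  ys <- if (corner %in% c(1L, 2L)) 1:40 else (size - 39L):size
  xs <- if (corner %in% c(1L, 3L)) 1:40 else (size - 39L):size
  img[ys, xs] <- 230
  pmin(pmax(img, 0), 255)
}

# mixed bright/textured probe images so mean-style encoders have
# above-threshold responses
mixed_probe_images <- function(n = 50L, cfg = synth_config()) {
  c(lapply(seq_len(ceiling(n * 0.6)), function(i) {
      matrix(as.numeric(make_informative_patch(cfg, i)$image), 224)
    }),
    lapply(seq_len(floor(n * 0.4)), function(i) {
      matrix(as.numeric(
        make_uninformative_patch(cfg, 1000L + i, "resin")$image), 224)
    }))
}

# small standardizable test volume with block structure (deterministic)
block_volume <- function(d = 3L, h = 300L, w = 300L) {
  vol <- array(0L, c(d, h, w))
  for (k in seq_len(d)) {
    sl <- outer(seq_len(h), seq_len(w), function(y, x) {
      as.integer((y * 7L + x * 13L + k * 31L) %% 256L)
    })
    vol[k, , ] <- sl
  }
  vol
}
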