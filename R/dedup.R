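# Perceptual-hash deduplication: difference hashes, Hamming distances,
# single-linkage near-duplicate groups within each source dataset, and
# random exemplar selection.

#' Difference hash of an image
#'
#' Reduces the image by exact area averaging to `hash_size` rows by
#' `hash_size + 1` columns and emits one bit per adjacent horizontal pair:
#' bit (r, c) = 1 iff pixel(r, c) < pixel(r, c + 1). Bits are serialized
#' row-major, giving `hash_size^2` bits (64 for the default size 8).
#'
#' @param image 2D numeric matrix.
#' @param hash_size side of the hash grid (default 8).
#' @return integer vector of 0/1 bits, length `hash_size^2`.
#' @export
dhash <- function(image, hash_size = 8L) {
  if (!is.matrix(image)) stop("dhash: input must be a 2D matrix")
  if (hash_size < 1) stop("dhash: hash_size must be >= 1")
  small <- area_resize(image, hash_size, hash_size + 1L)
  # strict "<" with a guard against pure floating residue of the
  # area-weighting, so exactly tied cells give bit 0
  bits <- (small[, seq_len(hash_size) + 1L, drop = FALSE] -
           small[, seq_len(hash_size), drop = FALSE]) > 1e-9
  as.integer(t(bits))  # row-major serialization
}

#' Hamming distance between two bit vectors
#'
#' @param a,b equal-length 0/1 integer vectors.
#' @return number of differing positions.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) stop("hamming: length mismatch")
  sum(a != b)
}

# all pairwise Hamming distances between rows of a 0/1 bit matrix
hamming_matrix <- function(B) {
  B <- matrix(as.numeric(B), nrow(B), ncol(B))
  s <- rowSums(B)
  D <- outer(s, s, "+") - 2 * tcrossprod(B)
  round(D)
}

#' Group near-duplicate hashes within one source
#'
#' Builds the graph with an edge between every pair of hashes at Hamming
#' distance strictly below `cutoff` and returns its connected components
#' (single-linkage transitive closure); singletons are their own groups and
#' the groups partition the input.
#'
#' @param hashes list of patch hashes, each `list(patch_id, source_id,
#'   bits)`, all from one source; or a 0/1 matrix with rownames = patch ids.
#' @param cutoff strict Hamming cutoff (default 12).
#' @return list of groups, each `list(member_ids, exemplar_id = NA)`.
#' @export
group_near_duplicates <- function(hashes, cutoff = 12L) {
  if (is.matrix(hashes)) {
    B <- hashes
    ids <- rownames(B)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(B)))
  } else {
    if (length(hashes) == 0L) return(list())
    srcs <- unique(vapply(hashes, function(h) h$source_id, character(1)))
    if (length(srcs) > 1L) {
      stop("group_near_duplicates: hashes span multiple sources")
    }
    ids <- vapply(hashes, function(h) h$patch_id, character(1))
    B <- do.call(rbind, lapply(hashes, function(h) h$bits))
  }
  n <- nrow(B)
  if (n == 0L) return(list())
  D <- hamming_matrix(B)
  A <- D < cutoff
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  lapply(split(ids, comp), function(m) {
    list(member_ids = m, exemplar_id = NA_character_)
  })
}

#' Pick one random exemplar per duplicate group
#'
#' Groups are visited in order of their smallest member id under a single
#' seeded generator, so the selection is reproducible regardless of how the
#' groups were enumerated.
#'
#' @param groups list of groups from [group_near_duplicates()].
#' @param seed RNG seed.
#' @return character vector of kept patch ids (one per group).
#' @export
select_exemplars <- function(groups, seed = 42L) {
  if (length(groups) == 0L) return(character(0))
  sizes <- vapply(groups, function(g) length(g$member_ids), integer(1))
  if (any(sizes == 0L)) stop("select_exemplars: empty group")
  ord <- order(vapply(groups, function(g) min(g$member_ids), character(1)))
  set.seed(seed)
  vapply(groups[ord], function(g) {
    m <- sort(g$member_ids)
    m[sample.int(length(m), 1L)]
  }, character(1))
}

#' Deduplicate a corpus of patches
#'
#' Hashes every patch, groups near-duplicates within each source dataset
#' (hashes are never compared across sources), and keeps one randomly
#' chosen exemplar per group.
#'
#' @param ps a [patch_set()].
#' @param cutoff strict Hamming cutoff (default 12).
#' @param seed RNG seed for exemplar selection.
#' @param hash_size difference-hash size (default 8).
#' @return list with `kept` (the deduplicated `patch_set`, stage set to
#'   "dedup") and `report` (group-size histogram, per-source group counts,
#'   reduction fraction).
#' @export
deduplicate_corpus <- function(ps, cutoff = 12L, seed = 42L, hash_size = 8L) {
  stopifnot(inherits(ps, "patch_set"))
  n0 <- length(ps)
  if (n0 == 0L) {
    return(list(kept = ps,
                report = list(n_before = 0L, n_after = 0L, reduction = 0,
                              group_sizes = integer(0))))
  }
  keep_ids <- character(0)
  group_sizes <- integer(0)
  for (src in unique(ps$records$source_id)) {
    ids <- ps$records$patch_id[ps$records$source_id == src]
    B <- do.call(rbind, lapply(ps$images[ids],
                               function(im) dhash(im, hash_size)))
    rownames(B) <- ids
    groups <- group_near_duplicates(B, cutoff)
    group_sizes <- c(group_sizes,
                     vapply(groups, function(g) length(g$member_ids),
                            integer(1)))
    keep_ids <- c(keep_ids, select_exemplars(groups, derive_seed(seed, src)))
  }
  kept <- subset_patches(ps, keep_ids)
  kept$records$stage <- "dedup"
  list(kept = kept,
       report = list(n_before = n0, n_after = length(kept),
                     reduction = 1 - length(kept) / n0,
                     group_sizes = sort(table(group_sizes))))
}
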