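# Corpus container, JSON-lines manifest I/O, and pipeline configuration.

empty_records <- function() {
  data.frame(patch_id = character(0), source_id = character(0),
             plane = character(0), slice_index = integer(0),
             y0 = integer(0), x0 = integer(0),
             edge_anchored = logical(0), padded = logical(0),
             stage = character(0), prob = numeric(0),
             stringsAsFactors = FALSE)
}

#' Construct a patch set
#'
#' The in-memory corpus container: a named list of 224x224 8-bit matrices
#' plus a provenance record per patch. `records` rows and `images` names
#' must agree; patch ids must be unique.
#'
#' @param images named list of integer matrices, names = patch ids.
#' @param records data.frame with one row per patch (patch_id, source_id,
#'   plane, slice_index, y0, x0, edge_anchored, padded, stage, prob).
#' @return object of class `patch_set`.
#' @export
patch_set <- function(images, records) {
  stopifnot(is.list(images), is.data.frame(records))
  if (length(images) != nrow(records)) {
    stop("patch_set: images and records disagree in length")
  }
  if (anyDuplicated(records$patch_id)) {
    stop("patch_set: duplicate patch ids")
  }
  if (length(images) > 0 && !identical(names(images), records$patch_id)) {
    images <- images[records$patch_id]
    if (anyNA(names(images))) stop("patch_set: image names do not match records")
  }
  rownames(records) <- NULL
  structure(list(images = images, records = records), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  st <- table(x$records$stage)
  cat(sprintf("<patch_set: %d patches, %d sources%s>\n",
              nrow(x$records), length(unique(x$records$source_id)),
              if (length(st)) paste0(", stage ",
                paste(names(st), st, sep = "=", collapse = " ")) else ""))
  invisible(x)
}

#' @export
length.patch_set <- function(x) nrow(x$records)

#' Subset a patch set by patch id
#' @param ps a `patch_set`.
#' @param ids character vector of patch ids to keep (order preserved).
#' @return the restricted `patch_set`.
#' @export
subset_patches <- function(ps, ids) {
  stopifnot(inherits(ps, "patch_set"))
  keep <- ps$records$patch_id %in% ids
  patch_set(ps$images[ps$records$patch_id[keep]],
            ps$records[keep, , drop = FALSE])
}

#' Combine patch sets
#' @param ... `patch_set` objects.
#' @return one `patch_set` with all patches; ids must not collide.
#' @export
bind_patches <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "patch_set")) {
    sets <- sets[[1]]
  }
  images <- do.call(c, lapply(sets, function(s) s$images))
  records <- data.table::rbindlist(lapply(sets, function(s) s$records),
                                   fill = TRUE)
  patch_set(images, as.data.frame(records))
}

#' Write a manifest as JSON lines
#'
#' One record per line; field order and unknown columns are preserved.
#'
#' @param records data.frame of patch records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(records) > 0) {
    jsonlite::stream_out(records, con, na = "null", auto_unbox = TRUE,
                         digits = NA, verbose = FALSE)
  }
  invisible(path)
}

#' Read a JSON-lines manifest
#'
#' @param path manifest file.
#' @return data.frame; unknown fields are kept, absent optional fields are
#'   filled with `NA`.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_records())
  out <- tryCatch(
    jsonlite::stream_in(textConnection(lines), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(out)) {
    # slow path only to report which line is malformed
    for (i in seq_along(lines)) {
      tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
        stop(sprintf("read_manifest: malformed JSON on line %d: %s",
                     i, conditionMessage(e)))
      })
    }
    stop("read_manifest: malformed manifest")
  }
  if (!"prob" %in% names(out)) out$prob <- NA_real_
  out
}

#' Default pipeline configuration
#'
#' All tunables of the curation pipeline with their standard values:
#' 224-pixel patches with a 112-pixel minimum keepable remainder, the 20%
#' axial-spacing anisotropy bound, a 5 GB per-source byte budget, hash size
#' 8 with Hamming cutoff 12 for deduplication, filter confidence threshold
#' 0.5, and the probe parameters (top-32 feature maps, heatmap threshold
#' 0.3, occlusion window 61 / stride 30).
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    patch_size = 224L,
    min_keep = 112L,
    max_rel_spacing_dev = 0.2,
    max_source_bytes = 5e9,
    unify_polarity = FALSE,
    clip_percentiles = NULL,     # optional c(lo, hi) intensity clipping
    hash_size = 8L,
    hamming_cutoff = 12L,
    filter_threshold = 0.5,
    contrast_floor = 8,
    top_k_maps = 32L,
    heatmap_threshold = 0.3,
    occlusion_window = 61L,
    occlusion_stride = 30L,
    seed = 42L
  )
}

#' Load and validate a configuration file
#'
#' Reads YAML or JSON, overlays the values on [default_config()], and
#' rejects unknown keys and type mismatches.
#'
#' @param path configuration file (`.yaml`, `.yml`, or `.json`); `NULL`
#'   returns the defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) return(cfg)
  if (!is.list(user)) stop("load_config: configuration must be a mapping")
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop(sprintf("load_config: unknown key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    v <- user[[k]]
    ref <- cfg[[k]]
    if (!is.null(ref) && is.numeric(ref)) {
      if (!is.numeric(v)) {
        stop(sprintf("load_config: key '%s' must be numeric, got %s",
                     k, class(v)[1]))
      }
      if (is.integer(ref)) v <- as.integer(v)
    }
    if (!is.null(ref) && is.logical(ref) && !is.logical(v)) {
      stop(sprintf("load_config: key '%s' must be logical", k))
    }
    cfg[[k]] <- v
  }
  cfg
}
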