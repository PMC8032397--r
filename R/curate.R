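# End-to-end curation: standardize -> deduplicate -> filter, with a stage
# report mirroring the raw / dedup / filtered corpus narrative.

#' Curate a corpus end to end
#'
#' Runs the three pipeline stages in order on a set of sources (or an
#' already-standardized patch set): standardization into 224x224 8-bit
#' patches, within-source near-duplicate removal, and informativeness
#' filtering with a trained model. The corpus seed fans out to independent
#' per-stage seeds via [derive_seed()].
#'
#' @param input list of [source_image()] objects, a directory of readable
#'   image/volume files, or a [patch_set()] (skips standardization).
#' @param filter_model a [train_filter()] model; `NULL` skips the filter
#'   stage.
#' @param config pipeline configuration, see [default_config()].
#' @param seed corpus seed (defaults to `config$seed`).
#' @return list of class `curation_result`: `patches` (the final
#'   `patch_set`), `stages` (patch sets after each stage), `report`
#'   (per-stage counts and reduction fractions).
#' @export
curate <- function(input, filter_model = NULL, config = default_config(),
                   seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.character(input)) {
    if (!dir.exists(input)) stop(sprintf("curate: no such directory: %s", input))
    files <- list.files(input, full.names = TRUE,
                        pattern = "\\.(tiff?|png|jpe?g|mrc|nii(\\.gz)?)$",
                        ignore.case = TRUE)
    if (length(files) == 0L) stop("curate: no readable inputs found")
    input <- lapply(files, read_source)
  }
  if (inherits(input, "source_image")) input <- list(input)
  if (inherits(input, "patch_set")) {
    raw <- input
  } else {
    raw <- tryCatch(
      bind_patches(lapply(input, standardize_source, config = config)),
      error = function(e) stop(sprintf("curate: standardize stage failed: %s",
                                       conditionMessage(e))))
  }
  counts <- c(raw = length(raw))
  dd <- tryCatch(
    deduplicate_corpus(raw, cutoff = config$hamming_cutoff,
                       seed = derive_seed(seed, "dedup"),
                       hash_size = config$hash_size),
    error = function(e) stop(sprintf("curate: dedup stage failed: %s",
                                     conditionMessage(e))))
  counts <- c(counts, dedup = length(dd$kept))
  stages <- list(raw = raw, dedup = dd$kept)
  final <- dd$kept
  filter_report <- NULL
  if (!is.null(filter_model)) {
    fl <- tryCatch(
      filter_corpus(dd$kept, filter_model),
      error = function(e) stop(sprintf("curate: filter stage failed: %s",
                                       conditionMessage(e))))
    counts <- c(counts, filtered = length(fl$kept))
    stages$filtered <- fl$kept
    final <- fl$kept
    filter_report <- fl$report
  }
  reductions <- 1 - counts[-1] / pmax(counts[-length(counts)], 1L)
  structure(list(patches = final, stages = stages,
                 report = list(counts = counts, reductions = reductions,
                               dedup = dd$report, filter = filter_report,
                               seed = seed)),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat("<curation_result>\n")
  cnt <- x$report$counts
  for (i in seq_along(cnt)) {
    red <- if (i > 1) sprintf("  (-%.1f%%)", 100 * x$report$reductions[i - 1])
           else ""
    cat(sprintf("  %-9s %6d%s\n", names(cnt)[i], cnt[i], red))
  }
  invisible(x)
}
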