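# Readers for the supported on-disk formats (TIFF/PNG/JPEG images,
# multi-page TIFF / MRC / NIfTI volumes) and the per-patch TIFF writer.
# All readers return source_image objects with pixels on their native
# scale; normalization happens in the standardization stage.

# scale [0,1] image data from tiff/png readers back to its bit depth
rescale_read <- function(m, bits) {
  if (max(m) <= 1) round(m * (2^bits - 1)) else m
}

# collapse an RGB(A) array to grayscale
to_gray <- function(m) {
  if (length(dim(m)) == 3L) {
    ch <- min(dim(m)[3], 3L)
    m <- apply(m[, , seq_len(ch), drop = FALSE], c(1, 2), mean)
  }
  m
}

#' Read a 2D image or 3D volume from disk
#'
#' Dispatches on file extension: `.tif/.tiff` (single- or multi-page),
#' `.png`, `.jpg/.jpeg` (requires the EBImage package), `.mrc` (voxel
#' spacing taken from the `cella`/`mx,my,mz` header fields), `.nii/.nii.gz`
#' (spacing from `pixdim`). Multi-page TIFFs become volumes with the page
#' axis as z.
#'
#' @param path input file.
#' @param source_id identifier; defaults to the file name without
#'   extension.
#' @param inverted polarity flag to attach.
#' @return a [source_image()].
#' @export
read_source <- function(path, source_id = NULL, inverted = FALSE) {
  if (!file.exists(path)) stop(sprintf("read_source: no such file: %s", path))
  if (is.null(source_id)) {
    source_id <- sub("\\.(tiff?|png|jpe?g|mrc|nii(\\.gz)?)$", "",
                     basename(path), ignore.case = TRUE)
  }
  low <- tolower(path)
  if (grepl("\\.tiff?$", low)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) to_gray(rescale_read(p, 8L)))
    if (length(pages) == 1L) {
      return(source_image(pages[[1]], source_id, inverted = inverted))
    }
    vol <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (k in seq_along(pages)) vol[k, , ] <- pages[[k]]
    return(source_image(vol, source_id, inverted = inverted))
  }
  if (grepl("\\.png$", low)) {
    m <- to_gray(png::readPNG(path))
    return(source_image(rescale_read(m, 8L), source_id, inverted = inverted))
  }
  if (grepl("\\.jpe?g$", low)) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("read_source: JPEG input requires the EBImage package")
    }
    m <- EBImage::imageData(EBImage::readImage(path))
    m <- to_gray(if (length(dim(m)) == 3L) aperm(m, c(2, 1, 3)) else t(m))
    return(source_image(rescale_read(m, 8L), source_id, inverted = inverted))
  }
  if (grepl("\\.mrc$", low)) {
    return(read_mrc(path, source_id, inverted))
  }
  if (grepl("\\.nii(\\.gz)?$", low)) {
    nii <- RNifti::readNifti(path)
    dm <- dim(nii)
    if (length(dm) != 3L) stop("read_source: only 3D NIfTI volumes supported")
    # NIfTI axes are (x, y, z); reorder to (z, y, x)
    vol <- aperm(as.array(nii), c(3, 2, 1))
    pd <- RNifti::pixdim(nii)           # (x, y, z) spacing, mm
    spacing <- rev(pd[1:3]) * 1e6        # mm -> nm
    if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- NULL
    return(source_image(vol, source_id, spacing_nm = spacing,
                        inverted = inverted))
  }
  stop(sprintf("read_source: unsupported file type: %s", basename(path)))
}

# Minimal MRC2014 reader: 1024-byte header, little-endian; modes 0 (int8),
# 1 (int16), 2 (float32), 6 (uint16). Spacing in nm from cella (Angstrom)
# over mx/my/mz. No R package on CRAN/Bioconductor reads MRC, so the
# format is parsed directly.
read_mrc <- function(path, source_id, inverted = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  mxyz <- hdr[8:10]                      # mx, my, mz
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop(sprintf("read_mrc: unsupported mode %d", mode)))
  # MRC data order: x fastest, then y, then z -> array (x, y, z)
  vol <- aperm(array(data, c(nx, ny, nz)), c(3, 2, 1))
  spacing <- NULL
  if (all(mxyz > 0) && all(cella > 0)) {
    spacing <- rev(cella / mxyz) / 10    # Angstrom -> nm, (z, y, x)
  }
  src <- if (nz == 1L) {
    source_image(matrix(vol[1, , ], ny, nx), source_id, inverted = inverted)
  } else {
    source_image(vol, source_id, spacing_nm = spacing, inverted = inverted)
  }
  src
}

#' Write the patches of a set as TIFF files plus a JSON-lines manifest
#'
#' Files are named `<patch_id>.tiff` (ids already encode source, plane,
#' slice and offsets); the manifest gains a `path` column.
#'
#' @param ps a [patch_set()].
#' @param dir output directory (created if missing).
#' @param manifest manifest file name within `dir`.
#' @return the manifest path, invisibly.
#' @export
write_patches <- function(ps, dir, manifest = "manifest.jsonl") {
  stopifnot(inherits(ps, "patch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- ps$records
  records$path <- file.path(dir, paste0(records$patch_id, ".tiff"))
  for (i in seq_len(nrow(records))) {
    tiff::writeTIFF(ps$images[[records$patch_id[i]]] / 255,
                    records$path[i], bits.per.sample = 8L)
  }
  mf <- file.path(dir, manifest)
  write_manifest(records, mf)
  invisible(mf)
}

#' Load a patch set from a manifest written by [write_patches()]
#'
#' @param manifest manifest path.
#' @return a [patch_set()].
#' @export
read_patches <- function(manifest) {
  records <- read_manifest(manifest)
  if (nrow(records) == 0L) return(patch_set(list(), empty_records()))
  bad <- records$path[!file.exists(records$path)]
  if (length(bad)) {
    stop(sprintf("read_patches: missing patch file(s): %s",
                 paste(head(bad, 5), collapse = ", ")))
  }
  images <- lapply(records$path, function(p) {
    as_uint8(rescale_read(to_gray(tiff::readTIFF(p)), 8L))
  })
  names(images) <- records$patch_id
  records$path <- NULL
  if (!"prob" %in% names(records)) records$prob <- NA_real_
  patch_set(images, records)
}
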