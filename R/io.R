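# ---------------------------------------------------------------------------
# Raster and manifest I/O. Images are loaded as [0,1] grayscale matrices and
# bilinearly resized to the working geometry; label rasters are reduced to a
# binary task mask by selecting one integer "view ID" (the label of the
# organ of interest) and resized with nearest-neighbour sampling.
# ---------------------------------------------------------------------------

.to_gray <- function(x) {
  if (length(dim(x)) == 3L) x <- apply(x[, , seq_len(min(3L, dim(x)[3])), drop = FALSE], c(1, 2), mean)
  as.matrix(x)
}

.resize_mat <- function(x, size, nearest = FALSE) {
  if (all(dim(x) == size)) return(x)
  filt <- if (nearest) "none" else "bilinear"
  as.matrix(EBImage::resize(x, w = size, h = size, filter = filt))
}

#' Load an image or mask raster
#'
#' PNG/TIFF rasters or a single axial slice of a NIfTI volume. Images are
#' min-max normalized to `[0, 1]` and bilinearly resized; masks are binarized
#' as equality with `view_id` (the integer label of the structure of
#' interest) and resized with nearest-neighbour sampling.
#'
#' @param path PNG, TIFF or NIfTI (.nii/.nii.gz) file.
#' @param kind `"image"` or `"mask"`.
#' @param view_id integer label selecting the structure in a label raster
#'   (required for masks with multi-label input).
#' @param slice axial (last-axis) slice index, required for NIfTI volumes.
#' @param size working raster side length.
#' @return a `size` x `size` numeric matrix.
#' @export
load_raster <- function(path, kind = c("image", "mask"), view_id = NULL,
                        slice = NULL, size = 256L) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lower <- tolower(path)
  x <- if (grepl("\\.png$", lower)) {
    .to_gray(png::readPNG(path))
  } else if (grepl("\\.tiff?$", lower)) {
    .to_gray(tiff::readTIFF(path))
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    if (length(dim(vol)) == 3L) {
      if (is.null(slice)) stop("NIfTI volume requires a slice index: ", path)
      if (slice < 1L || slice > dim(vol)[3])
        stop("slice ", slice, " out of range for ", path)
      as.matrix(vol[, , slice])
    } else as.matrix(vol)
  } else stop("unsupported raster format: ", path)
  if (kind == "image") {
    x <- .resize_mat(x, size, nearest = FALSE)
    rng <- range(x)
    if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
    x
  } else {
    if (!is.null(view_id)) {
      x <- (abs(x - view_id) < 0.5) * 1
    } else {
      x <- (x > 0.5) * 1
    }
    m <- .resize_mat(x, size, nearest = TRUE)
    (m > 0.5) * 1
  }
}

#' Write a binary mask as 8-bit PNG
#'
#' Foreground is stored as 255, background as 0, so a write/read round trip
#' is bit-identical.
#'
#' @param mask binary matrix.
#' @param path destination PNG.
#' @export
save_mask <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Load / save a dataset manifest
#'
#' Manifests are JSON arrays of records (image, mask, task_id, view_id,
#' split).
#'
#' @param records data.frame with columns image, mask, task_id, view_id,
#'   split.
#' @param path JSON file.
#' @param check_paths verify referenced files exist on load.
#' @return data.frame of records.
#' @export
save_manifest <- function(records, path) {
  jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  rec <- jsonlite::fromJSON(path)
  need <- c("image", "mask", "task_id", "view_id", "split")
  if (!all(need %in% names(rec)))
    stop("manifest missing fields: ", paste(setdiff(need, names(rec)), collapse = ", "))
  if (any(!rec$split %in% c("train", "val", "test")))
    stop("manifest split must be train/val/test")
  if (any(rec$view_id < 1)) stop("view_id must be >= 1")
  if (check_paths) {
    missing <- c(rec$image[!file.exists(rec$image)], rec$mask[!file.exists(rec$mask)])
    if (length(missing) > 0)
      stop("manifest references missing files: ", paste(utils::head(missing, 3), collapse = ", "))
  }
  rec
}

#' Export attention maps with a JSON sidecar
#'
#' Writes each stage's dense attention matrix as CSV plus a sidecar
#' recording the geometry and flattening convention.
#'
#' @param stage_attention `stage_attention` list from [predict_episode()].
#' @param dir output directory (created if needed).
#' @export
export_attention_maps <- function(stage_attention, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stage_attention)) {
    a <- stage_attention[[nm]]
    utils::write.csv(as.data.frame(ag_val(a$A)),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    jsonlite::write_json(
      list(S = a$S, H = a$H, W = a$W, Hq = a$Hq, Wq = a$Wq,
           stride = as.integer(sub("stride", "", nm)),
           flattening = a$flattening),
      file.path(dir, paste0(nm, ".json")), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
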