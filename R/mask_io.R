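# Raster and result file I/O.
#
# Masks travel as single-channel 8-bit indexed PNG or TIFF; class semantics
# live only in the JSON class-map sidecar. Results are JSON with a stable
# key order; ROI overlays are GeoJSON in the pixel coordinate frame
# (0-based, x = column, y = row).

.read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3L] > 1L) stop("multi-channel raster: expected a single-channel indexed image")
      img <- img[, , 1L]
    }
    m <- round(img * 255)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3L] > 1L) stop("multi-channel raster: expected a single-channel indexed image")
      img <- img[, , 1L]
    }
    m <- img
  } else stop("unsupported raster extension '", ext, "' (use png/tif/tiff)")
  storage.mode(m) <- "integer"
  m
}

.write_raster <- function(codes, path) {
  ext <- tolower(tools::file_ext(path))
  img <- codes / 255
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else stop("unsupported raster extension '", ext, "' (use png/tif/tiff)")
  invisible(path)
}

#' Read a segmentation label mask
#'
#' @param path Single-channel 8-bit indexed PNG or TIFF of class codes.
#' @param classmap A \code{tsr_class_map} object or path to its JSON sidecar.
#' @param mpp Microns per pixel; if NULL, taken from the sidecar's
#'   \code{mpp} entry (an error if absent there too).
#' @param slide_id Slide identifier; defaults to the file stem.
#' @return A validated \code{label_mask}. Unknown codes raise an error.
#' @export
read_label_mask <- function(path, classmap, mpp = NULL, slide_id = NULL) {
  cm <- if (inherits(classmap, "tsr_class_map")) classmap else read_class_map(classmap)
  if (is.null(mpp)) mpp <- attr(cm, "mpp")
  if (is.null(mpp)) stop("mpp not supplied and absent from class map sidecar")
  if (is.null(slide_id))
    slide_id <- tools::file_path_sans_ext(basename(path))
  label_mask(.read_raster(path), mpp, cm, slide_id)
}

#' Write a label mask raster
#'
#' @param mask A \code{label_mask}.
#' @param path Output PNG/TIFF path.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  .write_raster(mask$codes, path)
}

#' Read a binary artifact mask (nonzero = artifact)
#'
#' @param path PNG/TIFF path.
#' @return An \code{artifact_mask}.
#' @export
read_artifact_mask <- function(path) {
  artifact_mask(.read_raster(path) != 0L)
}

#' Write an artifact mask raster (255 = artifact)
#'
#' @param artifacts An \code{artifact_mask}.
#' @param path Output PNG/TIFF path.
#' @export
write_artifact_mask <- function(artifacts, path) {
  stopifnot(inherits(artifacts, "artifact_mask"))
  .write_raster(matrix(ifelse(artifacts$flags, 255L, 0L),
                       nrow(artifacts$flags), ncol(artifacts$flags)), path)
}

# deterministic serialization of one ROI record (stable key order)
.roi_to_list <- function(r) {
  list(center = as.numeric(r$center),
       diameter_px = r$diameter_px,
       composition = as.list(r$composition),
       composition_pass = r$composition_pass,
       quadrant_pass = r$quadrant_pass,
       eligible = r$eligible,
       tsr = if (is.na(r$tsr)) NULL else r$tsr)
}

#' Write a slide-level result to JSON
#'
#' The file holds slide id, parameters used, assessability, hotspot TSR in
#' percent (null when not assessable), the stroma-high/low classification,
#' the chosen ROI, and the candidate/eligible ROI census. Key order is fixed
#' so that write/read/write round-trips are byte-identical.
#'
#' @param result A \code{slide_result} from \code{\link{quantify_slide}}.
#' @param path Output JSON path.
#' @param provenance Optional provenance block (see \code{\link{provenance_block}}).
#' @export
write_slide_result <- function(result, path, provenance = NULL) {
  stopifnot(inherits(result, "slide_result"))
  out <- list(
    slide_id = result$slide_id,
    params = list(
      diameter_um = result$params$diameter_um,
      overlap_fraction = result$params$overlap_fraction,
      max_background_fraction = result$params$max_background_fraction,
      max_necrosis_fraction = result$params$max_necrosis_fraction,
      max_mucin_fraction = result$params$max_mucin_fraction,
      min_tumor_pixels_per_quadrant = result$params$min_tumor_pixels_per_quadrant),
    cutoff_percent = result$cutoff_percent,
    assessable = result$assessable,
    tsr_percent = if (result$assessable) result$tsr_percent else NULL,
    class_label = if (result$assessable) result$class_label else NULL,
    chosen_roi = if (result$assessable) .roi_to_list(result$chosen_roi) else NULL,
    n_candidates = result$n_candidates,
    n_eligible = result$n_eligible)
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a slide result JSON back into a \code{slide_result}
#'
#' @param path JSON path written by \code{\link{write_slide_result}}.
#' @return A \code{slide_result}; any provenance block is kept in
#'   \code{$provenance}.
#' @export
read_slide_result <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  chosen <- NULL
  if (!is.null(j$chosen_roi)) {
    cr <- j$chosen_roi
    chosen <- list(center = as.numeric(cr$center),
                   diameter_px = as.integer(cr$diameter_px),
                   composition = unlist(cr$composition),
                   composition_pass = cr$composition_pass,
                   quadrant_pass = cr$quadrant_pass,
                   eligible = cr$eligible,
                   tsr = if (is.null(cr$tsr)) NA_real_ else cr$tsr)
  }
  structure(list(
    slide_id = j$slide_id,
    params = do.call(roi_params, j$params),
    cutoff_percent = j$cutoff_percent,
    assessable = j$assessable,
    tsr_percent = if (isTRUE(j$assessable)) j$tsr_percent else NA_real_,
    class_label = if (isTRUE(j$assessable)) j$class_label else NA_character_,
    chosen_roi = chosen,
    n_candidates = as.integer(j$n_candidates),
    n_eligible = as.integer(j$n_eligible),
    provenance = j$provenance),
    class = "slide_result")
}

#' Export eligible ROIs as a GeoJSON overlay
#'
#' Writes a FeatureCollection with one polygonal (discretized circle)
#' feature per eligible ROI, properties \code{tsr_percent} and
#' \code{chosen}. Coordinates are in the pixel frame: 0-based, x = column,
#' y = row.
#'
#' @param result A \code{slide_result}.
#' @param rois List of ROI records from \code{\link{quantify_slide}}.
#' @param path Output GeoJSON path.
#' @param n_vertices Vertices per circle polygon.
#' @export
export_roi_overlay <- function(result, rois, path, n_vertices = 64L) {
  stopifnot(inherits(result, "slide_result"))
  elig <- Filter(function(r) isTRUE(r$eligible), rois)
  chosen_center <- if (result$assessable) result$chosen_roi$center else c(NA, NA)
  feats <- lapply(elig, function(r) {
    rad <- r$diameter_px / 2
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)
    ring <- cbind(r$center[1L] + rad * cos(th), r$center[2L] + rad * sin(th))
    ring[n_vertices + 1L, ] <- ring[1L, ]  # close the ring exactly
    is_chosen <- isTRUE(all(r$center == chosen_center))
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = list(tsr_percent = 100 * r$tsr, chosen = is_chosen))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a batch TSV (one row per slide)
#'
#' @param rows data.frame with columns id, tsr_percent, class_label,
#'   n_eligible, assessable (and optionally error).
#' @param path Output TSV path.
#' @export
write_batch_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
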