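# Label-mask container: a 2-D grid of tissue class codes with physical
# resolution. Rows index y (0-based in all user-facing coordinates),
# columns index x; pixel centers sit at integer coordinates.

#' Construct a label mask
#'
#' @param codes Integer matrix of class codes, rows = y, cols = x.
#' @param mpp Microns per pixel (finite, > 0).
#' @param class_map A \code{tsr_class_map}; every code in \code{codes} must
#'   be present in it.
#' @param slide_id Slide identifier string.
#'
#' @return An object of class \code{label_mask} with fields \code{codes},
#'   \code{mpp}, \code{class_map}, \code{slide_id}.
#' @export
label_mask <- function(codes, mpp, class_map = default_class_map(),
                       slide_id = "slide") {
  if (!is.matrix(codes)) stop("codes must be a matrix")
  storage.mode(codes) <- "integer"
  if (nrow(codes) < 1L || ncol(codes) < 1L) stop("mask dimensions must be >= 1")
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("mpp must be finite and positive")
  stopifnot(inherits(class_map, "tsr_class_map"))
  present <- unique(as.vector(codes))
  if (any(present < 0L | present > 255L))
    stop("unknown class code: codes must lie in [0, 255]")
  known <- as.integer(names(class_map$codes))
  bad <- setdiff(present, known)
  if (length(bad))
    stop("unknown class code ", paste(bad, collapse = ", "),
         " not present in class map")
  structure(list(codes = codes, mpp = mpp, class_map = class_map,
                 slide_id = as.character(slide_id)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask '%s': %d x %d px, mpp %.3g>\n",
              x$slide_id, nrow(x$codes), ncol(x$codes), x$mpp))
  invisible(x)
}

#' Construct an artifact mask
#'
#' @param flags Logical matrix, TRUE = artifact pixel. Shape must match the
#'   paired label mask.
#' @return An object of class \code{artifact_mask}.
#' @export
artifact_mask <- function(flags) {
  if (!is.matrix(flags)) stop("artifact flags must be a matrix")
  if (!is.logical(flags)) {
    flags <- matrix(as.logical(flags != 0), nrow(flags), ncol(flags))
  }
  structure(list(flags = flags), class = "artifact_mask")
}

#' Relabel artifact pixels to the excluded class
#'
#' Pixels flagged in the artifact mask are rewritten to the class map's
#' designated excluded code; all other pixels are untouched. The operation
#' is idempotent and conserves total pixel count.
#'
#' @param mask A \code{label_mask}.
#' @param artifacts An \code{artifact_mask} of identical shape (or NULL for
#'   a no-op).
#' @return A \code{label_mask} with artifact pixels excluded.
#' @export
apply_artifact_exclusion <- function(mask, artifacts) {
  stopifnot(inherits(mask, "label_mask"))
  if (is.null(artifacts)) return(mask)
  stopifnot(inherits(artifacts, "artifact_mask"))
  if (!identical(dim(mask$codes), dim(artifacts$flags)))
    stop("artifact mask shape does not match label mask")
  codes <- mask$codes
  codes[artifacts$flags] <- mask$class_map$roles[["excluded"]]
  label_mask(codes, mask$mpp, mask$class_map, mask$slide_id)
}
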