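# Tissue class vocabulary and role assignment.
#
# A class map ties the integer codes found in a segmentation raster to
# tissue class names, and designates which code plays each of the roles the
# TSR engine cares about: background, tumor_epithelium, tumor_stroma,
# necrosis, mucin and excluded (artifact). Codes without a designated role
# are treated as "other" tumor-associated tissue.

.tsr_roles <- c("background", "tumor_epithelium", "tumor_stroma",
                "necrosis", "mucin", "excluded", "other")

#' Construct a tissue class map
#'
#' @param codes Named character vector: names are integer class codes (as
#'   strings), values are class names. Codes must be unique integers in
#'   \code{[0, 255]} (8-bit indexed raster).
#' @param roles Named integer vector assigning exactly one code to each of
#'   the designated roles \code{background}, \code{tumor_epithelium},
#'   \code{tumor_stroma}, \code{necrosis}, \code{mucin}, \code{excluded}.
#'   Every role code must be present in \code{codes}.
#'
#' @return An object of class \code{tsr_class_map}.
#' @export
#' @examples
#' cm <- default_class_map()
#' cm$roles[["tumor_stroma"]]
class_map <- function(codes, roles) {
  code_int <- suppressWarnings(as.integer(names(codes)))
  if (anyNA(code_int)) stop("class map codes must be integers")
  if (anyDuplicated(code_int)) stop("class map codes must be unique")
  if (any(code_int < 0L | code_int > 255L))
    stop("class codes must lie in [0, 255] (8-bit indexed raster)")
  need <- setdiff(.tsr_roles, "other")
  if (!all(need %in% names(roles)))
    stop("roles must assign a code to each of: ", paste(need, collapse = ", "))
  roles <- as.integer(roles[need])
  names(roles) <- need
  if (anyDuplicated(roles)) stop("each designated role needs a distinct code")
  if (!all(roles %in% code_int)) stop("every role code must appear in the code map")
  structure(
    list(codes = stats::setNames(as.character(codes), as.character(code_int)),
         roles = roles),
    class = "tsr_class_map")
}

#' Default 8-bit class map
#'
#' Codes 0-10 cover background plus the ten tumor-associated tissue classes
#' of the colorectal segmentation vocabulary (tumor epithelium, tumor stroma,
#' necrosis, mucin, smooth muscle, mucosa, submucosa, adventitial tissue,
#' dense lymphocytic infiltrates, bleeding areas); code 255 marks pixels
#' excluded by the artifact mask. The map is user-extensible: additional
#' codes are treated as "other" tissue.
#'
#' @return A \code{tsr_class_map}.
#' @export
default_class_map <- function() {
  class_map(
    codes = c("0" = "background", "1" = "tumor_epithelium",
              "2" = "tumor_stroma", "3" = "necrosis", "4" = "mucin",
              "5" = "smooth_muscle", "6" = "mucosa", "7" = "submucosa",
              "8" = "adventitial", "9" = "lymphocytic", "10" = "bleeding",
              "255" = "excluded"),
    roles = c(background = 0L, tumor_epithelium = 1L, tumor_stroma = 2L,
              necrosis = 3L, mucin = 4L, excluded = 255L))
}

# role index (1..7, 7 = other) for each code 0..255; vectorized lookup table
.role_lookup <- function(cm) {
  lut <- rep.int(7L, 256L)
  known <- as.integer(names(cm$codes))
  for (i in seq_along(.tsr_roles[-7L])) {
    lut[cm$roles[[.tsr_roles[i]]] + 1L] <- i
  }
  # codes present in the map but without a role stay "other"
  lut
}

#' Read a class map from a JSON sidecar
#'
#' The sidecar holds \code{codes} (code string to class name), \code{roles}
#' (role name to code) and optionally \code{mpp} (microns per pixel of the
#' paired raster).
#'
#' @param path Path to the JSON file.
#' @return A \code{tsr_class_map}; if the sidecar carries \code{mpp} it is
#'   attached as attribute \code{"mpp"}.
#' @export
read_class_map <- function(path) {
  if (!file.exists(path)) stop("class map file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$codes) || is.null(j$roles))
    stop("class map JSON needs 'codes' and 'roles' entries")
  cm <- class_map(unlist(j$codes), unlist(j$roles))
  if (!is.null(j$mpp)) attr(cm, "mpp") <- as.numeric(j$mpp)
  cm
}

#' Write a class map (plus optional mpp) to JSON
#'
#' @param cm A \code{tsr_class_map}.
#' @param path Output path.
#' @param mpp Optional microns-per-pixel value to embed.
#' @export
write_class_map <- function(cm, path, mpp = NULL) {
  stopifnot(inherits(cm, "tsr_class_map"))
  out <- list(codes = as.list(cm$codes), roles = as.list(cm$roles))
  if (!is.null(mpp)) out$mpp <- mpp
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
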