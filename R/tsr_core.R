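# The TSR quantification engine.
#
# The whole tumor region is processed systematically with a circular
# sliding-window ROI (default 1 mm diameter, 70% overlap). Each candidate
# ROI is subjected to two eligibility tests: (i) composition thresholds on
# background, necrotic debris and mucin content, and (ii) a four-quadrant
# test requiring tumor epithelium in every quadrant. TSR is computed per
# eligible ROI as stroma / (stroma + tumor); the slide-level value is the
# hotspot: the maximum TSR over eligible ROIs.
#
# Geometry conventions: pixel centers at integer 0-based coordinates,
# x = column, y = row; disc membership is strict Euclidean distance
# < diameter_px / 2 from the ROI center.

#' ROI engine parameters
#'
#' @param diameter_um ROI diameter in microns (default 1000 = 1 mm).
#' @param overlap_fraction Sliding-window overlap in \code{[0, 1)}
#'   (default 0.70; stride = (1 - overlap) x diameter).
#' @param max_background_fraction ROI ineligible unless background (plus
#'   excluded/artifact) fraction is strictly below this (default 0.10).
#' @param max_necrosis_fraction Strict upper bound on necrotic debris
#'   fraction (default 0.20).
#' @param max_mucin_fraction Strict upper bound on mucin fraction
#'   (default 0.30).
#' @param min_tumor_pixels_per_quadrant Minimum tumor-epithelium pixels
#'   required in each of the four ROI quadrants (default 1).
#' @return A validated \code{roi_params} object.
#' @export
roi_params <- function(diameter_um = 1000,
                       overlap_fraction = 0.70,
                       max_background_fraction = 0.10,
                       max_necrosis_fraction = 0.20,
                       max_mucin_fraction = 0.30,
                       min_tumor_pixels_per_quadrant = 1L) {
  stopifnot(diameter_um > 0,
            overlap_fraction >= 0, overlap_fraction < 1,
            max_background_fraction > 0, max_background_fraction <= 1,
            max_necrosis_fraction > 0, max_necrosis_fraction <= 1,
            max_mucin_fraction > 0, max_mucin_fraction <= 1,
            min_tumor_pixels_per_quadrant >= 1)
  structure(list(diameter_um = diameter_um,
                 overlap_fraction = overlap_fraction,
                 max_background_fraction = max_background_fraction,
                 max_necrosis_fraction = max_necrosis_fraction,
                 max_mucin_fraction = max_mucin_fraction,
                 min_tumor_pixels_per_quadrant = as.integer(min_tumor_pixels_per_quadrant)),
            class = "roi_params")
}

# physical-to-pixel conversion: nearest integer, floor at 1
.diameter_px <- function(params, mpp) max(1L, as.integer(round(params$diameter_um / mpp)))

# max integer offset of a member pixel from the center (strict < d/2)
.max_offset <- function(diameter_px) as.integer(ceiling(diameter_px / 2) - 1L)

# square-window geometry for a given diameter: logical disc membership plus
# signed offsets, reused across all ROIs of a slide
.disc_geometry <- function(diameter_px) {
  R <- .max_offset(diameter_px)
  off <- seq.int(-R, R)
  dx <- matrix(off, 2L * R + 1L, 2L * R + 1L, byrow = TRUE)  # columns = x
  dy <- matrix(off, 2L * R + 1L, 2L * R + 1L)                # rows = y
  inside <- (dx * dx + dy * dy) < (diameter_px / 2)^2
  list(R = R, dx = dx, dy = dy, inside = inside, area = sum(inside))
}

#' Tumor analysis region
#'
#' Axis-aligned bounding box of all tumor-epithelium pixels, dilated by one
#' ROI radius on each side and clipped to the mask extent. Coordinates are
#' 0-based pixel positions (x = column, y = row).
#'
#' @param mask A \code{label_mask}.
#' @param params \code{roi_params}.
#' @return A list \code{(xmin, xmax, ymin, ymax, empty)}; \code{empty=TRUE}
#'   when the mask holds no tumor epithelium.
#' @export
tumor_analysis_region <- function(mask, params = roi_params()) {
  stopifnot(inherits(mask, "label_mask"))
  tum <- mask$class_map$roles[["tumor_epithelium"]]
  idx <- which(mask$codes == tum, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(list(xmin = NA_real_, xmax = NA_real_, ymin = NA_real_,
                ymax = NA_real_, empty = TRUE))
  d <- .diameter_px(params, mask$mpp)
  r <- floor(d / 2)
  H <- nrow(mask$codes); W <- ncol(mask$codes)
  list(xmin = max(0L, min(idx[, 2L]) - 1L - r),
       xmax = min(W - 1L, max(idx[, 2L]) - 1L + r),
       ymin = max(0L, min(idx[, 1L]) - 1L - r),
       ymax = min(H - 1L, max(idx[, 1L]) - 1L + r),
       empty = FALSE)
}

#' Sliding-window grid of candidate ROI centers
#'
#' Centers lie on a regular grid with stride
#' \code{round((1 - overlap) x diameter)} pixels (minimum 1), starting at
#' the smallest admissible position at or beyond region start + radius,
#' restricted to centers whose full disc lies inside the mask extent, in
#' deterministic row-major order (y outer, x inner).
#'
#' @param region Output of \code{\link{tumor_analysis_region}}.
#' @param params \code{roi_params}.
#' @param mask_extent \code{c(height, width)} in pixels.
#' @param mpp Microns per pixel (converts \code{diameter_um} to pixels).
#' @return Two-column matrix of centers (x, y); zero rows when no center is
#'   admissible.
#' @export
roi_grid <- function(region, params, mask_extent, mpp = 1.0) {
  if (isTRUE(region$empty)) return(cbind(x = numeric(0), y = numeric(0)))
  d <- max(1L, as.integer(round(params$diameter_um / mpp)))
  r <- d / 2
  R <- .max_offset(d)
  stride <- max(1L, as.integer(round((1 - params$overlap_fraction) * d)))
  H <- mask_extent[1L]; W <- mask_extent[2L]
  axis_centers <- function(lo, hi, n) {
    # lo/hi: region bounds on this axis; n: extent size
    c0 <- max(R, as.integer(ceiling(lo + r)))
    if (c0 + R > n - 1L) return(integer(0))
    cc <- seq.int(c0, n - 1L - R, by = stride)
    cc[cc - r < hi]   # disc must still reach into the region
  }
  xs <- axis_centers(region$xmin, region$xmax, W)
  ys <- axis_centers(region$ymin, region$ymax, H)
  if (!length(xs) || !length(ys)) return(cbind(x = numeric(0), y = numeric(0)))
  cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
}

# counts of pixels per role inside the disc at `center`; also quadrant
# tumor counts. Internal workhorse shared by the exported per-ROI ops.
.roi_counts <- function(codes, center, geom, role_lut, tumor_code) {
  cx <- center[1L]; cy <- center[2L]; R <- geom$R
  H <- nrow(codes); W <- ncol(codes)
  if (cx - R < 0L || cy - R < 0L || cx + R > W - 1L || cy + R > H - 1L)
    stop("ROI disc out of mask bounds")
  sub <- codes[(cy - R + 1L):(cy + R + 1L), (cx - R + 1L):(cx + R + 1L), drop = FALSE]
  disc_codes <- sub[geom$inside]
  counts <- tabulate(role_lut[disc_codes + 1L], nbins = 7L)
  tum <- (sub == tumor_code) & geom$inside
  # quadrants split by the lines x = cx, y = cy; pixels on a line go to the
  # right/lower quadrant (dx >= 0 / dy >= 0)
  qx <- geom$dx >= 0L; qy <- geom$dy >= 0L
  quad <- c(sum(tum & !qx & !qy), sum(tum & qx & !qy),
            sum(tum & !qx & qy), sum(tum & qx & qy))
  list(counts = counts, quad_tumor = quad, area = geom$area)
}

#' Composition of one ROI disc
#'
#' Fraction of disc pixels per class role (background, tumor_epithelium,
#' tumor_stroma, necrosis, mucin, excluded, other); fractions sum to 1.
#'
#' @param mask A \code{label_mask}.
#' @param center \code{c(x, y)} pixel center (0-based).
#' @param diameter_px Disc diameter in pixels.
#' @return Named numeric vector of fractions.
#' @export
roi_composition <- function(mask, center, diameter_px) {
  stopifnot(inherits(mask, "label_mask"))
  geom <- .disc_geometry(diameter_px)
  lut <- .role_lookup(mask$class_map)
  rc <- .roi_counts(mask$codes, center, geom, lut,
                    mask$class_map$roles[["tumor_epithelium"]])
  stats::setNames(rc$counts / rc$area, .tsr_roles)
}

#' Composition eligibility test
#'
#' TRUE iff effective background (background + excluded/artifact), necrosis
#' and mucin fractions are each strictly below their thresholds.
#'
#' @param comp Composition vector from \code{\link{roi_composition}}.
#' @param params \code{roi_params}.
#' @return Logical scalar.
#' @export
composition_eligibility <- function(comp, params = roi_params()) {
  bg_eff <- comp[["background"]] + comp[["excluded"]]
  (bg_eff < params$max_background_fraction) &&
    (comp[["necrosis"]] < params$max_necrosis_fraction) &&
    (comp[["mucin"]] < params$max_mucin_fraction)
}

#' Four-quadrant tumor presence test
#'
#' The disc is partitioned by the vertical and horizontal lines through its
#' center (pixels exactly on a line go to the right/lower quadrant); TRUE
#' iff every quadrant holds at least
#' \code{min_tumor_pixels_per_quadrant} tumor-epithelium pixels.
#'
#' @inheritParams roi_composition
#' @param params \code{roi_params}.
#' @return Logical scalar.
#' @export
quadrant_test <- function(mask, center, diameter_px, params = roi_params()) {
  stopifnot(inherits(mask, "label_mask"))
  geom <- .disc_geometry(diameter_px)
  lut <- .role_lookup(mask$class_map)
  rc <- .roi_counts(mask$codes, center, geom, lut,
                    mask$class_map$roles[["tumor_epithelium"]])
  all(rc$quad_tumor >= params$min_tumor_pixels_per_quadrant)
}

#' Tumor-stroma ratio of a composition
#'
#' TSR = stroma / (stroma + tumor); all other tissue classes are excluded
#' from the formula.
#'
#' @param comp Composition vector (fractions or raw pixel counts).
#' @return TSR fraction in \code{[0, 1]}.
#' @export
compute_tsr <- function(comp) {
  s <- comp[["tumor_stroma"]]; t <- comp[["tumor_epithelium"]]
  if (s + t <= 0) stop("undefined TSR: no stroma or tumor pixels in ROI")
  s / (s + t)
}

#' Classify a TSR percentage as stroma-high or stroma-low
#'
#' Stroma-high iff strictly above the cut-off (the default 77 mirrors the
#' automated cut-off; the visual convention uses 50 with the same strict
#' rule, so a value exactly at the cut-off is stroma-low).
#'
#' @param tsr_percent TSR in percent, in \code{[0, 100]}.
#' @param cutoff_percent Cut-off in percent (default 77).
#' @return \code{"stroma_high"} or \code{"stroma_low"}.
#' @export
classify_tsr <- function(tsr_percent, cutoff_percent = 77) {
  if (any(!is.finite(tsr_percent)) || any(tsr_percent < 0) || any(tsr_percent > 100))
    stop("tsr_percent must lie in [0, 100]")
  ifelse(tsr_percent > cutoff_percent, "stroma_high", "stroma_low")
}

#' Quantify one slide: sliding-window hotspot TSR
#'
#' Full pipeline: artifact exclusion, tumor analysis region, sliding-window
#' grid, per-ROI composition/eligibility/TSR, hotspot selection (maximum
#' TSR over eligible ROIs; ties resolved to the first ROI in row-major scan
#' order). A slide with no eligible ROI is reported as not assessable.
#'
#' @param mask A \code{label_mask}.
#' @param artifacts Optional \code{artifact_mask}.
#' @param params \code{roi_params}.
#' @param cutoff_percent Cut-off for the stroma-high/low label (default 77).
#' @return A list with \code{result} (a \code{slide_result}) and
#'   \code{rois} (list of per-candidate ROI records with fields center,
#'   diameter_px, composition, composition_pass, quadrant_pass, eligible,
#'   tsr).
#' @export
quantify_slide <- function(mask, artifacts = NULL, params = roi_params(),
                           cutoff_percent = 77) {
  stopifnot(inherits(mask, "label_mask"), inherits(params, "roi_params"))
  mask <- apply_artifact_exclusion(mask, artifacts)
  d <- .diameter_px(params, mask$mpp)
  region <- tumor_analysis_region(mask, params)
  centers <- roi_grid(region, params, dim(mask$codes), mask$mpp)
  geom <- .disc_geometry(d)
  lut <- .role_lookup(mask$class_map)
  tumor_code <- mask$class_map$roles[["tumor_epithelium"]]
  min_q <- params$min_tumor_pixels_per_quadrant
  rois <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    rc <- .roi_counts(mask$codes, ctr, geom, lut, tumor_code)
    comp <- stats::setNames(rc$counts / rc$area, .tsr_roles)
    cpass <- composition_eligibility(comp, params)
    qpass <- all(rc$quad_tumor >= min_q)
    eligible <- cpass && qpass
    tsr <- if (eligible) compute_tsr(comp) else NA_real_
    rois[[i]] <- list(center = as.numeric(ctr), diameter_px = d,
                      composition = comp, composition_pass = cpass,
                      quadrant_pass = qpass, eligible = eligible, tsr = tsr)
  }
  elig_idx <- which(vapply(rois, function(r) r$eligible, logical(1)))
  assessable <- length(elig_idx) >= 1L
  if (assessable) {
    tsrs <- vapply(rois[elig_idx], function(r) r$tsr, numeric(1))
    best <- elig_idx[which.max(tsrs)]  # first maximum in row-major order
    tsr_percent <- 100 * rois[[best]]$tsr
    chosen <- rois[[best]]
    label <- classify_tsr(tsr_percent, cutoff_percent)
  } else {
    tsr_percent <- NA_real_; chosen <- NULL; label <- NA_character_
  }
  result <- structure(list(
    slide_id = mask$slide_id,
    params = params,
    cutoff_percent = cutoff_percent,
    assessable = assessable,
    tsr_percent = tsr_percent,
    class_label = label,
    chosen_roi = chosen,
    n_candidates = nrow(centers),
    n_eligible = length(elig_idx)),
    class = "slide_result")
  list(result = result, rois = rois)
}

#' @export
print.slide_result <- function(x, ...) {
  if (x$assessable) {
    cat(sprintf("<slide_result '%s': TSR %.1f%% (%s), %d/%d ROIs eligible>\n",
                x$slide_id, x$tsr_percent, x$class_label,
                x$n_eligible, x$n_candidates))
  } else {
    cat(sprintf("<slide_result '%s': not assessable (%d candidates, 0 eligible)>\n",
                x$slide_id, x$n_candidates))
  }
  invisible(x)
}
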