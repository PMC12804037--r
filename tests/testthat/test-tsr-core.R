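cm <- default_class_map()

test_that("stride and grid follow the sliding-window geometry", {
  p <- roi_params(diameter_um = 1000, overlap_fraction = 0.70)
  # (1 - 0.7) x 1000 = 300 px stride on a full-extent region
  reg <- list(xmin = 0, xmax = 1599, ymin = 0, ymax = 999, empty = FALSE)
  g <- roi_grid(reg, p, c(1000, 1600), mpp = 1)
  expect_equal(unname(g[, "x"]), c(500, 800, 1100))
  expect_equal(unname(g[, "y"]), c(500, 500, 500))
  # overlap 0: stride equals diameter (plain tiling)
  p0 <- roi_params(diameter_um = 100, overlap_fraction = 0)
  reg2 <- list(xmin = 0, xmax = 299, ymin = 0, ymax = 299, empty = FALSE)
  g0 <- roi_grid(reg2, p0, c(300, 300), mpp = 1)
  expect_equal(sort(unique(unname(g0[, "x"]))), c(50, 150, 250))
  # empty region yields no centers
  expect_equal(nrow(roi_grid(list(empty = TRUE), p, c(100, 100))), 0)
})

test_that("tumor analysis region is the dilated clipped bounding box", {
  codes <- matrix(0L, 2000, 2000)
  codes[51, 51] <- 1L   # tumor pixel at (x=50, y=50)
  m <- label_mask(codes, 1, cm)
  r <- tumor_analysis_region(m, roi_params(diameter_um = 1000))
  expect_equal(unlist(r[c("xmin", "xmax", "ymin", "ymax")]),
               c(xmin = 0, xmax = 550, ymin = 0, ymax = 550))
  # no tumor: empty region
  expect_true(tumor_analysis_region(uniform_mask(0L), roi_params())$empty)
  # tumor everywhere: region equals the mask extent
  full <- tumor_analysis_region(uniform_mask(1L, size = 64),
                                roi_params(diameter_um = 32))
  expect_equal(unlist(full[c("xmin", "xmax", "ymin", "ymax")]),
               c(xmin = 0, xmax = 63, ymin = 0, ymax = 63))
})

test_that("roi composition counts disc pixels per role and sums to one", {
  m <- uniform_mask(2L, size = 101)
  comp <- roi_composition(m, c(50, 50), 80)
  expect_equal(comp[["tumor_stroma"]], 1.0)
  expect_equal(sum(comp), 1.0)
  # half-plane split through the center: both fractions 0.5 up to discretization
  codes <- matrix(2L, 101, 101); codes[, 52:101] <- 1L
  m2 <- label_mask(codes, 1, cm)
  comp2 <- roi_composition(m2, c(50, 50), 80)
  A <- sum(comp2) # = 1; disc area via geometry
  area <- sum(tsrquant:::.disc_geometry(80)$inside)
  expect_lt(abs(comp2[["tumor_stroma"]] - 0.5), 2 / sqrt(area))
  expect_lt(abs(comp2[["tumor_epithelium"]] - 0.5), 2 / sqrt(area))
  expect_equal(sum(comp2), 1.0)
  # out-of-bounds disc errors
  expect_error(roi_composition(m, c(2, 2), 80), "bounds")
})

test_that("composition eligibility applies strict thresholds", {
  p <- roi_params()
  base <- c(background = 0, tumor_epithelium = 0.5, tumor_stroma = 0.5,
            necrosis = 0, mucin = 0, excluded = 0, other = 0)
  ok <- base; ok["background"] <- 0.05; ok["necrosis"] <- 0.10
  ok["mucin"] <- 0.10; ok["tumor_stroma"] <- 0.75 - sum(ok[c("background","necrosis","mucin")])
  expect_true(composition_eligibility(ok, p))
  at10 <- base; at10["background"] <- 0.10; at10["tumor_stroma"] <- 0.40
  expect_false(composition_eligibility(at10, p))
  muc <- base; muc["mucin"] <- 0.35; muc["tumor_stroma"] <- 0.15
  expect_false(composition_eligibility(muc, p))
  # excluded pixels count toward effective background
  art <- base; art["excluded"] <- 0.12; art["tumor_stroma"] <- 0.38
  expect_false(composition_eligibility(art, p))
})

test_that("four-quadrant test requires tumor epithelium in every quadrant", {
  m <- uniform_mask(1L, size = 101)
  expect_true(quadrant_test(m, c(50, 50), 80))
  # tumor confined to the upper half fails
  codes <- matrix(2L, 101, 101); codes[1:50, ] <- 1L
  m2 <- label_mask(codes, 1, cm)
  expect_false(quadrant_test(m2, c(50, 50), 80))
  # exactly one tumor pixel per quadrant passes at min = 1
  codes3 <- matrix(2L, 101, 101)
  for (xy in list(c(40, 40), c(60, 40), c(40, 60), c(60, 60)))
    codes3[xy[2] + 1, xy[1] + 1] <- 1L
  m3 <- label_mask(codes3, 1, cm)
  expect_true(quadrant_test(m3, c(50, 50), 80, roi_params()))
  expect_false(quadrant_test(m3, c(50, 50), 80,
                             roi_params(min_tumor_pixels_per_quadrant = 2)))
})

test_that("TSR formula uses stroma and tumor only", {
  comp <- c(background = 0, tumor_epithelium = 250, tumor_stroma = 750,
            necrosis = 100, mucin = 0, excluded = 0, other = 0)
  expect_equal(compute_tsr(comp), 0.75)
  expect_equal(compute_tsr(c(tumor_stroma = 0, tumor_epithelium = 100)), 0)
  expect_equal(compute_tsr(c(tumor_stroma = 77, tumor_epithelium = 23)), 0.77)
  expect_error(compute_tsr(c(tumor_stroma = 0, tumor_epithelium = 0)),
               "undefined")
})

test_that("classification is strictly greater-than the cut-off", {
  expect_equal(classify_tsr(77.0, 77), "stroma_low")
  expect_equal(classify_tsr(77.01, 77), "stroma_high")
  expect_equal(classify_tsr(40, 50), "stroma_low")
  expect_equal(classify_tsr(51, 50), "stroma_high")
  expect_error(classify_tsr(101), "\\[0, 100\\]")
})

test_that("engine equals the naive reference on random masks", {
  p <- roi_params(diameter_um = 32)
  for (seed in 1:3) {
    m <- random_mask(seed, size = 128)
    q <- quantify_slide(m, NULL, p)
    ref <- ref_quantify(m, p)
    eng_elig <- vapply(q$rois, function(r) r$eligible, logical(1))
    expect_identical(eng_elig, ref$eligible)
    expect_equal(vapply(q$rois, function(r) r$tsr, numeric(1)), ref$tsr,
                 tolerance = 1e-12)
    expect_equal(q$result$tsr_percent, ref$tsr_percent, tolerance = 1e-12)
  }
})

test_that("hotspot tie-break picks the first maximal ROI in scan order", {
  # two identical pure-stroma+tumor zones -> equal TSR; first wins
  codes <- matrix(1L, 200, 200)
  m <- label_mask(codes, 1, cm)
  p <- roi_params(diameter_um = 60, overlap_fraction = 0)
  q <- quantify_slide(m, NULL, p)
  tsrs <- vapply(q$rois, function(r) r$tsr, numeric(1))
  first_max <- which(tsrs == max(tsrs, na.rm = TRUE))[1]
  expect_equal(q$result$chosen_roi$center, q$rois[[first_max]]$center)
})

test_that("outputs are invariant under consistent class-code permutation", {
  m <- random_mask(42, size = 128)
  p <- roi_params(diameter_um = 32)
  q1 <- quantify_slide(m, NULL, p)
  # permute codes: add 100 to codes 0..10, keep 255
  old <- as.integer(names(cm$codes))
  perm <- ifelse(old == 255L, 255L, old + 100L)
  cm2 <- class_map(stats::setNames(unname(cm$codes), perm),
                   stats::setNames(ifelse(cm$roles == 255L, 255L, cm$roles + 100L),
                                   names(cm$roles)))
  codes2 <- m$codes + 100L; codes2[m$codes == 255L] <- 255L
  m2 <- label_mask(codes2, m$mpp, cm2, m$slide_id)
  q2 <- quantify_slide(m2, NULL, p)
  expect_equal(q2$result$tsr_percent, q1$result$tsr_percent)
  expect_equal(q2$result$n_eligible, q1$result$n_eligible)
  expect_equal(vapply(q2$rois, function(r) r$tsr, numeric(1)),
               vapply(q1$rois, function(r) r$tsr, numeric(1)))
})

test_that("hotspot TSR is translation-equivariant by one stride", {
  p <- roi_params(diameter_um = 40, overlap_fraction = 0.70)
  stride <- max(1, round(0.3 * 40))
  set.seed(9)
  block <- matrix(sample(c(1L, 2L), 60 * 60, TRUE), 60, 60)
  big <- matrix(0L, 200, 200)
  m1 <- m2 <- big
  m1[41:100, 41:100] <- block
  m2[(41 + stride):(100 + stride), (41 + stride):(100 + stride)] <- block
  q1 <- quantify_slide(label_mask(m1, 1, cm), NULL, p)
  q2 <- quantify_slide(label_mask(m2, 1, cm), NULL, p)
  expect_equal(q2$result$tsr_percent, q1$result$tsr_percent)
  expect_equal(q2$result$n_eligible, q1$result$n_eligible)
})

test_that("degenerate slides are reported non-assessable", {
  q <- quantify_slide(uniform_mask(0L, 64), NULL, roi_params(diameter_um = 32))
  expect_false(q$result$assessable)
  expect_true(is.na(q$result$tsr_percent))
  # fully artifact-covered slide: every ROI fails the composition test
  m <- uniform_mask(2L, 64)
  art <- artifact_mask(matrix(TRUE, 64, 64))
  q2 <- quantify_slide(m, art, roi_params(diameter_um = 32))
  expect_false(q2$result$assessable)
})

test_that("identical inputs give byte-identical results (determinism)", {
  m <- random_mask(77, size = 96)
  p <- roi_params(diameter_um = 32)
  q1 <- quantify_slide(m, NULL, p)
  q2 <- quantify_slide(m, NULL, p)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_slide_result(q1$result, f1)
  write_slide_result(q2$result, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
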