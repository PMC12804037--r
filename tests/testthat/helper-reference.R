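# Independent naive reference implementations used as oracles.
# These deliberately share no code with the package: grid positions are
# enumerated by stepping candidate centers one by one, and every ROI is
# re-evaluated from first principles (explicit Euclidean distance test on
# the pixel coordinates of its bounding square).

ref_role_of_code <- function(code, cm) {
  for (role in c("background", "tumor_epithelium", "tumor_stroma",
                 "necrosis", "mucin", "excluded")) {
    if (code == cm$roles[[role]]) return(role)
  }
  "other"
}

# naive double-loop slide quantification
ref_quantify <- function(mask, params) {
  cm <- mask$class_map
  codes <- mask$codes
  H <- nrow(codes); W <- ncol(codes)
  d <- max(1, round(params$diameter_um / mask$mpp))
  r <- d / 2
  R <- ceiling(r) - 1

  role_names <- c("background", "tumor_epithelium", "tumor_stroma",
                  "necrosis", "mucin", "excluded", "other")
  role_by_code <- vapply(0:255, ref_role_of_code, character(1), cm = cm)

  tum_code <- cm$roles[["tumor_epithelium"]]
  idx <- which(codes == tum_code)
  if (!length(idx)) {
    return(list(assessable = FALSE, tsr_percent = NA_real_,
                eligible = logical(0), tsr = numeric(0),
                centers = cbind(x = numeric(0), y = numeric(0))))
  }
  prow <- (idx - 1) %% H          # 0-based y
  pcol <- (idx - 1) %/% H         # 0-based x
  rad_d <- floor(d / 2)
  xmin <- max(0, min(pcol) - rad_d); xmax <- min(W - 1, max(pcol) + rad_d)
  ymin <- max(0, min(prow) - rad_d); ymax <- min(H - 1, max(prow) + rad_d)
  stride <- max(1, round((1 - params$overlap_fraction) * d))

  axis <- function(lo, hi, n) {
    out <- integer(0)
    cc <- max(R, ceiling(lo + r))
    while (cc + R <= n - 1 && cc - r < hi) { out <- c(out, cc); cc <- cc + stride }
    out
  }
  gx <- axis(xmin, xmax, W); gy <- axis(ymin, ymax, H)

  # pixel coordinates of the (2R+1)^2 bounding square, relative to center
  sq <- expand.grid(ox = -R:R, oy = -R:R)

  centers <- NULL; elig <- logical(0); tsrs <- numeric(0)
  for (cy in gy) for (cx in gx) {
    px <- cx + sq$ox; py <- cy + sq$oy
    member <- sqrt((px - cx)^2 + (py - cy)^2) < r
    mx <- px[member]; my <- py[member]
    roles <- role_by_code[codes[cbind(my + 1, mx + 1)] + 1]
    counts <- vapply(role_names, function(rl) sum(roles == rl), numeric(1))
    A <- sum(counts)
    frac <- counts / A
    istum <- roles == "tumor_epithelium"
    quad <- c(sum(istum & mx < cx & my < cy), sum(istum & mx >= cx & my < cy),
              sum(istum & mx < cx & my >= cy), sum(istum & mx >= cx & my >= cy))
    cpass <- (frac[["background"]] + frac[["excluded"]]) < params$max_background_fraction &&
      frac[["necrosis"]] < params$max_necrosis_fraction &&
      frac[["mucin"]] < params$max_mucin_fraction
    qpass <- all(quad >= params$min_tumor_pixels_per_quadrant)
    e <- cpass && qpass
    tsr <- if (e) frac[["tumor_stroma"]] / (frac[["tumor_stroma"]] + frac[["tumor_epithelium"]])
           else NA_real_
    centers <- rbind(centers, c(cx, cy)); elig <- c(elig, e); tsrs <- c(tsrs, tsr)
  }
  best <- NA_integer_; bt <- -1
  for (i in seq_along(elig)) {
    if (elig[i] && tsrs[i] > bt) { bt <- tsrs[i]; best <- i }
  }
  list(assessable = any(elig),
       tsr_percent = if (any(elig)) 100 * bt else NA_real_,
       chosen = best, eligible = elig, tsr = tsrs, centers = centers)
}

# hand product-limit Kaplan-Meier at event times
ref_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1; out <- numeric(0)
  for (t in ut) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out <- c(out, s)
  }
  data.frame(time = ut, survival = out)
}

# brute-force 1-D Cox partial likelihood (Breslow) on a fine beta grid
ref_cox_beta <- function(times, events, x, grid = seq(-4, 4, by = 1e-4)) {
  ll <- vapply(grid, function(b) {
    eta <- b * x
    s <- 0
    for (i in which(events == 1)) {
      risk <- times >= times[i]
      s <- s + eta[i] - log(sum(exp(eta[risk])))
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

# random small mask with all tissue roles represented
random_mask <- function(seed, size = 256L, cm = default_class_map()) {
  set.seed(seed)
  codes <- matrix(sample(c(0L, 1L, 2L, 3L, 4L, 5L, 9L), size * size,
                         replace = TRUE,
                         prob = c(0.06, 0.35, 0.40, 0.05, 0.05, 0.05, 0.04)),
                  size, size)
  label_mask(codes, mpp = 1.0, class_map = cm,
             slide_id = sprintf("rand_%d", seed))
}

# uniform-code mask helper
uniform_mask <- function(code, size = 64L, cm = default_class_map(), mpp = 1.0) {
  label_mask(matrix(as.integer(code), size, size), mpp, cm, "uniform")
}
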