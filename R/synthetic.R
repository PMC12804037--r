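# Synthetic ground-truth generators.
#
# simulate_mask() builds label masks whose hotspot TSR is known exactly: a
# smooth stroma-fraction field (capped strictly below the hotspot target so
# the maximum is unique), a planted hotspot disc painted with a
# deterministically dithered stroma:tumor pixel ratio, and optional
# necrosis/mucin/background pockets plus artifact overlays. simulate_cohort()
# builds survival cohorts with a known threshold effect of TSR on hazard.

# bilinear upscale of a (g+1) x (g+1) corner grid to H x W
.bilinear_field <- function(grid, H, W) {
  g <- nrow(grid) - 1L
  up <- function(n) {
    u <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1) * g
    i <- pmin(floor(u), g - 1L)
    list(i = i, w = u - i)
  }
  ry <- up(H); rx <- up(W)
  iy1 <- ry$i + 1L; iy2 <- ry$i + 2L; ix1 <- rx$i + 1L; ix2 <- rx$i + 2L
  outer(1 - ry$w, 1 - rx$w) * grid[iy1, ix1, drop = FALSE] +
    outer(1 - ry$w, rx$w)   * grid[iy1, ix2, drop = FALSE] +
    outer(ry$w, 1 - rx$w)   * grid[iy2, ix1, drop = FALSE] +
    outer(ry$w, rx$w)       * grid[iy2, ix2, drop = FALSE]
}

# linear indices (into an H-row matrix) of disc member pixels around
# (cx, cy), strict distance < diameter/2; column-major member order
.disc_lin_idx <- function(cx, cy, diameter_px, H) {
  R <- as.integer(ceiling(diameter_px / 2) - 1L)
  off <- seq.int(-R, R)
  dx <- matrix(off, 2L * R + 1L, 2L * R + 1L, byrow = TRUE)
  dy <- matrix(off, 2L * R + 1L, 2L * R + 1L)
  inside <- (dx * dx + dy * dy) < (diameter_px / 2)^2
  rr <- (cy - R + 1L):(cy + R + 1L)          # 1-based rows
  cc <- (cx - R + 1L):(cx + R + 1L)
  lin <- outer(rr, (cc - 1L) * H, "+")
  list(idx = lin[inside], R = R)
}

#' Simulate a label mask with a known hotspot TSR
#'
#' Each pixel is drawn as tumor stroma with probability given by a smooth
#' spatial field (bilinearly upscaled low-resolution noise, bounded by
#' \code{field_range}), otherwise tumor epithelium. A hotspot disc is
#' painted with an exact stroma:tumor pixel ratio by deterministic
#' dithering, making the ground-truth hotspot TSR known by construction;
#' the field maximum must stay strictly below the hotspot target so the
#' maximum is unique. Pockets of necrosis/mucin/background and artifact
#' overlays are placed away from the hotspot.
#'
#' @param width,height Mask size in pixels.
#' @param mpp Microns per pixel.
#' @param seed Integer seed; the same seed reproduces the mask exactly.
#' @param field_range Range of the stroma-fraction field (default
#'   \code{c(0.25, 0.60)}); both ends must be strictly below the hotspot
#'   target when a hotspot is planted.
#' @param field_cells Low-resolution grid cells per axis for the field.
#' @param hotspot List \code{(center = c(x, y) or NULL for random,
#'   diameter_um, tsr)}; NULL plants no hotspot. Default: random center,
#'   1500 um diameter, target TSR 0.80.
#' @param pockets Named list of pocket specs, each
#'   \code{list(count, radius_px = c(min, max))}, for any of
#'   \code{necrosis}, \code{mucin}, \code{background}, \code{artifact}.
#' @param class_map Tissue class map (default \code{default_class_map()}).
#' @param slide_id Slide identifier.
#' @return List with \code{mask} (a \code{label_mask}), \code{artifacts}
#'   (an \code{artifact_mask} or NULL), and \code{truth} (hotspot center,
#'   diameter, exact painted TSR, seed and parameters).
#' @export
simulate_mask <- function(width = 2000L, height = 2000L, mpp = 1.0,
                          seed = 1L,
                          field_range = c(0.25, 0.60),
                          field_cells = 8L,
                          hotspot = list(center = NULL, diameter_um = 1500,
                                         tsr = 0.80),
                          pockets = list(
                            necrosis  = list(count = 3L, radius_px = c(40L, 80L)),
                            mucin     = list(count = 3L, radius_px = c(40L, 80L)),
                            background = list(count = 4L, radius_px = c(30L, 70L)),
                            artifact  = list(count = 2L, radius_px = c(30L, 60L))),
                          class_map = default_class_map(),
                          slide_id = sprintf("sim_%d", seed)) {
  stopifnot(width >= 1L, height >= 1L, mpp > 0,
            field_range[1] >= 0, field_range[2] <= 1,
            field_range[1] <= field_range[2])
  if (!is.null(hotspot)) {
    stopifnot(hotspot$tsr > 0, hotspot$tsr <= 1)
    if (field_range[2] >= hotspot$tsr)
      stop("field maximum must be strictly below the hotspot target TSR")
  }
  set.seed(seed)
  roles <- class_map$roles
  H <- as.integer(height); W <- as.integer(width)

  # stroma-fraction field and base tissue draw
  if (field_range[2] > field_range[1]) {
    grid <- matrix(stats::runif((field_cells + 1L)^2, field_range[1], field_range[2]),
                   field_cells + 1L, field_cells + 1L)
    field <- .bilinear_field(grid, H, W)
  } else {
    field <- matrix(field_range[1], H, W)
  }
  codes <- matrix(ifelse(stats::runif(H * W) < field,
                         roles[["tumor_stroma"]], roles[["tumor_epithelium"]]),
                  H, W)

  truth <- list(seed = seed, mpp = mpp, width = W, height = H,
                field_range = field_range, hotspot = NULL)
  hs_center <- NULL; hs_R <- 0L
  if (!is.null(hotspot)) {
    d_px <- max(1L, as.integer(round(hotspot$diameter_um / mpp)))
    R <- as.integer(ceiling(d_px / 2) - 1L)
    margin <- 5L
    lo <- R + margin; hix <- W - 1L - R - margin; hiy <- H - 1L - R - margin
    if (hix < lo || hiy < lo) stop("hotspot does not fit inside the mask")
    ctr <- hotspot$center
    if (is.null(ctr))
      ctr <- c(sample(lo:hix, 1L), sample(lo:hiy, 1L))
    if (ctr[1] - R < 0 || ctr[1] + R > W - 1 || ctr[2] - R < 0 || ctr[2] + R > H - 1)
      stop("hotspot disc extends outside the mask")
    dl <- .disc_lin_idx(ctr[1L], ctr[2L], d_px, H)
    K <- length(dl$idx)
    p <- hotspot$tsr
    ks <- seq_len(K) - 1
    stroma_flag <- (floor((ks + 1) * p) - floor(ks * p)) == 1
    codes[dl$idx[stroma_flag]] <- roles[["tumor_stroma"]]
    codes[dl$idx[!stroma_flag]] <- roles[["tumor_epithelium"]]
    hs_center <- ctr; hs_R <- dl$R
    truth$hotspot <- list(center = ctr, diameter_um = hotspot$diameter_um,
                          diameter_px = d_px, target_tsr = p,
                          tsr = sum(stroma_flag) / K)
  }

  # pockets, rejected if they would intersect the hotspot disc
  art <- NULL
  pocket_codes <- c(necrosis = roles[["necrosis"]], mucin = roles[["mucin"]],
                    background = roles[["background"]])
  placed <- list()
  for (type in names(pockets)) {
    sp <- pockets[[type]]
    if (is.null(sp) || sp$count < 1L) next
    for (k in seq_len(sp$count)) {
      rad <- if (sp$radius_px[1] == sp$radius_px[2]) sp$radius_px[1] else
        sample(sp$radius_px[1]:sp$radius_px[2], 1L)
      d_pock <- 2L * rad
      Rp <- as.integer(ceiling(d_pock / 2) - 1L)
      if (W - 1L - Rp < Rp || H - 1L - Rp < Rp) next
      ok <- FALSE
      for (try in 1:100) {
        px <- sample(Rp:(W - 1L - Rp), 1L); py <- sample(Rp:(H - 1L - Rp), 1L)
        if (is.null(hs_center) ||
            sum((c(px, py) - hs_center)^2) > (Rp + hs_R + 2L)^2) { ok <- TRUE; break }
      }
      if (!ok) next
      dl <- .disc_lin_idx(px, py, d_pock, H)
      if (type == "artifact") {
        if (is.null(art)) art <- matrix(FALSE, H, W)
        art[dl$idx] <- TRUE
      } else {
        codes[dl$idx] <- pocket_codes[[type]]
      }
      placed[[length(placed) + 1L]] <- list(type = type, center = c(px, py),
                                            radius_px = rad)
    }
  }
  truth$pockets <- placed
  list(mask = label_mask(codes, mpp, class_map, slide_id),
       artifacts = if (is.null(art)) NULL else artifact_mask(art),
       truth = truth)
}

#' Simulate a survival cohort with a TSR threshold effect
#'
#' TSR scores follow a two-component truncated-normal mixture emulating a
#' roughly 65/35 stroma-low/high split. Disease-free survival times are
#' exponential with the baseline hazard multiplied by \code{hazard_ratio}
#' for patients above the true cut-off, and by modest age and stage
#' effects. Censoring combines administrative follow-up with uniform
#' dropout. Overall survival is coupled to DFS: deaths occur at the DFS
#' event time (a fraction of DFS events are deaths) or after a positive
#' exponential lag, so OS times never precede DFS times.
#'
#' @param n Number of patients (>= 2).
#' @param seed Integer seed.
#' @param true_cutoff_percent True threshold (default 77).
#' @param hazard_ratio Hazard multiplier above the cut-off (default 2.5).
#' @param base_rate Baseline exponential hazard per month; the default
#'   \code{-log(0.82)/36} gives 82% 3-year event-free survival in the
#'   low group.
#' @param admin_censor_months Administrative censoring time (default 72).
#' @param dropout_fraction Fraction of patients with uniform dropout
#'   censoring on \code{(0, admin_censor_months)} (default 0.30).
#' @param mix_p_low,mix_mu,mix_sd Mixture weight of the low component and
#'   component means/SDs in percent.
#' @param beta_age Log-hazard per year of age (centered at 67).
#' @param beta_stage Log-hazard for stage III vs II.
#' @param p_death_direct Fraction of DFS events that are deaths (OS event
#'   at the DFS time).
#' @param p_death_after Fraction of DFS events followed by death after an
#'   exponential lag.
#' @param death_lag_rate Rate of the exponential death lag (per month).
#' @return List with \code{cohort} (data.frame: id, tsr_percent,
#'   dfs_months, dfs_event, os_months, os_event, age, stage) and
#'   \code{truth} (the generating parameters, including the true cut-off).
#' @export
simulate_cohort <- function(n = 1000L, seed = 1L,
                            true_cutoff_percent = 77,
                            hazard_ratio = 2.5,
                            base_rate = -log(0.82) / 36,
                            admin_censor_months = 72,
                            dropout_fraction = 0.30,
                            mix_p_low = 0.65,
                            mix_mu = c(60, 84),
                            mix_sd = c(14, 7),
                            beta_age = 0.02,
                            beta_stage = 0.5,
                            p_death_direct = 0.15,
                            p_death_after = 0.40,
                            death_lag_rate = log(2) / 12) {
  stopifnot(n >= 2, hazard_ratio > 0, base_rate > 0,
            admin_censor_months > 0,
            dropout_fraction >= 0, dropout_fraction <= 1,
            p_death_direct + p_death_after <= 1)
  set.seed(seed)
  low <- stats::runif(n) < mix_p_low
  tsr <- ifelse(low, stats::rnorm(n, mix_mu[1], mix_sd[1]),
                stats::rnorm(n, mix_mu[2], mix_sd[2]))
  tsr <- pmin(pmax(tsr, 0.5), 99.5)
  age <- pmin(pmax(round(stats::rnorm(n, 67, 10)), 30), 95)
  stage <- ifelse(stats::runif(n) < 0.5, "III", "II")
  high <- tsr > true_cutoff_percent
  lam <- base_rate * hazard_ratio^high *
    exp(beta_age * (age - 67) + beta_stage * (stage == "III"))
  t_dfs <- stats::rexp(n, lam)
  cens <- ifelse(stats::runif(n) < dropout_fraction,
                 stats::runif(n, 0, admin_censor_months), admin_censor_months)
  u <- stats::runif(n)
  t_death <- ifelse(u < p_death_direct, t_dfs,
                    ifelse(u < p_death_direct + p_death_after,
                           t_dfs + stats::rexp(n, death_lag_rate), Inf))
  cohort <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    tsr_percent = tsr,
    dfs_months = pmin(t_dfs, cens),
    dfs_event = as.integer(t_dfs <= cens),
    os_months = pmin(t_death, cens),
    os_event = as.integer(t_death <= cens),
    age = age,
    stage = stage,
    stringsAsFactors = FALSE)
  truth <- list(seed = seed, n = n, true_cutoff_percent = true_cutoff_percent,
                hazard_ratio = hazard_ratio, base_rate = base_rate,
                admin_censor_months = admin_censor_months,
                dropout_fraction = dropout_fraction,
                beta_age = beta_age, beta_stage = beta_stage)
  list(cohort = cohort, truth = truth)
}

#' Write a cohort table to TSV
#'
#' @param cohort Cohort data.frame.
#' @param path Output TSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
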