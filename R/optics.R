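#' Confocal longitudinal point spread function
#'
#' Depth-dependent sensitivity of the focused catheter beam,
#' `T(r) = (((r - z0)/zR)^2 + 1)^(-1/2)`, maximal (1) at the beam waist `z0`
#' and decaying with the Rayleigh length `zR`.
#'
#' @param r depth, mm (vectorized).
#' @param z0 beam-waist position, mm.
#' @param zR Rayleigh length, mm (> 0).
#' @return values in `(0, 1]`.
#' @export
confocal_psf <- function(r, z0, zR) {
  if (zR <= 0) stop("zR must be > 0")
  (((r - z0) / zR)^2 + 1)^(-1 / 2)
}

#' Spectral roll-off modulation
#'
#' Depth-scan sensitivity decay of the source/detector, modeled as a
#' Gaussian in depth: `s(r) = exp(-((r - zC)/zW)^2)`, maximal (1) at the scan
#' center `zC` with half width `zW`.
#'
#' @param r depth, mm (vectorized).
#' @param zC scan center, mm.
#' @param zW roll-off half width, mm (> 0).
#' @return values in `(0, 1]`.
#' @export
rolloff <- function(r, zC, zW) {
  if (zW <= 0) stop("zW must be > 0")
  exp(-((r - zC) / zW)^2)
}

#' Compensate an A-line and move to log domain
#'
#' Divides out the confocal PSF and roll-off and takes the natural log:
#' `y(r) = log I(r) - log T(r) - log s(r)`.  Under the single-scattering
#' forward model the result is linear in depth with slope `-mu_t`.  Pixels at
#' or below `noise_floor` (and non-positive pixels) are masked out (`NA`).
#'
#' @param profile intensity per depth pixel (linear scale).
#' @param sys a [system_params()] supplying `z0`, `zR`, `zC`, `zW` and the
#'   axial spacing.
#' @param noise_floor intensities `<=` this value are masked; default 0
#'   masks only non-positive pixels.
#' @return numeric vector of corrected log intensities with `NA` at masked
#'   pixels.
#' @export
compensate_log_signal <- function(profile, sys, noise_floor = 0) {
  stopifnot(inherits(sys, "system_params"))
  r <- (seq_along(profile) - 1) * sys$axial_spacing
  y <- ifelse(profile > pmax(noise_floor, 0), log(profile), NA_real_)
  if (all(is.na(y))) stop("no fit support: all pixels masked")
  y - log(confocal_psf(r, sys$z0, sys$zR)) - log(rolloff(r, sys$zC, sys$zW))
}

#' Fit the attenuation coefficient over a depth window
#'
#' Ordinary least squares of the compensated log signal on depth over the
#' half-open column window `[start_col, end_col)` (0-based).  The slope gives
#' `mu_t = -slope` (mm^-1); `log_i0` is the fitted log intensity at the
#' window's first column, i.e. the intercept re-anchored at the window start
#' so that a window anchored at the tissue entry recovers `log(I0)` exactly
#' on noiseless model signals.
#'
#' @param log_profile compensated log intensities (`NA` = masked).
#' @param window integer `c(start_col, end_col)`, half-open, 0-based.
#' @param axial_spacing mm per depth pixel.
#' @return object of class `optical_fit`: list with `mu_t`, `log_i0`, `r2`,
#'   `window`, `n_points`.
#' @export
fit_attenuation <- function(log_profile, window, axial_spacing) {
  start_col <- window[1]; end_col <- window[2]
  if (end_col - start_col < 3) stop("window must span >= 3 columns")
  cols <- seq.int(start_col, end_col - 1L)        # 0-based
  y <- log_profile[cols + 1L]
  keep <- !is.na(y)
  if (sum(keep) < 3) stop("fewer than 3 unmasked points in window")
  r <- cols[keep] * axial_spacing
  y <- y[keep]
  mx <- mean(r); my <- mean(y)
  sxx <- sum((r - mx)^2)
  slope <- sum((r - mx) * (y - my)) / sxx
  ss_tot <- sum((y - my)^2)
  ss_reg <- slope^2 * sxx
  r2 <- if (ss_tot < 1e-300) 1 else min(max(ss_reg / ss_tot, 0), 1)
  structure(list(mu_t = -slope,
                 log_i0 = my + slope * (start_col * axial_spacing - mx),
                 r2 = r2,
                 window = c(start_col, end_col),
                 n_points = sum(keep)),
            class = "optical_fit")
}

#' Backscattering coefficient from the fit intercept
#'
#' The fit intercept factorizes as `I0 = I' * mu_b`, with `I'` the locally
#' available intensity; given `I'` the backscattering coefficient is
#' `mu_b = exp(log_i0) / I'`.
#'
#' @param log_i0 fitted log intercept.
#' @param i_prime locally available intensity (> 0).
#' @return list with `mu_b` and `i_prime`.
#' @export
backscatter_coefficient <- function(log_i0, i_prime) {
  if (any(i_prime <= 0)) stop("i_prime must be > 0")
  list(mu_b = exp(log_i0) / i_prime, i_prime = i_prime)
}

#' Per-pixel attenuation and intercept maps
#'
#' For each A-line, slides a fit window of physical length `window_len` (mm)
#' over the analysis band `[boundary, boundary + analysis_depth)` anchored at
#' the lumen boundary, and assigns every band pixel the fit from the window
#' centered on it (edge pixels take the nearest fully-inside window).
#' Pixels below the noise floor (the 1st percentile of lumen-side
#' intensities, per A-line set) are excluded from fits.
#'
#' @param img a [polar_image()].
#' @param boundary integer vector of 0-based lumen boundary columns, one per
#'   A-line (e.g. `segment_lumen()$radius_px`).
#' @param sys a [system_params()].
#' @param window_len fit window length, mm (>= 3 axial pixels).
#' @param analysis_depth analysis band depth, mm (default 1.0, the
#'   superficial band where plaque annotation is meaningful).
#' @return list with matrices `mu_t`, `log_i0`, `r2` (NA outside the band)
#'   and logical matrix `roi`.
#' @export
attenuation_map <- function(img, boundary, sys, window_len = 0.25,
                            analysis_depth = 1.0) {
  stopifnot(inherits(img, "polar_image"), inherits(sys, "system_params"))
  if (is.null(boundary)) stop("boundary is required")
  px <- img$pixels
  n_al <- nrow(px); n_c <- ncol(px)
  if (length(boundary) != n_al)
    stop("boundary length must equal the A-line count")
  dz <- sys$axial_spacing
  w <- as.integer(round(window_len / dz))
  if (w < 3) stop("window_len must span at least 3 axial pixels")
  depth_px <- as.integer(round(analysis_depth / dz))
  mu <- li <- r2m <- matrix(NA_real_, n_al, n_c)
  roi <- matrix(FALSE, n_al, n_c)
  # noise floor: 1st percentile of lumen (pre-boundary) intensities
  lum <- unlist(lapply(seq_len(n_al), function(i)
    if (boundary[i] >= 1) px[i, seq_len(boundary[i])] else numeric(0)))
  floor_thr <- if (length(lum)) unname(stats::quantile(lum, 0.01)) else 0
  r_all <- (seq_len(n_c) - 1) * dz
  logT <- log(confocal_psf(r_all, sys$z0, sys$zR))
  logS <- log(rolloff(r_all, sys$zC, sys$zW))
  for (i in seq_len(n_al)) {
    b <- boundary[i]
    lo <- b; hi <- min(b + depth_px, n_c)      # 0-based half-open band
    if (hi - lo < w) next
    cols <- seq.int(lo, hi - 1L)               # 0-based
    roi[i, cols + 1L] <- TRUE
    p <- px[i, cols + 1L]
    ok <- p > max(floor_thr, 0)
    y <- rep(NA_real_, length(cols))
    y[ok] <- log(p[ok]) - logT[cols[ok] + 1L] - logS[cols[ok] + 1L]
    r <- cols * dz
    wt <- as.numeric(ok)
    y0 <- ifelse(ok, y, 0)
    cs <- function(v) cumsum(v)
    Cw <- cs(wt); Cx <- cs(wt * r); Cy <- cs(y0)
    Cxx <- cs(wt * r^2); Cxy <- cs(wt * r * y0); Cyy <- cs(y0^2)
    n_pos <- hi - lo - w + 1L                  # window start positions
    s_idx <- seq_len(n_pos); e_idx <- s_idx + w - 1L
    dsum <- function(C) C[e_idx] - c(0, C)[s_idx]
    n <- dsum(Cw); Sx <- dsum(Cx); Sy <- dsum(Cy)
    Sxx <- dsum(Cxx); Sxy <- dsum(Cxy); Syy <- dsum(Cyy)
    denom <- n * Sxx - Sx^2
    valid <- n >= 3 & denom > 1e-300
    slope <- ifelse(valid, (n * Sxy - Sx * Sy) / denom, NA_real_)
    mxw <- Sx / n; myw <- Sy / n
    ss_tot <- Syy - Sy^2 / n
    ss_reg <- slope^2 * (Sxx - Sx^2 / n)
    r2w <- ifelse(ss_tot < 1e-12, 1, pmin(pmax(ss_reg / ss_tot, 0), 1))
    # window-start-anchored intercept
    r_start <- (lo + s_idx - 1L) * dz
    icpt <- myw + slope * (r_start - mxw)
    # map each band pixel to the window centered on it (clamped)
    pix_pos <- pmin(pmax(cols - lo - (w %/% 2L) + 1L, 1L), n_pos)
    mu_i <- -slope[pix_pos]
    li_i <- icpt[pix_pos]
    r2_i <- r2w[pix_pos]
    # fill occasional invalid windows from the nearest valid one
    if (anyNA(mu_i) && !all(is.na(mu_i))) {
      good <- which(!is.na(mu_i))
      near <- good[pmax(1L, findInterval(seq_along(mu_i), good))]
      # findInterval gives the last good index <= position; extend left edge
      mu_i <- mu_i[near]; li_i <- li_i[near]; r2_i <- r2_i[near]
    }
    mu[i, cols + 1L] <- mu_i
    li[i, cols + 1L] <- li_i
    r2m[i, cols + 1L] <- r2_i
  }
  list(mu_t = mu, log_i0 = li, r2 = r2m, roi = roi,
       window_px = w, depth_px = depth_px)
}
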