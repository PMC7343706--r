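#' Optical parameters of a simulated tissue class
#'
#' The forward model renders each A-line as
#' `I(r) = I0 * T(r) * s(r) * exp(-mu_t * (r - r_entry))`, a single-scattering
#' Lambert-Beer decay modulated by the confocal point spread function `T` and
#' the system roll-off `s`.  `mu_t` is the total attenuation coefficient and
#' `i0_scale` the backscatter intercept of a tissue class; `texture_corr_len`
#' and `texture_amp` control the multiplicative spatial texture field
#' (`1 + amp * smoothed unit-variance noise`).
#'
#' @param mu_t attenuation coefficient, mm^-1 (> 0, or 0 for a non-decaying
#'   test medium).
#' @param i0_scale backscatter intercept, linear intensity counts (> 0).
#' @param texture_corr_len texture correlation length, pixels (>= 0).
#' @param texture_amp texture modulation amplitude, in `[0, 1)`.
#' @return object of class `tissue_optical_params`.
#' @export
tissue_optical_params <- function(mu_t, i0_scale, texture_corr_len = 0,
                                  texture_amp = 0) {
  if (mu_t < 0) stop("mu_t must be >= 0")
  if (i0_scale <= 0) stop("i0_scale must be > 0")
  if (texture_corr_len < 0) stop("texture_corr_len must be >= 0")
  if (texture_amp < 0 || texture_amp >= 1)
    stop("texture_amp must be in [0, 1)")
  structure(list(mu_t = mu_t, i0_scale = i0_scale,
                 texture_corr_len = texture_corr_len,
                 texture_amp = texture_amp),
            class = "tissue_optical_params")
}

#' Imaging-system parameters
#'
#' Beam and sampling geometry of the simulated catheter: beam-waist position
#' `z0` and Rayleigh length `zR` of the confocal point spread function, scan
#' center `zC` and half-width `zW` of the Gaussian roll-off, axial pixel
#' spacing and number of A-lines per frame.
#'
#' @param z0 beam-waist position, mm.
#' @param zR Rayleigh length, mm (> 0).
#' @param zC scan center, mm.
#' @param zW roll-off half width, mm (> 0).
#' @param axial_spacing mm per depth pixel (> 0).
#' @param n_alines A-lines per frame (integer >= 8).
#' @return object of class `system_params`.
#' @export
system_params <- function(z0 = 1.0, zR = 2.0, zC = 1.5, zW = 3.0,
                          axial_spacing = 0.005, n_alines = 360L) {
  if (zR <= 0) stop("zR must be > 0")
  if (zW <= 0) stop("zW must be > 0")
  if (axial_spacing <= 0) stop("axial_spacing must be > 0")
  n_alines <- as.integer(n_alines)
  if (n_alines < 8) stop("n_alines must be >= 8")
  structure(list(z0 = z0, zR = zR, zC = zC, zW = zW,
                 axial_spacing = axial_spacing, n_alines = n_alines),
            class = "system_params")
}

#' Default optical parameters for the three plaque tissue classes
#'
#' Representative values for intravascular OCT at 1300 nm: fibrous tissue has
#' moderate attenuation and homogeneous high backscatter; calcification lower
#' backscatter with sharply heterogeneous texture and bright rims; lipid high
#' attenuation and strong backscatter.
#'
#' @return named list (`fibrous`, `calcified`, `lipid`) of
#'   [tissue_optical_params()].
#' @export
default_tissue_params <- function() {
  list(
    fibrous   = tissue_optical_params(3.0, 20000, texture_corr_len = 4,
                                      texture_amp = 0.12),
    calcified = tissue_optical_params(5.5, 9000, texture_corr_len = 1.5,
                                      texture_amp = 0.45),
    lipid     = tissue_optical_params(9.0, 28000, texture_corr_len = 6,
                                      texture_amp = 0.25)
  )
}

#' Phantom geometry and acquisition specification
#'
#' Describes one simulated cross-section: a smooth lumen radius profile
#' (mean radius plus sinusoidal harmonics), annular tissue sectors that must
#' tile `[0, 360)` degrees without gaps or overlap, an optional guide-wire
#' shadow sector, the speckle looks `L` and the RNG seed.
#'
#' @param mean_radius_mm mean lumen radius, mm.
#' @param harmonics numeric vector of harmonic amplitudes (mm); element `h`
#'   adds `harmonics[h] * sin(h * theta + phase[h])` to the radius.
#' @param phase phases (radians) for each harmonic; recycled.
#' @param tissue_sectors data.frame with columns `start_deg`, `end_deg`,
#'   `label` (1 fibrous / 2 calcified / 3 lipid), `thickness_mm`.  Sectors
#'   must cover `[0, 360)` exactly.
#' @param guidewire_deg length-2 numeric `c(start, end)` degrees of the
#'   shadowed sector, or `NULL` for none.
#' @param looks speckle looks `L` (>= 1, or `Inf` for a noiseless phantom).
#' @param seed RNG seed.
#' @param floor_level intensity floor (counts) for lumen / beyond-plaque /
#'   shadowed pixels.
#' @param n_depth optional number of depth pixels; by default just deep
#'   enough to hold the thickest sector plus a margin.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(mean_radius_mm = 0.9,
                         harmonics = numeric(0),
                         phase = 0,
                         tissue_sectors = data.frame(
                           start_deg = c(0, 120, 240),
                           end_deg = c(120, 240, 360),
                           label = c(1L, 2L, 3L),
                           thickness_mm = 1.2),
                         guidewire_deg = NULL,
                         looks = 4,
                         seed = 1L,
                         floor_level = 2,
                         n_depth = NULL) {
  ts <- tissue_sectors[order(tissue_sectors$start_deg), , drop = FALSE]
  if (abs(ts$start_deg[1]) > 1e-9 || abs(ts$end_deg[nrow(ts)] - 360) > 1e-9)
    stop("tissue sectors must cover [0, 360) exactly")
  if (nrow(ts) > 1) {
    gaps <- ts$start_deg[-1] - ts$end_deg[-nrow(ts)]
    if (any(abs(gaps) > 1e-9))
      stop("tissue sectors have gaps or overlaps at ",
           paste(ts$end_deg[-nrow(ts)][abs(gaps) > 1e-9], collapse = ", "),
           " degrees")
  }
  if (any(!ts$label %in% 1:3)) stop("sector labels must be in 1:3")
  if (any(ts$thickness_mm < 1))
    stop("sector thickness must be >= 1 mm so the 1 mm analysis band lies inside tissue")
  if (looks < 1) stop("looks must be >= 1 (Inf for noiseless)")
  if (length(harmonics))
    phase <- rep_len(phase, length(harmonics))
  structure(list(mean_radius_mm = mean_radius_mm, harmonics = harmonics,
                 phase = phase, tissue_sectors = ts,
                 guidewire_deg = guidewire_deg, looks = looks,
                 seed = as.integer(seed), floor_level = floor_level,
                 n_depth = n_depth),
            class = "phantom_spec")
}

#' Lumen radius (mm) at given angles for a phantom spec
#' @param spec a [phantom_spec()].
#' @param theta angles in radians.
#' @return numeric vector of radii (mm).
#' @export
lumen_radius_mm <- function(spec, theta) {
  r <- rep(spec$mean_radius_mm, length(theta))
  for (h in seq_along(spec$harmonics))
    r <- r + spec$harmonics[h] * sin(h * theta + spec$phase[h])
  r
}

resolve_tissue_params <- function(params_by_label) {
  # accept names ("fibrous", ...) or label characters ("1", ...)
  out <- vector("list", 3)
  for (nm in names(params_by_label)) {
    idx <- if (nm %in% names(TISSUE_LABELS)) TISSUE_LABELS[[nm]]
           else suppressWarnings(as.integer(nm))
    if (is.na(idx) || idx < 1 || idx > 3)
      stop("unknown tissue label '", nm, "' in params_by_label")
    out[[idx]] <- params_by_label[[nm]]
  }
  out
}

speckle_factor <- function(n, looks) {
  if (is.infinite(looks)) rep(1, n)
  else rgamma(n, shape = looks, rate = looks)   # unit mean, var 1/L
}

#' Render a single A-line through the forward model
#'
#' Computes the expected intensity profile for a per-depth-pixel label vector
#' and multiplies it by unit-mean gamma speckle with shape `looks`.  Depth in
#' the exponential is measured from the tissue entry point of the ray, so the
#' log-signal slope within a single tissue is exactly `-mu_t`.  Attenuation
#' accumulates across tissue transitions; background (label 0) pixels sit at
#' the noise floor.
#'
#' @param labels_along_ray integer vector of labels (0..3) per depth pixel,
#'   starting with the background (lumen) pixels.
#' @param params_by_label named list of [tissue_optical_params()] for every
#'   tissue label present (names `fibrous`/`calcified`/`lipid` or `"1"`..`"3"`).
#' @param sys a [system_params()].
#' @param looks speckle looks (`Inf` = noiseless).
#' @param seed optional RNG seed for the speckle draw.
#' @param floor_level background intensity floor (counts).
#' @return numeric intensity profile, same length as `labels_along_ray`.
#' @export
render_aline <- function(labels_along_ray, params_by_label, sys,
                         looks = 4, seed = NULL, floor_level = 2) {
  stopifnot(inherits(sys, "system_params"))
  lab <- as.integer(labels_along_ray)
  unknown <- setdiff(unique(lab), 0:3)
  if (length(unknown))
    stop("unknown label in map: ", paste(unknown, collapse = ", "))
  pars <- resolve_tissue_params(params_by_label)
  for (l in setdiff(unique(lab), 0L))
    if (is.null(pars[[l]]))
      stop("unknown label in map: ", l, " (no optical parameters supplied)")
  if (!is.null(seed)) set.seed(seed)
  expected <- expected_aline(lab, pars, sys, floor_level)
  expected * speckle_factor(length(lab), looks)
}

# Expected (noiseless) profile for one ray; `pars` indexed by label.
expected_aline <- function(lab, pars, sys, floor_level) {
  n <- length(lab)
  dz <- sys$axial_spacing
  r_mm <- (seq_len(n) - 1) * dz
  out <- rep(floor_level, n)
  tis <- which(lab > 0L)
  if (!length(tis)) return(out)
  entry <- tis[1]
  mu <- vapply(lab, function(l) if (l > 0L) pars[[l]]$mu_t else 0, 0)
  i0 <- vapply(lab, function(l) if (l > 0L) pars[[l]]$i0_scale else 0, 0)
  # cumulative optical path from the entry pixel; A[entry] = 0
  A <- rep(0, n)
  if (entry < n) {
    inc <- mu[(entry + 1):n] * dz
    inc[lab[(entry + 1):n] == 0L] <- 0
    A[(entry + 1):n] <- cumsum(inc)
  }
  Tr <- confocal_psf(r_mm, sys$z0, sys$zR)
  sr <- rolloff(r_mm, sys$zC, sys$zW)
  val <- i0 * Tr * sr * exp(-A)
  out[tis] <- val[tis]
  out
}

# Separable Gaussian smoothing; rows (angle) wrap circularly, columns clip.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n_r <- nrow(mat); n_c <- ncol(mat)
  # rows: circular
  acc <- matrix(0, n_r, n_c)
  for (d in seq(-half, half)) {
    idx <- ((seq_len(n_r) - 1 + d) %% n_r) + 1
    acc <- acc + k[d + half + 1] * mat[idx, , drop = FALSE]
  }
  # columns: replicate edges
  out <- matrix(0, n_r, n_c)
  for (d in seq(-half, half)) {
    idx <- pmin(pmax(seq_len(n_c) + d, 1L), n_c)
    out <- out + k[d + half + 1] * acc[, idx, drop = FALSE]
  }
  out
}

#' Generate a full phantom cross-section
#'
#' Builds the label raster from the lumen profile and tissue sectors, renders
#' the expected image through the forward model, applies per-tissue
#' multiplicative texture fields (with a bright 2-px rim on calcified
#' regions), suppresses the guide-wire sector to the noise floor from the
#' lumen boundary outward, multiplies by speckle and rounds to integer
#' counts.  The same seed reproduces the phantom bit-for-bit.
#'
#' @param spec a [phantom_spec()].
#' @param params_by_label named list of [tissue_optical_params()]; default
#'   [default_tissue_params()].
#' @param sys a [system_params()].
#' @return list of class `oct_phantom`: `image` ([polar_image()]), `labels`
#'   ([tissue_label_map()]), `boundary` (integer vector of true lumen columns,
#'   0-based), `shadow` (logical per A-line), plus the inputs.
#' @export
generate_phantom <- function(spec, params_by_label = default_tissue_params(),
                             sys = system_params()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(sys, "system_params"))
  pars <- resolve_tissue_params(params_by_label)
  n_al <- sys$n_alines
  dz <- sys$axial_spacing
  theta_deg <- (seq_len(n_al) - 1) * 360 / n_al
  theta <- theta_deg * pi / 180
  b_px <- as.integer(round(lumen_radius_mm(spec, theta) / dz))  # 0-based col
  if (any(b_px < 0)) stop("lumen radius profile goes negative")
  ts <- spec$tissue_sectors
  sec_of <- function(deg) {
    i <- findInterval(deg, ts$start_deg, rightmost.closed = FALSE)
    pmax(i, 1L)
  }
  sec_idx <- sec_of(theta_deg)
  thick_px <- as.integer(round(ts$thickness_mm[sec_idx] / dz))
  lab_al <- as.integer(ts$label[sec_idx])
  n_depth <- spec$n_depth
  if (is.null(n_depth)) n_depth <- max(b_px + thick_px) + 16L
  labels <- matrix(0L, n_al, n_depth)
  for (i in seq_len(n_al)) {
    from <- b_px[i] + 1L               # 1-based first tissue column
    to <- min(b_px[i] + thick_px[i], n_depth)
    if (from <= to) labels[i, from:to] <- lab_al[i]
  }
  for (l in setdiff(unique(as.vector(labels)), 0L))
    if (is.null(pars[[l]]))
      stop("unknown label in map: ", l, " (no optical parameters supplied)")

  set.seed(spec$seed)
  img <- matrix(spec$floor_level, n_al, n_depth)
  for (i in seq_len(n_al))
    img[i, ] <- expected_aline(labels[i, ], pars, sys, spec$floor_level)

  # per-tissue multiplicative texture fields
  for (l in sort(setdiff(unique(as.vector(labels)), 0L))) {
    p <- pars[[l]]
    if (p$texture_amp > 0) {
      g <- matrix(rnorm(n_al * n_depth), n_al, n_depth)
      g <- gaussian_smooth(g, p$texture_corr_len)
      g <- g / max(sd(g), .Machine$double.eps)
      field <- pmax(1 + p$texture_amp * g, 0.05)
      idx <- labels == l
      img[idx] <- img[idx] * field[idx]
    }
  }
  # bright rim on calcified runs: first/last 2 px of each calcified segment
  if (any(labels == 2L)) {
    for (i in seq_len(n_al)) {
      runs <- rle(labels[i, ] == 2L)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (j in which(runs$values)) {
        s <- starts[j]; e <- ends[j]
        rim <- unique(c(s:min(s + 1L, e), max(e - 1L, s):e))
        img[i, rim] <- img[i, rim] * 2
      }
    }
  }
  shadow <- rep(FALSE, n_al)
  if (!is.null(spec$guidewire_deg)) {
    gw <- spec$guidewire_deg %% 360
    shadow <- if (gw[1] <= gw[2])
      theta_deg >= gw[1] & theta_deg < gw[2]
    else
      theta_deg >= gw[1] | theta_deg < gw[2]
    for (i in which(shadow))
      img[i, (b_px[i] + 1L):n_depth] <- spec$floor_level
  }
  img <- img * matrix(speckle_factor(n_al * n_depth, spec$looks),
                      n_al, n_depth)
  img <- round(pmin(pmax(img, 0), 65535))
  structure(list(image = polar_image(img, axial_spacing = dz),
                 labels = tissue_label_map(labels),
                 boundary = b_px,
                 shadow = shadow,
                 spec = spec, sys = sys, params = pars),
            class = "oct_phantom")
}
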