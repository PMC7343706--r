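#' First-order statistics of an intensity window
#'
#' Population moments of the window's gray values: mean, variance, median,
#' skewness (standardized third central moment) and kurtosis (standardized
#' fourth central moment).  Skewness and kurtosis are 0 by convention for a
#' zero-variance window.
#'
#' @param window numeric matrix or vector of intensities.
#' @return named numeric vector `mean`, `variance`, `median`, `skewness`,
#'   `kurtosis`.
#' @export
fos_features <- function(window) {
  x <- as.numeric(window)
  if (!length(x)) stop("window must be non-empty")
  m <- mean(x)
  d <- x - m
  v <- mean(d^2)
  if (v < 1e-300) {
    sk <- 0; ku <- 0
  } else {
    sk <- mean(d^3) / v^1.5
    ku <- mean(d^4) / v^2
  }
  c(mean = m, variance = v, median = median(x), skewness = sk, kurtosis = ku)
}

#' Quantize intensities to gray levels
#'
#' Uniform quantization of `x` into `levels` bins anchored to `gray_range`
#' (by default the range of `x`; pass the whole image's range to anchor a
#' window to the global scale).  Returns integer tones in `1..levels`; a
#' degenerate range maps everything to tone 1.
#'
#' @param x numeric vector/matrix.
#' @param levels number of gray levels (>= 2).
#' @param gray_range length-2 numeric `c(min, max)`.
#' @return integer vector/matrix of tones.
#' @export
quantize_gray <- function(x, levels, gray_range = range(x)) {
  if (levels < 2) stop("levels must be >= 2")
  mn <- gray_range[1]; mx <- gray_range[2]
  if (mx <= mn) {
    q <- rep(1L, length(x))
  } else {
    q <- as.integer(pmin(floor((x - mn) / (mx - mn) * levels), levels - 1)) + 1L
  }
  if (is.matrix(x)) q <- matrix(q, nrow(x), ncol(x))
  q
}

glcm_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                     `90` = c(-1L, 0L), `135` = c(-1L, -1L))

# Dense symmetric normalized co-occurrence matrix for one offset.
glcm_matrix <- function(q, levels, offset) {
  n_r <- nrow(q); n_c <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  P <- matrix(0, levels, levels)
  r1 <- max(1, 1 - dr):min(n_r, n_r - dr)
  c1 <- max(1, 1 - dc):min(n_c, n_c - dc)
  for (i in r1) for (j in c1) {
    a <- q[i, j]; b <- q[i + dr, j + dc]
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  tot <- sum(P)
  if (tot > 0) P <- P / tot
  P
}

glcm_scalars <- function(P) {
  levels <- nrow(P)
  i <- matrix(seq_len(levels), levels, levels)
  j <- t(i)
  pi_m <- rowSums(P); pj_m <- colSums(P)
  mu_i <- sum(seq_len(levels) * pi_m); mu_j <- sum(seq_len(levels) * pj_m)
  s_i <- sqrt(sum((seq_len(levels) - mu_i)^2 * pi_m))
  s_j <- sqrt(sum((seq_len(levels) - mu_j)^2 * pj_m))
  corr <- if (s_i < 1e-300 || s_j < 1e-300) 1 else
    sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j)
  nz <- P > 0
  c(correlation = corr,
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    energy = sum(P^2),
    entropy = -sum(P[nz] * log2(P[nz])),
    homogeneity = sum(P / (1 + (i - j)^2)),
    max_probability = max(P))
}

#' Gray-level co-occurrence features of a window
#'
#' Quantizes the window to `levels` tones (anchored to `gray_range`), builds
#' the symmetric normalized co-occurrence matrix at distance 1 for each
#' requested angle, computes seven scalar features per angle (correlation,
#' contrast, dissimilarity, energy, entropy in bits, homogeneity, maximum
#' probability) and averages them over the angles.
#'
#' @param window numeric matrix (>= 2x2).
#' @param levels gray levels (>= 2, default 32).
#' @param gray_range quantization anchor range (default window range).
#' @param angles subset of `c(0, 45, 90, 135)`.
#' @return named numeric vector of the 7 features.
#' @export
glcm_features <- function(window, levels = 32, gray_range = range(window),
                          angles = c(0, 45, 90, 135)) {
  window <- as.matrix(window)
  if (nrow(window) < 2 || ncol(window) < 2)
    stop("window must be at least 2x2")
  q <- quantize_gray(window, levels, gray_range)
  acc <- NULL
  for (a in angles) {
    P <- glcm_matrix(q, levels, glcm_offsets[[as.character(a)]])
    f <- glcm_scalars(P)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / length(angles)
}

#' Neighborhood gray-tone difference features of a window
#'
#' Computes the NGTDM over the window's interior pixels (3x3 neighborhoods,
#' center excluded from the neighbor mean) and the five Amadasun-King
#' scalars: coarseness, contrast, busyness, complexity and strength
#' ("texture length").  A small epsilon (1e-12) guards zero denominators, so
#' a constant window yields coarseness `1/eps` and zeros elsewhere.
#'
#' @param window integer-tone matrix (>= 3x3), e.g. from [quantize_gray()].
#' @param eps denominator guard.
#' @return named numeric vector `busyness`, `ngtdm_contrast`, `complexity`,
#'   `coarseness`, `strength`.
#' @export
ngtdm_features <- function(window, eps = 1e-12) {
  g <- as.matrix(window)
  n_r <- nrow(g); n_c <- ncol(g)
  if (n_r < 3 || n_c < 3) stop("window must be at least 3x3")
  tones <- sort(unique(as.vector(g)))
  s <- setNames(numeric(length(tones)), tones)
  n_i <- setNames(numeric(length(tones)), tones)
  for (i in 2:(n_r - 1)) for (j in 2:(n_c - 1)) {
    nb <- g[(i - 1):(i + 1), (j - 1):(j + 1)]
    a_bar <- (sum(nb) - g[i, j]) / 8
    key <- as.character(g[i, j])
    s[key] <- s[key] + abs(g[i, j] - a_bar)
    n_i[key] <- n_i[key] + 1
  }
  N <- (n_r - 2) * (n_c - 2)
  p <- n_i / N
  present <- p > 0
  ti <- tones[present]; pi_ <- p[present]; si <- s[present]
  Ng <- length(ti)
  coarse <- 1 / (eps + sum(pi_ * si))
  if (Ng <= 1) {
    return(c(busyness = 0, ngtdm_contrast = 0, complexity = 0,
             coarseness = coarse, strength = 0))
  }
  PI <- outer(pi_, pi_, "+")
  DIF <- outer(ti, ti, "-")
  contr <- (sum(outer(pi_, pi_) * DIF^2) / (Ng * (Ng - 1))) * (sum(si) / N)
  busy_den <- sum(abs(outer(ti * pi_, ti * pi_, "-")))
  busy <- if (busy_den < eps) 0 else sum(pi_ * si) / busy_den
  compl_ <- 0
  for (a in seq_len(Ng)) for (b in seq_len(Ng))
    compl_ <- compl_ + abs(ti[a] - ti[b]) / (N * (pi_[a] + pi_[b])) *
      (pi_[a] * si[a] + pi_[b] * si[b])
  strength <- sum(PI * DIF^2) / (eps + sum(si))
  c(busyness = unname(busy), ngtdm_contrast = unname(contr),
    complexity = unname(compl_), coarseness = unname(coarse),
    strength = unname(strength))
}

#' Differential box-counting fractal signature of a window
#'
#' Treats the window as an intensity surface.  At scale `s` the window is
#' tiled by `s` x `s` columns; with box height `h = s * G / M` (`G` = gray
#' range, `M` = window side) each column contributes
#' `ceil((max - gmin)/h) - ceil((min - gmin)/h) + 1` boxes, and
#' `N(s)` is the total.  The returned features are the four per-scale
#' log-counts `H_k = log N(s_k)`; their least-squares slope against
#' `log(1/s)` (the fractal-dimension estimate) is attached as attribute
#' `"fd"`.  A flat surface contributes one box per column, so a constant
#' window has `N(s) = (M/s)^2` (for `s | M`) and FD exactly 2.
#'
#' @param window numeric matrix.
#' @param scales integer vector of 4 box sizes; window side must be at least
#'   twice the largest.
#' @param gray_range intensity anchor range (default window range).
#' @return numeric vector `H1..H4` with attribute `fd`.
#' @export
fd_features <- function(window, scales = c(2, 3, 4, 5),
                        gray_range = range(window)) {
  win <- as.matrix(window)
  M <- min(dim(win))
  if (M < 2 * max(scales))
    stop("window side must be >= 2 x the largest scale")
  gmin <- gray_range[1]
  G <- gray_range[2] - gray_range[1]
  logN <- vapply(scales, function(s) {
    h <- s * G / M
    tot <- 0
    for (r0 in seq(1, nrow(win), by = s)) for (c0 in seq(1, ncol(win), by = s)) {
      cell <- win[r0:min(r0 + s - 1, nrow(win)),
                  c0:min(c0 + s - 1, ncol(win)), drop = FALSE]
      if (h <= 0) { tot <- tot + 1; next }
      nr <- ceiling((max(cell) - gmin) / h) - ceiling((min(cell) - gmin) / h) + 1
      tot <- tot + nr
    }
    log(tot)
  }, 0)
  x <- log(1 / scales)
  slope <- sum((x - mean(x)) * (logN - mean(logN))) / sum((x - mean(x))^2)
  structure(setNames(logN, paste0("H", seq_along(scales))), fd = slope)
}

#' Extract the (wrapped, clipped) analysis window around a pixel
#'
#' Rows (the angular coordinate) wrap circularly across the seam; columns
#' (depth) clip at the raster edges, shrinking the window.
#'
#' @param mat numeric matrix.
#' @param row0,col0 0-based target pixel.
#' @param window_px odd window side.
#' @return numeric matrix of the window.
#' @export
extract_window <- function(mat, row0, col0, window_px) {
  h <- window_px %/% 2L
  n_r <- nrow(mat); n_c <- ncol(mat)
  rows <- ((row0 - h):(row0 + h)) %% n_r + 1L
  cols <- (max(0L, col0 - h):min(n_c - 1L, col0 + h)) + 1L
  mat[rows, cols, drop = FALSE]
}

#' Build the per-pixel feature stack
#'
#' Assembles the 25 named features for each pixel of the analysis band
#' `[boundary, boundary + analysis_depth)`: the two optical features from
#' the attenuation maps, 21 texture features from the `window_px` x
#' `window_px` window centered on the pixel (computed in compiled code;
#' quantization and the fractal gray anchor use the whole image's intensity
#' range), and the relative-position features `x` (depth in px from the
#' lumen boundary) and `y` (A-line index).
#'
#' @param img a [polar_image()].
#' @param optical result of [attenuation_map()].
#' @param boundary integer vector of 0-based lumen boundary columns.
#' @param window_px odd texture window side (default 11).
#' @param levels gray levels for GLCM/NGTDM quantization (default 32).
#' @param scales fractal box sizes (default `c(2,3,4,5)`).
#' @param pixels optional 2-column integer matrix of 0-based `(row, col)`
#'   target pixels (must lie in the band); default all band pixels.
#' @return data.frame of class `feature_stack`: columns `row`, `col`
#'   (0-based) and the 25 features in [FEATURE_NAMES] order.
#' @export
build_feature_stack <- function(img, optical, boundary,
                                window_px = 11, levels = 32,
                                scales = c(2, 3, 4, 5), pixels = NULL) {
  stopifnot(inherits(img, "polar_image"))
  if (is.null(optical$mu_t) || is.null(optical$log_i0))
    stop("optical maps are required (run attenuation_map first)")
  if (window_px %% 2 != 1) stop("window_px must be odd")
  px <- img$pixels
  if (is.null(pixels)) {
    idx <- which(optical$roi, arr.ind = TRUE)
    pixels <- cbind(idx[, 1] - 1L, idx[, 2] - 1L)
  }
  pixels <- matrix(as.integer(pixels), ncol = 2)
  gr <- range(px)
  q <- quantize_gray(px, levels, gr)
  tex <- texture_sweep_cpp(px, q, levels, pixels[, 1], pixels[, 2],
                           as.integer(window_px), as.integer(scales),
                           gr[1], gr[2])
  colnames(tex) <- FEATURE_NAMES[3:23]
  mu <- optical$mu_t[pixels + 1L]
  li <- optical$log_i0[pixels + 1L]
  out <- data.frame(row = pixels[, 1], col = pixels[, 2],
                    mu_t = mu, log_i0 = li)
  out <- cbind(out, as.data.frame(tex))
  out$x <- pixels[, 2] - boundary[pixels[, 1] + 1L]
  out$y <- pixels[, 1]
  keep <- !is.na(out$mu_t) & !is.na(out$log_i0)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_stack", "data.frame")
  out
}
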