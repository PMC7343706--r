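#' Detect the guide-wire shadow sector
#'
#' The metal guide wire casts an angular sector of signal loss.  Each
#' A-line is summarized by its mean intensity on a log scale (which makes
#' the statistic robust to the order-of-magnitude brightness differences
#' between tissue sectors); A-lines falling more than `k` MADs below the
#' median summary are shadow candidates, and the longest contiguous
#' circular run of candidates spanning at least `min_span` A-lines is
#' flagged.
#'
#' @param img a [polar_image()].
#' @param k MAD multiplier for the threshold (default 3).
#' @param min_span minimum run length in A-lines (default 3).
#' @return logical vector, one flag per A-line (all `FALSE` when no run
#'   qualifies).
#' @export
detect_guidewire_shadow <- function(img, k = 3, min_span = 3) {
  stopifnot(inherits(img, "polar_image"))
  m <- log1p(rowMeans(img$pixels))
  thr <- median(m) - k * mad(m)
  cand <- m < thr
  n <- length(cand)
  out <- rep(FALSE, n)
  if (!any(cand)) return(out)
  # longest circular run of TRUE
  cc <- rep(cand, 2)
  r <- rle(cc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_span & starts <= n)
  if (!length(runs)) return(out)
  best <- runs[which.max(pmin(r$lengths[runs], n))]
  idx <- ((starts[best]:min(ends[best], starts[best] + n - 1L)) - 1L) %% n + 1L
  out[idx] <- TRUE
  out
}

# 3x3 median filter; rows (angle) wrap circularly, columns replicate edges.
# Median of 9 via a compare-exchange network, fully vectorized.
median_filter3 <- function(mat) {
  n_r <- nrow(mat); n_c <- ncol(mat)
  sr <- function(d) mat[((seq_len(n_r) - 1 + d) %% n_r) + 1L, , drop = FALSE]
  sc <- function(m, d) m[, pmin(pmax(seq_len(n_c) + d, 1L), n_c), drop = FALSE]
  v <- list()
  idx <- 1L
  for (dr in -1:1) for (dc in -1:1) {
    v[[idx]] <- sc(sr(dr), dc); idx <- idx + 1L
  }
  xch <- function(a, b) {
    lo <- pmin(v[[a]], v[[b]]); hi <- pmax(v[[a]], v[[b]])
    v[[a]] <<- lo; v[[b]] <<- hi
  }
  # Paeth's median-of-9 network
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 2); xch(4, 5); xch(7, 8)
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 4); xch(6, 9); xch(5, 8)
  xch(4, 7); xch(2, 5); xch(3, 6)
  xch(5, 8); xch(5, 3); xch(7, 5)
  xch(5, 3)
  v[[5]]
}

# Edge cost: negative axial gradient of the median-filtered image.
lumen_edge_cost <- function(px) {
  sm <- median_filter3(px)
  n_c <- ncol(sm)
  right <- sm[, pmin(seq_len(n_c) + 1L, n_c), drop = FALSE]
  left <- sm[, pmax(seq_len(n_c) - 1L, 1L), drop = FALSE]
  -(right - left) / 2
}

# Exact DP for one fixed start column with circular closure.
dp_fixed_start <- function(cost, s, start_col) {
  n_r <- nrow(cost); n_c <- ncol(cost)
  D <- rep(Inf, n_c)
  D[start_col] <- cost[1, start_col]
  P <- matrix(NA_integer_, n_r, n_c)
  for (i in 2:n_r) {
    best <- rep(Inf, n_c); arg <- rep(NA_integer_, n_c)
    for (d in -s:s) {
      j <- seq_len(n_c)
      pj <- j + d
      ok <- pj >= 1L & pj <= n_c
      cand <- rep(Inf, n_c)
      cand[ok] <- D[pj[ok]]
      upd <- cand < best          # strict: ties keep the smaller prev column
      best[upd] <- cand[upd]
      arg[upd] <- j[upd] + d
    }
    D <- best + cost[i, ]
    P[i, ] <- arg
  }
  term <- which(abs(seq_len(n_c) - start_col) <= s & is.finite(D))
  if (!length(term)) return(NULL)
  jend <- term[which.min(D[term])]
  path <- integer(n_r)
  path[n_r] <- jend
  for (i in n_r:2) path[i - 1] <- P[i, path[i]]
  list(path = path, cost = D[jend])
}

#' Segment the lumen boundary by dynamic programming
#'
#' Finds the closed boundary (one column per A-line) minimizing the summed
#' edge cost — the negative axial intensity gradient of a 3x3
#' median-filtered copy of the image, so the path locks onto the dark-lumen
#' to bright-tissue transition — subject to the smoothness constraint
#' `|r[i+1] - r[i]| <= s` including the circular wrap-around pair.  Closure
#' is handled by solving the DP once per candidate start column (all columns
#' for narrow images, otherwise one representative per 8 coarse radius
#' buckets) and keeping the lowest-cost closed path.  Ties break toward the
#' smaller radius.  Shadowed A-lines are assigned radii interpolated between
#' their non-shadowed neighbors.
#'
#' @param img a [polar_image()].
#' @param shadow optional logical per-A-line guide-wire mask
#'   (see [detect_guidewire_shadow()]).
#' @param smoothness maximum per-step radius change `s` in pixels (>= 1).
#' @return object of class `lumen_boundary`: list with `radius_px` (0-based
#'   boundary column per A-line), `shadowed` (logical), `total_cost`.
#' @export
segment_lumen <- function(img, shadow = NULL, smoothness = 2) {
  stopifnot(inherits(img, "polar_image"))
  s <- as.integer(smoothness)
  if (s < 1) stop("smoothness must be >= 1")
  px <- img$pixels
  n_r <- nrow(px); n_c <- ncol(px)
  if (n_c < 3) stop("image must have at least 3 columns")
  if (is.null(shadow)) shadow <- rep(FALSE, n_r)
  cost <- lumen_edge_cost(px)
  cost[shadow, ] <- 0                 # shadowed A-lines carry no evidence
  # candidate start columns: exhaustive when narrow, else 8 coarse buckets
  if (n_c <= 16) {
    starts <- seq_len(n_c)
  } else {
    breaks <- unique(round(seq(1, n_c + 1, length.out = 9)))
    starts <- vapply(seq_len(length(breaks) - 1), function(b) {
      rng <- breaks[b]:(breaks[b + 1] - 1)
      rng[which.min(cost[1, rng])]
    }, integer(1))
  }
  best <- NULL
  for (s0 in starts) {
    res <- dp_fixed_start(cost, s, s0)
    if (!is.null(res) && (is.null(best) || res$cost < best$cost ||
                          (res$cost == best$cost && res$path[1] < best$path[1])))
      best <- res
  }
  if (is.null(best)) stop("no feasible closed path")
  path <- best$path
  # interpolate across shadowed runs (circularly)
  if (any(shadow) && !all(shadow)) {
    good <- which(!shadow)
    for (i in which(shadow)) {
      dl <- (i - good) %% n_r; dr <- (good - i) %% n_r
      l <- good[which.min(dl)]; r <- good[which.min(dr)]
      gap <- (r - l) %% n_r
      if (gap == 0) { path[i] <- path[l]; next }
      t <- ((i - l) %% n_r) / gap
      path[i] <- as.integer(round((1 - t) * path[l] + t * path[r]))
    }
  }
  structure(list(radius_px = path - 1L,    # 0-based column index
                 shadowed = shadow,
                 total_cost = best$cost),
            class = "lumen_boundary")
}
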