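# Independent brute-force oracles, deliberately written with the simplest
# possible enumeration logic (no shared code with the implementation).

# --- GLCM oracle: enumerate every pixel pair explicitly -----------------
oracle_glcm <- function(q, levels, angles = c(0, 45, 90, 135)) {
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  feats <- NULL
  for (a in angles) {
    dr <- offs[[as.character(a)]][1]; dc <- offs[[as.character(a)]][2]
    P <- matrix(0, levels, levels)
    for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
        P[q[i, j], q[i2, j2]] <- P[q[i, j], q[i2, j2]] + 1
        P[q[i2, j2], q[i, j]] <- P[q[i2, j2], q[i, j]] + 1
      }
    }
    P <- P / sum(P)
    ii <- matrix(seq_len(levels), levels, levels)
    jj <- t(ii)
    pi_ <- rowSums(P); pj_ <- colSums(P)
    mi <- sum(seq_len(levels) * pi_); mj <- sum(seq_len(levels) * pj_)
    si <- sqrt(sum((seq_len(levels) - mi)^2 * pi_))
    sj <- sqrt(sum((seq_len(levels) - mj)^2 * pj_))
    f <- c(
      correlation = if (si == 0 || sj == 0) 1 else
        sum((ii - mi) * (jj - mj) * P) / (si * sj),
      contrast = sum((ii - jj)^2 * P),
      dissimilarity = sum(abs(ii - jj) * P),
      energy = sum(P^2),
      entropy = -sum(ifelse(P > 0, P * log2(P), 0)),
      homogeneity = sum(P / (1 + (ii - jj)^2)),
      max_probability = max(P))
    feats <- if (is.null(feats)) f else feats + f
  }
  feats / length(angles)
}

# --- NGTDM oracle: direct Amadasun-King enumeration ---------------------
oracle_ngtdm <- function(g, eps = 1e-12) {
  nr <- nrow(g); nc <- ncol(g)
  tones <- sort(unique(as.vector(g[2:(nr - 1), 2:(nc - 1)])))
  s <- rep(0, length(tones)); cnt <- rep(0, length(tones))
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    nb <- c(g[i - 1, j - 1], g[i - 1, j], g[i - 1, j + 1],
            g[i, j - 1], g[i, j + 1],
            g[i + 1, j - 1], g[i + 1, j], g[i + 1, j + 1])
    k <- match(g[i, j], tones)
    s[k] <- s[k] + abs(g[i, j] - mean(nb))
    cnt[k] <- cnt[k] + 1
  }
  N <- (nr - 2) * (nc - 2)
  p <- cnt / N
  Ng <- length(tones)
  coarse <- 1 / (eps + sum(p * s))
  if (Ng <= 1)
    return(c(busyness = 0, ngtdm_contrast = 0, complexity = 0,
             coarseness = coarse, strength = 0))
  contr_pp <- 0; busy_den <- 0; compl_ <- 0; str_num <- 0
  for (a in seq_len(Ng)) for (b in seq_len(Ng)) {
    d <- tones[a] - tones[b]
    contr_pp <- contr_pp + p[a] * p[b] * d^2
    busy_den <- busy_den + abs(tones[a] * p[a] - tones[b] * p[b])
    compl_ <- compl_ + abs(d) / (N * (p[a] + p[b])) *
      (p[a] * s[a] + p[b] * s[b])
    str_num <- str_num + (p[a] + p[b]) * d^2
  }
  c(busyness = if (busy_den < eps) 0 else sum(p * s) / busy_den,
    ngtdm_contrast = contr_pp / (Ng * (Ng - 1)) * sum(s) / N,
    complexity = compl_,
    coarseness = coarse,
    strength = str_num / (eps + sum(s)))
}

# --- FOS oracle: direct population moments ------------------------------
oracle_fos <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  c(mean = m, variance = m2, median = median(x),
    skewness = if (m2 == 0) 0 else m3 / m2^(3 / 2),
    kurtosis = if (m2 == 0) 0 else m4 / m2^2)
}

# --- exhaustive closed-path search for the lumen DP ---------------------
# Enumerates every column assignment (n_cols^n_alines paths), filters by the
# smoothness constraint including the wrap, returns the minimum total cost.
oracle_lumen_exhaustive <- function(cost, s) {
  n_r <- nrow(cost); n_c <- ncol(cost)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_c)), n_r)))
  ok <- rep(TRUE, nrow(grid))
  for (i in seq_len(n_r)) {
    j <- if (i == n_r) 1L else i + 1L
    ok <- ok & abs(grid[, j] - grid[, i]) <= s
  }
  grid <- grid[ok, , drop = FALSE]
  costs <- numeric(nrow(grid))
  for (i in seq_len(n_r)) costs <- costs + cost[cbind(i, grid[, i])]
  min(costs)
}

# --- shared fixtures ----------------------------------------------------
make_ray <- function(n_bg, n_tissue, label = 1L, n_tail = 0L) {
  c(rep(0L, n_bg), rep(label, n_tissue), rep(0L, n_tail))
}

neutral_sys <- function(axial_spacing = 0.005, n_alines = 360L) {
  # z0 = zC = 0 with huge zR, zW: T and s are 1 to machine precision
  system_params(z0 = 0, zR = 1e8, zC = 0, zW = 1e8,
                axial_spacing = axial_spacing, n_alines = n_alines)
}
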