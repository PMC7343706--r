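#' Per-class classification metrics on a pixel basis
#'
#' Compares a predicted tissue map with ground truth over the pixels the
#' truth labels as tissue (1..3).  For each class, one-vs-rest sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)`; `accuracy` is the per-class
#' recall (the per-image accuracy notion that is averaged over images by the
#' cross-validation layer) and `accuracy_binary` the standard one-vs-rest
#' accuracy `(TP+TN)/total`, both emitted and labeled.  All metrics are
#' percentages.
#'
#' @param pred,truth [tissue_label_map()]s (or integer matrices) of equal
#'   geometry.
#' @return object of class `eval_report`: `per_class` data.frame,
#'   `overall_accuracy` (%), `counts` (4x3 matrix: predicted 0..3 by true
#'   class 1..3).
#' @export
class_metrics <- function(pred, truth) {
  p <- if (inherits(pred, "tissue_label_map")) pred$labels else as.matrix(pred)
  t_ <- if (inherits(truth, "tissue_label_map")) truth$labels else as.matrix(truth)
  if (!identical(dim(p), dim(t_)))
    stop("prediction and truth geometry mismatch")
  sel <- t_ %in% 1:3
  pv <- factor(p[sel], levels = 0:3)
  tv <- factor(t_[sel], levels = 1:3)
  counts <- table(predicted = pv, true = tv)
  total <- sum(counts)
  per <- lapply(1:3, function(cl) {
    tp <- counts[as.character(cl), as.character(cl)]
    fn <- sum(counts[, as.character(cl)]) - tp
    fp <- sum(counts[as.character(cl), ]) - tp
    tn <- total - tp - fn - fp
    data.frame(class = names(TISSUE_LABELS)[cl + 1],
               sensitivity = 100 * tp / max(tp + fn, 1),
               specificity = 100 * tn / max(tn + fp, 1),
               accuracy = 100 * tp / max(tp + fn, 1),
               accuracy_binary = 100 * (tp + tn) / max(total, 1))
  })
  structure(list(per_class = do.call(rbind, per),
                 overall_accuracy = 100 * sum(diag(counts[2:4, ])) /
                   max(total, 1),
                 counts = counts),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("pixel-wise evaluation (%):\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("overall accuracy: %.1f%%\n", x$overall_accuracy))
  invisible(x)
}

#' Image-grouped k-fold cross-validation
#'
#' Splits whole labeled images into `k` folds (images are never split across
#' folds), trains the forest on the training folds' pixels and evaluates
#' per-class recall on each test fold, for a chosen feature set (`OP+RP`,
#' `FOS+RP`, `GLCM+RP`, `NGTDM+RP`, `FD+RP` or `ALL`).  Reports mean, SD and
#' median accuracy per class over folds.
#'
#' @param datasets list of labeled images: each element a list with `stack`
#'   (feature stack), `labels` (integer per stack row), and optionally
#'   `image_id`, `patient_id`.
#' @param k number of folds (<= number of images).
#' @param feature_set selector name (see [feature_set_columns()]).
#' @param cfg an [rf_config()].
#' @param seed seed for the fold shuffle (the forest uses `cfg$seed + fold`).
#' @param group_by `"image"` (default) or `"patient"`: the unit kept whole
#'   within a fold.
#' @return object of class `cv_report`: `folds` (per-fold per-class recall %
#'   and overall accuracy %), `summary` (mean/sd/median per class),
#'   `feature_set`, `assignments`.
#' @export
cross_validate <- function(datasets, k = 10, feature_set = "ALL",
                           cfg = rf_config(), seed = 1L,
                           group_by = c("image", "patient")) {
  group_by <- match.arg(group_by)
  n_img <- length(datasets)
  if (k > n_img) stop("k exceeds the number of images")
  cols <- setdiff(feature_set_columns(feature_set), character(0))
  ids <- if (group_by == "patient")
    vapply(datasets, function(d) as.character(d$patient_id), "")
  else vapply(seq_along(datasets), function(i)
    as.character(if (!is.null(datasets[[i]]$image_id)) datasets[[i]]$image_id
                 else i), "")
  units <- unique(ids)
  set.seed(seed)
  shuffled <- sample(units)
  fold_of_unit <- setNames(rep(seq_len(k), length.out = length(shuffled)),
                           shuffled)
  fold <- fold_of_unit[ids]
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    tr_x <- do.call(rbind, lapply(datasets[tr_idx], function(d)
      as.data.frame(d$stack)[, cols, drop = FALSE]))
    tr_y <- unlist(lapply(datasets[tr_idx], function(d) d$labels))
    cfg_f <- rf_config(cfg$n_tree, cfg$m_try, cfg$seed + f,
                       cfg$class_weighting)
    model <- suppressMessages(
      train_rf(tr_x, tr_y, cfg_f, features = cols))
    te_x <- do.call(rbind, lapply(datasets[te_idx], function(d)
      as.data.frame(d$stack)[, cols, drop = FALSE]))
    te_y <- unlist(lapply(datasets[te_idx], function(d) d$labels))
    pv <- predict(model$forest, newdata = te_x, type = "prob")
    prob3 <- matrix(0, nrow(te_x), 3, dimnames = list(NULL, c("1", "2", "3")))
    prob3[, colnames(pv)] <- pv
    pred <- max.col(prob3, ties.method = "first")
    rec <- vapply(1:3, function(cl) {
      n_cl <- sum(te_y == cl)
      if (n_cl == 0) NA_real_ else 100 * sum(pred == cl & te_y == cl) / n_cl
    }, 0)
    folds[[f]] <- data.frame(fold = f, fibrous = rec[1], calcified = rec[2],
                             lipid = rec[3],
                             overall = 100 * mean(pred == te_y))
  }
  folds <- do.call(rbind, folds)
  summ <- do.call(rbind, lapply(c("fibrous", "calcified", "lipid", "overall"),
    function(cl) data.frame(class = cl,
                            mean = mean(folds[[cl]], na.rm = TRUE),
                            sd = sd(folds[[cl]], na.rm = TRUE),
                            median = median(folds[[cl]], na.rm = TRUE))))
  structure(list(folds = folds, summary = summ, feature_set = feature_set,
                 assignments = data.frame(id = ids, fold = unname(fold))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, feature set %s (accuracy %%):\n",
              max(x$folds$fold), x$feature_set))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Patient-level holdout split
#'
#' Partitions images by patient id into a training and a testing set (by
#' default 24 training / 7 testing patients, scaled down proportionally when
#' fewer patients are supplied), trains on all training pixels and returns
#' the pixel-wise evaluation on the held-out patients.
#'
#' @param datasets as in [cross_validate()]; every element needs a
#'   `patient_id`.
#' @param n_test number of held-out patients.
#' @param feature_set selector name.
#' @param cfg an [rf_config()].
#' @param seed split seed.
#' @return list with `recall` (per-class %), `overall` (%), `test_patients`.
#' @export
patient_holdout <- function(datasets, n_test = 7, feature_set = "ALL",
                            cfg = rf_config(), seed = 1L) {
  pats <- vapply(datasets, function(d) as.character(d$patient_id), "")
  ups <- unique(pats)
  if (n_test >= length(ups)) stop("n_test must leave at least one training patient")
  set.seed(seed)
  test_p <- sample(ups, n_test)
  cols <- feature_set_columns(feature_set)
  tr <- which(!pats %in% test_p); te <- which(pats %in% test_p)
  tr_x <- do.call(rbind, lapply(datasets[tr], function(d)
    as.data.frame(d$stack)[, cols, drop = FALSE]))
  tr_y <- unlist(lapply(datasets[tr], function(d) d$labels))
  model <- suppressMessages(train_rf(tr_x, tr_y, cfg, features = cols))
  te_x <- do.call(rbind, lapply(datasets[te], function(d)
    as.data.frame(d$stack)[, cols, drop = FALSE]))
  te_y <- unlist(lapply(datasets[te], function(d) d$labels))
  pred <- as.integer(as.character(predict(model$forest, newdata = te_x)))
  rec <- vapply(1:3, function(cl) {
    n_cl <- sum(te_y == cl)
    if (n_cl == 0) NA_real_ else 100 * sum(pred == cl & te_y == cl) / n_cl
  }, 0)
  list(recall = setNames(rec, c("fibrous", "calcified", "lipid")),
       overall = 100 * mean(pred == te_y), test_patients = test_p)
}

#' Intraclass correlation (two-way random, absolute agreement, single)
#'
#' ICC(A,1) for paired measurements (e.g. annotated areas, mm^2, from two
#' readers), with the F-based 95% confidence interval from the two-way
#' ANOVA mean squares.
#'
#' @param areas_1,areas_2 paired numeric vectors (>= 3 pairs).
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci` (length 2), `ms` (mean squares).
#' @export
icc_agreement <- function(areas_1, areas_2, conf = 0.95) {
  n <- length(areas_1)
  if (length(areas_2) != n) stop("paired vectors must have equal length")
  if (n < 3) stop("at least 3 pairs are required")
  y <- cbind(areas_1, areas_2)
  k <- 2
  grand <- mean(y)
  rmean <- rowMeans(y); cmean <- colMeans(y)
  MSR <- k * sum((rmean - grand)^2) / (n - 1)
  MSC <- n * sum((cmean - grand)^2) / (k - 1)
  SSE <- sum((y - outer(rmean, rep(1, k)) -
                outer(rep(1, n), cmean) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  icc <- if (abs(denom) < 1e-300) 1 else (MSR - MSE) / denom
  alpha <- 1 - conf
  if (MSE < 1e-300 && MSC < 1e-300) {
    ci <- c(1, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lb <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    ub <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lb, ub)
  }
  list(icc = icc, ci = ci, ms = c(MSR = MSR, MSC = MSC, MSE = MSE))
}

#' Bland-Altman agreement
#'
#' Bias (mean difference) and 95% limits of agreement
#' `bias +- 1.96 * SD(differences)` for paired measurements.
#'
#' @param areas_1,areas_2 paired numeric vectors (>= 2 pairs).
#' @return list with `bias`, `loa` (lower, upper), `sd_diff`.
#' @export
bland_altman <- function(areas_1, areas_2) {
  if (length(areas_1) != length(areas_2))
    stop("paired vectors must have equal length")
  if (length(areas_1) < 2) stop("at least 2 pairs are required")
  d <- areas_2 - areas_1
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       sd_diff = s)
}

#' Regression agreement between two readers
#'
#' Ordinary least squares of reader 2 on reader 1: slope, intercept and R^2.
#'
#' @param areas_1,areas_2 paired numeric vectors (>= 3 pairs).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
regression_agreement <- function(areas_1, areas_2) {
  if (length(areas_1) != length(areas_2))
    stop("paired vectors must have equal length")
  if (length(areas_1) < 3) stop("at least 3 pairs are required")
  if (var(areas_1) < 1e-300) stop("zero variance in predictor")
  fit <- lm(areas_2 ~ areas_1)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((areas_2 - mean(areas_2))^2)
  r2 <- if (ss_tot < 1e-300) 1 else 1 - ss_res / ss_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}
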