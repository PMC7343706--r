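#' Random-forest configuration
#'
#' The two ensemble knobs are the number of trees (`n_tree`) and the number
#' of features sampled at each split (`m_try`).  Defaults: 100 trees and
#' `floor(sqrt(25)) = 5` candidate features.  `class_weighting = "balanced"`
#' draws stratified bootstrap samples of equal size per class, which guards
#' the rare calcified class against being swamped.
#'
#' @param n_tree number of trees (> 0).
#' @param m_try features sampled per node (1..25).
#' @param seed RNG seed controlling the ensemble's randomness.
#' @param class_weighting `"balanced"` or `"none"`.
#' @return object of class `rf_config`.
#' @export
rf_config <- function(n_tree = 100, m_try = 5, seed = 1L,
                      class_weighting = c("balanced", "none")) {
  if (n_tree < 1) stop("n_tree must be > 0")
  if (m_try < 1 || m_try > 25) stop("m_try must be in [1, 25]")
  class_weighting <- match.arg(class_weighting)
  structure(list(n_tree = as.integer(n_tree), m_try = as.integer(m_try),
                 seed = as.integer(seed), class_weighting = class_weighting),
            class = "rf_config")
}

stack_feature_columns <- function(stack) {
  intersect(FEATURE_NAMES, names(stack))
}

#' Train the tissue classifier
#'
#' Fits a random forest on the feature stack.  Deterministic given the
#' config seed; the fitted model carries a feature-name manifest and
#' prediction refuses stacks whose columns do not match it exactly.
#'
#' @param stack a [build_feature_stack()] result (or data.frame with feature
#'   columns), optionally restricted to a feature subset.
#' @param labels integer vector of tissue labels (1..3), one per stack row.
#' @param cfg an [rf_config()].
#' @param features character vector of feature columns to use; default all
#'   feature columns present in `stack`.
#' @return object of class `rf_model` with fields `forest`, `features`,
#'   `config`, `oob_accuracy`.
#' @export
train_rf <- function(stack, labels, cfg = rf_config(),
                     features = stack_feature_columns(stack)) {
  stopifnot(inherits(cfg, "rf_config"))
  if (nrow(stack) != length(labels))
    stop("feature/label length mismatch: ", nrow(stack), " rows vs ",
         length(labels), " labels")
  x <- as.data.frame(stack)[, features, drop = FALSE]
  if (anyNA(x)) stop("feature stack contains absent values")
  y <- factor(labels, levels = sort(unique(labels)))
  if (nlevels(y) < 2) stop("at least 2 classes are required for training")
  m_try <- min(cfg$m_try, ncol(x))
  set.seed(cfg$seed)
  if (cfg$class_weighting == "balanced") {
    ssize <- rep(min(table(y)), nlevels(y))
    forest <- randomForest::randomForest(
      x = x, y = y, ntree = cfg$n_tree, mtry = m_try,
      strata = y, sampsize = ssize)
  } else {
    forest <- randomForest::randomForest(
      x = x, y = y, ntree = cfg$n_tree, mtry = m_try)
  }
  oob <- 1 - forest$err.rate[cfg$n_tree, "OOB"]
  message(sprintf("random forest: %d trees, mtry %d, OOB accuracy %.3f",
                  cfg$n_tree, m_try, oob))
  structure(list(forest = forest, features = features, config = cfg,
                 oob_accuracy = unname(oob)),
            class = "rf_model")
}

#' Predict a pixel-wise tissue map
#'
#' Applies the trained forest to every stack row and rasterizes the result:
#' per-pixel class probabilities (tree-vote fractions, summing to 1) and the
#' argmax label, ties broken by the fixed class order fibrous < calcified <
#' lipid.  Pixels outside the stack's ROI stay background (0).
#'
#' @param model an [rf_model][train_rf()].
#' @param stack feature stack covering the ROI pixels (columns must match
#'   the model's manifest).
#' @param dim integer `c(n_alines, n_depth)` of the output raster.
#' @return list with `map` (a [tissue_label_map()]) and `prob` (3-slice
#'   array `[n_alines, n_depth, class]`, NA outside the ROI).
#' @export
predict_tissue_map <- function(model, stack, dim) {
  stopifnot(inherits(model, "rf_model"))
  have <- stack_feature_columns(stack)
  missing_f <- setdiff(model$features, have)
  if (length(missing_f))
    stop("feature manifest mismatch; missing: ",
         paste(missing_f, collapse = ", "))
  x <- as.data.frame(stack)[, model$features, drop = FALSE]
  pv <- predict(model$forest, newdata = x, type = "prob")
  prob3 <- matrix(0, nrow(x), 3, dimnames = list(NULL, c("1", "2", "3")))
  prob3[, colnames(pv)] <- pv
  pred <- max.col(prob3, ties.method = "first")   # fibrous < calcified < lipid
  lab <- matrix(0L, dim[1], dim[2])
  lab[cbind(stack$row + 1L, stack$col + 1L)] <- pred
  prob <- array(NA_real_, dim = c(dim[1], dim[2], 3))
  for (k in 1:3) {
    pl <- matrix(NA_real_, dim[1], dim[2])
    pl[cbind(stack$row + 1L, stack$col + 1L)] <- prob3[, k]
    prob[, , k] <- pl
  }
  list(map = tissue_label_map(lab), prob = prob)
}
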