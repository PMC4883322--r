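# Hierarchical two-stage SVM: stage 1 separates aggressive from normal
# episodes (polynomial kernel), stage 2 separates knocking from chasing
# (RBF kernel). Kernels, hierarchy, stratified cross-validation and metrics
# live here; the quadratic-program solver is delegated to libsvm via e1071,
# treated as an interchangeable component behind this surface.

#' @importFrom e1071 svm
NULL

FEATURE_COLS <- c("v_min", "v_max", "v_mean", "v_std", "dist")

#' Kernel specification
#'
#' @param kind `"polynomial"` or `"rbf"`.
#' @param C Soft-margin trade-off constant (> 0).
#' @param gamma RBF width (> 0; rbf only): K(x, y) = exp(-gamma * ||x - y||^2).
#' @param degree Polynomial degree (>= 1).
#' @param coef0 Polynomial constant: K(x, y) = (x . y + coef0)^degree.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("polynomial", "rbf"), C = 4.5, gamma = 3.5,
                        degree = 3, coef0 = 1) {
  kind <- match.arg(kind)
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  if (kind == "rbf" && gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (degree < 1) stop("degree must be >= 1", call. = FALSE)
  structure(list(kind = kind, C = C, gamma = gamma, degree = degree,
                 coef0 = coef0), class = "kernel_spec")
}

#' Evaluate a kernel on two feature vectors
#'
#' @param spec A [kernel_spec].
#' @param x,y Numeric vectors of equal length.
#' @return Scalar kernel value: `exp(-gamma * ||x-y||^2)` for rbf,
#'   `(x . y + coef0)^degree` for polynomial.
#' @export
kernel_eval <- function(spec, x, y) {
  if (length(x) != length(y))
    stop("x and y must have the same dimension", call. = FALSE)
  switch(spec$kind,
         rbf = exp(-spec$gamma * sum((x - y)^2)),
         polynomial = (sum(x * y) + spec$coef0)^spec$degree)
}

#' Train a binary SVM on standardized features
#'
#' Features are z-scored with the training-set mean and standard deviation
#' (stored in the model and re-applied at prediction time); the soft-margin
#' problem is then solved by libsvm with the requested kernel. Constant
#' features are left unscaled (divisor 1) rather than producing NaNs.
#'
#' @param x Numeric matrix or data frame of features (rows = episodes).
#' @param y Two-level factor (or vector coercible to one) of labels; the
#'   level order is preserved in predictions.
#' @param spec A [kernel_spec].
#' @return An `svm_model` carrying the fitted decision surface, the kernel
#'   spec and the standardization parameters.
#' @export
train_svm <- function(x, y, spec) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  xs <- scale(x, center = mu, scale = sd_)
  fit <- e1071::svm(
    xs, y, scale = FALSE, type = "C-classification",
    kernel = if (spec$kind == "rbf") "radial" else "polynomial",
    cost = spec$C,
    gamma = if (spec$kind == "rbf") spec$gamma else 1,
    degree = spec$degree, coef0 = spec$coef0)
  structure(list(fit = fit, spec = spec, center = mu, scale = sd_,
                 levels = levels(y)),
            class = "svm_model")
}

#' Predict with a trained SVM
#'
#' @param object An `svm_model` from [train_svm].
#' @param newdata Matrix or data frame of raw (unstandardized) features.
#' @param ... Unused.
#' @return Factor of predicted labels with the training level order.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), center = object$center,
              scale = object$scale)
  p <- stats::predict(object$fit, xs)
  factor(as.character(p), levels = object$levels)
}

#' Hierarchical episode classification
#'
#' Stage 1 decides aggressive versus normal; only episodes ruled aggressive
#' reach stage 2, which decides knocking versus chasing. Normal episodes
#' short-circuit and never see stage 2.
#'
#' @param stage1 `svm_model` with levels `c("normal", "aggressive")`.
#' @param stage2 `svm_model` with levels `c("knocking", "chasing")`.
#' @param x Matrix or data frame of raw feature rows.
#' @return Factor with levels `normal`, `knocking`, `chasing`.
#' @export
predict_hierarchical <- function(stage1, stage2, x) {
  x <- as.matrix(x)
  out <- rep("normal", nrow(x))
  s1 <- predict(stage1, x)
  agg <- s1 == "aggressive"
  if (any(agg)) out[agg] <- as.character(predict(stage2, x[agg, , drop = FALSE]))
  factor(out, levels = c("normal", "knocking", "chasing"))
}

#' Train both stages of the hierarchical classifier
#'
#' Fits the detection SVM (aggressive vs normal) on all episodes and the
#' classification SVM (knocking vs chasing) on the aggressive episodes.
#'
#' @param dataset Feature table with a `label` column in
#'   `{normal, knocking, chasing}`.
#' @param stage1_spec,stage2_spec [kernel_spec]s; defaults are the
#'   polynomial detection kernel (C = 4.5) and the RBF classification
#'   kernel (C = 4.5, gamma = 3.5).
#' @return List with `stage1` and `stage2` [train_svm] models, ready for
#'   [predict_hierarchical].
#' @export
train_hierarchical <- function(dataset,
                               stage1_spec = kernel_spec("polynomial",
                                                         C = 4.5),
                               stage2_spec = kernel_spec("rbf", C = 4.5,
                                                         gamma = 3.5)) {
  x <- as.matrix(dataset[, FEATURE_COLS])
  y1 <- factor(ifelse(dataset$label == "normal", "normal", "aggressive"),
               levels = c("normal", "aggressive"))
  agg <- dataset$label %in% c("knocking", "chasing")
  y2 <- factor(dataset$label[agg], levels = c("knocking", "chasing"))
  list(stage1 = train_svm(x, y1, stage1_spec),
       stage2 = train_svm(x[agg, , drop = FALSE], y2, stage2_spec))
}

# Stratified fold ids; deterministic in (labels, k, seed) and independent of
# the caller's RNG state.
stratified_folds <- function(y, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Stratified k-fold cross-validation of one classifier stage
#'
#' Stage 1 poses aggressive-versus-normal detection on the full dataset
#' (knocking and chasing collapse into "aggressive"); stage 2 poses
#' knocking-versus-chasing classification on the aggressive episodes only.
#' Folds are stratified by class from a fixed seed; standardization is
#' fitted on each training fold inside [train_svm], so no information leaks
#' from held-out episodes. Out-of-fold predictions are pooled into one
#' confusion matrix from which the metrics are computed. A class with fewer
#' members than `k` triggers a fall back to leave-one-out with a warning.
#'
#' @param dataset Feature table from [features_to_table] with a `label`
#'   column in `{normal, knocking, chasing}`.
#' @param stage 1 (detection) or 2 (classification).
#' @param spec A [kernel_spec] for the stage.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold construction.
#' @return For stage 1 a `detection_metrics` object, for stage 2 a
#'   `class_metrics` object; both carry the pooled confusion matrix in
#'   `$confusion`.
#' @export
cross_validate <- function(dataset, stage = 1, spec, k = 10, seed = 1) {
  stopifnot(stage %in% c(1, 2))
  if (stage == 1) {
    y <- factor(ifelse(dataset$label == "normal", "normal", "aggressive"),
                levels = c("normal", "aggressive"))
    x <- as.matrix(dataset[, FEATURE_COLS])
  } else {
    keep <- dataset$label %in% c("knocking", "chasing")
    y <- factor(dataset$label[keep], levels = c("knocking", "chasing"))
    x <- as.matrix(dataset[keep, FEATURE_COLS])
  }
  if (min(table(y)) < k) {
    warning("a class has fewer than k members; using leave-one-out")
    k <- length(y)
    folds <- seq_len(k)
  } else folds <- stratified_folds(y, k, seed)

  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    model <- train_svm(x[!te, , drop = FALSE], y[!te], spec)
    pred[te] <- predict(model, x[te, , drop = FALSE])
  }
  confusion <- table(truth = y, predicted = pred)
  if (stage == 1) {
    m <- detection_metrics(TP = confusion["aggressive", "aggressive"],
                           FP = confusion["normal", "aggressive"],
                           TN = confusion["normal", "normal"],
                           FN = confusion["aggressive", "normal"])
  } else {
    m <- classification_metrics(confusion)
  }
  m$confusion <- confusion
  m
}
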