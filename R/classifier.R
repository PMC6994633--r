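#' Train an SVM to identify HSCs from MOB profiles
#'
#' Fits a binary support vector machine on the (standardized) MOB features,
#' with the RBF kernel by default and hyperparameters chosen by grid search
#' under stratified k-fold cross-validation. Class weights are balanced by
#' inverse class frequency (stem-cell labels are typically rare). A Platt
#' probability map P(HSC | x) = logistic(A * f(x) + B) is fitted by logistic
#' regression on held-out-fold decision values, so the calibration never sees
#' its own training decisions. All randomness is controlled by `seed` and
#' recorded in the model metadata.
#'
#' The trained model is self-contained (support vectors, kernel, Platt
#' coefficients, standardization record) and serializes losslessly to JSON
#' with [write_classifier_model()].
#'
#' @param records MOB table with a label column.
#' @param label_col Name of the label column (default `"population"`).
#' @param positive Label of the positive (HSC) class.
#' @param features Feature subset (see [mob_features()]).
#' @param cost_grid Candidate soft-margin costs C.
#' @param gamma_scale Candidate RBF widths as multiples of the 1/p heuristic
#'   (features are standardized, so unit variance is assumed).
#' @param folds Cross-validation folds (reduced with a recorded warning when
#'   a class is too small).
#' @param kernel `"radial"` or `"linear"`.
#' @param threshold Probability threshold for the predicted label.
#' @param impute Missing-value policy for [build_feature_matrix()].
#' @param seed Integer seed for fold assignment.
#' @return List of class `classifier_model`.
#' @export
train_svm <- function(records, label_col = "population", positive = "HSC",
                      features = mob_features("all"),
                      cost_grid = c(0.1, 1, 10),
                      gamma_scale = c(0.5, 1, 2),
                      folds = 5L, kernel = c("radial", "linear"),
                      threshold = 0.5, impute = "drop", seed = 1L) {
  kernel <- match.arg(kernel)
  if (!label_col %in% names(records)) stop("no label column ", label_col)
  fm <- build_feature_matrix(records, features = features, impute = impute)
  labs <- as.character(records[[label_col]])[match(fm$cell_id, records$cell_id)]
  y <- labs == positive
  if (all(y) || !any(y)) stop("training data must contain both classes")
  x <- fm$x
  n <- nrow(x)
  p <- ncol(x)
  gamma_grid <- if (kernel == "radial") gamma_scale / p else 0
  cw <- c(n / (2 * sum(y)), n / (2 * sum(!y)))
  names(cw) <- c("TRUE", "FALSE")
  yf <- factor(y, levels = c("TRUE", "FALSE"))

  k <- as.integer(folds)
  min_class <- min(sum(y), sum(!y))
  warn <- character(0)
  if (min_class < k) {
    k <- max(2L, min_class)
    warn <- sprintf("folds reduced to %d (smallest class has %d members)", k, min_class)
  }
  fold_id <- with_seed(seed, stratified_folds(y, k))

  fit_one <- function(xtr, ytr, cost, gamma) {
    e1071::svm(xtr, ytr, kernel = kernel, cost = cost,
               gamma = if (kernel == "radial") gamma else 1 / p,
               scale = FALSE, class.weights = cw, probability = FALSE)
  }
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  cv_acc <- numeric(nrow(grid))
  cv_dec <- matrix(NA_real_, n, nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold_id != f
      te <- !tr
      m <- fit_one(x[tr, , drop = FALSE], yf[tr], grid$cost[gi], grid$gamma[gi])
      dv <- svm_decision(m, x[te, , drop = FALSE])
      # orient decision values so larger means more positive-class
      sgn <- svm_orientation(m, x[tr, , drop = FALSE], yf[tr])
      dv <- sgn * dv
      cv_dec[te, gi] <- dv
      correct <- correct + sum((dv >= 0) == y[te])
    }
    cv_acc[gi] <- correct / n
  }
  best <- which.max(cv_acc)  # ties resolve to smallest cost then gamma by grid order
  model_svm <- fit_one(x, yf, grid$cost[best], grid$gamma[best])
  sgn <- svm_orientation(model_svm, x, yf)
  platt <- fit_platt(cv_dec[, best], y)

  structure(list(
    features = fm$features, center = fm$center, scale = fm$scale,
    impute = fm$impute,
    kernel = kernel, cost = grid$cost[best],
    gamma = if (kernel == "radial") grid$gamma[best] else 1 / p,
    sv = unname(model_svm$SV), coefs = as.numeric(model_svm$coefs),
    rho = model_svm$rho, sign = sgn,
    platt_a = platt[1], platt_b = platt[2],
    threshold = threshold, positive = positive,
    negative_label = paste0("non-", positive),
    metadata = list(seed = as.integer(seed), folds = k,
                    cost_grid = cost_grid, gamma_grid = gamma_grid,
                    cv_accuracy = stats::setNames(cv_acc, paste0(
                      "C", grid$cost, "_g", signif(grid$gamma, 3))),
                    best_cv_accuracy = cv_acc[best],
                    class_weights = as.list(cw),
                    n_train = n, warnings = warn)
  ), class = "classifier_model")
}

# Stratified fold assignment: shuffles each class and deals folds round-robin.
stratified_folds <- function(y, k) {
  id <- integer(length(y))
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep_len(seq_len(k), length(idx))
  }
  id
}

# Raw libsvm decision values recomputed from the stored support vectors, so
# prediction does not depend on keeping the e1071 object around.
svm_decision_raw <- function(sv, coefs, rho, gamma, kernel, x) {
  x <- as.matrix(x)
  if (kernel == "radial") {
    d2 <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * tcrossprod(x, sv)
    kmat <- exp(-gamma * pmax(d2, 0))
  } else {
    kmat <- tcrossprod(x, sv)
  }
  drop(kmat %*% coefs) - rho
}

svm_decision <- function(m, x) {
  svm_decision_raw(unname(m$SV), as.numeric(m$coefs), m$rho,
                   m$gamma, if (m$kernel == 2) "radial" else "linear", x)
}

# libsvm's internal label order decides the sign of the decision value;
# determine empirically which sign points toward the positive class.
svm_orientation <- function(m, xtr, ytr) {
  dv <- svm_decision(m, xtr)
  pos <- ytr == "TRUE"
  if (mean(dv[pos]) >= mean(dv[!pos])) 1 else -1
}

# Platt scaling by logistic regression of the class on out-of-fold decision
# values; degenerate (perfectly separated) fits fall back to a steep but
# finite sigmoid.
fit_platt <- function(dec, y) {
  ok <- is.finite(dec)
  fit <- suppressWarnings(stats::glm(y[ok] ~ dec[ok], family = stats::binomial()))
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(a) || !is.finite(b) || a <= 0) {
    scale <- stats::sd(dec[ok])
    if (!is.finite(scale) || scale == 0) scale <- 1
    a <- 10 / scale
    b <- -a * mean(dec[ok])
  }
  c(a, b)
}

#' Predict HSC identity and probability for MOB records
#'
#' Standardizes the records with the model's training statistics, evaluates
#' the SVM decision function from the stored support vectors, and maps it to
#' a probability through the model's Platt sigmoid. The predicted label is
#' positive when the probability reaches the threshold.
#'
#' @param model A `classifier_model`.
#' @param records MOB table containing the model's features.
#' @param threshold Probability threshold override.
#' @return `data.frame` with `cell_id`, `decision_value`, `probability`,
#'   `predicted` (e.g. "HSC" / "non-HSC") and `predicted_positive`.
#' @export
predict_hsc <- function(model, records, threshold = NULL) {
  stopifnot(inherits(model, "classifier_model"))
  thr <- threshold %||% model$threshold
  x <- standardize_records(records, model$features, model$center, model$scale)
  if (anyNA(x)) {
    if (model$impute == "median") {
      for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- 0  # training median = 0 after z-scoring
    } else {
      bad <- colnames(x)[colSums(is.na(x)) > 0]
      stop("missing feature value(s) in: ", paste(bad, collapse = ", "))
    }
  }
  dv <- model$sign * svm_decision_raw(model$sv, model$coefs, model$rho,
                                      model$gamma, model$kernel, x)
  prob <- stats::plogis(model$platt_a * dv + model$platt_b)
  data.frame(
    cell_id = records$cell_id,
    decision_value = dv,
    probability = prob,
    predicted = ifelse(prob >= thr, model$positive, model$negative_label),
    predicted_positive = prob >= thr
  )
}

#' Evaluate predictions against a reporter ground truth
#'
#' Confusion counts with the reporter-based definitions: sensitivity (true
#' positive rate) is the fraction of reporter-positive cells predicted
#' positive; specificity (true negative rate) is the fraction of
#' reporter-negative cells predicted negative. With replicate ids, per-
#' replicate values plus their mean and standard deviation are reported.
#'
#' @param predicted_positive Logical vector of predicted labels.
#' @param reporter_positive Logical vector of ground-truth labels (e.g.
#'   Hoxb5-mCherry positivity).
#' @param replicate Optional replicate/experiment id per cell.
#' @return List of class `evaluation_report`: `confusion` (TP, FN, TN, FP),
#'   `sensitivity`, `specificity`, and optionally `per_replicate`,
#'   `sensitivity_mean`, `sensitivity_sd`, `specificity_mean`,
#'   `specificity_sd`.
#' @export
evaluate_against_reporter <- function(predicted_positive, reporter_positive,
                                      replicate = NULL) {
  if (length(predicted_positive) != length(reporter_positive)) {
    stop("prediction and truth lengths differ")
  }
  pp <- as.logical(predicted_positive)
  tp_ <- as.logical(reporter_positive)
  one <- function(p, t) {
    tp <- sum(p & t); fn <- sum(!p & t); tn <- sum(!p & !t); fp <- sum(p & !t)
    list(confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }
  out <- one(pp, tp_)
  if (!is.null(replicate)) {
    reps <- unique(replicate)
    per <- do.call(rbind, lapply(reps, function(r) {
      sel <- replicate == r
      o <- one(pp[sel], tp_[sel])
      data.frame(replicate = r, n = sum(sel),
                 sensitivity = o$sensitivity, specificity = o$specificity)
    }))
    out$per_replicate <- per
    out$sensitivity_mean <- mean(per$sensitivity, na.rm = TRUE)
    out$sensitivity_sd <- stats::sd(per$sensitivity[!is.na(per$sensitivity)])
    out$specificity_mean <- mean(per$specificity, na.rm = TRUE)
    out$specificity_sd <- stats::sd(per$specificity[!is.na(per$specificity)])
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("sensitivity %.3f, specificity %.3f (TP %d FN %d TN %d FP %d)\n",
              x$sensitivity, x$specificity,
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  invisible(x)
}

#' Serialize / deserialize a classifier model as JSON
#'
#' The JSON envelope holds metadata, the standardization record, the Platt
#' coefficients and the support-vector arrays at full numeric precision, so
#' save -> load -> predict reproduces predictions bit-identically.
#'
#' @param model A `classifier_model`.
#' @param path Output / input JSON path.
#' @return `read_classifier_model` returns the model; `write_classifier_model`
#'   returns `path` invisibly.
#' @export
write_classifier_model <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  obj <- unclass(model)
  obj$sv <- list(values = as.numeric(model$sv), dim = dim(model$sv))
  obj$format <- "mobflim-classifier/1"
  obj$package_version <- as.character(utils::packageVersion("mobflim"))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_classifier_model
#' @export
read_classifier_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mobflim-classifier/1")) {
    stop("not a mobflim classifier model file: ", path)
  }
  named <- function(v) stats::setNames(as.numeric(v), obj$features)
  structure(list(
    features = obj$features, center = named(obj$center),
    scale = named(obj$scale), impute = obj$impute,
    kernel = obj$kernel, cost = obj$cost, gamma = obj$gamma,
    sv = matrix(obj$sv$values, obj$sv$dim[1], obj$sv$dim[2]),
    coefs = as.numeric(obj$coefs), rho = obj$rho, sign = obj$sign,
    platt_a = obj$platt_a, platt_b = obj$platt_b,
    threshold = obj$threshold, positive = obj$positive,
    negative_label = obj$negative_label,
    metadata = obj$metadata
  ), class = "classifier_model")
}
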