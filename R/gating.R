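#' Canonical MOB feature names
#'
#' The five metabolic optical biomarkers in their fixed order, plus the
#' mapping onto MOB-table column names.
#'
#' @param subset `"all"` for the five MOBs or `"single3"` for the three
#'   single-cell parameters (orr, alpha_bound, tau_bound), or a character
#'   vector of feature names.
#' @return Character vector of feature names.
#' @export
mob_features <- function(subset = "all") {
  all5 <- c("orr", "alpha_bound", "tau_bound", "edge_center_ratio", "polarity")
  if (identical(subset, "all")) return(all5)
  if (identical(subset, "single3")) return(all5[1:3])
  bad <- setdiff(subset, all5)
  if (length(bad)) stop("unknown MOB features: ", paste(bad, collapse = ", "))
  all5[all5 %in% subset]
}

feature_column <- function(feature) {
  ifelse(feature == "tau_bound", "tau_bound_ns", feature)
}

#' Build a standardized feature matrix from MOB records
#'
#' Selects the requested MOB columns, applies the missing-value policy
#' (tau_bound can be missing for nearly pure-free cells), and z-scores each
#' column. The standardization record is kept so gates and classifiers can
#' be applied to new data on the training scale.
#'
#' @param records MOB table (see [extract_mob_table()]).
#' @param features Feature subset (see [mob_features()]).
#' @param impute `"drop"` removes rows with missing values; `"median"`
#'   replaces them with the column median.
#' @return A `feature_matrix`: list with `x` (standardized matrix), `center`,
#'   `scale`, `cell_id`, `population`, `features`, `impute`.
#' @export
build_feature_matrix <- function(records, features = mob_features("all"),
                                 impute = c("drop", "median")) {
  impute <- match.arg(impute)
  features <- mob_features(features)
  cols <- feature_column(features)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("records lack feature columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(records[, cols, drop = FALSE])
  colnames(x) <- features
  keep <- rep(TRUE, nrow(x))
  if (impute == "drop") {
    keep <- stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
  } else {
    for (j in seq_len(ncol(x))) {
      mj <- is.na(x[, j])
      if (any(mj)) x[mj, j] <- stats::median(x[, j], na.rm = TRUE)
    }
  }
  if (nrow(x) < 2L) stop("need at least 2 cells after the missing-value policy")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    stop("constant feature column(s): ", paste(features[zero], collapse = ", "))
  }
  structure(list(
    x = sweep(sweep(x, 2, ctr), 2, scl, "/"),
    center = ctr, scale = scl,
    cell_id = records$cell_id[keep],
    population = if ("population" %in% names(records)) {
      as.character(records$population[keep])
    } else rep(NA_character_, sum(keep)),
    features = features, impute = impute
  ), class = "feature_matrix")
}

# Standardize new records with a stored record (center/scale, feature order).
standardize_records <- function(records, features, center, scale) {
  cols <- feature_column(features)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("records lack feature columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(records[, cols, drop = FALSE])
  colnames(x) <- features
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Principal-component projection of a feature matrix
#'
#' PCA of the standardized features by singular value decomposition, keeping
#' `k` components. Loadings are sign-fixed (the largest-magnitude entry of
#' each loading is made positive) so projections are reproducible across
#' platforms. Explained-variance fractions are reported for all components.
#'
#' @param fm A `feature_matrix`, or a plain numeric matrix.
#' @param k Number of components to keep.
#' @return List of class `pca_model`: `scores` (n x k), `loadings` (p x k),
#'   `explained` (length-p variance fractions), `center`, `scale`,
#'   `features`.
#' @export
pca_project <- function(fm, k = 3L) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (k > ncol(x)) stop("k exceeds the number of features")
  if (nrow(x) < k) stop("need at least k rows")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- sweep(x, 2, pc$center) %*% load
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(k))
  ev <- pc$sdev^2
  structure(list(
    scores = scores,
    loadings = load,
    pca_center = pc$center,
    explained = ev / sum(ev),
    k = k,
    center = if (inherits(fm, "feature_matrix")) fm$center else NULL,
    scale = if (inherits(fm, "feature_matrix")) fm$scale else NULL,
    features = if (inherits(fm, "feature_matrix")) fm$features else colnames(x)
  ), class = "pca_model")
}

#' Fit an LDA planar gate in PC space
#'
#' Binary Fisher discriminant of the target population against the pooled
#' rest: the plane normal is `w proportional to Sigma_pooled^-1 (mu_target -
#' mu_rest)` (normalized to unit length) and the offset is placed at the
#' equal-priors decision threshold, the midpoint of the projected class
#' means. The positive side contains the target mean; points exactly on the
#' plane count as positive.
#'
#' @param scores Numeric matrix of coordinates (e.g. PCA scores).
#' @param is_target Logical vector: TRUE for the target population.
#' @param ridge Ridge added to the pooled covariance when it is numerically
#'   singular; recorded in the result.
#' @return List of class `lda_gate`: `w` (unit normal), `b` (offset),
#'   `mu_target`, `mu_rest`, `ridge_used`.
#' @export
fit_lda_gate <- function(scores, is_target, ridge = 1e-6) {
  scores <- as.matrix(scores)
  is_target <- as.logical(is_target)
  stopifnot(nrow(scores) == length(is_target))
  n1 <- sum(is_target)
  n0 <- sum(!is_target)
  if (n1 < 2L || n0 < 2L) stop("both classes need at least 2 members")
  x1 <- scores[is_target, , drop = FALSE]
  x0 <- scores[!is_target, , drop = FALSE]
  mu1 <- colMeans(x1)
  mu0 <- colMeans(x0)
  sw <- (crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x0, 2, mu0))) /
    (n1 + n0 - 2)
  ridge_used <- 0
  if (!is.finite(rcond_sym(sw)) || rcond_sym(sw) < 1e-10) {
    sw <- sw + diag(ridge, ncol(sw))
    ridge_used <- ridge
  }
  w <- solve(sw, mu1 - mu0)
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("identical class means: no discriminant direction")
  w <- w / nw
  b <- sum(w * (mu1 + mu0)) / 2
  structure(list(w = w, b = b, mu_target = mu1, mu_rest = mu0,
                 ridge_used = ridge_used), class = "lda_gate")
}

rcond_sym <- function(m) {
  ev <- tryCatch(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (anyNA(ev) || any(ev <= 0)) return(0)
  min(ev) / max(ev)
}

#' Full MOB gate model: standardization + PCA + LDA plane
#'
#' Composes [build_feature_matrix()], [pca_project()] and [fit_lda_gate()]
#' into a single serializable gate for a target population.
#'
#' @param records MOB table with a `population` column.
#' @param target Target population label.
#' @param features Feature subset (see [mob_features()]).
#' @param k Number of principal components.
#' @param impute Missing-value policy.
#' @return List of class `gate_model` bundling the standardization record,
#'   PCA loadings/explained variance and the LDA plane.
#' @export
fit_gate_model <- function(records, target, features = mob_features("all"),
                           k = 3L, impute = "drop") {
  fm <- build_feature_matrix(records, features = features, impute = impute)
  if (!any(fm$population == target)) stop("no cells of target population ", target)
  pca <- pca_project(fm, k = k)
  lda <- fit_lda_gate(pca$scores, fm$population == target)
  structure(list(
    target = target, features = fm$features, impute = fm$impute,
    center = fm$center, scale = fm$scale,
    pca_center = pca$pca_center, loadings = pca$loadings,
    explained = pca$explained, k = k,
    w = lda$w, b = lda$b, ridge_used = lda$ridge_used,
    mu_target = lda$mu_target, mu_rest = lda$mu_rest
  ), class = "gate_model")
}

#' Apply a planar gate to MOB records
#'
#' Standardizes the records with the gate's training statistics, projects
#' them onto its principal components, and reports each cell's signed
#' distance to the LDA plane and side (distance >= 0 is the target side),
#' plus the per-population fraction on the target side.
#'
#' @param model A `gate_model`.
#' @param records MOB table.
#' @return List with `cells` (cell_id, population, signed_distance,
#'   target_side) and `fractions` (per-population target-side fraction).
#' @export
apply_gate <- function(model, records) {
  stopifnot(inherits(model, "gate_model"))
  x <- standardize_records(records, model$features, model$center, model$scale)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  scores <- sweep(x, 2, model$pca_center) %*% model$loadings
  d <- drop(scores %*% model$w) - model$b
  pop <- if ("population" %in% names(records)) {
    as.character(records$population[keep])
  } else rep(NA_character_, sum(keep))
  cells <- data.frame(
    cell_id = records$cell_id[keep],
    population = pop,
    signed_distance = d,
    target_side = d >= 0
  )
  fr <- tapply(cells$target_side, cells$population, mean)
  fractions <- data.frame(population = names(fr),
                          fraction_target_side = as.numeric(fr))
  rownames(fractions) <- NULL
  list(cells = cells, fractions = fractions)
}

#' Per-population centroids in a feature space
#'
#' @param values Numeric matrix or data.frame of coordinates (cells x dims).
#' @param population Population label per row.
#' @return `data.frame`: one row per population with `n` and the mean of
#'   every coordinate.
#' @export
population_centroids <- function(values, population) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(population))
  pops <- unique(as.character(population))
  if (any(is.na(pops))) stop("missing population labels")
  rows <- lapply(pops, function(p) {
    sel <- population == p
    if (!any(sel)) stop("empty population ", p)
    cbind(data.frame(population = p, n = sum(sel)),
          as.data.frame(t(colMeans(values[sel, , drop = FALSE]))))
  })
  do.call(rbind, rows)
}

#' Serialize / deserialize a gate model as JSON
#'
#' @param model A `gate_model`.
#' @param path Output / input JSON path.
#' @return `read_gate_model` returns the `gate_model`; `write_gate_model`
#'   returns `path` invisibly.
#' @export
write_gate_model <- function(model, path) {
  stopifnot(inherits(model, "gate_model"))
  obj <- unclass(model)
  obj$loadings <- list(values = as.numeric(model$loadings),
                       dim = dim(model$loadings),
                       dimnames = dimnames(model$loadings))
  obj$format <- "mobflim-gate/1"
  obj$package_version <- as.character(utils::packageVersion("mobflim"))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_gate_model
#' @export
read_gate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mobflim-gate/1")) {
    stop("not a mobflim gate model file: ", path)
  }
  load <- matrix(obj$loadings$values, obj$loadings$dim[1], obj$loadings$dim[2],
                 dimnames = obj$loadings$dimnames)
  named <- function(v, nm = obj$features) stats::setNames(as.numeric(v), nm)
  structure(list(
    target = obj$target, features = obj$features, impute = obj$impute,
    center = named(obj$center), scale = named(obj$scale),
    pca_center = named(obj$pca_center), loadings = load,
    explained = as.numeric(obj$explained), k = obj$k,
    w = stats::setNames(as.numeric(obj$w), colnames(load)),
    b = obj$b, ridge_used = obj$ridge_used,
    mu_target = stats::setNames(as.numeric(obj$mu_target), colnames(load)),
    mu_rest = stats::setNames(as.numeric(obj$mu_rest), colnames(load))
  ), class = "gate_model")
}
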