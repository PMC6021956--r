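#' Analytic Ledoit-Wolf shrinkage intensity
#'
#' Estimates the optimal intensity for shrinking an empirical covariance
#' toward the scaled identity `nu * I` (`nu = trace / D`):
#' `lambda = min(b2, d2) / d2`, where `d2` is the squared Frobenius
#' dispersion of the sample covariance around the target and `b2` the
#' estimated sampling variance of its entries. Clipped to `[0, 1]`.
#'
#' @param samples n x D matrix of (within-class centered) observations.
#' @param center subtract the column means first (default `TRUE`; pass
#'   `FALSE` when the rows are already centered).
#' @return list with `lambda` (in `[0, 1]`), `nu`, and `sigma` (the n-divisor
#'   empirical covariance).
#' @export
ledoit_wolf_lambda <- function(samples, center = TRUE) {
  X <- as.matrix(samples)
  n <- nrow(X); D <- ncol(X)
  if (n < 2)
    stop_hbci("need at least 2 samples to estimate shrinkage",
              "hbci_estimation_error")
  if (center) X <- X - rep(colMeans(X), each = n)
  S <- crossprod(X) / n
  nu <- sum(diag(S)) / D
  if (nu == 0) {
    warning("degenerate input: zero empirical covariance (nu = 0)")
    return(list(lambda = 1, nu = 0, sigma = S))
  }
  d2 <- sum((S - diag(nu, D))^2)
  if (d2 == 0) return(list(lambda = 1, nu = nu, sigma = S))
  b2 <- 0
  for (k in seq_len(n)) {
    xk <- X[k, ]
    b2 <- b2 + sum((tcrossprod(xk) - S)^2)
  }
  b2 <- min(b2 / n^2, d2)
  list(lambda = max(0, min(1, b2 / d2)), nu = nu, sigma = S)
}

#' Fit a shrinkage linear discriminant
#'
#' Binary LDA with the pooled within-class covariance replaced by the shrunk
#' estimate `(1 - lambda) Sigma + lambda nu I` (or `lambda I` with
#' `target = "identity"`, matching the unscaled-identity formulation);
#' `lambda` defaults to the analytic Ledoit-Wolf value. The weight vector is
#' `w = Sigma_shrunk^-1 (mu1 - mu2)` and the bias places the midpoint of the
#' class means on the decision boundary: positive decision values vote for
#' the first class of the pair; an exact 0 resolves to the second class.
#'
#' @param features a [feature_matrix()] (or plain matrix with `labels`).
#' @param class_pair ordered pair of labels; the first is the positive class.
#' @param lambda optional fixed shrinkage intensity in `[0, 1]`.
#' @param target `"scaled_identity"` (default) or `"identity"`.
#' @param labels required when `features` is a bare matrix.
#' @return an object of class `slda` with `w`, `b`, `lambda`, `nu`,
#'   `class_pair`, `feature_names`.
#' @export
fit_slda <- function(features, class_pair, lambda = NULL,
                     target = c("scaled_identity", "identity"),
                     labels = NULL) {
  target <- match.arg(target)
  if (inherits(features, "feature_matrix")) {
    X <- features$values
    labels <- features$labels
    fnames <- features$feature_names
  } else {
    X <- as.matrix(features)
    fnames <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  }
  stopifnot(length(class_pair) == 2, !is.null(labels))
  i1 <- which(labels == class_pair[1]); i2 <- which(labels == class_pair[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop_hbci(sprintf("need >= 2 trials of both '%s' and '%s'",
                      class_pair[1], class_pair[2]), "hbci_training_error")
  X <- X[c(i1, i2), , drop = FALSE]
  mu1 <- colMeans(X[seq_along(i1), , drop = FALSE])
  mu2 <- colMeans(X[length(i1) + seq_along(i2), , drop = FALSE])
  Xc <- rbind(sweep(X[seq_along(i1), , drop = FALSE], 2, mu1),
              sweep(X[length(i1) + seq_along(i2), , drop = FALSE], 2, mu2))
  lw <- ledoit_wolf_lambda(Xc, center = FALSE)
  if (is.null(lambda)) lambda <- lw$lambda
  assert_scalar_num(lambda, "lambda", lo = 0, hi = 1)
  D <- ncol(X)
  tgt <- if (target == "scaled_identity") lw$nu else 1
  sigma <- (1 - lambda) * lw$sigma + diag(lambda * tgt, D)
  w <- if (lw$nu == 0 && lambda == 1 && target == "scaled_identity") {
    # fully degenerate input: fall back to the mean-difference direction
    mu1 - mu2
  } else {
    solve(sigma, mu1 - mu2)
  }
  structure(list(w = as.numeric(w), b = sum(w * (mu1 + mu2)) / 2,
                 lambda = lambda, nu = lw$nu, target = target,
                 class_pair = class_pair, feature_names = fnames),
            class = "slda")
}

#' @export
print.slda <- function(x, ...) {
  cat(sprintf("<slda> %s vs %s: D = %d, lambda = %.4f, nu = %.4g (target %s)\n",
              x$class_pair[1], x$class_pair[2], length(x$w), x$lambda, x$nu,
              x$target))
  invisible(x)
}

#' @export
coef.slda <- function(object, ...) c(object$w, bias = object$b)

#' Predict from a shrinkage LDA
#'
#' @param object an [fit_slda()] model.
#' @param newdata a [feature_matrix()] or numeric matrix (trials x features).
#' @param ... unused.
#' @return data.frame with `decision` (continuous value `w . x - b`) and
#'   `label` (first class of the pair when positive, second otherwise;
#'   exact ties go to the second class).
#' @export
predict.slda <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$values
  else as.matrix(newdata)
  if (ncol(X) != length(object$w))
    stop_hbci("feature dimension does not match the model",
              "hbci_prediction_error")
  dec <- as.numeric(X %*% object$w) - object$b
  data.frame(decision = dec,
             label = ifelse(dec > 0, object$class_pair[1], object$class_pair[2]),
             stringsAsFactors = FALSE)
}

#' Fit a two-layer meta classifier
#'
#' First layer: one shrinkage LDA per modality. Second layer: a shrinkage LDA
#' over the base classifiers' continuous decision values. By default the
#' meta-training decision values are generated out-of-fold through a
#' stratified inner cross-validation so the second layer never sees
#' resubstitution outputs (`mode = "naive"` trains both layers on the same
#' trials instead). Base models are refit on all training trials for
#' deployment.
#'
#' @param train_features named list of [feature_matrix()]s (e.g. `EEG`,
#'   `HbR`, `HbO`), aligned on the same trials.
#' @param class_pair ordered pair of labels.
#' @param combination names of the modalities to fuse (default: all of
#'   `train_features`).
#' @param inner_folds stratified inner folds for the out-of-fold decision
#'   values (reduced with a warning if a class has fewer trials).
#' @param mode `"cv"` (default) or `"naive"`.
#' @param target shrinkage target, passed to [fit_slda()].
#' @return an object of class `meta_slda`.
#' @export
fit_meta <- function(train_features, class_pair,
                     combination = names(train_features), inner_folds = 5,
                     mode = c("cv", "naive"),
                     target = "scaled_identity") {
  mode <- match.arg(mode)
  stopifnot(length(combination) >= 1,
            all(combination %in% names(train_features)))
  fms <- train_features[combination]
  labels <- fms[[1]]$labels
  for (f in fms) stopifnot(identical(f$labels, labels))
  keep <- which(labels %in% class_pair)
  fms <- lapply(fms, subset_features, idx = keep)
  labels <- labels[keep]
  n_min <- min(table(labels))
  k <- inner_folds
  if (n_min < k) {
    warning(sprintf("reducing inner folds from %d to %d (smallest class)",
                    k, n_min))
    k <- max(2L, n_min)
  }
  dec <- matrix(NA_real_, length(labels), length(fms),
                dimnames = list(NULL, combination))
  if (mode == "cv") {
    # deterministic stratified assignment: within each class, trials are
    # dealt round-robin into the k folds, so a fitted meta model is a pure
    # function of its training data
    fold <- integer(length(labels))
    for (cl in class_pair) {
      idx <- which(labels == cl)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    for (f in seq_len(k)) {
      tr <- which(fold != f); te <- which(fold == f)
      for (m in combination) {
        base <- fit_slda(subset_features(fms[[m]], tr), class_pair,
                         target = target)
        dec[te, m] <- predict(base, subset_features(fms[[m]], te))$decision
      }
    }
  } else {
    for (m in combination) {
      base <- fit_slda(fms[[m]], class_pair, target = target)
      dec[, m] <- predict(base, fms[[m]])$decision
    }
  }
  meta <- fit_slda(dec, class_pair, labels = labels, target = target)
  base_models <- lapply(combination, function(m)
    fit_slda(fms[[m]], class_pair, target = target))
  names(base_models) <- combination
  structure(list(base = base_models, meta = meta, combination = combination,
                 class_pair = class_pair, inner_folds = k, mode = mode),
            class = "meta_slda")
}

#' @export
print.meta_slda <- function(x, ...) {
  cat(sprintf("<meta_slda> %s vs %s over {%s}, %s meta outputs (%d inner folds)\n",
              x$class_pair[1], x$class_pair[2],
              paste(x$combination, collapse = ", "), x$mode, x$inner_folds))
  invisible(x)
}

#' Predict from a two-layer meta classifier
#'
#' @param object a [fit_meta()] model.
#' @param test_features named list of [feature_matrix()]s containing at least
#'   the modalities of the model's combination, aligned on the same trials.
#' @param ... unused.
#' @return data.frame with `decision` and `label`.
#' @export
predict.meta_slda <- function(object, test_features, ...) {
  missing_mod <- setdiff(object$combination, names(test_features))
  if (length(missing_mod))
    stop_hbci(sprintf("missing modality: %s", paste(missing_mod, collapse = ", ")),
              "hbci_prediction_error")
  dec <- vapply(object$combination, function(m)
    predict(object$base[[m]], test_features[[m]])$decision,
    numeric(nrow(test_features[[object$combination[1]]]$values)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  colnames(dec) <- object$combination
  predict(object$meta, dec)
}
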