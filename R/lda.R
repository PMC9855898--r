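#' Fit a two-class linear discriminant model
#'
#' Pooled within-class covariance LDA with equal priors by default (the
#' chemometric convention for imbalanced clinical classes) and automatic
#' ridge stabilisation: when the pooled covariance has condition number above
#' 1e10, `ridge = 1e-8 * trace(S)/p` is added to the diagonal, which keeps
#' the near-degenerate many-variables/few-samples fits solvable without
#' materially moving the discriminant direction.
#'
#' @param X training matrix, samples x variables.
#' @param labels two-class labels; classes are ordered by `sort()` and ties
#'   in prediction go to the first.
#' @param priors `"equal"` (default), `"proportional"`, or a numeric vector
#'   of two priors summing to 1 (in sorted class order).
#' @param ridge `"auto"` (default), a number added to the covariance
#'   diagonal, or 0 to disable.
#' @return an `lda_model`: `classes`, `means` (2 x p), `pooled_cov`,
#'   `priors`, `canonical_direction` (`solve(S, mu1 - mu2)`), `threshold`
#'   (decision point on the canonical axis), `ridge_used`.
#' @export
fit_lda <- function(X, labels, priors = "equal", ridge = "auto") {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("exactly two classes required")
  n_k <- table(factor(labels, classes))
  if (any(n_k < 2)) stop("each class needs >= 2 training samples")
  p <- ncol(X); n <- nrow(X)
  if (any(n_k < p / 3))
    warning("class size below p/3 (", paste(n_k, collapse = "/"),
            " samples for ", p, " variables): fit may be unstable")
  means <- rbind(colMeans(X[labels == classes[1], , drop = FALSE]),
                 colMeans(X[labels == classes[2], , drop = FALSE]))
  rownames(means) <- classes
  S <- matrix(0, p, p)
  for (k in classes) {
    Xk <- X[labels == k, , drop = FALSE]
    S <- S + crossprod(sweep(Xk, 2, colMeans(Xk)))
  }
  S <- S / (n - 2)
  ridge_used <- 0
  if (identical(ridge, "auto")) {
    if (p > 1 && kappa(S, exact = FALSE) > 1e10 || rcond(S) < 1e-12)
      ridge_used <- 1e-8 * sum(diag(S)) / p
  } else ridge_used <- as.numeric(ridge)
  if (ridge_used > 0) S <- S + diag(ridge_used, p)
  Sinv_d <- try(solve(S, t(means[1, , drop = FALSE] - means[2, , drop = FALSE])),
                silent = TRUE)
  if (inherits(Sinv_d, "try-error"))
    stop("pooled covariance singular even after ridge; reduce the number ",
         "of variables")
  w <- as.vector(Sinv_d)
  pr <- if (identical(priors, "equal")) c(0.5, 0.5)
        else if (identical(priors, "proportional")) as.vector(n_k) / n
        else { stopifnot(length(priors) == 2, abs(sum(priors) - 1) < 1e-9)
               as.numeric(priors) }
  names(pr) <- classes
  # g1(x) - g2(x) = x'w - threshold with threshold below; >= 0 -> class 1
  threshold <- sum((means[1, ] + means[2, ]) * w) / 2 - log(pr[1] / pr[2])
  structure(list(classes = classes, means = means, pooled_cov = S,
                 priors = pr, canonical_direction = w,
                 threshold = unname(threshold), ridge_used = ridge_used,
                 p = p),
            class = "lda_model")
}

#' Predict class labels with a fitted LDA model
#'
#' @param object an `lda_model`.
#' @param newdata matrix (or vector for one sample) with matching variables.
#' @param ... unused.
#' @return character vector of predicted labels; a sample exactly on the
#'   boundary goes to the first class in sorted order.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  s <- canonical_scores(object, newdata)
  ifelse(s >= 0, object$classes[1], object$classes[2])
}

#' Canonical discriminant scores
#'
#' One-dimensional scores `x' S^-1 (mu1 - mu2)` shifted so the decision
#' threshold sits at 0: positive scores predict the first class in sorted
#' label order, so the score sign reproduces [predict.lda_model()] exactly.
#'
#' @param model an `lda_model`.
#' @param X matrix or single-sample vector.
#' @return numeric scores, histogram-ready.
#' @export
canonical_scores <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stop("variable count mismatch: model has ", model$p, ", data has ",
         ncol(X))
  as.vector(X %*% model$canonical_direction) - model$threshold
}

#' Leave-one-out cross-validated LDA
#'
#' Each sample is predicted by a model refitted from scratch on the other
#' `n - 1` samples (class means, pooled covariance and ridge are all
#' recomputed per fold, so the held-out row never influences its own
#' prediction).
#'
#' @param X training matrix.
#' @param labels two-class labels.
#' @param priors,ridge passed to [fit_lda()].
#' @return list with `predicted` (LOO labels) and `scores` (LOO canonical
#'   scores).
#' @export
loo_cv_lda <- function(X, labels, priors = "equal", ridge = "auto") {
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples for LOO")
  if (any(table(labels) < 3))
    stop("a LOO fold would lose an entire class (class with < 3 samples ",
         "cannot be refitted with >= 2)")
  pred <- character(n)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      fit_lda(X[-i, , drop = FALSE], labels[-i], priors, ridge))
    sc[i] <- canonical_scores(fit, X[i, ])
    pred[i] <- ifelse(sc[i] >= 0, fit$classes[1], fit$classes[2])
  }
  list(predicted = pred, scores = sc)
}

#' Build a classification report
#'
#' Summarises LOO (internal) and external-test performance per class in the
#' standard layout: per-class classification % (LOO), external prediction %,
#' and a pooled total-rate column, plus a pooled `Total` row and the
#' confusion counts the percentages recompute from.
#'
#' @param loo_pred LOO predicted labels on the training set.
#' @param labels_train true training labels.
#' @param test_pred predicted labels on the external test set (optional).
#' @param labels_test true test labels (optional).
#' @param sample_ids_train,sample_ids_test ids used to report misclassified
#'   samples.
#' @return a `classification_report`: `rates` data.frame, `confusion_loo`,
#'   `confusion_test`, `misclassified` (ids).
#' @export
classification_report <- function(loo_pred, labels_train,
                                  test_pred = NULL, labels_test = NULL,
                                  sample_ids_train = NULL,
                                  sample_ids_test = NULL) {
  classes <- sort(unique(as.character(labels_train)))
  conf <- function(pred, truth)
    table(truth = factor(truth, classes), predicted = factor(pred, classes))
  cm_loo <- conf(loo_pred, labels_train)
  cm_test <- if (!is.null(test_pred)) conf(test_pred, labels_test)
  pct <- function(cm, k) {
    tot <- sum(cm[k, ])
    if (tot == 0) NA_real_ else 100 * cm[k, k] / tot
  }
  rows <- lapply(classes, function(k) {
    loo_ok <- cm_loo[k, k]; loo_n <- sum(cm_loo[k, ])
    ext_ok <- if (!is.null(cm_test)) cm_test[k, k] else NA
    ext_n <- if (!is.null(cm_test)) sum(cm_test[k, ]) else NA
    data.frame(class = k,
               classification = pct(cm_loo, k),
               external_prediction = if (!is.null(cm_test)) pct(cm_test, k)
                                     else NA_real_,
               total_rate = if (!is.null(cm_test) && (loo_n + ext_n) > 0)
                 100 * (loo_ok + ext_ok) / (loo_n + ext_n)
                 else pct(cm_loo, k))
  })
  tot <- data.frame(
    class = "Total",
    classification = 100 * sum(diag(cm_loo)) / sum(cm_loo),
    external_prediction = if (!is.null(cm_test))
      100 * sum(diag(cm_test)) / sum(cm_test) else NA_real_,
    total_rate = if (!is.null(cm_test))
      100 * (sum(diag(cm_loo)) + sum(diag(cm_test))) /
        (sum(cm_loo) + sum(cm_test))
      else 100 * sum(diag(cm_loo)) / sum(cm_loo))
  rates <- rbind(do.call(rbind, rows), tot)
  mis <- character(0)
  if (!is.null(sample_ids_train))
    mis <- c(mis, sample_ids_train[loo_pred != labels_train])
  if (!is.null(sample_ids_test) && !is.null(test_pred))
    mis <- c(mis, sample_ids_test[test_pred != labels_test])
  structure(list(rates = rates, confusion_loo = cm_loo,
                 confusion_test = cm_test, misclassified = mis),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  print(transform(x$rates,
                  classification = round(classification, 2),
                  external_prediction = round(external_prediction, 2),
                  total_rate = round(total_rate, 2)),
        row.names = FALSE)
  if (length(x$misclassified))
    cat("  misclassified:", paste(x$misclassified, collapse = ", "), "\n")
  invisible(x)
}
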