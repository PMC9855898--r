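#' Fit a SIMCA class model
#'
#' One class at a time: the class training rows are autoscaled (their own
#' center and scale), an A-component NIPALS PCA spans the inner class space,
#' and the class residual standard deviation `s0` with an F-test limit at
#' significance `alpha` defines the 95% (by default) class space:
#' `s0^2 = sum(E^2) / ((n - A - 1)(p - A))`, and a sample is accepted when
#' its reduced distance `d = s(x)/s0` satisfies
#' `d^2 <= F(1 - alpha; p - A, (n - A - 1)(p - A))`.
#'
#' @param X_class training rows of one class, samples x variables.
#' @param A number of principal components for the inner space.
#' @param alpha significance level of the acceptance F-test (default 0.05).
#' @param class_label label stored with the model.
#' @return a `simca_class_model`: autoscaling `center`/`scale`, `pca`
#'   (the NIPALS model), `s0`, `df` (`nu1 = p - A`,
#'   `nu2 = (n - A - 1)(p - A)`), `alpha`, `crit_distance`
#'   (`sqrt(qf(1 - alpha, nu1, nu2))`), the training scores' variances, and
#'   the autoscaled training data `Xs` (kept for the diagnostics).
#' @export
fit_simca_class <- function(X_class, A, alpha = 0.05, class_label = "class") {
  X_class <- as.matrix(X_class)
  n <- nrow(X_class); p <- ncol(X_class)
  if (n < A + 2) stop("class '", class_label, "' needs at least A + 2 = ",
                      A + 2, " samples, has ", n)
  if (p <= A) stop("A must be smaller than the number of variables")
  ctr <- colMeans(X_class)
  scl <- apply(X_class, 2, stats::sd)
  zero <- scl < .Machine$double.eps * 1e3
  if (any(zero))
    stop("zero-variance variable(s) within class '", class_label, "': ",
         paste(if (!is.null(colnames(X_class))) colnames(X_class)[zero]
               else which(zero), collapse = ", "))
  Xs <- sweep(sweep(X_class, 2, ctr), 2, scl, "/")
  pca <- fit_nipals(Xs, A, center = FALSE, scale = FALSE)
  E <- Xs - tcrossprod(pca$scores, pca$loadings)
  nu1 <- p - A
  nu2 <- (n - A - 1) * (p - A)
  if (nu1 < 1 || nu2 < 1) stop("non-positive residual degrees of freedom")
  s0 <- sqrt(sum(E^2) / nu2)
  if (s0 <= 0) stop("zero class residual standard deviation")
  structure(list(class_label = class_label, center = ctr, scale = scl,
                 pca = pca, s0 = s0, df = c(nu1 = nu1, nu2 = nu2),
                 alpha = alpha,
                 crit_distance = sqrt(stats::qf(1 - alpha, nu1, nu2)),
                 score_var = colSums(pca$scores^2) / (n - 1),
                 n = n, p = p, A = A, Xs = Xs),
            class = "simca_class_model")
}

#' @export
print.simca_class_model <- function(x, ...) {
  cat("<simca_class_model> '", x$class_label, "': ", x$n, " samples, ",
      x$p, " variables, A = ", x$A, "\n  s0 = ", signif(x$s0, 4),
      ", crit distance = ", signif(x$crit_distance, 4),
      " (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

# autoscale new rows with the class model's own center/scale
simca_standardize <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stop("variable count mismatch: model has ", model$p, ", data has ",
         ncol(X))
  sweep(sweep(X, 2, model$center), 2, model$scale, "/")
}

# per-variable residual sums of squares of X in the model's autoscaled space
simca_residuals <- function(model, X) {
  Xs <- simca_standardize(model, X)
  T_ <- Xs %*% model$pca$loadings
  Xs - tcrossprod(T_, model$pca$loadings)
}

#' Reduced distance of samples to a SIMCA class model
#'
#' @param model a `simca_class_model`.
#' @param X matrix (or single-sample vector) on the same variables.
#' @param augmented also fold score-space leverage into the distance
#'   ("unweighted augmented distance"): the Hotelling score distance,
#'   rescaled so its own F-limit maps onto `crit_distance`, is combined with
#'   the residual distance as `sqrt(d_resid^2 + d_score^2)`. Default
#'   `FALSE` (pure residual distance).
#' @return data.frame with `distance` (reduced, `s(x)/s0`) and `accepted`
#'   (`distance <= crit_distance`).
#' @export
distance_to_model <- function(model, X, augmented = FALSE) {
  E <- simca_residuals(model, X)
  s2 <- rowSums(E^2) / model$df["nu1"]
  d <- sqrt(s2) / model$s0
  if (augmented) {
    Xs <- simca_standardize(model, X)
    T_ <- Xs %*% model$pca$loadings
    t2 <- rowSums(sweep(T_^2, 2, model$score_var, "/"))
    n <- model$n; A <- model$A
    t2crit <- A * (n - 1) / (n - A) *
      stats::qf(1 - model$alpha, A, n - A)
    d_score <- sqrt(t2 / t2crit) * model$crit_distance
    d <- sqrt(d^2 + d_score^2)
  }
  data.frame(distance = unname(d),
             accepted = unname(d <= model$crit_distance))
}

#' Four-way SIMCA assignment
#'
#' Each sample is tested against every class model; membership is the class
#' set that accepts it (`"both"` for the overlap region, `"none"` outside
#' every class space), and `forced_class` is the nearest model regardless of
#' acceptance (ties to the first model).
#'
#' @param models list of two (or more) `simca_class_model`s.
#' @param X sample matrix.
#' @param augmented passed to [distance_to_model()].
#' @return a `simca_assignment` data.frame: one `d_<class>` column per
#'   model, `membership`, `forced_class`.
#' @export
simca_assign <- function(models, X, augmented = FALSE) {
  stopifnot(length(models) >= 2)
  labs <- vapply(models, `[[`, "", "class_label")
  dist <- sapply(models, function(m)
    distance_to_model(m, X, augmented)$distance)
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = 1)
  acc <- sweep(dist, 2, vapply(models, `[[`, 0, "crit_distance"), "<=")
  membership <- apply(acc, 1, function(a) {
    if (all(a)) "both" else if (!any(a)) "none" else labs[which(a)[1]]
  })
  if (length(models) > 2)
    membership <- apply(acc, 1, function(a)
      if (sum(a) == 0) "none" else if (sum(a) > 1) "multiple"
      else labs[which(a)])
  forced <- labs[apply(dist, 1, which.min)]
  out <- as.data.frame(dist)
  colnames(out) <- paste0("d_", labs)
  out$membership <- membership
  out$forced_class <- forced
  class(out) <- c("simca_assignment", "data.frame")
  out
}

#' Modelling power of each variable
#'
#' `MP_j = 1 - s_j(residual) / s_j(total)` on the class training data, with
#' the per-variable residual SD over `n - A - 1` degrees of freedom and the
#' total SD equal to 1 by autoscaling. Values are clipped to `[0, 1]`; a
#' variable fully reconstructed by the inner components reaches 1, a
#' pure-noise variable falls towards 0.
#'
#' @param model a `simca_class_model`.
#' @return numeric vector of modelling powers, one per variable.
#' @export
modelling_power <- function(model) {
  E <- model$Xs - tcrossprod(model$pca$scores, model$pca$loadings)
  s_res <- sqrt(colSums(E^2) / (model$n - model$A - 1))
  mp <- 1 - s_res
  pmin(pmax(mp, 0), 1)
}

#' Discriminant power of each variable
#'
#' Ratio of cross-fitted to self-fitted per-variable residuals between two
#' class models:
#' `DP_j = sqrt((SS_j(X2|M1) + SS_j(X1|M2)) / (SS_j(X1|M1) + SS_j(X2|M2)))`,
#' each residual taken in the respective model's autoscaled space. A variable
#' distributed identically in both classes gives DP near 1; strongly
#' class-shifted variables give DP >> 1. Symmetric under swapping the class
#' roles.
#'
#' @param model1,model2 fitted `simca_class_model`s.
#' @param X1,X2 the corresponding class training blocks (default: the rows
#'   stored in each model, i.e. its own training data).
#' @return numeric vector of discriminant powers (>= 0; `Inf` with a warning
#'   when a self-residual denominator is zero).
#' @export
discriminant_power <- function(model1, model2, X1 = NULL, X2 = NULL) {
  X1 <- X1 %||% simca_unscale(model1)
  X2 <- X2 %||% simca_unscale(model2)
  cross <- colSums(simca_residuals(model1, X2)^2) +
           colSums(simca_residuals(model2, X1)^2)
  self <- colSums(simca_residuals(model1, X1)^2) +
          colSums(simca_residuals(model2, X2)^2)
  zero <- self <= 0
  if (any(zero)) {
    warning("zero self-residual for variable(s) ",
            paste(which(zero), collapse = ", "), "; DP set to Inf")
    self[zero] <- 0
  }
  dp <- sqrt(cross / self)
  unname(dp)
}

# reconstruct the raw training block from the stored autoscaled rows
simca_unscale <- function(model)
  sweep(sweep(model$Xs, 2, model$scale, "*"), 2, model$center, "+")

#' Interclass distance between two SIMCA models
#'
#' `D = sqrt((SS(X1|M2) + SS(X2|M1)) / (SS(X1|M1) + SS(X2|M2)))` aggregated
#' over all samples and variables. A class against its own model gives
#' exactly 1; well-separated classes give values of 3 and above.
#'
#' @inheritParams discriminant_power
#' @return scalar distance.
#' @export
class_distance <- function(model1, model2, X1 = NULL, X2 = NULL) {
  X1 <- X1 %||% simca_unscale(model1)
  X2 <- X2 %||% simca_unscale(model2)
  cross <- sum(simca_residuals(model1, X2)^2) +
           sum(simca_residuals(model2, X1)^2)
  self <- sum(simca_residuals(model1, X1)^2) +
          sum(simca_residuals(model2, X2)^2)
  if (self <= 0) { warning("zero self-residual; distance set to Inf")
                   return(Inf) }
  sqrt(cross / self)
}

#' Cooman coordinates for a two-class SIMCA
#'
#' Per-sample reduced distances to both class models, ready for a Cooman
#' plot: the two critical distances give the 95% class-space lines and the
#' diagonal `d1 = d2` is the equal-class-distance line.
#'
#' @param models list of exactly two `simca_class_model`s.
#' @param X sample matrix.
#' @param labels optional true labels carried into the output.
#' @param augmented passed to [distance_to_model()].
#' @return data.frame `d1`, `d2` (plus `label`), with attributes `crit1`,
#'   `crit2`, `classes`.
#' @export
coomans_coordinates <- function(models, X, labels = NULL, augmented = FALSE) {
  if (length(models) != 2) stop("exactly two class models required")
  d1 <- distance_to_model(models[[1]], X, augmented)$distance
  d2 <- distance_to_model(models[[2]], X, augmented)$distance
  out <- data.frame(d1 = d1, d2 = d2)
  if (!is.null(labels)) out$label <- as.character(labels)
  attr(out, "crit1") <- models[[1]]$crit_distance
  attr(out, "crit2") <- models[[2]]$crit_distance
  attr(out, "classes") <- c(models[[1]]$class_label, models[[2]]$class_label)
  out
}

#' Leave-one-out SIMCA cross-validation
#'
#' For each training sample the model of its own class is refitted without
#' it; acceptance by the refitted own-class model and the (unchanged) other
#' model gives the cross-validated membership and forced assignment.
#'
#' @param X training matrix.
#' @param labels two-class labels.
#' @param A components per class: single number or named vector by class.
#' @param alpha acceptance significance.
#' @return data.frame per training sample: `own_accepted`, `other_accepted`,
#'   `forced_class`, `d_own`, `d_other`.
#' @export
simca_loo <- function(X, labels, A, alpha = 0.05) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  stopifnot(length(classes) == 2)
  A_by <- component_map(A, classes)
  full <- lapply(classes, function(k)
    fit_simca_class(X[labels == k, , drop = FALSE], A_by[[k]], alpha, k))
  names(full) <- classes
  n <- nrow(X)
  out <- data.frame(own_accepted = logical(n), other_accepted = logical(n),
                    forced_class = character(n), d_own = numeric(n),
                    d_other = numeric(n))
  for (i in seq_len(n)) {
    k <- labels[i]; other <- setdiff(classes, k)
    idx <- which(labels == k)
    # trailing components of a fold refit may stall on near-tied noise
    # eigenvalues; convergence is still recorded in the refit model
    refit <- suppressWarnings(
      fit_simca_class(X[setdiff(idx, i), , drop = FALSE],
                      A_by[[k]], alpha, k))
    down <- distance_to_model(refit, X[i, ])
    doth <- distance_to_model(full[[other]], X[i, ])
    out$own_accepted[i] <- down$accepted
    out$other_accepted[i] <- doth$accepted
    out$d_own[i] <- down$distance
    out$d_other[i] <- doth$distance
    out$forced_class[i] <- if (down$distance <= doth$distance) k else other
  }
  out
}

component_map <- function(A, classes) {
  if (length(A) == 1) A <- stats::setNames(rep(A, length(classes)), classes)
  if (is.null(names(A))) names(A) <- classes
  as.list(A[classes])
}

#' Full SIMCA classification report
#'
#' Fits one class model per class on the training data and summarises, per
#' class and pooled: training classification % (acceptance by the own-class
#' model), LOO % (own-class acceptance under leave-one-out refitting), CV
#' efficiency (`sqrt(sensitivity x specificity)` under LOO), forced-model
#' efficiency (same under forced nearest-model assignment in LOO) and the
#' external-test total rate (forced assignment on held-out samples). Also
#' carries the modelling/discriminant power table, the interclass distance
#' and the Cooman coordinates of all samples.
#'
#' @param X_train,labels_train training data (two classes).
#' @param X_test,labels_test optional external test set.
#' @param A components per class (single number or named by class).
#' @param alpha acceptance significance (default 0.05).
#' @param variable_names optional names for the MP/DP table rows.
#' @param augmented use the augmented distance for the Cooman coordinates.
#' @return a `simca_report`: `summary`, `mp_dp`, `class_distance`, `models`,
#'   `loo`, `assign_train`, `assign_test`, `cooman`.
#' @export
simca_report <- function(X_train, labels_train, X_test = NULL,
                         labels_test = NULL, A = 3, alpha = 0.05,
                         variable_names = NULL, augmented = FALSE) {
  X_train <- as.matrix(X_train)
  labels_train <- as.character(labels_train)
  classes <- sort(unique(labels_train))
  stopifnot(length(classes) == 2)
  A_by <- component_map(A, classes)
  models <- lapply(classes, function(k)
    fit_simca_class(X_train[labels_train == k, , drop = FALSE],
                    A_by[[k]], alpha, k))
  names(models) <- classes

  train_assign <- simca_assign(models, X_train)
  own_acc_full <- vapply(seq_len(nrow(X_train)), function(i)
    train_assign[i, paste0("d_", labels_train[i])] <=
      models[[labels_train[i]]]$crit_distance, logical(1))

  loo <- simca_loo(X_train, labels_train, A, alpha)

  per_class <- lapply(classes, function(k) {
    own <- labels_train == k
    sens_cv <- mean(loo$own_accepted[own])
    spec_cv <- mean(!loo$other_accepted[!own])   # strangers rejected by k
    sens_f <- mean(loo$forced_class[own] == k)
    spec_f <- mean(loo$forced_class[!own] != k)
    ext <- NA_real_
    if (!is.null(X_test)) {
      ta <- simca_assign(models, X_test)
      ext <- mean(ta$forced_class[labels_test == k] == k) * 100
    }
    data.frame(class = k,
               classification = 100 * mean(own_acc_full[own]),
               loo = 100 * sens_cv,
               cv_efficiency = 100 * sqrt(sens_cv * spec_cv),
               efficiency_forced = 100 * sqrt(sens_f * spec_f),
               total_rate = ext)
  })
  pooled_sens_cv <- mean(loo$own_accepted)
  pooled_spec_cv <- mean(!loo$other_accepted)
  pooled_f <- mean(loo$forced_class == labels_train)
  ext_tot <- NA_real_
  assign_test <- NULL
  if (!is.null(X_test)) {
    assign_test <- simca_assign(models, X_test)
    ext_tot <- 100 * mean(assign_test$forced_class == labels_test)
  }
  summary <- rbind(
    do.call(rbind, per_class),
    data.frame(class = "Total",
               classification = 100 * mean(own_acc_full),
               loo = 100 * pooled_sens_cv,
               cv_efficiency = 100 * sqrt(pooled_sens_cv * pooled_spec_cv),
               efficiency_forced = 100 * pooled_f,
               total_rate = ext_tot))

  dp <- discriminant_power(models[[1]], models[[2]])
  mp1 <- modelling_power(models[[1]])
  mp2 <- modelling_power(models[[2]])
  vn <- variable_names %||% colnames(X_train) %||%
    paste0("V", seq_len(ncol(X_train)))
  mp_dp <- data.frame(variable = vn, DP = dp)
  mp_dp[[paste0("MP_", classes[1])]] <- mp1
  mp_dp[[paste0("MP_", classes[2])]] <- mp2

  all_X <- rbind(X_train, if (!is.null(X_test)) as.matrix(X_test))
  all_lab <- c(labels_train,
               if (!is.null(labels_test)) as.character(labels_test))
  cooman <- coomans_coordinates(models, all_X, all_lab, augmented)

  structure(list(summary = summary, mp_dp = mp_dp,
                 class_distance = class_distance(models[[1]], models[[2]]),
                 models = models, loo = loo, assign_train = train_assign,
                 assign_test = assign_test, cooman = cooman),
            class = "simca_report")
}

#' @export
print.simca_report <- function(x, ...) {
  cat("<simca_report> interclass distance =",
      signif(x$class_distance, 4), "\n")
  s <- x$summary
  s[, -1] <- round(s[, -1], 2)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Serialize a SIMCA class model to JSON
#'
#' @param model a `simca_class_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_simca_model <- function(model, path) {
  stopifnot(inherits(model, "simca_class_model"))
  payload <- list(
    class_label = model$class_label, center = model$center,
    scale = model$scale, loadings = model$pca$loadings,
    scores = model$pca$scores, s0 = model$s0, df = as.list(model$df),
    alpha = model$alpha, crit_distance = model$crit_distance,
    score_var = model$score_var, n = model$n, p = model$p, A = model$A,
    Xs = model$Xs,
    explained_variance = model$pca$explained_variance)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Reload a SIMCA class model from JSON
#'
#' @param path file written by [write_simca_model()].
#' @return a `simca_class_model` whose statistics reproduce the original's.
#' @export
read_simca_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, nr, nc) {
    if (is.matrix(m)) return(m)
    if (nc == 0 || nr == 0) return(matrix(0, nr, nc))
    matrix(unlist(m), nrow = nr, byrow = TRUE)
  }
  loadings <- as_mat(pl$loadings, pl$p, pl$A)
  scores <- as_mat(pl$scores, pl$n, pl$A)
  Xs <- as_mat(pl$Xs, pl$n, pl$p)
  pca <- structure(list(center = rep(0, pl$p), scale = rep(1, pl$p),
                        loadings = loadings, scores = scores,
                        explained_variance = pl$explained_variance,
                        eig = colSums(scores^2) / (pl$n - 1),
                        A = pl$A, n = pl$n, p = pl$p),
                   class = "nipals_pca")
  structure(list(class_label = pl$class_label, center = pl$center,
                 scale = pl$scale, pca = pca, s0 = pl$s0,
                 df = c(nu1 = pl$df$nu1, nu2 = pl$df$nu2), alpha = pl$alpha,
                 crit_distance = pl$crit_distance,
                 score_var = pl$score_var, n = pl$n, p = pl$p, A = pl$A,
                 Xs = Xs),
            class = "simca_class_model")
}

#' Recognition-guided truncation of a SELECT ranking for SIMCA
#'
#' Reduces a ranked variable set to `k_target` variables for SIMCA: at each
#' step the candidate whose removal yields the highest training recognition
#' (pooled own-class acceptance) is dropped, preferring the lowest SELECT
#' weight on ties, until `k_target` variables remain.
#'
#' @param X training matrix (all candidate variables).
#' @param labels two-class labels.
#' @param ranking column indices in SELECT order.
#' @param weights SELECT weights aligned with `ranking`.
#' @param k_target final variable count (default 10).
#' @param A,alpha SIMCA settings used for the recognition refits.
#' @return list `selected` (indices, original ranking order), `recognition`
#'   (training recognition of the final set).
#' @export
truncate_for_simca <- function(X, labels, ranking, weights, k_target = 10,
                               A = 3, alpha = 0.05) {
  X <- as.matrix(X)
  stopifnot(length(ranking) == length(weights), k_target >= 1)
  recog <- function(cols) {
    classes <- sort(unique(labels))
    A_by <- component_map(A, classes)
    models <- lapply(classes, function(k)
      suppressWarnings(
        fit_simca_class(X[labels == k, cols, drop = FALSE], A_by[[k]],
                        alpha, k)))
    names(models) <- classes
    acc <- vapply(seq_len(nrow(X)), function(i)
      distance_to_model(models[[labels[i]]], X[i, cols])$accepted,
      logical(1))
    mean(acc)
  }
  keep <- ranking
  w <- weights
  while (length(keep) > k_target) {
    cand_r <- vapply(seq_along(keep), function(j)
      recog(keep[-j]), numeric(1))
    best <- max(cand_r)
    tied <- which(cand_r >= best - 1e-12)
    drop_j <- tied[which.min(w[tied])]
    keep <- keep[-drop_j]; w <- w[-drop_j]
  }
  list(selected = keep, recognition = recog(keep))
}
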