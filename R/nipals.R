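#' NIPALS principal component analysis
#'
#' Sequential NIPALS with deflation. Used with centering only for exploratory
#' PCA of pre-treated spectra, and with full autoscaling as the inner engine
#' of SIMCA class models. Component signs are fixed so the largest-magnitude
#' loading element of each component is positive, making runs reproducible.
#'
#' @param X numeric matrix, samples x variables.
#' @param A number of components, `0 <= A <= min(n - 1, p)`.
#' @param tol convergence tolerance on the relative score change
#'   (default 1e-10).
#' @param max_iter maximum NIPALS iterations per component (default 500);
#'   non-convergence is recorded in the model and raised as a warning.
#' @param scale autoscale columns (unit variance) in addition to centering.
#' @param center subtract column means (default TRUE; pass FALSE for data
#'   already centered/scaled externally).
#' @return a `nipals_pca` model: `center`, `scale`, `loadings` (p x A,
#'   orthonormal), `scores` (n x A, orthogonal), `explained_variance`
#'   (fraction per component), `eig` (score variances), `A`, `iterations`,
#'   `converged`, `total_ss`.
#' @export
fit_nipals <- function(X, A, tol = 1e-10, max_iter = 500, scale = FALSE,
                       center = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2, A >= 0, A <= min(n - 1, p))
  ctr <- if (center) colMeans(X) else rep(0, p)
  scl <- rep(1, p)
  if (scale) {
    scl <- apply(X, 2, stats::sd)
    zero <- scl < .Machine$double.eps * 1e3
    if (any(zero))
      stop("zero-variance column(s) with scaling on: ",
           paste(if (!is.null(colnames(X))) colnames(X)[zero]
                 else which(zero), collapse = ", "))
  }
  Xw <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  total_ss <- sum(Xw^2)
  loadings <- matrix(0, p, A)
  scores <- matrix(0, n, A)
  iterations <- integer(A)
  converged <- rep(TRUE, A)
  if (A > 0) {
    for (a in seq_len(A)) {
      t_vec <- Xw[, which.max(colSums(Xw^2))]
      if (sum(t_vec^2) == 0) stop("residual matrix exhausted before ", A,
                                  " components")
      for (it in seq_len(max_iter)) {
        p_vec <- crossprod(Xw, t_vec) / sum(t_vec^2)
        p_vec <- p_vec / sqrt(sum(p_vec^2))
        t_new <- Xw %*% p_vec
        delta <- sqrt(sum((t_new - t_vec)^2)) /
          max(sqrt(sum(t_new^2)), .Machine$double.eps)
        t_vec <- t_new
        if (delta < tol) break
      }
      iterations[a] <- it
      if (it == max_iter && delta >= tol) {
        converged[a] <- FALSE
        warning("NIPALS component ", a, " did not converge in ", max_iter,
                " iterations (last relative change ", format(delta), ")")
      }
      jmax <- which.max(abs(p_vec))
      if (p_vec[jmax] < 0) { p_vec <- -p_vec; t_vec <- -t_vec }
      loadings[, a] <- p_vec
      scores[, a] <- t_vec
      Xw <- Xw - tcrossprod(t_vec, p_vec)
    }
  }
  rownames(loadings) <- colnames(X)
  structure(list(center = ctr, scale = scl, loadings = loadings,
                 scores = scores,
                 explained_variance = colSums(scores^2) / total_ss,
                 eig = colSums(scores^2) / (n - 1),
                 A = A, iterations = iterations, converged = converged,
                 total_ss = total_ss, n = n, p = p),
            class = "nipals_pca")
}

#' @export
print.nipals_pca <- function(x, ...) {
  cat("<nipals_pca> ", x$A, " component(s), ", x$n, " x ", x$p, " data\n",
      sep = "")
  if (x$A > 0)
    cat("  explained variance:",
        paste0(round(100 * x$explained_variance, 2), "%", collapse = ", "),
        "\n")
  invisible(x)
}

#' Project new samples onto a fitted PCA model
#'
#' @param model a `nipals_pca` model.
#' @param X_new matrix (or vector for one sample) with the same variables.
#' @return score matrix, `nrow(X_new)` x `A`.
#' @export
project_pca <- function(model, X_new) {
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != model$p)
    stop("variable count mismatch: model has ", model$p, ", data has ",
         ncol(X_new))
  Xs <- sweep(sweep(X_new, 2, model$center), 2, model$scale, "/")
  Xs %*% model$loadings
}

#' Residual statistics of samples against a PCA model
#'
#' Residuals are taken in the model's standardized space:
#' `E = standardized(X) - scores %*% t(loadings)`. Per-sample residual SD
#' uses `p - A` degrees of freedom; per-variable residual SD uses
#' `n - A - 1`.
#'
#' @param model a `nipals_pca` model.
#' @param X sample matrix.
#' @return list with `sample_sd` (length n), `variable_sd` (length p) and
#'   `E` (the residual matrix).
#' @export
residual_stats <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (model$p <= model$A) stop("p <= A: no residual degrees of freedom")
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  T_ <- Xs %*% model$loadings
  E <- Xs - tcrossprod(T_, model$loadings)
  n <- nrow(X)
  list(sample_sd = sqrt(rowSums(E^2) / (model$p - model$A)),
       variable_sd = sqrt(colSums(E^2) / max(n - model$A - 1, 1)),
       E = E)
}

#' Flag PCA outliers
#'
#' Screens samples by two configurable rules: residual distance above the
#' F-limit at `alpha`, or score-space leverage above `leverage_mult * A / n`.
#'
#' @param model a `nipals_pca` fitted on the samples in `X`.
#' @param X the training matrix the model was fitted on.
#' @param alpha significance for the residual F-limit (default 0.01).
#' @param leverage_mult leverage threshold multiplier (default 3).
#' @return logical vector, `TRUE` for flagged samples.
#' @export
pca_outliers <- function(model, X, alpha = 0.01, leverage_mult = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  rs <- residual_stats(model, X)
  df1 <- model$p - model$A
  df2 <- max((n - model$A - 1) * (model$p - model$A), 1)
  s0 <- sqrt(sum(rs$E^2) / df2)
  res_flag <- (rs$sample_sd / s0)^2 > stats::qf(1 - alpha, df1, df2)
  lev <- rep(0, n)
  if (model$A > 0) {
    T_ <- project_pca(model, X)
    lev <- rowSums(sweep(T_^2, 2, colSums(T_^2), "/"))
    lev_flag <- lev > leverage_mult * model$A / n
  } else lev_flag <- rep(FALSE, n)
  res_flag | lev_flag
}
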