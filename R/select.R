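#' Fisher class-separation weights
#'
#' Two-class discrimination weight per column:
#' `w = (mean1 - mean2)^2 / (s1^2 + s2^2)` with per-class `n - 1` sample
#' variances. Scale-invariant. A column with zero pooled variance gets
#' weight 0 when the class means coincide and `Inf` (selected first) when
#' they differ.
#'
#' @param X numeric matrix (or vector for one variable).
#' @param labels two-class factor/character vector.
#' @return numeric weight per column.
#' @export
fisher_weight <- function(X, labels) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("exactly two classes required, got ",
                             length(cls))
  i1 <- labels == cls[1]; i2 <- !i1
  if (sum(i1) < 2 || sum(i2) < 2)
    stop("each class needs >= 2 samples")
  m1 <- colMeans(X[i1, , drop = FALSE]); m2 <- colMeans(X[i2, , drop = FALSE])
  v1 <- colVars(X[i1, , drop = FALSE]); v2 <- colVars(X[i2, , drop = FALSE])
  num <- (m1 - m2)^2
  den <- v1 + v2
  w <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  unname(w)
}

colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

#' Orthogonalize all columns against one predictor
#'
#' Every other column is replaced by its residual after least-squares
#' regression (with intercept) on column `j`; column means are preserved, so
#' a column already uncorrelated with `j` is returned unchanged. Column `j`
#' itself is zeroed out of the candidate pool.
#'
#' @param X numeric matrix.
#' @param j column index to decorrelate against.
#' @return matrix of the same shape.
#' @export
orthogonalize_against <- function(X, j) {
  X <- as.matrix(X)
  x <- X[, j]
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= .Machine$double.eps * 1e3)
    stop("degenerate column ", j, " (zero variance)")
  xc <- x - mean(x)
  b <- crossprod(xc, X) / sum(xc^2)      # 1 x p slopes
  X <- X - outer(xc, as.vector(b))
  X[, j] <- 0
  X
}

#' SELECT stepwise orthogonalization variable selection
#'
#' Iteratively picks the predictor with the largest Fisher class-separation
#' weight on the current working matrix, then decorrelates all remaining
#' predictors against it, so each new pick carries information not already
#' captured. Stops at `k_max` variables, at the training-objects rule
#' `k <= floor(n / min_ratio)` (at least `min_ratio` training samples per
#' selected variable, default 3), or when the best remaining weight falls
#' below `weight_floor`.
#'
#' @param X training matrix, samples x variables.
#' @param labels two-class labels.
#' @param k_max maximum number of variables to select (default 20).
#' @param min_ratio minimum training-samples-per-variable ratio (default 3).
#' @param weight_floor stop when the best weight is below this (default 0,
#'   disabled).
#' @param wavenumbers optional grid to translate selected indices.
#' @return a `select_result`: `selected` (ordered column indices), `weights`
#'   (criterion value at selection time), `k`, `wavenumbers` (when given),
#'   `X_ortho` (working matrix after the final step), `stop_reason`
#'   (`"k_max"`, `"ratio_rule"` or `"weight_floor"`).
#' @export
run_select <- function(X, labels, k_max = 20, min_ratio = 3,
                       weight_floor = 0, wavenumbers = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  limit <- floor(n / min_ratio)
  if (limit < 1) stop("training set too small for min_ratio = ", min_ratio)
  k_allow <- min(k_max, limit, ncol(X))
  Xw <- X
  selected <- integer(0)
  weights <- numeric(0)
  stop_reason <- NULL
  while (length(selected) < k_allow) {
    w <- fisher_weight(Xw, labels)
    w[selected] <- -Inf
    wmax <- max(w)
    if (wmax < weight_floor || wmax <= 0) { stop_reason <- "weight_floor"; break }
    j <- which(w == wmax)[1]             # tie -> lowest column index
    selected <- c(selected, j)
    weights <- c(weights, wmax)
    Xw <- orthogonalize_against(Xw, j)
  }
  if (is.null(stop_reason))
    stop_reason <- if (k_allow == limit && limit <= k_max) "ratio_rule"
                   else "k_max"
  structure(list(selected = selected, weights = weights,
                 k = length(selected),
                 wavenumbers = if (!is.null(wavenumbers))
                   wavenumbers[selected],
                 X_ortho = Xw, stop_reason = stop_reason,
                 n_train = n, min_ratio = min_ratio, k_max = k_max),
            class = "select_result")
}

#' @export
print.select_result <- function(x, ...) {
  cat("<select_result> ", x$k, " variable(s) selected (stop: ",
      x$stop_reason, ")\n", sep = "")
  tab <- data.frame(step = seq_len(x$k), column = x$selected,
                    weight = signif(x$weights, 4))
  if (!is.null(x$wavenumbers)) tab$wavenumber <- round(x$wavenumbers, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
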