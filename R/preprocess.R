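#' Average instrumental replicates
#'
#' Collapses each replicate group (from the `replicate_of` map) to its
#' arithmetic mean spectrum, one row per biological sample. Labels are carried
#' over (they must agree within a group).
#'
#' @param x a [spectra_set()] with a replicate map.
#' @return a `spectra_set` with one spectrum per biological sample, in first
#'   appearance order.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.null(x$replicate_of))
    stop("no replicate map present; nothing to average")
  groups <- x$replicate_of[x$sample_ids]
  uniq <- unique(unname(groups))
  counts <- table(groups)
  if (any(counts == 0)) stop("replicate group with 0 rows")
  M <- rowsum(x$absorbance, group = unname(groups), reorder = FALSE) /
    as.vector(counts[uniq])
  M <- M[uniq, , drop = FALSE]
  labels <- NULL
  if (!is.null(x$labels)) {
    agg <- tapply(x$labels, groups, function(l) {
      u <- unique(l)
      if (length(u) > 1) stop("conflicting labels within a replicate group")
      u
    })
    labels <- as.character(agg[uniq])
  }
  out <- spectra_set(x$wavenumbers, M, sample_ids = uniq, labels = labels)
  out$replicate_of <- NULL
  out
}

# contiguous uniform segments of a descending grid; splits at spacing jumps
# larger than 1.5x the median step, errors if spacing varies within a
# segment beyond tol (cm^-1)
grid_segments <- function(wn, tol = 1e-6) {
  if (length(wn) < 2) return(list(seq_along(wn)))
  step <- -diff(wn)                      # positive for descending grid
  med <- stats::median(step)
  breaks <- which(step > 1.5 * med)
  bounds <- c(0, breaks, length(wn))
  segs <- lapply(seq_len(length(bounds) - 1), function(i)
    (bounds[i] + 1):bounds[i + 1])
  for (s in segs) {
    if (length(s) < 2) next
    st <- step[s[-length(s)]]
    if (diff(range(st)) > tol)
      stop("non-uniform grid spacing within a region (max deviation ",
           format(diff(range(st))), " cm-1 exceeds tolerance ", tol, ")")
  }
  segs
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Least-squares polynomial filtering applied separately within each
#' contiguous uniform grid segment (never convolving across the gap between
#' spectral regions); boundary points use the polynomial fit of the edge
#' windows. Derivatives are taken with respect to wavenumber: because the grid
#' is stored descending, odd derivatives are sign-flipped relative to the
#' column index direction.
#'
#' @param x a [spectra_set()].
#' @param window odd filter length, `> polyorder`.
#' @param polyorder polynomial order.
#' @param deriv derivative order, `<= polyorder` (0 = smoothing).
#' @return filtered `spectra_set`; derivative units are absorbance per
#'   (cm^-1)^deriv.
#' @export
savitzky_golay <- function(x, window = 9, polyorder = 2, deriv = 0) {
  stopifnot(inherits(x, "spectra_set"))
  if (window %% 2 != 1) stop("window must be odd, got ", window)
  if (window <= polyorder) stop("window must exceed polyorder")
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  if (length(x$wavenumbers) < window)
    stop("grid shorter than filter window")
  segs <- grid_segments(x$wavenumbers)
  out <- x$absorbance
  for (s in segs) {
    if (length(s) < window)
      stop("grid segment of ", length(s), " points shorter than window ",
           window)
    d <- if (length(s) > 1) x$wavenumbers[s[1]] - x$wavenumbers[s[2]] else 1
    block <- x$absorbance[, s, drop = FALSE]
    filt <- t(apply(block, 1, signal::sgolayfilt, p = polyorder, n = window,
                    m = deriv, ts = d))
    # descending storage: d/dv = -(1/d) d/dindex
    out[, s] <- filt * (-1)^deriv
  }
  y <- x; y$absorbance <- out
  y
}

#' Standard normal variate transform
#'
#' Row-wise centering and unit-variance scaling (`n - 1` denominator),
#' removing per-spectrum offset and multiplicative scatter.
#'
#' @param x a [spectra_set()].
#' @return transformed `spectra_set`; every row has mean 0 and sd 1.
#' @export
snv <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  m <- rowMeans(x$absorbance)
  s <- apply(x$absorbance, 1, stats::sd)
  zero <- s < .Machine$double.eps * 1e3
  if (any(zero))
    stop("constant spectrum (zero row variance) for sample(s): ",
         paste(x$sample_ids[zero], collapse = ", "))
  y <- x
  y$absorbance <- (x$absorbance - m) / s
  y
}

#' Extended multiplicative scatter correction
#'
#' Fits each spectrum as `x ~ a + b*ref + c*v + d*v^2` (v = wavenumber,
#' internally rescaled to [-1, 1] for conditioning) and returns
#' `(x - a - c*v - d*v^2) / b`.
#'
#' @param x a [spectra_set()].
#' @param reference reference spectrum on the same grid; default the mean
#'   spectrum of `x` (for a test set pass the training mean).
#' @return corrected `spectra_set`.
#' @export
emsc <- function(x, reference = NULL) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.null(reference)) reference <- colMeans(x$absorbance)
  if (length(reference) != length(x$wavenumbers))
    stop("reference spectrum length does not match grid")
  v <- x$wavenumbers
  v <- 2 * (v - min(v)) / (max(v) - min(v)) - 1
  B <- cbind(1, reference, v, v^2)
  coef <- qr.coef(qr(B), t(x$absorbance))       # 4 x n
  b <- coef[2, ]
  deg <- abs(b) < 1e-8
  if (any(deg))
    stop("degenerate multiplicative term (|b| < 1e-8) for sample(s): ",
         paste(x$sample_ids[deg], collapse = ", "))
  poly_part <- B[, c(1, 3, 4)] %*% coef[c(1, 3, 4), , drop = FALSE]
  y <- x
  y$absorbance <- t((t(x$absorbance) - poly_part) / rep(b, each = length(v)))
  dimnames(y$absorbance) <- dimnames(x$absorbance)
  y
}

#' Restrict a spectra set to wavenumber regions
#'
#' Keeps grid points falling inside any of the given `(high, low)` ranges
#' (inclusive), preserving descending order.
#'
#' @param x a [spectra_set()].
#' @param regions matrix/list of `(high, low)` ranges, default
#'   [default_regions()].
#' @return restricted `spectra_set`.
#' @export
restrict_regions <- function(x, regions = default_regions()) {
  stopifnot(inherits(x, "spectra_set"))
  regions <- as_regions(regions)
  keep <- rep(FALSE, length(x$wavenumbers))
  for (i in seq_len(nrow(regions)))
    keep <- keep | (x$wavenumbers <= regions[i, 1] &
                    x$wavenumbers >= regions[i, 2])
  if (!any(keep)) stop("no grid points inside the requested regions")
  y <- x
  y$wavenumbers <- x$wavenumbers[keep]
  y$absorbance <- x$absorbance[, keep, drop = FALSE]
  y
}

#' Column mean-centering with reusable means
#'
#' @param X numeric matrix (samples x variables).
#' @param means optional column means to subtract (training means applied to
#'   a test set); computed from `X` when omitted.
#' @return list with `X` (centered matrix) and `means` (the means used).
#' @export
mean_center <- function(X, means = NULL) {
  X <- as.matrix(X)
  if (is.null(means)) means <- colMeans(X)
  if (length(means) != ncol(X)) stop("means length does not match columns")
  list(X = sweep(X, 2, means), means = means)
}

#' Preprocessing plan
#'
#' An ordered list of preprocessing steps applied by [apply_plan()]. The
#' default reproduces the study pipeline: replicate averaging, mild
#' Savitzky-Golay smoothing (window 9, order 2), SNV, restriction to the two
#' analysed regions.
#'
#' @param steps character vector drawn from `"average_replicates"`,
#'   `"savgol"`, `"snv"`, `"emsc"`, `"restrict"`.
#' @param savgol list(window, polyorder, deriv).
#' @param regions regions for the restrict step.
#' @param emsc_reference optional EMSC reference spectrum.
#' @return a `preprocess_plan`.
#' @export
preprocess_plan <- function(steps = c("average_replicates", "savgol", "snv",
                                      "restrict"),
                            savgol = list(window = 9, polyorder = 2, deriv = 0),
                            regions = default_regions(),
                            emsc_reference = NULL) {
  stopifnot(savgol$window %% 2 == 1, savgol$window > savgol$polyorder,
            savgol$deriv <= savgol$polyorder)
  structure(list(steps = steps, savgol = savgol, regions = regions,
                 emsc_reference = emsc_reference),
            class = "preprocess_plan")
}

#' Apply a preprocessing plan
#'
#' @param x a [spectra_set()].
#' @param plan a [preprocess_plan()].
#' @return preprocessed `spectra_set`. The `average_replicates` step is
#'   skipped silently when no replicate map is present.
#' @export
apply_plan <- function(x, plan = preprocess_plan()) {
  stopifnot(inherits(plan, "preprocess_plan"))
  for (st in plan$steps) {
    x <- switch(st,
      average_replicates = if (is.null(x$replicate_of)) x
                           else average_replicates(x),
      savgol = savitzky_golay(x, plan$savgol$window, plan$savgol$polyorder,
                              plan$savgol$deriv),
      snv = snv(x),
      emsc = emsc(x, plan$emsc_reference),
      restrict = restrict_regions(x, plan$regions),
      stop("unknown preprocessing step: ", st))
  }
  x
}
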