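#' Default wavenumber grid
#'
#' Two uniform descending segments covering the analysed mid-IR ranges
#' 1583-1050 cm^-1 (biochemical fingerprint region, extended) and
#' 2973-2700 cm^-1 (C-H stretching region), with 838 points in total. Points
#' are allocated to the segments proportionally to their widths (554 + 284),
#' giving per-segment spacings of 533/553 and 273/283 cm^-1 — both within
#' 1e-3 of the nominal common spacing 806/836 cm^-1.
#'
#' @param n_total total number of grid points (default 838).
#' @param regions matrix/list of `(high, low)` ranges; default the two ranges
#'   above.
#' @return descending numeric wavenumber grid.
#' @export
default_grid <- function(n_total = 838, regions = default_regions()) {
  regions <- as_regions(regions)
  widths <- regions[, 1] - regions[, 2]
  n <- round(n_total * widths / sum(widths))
  n[1] <- n_total - sum(n[-1])          # largest segment absorbs rounding
  pts <- lapply(seq_len(nrow(regions)), function(i)
    seq(regions[i, 1], regions[i, 2], length.out = n[i]))
  sort(unlist(pts), decreasing = TRUE)
}

#' Uniform grid from ranges and a fixed spacing
#'
#' @param regions matrix/list of `(high, low)` ranges in cm^-1.
#' @param spacing grid spacing in cm^-1 (> 0).
#' @return descending grid; each segment runs from its high edge downward in
#'   steps of `spacing` (the low edge is included only when the width is a
#'   multiple of `spacing`).
#' @export
make_grid <- function(regions, spacing) {
  stopifnot(spacing > 0)
  regions <- as_regions(regions)
  pts <- lapply(seq_len(nrow(regions)), function(i)
    seq(regions[i, 1], regions[i, 2], by = -spacing))
  sort(unlist(pts), decreasing = TRUE)
}

#' The two analysed spectral regions
#' @return 2x2 matrix with columns `high`, `low` (cm^-1).
#' @export
default_regions <- function()
  matrix(c(2973, 2700, 1583, 1050), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("high", "low")))

as_regions <- function(regions) {
  if (is.list(regions) && !is.data.frame(regions))
    regions <- do.call(rbind, regions)
  regions <- matrix(as.numeric(as.matrix(regions)), ncol = 2)
  regions <- t(apply(regions, 1, function(r) c(max(r), min(r))))
  colnames(regions) <- c("high", "low")
  regions[order(regions[, 1], decreasing = TRUE), , drop = FALSE]
}

#' Reference ranges of the clinical parameters per class
#'
#' Cohort descriptive statistics (max / min / mean per class, mg/dL and mmHg)
#' used as generator defaults: MetS patients have markedly higher
#' triglycerides and glucose and lower HDL than the no-MetS group.
#'
#' @return data.frame with columns `param`, `class`, `max`, `min`, `mean`.
#' @export
default_clinical_ranges <- function() {
  df <- rbind(
    data.frame(param = c("SP", "DP", "TGL", "HDL", "GLU"), class = "MetS",
               max  = c(174, 109, 338, 58, 164),
               min  = c(120, 75, 88, 25, 82),
               mean = c(136, 87, 242, 37, 114)),
    data.frame(param = c("SP", "DP", "TGL", "HDL", "GLU"), class = "noMetS",
               max  = c(178, 115, 215, 95, 123),
               min  = c(94, 61, 33, 29, 63),
               mean = c(126, 79, 109, 55, 91)))
  df
}

#' Default band library for the spectra generator
#'
#' Gaussian absorption bands placed on the analysed grid. The ten
#' `informative` bands sit at the discriminating band centers (amide II
#' protein bands linked negatively to HDL; CH2/CH3 stretching bands of
#' lipids linked to TGL; C-O carbohydrate bands linked to GLU; the remaining
#' centers linked to blood pressure and TGL), each receiving in addition a
#' direct class shift scaled by the generator's `effect_size`. The unnamed
#' background bands are class-neutral and shared by all samples, emulating
#' the common plasma matrix.
#'
#' @return data.frame with columns `center` (cm^-1), `width` (Gaussian sd,
#'   cm^-1), `base` (absorbance), `link` (clinical variable or `"none"`),
#'   `sign` (+1/-1 link direction), `strength` (amplitude scale, absorbance
#'   units), `informative` (logical).
#' @export
default_band_library <- function() {
  info <- data.frame(
    center = c(2860.22, 1423.36, 1562.22, 1578.61, 1108.98,
               1316.32, 2948.94, 1557.40, 1133.09, 1247.85),
    width  = 5,
    base   = 0.05,
    link   = c("TGL", "SP", "HDL", "HDL", "GLU",
               "DP", "TGL", "HDL", "GLU", "TGL"),
    sign   = c(1, 1, -1, -1, 1, 1, 1, -1, 1, 1),
    strength = 0.008,
    informative = TRUE)
  bg <- data.frame(
    center = c(1545, 1450, 1400, 1160, 1080, 2930, 2855, 1500),
    width  = c(25, 20, 30, 25, 22, 20, 15, 35),
    base   = c(0.35, 0.20, 0.25, 0.18, 0.20, 0.30, 0.25, 0.15),
    link   = "none", sign = 1, strength = 0, informative = FALSE)
  rbind(info, bg)
}

#' Generator configuration
#'
#' Defines the synthetic study conditions: class sizes (19 MetS / 86 noMetS),
#' clinical value distributions (truncated normals within the reference
#' ranges), the band library, the controlled between-class spectral effect
#' size, replicate structure and noise/baseline/scatter levels.
#'
#' @param n_mets,n_nomets class sizes.
#' @param seed RNG seed; regeneration with the same config is bit-identical.
#' @param clinical_ranges per-class per-parameter (max, min, mean), default
#'   [default_clinical_ranges()]; truncated-normal sd is `(max - min)/4`.
#' @param band_library see [default_band_library()].
#' @param effect_size between-class shift of each informative band amplitude
#'   in units of its within-class SD (default 6, a strong-signal regime).
#' @param noise_sd additive absorbance noise sd per point (default 0.005).
#' @param baseline_offset_sd,baseline_slope_sd sd of the per-spectrum linear
#'   baseline offset (absorbance) and slope (absorbance per cm^-1).
#' @param scatter_sd sd of the per-spectrum multiplicative scatter factor
#'   around 1 (default 0.05).
#' @param n_replicates instrumental replicates per sample (default 3,
#'   averaged downstream); replicate ids are `"<sample>_rep<N>"`.
#' @param grid wavenumber grid, default [default_grid()].
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_mets = 19, n_nomets = 86, seed = 1,
                             clinical_ranges = default_clinical_ranges(),
                             band_library = default_band_library(),
                             effect_size = 6,
                             noise_sd = 0.005,
                             baseline_offset_sd = 0.01,
                             baseline_slope_sd = 1e-5,
                             scatter_sd = 0.05,
                             n_replicates = 3,
                             grid = default_grid()) {
  stopifnot(n_mets >= 0, n_nomets >= 0, n_replicates >= 1,
            all(band_library$width > 0), noise_sd >= 0, scatter_sd >= 0)
  with(clinical_ranges,
       stopifnot(all(min <= mean), all(mean <= max)))
  structure(list(n_mets = n_mets, n_nomets = n_nomets, seed = as.integer(seed),
                 clinical_ranges = clinical_ranges,
                 band_library = band_library, effect_size = effect_size,
                 noise_sd = noise_sd,
                 baseline_offset_sd = baseline_offset_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 scatter_sd = scatter_sd, n_replicates = n_replicates,
                 grid = grid),
            class = "generator_config")
}

# truncated normal draws by inverse-CDF (deterministic given the RNG stream)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic clinical table
#'
#' Each parameter is drawn per class from a truncated normal with the
#' reference mean, sd `(max - min)/4`, truncated to `[min, max]`. Sex is
#' Bernoulli(0.5).
#'
#' @param config a [generator_config()]. The RNG is seeded from
#'   `config$seed`.
#' @return a [clinical_table()] with labels attached.
#' @export
generate_clinical <- function(config) {
  set.seed(config$seed)
  n <- c(MetS = config$n_mets, noMetS = config$n_nomets)
  ranges <- config$clinical_ranges
  out <- lapply(names(n), function(cl) {
    if (n[[cl]] == 0) return(NULL)
    r <- ranges[ranges$class == cl, ]
    vals <- sapply(c("TGL", "HDL", "SP", "DP", "GLU"), function(p) {
      ri <- r[r$param == p, ]
      rtruncnorm(n[[cl]], ri$mean, (ri$max - ri$min) / 4, ri$min, ri$max)
    })
    vals <- matrix(vals, nrow = n[[cl]],
                   dimnames = list(NULL, c("TGL", "HDL", "SP", "DP", "GLU")))
    data.frame(vals, label = cl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  ids <- sprintf("S%03d", seq_len(nrow(out)))
  sex <- sample(c("M", "F"), nrow(out), replace = TRUE)
  clinical_table(ids, out$TGL, out$HDL, out$SP, out$DP, out$GLU,
                 sex = sex, label = out$label)
}

# within-class standardization constants for the clinical->band links:
# pooled center = midpoint of the class means, scale = mean of the class
# (max-min)/4 sds — fixed population constants, not sample estimates
link_standardizers <- function(ranges) {
  vars <- unique(ranges$param)
  out <- lapply(vars, function(p) {
    r <- ranges[ranges$param == p, ]
    list(center = mean(r$mean), scale = mean((r$max - r$min) / 4))
  })
  stats::setNames(out, vars)
}

#' Generate FTIR-like spectra from a clinical table
#'
#' Each spectrum is a sum of Gaussian bands plus a linear baseline, a
#' multiplicative scatter factor and additive noise:
#' `x_i(v) = baseline_i(v) + scatter_i * sum_b amp_ib * exp(-(v - c_b)^2 / (2 w_b^2)) + e`.
#' Linked band amplitudes covary with the standardized clinical value and, for
#' informative bands, carry the controlled class shift
#' `strength * effect_size/2 * (+1 MetS / -1 noMetS)` in the link direction.
#'
#' @param clinical a [clinical_table()] with labels.
#' @param config a [generator_config()]; the RNG is seeded from
#'   `config$seed + 1` so clinical and spectra streams are decoupled.
#' @return a [spectra_set()] (with replicates when `config$n_replicates > 1`).
#' @export
generate_spectra <- function(clinical, config) {
  stopifnot(nrow(clinical) > 0)
  set.seed(config$seed + 1L)
  grid <- config$grid
  bands <- config$band_library
  inside <- bands$center <= max(grid) & bands$center >= min(grid)
  if (any(!inside)) {
    warning("band center(s) outside grid skipped: ",
            paste(bands$center[!inside], collapse = ", "))
    bands <- bands[inside, , drop = FALSE]
  }
  std <- link_standardizers(config$clinical_ranges)
  n <- nrow(clinical)
  g <- ifelse(clinical$label == "MetS", 1, -1)

  # n x nbands amplitude matrix
  amp <- matrix(rep(bands$base, each = n), nrow = n)
  for (b in seq_len(nrow(bands))) {
    if (bands$link[b] == "none" || bands$strength[b] == 0) next
    z <- (clinical[[bands$link[b]]] - std[[bands$link[b]]]$center) /
      std[[bands$link[b]]]$scale
    shift <- if (bands$informative[b]) config$effect_size / 2 * g else 0
    amp[, b] <- amp[, b] + bands$strength[b] * bands$sign[b] * (z + shift)
  }
  # nbands x p band profiles
  prof <- exp(-outer(bands$center, grid, "-")^2 / (2 * bands$width^2))
  clean <- amp %*% prof

  nrep <- config$n_replicates
  N <- n * nrep
  scatter <- 1 + stats::rnorm(N, 0, config$scatter_sd)
  offs <- stats::rnorm(N, 0, config$baseline_offset_sd)
  slope <- stats::rnorm(N, 0, config$baseline_slope_sd)
  noise <- matrix(stats::rnorm(N * length(grid), 0, config$noise_sd), nrow = N)
  base_mat <- outer(offs, rep(1, length(grid))) + outer(slope, grid - mean(grid))
  rep_idx <- rep(seq_len(n), each = nrep)
  X <- base_mat + scatter * clean[rep_idx, , drop = FALSE] + noise

  if (nrep > 1) {
    ids <- paste0(rep(clinical$sample_id, each = nrep), "_rep",
                  rep(seq_len(nrep), times = n))
    labels <- rep(clinical$label, each = nrep)
  } else {
    ids <- clinical$sample_id
    labels <- clinical$label
  }
  spectra_set(grid, X, sample_ids = ids, labels = labels)
}

#' Generate a complete synthetic dataset
#'
#' Couples [generate_clinical()] and [generate_spectra()] under one seed and
#' records the ground truth: the generating class of every sample and, per
#' grid point, whether it is the nearest point to an informative band center.
#'
#' @param config a [generator_config()] (or arguments passed on to it).
#' @param ... overrides forwarded to [generator_config()] when `config` is
#'   missing.
#' @return a `synthetic_dataset` list with elements `spectra`, `clinical`,
#'   `truth` (`$class` named per sample, `$informative` logical per grid
#'   point, `$centers` the informative band centers) and `config`.
#' @export
make_dataset <- function(config = NULL, ...) {
  if (is.null(config)) config <- generator_config(...)
  stopifnot(inherits(config, "generator_config"))
  clinical <- generate_clinical(config)
  spectra <- generate_spectra(clinical, config)
  centers <- config$band_library$center[config$band_library$informative]
  centers <- centers[centers <= max(config$grid) & centers >= min(config$grid)]
  informative <- rep(FALSE, length(config$grid))
  informative[vapply(centers, function(cc)
    which.min(abs(config$grid - cc)), integer(1))] <- TRUE
  truth <- list(class = stats::setNames(clinical$label, clinical$sample_id),
                informative = informative, centers = centers)
  structure(list(spectra = spectra, clinical = clinical, truth = truth,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$clinical), " samples (",
      sum(x$clinical$label == "MetS"), " MetS / ",
      sum(x$clinical$label == "noMetS"), " noMetS), ",
      length(x$spectra$wavenumbers), " wavenumbers, ",
      x$config$n_replicates, " replicate(s)\n", sep = "")
  invisible(x)
}
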