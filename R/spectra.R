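#' Spectra set container
#'
#' Bundles a wavenumber grid with an absorbance matrix, sample identifiers and
#' optional replicate structure and class labels. The grid is always stored in
#' descending wavenumber order (FTIR convention); the absorbance columns are
#' reordered to match on construction.
#'
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly monotone
#'   (any input order; stored descending).
#' @param absorbance numeric matrix, samples in rows, one column per
#'   wavenumber, arbitrary absorbance units.
#' @param sample_ids character vector of unique sample identifiers. When
#'   omitted, row names of `absorbance` (or `S1..Sn`) are used.
#' @param replicate_of optional named character vector mapping each replicate
#'   id to its biological sample id. When `NULL`, ids of the form
#'   `"<sample>_rep<N>"` are parsed automatically.
#' @param labels optional per-sample class labels, `"MetS"`/`"noMetS"`
#'   (or `NA`).
#'
#' @return an object of class `spectra_set` with fields `wavenumbers`,
#'   `absorbance`, `sample_ids`, `replicate_of`, `labels`.
#' @export
spectra_set <- function(wavenumbers, absorbance, sample_ids = NULL,
                        replicate_of = NULL, labels = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (ncol(absorbance) != length(wavenumbers))
    stop("ncol(absorbance) [", ncol(absorbance), "] != length(wavenumbers) [",
         length(wavenumbers), "]")
  if (anyDuplicated(wavenumbers))
    stop("duplicate wavenumbers: ",
         paste(unique(wavenumbers[duplicated(wavenumbers)]), collapse = ", "))
  if (anyNA(wavenumbers)) stop("NA in wavenumber grid")
  if (anyNA(absorbance)) stop("NA/NaN in absorbance matrix")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(absorbance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance))
    stop("length(sample_ids) != nrow(absorbance)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))

  ord <- order(wavenumbers, decreasing = TRUE)
  wavenumbers <- wavenumbers[ord]
  absorbance <- absorbance[, ord, drop = FALSE]
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- format_wn(wavenumbers)

  if (is.null(replicate_of)) replicate_of <- parse_replicates(sample_ids)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(sample_ids))
      stop("length(labels) != number of samples")
    names(labels) <- sample_ids
  }
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         sample_ids = sample_ids, replicate_of = replicate_of,
         labels = labels),
    class = "spectra_set")
}

format_wn <- function(wn) formatC(wn, format = "f", digits = 4)

# ids of the form "<sample>_rep<N>" define replicate groups; NULL when no id
# matches the convention
parse_replicates <- function(ids) {
  hit <- grepl("^.+_rep[0-9]+$", ids)
  if (!any(hit)) return(NULL)
  parents <- ifelse(hit, sub("_rep[0-9]+$", "", ids), ids)
  stats::setNames(parents, ids)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " spectra x ",
      length(x$wavenumbers), " wavenumbers [",
      format(max(x$wavenumbers), nsmall = 2), " .. ",
      format(min(x$wavenumbers), nsmall = 2), " cm-1]\n", sep = "")
  if (!is.null(x$replicate_of))
    cat("  replicates of", length(unique(x$replicate_of)),
        "biological samples\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels, useNA = "no")
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample
#'
#' @param x a [spectra_set()].
#' @param ids sample ids or logical/integer index into the rows.
#' @return a `spectra_set` with the selected samples.
#' @export
subset_samples <- function(x, ids) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.character(ids)) {
    idx <- match(ids, x$sample_ids)
    if (anyNA(idx)) stop("unknown sample ids: ",
                         paste(ids[is.na(idx)], collapse = ", "))
  } else idx <- ids
  keep <- x$sample_ids[idx]
  spectra_set(x$wavenumbers, x$absorbance[idx, , drop = FALSE],
              sample_ids = keep,
              replicate_of = if (!is.null(x$replicate_of)) x$replicate_of[keep],
              labels = if (!is.null(x$labels)) x$labels[keep])
}

#' Clinical parameter table
#'
#' Per-sample table of the five measured MetS-relevant clinical parameters:
#' triglycerides (TGL, mg/dL), HDL cholesterol (mg/dL), systolic and diastolic
#' blood pressure (SP/DP, mmHg) and fasting glucose (GLU, mg/dL), with
#' optional sex and class label.
#'
#' @param sample_id character ids.
#' @param TGL,HDL,SP,DP,GLU numeric clinical values (units above).
#' @param sex `"M"`, `"F"` or `"unknown"`.
#' @param label `"MetS"`, `"noMetS"` or `"unknown"`.
#' @return a data.frame of class `clinical_table`.
#' @export
clinical_table <- function(sample_id, TGL, HDL, SP, DP, GLU,
                           sex = "unknown", label = "unknown") {
  df <- data.frame(sample_id = as.character(sample_id),
                   TGL = as.numeric(TGL), HDL = as.numeric(HDL),
                   SP = as.numeric(SP), DP = as.numeric(DP),
                   GLU = as.numeric(GLU),
                   sex = rep_len(as.character(sex), length(sample_id)),
                   label = rep_len(as.character(label), length(sample_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in clinical table")
  bad_sex <- !df$sex %in% c("M", "F", "unknown")
  if (any(bad_sex)) stop("invalid sex value(s): ",
                         paste(unique(df$sex[bad_sex]), collapse = ", "))
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Validate a clinical table for classification use
#'
#' All five parameters must be present, non-missing and strictly positive for
#' every sample that enters classification.
#'
#' @param clinical a [clinical_table()].
#' @return the table, invisibly; errors name offending samples.
#' @export
validate_clinical <- function(clinical) {
  vars <- c("TGL", "HDL", "SP", "DP", "GLU")
  miss <- setdiff(vars, names(clinical))
  if (length(miss)) stop("missing clinical columns: ",
                         paste(miss, collapse = ", "))
  vals <- as.matrix(clinical[, vars])
  bad <- apply(!is.finite(vals) | vals <= 0, 1, any)
  if (any(bad))
    stop("missing/non-positive clinical values for sample(s): ",
         paste(clinical$sample_id[bad], collapse = ", "))
  invisible(clinical)
}
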