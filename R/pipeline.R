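#' Stratified train/test split
#'
#' Draws the external test set at random (stratified by class so each class
#' keeps its ratio within one sample, guaranteeing MetS samples in a small
#' test set) and uses the identical split for every downstream branch.
#'
#' @param labels per-sample class labels (named by sample id when available).
#' @param n_test test-set size (default 10; the training set is the rest,
#'   95 of 105 under the default design).
#' @param stratified stratify by class (default TRUE).
#' @param seed RNG seed for the draw.
#' @return list `train` / `test` of indices (plus `train_ids` / `test_ids`
#'   when labels are named).
#' @export
split_train_test <- function(labels, n_test = 10, stratified = TRUE,
                             seed = 1) {
  labels <- if (is.null(names(labels))) as.character(labels)
            else stats::setNames(as.character(labels), names(labels))
  n <- length(labels)
  stopifnot(n_test >= 1, n_test < n)
  set.seed(seed)
  if (stratified) {
    classes <- sort(unique(labels))
    quota <- round(n_test * table(factor(labels, classes)) / n)
    # largest-remainder fixup so quotas sum to n_test
    while (sum(quota) > n_test) quota[which.max(quota)] <- quota[which.max(quota)] - 1
    while (sum(quota) < n_test) quota[which.min(quota)] <- quota[which.min(quota)] + 1
    test <- unlist(lapply(classes, function(k)
      sample(which(labels == k), quota[[k]])))
    test <- sort(test)
  } else {
    test <- sort(sample(n, n_test))
  }
  train <- setdiff(seq_len(n), test)
  if (length(unique(labels[train])) < length(unique(labels)))
    stop("a class is absent from the training set; reduce n_test or stratify")
  out <- list(train = train, test = test)
  if (!is.null(names(labels))) {
    out$train_ids <- names(labels)[train]
    out$test_ids <- names(labels)[test]
  }
  out
}

#' Count wavenumbers inside a spectral region
#'
#' @param wavenumbers numeric vector of wavenumbers (cm^-1).
#' @param region `(high, low)` bounds, order-agnostic, inclusive.
#' @return integer count.
#' @export
count_in_region <- function(wavenumbers, region) {
  hi <- max(region); lo <- min(region)
  sum(wavenumbers >= lo & wavenumbers <= hi)
}

#' Pipeline configuration
#'
#' @param plan preprocessing plan ([preprocess_plan()]).
#' @param n_test external test-set size (default 10).
#' @param stratified stratified split (default TRUE).
#' @param seed seed for the split (and recorded in the outputs).
#' @param select_k_lda SELECT size for the LDA branch (default 20).
#' @param select_k_simca variable count for the SIMCA spectral branch
#'   (default 10, recognition-guided truncation of the LDA-branch ranking).
#' @param min_ratio SELECT training-objects rule (default 3).
#' @param lda_priors,lda_ridge passed to [fit_lda()].
#' @param simca_A_clinical components per class for SIMCA on the clinical
#'   parameters (default 4).
#' @param simca_A_spectral components per class for SIMCA on the selected
#'   wavenumbers (default 3).
#' @param alpha SIMCA acceptance significance (default 0.05).
#' @param thresholds rule-engine thresholds ([mets_thresholds()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(plan = preprocess_plan(), n_test = 10,
                            stratified = TRUE, seed = 1,
                            select_k_lda = 20, select_k_simca = 10,
                            min_ratio = 3, lda_priors = "equal",
                            lda_ridge = "auto", simca_A_clinical = 4,
                            simca_A_spectral = 3, alpha = 0.05,
                            thresholds = mets_thresholds()) {
  structure(list(plan = plan, n_test = n_test, stratified = stratified,
                 seed = as.integer(seed), select_k_lda = select_k_lda,
                 select_k_simca = select_k_simca, min_ratio = min_ratio,
                 lda_priors = lda_priors, lda_ridge = lda_ridge,
                 simca_A_clinical = simca_A_clinical,
                 simca_A_spectral = simca_A_spectral, alpha = alpha,
                 thresholds = thresholds),
            class = "pipeline_config")
}

#' Run the dual classification study end to end
#'
#' Orchestrates the full analysis on a paired spectra + clinical dataset:
#' preprocessing (replicate averaging, Savitzky-Golay, SNV, region
#' restriction), NCEP-ATP-III rule labels, one shared stratified train/test
#' split, exploratory PCA, and the four classification branches — LDA on the
#' five clinical parameters, SELECT-LDA on the spectra, SIMCA on the
#' clinical parameters and SELECT-SIMCA on the spectra (the SIMCA branch
#' consumes the SELECT-LDA ranking truncated to `select_k_simca` variables
#' by training-recognition-guided removal).
#'
#' @param dataset a `synthetic_dataset` from [make_dataset()], or a list
#'   with elements `spectra` ([spectra_set()], labels optional) and
#'   `clinical` ([clinical_table()] with labels).
#' @param config a [pipeline_config()].
#' @return a `mets_run` bundle: `lda_clinical`, `lda_spectral`
#'   (classification reports), `simca_clinical`, `simca_spectral` (SIMCA
#'   reports), `select` (the SELECT result), `selected_wavenumbers_lda`,
#'   `selected_wavenumbers_simca`, `pca_clinical`, `pca_spectral`,
#'   `rule_labels`, `split`, `config`, `seed`.
#' @export
run_dual_classification <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  clinical <- dataset$clinical
  validate_clinical(clinical)

  # preprocessing (replicates averaged first, then SG/SNV/restrict)
  spec <- apply_plan(dataset$spectra, config$plan)
  if (!identical(spec$sample_ids, clinical$sample_id))
    spec <- subset_samples(spec, clinical$sample_id)

  labels <- stats::setNames(clinical$label, clinical$sample_id)
  if (any(labels == "unknown"))
    stop("clinical table carries unlabelled samples; label them (e.g. with ",
         "classify_mets) before running the pipeline")
  rule_labels <- classify_mets(clinical, config$thresholds)

  split <- split_train_test(labels, config$n_test, config$stratified,
                            config$seed)
  tr <- split$train; te <- split$test

  Xc <- as.matrix(clinical[, c("TGL", "HDL", "SP", "DP", "GLU")])
  rownames(Xc) <- clinical$sample_id
  Xs <- spec$absorbance

  # exploratory PCA: autoscaled for the heterogeneous clinical units,
  # centering only for the pre-treated spectra
  pca_clinical <- fit_nipals(Xc, A = min(4, ncol(Xc)), scale = TRUE)
  pca_spectral <- fit_nipals(Xs, A = 2, scale = FALSE)

  # centering: training means applied to the test rows
  cc <- mean_center(Xc[tr, , drop = FALSE])
  Xc_tr <- cc$X; Xc_te <- mean_center(Xc[te, , drop = FALSE], cc$means)$X
  cs <- mean_center(Xs[tr, , drop = FALSE])
  Xs_tr <- cs$X; Xs_te <- mean_center(Xs[te, , drop = FALSE], cs$means)$X

  # branch 1: LDA on clinical parameters
  lda_clin_fit <- fit_lda(Xc_tr, labels[tr], config$lda_priors,
                          config$lda_ridge)
  loo_c <- loo_cv_lda(Xc_tr, labels[tr], config$lda_priors, config$lda_ridge)
  lda_clinical <- classification_report(
    loo_c$predicted, labels[tr], predict(lda_clin_fit, Xc_te), labels[te],
    names(labels)[tr], names(labels)[te])

  # branch 2: SELECT-LDA on spectra
  sel <- run_select(Xs_tr, labels[tr], k_max = config$select_k_lda,
                    min_ratio = config$min_ratio,
                    wavenumbers = spec$wavenumbers)
  cols <- sel$selected
  lda_spec_fit <- suppressWarnings(
    fit_lda(Xs_tr[, cols, drop = FALSE], labels[tr], config$lda_priors,
            config$lda_ridge))
  loo_s <- suppressWarnings(
    loo_cv_lda(Xs_tr[, cols, drop = FALSE], labels[tr], config$lda_priors,
               config$lda_ridge))
  lda_spectral <- classification_report(
    loo_s$predicted, labels[tr],
    predict(lda_spec_fit, Xs_te[, cols, drop = FALSE]), labels[te],
    names(labels)[tr], names(labels)[te])

  # branch 3: SIMCA on clinical parameters
  simca_clinical <- simca_report(
    Xc_tr, labels[tr], Xc_te, labels[te], A = config$simca_A_clinical,
    alpha = config$alpha,
    variable_names = c("TGL", "HDL", "SP", "DP", "GLU"))

  # branch 4: SELECT-SIMCA on spectra, 20 -> 10 recognition-guided
  trunc <- truncate_for_simca(Xs_tr, labels[tr], sel$selected, sel$weights,
                              k_target = config$select_k_simca,
                              A = config$simca_A_spectral,
                              alpha = config$alpha)
  cols10 <- trunc$selected
  simca_spectral <- simca_report(
    Xs_tr[, cols10, drop = FALSE], labels[tr],
    Xs_te[, cols10, drop = FALSE], labels[te],
    A = config$simca_A_spectral, alpha = config$alpha,
    variable_names = format_wn(spec$wavenumbers[cols10]))

  structure(list(
    lda_clinical = lda_clinical, lda_spectral = lda_spectral,
    simca_clinical = simca_clinical, simca_spectral = simca_spectral,
    select = sel,
    selected_wavenumbers_lda = spec$wavenumbers[sel$selected],
    selected_wavenumbers_simca = spec$wavenumbers[cols10],
    simca_recognition = trunc$recognition,
    pca_clinical = pca_clinical, pca_spectral = pca_spectral,
    rule_labels = rule_labels, labels = labels, split = split,
    config = config, seed = config$seed),
    class = "mets_run")
}

#' @export
print.mets_run <- function(x, ...) {
  cat("<mets_run> seed", x$seed, "\n\n-- LDA, clinical parameters --\n")
  print(x$lda_clinical)
  cat("\n-- SELECT-LDA, ", length(x$selected_wavenumbers_lda),
      " wavenumbers --\n", sep = "")
  print(x$lda_spectral)
  cat("\n-- SIMCA, clinical parameters --\n")
  print(x$simca_clinical)
  cat("\n-- SELECT-SIMCA, ", length(x$selected_wavenumbers_simca),
      " wavenumbers --\n", sep = "")
  print(x$simca_spectral)
  invisible(x)
}
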