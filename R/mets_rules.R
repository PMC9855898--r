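#' NCEP-ATP-III criteria thresholds
#'
#' MetS is diagnosed when at least `n_required` of the risk-factor criteria
#' are met. With waist circumference unavailable, four criteria are
#' evaluable from the clinical table: elevated triglycerides
#' (TGL >= 150 mg/dL), low HDL (< 50 mg/dL in women, < 40 mg/dL in men),
#' elevated blood pressure (SP > 130 or DP > 85 mmHg — one combined
#' criterion), and elevated fasting glucose (> 110 mg/dL). TGL is inclusive;
#' glucose and blood pressure are strict by default (`bp_inclusive` switches
#' to >=).
#'
#' @param tgl_min triglyceride cut-off, mg/dL (criterion met when `>=`).
#' @param hdl_max_female,hdl_max_male HDL cut-offs, mg/dL (met when `<`).
#' @param bp_sys,bp_dia blood-pressure cut-offs, mmHg (met when `>`, or `>=`
#'   with `bp_inclusive = TRUE`).
#' @param glu_min fasting-glucose cut-off, mg/dL (met when `>`).
#' @param n_required criteria needed for a MetS label (default 3).
#' @param unknown_sex_hdl HDL cut-off used when sex is unknown: `"male"`
#'   (conservative default, 40 mg/dL) or `"female"`.
#' @param bp_inclusive treat the blood-pressure cut-offs as `>=`.
#' @return a `mets_thresholds` list.
#' @export
mets_thresholds <- function(tgl_min = 150, hdl_max_female = 50,
                            hdl_max_male = 40, bp_sys = 130, bp_dia = 85,
                            glu_min = 110, n_required = 3,
                            unknown_sex_hdl = c("male", "female"),
                            bp_inclusive = FALSE) {
  unknown_sex_hdl <- match.arg(unknown_sex_hdl)
  stopifnot(tgl_min > 0, hdl_max_female > 0, hdl_max_male > 0, bp_sys > 0,
            bp_dia > 0, glu_min > 0, n_required >= 1, n_required <= 5)
  structure(list(tgl_min = tgl_min, hdl_max_female = hdl_max_female,
                 hdl_max_male = hdl_max_male, bp_sys = bp_sys,
                 bp_dia = bp_dia, glu_min = glu_min, n_required = n_required,
                 unknown_sex_hdl = unknown_sex_hdl,
                 bp_inclusive = bp_inclusive),
            class = "mets_thresholds")
}

#' Count MetS criteria met
#'
#' Vectorised over the rows of a clinical table. Blood pressure counts as a
#' single criterion, met when either the systolic or the diastolic cut-off is
#' exceeded.
#'
#' @param clinical a [clinical_table()] (or any data.frame with columns TGL,
#'   HDL, SP, DP, GLU and optionally sex).
#' @param thresholds a [mets_thresholds()].
#' @return integer vector of criteria counts (0..4 without waist
#'   circumference), named by sample id when available.
#' @export
count_criteria <- function(clinical, thresholds = mets_thresholds()) {
  validate_clinical(clinical)
  th <- thresholds
  sex <- if ("sex" %in% names(clinical)) clinical$sex else "unknown"
  sex <- rep_len(as.character(sex), nrow(clinical))
  hdl_cut <- ifelse(sex == "F", th$hdl_max_female,
             ifelse(sex == "M", th$hdl_max_male,
                    if (th$unknown_sex_hdl == "male") th$hdl_max_male
                    else th$hdl_max_female))
  gt <- if (th$bp_inclusive) `>=` else `>`
  met <- cbind(tgl = clinical$TGL >= th$tgl_min,
               hdl = clinical$HDL < hdl_cut,
               bp  = gt(clinical$SP, th$bp_sys) | gt(clinical$DP, th$bp_dia),
               glu = clinical$GLU > th$glu_min)
  counts <- as.integer(rowSums(met))
  if ("sample_id" %in% names(clinical)) names(counts) <- clinical$sample_id
  counts
}

#' Classify MetS from clinical parameters
#'
#' @inheritParams count_criteria
#' @return character vector of labels, `"MetS"` when
#'   [count_criteria()] `>= n_required`, else `"noMetS"`.
#' @export
classify_mets <- function(clinical, thresholds = mets_thresholds()) {
  counts <- count_criteria(clinical, thresholds)
  stats::setNames(ifelse(counts >= thresholds$n_required, "MetS", "noMetS"),
                  names(counts))
}
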