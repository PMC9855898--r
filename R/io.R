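#' Read a wide-format spectra CSV
#'
#' The interchange format is comma-separated UTF-8 with '.' decimals. In
#' `"samples_rows"` orientation the header row holds the numeric wavenumbers
#' and the first column the sample ids; `"samples_cols"` is the transpose
#' (first column wavenumbers, remaining columns one sample each).
#'
#' @param path file path.
#' @param orientation `"samples_rows"` (default) or `"samples_cols"`.
#' @return a [spectra_set()]; the grid is sorted descending and replicate ids
#'   of the form `sampleID_repN` are detected.
#' @export
read_spectra_csv <- function(path, orientation = c("samples_rows", "samples_cols")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (orientation == "samples_cols") {
    wn_chr <- raw[[1]]
    ids <- colnames(raw)[-1]
    mat_chr <- t(as.matrix(raw[, -1, drop = FALSE]))
  } else {
    wn_chr <- colnames(raw)[-1]
    ids <- raw[[1]]
    mat_chr <- as.matrix(raw[, -1, drop = FALSE])
  }
  wn <- suppressWarnings(as.numeric(wn_chr))
  if (anyNA(wn))
    stop("non-numeric wavenumber header entries: ",
         paste(utils::head(wn_chr[is.na(wn)], 5), collapse = ", "))
  if (anyDuplicated(wn))
    stop("duplicate wavenumber(s) in ", path, ": ",
         paste(unique(wn[duplicated(wn)]), collapse = ", "))
  mat <- suppressWarnings(matrix(as.numeric(mat_chr), nrow = nrow(mat_chr)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("non-numeric absorbance cell at sample '", ids[bad[1]],
         "', wavenumber ", wn[bad[2]])
  }
  spectra_set(wn, mat, sample_ids = ids)
}

#' Write a spectra set as a wide CSV
#'
#' @param x a [spectra_set()].
#' @param path output file path.
#' @return `path`, invisibly. Values are written with 15 significant digits so
#'   a read/write round trip preserves them to better than 1e-12 relative.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  df <- data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE)
  vals <- as.data.frame(x$absorbance)
  colnames(vals) <- formatC(x$wavenumbers, format = "g", digits = 15)
  utils::write.csv(cbind(df, vals), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical parameter CSV
#'
#' Requires columns for the five parameters (case-insensitive; aliases
#' configurable): TGL, HDL, SP, DP, GLU. A `sample_id` column is used when
#' present, otherwise ids `S1..Sn` are assigned. Missing `sex`/`label`
#' columns default to `"unknown"`.
#'
#' @param path file path.
#' @param aliases named list mapping canonical names to accepted column-name
#'   aliases (matched case-insensitively).
#' @return a [clinical_table()].
#' @export
read_clinical_csv <- function(path, aliases = clinical_aliases()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("empty clinical file: ", path)
    return(clinical_table(character(), numeric(), numeric(), numeric(),
                          numeric(), numeric()))
  }
  lower <- tolower(trimws(colnames(raw)))
  pick <- function(canon) {
    hit <- which(lower %in% tolower(aliases[[canon]]))
    if (length(hit) == 0) return(NA_integer_)
    hit[1]
  }
  cols <- vapply(c("sample_id", "TGL", "HDL", "SP", "DP", "GLU", "sex", "label"),
                 pick, integer(1))
  ids <- if (is.na(cols["sample_id"])) paste0("S", seq_len(nrow(raw)))
         else as.character(raw[[cols["sample_id"]]])
  need <- c("TGL", "HDL", "SP", "DP", "GLU")
  absent <- need[is.na(cols[need])]
  if (length(absent))
    stop("clinical file lacks required column(s): ",
         paste(absent, collapse = ", "))
  num <- lapply(need, function(v) {
    x <- suppressWarnings(as.numeric(raw[[cols[v]]]))
    if (anyNA(x))
      stop("missing/non-numeric ", v, " for sample(s): ",
           paste(ids[is.na(x)], collapse = ", "))
    x
  })
  names(num) <- need
  clinical_table(ids, num$TGL, num$HDL, num$SP, num$DP, num$GLU,
                 sex = if (is.na(cols["sex"])) "unknown"
                       else as.character(raw[[cols["sex"]]]),
                 label = if (is.na(cols["label"])) "unknown"
                         else as.character(raw[[cols["label"]]]))
}

#' Default column-name aliases for clinical CSVs
#' @return named list of accepted aliases per canonical column.
#' @export
clinical_aliases <- function() {
  list(sample_id = c("sample_id", "id", "sample"),
       TGL = c("tgl", "triglycerides", "tg"),
       HDL = c("hdl", "hdl_cholesterol"),
       SP = c("sp", "sbp", "systolic", "systolic_bp"),
       DP = c("dp", "dbp", "diastolic", "diastolic_bp"),
       GLU = c("glu", "glucose", "fasting_glucose"),
       sex = c("sex", "gender"),
       label = c("label", "class", "group"))
}

#' Write a clinical table as CSV
#' @param clinical a [clinical_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(as.data.frame(clinical), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Minimal read-only support for the common AFFN `(X++(Y..Y))` and `(XY..XY)`
#' tabular forms, enough to ingest one exported instrument spectrum. The
#' internal model remains the wide table; multi-block files are not supported.
#'
#' @param path file path.
#' @param sample_id id for the resulting single-row [spectra_set()]; defaults
#'   to the `##TITLE=` entry or the file name.
#' @return a one-sample `spectra_set`.
#' @export
read_jcampdx <- function(path, sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\$\\$.*$", "", lines)           # strip comments
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "\\s*="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  title <- get_field("TITLE")
  xfac <- as.numeric(get_field("XFACTOR") %||% "1")
  yfac <- as.numeric(get_field("YFACTOR") %||% "1")
  start <- grep("^##(XYDATA|XYPOINTS)\\s*=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA/##XYPOINTS block in ", path)
  form <- toupper(get_field("XYDATA") %||% get_field("XYPOINTS"))
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- end[end > start[1]]
  body <- lines[(start[1] + 1):(if (length(end)) end[1] - 1 else length(lines))]
  body <- body[nzchar(trimws(body))]
  if (grepl("X\\+\\+", form)) {
    xs <- c(); ys <- c()
    for (ln in body) {
      tok <- as.numeric(strsplit(trimws(ln), "[,;[:space:]]+")[[1]])
      if (anyNA(tok) || length(tok) < 2)
        stop("unparseable JCAMP data line: ", ln)
      x0 <- tok[1]; yy <- tok[-1]
      # per-line x restart; spacing from declared DELTAX or inferred later
      xs <- c(xs, x0); ys <- c(ys, list(yy))
    }
    deltax <- as.numeric(get_field("DELTAX") %||% NA)
    if (is.na(deltax)) {
      npts <- lengths(ys)
      if (length(xs) > 1) deltax <- (xs[2] - xs[1]) / npts[1]
      else {
        lastx <- as.numeric(get_field("LASTX"))
        deltax <- (lastx - xs[1]) / (npts[1] - 1)
      }
    }
    wn <- unlist(mapply(function(x0, yy) x0 + deltax * (seq_along(yy) - 1),
                        xs, ys, SIMPLIFY = FALSE))
    y <- unlist(ys)
  } else {
    tok <- as.numeric(strsplit(paste(trimws(body), collapse = " "),
                               "[,;[:space:]]+")[[1]])
    if (anyNA(tok) || length(tok) %% 2 != 0)
      stop("unparseable (XY..XY) data in ", path)
    wn <- tok[seq(1, length(tok), 2)]
    y <- tok[seq(2, length(tok), 2)]
  }
  id <- sample_id %||% title %||% basename(path)
  spectra_set(wn * xfac, matrix(y * yfac, nrow = 1), sample_ids = id)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write report tables to disk
#'
#' Serialises a classification or SIMCA report either as one CSV per table
#' kind (`<prefix>_rates.csv`, `<prefix>_simca_summary.csv`,
#' `<prefix>_mp_dp.csv`, `<prefix>_cooman.csv`, as applicable) or as a single
#' JSON file `<prefix>.json` holding all tables at full precision.
#'
#' @param report a `classification_report` or `simca_report` (or a plain named
#'   list of data.frames).
#' @param path_prefix output path prefix (directory must exist).
#' @param format `"csv"` or `"json"`.
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(report, path_prefix, format = c("csv", "json")) {
  format <- match.arg(format)
  tabs <- report_tables(report)
  if (format == "json") {
    f <- paste0(path_prefix, ".json")
    jsonlite::write_json(tabs, f, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, na = "null")
    return(invisible(f))
  }
  out <- character()
  for (nm in names(tabs)) {
    tb <- tabs[[nm]]
    if (!is.data.frame(tb)) tb <- as.data.frame(tb)
    f <- paste0(path_prefix, "_", nm, ".csv")
    ok <- try(utils::write.csv(tb, f, row.names = FALSE, quote = FALSE),
              silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write report file: ", f)
    out <- c(out, f)
  }
  invisible(out)
}

# flatten a report object to its named component tables
report_tables <- function(report) {
  if (inherits(report, "classification_report"))
    return(list(rates = report$rates))
  if (inherits(report, "simca_report")) {
    tabs <- list(simca_summary = report$summary, mp_dp = report$mp_dp)
    if (!is.null(report$cooman)) tabs$cooman <- report$cooman
    return(tabs)
  }
  if (is.data.frame(report)) return(list(report = report))
  stopifnot(is.list(report))
  report
}

#' Read back a JSON report written by [write_report()]
#' @param path the `.json` file.
#' @return named list of data.frames.
#' @export
read_report_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(lst, function(x) if (is.list(x) && !is.data.frame(x))
    as.data.frame(x, stringsAsFactors = FALSE) else x)
}
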