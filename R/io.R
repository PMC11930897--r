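# Tabular readers/writers for cohorts and ratings.
# CSV dialect: UTF-8, comma separator, "." decimal, header required,
# booleans serialised as true/false, NA as empty field.

COHORT_COLUMNS <- c("patient_id", "nodule_id", "age_years", "sex",
                    "long_axis_mm", "short_axis_mm", "mean_diameter_mm",
                    "gvr", "suspicious_features", "border", "pathology",
                    "followup_months")

#' Read a cohort from CSV or JSON
#'
#' CSV input is flat (one row per nodule, patient attributes repeated).
#' Required columns: `patient_id`, `nodule_id`, `gvr`, `suspicious_features`,
#' `pathology`, and `mean_diameter_mm` or both of
#' `long_axis_mm`/`short_axis_mm`. GVR is parsed case-insensitively from
#' roman numerals or digits 1-4. Unknown columns are preserved as opaque
#' annotations on the nodule table. JSON input mirrors [write_cohort()]'s
#' schema with `patients` and `nodules` arrays.
#'
#' @param source path to the file.
#' @param format "csv" or "json"; guessed from the file extension by default.
#' @param label cohort label; defaults to the stored label (JSON) or "".
#' @return a validated [ggn_cohort()].
#' @export
read_cohort <- function(source, format = c("auto", "csv", "json"),
                        label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", source, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(source)) stop("cohort source not found: ", source)

  if (format == "json") {
    obj <- jsonlite::read_json(source, simplifyVector = TRUE)
    nodules <- as.data.frame(obj$nodules, stringsAsFactors = FALSE)
    patients <- if (!is.null(obj$patients) && length(obj$patients) > 0) {
      as.data.frame(obj$patients, stringsAsFactors = FALSE)
    } else NULL
    if (!is.null(patients) && "nodule_ids" %in% names(patients)) {
      patients$nodule_ids <- NULL
    }
    lab <- if (!is.null(label)) label else if (!is.null(obj$label)) obj$label else ""
    check_cohort_schema(nodules)
    return(ggn_cohort(nodules, patients = patients, label = lab))
  }

  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), encoding = "UTF-8")
  check_cohort_schema(df)
  if ("suspicious_features" %in% names(df)) {
    df$suspicious_features <- parse_bool(df$suspicious_features,
                                         "suspicious_features")
  }
  pat_cols <- intersect(c("patient_id", "age_years", "sex", "followup_months"),
                        names(df))
  patients <- unique(df[, pat_cols, drop = FALSE])
  ggn_cohort(df, patients = patients,
             label = if (is.null(label)) "" else label)
}

check_cohort_schema <- function(df) {
  required <- c("patient_id", "nodule_id", "gvr", "suspicious_features",
                "pathology")
  miss <- setdiff(required, names(df))
  has_diam <- "mean_diameter_mm" %in% names(df) ||
    all(c("long_axis_mm", "short_axis_mm") %in% names(df))
  if (!has_diam) miss <- c(miss, "mean_diameter_mm")
  if (length(miss) > 0) {
    stop("cohort schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

parse_bool <- function(x, field) {
  if (is.logical(x)) return(x)
  x0 <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("true", "t", "1", "yes")] <- TRUE
  out[x0 %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(x0) & x0 != "" & is.na(out))
  if (length(bad) > 0) {
    stop("unparseable ", field, " value at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

cohort_as_flat_table <- function(cohort) {
  nod <- cohort$nodules
  pat <- cohort$patients
  df <- merge(nod, pat, by = "patient_id", sort = FALSE)
  extra <- setdiff(names(df), COHORT_COLUMNS)
  df <- df[, c(COHORT_COLUMNS, extra), drop = FALSE]
  # stable nodule order regardless of merge internals
  df <- df[match(nod$nodule_id, df$nodule_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a cohort to CSV or JSON
#'
#' CSV output is one row per nodule with the deterministic column order
#' `patient_id, nodule_id, age_years, sex, long_axis_mm, short_axis_mm,
#' mean_diameter_mm, gvr, suspicious_features, border, pathology,
#' followup_months` (annotations appended after). Booleans are written as
#' `true`/`false`, missing values as empty fields. JSON output carries
#' `label`, a `patients` array (with per-patient `nodule_ids`) and a
#' `nodules` array. [read_cohort()] inverts either format field-for-field.
#'
#' @param cohort a `ggn_cohort`.
#' @param sink output path.
#' @param format "csv" or "json"; guessed from the extension by default.
#' @return `sink`, invisibly.
#' @export
write_cohort <- function(cohort, sink, format = c("auto", "csv", "json")) {
  validate_cohort(cohort)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", sink, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    pat <- cohort$patients
    nod <- cohort$nodules
    pat$nodule_ids <- lapply(pat$patient_id,
                             function(p) nod$nodule_id[nod$patient_id == p])
    jsonlite::write_json(list(label = cohort$label, patients = pat,
                              nodules = nod),
                         sink, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    return(invisible(sink))
  }
  df <- cohort_as_flat_table(cohort)
  df$suspicious_features <- ifelse(df$suspicious_features, "true", "false")
  for (col in names(df)) {    # full precision so the round trip is exact
    if (is.double(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), NA, sprintf("%.17g", df[[col]]))
    }
  }
  utils::write.csv(df, sink, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(sink)
}

#' Read an inter-rater ratings table
#'
#' Expects CSV columns `subject_id`, `rater_id`, `category` (long format) and
#' returns a complete subjects-by-raters matrix of ordinal category ranks.
#'
#' @param source path to the ratings CSV.
#' @return integer matrix, rows = subjects, columns = raters.
#' @export
read_ratings <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  miss <- setdiff(c("subject_id", "rater_id", "category"), names(df))
  if (length(miss) > 0) {
    stop("ratings schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  subjects <- unique(as.character(df$subject_id))
  raters <- unique(as.character(df$rater_id))
  m <- matrix(NA_integer_, nrow = length(subjects), ncol = length(raters),
              dimnames = list(subjects, raters))
  m[cbind(match(as.character(df$subject_id), subjects),
          match(as.character(df$rater_id), raters))] <-
    category_rank(df$category)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete ratings design: missing (subject, rater) pair(s): ",
         paste(utils::head(paste0("(", subjects[idx[, 1]], ", ",
                                  raters[idx[, 2]], ")"), 5),
               collapse = ", "))
  }
  m
}
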