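#' @keywords internal
"_PACKAGE"

GVR_LEVELS <- c("I", "II", "III", "IV")
CATEGORY_LEVELS <- c("2", "3", "4a", "4b", "4x")
BORDER_LEVELS <- c("blurry", "clear", "sharp")
SYSTEM_IDS <- c("LUNGRADS10", "LUNGRADS2022", "CLUNGRADS2022")

#' Ordinal rank of a Lung-RADS category
#'
#' Categories are ordered 2 < 3 < 4a < 4b < 4x and mapped to ranks 1..5.
#' The ranks are the ordinal scores used for ROC analysis.
#'
#' @param category character vector of categories ("2", "3", "4a", "4b", "4x").
#' @return integer vector of ranks in 1..5.
#' @export
#' @examples
#' category_rank(c("2", "4a", "4x"))
category_rank <- function(category) {
  r <- match(as.character(category), CATEGORY_LEVELS)
  if (anyNA(r) && !anyNA(category)) {
    bad <- setdiff(unique(as.character(category)), CATEGORY_LEVELS)
    stop("unknown category value(s): ", paste(bad, collapse = ", "))
  }
  r
}

#' Parse GVR (nodule-vessel relationship) type labels
#'
#' The GVR taxonomy has four types describing how pulmonary vessels relate
#' to a ground-glass nodule: I (vessels pass beside the nodule), II (vessels
#' pass through without thickening or distortion), III (vessels pass through
#' with localised thickening), IV (increased, thickened, twisted, convoluted
#' vessels). Accepts roman numerals (any case) or digits 1-4; empty strings
#' and NA become NA (absent).
#'
#' @param x character or integer vector.
#' @return character vector with values in `c("I","II","III","IV")` or NA.
#' @export
#' @examples
#' parse_gvr(c("iii", "4", "I", NA))
parse_gvr <- function(x) {
  x <- trimws(toupper(as.character(x)))
  out <- rep(NA_character_, length(x))
  blank <- is.na(x) | x == ""
  numeric_map <- c("1" = "I", "2" = "II", "3" = "III", "4" = "IV")
  out[!blank & x %in% GVR_LEVELS] <- x[!blank & x %in% GVR_LEVELS]
  idx <- !blank & x %in% names(numeric_map)
  out[idx] <- numeric_map[x[idx]]
  bad <- which(!blank & is.na(out))
  if (length(bad) > 0) {
    stop("unparseable GVR value(s) at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Mean nodule diameter from its two axes
#'
#' The mean diameter of a nodule is the average of the maximum diameter and
#' its perpendicular minor diameter, measured on lung-window CT images. The
#' raw arithmetic mean is returned; no rounding is applied, so threshold
#' comparisons downstream see the exact value.
#'
#' @param long_axis_mm maximum diameter in mm (positive, finite).
#' @param short_axis_mm perpendicular minor diameter in mm (positive, finite,
#'   not exceeding `long_axis_mm`).
#' @return mean diameter in mm.
#' @export
#' @examples
#' mean_diameter(16, 14)  # 15
mean_diameter <- function(long_axis_mm, short_axis_mm) {
  check_axis <- function(x, name) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop("invalid ", name, ": must be finite and > 0")
    }
  }
  check_axis(long_axis_mm, "long_axis_mm")
  check_axis(short_axis_mm, "short_axis_mm")
  if (any(short_axis_mm > long_axis_mm)) {
    stop("invalid short_axis_mm: exceeds long_axis_mm")
  }
  (long_axis_mm + short_axis_mm) / 2
}

#' Assemble a screening cohort of patients and nodules
#'
#' A cohort bundles a nodule table with a patient table. Each nodule carries
#' its diameter(s), optional GVR type, suspicious-feature flag, optional
#' border type and optional pathology label ("invasive" = minimally invasive
#' or invasive adenocarcinoma; "noninvasive" = benign, inflammatory, or
#' adenomatous precursor lesions).
#'
#' @param nodules data.frame with columns `nodule_id`, `patient_id`, and
#'   `mean_diameter_mm` or both of `long_axis_mm`/`short_axis_mm`; optional
#'   `gvr`, `suspicious_features`, `border`, `pathology`.
#' @param patients optional data.frame with `patient_id` and optional
#'   `age_years`, `sex`, `followup_months`. Derived from `nodules` if absent.
#' @param label free-text cohort label (e.g. "training").
#' @return an object of class `ggn_cohort` with elements `patients`,
#'   `nodules`, `label`.
#' @export
ggn_cohort <- function(nodules, patients = NULL, label = "") {
  nodules <- as.data.frame(nodules, stringsAsFactors = FALSE)
  n <- nrow(nodules)
  req <- c("nodule_id", "patient_id")
  miss <- setdiff(req, names(nodules))
  if (length(miss) > 0) {
    stop("nodule table missing required column(s): ", paste(miss, collapse = ", "))
  }
  nodules$nodule_id <- as.character(nodules$nodule_id)
  nodules$patient_id <- as.character(nodules$patient_id)

  has_axes <- all(c("long_axis_mm", "short_axis_mm") %in% names(nodules)) &&
    !all(is.na(nodules$long_axis_mm))
  if (!("mean_diameter_mm" %in% names(nodules))) {
    if (!has_axes) {
      stop("nodule table missing required column(s): mean_diameter_mm ",
           "(or both long_axis_mm and short_axis_mm)")
    }
    nodules$mean_diameter_mm <- mean_diameter(nodules$long_axis_mm,
                                              nodules$short_axis_mm)
  }
  if (!("long_axis_mm" %in% names(nodules))) nodules$long_axis_mm <- rep(NA_real_, n)
  if (!("short_axis_mm" %in% names(nodules))) nodules$short_axis_mm <- rep(NA_real_, n)
  for (col in c("long_axis_mm", "short_axis_mm", "mean_diameter_mm")) {
    nodules[[col]] <- as.numeric(nodules[[col]])
  }
  if (!("gvr" %in% names(nodules))) nodules$gvr <- rep(NA_character_, n)
  nodules$gvr <- parse_gvr(nodules$gvr)
  if (!("suspicious_features" %in% names(nodules))) {
    nodules$suspicious_features <- rep(NA, n)
  }
  if (anyNA(nodules$suspicious_features)) {
    warning("absent suspicious_features treated as FALSE for ",
            sum(is.na(nodules$suspicious_features)), " nodule(s)")
    nodules$suspicious_features[is.na(nodules$suspicious_features)] <- FALSE
  }
  nodules$suspicious_features <- as.logical(nodules$suspicious_features)
  if (!("border" %in% names(nodules))) nodules$border <- rep(NA_character_, n)
  nodules$border <- as.character(nodules$border)
  if (!("pathology" %in% names(nodules))) nodules$pathology <- rep(NA_character_, n)
  nodules$pathology <- parse_pathology(nodules$pathology)

  canonical <- c("nodule_id", "patient_id", "long_axis_mm", "short_axis_mm",
                 "mean_diameter_mm", "gvr", "suspicious_features", "border",
                 "pathology")
  patient_level <- c("age_years", "sex", "followup_months")
  extra <- setdiff(names(nodules), c(canonical, patient_level))
  nodules_full <- nodules
  nodules <- nodules[, c(canonical, extra), drop = FALSE]

  if (is.null(patients)) {
    keep <- intersect(c("patient_id", "age_years", "sex", "followup_months"),
                      names(nodules_full))
    patients <- unique(nodules_full[, keep, drop = FALSE])
  }
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  patients$patient_id <- as.character(patients$patient_id)
  for (col in c("age_years", "followup_months")) {
    if (!(col %in% names(patients))) patients[[col]] <- rep(NA_real_, nrow(patients))
    patients[[col]] <- as.numeric(patients[[col]])
  }
  if (!("sex" %in% names(patients))) patients$sex <- rep(NA_character_, nrow(patients))
  patients <- patients[, c("patient_id", "age_years", "sex", "followup_months")]
  rownames(patients) <- rownames(nodules) <- NULL

  obj <- structure(list(patients = patients, nodules = nodules,
                        label = as.character(label)),
                   class = "ggn_cohort")
  validate_cohort(obj)
}

parse_pathology <- function(x) {
  x0 <- trimws(tolower(as.character(x)))
  out <- rep(NA_character_, length(x0))
  blank <- is.na(x0) | x0 == ""
  out[!blank & x0 == "invasive"] <- "invasive"
  out[!blank & x0 == "noninvasive"] <- "noninvasive"
  bad <- which(!blank & is.na(out))
  if (length(bad) > 0) {
    stop("unparseable pathology value at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": ", paste(unique(x0[bad]), collapse = ", "),
         " (expected 'invasive' or 'noninvasive')")
  }
  out
}

#' Validate a cohort's structural invariants
#'
#' Checks that diameters are positive and finite, short axes do not exceed
#' long axes, stored mean diameters agree with the axis average where both
#' axes are present, nodule ids are unique, every nodule's patient resolves
#' to exactly one patient row, and categorical fields take admissible values.
#'
#' @param cohort a `ggn_cohort`.
#' @return the cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ggn_cohort"))
  nod <- cohort$nodules
  pat <- cohort$patients
  if (anyDuplicated(nod$nodule_id)) {
    stop("duplicate nodule_id: ",
         paste(unique(nod$nodule_id[duplicated(nod$nodule_id)]), collapse = ", "))
  }
  if (anyDuplicated(pat$patient_id)) {
    stop("duplicate patient_id in patient table: ",
         paste(unique(pat$patient_id[duplicated(pat$patient_id)]), collapse = ", "))
  }
  orphan <- setdiff(nod$patient_id, pat$patient_id)
  if (length(orphan) > 0) {
    stop("nodule patient_id not in patient table: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  d <- nod$mean_diameter_mm
  if (nrow(nod) > 0 && (any(!is.finite(d)) || any(d <= 0))) {
    stop("invalid mean_diameter_mm: must be finite and > 0")
  }
  both <- !is.na(nod$long_axis_mm) & !is.na(nod$short_axis_mm)
  if (any(both)) {
    if (any(nod$short_axis_mm[both] > nod$long_axis_mm[both])) {
      stop("invalid short_axis_mm: exceeds long_axis_mm")
    }
    implied <- (nod$long_axis_mm[both] + nod$short_axis_mm[both]) / 2
    if (any(abs(implied - d[both]) > 1e-8)) {
      stop("mean_diameter_mm inconsistent with (long_axis_mm + short_axis_mm)/2")
    }
  }
  okb <- is.na(nod$border) | nod$border %in% BORDER_LEVELS
  if (!all(okb)) {
    stop("invalid border value(s): ",
         paste(unique(nod$border[!okb]), collapse = ", "))
  }
  if (any(!is.na(pat$age_years) & pat$age_years <= 0)) {
    stop("invalid age_years: must be > 0")
  }
  invisible(cohort)
}

#' @export
print.ggn_cohort <- function(x, ...) {
  cat("Screening cohort", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  patients:", nrow(x$patients), "  nodules:", nrow(x$nodules), "\n")
  if (nrow(x$nodules) > 0) {
    gv <- table(factor(x$nodules$gvr, levels = GVR_LEVELS), useNA = "ifany")
    cat("  GVR types:", paste(names(gv), gv, sep = "=", collapse = " "), "\n")
    cat("  mean diameter (mm):",
        sprintf("%.1f +/- %.1f", mean(x$nodules$mean_diameter_mm),
                stats::sd(x$nodules$mean_diameter_mm)), "\n")
    pt <- table(factor(x$nodules$pathology,
                       levels = c("invasive", "noninvasive")), useNA = "ifany")
    cat("  pathology:", paste(names(pt), pt, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.ggn_cohort <- function(object, ...) print(object, ...)
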