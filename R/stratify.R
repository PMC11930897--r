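# The three rule engines. All diameter thresholds are inclusive at the
# printed boundary (>= 20 mm, >= 30 mm) and operate on raw, unrounded mm.
# The 4x upgrade applies after base categorisation and only to base
# categories 3/4a/4b: a suspicious category-2 nodule stays category 2.

#' Categorise a pGGN under Lung-RADS 1.0
#'
#' Diameter-only baseline: mean diameter < 20 mm is category 2, >= 20 mm is
#' category 3; a category-3 nodule with other suspicious malignant imaging
#' features is upgraded to 4x. The GVR type is ignored.
#'
#' @param mean_diameter_mm mean diameter in mm (vectorised).
#' @param suspicious_features logical flag(s); NA is rejected.
#' @return character vector of categories.
#' @export
#' @examples
#' categorize_lungrads10(c(19.9, 20, 25), c(FALSE, FALSE, TRUE))
categorize_lungrads10 <- function(mean_diameter_mm, suspicious_features) {
  categorize_diameter_rule(mean_diameter_mm, suspicious_features, cutoff = 20)
}

#' Categorise a pGGN under Lung-RADS v2022
#'
#' As [categorize_lungrads10()] but with the revised 30-mm cutoff: < 30 mm is
#' category 2, >= 30 mm is category 3, category 3 with suspicious features
#' upgrades to 4x.
#'
#' @inheritParams categorize_lungrads10
#' @return character vector of categories.
#' @export
categorize_lungrads2022 <- function(mean_diameter_mm, suspicious_features) {
  categorize_diameter_rule(mean_diameter_mm, suspicious_features, cutoff = 30)
}

categorize_diameter_rule <- function(mean_diameter_mm, suspicious_features,
                                     cutoff) {
  check_rule_inputs(mean_diameter_mm, suspicious_features)
  cat <- ifelse(mean_diameter_mm >= cutoff, "3", "2")
  cat[cat == "3" & suspicious_features] <- "4x"
  cat
}

#' Categorise a pGGN under cLung-RADS v2022
#'
#' The complementary system grades by the nodule-vessel relationship (GVR)
#' as well as diameter: GVR I with diameter < 30 mm is category 2; GVR I
#' with diameter >= 30 mm, or GVR II at any size, is category 3; GVR III
#' (any size) is 4a; GVR IV (any size) is 4b; and a base category 3, 4a or
#' 4b nodule with other suspicious malignant imaging features upgrades to
#' 4x. Category-2 nodules are never upgraded.
#'
#' @param gvr GVR type(s) in `c("I","II","III","IV")` (see [parse_gvr()]).
#' @inheritParams categorize_lungrads10
#' @return character vector of categories.
#' @export
#' @examples
#' categorize_clungrads2022("III", 15, FALSE)  # "4a"
#' categorize_clungrads2022("IV", 35, TRUE)    # "4x"
categorize_clungrads2022 <- function(gvr, mean_diameter_mm,
                                     suspicious_features) {
  check_rule_inputs(mean_diameter_mm, suspicious_features)
  gvr <- parse_gvr(gvr)
  if (anyNA(gvr)) {
    stop("cLung-RADS v2022 requires a GVR type for every nodule; ",
         sum(is.na(gvr)), " nodule(s) have none")
  }
  n <- max(length(gvr), length(mean_diameter_mm))
  gvr <- rep_len(gvr, n)
  d <- rep_len(mean_diameter_mm, n)
  flag <- rep_len(suspicious_features, n)
  cat <- character(n)
  cat[gvr == "I"] <- ifelse(d[gvr == "I"] >= 30, "3", "2")
  cat[gvr == "II"] <- "3"
  cat[gvr == "III"] <- "4a"
  cat[gvr == "IV"] <- "4b"
  upgrade <- flag & cat %in% c("3", "4a", "4b")
  cat[upgrade] <- "4x"
  cat
}

check_rule_inputs <- function(mean_diameter_mm, suspicious_features) {
  if (length(mean_diameter_mm) > 0 &&
      (!is.numeric(mean_diameter_mm) || any(!is.finite(mean_diameter_mm)) ||
       any(mean_diameter_mm <= 0))) {
    stop("invalid mean_diameter_mm: must be finite and > 0")
  }
  if (anyNA(suspicious_features)) {
    stop("suspicious_features must be defined (TRUE/FALSE) for every nodule")
  }
  invisible(TRUE)
}

#' Categories reachable under each system
#'
#' The diameter-only baselines can emit only categories 2, 3 and 4x for
#' pGGNs; cLung-RADS v2022 can emit all five.
#'
#' @param system one of `"LUNGRADS10"`, `"LUNGRADS2022"`, `"CLUNGRADS2022"`.
#' @return character vector of reachable categories.
#' @export
reachable_categories <- function(system) {
  system <- match.arg(system, SYSTEM_IDS)
  if (system == "CLUNGRADS2022") CATEGORY_LEVELS else c("2", "3", "4x")
}

#' Binary invasiveness call from a category
#'
#' Under cLung-RADS v2022, categories 4a-4x are called invasive (positive).
#' Under the two baselines the only reachable category at or above 4 is 4x,
#' so positivity is category 4x.
#'
#' @param system system id.
#' @param category category value(s); must be reachable under `system`.
#' @return logical vector.
#' @export
#' @examples
#' is_positive("CLUNGRADS2022", c("3", "4a"))  # FALSE TRUE
is_positive <- function(system, category) {
  system <- match.arg(system, SYSTEM_IDS)
  category <- as.character(category)
  bad <- setdiff(unique(category), reachable_categories(system))
  if (length(bad) > 0) {
    stop("category not reachable under ", system, ": ",
         paste(bad, collapse = ", "))
  }
  if (system == "CLUNGRADS2022") {
    category %in% c("4a", "4b", "4x")
  } else {
    category == "4x"
  }
}

#' Stratify every nodule in a cohort under one system
#'
#' Applies the chosen rule engine to each nodule and attaches the binary
#' invasiveness call. Deterministic and order-preserving; if any nodule
#' fails the system's preconditions no partial output is returned.
#'
#' @param cohort a [ggn_cohort()].
#' @param system system id.
#' @return data.frame with columns `nodule_id`, `system`, `category`,
#'   `positive`.
#' @export
stratify_cohort <- function(cohort, system) {
  system <- match.arg(system, SYSTEM_IDS)
  validate_cohort(cohort)
  nod <- cohort$nodules
  if (system == "CLUNGRADS2022" && anyNA(nod$gvr)) {
    first <- nod$nodule_id[which(is.na(nod$gvr))[1]]
    stop("stratification failed under CLUNGRADS2022: nodule '", first,
         "' has no GVR type (required by cLung-RADS v2022)")
  }
  cat <- tryCatch(
    switch(system,
           LUNGRADS10 = categorize_lungrads10(nod$mean_diameter_mm,
                                              nod$suspicious_features),
           LUNGRADS2022 = categorize_lungrads2022(nod$mean_diameter_mm,
                                                  nod$suspicious_features),
           CLUNGRADS2022 = categorize_clungrads2022(nod$gvr,
                                                    nod$mean_diameter_mm,
                                                    nod$suspicious_features)),
    error = function(e) {
      stop("stratification failed for cohort '", cohort$label, "' under ",
           system, ": ", conditionMessage(e), call. = FALSE)
    })
  data.frame(nodule_id = nod$nodule_id,
             system = rep_len(system, nrow(nod)),
             category = as.character(cat),
             positive = is_positive(system, cat),
             stringsAsFactors = FALSE)
}
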