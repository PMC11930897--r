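# Evaluation pipeline: stratify -> binarize -> metric panel + ordinal AUC,
# per system, plus pairwise paired DeLong comparisons and report writers.

#' Evaluate one rule set against pathology on a cohort
#'
#' Stratifies the cohort under `system`, binarizes the categories through
#' [is_positive()], computes the full metric panel from the exact confusion
#' cells, and the ordinal ROC AUC from the category ranks against the
#' pathology labels. When pathology is single-class the AUC is omitted with
#' a warning and the panel is still produced.
#'
#' @param cohort a [ggn_cohort()] whose nodules carry pathology labels.
#' @param system system id.
#' @param beta F-beta weight (default 0.5, weighting precision).
#' @return object of class `system_evaluation`: list with `system`, `label`,
#'   `n`, `cm`, `panel`, `auc` (an `auc_result` or NULL), `strata` (the
#'   per-nodule stratification table).
#' @export
#' @examples
#' co <- fixture_exact_cohort(calibration_target("CLUNGRADS2022", 131, 14, 7, 17))
#' evaluate_system(co, "CLUNGRADS2022")
evaluate_system <- function(cohort, system, beta = 0.5) {
  system <- match.arg(system, SYSTEM_IDS)
  validate_cohort(cohort)
  path <- cohort$nodules$pathology
  if (anyNA(path)) {
    stop("cannot evaluate: nodule(s) without pathology label: ",
         paste(utils::head(cohort$nodules$nodule_id[is.na(path)], 5),
               collapse = ", "))
  }
  labels <- path == "invasive"
  strata <- stratify_cohort(cohort, system)
  cm <- confusion_matrix(strata$positive, labels)
  panel <- panel_from_cm(cm, beta = beta)
  auc <- if (length(unique(labels)) < 2) {
    warning("single-class pathology: AUC undefined, omitted")
    NULL
  } else {
    ordinal_auc(category_rank(strata$category), labels)
  }
  structure(list(system = system, label = cohort$label,
                 n = nrow(cohort$nodules), cm = cm, panel = panel,
                 auc = auc, strata = strata),
            class = "system_evaluation")
}

#' @export
print.system_evaluation <- function(x, ...) {
  cat(sprintf("%s on cohort '%s' (n = %d nodules)\n", x$system, x$label, x$n))
  print(x$panel)
  if (!is.null(x$auc)) print(x$auc)
  invisible(x)
}

#' Evaluate several rule sets and compare their AUCs
#'
#' Runs [evaluate_system()] for each requested system on the same cohort
#' and performs all pairwise paired DeLong comparisons of the systems'
#' category-rank scores.
#'
#' @param cohort a [ggn_cohort()].
#' @param systems character vector of system ids (at least one).
#' @param beta F-beta weight.
#' @return object of class `evaluation_report`: list with `label`, `beta`,
#'   `systems` (named list of `system_evaluation`), `comparisons` (named
#'   list of `delong_result`).
#' @export
evaluation_report <- function(cohort,
                              systems = SYSTEM_IDS,
                              beta = 0.5) {
  if (length(systems) == 0) stop("at least one system must be requested")
  systems <- vapply(systems, function(s) match.arg(s, SYSTEM_IDS), "")
  if (anyDuplicated(systems)) stop("duplicate system ids requested")
  evals <- lapply(systems, evaluate_system, cohort = cohort, beta = beta)
  names(evals) <- systems

  comparisons <- list()
  labels <- cohort$nodules$pathology == "invasive"
  if (length(systems) > 1 && length(unique(labels)) == 2) {
    pairs <- utils::combn(systems, 2, simplify = FALSE)
    for (pr in pairs) {
      key <- paste(pr, collapse = "_vs_")
      comparisons[[key]] <- delong_paired_test(
        category_rank(evals[[pr[1]]]$strata$category),
        category_rank(evals[[pr[2]]]$strata$category),
        labels)
    }
  }
  structure(list(label = cohort$label, beta = beta, systems = evals,
                 comparisons = comparisons),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report for cohort '", x$label, "'\n", sep = "")
  for (ev in x$systems) {
    cat("\n")
    print(ev)
  }
  if (length(x$comparisons) > 0) cat("\nPairwise DeLong comparisons:\n")
  for (key in names(x$comparisons)) {
    cmp <- x$comparisons[[key]]
    cat(sprintf("  %s: dAUC %+.3f, p = %.4g\n",
                key, cmp$difference, cmp$p_two_sided))
  }
  invisible(x)
}

report_table <- function(report) {
  rows <- lapply(report$systems, function(ev) {
    p <- ev$panel
    data.frame(cohort = report$label, system = ev$system, n = ev$n,
               tp = ev$cm$tp, fp = ev$cm$fp, fn = ev$cm$fn, tn = ev$cm$tn,
               recall_pct = percent(p$recall),
               precision_pct = percent(p$precision),
               mcc_pct = percent(p$mcc),
               f1_pct = percent(p$f1),
               f_weighted_pct = percent(p$f_weighted),
               accuracy_pct = percent(p$accuracy),
               auc = if (is.null(ev$auc)) NA_real_ else ev$auc$auc,
               auc_ci_low = if (is.null(ev$auc)) NA_real_ else ev$auc$ci_low,
               auc_ci_high = if (is.null(ev$auc)) NA_real_ else ev$auc$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an evaluation report to CSV, JSON or Markdown
#'
#' CSV/JSON carry one row/object per system with the exact cells and the
#' display-rounded percent metrics (`recall_pct`, `precision_pct`,
#' `mcc_pct`, `f1_pct`, `f_weighted_pct`, `accuracy_pct`) plus the AUC and
#' its confidence bounds. The Markdown layout mirrors the conventional
#' accuracy-table row order (TP, FP, FN, TN, Recall, Precision, MCC, F1,
#' F_weighted, Accuracy, AUC) with systems as columns. JSON additionally
#' records the pairwise DeLong comparisons and run metadata.
#'
#' @param report an `evaluation_report`.
#' @param sink output path.
#' @param format "csv", "json" or "md"; guessed from the extension.
#' @param metadata optional named list (e.g. seed, config hash) stored in
#'   the JSON output.
#' @return `sink`, invisibly.
#' @export
write_report <- function(report, sink, format = c("auto", "csv", "json", "md"),
                         metadata = list()) {
  stopifnot(inherits(report, "evaluation_report"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sink))
    format <- if (ext %in% c("json", "md")) ext else "csv"
  }
  tab <- report_table(report)
  if (format == "csv") {
    utils::write.csv(tab, sink, row.names = FALSE, na = "")
  } else if (format == "json") {
    payload <- list(
      cohort = report$label, beta = report$beta,
      systems = tab,
      comparisons = lapply(report$comparisons, unclass),
      metadata = c(metadata, list(tool_version =
        as.character(utils::packageVersion("lungrads")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))))
    jsonlite::write_json(payload, sink, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    lines <- c(paste0("# Evaluation report: ", report$label), "")
    fmt1 <- function(v) ifelse(is.na(v), "--", sprintf("%.1f", v))
    header <- paste0("| metric | ", paste(tab$system, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---|", nrow(tab) + 1), collapse = ""))
    rows <- c(
      paste0("| TP | ", paste(tab$tp, collapse = " | "), " |"),
      paste0("| FP | ", paste(tab$fp, collapse = " | "), " |"),
      paste0("| FN | ", paste(tab$fn, collapse = " | "), " |"),
      paste0("| TN | ", paste(tab$tn, collapse = " | "), " |"),
      paste0("| Recall, % | ", paste(fmt1(tab$recall_pct), collapse = " | "), " |"),
      paste0("| Precision, % | ", paste(fmt1(tab$precision_pct), collapse = " | "), " |"),
      paste0("| MCC, % | ", paste(fmt1(tab$mcc_pct), collapse = " | "), " |"),
      paste0("| F1, % | ", paste(fmt1(tab$f1_pct), collapse = " | "), " |"),
      paste0("| F_weighted, % | ", paste(fmt1(tab$f_weighted_pct), collapse = " | "), " |"),
      paste0("| Accuracy, % | ", paste(fmt1(tab$accuracy_pct), collapse = " | "), " |"),
      paste0("| AUC | ", paste(ifelse(is.na(tab$auc), "--",
                                      sprintf("%.3f", tab$auc)),
                               collapse = " | "), " |"))
    writeLines(c(lines, header, sep, rows), sink)
  }
  invisible(sink)
}

#' Compare two rule sets with a paired DeLong test
#'
#' Uses each system's ordinal category ranks on the same nodules as paired
#' scores against the pathology labels.
#'
#' @param cohort a [ggn_cohort()] with pathology labels.
#' @param system_a,system_b system ids.
#' @return a `delong_result`.
#' @export
compare_models <- function(cohort, system_a, system_b) {
  system_a <- match.arg(system_a, SYSTEM_IDS)
  system_b <- match.arg(system_b, SYSTEM_IDS)
  validate_cohort(cohort)
  path <- cohort$nodules$pathology
  if (anyNA(path)) stop("cannot compare: unlabeled nodules present")
  sa <- stratify_cohort(cohort, system_a)
  sb <- stratify_cohort(cohort, system_b)
  delong_paired_test(category_rank(sa$category), category_rank(sb$category),
                     path == "invasive")
}

#' Inter-rater agreement from a ratings file
#'
#' Reads a long-format ratings CSV (`subject_id`, `rater_id`, `category`)
#' and computes ICC(2,1) on the ordinal category ranks.
#'
#' @param ratings_source path to the ratings CSV, or a ratings matrix.
#' @return an `icc_result`.
#' @export
rate_agreement <- function(ratings_source) {
  m <- if (is.matrix(ratings_source)) ratings_source
       else read_ratings(ratings_source)
  if (ncol(m) < 2) {
    stop("agreement needs at least 2 raters; found ", ncol(m))
  }
  icc_absolute_agreement(m)
}
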