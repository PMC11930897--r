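# Seeded synthetic screening-cohort generator. Defaults emulate the
# cLung-RADS v2022 development cohort: 526 patients / 572 pGGNs, nodule
# multiplicity 487/32/7, per-set GVR mixes, lognormal diameters
# moment-matched to the reported mean +/- SD, and invasiveness conditionals
# solved so the expected invasive count over the pooled mix is 421/572.

#' Published benchmark confusion matrices for the three rule sets
#'
#' The per-system TP/FP/FN/TN cells reported in the cLung-RADS v2022
#' development study, for its training (n = 169) and validation (n = 403)
#' sets. These are the calibration targets used by [calibrate_to_cells()]
#' and [fixture_exact_cohort()]. Note two quirks carried over as printed:
#' the training Lung-RADS v2022 column sums to 168, and the validation
#' cLung-RADS positives (310) are fewer than the validation GVR III+IV
#' count (327), so no single generating process reproduces every column
#' jointly.
#'
#' @return data.frame with columns `set`, `system`, `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' subset(reference_cells(), set == "training" & system == "CLUNGRADS2022")
reference_cells <- function() {
  data.frame(
    set = rep(c("training", "validation"), each = 3),
    system = rep(c("LUNGRADS10", "LUNGRADS2022", "CLUNGRADS2022"), 2),
    tp = c(9, 3, 131, 27, 5, 257),
    fp = c(1, 0, 14, 2, 0, 53),
    fn = c(129, 135, 7, 256, 278, 26),
    tn = c(30, 30, 17, 118, 120, 67),
    stringsAsFactors = FALSE
  )
}

lognormal_params <- function(mean_mm, sd_mm) {
  cv2 <- (sd_mm / mean_mm)^2
  sdlog2 <- log1p(cv2)
  list(meanlog = log(mean_mm) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Configuration for the synthetic-cohort generator
#'
#' Presets carry the composition of the development cohort's training set,
#' validation set, or their pool: patient count, nodule multiplicity, GVR
#' mix, lognormal diameter parameters (moment-matched to the reported
#' mean +/- SD in mm), age and sex distributions, per-GVR suspicious-flag
#' probabilities, and per-(GVR, flag) invasiveness conditionals. Any field
#' can be overridden through `...`.
#'
#' Default invasiveness rises with GVR type (0.25, 0.45, 0.75 for I-III)
#' and the GVR IV rate is solved so the expected invasive count equals the
#' reported pathology split (421 invasive of 572 pooled; 138/169 training;
#' 283/403 validation). Flags do not alter invasiveness by default; they
#' only drive the 4x upgrade.
#'
#' @param set preset: "pooled", "training" or "validation".
#' @param n_patients number of patients to simulate. Alternatively override
#'   `n_nodules` to fix the cohort size in nodules (patients are then
#'   accrued until that many nodules exist, as in a study that enrols to a
#'   target nodule count).
#' @param seed default seed stored in the config (an explicit seed passed to
#'   [generate_cohort()] takes precedence).
#' @param ... named overrides of any config field.
#' @return object of class `ggn_sim_config`.
#' @export
generator_config <- function(set = c("pooled", "training", "validation"),
                             n_patients = NULL, seed = 1L, ...) {
  set <- match.arg(set)
  presets <- list(
    pooled = list(n_patients = 526L,
                  multiplicity_probs = c(487, 32, 7) / 526,
                  gvr_probs = c(I = 50, II = 60, III = 70, IV = 392) / 572,
                  diameter_mean_mm = 13.6, diameter_sd_mm = 6.1,
                  age_mean = 56.6, age_sd = 9.5, female_prob = 341 / 526,
                  invasive_rate = 421 / 572),
    training = list(n_patients = 157L,
                    multiplicity_probs = c(146, 10, 1) / 157,
                    gvr_probs = c(I = 15, II = 19, III = 19, IV = 116) / 169,
                    diameter_mean_mm = 13.8, diameter_sd_mm = 6.4,
                    age_mean = 57.5, age_sd = 9.1, female_prob = 99 / 157,
                    invasive_rate = 138 / 169),
    validation = list(n_patients = 369L,
                      multiplicity_probs = c(340, 23, 6) / 369,
                      gvr_probs = c(I = 35, II = 41, III = 51, IV = 276) / 403,
                      diameter_mean_mm = 13.5, diameter_sd_mm = 6.0,
                      age_mean = 56.2, age_sd = 9.7, female_prob = 242 / 369,
                      invasive_rate = 283 / 403)
  )
  p <- presets[[set]]
  base_inv <- c(I = 0.25, II = 0.45, III = 0.75, IV = NA)
  # solve the GVR IV conditional so the expected invasive fraction over the
  # preset GVR mix equals the reported pathology split
  base_inv["IV"] <- (p$invasive_rate -
                       sum(p$gvr_probs[1:3] * base_inv[1:3])) / p$gvr_probs[4]
  p_inv <- cbind(unflagged = base_inv, flagged = base_inv)

  lp <- lognormal_params(p$diameter_mean_mm, p$diameter_sd_mm)
  cfg <- list(
    set = set,
    n_patients = if (is.null(n_patients)) p$n_patients else as.integer(n_patients),
    multiplicity_probs = p$multiplicity_probs,
    gvr_probs = p$gvr_probs,
    diameter_logmean = lp$meanlog,
    diameter_logsd = lp$sdlog,
    age_mean = p$age_mean, age_sd = p$age_sd,
    female_prob = p$female_prob,
    n_nodules = NULL,
    followup_mean = 43.5, followup_sd = 12,
    p_suspicious_given_gvr = c(I = 0.05, II = 0.42, III = 0.20, IV = 0.25),
    p_invasive_given_gvr_and_flag = p_inv,
    calibration = NULL,
    seed = as.integer(seed)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(structure(cfg, class = "ggn_sim_config"))
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "ggn_sim_config"))
  check_probs <- function(p, name, len) {
    if (length(p) != len || any(!is.finite(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-12) {
      stop("invalid ", name, ": must be ", len,
           " nonnegative probabilities summing to 1")
    }
  }
  check_probs(config$multiplicity_probs, "multiplicity_probs", 3)
  check_probs(config$gvr_probs, "gvr_probs", 4)
  frac_ok <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (!frac_ok(config$p_suspicious_given_gvr) ||
      length(config$p_suspicious_given_gvr) != 4) {
    stop("invalid p_suspicious_given_gvr: need 4 fractions in [0,1]")
  }
  pm <- config$p_invasive_given_gvr_and_flag
  if (!is.matrix(pm) || nrow(pm) != 4 || ncol(pm) != 2 || !frac_ok(pm)) {
    stop("invalid p_invasive_given_gvr_and_flag: need a 4x2 matrix of fractions")
  }
  if (config$n_patients < 1) stop("n_patients must be >= 1")
  if (config$diameter_logsd <= 0) stop("diameter_logsd must be > 0")
  config
}

#' @export
print.ggn_sim_config <- function(x, ...) {
  cat("Synthetic cohort config (preset:", x$set, ")\n")
  cat("  patients:", x$n_patients,
      " multiplicity:", paste(round(x$multiplicity_probs, 3), collapse = "/"), "\n")
  cat("  GVR mix:", paste(names(x$gvr_probs),
                          round(x$gvr_probs, 3), sep = "=", collapse = " "), "\n")
  dm <- exp(x$diameter_logmean + x$diameter_logsd^2 / 2)
  cat(sprintf("  diameter lognormal: mean %.1f mm (meanlog %.3f, sdlog %.3f)\n",
              dm, x$diameter_logmean, x$diameter_logsd))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibrated to %s: P(inv|pos)=%.3f P(inv|neg)=%.3f\n",
                x$calibration$system, x$calibration$p_invasive_positive,
                x$calibration$p_invasive_negative))
  }
  invisible(x)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic screening cohort
#'
#' Draws patients (age, sex, follow-up, nodule multiplicity) and nodules
#' (GVR type, lognormal diameter split into plausible long/short axes,
#' suspicious-feature flag, pathology) from the distributions in `config`.
#' Pathology is sampled from the per-(GVR, flag) conditionals, or — for a
#' config produced by [calibrate_to_cells()] — from the per-stratum
#' conditionals of the calibrated system. Bit-identical for a given seed;
#' the caller's RNG state is left untouched. Ages are truncated to
#' `[18, 90]`, follow-up to at least 3 months.
#'
#' @param config a `ggn_sim_config`.
#' @param seed integer seed; defaults to `config$seed`.
#' @param label cohort label; defaults to the preset name.
#' @return a [ggn_cohort()].
#' @export
generate_cohort <- function(config, seed = config$seed, label = config$set) {
  validate_sim_config(config)
  with_seed(seed, {
    if (!is.null(config$n_nodules)) {
      # fixed cohort size in nodules: accrue patients until the target is
      # reached, trimming the last patient's multiplicity
      target <- as.integer(config$n_nodules)
      if (target < 1) stop("n_nodules must be >= 1")
      draws <- sample.int(3, target, replace = TRUE,
                          prob = config$multiplicity_probs)
      cum <- cumsum(draws)
      np <- which(cum >= target)[1]
      mult <- draws[seq_len(np)]
      mult[np] <- mult[np] - (cum[np] - target)
    } else {
      np <- config$n_patients
      mult <- sample.int(3, np, replace = TRUE,
                         prob = config$multiplicity_probs)
    }
    age <- pmin(90, pmax(18, stats::rnorm(np, config$age_mean, config$age_sd)))
    sex <- ifelse(stats::runif(np) < config$female_prob, "female", "male")
    fup <- pmax(3, stats::rnorm(np, config$followup_mean, config$followup_sd))
    pid <- sprintf("P%05d", seq_len(np))
    patients <- data.frame(patient_id = pid, age_years = age, sex = sex,
                           followup_months = fup, stringsAsFactors = FALSE)

    nn <- sum(mult)
    owner <- rep(pid, times = mult)
    gvr <- GVR_LEVELS[sample.int(4, nn, replace = TRUE,
                                 prob = config$gvr_probs)]
    d <- stats::rlnorm(nn, config$diameter_logmean, config$diameter_logsd)
    ratio <- stats::runif(nn, 0.75, 1)
    long <- 2 * d / (1 + ratio)
    short <- ratio * long
    flag <- stats::runif(nn) < config$p_suspicious_given_gvr[gvr]

    if (!is.null(config$calibration)) {
      cal <- config$calibration
      cat <- switch(cal$system,
                    LUNGRADS10 = categorize_lungrads10(d, flag),
                    LUNGRADS2022 = categorize_lungrads2022(d, flag),
                    CLUNGRADS2022 = categorize_clungrads2022(gvr, d, flag))
      pos <- is_positive(cal$system, cat)
      p_inv <- ifelse(pos, cal$p_invasive_positive, cal$p_invasive_negative)
    } else {
      p_inv <- config$p_invasive_given_gvr_and_flag[cbind(match(gvr, GVR_LEVELS),
                                                          flag + 1L)]
    }
    pathology <- ifelse(stats::runif(nn) < p_inv, "invasive", "noninvasive")

    nodules <- data.frame(
      nodule_id = sprintf("N%05d", seq_len(nn)),
      patient_id = owner,
      long_axis_mm = long, short_axis_mm = short, mean_diameter_mm = d,
      gvr = gvr, suspicious_features = flag,
      border = "clear", pathology = pathology,
      stringsAsFactors = FALSE)
    ggn_cohort(nodules, patients = patients, label = label)
  })
}

#' Calibration target: confusion cells for one system
#'
#' @param system system id the cells refer to.
#' @param tp,fp,fn,tn target cells.
#' @param n cohort size; must equal the cell sum.
#' @return object of class `calibration_target`.
#' @export
calibration_target <- function(system, tp, fp, fn, tn, n = tp + fp + fn + tn) {
  system <- match.arg(system, SYSTEM_IDS)
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("calibration target cells must be nonnegative")
  }
  if (sum(cells) != n) {
    stop("calibration target cells sum to ", sum(cells),
         " but cohort size is ", n)
  }
  if (n <= 0) stop("calibration target is empty")
  structure(list(system = system, tp = tp, fp = fp, fn = fn, tn = tn, n = n),
            class = "calibration_target")
}

#' Calibrate a generator config to target confusion cells
#'
#' Solves, in closed form, the suspicious-flag and invasiveness
#' probabilities so that the *expected* confusion cells of a generated
#' cohort, stratified under the target's system, equal the target cells.
#' The cohort splits into a predicted-positive and a predicted-negative
#' stratum; the solution sets `P(positive stratum) = (TP+FP)/n` by
#' adjusting flag probabilities, `P(invasive | positive) = TP/(TP+FP)` and
#' `P(invasive | negative) = FN/(FN+TN)`.
#'
#' @param target a [calibration_target()].
#' @param base a `ggn_sim_config` providing all other distributions.
#' @return a new `ggn_sim_config` with the `calibration` field set.
#' @export
#' @examples
#' cfg <- calibrate_to_cells(
#'   calibration_target("CLUNGRADS2022", 131, 14, 7, 17),
#'   generator_config("training"))
#' cfg$calibration$p_invasive_positive  # 131/145
calibrate_to_cells <- function(target, base) {
  stopifnot(inherits(target, "calibration_target"))
  validate_sim_config(base)
  pos_frac <- (target$tp + target$fp) / target$n
  cfg <- base
  g <- base$gvr_probs
  p_ge <- function(cut) {
    stats::plnorm(cut, base$diameter_logmean, base$diameter_logsd,
                  lower.tail = FALSE)
  }
  flag <- base$p_suspicious_given_gvr

  if (target$system == "CLUNGRADS2022") {
    base_pos <- g[["III"]] + g[["IV"]]
    extra <- pos_frac - base_pos
    if (extra < -1e-9) {
      stop("infeasible calibration: GVR III+IV probability mass (",
           signif(base_pos, 4), ") already exceeds the target positive ",
           "fraction (", signif(pos_frac, 4), "); lower gvr_probs for III/IV")
    }
    denom <- g[["II"]] + g[["I"]] * p_ge(30)
    f <- if (denom > 0) max(0, extra) / denom else 0
    if (f > 1 + 1e-9) {
      stop("infeasible calibration: even flagging every GVR I/II nodule ",
           "cannot reach the target positive fraction ", signif(pos_frac, 4))
    }
    flag[c("I", "II")] <- min(1, f)
  } else {
    cut <- if (target$system == "LUNGRADS10") 20 else 30
    pge <- p_ge(cut)
    f <- if (pge > 0) pos_frac / pge else 0
    if (f > 1 + 1e-9) {
      stop("infeasible calibration: the probability of a diameter >= ", cut,
           " mm (", signif(pge, 4), ") is below the target positive fraction (",
           signif(pos_frac, 4), ")")
    }
    flag[] <- min(1, f)
  }

  cfg$p_suspicious_given_gvr <- flag
  cfg$calibration <- list(
    system = target$system,
    p_invasive_positive = if (target$tp + target$fp > 0) {
      target$tp / (target$tp + target$fp)
    } else 0,
    p_invasive_negative = if (target$fn + target$tn > 0) {
      target$fn / (target$fn + target$tn)
    } else 0)
  validate_sim_config(cfg)
}

#' Deterministic fixture cohort reproducing exact confusion cells
#'
#' Builds, without randomness, a minimal cohort whose stratification under
#' the given system yields exactly the target cells: predicted positives
#' are GVR IV nodules (or suspicious-flagged nodules above the diameter
#' cutoff for the baselines), predicted negatives are small GVR I nodules,
#' and pathology is assigned per cell.
#'
#' @param target a [calibration_target()]; its `system` may be overridden.
#' @param system system id (defaults to the target's).
#' @param label cohort label.
#' @return a [ggn_cohort()] with `n` single-nodule patients.
#' @export
#' @examples
#' co <- fixture_exact_cohort(calibration_target("CLUNGRADS2022", 131, 14, 7, 17))
#' nrow(co$nodules)  # 169
fixture_exact_cohort <- function(target, system = target$system,
                                 label = "fixture") {
  stopifnot(inherits(target, "calibration_target"))
  system <- match.arg(system, SYSTEM_IDS)
  if (system == "CLUNGRADS2022") {
    pos <- list(gvr = "IV", d = 13, flag = FALSE)
    neg <- list(gvr = "I", d = 10, flag = FALSE)
  } else if (system == "LUNGRADS10") {
    pos <- list(gvr = "IV", d = 25, flag = TRUE)
    neg <- list(gvr = "I", d = 10, flag = FALSE)
  } else {
    pos <- list(gvr = "IV", d = 31, flag = TRUE)
    neg <- list(gvr = "I", d = 10, flag = FALSE)
  }
  counts <- c(tp = target$tp, fp = target$fp, fn = target$fn, tn = target$tn)
  strata <- list(tp = pos, fp = pos, fn = neg, tn = neg)
  path <- c(tp = "invasive", fp = "noninvasive",
            fn = "invasive", tn = "noninvasive")
  rows <- do.call(rbind, lapply(names(counts), function(cell) {
    k <- counts[[cell]]
    if (k == 0) return(NULL)
    s <- strata[[cell]]
    data.frame(gvr = s$gvr, mean_diameter_mm = s$d,
               suspicious_features = s$flag, pathology = path[[cell]],
               stringsAsFactors = FALSE)[rep(1, k), , drop = FALSE]
  }))
  n <- nrow(rows)
  rows$nodule_id <- sprintf("N%05d", seq_len(n))
  rows$patient_id <- sprintf("P%05d", seq_len(n))
  rows$long_axis_mm <- rows$mean_diameter_mm
  rows$short_axis_mm <- rows$mean_diameter_mm
  patients <- data.frame(patient_id = rows$patient_id, age_years = 57,
                         sex = "female", followup_months = 43.5,
                         stringsAsFactors = FALSE)
  co <- ggn_cohort(rows, patients = patients, label = label)
  # verify the construction before handing it out
  s <- stratify_cohort(co, system)
  got <- confusion_matrix(s$positive, co$nodules$pathology == "invasive")
  if (got$tp != target$tp || got$fp != target$fp ||
      got$fn != target$fn || got$tn != target$tn) {
    stop("internal error: fixture cells do not match the target under ", system)
  }
  co
}
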