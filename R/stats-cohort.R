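## Cohort-level analysis: the rim-positive vs rim-negative baseline
## comparison and the multivariate logistic model, dispatched to the named
## tests exactly as the study's analysis plan prescribes. Two-sided p < .05
## is the significance convention; no multiple-testing correction is applied.

.REQUIRED_COHORT <- c("age", "gender", "location", "time_from_so_bin",
                      "iph_volume_cc", "pdr_volume_cc", "pdr_positive",
                      "nihss_admission", "nihss_discharge", "removal",
                      "death")

.checkCohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("schema error: cohort must be a nonempty data.frame")
  missing <- setdiff(.REQUIRED_COHORT, names(cohort))
  if (length(missing))
    stop("schema error: cohort is missing columns: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

.medIQR <- function(x) {
  if (!length(x) || all(is.na(x))) return("-")
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
}

#' Analyze a cohort table: baseline comparison and multivariate model
#'
#' Produces a baseline-characteristics comparison of rim-positive versus
#' rim-negative patients with the appropriate named test per variable -
#' Mann-Whitney U for age, hematoma volume and NIHSS; Pearson chi-squared
#' for gender and deep-vs-lobar location; Fisher exact for
#' supra/infratentorial location, hematoma removal and mortality;
#' Kruskal-Wallis for rim volume across onset-time bins; Pearson correlation
#' between rim and hematoma volumes among positives - and a multivariate
#' logistic model of rim positivity with gender (male), age per 10-year
#' interval, deep location, onset-to-MRI time in hours (bin midpoints;
#' wake-up cases at 3.0 h), admission NIHSS and log hematoma volume.
#' Deterministic given the cohort.
#'
#' @param cohort data.frame with the patient-record columns (see
#'   [makeCohort()]).
#' @param includeLogistic fit the multivariate model (default `TRUE`;
#'   requires both outcome classes).
#' @return A list with elements `baseline` (data.frame: variable, summaries,
#'   test, statistic, p), `tests` (the underlying `htest` objects),
#'   `counts` (contingency tables used) and `logistic` (a
#'   [LogisticFit-class] plus a tidy `data.frame`, or `NULL`).
#' @export
analyzeCohort <- function(cohort, includeLogistic = TRUE) {
  .checkCohort(cohort)
  pos <- as.logical(cohort$pdr_positive)
  tests <- list()
  counts <- list()
  rows <- list()
  addRow <- function(variable, allS, posS, negS, test, stat, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, all = allS, pdr_positive = posS,
      pdr_negative = negS, test = test,
      statistic = if (is.null(stat)) NA_real_ else unname(stat),
      p_value = if (is.null(p)) NA_real_ else p, stringsAsFactors = FALSE)

  ## continuous variables: Mann-Whitney U
  for (v in c("age", "iph_volume_cc", "nihss_admission", "nihss_discharge")) {
    x <- cohort[[v]]
    ht <- if (any(pos) && any(!pos)) mannWhitneyU(x[pos], x[!pos]) else NULL
    tests[[v]] <- ht
    addRow(v, .medIQR(x), .medIQR(x[pos]), .medIQR(x[!pos]),
           "Mann-Whitney U", ht$statistic, ht$p.value)
  }

  ## gender: Pearson chi-squared on the 2x2 cross-tab (rows M/F)
  gtab <- rbind(M = c(sum(cohort$gender == "M" & pos),
                      sum(cohort$gender == "M" & !pos)),
                F = c(sum(cohort$gender == "F" & pos),
                      sum(cohort$gender == "F" & !pos)))
  colnames(gtab) <- c("PDR+", "PDR-")
  counts$gender <- gtab
  tests$gender <- tryCatch(pearsonChi2(gtab), error = function(e) NULL)
  addRow("gender (male)", sprintf("%d/%d", sum(cohort$gender == "M"),
                                  nrow(cohort)),
         sprintf("%d", gtab["M", 1]), sprintf("%d", gtab["M", 2]),
         "Pearson chi-squared", tests$gender$statistic,
         tests$gender$p.value)

  ## location supra- vs infratentorial: Fisher exact
  supra <- cohort$location %in% c("deep", "lobar")
  stab <- rbind(supratentorial = c(sum(supra & pos), sum(supra & !pos)),
                infratentorial = c(sum(!supra & pos), sum(!supra & !pos)))
  colnames(stab) <- c("PDR+", "PDR-")
  counts$tentorium <- stab
  tests$tentorium <- fisherExact2x2(stab)
  addRow("location (supra/infratentorial)",
         sprintf("%d/%d", sum(supra), sum(!supra)),
         sprintf("%d/%d", stab[1, 1], stab[2, 1]),
         sprintf("%d/%d", stab[1, 2], stab[2, 2]),
         "Fisher exact", NULL, tests$tentorium$p.value)

  ## deep vs lobar: Pearson chi-squared (among supratentorial cases)
  dl <- cohort$location[supra]
  dlpos <- pos[supra]
  dtab <- rbind(deep = c(sum(dl == "deep" & dlpos), sum(dl == "deep" & !dlpos)),
                lobar = c(sum(dl == "lobar" & dlpos),
                          sum(dl == "lobar" & !dlpos)))
  counts$deep_lobar <- dtab
  tests$deep_lobar <- tryCatch(pearsonChi2(dtab), error = function(e) NULL)
  addRow("location (deep/lobar)", sprintf("%d/%d", sum(dl == "deep"),
                                          sum(dl == "lobar")),
         sprintf("%d/%d", dtab[1, 1], dtab[2, 1]),
         sprintf("%d/%d", dtab[1, 2], dtab[2, 2]),
         "Pearson chi-squared",
         tests$deep_lobar$statistic, tests$deep_lobar$p.value)

  ## removal and mortality: Fisher exact
  for (v in c("removal", "death")) {
    ev <- as.logical(cohort[[v]])
    tab <- rbind(event = c(sum(ev & pos), sum(ev & !pos)),
                 none = c(sum(!ev & pos), sum(!ev & !pos)))
    colnames(tab) <- c("PDR+", "PDR-")
    counts[[v]] <- tab
    tests[[v]] <- fisherExact2x2(tab)
    addRow(v, sprintf("%d (%.1f%%)", sum(ev), 100 * mean(ev)),
           sprintf("%d", tab[1, 1]), sprintf("%d", tab[1, 2]),
           "Fisher exact", NULL, tests[[v]]$p.value)
  }

  ## rim volume across onset-time bins: Kruskal-Wallis (positives only)
  if (sum(pos) >= 4L) {
    byBin <- split(cohort$pdr_volume_cc[pos], cohort$time_from_so_bin[pos])
    byBin <- byBin[vapply(byBin, length, integer(1)) > 0L]
    if (length(byBin) >= 2L) {
      tests$pdr_volume_by_time <- kruskalWallisH(byBin)
      addRow("pdr_volume_cc by time bin", .medIQR(cohort$pdr_volume_cc[pos]),
             "-", "-", "Kruskal-Wallis",
             tests$pdr_volume_by_time$statistic,
             tests$pdr_volume_by_time$p.value)
    }
  }

  ## rim vs hematoma volume: Pearson correlation among positives, computed
  ## on log volumes (volumes are log-normal; cf. log IPH volume in the
  ## multivariate model)
  if (sum(pos) >= 3L) {
    tests$pdr_iph_correlation <-
      pearsonCorrelation(log(cohort$iph_volume_cc[pos]),
                         log(cohort$pdr_volume_cc[pos]))
    addRow("pdr~iph volume correlation (log scale)", "-",
           sprintf("r = %.3f", tests$pdr_iph_correlation$estimate), "-",
           "Pearson correlation", tests$pdr_iph_correlation$estimate,
           tests$pdr_iph_correlation$p.value)
  }

  logistic <- NULL
  if (includeLogistic && any(pos) && any(!pos)) {
    design <- data.frame(
      gender_male = as.numeric(cohort$gender == "M"),
      age_per_10y = cohort$age / 10,
      location_deep = as.numeric(cohort$location == "deep"),
      time_hours = .TIME_BIN_MID[as.character(cohort$time_from_so_bin)],
      nihss_admission = cohort$nihss_admission,
      log_iph_volume = log(cohort$iph_volume_cc)
    )
    fit <- tryCatch(fitLogistic(design, pos), error = function(e) {
      warning("multivariate model not fitted: ", conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) {
    tidy <- data.frame(
      term = names(fit@coefficients),
      odds_ratio = unname(fit@oddsRatios),
      ci_lower = unname(fit@ci[, "lower"]),
      ci_upper = unname(fit@ci[, "upper"]),
      p_value = unname(fit@pValues),
      stringsAsFactors = FALSE
    )
    logistic <- list(fit = fit, table = tidy)
    }
  }

  list(baseline = do.call(rbind, rows), tests = tests, counts = counts,
       logistic = logistic)
}
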