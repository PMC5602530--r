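## Synthetic patient cohorts with the marginal structure of an 83-patient
## hyperacute hemorrhage series.

.TIME_BINS <- c("<=1", "1-2", "2-3", "3-4", "4-5", "5-6", "wakeup")
.TIME_BIN_MID <- c("<=1" = 0.5, "1-2" = 1.5, "2-3" = 2.5, "3-4" = 3.5,
                   "4-5" = 4.5, "5-6" = 5.5, "wakeup" = 3.0)

.COHORT_COLUMNS <- c("id", "age", "gender", "location", "time_from_so_bin",
                     "time_hours", "iph_volume_cc", "phe_volume_cc",
                     "pdr_volume_cc", "pdr_positive", "nihss_admission",
                     "nihss_discharge", "removal", "death",
                     "adc_median_iph", "adc_median_phe", "adc_median_pdr",
                     "adc_median_mirror")

#' Default cohort specification
#'
#' Marginals mirror the baseline table of the 83-patient study cohort: PDR
#' prevalence 56/83 = 0.675, 54/83 male, male age 64 (54.75-73.25) and female
#' age 71 (58-80.5) years, hematoma volume 12.9 (7.9-26.6) cc, rim volume
#' 1.98 (0.97-4.74) cc among positives, admission NIHSS 11 (7-15), discharge
#' 7 (3.5-11), onset-to-MRI bin weights (19, 32, 10, 3, 2, 2, 15)/83
#' (including the wake-up stratum), locations 66 deep / 15 lobar / 2
#' infratentorial, removal 4/83, mortality 7/83, and a target Pearson
#' correlation of 0.652 between (log) rim and hematoma volumes.
#'
#' @param nPatients cohort size (default 83).
#' @param pdrPrevalence rim-positivity probability (default 56/83).
#' @param pdrIphCorrelation target log-volume Pearson correlation.
#' @param ... named overrides of any other [CohortSpec-class] slot.
#' @return A validated [CohortSpec-class].
#' @export
defaultCohortSpec <- function(nPatients = 83L, pdrPrevalence = 56 / 83,
                              pdrIphCorrelation = 0.652, ...) {
  args <- list(
    Class = "CohortSpec",
    nPatients = as.integer(nPatients),
    pdrPrevalence = pdrPrevalence,
    maleFraction = 54 / 83,
    ageMale = c(64, 54.75, 73.25),
    ageFemale = c(71, 58, 80.5),
    iphVolume = c(12.9, 7.9, 26.6),
    pdrVolume = c(1.98, 0.97, 4.74),
    nihssAdmission = c(11, 7, 15),
    nihssDischarge = c(7, 3.5, 11),
    timeBinWeights = setNames(c(19, 32, 10, 3, 2, 2, 15) / 83, .TIME_BINS),
    locationWeights = c(deep = 66, lobar = 15, infratentorial = 2) / 83,
    removalFraction = 4 / 83,
    mortalityFraction = 7 / 83,
    pdrIphCorrelation = pdrIphCorrelation,
    compartments = defaultCompartments()
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(new, args)
}

## log-normal sigma implied by a (median, P25, P75) triple, averaging the two
## half-widths on the log scale
.logSigma <- function(mpq) {
  (log(mpq[1] / mpq[2]) + log(mpq[3] / mpq[1])) / 2 / qnorm(0.75)
}

#' Generate a synthetic patient cohort
#'
#' Draws one patient record per row: demographics, location, onset-to-MRI
#' bin (wake-up cases receive a latent onset time uniform in (0, 6] h),
#' hematoma / edema / rim volumes, NIHSS scores, removal and death flags,
#' and per-compartment ADC medians. Rim positivity is Bernoulli with the
#' spec prevalence; among positives the rim volume is coupled to the
#' hematoma volume through a log-linear link with log-scale Pearson
#' correlation `pdrIphCorrelation` (both volumes are log-normal, so the
#' linear coupling lives on the log scale). Negative rim status forces a
#' rim volume of exactly 0. Reproducible from `(cspec, seed)`.
#'
#' @param cspec a [CohortSpec-class].
#' @param seed integer RNG seed.
#' @return A `data.frame` with one row per patient (possibly 0 rows).
#' @examples
#' coh <- makeCohort(defaultCohortSpec(), seed = 1)
#' table(coh$pdr_positive)
#' @export
makeCohort <- function(cspec, seed) {
  validObject(cspec)
  n <- cspec@nPatients
  if (n < 0L) stop("parameter error: nPatients must be >= 0")
  set.seed(as.integer(seed))
  if (n == 0L) {
    empty <- as.data.frame(setNames(rep(list(logical(0)),
                                        length(.COHORT_COLUMNS)),
                                    .COHORT_COLUMNS))
    return(empty)
  }

  gender <- ifelse(runif(n) < cspec@maleFraction, "M", "F")
  age <- numeric(n)
  nm <- sum(gender == "M")
  age[gender == "M"] <- rSplitNormal(nm, cspec@ageMale[1], cspec@ageMale[2],
                                     cspec@ageMale[3])
  age[gender == "F"] <- rSplitNormal(n - nm, cspec@ageFemale[1],
                                     cspec@ageFemale[2], cspec@ageFemale[3])
  age <- pmin(pmax(round(age), 18), 99)

  location <- sample(names(cspec@locationWeights), n, replace = TRUE,
                     prob = cspec@locationWeights)
  bin <- sample(.TIME_BINS, n, replace = TRUE, prob = cspec@timeBinWeights)
  timeHours <- ifelse(bin == "wakeup", runif(n, 0, 6),
                      .TIME_BIN_MID[bin] + runif(n, -0.5, 0.5))
  timeHours <- pmin(pmax(timeHours, 0.05), 6)

  ## hematoma volume: log-normal matching the printed median/IQR
  sigI <- .logSigma(cspec@iphVolume)
  logIph <- log(cspec@iphVolume[1]) + rnorm(n, 0, sigI)
  iphVol <- exp(logIph)
  pheVol <- iphVol * 1.4 * exp(rnorm(n, 0, 0.3))

  pdrPos <- runif(n) < cspec@pdrPrevalence

  ## rim volume coupled to hematoma volume through a log-linear link whose
  ## log-scale Pearson correlation is the spec target (volumes are
  ## log-normal, so the log scale is where the linear coupling lives)
  sigP <- .logSigma(cspec@pdrVolume)
  rho <- cspec@pdrIphCorrelation
  beta <- rho * sigP / sigI
  epsSD <- sigP * sqrt(1 - rho^2)
  logPdr <- log(cspec@pdrVolume[1]) + beta * (logIph -
              log(cspec@iphVolume[1])) + rnorm(n, 0, epsSD)
  pdrVol <- ifelse(pdrPos, exp(logPdr), 0)

  nihssA <- pmin(pmax(round(rSplitNormal(n, cspec@nihssAdmission[1],
                                         cspec@nihssAdmission[2],
                                         cspec@nihssAdmission[3])), 0), 42)
  nihssD <- pmin(pmax(round(rSplitNormal(n, cspec@nihssDischarge[1],
                                         cspec@nihssDischarge[2],
                                         cspec@nihssDischarge[3])), 0), 42)

  removal <- runif(n) < cspec@removalFraction
  death <- runif(n) < cspec@mortalityFraction

  drawADC <- function(name) {
    cs <- cspec@compartments[[name]]
    rSplitNormal(n, cs@adcMedian, cs@adcIQR[1], cs@adcIQR[2])
  }
  adcIph <- drawADC("IPH")
  adcPhe <- drawADC("PHE")
  adcPdr <- ifelse(pdrPos, drawADC("PDR"), NA_real_)
  adcMirror <- drawADC("BACKGROUND_BRAIN")

  data.frame(
    id = sprintf("case%03d", seq_len(n)),
    age = age, gender = gender, location = location,
    time_from_so_bin = bin, time_hours = timeHours,
    iph_volume_cc = iphVol, phe_volume_cc = pheVol, pdr_volume_cc = pdrVol,
    pdr_positive = pdrPos, nihss_admission = nihssA,
    nihss_discharge = nihssD, removal = removal, death = death,
    adc_median_iph = adcIph, adc_median_phe = adcPhe,
    adc_median_pdr = adcPdr, adc_median_mirror = adcMirror,
    stringsAsFactors = FALSE
  )
}
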