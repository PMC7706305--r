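#' Validate raw fluorescence signals
#'
#' Checks the scientific invariants of a raw light-curve measurement and
#' reports every violation without modifying or rejecting the object:
#' all signals positive, Fm > F0, and per light step Fm' > Ft' and
#' Fm' > F0'. Violations name the offending light step (Lss1..LssK).
#'
#' @param raw a [RawFluorescence-class] object.
#' @return character vector of violation messages; empty if the record is
#'   consistent.
#' @examples
#' raw <- RawFluorescence(200, 1000,
#'   data.frame(F0p = 300, Ftp = 500, Fmp = 800))
#' validateFluorescence(raw)  # character(0)
#' @export
validateFluorescence <- function(raw) {
  stopifnot(is(raw, "RawFluorescence"))
  msg <- character(0)
  s <- raw@steps
  if (!is.finite(raw@F0) || raw@F0 <= 0) msg <- c(msg, "F0 must be > 0")
  if (!is.finite(raw@Fm) || raw@Fm <= 0) msg <- c(msg, "Fm must be > 0")
  if (is.finite(raw@F0) && is.finite(raw@Fm) && raw@Fm <= raw@F0)
    msg <- c(msg, "Fm>F0 violated")
  for (k in seq_len(nrow(s))) {
    lab <- paste0("Lss", k)
    if (any(!is.finite(unlist(s[k, ]))) || any(unlist(s[k, ]) <= 0))
      msg <- c(msg, paste0(lab, ": signals must be > 0"))
    if (s$Fmp[k] <= s$Ftp[k])
      msg <- c(msg, paste0(lab, ": Fmp>Ftp violated"))
    if (s$Fmp[k] <= s$F0p[k])
      msg <- c(msg, paste0(lab, ": Fmp>F0p violated"))
  }
  msg
}

#' Dark-adapted fluorescence parameters
#'
#' Variable fluorescence Fv = Fm - F0 and the maximum quantum yield of PSII
#' photochemistry, QY max = Fv/Fm.
#'
#' @param F0,Fm dark-adapted minimal and maximal fluorescence, a.u.
#' @return named numeric vector `c(Fv, QYmax)`.
#' @examples
#' deriveDark(200, 1000)  # Fv = 800, QYmax = 0.8
#' @export
deriveDark <- function(F0, Fm) {
  if (!is.finite(F0) || !is.finite(Fm) || F0 <= 0 || Fm <= F0)
    stop("deriveDark requires Fm > F0 > 0")
  c(Fv = Fm - F0, QYmax = (Fm - F0) / Fm)
}

#' Light-adapted fluorescence parameters for one actinic step
#'
#' Given the light-adapted signals (F0', Ft', Fm') of one actinic step and
#' the dark-adapted reference (F0, Fm), computes:
#' Fv' = Fm' - F0'; QY' = (Fm' - Ft')/Fm'; NPQ = (Fm - Fm')/Fm';
#' qN = (Fm - Fm')/(Fm - F0'); qP = (Fm' - Ft')/(Fm' - F0');
#' Fq' = Fm' - Ft'. NPQ and qN use the dark-adapted Fm as reference.
#'
#' @param step numeric vector or one-row data.frame with elements
#'   F0p, Ftp, Fmp.
#' @param F0,Fm dark-adapted reference signals.
#' @return named numeric vector
#'   `c(Fvprime, QYprime, NPQ, qN, qP, Fqprime)`.
#' @examples
#' deriveLight(c(F0p = 300, Ftp = 500, Fmp = 800), F0 = 200, Fm = 1000)
#' @export
deriveLight <- function(step, F0, Fm) {
  step <- unlist(step)[c("F0p", "Ftp", "Fmp")]
  if (any(is.na(step))) stop("step must provide F0p, Ftp and Fmp")
  F0p <- step[["F0p"]]; Ftp <- step[["Ftp"]]; Fmp <- step[["Fmp"]]
  if (any(!is.finite(c(F0p, Ftp, Fmp, F0, Fm))) || any(c(F0p, Ftp, Fmp, F0, Fm) <= 0))
    stop("all fluorescence signals must be positive")
  if (Fmp <= F0p) stop("Fm' must exceed F0' (zero or negative qP denominator)")
  if (Fmp <= Ftp) stop("Fm' must exceed Ft'")
  if (Fm <= F0p) stop("Fm must exceed F0' (zero or negative qN denominator)")
  c(Fvprime = Fmp - F0p,
    QYprime = (Fmp - Ftp) / Fmp,
    NPQ = (Fm - Fmp) / Fmp,
    qN = (Fm - Fmp) / (Fm - F0p),
    qP = (Fmp - Ftp) / (Fmp - F0p),
    Fqprime = Fmp - Ftp)
}

#' Derive the full set of fluorescence parameters for one measurement
#'
#' Applies [deriveDark()] and [deriveLight()] across all light steps of a
#' raw record.
#'
#' @param raw a [RawFluorescence-class] object.
#' @return list with elements `Fv`, `QYmax` and `steps`, a data.frame with
#'   one row per light step (Fvprime, QYprime, NPQ, qN, qP, Fqprime).
#' @export
deriveFluorescence <- function(raw) {
  stopifnot(is(raw, "RawFluorescence"))
  dark <- deriveDark(raw@F0, raw@Fm)
  per <- lapply(seq_len(nrow(raw@steps)), function(k)
    deriveLight(raw@steps[k, ], raw@F0, raw@Fm))
  steps <- as.data.frame(do.call(rbind, per))
  list(Fv = unname(dark["Fv"]), QYmax = unname(dark["QYmax"]), steps = steps)
}

#' Trait vocabulary of the pipeline
#'
#' The fixed set of trait names a fully populated [TraitTable-class]
#' contains: dark-adapted fluorescence (F0, Fm, Fv, QYmax), nine per-step
#' light-curve parameters for each actinic step, the rosette morphology
#' traits and the mask-averaged leaf temperature.
#'
#' @param nsteps number of actinic light steps.
#' @return character vector of trait names.
#' @export
traitVocabulary <- function(nsteps = 6) {
  per <- c("F0p", "Ftp", "Fmp", "Fvp", "QYp", "NPQ", "qP", "qN", "Fq")
  light <- as.vector(t(outer(per, paste0("_Lss", seq_len(nsteps)), paste0)))
  c("F0", "Fm", "Fv", "QYmax", light,
    "area", "perimeter", "convex_hull_area", "compactness", "roundness",
    "eccentricity", "isotropy", "RMS", "SOL",
    "major_axis", "minor_axis", "aspect_ratio",
    "temperature")
}

#' Assemble plant-day records into a long-format trait table
#'
#' Flattens per plant-day measurements (raw + derived fluorescence, rosette
#' morphology, leaf temperature) into the long (plant, day, trait, value)
#' layout used by all downstream statistics. Trait names follow
#' [traitVocabulary()]; light-step parameters are suffixed `_Lss1` ...
#' `_LssK`.
#'
#' @param records list of records, each a list with elements `plant` (a row
#'   of the design registry: plant_id, genotype, treatment), `das`, and any
#'   of `raw` ([RawFluorescence-class]), `fluor` (result of
#'   [deriveFluorescence()]), `morpho` (named list of morphology traits) and
#'   `temperature`.
#' @return a [TraitTable-class]; duplicate (plant, day, trait) rows raise an
#'   integrity error.
#' @export
assembleTraitTable <- function(records) {
  if (length(records) == 0L)
    return(TraitTable(data.frame(plant_id = character(0),
                                 genotype = character(0),
                                 treatment = character(0),
                                 das = integer(0), trait = character(0),
                                 value = numeric(0))))
  rows <- lapply(records, function(rec) {
    vals <- c()
    if (!is.null(rec$raw)) {
      s <- rec$raw@steps
      vals <- c(vals, F0 = rec$raw@F0, Fm = rec$raw@Fm)
      for (k in seq_len(nrow(s)))
        vals <- c(vals,
                  stats::setNames(c(s$F0p[k], s$Ftp[k], s$Fmp[k]),
                                  paste0(c("F0p", "Ftp", "Fmp"), "_Lss", k)))
    }
    if (!is.null(rec$fluor)) {
      vals <- c(vals, Fv = rec$fluor$Fv, QYmax = rec$fluor$QYmax)
      st <- rec$fluor$steps
      for (k in seq_len(nrow(st)))
        vals <- c(vals, stats::setNames(
          c(st$Fvprime[k], st$QYprime[k], st$NPQ[k], st$qP[k], st$qN[k],
            st$Fqprime[k]),
          paste0(c("Fvp", "QYp", "NPQ", "qP", "qN", "Fq"), "_Lss", k)))
    }
    if (!is.null(rec$morpho)) {
      m <- unlist(rec$morpho)
      vals <- c(vals, m[!is.na(m)])
    }
    if (!is.null(rec$temperature))
      vals <- c(vals, temperature = rec$temperature)
    if (length(vals) == 0L) return(NULL)
    data.frame(plant_id = rec$plant$plant_id,
               genotype = rec$plant$genotype,
               treatment = rec$plant$treatment,
               das = as.integer(rec$das),
               trait = names(vals), value = unname(vals),
               stringsAsFactors = FALSE)
  })
  TraitTable(do.call(rbind, rows))
}
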