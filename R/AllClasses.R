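#' @import methods
NULL

GENOTYPES  <- c("WT", "hsp101")
TREATMENTS <- c("control", "HS3h", "HS6h", "HS9h")
STRESS_HOURS <- c(control = 0, HS3h = 3, HS6h = 6, HS9h = 9)

#' Light-curve protocol for kinetic chlorophyll fluorescence
#'
#' Describes the actinic light-step sequence applied after dark adaptation:
#' an ordered set of increasing photon-flux densities, each held for a fixed
#' interval ending in a saturating flash.
#'
#' @slot actinicIntensities strictly increasing photon-flux values
#'   (micromol m^-2 s^-1), one per light step (Lss1, Lss2, ...).
#' @slot stepDuration duration of each actinic step in seconds.
#' @slot darkAdaptation dark-adaptation period preceding the curve, minutes.
#'
#' @export
setClass("LightProtocol",
  representation(
    actinicIntensities = "numeric",
    stepDuration = "numeric",
    darkAdaptation = "numeric"
  )
)

setValidity("LightProtocol", function(object) {
  msg <- NULL
  iv <- object@actinicIntensities
  if (length(iv) < 1L || any(!is.finite(iv)) || any(iv <= 0))
    msg <- c(msg, "actinic intensities must be positive and finite")
  if (length(iv) > 1L && any(diff(iv) <= 0))
    msg <- c(msg, "actinic intensities must be strictly increasing")
  if (object@stepDuration <= 0) msg <- c(msg, "stepDuration must be positive")
  if (object@darkAdaptation < 0) msg <- c(msg, "darkAdaptation must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @param actinicIntensities,stepDuration,darkAdaptation see slot descriptions.
#' @return `LightProtocol()` returns a validated protocol object. The default
#'   is the six-step curve at 95, 210, 320, 440, 555 and 670 micromol m^-2 s^-1
#'   with 60 s steps after 15 min of dark adaptation.
#' @rdname LightProtocol-class
#' @export
LightProtocol <- function(actinicIntensities = c(95, 210, 320, 440, 555, 670),
                          stepDuration = 60, darkAdaptation = 15) {
  new("LightProtocol", actinicIntensities = as.numeric(actinicIntensities),
      stepDuration = as.numeric(stepDuration),
      darkAdaptation = as.numeric(darkAdaptation))
}

#' Parameters of the synthetic heat-stress experiment
#'
#' Holds every tunable constant of the generator: logistic growth and its
#' per-stress-hour penalty, the quantum-yield dip and genotype-specific
#' recovery delays, the light-curve fluorescence model, quenching loss and
#' its coupling to the latent per-plant tolerance, leaf temperature offsets,
#' mortality under the longest stress, and rosette morphology responses.
#' Units are stated per slot; all rates are per stress hour unless noted.
#'
#' @slot initialArea mean projected rosette area at the first imaging day, mm^2.
#' @slot areaCV lognormal coefficient of variation of the initial area.
#' @slot growthRate logistic growth rate, per day.
#' @slot carryingCapacity logistic carrying capacity, mm^2.
#' @slot growthPenaltyPerHour fraction of the growth rate lost per stress hour.
#' @slot hsp101GrowthExtra extra growth penalty fraction for hsp101 at
#'   genotype-gap factor 1.
#' @slot toleranceGrowthCoupling strength with which the latent tolerance
#'   (uniform on 0..1) modulates the post-stress growth penalty.
#' @slot genotypeGap named per-treatment multiplier of all hsp101-specific
#'   effect terms; encodes that the genotypes separate most clearly at
#'   intermediate stress and hardly at all at the most severe one.
#' @slot acuteAreaDropPerHour acute projected-area shrink (wilting, leaf
#'   movement) on the stress day, per stress hour; decays over two days.
#' @slot qymaxBaseline dark-adapted Fv/Fm of an unstressed plant.
#' @slot qymaxPlantSD plant-to-plant SD of the Fv/Fm baseline.
#' @slot qyDipPerHour Fv/Fm depression on the stress day per stress hour.
#' @slot hsp101DipExtra extra Fv/Fm dip fraction for hsp101 at gap factor 1.
#' @slot recoveryDelay named (WT, hsp101) days until the Fv/Fm deficit has
#'   decayed to zero; the deficit declines linearly in between.
#' @slot fmBaseline dark-adapted Fm signal level, arbitrary units.
#' @slot fmPlantCV lognormal CV of the per-plant Fm level.
#' @slot fmDepressionPerHour multiplicative Fm depression per stress hour on
#'   the stress day (halves each following day).
#' @slot fmDepressionCap upper bound on the total Fm depression fraction.
#' @slot npqMax,npqHalf saturating NPQ light response: NPQ(I) =
#'   npqMax * I / (I + npqHalf).
#' @slot qpHalf half-saturation intensity of the photochemical-quenching
#'   decline, qP(I) = 1 / (1 + I / qpHalf).
#' @slot qpDropPerHour loss of qP per stress hour on the stress day.
#' @slot hsp101QpExtra extra qP loss fraction for hsp101 at gap factor 1.
#' @slot toleranceQpCoupling coupling of the latent tolerance to qP retention;
#'   0 decouples early quenching from later growth.
#' @slot hsp101QpRecoveryExtra extra days of qP recovery for hsp101.
#' @slot npqDropFactor fraction of the qP loss also applied to NPQ.
#' @slot signalNoiseCV multiplicative Gaussian noise SD per raw signal.
#' @slot curveNoiseCV shared multiplicative noise SD per light curve.
#' @slot ambientTemp growth-room air temperature, degrees C.
#' @slot transpirationCooling leaf cooling below ambient, degrees C.
#' @slot tempOffsetPerHour leaf-temperature elevation per stress hour on the
#'   stress day, degrees C.
#' @slot tempDecayPerDay daily multiplicative decay of the temperature offset.
#' @slot thermalNoiseSD per-pixel thermal noise SD, degrees C.
#' @slot plantTempSD plant-level temperature jitter SD, degrees C.
#' @slot deathProbability probability that a plant under the longest stress
#'   treatment dies on the stress day.
#' @slot runtProbability probability that a plant fails to grow (and is later
#'   excluded by the quality filter).
#' @slot leafCount mean number of leaves rendered per rosette.
#' @slot leafAspect length-to-width ratio of a rendered leaf.
#' @slot aspectDropPerHour reduction of the leaf aspect ratio per stress hour
#'   (drives the slenderness-of-leaves response).
#' @slot lobeJitter baseline relative SD of leaf lengths.
#' @slot stressJitterBoost increase of leaf-length irregularity under stress
#'   (drives the compactness response).
#' @slot hsp101MorphExtra extra morphology response for hsp101 at gap factor 1.
#'
#' @export
setClass("SimulationParams",
  representation(
    initialArea = "numeric", areaCV = "numeric",
    growthRate = "numeric", carryingCapacity = "numeric",
    growthPenaltyPerHour = "numeric", hsp101GrowthExtra = "numeric",
    toleranceGrowthCoupling = "numeric", genotypeGap = "numeric",
    acuteAreaDropPerHour = "numeric",
    qymaxBaseline = "numeric", qymaxPlantSD = "numeric",
    qyDipPerHour = "numeric", hsp101DipExtra = "numeric",
    recoveryDelay = "numeric",
    fmBaseline = "numeric", fmPlantCV = "numeric",
    fmDepressionPerHour = "numeric", fmDepressionCap = "numeric",
    npqMax = "numeric", npqHalf = "numeric", qpHalf = "numeric",
    qpDropPerHour = "numeric", hsp101QpExtra = "numeric",
    toleranceQpCoupling = "numeric", hsp101QpRecoveryExtra = "numeric",
    npqDropFactor = "numeric",
    signalNoiseCV = "numeric", curveNoiseCV = "numeric",
    ambientTemp = "numeric", transpirationCooling = "numeric",
    tempOffsetPerHour = "numeric", tempDecayPerDay = "numeric",
    thermalNoiseSD = "numeric", plantTempSD = "numeric",
    deathProbability = "numeric", runtProbability = "numeric",
    leafCount = "numeric", leafAspect = "numeric",
    aspectDropPerHour = "numeric", lobeJitter = "numeric",
    stressJitterBoost = "numeric", hsp101MorphExtra = "numeric"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- NULL
  in01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (!in01(object@deathProbability)) msg <- c(msg, "deathProbability must be in [0,1]")
  if (!in01(object@runtProbability)) msg <- c(msg, "runtProbability must be in [0,1]")
  sds <- c(object@areaCV, object@qymaxPlantSD, object@fmPlantCV,
           object@signalNoiseCV, object@curveNoiseCV, object@thermalNoiseSD,
           object@plantTempSD, object@lobeJitter)
  if (any(!is.finite(sds)) || any(sds < 0)) msg <- c(msg, "noise SDs must be >= 0")
  pens <- c(object@growthPenaltyPerHour * 9, object@qyDipPerHour * 9,
            object@qpDropPerHour * 9, object@acuteAreaDropPerHour * 9,
            object@fmDepressionCap)
  if (any(!is.finite(pens)) || any(pens < 0) || any(pens > 1))
    msg <- c(msg, "penalty terms must stay within [0,1] over the 9 h range")
  if (!identical(sort(names(object@genotypeGap)), sort(TREATMENTS)))
    msg <- c(msg, "genotypeGap must be named by treatment")
  if (!identical(sort(names(object@recoveryDelay)), sort(GENOTYPES)))
    msg <- c(msg, "recoveryDelay must be named by genotype")
  if (object@growthRate < 0 || object@carryingCapacity <= 0 || object@initialArea <= 0)
    msg <- c(msg, "growth parameters must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @param ... named slot overrides, e.g. `SimulationParams(deathProbability = 0)`.
#' @return `SimulationParams()` returns the default parameter set, calibrated
#'   to the qualitative recovery dynamics the pipeline is designed around:
#'   an Fv/Fm dip on the stress day with WT recovering after 1 day and hsp101
#'   after 2, growth reduction proportional to stress hours, roughly 10%
#'   mortality under 9 h of stress, and tolerance-coupled quenching retention.
#' @rdname SimulationParams-class
#' @export
SimulationParams <- function(...) {
  defaults <- list(
    initialArea = 150, areaCV = 0.15,
    growthRate = 0.35, carryingCapacity = 2500,
    growthPenaltyPerHour = 0.08, hsp101GrowthExtra = 0.35,
    toleranceGrowthCoupling = 0.5,
    genotypeGap = c(control = 0, HS3h = 0.5, HS6h = 1, HS9h = 0.15),
    acuteAreaDropPerHour = 0.05,
    qymaxBaseline = 0.80, qymaxPlantSD = 0.005,
    qyDipPerHour = 0.022, hsp101DipExtra = 0.5,
    recoveryDelay = c(WT = 1, hsp101 = 2),
    fmBaseline = 1000, fmPlantCV = 0.05,
    fmDepressionPerHour = 0.05, fmDepressionCap = 0.6,
    npqMax = 2.0, npqHalf = 300, qpHalf = 500,
    qpDropPerHour = 0.055, hsp101QpExtra = 0.5,
    toleranceQpCoupling = 1.0, hsp101QpRecoveryExtra = 1,
    npqDropFactor = 0.6,
    signalNoiseCV = 0.02, curveNoiseCV = 0.03,
    ambientTemp = 22, transpirationCooling = 1.5,
    tempOffsetPerHour = 0.25, tempDecayPerDay = 0.4,
    thermalNoiseSD = 0.1, plantTempSD = 0.2,
    deathProbability = 0.1, runtProbability = 0.02,
    leafCount = 10, leafAspect = 2.8,
    aspectDropPerHour = 0.04, lobeJitter = 0.12,
    stressJitterBoost = 0.8, hsp101MorphExtra = 0.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown SimulationParams fields: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  do.call(new, c(list("SimulationParams"), defaults))
}

#' Factorial design of the heat-stress phenotyping experiment
#'
#' A registry of plants (genotype, treatment, tray, position), the imaging
#' days expressed as days after stress imposition (DAS, with the stress day
#' at DAS 0), and the fluorescence light-curve protocol.
#'
#' @slot plants data.frame with columns plant_id, genotype, treatment, tray,
#'   position, replicate.
#' @slot days integer imaging days (DAS).
#' @slot protocol a [LightProtocol-class] object.
#'
#' @seealso [buildDesign()]
#' @export
setClass("ExperimentDesign",
  representation(plants = "data.frame", days = "integer",
                 protocol = "LightProtocol")
)

setValidity("ExperimentDesign", function(object) {
  msg <- NULL
  p <- object@plants
  need <- c("plant_id", "genotype", "treatment", "tray", "position")
  if (!all(need %in% names(p)))
    return(paste("plants must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$plant_id)) msg <- c(msg, "plant_id values must be unique")
  if (!all(p$genotype %in% GENOTYPES)) msg <- c(msg, "unknown genotype")
  if (!all(p$treatment %in% TREATMENTS)) msg <- c(msg, "unknown treatment")
  cnt <- table(p$genotype, p$treatment)
  if (length(unique(as.vector(cnt))) != 1L)
    msg <- c(msg, "design must be balanced across genotype x treatment")
  if (any(p$position < 1 | p$position > 20))
    msg <- c(msg, "each tray holds at most 20 positions")
  if (anyDuplicated(p[, c("tray", "position")]))
    msg <- c(msg, "tray positions must be unique")
  if (length(object@days) < 1L) msg <- c(msg, "at least one imaging day required")
  if (is.null(msg)) TRUE else msg
})

#' Simulated experiment: latent plant-day states plus registry
#'
#' @slot design the [ExperimentDesign-class] that was simulated.
#' @slot params the [SimulationParams-class] used.
#' @slot states data.frame of latent per plant-day states (one row per alive
#'   plant and imaging day): true area, Fv/Fm, quenching retention, Fm
#'   depression, temperature offset and the morphology state.
#' @slot registry per-plant data.frame with the latent tolerance and the
#'   died / runt / excluded quality flags.
#'
#' @seealso [simulateExperiment()]
#' @export
setClass("SimulatedExperiment",
  representation(design = "ExperimentDesign", params = "SimulationParams",
                 states = "data.frame", registry = "data.frame")
)

#' Binary top-view rosette mask
#'
#' @slot mask logical matrix, TRUE for rosette pixels (row-major, origin
#'   top-left).
#' @slot scale physical pixel size, mm per pixel.
#' @export
setClass("RosetteMask",
  representation(mask = "matrix", scale = "numeric")
)

setValidity("RosetteMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (length(object@scale) != 1L || !is.finite(object@scale) || object@scale <= 0)
    return("scale must be a positive number (mm per pixel)")
  TRUE
})

#' @param mask logical (or 0/1) matrix.
#' @param scale mm per pixel.
#' @rdname RosetteMask-class
#' @export
RosetteMask <- function(mask, scale = 1) {
  m <- mask
  if (!is.logical(m)) {
    if (!all(m %in% c(0, 1))) stop("mask raster must be binary-valued")
    m <- matrix(as.logical(m), nrow(mask), ncol(mask))
  }
  new("RosetteMask", mask = m, scale = as.numeric(scale))
}

#' Thermal raster paired with a rosette mask
#'
#' @slot grid numeric matrix of surface temperatures in degrees C.
#' @export
setClass("ThermalRaster", representation(grid = "matrix"))

setValidity("ThermalRaster", function(object) {
  if (!is.numeric(object@grid)) return("grid must be a numeric matrix")
  if (any(!is.finite(object@grid))) return("thermal values must be finite")
  TRUE
})

#' @param grid numeric matrix, degrees C.
#' @rdname ThermalRaster-class
#' @export
ThermalRaster <- function(grid) new("ThermalRaster", grid = grid)

#' Raw chlorophyll-fluorescence signals for one plant and day
#'
#' Dark-adapted minimal (F0) and maximal (Fm) fluorescence plus, per actinic
#' light step, the light-adapted minimal (F0'), steady-state (Ft') and
#' maximal (Fm') signals. The class checks structure only; scientific
#' invariants (positivity, Fm > F0, per-step ordering) are reported by
#' [validateFluorescence()] so that faulty measurements can be represented
#' and inspected.
#'
#' @slot F0,Fm dark-adapted signals, arbitrary units.
#' @slot steps data.frame with one row per light step and columns
#'   F0p, Ftp, Fmp.
#' @export
setClass("RawFluorescence",
  representation(F0 = "numeric", Fm = "numeric", steps = "data.frame")
)

setValidity("RawFluorescence", function(object) {
  msg <- NULL
  if (length(object@F0) != 1L || length(object@Fm) != 1L)
    msg <- c(msg, "F0 and Fm must be scalars")
  if (!all(c("F0p", "Ftp", "Fmp") %in% names(object@steps)))
    msg <- c(msg, "steps must have columns F0p, Ftp, Fmp")
  if (is.null(msg)) TRUE else msg
})

#' @param F0,Fm dark-adapted signals.
#' @param steps data.frame (F0p, Ftp, Fmp), one row per light step.
#' @rdname RawFluorescence-class
#' @export
RawFluorescence <- function(F0, Fm, steps) {
  new("RawFluorescence", F0 = as.numeric(F0), Fm = as.numeric(Fm),
      steps = as.data.frame(steps))
}

#' Long-format trait table
#'
#' The central exchange object of the pipeline: one row per
#' (plant, day, trait) with the plant's genotype and treatment carried along.
#' Duplicate (plant, day, trait) triples are an integrity error.
#'
#' @slot data data.frame with columns plant_id, genotype, treatment, das,
#'   trait, value.
#' @seealso [assembleTraitTable()], [traitData()]
#' @export
setClass("TraitTable", representation(data = "data.frame"))

setValidity("TraitTable", function(object) {
  d <- object@data
  need <- c("plant_id", "genotype", "treatment", "das", "trait", "value")
  if (!all(need %in% names(d)))
    return(paste("trait table needs columns:", paste(need, collapse = ", ")))
  if (nrow(d) &&
      anyDuplicated(paste(d$plant_id, d$das, d$trait, sep = "\r")))
    return("duplicate (plant, das, trait) rows")
  TRUE
})

#' @param data long-format data.frame (see slot description).
#' @rdname TraitTable-class
#' @export
TraitTable <- function(data) new("TraitTable", data = as.data.frame(data))

#' Feature matrix for genotype classification
#'
#' One row per plant-day sample, one column per trait, with the genotype
#' label (WT = 0, hsp101 = 1) and the owning plant of every row so that
#' cross-validation can keep all days of a plant in one fold.
#'
#' @slot X numeric matrix, samples x traits.
#' @slot y integer class labels (0 = WT, 1 = hsp101).
#' @slot plant character plant id per row.
#' @slot das integer day per row.
#' @export
setClass("FeatureMatrix",
  representation(X = "matrix", y = "integer", plant = "character",
                 das = "integer")
)

setValidity("FeatureMatrix", function(object) {
  msg <- NULL
  n <- nrow(object@X)
  if (length(object@y) != n || length(object@plant) != n || length(object@das) != n)
    msg <- c(msg, "labels, plants and days must match the number of rows")
  if (any(!object@y %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
  if (any(!is.finite(object@X))) msg <- c(msg, "feature matrix must be finite")
  if (is.null(msg)) TRUE else msg
})

#' L1-regularized logistic genotype classifier
#'
#' @slot weights named coefficient vector on the standardized feature scale.
#' @slot intercept model intercept (unpenalized).
#' @slot lambda L1 penalty weight on the mean logistic loss.
#' @slot center,scale standardization parameters fitted on the training data.
#' @slot converged whether the optimizer reached its tolerance.
#' @slot iterations number of optimizer iterations used.
#' @slot objective final value of the penalized objective.
#' @export
setClass("ClassifierModel",
  representation(weights = "numeric", intercept = "numeric",
                 lambda = "numeric", center = "numeric", scale = "numeric",
                 converged = "logical", iterations = "integer",
                 objective = "numeric")
)
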