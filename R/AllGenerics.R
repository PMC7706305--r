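#' Accessors for the core classes
#'
#' `plants()` returns the plant registry of a design, `imagingDays()` the DAS
#' vector, `lightProtocol()` the fluorescence protocol, `traitData()` the
#' long-format data.frame inside a [TraitTable-class], `maskMatrix()` the
#' logical raster of a [RosetteMask-class] and `pixelScale()` its mm/pixel
#' size. `plantStates()` and `plantRegistry()` expose the latent states and
#' per-plant flags of a [SimulatedExperiment-class].
#'
#' @param x an object of the matching class.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("plants", function(x) standardGeneric("plants"))
#' @rdname accessors
#' @export
setMethod("plants", "ExperimentDesign", function(x) x@plants)

#' @rdname accessors
#' @export
setGeneric("imagingDays", function(x) standardGeneric("imagingDays"))
#' @rdname accessors
#' @export
setMethod("imagingDays", "ExperimentDesign", function(x) x@days)

#' @rdname accessors
#' @export
setGeneric("lightProtocol", function(x) standardGeneric("lightProtocol"))
#' @rdname accessors
#' @export
setMethod("lightProtocol", "ExperimentDesign", function(x) x@protocol)

#' @rdname accessors
#' @export
setGeneric("traitData", function(x) standardGeneric("traitData"))
#' @rdname accessors
#' @export
setMethod("traitData", "TraitTable", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "RosetteMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))
#' @rdname accessors
#' @export
setMethod("pixelScale", "RosetteMask", function(x) x@scale)

#' @rdname accessors
#' @export
setGeneric("plantStates", function(x) standardGeneric("plantStates"))
#' @rdname accessors
#' @export
setMethod("plantStates", "SimulatedExperiment", function(x) x@states)

#' @rdname accessors
#' @export
setGeneric("plantRegistry", function(x) standardGeneric("plantRegistry"))
#' @rdname accessors
#' @export
setMethod("plantRegistry", "SimulatedExperiment", function(x) x@registry)

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @rdname accessors
#' @export
setMethod("modelWeights", "ClassifierModel", function(x) x@weights)

setMethod("show", "LightProtocol", function(object) {
  cat("LightProtocol:", length(object@actinicIntensities), "actinic steps (",
      paste(object@actinicIntensities, collapse = ", "),
      "umol m-2 s-1 ),", object@stepDuration, "s each,",
      object@darkAdaptation, "min dark adaptation\n")
})

setMethod("show", "ExperimentDesign", function(object) {
  p <- object@plants
  cat("ExperimentDesign:", nrow(p), "plants (",
      length(unique(p$genotype)), "genotypes x",
      length(unique(p$treatment)), "treatments ) on",
      length(unique(p$tray)), "trays; DAS",
      min(object@days), "..", max(object@days), "\n")
})

setMethod("show", "SimulatedExperiment", function(object) {
  r <- object@registry
  cat("SimulatedExperiment:", nrow(object@states), "plant-day states;",
      sum(r$died), "died,", sum(r$runt), "did not grow\n")
})

setMethod("show", "RosetteMask", function(object) {
  cat("RosetteMask:", nrow(object@mask), "x", ncol(object@mask), "px,",
      sum(object@mask), "foreground px at", object@scale, "mm/px (",
      round(sum(object@mask) * object@scale^2, 1), "mm^2 )\n")
})

setMethod("show", "TraitTable", function(object) {
  d <- object@data
  cat("TraitTable:", nrow(d), "rows;",
      length(unique(d$plant_id)), "plants,",
      length(unique(d$das)), "days,",
      length(unique(d$trait)), "traits\n")
})

setMethod("show", "RawFluorescence", function(object) {
  cat("RawFluorescence: F0 =", signif(object@F0, 4),
      ", Fm =", signif(object@Fm, 4), ",",
      nrow(object@steps), "light steps\n")
})

setMethod("show", "ClassifierModel", function(object) {
  nz <- sum(object@weights != 0)
  cat("ClassifierModel: lambda =", signif(object@lambda, 3), ",",
      nz, "/", length(object@weights), "nonzero weights,",
      if (object@converged) "converged" else "NOT converged",
      "in", object@iterations, "iterations\n")
})
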