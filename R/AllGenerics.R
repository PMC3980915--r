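#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("networkSpec", function(x) standardGeneric("networkSpec"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("stimuli", function(x) standardGeneric("stimuli"))
#' @rdname accessors
#' @export
setGeneric("spikeEvents", function(x) standardGeneric("spikeEvents"))
#' @rdname accessors
#' @export
setGeneric("scheduleEntries", function(x) standardGeneric("scheduleEntries"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("spikePairs", function(x) standardGeneric("spikePairs"))
#' @rdname accessors
#' @export
setGeneric("pngSupport", function(x) standardGeneric("pngSupport"))
#' @rdname accessors
#' @export
setGeneric("selectivity", function(x) standardGeneric("selectivity"))
#' @rdname accessors
#' @export
setGeneric("reactionStrength", function(x) standardGeneric("reactionStrength"))
#' @rdname accessors
#' @export
setGeneric("pngSize", function(x) standardGeneric("pngSize"))
#' @rdname accessors
#' @export
setGeneric("pngNeurons", function(x) standardGeneric("pngNeurons"))
#' @rdname accessors
#' @export
setGeneric("stimulusLabel", function(x) standardGeneric("stimulusLabel"))

#' Accessors for the core classes
#'
#' Slot accessors: \code{networkSpec}, \code{edges}, \code{positions}
#' (network); \code{stimuli} (stimulus set); \code{spikeEvents} (raster);
#' \code{scheduleEntries} (schedule); \code{fragments}, \code{stimulusLabel}
#' (fragment set); \code{spikePairs}, \code{pngSupport}, \code{pngSize},
#' \code{pngNeurons}, \code{selectivity}, \code{reactionStrength}
#' (polychronous group).
#'
#' @param x an object of the matching class.
#' @return the slot contents (see the class documentation).
#' @name accessors
NULL

setMethod("networkSpec", "SpikingNetwork", function(x) x@spec)
setMethod("edges", "SpikingNetwork", function(x) x@edges)
setMethod("positions", "SpikingNetwork", function(x) x@positions)
setMethod("stimuli", "StimulusSet", function(x) x@stimuli)
setMethod("spikeEvents", "SpikeRaster", function(x) x@events)
setMethod("scheduleEntries", "PresentationSchedule", function(x) x@entries)
setMethod("fragments", "FragmentSet", function(x) x@fragments)
setMethod("stimulusLabel", "FragmentSet", function(x) x@label)
setMethod("spikePairs", "PolychronousGroup", function(x) x@pairs)
setMethod("pngSupport", "PolychronousGroup", function(x) x@support)
setMethod("selectivity", "PolychronousGroup", function(x) x@selectivity)
setMethod("reactionStrength", "PolychronousGroup", function(x) x@reactionStrength)
setMethod("pngSize", "PolychronousGroup", function(x) nrow(x@pairs))
setMethod("pngNeurons", "PolychronousGroup", function(x) sort(unique(x@pairs[, 1])))
setMethod("stimulusLabel", "PolychronousGroup", function(x) x@stimulus)

setMethod("show", "NetworkSpec", function(object) {
  cat("NetworkSpec:", object@nExc, "exc +", object@nInh, "inh neurons,",
      object@nInputExc + object@nInputInh, "input nodes\n")
  cat("  wExcMax", object@wExcMax, "| wInhMax", object@wInhMax,
      "| T", object@tRefract, "ms | tau", object@tauM, "ms\n")
  cat("  delays exc [", paste(object@delayExcRange, collapse = ", "),
      "] ms, inh [", paste(object@delayInhRange, collapse = ", "), "] ms, S^",
      object@sphereDim - 1L, " placement\n", sep = "")
})

setMethod("show", "SpikingNetwork", function(object) {
  cat("SpikingNetwork:", nrow(object@positions), "neurons,",
      nrow(object@edges), "synapses\n")
  print(object@spec)
})

setMethod("show", "StimulusSet", function(object) {
  cat("StimulusSet:", length(object@stimuli), "stimuli x",
      object@nodesPerStimulus, "nodes;", object@stimRate, "Hz for",
      object@stimDuration, "ms over", object@noiseRate, "Hz noise\n")
})

setMethod("show", "SpikeRaster", function(object) {
  e <- object@events
  cat("SpikeRaster:", nrow(e), "events")
  if (nrow(e)) cat(" over [", min(e$time), ",", max(e$time), "] ms;",
                   sum(e$kind != "input"), "neuronal")
  cat("\n")
})

setMethod("show", "PresentationSchedule", function(object) {
  e <- object@entries
  cat("PresentationSchedule:", nrow(e), "presentations of",
      length(unique(e$label)), "stimuli\n")
})

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet '", object@label, "': ", length(object@fragments),
      " fragments, window ", object@windowLength, " ms\n", sep = "")
})

setMethod("show", "PolychronousGroup", function(object) {
  cat("PolychronousGroup for '", object@stimulus, "': ", nrow(object@pairs),
      " pairs (", length(unique(object@pairs[, 1])), " neurons), support ",
      object@support, "\n", sep = "")
  cat("  R =", object@reactionStrength, "| R/|G| =",
      round(object@reactionStrength / max(1L, nrow(object@pairs)), 3),
      "| S =", object@selectivity, "\n")
})

setMethod("show", "ConversionResult", function(object) {
  cat("ConversionResult:", nrow(object@stimuli), "stimuli; success fraction",
      object@aggregates$successFraction, "\n")
  print(object@aggregates)
})

#' @rdname accessors
#' @export
setGeneric("resultRows", function(x) standardGeneric("resultRows"))
#' @rdname accessors
#' @export
setGeneric("resultAggregates", function(x) standardGeneric("resultAggregates"))
setMethod("resultRows", "ConversionResult", function(x) x@stimuli)
setMethod("resultAggregates", "ConversionResult", function(x) x@aggregates)
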