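#' @import methods
#' @importFrom stats runif rpois ks.test
#' @importFrom utils read.csv write.csv head
#' @useDynLib polychron, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.synCountNames <- c("affExcOnExc", "affExcOnInh", "affInhOnExc", "affInhOnInh",
                    "recExcOnExc", "recExcOnInh", "recInhOnExc", "recInhOnInh")

#' Structural parameters of the chaotic LIF network
#'
#' Holds every parameter needed to realize a network: neuron and input-node
#' counts, weight bounds, the LIF soma constants (threshold fixed at 1,
#' refractory period \code{tRefract}, membrane decay \code{tauM}), the
#' per-target synapse counts for the eight connection groups, propagation
#' delay ranges, and the dimension of the hypersphere on which neurons are
#' placed. Validity enforces the coincidence-detection regime: six maximal
#' excitatory weights must reach threshold while five must not.
#'
#' @slot nExc,nInh number of excitatory / inhibitory neurons.
#' @slot nInputExc,nInputInh number of excitatory / inhibitory input nodes.
#' @slot wExcMax,wInhMax upper bounds of the uniform weight distributions.
#' @slot threshold firing threshold (dimensionless, 1).
#' @slot tRefract absolute refractory period, ms.
#' @slot tauM membrane potential decay constant, ms.
#' @slot synCounts named integer vector of per-target synapse counts
#'   (afferent/recurrent x excitatory/inhibitory x target type).
#' @slot delayExcRange,delayInhRange inclusive integer delay ranges, ms.
#' @slot sphereDim dimension of the embedding space (unit sphere surface).
#' @slot seed integer seed recorded for provenance (NA if unset).
#' @export
setClass("NetworkSpec", representation(
  nExc = "integer", nInh = "integer",
  nInputExc = "integer", nInputInh = "integer",
  wExcMax = "numeric", wInhMax = "numeric", threshold = "numeric",
  tRefract = "integer", tauM = "numeric",
  synCounts = "integer",
  delayExcRange = "integer", delayInhRange = "integer",
  sphereDim = "integer", seed = "integer"))

setValidity("NetworkSpec", function(object) {
  msg <- character()
  cnt <- c(object@nExc, object@nInh, object@nInputExc, object@nInputInh)
  if (any(cnt <= 0L)) msg <- c(msg, "all neuron/input counts must be positive")
  if (!identical(sort(names(object@synCounts)), sort(.synCountNames)))
    msg <- c(msg, "synCounts must be named by the eight connection groups")
  else if (any(object@synCounts < 0L))
    msg <- c(msg, "synapse counts must be non-negative")
  if (object@wExcMax * 6 < object@threshold)
    msg <- c(msg, "six maximal excitatory spikes must reach threshold (wExcMax*6 >= threshold)")
  if (object@wExcMax * 5 >= object@threshold)
    msg <- c(msg, "five maximal excitatory spikes must stay below threshold (wExcMax*5 < threshold)")
  for (r in list(object@delayExcRange, object@delayInhRange))
    if (length(r) != 2L || r[1] < 1L || r[2] < r[1])
      msg <- c(msg, "delay ranges must be positive non-decreasing [min, max] in ms")
  if (object@sphereDim < 2L) msg <- c(msg, "sphereDim must be >= 2")
  if (object@tauM <= 0 || object@tRefract < 0L)
    msg <- c(msg, "tauM must be positive and tRefract non-negative")
  if (length(msg)) msg else TRUE
})

#' A realized network: positions, connectivity, and the spec that made it
#'
#' @slot spec the \linkS4class{NetworkSpec} used for construction.
#' @slot positions numeric matrix, one unit-norm row per neuron (excitatory
#'   rows first), on the sphere surface in \code{sphereDim}-space.
#' @slot edges data.frame of directed synapses with columns \code{source}
#'   (global unit id), \code{target} (global neuron id), \code{weight}
#'   (positive), \code{delay} (integer ms), \code{type} ("exc"/"inh"),
#'   \code{group} ("afferent"/"recurrent").
#' @export
setClass("SpikingNetwork", representation(
  spec = "NetworkSpec", positions = "matrix", edges = "data.frame"))

setValidity("SpikingNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("source", "target", "weight", "delay", "type", "group")
  if (!all(need %in% names(e))) return("edges must have source/target/weight/delay/type/group")
  if (nrow(object@positions) != object@spec@nExc + object@spec@nInh)
    msg <- c(msg, "one position row per neuron required")
  if (any(e$source == e$target)) msg <- c(msg, "self-edges are forbidden")
  if (any(e$weight <= 0)) msg <- c(msg, "weights must be positive")
  exc <- e$type == "exc"
  sp <- object@spec
  if (any(e$weight[exc] >= sp@wExcMax) || any(e$weight[!exc] >= sp@wInhMax))
    msg <- c(msg, "weights must lie strictly inside (0, wMax)")
  if (any(e$delay[exc] < sp@delayExcRange[1] | e$delay[exc] > sp@delayExcRange[2]))
    msg <- c(msg, "excitatory delays out of range")
  if (any(e$delay[!exc] < sp@delayInhRange[1] | e$delay[!exc] > sp@delayInhRange[2]))
    msg <- c(msg, "inhibitory delays out of range")
  if (length(msg)) msg else TRUE
})

#' A stimulus dictionary over the input-node array
#'
#' Each stimulus is a fixed subset of input nodes; a presentation drives
#' every node of the subset with an independent Poisson train at
#' \code{stimRate} for \code{stimDuration} ms, on top of continuous
#' background noise at \code{noiseRate} on all nodes.
#'
#' @slot stimuli named list of integer vectors of global input-node ids.
#' @slot nodesPerStimulus subset size.
#' @slot stimRate per-node stimulus rate, Hz.
#' @slot stimDuration stimulus length, ms.
#' @slot noiseRate per-node background rate, Hz.
#' @slot nInput total number of input nodes.
#' @export
setClass("StimulusSet", representation(
  stimuli = "list", nodesPerStimulus = "integer", stimRate = "numeric",
  stimDuration = "integer", noiseRate = "numeric", nInput = "integer"))

setValidity("StimulusSet", function(object) {
  msg <- character()
  if (length(object@stimuli) < 1L) msg <- c(msg, "at least one stimulus required")
  sizes <- lengths(object@stimuli)
  if (any(sizes != object@nodesPerStimulus))
    msg <- c(msg, "every stimulus must have exactly nodesPerStimulus nodes")
  ids <- unlist(object@stimuli, use.names = FALSE)
  if (length(ids) && (min(ids) < 0L || max(ids) >= object@nInput))
    msg <- c(msg, "node ids must be in [0, nInput)")
  if (object@noiseRate < 0 || object@stimRate < 0)
    msg <- c(msg, "rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Presentation schedule
#'
#' Ordered windows, one per stimulus presentation. Each window is
#' \code{[onset, end)} in integer ms and ends exactly at the next onset
#' (the last at the end of the run).
#'
#' @slot entries data.frame with columns \code{label}, \code{onset},
#'   \code{end}.
#' @export
setClass("PresentationSchedule", representation(entries = "data.frame"))

setValidity("PresentationSchedule", function(object) {
  e <- object@entries
  if (!all(c("label", "onset", "end") %in% names(e)))
    return("entries must have label/onset/end")
  if (nrow(e) > 1L && any(diff(e$onset) <= 0)) return("onsets must be strictly increasing")
  if (any(e$end <= e$onset)) return("windows must have positive length")
  if (nrow(e) > 1L && any(e$end[-nrow(e)] > e$onset[-1]))
    return("windows must not overlap")
  TRUE
})

#' Spike raster
#'
#' Time-stamped spikes of input nodes and neurons on the 1 ms grid.
#'
#' @slot events data.frame with columns \code{time} (integer ms),
#'   \code{id} (global unit id), \code{kind} ("input"/"exc"/"inh"),
#'   sorted by time.
#' @export
setClass("SpikeRaster", representation(events = "data.frame"))

setValidity("SpikeRaster", function(object) {
  e <- object@events
  if (!all(c("time", "id", "kind") %in% names(e)))
    return("events must have time/id/kind")
  if (nrow(e) && min(e$time) < 0L) return("times must be non-negative")
  if (is.unsorted(e$time)) return("events must be time-sorted")
  if (nrow(e) && !all(e$kind %in% c("input", "exc", "inh")))
    return("kind must be input/exc/inh")
  TRUE
})

#' Stimulus-locked excitatory spike fragments
#'
#' One fragment per presentation of a stimulus: the set of (excitatory
#' neuron, onset-relative time) pairs emitted before the next onset.
#' Neuron ids are global; \code{excOffset} maps them to the compact
#' excitatory index used by the detection kernels.
#'
#' @slot label the stimulus label.
#' @slot fragments list of 2-column integer matrices (neuron id, rel. time).
#' @slot windowLength the common alignment window L, ms (max window).
#' @slot excOffset global id of excitatory neuron 0.
#' @slot nExc number of excitatory neurons.
#' @export
setClass("FragmentSet", representation(
  label = "character", fragments = "list", windowLength = "integer",
  excOffset = "integer", nExc = "integer"))

setValidity("FragmentSet", function(object) {
  if (length(object@fragments) < 1L) return("at least one fragment required")
  for (f in object@fragments) {
    if (!is.matrix(f) || ncol(f) != 2L) return("fragments must be 2-column matrices")
    if (nrow(f)) {
      if (min(f[, 2]) < 0L || max(f[, 2]) >= object@windowLength)
        return("relative times must be in [0, windowLength)")
      idx <- f[, 1] - object@excOffset
      if (min(idx) < 0L || max(idx) >= object@nExc)
        return("fragment neurons must be excitatory")
    }
  }
  TRUE
})

#' A polychronous neuronal group
#'
#' A set of (excitatory neuron, relative firing time) pairs detected at
#' support \code{support}, normalized so the earliest time is 0, with its
#' response statistics for the stimulus it was detected on.
#'
#' @slot pairs 2-column integer matrix (global neuron id, relative ms).
#' @slot support the support n used for detection.
#' @slot stimulus stimulus label.
#' @slot reactionStrength min over presentations of the group's activity.
#' @slot selectivity selectivity S in (0, 1], or NA when degenerate
#'   (reaction strength 0).
#' @export
setClass("PolychronousGroup", representation(
  pairs = "matrix", support = "integer", stimulus = "character",
  reactionStrength = "numeric", selectivity = "numeric"))

setValidity("PolychronousGroup", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must be a 2-column matrix")
  if (nrow(p) && min(p[, 2]) != 0L) return("minimum relative time must be 0")
  if (object@support < 1L) return("support must be >= 1")
  TRUE
})

#' Result of one conversion experiment condition
#'
#' @slot stimuli per-stimulus data.frame (label, support, size,
#'   reactionStrength, relStrength, selectivity, success).
#' @slot aggregates one-row data.frame of condition-level summaries.
#' @slot config list of the fully resolved condition parameters.
#' @export
setClass("ConversionResult", representation(
  stimuli = "data.frame", aggregates = "data.frame", config = "list"))
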