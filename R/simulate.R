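# Compressed-sparse-row form of the connectivity indexed by source unit,
# for the C++ stepping core. Weights are signed (negative = inhibitory),
# targets are 0-based neuron indices.
.asCsr <- function(net) {
  spec <- net@spec
  ids <- unitIds(spec)
  e <- net@edges
  o <- base::order(e$source, method = "radix")
  src <- e$source[o]
  cnt <- tabulate(src + 1L, nbins = ids$nUnits)
  list(ptr = c(0L, cumsum(cnt)),
       tgt = as.integer(e$target[o] - ids$excOffset),
       w = ifelse(e$type[o] == "exc", e$weight[o], -e$weight[o]),
       del = as.integer(e$delay[o]),
       nIn = ids$nInput,
       nNeurons = spec@nExc + spec@nInh,
       maxDelay = max(spec@delayExcRange[2], spec@delayInhRange[2]))
}

.neuronKind <- function(idx0, nExc) ifelse(idx0 < nExc, "exc", "inh")

#' Simulate the network on a fixed input spike stream
#'
#' Open-loop clock-driven LIF simulation at 1 ms resolution. Per step the
#' membrane potentials decay by \code{exp(-1/tau)}, delayed synaptic events
#' arriving in the step are summed onto them, refractory neurons are held
#' at 0, and every non-refractory neuron at or above threshold fires:
#' reset to 0 and one delayed event per efferent synapse. With an empty
#' input the network is silent forever (no spontaneous firing).
#'
#' @param net a \linkS4class{SpikingNetwork}.
#' @param input a \linkS4class{SpikeRaster} of input-node events (rows with
#'   other kinds are ignored).
#' @param tEnd last simulated ms; defaults to the last input spike plus
#'   50 ms of run-out.
#' @param returnState also return the final membrane potentials.
#' @return a \linkS4class{SpikeRaster} of neuron spikes, or (with
#'   \code{returnState}) a list with elements \code{raster} and \code{v}.
#' @export
simulateRaster <- function(net, input, tEnd = NULL, returnState = FALSE) {
  csr <- .asCsr(net)
  ev <- spikeEvents(input)
  ev <- ev[ev$id < csr$nIn, ]
  if (is.null(tEnd)) tEnd <- if (nrow(ev)) max(ev$time) + 50L else 50L
  res <- cpp_simulate_open(csr$ptr, csr$tgt, csr$w, csr$del, csr$nIn,
                           csr$nNeurons, as.integer(ev$time),
                           as.integer(ev$id), as.integer(tEnd),
                           net@spec@tauM, net@spec@threshold,
                           net@spec@tRefract, csr$maxDelay)
  raster <- new("SpikeRaster", events = data.frame(
    time = res$time, id = res$neuron + csr$nIn,
    kind = .neuronKind(res$neuron, net@spec@nExc)))
  if (returnState) list(raster = raster, v = res$v) else raster
}

#' Run a closed-loop presentation sequence
#'
#' Presents the stimuli of \code{order} one after another: each is a 30 ms
#' (\code{stimDuration}) Poisson burst on its node subset over continuous
#' background noise on all input nodes. The next onset is the first ms at
#' least \code{stimDuration} after the previous onset at which no neuron
#' has spiked for \code{quietMs}, capped at \code{maxGapMs} after onset —
#' i.e. each stimulus is presented only after the network's reaction to
#' the previous one has died out. If the cap is hit with the network still
#' active for \code{runawayLimit} consecutive presentations, the run
#' aborts (the self-sustaining activity regime of an under-inhibited
#' network).
#'
#' @param net a \linkS4class{SpikingNetwork}.
#' @param sset a \linkS4class{StimulusSet} over the same input array.
#' @param order character vector of stimulus labels.
#' @param quietMs width of the trailing window used to judge quiescence, ms.
#' @param maxGapMs hard cap on the window length, ms.
#' @param runawayLimit consecutive capped windows tolerated before abort.
#' @param quietSpikes absolute trailing-spike-count floor below which the
#'   network always counts as quiet (default 0).
#' @param baselineFactor the reaction is considered faded when the trailing
#'   count returns to within this factor of the noise-driven activity
#'   floor (the running minimum of the trailing count, measured from the
#'   second half of the warmup onward); the floor is capped at half the
#'   refractory-limited maximum so self-sustaining activity never passes
#'   as a baseline.
#' @param warmupMs noise-only settling period before the first
#'   presentation, ms, over which the activity floor is first measured.
#' @param seed optional integer seed for the stimulus/noise streams.
#' @return list with \code{raster} (input and neuron events merged,
#'   time-sorted) and \code{schedule}.
#' @examples
#' \donttest{
#' net <- buildNetwork(NetworkSpec(), seed = 1)
#' sset <- makeStimulusSet(3, NetworkSpec(), seed = 1)
#' run <- presentStimuli(net, sset, presentationOrder(sset, 5, seed = 1),
#'                       seed = 1)
#' run$schedule
#' }
#' @export
presentStimuli <- function(net, sset, order, quietMs = 20L, maxGapMs = 120L,
                           runawayLimit = 20L, quietSpikes = 0L,
                           baselineFactor = 1.25, warmupMs = 200L,
                           seed = NA_integer_) {
  if (!all(order %in% names(sset@stimuli)))
    stop("unknown stimulus label in `order`")
  if (sset@nInput != net@spec@nInputExc + net@spec@nInputInh)
    stop("stimulus set and network disagree on the input array size")
  if (!is.na(seed)) set.seed(deriveSeeds(seed, 1L, "present"))
  csr <- .asCsr(net)
  labels <- names(sset@stimuli)
  res <- cpp_present_stimuli(csr$ptr, csr$tgt, csr$w, csr$del, csr$nIn,
                             csr$nNeurons, unname(sset@stimuli),
                             match(order, labels) - 1L,
                             sset@stimDuration, sset@stimRate,
                             sset@noiseRate, net@spec@tauM,
                             net@spec@threshold, net@spec@tRefract,
                             csr$maxDelay, as.integer(quietMs),
                             as.integer(maxGapMs), as.integer(runawayLimit),
                             as.integer(quietSpikes), baselineFactor,
                             as.integer(warmupMs))
  ev <- data.frame(
    time = c(res$in_time, res$time),
    id = c(res$in_node, res$neuron + csr$nIn),
    kind = c(rep("input", length(res$in_time)),
             .neuronKind(res$neuron, net@spec@nExc)))
  ev <- ev[base::order(ev$time, ev$id, method = "radix"), ]
  rownames(ev) <- NULL
  sched <- new("PresentationSchedule", entries = data.frame(
    label = order, onset = res$onset, end = res$end))
  list(raster = new("SpikeRaster", events = ev), schedule = sched)
}
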