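#' Draw a stimulus dictionary
#'
#' Each of the \code{nStimuli} stimuli is an independent uniform sample of
#' \code{nodesPerStimulus} input nodes, without replacement within a
#' stimulus, from the whole input array (excitatory and inhibitory nodes
#' alike); subsets of different stimuli may overlap.
#'
#' @param nStimuli number of stimuli.
#' @param spec the \linkS4class{NetworkSpec} defining the input array.
#' @param nodesPerStimulus subset size (default 100).
#' @param stimRate per-node Poisson rate during a presentation, Hz.
#' @param stimDuration presentation length, ms.
#' @param noiseRate per-node background rate, Hz.
#' @param seed optional integer seed.
#' @return a \linkS4class{StimulusSet} with labels "S1", "S2", ...
#' @examples
#' sset <- makeStimulusSet(10, NetworkSpec(), seed = 1)
#' lengths(stimuli(sset))
#' @export
makeStimulusSet <- function(nStimuli, spec = NetworkSpec(),
                            nodesPerStimulus = 100L, stimRate = 300,
                            stimDuration = 30L, noiseRate = 3,
                            seed = NA_integer_) {
  if (nStimuli < 1) stop("nStimuli must be >= 1")
  nInput <- spec@nInputExc + spec@nInputInh
  if (nodesPerStimulus > nInput)
    stop("nodesPerStimulus exceeds the input-node pool (", nInput, ")")
  if (!is.na(seed)) set.seed(deriveSeeds(seed, 1L, "stimuli"))
  subsets <- lapply(seq_len(nStimuli), function(i)
    sort(sample.int(nInput, nodesPerStimulus) - 1L))
  names(subsets) <- paste0("S", seq_len(nStimuli))
  new("StimulusSet", stimuli = subsets,
      nodesPerStimulus = as.integer(nodesPerStimulus),
      stimRate = stimRate, stimDuration = as.integer(stimDuration),
      noiseRate = noiseRate, nInput = as.integer(nInput))
}

#' Randomized presentation order
#'
#' A single shuffle of all (stimulus x repetition) pairs, so every stimulus
#' appears exactly \code{nPresentations} times in interleaved order.
#'
#' @param sset a \linkS4class{StimulusSet}.
#' @param nPresentations repetitions per stimulus (default 100).
#' @param seed optional integer seed.
#' @return character vector of stimulus labels.
#' @export
presentationOrder <- function(sset, nPresentations = 100L, seed = NA_integer_) {
  if (!is.na(seed)) set.seed(deriveSeeds(seed, 1L, "order"))
  sample(rep(names(sset@stimuli), nPresentations))
}

#' Generate an input spike stream with a fixed-gap schedule
#'
#' Open-loop variant of the input model: each presentation occupies a
#' window of \code{stimDuration + gapMs} ms; the stimulated nodes emit
#' Poisson trains at the stimulus rate for the first \code{stimDuration}
#' ms, and every input node emits Poisson background noise throughout the
#' run. The closed-loop pipeline (\code{\link{presentStimuli}}) instead
#' ends each window as soon as network activity has faded.
#'
#' @param sset a \linkS4class{StimulusSet}.
#' @param order character vector of stimulus labels to present, in order.
#' @param gapMs silent gap appended to each presentation window, ms.
#' @param seed optional integer seed.
#' @return list with elements \code{raster} (a \linkS4class{SpikeRaster} of
#'   input events) and \code{schedule} (a
#'   \linkS4class{PresentationSchedule}).
#' @export
generateInputSpikes <- function(sset, order, gapMs = 120L,
                                seed = NA_integer_) {
  if (!all(order %in% names(sset@stimuli)))
    stop("unknown stimulus label in `order`")
  if (!is.na(seed)) set.seed(deriveSeeds(seed, 1L, "input"))
  W <- sset@stimDuration + as.integer(gapMs)
  nPres <- length(order)
  tEnd <- nPres * W
  onsets <- (seq_len(nPres) - 1L) * W

  times <- integer(0); nodes <- integer(0)
  for (p in seq_len(nPres)) {
    sub <- sset@stimuli[[order[p]]]
    nSpk <- stats::rpois(1, length(sub) * sset@stimRate *
                              sset@stimDuration / 1000)
    if (nSpk > 0) {
      times <- c(times, onsets[p] + sample.int(sset@stimDuration, nSpk,
                                               replace = TRUE) - 1L)
      nodes <- c(nodes, sub[sample.int(length(sub), nSpk, replace = TRUE)])
    }
  }
  nNoise <- stats::rpois(1, sset@nInput * sset@noiseRate * tEnd / 1000)
  if (nNoise > 0) {
    times <- c(times, sample.int(tEnd, nNoise, replace = TRUE) - 1L)
    nodes <- c(nodes, sample.int(sset@nInput, nNoise, replace = TRUE) - 1L)
  }
  o <- base::order(times, nodes, method = "radix")
  raster <- new("SpikeRaster", events = data.frame(
    time = times[o], id = nodes[o],
    kind = rep("input", length(o))))
  ends <- onsets + W
  sched <- new("PresentationSchedule", entries = data.frame(
    label = order, onset = onsets, end = ends))
  list(raster = raster, schedule = sched)
}
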