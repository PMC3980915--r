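#' Baseline condition parameters
#'
#' The reference operating point of the conversion experiments: 10
#' stimuli, 100 input nodes per stimulus, 300 Hz stimulus rate, 3 Hz
#' background noise, 100 presentations per stimulus, on the default
#' network.
#'
#' @return named list of condition parameters accepted by
#'   \code{\link{runCondition}}.
#' @export
baselineCondition <- function() {
  list(nStimuli = 10L, nodesPerStimulus = 100L, stimRate = 300,
       noiseRate = 3, nPresentations = 100L, stimDuration = 30L,
       permuteDelays = FALSE, quietMs = 20L, maxGapMs = 120L,
       runawayLimit = 20L)
}

#' Run one experiment condition end to end
#'
#' Builds the network, draws the stimulus dictionary and presentation
#' order, runs the closed-loop simulation, extracts the per-stimulus
#' fragment sets, scans each for its most selective polychronous group,
#' and aggregates the group statistics. All randomness descends from
#' \code{seed} through labelled child streams, so a condition is exactly
#' reproducible.
#'
#' @param nStimuli,nodesPerStimulus,stimRate,noiseRate,nPresentations,stimDuration
#'   input-signal parameters (defaults = the baseline condition).
#' @param spec the \linkS4class{NetworkSpec}.
#' @param permuteDelays if TRUE, the recurrent excitatory delays are
#'   randomly permuted after construction (the structure-destroying
#'   control).
#' @param quietMs,maxGapMs,runawayLimit closed-loop schedule parameters,
#'   see \code{\link{presentStimuli}}.
#' @param seed master seed of the condition.
#' @return a \linkS4class{ConversionResult}: per-stimulus rows (support,
#'   size, reaction strength, relative strength, selectivity, success),
#'   and aggregates (mean/sd of size and relative strength, mean pairwise
#'   intersection ratio, success fraction).
#' @examples
#' \donttest{
#' res <- runCondition(nStimuli = 3, nPresentations = 20, seed = 1)
#' resultRows(res)
#' }
#' @export
runCondition <- function(nStimuli = 10L, nodesPerStimulus = 100L,
                         stimRate = 300, noiseRate = 3,
                         nPresentations = 100L, stimDuration = 30L,
                         spec = NetworkSpec(), permuteDelays = FALSE,
                         quietMs = 20L, maxGapMs = 120L, runawayLimit = 20L,
                         seed = 1L) {
  seeds <- deriveSeeds(seed, 5L, "condition")
  net <- buildNetwork(spec, seed = seeds[1])
  if (permuteDelays) net <- permuteExcitatoryDelays(net, seed = seeds[2])
  sset <- makeStimulusSet(nStimuli, spec, nodesPerStimulus = nodesPerStimulus,
                          stimRate = stimRate, stimDuration = stimDuration,
                          noiseRate = noiseRate, seed = seeds[3])
  ord <- presentationOrder(sset, nPresentations, seed = seeds[4])
  run <- presentStimuli(net, sset, ord, quietMs = quietMs,
                        maxGapMs = maxGapMs, runawayLimit = runawayLimit,
                        seed = seeds[5])
  labels <- names(stimuli(sset))
  allFs <- lapply(labels, function(lb)
    extractFragments(run$raster, run$schedule, lb, spec))
  names(allFs) <- labels

  scans <- lapply(labels, function(lb) findSelectivePNG(allFs[[lb]], allFs))
  rows <- do.call(rbind, lapply(seq_along(labels), function(i) {
    g <- scans[[i]]$group
    if (is.null(g))
      return(data.frame(label = labels[i], support = NA_integer_,
                        size = 0L, reactionStrength = NA_real_,
                        relStrength = NA_real_, selectivity = NA_real_,
                        success = FALSE))
    data.frame(label = labels[i], support = pngSupport(g),
               size = pngSize(g), reactionStrength = reactionStrength(g),
               relStrength = reactionStrength(g) / pngSize(g),
               selectivity = selectivity(g), success = scans[[i]]$success)
  }))

  groups <- Filter(Negate(is.null), lapply(scans, `[[`, "group"))
  inter <- if (length(groups) >= 2) {
    cmb <- utils::combn(length(groups), 2)
    vapply(seq_len(ncol(cmb)), function(j)
      pngIntersectionRatio(groups[[cmb[1, j]]], groups[[cmb[2, j]]],
                           spec@nExc), numeric(1))
  } else numeric(0)

  agg <- data.frame(
    nStimuli = nStimuli, nodesPerStimulus = nodesPerStimulus,
    stimRate = stimRate, noiseRate = noiseRate,
    permuteDelays = permuteDelays, seed = seed,
    successFraction = mean(rows$success),
    meanSize = mean(rows$size), sdSize = stats::sd(rows$size),
    meanRelStrength = mean(rows$relStrength, na.rm = TRUE),
    sdRelStrength = stats::sd(rows$relStrength, na.rm = TRUE),
    meanIntersection = if (length(inter)) mean(inter) else NA_real_,
    sdIntersection = if (length(inter) > 1) stats::sd(inter) else NA_real_)

  cfg <- list(nStimuli = nStimuli, nodesPerStimulus = nodesPerStimulus,
              stimRate = stimRate, noiseRate = noiseRate,
              nPresentations = nPresentations, stimDuration = stimDuration,
              permuteDelays = permuteDelays, quietMs = quietMs,
              maxGapMs = maxGapMs, runawayLimit = runawayLimit, seed = seed,
              spec = spec)
  new("ConversionResult", stimuli = rows, aggregates = agg, config = cfg)
}

#' Run a one-factor-at-a-time experiment series
#'
#' Varies exactly one axis of the input signal away from the baseline
#' point — the star design: number of stimuli, nodes per stimulus,
#' background noise rate, or delay randomization (where the grid is over
#' stimulus counts and every condition runs on a delay-permuted network).
#' Conditions that abort (runaway activity) are recorded and the series
#' continues.
#'
#' @param axis one of \code{"nStimuli"}, \code{"nodesPerStimulus"},
#'   \code{"noiseRate"}, \code{"delayRandomization"}.
#' @param grid numeric vector of axis values.
#' @param replicates independent repetitions per grid point (default 1;
#'   the delay-randomization control conventionally uses 10).
#' @param baseline named list of condition parameters to start from
#'   (default \code{\link{baselineCondition}}).
#' @param spec the \linkS4class{NetworkSpec}.
#' @param seed master seed; each (grid point, replicate) gets its own
#'   child seed.
#' @return list with \code{aggregates} (one row per condition x
#'   replicate), \code{perStimulus} (tidy per-stimulus rows), and
#'   \code{results} (the \linkS4class{ConversionResult} objects;
#'   \code{NULL} where a condition failed, with the message in
#'   \code{aggregates$error}).
#' @export
runStarSeries <- function(axis = c("nStimuli", "nodesPerStimulus",
                                   "noiseRate", "delayRandomization"),
                          grid, replicates = 1L,
                          baseline = baselineCondition(),
                          spec = NetworkSpec(), seed = 1L) {
  axis <- match.arg(axis)
  cells <- expand.grid(value = grid, replicate = seq_len(replicates))
  seeds <- deriveSeeds(seed, nrow(cells), paste0("series-", axis))
  results <- vector("list", nrow(cells))
  aggs <- vector("list", nrow(cells))
  perStim <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- baseline
    v <- cells$value[i]
    if (axis == "delayRandomization") {
      p$nStimuli <- as.integer(v); p$permuteDelays <- TRUE
    } else if (axis == "nStimuli") p$nStimuli <- as.integer(v)
    else if (axis == "nodesPerStimulus") p$nodesPerStimulus <- as.integer(v)
    else p$noiseRate <- v
    res <- tryCatch(
      runCondition(nStimuli = p$nStimuli,
                   nodesPerStimulus = p$nodesPerStimulus,
                   stimRate = p$stimRate, noiseRate = p$noiseRate,
                   nPresentations = p$nPresentations,
                   stimDuration = p$stimDuration, spec = spec,
                   permuteDelays = p$permuteDelays, quietMs = p$quietMs,
                   maxGapMs = p$maxGapMs, runawayLimit = p$runawayLimit,
                   seed = seeds[i]),
      error = function(e) e)
    if (inherits(res, "error")) {
      aggs[[i]] <- data.frame(axis = axis, value = v,
                              replicate = cells$replicate[i],
                              error = conditionMessage(res))
    } else {
      results[[i]] <- res
      a <- resultAggregates(res)
      a$axis <- axis; a$value <- v; a$replicate <- cells$replicate[i]
      a$error <- NA_character_
      aggs[[i]] <- a
      r <- resultRows(res)
      r$axis <- axis; r$value <- v; r$replicate <- cells$replicate[i]
      perStim[[i]] <- r
    }
  }
  list(aggregates = .rbindFill(aggs),
       perStimulus = do.call(rbind, perStim),
       results = results)
}

# minimal rbind with column union (avoids a dplyr dependency)
.rbindFill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[cols]
  }))
}
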