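#' Create a network specification
#'
#' Defaults reproduce the reference configuration: 700 excitatory and 300
#' inhibitory neurons, a 1000-node input array split 700/300, maximal
#' excitatory weight 0.19 (so that six coincident maximal spikes reach the
#' unit threshold but five do not), maximal inhibitory weight 10 (the
#' excitation/inhibition balance knob, just above the self-sustained
#' activity threshold), refractory period 6 ms, membrane decay 3 ms,
#' excitatory delays 1-10 ms and inhibitory delays 1-3 ms, neurons placed on
#' the unit sphere in 4-space.
#'
#' @param nExc,nInh excitatory / inhibitory neuron counts.
#' @param nInputExc,nInputInh excitatory / inhibitory input-node counts.
#' @param wExcMax,wInhMax maximal excitatory / inhibitory synaptic weights.
#' @param threshold firing threshold (dimensionless).
#' @param tRefract absolute refractory period, ms.
#' @param tauM membrane decay constant, ms.
#' @param synCounts named integer vector of per-target synapse counts; see
#'   \linkS4class{NetworkSpec}.
#' @param delayExcRange,delayInhRange inclusive integer delay ranges, ms.
#' @param sphereDim dimension of the placement space.
#' @param seed optional integer seed recorded in the spec and used by
#'   \code{\link{buildNetwork}}.
#' @return a \linkS4class{NetworkSpec}.
#' @examples
#' spec <- NetworkSpec()
#' spec
#' @export
NetworkSpec <- function(nExc = 700L, nInh = 300L,
                        nInputExc = 700L, nInputInh = 300L,
                        wExcMax = 0.19, wInhMax = 10,
                        threshold = 1.0, tRefract = 6L, tauM = 3,
                        synCounts = c(affExcOnExc = 300L, affExcOnInh = 300L,
                                      affInhOnExc = 10L, affInhOnInh = 30L,
                                      recExcOnExc = 100L, recExcOnInh = 100L,
                                      recInhOnExc = 10L, recInhOnInh = 3L),
                        delayExcRange = c(1L, 10L), delayInhRange = c(1L, 3L),
                        sphereDim = 4L, seed = NA_integer_) {
  new("NetworkSpec",
      nExc = as.integer(nExc), nInh = as.integer(nInh),
      nInputExc = as.integer(nInputExc), nInputInh = as.integer(nInputInh),
      wExcMax = wExcMax, wInhMax = wInhMax, threshold = threshold,
      tRefract = as.integer(tRefract), tauM = tauM,
      synCounts = vapply(synCounts, as.integer, integer(1)),
      delayExcRange = as.integer(delayExcRange),
      delayInhRange = as.integer(delayInhRange),
      sphereDim = as.integer(sphereDim), seed = as.integer(seed))
}

# global unit-id layout: input nodes first (excitatory, then inhibitory),
# then excitatory neurons, then inhibitory neurons; ids are 0-based
unitIds <- function(spec) {
  nIn <- spec@nInputExc + spec@nInputInh
  list(inputExc = seq_len(spec@nInputExc) - 1L,
       inputInh = spec@nInputExc + seq_len(spec@nInputInh) - 1L,
       exc = nIn + seq_len(spec@nExc) - 1L,
       inh = nIn + spec@nExc + seq_len(spec@nInh) - 1L,
       nInput = nIn, excOffset = nIn,
       nUnits = nIn + spec@nExc + spec@nInh)
}

#' Sample points uniformly on a hypersphere surface
#'
#' Rows of iid standard normals normalized to unit length are uniform on
#' the surface of the unit sphere in \code{dim}-space.
#'
#' @param count number of points (may be 0).
#' @param dim embedding dimension, at least 2.
#' @return a \code{count x dim} matrix of unit-norm rows.
#' @export
sampleSpherePoints <- function(count, dim) {
  if (dim < 2) stop("dim must be >= 2")
  if (count == 0) return(matrix(numeric(0), nrow = 0, ncol = dim))
  p <- matrix(stats::rnorm(count * dim), nrow = count, ncol = dim)
  p / sqrt(rowSums(p^2))
}

#' Geodesic distance on the unit sphere
#'
#' Arc length between two unit vectors: the arccosine of their inner
#' product, clamped to [0, pi].
#'
#' @param p,q unit-norm numeric vectors of equal length.
#' @return the angle in radians.
#' @export
sphericalDistance <- function(p, q) {
  if (abs(sum(p^2) - 1) > 1e-6 || abs(sum(q^2) - 1) > 1e-6)
    stop("inputs must be unit vectors")
  acos(min(1, max(-1, sum(p * q))))
}

#' Map a spherical distance to an integer conduction delay
#'
#' The affine image \code{dmin + (d/pi) (dmax - dmin)}, rounded to the
#' nearest millisecond; monotone in d and always inside the range.
#'
#' @param d spherical distance(s) in [0, pi]; vectorized.
#' @param range integer \code{c(dmin, dmax)}, ms.
#' @return integer delay(s) in \code{[dmin, dmax]}.
#' @export
delayFromDistance <- function(d, range) {
  d <- pmin(pi, pmax(0, d))
  as.integer(pmin(range[2], pmax(range[1],
    round(range[1] + d / pi * (range[2] - range[1])))))
}

# sample k sources for each of `targets` from `pool`, excluding the target
# itself when it belongs to the pool
.sampleSources <- function(targets, pool, k) {
  if (k == 0L) return(matrix(integer(0), nrow = 0, ncol = length(targets)))
  if (k > length(pool) - as.integer(any(targets %in% pool)))
    stop("requested synapse count exceeds eligible pool size")
  vapply(targets, function(tg) {
    elig <- pool[pool != tg]
    elig[sample.int(length(elig), k)]
  }, integer(k))
}

.edgeBlock <- function(srcMat, targets, type, group) {
  k <- nrow(srcMat)
  data.frame(source = as.vector(srcMat),
             target = rep(targets, each = k),
             weight = NA_real_, delay = NA_integer_,
             type = type, group = group)
}

#' Realize a network from a specification
#'
#' Places every neuron at a uniform random point on the hypersphere, then
#' draws, independently for each postsynaptic neuron, the prescribed number
#' of presynaptic sources for each of the eight connection groups (uniform
#' without replacement from the eligible pool, never the neuron itself).
#' Weights are uniform on (0, max). Neuron-to-neuron excitatory delays are
#' the affine image of the spherical distance between the connected
#' neurons; afferent excitatory delays are uniform integers in the
#' excitatory range, and all inhibitory delays uniform integers in the
#' inhibitory range.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @param seed optional integer; defaults to \code{spec@seed}. When set,
#'   independent child streams are derived for placement/topology, weights,
#'   and delays.
#' @return a \linkS4class{SpikingNetwork}.
#' @examples
#' net <- buildNetwork(NetworkSpec(), seed = 1)
#' table(edges(net)$type, edges(net)$group)
#' @export
buildNetwork <- function(spec, seed = spec@seed) {
  if (!is.na(seed)) set.seed(deriveSeeds(seed, 1L, "network"))
  ids <- unitIds(spec)
  sc <- spec@synCounts
  positions <- sampleSpherePoints(spec@nExc + spec@nInh, spec@sphereDim)

  blocks <- list(
    .edgeBlock(.sampleSources(ids$exc, ids$inputExc, sc[["affExcOnExc"]]),
               ids$exc, "exc", "afferent"),
    .edgeBlock(.sampleSources(ids$inh, ids$inputExc, sc[["affExcOnInh"]]),
               ids$inh, "exc", "afferent"),
    .edgeBlock(.sampleSources(ids$exc, ids$inputInh, sc[["affInhOnExc"]]),
               ids$exc, "inh", "afferent"),
    .edgeBlock(.sampleSources(ids$inh, ids$inputInh, sc[["affInhOnInh"]]),
               ids$inh, "inh", "afferent"),
    .edgeBlock(.sampleSources(ids$exc, ids$exc, sc[["recExcOnExc"]]),
               ids$exc, "exc", "recurrent"),
    .edgeBlock(.sampleSources(ids$inh, ids$exc, sc[["recExcOnInh"]]),
               ids$inh, "exc", "recurrent"),
    .edgeBlock(.sampleSources(ids$exc, ids$inh, sc[["recInhOnExc"]]),
               ids$exc, "inh", "recurrent"),
    .edgeBlock(.sampleSources(ids$inh, ids$inh, sc[["recInhOnInh"]]),
               ids$inh, "inh", "recurrent"))
  e <- do.call(rbind, blocks)

  exc <- e$type == "exc"
  e$weight[exc] <- stats::runif(sum(exc)) * spec@wExcMax
  e$weight[!exc] <- stats::runif(sum(!exc)) * spec@wInhMax

  rec_exc <- exc & e$group == "recurrent"
  si <- e$source[rec_exc] - ids$excOffset + 1L  # neuron row indices
  ti <- e$target[rec_exc] - ids$excOffset + 1L
  inner <- rowSums(positions[si, , drop = FALSE] * positions[ti, , drop = FALSE])
  e$delay[rec_exc] <- delayFromDistance(acos(pmin(1, pmax(-1, inner))),
                                        spec@delayExcRange)
  aff_exc <- exc & e$group == "afferent"
  e$delay[aff_exc] <- sample(seq(spec@delayExcRange[1], spec@delayExcRange[2]),
                             sum(aff_exc), replace = TRUE)
  e$delay[!exc] <- sample(seq(spec@delayInhRange[1], spec@delayInhRange[2]),
                          sum(!exc), replace = TRUE)
  rownames(e) <- NULL
  new("SpikingNetwork", spec = spec, positions = positions, edges = e)
}

#' Randomly permute the neuron-to-neuron excitatory delays
#'
#' The control that destroys the hypersphere delay structure while keeping
#' everything else fixed: the multiset of recurrent excitatory delays is
#' shuffled across those edges; topology, weights and all other delays are
#' untouched.
#'
#' @param net a \linkS4class{SpikingNetwork}.
#' @param seed optional integer seed.
#' @return a new \linkS4class{SpikingNetwork}.
#' @export
permuteExcitatoryDelays <- function(net, seed = NA_integer_) {
  if (!is.na(seed)) set.seed(deriveSeeds(seed, 1L, "permute"))
  e <- net@edges
  idx <- which(e$type == "exc" & e$group == "recurrent")
  e$delay[idx] <- e$delay[idx][sample.int(length(idx))]
  new("SpikingNetwork", spec = net@spec, positions = net@positions, edges = e)
}
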