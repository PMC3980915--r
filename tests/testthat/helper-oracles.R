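# Independent brute-force oracles for the alignment algorithm and the
# response metrics, written as direct transcriptions of the definitions
# (naive loops, no shared code with the package kernels).

# best shift of frag against count matrix C: argmax_s sum C[a, tf - s],
# ties by smallest |s| then smallest s
oracleBestShift <- function(C, frag) {
  L <- ncol(C)
  shifts <- seq(-(L - 1), L - 1)
  score <- vapply(shifts, function(s) {
    tot <- 0
    for (p in seq_len(nrow(frag))) {
      t <- frag[p, 2] - s
      if (t >= 0 && t < L) tot <- tot + C[frag[p, 1] + 1, t + 1]
    }
    tot
  }, numeric(1))
  best <- max(score)
  cand <- shifts[score == best]
  cand <- cand[order(abs(cand), cand)]
  list(shift = cand[1], score = best)
}

# the full detection procedure, naive: init C from fragment 1, align each
# following fragment at its oracle best shift, threshold at n
oracleDetect <- function(frags, n, nNeurons, L) {
  C <- matrix(0L, nNeurons, L)
  f1 <- frags[[1]]
  for (p in seq_len(nrow(f1)))
    if (f1[p, 2] < L) C[f1[p, 1] + 1, f1[p, 2] + 1] <- 1L
  for (i in seq_along(frags)[-1]) {
    f <- frags[[i]]
    s <- oracleBestShift(C, f)$shift
    for (p in seq_len(nrow(f))) {
      t <- f[p, 2] - s
      if (t >= 0 && t < L) C[f[p, 1] + 1, t + 1] <- C[f[p, 1] + 1, t + 1] + 1L
    }
  }
  hit <- which(C >= n, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  tmin <- min(hit[, 2])
  pairs <- cbind(neuron = hit[, 1] - 1L, time = hit[, 2] - tmin)
  pairs[order(pairs[, 2], pairs[, 1]), , drop = FALSE]
}

# activity: explicit maximization over every shift with possible overlap
oracleActivity <- function(g, frag) {
  if (!nrow(g) || !nrow(frag)) return(0L)
  shifts <- seq(min(frag[, 2]) - max(g[, 2]), max(frag[, 2]) - min(g[, 2]))
  fkey <- paste(frag[, 1], frag[, 2])
  best <- 0L
  for (s in shifts) {
    ov <- sum(paste(g[, 1], g[, 2] + s) %in% fkey)
    if (ov > best) best <- ov
  }
  best
}

# uniform sphere points by rejection from the enclosing cube (independent
# of the normalized-Gaussian construction used by the package)
oracleSpherePoints <- function(count, dim) {
  out <- matrix(NA_real_, 0, dim)
  while (nrow(out) < count) {
    x <- matrix(stats::runif(2 * count * dim, -1, 1), ncol = dim)
    r2 <- rowSums(x^2)
    keep <- r2 <= 1 & r2 > 1e-8
    out <- rbind(out, x[keep, , drop = FALSE] / sqrt(r2[keep]))
  }
  out[seq_len(count), , drop = FALSE]
}

# geodesic arc length by numeric integration along the great circle
oracleArcLength <- function(p, q, nsteps = 20000) {
  u <- q - sum(p * q) * p
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) return(if (sum(p * q) > 0) 0 else pi)
  u <- u / nu
  theta <- atan2(nu, sum(p * q))
  ts <- seq(0, theta, length.out = nsteps + 1)
  pts <- outer(cos(ts), p) + outer(sin(ts), u)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# random small fragment on nNeurons x L
randomFragment <- function(nNeurons, L, density = 0.3) {
  cells <- which(matrix(stats::runif(nNeurons * L) < density, nNeurons, L),
                 arr.ind = TRUE)
  cbind(neuron = as.integer(cells[, 1] - 1L), time = as.integer(cells[, 2] - 1L))
}

# build a FragmentSet from bare pair matrices (neuron index from 0)
fragSet <- function(frags, L, label = "A", excOffset = 0L, nExc = 6L) {
  frags <- lapply(frags, function(f) {
    f <- rbind(f)
    storage.mode(f) <- "integer"
    colnames(f) <- c("neuron", "time")
    f
  })
  new("FragmentSet", label = label, fragments = frags,
      windowLength = as.integer(L), excOffset = as.integer(excOffset),
      nExc = as.integer(nExc))
}

# compact network spec for structural tests
smallSpec <- function(...) {
  NetworkSpec(nExc = 40L, nInh = 20L, nInputExc = 30L, nInputInh = 15L,
              synCounts = c(affExcOnExc = 10L, affExcOnInh = 10L,
                            affInhOnExc = 4L, affInhOnInh = 6L,
                            recExcOnExc = 8L, recExcOnInh = 8L,
                            recInhOnExc = 4L, recInhOnInh = 3L), ...)
}

# hand-built network: one target neuron (excitatory, id nIn) fed by k
# afferent excitatory synapses of weight w and delay d from input nodes
# 0..k-1; used to probe the LIF soma in isolation
probeNetwork <- function(k, w = 0.19, delay = 1L, tauM = 3, tRefract = 6L) {
  spec <- NetworkSpec(nExc = 1L, nInh = 1L, nInputExc = max(k, 6L),
                      nInputInh = 1L, wExcMax = 0.199,
                      synCounts = c(affExcOnExc = 0L, affExcOnInh = 0L,
                                    affInhOnExc = 0L, affInhOnInh = 0L,
                                    recExcOnExc = 0L, recExcOnInh = 0L,
                                    recInhOnExc = 0L, recInhOnInh = 0L),
                      tauM = tauM, tRefract = tRefract)
  nIn <- spec@nInputExc + spec@nInputInh
  edges <- data.frame(source = seq_len(k) - 1L, target = nIn,
                      weight = w, delay = as.integer(delay),
                      type = "exc", group = "afferent")
  new("SpikingNetwork", spec = spec,
      positions = polychron::sampleSpherePoints(2, 4), edges = edges)
}

inputRaster <- function(times, ids) {
  o <- order(times, ids)
  new("SpikeRaster", events = data.frame(time = as.integer(times[o]),
                                         id = as.integer(ids[o]),
                                         kind = rep("input", length(o))))
}
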