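# Deterministic child seeds: one master seed spawns independent, labelled
# streams (topology, weights, stimuli, noise, ...) so each source of
# randomness can be varied in isolation. Plain 31-bit LCG walk keyed by the
# label; values always fit a 32-bit R integer.
deriveSeeds <- function(master, n = 1L, context = "") {
  stopifnot(is.finite(master))
  m <- 2147483647
  ch <- utf8ToInt(context)
  h <- if (length(ch)) sum(ch * seq_along(ch)) %% m else 0
  cur <- ((as.double(master) %% m) * 48271 + h + 1) %% m
  out <- integer(n)
  for (i in seq_len(n)) {
    cur <- (cur * 48271 + 12345) %% m
    out[i] <- as.integer(cur)
  }
  out
}

#' Count refractory-period violations in a raster
#'
#' Number of consecutive same-neuron spike pairs closer than
#' \code{tRefract} ms; 0 on any raster a correct simulation produced.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param tRefract the absolute refractory period, ms.
#' @return integer violation count.
#' @export
refractoryViolations <- function(raster, tRefract) {
  e <- spikeEvents(raster)
  e <- e[e$kind != "input", ]
  if (!nrow(e)) return(0L)
  sum(vapply(split(e$time, e$id), function(ts)
    sum(diff(sort(ts)) < tRefract), integer(1)))
}
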