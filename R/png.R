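#' Extract stimulus-locked spike fragments
#'
#' For every presentation of \code{label} in the schedule, collects the
#' excitatory-neuron spikes falling in its window \code{[onset, end)} as a
#' set of (neuron id, time - onset) pairs — the raw material of group
#' detection. Empty presentations yield empty fragments (kept, not
#' dropped); input-node and inhibitory spikes are excluded.
#'
#' @param raster a \linkS4class{SpikeRaster} (e.g. from
#'   \code{\link{presentStimuli}}).
#' @param schedule the matching \linkS4class{PresentationSchedule}.
#' @param label stimulus label to extract.
#' @param spec the \linkS4class{NetworkSpec} (defines the id layout).
#' @return a \linkS4class{FragmentSet}.
#' @export
extractFragments <- function(raster, schedule, label, spec = NetworkSpec()) {
  sel <- scheduleEntries(schedule)
  L <- max(sel$end - sel$onset)  # common alignment window across the run
  sel <- sel[sel$label == label, ]
  if (!nrow(sel)) stop("label '", label, "' absent from the schedule")
  ids <- unitIds(spec)
  e <- spikeEvents(raster)
  e <- e[e$kind == "exc", ]
  frags <- vector("list", nrow(sel))
  for (i in seq_len(nrow(sel))) {
    inWin <- e$time >= sel$onset[i] & e$time < sel$end[i]
    id <- e$id[inWin]
    rel <- e$time[inWin] - sel$onset[i]
    key <- (id - ids$excOffset) * L + rel
    keep <- !duplicated(key)
    frags[[i]] <- cbind(neuron = as.integer(id[keep]),
                        time = as.integer(rel[keep]))
  }
  new("FragmentSet", label = label, fragments = frags,
      windowLength = as.integer(L), excOffset = as.integer(ids$excOffset),
      nExc = spec@nExc)
}

.fragIdx <- function(fs) lapply(fs@fragments, function(f) {
  f[, 1] <- f[, 1] - fs@excOffset
  f
})

#' Build the alignment count matrix over a fragment set
#'
#' Step 1-2 of the detection algorithm: the matrix C (neurons x time bins)
#' is initialized to 1 on the pairs of the first fragment; every following
#' fragment is aligned at its best shift (the s maximizing the sum of C
#' over the shifted fragment, ties broken by smallest |s| then smallest s)
#' and its in-bounds pairs incremented. After i fragments no cell exceeds
#' i; thresholding C gives the group at any support.
#'
#' @param fs a \linkS4class{FragmentSet}.
#' @return list with \code{C} (integer matrix, rows = excitatory neurons in
#'   id order, columns = ms bins 0..L-1) and \code{shifts} (the per-fragment
#'   alignment shifts, first 0).
#' @export
buildCountMatrix <- function(fs) {
  cpp_build_count_matrix(.fragIdx(fs), fs@nExc, fs@windowLength)
}

#' Best alignment shift of a fragment against a count matrix
#'
#' @param C integer count matrix (rows = neurons, columns = time bins).
#' @param frag 2-column integer matrix (neuron row index 0-based, time).
#' @return list with \code{shift} and its \code{score}.
#' @export
bestShift <- function(C, frag) {
  storage.mode(frag) <- "integer"
  cpp_best_shift(C, frag)
}

#' Detect the polychronous group at a given support
#'
#' Thresholds the alignment count matrix: the group G consists of every
#' (neuron, t) cell counted at least \code{n} times, with times normalized
#' by the earliest such t. Returns \code{NULL} when no cell reaches
#' \code{n}.
#'
#' @param fs a \linkS4class{FragmentSet} with N fragments.
#' @param n the support, between 1 and N.
#' @param C optional precomputed \code{\link{buildCountMatrix}} result.
#' @return a \linkS4class{PolychronousGroup} (with response statistics
#'   unset, NA) or \code{NULL}.
#' @export
detectPNG <- function(fs, n, C = NULL) {
  N <- length(fs@fragments)
  if (n < 1 || n > N) stop("support n must be in [1, ", N, "]")
  if (is.null(C)) C <- buildCountMatrix(fs)
  hit <- which(C$C >= n, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  tmin <- min(hit[, 2])
  pairs <- cbind(neuron = as.integer(hit[, 1] - 1L + fs@excOffset),
                 time = as.integer(hit[, 2] - tmin))
  pairs <- pairs[base::order(pairs[, 2], pairs[, 1]), , drop = FALSE]
  new("PolychronousGroup", pairs = pairs, support = as.integer(n),
      stimulus = fs@label, reactionStrength = NA_real_,
      selectivity = NA_real_)
}

.pairsOf <- function(g) {
  p <- if (is(g, "PolychronousGroup")) g@pairs else g
  storage.mode(p) <- "integer"
  p
}

# bucket size for the C++ kernels: one bucket per possible global id
.idSpan <- function(...) {
  mx <- max(1L, vapply(list(...), function(p)
    if (nrow(p)) max(p[, 1]) else 0L, numeric(1)))
  as.integer(mx + 1L)
}

#' Activity of a group in a spike fragment
#'
#' The maximum over integer shifts s of the number of group pairs that,
#' with s added to their times, occur in the fragment; 0 when the group
#' and fragment share no neuron. Bounded by min(|G|, |fragment|).
#'
#' @param g a \linkS4class{PolychronousGroup} or 2-column pair matrix.
#' @param frag 2-column integer matrix (neuron id, time).
#' @return integer activity.
#' @export
pngActivity <- function(g, frag) {
  g <- .pairsOf(g); frag <- .pairsOf(frag)
  cpp_activity(g, frag, .idSpan(g, frag))
}

#' Reaction strength of a group to its stimulus
#'
#' The minimum of \code{\link{pngActivity}} over all fragments of the set:
#' the worst-case number of group elements realized in a presentation.
#'
#' @param g a \linkS4class{PolychronousGroup} or pair matrix.
#' @param fs a \linkS4class{FragmentSet}.
#' @return integer reaction strength.
#' @export
pngReactionStrength <- function(g, fs) {
  g <- .pairsOf(g)
  span <- max(.idSpan(g), fs@excOffset + fs@nExc)
  min(cpp_activities(g, .noNames(fs@fragments), span))
}

.noNames <- function(fl) lapply(fl, function(f) { storage.mode(f) <- "integer"; f })

#' Selectivity of a group for its stimulus
#'
#' N_A divided by the number of (stimulus, presentation) fragments — over
#' all stimuli, the group's own included — whose activity reaches the
#' group's reaction strength. 1 means no foreign presentation matches the
#' group at its threshold level; always in (0, 1] when the reaction
#' strength is positive. A reaction strength of 0 makes the measure
#' meaningless (every fragment qualifies) and yields NA with attribute
#' \code{degenerate}.
#'
#' @param g a \linkS4class{PolychronousGroup} or pair matrix.
#' @param allFs named list of \linkS4class{FragmentSet}s, one per stimulus.
#' @param label the group's stimulus (must be in \code{allFs}).
#' @return selectivity in (0, 1], or NA (degenerate).
#' @export
pngSelectivity <- function(g, allFs, label) {
  if (!label %in% names(allFs)) stop("label '", label, "' not in allFs")
  g <- .pairsOf(g)
  R <- pngReactionStrength(g, allFs[[label]])
  if (R == 0) return(structure(NA_real_, degenerate = TRUE))
  span <- max(.idSpan(g),
              max(vapply(allFs, function(f) f@excOffset + f@nExc, numeric(1))))
  qualifying <- sum(vapply(allFs, function(fs)
    sum(cpp_activities(g, .noNames(fs@fragments), span) >= R), numeric(1)))
  length(allFs[[label]]@fragments) / qualifying
}

#' Pairwise independence measure of two groups
#'
#' The observed size of the intersection of the two groups' neuron sets,
#' divided by its expectation |S1||S2|/N+ under independent uniform draws
#' from the N+ excitatory neurons. Values near 1 indicate independent
#' groups; times are ignored.
#'
#' @param g1,g2 \linkS4class{PolychronousGroup}s or pair matrices
#'   (non-empty).
#' @param nExc N+, the number of excitatory neurons.
#' @return non-negative ratio.
#' @export
pngIntersectionRatio <- function(g1, g2, nExc) {
  n1 <- unique(.pairsOf(g1)[, 1]); n2 <- unique(.pairsOf(g2)[, 1])
  if (!length(n1) || !length(n2)) stop("groups must be non-empty")
  length(intersect(n1, n2)) * nExc / (length(n1) * length(n2))
}

#' Scan supports for the most selective group
#'
#' Builds the count matrix once, then walks the achievable supports in
#' descending order (only values actually present in C change the group).
#' Returns the first group with selectivity 1; if none, the group with the
#' maximal selectivity (ties to the larger support), flagged unsuccessful.
#' Degenerate groups (reaction strength 0) never count as selective.
#'
#' @param fs the \linkS4class{FragmentSet} of the target stimulus (at
#'   least 2 fragments).
#' @param allFs named list of fragment sets for all stimuli (used as the
#'   selectivity reference).
#' @param minSupport smallest support scanned (default 2).
#' @return list with \code{group} (a \linkS4class{PolychronousGroup} with
#'   \code{reactionStrength} and \code{selectivity} filled, or NULL when
#'   every support yields an empty group) and \code{success} (logical:
#'   selectivity exactly 1 found).
#' @export
findSelectivePNG <- function(fs, allFs, minSupport = 2L) {
  if (length(fs@fragments) < 2L) stop("need at least 2 fragments")
  C <- buildCountMatrix(fs)
  supports <- sort(unique(C$C[C$C >= minSupport]), decreasing = TRUE)
  best <- NULL; bestS <- -Inf
  for (n in supports) {
    g <- detectPNG(fs, n, C = C)
    R <- pngReactionStrength(g, fs)
    S <- if (R == 0) structure(NA_real_, degenerate = TRUE)
         else pngSelectivity(g, allFs, fs@label)
    g@reactionStrength <- as.numeric(R)
    g@selectivity <- as.numeric(S)
    if (!is.na(S) && S >= 1) return(list(group = g, success = TRUE))
    if (!is.na(S) && S > bestS) { best <- g; bestS <- S }
    if (is.null(best)) best <- g  # keep something even if all degenerate
  }
  list(group = best, success = FALSE)
}
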