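#' Read and write spike rasters as CSV
#'
#' Plain-text representation: columns \code{time_ms,unit_id,kind}, sorted
#' by time, optionally preceded by \code{#}-comment header lines (the
#' writer records the package version; a run seed can be added via
#' \code{comment}). Round-trips losslessly; times are integer ms
#' throughout.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param path file path.
#' @param comment optional extra header comment line(s).
#' @return \code{readRaster} returns a \linkS4class{SpikeRaster};
#'   \code{writeRaster} returns \code{path} invisibly.
#' @export
writeRaster <- function(raster, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# polychron raster v",
                      as.character(utils::packageVersion("polychron"))),
               if (!is.null(comment)) paste0("# ", comment)), con)
  writeLines("time_ms,unit_id,kind", con)
  e <- spikeEvents(raster)
  if (nrow(e))
    writeLines(paste(e$time, e$id, e$kind, sep = ","), con)
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body) || body[1] != "time_ms,unit_id,kind")
    stop("not a raster file (missing header): ", path)
  body <- body[-1]
  if (!length(body))
    return(new("SpikeRaster", events = data.frame(
      time = integer(0), id = integer(0), kind = character(0))))
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed raster line ", bad[1] + sum(startsWith(lines, "#")) + 1L,
         " in ", path)
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  ev <- data.frame(time = as.integer(m[, 1]), id = as.integer(m[, 2]),
                   kind = m[, 3])
  if (anyNA(ev$time) || anyNA(ev$id)) stop("non-numeric raster field in ", path)
  ev <- ev[base::order(ev$time, ev$id, method = "radix"), ]
  rownames(ev) <- NULL
  new("SpikeRaster", events = ev)
}

#' Read and write presentation schedules as CSV
#'
#' Columns \code{label,onset_ms,end_ms}.
#'
#' @param schedule a \linkS4class{PresentationSchedule}.
#' @param path file path.
#' @return \code{readSchedule} returns a
#'   \linkS4class{PresentationSchedule}; the writer returns \code{path}
#'   invisibly.
#' @export
writeSchedule <- function(schedule, path) {
  e <- scheduleEntries(schedule)
  utils::write.csv(data.frame(label = e$label, onset_ms = e$onset,
                              end_ms = e$end),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("PresentationSchedule", entries = data.frame(
    label = as.character(d$label), onset = as.integer(d$onset_ms),
    end = as.integer(d$end_ms)))
}

#' Read and write a realized network as plain text
#'
#' A directory with \code{spec.json} (all specification fields),
#' \code{positions.csv} (one unit-norm row per neuron) and
#' \code{edges.csv} (source, target, weight, delay, type, group).
#' Round-trips the network exactly up to floating-point text precision
#' (weights/positions are written with 17 significant digits, i.e.
#' losslessly).
#'
#' @param net a \linkS4class{SpikingNetwork}.
#' @param dir directory path (created if needed).
#' @return \code{readNetwork} returns a \linkS4class{SpikingNetwork}; the
#'   writer returns \code{dir} invisibly.
#' @export
writeNetwork <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- net@spec
  specList <- list(nExc = sp@nExc, nInh = sp@nInh, nInputExc = sp@nInputExc,
                   nInputInh = sp@nInputInh, wExcMax = sp@wExcMax,
                   wInhMax = sp@wInhMax, threshold = sp@threshold,
                   tRefract = sp@tRefract, tauM = sp@tauM,
                   synCounts = as.list(sp@synCounts),
                   delayExcRange = sp@delayExcRange,
                   delayInhRange = sp@delayInhRange,
                   sphereDim = sp@sphereDim, seed = sp@seed)
  jsonlite::write_json(specList, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(format(as.data.frame(net@positions), digits = 17),
                   file.path(dir, "positions.csv"), row.names = FALSE,
                   quote = FALSE)
  e <- net@edges
  e$weight <- format(e$weight, digits = 17)
  utils::write.csv(e, file.path(dir, "edges.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(dir) {
  sl <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- NetworkSpec(nExc = sl$nExc, nInh = sl$nInh,
                      nInputExc = sl$nInputExc, nInputInh = sl$nInputInh,
                      wExcMax = sl$wExcMax, wInhMax = sl$wInhMax,
                      threshold = sl$threshold, tRefract = sl$tRefract,
                      tauM = sl$tauM, synCounts = unlist(sl$synCounts),
                      delayExcRange = sl$delayExcRange,
                      delayInhRange = sl$delayInhRange,
                      sphereDim = sl$sphereDim,
                      seed = if (is.null(sl$seed)) NA_integer_ else sl$seed)
  pos <- as.matrix(utils::read.csv(file.path(dir, "positions.csv")))
  dimnames(pos) <- NULL
  e <- utils::read.csv(file.path(dir, "edges.csv"), stringsAsFactors = FALSE)
  e$source <- as.integer(e$source); e$target <- as.integer(e$target)
  e$delay <- as.integer(e$delay)
  new("SpikingNetwork", spec = spec, positions = pos, edges = e)
}

#' Write and read detected groups as JSON
#'
#' One record per group: stimulus, support, pairs (neuron id, relative
#' ms), size, reaction strength, relative strength, selectivity.
#'
#' @param groups list of \linkS4class{PolychronousGroup}s.
#' @param path file path.
#' @return \code{readGroups} returns a list of
#'   \linkS4class{PolychronousGroup}s.
#' @export
writeGroups <- function(groups, path) {
  recs <- lapply(groups, function(g) list(
    stimulus = g@stimulus, support = g@support,
    pairs = unname(apply(g@pairs, 1, function(r) c(r[1], r[2]),
                         simplify = FALSE)),
    size = nrow(g@pairs), R = g@reactionStrength,
    R_rel = g@reactionStrength / max(1L, nrow(g@pairs)),
    selectivity = g@selectivity))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeGroups
#' @export
readGroups <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    pr <- do.call(rbind, lapply(r$pairs, function(p)
      c(as.integer(p[[1]]), as.integer(p[[2]]))))
    colnames(pr) <- c("neuron", "time")
    new("PolychronousGroup", pairs = pr, support = as.integer(r$support),
        stimulus = r$stimulus,
        reactionStrength = if (is.null(r$R)) NA_real_ else as.numeric(r$R),
        selectivity = if (is.null(r$selectivity)) NA_real_
                      else as.numeric(r$selectivity))
  })
}

.configDefaults <- function() {
  list(
    network = list(nExc = 700L, nInh = 300L, nInputExc = 700L,
                   nInputInh = 300L, wExcMax = 0.19, wInhMax = 10,
                   threshold = 1.0, tRefract = 6L, tauM = 3,
                   delayExcRange = c(1L, 10L), delayInhRange = c(1L, 3L),
                   sphereDim = 4L),
    stimuli = list(nStimuli = 10L, nodesPerStimulus = 100L, stimRate = 300,
                   stimDuration = 30L, noiseRate = 3, nPresentations = 100L),
    run = list(quietMs = 20L, maxGapMs = 120L, runawayLimit = 20L),
    seed = 1L)
}

#' Load and validate an experiment configuration
#'
#' YAML (or JSON) tree with sections \code{network}, \code{stimuli},
#' \code{run} and a top-level \code{seed}; every omitted key is filled
#' from the baseline defaults, unknown keys are rejected, and basic range
#' checks are applied. An empty file yields the full baseline
#' configuration.
#'
#' @param path path to a YAML/JSON file, or NULL for pure defaults.
#' @return the fully resolved configuration list.
#' @export
loadConfig <- function(path = NULL) {
  defaults <- .configDefaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(user), c("network", "stimuli", "run"))) {
    extra <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(extra))
      stop("unknown key(s) in '", sec, "': ", paste(extra, collapse = ", "))
    defaults[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  if (!is.null(user$seed)) defaults$seed <- user$seed
  cfg <- defaults
  if (cfg$stimuli$noiseRate < 0) stop("config: noiseRate must be >= 0")
  if (cfg$stimuli$stimRate < 0) stop("config: stimRate must be >= 0")
  nIn <- cfg$network$nInputExc + cfg$network$nInputInh
  if (cfg$stimuli$nodesPerStimulus > nIn)
    stop("config: nodesPerStimulus exceeds the input pool (", nIn, ")")
  if (cfg$stimuli$nStimuli < 1) stop("config: nStimuli must be >= 1")
  cfg
}

#' Build a run manifest for a set of artifact files
#'
#' Records the package version, master seed, resolved configuration and
#' the md5 checksum of every produced file — enough to rerun and verify a
#' stage.
#'
#' @param files character vector of file paths.
#' @param seed the master seed of the stage.
#' @param config the resolved configuration list.
#' @param path optional JSON output path.
#' @return the manifest list (invisibly written to \code{path} if given).
#' @export
runManifest <- function(files, seed, config = list(), path = NULL) {
  man <- list(
    tool = "polychron",
    version = as.character(utils::packageVersion("polychron")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(man)
}
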