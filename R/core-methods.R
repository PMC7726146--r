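#' Construct a SpikeTrain
#'
#' @param electrodeId electrode label.
#' @param times numeric vector of spike times in seconds. Sorted on
#'   construction; exact duplicates are rejected by validity.
#' @param tStart,tStop recording interval bounds in seconds; times must lie in
#'   \code{[tStart, tStop)}.
#' @param sort sort \code{times} before validation (default TRUE). With
#'   \code{sort = FALSE} unsorted input is a validation error.
#'
#' @return a [SpikeTrain-class] object.
#' @examples
#' SpikeTrain("ch1", c(0.10, 0.25), tStart = 0, tStop = 1)
#' @export
SpikeTrain <- function(electrodeId, times = numeric(), tStart = 0, tStop,
                       sort = TRUE) {
  times <- as.numeric(times)
  if (sort) times <- base::sort(times)
  new("SpikeTrain", electrodeId = as.character(electrodeId), times = times,
      tStart = as.numeric(tStart), tStop = as.numeric(tStop))
}

#' Construct a RecordingSession
#'
#' @param trains list of [SpikeTrain-class] objects (or a single train).
#' @param samplingRate acquisition rate in Hz, or NA for timestamp-only data.
#' @param annotations free-form metadata list.
#'
#' @return a [RecordingSession-class] object with trains named by electrode.
#' @export
RecordingSession <- function(trains, samplingRate = NA_real_,
                             annotations = list()) {
  if (is(trains, "SpikeTrain")) trains <- list(trains)
  names(trains) <- vapply(trains, function(x) x@electrodeId, character(1L))
  new("RecordingSession", trains = trains,
      samplingRate = as.numeric(samplingRate), annotations = annotations)
}

#' Construct a ModuleMap
#'
#' @param modules named list, module label -> character vector of electrode
#'   ids, e.g. \code{list(N1 = c("ch1","ch2"), N2 = c("ch3","ch4"),
#'   CTRL = "ch5")}. The entry named \code{controlLabel} flags control
#'   electrodes.
#' @param controlLabel reserved control label (default \code{"CTRL"}).
#' @param excluded electrode ids excluded from all analyses.
#'
#' @return a [ModuleMap-class] object.
#' @export
ModuleMap <- function(modules, controlLabel = "CTRL", excluded = character()) {
  if (length(modules) == 0L)
    stop("module map contains no modules")
  if (is.null(names(modules)) || any(!nzchar(names(modules))))
    stop("'modules' must be a named list of electrode vectors")
  electrodes <- unlist(lapply(modules, as.character), use.names = FALSE)
  labels <- rep(names(modules), lengths(modules))
  if (anyDuplicated(electrodes))
    stop("electrode assigned to more than one module: ",
         paste(unique(electrodes[duplicated(electrodes)]), collapse = ", "))
  assignment <- stats::setNames(labels, electrodes)
  new("ModuleMap", assignment = assignment,
      controlLabel = as.character(controlLabel),
      excluded = as.character(excluded))
}

#' Construct a TraceBlock
#'
#' @param samples channels x samples numeric matrix, microvolts. A plain
#'   vector is treated as a single channel.
#' @param samplingRate sampling rate in Hz.
#' @param channelIds one id per channel (default \code{ch1, ch2, ...}).
#' @return a [TraceBlock-class] object.
#' @export
TraceBlock <- function(samples, samplingRate, channelIds = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (is.null(channelIds)) channelIds <- paste0("ch", seq_len(nrow(samples)))
  new("TraceBlock", samples = samples, samplingRate = as.numeric(samplingRate),
      channelIds = as.character(channelIds))
}

## ---- accessors -------------------------------------------------------------

#' Accessors for spike-train containers
#'
#' @param x a [SpikeTrain-class], [RecordingSession-class],
#'   [TraceBlock-class], [RateHistogram-class] or [PSTH-class] object.
#' @param electrode electrode id (for sessions).
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("electrodeIds", "RecordingSession",
          function(x) unname(names(x@trains)))
#' @rdname accessors
#' @export
setMethod("electrodeIds", "SpikeTrain", function(x) x@electrodeId)
#' @rdname accessors
#' @export
setMethod("electrodeIds", "TraceBlock", function(x) x@channelIds)

#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x, electrode) x@times)
#' @rdname accessors
#' @export
setMethod("spikeTimes", "RecordingSession", function(x, electrode) {
  if (!electrode %in% names(x@trains))
    stop("unknown electrode: ", electrode)
  x@trains[[electrode]]@times
})

#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(x, ...) length(x@times))
#' @rdname accessors
#' @export
setMethod("nSpikes", "RecordingSession", function(x, ...)
  sum(vapply(x@trains, function(t) length(t@times), integer(1L))))

#' @rdname accessors
#' @export
setMethod("tStart", "SpikeTrain", function(x) x@tStart)
#' @rdname accessors
#' @export
setMethod("tStop", "SpikeTrain", function(x) x@tStop)
#' @rdname accessors
#' @export
setMethod("tStart", "RecordingSession", function(x) {
  if (!length(x@trains)) return(NA_real_)
  x@trains[[1L]]@tStart
})
#' @rdname accessors
#' @export
setMethod("tStop", "RecordingSession", function(x) {
  if (!length(x@trains)) return(NA_real_)
  x@trains[[1L]]@tStop
})

#' @rdname accessors
#' @export
setMethod("duration", "SpikeTrain", function(x) x@tStop - x@tStart)
#' @rdname accessors
#' @export
setMethod("duration", "RecordingSession", function(x) tStop(x) - tStart(x))

#' @rdname accessors
#' @export
setMethod("samplingRate", "RecordingSession", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "TraceBlock", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("rates", "RateHistogram", function(x) x@rates)
#' @rdname accessors
#' @export
setMethod("binWidth", "RateHistogram", function(x) x@binWidth)
#' @rdname accessors
#' @export
setMethod("binWidth", "PSTH", function(x) x@binWidth)

#' Subset a session by electrode
#'
#' @param x a RecordingSession.
#' @param i electrode ids or indices.
#' @return a RecordingSession with the selected trains.
#' @export
setMethod("[", c("RecordingSession", "ANY", "missing", "ANY"),
  function(x, i, j, ..., drop = TRUE) {
    initialize(x, trains = x@trains[i])
  })

## ---- ModuleMap accessors ---------------------------------------------------

#' Accessors for ModuleMap
#'
#' @param x a [ModuleMap-class].
#' @param electrodes electrode ids.
#' @param module a module label.
#' @name map-accessors
NULL

#' @rdname map-accessors
#' @export
setMethod("moduleLabels", "ModuleMap", function(x) {
  labs <- unique(unname(x@assignment))
  labs[labs != x@controlLabel]
})

#' @rdname map-accessors
#' @export
setMethod("moduleOf", "ModuleMap", function(x, electrodes) {
  out <- x@assignment[electrodes]
  names(out) <- electrodes
  out
})

#' @rdname map-accessors
#' @export
setMethod("electrodesOf", "ModuleMap", function(x, module) {
  names(x@assignment)[x@assignment == module]
})

#' @rdname map-accessors
#' @export
setMethod("isControl", "ModuleMap", function(x, electrodes) {
  stats::setNames(x@assignment[electrodes] == x@controlLabel, electrodes)
})

#' Electrodes covered by a map
#' @param x a ModuleMap.
#' @export
setMethod("electrodeIds", "ModuleMap", function(x) names(x@assignment))

## ---- show ------------------------------------------------------------------

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes in [%g, %g) s\n",
              object@electrodeId, length(object@times),
              object@tStart, object@tStop))
})

setMethod("show", "RecordingSession", function(object) {
  cat(sprintf("RecordingSession: %d electrodes, %d spikes, [%g, %g) s\n",
              length(object@trains), nSpikes(object),
              tStart(object), tStop(object)))
  if (!is.na(object@samplingRate))
    cat(sprintf("  sampling rate: %g Hz\n", object@samplingRate))
})

setMethod("show", "ModuleMap", function(object) {
  labs <- unique(unname(object@assignment))
  for (l in labs) {
    tag <- if (l == object@controlLabel) " (control)" else ""
    cat(sprintf("  %s%s: %s\n", l, tag,
                paste(electrodesOf(object, l), collapse = ", ")))
  }
  if (length(object@excluded))
    cat("  excluded:", paste(object@excluded, collapse = ", "), "\n")
})

setMethod("show", "TraceBlock", function(object) {
  cat(sprintf("TraceBlock: %d channels x %d samples at %g Hz (%.3f s)\n",
              nrow(object@samples), ncol(object@samples),
              object@samplingRate,
              ncol(object@samples) / object@samplingRate))
})

setMethod("show", "RateHistogram", function(object) {
  cat(sprintf("RateHistogram '%s': %d bins of %g s%s\n",
              object@electrodeId, length(object@rates), object@binWidth,
              if (object@smoothed)
                sprintf(", smoothed (%d-bin Gaussian)", object@kernelBins)
              else ""))
})

setMethod("show", "CCSummary", function(object) {
  cat("Correlation summary\n")
  cat(sprintf("  intra-CC (pooled): %.3f over %d pairs\n",
              object@intraOverall, object@nPairs[["intra"]]))
  for (m in names(object@intraModule))
    cat(sprintf("    %s: %.3f\n", m, object@intraModule[[m]]))
  cat(sprintf("  inter-CC (pooled): %.3f over %d pairs\n",
              object@interOverall, object@nPairs[["inter"]]))
  if (nrow(object@interPairs))
    for (k in seq_len(nrow(object@interPairs)))
      cat(sprintf("    %s-%s: %.3f\n", object@interPairs$module1[k],
                  object@interPairs$module2[k], object@interPairs$cc[k]))
  if (!is.na(object@control))
    cat(sprintf("  control pairs: %.3f over %d pairs\n", object@control,
                object@nPairs[["control"]]))
  if (length(object@flagged))
    cat("  flagged (undefined intra-CC):",
        paste(object@flagged, collapse = ", "), "\n")
})

setMethod("show", "PSTH", function(object) {
  cat(sprintf(
    "PSTH '%s': %d x %g ms bins over %g ms, %d trials (blank %g ms)\n",
    object@electrodeId, length(object@counts), object@binWidth * 1e3,
    object@window * 1e3, object@nTrials, object@blank * 1e3))
})

setMethod("show", "SimConfig", function(object) {
  labs <- vapply(object@modules, `[[`, character(1L), "label")
  cat(sprintf("SimConfig: %d modules (%s), %d couplings, %g s\n",
              length(labs), paste(labs, collapse = ", "),
              length(object@couplings), object@duration))
})

## ---- session utilities -----------------------------------------------------

#' Crop a session to a sub-interval
#'
#' Restricts every train to spikes in \code{[tStart, tStop)} and resets the
#' session interval accordingly. Used e.g. to compare network correlation
#' before and after a structural manipulation within one recording.
#'
#' @param session a [RecordingSession-class].
#' @param tStart,tStop new interval bounds (s), inside the recording.
#' @return a cropped [RecordingSession-class].
#' @export
cropSession <- function(session, tStart, tStop) {
  if (tStop <= tStart) stop("tStop must be greater than tStart")
  trains <- lapply(session@trains, function(tr) {
    keep <- tr@times >= tStart & tr@times < tStop
    SpikeTrain(tr@electrodeId, tr@times[keep], tStart, tStop, sort = FALSE)
  })
  RecordingSession(trains, samplingRate = session@samplingRate,
                   annotations = session@annotations)
}
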