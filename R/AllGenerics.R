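#' @include AllClasses.R
NULL

#' Construct a MultiChannelSignal
#'
#' @param data channels x samples numeric matrix.
#' @param samplingRate sampling rate in Hz.
#' @param channelNames optional channel labels; defaults to ch01, ch02, ...
#' @param startTime start time in seconds.
#' @return a \linkS4class{MultiChannelSignal}.
#' @examples
#' x <- MultiChannelSignal(matrix(rnorm(512), 2), samplingRate = 256)
#' nChannels(x)
#' @export
MultiChannelSignal <- function(data, samplingRate, channelNames = NULL,
                               startTime = 0) {
  data <- as.matrix(data)
  if (is.null(channelNames))
    channelNames <- sprintf("ch%02d", seq_len(nrow(data)))
  new("MultiChannelSignal", data = data, samplingRate = samplingRate,
      channelNames = channelNames, startTime = startTime)
}

#' Construct a PhaseTrajectory
#'
#' @param phases time x oscillator matrix of phases in radians (any real
#'   values; they are wrapped to [-pi, pi]).
#' @param dt step in seconds.
#' @param t0 start time in seconds.
#' @param guard edge guard in seconds flagged unreliable.
#' @return a \linkS4class{PhaseTrajectory}.
#' @export
PhaseTrajectory <- function(phases, dt, t0 = 0, guard = 0) {
  new("PhaseTrajectory", phases = wrapPhase(as.matrix(phases)), dt = dt,
      t0 = t0, guard = guard)
}

#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("phaseMatrix", function(x) standardGeneric("phaseMatrix"))
#' @rdname accessors
#' @export
setGeneric("hyperedges", function(x) standardGeneric("hyperedges"))
#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setGeneric("windowBoundaries", function(x) standardGeneric("windowBoundaries"))
#' @rdname accessors
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' Accessors for chimeraNet containers
#'
#' Small read-only accessors: \code{signalData} (channels x samples matrix),
#' \code{samplingRate}, \code{channelNames}, \code{nChannels},
#' \code{phaseMatrix} (time x oscillator), \code{hyperedges} (E x 3 integer
#' matrix), \code{windowLabels} (per-window label table),
#' \code{windowBoundaries} and \code{communityLabels}.
#'
#' @param x the object.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
setMethod("signalData", "MultiChannelSignal", function(x) x@data)
#' @rdname accessors
setMethod("samplingRate", "MultiChannelSignal", function(x) x@samplingRate)
#' @rdname accessors
setMethod("channelNames", "MultiChannelSignal", function(x) x@channelNames)
#' @rdname accessors
setMethod("nChannels", "MultiChannelSignal", function(x) nrow(x@data))
#' @rdname accessors
setMethod("phaseMatrix", "PhaseTrajectory", function(x) x@phases)
#' @rdname accessors
setMethod("nChannels", "PhaseTrajectory", function(x) ncol(x@phases))
#' @rdname accessors
setMethod("hyperedges", "Hypergraph", function(x) x@hyperedges)
#' @rdname accessors
setMethod("nChannels", "Hypergraph", function(x) length(x@nodes))
#' @rdname accessors
setMethod("windowLabels", "LabeledEpisode", function(x) x@windowLabels)
#' @rdname accessors
setMethod("signalData", "LabeledEpisode", function(x) x@signal@data)
#' @rdname accessors
setMethod("windowBoundaries", "WindowPlan", function(x) x@boundaries)
#' @rdname accessors
setMethod("communityLabels", "ClusterAssignment", function(x) x@labels)
#' @rdname accessors
setMethod("communityLabels", "KuramotoParams", function(x) x@community)

setMethod("show", "MultiChannelSignal", function(object) {
  cat(sprintf("MultiChannelSignal: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
})

setMethod("show", "PhaseTrajectory", function(object) {
  cat(sprintf("PhaseTrajectory: %d steps x %d oscillators, dt = %g s, guard = %g s\n",
              nrow(object@phases), ncol(object@phases), object@dt, object@guard))
})

setMethod("show", "KuramotoParams", function(object) {
  cat(sprintf(paste0("KuramotoParams: C = %d (communities %d/%d), K = %.3f, ",
                     "alpha = %.3f rad, r = %.2f\n"),
              object@nOscillators, sum(object@community == 0L),
              sum(object@community == 1L), object@couplingK,
              object@phaseLagAlpha, object@interCouplingRatio))
  cat(sprintf("  mean frequency: %.2f Hz (community 0), %.2f Hz (community 1)\n",
              mean(object@omega[object@community == 0L]) / (2 * pi),
              mean(object@omega[object@community == 1L]) / (2 * pi)))
})

setMethod("show", "EpisodeSpec", function(object) {
  cat("EpisodeSpec (simulated seconds):\n")
  print(round(object@durations, 2))
  cat(sprintf("  compression x%g, %g Hz, noise sd %g, seed %d\n",
              object@timeCompression, object@samplingRate, object@noiseSd,
              object@seed))
})

setMethod("show", "LabeledEpisode", function(object) {
  wl <- object@windowLabels
  cat(sprintf("LabeledEpisode: %.1f s, onset at %.1f s, %d windows (%d chimera, states: %s)\n",
              ncol(object@signal@data) / object@signal@samplingRate,
              object@onsetTime, nrow(wl), sum(wl$ychimera),
              paste(table(factor(wl$ystate, levels = 0:3)), collapse = "/")))
})

setMethod("show", "Hypergraph", function(object) {
  cat(sprintf("Hypergraph: %d nodes, %d hyperedges (tau = %g, density %.1f%%)\n",
              length(object@nodes), nrow(object@hyperedges), object@tau,
              100 * hyperedgeDensity(object)))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: k = %d, sizes %s\n", object@k,
              paste(tabulate(object@labels + 1L, object@k), collapse = "/")))
})

setMethod("show", "WindowPlan", function(object) {
  cat(sprintf("WindowPlan: %d windows of %g s, overlap %g%%\n",
              nrow(object@boundaries), object@windowLength,
              100 * object@overlap))
})
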