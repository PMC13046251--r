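#' @import methods
#' @importFrom stats approx coef cor fft kmeans lm mad median na.omit quantile
#'   rnorm runif sd var
#' @importFrom utils head tail
#' @useDynLib chimeraNet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importMethodsFrom Matrix %*% crossprod t
NULL

#' Multichannel sampled recording
#'
#' Container for a multichannel time series (synthetic EEG or real recordings
#' imported from a plain numeric matrix), stored channels x samples together
#' with its sampling rate, channel names and start time.
#'
#' @slot data numeric matrix, channels x samples (microvolts or arbitrary
#'   synthetic units).
#' @slot samplingRate sampling rate in Hz, strictly positive.
#' @slot channelNames character vector, one label per channel row.
#' @slot startTime recording start in seconds.
#' @exportClass MultiChannelSignal
setClass("MultiChannelSignal",
  representation(data = "matrix", samplingRate = "numeric",
                 channelNames = "character", startTime = "numeric"),
  prototype(startTime = 0))

setValidity("MultiChannelSignal", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@channelNames) != nrow(object@data))
    msg <- c(msg, "channelNames length must equal the number of channel rows")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "signal data must be finite")
  if (length(msg)) msg else TRUE
})

#' Per-channel instantaneous phase trajectory
#'
#' Phases are stored time x oscillator in radians, wrapped to [-pi, pi].
#' \code{guard} records how many seconds at each edge are unreliable
#' (Hilbert edge effects) and should be excluded downstream; it is 0 for
#' phases produced by the numerical integrator.
#'
#' @slot phases numeric matrix, time x oscillator, radians in [-pi, pi].
#' @slot dt sampling step in seconds.
#' @slot t0 start time in seconds.
#' @slot guard guard interval in seconds flagged at each edge.
#' @exportClass PhaseTrajectory
setClass("PhaseTrajectory",
  representation(phases = "matrix", dt = "numeric", t0 = "numeric",
                 guard = "numeric"),
  prototype(t0 = 0, guard = 0))

setValidity("PhaseTrajectory", function(object) {
  msg <- character()
  if (nrow(object@phases) < 2L) msg <- c(msg, "need at least 2 time steps")
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  rng <- range(object@phases)
  if (rng[1] < -pi - 1e-9 || rng[2] > pi + 1e-9)
    msg <- c(msg, "phases must be wrapped to [-pi, pi]")
  if (object@guard < 0) msg <- c(msg, "guard must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Kuramoto-Sakaguchi network parameters
#'
#' Parameters of the two-community oscillator network
#' \deqn{d\theta_i/dt = \omega_i + (1/C)\sum_j K_{ij} \sin(\theta_j - \theta_i
#'  - \alpha)}
#' with \eqn{K_{ij} = K} inside a community and \eqn{r K} across communities.
#' Community 0 is the synchronization-prone (delta-band) population,
#' community 1 the desynchronized (alpha-band) population.
#'
#' @slot nOscillators number of oscillators C.
#' @slot omega natural frequencies in rad/s, strictly positive.
#' @slot couplingK global coupling, dimensionless, in [0, 1.5].
#' @slot phaseLagAlpha Sakaguchi phase lag in radians, in [0, pi/2].
#' @slot community integer community id per oscillator (0 or 1).
#' @slot interCouplingRatio cross-community coupling factor r in [0, 1].
#' @exportClass KuramotoParams
setClass("KuramotoParams",
  representation(nOscillators = "integer", omega = "numeric",
                 couplingK = "numeric", phaseLagAlpha = "numeric",
                 community = "integer", interCouplingRatio = "numeric"))

setValidity("KuramotoParams", function(object) {
  msg <- character()
  C <- object@nOscillators
  if (length(object@omega) != C) msg <- c(msg, "omega length must equal nOscillators")
  if (any(object@omega <= 0)) msg <- c(msg, "omega must be strictly positive")
  if (object@couplingK < 0 || object@couplingK > 1.5)
    msg <- c(msg, "couplingK must lie in [0, 1.5]")
  if (object@phaseLagAlpha < 0 || object@phaseLagAlpha > pi / 2)
    msg <- c(msg, "phaseLagAlpha must lie in [0, pi/2]")
  if (length(object@community) != C)
    msg <- c(msg, "community length must equal nOscillators")
  if (!all(object@community %in% c(0L, 1L)))
    msg <- c(msg, "community ids must be 0 or 1")
  if (object@interCouplingRatio < 0 || object@interCouplingRatio > 1)
    msg <- c(msg, "interCouplingRatio must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic episode specification
#'
#' Segment durations are expressed in simulated seconds; multiplying by
#' \code{timeCompression} and dividing by 60 converts them to the uncompressed
#' clinical minutes in which window labels are expressed.
#'
#' @slot durations named numeric vector of segment durations (seconds) with
#'   names baseline, emergence, stabilization, transition, ictal, postictal.
#' @slot timeCompression factor mapping clinical minutes to simulated time.
#' @slot samplingRate sampling rate in Hz.
#' @slot noiseSd observation noise standard deviation (signal units).
#' @slot amplitude oscillation amplitude (signal units).
#' @slot seed integer random seed.
#' @slot baselineK weak baseline coupling.
#' @slot ictalK coupling reached during the ictal segment.
#' @slot wanderSd sd (rad/s) of the slow baseline frequency wander.
#' @slot wanderPeriod refresh period (s) of the frequency wander.
#' @exportClass EpisodeSpec
setClass("EpisodeSpec",
  representation(durations = "numeric", timeCompression = "numeric",
                 samplingRate = "numeric", noiseSd = "numeric",
                 amplitude = "numeric", seed = "integer",
                 baselineK = "numeric", ictalK = "numeric",
                 wanderSd = "numeric", wanderPeriod = "numeric"))

.SEGMENTS <- c("baseline", "emergence", "stabilization", "transition",
               "ictal", "postictal")

setValidity("EpisodeSpec", function(object) {
  msg <- character()
  if (!identical(names(object@durations), .SEGMENTS))
    msg <- c(msg, "durations must be named baseline, emergence, stabilization, transition, ictal, postictal")
  if (any(object@durations < 0)) msg <- c(msg, "durations must be >= 0")
  if (object@timeCompression <= 0) msg <- c(msg, "timeCompression must be > 0")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@durations["ictal"] == 0 && object@durations["postictal"] > 0)
    msg <- c(msg, "zero-length ictal segment with nonzero postictal is invalid")
  if (length(msg)) msg else TRUE
})

#' Labelled synthetic episode
#'
#' @slot signal the synthesized \linkS4class{MultiChannelSignal}.
#' @slot windowLabels data.frame with one row per analysis window: start, end
#'   (seconds), clusterR0, clusterR1 (ground-truth community order
#'   parameters), contrast, ychimera (0/1), ystate (0..3), ytime (minutes,
#'   [0, 90]).
#' @slot onsetTime seizure (ictal) onset in simulated seconds.
#' @slot segmentBoundaries named numeric vector of segment start times.
#' @slot params the \linkS4class{KuramotoParams} used.
#' @slot spec the \linkS4class{EpisodeSpec} used.
#' @slot phases ground-truth \linkS4class{PhaseTrajectory} or NULL when
#'   dropped to save memory.
#' @exportClass LabeledEpisode
setClass("LabeledEpisode",
  representation(signal = "MultiChannelSignal", windowLabels = "data.frame",
                 onsetTime = "numeric", segmentBoundaries = "numeric",
                 params = "KuramotoParams", spec = "EpisodeSpec",
                 phases = "ANY"))

setValidity("LabeledEpisode", function(object) {
  msg <- character()
  wl <- object@windowLabels
  need <- c("start", "end", "contrast", "ychimera", "ystate", "ytime")
  if (!all(need %in% names(wl)))
    msg <- c(msg, "windowLabels must contain start, end, contrast, ychimera, ystate, ytime")
  else {
    dur <- ncol(object@signal@data) / object@signal@samplingRate
    if (nrow(wl) && (min(wl$start) < -1e-9 || max(wl$end) > dur + 1e-6))
      msg <- c(msg, "window label times must lie inside the recording")
    if (nrow(wl) && !all(wl$ystate %in% 0:3))
      msg <- c(msg, "state labels must be in {0,1,2,3}")
    if (nrow(wl) && (any(wl$ytime < 0) || any(wl$ytime > 90)))
      msg <- c(msg, "ytime must lie in [0, 90] minutes")
  }
  if (length(msg)) msg else TRUE
})

#' Hypergraph of 3-clique hyperedges over channels
#'
#' @slot nodes channel names.
#' @slot hyperedges integer matrix, one row per hyperedge, three distinct
#'   node indices per row (stored sorted increasing).
#' @slot weights optional per-hyperedge attention weight in [0, 1] (length 0
#'   when absent).
#' @slot sourceAdjacency the symmetric adjacency the hyperedges were
#'   detected on.
#' @slot tau detection threshold used.
#' @exportClass Hypergraph
setClass("Hypergraph",
  representation(nodes = "character", hyperedges = "matrix",
                 weights = "numeric", sourceAdjacency = "matrix",
                 tau = "numeric"))

setValidity("Hypergraph", function(object) {
  msg <- character()
  he <- object@hyperedges
  if (nrow(he)) {
    if (ncol(he) != 3L) msg <- c(msg, "hyperedges must have 3 columns")
    else {
      if (any(he[, 1] >= he[, 2]) || any(he[, 2] >= he[, 3]))
        msg <- c(msg, "hyperedge rows must hold 3 distinct sorted node indices")
      if (anyDuplicated(he)) msg <- c(msg, "duplicate hyperedges")
      if (max(he) > length(object@nodes)) msg <- c(msg, "node index out of range")
    }
  }
  if (length(object@weights) &&
      (length(object@weights) != nrow(he) ||
       any(object@weights < 0) || any(object@weights > 1)))
    msg <- c(msg, "weights must be per-hyperedge values in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Spectral community assignment of channels
#'
#' @slot labels integer community id per channel, in 0..(k-1).
#' @slot k number of communities.
#' @slot eigengap successive eigenvalue gaps of the normalized Laplacian,
#'   kept for diagnostics.
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(labels = "integer", k = "integer", eigengap = "numeric"))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (!all(object@labels %in% (seq_len(object@k) - 1L)))
    msg <- c(msg, "labels must lie in 0..k-1")
  if (length(unique(object@labels)) != object@k)
    msg <- c(msg, "every cluster must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Analysis window plan
#'
#' Half-open windows [start, start + length) of equal length; with the
#' default 5-second windows and 50\% overlap the hop is 2.5 s. A sample
#' falling exactly on a boundary belongs to the later window.
#'
#' @slot windowLength window length in seconds.
#' @slot overlap overlap fraction in [0, 1).
#' @slot boundaries two-column matrix of [start, end) times in seconds.
#' @exportClass WindowPlan
setClass("WindowPlan",
  representation(windowLength = "numeric", overlap = "numeric",
                 boundaries = "matrix"))

setValidity("WindowPlan", function(object) {
  msg <- character()
  if (object@overlap < 0 || object@overlap >= 1)
    msg <- c(msg, "overlap must lie in [0, 1)")
  b <- object@boundaries
  if (ncol(b) != 2L) msg <- c(msg, "boundaries must have two columns")
  else if (nrow(b)) {
    if (any(abs((b[, 2] - b[, 1]) - object@windowLength) > 1e-9))
      msg <- c(msg, "all windows must have length windowLength")
    if (is.unsorted(b[, 1], strictly = TRUE) && nrow(b) > 1L)
      msg <- c(msg, "windows must be ordered")
  }
  if (length(msg)) msg else TRUE
})
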