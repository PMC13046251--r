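#' Default synthetic episode specification
#'
#' Segment durations mirror the characteristic pre-seizure chimera
#' progression: a 20-minute interictal baseline, 20 minutes of chimera
#' emergence, 45 minutes of stable chimera, a 7.5-minute rapid transition to
#' global synchronization, a 1.5-minute seizure and a 10-minute post-ictal
#' recovery — all expressed here in simulated seconds after the default
#' 10-fold time compression (e.g. 45 clinical minutes = 270 s simulated).
#' Labels are always reported in uncompressed clinical minutes.
#'
#' @param timeCompression clinical-minutes-to-simulated-time factor.
#' @param samplingRate sampling rate in Hz.
#' @param noiseSd observation noise sd.
#' @param amplitude oscillation amplitude.
#' @param seed integer seed.
#' @return an \linkS4class{EpisodeSpec}.
#' @examples defaultEpisodeSpec(seed = 7)
#' @export
defaultEpisodeSpec <- function(timeCompression = 10, samplingRate = 256,
                               noiseSd = 0.1, amplitude = 1, seed = 42L) {
  minutes <- c(baseline = 20, emergence = 20, stabilization = 45,
               transition = 7.5, ictal = 1.5, postictal = 10)
  new("EpisodeSpec", durations = minutes * 60 / timeCompression,
      timeCompression = timeCompression, samplingRate = samplingRate,
      noiseSd = noiseSd, amplitude = amplitude, seed = as.integer(seed),
      baselineK = 0.1, ictalK = 1.2, wanderSd = 0.8, wanderPeriod = 0.5)
}

#' Short episode specification for the training benchmark
#'
#' A compressed variant of \code{\link{defaultEpisodeSpec}} (about 100 s of
#' simulated signal per episode) used for the desk-scale learning benchmark,
#' where tens of episodes must be generated and a model trained on them in
#' minutes. Dynamics, noise and labelling rules are identical; only segment
#' durations shrink.
#'
#' @inheritParams defaultEpisodeSpec
#' @return an \linkS4class{EpisodeSpec}.
#' @export
benchmarkEpisodeSpec <- function(timeCompression = 10, samplingRate = 256,
                                 noiseSd = 0.1, amplitude = 1, seed = 42L) {
  minutes <- c(baseline = 4.5, emergence = 3, stabilization = 5,
               transition = 1.5, ictal = 0.5, postictal = 2.5)
  new("EpisodeSpec", durations = minutes * 60 / timeCompression,
      timeCompression = timeCompression, samplingRate = samplingRate,
      noiseSd = noiseSd, amplitude = amplitude, seed = as.integer(seed),
      baselineK = 0.1, ictalK = 1.2, wanderSd = 0.8, wanderPeriod = 0.5)
}

# Per-step schedules implementing the piecewise episode dynamics.
# Returns list(K, r, m, amp) each of length nsteps, plus segment boundaries.
.episodeSchedules <- function(spec, params, dt) {
  dur <- spec@durations
  nsteps <- as.integer(round(sum(dur) / dt))
  segSteps <- round(cumsum(dur) / dt)
  segStart <- c(0, head(segSteps, -1)) + 1L
  segEnd <- segSteps
  K <- numeric(nsteps); r <- numeric(nsteps)
  m <- numeric(nsteps); amp <- numeric(nsteps)
  ramp <- function(n, from, to) if (n <= 0) numeric(0) else
    seq(from, to, length.out = n)
  fill <- function(seg) {
    n <- segEnd[seg] - segStart[seg] + 1L
    if (segEnd[seg] < segStart[seg]) n <- 0L
    n
  }
  idx <- function(seg) if (fill(seg) > 0) segStart[seg]:segEnd[seg] else integer(0)
  K0 <- spec@baselineK; Ks <- params@couplingK; Ki <- spec@ictalK
  r0 <- params@interCouplingRatio
  # baseline: weak coupling, full frequency wander
  K[idx(1)] <- K0; r[idx(1)] <- r0; m[idx(1)] <- 0; amp[idx(1)] <- 1
  # emergence: coupling ramps up, wander ramps out
  K[idx(2)] <- ramp(fill(2), K0, Ks); r[idx(2)] <- r0
  amp[idx(2)] <- ramp(fill(2), 1, 0)
  # stabilization: stable chimera
  K[idx(3)] <- Ks; r[idx(3)] <- r0
  # transition: coupling and cross-coupling ramp, frequencies entrain
  K[idx(4)] <- ramp(fill(4), Ks, Ki); r[idx(4)] <- ramp(fill(4), r0, 1)
  m[idx(4)] <- ramp(fill(4), 0, 1)
  # ictal: near-global synchrony
  K[idx(5)] <- Ki; r[idx(5)] <- 1; m[idx(5)] <- 1
  # postictal: decay back to baseline
  K[idx(6)] <- ramp(fill(6), Ki, K0); r[idx(6)] <- r0
  m[idx(6)] <- ramp(fill(6), 1, 0); amp[idx(6)] <- ramp(fill(6), 0, 1)
  boundaries <- c(start = 0, cumsum(dur) * 1)
  names(boundaries) <- c("baseline", .SEGMENTS[-1], "end")
  list(K = K, r = r, m = m, amp = amp, nsteps = nsteps,
       boundaries = boundaries)
}

#' Generate a labelled synthetic chimera episode
#'
#' Concatenates the six-segment piecewise dynamics (baseline, emergence,
#' stabilization, transition, ictal, postictal) in a single continuous
#' integration: coupling ramps from the weak baseline value to the chimera
#' operating point, holds, then ramps toward global synchronization while
#' natural frequencies entrain to the delta rhythm, and finally relaxes.
#' During baseline and post-ictal recovery a slow per-oscillator frequency
#' wander decoheres the synchronization-prone community, so interictal
#' windows genuinely lack phase alignment.
#'
#' Window labels are computed from the ground-truth phases on the true
#' communities: \code{ychimera} applies the contrast rule
#' \eqn{\max(R_{cluster}) - \min(R_{cluster}) > 0.3}; \code{ystate} is 0
#' baseline, 1 pre-ictal (emergence + stabilization + transition), 2 ictal,
#' 3 post-ictal, assigned by window midpoint; \code{ytime} is the
#' uncompressed minutes to seizure onset measured from the window end,
#' capped at 90, with 0 during the seizure and 90 afterwards.
#'
#' @param spec an \linkS4class{EpisodeSpec}.
#' @param params a \linkS4class{KuramotoParams}; defaults to
#'   \code{defaultKuramotoParams(seed = spec@seed)}.
#' @param windowLength,overlap analysis window geometry for the labels.
#' @param storePhases keep the ground-truth phase trajectory in the result
#'   (memory-heavy; default FALSE).
#' @return a \linkS4class{LabeledEpisode}.
#' @examples
#' ep <- generateEpisode(benchmarkEpisodeSpec(seed = 1))
#' head(windowLabels(ep))
#' @export
generateEpisode <- function(spec, params = NULL, windowLength = 5,
                            overlap = 0.5, storePhases = FALSE) {
  stopifnot(is(spec, "EpisodeSpec"))
  validObject(spec)
  if (is.null(params)) params <- defaultKuramotoParams(seed = spec@seed)
  dt <- 1 / spec@samplingRate
  sch <- .episodeSchedules(spec, params, dt)
  C <- params@nOscillators
  set.seed(.deriveSeed(spec@seed, 4L))
  init <- runif(C, -pi, pi)
  nblocks <- max(1L, as.integer(ceiling(sch$nsteps * dt / spec@wanderPeriod)))
  detune <- matrix(rnorm(nblocks * C, sd = spec@wanderSd), nblocks, C)
  omegaTarget <- mean(params@omega[params@community == 0L])
  traj <- simulateKuramoto(params, duration = sch$nsteps * dt, dt = dt,
                           initialPhases = init,
                           schedules = list(K = sch$K, r = sch$r, m = sch$m,
                                            amp = sch$amp, detune = detune,
                                            detuneEvery =
                                              as.integer(round(spec@wanderPeriod / dt)),
                                            omegaTarget = omegaTarget))
  signal <- phasesToSignal(traj, amplitude = spec@amplitude,
                           noiseSd = spec@noiseSd, seed = spec@seed)
  onset <- unname(sch$boundaries["ictal"])
  wl <- .episodeLabels(traj, params, spec, sch$boundaries, onset,
                       windowLength, overlap)
  new("LabeledEpisode", signal = signal, windowLabels = wl,
      onsetTime = onset, segmentBoundaries = sch$boundaries, params = params,
      spec = spec, phases = if (storePhases) traj else NULL)
}

# ground-truth per-window labels from the simulated phases
.episodeLabels <- function(traj, params, spec, boundaries, onset,
                           windowLength, overlap) {
  fs <- 1 / traj@dt
  total <- nrow(traj@phases) / fs
  plan <- windowPlan(total, windowLength = windowLength, overlap = overlap)
  b <- plan@boundaries
  comm <- params@community
  Z0 <- Mod(rowMeans(exp(1i * traj@phases[, comm == 0L, drop = FALSE])))
  Z1 <- Mod(rowMeans(exp(1i * traj@phases[, comm == 1L, drop = FALSE])))
  n <- nrow(b)
  R0 <- numeric(n); R1 <- numeric(n)
  for (w in seq_len(n)) {
    i0 <- floor(b[w, 1] * fs) + 1L
    i1 <- min(ceiling(b[w, 2] * fs), length(Z0))
    R0[w] <- mean(Z0[i0:i1]); R1[w] <- mean(Z1[i0:i1])
  }
  contrast <- pmax(R0, R1) - pmin(R0, R1)
  mid <- (b[, 1] + b[, 2]) / 2
  seg <- findInterval(mid, boundaries[.SEGMENTS], rightmost.closed = FALSE)
  seg <- pmin(pmax(seg, 1L), 6L)
  ystate <- c(0L, 1L, 1L, 1L, 2L, 3L)[seg]
  toOnsetMin <- (onset - b[, 2]) * spec@timeCompression / 60
  ytime <- ifelse(ystate == 2L, 0,
                  ifelse(mid >= boundaries["postictal"], 90,
                         pmin(90, pmax(0, toOnsetMin))))
  data.frame(start = b[, 1], end = b[, 2], clusterR0 = R0, clusterR1 = R1,
             contrast = contrast,
             ychimera = as.integer(contrast - 0.3 > 1e-12),
             ystate = ystate, ytime = ytime)
}

#' Write / read an episode as plain-text files
#'
#' \code{writeEpisode} serializes a labelled episode as three files under
#' \code{prefix}: \code{<prefix>_signal.tsv} (channels x samples, one channel
#' per row), \code{<prefix>_labels.tsv} (the window label table) and
#' \code{<prefix>_meta.json} (sampling rate, channel names, segment
#' boundaries, onset, seed). \code{readEpisodeSignal} reads the signal +
#' metadata pair back into a \linkS4class{MultiChannelSignal}.
#'
#' @param episode a \linkS4class{LabeledEpisode}.
#' @param prefix path prefix for the output files.
#' @return \code{writeEpisode} returns the three paths invisibly;
#'   \code{readEpisodeSignal} returns a \linkS4class{MultiChannelSignal}.
#' @export
writeEpisode <- function(episode, prefix) {
  stopifnot(is(episode, "LabeledEpisode"))
  paths <- paste0(prefix, c("_signal.tsv", "_labels.tsv", "_meta.json"))
  utils::write.table(signif(episode@signal@data, 8), paths[1], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(episode@windowLabels, paths[2], sep = "\t",
                     row.names = FALSE)
  meta <- list(samplingRate = episode@signal@samplingRate,
               channelNames = episode@signal@channelNames,
               startTime = episode@signal@startTime,
               segmentBoundaries = as.list(episode@segmentBoundaries),
               onsetTime = episode@onsetTime,
               timeCompression = episode@spec@timeCompression,
               seed = episode@spec@seed,
               community = episode@params@community)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), paths[3])
  invisible(paths)
}

#' @rdname writeEpisode
#' @export
readEpisodeSignal <- function(prefix) {
  x <- as.matrix(utils::read.table(paste0(prefix, "_signal.tsv"), sep = "\t"))
  meta <- jsonlite::fromJSON(paste0(prefix, "_meta.json"))
  MultiChannelSignal(unname(x), samplingRate = meta$samplingRate,
                     channelNames = meta$channelNames,
                     startTime = meta$startTime)
}
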