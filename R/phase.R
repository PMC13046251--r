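#' Build an analysis window plan
#'
#' Half-open windows [start, start + windowLength) advancing by
#' \code{windowLength * (1 - overlap)} seconds; with the defaults, 5-second
#' windows with 50\% overlap advance by exactly 2.5 s. Sample indexing is
#' 0-based in time: a sample at an exact boundary belongs to the later
#' window.
#'
#' @param totalDuration recording duration in seconds.
#' @param windowLength window length in seconds (default 5).
#' @param overlap overlap fraction in [0, 1) (default 0.5).
#' @return a \linkS4class{WindowPlan}.
#' @examples windowPlan(20)
#' @export
windowPlan <- function(totalDuration, windowLength = 5, overlap = 0.5) {
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  if (windowLength <= 0 || totalDuration < windowLength)
    stop("need totalDuration >= windowLength > 0")
  hop <- windowLength * (1 - overlap)
  starts <- seq(0, totalDuration - windowLength + 1e-9, by = hop)
  new("WindowPlan", windowLength = windowLength, overlap = overlap,
      boundaries = cbind(start = starts, end = starts + windowLength))
}

#' Instantaneous phase via the analytic signal
#'
#' Computes, per channel, the analytic signal \eqn{\tilde x = x + i H[x]}
#' (Hilbert transform implemented in the frequency domain) and returns the
#' instantaneous phase \eqn{\phi = \arg \tilde x} in [-pi, pi]. Signals are
#' assumed mean-free (bandpass them first). The first and last 0.5 s are
#' flagged as an edge guard: the circular convolution underlying the
#' frequency-domain Hilbert transform distorts phases near the boundaries,
#' and downstream windowing excludes the flagged samples.
#'
#' @param signal a \linkS4class{MultiChannelSignal} with >= 2 samples.
#' @param guard guard duration in seconds (default 0.5).
#' @return a \linkS4class{PhaseTrajectory} (time x channel).
#' @examples
#' t <- seq(0, 4, by = 1 / 256)[-1]
#' s <- MultiChannelSignal(rbind(cos(2 * pi * 10 * t)), samplingRate = 256)
#' ph <- analyticPhase(s)
#' @export
analyticPhase <- function(signal, guard = 0.5) {
  stopifnot(is(signal, "MultiChannelSignal"))
  x <- t(signal@data)                    # samples x channels
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples per channel")
  zero <- which(apply(x, 2, function(col) all(col == 0)))
  if (length(zero))
    stop("undefined phase: all-zero channel(s) ",
         paste(signal@channelNames[zero], collapse = ", "))
  # zero-pad to a highly composite length: R's FFT is O(n^2) for prime n.
  # The padding distortion is confined to the edges, inside the guard.
  m <- stats::nextn(n, c(2, 3, 5))
  xp <- if (m > n) rbind(x, matrix(0, m - n, ncol(x))) else x
  X <- stats::mvfft(xp)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[c(1, m / 2 + 1)] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((m + 1) / 2)] <- 2
  }
  analytic <- stats::mvfft(X * h, inverse = TRUE)[seq_len(n), , drop = FALSE] / m
  PhaseTrajectory(Arg(analytic), dt = 1 / signal@samplingRate,
                  t0 = signal@startTime, guard = guard)
}

#' Windowed phase-locking-value matrices
#'
#' For every window of the plan, computes
#' \eqn{PLV_{ij} = |\langle e^{i(\phi_i - \phi_j)} \rangle_t|} over the
#' in-window samples (raw samples, not decimated), after excluding the
#' trajectory's edge-guard samples. The result for each window is a
#' symmetric C x C matrix with unit diagonal and entries in [0, 1].
#'
#' @param phases a \linkS4class{PhaseTrajectory}.
#' @param plan a \linkS4class{WindowPlan}; defaults to 5-s windows with 50\%
#'   overlap spanning the trajectory.
#' @return list of PLV matrices, one per window, each carrying its window
#'   interval as \code{attr(, "window")}.
#' @export
plvMatrices <- function(phases, plan = NULL) {
  stopifnot(is(phases, "PhaseTrajectory"))
  ph <- phases@phases
  n <- nrow(ph)
  fs <- 1 / phases@dt
  if (is.null(plan)) plan <- windowPlan(n / fs)
  b <- plan@boundaries
  gl <- ceiling(phases@guard * fs)             # guard samples per edge
  lo <- gl + 1L
  hi <- n - gl
  E <- exp(1i * ph)
  out <- vector("list", nrow(b))
  for (w in seq_len(nrow(b))) {
    i0 <- max(floor(b[w, 1] * fs) + 1L, lo)    # half-open [start, end)
    i1 <- min(ceiling(b[w, 2] * fs), hi)
    if (i1 < i0)
      stop(sprintf("window [%g, %g) is empty after guard exclusion",
                   b[w, 1], b[w, 2]))
    Ew <- E[i0:i1, , drop = FALSE]
    M <- Mod(crossprod(Conj(Ew), Ew)) / nrow(Ew)
    M[M > 1] <- 1
    diag(M) <- 1
    attr(M, "window") <- b[w, ]
    out[[w]] <- M
  }
  attr(out, "plan") <- plan
  out
}
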