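#' Default two-community Kuramoto-Sakaguchi parameters
#'
#' Builds the default 23-oscillator network used throughout the package: a
#' 12-oscillator synchronization-prone community centred in the delta band
#' (2.3 Hz) and an 11-oscillator desynchronized community in the alpha band
#' (9.1 Hz), coupled at K = 0.71 with Sakaguchi phase lag 0.28 rad and
#' cross-community ratio r = 0.7 — the chimera operating point.
#'
#' The synchronized-target community is drawn with a small within-network
#' frequency spread (sd 0.01 Hz): its members are near-identical oscillators,
#' which is what allows them to lock at couplings of order 1 rad/s. The
#' desynchronized community keeps the full 1.3 Hz alpha-band spread, so it
#' stays incoherent at any admissible coupling; the synchronization contrast
#' between the two is the chimera. Draws are truncated at 3 sd and at zero to
#' keep all frequencies positive.
#'
#' @param nOscillators total oscillator count (default 23, split
#'   ceiling/floor between the two communities).
#' @param couplingK global coupling, in [0, 1.5].
#' @param phaseLagAlpha phase lag in radians, in [0, pi/2].
#' @param interCouplingRatio cross-community coupling factor r.
#' @param freqSync,freqDesync community centre frequencies in Hz.
#' @param sdSync,sdDesync within-network frequency sd in Hz.
#' @param seed integer seed for the frequency draws.
#' @return a \linkS4class{KuramotoParams}.
#' @examples
#' defaultKuramotoParams(seed = 1)
#' @export
defaultKuramotoParams <- function(nOscillators = 23L, couplingK = 0.71,
                                  phaseLagAlpha = 0.28,
                                  interCouplingRatio = 0.7,
                                  freqSync = 2.3, sdSync = 0.01,
                                  freqDesync = 9.1, sdDesync = 1.3,
                                  seed = 42L) {
  nOscillators <- as.integer(nOscillators)
  n0 <- as.integer(ceiling(nOscillators / 2))
  n1 <- nOscillators - n0
  set.seed(.deriveSeed(seed, 1L))
  draw <- function(n, mu, sdev) {
    z <- pmin(3, pmax(-3, rnorm(n)))
    pmax(mu + sdev * z, mu * 1e-3 + 1e-6)
  }
  omega <- 2 * pi * c(draw(n0, freqSync, sdSync), draw(n1, freqDesync, sdDesync))
  new("KuramotoParams", nOscillators = nOscillators, omega = omega,
      couplingK = couplingK, phaseLagAlpha = phaseLagAlpha,
      community = c(rep(0L, n0), rep(1L, n1)),
      interCouplingRatio = interCouplingRatio)
}

#' Simulate a Kuramoto-Sakaguchi oscillator network
#'
#' Integrates
#' \deqn{d\theta_i/dt = \omega_i + (1/C)\sum_j K_{ij}\sin(\theta_j - \theta_i
#'   - \alpha)}
#' with \eqn{K_{ij} = K} within a community and \eqn{r K} across communities,
#' using a classical fourth-order Runge-Kutta stepper (compiled). The
#' trajectory has \code{ceiling(duration/dt) + 1} rows and phases wrapped to
#' [-pi, pi]. Identical inputs and seed give bit-identical output.
#'
#' @param params a \linkS4class{KuramotoParams}.
#' @param duration integration time in seconds (>= dt).
#' @param dt step in seconds (default 1/256, matching the default sampling
#'   rate).
#' @param initialPhases optional vector of initial phases; when absent they
#'   are drawn uniformly on [-pi, pi) using \code{seed}.
#' @param seed integer seed, required when \code{initialPhases} is absent.
#' @param schedules optional list of per-step schedules overriding the
#'   constant parameters: numeric vectors \code{K}, \code{r}, \code{m}
#'   (entrainment weight toward \code{omegaTarget}), \code{amp} (frequency
#'   wander amplitude), scalar \code{omegaTarget} and matrix \code{detune}
#'   (blocks x C) refreshed every \code{detuneEvery} steps. Used by the
#'   episode generator; ordinary simulations leave it NULL.
#' @return a \linkS4class{PhaseTrajectory} with \code{guard = 0}.
#' @examples
#' p <- defaultKuramotoParams(seed = 1)
#' traj <- simulateKuramoto(p, duration = 2, seed = 1)
#' traj
#' @export
simulateKuramoto <- function(params, duration, dt = 1 / 256,
                             initialPhases = NULL, seed = NULL,
                             schedules = NULL) {
  stopifnot(is(params, "KuramotoParams"))
  validObject(params)
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(dt) || dt <= 0)
    stop("duration and dt must be positive")
  if (duration < dt) stop("duration must be >= dt")
  C <- params@nOscillators
  if (is.null(initialPhases)) {
    if (is.null(seed)) stop("seed must be supplied when initialPhases is absent")
    set.seed(.deriveSeed(seed, 2L))
    initialPhases <- runif(C, -pi, pi)
  }
  if (length(initialPhases) != C)
    stop("initialPhases length must equal the oscillator count")
  nsteps <- as.integer(ceiling(duration / dt - 1e-9))
  const <- function(v) rep(v, nsteps)
  if (is.null(schedules)) schedules <- list()
  K_t <- if (is.null(schedules$K)) const(params@couplingK) else schedules$K
  r_t <- if (is.null(schedules$r)) const(params@interCouplingRatio) else schedules$r
  m_t <- if (is.null(schedules$m)) const(0) else schedules$m
  amp <- if (is.null(schedules$amp)) const(0) else schedules$amp
  detune <- if (is.null(schedules$detune)) matrix(0, 1, C) else schedules$detune
  detuneEvery <- if (is.null(schedules$detuneEvery)) 0L else
    as.integer(schedules$detuneEvery)
  omegaTarget <- if (is.null(schedules$omegaTarget)) 0 else schedules$omegaTarget
  ph <- .rk4_kuramoto(as.numeric(initialPhases), params@omega,
                      params@community, params@phaseLagAlpha, dt, nsteps,
                      K_t, r_t, m_t, omegaTarget, amp, detune, detuneEvery)
  PhaseTrajectory(ph, dt = dt)
}

#' Synthesize observed signals from a phase trajectory
#'
#' Observation model \eqn{x_c(t) = A \sin\theta_c(t) + \epsilon} with
#' independent Gaussian noise per sample and channel. Deterministic given the
#' seed.
#'
#' @param traj a \linkS4class{PhaseTrajectory}.
#' @param amplitude oscillation amplitude (>= 0).
#' @param noiseSd noise standard deviation (>= 0).
#' @param seed integer seed for the noise draws.
#' @return a \linkS4class{MultiChannelSignal} (channels x samples) at
#'   sampling rate 1/dt.
#' @export
phasesToSignal <- function(traj, amplitude = 1, noiseSd = 0.1, seed = 42L) {
  stopifnot(is(traj, "PhaseTrajectory"))
  if (amplitude < 0 || noiseSd < 0) stop("amplitude and noiseSd must be >= 0")
  x <- t(amplitude * sin(traj@phases))
  if (noiseSd > 0) {
    set.seed(.deriveSeed(seed, 3L))
    x <- x + matrix(rnorm(length(x), sd = noiseSd), nrow(x), ncol(x))
  }
  MultiChannelSignal(x, samplingRate = 1 / traj@dt, startTime = traj@t0)
}

#' Recover Kuramoto parameters from a phase trajectory by regression
#'
#' Uses the identity \eqn{\sin(\Delta - \alpha) = \sin\Delta\cos\alpha -
#' \cos\Delta\sin\alpha} to make the mean-field Kuramoto-Sakaguchi model
#' linear in \eqn{(\omega_i, K\cos\alpha, K\sin\alpha)}: central-difference
#' phase derivatives are regressed on a per-oscillator intercept,
#' \eqn{(1/C)\sum_j\sin(\theta_j-\theta_i)} and
#' \eqn{(1/C)\sum_j\cos(\theta_j-\theta_i)}, pooled over all oscillators and
#' interior time steps. Returns \eqn{\hat K = \sqrt{a^2+b^2}} and
#' \eqn{\hat\alpha = \mathrm{atan2}(b, a)} mapped into [0, pi/2].
#'
#' @param traj a \linkS4class{PhaseTrajectory} with at least 3 time steps.
#' @return list with \code{omega} (rad/s per oscillator), \code{couplingK},
#'   \code{phaseLagAlpha}, and logical \code{alphaUnidentifiable}, set when
#'   the coupling signal is too weak (\eqn{\hat K < 0.02}) for the phase lag
#'   to mean anything.
#' @examples
#' p <- defaultKuramotoParams(interCouplingRatio = 1, seed = 3)
#' est <- estimateKuramotoParams(simulateKuramoto(p, duration = 20, seed = 3))
#' est$couplingK
#' @export
estimateKuramotoParams <- function(traj) {
  stopifnot(is(traj, "PhaseTrajectory"))
  ph <- traj@phases
  if (nrow(ph) < 3L) stop("need at least 3 time steps")
  un <- .unwrapPhases(ph)
  Tn <- nrow(un); C <- ncol(un)
  dth <- (un[3:Tn, , drop = FALSE] - un[1:(Tn - 2), , drop = FALSE]) /
    (2 * traj@dt)
  mid <- ph[2:(Tn - 1), , drop = FALSE]
  # mean-field sums via the network phasor: (1/C) sum_j sin(theta_j - theta_i)
  Z <- rowMeans(exp(1i * mid))           # per-time mean phasor
  Ei <- exp(1i * mid)
  S <- Im(Z * Conj(Ei))                  # (1/C) sum_j sin(theta_j - theta_i)
  Cc <- Re(Z * Conj(Ei))                 # (1/C) sum_j cos(theta_j - theta_i)
  nT <- Tn - 2
  # per-oscillator intercepts: demean response and regressors within channel
  y <- as.numeric(sweep(dth, 2, colMeans(dth)))
  x1 <- as.numeric(sweep(S, 2, colMeans(S)))
  x2 <- as.numeric(sweep(Cc, 2, colMeans(Cc)))
  X <- cbind(x1, x2)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    stop("unidentifiable: rank-deficient design (phases fully locked?)")
  ab <- solve(XtX, crossprod(X, y))
  # field = omega + (K cos a) S - (K sin a) C, so the coefficient on C is
  # -K sin(alpha)
  a <- ab[1]; b <- -ab[2]
  K <- sqrt(a^2 + b^2)
  alpha <- atan2(b, a)
  alpha <- min(max(alpha, 0), pi / 2)
  omega <- colMeans(dth) - ab[1] * colMeans(S) - ab[2] * colMeans(Cc)
  list(omega = omega, couplingK = K, phaseLagAlpha = alpha,
       alphaUnidentifiable = K < 0.02)
}
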