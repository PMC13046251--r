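test_that("uncoupled oscillators advance linearly at their natural frequency", {
  p <- new("KuramotoParams", nOscillators = 2L, omega = c(1, 2),
           couplingK = 0, phaseLagAlpha = 0, community = c(0L, 1L),
           interCouplingRatio = 1)
  traj <- simulateKuramoto(p, duration = 1, dt = 1 / 256,
                           initialPhases = c(0, 0))
  un <- apply(phaseMatrix(traj), 2, function(col)
    col[1] + c(0, cumsum(wrapPhase(diff(col)))))
  expect_equal(un[nrow(un), ], c(1, 2), tolerance = 1e-6)
})

test_that("identical oscillators started together stay identical", {
  p <- new("KuramotoParams", nOscillators = 4L, omega = rep(3, 4),
           couplingK = 0.9, phaseLagAlpha = 0, community = rep(0L, 4),
           interCouplingRatio = 1)
  traj <- simulateKuramoto(p, duration = 5, initialPhases = rep(0.3, 4))
  spread <- apply(phaseMatrix(traj), 1, function(r) diff(range(r)))
  expect_lt(max(spread), 1e-9)
})

test_that("default two-community network forms a chimera, against a fine-step oracle", {
  skip_if_not_installed("deSolve")
  p <- defaultKuramotoParams(seed = 5)
  comm <- communityLabels(p)
  set.seed(99)
  init <- runif(23, -pi, pi)
  dur <- 20
  traj <- simulateKuramoto(p, duration = dur, initialPhases = init)
  ph <- phaseMatrix(traj)
  late <- ph[nrow(ph) - (0:(5 * 256)), ]
  R0 <- mean(Mod(rowMeans(exp(1i * late[, comm == 0]))))
  R1 <- mean(Mod(rowMeans(exp(1i * late[, comm == 1]))))
  expect_gt(R0, 0.9)
  expect_lt(R1, 0.6)
  # independent oracle: naive pairwise field integrated by deSolve's rk4 at
  # a 10x finer step
  Kmat <- matrix(p@couplingK * p@interCouplingRatio, 23, 23)
  same <- outer(comm, comm, "==")
  Kmat[same] <- p@couplingK
  field <- function(t, th, parms) {
    dth <- vapply(seq_len(23), function(i)
      p@omega[i] + sum(Kmat[i, ] * sin(th - th[i] - p@phaseLagAlpha)) / 23,
      numeric(1))
    list(dth)
  }
  sol <- deSolve::ode(y = init, times = seq(0, dur, by = 1 / 2560),
                      func = field, parms = NULL, method = "rk4")
  phO <- sol[, -1]
  lateO <- phO[seq(nrow(phO) - 5 * 2560, nrow(phO), by = 10), ]
  R0o <- mean(Mod(rowMeans(exp(1i * lateO[, comm == 0]))))
  R1o <- mean(Mod(rowMeans(exp(1i * lateO[, comm == 1]))))
  expect_lt(abs(R0 - R0o), 0.02)
  expect_lt(abs(R1 - R1o), 0.02)
})

test_that("halving the integration step leaves final phases unchanged to 1e-4", {
  p <- defaultKuramotoParams(seed = 2)
  set.seed(7)
  init <- runif(23, -pi, pi)
  t1 <- simulateKuramoto(p, duration = 10, dt = 1 / 256, initialPhases = init)
  t2 <- simulateKuramoto(p, duration = 10, dt = 1 / 512, initialPhases = init)
  f1 <- phaseMatrix(t1)[nrow(phaseMatrix(t1)), ]
  f2 <- phaseMatrix(t2)[nrow(phaseMatrix(t2)), ]
  expect_lt(max(abs(wrapPhase(f1 - f2))), 1e-4)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- defaultKuramotoParams(seed = 3)
  t1 <- simulateKuramoto(p, duration = 2, seed = 11)
  t2 <- simulateKuramoto(p, duration = 2, seed = 11)
  t3 <- simulateKuramoto(p, duration = 2, seed = 12)
  expect_identical(phaseMatrix(t1), phaseMatrix(t2))
  expect_false(identical(phaseMatrix(t1), phaseMatrix(t3)))
})

test_that("network synchrony is monotone in coupling strength", {
  Kgrid <- seq(0.1, 1.2, by = 0.1)
  meanR <- vapply(Kgrid, function(K) {
    mean(vapply(1:10, function(s) {
      set.seed(s)
      om <- 2 * pi * 1 + rnorm(12, sd = 0.3)
      p <- new("KuramotoParams", nOscillators = 12L, omega = abs(om),
               couplingK = K, phaseLagAlpha = 0, community = rep(0L, 12),
               interCouplingRatio = 1)
      traj <- simulateKuramoto(p, duration = 20, seed = s)
      ph <- phaseMatrix(traj)
      mean(Mod(rowMeans(exp(1i * ph[(nrow(ph) / 2):nrow(ph), ]))))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(Kgrid, meanR, method = "spearman"), 0.9)
})

test_that("observation model is exact without noise and calibrated with it", {
  tr <- fixtureStabTraj(1, duration = 5)$traj
  s0 <- phasesToSignal(tr, amplitude = 1, noiseSd = 0)
  expect_equal(signalData(s0), t(sin(phaseMatrix(tr))), tolerance = 1e-12)
  ph2 <- PhaseTrajectory(matrix(runif(1e5, -pi, pi), ncol = 1), dt = 1 / 256)
  sn <- phasesToSignal(ph2, amplitude = 0, noiseSd = 1, seed = 8)
  expect_gt(sd(signalData(sn)), 0.98)
  expect_lt(sd(signalData(sn)), 1.02)
})

test_that("noiseless signals round-trip through the phase extractor", {
  tr <- fixtureStabTraj(1, duration = 10)$traj
  sig <- phasesToSignal(tr, amplitude = 1, noiseSd = 0)
  rec <- analyticPhase(sig)
  g <- ceiling(0.5 * 256)
  idx <- (g + 1):(nrow(phaseMatrix(tr)) - g)
  # sin(theta) has phase theta - pi/2
  err <- wrapPhase(phaseMatrix(rec)[idx, ] + pi / 2 - phaseMatrix(tr)[idx, ])
  expect_lt(mean(abs(err)), 0.05)
})

test_that("vector-field regression recovers known coupling and phase lag", {
  # slow oscillators keep finite-difference truncation far below tolerance
  set.seed(21)
  p <- new("KuramotoParams", nOscillators = 10L,
           omega = abs(1 + rnorm(10, sd = 0.3)), couplingK = 0.5,
           phaseLagAlpha = 0.2, community = rep(0L, 10),
           interCouplingRatio = 1)
  traj <- simulateKuramoto(p, duration = 60, dt = 1 / 256, seed = 21)
  est <- estimateKuramotoParams(traj)
  expect_lt(abs(est$couplingK - 0.5), 1e-3)
  expect_lt(abs(est$phaseLagAlpha - 0.2), 1e-3)
  expect_false(est$alphaUnidentifiable)
  # Monte-Carlo with phase observation noise
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    ph <- phaseMatrix(traj) + matrix(rnorm(length(phaseMatrix(traj)),
                                           sd = 0.05),
                                     nrow(phaseMatrix(traj)))
    estimateKuramotoParams(PhaseTrajectory(ph, dt = 1 / 256))$couplingK - 0.5
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.05)
})

test_that("zero coupling is reported as unidentifiable phase lag", {
  set.seed(4)
  p <- new("KuramotoParams", nOscillators = 8L,
           omega = abs(2 + rnorm(8)), couplingK = 0, phaseLagAlpha = 0.3,
           community = rep(0L, 8), interCouplingRatio = 1)
  est <- estimateKuramotoParams(simulateKuramoto(p, duration = 30, seed = 4))
  expect_lt(est$couplingK, 0.02)
  expect_true(est$alphaUnidentifiable)
})

test_that("fully locked identical phases are flagged rank-deficient", {
  ph <- matrix(rep(seq(0, 10, by = 1 / 64), 4), ncol = 4)
  expect_error(estimateKuramotoParams(PhaseTrajectory(ph, dt = 1 / 64)),
               "unidentifiable")
})

test_that("episode labels follow the state and time-to-onset rules", {
  ep <- fixtureEpisode(1)
  wl <- windowLabels(ep)
  b <- ep@segmentBoundaries
  # ictal windows: state 2, time 0
  ict <- wl[(wl$start + wl$end) / 2 >= b["ictal"] &
              (wl$start + wl$end) / 2 < b["postictal"], ]
  expect_true(all(ict$ystate == 2))
  expect_true(all(ict$ytime == 0))
  expect_true(all(wl$ytime[wl$ystate == 2] == 0))
  # chimera flag is exactly the contrast rule on ground-truth communities
  expect_identical(wl$ychimera, as.integer(wl$contrast > 0.3))
  # far-from-onset windows saturate at the 90-minute cap
  far <- generateEpisode(defaultEpisodeSpec(seed = 2))
  wf <- windowLabels(far)
  expect_equal(wf$ytime[1], 90)
  expect_equal(wf$ystate[1], 0)
  expect_true(all(wf$ytime >= 0 & wf$ytime <= 90))
})

test_that("stabilization windows are chimera-labelled in most runs", {
  frac <- vapply(1:5, function(s) {
    ep <- fixtureEpisode(s)
    wl <- windowLabels(ep)
    b <- ep@segmentBoundaries
    stab <- wl$start >= b["stabilization"] & wl$end <= b["transition"]
    mean(wl$ychimera[stab])
  }, numeric(1))
  expect_gt(mean(frac), 0.8)
})

test_that("invalid episode specifications are rejected", {
  sp <- benchmarkEpisodeSpec()
  sp@durations["ictal"] <- 0
  expect_error(validObject(sp), "ictal")
  expect_error(simulateKuramoto(defaultKuramotoParams(), duration = -1),
               "positive")
  expect_error(simulateKuramoto(defaultKuramotoParams(), duration = 1),
               "seed")
})

test_that("episodes round-trip through the plain-text serialization", {
  ep <- fixtureEpisode(1)
  pre <- file.path(tempdir(), "ep1")
  writeEpisode(ep, pre)
  sig <- readEpisodeSignal(pre)
  expect_equal(samplingRate(sig), samplingRate(ep@signal))
  expect_equal(signalData(sig), signalData(ep@signal), tolerance = 1e-6)
  expect_equal(channelNames(sig), channelNames(ep@signal))
})
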