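test_that("spectral clustering recovers planted blocks, exactly and under noise", {
  S <- matrix(0.05, 10, 10)
  S[1:5, 1:5] <- S[6:10, 6:10] <- 0.9
  diag(S) <- 1
  cl <- spectralClusters(S, k = 2)
  labs <- communityLabels(cl)
  expect_equal(length(unique(labs[1:5])), 1)
  expect_equal(length(unique(labs[6:10])), 1)
  expect_true(labs[1] != labs[6])
  expect_error(spectralClusters(S, k = 10), "k")
  ok <- vapply(1:50, function(s) {
    set.seed(s)
    Sn <- S + matrix(rnorm(100, sd = 0.05), 10)
    Sn <- pmin(pmax((Sn + t(Sn)) / 2, 0), 1)
    diag(Sn) <- 1
    adjustedRand(communityLabels(spectralClusters(Sn, k = 2, seed = s)),
                 rep(1:2, each = 5)) > 0.9
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("order parameter matches closed forms and the von Mises resultant", {
  expect_identical(orderParameter(rep(0.7, 9)), 1)
  expect_lt(orderParameter(c(0, pi / 2, pi, 3 * pi / 2)), 1e-15)
  expect_error(orderParameter(numeric(0)), "empty")
  # invariances
  set.seed(8)
  ph <- runif(15, -pi, pi)
  expect_lt(abs(orderParameter(ph) - orderParameter(ph + 2.2)), 1e-12)
  expect_lt(abs(orderParameter(ph) - orderParameter(sample(ph))), 1e-12)
  # von Mises(kappa = 2) mean resultant length = I1(2)/I0(2)
  kappa <- 2
  set.seed(10)
  u <- runif(1e5); v <- runif(1e5)
  # Best-Fisher sampler
  a <- 1 + sqrt(1 + 4 * kappa^2); b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  z <- cos(pi * u); f <- (1 + r * z) / (r + z); c <- kappa * (r - f)
  accept <- c * (2 - c) - v > 0 | log(c / v) + 1 - c >= 0
  theta <- ifelse(runif(1e5) > 0.5, acos(f), -acos(f))[accept]
  popR <- besselI(kappa, 1) / besselI(kappa, 0)
  expect_lt(abs(orderParameter(theta) - popR), 0.01)
})

test_that("the contrast rule is strict at the 0.3 threshold", {
  l1 <- chimeraLabel(c(0.95, 0.40))
  expect_equal(l1$contrast, 0.55)
  expect_equal(l1$ychimera, 1L)
  expect_equal(chimeraLabel(c(0.60, 0.35))$ychimera, 0L)
  l3 <- chimeraLabel(c(0.65, 0.35))
  expect_equal(l3$contrast, 0.30)
  expect_equal(l3$ychimera, 0L)          # strictly greater than
  expect_error(chimeraLabel(0.5), "single")
  # invariant under cluster relabeling
  expect_equal(chimeraLabel(c(0.4, 0.9))$contrast,
               chimeraLabel(c(0.9, 0.4))$contrast)
})

test_that("windowed chimera index separates synchrony, incoherence and chimera", {
  fs <- 256
  n <- fs * 15
  t <- seq_len(n) / fs
  # global synchrony: all channels share one phase (plus small jitter)
  set.seed(1)
  base <- 2 * pi * 2 * t
  sync <- PhaseTrajectory(wrapPhase(outer(base, rep(1, 8)) +
                                      rnorm(n * 8, sd = 0.05)), dt = 1 / fs)
  sSync <- chimeraIndexSeries(sync)
  expect_true(all(sSync$contrast < 0.1))
  # full incoherence: independent random-walk phases (finite-size cluster
  # order parameters need the full 23-channel montage to stay small)
  set.seed(2)
  inc <- PhaseTrajectory(apply(matrix(rnorm(n * 23, sd = 0.3), n, 23), 2,
                               cumsum), dt = 1 / fs)
  sInc <- chimeraIndexSeries(inc)
  expect_gte(mean(sInc$contrast < 0.15), 0.9)
  expect_true(all(sInc$ychimera[sInc$contrast <= 0.3] == 0))
})

test_that("measured window labels agree with generator ground truth", {
  accs <- vapply(1:2, function(s) {
    ep <- generateEpisode(benchmarkEpisodeSpec(seed = s), storePhases = TRUE)
    series <- chimeraIndexSeries(ep@phases, seed = s)
    truth <- windowLabels(ep)$ychimera[seq_len(nrow(series))]
    mean(series$ychimera == truth)
  }, numeric(1))
  expect_gt(mean(accs), 0.85)
})

test_that("three-phase segmentation finds emergence, stabilization, transition", {
  hits <- 0L
  runs <- 5L
  for (s in seq_len(runs)) {
    ep <- generateEpisode(benchmarkEpisodeSpec(seed = s), storePhases = TRUE)
    series <- chimeraIndexSeries(ep@phases, seed = s)
    seg <- segmentThreePhases(series)
    wl <- windowLabels(ep)
    # truth onsets from the generator's own labels
    r <- rle(wl$ychimera)
    ends <- cumsum(r$lengths)
    pos <- which(r$values == 1 & r$lengths >= 3)
    truthEmergence <- ends[pos[1]] - r$lengths[pos[1]] + 1L
    # the generator-truth analogue of the transition rule: the first window
    # whose ground-truth minimum cluster order parameter exceeds 0.7
    truthTransition <- which(pmin(wl$clusterR0, wl$clusterR1) > 0.7)[1]
    ok <- seg$detected &&
      abs(seg$emergence - truthEmergence) <= 2 &&
      !is.na(seg$transition) &&
      abs(seg$transition - truthTransition) <= 2
    hits <- hits + ok
  }
  expect_gte(hits / runs, 0.8)
  # monotone ramp with no plateau: emergence without stabilization
  n <- 30
  ramp <- data.frame(start = seq(0, by = 2.5, length.out = n),
                     end = seq(5, by = 2.5, length.out = n),
                     clusterR0 = seq(0.3, 0.95, length.out = n),
                     clusterR1 = 0.25,
                     contrast = seq(0.05, 0.7, length.out = n))
  ramp$ychimera <- as.integer(ramp$contrast > 0.3)
  segRamp <- segmentThreePhases(ramp, slopeMax = 0.005)
  expect_true(segRamp$detected)
  expect_false(is.na(segRamp$emergence))
  expect_true(is.na(segRamp$stabilization))
  # flat baseline: nothing detected
  flat <- ramp
  flat$contrast <- 0.05
  flat$ychimera <- 0L
  segFlat <- segmentThreePhases(flat)
  expect_false(segFlat$detected)
})
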