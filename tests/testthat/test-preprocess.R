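mkSine <- function(freq, fs, dur, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sin(2 * pi * freq * t + phase)
}

test_that("resampling halves the length for a 2:1 ratio and preserves tones", {
  x <- MultiChannelSignal(rbind(mkSine(10, 512, 2)), samplingRate = 512)
  y <- resampleSignal(x, 256)
  expect_equal(ncol(signalData(y)), 512)
  expect_equal(samplingRate(y), 256)
  ref <- mkSine(10, 256, 2)
  n <- length(ref)
  core <- 30:(n - 30)             # ignore FIR edge transients
  expect_gt(cor(signalData(y)[1, core], ref[core]), 0.999)
  expect_identical(resampleSignal(x, 512), x)
})

test_that("zero-phase bandpass removes DC, keeps the passband, kills 60 Hz", {
  fs <- 256
  x10 <- mkSine(10, fs, 8)
  sig <- MultiChannelSignal(rbind(x10 + 5), samplingRate = fs)
  filt <- bandpassFilter(sig)
  y <- signalData(filt)[1, ]
  core <- (fs + 1):(length(y) - fs)
  expect_lt(abs(mean(y[core])), 1e-2)
  # passband gain and zero phase at 10 Hz
  g <- sd(y[core]) / sd(x10[core])
  expect_gt(g, 0.95); expect_lt(g, 1.05)
  cc <- ccf(y[core], x10[core], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # 60 Hz stopband: measured forward-backward attenuation matches twice the
  # designed squared magnitude response
  x60 <- MultiChannelSignal(rbind(mkSine(60, fs, 8)), samplingRate = fs)
  y60 <- signalData(bandpassFilter(x60))[1, core]
  att <- 20 * log10(sd(mkSine(60, fs, 8)[core]) / sd(y60))
  bf <- signal::butter(4, c(1, 50) / (fs / 2), "pass")
  H <- signal::freqz(bf$b, bf$a, Fs = fs)
  pred <- -2 * 20 * log10(Mod(H$h[which.min(abs(H$f - 60))]))
  expect_lt(abs(att - pred), 1.5)
  expect_gt(att, 15)
  expect_error(bandpassFilter(sig, high = 130), "Nyquist")
})

test_that("artifact criteria flag the right components", {
  fs <- 256; dur <- 30
  n <- fs * dur
  t <- seq_len(n) / fs
  # slow heavy-tailed component: blocks of lognormal amplitude on a 0.1 Hz
  # carrier -> high kurtosis, low HF power, high 1-s autocorrelation
  set.seed(5)
  blocks <- rep(exp(rnorm(ceiling(dur / 4), sd = 2.0)), each = 4 * fs)[1:n]
  blink <- blocks * sin(2 * pi * 0.1 * t)
  sine <- sin(2 * pi * 10 * t)
  set.seed(6)
  hf <- signal::filtfilt(signal::butter(4, 35 / (fs / 2), "high"), rnorm(n))
  sources <- rbind(blink, sine, hf)
  sources <- sources / apply(sources, 1, sd)
  mixing <- matrix(0.5, 6, 3)
  ch <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4")
  flags <- flagArtifactComponents(mixing, sources, fs, channelNames = ch)
  # component 1: kurtosis only
  expect_gt(flags$kurtosis[1], 5)
  expect_lt(flags$hfPowerRatio[1], 0.4)
  expect_gt(flags$lag1sAutocorrelation[1], 0.3)
  expect_identical(flags$criteriaHit[[1]], 1L)
  expect_true(flags$flagged[1])
  # component 2: a pure sinusoid has kurtosis 1.5 and trips nothing
  expect_equal(flags$kurtosis[2], 1.5, tolerance = 0.01)
  expect_false(flags$flagged[2])
  # component 3: EMG-like high-frequency noise
  expect_gt(flags$hfPowerRatio[3], 0.4)
  expect_true(2L %in% flags$criteriaHit[[3]])
  # EOG criterion fires on a correlated reference
  flags2 <- flagArtifactComponents(mixing, sources, fs, channelNames = ch,
                                   eogReference = blink + rnorm(n, sd = 0.1))
  expect_true(5L %in% flags2$criteriaHit[[1]])
  expect_error(flagArtifactComponents(mixing, sources[, 1:100], fs),
               "2 s")
})

test_that("frontal-topography criterion uses Fp1/Fp2 weight share", {
  fs <- 256
  set.seed(7)
  src <- rbind(rnorm(fs * 4))
  mixing <- matrix(c(3, 3, 0.2, 0.2, 0.2, 0.2), ncol = 1)
  ch <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4")
  fl <- flagArtifactComponents(mixing, src, fs, channelNames = ch)
  expect_gt(fl$frontalWeight[1], 0.7)
  expect_true(3L %in% fl$criteriaHit[[1]])
  expect_message(flagArtifactComponents(mixing, src, fs,
                                        channelNames = paste0("ch", 1:6)),
                 "skipped")
})

test_that("ICA separates and flagging recovers injected artifact sources", {
  fs <- 256; dur <- 30; n <- fs * dur
  t <- seq_len(n) / fs
  nGood <- 5; nBad <- 3; C <- 8
  set.seed(11)
  # benign rhythms: steady integer-frequency oscillations (autocorrelation
  # at a 1-second lag is then ~1, clearing the random-noise criterion)
  good <- t(vapply(1:nGood, function(i)
    sin(2 * pi * (2 * i + 1) * t + runif(1, 0, 2 * pi)), numeric(n)))
  blocks <- rep(exp(rnorm(ceiling(dur / 4), sd = 1.3)), each = 4 * fs)[1:n]
  bad <- rbind(blocks * sin(2 * pi * 0.1 * t),
               signal::filtfilt(signal::butter(4, 38 / (fs / 2), "high"),
                                rnorm(n)),
               rt(n, df = 3))
  S <- rbind(good, bad)
  S <- S / apply(S, 1, sd)
  set.seed(12)
  A <- matrix(rnorm(C * C), C)
  X <- A %*% S
  sig <- MultiChannelSignal(X, samplingRate = fs)
  dec <- icaDecompose(sig, nComponents = C, seed = 42)
  flags <- flagArtifactComponents(dec$mixing, dec$sources, fs)
  # match estimated components to the injected artifact sources
  cmat <- abs(cor(t(dec$sources), t(bad)))
  matched <- apply(cmat, 2, which.max)
  expect_true(all(apply(cmat, 2, max) > 0.9))
  expect_true(all(flags$flagged[matched]))
  # benign narrowband sources are not flagged
  cg <- abs(cor(t(dec$sources), t(good)))
  benign <- apply(cg, 2, which.max)[apply(cg, 2, max) > 0.9]
  expect_false(any(flags$flagged[benign]))
  # removal reconstructs the signal without the flagged components
  clean <- removeComponents(dec, flags, fs, channelNames(sig))
  expect_equal(dim(signalData(clean)), dim(X))
})

test_that("interictal z-scoring uses only masked statistics", {
  fs <- 256
  set.seed(9)
  inter <- matrix(rnorm(2 * fs * 20, mean = 3, sd = 2), nrow = 2)
  ictal <- inter[, 1:(fs * 5)] * 10
  x <- MultiChannelSignal(cbind(inter, ictal), samplingRate = fs)
  mask <- c(rep(TRUE, ncol(inter)), rep(FALSE, ncol(ictal)))
  z <- zscoreInterictal(x, mask)
  zm <- signalData(z)[, mask]
  expect_lt(max(abs(rowMeans(zm))), 0.02)
  expect_true(all(abs(apply(zm, 1, sd) - 1) < 0.02))
  # no leakage: the ictal/interictal scale ratio is preserved
  ratio <- apply(signalData(z)[, !mask], 1, sd) / apply(zm, 1, sd)
  expect_equal(unname(ratio), rep(10, 2), tolerance = 0.5)
  # whole-signal z-scoring (deliberately wrong) shrinks that ratio's scale
  zAll <- zscoreInterictal(x, rep(TRUE, ncol(signalData(x))))
  expect_lt(sd(signalData(zAll)[1, mask]), 0.9)
  # idempotence
  z2 <- zscoreInterictal(z, mask)
  expect_lt(max(abs(signalData(z2) - signalData(z))), 1e-10)
  # degenerate channel is named
  bad <- MultiChannelSignal(rbind(rep(1, fs * 2), rnorm(fs * 2)),
                            samplingRate = fs,
                            channelNames = c("flat", "ok"))
  expect_error(zscoreInterictal(bad, rep(TRUE, fs * 2)), "flat")
})
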