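#' Resample a recording to a target rate
#'
#' Polyphase FIR resampling (via \code{signal::resample}) with an
#' anti-aliasing filter; the rational resampling factors are reduced by their
#' greatest common divisor. Output length is
#' \code{round(n * target / source)}. Upsampling is permitted but noted with
#' a message.
#'
#' @param signal a \linkS4class{MultiChannelSignal}.
#' @param targetRate target sampling rate in Hz (> 0).
#' @return the resampled \linkS4class{MultiChannelSignal}.
#' @export
resampleSignal <- function(signal, targetRate) {
  stopifnot(is(signal, "MultiChannelSignal"))
  if (targetRate <= 0) stop("targetRate must be > 0")
  src <- signal@samplingRate
  if (isTRUE(all.equal(targetRate, src))) return(signal)
  if (targetRate > src) message("upsampling from ", src, " to ", targetRate, " Hz")
  nOut <- round(ncol(signal@data) * targetRate / src)
  res <- t(apply(signal@data, 1, .resampleVec, r = targetRate / src,
                 nOut = nOut))
  MultiChannelSignal(res, samplingRate = targetRate,
                     channelNames = signal@channelNames,
                     startTime = signal@startTime)
}

# Polyphase resampling by rate ratio r with the anti-aliasing FIR's group
# delay compensated (the stock routine leaves a (2d+1)/2-sample shift in).
# Kaiser-windowed sinc interpolation on the filtered samples.
.resampleVec <- function(x, r, nOut, d = 5L) {
  shift <- 0
  if (r < 1) {
    b <- signal::fir1(2L * d + 1L, r)      # linear-phase anti-aliasing FIR
    shift <- (length(b) - 1) / 2           # group delay in input samples
    x <- signal::fftfilt(b, c(x, numeric(2L * d + 2L)))
  }
  t <- seq(1, by = 1 / r, length.out = nOut) + shift
  idx <- trunc(t)
  frac <- t - idx
  xpad <- c(numeric(d), x, numeric(d + 2L))
  y <- numeric(nOut)
  for (i in (-d):d) {
    u <- frac - i
    w <- ifelse(u == 0, 1, sin(pi * u) / (pi * u)) *
      (0.5 + 0.5 * cos(pi * u / (d + 0.5)))
    y <- y + xpad[idx + i + d] * w
  }
  y
}

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth bandpass (default 1-50 Hz) applied forward and
#' backward (\code{signal::filtfilt}), giving zero net phase shift and
#' doubling the effective stopband attenuation relative to a single pass.
#'
#' @param signal a \linkS4class{MultiChannelSignal}.
#' @param low,high band edges in Hz; requires 0 < low < high < Nyquist.
#' @param order filter order (default 4).
#' @return the filtered \linkS4class{MultiChannelSignal}.
#' @export
bandpassFilter <- function(signal, low = 1, high = 50, order = 4) {
  stopifnot(is(signal, "MultiChannelSignal"))
  nyq <- signal@samplingRate / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq) stop("high band edge must be below the Nyquist frequency")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filt <- t(apply(signal@data, 1, function(ch)
    signal::filtfilt(bf, ch)))
  MultiChannelSignal(filt, samplingRate = signal@samplingRate,
                     channelNames = signal@channelNames,
                     startTime = signal@startTime)
}

#' Minimal symmetric FastICA decomposition
#'
#' Whitens the channels (eigendecomposition of the covariance) and runs
#' symmetric fixed-point ICA with the log-cosh contrast. Deterministic given
#' the seed. Returns the decomposition in mixing/sources form,
#' \eqn{X \approx \bar X + A S}: \code{mixing} is channels x components and
#' \code{sources} components x samples.
#'
#' @param signal a \linkS4class{MultiChannelSignal}.
#' @param nComponents number of components (default
#'   \code{min(20, nChannels)}).
#' @param seed integer seed for the random orthogonal start.
#' @param tol convergence tolerance on the update (default 1e-4).
#' @param maxIter maximum fixed-point iterations (default 200).
#' @return list with \code{mixing}, \code{sources}, \code{means} (per-channel
#'   means removed before decomposition) and \code{converged}.
#' @export
icaDecompose <- function(signal, nComponents = NULL, seed = 42L,
                         tol = 1e-4, maxIter = 200L) {
  stopifnot(is(signal, "MultiChannelSignal"))
  X <- signal@data                          # channels x samples
  C <- nrow(X); n <- ncol(X)
  if (is.null(nComponents)) nComponents <- min(20L, C)
  nc <- min(nComponents, C)
  mu <- rowMeans(X)
  Xc <- X - mu
  ed <- eigen(tcrossprod(Xc) / n, symmetric = TRUE)
  keep <- seq_len(nc)
  Kw <- diag(1 / sqrt(pmax(ed$values[keep], 1e-12)), nc) %*%
    t(ed$vectors[, keep, drop = FALSE])     # nc x C whitening
  Z <- Kw %*% Xc                            # nc x n, white
  set.seed(.deriveSeed(seed, 5L))
  W <- qr.Q(qr(matrix(rnorm(nc * nc), nc)))
  sym <- function(W) {                      # symmetric decorrelation
    s <- svd(W); s$u %*% t(s$v)
  }
  W <- sym(W)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W1 <- sym(tcrossprod(G, Z) / n - diag(gp, nc) %*% W)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- W %*% Z                              # nc x n unit-variance sources
  A <- t(solve(tcrossprod(S) / n, S %*% t(Xc) / n))  # channels x nc
  list(mixing = A, sources = S, means = mu, converged = converged)
}

#' Flag artifactual ICA components
#'
#' Evaluates the five automated artifact criteria on each independent
#' component: (1) plain kurtosis (fourth standardized moment, so a Gaussian
#' scores 3 and a sinusoid 1.5) > 5.0; (2) high-frequency power ratio (Welch
#' power above 30 Hz over total) > 40\%; (3) frontal topography with > 70\%
#' of absolute mixing weight on Fp1/Fp2; (4) temporal autocorrelation at a
#' 1-second lag < 0.3; (5) absolute correlation with an EOG reference > 0.8.
#' A component is flagged when any applicable criterion fires. Criterion 3
#' is skipped (with a message) when no Fp1/Fp2 channels exist; criterion 5
#' when no EOG reference is supplied. Inequalities are strict.
#'
#' @param mixing channels x components mixing matrix.
#' @param sources components x samples source matrix.
#' @param samplingRate sampling rate in Hz; at least 2 s of samples are
#'   required for the autocorrelation criterion.
#' @param channelNames channel labels matching the mixing rows.
#' @param eogReference optional EOG reference, a numeric vector or a
#'   rows-as-channels matrix aligned with \code{sources} columns.
#' @return data.frame with one row per component: kurtosis, hfPowerRatio,
#'   frontalWeight, lag1sAutocorrelation, eogCorrelation, flagged, and a
#'   list-column criteriaHit with the indices of the criteria met.
#' @export
flagArtifactComponents <- function(mixing, sources, samplingRate,
                                   channelNames = NULL, eogReference = NULL) {
  mixing <- as.matrix(mixing); sources <- as.matrix(sources)
  if (ncol(mixing) != nrow(sources))
    stop("mixing columns must match source rows")
  n <- ncol(sources); fs <- samplingRate
  lag <- round(fs)
  if (n < 2 * lag)
    stop("autocorrelation criterion unavailable: need at least 2 s of samples")
  if (is.null(channelNames)) channelNames <- rownames(mixing)
  frontal <- if (!is.null(channelNames)) which(toupper(channelNames) %in%
                                                 c("FP1", "FP2")) else integer(0)
  if (length(frontal) == 0)
    message("Fp1/Fp2 not present: frontal-topography criterion skipped")
  eog <- NULL
  if (!is.null(eogReference)) {
    eog <- if (is.matrix(eogReference)) eogReference else rbind(eogReference)
    if (ncol(eog) != n) stop("eogReference length must match source samples")
  }
  nc <- nrow(sources)
  res <- data.frame(component = seq_len(nc), kurtosis = NA_real_,
                    hfPowerRatio = NA_real_, frontalWeight = NA_real_,
                    lag1sAutocorrelation = NA_real_,
                    eogCorrelation = NA_real_, flagged = FALSE)
  res$criteriaHit <- vector("list", nc)
  for (j in seq_len(nc)) {
    s <- sources[j, ]
    z <- (s - mean(s)) / sd(s)
    res$kurtosis[j] <- mean(z^4)
    psd <- .welchPSD(cbind(s), fs)
    tot <- sum(psd$psd[psd$freq > 0, 1])
    res$hfPowerRatio[j] <- sum(psd$psd[psd$freq > 30, 1]) / tot
    if (length(frontal))
      res$frontalWeight[j] <- sum(abs(mixing[frontal, j])) /
        sum(abs(mixing[, j]))
    res$lag1sAutocorrelation[j] <- cor(s[1:(n - lag)], s[(lag + 1):n])
    if (!is.null(eog))
      res$eogCorrelation[j] <- max(abs(cor(s, t(eog))))
    hit <- integer(0)
    if (res$kurtosis[j] > 5.0) hit <- c(hit, 1L)
    if (res$hfPowerRatio[j] > 0.4) hit <- c(hit, 2L)
    if (length(frontal) && res$frontalWeight[j] > 0.7) hit <- c(hit, 3L)
    if (res$lag1sAutocorrelation[j] < 0.3) hit <- c(hit, 4L)
    if (!is.null(eog) && res$eogCorrelation[j] > 0.8) hit <- c(hit, 5L)
    res$criteriaHit[[j]] <- hit
    res$flagged[j] <- length(hit) > 0
  }
  res
}

#' Remove flagged components and remix
#'
#' Zeroes the flagged sources and reconstructs the channel signals from the
#' remaining components (adding back the channel means).
#'
#' @param decomposition result of \code{\link{icaDecompose}}.
#' @param flags result of \code{\link{flagArtifactComponents}} (or a logical
#'   vector per component).
#' @param samplingRate sampling rate of the reconstructed signal.
#' @param channelNames channel labels for the reconstruction.
#' @return a cleaned \linkS4class{MultiChannelSignal}.
#' @export
removeComponents <- function(decomposition, flags, samplingRate,
                             channelNames = NULL) {
  drop <- if (is.data.frame(flags)) flags$flagged else as.logical(flags)
  S <- decomposition$sources
  S[drop, ] <- 0
  X <- decomposition$mixing %*% S + decomposition$means
  MultiChannelSignal(X, samplingRate = samplingRate,
                     channelNames = channelNames)
}

#' Channel-wise z-scoring from interictal statistics
#'
#' Normalizes every channel with the mean and standard deviation computed
#' exclusively on the interictal (masked) samples, then applies the
#' transform to all samples — ictal amplitudes are expressed on the
#' interictal scale without leaking ictal statistics into the normalization.
#'
#' @param signal a \linkS4class{MultiChannelSignal}.
#' @param interictalMask logical vector, one entry per sample, selecting at
#'   least 256 samples.
#' @return the z-scored \linkS4class{MultiChannelSignal}.
#' @export
zscoreInterictal <- function(signal, interictalMask) {
  stopifnot(is(signal, "MultiChannelSignal"))
  mask <- as.logical(interictalMask)
  if (length(mask) != ncol(signal@data))
    stop("interictalMask length must equal the sample count")
  if (sum(mask) < 256) stop("interictal mask must select at least 256 samples")
  sub <- signal@data[, mask, drop = FALSE]
  mu <- rowMeans(sub)
  sigma <- apply(sub, 1, sd)
  degen <- which(sigma <= 0 | !is.finite(sigma))
  if (length(degen))
    stop("degenerate channel(s) with zero interictal variance: ",
         paste(signal@channelNames[degen], collapse = ", "))
  MultiChannelSignal((signal@data - mu) / sigma,
                     samplingRate = signal@samplingRate,
                     channelNames = signal@channelNames,
                     startTime = signal@startTime)
}

#' Full preprocessing pipeline
#'
#' Applies the fixed preprocessing order: resample to the target rate,
#' zero-phase Butterworth bandpass, ICA artifact flagging and removal, then
#' interictal z-scoring. ICA removal precedes the z-scoring mask use; for
#' synthetic episodes the interictal mask is the baseline segment.
#'
#' @param signal a \linkS4class{MultiChannelSignal}.
#' @param interictalMask logical per-sample mask at the \emph{target} rate;
#'   defaults to all samples.
#' @param targetRate resampling target in Hz (default 256).
#' @param low,high,order bandpass settings.
#' @param runICA run the ICA flagging/removal stage (default FALSE; most
#'   synthetic episodes contain no injected artifacts).
#' @param nComponents,seed ICA settings.
#' @param eogReference optional EOG reference passed to the flagging step.
#' @return list with the preprocessed \code{signal} and, when ICA ran, the
#'   per-component \code{componentReport}.
#' @export
preprocessSignal <- function(signal, interictalMask = NULL, targetRate = 256,
                             low = 1, high = 50, order = 4, runICA = FALSE,
                             nComponents = NULL, seed = 42L,
                             eogReference = NULL) {
  s <- resampleSignal(signal, targetRate)
  s <- bandpassFilter(s, low = low, high = high, order = order)
  report <- NULL
  if (runICA) {
    dec <- icaDecompose(s, nComponents = nComponents, seed = seed)
    report <- flagArtifactComponents(dec$mixing, dec$sources, targetRate,
                                     channelNames = s@channelNames,
                                     eogReference = eogReference)
    s <- removeComponents(dec, report, targetRate, s@channelNames)
  }
  if (is.null(interictalMask)) interictalMask <- rep(TRUE, ncol(s@data))
  s <- zscoreInterictal(s, interictalMask)
  list(signal = s, componentReport = report)
}
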