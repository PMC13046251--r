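#' Wrap phases to the interval (-pi, pi]
#'
#' @param x numeric vector or matrix of phases in radians.
#' @return object of the same shape with every value wrapped.
#' @examples wrapPhase(c(0, 3 * pi, -3 * pi))
#' @export
wrapPhase <- function(x) {
  w <- (x + pi) %% (2 * pi)
  w - pi + ifelse(w == 0, 2 * pi, 0)
}

#' Kuramoto order parameter
#'
#' Modulus of the mean unit phasor \eqn{R = |\sum_j e^{i\phi_j}| / N}:
#' 1 for perfectly aligned phases, near 0 for incoherent ones.
#'
#' @param phases numeric vector of phases in radians (N >= 1).
#' @return R in [0, 1].
#' @examples
#' orderParameter(rep(0.3, 8))            # 1
#' orderParameter(c(0, pi/2, pi, 3*pi/2)) # 0
#' @export
orderParameter <- function(phases) {
  if (length(phases) < 1L) stop("orderParameter: empty phase set")
  Mod(mean(exp(1i * phases)))
}

# deterministic per-task seed derived from a base seed; kept below 2^31
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12289) %% 2147483629)
}

# unwrap phase columns (inverse of wrapping, base::diff convention)
.unwrapPhases <- function(ph) {
  apply(ph, 2, function(col) {
    d <- diff(col)
    col[1] + c(0, cumsum(wrapPhase(d)))
  })
}

# Welch power spectral density, Hann window segments with 50% overlap.
# Returns list(freq, psd) with psd one column per channel of `x` (samples x
# channels matrix).
.welchPSD <- function(x, fs, segmentSec = 2, overlap = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  seg <- min(n, max(8L, round(segmentSec * fs)))
  hop <- max(1L, round(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  u <- sum(win^2)
  nf <- seg %/% 2L + 1L
  acc <- matrix(0, nf, ncol(x))
  for (s in starts) {
    segx <- x[s:(s + seg - 1L), , drop = FALSE]
    segx <- sweep(segx, 2, colMeans(segx))
    X <- stats::mvfft(segx * win)
    p <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (u * fs)
    p[2:(nf - 1L), ] <- 2 * p[2:(nf - 1L), ]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg, psd = acc / length(starts))
}
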