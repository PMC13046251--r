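#' Per-channel feature vectors for adjacency refinement
#'
#' Computes, per channel over a time window, the nine features that condition
#' the adjacency refiner: mean, variance, skewness, Welch band-power
#' fractions in the five canonical bands (delta 1-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-50 Hz) and the spectral (Shannon) entropy of the
#' normalized periodogram in nats. Zero-variance channels get skewness 0 and
#' a degenerate flag.
#'
#' @param signal a \linkS4class{MultiChannelSignal}.
#' @param window optional c(start, end) in seconds (>= 2 s for stable
#'   spectral estimates); default whole recording.
#' @return data.frame with one row per channel: mean, variance, skewness,
#'   delta, theta, alpha, beta, gamma, spectralEntropy, degenerate.
#' @export
channelFeatures <- function(signal, window = NULL) {
  stopifnot(is(signal, "MultiChannelSignal"))
  fs <- signal@samplingRate
  x <- t(signal@data)
  if (!is.null(window)) {
    if (diff(window) < 2) stop("feature window must be at least 2 s")
    i0 <- floor(window[1] * fs) + 1L
    i1 <- min(ceiling(window[2] * fs), nrow(x))
    x <- x[i0:i1, , drop = FALSE]
  }
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  degenerate <- v <= 0
  skew <- ifelse(degenerate, 0,
                 colMeans(sweep(x, 2, mu)^3) / pmax(v, 1e-300)^1.5)
  psd <- .welchPSD(x, fs)
  f <- psd$freq
  tot <- colSums(psd$psd[f > 0, , drop = FALSE])
  bandFrac <- function(lo, hi) {
    colSums(psd$psd[f > lo & f <= hi, , drop = FALSE]) / pmax(tot, 1e-300)
  }
  p <- sweep(psd$psd[f > 0, , drop = FALSE], 2, pmax(tot, 1e-300), "/")
  entropy <- -colSums(ifelse(p > 0, p * log(p), 0))
  data.frame(mean = mu, variance = v, skewness = skew,
             delta = bandFrac(1, 4), theta = bandFrac(4, 8),
             alpha = bandFrac(8, 13), beta = bandFrac(13, 30),
             gamma = bandFrac(30, 50), spectralEntropy = entropy,
             degenerate = degenerate,
             row.names = signal@channelNames)
}

#' Initialize an adjacency-refiner MLP
#'
#' Three dense layers (128, 64, C^2) mapping the flattened channel-feature
#' matrix to per-pair attention scores. Weights are Glorot-initialized and
#' deterministic given the seed.
#'
#' @param nChannels channel count C.
#' @param nFeatures features per channel (default 9).
#' @param seed integer seed.
#' @return list of weight matrices/biases usable by
#'   \code{\link{refineAdjacency}}.
#' @export
initRefiner <- function(nChannels, nFeatures = 9L, seed = 42L) {
  set.seed(.deriveSeed(seed, 6L))
  dims <- c(nChannels * nFeatures, 128L, 64L, nChannels^2)
  glorot <- function(din, dout)
    matrix(runif(din * dout, -1, 1) * sqrt(6 / (din + dout)), din, dout)
  list(W1 = glorot(dims[1], dims[2]), b1 = numeric(dims[2]),
       W2 = glorot(dims[2], dims[3]), b2 = numeric(dims[3]),
       W3 = glorot(dims[3], dims[4]), b3 = numeric(dims[4]),
       nChannels = nChannels)
}

#' Feature-conditioned adjacency refinement
#'
#' With a refiner, maps the channel features through the MLP to C^2
#' attention scores, multiplies them elementwise with the PLV matrix,
#' applies a row-wise softmax, symmetrizes as \eqn{(M + M^T)/2} and
#' max-normalizes back to [0, 1] so the downstream clique threshold keeps
#' its meaning (a row softmax over C entries would otherwise cap values near
#' 1/C). In identity mode (\code{refiner = NULL}) the PLV matrix is passed
#' through unchanged up to max-normalization, so the ranking of entries is
#' exactly the PLV ranking.
#'
#' @param features data.frame from \code{\link{channelFeatures}}.
#' @param plv a symmetric PLV matrix in [0, 1].
#' @param refiner a refiner from \code{\link{initRefiner}} or NULL for
#'   identity mode.
#' @return symmetric refined adjacency matrix with entries in [0, 1].
#' @export
refineAdjacency <- function(features, plv, refiner = NULL) {
  plv <- as.matrix(plv)
  C <- nrow(plv)
  if (ncol(plv) != C) stop("plv must be square")
  if (is.null(refiner)) {
    m <- max(plv)
    return(if (m > 0) plv / m else plv)
  }
  xin <- as.numeric(as.matrix(features[, seq_len(9), drop = FALSE]))
  relu <- function(z) pmax(z, 0)
  h1 <- relu(drop(xin %*% refiner$W1) + refiner$b1)
  h2 <- relu(drop(h1 %*% refiner$W2) + refiner$b2)
  att <- drop(h2 %*% refiner$W3) + refiner$b3
  if (length(att) != C * C)
    stop("refiner output dimension must be C^2")
  M <- matrix(att, C, C) * plv
  M <- exp(M - apply(M, 1, max))
  M <- M / rowSums(M)                       # row-wise softmax
  M <- (M + t(M)) / 2
  M / max(M)
}

#' Detect 3-clique hyperedges
#'
#' Enumerates every channel triplet \{i, j, k\} whose three pairwise
#' adjacency entries all strictly exceed the threshold tau; each such
#' triplet becomes a hyperedge. Enumeration is exhaustive and
#' order-independent.
#'
#' @param adjacency symmetric matrix with entries in [0, 1].
#' @param tau detection threshold in [0, 1] (default 0.65).
#' @param channelNames optional node labels.
#' @return a \linkS4class{Hypergraph}.
#' @examples
#' A <- matrix(1, 5, 5)
#' nrow(hyperedges(detect3Cliques(A)))  # choose(5, 3) = 10
#' @export
detect3Cliques <- function(adjacency, tau = 0.65, channelNames = NULL) {
  A <- as.matrix(adjacency)
  C <- nrow(A)
  if (ncol(A) != C) stop("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  if (C < 3) stop("need at least 3 channels")
  if (is.null(channelNames)) channelNames <- sprintf("ch%02d", seq_len(C))
  trip <- utils::combn(C, 3)
  keep <- A[cbind(trip[1, ], trip[2, ])] > tau &
    A[cbind(trip[2, ], trip[3, ])] > tau &
    A[cbind(trip[1, ], trip[3, ])] > tau
  he <- t(trip[, keep, drop = FALSE])
  colnames(he) <- c("i", "j", "k")
  new("Hypergraph", nodes = channelNames, hyperedges = he,
      weights = numeric(0), sourceAdjacency = A, tau = tau)
}

#' Hyperedge density
#'
#' Fraction of possible 3-node hyperedges present:
#' \eqn{|E| / \binom{C}{3}}. The operating range on calibrated adjacency
#' matrices is 10-30\%.
#'
#' @param h a \linkS4class{Hypergraph} with C >= 3 nodes.
#' @return density in [0, 1].
#' @export
hyperedgeDensity <- function(h) {
  stopifnot(is(h, "Hypergraph"))
  C <- length(h@nodes)
  if (C < 3) stop("need at least 3 nodes")
  nrow(h@hyperedges) / choose(C, 3)
}

#' Node x hyperedge incidence matrix
#'
#' @param h a \linkS4class{Hypergraph}.
#' @return binary C x E matrix.
#' @export
incidenceMatrix <- function(h) {
  stopifnot(is(h, "Hypergraph"))
  C <- length(h@nodes); E <- nrow(h@hyperedges)
  M <- matrix(0L, C, E, dimnames = list(h@nodes, NULL))
  if (E) for (col in 1:3) M[cbind(h@hyperedges[, col], seq_len(E))] <- 1L
  M
}

#' Serialize / read a hypergraph as line-oriented text
#'
#' Header: \code{# chimeraNet hypergraph C=<C> tau=<tau>}, then one
#' \code{i j k weight} line per hyperedge (weight 1 when no attention
#' weights are attached).
#'
#' @param h a \linkS4class{Hypergraph}.
#' @param path output file.
#' @return \code{writeHypergraph} returns \code{path} invisibly;
#'   \code{readHypergraph} returns a \linkS4class{Hypergraph} (without the
#'   source adjacency, which is not serialized).
#' @export
writeHypergraph <- function(h, path) {
  stopifnot(is(h, "Hypergraph"))
  wts <- if (length(h@weights)) h@weights else rep(1, nrow(h@hyperedges))
  lines <- c(sprintf("# chimeraNet hypergraph C=%d tau=%g", length(h@nodes),
                     h@tau),
             paste("#", paste(h@nodes, collapse = " ")),
             if (nrow(h@hyperedges))
               sprintf("%d %d %d %g", h@hyperedges[, 1], h@hyperedges[, 2],
                       h@hyperedges[, 3], wts))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeHypergraph
#' @export
readHypergraph <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("# chimeraNet hypergraph ", "", lines[1]), " ")[[1]]
  C <- as.integer(sub("C=", "", hdr[1]))
  tau <- as.numeric(sub("tau=", "", hdr[2]))
  nodes <- strsplit(sub("^# ", "", lines[2]), " ")[[1]]
  body <- lines[-(1:2)]
  he <- if (length(body)) {
    m <- do.call(rbind, lapply(strsplit(body, " "), as.numeric))
    matrix(as.integer(m[, 1:3]), ncol = 3,
           dimnames = list(NULL, c("i", "j", "k")))
  } else matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "k")))
  wts <- if (length(body)) do.call(rbind, lapply(strsplit(body, " "),
                                                 as.numeric))[, 4] else numeric(0)
  new("Hypergraph", nodes = nodes, hyperedges = he,
      weights = if (all(wts == 1)) numeric(0) else wts,
      sourceAdjacency = diag(C), tau = tau)
}
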