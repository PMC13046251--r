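#' Spectral clustering of channels on a PLV matrix
#'
#' Normalized-Laplacian spectral clustering treating the PLV matrix as a
#' similarity: embed channels in the k smallest eigenvectors of
#' \eqn{L = I - D^{-1/2} S D^{-1/2}} (rows normalized to unit length), then
#' k-means with multiple deterministic restarts. If the similarity graph is
#' disconnected a uniform 1e-6 similarity is added (with a message). The
#' eigengap sequence is kept for diagnostics.
#'
#' @param plv symmetric similarity matrix (PLV) in [0, 1].
#' @param k cluster count, 2 <= k <= C - 1 (default 2: the most and least
#'   synchronized communities).
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts (default 10).
#' @return a \linkS4class{ClusterAssignment} with 0-based labels.
#' @examples
#' S <- matrix(0.05, 10, 10)
#' S[1:5, 1:5] <- S[6:10, 6:10] <- 0.9; diag(S) <- 1
#' communityLabels(spectralClusters(S))
#' @export
spectralClusters <- function(plv, k = 2L, seed = 42L, nstart = 10L) {
  S <- as.matrix(plv)
  C <- nrow(S)
  if (k < 2 || k > C - 1) stop("need 2 <= k <= C - 1")
  S <- (S + t(S)) / 2
  diag(S) <- 0
  if (any(rowSums(S) <= 0)) {
    message("disconnected similarity graph: adding 1e-6 uniform similarity")
    S <- S + 1e-6
    diag(S) <- 0
  }
  d <- 1 / sqrt(rowSums(S))
  L <- diag(C) - (d * S) %*% diag(d)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- rev(seq_len(C))                      # ascending eigenvalues
  vals <- ev$values[ord]
  U <- ev$vectors[, ord[seq_len(k)], drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  U <- U / pmax(nrm, 1e-12)
  set.seed(.deriveSeed(seed, 7L))
  km <- kmeans(U, centers = k, nstart = nstart, iter.max = 50)
  new("ClusterAssignment", labels = as.integer(km$cluster - 1L),
      k = as.integer(k), eigengap = diff(vals))
}

#' Chimera contrast label
#'
#' Applies the contrast rule to per-cluster order parameters: contrast is
#' \eqn{\max(R_{cluster}) - \min(R_{cluster})}; the window is labelled
#' chimera when the contrast strictly exceeds the threshold (default 0.3).
#'
#' @param clusterR numeric vector of per-cluster order parameters (>= 2
#'   clusters).
#' @param threshold labelling threshold (default 0.3).
#' @return list with \code{contrast} and \code{ychimera} (0/1).
#' @examples
#' chimeraLabel(c(0.95, 0.40))  # contrast 0.55 -> chimera
#' @export
chimeraLabel <- function(clusterR, threshold = 0.3) {
  if (length(clusterR) < 2)
    stop("contrast is undefined for a single cluster")
  contrast <- max(clusterR) - min(clusterR)
  # strict inequality, guarded against floating-point round-off
  list(contrast = contrast,
       ychimera = as.integer(contrast - threshold > 1e-12))
}

# align new cluster labels to previous ones by maximal overlap (greedy)
.alignClusters <- function(labels, prev, k) {
  if (is.null(prev)) return(labels)
  overlap <- matrix(0L, k, k)
  for (a in seq_len(k) - 1L)
    for (b in seq_len(k) - 1L)
      overlap[a + 1, b + 1] <- sum(labels == a & prev == b)
  mapping <- rep(NA_integer_, k)
  for (i in seq_len(k)) {
    best <- which(overlap == max(overlap), arr.ind = TRUE)[1, ]
    mapping[best[1]] <- best[2] - 1L
    overlap[best[1], ] <- -1L
    overlap[, best[2]] <- -1L
  }
  mapping[labels + 1L]
}

#' Windowed chimera-index series
#'
#' For every analysis window: spectral-cluster the window's PLV matrix
#' (re-clustered each window, with labels aligned to the previous window by
#' maximal overlap to prevent label switching), compute the per-cluster
#' Kuramoto order parameter (time-average of the instantaneous order
#' parameter over the in-window samples) and apply the contrast rule.
#'
#' @param phases a \linkS4class{PhaseTrajectory}.
#' @param plan a \linkS4class{WindowPlan}; defaults to 5-s windows, 50\%
#'   overlap.
#' @param k cluster count (default 2).
#' @param threshold chimera contrast threshold (default 0.3).
#' @param seed seed for the clustering.
#' @return data.frame with one row per window: start, end, clusterR0 ...
#'   clusterR(k-1), contrast, ychimera.
#' @export
chimeraIndexSeries <- function(phases, plan = NULL, k = 2L, threshold = 0.3,
                               seed = 42L) {
  stopifnot(is(phases, "PhaseTrajectory"))
  fs <- 1 / phases@dt
  n <- nrow(phases@phases)
  if (is.null(plan)) plan <- windowPlan(n / fs)
  plvs <- plvMatrices(phases, plan)
  b <- plan@boundaries
  gl <- ceiling(phases@guard * fs)
  E <- exp(1i * phases@phases)
  prev <- NULL
  rows <- vector("list", length(plvs))
  for (w in seq_along(plvs)) {
    cl <- spectralClusters(plvs[[w]], k = k, seed = .deriveSeed(seed, w))
    labels <- .alignClusters(communityLabels(cl), prev, k)
    prev <- labels
    i0 <- max(floor(b[w, 1] * fs) + 1L, gl + 1L)
    i1 <- min(ceiling(b[w, 2] * fs), n - gl)
    R <- vapply(seq_len(k) - 1L, function(g) {
      mean(Mod(rowMeans(E[i0:i1, labels == g, drop = FALSE])))
    }, numeric(1))
    lab <- chimeraLabel(R, threshold)
    rows[[w]] <- c(b[w, 1], b[w, 2], R, lab$contrast, lab$ychimera)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("start", "end", paste0("clusterR", seq_len(k) - 1L),
                  "contrast", "ychimera")
  out
}

#' Segment the three-phase chimera progression
#'
#' Reconstructs the emergence / stabilization / transition structure from a
#' windowed chimera series: emergence onset is the first window of the
#' earliest run of at least \code{runLength} consecutive chimera-positive
#' windows; stabilization onset the first window whose centered
#' \code{maWindows}-window moving average of contrast exceeds
#' \code{contrastThreshold} with slope magnitude below \code{slopeMax} per
#' window; transition onset the first window after stabilization where the
#' minimum cluster order parameter rises above \code{rTransition}
#' (approach to global synchrony). All constants are exposed; they are
#' package reconstructions of a qualitative description, not literature
#' values.
#'
#' @param series data.frame from \code{\link{chimeraIndexSeries}} (>= 10
#'   windows).
#' @param runLength consecutive-positive-window requirement (default 3).
#' @param contrastThreshold moving-average contrast level (default 0.3).
#' @param slopeMax plateau slope bound per window (default 0.01).
#' @param rTransition min-cluster order parameter marking the approach to
#'   global synchrony (default 0.7).
#' @param maWindows moving-average width (default 5, centered).
#' @return list with \code{detected} (logical), and window indices and start
#'   times for \code{emergence}, \code{stabilization}, \code{transition}
#'   (NA when absent).
#' @export
segmentThreePhases <- function(series, runLength = 3L,
                               contrastThreshold = 0.3, slopeMax = 0.01,
                               rTransition = 0.7, maWindows = 5L) {
  if (nrow(series) < 10) stop("need at least 10 windows")
  y <- series$ychimera
  n <- length(y)
  res <- list(detected = FALSE, emergence = NA_integer_,
              stabilization = NA_integer_, transition = NA_integer_,
              emergenceTime = NA_real_, stabilizationTime = NA_real_,
              transitionTime = NA_real_)
  runs <- rle(y)
  ends <- cumsum(runs$lengths)
  pos <- which(runs$values == 1 & runs$lengths >= runLength)
  if (!length(pos)) return(res)               # no chimera phases detected
  res$detected <- TRUE
  res$emergence <- ends[pos[1]] - runs$lengths[pos[1]] + 1L
  res$emergenceTime <- series$start[res$emergence]
  half <- maWindows %/% 2L
  ma <- stats::filter(series$contrast, rep(1 / maWindows, maWindows),
                      sides = 2)
  # least-squares slope of the moving average over a +/-2 window
  # neighbourhood (less noisy than a one-step difference)
  n2 <- length(ma)
  slope <- rep(NA_real_, n2)
  for (i in 3:(n2 - 2)) {
    y <- ma[(i - 2):(i + 2)]
    if (!anyNA(y)) slope[i] <- sum((-2:2) * y) / 10
  }
  stab <- which(seq_len(n) >= res$emergence & !is.na(ma) &
                  ma > contrastThreshold & !is.na(slope) &
                  abs(slope) < slopeMax)
  if (length(stab)) {
    res$stabilization <- stab[1]
    res$stabilizationTime <- series$start[stab[1]]
    rCols <- grep("^clusterR", names(series))
    minR <- do.call(pmin, series[rCols])
    tr <- which(seq_len(n) > res$stabilization & minR > rTransition)
    if (length(tr)) {
      res$transition <- tr[1]
      res$transitionTime <- series$start[tr[1]]
    }
  }
  res
}
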