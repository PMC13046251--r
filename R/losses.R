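#' Loss weights and constants
#'
#' The multi-task weighting: chimera 1.0, state 0.8, time 0.5, physics
#' 0.03, structure 0.02; focal parameters gamma 2, alpha 0.7; label
#' smoothing 0.1; Huber knot 5 minutes. \code{lambdaDiv} (community-size
#' diversity inside the structure loss) defaults to 0.1 and, unlike the
#' others, is a package choice with no literature value.
#' \code{entropySign} switches the sign of the diversity term: +1 follows
#' the printed formula (entropy penalized), -1 the accompanying prose
#' (entropy encouraged); see the methods vignette for the ambiguity.
#'
#' @param lambdaChimera,lambdaState,lambdaTime,lambdaPhysics,lambdaStructure
#'   task weights.
#' @param lambdaDiv diversity weight inside the structure loss.
#' @param focalGamma,focalAlpha focal-loss parameters.
#' @param smoothingEps label-smoothing mass.
#' @param huberDelta Huber knot in minutes.
#' @param entropySign +1 or -1 (see above).
#' @return named list of weights.
#' @export
lossWeights <- function(lambdaChimera = 1.0, lambdaState = 0.8,
                        lambdaTime = 0.5, lambdaPhysics = 0.03,
                        lambdaStructure = 0.02, lambdaDiv = 0.1,
                        focalGamma = 2, focalAlpha = 0.7,
                        smoothingEps = 0.1, huberDelta = 5.0,
                        entropySign = 1) {
  w <- list(lambdaChimera = lambdaChimera, lambdaState = lambdaState,
            lambdaTime = lambdaTime, lambdaPhysics = lambdaPhysics,
            lambdaStructure = lambdaStructure, lambdaDiv = lambdaDiv,
            focalGamma = focalGamma, focalAlpha = focalAlpha,
            smoothingEps = smoothingEps, huberDelta = huberDelta,
            entropySign = entropySign)
  if (any(unlist(w[1:10]) < 0)) stop("weights must be >= 0")
  w
}

#' Alpha-balanced focal loss
#'
#' \eqn{-\alpha (1-p)^\gamma \log p} for positives,
#' \eqn{-(1-\alpha) p^\gamma \log(1-p)} for negatives, averaged over the
#' batch. Probabilities are clamped at 1e-7. With \eqn{\gamma = 0} and
#' \eqn{\alpha = 0.5} this is half the binary cross-entropy.
#'
#' @param p predicted probabilities in (0, 1).
#' @param y binary labels (0/1).
#' @param gamma focusing exponent (default 2).
#' @param alpha positive-class weight (default 0.7).
#' @return mean loss value.
#' @examples
#' focalLoss(0.5, 1)  # 0.7 * 0.25 * log(2)
#' @export
focalLoss <- function(p, y, gamma = 2, alpha = 0.7) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  l <- ifelse(y == 1, -alpha * (1 - p)^gamma * log(p),
              -(1 - alpha) * p^gamma * log(1 - p))
  mean(l)
}

#' Label-smoothed cross-entropy for the 4-state task
#'
#' Cross-entropy against the smoothed target (1 - eps on the true class,
#' eps/3 on each other class), averaged over rows.
#'
#' @param probs probability matrix (rows = windows, 4 columns) or a single
#'   probability vector.
#' @param y integer state labels in 0..3.
#' @param eps smoothing mass (default 0.1).
#' @return mean loss value.
#' @export
stateLoss <- function(probs, y, eps = 0.1) {
  probs <- if (is.matrix(probs)) probs else matrix(probs, nrow = 1)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stop("probs rows must sum to 1")
  K <- ncol(probs)
  Q <- matrix(eps / (K - 1), nrow(probs), K)
  Q[cbind(seq_len(nrow(probs)), y + 1L)] <- 1 - eps
  -mean(rowSums(Q * log(pmax(probs, 1e-12))))
}

#' Huber (smooth L1) time-to-seizure loss
#'
#' \eqn{0.5 e^2 / \delta} for \eqn{|e| \le \delta}, \eqn{|e| - \delta/2}
#' otherwise, with the knot at 5 minutes; averaged over the batch.
#'
#' @param pred predicted minutes (>= 0).
#' @param y target minutes.
#' @param delta knot in minutes (default 5).
#' @return mean loss value.
#' @examples
#' timeLoss(20, 0)  # 17.5
#' @export
timeLoss <- function(pred, y, delta = 5.0) {
  e <- pred - y
  mean(ifelse(abs(e) <= delta, 0.5 * e^2 / delta, abs(e) - delta / 2))
}

#' Kuramoto-consistency physics loss
#'
#' Penalizes the mismatch between finite-difference phase velocities of the
#' per-window phase estimates and the mean-field Kuramoto-Sakaguchi vector
#' field evaluated with the readout's own frequency, coupling and phase-lag
#' estimates:
#' \deqn{(1/C)\sum_i \| d\hat\theta_i/dt - f_{Kuramoto}(\hat\theta_i)\|^2}
#' The derivative uses central circular differences across consecutive
#' windows (differences wrapped to \eqn{(-\pi,\pi]} before dividing by
#' twice the hop), averaged over channels and interior windows.
#'
#' @param readouts either a list of per-window physics readouts (each with
#'   phases, frequencies, couplingK, phaseLagAlpha) or a single list with
#'   matrix-valued fields (rows = windows).
#' @param hop window hop in seconds.
#' @return mean squared residual (rad/s)^2.
#' @export
physicsLoss <- function(readouts, hop) {
  r <- if (!is.null(readouts$phases)) readouts else
    list(phases = do.call(rbind, lapply(readouts, `[[`, "phases")),
         frequencies = do.call(rbind, lapply(readouts, `[[`, "frequencies")),
         couplingK = vapply(readouts, `[[`, numeric(1), "couplingK"),
         phaseLagAlpha = vapply(readouts, `[[`, numeric(1), "phaseLagAlpha"))
  ph <- as.matrix(r$phases)
  W <- nrow(ph); C <- ncol(ph)
  if (W < 3) stop("physics loss needs at least 3 consecutive windows")
  fr <- as.matrix(r$frequencies)
  K <- rep(r$couplingK, length.out = W)
  al <- rep(r$phaseLagAlpha, length.out = W)
  dth <- wrapPhase(ph[3:W, , drop = FALSE] - ph[1:(W - 2), , drop = FALSE]) /
    (2 * hop)
  mid <- 2:(W - 1)
  resid <- matrix(0, length(mid), C)
  for (i in seq_along(mid)) {
    w <- mid[i]
    th <- ph[w, ]
    mf <- colMeans(sin(outer(th, th, "-") - al[w]))  # (1/C) sum_j sin(th_j - th_i - a)
    f <- fr[w, ] + K[w] * mf
    resid[i, ] <- dth[i, ] - f
  }
  mean(resid^2)
}

#' Chimera structure loss
#'
#' \eqn{-|R_{sync} - R_{desync}| + \lambda_{div}\,H(assignments)} where the
#' order parameters belong to the most and least synchronized communities
#' found by spectral clustering on the predicted phases (similarity
#' \eqn{(\cos(\theta_i - \theta_j) + 1)/2}) and \eqn{H} is the Shannon
#' entropy of the community-size proportions. With the printed sign
#' (\code{entropySign = +1}) larger entropy increases the loss; the prose
#' reading is selected with \code{entropySign = -1}.
#'
#' @param phases predicted phase vector (radians).
#' @param assignments optional \linkS4class{ClusterAssignment}; computed by
#'   spectral clustering when absent.
#' @param lambdaDiv diversity weight (default 0.1).
#' @param entropySign +1 (printed formula) or -1.
#' @param k community count when clustering internally.
#' @param seed clustering seed.
#' @return loss value.
#' @examples
#' a <- new("ClusterAssignment", labels = rep(0:1, each = 4), k = 2L,
#'          eigengap = numeric(0))
#' ph <- c(rep(0, 4), c(0, pi / 2, pi, 3 * pi / 2))
#' structureLoss(ph, a)  # -1 + 0.1 * log(2)
#' @export
structureLoss <- function(phases, assignments = NULL, lambdaDiv = 0.1,
                          entropySign = 1, k = 2L, seed = 42L) {
  phases <- as.numeric(phases)
  C <- length(phases)
  if (is.null(assignments)) {
    S <- (cos(outer(phases, phases, "-")) + 1) / 2
    assignments <- tryCatch(spectralClusters(S, k = k, seed = seed),
                            error = function(e) {
                              message("degenerate clustering, using a balanced fallback split")
                              new("ClusterAssignment",
                                  labels = rep(seq_len(k) - 1L, length.out = C),
                                  k = as.integer(k), eigengap = numeric(0))
                            })
  }
  labels <- communityLabels(assignments)
  kk <- assignments@k
  R <- vapply(seq_len(kk) - 1L, function(g)
    orderParameter(phases[labels == g]), numeric(1))
  p <- tabulate(labels + 1L, kk) / C
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  -(max(R) - min(R)) + lambdaDiv * entropySign * H
}

#' Weighted multi-task total loss
#'
#' \eqn{\lambda_{chimera} L_{chimera} + \lambda_{state} L_{state} +
#' \lambda_{time} L_{time} + \lambda_1 L_{physics} + \lambda_2
#' L_{structure}}.
#'
#' @param parts named list/vector with chimera, state, time, physics,
#'   structure components (all finite).
#' @param weights a \code{\link{lossWeights}} list.
#' @return the weighted sum.
#' @examples
#' totalLoss(list(chimera = 1, state = 1, time = 1, physics = 1,
#'                structure = 1))  # 2.35
#' @export
totalLoss <- function(parts, weights = lossWeights()) {
  parts <- unlist(parts)
  need <- c("chimera", "state", "time", "physics", "structure")
  if (!all(need %in% names(parts))) stop("missing loss parts")
  bad <- need[!is.finite(parts[need])]
  if (length(bad)) stop("non-finite loss part: ", paste(bad, collapse = ", "))
  sum(parts[need] * c(weights$lambdaChimera, weights$lambdaState,
                      weights$lambdaTime, weights$lambdaPhysics,
                      weights$lambdaStructure))
}
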