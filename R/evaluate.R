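#' Stratified episode-level cross-validation folds
#'
#' Assigns episodes to disjoint folds, balancing both fold sizes
#' (difference at most one) and total seizure counts across folds (greedy
#' assignment of episodes in decreasing seizure count to the fold with the
#' smallest running total that still has capacity). Deterministic given the
#' seed, which breaks ties.
#'
#' @param seizureCounts integer vector, one entry per episode.
#' @param nFolds fold count (default 4).
#' @param seed tie-breaking seed.
#' @return integer fold assignment (1..nFolds) per episode.
#' @examples
#' table(splitEpisodes(rep(1, 22)))  # sizes 6/6/5/5
#' @export
splitEpisodes <- function(seizureCounts, nFolds = 4L, seed = 42L) {
  n <- length(seizureCounts)
  if (n < nFolds) stop("fewer episodes than folds")
  cap <- rep(floor(n / nFolds), nFolds)
  cap[seq_len(n - sum(cap))] <- cap[seq_len(n - sum(cap))] + 1L
  set.seed(.deriveSeed(seed, 12L))
  ord <- order(-seizureCounts, runif(n))
  fold <- integer(n)
  tot <- numeric(nFolds)
  size <- integer(nFolds)
  for (i in ord) {
    open <- which(size < cap)
    f <- open[order(tot[open], size[open])][1]
    fold[i] <- f
    tot[f] <- tot[f] + seizureCounts[i]
    size[f] <- size[f] + 1L
  }
  fold
}

#' Alarm generation from per-window probabilities
#'
#' An alarm fires at the k-th consecutive window whose probability strictly
#' exceeds the threshold; once fired, further alarms are suppressed until
#' the refractory period has elapsed.
#'
#' @param prob per-window probabilities, time-ordered.
#' @param times per-window times in minutes (window ends on the
#'   uncompressed clock).
#' @param k consecutive supra-threshold windows required (default 2).
#' @param refractory suppression period in minutes (default 30).
#' @param threshold probability threshold (default 0.5).
#' @return numeric vector of alarm times (possibly empty).
#' @export
alarmsFromWindows <- function(prob, times, k = 2L, refractory = 30,
                              threshold = 0.5) {
  stopifnot(length(prob) == length(times), k >= 1, refractory >= 0)
  if (is.unsorted(times)) stop("windows must be time-ordered")
  run <- 0L
  last <- -Inf
  alarms <- numeric(0)
  for (i in seq_along(prob)) {
    run <- if (prob[i] > threshold) run + 1L else 0L
    if (run >= k && times[i] >= last + refractory) {
      alarms <- c(alarms, times[i])
      last <- times[i]
    }
  }
  alarms
}

#' Seizure-prediction metrics from alarms
#'
#' A seizure counts as predicted at horizon H when any alarm falls in
#' \code{[onset - H, onset)} (uncompressed minutes, half-open). False
#' positives are alarms outside all pre-ictal (\code{[onset - 90, onset)})
#' and ictal intervals; alarms during a seizure are neither true nor false
#' positives. The false-positive rate divides by the recording hours
#' outside pre-ictal and ictal time.
#'
#' @param alarms list with one numeric vector of alarm times (minutes) per
#'   episode.
#' @param episodes list with one record per episode: \code{onset},
#'   \code{ictalEnd} and \code{duration} (all minutes); \code{onset} may be
#'   NA for seizure-free records.
#' @param horizons prediction horizons in minutes.
#' @param preictal pre-ictal span in minutes (default 90).
#' @return list with \code{horizonSensitivity} (one fraction per horizon),
#'   \code{fpPerHour}, \code{nSeizures} and \code{nFalsePositives}.
#' @export
predictionMetrics <- function(alarms, episodes, horizons = c(30, 60, 90),
                              preictal = 90) {
  stopifnot(length(alarms) == length(episodes))
  hits <- matrix(0, length(episodes), length(horizons))
  nSeiz <- 0L
  fp <- 0L
  elig <- 0
  for (i in seq_along(episodes)) {
    e <- episodes[[i]]
    a <- alarms[[i]]
    hasSeiz <- !is.na(e$onset)
    if (hasSeiz) {
      nSeiz <- nSeiz + 1L
      for (h in seq_along(horizons))
        hits[i, h] <- any(a >= e$onset - horizons[h] & a < e$onset)
      pre <- c(max(0, e$onset - preictal), e$onset)
      ict <- c(e$onset, e$ictalEnd)
      fp <- fp + sum(a < pre[1] | a >= ict[2])
      elig <- elig + e$duration - (pre[2] - pre[1]) - (ict[2] - ict[1])
    } else {
      fp <- fp + length(a)
      elig <- elig + e$duration
    }
  }
  if (elig <= 0) stop("zero eligible recording time")
  list(horizonSensitivity = if (nSeiz > 0)
         stats::setNames(colSums(hits) / nSeiz, paste0("H", horizons)) else
         stats::setNames(rep(NA_real_, length(horizons)),
                         paste0("H", horizons)),
       fpPerHour = fp / (elig / 60), nSeizures = nSeiz,
       nFalsePositives = fp)
}

#' Binary classification metrics
#'
#' Confusion-matrix metrics at the 0.5 threshold plus rank-based AUC-ROC
#' (Mann-Whitney statistic) and AUC-PR (precision steps at each recalled
#' positive). With single-class labels the AUCs are undefined and reported
#' NA with a message.
#'
#' @param prob predicted probabilities (or scores).
#' @param labels binary labels (0/1).
#' @param threshold decision threshold (default 0.5).
#' @return list with accuracy, sensitivity, specificity, precision, f1,
#'   aucROC, aucPR and the confusion counts.
#' @export
classificationMetrics <- function(prob, labels, threshold = 0.5) {
  stopifnot(length(prob) == length(labels), length(prob) > 0)
  pred <- as.integer(prob > threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  fp <- sum(pred == 1 & labels == 0); tn <- sum(pred == 0 & labels == 0)
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0) {
    message("single-class labels: AUC undefined")
    aucROC <- aucPR <- NA_real_
  } else {
    r <- rank(prob)
    aucROC <- (sum(r[labels == 1]) - pos * (pos + 1) / 2) / (pos * neg)
    ord <- order(-prob)
    lo <- labels[ord]
    cumTP <- cumsum(lo == 1)
    prec <- cumTP / seq_along(lo)
    aucPR <- sum(prec[lo == 1]) / pos
  }
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = if (pos > 0) tp / pos else NA_real_,
       specificity = if (neg > 0) tn / neg else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else
         NA_real_,
       aucROC = aucROC, aucPR = aucPR,
       confusion = c(tp = tp, fn = fn, fp = fp, tn = tn))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the per-unit (per-episode) metric values with replacement and
#' returns the percentile interval of the resampled means. Deterministic
#' given the seed.
#'
#' @param values numeric metric values, one per unit (>= 2).
#' @param nBoot bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed resampling seed.
#' @return c(low, high).
#' @export
bootstrapCI <- function(values, nBoot = 1000L, level = 0.95, seed = 42L) {
  n <- length(values)
  if (n < 2) stop("need at least 2 units")
  set.seed(.deriveSeed(seed, 13L))
  stat <- vapply(seq_len(nBoot), function(b)
    mean(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  unname(quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{(p_o - p_e) / (1 - p_e)} with
#' marginal-product chance agreement. Undefined (NA, with a message) when
#' the expected agreement is 1.
#'
#' @param a,b equal-length label vectors (>= 2 items).
#' @return kappa in [-1, 1], or NA when undefined.
#' @examples
#' cohensKappa(c(1, 1, 0, 0), c(1, 1, 0, 0))  # 1
#' @export
cohensKappa <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need two equal-length label vectors with >= 2 items")
  lev <- union(unique(a), unique(b))
  ta <- factor(a, levels = lev)
  tb <- factor(b, levels = lev)
  n <- length(a)
  po <- mean(ta == tb)
  pe <- sum((table(ta) / n) * (table(tb) / n))
  if (abs(1 - pe) < 1e-12) {
    message("expected agreement is 1: kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Evaluate a trained model on held-out episodes
#'
#' Computes window-level chimera detection metrics, state accuracy,
#' time-regression MAE, alarm-based horizon sensitivity and FP/hr (on the
#' uncompressed clinical clock), and per-episode bootstrap confidence
#' intervals for chimera accuracy.
#'
#' @param model a trained model.
#' @param inputsList held-out episode inputs
#'   (\code{\link{buildModelInputs}}).
#' @param episodes the matching \linkS4class{LabeledEpisode} objects (for
#'   onset times and durations).
#' @param k,refractory,threshold alarm policy
#'   (\code{\link{alarmsFromWindows}}).
#' @param nBoot bootstrap resamples for the CI.
#' @param seed bootstrap seed.
#' @return list with \code{chimera} (classification metrics),
#'   \code{stateAccuracy}, \code{timeMAE}, \code{prediction}
#'   (horizon sensitivity and FP/hr), \code{accuracyCI} and the per-episode
#'   accuracy vector.
#' @export
evaluateModel <- function(model, inputsList, episodes, k = 2L,
                          refractory = 30, threshold = 0.5, nBoot = 1000L,
                          seed = 42L) {
  stopifnot(length(inputsList) == length(episodes))
  probs <- labs <- states <- statePred <- times <- timePred <- numeric(0)
  accPer <- numeric(length(inputsList))
  alarms <- vector("list", length(inputsList))
  epRec <- vector("list", length(inputsList))
  for (i in seq_along(inputsList)) {
    vi <- inputsList[[i]]
    pr <- predictEpisode(model, vi)
    wl <- vi$labels
    probs <- c(probs, pr$pChimera); labs <- c(labs, wl$ychimera)
    states <- c(states, wl$ystate); statePred <- c(statePred, pr$state)
    times <- c(times, wl$ytime); timePred <- c(timePred, pr$timeEstimate)
    accPer[i] <- mean((pr$pChimera > threshold) == wl$ychimera)
    ep <- episodes[[i]]
    comp <- ep@spec@timeCompression / 60      # simulated s -> clinical min
    alarms[[i]] <- alarmsFromWindows(pr$pState1, wl$end * comp, k = k,
                                     refractory = refractory,
                                     threshold = threshold)
    epRec[[i]] <- list(onset = ep@onsetTime * comp,
                       ictalEnd = unname(ep@segmentBoundaries["postictal"]) *
                         comp,
                       duration = unname(ep@segmentBoundaries["end"]) * comp)
  }
  list(chimera = classificationMetrics(probs, labs, threshold),
       stateAccuracy = mean(statePred == states),
       timeMAE = mean(abs(timePred - times)),
       prediction = predictionMetrics(alarms, epRec),
       accuracyCI = if (length(accPer) >= 2)
         bootstrapCI(accPer, nBoot = nBoot, seed = seed) else c(NA, NA),
       episodeAccuracy = accPer)
}
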