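#' Training configuration
#'
#' Two-stage optimization settings: AdamW with main learning rate 3e-4 and
#' physics-module learning rate fixed at 0.1 x main (3e-5), weight decay
#' 0.01, cosine-annealing schedule, gradient clipping at norm 1.0, early
#' stopping on validation chimera accuracy with patience 15. Each
#' optimization step processes one episode (about 40-80 windows, matching
#' the reference batch order of magnitude). Pretraining (masked-node
#' reconstruction, mask rate 15\%, learning rate 1e-3) is off by default at
#' desk scale.
#'
#' @param lrMain main learning rate.
#' @param weightDecay AdamW weight decay.
#' @param maxEpochs supervised epoch budget (desk default 30; 100 at paper
#'   scale).
#' @param patience early-stopping patience in epochs.
#' @param gradClip maximum global gradient norm.
#' @param pretrainEpochs masked-pretraining epochs (0 disables).
#' @param maskRate node masking rate for pretraining.
#' @param lrPretrain pretraining learning rate.
#' @param seed integer seed controlling init, shuffling and dropout.
#' @return config list; \code{lrPhysics} is always \code{0.1 * lrMain}.
#' @export
trainConfig <- function(lrMain = 3e-4, weightDecay = 0.01, maxEpochs = 30L,
                        patience = 15L, gradClip = 1.0, pretrainEpochs = 0L,
                        maskRate = 0.15, lrPretrain = 1e-3, seed = 42L) {
  list(lrMain = lrMain, lrPhysics = 0.1 * lrMain, weightDecay = weightDecay,
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       gradClip = gradClip, pretrainEpochs = as.integer(pretrainEpochs),
       maskRate = maskRate, lrPretrain = lrPretrain, seed = as.integer(seed))
}

#' Cosine-annealed learning rate
#'
#' \eqn{lr(t) = lr_{max} (1 + \cos(\pi t / T)) / 2}; at half the budget the
#' rate is exactly half the maximum.
#'
#' @param epoch current epoch (1-based).
#' @param maxEpochs schedule length.
#' @param lrMax peak rate.
#' @return the annealed rate.
#' @export
cosineLR <- function(epoch, maxEpochs, lrMax) {
  lrMax * (1 + cos(pi * (epoch - 1) / maxEpochs)) / 2
}

# Early-stopping rule: stop after `patience` consecutive epochs without a
# strict improvement over the running best. Returns the stopping epoch, or
# NA if training runs to the end of the sequence.
.stopEpoch <- function(accSeq, patience) {
  best <- -Inf
  for (i in seq_along(accSeq)) {
    if (accSeq[i] > best + 1e-12) {
      best <- accSeq[i]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(i)
    }
  }
  NA_integer_
}

# AdamW with two parameter groups (physics head at 0.1 x main rate) and
# global gradient-norm clipping
.adamwInit <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

.adamwStep <- function(opt, params, grads, lr, lrPhysics, weightDecay,
                       gradClip, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g)
    if (is.null(g)) 0 else sum(g^2), numeric(1))))
  scale <- if (gradClip > 0 && gn > gradClip) gradClip / gn else 1
  opt$t <- opt$t + 1L
  b1c <- 1 - beta1^opt$t
  b2c <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g * scale
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    rate <- if (startsWith(nm, "phys.")) lrPhysics else lr
    params[[nm]] <- params[[nm]] -
      rate * ((opt$m[[nm]] / b1c) / (sqrt(opt$v[[nm]] / b2c) + eps) +
                weightDecay * params[[nm]])
  }
  list(opt = opt, params = params, gradNorm = gn, clipped = scale < 1)
}

# differentiable supervised loss for one episode
.episodeLossAD <- function(model, inputs, tape, weights, train = TRUE) {
  out <- .forwardAD(model, inputs, tape, train = train)
  wl <- inputs$labels
  W <- inputs$W
  # focal chimera loss
  p <- out$pChimera
  pc <- adAddConst(adScale(p, 1 - 2e-7, tape), 1e-7, tape)
  omp <- adScale(adAddConst(pc, -1, tape), -1, tape)
  lp <- adLog(pc, tape)
  lomp <- adLog(omp, tape)
  g <- weights$focalGamma
  powP <- if (g == 2) adMul(pc, pc, tape) else adExp(adScale(lp, g, tape), tape)
  powOmp <- if (g == 2) adMul(omp, omp, tape) else
    adExp(adScale(lomp, g, tape), tape)
  ymask <- matrix(wl$ychimera, ncol = 1)
  posTerm <- adScale(adMul(powOmp, lp, tape), -weights$focalAlpha, tape)
  negTerm <- adScale(adMul(powP, lomp, tape), -(1 - weights$focalAlpha), tape)
  lch <- adMean(adAdd(adMul(posTerm, adInput(tape, ymask), tape),
                      adMul(negTerm, adInput(tape, 1 - ymask), tape), tape),
                tape)
  # smoothed cross-entropy state loss
  eps <- weights$smoothingEps
  Q <- matrix(eps / 3, W, 4)
  Q[cbind(seq_len(W), wl$ystate + 1L)] <- 1 - eps
  lst <- adScale(adSum(adMul(adLog(out$stateProbs, tape),
                             adInput(tape, Q), tape), tape), -1 / W, tape)
  # Huber time loss
  lti <- adHuber(out$timeEst, wl$ytime, weights$huberDelta, tape)
  # physics + structure losses on the per-window readouts
  lph <- .physicsLossAD(out, inputs$hop, tape)
  lstr <- adStructureLoss(out$phases, tape, lambdaDiv = weights$lambdaDiv,
                          entropySign = weights$entropySign)
  total <- adAdd(adAdd(adScale(lch, weights$lambdaChimera, tape),
                       adScale(lst, weights$lambdaState, tape), tape),
                 adAdd(adScale(lti, weights$lambdaTime, tape),
                       adAdd(adScale(lph, weights$lambdaPhysics, tape),
                             adScale(lstr, weights$lambdaStructure, tape),
                             tape), tape), tape)
  list(total = total, out = out,
       parts = c(chimera = lch$val[1], state = lst$val[1], time = lti$val[1],
                 physics = lph$val[1], structure = lstr$val[1]))
}

# Kuramoto-consistency loss as tape operations
.physicsLossAD <- function(out, hop, tape) {
  W <- nrow(out$phases$val)
  if (W < 3) return(adInput(tape, matrix(0, 1, 1)))
  C <- ncol(out$phases$val)
  ph <- out$phases
  dth <- adScale(adWrap(adSub(adRowsel(ph, 3:W, tape),
                              adRowsel(ph, 1:(W - 2), tape), tape), tape),
                 1 / (2 * hop), tape)
  mid <- 2:(W - 1)
  thm <- adRowsel(ph, mid, tape)
  alm <- adRowsel(out$alpha, mid, tape)
  A <- adAddColvec(thm, alm, tape)                 # theta_i + alpha per row
  S <- adRowMeans(adSin(thm, tape), tape)          # mean_j sin(theta_j)
  Cc <- adRowMeans(adCos(thm, tape), tape)
  mf <- adSub(adMulCol(adCos(A, tape), S, tape),
              adMulCol(adSin(A, tape), Cc, tape), tape)
  f <- adAdd(adRowsel(out$freqs, mid, tape),
             adMulCol(mf, adRowsel(out$K, mid, tape), tape), tape)
  resid <- adSub(dth, f, tape)
  adMean(adMul(resid, resid, tape), tape)
}

#' Masked-node pretraining loss
#'
#' Self-supervised objective: mask \code{ceiling(C * maskRate)} nodes per
#' window (their input features replaced by a learned mask token), run the
#' hypergraph encoder, and reconstruct (a) the masked nodes' feature
#' vectors (mean squared error) and (b) their rows of the thresholded
#' adjacency (binary cross-entropy); the loss is the sum.
#'
#' @param model a model from \code{\link{initChimeraNet}}.
#' @param inputs episode inputs from \code{\link{buildModelInputs}}.
#' @param maskRate node masking fraction (default 0.15).
#' @param seed mask-draw seed.
#' @param gradient also return parameter gradients.
#' @return list with \code{loss} and the \code{mse}/\code{bce} parts (and
#'   \code{grads} when requested).
#' @export
pretrainStep <- function(model, inputs, maskRate = 0.15, seed = 42L,
                         gradient = FALSE) {
  C <- inputs$C; W <- inputs$W
  nMask <- as.integer(ceiling(C * maskRate))
  if (nMask < 1) stop("maskRate too small: no nodes masked")
  if (nMask >= C) stop("mask would cover all nodes")
  set.seed(.deriveSeed(seed, 11L))
  maskIdx <- unlist(lapply(seq_len(W) - 1L, function(w)
    w * C + sample.int(C, nMask)))
  Xn <- .normFeatures(model, inputs$X)
  Xmasked <- Xn
  Xmasked[maskIdx, ] <- 0
  maskCol <- matrix(0, nrow(Xn), 1)
  maskCol[maskIdx, 1] <- 1
  tape <- adTape()
  pn <- lapply(model$params, function(x) adInput(tape, x))
  H0 <- adAdd(adInput(tape, Xmasked),
              adMatmul(adInput(tape, maskCol), pn[["pre.maskTok"]], tape),
              tape)
  H <- .convStackAD(model, pn, H0, inputs, tape, train = FALSE)
  Hm <- adRowsel(H, maskIdx, tape)
  featPred <- adAddBias(adMatmul(Hm, pn[["pre.recW"]], tape),
                        pn[["pre.recb"]], tape)
  dfe <- adSub(featPred, adInput(tape, Xn[maskIdx, , drop = FALSE]), tape)
  mse <- adMean(adMul(dfe, dfe, tape), tape)
  adjT <- do.call(rbind, lapply(seq_len(W), function(w) {
    rows <- maskIdx[maskIdx > (w - 1) * C & maskIdx <= w * C] - (w - 1) * C
    inputs$adjBin[[w]][rows, , drop = FALSE]
  }))
  adjLogits <- adAddBias(adMatmul(Hm, pn[["pre.adjW"]], tape),
                         pn[["pre.adjb"]], tape)
  bce <- adBCElogits(adjLogits, adjT, tape)
  loss <- adAdd(mse, bce, tape)
  res <- list(loss = loss$val[1], mse = mse$val[1], bce = bce$val[1],
              nMasked = nMask)
  if (gradient) {
    adBackward(tape, loss)
    res$grads <- lapply(pn, function(n) n$grad)
  }
  res
}

#' Train the hypergraph-convolution state-space model
#'
#' Optional masked pretraining followed by supervised multi-task training:
#' AdamW with two parameter groups (the physics heads at 0.1 x the main
#' rate), cosine-annealed learning rate, global gradient clipping at norm
#' 1.0, and early stopping on validation window-level chimera accuracy with
#' the configured patience. Each step processes one episode. Feature
#' normalization statistics are computed from the training episodes and
#' stored in the model. Fully reproducible given the config seed.
#'
#' @param trainInputs list of episode inputs (\code{\link{buildModelInputs}}).
#' @param valInputs held-out episode inputs for early stopping (non-empty).
#' @param config a \code{\link{modelConfig}}.
#' @param cfg a \code{\link{trainConfig}}.
#' @param weights a \code{\link{lossWeights}}; set
#'   \code{lambdaPhysics = lambdaStructure = 0} for the no-physics
#'   ablation.
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (best-validation checkpoint),
#'   \code{history} (per-epoch loss parts, validation accuracy, learning
#'   rate, clip engagement), \code{bestEpoch} and \code{valAccuracy}.
#' @export
trainChimeraNet <- function(trainInputs, valInputs, config = modelConfig(),
                       cfg = trainConfig(), weights = lossWeights(),
                       verbose = FALSE) {
  if (!length(valInputs)) stop("validation set must be non-empty")
  model <- initChimeraNet(config, seed = cfg$seed)
  allX <- do.call(rbind, lapply(trainInputs, `[[`, "X"))
  model$featNorm <- list(mean = colMeans(allX),
                         sd = pmax(apply(allX, 2, sd), 1e-6))
  opt <- .adamwInit(model$params)
  if (cfg$pretrainEpochs > 0) {
    for (ep in seq_len(cfg$pretrainEpochs)) {
      set.seed(.deriveSeed(cfg$seed, 100L + ep))
      for (i in sample(seq_along(trainInputs))) {
        st <- pretrainStep(model, trainInputs[[i]], maskRate = cfg$maskRate,
                           seed = .deriveSeed(cfg$seed, 200L + ep * 997L + i),
                           gradient = TRUE)
        up <- .adamwStep(opt, model$params, st$grads,
                         cosineLR(ep, cfg$pretrainEpochs, cfg$lrPretrain),
                         cosineLR(ep, cfg$pretrainEpochs, cfg$lrPretrain),
                         cfg$weightDecay, cfg$gradClip)
        opt <- up$opt; model$params <- up$params
      }
    }
    opt <- .adamwInit(model$params)     # fresh optimizer for fine-tuning
  }
  best <- list(acc = -Inf, params = model$params, bn = NULL, epoch = 0L)
  hist <- list()
  for (ep in seq_len(cfg$maxEpochs)) {
    lr <- cosineLR(ep, cfg$maxEpochs, cfg$lrMain)
    lrP <- cosineLR(ep, cfg$maxEpochs, cfg$lrPhysics)
    set.seed(.deriveSeed(cfg$seed, 300L + ep))
    ord <- sample(seq_along(trainInputs))
    parts <- numeric(5)
    nclip <- 0L
    for (i in ord) {
      tape <- adTape()
      le <- .episodeLossAD(model, trainInputs[[i]], tape, weights,
                           train = TRUE)
      adBackward(tape, le$total)
      grads <- lapply(le$out$paramNodes, function(n) n$grad)
      up <- .adamwStep(opt, model$params, grads, lr, lrP, cfg$weightDecay,
                       cfg$gradClip)
      opt <- up$opt; model$params <- up$params
      nclip <- nclip + up$clipped
      parts <- parts + le$parts
    }
    parts <- parts / length(trainInputs)
    acc <- mean(vapply(valInputs, function(vi) {
      pred <- predictEpisode(model, vi)
      mean((pred$pChimera > 0.5) == vi$labels$ychimera)
    }, numeric(1)))
    hist[[ep]] <- c(epoch = ep, chimera = parts[1], state = parts[2],
                    time = parts[3], physics = parts[4],
                    structure = parts[5], valAccuracy = acc, lr = lr,
                    clipFrac = nclip / length(trainInputs))
    if (verbose)
      message(sprintf("epoch %d: loss parts %.3f/%.3f/%.3f val acc %.3f",
                      ep, parts[1], parts[2], parts[3], acc))
    if (acc > best$acc + 1e-12) {
      best <- list(acc = acc, params = model$params,
                   bn = lapply(model$bn, function(e)
                     list(mean = e$mean, var = e$var)), epoch = ep)
    }
    accSeq <- vapply(hist, `[[`, numeric(1), "valAccuracy")
    if (!is.na(.stopEpoch(accSeq, cfg$patience))) break
  }
  model$params <- best$params
  if (!is.null(best$bn))
    for (nm in names(best$bn)) {
      model$bn[[nm]]$mean <- best$bn[[nm]]$mean
      model$bn[[nm]]$var <- best$bn[[nm]]$var
    }
  list(model = model, history = as.data.frame(do.call(rbind, hist)),
       bestEpoch = best$epoch, valAccuracy = best$acc)
}
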