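#' Model configuration
#'
#' Architecture hyperparameters for the hypergraph-convolution +
#' selective-state-space network. The desk-scale defaults (two convolution
#' layers 16 -> 32, two state-space blocks of dimension 32) train on a CPU
#' in minutes; \code{fullScale = TRUE} selects the full-size architecture
#' (64 -> 128 -> 256 convolutions, state dimension 256, 4 blocks, 128-wide
#' heads).
#'
#' @param nChannels channel count C.
#' @param nFeatures per-node input features (9 signal features plus node
#'   strength and hyperedge participation).
#' @param convDims hypergraph-convolution output dimensions.
#' @param attnHidden hidden width of the hyperedge attention scorer.
#' @param nBlocks number of state-space blocks.
#' @param headHidden hidden width of the chimera/time heads; the state head
#'   uses \code{c(headHidden, headHidden %/% 2)}.
#' @param dropout dropout probability (train mode).
#' @param tau hyperedge detection threshold.
#' @param fullScale use the full-size architecture.
#' @return a config list.
#' @export
modelConfig <- function(nChannels = 23L, nFeatures = 11L,
                        convDims = c(16L, 32L), attnHidden = 8L,
                        nBlocks = 2L, headHidden = 16L, dropout = 0.3,
                        tau = 0.65, fullScale = FALSE) {
  if (fullScale) {
    convDims <- c(64L, 128L, 256L); attnHidden <- 32L
    nBlocks <- 4L; headHidden <- 128L
  }
  list(nChannels = as.integer(nChannels), nFeatures = as.integer(nFeatures),
       convDims = as.integer(convDims), attnHidden = as.integer(attnHidden),
       stateDim = as.integer(convDims[length(convDims)]),
       nBlocks = as.integer(nBlocks), headHidden = as.integer(headHidden),
       dropout = dropout, tau = tau)
}

.glorot <- function(din, dout)
  matrix(runif(din * dout, -1, 1) * sqrt(6 / (din + dout)), din, dout)

#' Initialize model parameters
#'
#' Builds the full parameter set: hypergraph-convolution layers with
#' hyperedge attention scorers, layer norms and residual projections;
#' state-space blocks with input-dependent diagonal state matrices; the
#' three prediction heads (with batch-norm state); the physics extraction
#' heads, whose biases are set so that freshly initialized outputs sit near
#' the theoretical chimera operating point (K about 0.7, phase lag about
#' pi/6); and the masked-pretraining reconstruction heads.
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed integer seed.
#' @return a model object (list with \code{params}, \code{bn} running
#'   statistics, \code{config}).
#' @export
initChimeraNet <- function(config = modelConfig(), seed = 42L) {
  set.seed(.deriveSeed(seed, 8L))
  p <- list()
  din <- config$nFeatures
  for (l in seq_along(config$convDims)) {
    dout <- config$convDims[l]
    p[[paste0("conv", l, ".W")]] <- .glorot(2 * din, dout)
    p[[paste0("conv", l, ".b")]] <- matrix(0, 1, dout)
    p[[paste0("conv", l, ".attW1")]] <- .glorot(din, config$attnHidden)
    p[[paste0("conv", l, ".attb1")]] <- matrix(0, 1, config$attnHidden)
    p[[paste0("conv", l, ".attW2")]] <- .glorot(config$attnHidden, 1)
    p[[paste0("conv", l, ".attb2")]] <- matrix(0, 1, 1)
    p[[paste0("conv", l, ".lnG")]] <- matrix(1, 1, dout)
    p[[paste0("conv", l, ".lnB")]] <- matrix(0, 1, dout)
    if (din != dout) p[[paste0("conv", l, ".res")]] <- .glorot(din, dout)
    din <- dout
  }
  d <- config$stateDim
  for (k in seq_len(config$nBlocks)) {
    for (w in c("Wa", "Wb", "Wc", "Wd"))
      p[[paste0("ssm", k, ".", w)]] <- .glorot(d, d) * 0.5
    p[[paste0("ssm", k, ".ba")]] <- matrix(0.5, 1, d)
    p[[paste0("ssm", k, ".bb")]] <- matrix(0, 1, d)
    p[[paste0("ssm", k, ".bc")]] <- matrix(1, 1, d)
    p[[paste0("ssm", k, ".bd")]] <- matrix(1, 1, d)
    p[[paste0("ssm", k, ".logDelta")]] <- matrix(log(0.01), 1, 1)
    p[[paste0("ssm", k, ".lnG")]] <- matrix(1, 1, d)
    p[[paste0("ssm", k, ".lnB")]] <- matrix(0, 1, d)
  }
  hh <- config$headHidden
  head <- function(name, dims) {
    din <- d
    for (i in seq_along(dims)) {
      p[[paste0(name, ".W", i)]] <<- .glorot(din, dims[i])
      p[[paste0(name, ".b", i)]] <<- matrix(0, 1, dims[i])
      din <- dims[i]
    }
  }
  head("chimera", c(hh, 1L))
  head("state", c(hh, max(hh %/% 2L, 4L), 4L))
  head("time", c(hh, 1L))
  p[["chimera.bnG"]] <- matrix(1, 1, hh); p[["chimera.bnB"]] <- matrix(0, 1, hh)
  p[["state.bnG"]] <- matrix(1, 1, hh); p[["state.bnB"]] <- matrix(0, 1, hh)
  p[["time.bnG"]] <- matrix(1, 1, hh); p[["time.bnB"]] <- matrix(0, 1, hh)
  # positive output bias keeps the ReLU regression head alive at init
  p[["time.b2"]] <- matrix(10, 1, 1)
  C <- config$nChannels
  p[["phys.phW"]] <- .glorot(d, C) * 0.1; p[["phys.phb"]] <- matrix(0, 1, C)
  # frequencies start near the drift scale resolvable by wrapped
  # window-to-window phase differences (well under pi per 2 hops)
  p[["phys.frW"]] <- .glorot(d, C) * 0.1; p[["phys.frb"]] <- matrix(-1.2, 1, C)
  p[["phys.kW"]] <- .glorot(d, 1) * 0.1
  p[["phys.kb"]] <- matrix(log(0.7 / 0.3), 1, 1)       # sigmoid -> 0.7
  p[["phys.aW"]] <- .glorot(d, 1) * 0.1
  p[["phys.ab"]] <- matrix(log((1 / 3) / (2 / 3)), 1, 1) # (pi/2) sigmoid -> pi/6
  p[["pre.maskTok"]] <- matrix(0, 1, config$nFeatures)
  p[["pre.recW"]] <- .glorot(config$stateDim, config$nFeatures)
  p[["pre.recb"]] <- matrix(0, 1, config$nFeatures)
  p[["pre.adjW"]] <- .glorot(config$stateDim, C)
  p[["pre.adjb"]] <- matrix(0, 1, C)
  bn <- list()
  for (nm in c("chimera", "state", "time")) {
    e <- new.env(parent = emptyenv())
    e$mean <- numeric(hh); e$var <- rep(1, hh)
    bn[[nm]] <- e
  }
  list(params = p, bn = bn, config = config,
       featNorm = list(mean = numeric(config$nFeatures),
                       sd = rep(1, config$nFeatures)))
}

#' Build model inputs from a labelled episode
#'
#' Runs the analysis pipeline once per episode: Hilbert phases, windowed PLV,
#' per-window channel features, identity-refined adjacency and 3-clique
#' hypergraphs. Node features are the 9 signal features plus two structural
#' ones (node strength = mean adjacency to other channels, and normalized
#' hyperedge participation). All windows of the episode are stacked into one
#' node-feature matrix with a block-diagonal hyperedge structure so a full
#' episode is a single forward pass.
#'
#' @param episode a \linkS4class{LabeledEpisode}.
#' @param tau hyperedge threshold (default 0.65).
#' @param pairwiseOnly build 2-node edges instead of 3-clique hyperedges
#'   (the pairwise-graph ablation).
#' @return list with the stacked features, pooling/incidence structures,
#'   window labels and bookkeeping, consumed by the training and prediction
#'   functions.
#' @export
buildModelInputs <- function(episode, tau = 0.65, pairwiseOnly = FALSE) {
  stopifnot(is(episode, "LabeledEpisode"))
  sig <- episode@signal
  C <- nChannels(sig)
  ph <- analyticPhase(sig)
  total <- ncol(sig@data) / sig@samplingRate
  plan <- windowPlan(total)
  plvs <- plvMatrices(ph, plan)
  W <- length(plvs)
  feats <- matrix(0, W * C, 11L)
  adjBin <- vector("list", W)
  eOff <- 0L
  pairs <- list()
  for (w in seq_len(W)) {
    fw <- channelFeatures(sig, window = plan@boundaries[w, ])
    A <- refineAdjacency(fw, plvs[[w]])
    adjBin[[w]] <- (A > tau) * 1
    strength <- (rowSums(A) - diag(A)) / (C - 1)
    if (pairwiseOnly) {
      idx <- which(upper.tri(A) & A > tau, arr.ind = TRUE)
      deg <- tabulate(c(idx), C) / (C - 1)
      mem <- if (nrow(idx)) cbind(edge = rep(seq_len(nrow(idx)), 2),
                                  node = c(idx[, 1], idx[, 2])) else
        cbind(edge = integer(0), node = integer(0))
      nm <- 2L
    } else {
      hg <- detect3Cliques(A, tau = tau)
      he <- hyperedges(hg)
      deg <- tabulate(c(he), C) / choose(C - 1, 2)
      mem <- if (nrow(he)) cbind(edge = rep(seq_len(nrow(he)), 3),
                                 node = c(he)) else
        cbind(edge = integer(0), node = integer(0))
      nm <- 3L
    }
    feats[(w - 1) * C + seq_len(C), ] <-
      cbind(as.matrix(fw[, 1:9]), strength, deg)
    if (nrow(mem)) {
      pairs[[w]] <- cbind(edge = mem[, "edge"] + eOff,
                          node = mem[, "node"] + (w - 1L) * C)
      eOff <- eOff + max(mem[, "edge"])
    }
  }
  mem <- if (length(pairs)) do.call(rbind, pairs) else
    cbind(edge = integer(0), node = integer(0))
  N <- W * C
  E <- eOff
  poolM <- if (E > 0)
    Matrix::sparseMatrix(i = mem[, "edge"], j = mem[, "node"],
                         x = 1 / nm, dims = c(E, N)) else
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(0, N))
  winM <- Matrix::sparseMatrix(i = rep(seq_len(W), each = C),
                               j = seq_len(N), x = 1 / C, dims = c(W, N))
  np <- nrow(mem)
  Mnp <- Matrix::sparseMatrix(i = mem[, "node"], j = seq_len(np), x = 1,
                              dims = c(N, np))
  Mpe <- Matrix::sparseMatrix(i = seq_len(np), j = mem[, "edge"], x = 1,
                              dims = c(np, max(E, 1L)))
  wl <- windowLabels(episode)
  stopifnot(nrow(wl) == W)
  list(X = feats, poolM = poolM, winM = winM,
       aggPlan = list(node = mem[, "node"], edge = mem[, "edge"], nNodes = N,
                      Mnp = Mnp, Mpe = Mpe),
       W = W, C = C, nEdges = E,
       hop = plan@windowLength * (1 - plan@overlap),
       labels = wl,
       adjBin = adjBin)
}

# normalize node features with the stored training statistics
.normFeatures <- function(model, X) {
  sweep(sweep(X, 2, model$featNorm$mean), 2, model$featNorm$sd, "/")
}

# dropout mask as a constant (inverted dropout)
.dropMask <- function(dim1, dim2, pdrop) {
  matrix((runif(dim1 * dim2) > pdrop) / (1 - pdrop), dim1, dim2)
}

# Full differentiable forward pass over one episode's stacked windows.
# Returns the AD nodes for every output plus the parameter-node map.
.convStackAD <- function(model, pn, H, inputs, tape, train = TRUE) {
  cfg <- model$config
  din <- cfg$nFeatures
  for (l in seq_along(cfg$convDims)) {
    nm <- function(s) pn[[paste0("conv", l, ".", s)]]
    if (inputs$nEdges > 0) {
      P <- adConstmul(inputs$poolM, H, tape)
      s1 <- adTanh(adAddBias(adMatmul(P, nm("attW1"), tape), nm("attb1"),
                             tape), tape)
      sc <- adAddBias(adMatmul(s1, nm("attW2"), tape), nm("attb2"), tape)
      AGG <- adHyperAgg(P, sc, inputs$aggPlan, tape)
    } else {
      AGG <- adInput(tape, matrix(0, nrow(H$val), din))
    }
    lin <- adAddBias(adMatmul(adCbind(H, AGG, tape), nm("W"), tape),
                     nm("b"), tape)
    act <- adElu(lin, tape)
    normd <- adLayerNorm(act, nm("lnG"), nm("lnB"), tape)
    res <- if (din != cfg$convDims[l]) adMatmul(H, nm("res"), tape) else H
    H <- adAdd(normd, res, tape)
    if (train && cfg$dropout > 0)
      H <- adMul(H, adInput(tape, .dropMask(nrow(H$val), ncol(H$val),
                                            cfg$dropout)), tape)
    din <- cfg$convDims[l]
  }
  H
}

.forwardAD <- function(model, inputs, tape, train = TRUE) {
  cfg <- model$config
  pn <- lapply(model$params, function(x) adInput(tape, x))
  H <- adInput(tape, .normFeatures(model, inputs$X))
  H <- .convStackAD(model, pn, H, inputs, tape, train = train)
  z <- adConstmul(inputs$winM, H, tape)
  for (k in seq_len(cfg$nBlocks)) {
    nm <- function(s) pn[[paste0("ssm", k, ".", s)]]
    y <- .ssmBlockAD(z, nm, tape)
    z <- adLayerNorm(adAdd(z, y, tape), nm("lnG"), nm("lnB"), tape)
  }
  heads <- .headsAD(model, pn, z, tape, train = train)
  c(heads, list(z = z, H = H, paramNodes = pn))
}

# Selective state-space block (Eqs of the continuous system discretized by
# zero-order hold with learnable step): diagonal A = -softplus(Wa z + ba),
# input drive v = Wb z + bb, readout y = (Wc z + bc) * h + (Wd z + bd) * z.
.ssmBlockAD <- function(z, nm, tape) {
  a <- adScale(adSoftplus(adAddBias(adMatmul(z, nm("Wa"), tape), nm("ba"),
                                    tape), tape), -1, tape)
  delta <- adExp(nm("logDelta"), tape)
  abar <- adExp(adScalarmul(a, delta, tape), tape)
  v <- adAddBias(adMatmul(z, nm("Wb"), tape), nm("bb"), tape)
  ubar <- adMul(adZohCoef(a, delta, tape), v, tape)
  h <- adScan(abar, ubar, tape)
  cc <- adAddBias(adMatmul(z, nm("Wc"), tape), nm("bc"), tape)
  dd <- adAddBias(adMatmul(z, nm("Wd"), tape), nm("bd"), tape)
  adAdd(adMul(cc, h, tape), adMul(dd, z, tape), tape)
}

.headsAD <- function(model, pn, z, tape, train = TRUE) {
  cfg <- model$config
  drop <- function(x) {
    if (train && cfg$dropout > 0)
      adMul(x, adInput(tape, .dropMask(nrow(x$val), ncol(x$val),
                                       cfg$dropout)), tape)
    else x
  }
  dense <- function(x, name, i) adAddBias(adMatmul(x, pn[[paste0(name, ".W", i)]],
                                                   tape), pn[[paste0(name, ".b", i)]], tape)
  # chimera head: FC -> BN -> ReLU -> dropout -> FC -> sigmoid
  h <- dense(z, "chimera", 1)
  h <- adBatchNorm(h, pn[["chimera.bnG"]], pn[["chimera.bnB"]],
                   model$bn$chimera, train, tape)
  h <- drop(adRelu(h, tape))
  pChimera <- adSigmoid(dense(h, "chimera", 2), tape)
  # state head: FC -> BN -> ReLU -> FC -> ReLU -> dropout -> FC -> softmax
  h <- dense(z, "state", 1)
  h <- adBatchNorm(h, pn[["state.bnG"]], pn[["state.bnB"]], model$bn$state,
                   train, tape)
  h <- adRelu(h, tape)
  h <- drop(adRelu(dense(h, "state", 2), tape))
  stateLogits <- dense(h, "state", 3)
  stateProbs <- adRowSoftmax(stateLogits, tape)
  # time head: FC -> BN -> ReLU -> dropout -> FC -> ReLU
  h <- dense(z, "time", 1)
  h <- adBatchNorm(h, pn[["time.bnG"]], pn[["time.bnB"]], model$bn$time,
                   train, tape)
  h <- drop(adRelu(h, tape))
  timeEst <- adRelu(dense(h, "time", 2), tape)
  # physics readout
  phases <- adScale(adTanh(adAddBias(adMatmul(z, pn[["phys.phW"]], tape),
                                     pn[["phys.phb"]], tape), tape), pi, tape)
  freqs <- adSoftplus(adAddBias(adMatmul(z, pn[["phys.frW"]], tape),
                                pn[["phys.frb"]], tape), tape)
  K <- adSigmoid(adAddBias(adMatmul(z, pn[["phys.kW"]], tape),
                           pn[["phys.kb"]], tape), tape)
  alpha <- adScale(adSigmoid(adAddBias(adMatmul(z, pn[["phys.aW"]], tape),
                                       pn[["phys.ab"]], tape), tape),
                   pi / 2, tape)
  list(pChimera = pChimera, stateProbs = stateProbs, stateLogits = stateLogits,
       timeEst = timeEst, phases = phases, freqs = freqs, K = K,
       alpha = alpha)
}

#' Predict per-window outputs for an episode (evaluation mode)
#'
#' @param model a trained model from \code{\link{initChimeraNet}} /
#'   \code{\link{trainChimeraNet}}.
#' @param inputs episode inputs from \code{\link{buildModelInputs}}.
#' @return data.frame with pChimera, the four state probabilities, state
#'   (argmax), timeEstimate, and the per-window physics readouts K and
#'   alpha.
#' @export
predictEpisode <- function(model, inputs) {
  tape <- adTape()
  out <- .forwardAD(model, inputs, tape, train = FALSE)
  sp <- out$stateProbs$val
  data.frame(pChimera = as.numeric(out$pChimera$val),
             pState0 = sp[, 1], pState1 = sp[, 2], pState2 = sp[, 3],
             pState3 = sp[, 4], state = max.col(sp) - 1L,
             timeEstimate = as.numeric(out$timeEst$val),
             K = as.numeric(out$K$val), alpha = as.numeric(out$alpha$val))
}

# ---------------------------------------------------------------------------
# Stand-alone numeric operations (no tape): the documented building blocks.

#' Single hypergraph-convolution layer (numeric forward)
#'
#' Implements one propagation step
#' \eqn{h_i' = \sigma(W [h_i \,\|\, AGG_i])} with attention-weighted
#' hyperedge aggregation: hyperedge embeddings are mean-pooled members,
#' scored by a two-layer attention net, softmax-normalized over each node's
#' incident hyperedges, and summed. Nodes in no hyperedge aggregate a zero
#' vector. ELU activation, layer normalization and a residual projection
#' follow; dropout applies in train mode only.
#'
#' @param h a \linkS4class{Hypergraph}.
#' @param emb C x d node embedding matrix.
#' @param layer parameter list with W (2d x dout), b, attW1, attb1, attW2,
#'   attb2, lnG, lnB and optional res (d x dout).
#' @param train apply dropout (default FALSE).
#' @param dropout dropout probability.
#' @param seed seed for the dropout mask.
#' @return C x dout matrix of updated node embeddings, with the per-pair
#'   attention weights attached as \code{attr(, "attention")}.
#' @export
hypergraphConv <- function(h, emb, layer, train = FALSE, dropout = 0.3,
                           seed = 42L) {
  stopifnot(is(h, "Hypergraph"))
  emb <- as.matrix(emb)
  C <- length(h@nodes)
  if (nrow(emb) != C) stop("embedding rows must match hypergraph nodes")
  he <- h@hyperedges
  E <- nrow(he)
  if (E > 0) {
    P <- (emb[he[, 1], , drop = FALSE] + emb[he[, 2], , drop = FALSE] +
            emb[he[, 3], , drop = FALSE]) / 3
    s <- drop(tanh(sweep(P %*% layer$attW1, 2, as.numeric(layer$attb1), "+")) %*%
                layer$attW2) + as.numeric(layer$attb2)
    mem <- cbind(edge = rep(seq_len(E), 3), node = c(he))
    sv <- s[mem[, "edge"]]
    mx <- rep(-Inf, C)
    mxa <- tapply(sv, mem[, "node"], max)
    mx[as.integer(names(mxa))] <- mxa
    w <- exp(sv - mx[mem[, "node"]])
    den <- rep(1, C)
    dena <- rowsum(w, mem[, "node"])
    den[as.integer(rownames(dena))] <- dena
    alpha <- w / den[mem[, "node"]]
    AGG <- matrix(0, C, ncol(emb))
    acc <- rowsum(alpha * P[mem[, "edge"], , drop = FALSE], mem[, "node"])
    AGG[as.integer(rownames(acc)), ] <- acc
  } else {
    AGG <- matrix(0, C, ncol(emb))
    alpha <- numeric(0)
    mem <- NULL
  }
  lin <- sweep(cbind(emb, AGG) %*% layer$W, 2, as.numeric(layer$b), "+")
  act <- ifelse(lin > 0, lin, exp(pmin(lin, 30)) - 1)
  mu <- rowMeans(act)
  v <- rowMeans((act - mu)^2)
  xhat <- (act - mu) / sqrt(v + 1e-5)
  out <- sweep(sweep(xhat, 2, as.numeric(layer$lnG), "*"), 2,
               as.numeric(layer$lnB), "+")
  res <- if (!is.null(layer$res)) emb %*% layer$res else emb
  out <- out + res
  if (train && dropout > 0) {
    set.seed(.deriveSeed(seed, 9L))
    out <- out * .dropMask(nrow(out), ncol(out), dropout)
  }
  attr(out, "attention") <- if (!is.null(mem))
    data.frame(node = mem[, "node"], edge = mem[, "edge"], alpha = alpha)
  out
}

#' Selective state-space block (numeric forward)
#'
#' Discrete recurrence obtained from the continuous system
#' \eqn{h'(t) = A(z_t) h(t) + B(z_t) z_t}, \eqn{y(t) = C(z_t) h(t) +
#' D(z_t) z_t} by zero-order hold with step \eqn{\Delta}: all four maps are
#' input-dependent affine functions of \eqn{z_t}; the state matrix is
#' diagonal and parameterized as \eqn{-\mathrm{softplus}(\cdot)} for
#' stability, so \eqn{\bar A = e^{\Delta A}} elementwise and
#' \eqn{\bar B = (\bar A - I) A^{-1} B} (with the small-\eqn{|A|} series
#' fallback). Complexity is linear in the sequence length.
#'
#' @param z T x d input sequence (rows are 5-second windows).
#' @param params block parameters (Wa, ba, Wb, bb, Wc, bc, Wd, bd,
#'   logDelta).
#' @param method "scan" for the doubling parallel prefix scan, "naive" for
#'   the step-by-step recurrence (the reference implementation).
#' @return T x d output sequence y.
#' @export
mambaBlock <- function(z, params, method = c("scan", "naive")) {
  method <- match.arg(method)
  z <- as.matrix(z)
  if (nrow(z) < 1) stop("need a sequence of length >= 1")
  aff <- function(W, b) sweep(z %*% W, 2, as.numeric(b), "+")
  a <- -log1p(exp(pmin(aff(params$Wa, params$ba), 30)))
  a[a > -1e-12] <- -1e-12
  delta <- exp(params$logDelta[1])
  abar <- exp(a * delta)
  x <- a * delta
  coef <- ifelse(abs(x) < 1e-4, delta * (1 + x / 2), expm1(x) / a)
  u <- coef * aff(params$Wb, params$bb)
  Tn <- nrow(z)
  if (!all(is.finite(u)) || !all(is.finite(abar)))
    stop("non-finite state-space parameters at step ",
         which(!is.finite(rowSums(u) + rowSums(abar)))[1])
  if (method == "naive") {
    h <- u
    for (t in seq_len(Tn)[-1]) h[t, ] <- abar[t, ] * h[t - 1, ] + u[t, ]
  } else {
    # Blelloch-style doubling scan on the associative pairs (a, u)
    A <- abar; h <- u
    off <- 1L
    while (off < Tn) {
      idx <- (off + 1L):Tn
      h[idx, ] <- h[idx, ] + A[idx, , drop = FALSE] *
        h[idx - off, , drop = FALSE]
      A[idx, ] <- A[idx, , drop = FALSE] * A[idx - off, , drop = FALSE]
      off <- off * 2L
    }
  }
  aff(params$Wc, params$bc) * h + aff(params$Wd, params$bd) * z
}

#' Physics extraction heads (numeric forward)
#'
#' Maps a window embedding to interpretable oscillator quantities with
#' range-enforcing activations: phases \eqn{\pi \tanh(\cdot)} in
#' \eqn{[-\pi,\pi]}, frequencies \eqn{\mathrm{softplus}} (positive, rad/s),
#' coupling \eqn{\mathrm{sigmoid}} in [0,1] and phase lag
#' \eqn{(\pi/2)\,\mathrm{sigmoid}} in \eqn{[0,\pi/2]}. At freshly
#' initialized parameters the coupling output sits near 0.7 and the phase
#' lag near \eqn{\pi/6}.
#'
#' @param zFinal embedding vector (length stateDim) or T x d matrix.
#' @param model a model from \code{\link{initChimeraNet}}.
#' @return list with phases, frequencies (both per channel), couplingK and
#'   phaseLagAlpha; matrices with one row per input row when zFinal is a
#'   matrix.
#' @export
physicsReadout <- function(zFinal, model) {
  z <- if (is.matrix(zFinal)) zFinal else matrix(zFinal, nrow = 1)
  p <- model$params
  aff <- function(W, b) sweep(z %*% W, 2, as.numeric(b), "+")
  sig <- function(x) 1 / (1 + exp(-x))
  list(phases = pi * tanh(aff(p$phys.phW, p$phys.phb)),
       frequencies = log1p(exp(pmin(aff(p$phys.frW, p$phys.frb), 30))),
       couplingK = as.numeric(sig(aff(p$phys.kW, p$phys.kb))),
       phaseLagAlpha = as.numeric(pi / 2 * sig(aff(p$phys.aW, p$phys.ab))))
}

#' Multi-task prediction heads (numeric forward)
#'
#' The three task heads on a window embedding: chimera probability
#' (sigmoid), state probabilities (softmax over 4 classes), time estimate
#' (ReLU, minutes). Heads include batch normalization and dropout;
#' evaluation mode (default) disables dropout and uses the stored running
#' batch-norm statistics, so repeated calls are identical. Train mode
#' requires a batch of at least 2 rows.
#'
#' @param zFinal embedding matrix (rows = windows) or a single vector.
#' @param model a model from \code{\link{initChimeraNet}}.
#' @param train train mode (default FALSE).
#' @param seed dropout seed for train mode.
#' @return list with pChimera, stateProbs, timeEstimate.
#' @export
predictHeads <- function(zFinal, model, train = FALSE, seed = 42L) {
  z <- if (is.matrix(zFinal)) zFinal else matrix(zFinal, nrow = 1)
  if (train && nrow(z) < 2)
    stop("train mode with batch normalization needs a batch of >= 2 windows")
  if (train) set.seed(.deriveSeed(seed, 10L))
  tape <- adTape()
  pn <- lapply(model$params, function(x) adInput(tape, x))
  out <- .headsAD(model, pn, adInput(tape, z), tape, train = train)
  list(pChimera = as.numeric(out$pChimera$val),
       stateProbs = out$stateProbs$val,
       timeEstimate = as.numeric(out$timeEst$val))
}
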