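# Minimal tape-based reverse-mode automatic differentiation.
#
# All values are numeric matrices. A tape records nodes in creation order;
# backward() walks it in reverse. Only the operations the network needs are
# implemented, including two fused ops: the per-node softmax attention
# aggregation over hyperedges and the diagonal state-space scan, whose
# adjoints are coded directly for speed.

adTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

adNode <- function(tape, val, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- n
  n
}

adInput <- function(tape, x) adNode(tape, as.matrix(x))

.accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# seed the output node with gradient 1 and sweep the tape in reverse
adBackward <- function(tape, node) {
  node$grad <- matrix(1, nrow(node$val), ncol(node$val))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
  }
  invisible(NULL)
}

adMatmul <- function(a, b, tape) adNode(tape, a$val %*% b$val, list(a, b),
  function(n) {
    .accum(n$parents[[1]], n$grad %*% t(n$parents[[2]]$val))
    .accum(n$parents[[2]], crossprod(n$parents[[1]]$val, n$grad))
  })

# sparse/dense constant matrix times node
adConstmul <- function(M, a, tape) adNode(tape, as.matrix(M %*% a$val),
  list(a), function(n) .accum(n$parents[[1]], as.matrix(Matrix::crossprod(M, n$grad))))

adAdd <- function(a, b, tape) adNode(tape, a$val + b$val, list(a, b),
  function(n) { .accum(n$parents[[1]], n$grad); .accum(n$parents[[2]], n$grad) })

adSub <- function(a, b, tape) adNode(tape, a$val - b$val, list(a, b),
  function(n) { .accum(n$parents[[1]], n$grad); .accum(n$parents[[2]], -n$grad) })

adMul <- function(a, b, tape) adNode(tape, a$val * b$val, list(a, b),
  function(n) {
    .accum(n$parents[[1]], n$grad * n$parents[[2]]$val)
    .accum(n$parents[[2]], n$grad * n$parents[[1]]$val)
  })

adScale <- function(a, s, tape) adNode(tape, a$val * s, list(a),
  function(n) .accum(n$parents[[1]], n$grad * s))

adAddConst <- function(a, k, tape) adNode(tape, a$val + k, list(a),
  function(n) .accum(n$parents[[1]], n$grad))

# add a 1 x d bias row to every row of X
adAddBias <- function(X, b, tape) adNode(tape, sweep(X$val, 2, as.numeric(b$val), "+"),
  list(X, b), function(n) {
    .accum(n$parents[[1]], n$grad)
    .accum(n$parents[[2]], matrix(colSums(n$grad), 1))
  })

adTanh <- function(a, tape) { v <- tanh(a$val); adNode(tape, v, list(a),
  local({v <- v; function(n) .accum(n$parents[[1]], n$grad * (1 - v^2))})) }

adSigmoid <- function(a, tape) { v <- 1 / (1 + exp(-a$val));
  adNode(tape, v, list(a),
    local({v <- v; function(n) .accum(n$parents[[1]], n$grad * v * (1 - v))})) }

adSoftplus <- function(a, tape) {
  v <- ifelse(a$val > 30, a$val, log1p(exp(pmin(a$val, 30))))
  adNode(tape, v, list(a), function(n)
    .accum(n$parents[[1]], n$grad / (1 + exp(-n$parents[[1]]$val))))
}

adExp <- function(a, tape) { v <- exp(a$val); adNode(tape, v, list(a),
  local({v <- v; function(n) .accum(n$parents[[1]], n$grad * v)})) }

adRelu <- function(a, tape) adNode(tape, pmax(a$val, 0), list(a),
  function(n) .accum(n$parents[[1]], n$grad * (n$parents[[1]]$val > 0)))

adElu <- function(a, tape) {
  v <- ifelse(a$val > 0, a$val, exp(pmin(a$val, 30)) - 1)
  adNode(tape, v, list(a), local({v <- v; function(n)
    .accum(n$parents[[1]], n$grad * ifelse(v > 0, 1, v + 1))}))
}

adSin <- function(a, tape) adNode(tape, sin(a$val), list(a),
  function(n) .accum(n$parents[[1]], n$grad * cos(n$parents[[1]]$val)))

adCos <- function(a, tape) adNode(tape, cos(a$val), list(a),
  function(n) .accum(n$parents[[1]], -n$grad * sin(n$parents[[1]]$val)))

adSqrt <- function(a, tape) { v <- sqrt(pmax(a$val, 1e-12));
  adNode(tape, v, list(a), local({v <- v; function(n)
    .accum(n$parents[[1]], n$grad / (2 * v))})) }

adSum <- function(a, tape) adNode(tape, matrix(sum(a$val), 1, 1), list(a),
  function(n) .accum(n$parents[[1]],
                     matrix(n$grad[1], nrow(n$parents[[1]]$val),
                            ncol(n$parents[[1]]$val))))

adMean <- function(a, tape) {
  N <- length(a$val)
  adNode(tape, matrix(mean(a$val), 1, 1), list(a), function(n)
    .accum(n$parents[[1]], matrix(n$grad[1] / N, nrow(n$parents[[1]]$val),
                                  ncol(n$parents[[1]]$val))))
}

adRowsel <- function(a, idx, tape) adNode(tape, a$val[idx, , drop = FALSE],
  list(a), local({idx <- idx; function(n) {
    g <- matrix(0, nrow(n$parents[[1]]$val), ncol(n$parents[[1]]$val))
    gsel <- rowsum(n$grad, idx)              # idx may repeat
    g[as.integer(rownames(gsel)), ] <- gsel
    .accum(n$parents[[1]], g)
  }}))

adColsel <- function(a, idx, tape) adNode(tape, a$val[, idx, drop = FALSE],
  list(a), local({idx <- idx; function(n) {
    g <- matrix(0, nrow(n$parents[[1]]$val), ncol(n$parents[[1]]$val))
    g[, idx] <- g[, idx] + n$grad
    .accum(n$parents[[1]], g)
  }}))

adCbind <- function(a, b, tape) adNode(tape, cbind(a$val, b$val), list(a, b),
  function(n) {
    da <- ncol(n$parents[[1]]$val)
    .accum(n$parents[[1]], n$grad[, seq_len(da), drop = FALSE])
    .accum(n$parents[[2]], n$grad[, -seq_len(da), drop = FALSE])
  })

# wrap values to (-pi, pi]; the wrap offset is locally constant, so the
# gradient passes through unchanged
adWrap <- function(a, tape) adNode(tape, wrapPhase(a$val), list(a),
  function(n) .accum(n$parents[[1]], n$grad))

# row-wise softmax
adRowSoftmax <- function(a, tape) {
  v <- exp(a$val - apply(a$val, 1, max))
  v <- v / rowSums(v)
  adNode(tape, v, list(a), local({v <- v; function(n)
    .accum(n$parents[[1]], v * (n$grad - rowSums(n$grad * v)))}))
}

# layer normalization with learnable gain/shift (per row)
adLayerNorm <- function(X, gamma, beta, tape, eps = 1e-5) {
  x <- X$val
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  val <- sweep(xhat, 2, as.numeric(gamma$val), "*")
  val <- sweep(val, 2, as.numeric(beta$val), "+")
  adNode(tape, val, list(X, gamma, beta),
    local({xhat <- xhat; inv <- inv; function(n) {
      g <- n$grad
      gam <- as.numeric(n$parents[[2]]$val)
      .accum(n$parents[[2]], matrix(colSums(g * xhat), 1))
      .accum(n$parents[[3]], matrix(colSums(g), 1))
      gx <- sweep(g, 2, gam, "*")
      d <- ncol(gx)
      .accum(n$parents[[1]],
             inv * (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat)))
    }}))
}

# batch normalization over rows (the window batch); train mode updates the
# running statistics stored in `state` (an environment) by side effect
adBatchNorm <- function(X, gamma, beta, state, train, tape, eps = 1e-5,
                        momentum = 0.1) {
  x <- X$val
  if (train) {
    if (nrow(x) < 2) stop("batch norm needs a batch of at least 2 in train mode")
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, inv, "*")
  val <- sweep(sweep(xhat, 2, as.numeric(gamma$val), "*"), 2,
               as.numeric(beta$val), "+")
  adNode(tape, val, list(X, gamma, beta),
    local({xhat <- xhat; inv <- inv; train <- train; function(n) {
      g <- n$grad
      gam <- as.numeric(n$parents[[2]]$val)
      .accum(n$parents[[2]], matrix(colSums(g * xhat), 1))
      .accum(n$parents[[3]], matrix(colSums(g), 1))
      gx <- sweep(g, 2, gam, "*")
      if (train) {
        m <- nrow(g)
        dx <- sweep(gx - matrix(colMeans(gx), m, ncol(gx), byrow = TRUE) -
                      xhat * matrix(colMeans(gx * xhat), m, ncol(gx),
                                    byrow = TRUE), 2, inv, "*")
      } else dx <- sweep(gx, 2, inv, "*")
      .accum(n$parents[[1]], dx)
    }}))
}

# Attention-weighted hyperedge aggregation.
# P: E x d pooled hyperedge embeddings (node);  s: E x 1 scores (node);
# plan: one entry per (node, incident hyperedge) pair, with precomputed
# sparse operators Mnp (nNodes x npairs, pair -> node scatter) and
# Mpe (npairs x nEdges, edge -> pair gather) plus the raw index vectors.
# Per-node softmax over incident-hyperedge scores, AGG_i = sum_e alpha_ie
# P_e; nodes in no hyperedge get a zero row.
adHyperAgg <- function(P, s, plan, tape) {
  sv <- as.numeric(s$val)[plan$edge]
  w <- exp(sv - max(sv))
  den <- as.numeric(plan$Mnp %*% w)
  den[den == 0] <- 1
  alpha <- w / den[plan$node]
  agg <- as.matrix(plan$Mnp %*% (alpha * P$val[plan$edge, , drop = FALSE]))
  adNode(tape, agg, list(P, s),
    local({alpha <- alpha; plan <- plan; function(n) {
      G <- n$grad
      Pv <- n$parents[[1]]$val
      Gp <- G[plan$node, , drop = FALSE]
      .accum(n$parents[[1]],
             as.matrix(Matrix::crossprod(plan$Mpe, alpha * Gp)))
      q <- rowSums(Gp * Pv[plan$edge, , drop = FALSE])
      cbar <- as.numeric(plan$Mnp %*% (alpha * q))
      dpair <- alpha * (q - cbar[plan$node])
      .accum(n$parents[[2]],
             as.matrix(Matrix::crossprod(plan$Mpe, dpair)))
    }}))
}

# Diagonal-state scan h_t = a_t * h_{t-1} + u_t (rows are time steps).
adScan <- function(a, u, tape) {
  av <- a$val; uv <- u$val
  Tn <- nrow(av)
  h <- uv
  for (t in seq_len(Tn)[-1]) h[t, ] <- av[t, ] * h[t - 1, ] + uv[t, ]
  adNode(tape, h, list(a, u), local({h <- h; function(n) {
    G <- n$grad
    av <- n$parents[[1]]$val
    Tn <- nrow(G)
    du <- G
    da <- matrix(0, Tn, ncol(G))
    if (Tn > 1) {
      for (t in Tn:2) {
        da[t, ] <- du[t, ] * h[t - 1, ]
        du[t - 1, ] <- du[t - 1, ] + av[t, ] * du[t, ]
      }
    }
    .accum(n$parents[[1]], da)
    .accum(n$parents[[2]], du)
  }}))
}

adLog <- function(a, tape, eps = 1e-12) adNode(tape, log(pmax(a$val, eps)),
  list(a), function(n)
    .accum(n$parents[[1]], n$grad / pmax(n$parents[[1]]$val, 1e-12)))

# multiply a matrix node by a 1x1 scalar node
adScalarmul <- function(a, s, tape) adNode(tape, a$val * s$val[1],
  list(a, s), function(n) {
    .accum(n$parents[[1]], n$grad * n$parents[[2]]$val[1])
    .accum(n$parents[[2]], matrix(sum(n$grad * n$parents[[1]]$val), 1, 1))
  })

# add a column vector node (m x 1) to every column of X (m x d)
adAddColvec <- function(X, cv, tape) adNode(tape,
  X$val + as.numeric(cv$val), list(X, cv), function(n) {
    .accum(n$parents[[1]], n$grad)
    .accum(n$parents[[2]], matrix(rowSums(n$grad), ncol = 1))
  })

# multiply every column of X (m x d) by a column vector node (m x 1)
adMulCol <- function(X, cv, tape) adNode(tape, X$val * as.numeric(cv$val),
  list(X, cv), function(n) {
    .accum(n$parents[[1]], n$grad * as.numeric(n$parents[[2]]$val))
    .accum(n$parents[[2]],
           matrix(rowSums(n$grad * n$parents[[1]]$val), ncol = 1))
  })

adRowMeans <- function(a, tape) adNode(tape, matrix(rowMeans(a$val), ncol = 1),
  list(a), function(n) {
    d <- ncol(n$parents[[1]]$val)
    .accum(n$parents[[1]],
           matrix(n$grad[, 1] / d, nrow(n$grad), d))
  })

# zero-order-hold input coefficient (exp(a*delta) - 1) / a with the small-|a|
# series fallback; a is a matrix node, delta a 1x1 node
adZohCoef <- function(a, delta, tape) {
  av <- a$val; dl <- delta$val[1]
  x <- av * dl
  small <- abs(x) < 1e-4
  coef <- ifelse(small, dl * (1 + x / 2), expm1(x) / av)
  adNode(tape, coef, list(a, delta),
    local({small <- small; dl <- dl; function(n) {
      av <- n$parents[[1]]$val
      x <- av * dl
      dda <- ifelse(small, dl^2 / 2, (dl * exp(x) * av - expm1(x)) / av^2)
      ddd <- exp(x)
      .accum(n$parents[[1]], n$grad * dda)
      .accum(n$parents[[2]], matrix(sum(n$grad * ddd), 1, 1))
    }}))
}

# mean Huber (smooth L1) loss with knot delta; y is a plain numeric target
adHuber <- function(pred, y, delta, tape) {
  e <- as.numeric(pred$val) - as.numeric(y)
  l <- ifelse(abs(e) <= delta, 0.5 * e^2 / delta, abs(e) - delta / 2)
  adNode(tape, matrix(mean(l), 1, 1), list(pred),
    local({e <- e; delta <- delta; function(n) {
      d <- ifelse(abs(e) <= delta, e / delta, sign(e))
      .accum(n$parents[[1]], matrix(n$grad[1] * d / length(e), ncol = 1))
    }}))
}

# mean binary cross-entropy on logits against a constant 0/1 target matrix
adBCElogits <- function(logits, target, tape) {
  p <- 1 / (1 + exp(-logits$val))
  eps <- 1e-12
  l <- -(target * log(p + eps) + (1 - target) * log(1 - p + eps))
  adNode(tape, matrix(mean(l), 1, 1), list(logits),
    local({p <- p; target <- target; function(n)
      .accum(n$parents[[1]], n$grad[1] * (p - target) / length(p))}))
}

# chimera structure loss on per-window predicted phases:
# mean_w [ -|R_sync - R_desync| + lambdaDiv * entropySign * H(sizes) ],
# with community assignments recomputed per window by spectral clustering on
# the phase-alignment similarity (cos(thetai - thetaj) rescaled to [0,1]).
# Assignments are treated as constants for the gradient.
adStructureLoss <- function(phases, tape, lambdaDiv = 0.1, entropySign = 1,
                            k = 2L, seed = 42L) {
  ph <- phases$val
  W <- nrow(ph); C <- ncol(ph)
  tot <- 0
  grad <- matrix(0, W, C)
  for (w in seq_len(W)) {
    th <- ph[w, ]
    S <- (cos(outer(th, th, "-")) + 1) / 2
    labels <- tryCatch(
      communityLabels(spectralClusters(S, k = k, seed = .deriveSeed(seed, w),
                                       nstart = 2L)),
      error = function(e) rep(c(0L, 1L), length.out = C))
    R <- numeric(k); gR <- matrix(0, k, C)
    for (g in seq_len(k) - 1L) {
      id <- which(labels == g)
      Cm <- mean(cos(th[id])); Sm <- mean(sin(th[id]))
      R[g + 1] <- sqrt(Cm^2 + Sm^2)
      gR[g + 1, id] <- (-Cm * sin(th[id]) + Sm * cos(th[id])) /
        (length(id) * max(R[g + 1], 1e-9))
    }
    hi <- which.max(R); lo <- which.min(R)
    p <- tabulate(labels + 1L, k) / C
    H <- -sum(ifelse(p > 0, p * log(p), 0))
    tot <- tot + (-(R[hi] - R[lo]) + lambdaDiv * entropySign * H)
    grad[w, ] <- -(gR[hi, ] - gR[lo, ])
  }
  adNode(tape, matrix(tot / W, 1, 1), list(phases),
    local({grad <- grad; W <- W; function(n)
      .accum(n$parents[[1]], n$grad[1] * grad / W)}))
}
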