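mkLayer <- function(din, dout, seed = 1) {
  set.seed(seed)
  g <- function(a, b) matrix(rnorm(a * b, sd = 0.3), a, b)
  list(W = g(2 * din, dout), b = matrix(0, 1, dout),
       attW1 = g(din, 4), attb1 = matrix(0, 1, 4),
       attW2 = g(4, 1), attb2 = matrix(0, 1, 1),
       lnG = matrix(1, 1, dout), lnB = matrix(0, 1, dout),
       res = if (din != dout) g(din, dout))
}

mkGraph <- function(A, tau = 0.5) detect3Cliques(A, tau = tau)

test_that("isolated nodes aggregate a zero vector", {
  C <- 6
  h <- detect3Cliques(diag(C), tau = 0.65)     # no hyperedges at all
  expect_equal(nrow(hyperedges(h)), 0)
  set.seed(2)
  emb <- matrix(rnorm(C * 5), C)
  layer <- mkLayer(5, 7)
  out <- hypergraphConv(h, emb, layer)
  # reference: sigma(W [h || 0]) + layer norm + residual, computed directly
  lin <- sweep(cbind(emb, matrix(0, C, 5)) %*% layer$W, 2,
               as.numeric(layer$b), "+")
  act <- ifelse(lin > 0, lin, exp(lin) - 1)
  xh <- (act - rowMeans(act)) / sqrt(rowMeans((act - rowMeans(act))^2) + 1e-5)
  ref <- xh + emb %*% layer$res
  expect_equal(unclass(out), ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("attention weights over each node's hyperedges sum to one", {
  A <- randomAdjacency(9, 4)
  h <- mkGraph(A)
  set.seed(3)
  out <- hypergraphConv(h, matrix(rnorm(9 * 5), 9), mkLayer(5, 5))
  att <- attr(out, "attention")
  sums <- tapply(att$alpha, att$node, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("hypergraph convolution is permutation-equivariant", {
  C <- 9
  A <- randomAdjacency(C, 11)
  set.seed(4)
  emb <- matrix(rnorm(C * 5), C)
  layer <- mkLayer(5, 7, seed = 5)
  out <- unclass(hypergraphConv(mkGraph(A), emb, layer))
  for (s in 1:5) {
    set.seed(s)
    perm <- sample(C)
    outP <- unclass(hypergraphConv(mkGraph(A[perm, perm]),
                                   emb[perm, , drop = FALSE], layer))
    expect_equal(outP, out[perm, , drop = FALSE], tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("state-space block reduces to the skip path when Wa, Wb, Wc vanish", {
  d <- 6
  set.seed(6)
  z <- matrix(rnorm(12 * d), 12)
  params <- list(Wa = matrix(0, d, d), ba = matrix(0.5, 1, d),
                 Wb = matrix(0, d, d), bb = matrix(0, 1, d),
                 Wc = matrix(0, d, d), bc = matrix(1, 1, d),
                 Wd = matrix(rnorm(d * d, sd = 0.3), d), bd = matrix(1, 1, d),
                 logDelta = matrix(log(0.01), 1, 1))
  y <- mambaBlock(z, params)
  D <- sweep(z %*% params$Wd, 2, as.numeric(params$bd), "+")
  expect_equal(y, D * z, tolerance = 1e-12)
})

test_that("state-space output length matches input length", {
  d <- 4
  set.seed(7)
  params <- list(Wa = matrix(rnorm(d * d, sd = 0.3), d),
                 ba = matrix(0.5, 1, d),
                 Wb = matrix(rnorm(d * d, sd = 0.3), d), bb = matrix(0, 1, d),
                 Wc = matrix(rnorm(d * d, sd = 0.3), d), bc = matrix(1, 1, d),
                 Wd = matrix(rnorm(d * d, sd = 0.3), d), bd = matrix(1, 1, d),
                 logDelta = matrix(log(0.01), 1, 1))
  for (Tn in c(1, 7, 360)) {
    z <- matrix(rnorm(Tn * d), Tn)
    expect_equal(dim(mambaBlock(z, params)), c(Tn, d))
  }
})

test_that("the doubling scan equals the naive recurrence", {
  d <- 8
  set.seed(8)
  params <- list(Wa = matrix(rnorm(d * d, sd = 0.5), d),
                 ba = matrix(0.2, 1, d),
                 Wb = matrix(rnorm(d * d, sd = 0.5), d),
                 bb = matrix(0.1, 1, d),
                 Wc = matrix(rnorm(d * d, sd = 0.5), d), bc = matrix(1, 1, d),
                 Wd = matrix(rnorm(d * d, sd = 0.5), d), bd = matrix(1, 1, d),
                 logDelta = matrix(log(0.05), 1, 1))
  z <- matrix(rnorm(64 * d), 64)
  expect_equal(mambaBlock(z, params, method = "scan"),
               mambaBlock(z, params, method = "naive"), tolerance = 1e-5)
})

test_that("physics readout respects its ranges and chimera-regime initialization", {
  m <- initChimeraNet(tinyConfig(), seed = 9)
  set.seed(10)
  Z <- matrix(rnorm(100 * m$config$stateDim), 100)
  r <- physicsReadout(Z, m)
  expect_true(all(abs(r$phases) <= pi))
  expect_true(all(r$frequencies > 0))
  expect_true(all(r$couplingK >= 0 & r$couplingK <= 1))
  expect_true(all(r$phaseLagAlpha >= 0 & r$phaseLagAlpha <= pi / 2))
  expect_gt(mean(r$couplingK), 0.6)
  expect_lt(mean(r$couplingK), 0.8)
  expect_lt(abs(mean(r$phaseLagAlpha) - pi / 6), 0.15)
  expect_identical(physicsReadout(Z[1, ], m), physicsReadout(Z[1, ], m))
})

test_that("prediction heads obey their output contracts", {
  m <- initChimeraNet(tinyConfig(), seed = 11)
  set.seed(12)
  Z <- matrix(rnorm(20 * m$config$stateDim), 20)
  out <- predictHeads(Z, m)
  expect_true(all(abs(rowSums(out$stateProbs) - 1) < 1e-6))
  expect_true(all(out$pChimera >= 0 & out$pChimera <= 1))
  expect_true(all(out$timeEstimate >= 0))
  expect_identical(out, predictHeads(Z, m))    # eval mode is deterministic
  expect_error(predictHeads(Z[1, ], m, train = TRUE), "batch")
})

test_that("automatic gradients match finite differences through the full model", {
  inp <- fixtureInputs(1)
  m <- tinyModel(inp)
  w <- lossWeights()
  tape <- chimeraNet:::adTape()
  le <- chimeraNet:::.episodeLossAD(m, inp, tape, w, train = FALSE)
  chimeraNet:::adBackward(tape, le$total)
  grads <- lapply(le$out$paramNodes, function(n) n$grad)
  f <- function(model) {
    tp <- chimeraNet:::adTape()
    chimeraNet:::.episodeLossAD(model, inp, tp, w, train = FALSE)$total$val[1]
  }
  for (nm in c("conv1.W", "conv2.attW1", "ssm1.Wa", "ssm2.logDelta",
               "chimera.W1", "state.W3", "time.W2", "phys.phW", "phys.kb")) {
    g <- grads[[nm]]
    i <- which.max(abs(g))
    mm <- m
    hstep <- 1e-5
    mm$params[[nm]][i] <- mm$params[[nm]][i] + hstep
    fp <- f(mm)
    mm$params[[nm]][i] <- mm$params[[nm]][i] - 2 * hstep
    fm <- f(mm)
    num <- (fp - fm) / (2 * hstep)
    expect_lt(abs(g[i] - num) / max(abs(num), 1e-6), 1e-3)
  }
})

test_that("every supervised parameter group receives gradient", {
  inp <- fixtureInputs(1)
  m <- tinyModel(inp)
  tape <- chimeraNet:::adTape()
  le <- chimeraNet:::.episodeLossAD(m, inp, tape, lossWeights(), train = FALSE)
  chimeraNet:::adBackward(tape, le$total)
  for (nm in names(m$params)) {
    if (startsWith(nm, "pre.")) next       # pretraining heads: separate loss
    g <- le$out$paramNodes[[nm]]$grad
    expect_false(is.null(g), info = nm)
    expect_gt(sum(abs(g)), 0, label = paste("gradient mass of", nm))
  }
})

test_that("the reduced model forward pass is fast and finite", {
  inp <- fixtureInputs(1)
  m <- tinyModel(inp)
  elapsed <- system.time(pred <- predictEpisode(m, inp))["elapsed"]
  expect_lt(elapsed, 5)
  expect_true(all(is.finite(pred$pChimera)))
  expect_equal(nrow(pred), inp$W)
})

test_that("the model can overfit a single episode", {
  inp <- fixtureInputs(1)
  m <- tinyModel(inp)
  w <- lossWeights(smoothingEps = 0)
  opt <- chimeraNet:::.adamwInit(m$params)
  loss <- NA
  for (step in 1:200) {
    tape <- chimeraNet:::adTape()
    le <- chimeraNet:::.episodeLossAD(m, inp, tape, w, train = FALSE)
    chimeraNet:::adBackward(tape, le$total)
    grads <- lapply(le$out$paramNodes, function(n) n$grad)
    up <- chimeraNet:::.adamwStep(opt, m$params, grads, 1e-2, 1e-3, 0, 0)
    opt <- up$opt
    m$params <- up$params
    loss <- le$total$val[1]
    if (loss < 0.1) break
  }
  expect_lt(loss, 0.1)
})

test_that("masked pretraining masks ceiling(C * rate) nodes and is learnable", {
  inp <- fixtureInputs(1)
  m <- tinyModel(inp)
  st <- pretrainStep(m, inp, maskRate = 0.15, seed = 1)
  expect_equal(st$nMasked, 4L)             # ceiling(23 * 0.15)
  expect_true(is.finite(st$loss))
  expect_error(pretrainStep(m, inp, maskRate = 1), "all nodes")
  opt <- chimeraNet:::.adamwInit(m$params)
  first <- st$loss
  for (i in 1:15) {
    st <- pretrainStep(m, inp, maskRate = 0.15, seed = 1, gradient = TRUE)
    up <- chimeraNet:::.adamwStep(opt, m$params, st$grads, 3e-3, 3e-3, 0, 0)
    opt <- up$opt
    m$params <- up$params
  }
  expect_lt(pretrainStep(m, inp, maskRate = 0.15, seed = 1)$loss, first)
})

test_that("early stopping and the cosine schedule follow their closed forms", {
  expect_equal(chimeraNet:::.stopEpoch(c(0.6, 0.7, rep(0.65, 15)), 15), 17)
  expect_true(is.na(chimeraNet:::.stopEpoch(c(0.6, 0.7, rep(0.65, 14)), 15)))
  expect_equal(cosineLR(16, 30, 3e-4), 0.5 * 3e-4)
  expect_equal(cosineLR(1, 30, 3e-4), 3e-4)
  expect_equal(trainConfig(lrMain = 1e-3)$lrPhysics, 1e-4)
})
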