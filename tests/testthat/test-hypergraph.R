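test_that("channel features capture band power, symmetry and degeneracy", {
  fs <- 256
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  set.seed(3)
  sig <- MultiChannelSignal(rbind(sin(2 * pi * 10 * t), rnorm(length(t)),
                                  rep(2, length(t))),
                            samplingRate = fs,
                            channelNames = c("alpha", "noise", "flat"))
  f <- channelFeatures(sig)
  expect_gt(f["alpha", "alpha"], 0.9)
  expect_lt(abs(f["alpha", "skewness"]), 0.05)
  expect_true(f["flat", "degenerate"])
  expect_equal(f["flat", "variance"], 0)
  expect_equal(f["flat", "skewness"], 0)
  # band fractions partition at most the whole spectrum
  bands <- rowSums(f[, c("delta", "theta", "alpha", "beta", "gamma")])
  expect_true(all(bands <= 1 + 1e-9))
  # white noise skewness averages near zero
  sk <- vapply(1:50, function(s) {
    set.seed(s)
    channelFeatures(MultiChannelSignal(rbind(rnorm(512)),
                                       samplingRate = fs))$skewness
  }, numeric(1))
  expect_lt(abs(mean(sk)), 0.1)
})

test_that("identity-mode refinement is a rank-preserving pass-through", {
  A <- randomAdjacency(10, 31)
  ref <- refineAdjacency(NULL, A)
  expect_equal(cor(c(ref), c(A), method = "spearman"), 1.0)
  expect_true(all(ref >= 0 & ref <= 1))
})

test_that("MLP refinement keeps the output symmetric in [0, 1]", {
  ep <- fixtureEpisode(1)
  f <- channelFeatures(ep@signal, window = c(60, 65))
  A <- randomAdjacency(23, 7)
  refiner <- initRefiner(23, seed = 1)
  M <- refineAdjacency(f, A, refiner)
  expect_true(isSymmetric(M))
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(max(M), 1)
  bad <- refiner                     # wrong output dimension (not C^2)
  bad$W3 <- bad$W3[, 1:500]
  bad$b3 <- bad$b3[1:500]
  expect_error(refineAdjacency(f, A, bad), "C\\^2")
})

test_that("a refiner that suppresses one channel lowers its refined weight", {
  C <- 8
  A <- randomAdjacency(C, 13)
  f <- as.data.frame(matrix(rnorm(C * 9), C, 9))
  # constant-output refiner: layers collapse to the bias of the last layer,
  # which scores channel 3 pairs low and everything else high
  att <- matrix(2, C, C)
  att[3, ] <- att[, 3] <- -5
  refiner <- list(W1 = matrix(0, C * 9, 4), b1 = numeric(4),
                  W2 = matrix(0, 4, 4), b2 = numeric(4),
                  W3 = matrix(0, 4, C * C), b3 = as.numeric(att),
                  nChannels = C)
  M <- refineAdjacency(f, A, refiner)
  off <- function(X, i) mean(X[i, -i])
  relRef <- off(M, 3) / mean(M[upper.tri(M)])
  relPLV <- off(A, 3) / mean(A[upper.tri(A)])
  expect_lt(relRef, relPLV)
})

test_that("3-clique detection is exhaustive, strict and tau-monotone", {
  A1 <- matrix(1, 5, 5)
  expect_equal(nrow(hyperedges(detect3Cliques(A1))), choose(5, 3))
  inc <- matrix(0.66, 3, 3); inc[1, 2] <- inc[2, 1] <- 0.70
  diag(inc) <- 1
  expect_equal(nrow(hyperedges(detect3Cliques(inc))), 1)
  exc <- matrix(0.70, 3, 3); exc[1, 2] <- exc[2, 1] <- 0.65
  diag(exc) <- 1
  expect_equal(nrow(hyperedges(detect3Cliques(exc))), 0)  # strict >
  expect_error(detect3Cliques(A1, tau = 1.2), "tau")
  # brute-force oracle, permutation equivariance and tau monotonicity
  bruteCliques <- function(A, tau) {
    C <- nrow(A)
    out <- NULL
    for (i in 1:(C - 2)) for (j in (i + 1):(C - 1)) for (k in (j + 1):C)
      if (A[i, j] > tau && A[j, k] > tau && A[i, k] > tau)
        out <- rbind(out, c(i, j, k))
    if (is.null(out)) matrix(integer(0), 0, 3) else out
  }
  for (s in 1:100) {
    A <- randomAdjacency(10, s)
    tau <- runif(1, 0.3, 0.7)
    he <- unname(hyperedges(detect3Cliques(A, tau)))
    expect_equal(he[order(he[, 1], he[, 2], he[, 3]), , drop = FALSE],
                 bruteCliques(A, tau))
    heHi <- hyperedges(detect3Cliques(A, tau + 0.1))
    expect_lte(nrow(heHi), nrow(he))
  }
  set.seed(77)
  A <- randomAdjacency(9, 202)
  perm <- sample(9)
  he1 <- hyperedges(detect3Cliques(A, 0.5))
  he2 <- hyperedges(detect3Cliques(A[perm, perm], 0.5))
  mapped <- t(apply(matrix(match(perm, seq_len(9))[he2], ncol = 3), 1, sort))
  key <- function(m) sort(apply(m, 1, paste, collapse = "-"))
  expect_equal(key(mapped), key(unname(he1)))
})

test_that("hyperedge density normalizes by C choose 3", {
  empty <- detect3Cliques(diag(5), tau = 0.65)
  expect_equal(hyperedgeDensity(empty), 0)
  full <- detect3Cliques(matrix(1, 23, 23), tau = 0.65)
  expect_equal(nrow(hyperedges(full)), 1771)
  expect_equal(hyperedgeDensity(full), 1.0)
})

test_that("hypergraphs serialize to line-oriented text and back", {
  A <- randomAdjacency(7, 3)
  h <- detect3Cliques(A, tau = 0.5)
  path <- file.path(tempdir(), "hg.txt")
  writeHypergraph(h, path)
  h2 <- readHypergraph(path)
  expect_equal(hyperedges(h2), hyperedges(h))
  expect_equal(h2@tau, 0.5)
  expect_equal(h2@nodes, h@nodes)
  M <- incidenceMatrix(h)
  expect_equal(dim(M), c(7, nrow(hyperedges(h))))
  expect_true(all(colSums(M) == 3))
})
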