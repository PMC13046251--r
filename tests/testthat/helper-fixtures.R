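# Shared fixtures, built once per test run and cached.

.fix <- new.env()

# short labelled chimera episode (benchmark geometry)
fixtureEpisode <- function(seed = 1L) {
  key <- paste0("ep", seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- generateEpisode(benchmarkEpisodeSpec(seed = seed))
  .fix[[key]]
}

# stationary chimera (stabilization regime) trajectory at the default
# operating point
fixtureStabTraj <- function(seed = 1L, duration = 60) {
  key <- paste0("stab", seed, "_", duration)
  if (is.null(.fix[[key]])) {
    p <- defaultKuramotoParams(seed = seed)
    .fix[[key]] <- list(params = p,
                        traj = simulateKuramoto(p, duration = duration,
                                                seed = seed))
  }
  .fix[[key]]
}

fixtureInputs <- function(seed = 1L) {
  key <- paste0("inp", seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- buildModelInputs(fixtureEpisode(seed))
  .fix[[key]]
}

# tiny model sized for fast tests
tinyConfig <- function(dropout = 0) {
  modelConfig(convDims = c(8L, 12L), attnHidden = 4L, nBlocks = 2L,
              headHidden = 8L, dropout = dropout)
}

tinyModel <- function(inputs, seed = 3L, dropout = 0) {
  m <- initChimeraNet(tinyConfig(dropout), seed = seed)
  m$featNorm <- list(mean = colMeans(inputs$X),
                     sd = pmax(apply(inputs$X, 2, sd), 1e-6))
  m
}

# adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxidx <- (ai + bj) / 2
  (sumij - expected) / (maxidx - expected)
}

# random symmetric matrix in [0, 1] with unit diagonal
randomAdjacency <- function(C, seed) {
  set.seed(seed)
  A <- matrix(runif(C * C), C, C)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}
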