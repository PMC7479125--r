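# Fixture builders and independent oracles shared across test files.
# Everything is generated in code under explicit seeds; no stored data.

# Random undirected weighted network with given density.
randomNetwork <- function(n, density = 0.4, seed = 1, hemisphereTags = "L",
                          wMin = 0.05, wMax = 0.95) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    on <- runif(sum(ut)) < density
    w[ut][on] <- runif(sum(on), wMin, wMax)
    w <- w + t(w)
  })
  weightedNetwork(w, hemisphereTags = hemisphereTags)
}

# Core-periphery network: dense, strong core among the first nHub nodes.
corePeripheryNetwork <- function(n = 30, nHub = 5, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      hubs <- (i <= nHub) + (j <= nHub)
      p <- c(0.2, 0.5, 0.95)[hubs + 1]
      if (runif(1) < p)
        w[i, j] <- w[j, i] <- runif(1, 0.2, 0.6) * c(1, 1.2, 2)[hubs + 1]
    }
    w
  })
  weightedNetwork(w)
}

# Brute-force weighted rich-club coefficient at one degree level:
# explicit pairwise subgraph enumeration and a full sort of all weights.
# Deliberately independent of the package's vectorized implementation.
oraclePhi <- function(w, k) {
  n <- nrow(w)
  deg <- vapply(seq_len(n), function(i) sum(w[i, ] > 0), 0L)
  S <- which(deg > k)
  if (length(S) < 2) return(NA_real_)
  tot <- 0; ecount <- 0L
  for (a in seq_along(S)) for (b in seq_along(S)) {
    if (a < b && w[S[a], S[b]] > 0) {
      tot <- tot + w[S[a], S[b]]
      ecount <- ecount + 1L
    }
  }
  if (ecount == 0) return(NA_real_)
  allw <- numeric(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (w[i, j] > 0) allw <- c(allw, w[i, j])
  tot / sum(sort(allw, decreasing = TRUE)[seq_len(ecount)])
}

# Brute-force covariate-adjusted Spearman: explicit rank, residual on an
# lm per variable, then Pearson via cor().
oraclePartialSpearman <- function(x, y, covs) {
  cm <- as.matrix(covs)
  cm <- scale(cm, center = TRUE, scale = FALSE)
  rx <- resid(lm(rank(x) ~ cm))
  ry <- resid(lm(rank(y) ~ cm))
  cor(rx, ry)
}

# Long metric table for the statistics functions: nPer subjects per group,
# Gaussian L/R values with optional group / hemisphere / interaction shifts.
simulateMetricTable <- function(nPer = 20, groupShift = 0, hemiShift = 0,
                                interShift = 0, seed = 1) {
  withr::with_seed(seed, {
    nS <- 2 * nPer
    ids <- sprintf("s%03d", seq_len(nS))
    grp <- rep(c("NC", "BD"), each = nPer)
    age <- runif(nS, 21, 50)
    sex <- sample(c("M", "F"), nS, replace = TRUE)
    hand <- runif(nS, 0.75, 1)
    base <- rnorm(nS)
    L <- base + rnorm(nS) + ifelse(grp == "BD", groupShift, 0)
    R <- base + rnorm(nS) + ifelse(grp == "BD", groupShift, 0) + hemiShift +
      ifelse(grp == "BD", interShift, 0)
    data.frame(subject_id = rep(ids, 2), group = rep(grp, 2),
               hemisphere = rep(c("L", "R"), each = nS),
               value = c(L, R), age = rep(age, 2), sex = rep(sex, 2),
               handscore = rep(hand, 2), stringsAsFactors = FALSE)
  })
}

# Sorted degree sequence / weight multiset helpers.
degSeq <- function(net) sort(as.integer(nodalDegree(net)))
weightMultiset <- function(net) {
  w <- edgeWeights(net)
  sort(w[upper.tri(w)][w[upper.tri(w)] > 0])
}

# Mean asymmetry score of one metric within one group from a long table.
meanASByGroup <- function(rows, metric, grp) {
  sub <- rows[rows$metric == metric & rows$group == grp, ]
  lh <- sub[sub$hemisphere == "L", ]
  rh <- sub[sub$hemisphere == "R", ]
  rh <- rh[match(lh$subject_id, rh$subject_id), ]
  mean(suppressWarnings(asymmetryScore(rh$value, lh$value)), na.rm = TRUE)
}

writeTmpMatrix <- function(m, sep = "\t") {
  p <- tempfile(fileext = ".tsv")
  writeLines(apply(m, 1, paste, collapse = sep), p)
  p
}
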