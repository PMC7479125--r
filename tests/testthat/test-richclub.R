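test_that("nodal degree counts edges, ignoring weights", {
  empty <- weightedNetwork(matrix(0, 5, 5))
  expect_equal(unname(nodalDegree(empty)), rep(0L, 5))

  full <- randomNetwork(45, density = 1, seed = 1)
  expect_equal(unname(nodalDegree(full)), rep(44L, 45))

  net <- randomNetwork(20, density = 0.4, seed = 3)
  w <- edgeWeights(net)
  oracle <- vapply(1:20, function(i) sum(w[i, ] > 0), 0L)
  expect_equal(unname(nodalDegree(net)), oracle)
})

test_that("weighted rich-club coefficient reproduces the hand-worked 4-node example", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 3; w[1, 3] <- 2; w[2, 3] <- 2; w[3, 4] <- 1
  w <- w + t(w)
  net <- weightedNetwork(w)
  cur <- as.data.frame(weightedRichClub(net, kValues = 0:2))
  # k = 0: full graph, ratio of everything over everything
  expect_equal(cur$phi[cur$k == 0], 1.0)
  # k = 1: S = {1,2,3}, W = 7, top-3 weights 3+2+2 = 7
  expect_equal(cur$phi[cur$k == 1], 1.0)
  # k = 2: only node 3 has degree > 2 -> masked
  expect_false(cur$defined[cur$k == 2])
  expect_true(is.na(cur$phi[cur$k == 2]))
})

test_that("phi matches the brute-force oracle on small random graphs", {
  for (seed in 1:40) {
    n <- 4 + (seed %% 5)
    net <- randomNetwork(n, density = 0.5, seed = seed)
    w <- edgeWeights(net)
    cur <- as.data.frame(weightedRichClub(net))
    for (i in seq_len(nrow(cur))) {
      expected <- oraclePhi(w, cur$k[i])
      if (is.na(expected)) expect_false(cur$defined[i])
      else expect_equal(cur$phi[i], expected, tolerance = 1e-14)
    }
  }
})

test_that("phi lies in [0, 1] wherever defined", {
  for (seed in 41:60) {
    cur <- as.data.frame(weightedRichClub(randomNetwork(15, 0.3, seed = seed)))
    ok <- cur$defined
    expect_true(all(cur$phi[ok] >= 0 & cur$phi[ok] <= 1 + 1e-12))
  }
})

test_that("Maslov rewiring preserves degrees and the weight multiset, deterministically", {
  for (seed in 1:25) {
    net <- randomNetwork(12 + seed %% 8, density = 0.4, seed = seed)
    rw <- maslovRewire(net, nSwapPerEdge = 10, seed = 100 + seed)
    expect_identical(degSeq(rw), degSeq(net))
    expect_equal(weightMultiset(rw), weightMultiset(net), tolerance = 1e-15)
    # total strength conserved exactly
    expect_equal(sum(edgeWeights(rw)), sum(edgeWeights(net)), tolerance = 1e-12)
    # no self-loops (zero diagonal enforced by the class invariant)
    expect_true(all(diag(edgeWeights(rw)) == 0))
  }
  # determinism under a fixed seed
  net <- randomNetwork(15, 0.4, seed = 9)
  expect_identical(edgeWeights(maslovRewire(net, seed = 5)),
                   edgeWeights(maslovRewire(net, seed = 5)))
})

test_that("swap-free and degenerate graphs are handled", {
  # star graph admits no legal double-edge swap: topology unchanged
  w <- matrix(0, 6, 6); w[1, 2:6] <- 0.5; w <- w + t(w)
  star <- weightedNetwork(w)
  rw <- maslovRewire(star, seed = 1)
  expect_identical(edgeWeights(rw), edgeWeights(star))

  # zero swaps leaves any input untouched
  net <- randomNetwork(10, 0.5, seed = 2)
  expect_identical(edgeWeights(maslovRewire(net, nSwapPerEdge = 0, seed = 1)),
                   edgeWeights(net))

  one <- matrix(0, 3, 3); one[1, 2] <- one[2, 1] <- 0.4
  expect_warning(maslovRewire(weightedNetwork(one), seed = 1), "fewer than 2")
})

test_that("normalized rich club detects the built-in core and is seeded", {
  net <- corePeripheryNetwork(30, 5, seed = 4)
  cur <- normalizedRichClub(net, nNull = 60, seed = 11)
  df <- as.data.frame(cur)
  topK <- df[df$defined & df$k >= quantile(df$k[df$defined], 0.7), ]
  expect_true(all(topK$phi_norm > 1))

  # reproducible under the same seed, even with a single null
  a <- normalizedRichClub(net, nNull = 1, seed = 3)
  b <- normalizedRichClub(net, nNull = 1, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(normalizedRichClub(net, nNull = 0), "at least 1")
})

test_that("hub selection returns the top 16% by degree with documented tie-breaks", {
  net <- randomNetwork(45, density = 0.3, seed = 21)
  hp <- selectHubs(net, 0.16)
  expect_length(hubIds(hp), 7L)
  expect_length(peripheralIds(hp), 38L)
  # hubs have degree >= every peripheral node (strength-resolved ties aside)
  deg <- nodalDegree(net)
  expect_gte(min(deg[hubIds(hp)]), max(deg[peripheralIds(hp)]) - 1L)

  # unique maximum-degree node is always a hub
  w <- matrix(0, 10, 10); w[1, 2:9] <- 0.5; w[2, 3] <- 0.5
  w <- w + t(w)
  hp2 <- selectHubs(weightedNetwork(w), 0.16)
  expect_true("n1" %in% hubIds(hp2))

  # all-equal degrees: deterministic fallback to node order
  full <- randomNetwork(45, density = 1, seed = 1, wMin = 0.5, wMax = 0.5)
  hp3 <- selectHubs(full, 0.16)
  expect_identical(hubIds(hp3), nodeIds(full)[1:7])

  expect_error(selectHubs(net, 0), "fraction")
  expect_error(selectHubs(net, 1.2), "fraction")
})

test_that("edge classification partitions the edge set with the expected combinatorics", {
  full <- randomNetwork(45, density = 1, seed = 5)
  hp <- selectHubs(full, 0.16)
  cls <- classifyEdges(full, hp)
  counts <- table(edgeTable(cls)$class)
  expect_equal(unname(counts[["rich_club"]]), choose(7, 2))   # 21
  expect_equal(unname(counts[["feeder"]]), 7 * 38)            # 266
  expect_equal(unname(counts[["local"]]), choose(38, 2))      # 703
  expect_equal(sum(counts), choose(45, 2))                    # 990

  empty <- weightedNetwork(matrix(0, 45, 45))
  expect_equal(nrow(edgeTable(classifyEdges(empty, hp))), 0L)

  net <- randomNetwork(45, 0.3, seed = 6)
  cls2 <- classifyEdges(net, hp)
  expect_equal(nrow(edgeTable(cls2)), sum(edgeWeights(net) > 0) / 2)
})

test_that("class densities and strengths are additive to whole-network totals", {
  full <- randomNetwork(45, density = 1, seed = 5)
  hp <- selectHubs(full, 0.16)
  cls <- classifyEdges(full, hp)
  expect_equal(classDensity(cls, "rich_club"), 21 / 990, tolerance = 1e-15)

  for (seed in 1:10) {
    net <- randomNetwork(45, density = 0.35, seed = seed)
    cls <- classifyEdges(net, selectHubs(net, 0.16))
    dTot <- sum(edgeWeights(net) > 0) / 2 / choose(45, 2)
    sTot <- sum(edgeWeights(net)) / 2
    dSum <- sum(vapply(c("rich_club", "feeder", "local"),
                       function(l) classDensity(cls, l), 0))
    sSum <- sum(vapply(c("rich_club", "feeder", "local"),
                       function(l) classStrength(cls, l), 0))
    expect_equal(dSum, dTot, tolerance = 1e-12)
    expect_equal(sSum, sTot, tolerance = 1e-12)
  }

  # single feeder edge; linearity in the weights. Partition with hubs
  # n1..n7 (all-equal degrees resolve to node order), so edge (n1, n45)
  # joins a hub to a peripheral node.
  hp <- selectHubs(randomNetwork(45, density = 1, seed = 1,
                                 wMin = 0.5, wMax = 0.5), 0.16)
  w <- matrix(0, 45, 45); w[1, 45] <- w[45, 1] <- 0.5
  one <- weightedNetwork(w)
  clsOne <- classifyEdges(one, hp)
  expect_equal(classStrength(clsOne, "feeder"), 0.5)
  expect_equal(classStrength(clsOne, "rich_club"), 0)
  expect_equal(classStrength(clsOne, "local"), 0)
  two <- weightedNetwork(2 * w)
  expect_equal(classStrength(classifyEdges(two, hp), "feeder"), 1.0)
})
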