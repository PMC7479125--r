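test_that("cohort specifications are validated", {
  expect_s4_class(cohortSpec(), "CohortSpec")
  expect_error(cohortSpec(nNc = 0), "positive")
  expect_error(cohortSpec(bdLocalDeficit = 1), "deficits")
  expect_error(cohortSpec(baseDensity = 0), "baseDensity")
  expect_error(cohortSpec(degreeDropRate = 1), "degreeDropRate")
  # infeasible density / hub combination caught at generation time
  expect_error(generateBaseConnectome(cohortSpec(baseDensity = 0.01)),
               "infeasible")
})

test_that("template is exactly mirror-symmetric when no asymmetry is injected", {
  sp <- cohortSpec(coreWeightBoost = 1, ncLocalRightward = 0,
                   bdFeederLeftward = 0, seed = 5)
  base <- generateBaseConnectome(sp)
  w <- edgeWeights(base$fa)
  expect_identical(unname(w[1:45, 1:45]), unname(w[46:90, 46:90]))
})

test_that("generation is deterministic under the master seed", {
  sp <- cohortSpec(nNc = 3, nBd = 3, seed = 17)
  a <- generateBaseConnectome(sp)
  b <- generateBaseConnectome(sp)
  expect_identical(edgeWeights(a$fa), edgeWeights(b$fa))
  expect_identical(fiberCounts(a$fn), fiberCounts(b$fn))

  ca <- generateCohort(sp)
  cb <- generateCohort(sp)
  expect_identical(edgeWeights(ca$subjects[[2]]$fa),
                   edgeWeights(cb$subjects[[2]]$fa))
  expect_identical(ca$phenotypes, cb$phenotypes)
})

test_that("every generated matrix passes the connectome invariants", {
  sp <- cohortSpec(nNc = 3, nBd = 3, seed = 23)
  co <- generateCohort(sp)
  for (s in co$subjects) {
    w <- edgeWeights(s$fa)
    expect_true(isSymmetric(w))
    expect_true(all(w >= 0) && all(w < 1))
    expect_true(all(diag(w) == 0))
    expect_true(validObject(s$fn))
  }
  # round-trips through the io layer
  p <- tempfile(fileext = ".tsv")
  writeMatrix(co$subjects[[1]]$fa, p)
  expect_s4_class(readMatrix(p, expectedN = 90), "WeightedNetwork")
})

test_that("default cohort reproduces the study's group sizes and ranges", {
  sp <- cohortSpec(seed = 31)  # defaults: 55 NC, 49 BD
  co <- generateCohort(sp)
  ph <- co$phenotypes
  expect_equal(sum(ph$group == "NC"), 55L)
  expect_equal(sum(ph$group == "BD"), 49L)
  expect_true(all(ph$age >= 21 & ph$age <= 50))
  expect_true(all(ph$handscore >= 0.75 & ph$handscore <= 1))
  expect_true(all(is.na(ph$ymrs[ph$group == "NC"])))
  expect_true(all(ph$ymrs[ph$group == "BD"] >= 0 &
                    ph$ymrs[ph$group == "BD"] <= 41))
  expect_true(all(ph$hamd[ph$group == "BD"] >= 0 &
                    ph$hamd[ph$group == "BD"] <= 32))
})

test_that("hemispheric template exhibits rich-club organization by construction", {
  sp <- cohortSpec(seed = 7)
  base <- generateBaseConnectome(sp)
  left <- splitHemispheres(base$fa, base$nodes)@left
  cur <- as.data.frame(normalizedRichClub(left, nNull = 50, seed = 2))
  topK <- cur[cur$defined & cur$k >= quantile(cur$k[cur$defined], 0.75), ]
  expect_gt(nrow(topK), 0)
  expect_true(all(topK$phi_norm > 1))
})

test_that("designated hubs are recovered by degree-based hub selection", {
  sp <- cohortSpec(nNc = 4, nBd = 4, seed = 13)
  co <- generateCohort(sp)
  nets <- lapply(co$subjects, function(s) {
    splitHemispheres(applyFnThreshold(s$fa, s$fn), co$nodes,
                     s$subject_id)
  })
  hemis <- c(lapply(nets, slot, "left"), lapply(nets, slot, "right"))
  hubs <- selectHubs(groupAverage(unname(hemis)), 0.16)
  truthNames <- sub("\\.(L|R)$", "", co$truth$hubNodeIds[1:7])
  # degree realizations at the hub/peripheral boundary are stochastic, so
  # near-complete rather than exact recovery is the guaranteed behaviour
  expect_gte(length(intersect(hubIds(hubs), truthNames)), 6L)
})

test_that("null generator (all effects zero) keeps pipeline type-I error near nominal", {
  rates <- t(vapply(1:100, function(r) {
    sp <- cohortSpec(nNc = 12, nBd = 12, nNodesPerHemi = 20, hubCount = 3,
                     bdFeederDeficit = 0, bdLocalDeficit = 0,
                     ncLocalRightward = 0, bdFeederLeftward = 0,
                     degreeDropRate = 0, seed = 1000 + r)
    co <- generateCohort(sp)
    pairs <- lapply(co$subjects, function(s)
      splitHemispheres(applyFnThreshold(s$fa, s$fn), co$nodes, s$subject_id))
    hemis <- c(lapply(pairs, slot, "left"), lapply(pairs, slot, "right"))
    hubs <- selectHubs(groupAverage(unname(hemis)), 0.16)
    rows <- do.call(rbind, lapply(seq_along(pairs), function(i) {
      do.call(rbind, lapply(c("L", "R"), function(h) {
        net <- if (h == "L") pairs[[i]]@left else pairs[[i]]@right
        cm <- connectivityMeasures(net, hubs)
        data.frame(subject_id = co$subjects[[i]]$subject_id, hemisphere = h,
                   metric = cm$metric, value = cm$value)
      }))
    }))
    rows <- merge(rows, co$phenotypes, by = "subject_id")
    tab <- rows[rows$metric == "strength_local", ]
    res <- mixedAnova(tab, covariates = c("age", "sex", "handscore"))
    res$p < 0.05
  }, logical(3)))
  # per-effect rejection rate over 100 null cohorts: within Monte-Carlo
  # error of the nominal 5% (3 binomial sds above 0.05 is ~0.115)
  expect_true(all(colMeans(rates) <= 0.115))
})
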