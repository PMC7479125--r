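#' Construct a synthetic-cohort specification
#'
#' Bundles all generator parameters into a validated [CohortSpec-class].
#' Defaults emulate the structure of an FA-weighted structural-connectome
#' cohort: 55 controls and 49 patients, 45 regions per hemisphere with 7
#' designated hub regions, a core-periphery topology whose hub-hub edges
#' are both denser and stronger (so a rich-club effect exists by
#' construction), FA-like weights from a clipped normal with mean 0.45 and
#' sd 0.10 (a plausible white-matter FA range), patient-group deficits
#' concentrated in feeder and local edges, a rightward local-connection
#' asymmetry and a patient-specific leftward feeder asymmetry on the AS
#' (percent) scale, and clinical scores monotonically linked to the latent
#' severity that drives right-hemisphere peripheral disconnection.
#'
#' @param nNc,nBd subject counts (defaults 55 / 49).
#' @param nNodesPerHemi regions per hemisphere (default 45; with 45 the
#'   packaged atlas labels are used).
#' @param hubCount designated hubs per hemisphere (default 7).
#' @param baseDensity target within-hemisphere connection density (0.30).
#' @param faMean,faSd FA-like weight distribution (0.45, 0.10), clipped to
#'   (0.05, 0.95).
#' @param coreWeightBoost multiplicative hub-hub weight advantage (1.5).
#' @param bdFeederDeficit,bdLocalDeficit fractional FA reduction of feeder
#'   / local edges in patients (0.10, 0.15).
#' @param ncLocalRightward target mean AS of local-connection measures in
#'   the shared template, percent (+5 = rightward).
#' @param bdFeederLeftward target magnitude of the patients' leftward
#'   feeder asymmetry, percent (5 means AS = -5).
#' @param subjectNoiseSd sd of per-edge multiplicative lognormal noise
#'   (0.10).
#' @param subjectScaleSd sd of the per-subject global lognormal scale
#'   (0.05).
#' @param fnMean mean streamline count of adopted edges (20).
#' @param fnSubthresholdFrac fraction of template edges given counts <= 3
#'   so they fail the fiber-number rule (0.05).
#' @param interHemiDensity density of inter-hemispheric template edges
#'   (0.10); these are discarded by the hemisphere split.
#' @param degreeDropRate maximum dropout probability of right-hemisphere
#'   connections at the symptom regions in patients (0.3); scaled per
#'   subject by latent severity, 0 disables the injected degree asymmetry.
#' @param symptomLinkSlope slope of the logistic link from latent severity
#'   to symptom-score means (1.5).
#' @param seed master seed (42).
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nNc = 55L, nBd = 49L, nNodesPerHemi = 45L,
                       hubCount = 7L, baseDensity = 0.30,
                       faMean = 0.45, faSd = 0.10, coreWeightBoost = 1.5,
                       bdFeederDeficit = 0.10, bdLocalDeficit = 0.15,
                       ncLocalRightward = 5, bdFeederLeftward = 5,
                       subjectNoiseSd = 0.10, subjectScaleSd = 0.05,
                       fnMean = 20, fnSubthresholdFrac = 0.05,
                       interHemiDensity = 0.10, degreeDropRate = 0.3,
                       symptomLinkSlope = 1.5, seed = 42L) {
  new("CohortSpec", nNc = as.integer(nNc), nBd = as.integer(nBd),
      nNodesPerHemi = as.integer(nNodesPerHemi),
      hubCount = as.integer(hubCount), baseDensity = baseDensity,
      faMean = faMean, faSd = faSd, coreWeightBoost = coreWeightBoost,
      bdFeederDeficit = bdFeederDeficit, bdLocalDeficit = bdLocalDeficit,
      ncLocalRightward = ncLocalRightward,
      bdFeederLeftward = bdFeederLeftward,
      subjectNoiseSd = subjectNoiseSd, subjectScaleSd = subjectScaleSd,
      fnMean = fnMean, fnSubthresholdFrac = fnSubthresholdFrac,
      interHemiDensity = interHemiDensity, degreeDropRate = degreeDropRate,
      symptomLinkSlope = symptomLinkSlope, seed = as.integer(seed))
}

## Synthetic node table for non-45 layouts (left block first, then
## homologues in matching order, as in the packaged atlas table).
.syntheticNodeTable <- function(nh) {
  data.frame(region_id = seq_len(2 * nh),
             region_name = rep(paste0("R", seq_len(nh)), 2),
             hemisphere = rep(c("L", "R"), each = nh),
             homologue_id = c(nh + seq_len(nh), seq_len(nh)),
             stringsAsFactors = FALSE)
}

## AS target -> multiplicative right-hemisphere scale factor: for a pure
## scale f on the right, AS(strength) = 100 (f - 1)/(f + 1), so
## f = (100 + AS)/(100 - AS) in closed form.
.asScale <- function(as) (100 + as) / (100 - as)

#' Generate the population template connectome
#'
#' Builds a 2n-node whole-brain template with core-periphery structure:
#' designated hub regions receive elevated connection probability and a
#' multiplicative weight boost on hub-hub edges, homologous edges are
#' mirrored between hemispheres, inter-hemispheric edges are added at
#' `interHemiDensity`, and the rightward local-connection asymmetry target
#' is applied as a closed-form scale factor on right-hemisphere local
#' weights. Streamline counts are drawn so that `fnSubthresholdFrac` of the
#' template edges fails the fiber-number rule.
#'
#' @param spec a [CohortSpec-class].
#' @return list with elements `fa` ([WeightedNetwork-class], 2n nodes),
#'   `fn` ([FiberCountMatrix-class]), `fnLambda` (per-edge count means used
#'   for subject draws), `nodes` (node table), `hubNodeIds` (true hub
#'   labels, both hemispheres), `masks` (logical 2n x 2n masks for the
#'   within-hemisphere feeder/local/right-hemisphere edge sets).
#' @export
generateBaseConnectome <- function(spec) {
  validObject(spec)
  nh <- spec@nNodesPerHemi
  h <- spec@hubCount
  n <- 2L * nh
  nodes <- if (nh == 45L) defaultNodeTable() else .syntheticNodeTable(nh)
  ids <- nodeTableIds(nodes)

  nhh <- choose(h, 2); nhp <- h * (nh - h); npp <- choose(nh - h, 2)
  total <- nhh + nhp + npp
  pHH <- 0.90
  p0 <- (total * spec@baseDensity - nhh * pHH) / (1.8 * nhp + npp)
  pHP <- 1.8 * p0
  if (p0 <= 0 || p0 > 1 || pHP > 1)
    stop("infeasible baseDensity/hubCount combination (peripheral p = ",
         signif(p0, 3), ", feeder p = ", signif(pHP, 3), ")")

  withr::with_seed(deriveSeed(spec@seed, "template"), {
    isHub <- seq_len(nh) <= h
    pm <- matrix(p0, nh, nh)
    pm[isHub, ] <- pHP; pm[, isHub] <- pHP
    pm[isHub, isHub] <- pHH
    adj <- matrix(FALSE, nh, nh)
    ut <- upper.tri(adj)
    adj[ut] <- stats::runif(sum(ut)) < pm[ut]
    wts <- matrix(0, nh, nh)
    wts[ut][adj[ut]] <- pmin(0.95, pmax(0.05, stats::rnorm(
      sum(adj[ut]), spec@faMean, spec@faSd)))
    wts[isHub, isHub][upper.tri(wts[isHub, isHub])] <-
      pmin(0.95, wts[isHub, isHub][upper.tri(wts[isHub, isHub])] *
             spec@coreWeightBoost)
    hemi <- wts + t(wts)

    w <- matrix(0, n, n)
    w[1:nh, 1:nh] <- hemi
    w[nh + (1:nh), nh + (1:nh)] <- hemi  # mirrored homologous edges
    cross <- matrix(0, nh, nh)
    cut <- stats::runif(nh * nh) < spec@interHemiDensity
    cross[cut] <- pmin(0.95, pmax(0.05, stats::rnorm(
      sum(cut), spec@faMean, spec@faSd)))
    ## keep whole-brain matrix symmetric: cross block and its transpose
    w[1:nh, nh + (1:nh)] <- cross
    w[nh + (1:nh), 1:nh] <- t(cross)
    diag(w) <- 0

    ## class masks in whole-brain coordinates (within-hemisphere edges only)
    isHub90 <- c(isHub, isHub)
    within <- matrix(FALSE, n, n)
    within[1:nh, 1:nh] <- TRUE
    within[nh + (1:nh), nh + (1:nh)] <- TRUE
    diag(within) <- FALSE
    hubPair <- outer(isHub90, isHub90, `&`)
    perPair <- outer(!isHub90, !isHub90, `&`)
    masks <- list(
      feeder = within & !hubPair & !perPair,
      local = within & perPair,
      right = {
        m <- matrix(FALSE, n, n); m[nh + (1:nh), nh + (1:nh)] <- TRUE; m
      })

    ## rightward local asymmetry of the shared template
    fLoc <- .asScale(spec@ncLocalRightward)
    w[masks$local & masks$right] <- pmin(0.999, w[masks$local & masks$right] * fLoc)

    ## streamline-count means: adopted edges well above the threshold, a
    ## small fraction deliberately below it. Means are assigned on the
    ## hemisphere template and mirrored, so with zero asymmetry targets
    ## the two hemispheres stay statistically identical after thresholding.
    lamH <- matrix(0, nh, nh)
    hpos <- which(upper.tri(hemi) & hemi > 0)
    lamH[hpos] <- spec@fnMean
    nSub <- floor(spec@fnSubthresholdFrac * length(hpos))
    if (nSub > 0)
      lamH[sample(hpos, nSub)] <- stats::runif(nSub, 0.5, 2.5)
    lamH <- lamH + t(lamH)
    lam <- matrix(0, n, n)
    lam[1:nh, 1:nh] <- lamH
    lam[nh + (1:nh), nh + (1:nh)] <- lamH
    crossLam <- matrix(0, nh, nh)
    crossLam[cross > 0] <- spec@fnMean
    lam[1:nh, nh + (1:nh)] <- crossLam
    lam[nh + (1:nh), 1:nh] <- t(crossLam)
    pos <- which(upper.tri(w) & w > 0)
    fnCounts <- matrix(0, n, n)
    fnCounts[pos] <- stats::rpois(length(pos), lam[pos])
    fnCounts <- fnCounts + t(fnCounts)

    fa <- weightedNetwork(w, nodeIds = ids,
                          hemisphereTags = nodes$hemisphere)
    list(fa = fa, fn = fiberCountMatrix(fnCounts), fnLambda = lam,
         nodes = nodes, hubNodeIds = ids[isHub90], masks = masks)
  })
}

#' Generate a seeded synthetic cohort
#'
#' Perturbs the population template per subject: multiplicative lognormal
#' per-edge noise plus a global per-subject scale; patients additionally
#' receive the feeder/local FA deficits, a leftward feeder scale factor on
#' the right hemisphere, and latent-severity-driven dropout of
#' right-hemisphere edges at three designated peripheral "symptom" regions
#' (which injects regional-degree asymmetry). Clinical scores are
#' negative-binomial counts whose means increase monotonically (logistic
#' link) with the same latent severity, so covariate-adjusted Spearman
#' correlations between degree asymmetry and symptoms have recoverable
#' signal. Ages, sex and handedness are drawn within the demographic ranges
#' typical of such cohorts (age 21-50, handscore 0.75-1).
#'
#' @param spec a [CohortSpec-class].
#' @return list with `subjects` (list of `list(subject_id, fa, fn)`),
#'   `phenotypes` (data.frame), `nodes`, `template` (output of
#'   [generateBaseConnectome()]), `truth` (injected ground truth: hub ids,
#'   symptom regions, per-subject severities).
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  base <- generateBaseConnectome(spec)
  nh <- spec@nNodesPerHemi
  n <- 2L * nh
  w0 <- edgeWeights(base$fa)
  masks <- base$masks
  ut <- upper.tri(w0)
  pos <- which(ut & w0 > 0)
  symptomRegions <- (nh - 2):nh  # peripheral by construction (hubs are 1..h)

  ids <- c(sprintf("NC%03d", seq_len(spec@nNc)),
           sprintf("BD%03d", seq_len(spec@nBd)))
  groups <- rep(c("NC", "BD"), c(spec@nNc, spec@nBd))

  pheno <- withr::with_seed(deriveSeed(spec@seed, "phenotypes"), {
    nS <- length(ids)
    sev <- stats::plogis(stats::rnorm(nS))  # latent severity in (0,1)
    mu1 <- 41 * stats::plogis(-1 + spec@symptomLinkSlope * stats::qlogis(sev))
    mu2 <- 32 * stats::plogis(-1 + spec@symptomLinkSlope * stats::qlogis(sev))
    ymrs <- pmin(41, stats::rnbinom(nS, size = 8, mu = pmax(mu1, 0.5)))
    hamd <- pmin(32, stats::rnbinom(nS, size = 8, mu = pmax(mu2, 0.5)))
    data.frame(subject_id = ids, group = groups,
               age = sample(21:50, nS, replace = TRUE),
               sex = sample(c("M", "F"), nS, replace = TRUE),
               handscore = round(stats::runif(nS, 0.75, 1), 2),
               ymrs = ifelse(groups == "BD", ymrs, NA_real_),
               hamd = ifelse(groups == "BD", hamd, NA_real_),
               severity = sev, stringsAsFactors = FALSE)
  })

  ## right-hemisphere edges incident to a symptom region (upper triangle)
  sympRight <- matrix(FALSE, n, n)
  sympRight[nh + symptomRegions, nh + (1:nh)] <- TRUE
  sympRight[nh + (1:nh), nh + symptomRegions] <- TRUE
  sympRight <- sympRight & masks$right
  fBdFeeder <- .asScale(-spec@bdFeederLeftward)

  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sid <- ids[i]
    subjects[[i]] <- withr::with_seed(deriveSeed(spec@seed, "subject", sid), {
      w <- w0
      if (groups[i] == "BD") {
        w[masks$feeder] <- w[masks$feeder] * (1 - spec@bdFeederDeficit)
        w[masks$local] <- w[masks$local] * (1 - spec@bdLocalDeficit)
        w[masks$feeder & masks$right] <- w[masks$feeder & masks$right] * fBdFeeder
      }
      ## per-edge lognormal noise + per-subject global scale, symmetric
      noise <- matrix(1, n, n)
      noise[pos] <- exp(stats::rnorm(length(pos), 0, spec@subjectNoiseSd))
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      w <- w * noise * exp(stats::rnorm(1, 0, spec@subjectScaleSd))
      ## severity-driven right-hemisphere peripheral dropout (patients)
      drop <- matrix(FALSE, n, n)
      if (groups[i] == "BD") {
        cand <- which(ut & sympRight & w > 0)
        pDrop <- spec@degreeDropRate * pheno$severity[i]
        hit <- cand[stats::runif(length(cand)) < pDrop]
        drop[hit] <- TRUE
        drop <- drop | t(drop)
        w[drop] <- 0
      }
      w <- pmin(w, 0.999)
      fnCt <- matrix(0, n, n)
      epos <- which(ut & w0 > 0)
      fnCt[epos] <- stats::rpois(length(epos), base$fnLambda[epos])
      fnCt[drop] <- 0
      fnCt[w == 0] <- 0
      fnCt[lower.tri(fnCt)] <- t(fnCt)[lower.tri(fnCt)]
      list(subject_id = sid,
           fa = weightedNetwork(w, nodeIds = nodeIds(base$fa),
                                hemisphereTags = base$nodes$hemisphere),
           fn = fiberCountMatrix(fnCt))
    })
  }

  list(subjects = subjects,
       phenotypes = pheno[, setdiff(names(pheno), "severity")],
       nodes = base$nodes, template = base,
       truth = list(hubNodeIds = base$hubNodeIds,
                    symptomRegions = symptomRegions,
                    severity = stats::setNames(pheno$severity, ids)))
}

#' Write a synthetic cohort to disk in the package's exchange formats
#'
#' One full-precision matrix file per subject per matrix type, a YAML
#' manifest mapping subject ids to those files, a phenotype TSV and the
#' node table — exactly the formats [readMatrix()], [readManifest()],
#' [readPhenotypes()] and [readNodeTable()] consume.
#'
#' @param cohort output of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list()
  for (s in cohort$subjects) {
    faP <- paste0(s$subject_id, "_fa.tsv")
    fnP <- paste0(s$subject_id, "_fn.tsv")
    writeMatrix(s$fa, file.path(dir, faP))
    writeMatrix(s$fn, file.path(dir, fnP))
    man[[s$subject_id]] <- list(fa_path = faP, fn_path = fnP)
  }
  manPath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, manPath)
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$nodes, file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manPath)
}
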