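#' @import methods
NULL

.SYM_TOL <- 1e-10

#' WeightedNetwork: an undirected, nonnegatively weighted connectome
#'
#' The central container of the package: a square symmetric matrix of
#' nonnegative edge weights (mean fractional anisotropy of the fiber bundle
#' linking two grey-matter regions, dimensionless) with a zero diagonal,
#' ordered region labels, and a per-node hemisphere tag. A whole-brain
#' network carries both `"L"` and `"R"` tags; a hemispheric network carries a
#' single constant tag.
#'
#' @slot weights square numeric matrix, symmetric to 1e-10, zero diagonal,
#'   all entries >= 0.
#' @slot nodeIds character vector of unique region labels, one per row.
#' @slot hemisphereTags character vector in `{"L","R"}`, one per node.
#'
#' @seealso [weightedNetwork()], [edgeWeights()], [nodalDegree()]
#' @export
setClass("WeightedNetwork",
  representation(weights = "matrix", nodeIds = "character",
                 hemisphereTags = "character"))

setValidity("WeightedNetwork", function(object) {
  w <- object@weights
  n <- nrow(w)
  msgs <- character(0)
  if (is.null(n) || n != ncol(w))
    return("weight matrix must be square")
  if (!is.numeric(w) || anyNA(w))
    msgs <- c(msgs, "weights must be numeric with no missing values")
  else {
    if (any(w < 0)) msgs <- c(msgs, "negative edge weight")
    if (n > 0 && any(abs(diag(w)) > 0)) msgs <- c(msgs, "diagonal must be zero")
    if (n > 1 && max(abs(w - t(w))) > .SYM_TOL)
      msgs <- c(msgs, sprintf("matrix asymmetry exceeds tolerance %g", .SYM_TOL))
  }
  if (length(object@nodeIds) != n)
    msgs <- c(msgs, "nodeIds length must match matrix dimension")
  if (anyDuplicated(object@nodeIds))
    msgs <- c(msgs, "nodeIds must be unique")
  if (length(object@hemisphereTags) != n)
    msgs <- c(msgs, "hemisphereTags length must match matrix dimension")
  if (!all(object@hemisphereTags %in% c("L", "R")))
    msgs <- c(msgs, "hemisphereTags must be 'L' or 'R'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a WeightedNetwork
#'
#' Validates and wraps a weight matrix. Small numerical asymmetry (at most
#' 1e-10) is symmetrized away; anything larger is an error, since FA
#' connectivity matrices are undirected by construction.
#'
#' @param weights square numeric matrix of nonnegative weights.
#' @param nodeIds region labels; defaults to `"n1"..."nN"`.
#' @param hemisphereTags per-node `"L"`/`"R"` labels, or a single value
#'   recycled to all nodes (hemispheric network).
#' @return A validated [WeightedNetwork-class] object.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.4
#' weightedNetwork(w, hemisphereTags = "L")
#' @export
weightedNetwork <- function(weights, nodeIds = NULL, hemisphereTags = "L") {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  n <- nrow(weights)
  if (n != ncol(weights))
    stop("weight matrix must be square (got ", n, " x ", ncol(weights), ")")
  if (anyNA(weights)) stop("weight matrix contains missing values")
  if (n > 1) {
    asym <- max(abs(weights - t(weights)))
    if (asym > .SYM_TOL)
      stop("matrix asymmetry ", format(asym), " exceeds tolerance ", .SYM_TOL)
    weights <- (weights + t(weights)) / 2
  }
  diag(weights) <- 0
  if (is.null(nodeIds)) nodeIds <- paste0("n", seq_len(n))
  if (length(hemisphereTags) == 1L) hemisphereTags <- rep(hemisphereTags, n)
  dimnames(weights) <- list(nodeIds, nodeIds)
  new("WeightedNetwork", weights = weights, nodeIds = as.character(nodeIds),
      hemisphereTags = as.character(hemisphereTags))
}

#' FiberCountMatrix: streamline counts between region pairs
#'
#' Symmetric matrix of nonnegative integer streamline counts from
#' deterministic tractography, used only for the fiber-number edge-adoption
#' rule (an edge is kept when its count strictly exceeds the threshold).
#'
#' @slot counts square symmetric integer-valued matrix, zero diagonal.
#' @seealso [fiberCountMatrix()], [applyFnThreshold()]
#' @export
setClass("FiberCountMatrix", representation(counts = "matrix"))

setValidity("FiberCountMatrix", function(object) {
  ct <- object@counts
  if (nrow(ct) != ncol(ct)) return("count matrix must be square")
  if (anyNA(ct)) return("count matrix contains missing values")
  if (any(ct < 0)) return("negative fiber count")
  if (any(abs(ct - round(ct)) > 1e-8)) return("fiber counts must be integers")
  if (nrow(ct) > 0 && any(diag(ct) != 0)) return("diagonal must be zero")
  if (nrow(ct) > 1 && max(abs(ct - t(ct))) > 0) return("count matrix must be symmetric")
  TRUE
})

#' @rdname FiberCountMatrix-class
#' @param counts square symmetric matrix of nonnegative integers.
#' @return A validated [FiberCountMatrix-class] object.
#' @export
fiberCountMatrix <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("FiberCountMatrix", counts = counts)
}

#' HemispherePair: homologue-aligned left and right hemispheric networks
#'
#' Produced by [splitHemispheres()]. Node `i` of the right network is the
#' contralateral homologue of node `i` of the left network, so hemispheric
#' contrasts reduce to index arithmetic.
#'
#' @slot left,right 45-node (in general n-node) [WeightedNetwork-class]s.
#' @slot subjectId subject identifier.
#' @export
setClass("HemispherePair",
  representation(left = "WeightedNetwork", right = "WeightedNetwork",
                 subjectId = "character"))

setValidity("HemispherePair", function(object) {
  if (length(object@left@nodeIds) != length(object@right@nodeIds))
    return("left and right networks must have the same node count")
  TRUE
})

#' RichClubCurve: weighted rich-club coefficients over degree levels
#'
#' For each degree level k, `phi` is the ratio of the total weight among
#' nodes of degree > k to the sum of the equally many strongest edge weights
#' anywhere in the network. Levels where the > k subgraph has fewer than two
#' nodes or no edges are undefined and carried as masked (`definedMask`
#' FALSE, values NA), never imputed as zero. When a null ensemble has been
#' attached, `phiNorm = phi / phiNullMean`; values above 1 indicate
#' rich-club organization.
#'
#' @slot kValues integer degree levels.
#' @slot phi weighted rich-club coefficient per level, in \[0, 1\] where
#'   defined.
#' @slot phiNullMean mean coefficient over the Maslov null ensemble (NA when
#'   no ensemble was computed).
#' @slot phiNorm normalized coefficient `phi / phiNullMean`.
#' @slot nNull null-ensemble size (0 when none).
#' @slot definedMask logical validity flag per level.
#' @seealso [weightedRichClub()], [normalizedRichClub()]
#' @export
setClass("RichClubCurve",
  representation(kValues = "integer", phi = "numeric", phiNullMean = "numeric",
                 phiNorm = "numeric", nNull = "integer",
                 definedMask = "logical"))

setValidity("RichClubCurve", function(object) {
  len <- length(object@kValues)
  if (length(object@phi) != len || length(object@definedMask) != len ||
      length(object@phiNullMean) != len || length(object@phiNorm) != len)
    return("all curve slots must have equal length")
  ok <- object@definedMask
  if (any(ok & (object@phi < -1e-12 | object@phi > 1 + 1e-12), na.rm = TRUE))
    return("phi must lie in [0, 1] where defined")
  TRUE
})

#' HubPartition: hub and peripheral node sets
#'
#' Nodes ranked by nodal degree on a group-average network; the top
#' `floor(fraction * n)` are hubs (16% of 45 regions gives 7), the rest are
#' peripheral. Ties at the cut are broken by higher nodal strength, then by
#' node order.
#'
#' @slot hubIds,peripheralIds disjoint node-id sets whose union covers the
#'   network.
#' @slot fraction the hub fraction used.
#' @seealso [selectHubs()]
#' @export
setClass("HubPartition",
  representation(hubIds = "character", peripheralIds = "character",
                 fraction = "numeric"))

setValidity("HubPartition", function(object) {
  if (length(intersect(object@hubIds, object@peripheralIds)))
    return("hub and peripheral sets must be disjoint")
  if (object@fraction <= 0 || object@fraction >= 1)
    return("fraction must lie in (0, 1)")
  TRUE
})

#' EdgeClassification: rich-club / feeder / local label per existing edge
#'
#' Every existing (weight > 0) undirected edge is labelled exactly once:
#' `rich_club` when both endpoints are hubs, `local` when both are
#' peripheral, `feeder` otherwise.
#'
#' @slot edges data.frame with columns `from`, `to`, `weight`, `class`.
#' @slot nodeIds node ids of the classified network (defines the possible
#'   edge count for densities).
#' @slot hubIds hub set used for the classification.
#' @seealso [classifyEdges()], [classDensity()], [classStrength()]
#' @export
setClass("EdgeClassification",
  representation(edges = "data.frame", nodeIds = "character",
                 hubIds = "character"))

setValidity("EdgeClassification", function(object) {
  ed <- object@edges
  need <- c("from", "to", "weight", "class")
  if (!all(need %in% names(ed)))
    return("edges must have columns from, to, weight, class")
  if (nrow(ed) && !all(ed$class %in% c("rich_club", "feeder", "local")))
    return("edge class must be rich_club, feeder or local")
  TRUE
})

edgeClassLevels <- c("rich_club", "feeder", "local")

#' CohortSpec: parameters of the synthetic connectome cohort generator
#'
#' Bundles every knob of the generator: cohort sizes, core-periphery
#' topology, FA-like edge-weight distribution, group deficits concentrated
#' in feeder/local edges, target hemispheric asymmetries on the AS scale,
#' and the master seed. See [cohortSpec()] for defaults and units.
#'
#' @slot nNc,nBd subject counts per group.
#' @slot nNodesPerHemi regions per hemisphere (45).
#' @slot hubCount designated hub regions per hemisphere (7).
#' @slot baseDensity target within-hemisphere connection density in (0, 1].
#' @slot faMean,faSd mean and sd of the clipped-normal FA-like edge weights.
#' @slot coreWeightBoost multiplicative weight advantage of hub-hub edges.
#' @slot bdFeederDeficit,bdLocalDeficit fractional FA reduction of feeder /
#'   local edges in the patient group, in \[0, 1).
#' @slot ncLocalRightward,bdFeederLeftward target asymmetry magnitudes on
#'   the AS scale (percent units).
#' @slot subjectNoiseSd sd of multiplicative lognormal per-edge noise.
#' @slot subjectScaleSd sd of the per-subject global lognormal scale factor.
#' @slot fnMean mean streamline count of adopted edges.
#' @slot fnSubthresholdFrac fraction of template edges given counts <= 3 so
#'   they fail the fiber-number rule.
#' @slot interHemiDensity density of (later discarded) inter-hemispheric
#'   edges in the whole-brain template.
#' @slot degreeDropRate maximum per-edge dropout probability of
#'   right-hemisphere connections at the designated symptom regions in
#'   patients (scaled by latent severity); 0 disables the injected
#'   regional-degree asymmetry.
#' @slot symptomLinkSlope strength of the monotone link between the latent
#'   severity driving right-hemisphere disconnection and clinical scores.
#' @slot seed master seed; all sub-draws derive from it.
#' @export
setClass("CohortSpec",
  representation(nNc = "integer", nBd = "integer", nNodesPerHemi = "integer",
                 hubCount = "integer", baseDensity = "numeric",
                 faMean = "numeric", faSd = "numeric",
                 coreWeightBoost = "numeric",
                 bdFeederDeficit = "numeric", bdLocalDeficit = "numeric",
                 ncLocalRightward = "numeric", bdFeederLeftward = "numeric",
                 subjectNoiseSd = "numeric", subjectScaleSd = "numeric",
                 fnMean = "numeric", fnSubthresholdFrac = "numeric",
                 interHemiDensity = "numeric", degreeDropRate = "numeric",
                 symptomLinkSlope = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msgs <- character(0)
  if (object@nNc < 1 || object@nBd < 1) msgs <- c(msgs, "subject counts must be positive")
  if (object@nNodesPerHemi < 2) msgs <- c(msgs, "need at least 2 nodes per hemisphere")
  if (object@hubCount < 1 || object@hubCount >= object@nNodesPerHemi)
    msgs <- c(msgs, "hubCount must be in [1, nNodesPerHemi)")
  if (object@baseDensity <= 0 || object@baseDensity > 1)
    msgs <- c(msgs, "baseDensity must lie in (0, 1]")
  if (object@faMean <= 0 || object@faMean >= 1) msgs <- c(msgs, "faMean must lie in (0, 1)")
  if (object@faSd <= 0) msgs <- c(msgs, "faSd must be positive")
  if (object@coreWeightBoost <= 0) msgs <- c(msgs, "coreWeightBoost must be positive")
  for (d in c(object@bdFeederDeficit, object@bdLocalDeficit))
    if (d < 0 || d >= 1) msgs <- c(msgs, "deficits must lie in [0, 1)")
  if (abs(object@ncLocalRightward) >= 100 || abs(object@bdFeederLeftward) >= 100)
    msgs <- c(msgs, "asymmetry targets must lie in (-100, 100)")
  if (object@subjectNoiseSd < 0 || object@subjectScaleSd < 0)
    msgs <- c(msgs, "noise sds must be nonnegative")
  if (object@fnSubthresholdFrac < 0 || object@fnSubthresholdFrac >= 1)
    msgs <- c(msgs, "fnSubthresholdFrac must lie in [0, 1)")
  if (object@degreeDropRate < 0 || object@degreeDropRate >= 1)
    msgs <- c(msgs, "degreeDropRate must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})
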