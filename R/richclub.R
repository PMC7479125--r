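#' Nodal degree and strength
#'
#' The nodal degree is the number of edges attached to a node (binary
#' count; weights ignored). The nodal strength is the sum of the FA weights
#' of those edges; it is used only as a documented tie-break when ranking
#' nodes for hub selection.
#'
#' @param net a [WeightedNetwork-class].
#' @return named integer (degree) or numeric (strength) vector, one entry
#'   per node.
#' @export
nodalDegree <- function(net) {
  w <- edgeWeights(net)
  d <- as.integer(colSums(w > 0))
  names(d) <- nodeIds(net)
  d
}

#' @rdname nodalDegree
#' @export
nodalStrength <- function(net) {
  w <- edgeWeights(net)
  s <- colSums(w)
  names(s) <- nodeIds(net)
  s
}

## phi(k) for all k on one weight matrix. Returns list(k, phi, defined).
## For each level k: S = nodes of degree > k, W>k = total weight among S,
## E>k = edge count among S, phi = W>k / sum of the E>k strongest weights
## in the whole network. Undefined (masked) when |S| < 2 or E>k = 0.
.phiCurve <- function(w, kValues = NULL) {
  deg <- colSums(w > 0)
  maxDeg <- if (length(deg)) max(deg) else 0L
  if (is.null(kValues))
    kValues <- if (maxDeg >= 1) 0:(maxDeg - 1L) else integer(0)
  ut <- w[upper.tri(w)]
  wv <- sort(ut[ut > 0], decreasing = TRUE)
  cw <- cumsum(wv)
  phi <- rep(NA_real_, length(kValues))
  defined <- logical(length(kValues))
  ord <- order(deg)                      # ascending degrees
  sdeg <- deg[ord]
  for (i in seq_along(kValues)) {
    k <- kValues[i]
    keep <- deg > k
    if (sum(keep) < 2) next
    sub <- w[keep, keep, drop = FALSE]
    subut <- sub[upper.tri(sub)]
    ek <- sum(subut > 0)
    if (ek == 0) next
    phi[i] <- sum(subut) / cw[ek]
    defined[i] <- TRUE
  }
  list(k = as.integer(kValues), phi = phi, defined = defined)
}

#' Weighted rich-club curve
#'
#' For every degree level k, the weighted rich-club coefficient is the sum
#' of the weights among the nodes of degree > k, divided by the sum of the
#' equally many strongest edge weights anywhere in the network. The ratio
#' lies in \[0, 1\]; levels where the > k subgraph has fewer than two nodes
#' or no edges are masked as undefined.
#'
#' @param net a [WeightedNetwork-class].
#' @param kValues degree levels to evaluate; defaults to `0:(maxdeg - 1)`.
#' @return a [RichClubCurve-class] with `phi` only (no null ensemble).
#' @seealso [normalizedRichClub()]
#' @export
weightedRichClub <- function(net, kValues = NULL) {
  cur <- .phiCurve(edgeWeights(net), kValues)
  nak <- rep(NA_real_, length(cur$k))
  new("RichClubCurve", kValues = cur$k, phi = cur$phi, phiNullMean = nak,
      phiNorm = nak, nNull = 0L, definedMask = cur$defined)
}

#' Degree- and weight-preserving Maslov rewiring
#'
#' Randomizes the topology by repeated double-edge swaps
#' `(a,b),(c,d) -> (a,d),(c,b)`, rejecting self-loops and multi-edges. Each
#' weight travels with its edge through the swaps, so the degree sequence
#' of every node and the multiset of edge weights are preserved exactly
#' (hence total strength is conserved; per-node strength only
#' approximately). The swap loop runs in compiled code; `nSwapPerEdge *
#' nEdges` successful swaps are attempted, with an attempt cap for graphs
#' (such as stars) that admit few or no legal swaps.
#'
#' @param net a [WeightedNetwork-class] with at least 2 edges.
#' @param nSwapPerEdge target successful swaps per edge (default 10).
#' @param seed integer seed; the result is a deterministic function of
#'   (net, nSwapPerEdge, seed).
#' @return a rewired [WeightedNetwork-class]; the achieved swap count is in
#'   `attr(, "swaps")`.
#' @export
maslovRewire <- function(net, nSwapPerEdge = 10L, seed = 1L) {
  w <- edgeWeights(net)
  ed <- upperTriEdges(w)
  if (nrow(ed) < 2) {
    warning("fewer than 2 edges; returning an unchanged copy")
    out <- weightedNetwork(w, nodeIds = nodeIds(net),
                           hemisphereTags = hemisphereTags(net))
    attr(out, "swaps") <- 0L
    return(out)
  }
  target <- as.integer(nSwapPerEdge) * nrow(ed)
  res <- withr::with_seed(as.integer(seed),
    rewire_edge_list(cbind(ed$from, ed$to), nrow(w), target,
                     max(1000L, 50L * target)))
  newEd <- res$edges
  wNew <- matrix(0, nrow(w), ncol(w))
  wNew[cbind(newEd[, 1], newEd[, 2])] <- ed$weight
  wNew <- wNew + t(wNew)
  out <- weightedNetwork(wNew, nodeIds = nodeIds(net),
                         hemisphereTags = hemisphereTags(net))
  attr(out, "swaps") <- res$swaps
  out
}

#' Normalized rich-club curve against a Maslov null ensemble
#'
#' Divides the observed weighted rich-club coefficient at every degree
#' level by its mean over an ensemble of degree- and weight-preserving
#' rewired networks ([maslovRewire()]). Values above 1 over a range of
#' degrees indicate rich-club organization. Because rewiring preserves the
#' degree sequence, observed and null curves share the same degree levels;
#' a level is masked if it is undefined in the observed network or in any
#' null replicate.
#'
#' @param net a [WeightedNetwork-class].
#' @param nNull null-ensemble size (default 1000, per-subject convention).
#' @param seed integer seed; replicate r uses the sub-seed
#'   `deriveSeed(seed, "null", r)`.
#' @param nSwapPerEdge swaps per edge for each null (default 10).
#' @return a [RichClubCurve-class] with `phi`, `phiNullMean`, `phiNorm`
#'   filled; `attr(, "phiNullSd")` carries the per-level null standard
#'   deviation for Monte-Carlo error assessment.
#' @export
normalizedRichClub <- function(net, nNull = 1000L, seed = 1L,
                               nSwapPerEdge = 10L) {
  if (nNull < 1) stop("nNull must be at least 1")
  obs <- weightedRichClub(net)
  nk <- length(obs@kValues)
  if (nk == 0) return(obs)
  nullPhi <- matrix(NA_real_, nNull, nk)
  nullDef <- matrix(FALSE, nNull, nk)
  for (r in seq_len(nNull)) {
    rw <- maslovRewire(net, nSwapPerEdge = nSwapPerEdge,
                       seed = deriveSeed(seed, "null", r))
    cur <- .phiCurve(edgeWeights(rw), kValues = obs@kValues)
    nullPhi[r, ] <- cur$phi
    nullDef[r, ] <- cur$defined
  }
  defined <- obs@definedMask & colSums(nullDef) == nNull
  nullMean <- ifelse(defined, colMeans(nullPhi), NA_real_)
  nullSd <- rep(NA_real_, nk)
  nullSd[defined] <- apply(nullPhi[, defined, drop = FALSE], 2, stats::sd)
  phiNorm <- ifelse(defined & nullMean > 0, obs@phi / nullMean, NA_real_)
  out <- new("RichClubCurve", kValues = obs@kValues, phi = obs@phi,
             phiNullMean = nullMean, phiNorm = phiNorm,
             nNull = as.integer(nNull), definedMask = defined)
  attr(out, "phiNullSd") <- nullSd
  out
}

#' Select hub nodes from a group-average network
#'
#' Ranks nodes by nodal degree (descending) on the supplied group-average
#' network and takes the top `floor(fraction * n)` as hubs — for 45 regions
#' and the conventional 16% fraction, exactly 7 hubs and 38 peripheral
#' nodes. Ties at the cut are broken by higher nodal strength, then by node
#' order, so the partition is deterministic.
#'
#' @param avgNet group-average [WeightedNetwork-class].
#' @param fraction hub fraction in (0, 1); default 0.16.
#' @return a [HubPartition-class].
#' @export
selectHubs <- function(avgNet, fraction = 0.16) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  deg <- nodalDegree(avgNet)
  str <- nodalStrength(avgNet)
  nHub <- floor(fraction * length(deg))
  if (nHub < 1) stop("fraction ", fraction, " selects no hubs for n = ",
                     length(deg))
  ord <- order(-deg, -str, seq_along(deg))
  ids <- nodeIds(avgNet)
  new("HubPartition", hubIds = ids[ord[seq_len(nHub)]],
      peripheralIds = ids[ord[-seq_len(nHub)]], fraction = fraction)
}

#' Classify edges as rich-club, feeder or local
#'
#' Every existing edge is labelled exactly once by the hub membership of
#' its endpoints: `rich_club` (hub-hub), `feeder` (hub-peripheral) or
#' `local` (peripheral-peripheral).
#'
#' @param net a [WeightedNetwork-class].
#' @param hubs a [HubPartition-class] covering `net`'s nodes.
#' @return an [EdgeClassification-class].
#' @export
classifyEdges <- function(net, hubs) {
  ids <- nodeIds(net)
  if (!setequal(c(hubIds(hubs), peripheralIds(hubs)), ids))
    stop("hub partition does not cover the network's nodes")
  ed <- upperTriEdges(edgeWeights(net))
  isHub <- ids %in% hubIds(hubs)
  nh <- isHub[ed$from] + isHub[ed$to]
  ed$class <- c("local", "feeder", "rich_club")[nh + 1L]
  ed$from <- ids[ed$from]
  ed$to <- ids[ed$to]
  new("EdgeClassification", edges = ed, nodeIds = ids, hubIds = hubIds(hubs))
}

#' Per-class connectivity density and strength
#'
#' `classDensity` is the number of existing edges of a class divided by the
#' total number of possible edges of the hemispheric network, `n(n-1)/2`
#' (990 for 45 nodes) — the denominator is deliberately NOT the per-class
#' possible-edge count, so the three class densities sum to the overall
#' network density. `classStrength` is the sum of the FA weights over the
#' edges of the class, each undirected edge counted once.
#'
#' @param cls an [EdgeClassification-class].
#' @param classLabel one of `"rich_club"`, `"feeder"`, `"local"`.
#' @return a nonnegative real; density lies in \[0, 1\].
#' @export
classDensity <- function(cls, classLabel = edgeClassLevels) {
  classLabel <- match.arg(classLabel)
  n <- length(cls@nodeIds)
  if (n < 2) return(0)
  sum(cls@edges$class == classLabel) / (n * (n - 1) / 2)
}

#' @rdname classDensity
#' @export
classStrength <- function(cls, classLabel = edgeClassLevels) {
  classLabel <- match.arg(classLabel)
  sum(cls@edges$weight[cls@edges$class == classLabel])
}

#' All six per-class connectivity measures of one hemispheric network
#'
#' @param net a [WeightedNetwork-class].
#' @param hubs the common [HubPartition-class].
#' @return data.frame with columns `metric`
#'   (`density_rich_club`, ..., `strength_local`) and `value`.
#' @export
connectivityMeasures <- function(net, hubs) {
  cls <- classifyEdges(net, hubs)
  data.frame(
    metric = c(paste0("density_", edgeClassLevels),
               paste0("strength_", edgeClassLevels)),
    value = c(vapply(edgeClassLevels, function(l) classDensity(cls, l), 0),
              vapply(edgeClassLevels, function(l) classStrength(cls, l), 0)),
    row.names = NULL)
}
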