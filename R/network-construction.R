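#' Fiber-number edge-adoption rule
#'
#' A white-matter connection is adopted only when its streamline count is
#' strictly larger than the threshold (default 3); all other FA weights are
#' set to zero. The strict inequality suppresses pseudo-connections from
#' tractography noise, so a count exactly at the threshold is discarded.
#'
#' @param fa [WeightedNetwork-class] of mean-FA weights.
#' @param fn [FiberCountMatrix-class] of streamline counts, same dimensions.
#' @param threshold integer count threshold; edges kept where `fn > threshold`.
#' @return a [WeightedNetwork-class] with the filtered weights.
#' @examples
#' fa <- weightedNetwork(matrix(c(0, .5, .5, 0), 2))
#' fn <- fiberCountMatrix(matrix(c(0, 3, 3, 0), 2))
#' sum(edgeWeights(applyFnThreshold(fa, fn))) # 0: count 3 is not "larger than 3"
#' @export
applyFnThreshold <- function(fa, fn, threshold = 3L) {
  stopifnot(is(fa, "WeightedNetwork"), is(fn, "FiberCountMatrix"))
  w <- fa@weights
  ct <- fn@counts
  if (!all(dim(w) == dim(ct)))
    stop("FA (", nrow(w), " nodes) and fiber-count (", nrow(ct),
         " nodes) matrices must match")
  w[ct <= threshold] <- 0
  weightedNetwork(w, nodeIds = fa@nodeIds, hemisphereTags = fa@hemisphereTags)
}

#' Split a whole-brain network into homologue-aligned hemispheric networks
#'
#' Discards all inter-hemispheric connections and extracts the two
#' within-hemisphere principal submatrices. The right-hemisphere network is
#' reordered so that its i-th node is the contralateral homologue of the
#' i-th left-hemisphere node; per-edge weights are carried over exactly.
#'
#' @param whole [WeightedNetwork-class] whose nodes match `nodes`.
#' @param nodes node table from [readNodeTable()] / [defaultNodeTable()].
#' @param subjectId identifier stored in the result.
#' @return a [HemispherePair-class].
#' @export
splitHemispheres <- function(whole, nodes, subjectId = "subject") {
  n <- nNodes(whole)
  if (n != nrow(nodes))
    stop("network has ", n, " nodes but node table has ", nrow(nodes))
  li <- which(nodes$hemisphere == "L")
  ri0 <- which(nodes$hemisphere == "R")
  ## align right nodes to the homologues of the left ordering
  ri <- match(nodes$homologue_id[li], nodes$region_id)
  if (!setequal(ri, ri0)) stop("homologue map does not cover the right hemisphere")
  w <- whole@weights
  ## hemispheric networks share region names as node ids, so a hub
  ## partition from a pooled average applies to either hemisphere
  rn <- nodes$region_name
  left <- weightedNetwork(w[li, li, drop = FALSE], nodeIds = rn[li],
                          hemisphereTags = "L")
  right <- weightedNetwork(w[ri, ri, drop = FALSE], nodeIds = rn[ri],
                           hemisphereTags = "R")
  new("HemispherePair", left = left, right = right,
      subjectId = as.character(subjectId))
}

#' Elementwise group-average network
#'
#' Arithmetic mean of the weight matrices across networks. By default
#' absent (zero) edges enter the mean as true zeros, which preserves
#' density differences between subjects; `mode = "nonzero_only"` averages
#' each edge over only the subjects possessing it.
#'
#' @param nets list of [WeightedNetwork-class]s over the same node set.
#' @param mode `"include_zeros"` (default) or `"nonzero_only"`.
#' @return a [WeightedNetwork-class] of mean weights.
#' @export
groupAverage <- function(nets, mode = c("include_zeros", "nonzero_only")) {
  mode <- match.arg(mode)
  if (!length(nets)) stop("cannot average an empty list of networks")
  ids <- nodeIds(nets[[1]])
  for (nt in nets)
    if (!identical(nodeIds(nt), ids))
      stop("all networks must share the same node set")
  acc <- Reduce(`+`, lapply(nets, edgeWeights))
  if (mode == "include_zeros") {
    avg <- acc / length(nets)
  } else {
    cnt <- Reduce(`+`, lapply(nets, function(nt) (edgeWeights(nt) > 0) * 1))
    avg <- acc / pmax(cnt, 1)
    avg[cnt == 0] <- 0
  }
  weightedNetwork(avg, nodeIds = ids,
                  hemisphereTags = hemisphereTags(nets[[1]]))
}
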