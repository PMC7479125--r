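#' Accessors for network containers
#'
#' @param x a [WeightedNetwork-class], [FiberCountMatrix-class],
#'   [HubPartition-class] or [EdgeClassification-class] object.
#' @return `edgeWeights` the symmetric weight matrix; `nodeIds` the region
#'   labels; `hemisphereTags` the per-node hemisphere labels; `nNodes` the
#'   node count; `fiberCounts` the streamline-count matrix; `hubIds` /
#'   `peripheralIds` the node sets of a partition; `edgeTable` the per-edge
#'   classification data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))
#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("hemisphereTags", function(x) standardGeneric("hemisphereTags"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("fiberCounts", function(x) standardGeneric("fiberCounts"))
#' @rdname accessors
#' @export
setGeneric("hubIds", function(x) standardGeneric("hubIds"))
#' @rdname accessors
#' @export
setGeneric("peripheralIds", function(x) standardGeneric("peripheralIds"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setMethod("edgeWeights", "WeightedNetwork", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("nodeIds", "WeightedNetwork", function(x) x@nodeIds)
#' @rdname accessors
#' @export
setMethod("hemisphereTags", "WeightedNetwork", function(x) x@hemisphereTags)
#' @rdname accessors
#' @export
setMethod("nNodes", "WeightedNetwork", function(x) length(x@nodeIds))
#' @rdname accessors
#' @export
setMethod("fiberCounts", "FiberCountMatrix", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("hubIds", "HubPartition", function(x) x@hubIds)
#' @rdname accessors
#' @export
setMethod("peripheralIds", "HubPartition", function(x) x@peripheralIds)
#' @rdname accessors
#' @export
setMethod("edgeTable", "EdgeClassification", function(x) x@edges)

setMethod("show", "WeightedNetwork", function(object) {
  w <- object@weights
  n <- nrow(w)
  ne <- if (n > 1) sum(w[upper.tri(w)] > 0) else 0L
  hemi <- paste(unique(object@hemisphereTags), collapse = "+")
  cat(sprintf("WeightedNetwork: %d nodes (%s), %d edges, density %.3f\n",
              n, hemi, ne, if (n > 1) ne / (n * (n - 1) / 2) else 0))
})

setMethod("show", "HemispherePair", function(object) {
  cat(sprintf("HemispherePair '%s': %d homologue-aligned nodes per hemisphere\n",
              object@subjectId, length(object@left@nodeIds)))
})

setMethod("show", "RichClubCurve", function(object) {
  nd <- sum(object@definedMask)
  cat(sprintf("RichClubCurve: k = %s..%s, %d defined levels, n_null = %d\n",
              if (length(object@kValues)) min(object@kValues) else NA,
              if (length(object@kValues)) max(object@kValues) else NA,
              nd, object@nNull))
})

setMethod("show", "HubPartition", function(object) {
  cat(sprintf("HubPartition: %d hubs / %d peripheral (fraction %.2f)\n  hubs: %s\n",
              length(object@hubIds), length(object@peripheralIds),
              object@fraction, paste(object@hubIds, collapse = ", ")))
})

setMethod("show", "EdgeClassification", function(object) {
  tab <- table(factor(object@edges$class, levels = edgeClassLevels))
  cat(sprintf("EdgeClassification: %d edges (%s)\n", nrow(object@edges),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0(
    "CohortSpec: %d NC + %d BD subjects, %d nodes/hemisphere (%d hubs)\n",
    "  density %.2f, FA ~ N(%.2f, %.2f) clipped, core boost %.2f\n",
    "  deficits feeder/local %.2f/%.2f, AS targets NC-local %+.1f, BD-feeder %+.1f, seed %d\n"),
    object@nNc, object@nBd, object@nNodesPerHemi, object@hubCount,
    object@baseDensity, object@faMean, object@faSd, object@coreWeightBoost,
    object@bdFeederDeficit, object@bdLocalDeficit,
    object@ncLocalRightward, -object@bdFeederLeftward, object@seed))
})

#' Tabular view of a rich-club curve
#'
#' @param x a [RichClubCurve-class].
#' @param ... unused.
#' @return data.frame with columns `k`, `phi`, `phi_null_mean`, `phi_norm`,
#'   `defined`.
#' @export
as.data.frame.RichClubCurve <- function(x, ...) {
  data.frame(k = x@kValues, phi = x@phi, phi_null_mean = x@phiNullMean,
             phi_norm = x@phiNorm, defined = x@definedMask)
}
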