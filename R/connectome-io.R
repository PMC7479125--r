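#' Read a connectivity matrix from a delimited text file
#'
#' Reads a dense whitespace- or comma-delimited numeric matrix (dialect
#' auto-detected from the first line), validates the connectome invariants
#' (square, symmetric to 1e-10, zero diagonal, nonnegative, no missing
#' values) and returns a [WeightedNetwork-class]. Values on the diagonal
#' must already be zero; asymmetry above the tolerance is an error rather
#' than being silently symmetrized.
#'
#' @param path path to the matrix file.
#' @param expectedN optional expected node count; mismatch is an error.
#' @param nodeIds optional region labels (defaults to `n1...nN`).
#' @param hemisphereTags per-node hemisphere labels, or a single value.
#' @return a [WeightedNetwork-class].
#' @seealso [writeMatrix()], [readFiberCounts()]
#' @export
readMatrix <- function(path, expectedN = NULL, nodeIds = NULL,
                       hemisphereTags = "L") {
  m <- .readDenseMatrix(path)
  if (nrow(m) != ncol(m))
    stop("matrix in '", path, "' is not square: ", nrow(m), " x ", ncol(m))
  if (anyNA(m)) stop("matrix in '", path, "' contains missing values")
  if (any(m < 0)) stop("matrix in '", path, "' contains negative entries")
  if (!is.null(expectedN) && nrow(m) != expectedN)
    stop("expected ", expectedN, " nodes, found ", nrow(m), " in '", path, "'")
  weightedNetwork(m, nodeIds = nodeIds, hemisphereTags = hemisphereTags)
}

#' @rdname readMatrix
#' @return `readFiberCounts`: a [FiberCountMatrix-class].
#' @export
readFiberCounts <- function(path, expectedN = NULL) {
  m <- .readDenseMatrix(path)
  if (!is.null(expectedN) && nrow(m) != expectedN)
    stop("expected ", expectedN, " nodes, found ", nrow(m), " in '", path, "'")
  fiberCountMatrix(m)
}

.readDenseMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "numeric",
                          strip.white = TRUE, blank.lines.skip = TRUE)
  as.matrix(df)
}

#' Write a connectivity matrix to a delimited text file
#'
#' Full-precision (17 significant digits) tab-delimited output, so that
#' `readMatrix(writeMatrix(x))` reproduces the values exactly.
#'
#' @param x a [WeightedNetwork-class], [FiberCountMatrix-class] or plain
#'   matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(x, path) {
  m <- if (is(x, "WeightedNetwork")) x@weights
       else if (is(x, "FiberCountMatrix")) x@counts
       else as.matrix(x)
  lines <- apply(m, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read (or load the packaged) region node table
#'
#' The node table maps the 90 normalized-atlas regions to a hemisphere and
#' to the index of the contralateral homologue. The packaged default
#' (`defaultNodeTable()`) lists all 45 left-hemisphere regions first, then
#' their homologues in matching order, so hemisphere splitting and
#' homologue pairing are index arithmetic.
#'
#' Structural requirements checked on load: exactly two hemispheres with
#' equal node counts, and a homologue map that is an involution crossing
#' hemispheres (applying it twice is the identity).
#'
#' @param path path to a TSV with columns `region_id`, `region_name`,
#'   `hemisphere`, `homologue_id`.
#' @return data.frame with the four columns above.
#' @export
readNodeTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "region_name", "hemisphere", "homologue_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("node table missing columns: ", paste(miss, collapse = ", "))
  hemi <- table(tab$hemisphere)
  if (length(hemi) != 2L)
    stop("node table must contain exactly two hemispheres, found: ",
         paste(names(hemi), collapse = ", "))
  if (hemi[[1]] != hemi[[2]])
    stop("unequal hemisphere node counts: ", hemi[[1]], " vs ", hemi[[2]])
  idx <- match(tab$homologue_id, tab$region_id)
  if (anyNA(idx)) stop("homologue_id refers to unknown region_id")
  if (any(tab$hemisphere[idx] == tab$hemisphere))
    stop("homologue mapping must cross hemispheres")
  if (!identical(tab$region_id[idx[idx]], tab$region_id))
    stop("homologue mapping is not an involution")
  tab
}

#' @rdname readNodeTable
#' @export
defaultNodeTable <- function() {
  readNodeTable(system.file("extdata", "aal90_nodes.tsv", package = "hemirc",
                            mustWork = TRUE))
}

nodeTableIds <- function(nodes) paste(nodes$region_name, nodes$hemisphere, sep = ".")

#' Read a phenotype table
#'
#' Expects a delimited table with header and columns `subject_id`, `group`
#' (`NC`/`BD`), `age` (years), `sex` (`M`/`F`), `handscore`, `ymrs`, `hamd`.
#' Symptom scores may be missing for controls; a missing score in a patient
#' row raises a warning but the record is retained (flagged via NA).
#'
#' @param path path to a TSV/CSV file.
#' @return typed data.frame, one row per subject.
#' @export
readPhenotypes <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("subject_id", "group", "age", "sex", "handscore")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("phenotype table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  bad <- setdiff(unique(tab$group), c("NC", "BD"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  if (any(!nzchar(tab$group))) stop("empty group label")
  for (sc in c("ymrs", "hamd")) {
    if (!sc %in% names(tab)) tab[[sc]] <- NA_real_
    tab[[sc]] <- suppressWarnings(as.numeric(tab[[sc]]))
    nbd <- tab$group == "BD" & is.na(tab[[sc]])
    if (any(nbd))
      warning(sum(nbd), " BD subject(s) missing ", toupper(sc),
              "; retained with missing flag")
  }
  tab$age <- as.numeric(tab$age)
  tab$handscore <- as.numeric(tab$handscore)
  tab
}

#' Read a cohort manifest
#'
#' YAML manifest mapping each subject id to its FA- and fiber-count matrix
#' files, e.g. `sub01: {fa_path: sub01_fa.tsv, fn_path: sub01_fn.tsv}`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path path to the YAML manifest.
#' @return data.frame with columns `subject_id`, `fa_path`, `fn_path`.
#' @export
readManifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (!length(man)) stop("empty manifest")
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  rows <- lapply(names(man), function(sid) {
    entry <- man[[sid]]
    if (is.null(entry$fa_path) || is.null(entry$fn_path))
      stop("manifest entry '", sid, "' must provide fa_path and fn_path")
    data.frame(subject_id = sid, fa_path = resolve(entry$fa_path),
               fn_path = resolve(entry$fn_path), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
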