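#' Derive a reproducible sub-seed from a master seed and string keys
#'
#' Stable 31-bit polynomial hash of the master seed together with arbitrary
#' keys (subject id, hemisphere, replicate index ...). Used so that every
#' stochastic stage of the pipeline draws from its own stream while being
#' fully determined by one master seed.
#'
#' @param master integer master seed.
#' @param ... additional keys, coerced to character.
#' @return an integer in `[0, 2^31 - 2]`.
#' @examples
#' deriveSeed(42, "BD001", "L")
#' @export
deriveSeed <- function(master, ...) {
  s <- paste(c(format(master), vapply(list(...), as.character, "")),
             collapse = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

## Two independent 31-bit polynomial hashes over the deparsed object;
## cheap content fingerprint for run provenance (not cryptographic).
configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h1 <- 0; h2 <- 7
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#'
#' @param p numeric vector of p-values.
#' @return character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `""` otherwise.
#' @export
significanceStars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

upperTriEdges <- function(w) {
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  data.frame(from = idx[, 1], to = idx[, 2], weight = w[idx])
}
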