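#' @keywords internal
"_PACKAGE"

## Coordinate contract used throughout the package:
##  - genomic coordinates are 0-based, intervals half-open [start, end)
##  - every report table written to disk is 1-based inclusive
##  - promoter-relative coordinates increase downstream in promoter
##    orientation; rel 0 is the first anchor base; on the minus strand
##    "upstream" is the higher-coordinate side

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a root seed
#'
#' All randomness in the package flows from one root seed via named
#' sub-streams, so stages can be re-run independently with identical
#' results. The derivation is a Lehmer-style multiplicative hash kept
#' below 2^31.
#'
#' @param seed Integer root seed.
#' @param k Integer sub-stream index (or a string, hashed to one).
#' @return An integer seed in [0, 2^31).
#' @export
substream_seed <- function(seed, k) {
  if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919 + 12345) %% 2147483647)
}

## Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## first index at which cumsum(x) >= q * sum(x); directional quantile
## (upstream -> downstream), ties resolved upstream by construction
dir_quantile_index <- function(counts, q) {
  tot <- sum(counts)
  stopifnot(tot > 0)
  which(cumsum(counts) >= q * tot)[1L]
}

#' Write a report table as TSV (1-based inclusive coordinates)
#'
#' All coordinate columns in report tables are 1-based inclusive; the
#' conversion from the internal 0-based half-open convention happens in
#' the writers, never in analysis code.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()]
#' @param path Input path.
#' @return A data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a plain-text key:value run manifest
#'
#' @param params Named list of scalar parameters.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(params, path) {
  lines <- vapply(names(params), function(k) {
    paste0(k, ": ", paste(format(params[[k]], digits = 12), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
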