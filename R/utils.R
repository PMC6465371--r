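#' @importFrom methods is
#' @importFrom stats quantile median kmeans fisher.test p.adjust wilcox.test
#'   ks.test cor cor.test loess predict lm coef rpois rnorm runif rlnorm
#'   rmultinom pnorm sd complete.cases setNames var fitted approx
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so that seeded internals do not disturb
#' user-level random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

## Plain TSV I/O used for every tabular artifact; fixed dialect so that
## pipeline outputs are byte-stable across reruns.
write_tsv0 <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv0 <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
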