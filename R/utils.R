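#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats cor dpois median p.adjust ppois quantile rbinom rlnorm
#'   rnorm runif setNames binom.test
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a per-sample seed from a base seed and a sample name, so that
## samples are reproducible independently of generation order.
## FNV-1a over the name, folded into [0, 2^31 - 2].
derive_seed <- function(seed, name) {
  h <- 2166136261 %% 2147483647
  for (code in utf8ToInt(as.character(name))) {
    h <- bitwXor(h, code)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

## Short hex digest of an R object (FNV-1a over its serialization).
## Used to stamp output files with the configuration they came from.
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261 %% 2147483647
  for (b in as.integer(bytes)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
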