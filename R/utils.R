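# Shared internal helpers: seed fan-out, small numeric utilities, input checks.

#' @importFrom data.table data.table CJ .N
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' One global seed is fanned out to per-stage seeds by hashing the stage
#' label, so that toggling one pipeline stage does not shift the random
#' stream of another.  The result is always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1L, "detect") != derive_seed(1L, "simulate")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 7919 + h) %% 2147483629)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

rb_stop <- function(msg, class) {
  stop(structure(class = c(class, "rb_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# 1-based closed interval overlap length
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- interval_overlap(s1, e1, s2, e2)
  pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

.rb_cache <- new.env(parent = emptyenv())

# memoised BLOSUM62 from Biostrings' bundled data
blosum62 <- function() {
  if (is.null(.rb_cache$BLOSUM62)) {
    e <- new.env()
    utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
    .rb_cache$BLOSUM62 <- e$BLOSUM62
  }
  .rb_cache$BLOSUM62
}

# deterministic RNG scope: run fn under a seed without disturbing caller RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
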