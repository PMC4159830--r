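#' @import methods
#' @importFrom stats runif rbinom rmultinom p.adjust phyper setNames
#' @importFrom utils head tail write.table read.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib heterosisDGE, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `expr` under a locally seeded RNG stream; the caller's global
## RNG state is restored afterwards so no operation leaks random state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Stable log(sum(exp(x))).
logSumExp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

reverseComplement1 <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Random DNA of given lengths at a target GC content.
randomDna <- function(lengths, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
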