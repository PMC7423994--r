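## Internal numeric helpers shared across modules.

#' @importFrom methods is new validObject setClass setValidity setGeneric
#'   setMethod show
#' @importFrom stats rlnorm rnbinom rpois rbinom runif median var prcomp
#'   hclust dist pchisq fisher.test p.adjust pnorm phyper dbeta qbeta lm coef
#'   mad isoreg approx quantile setNames sd residuals cor
#' @importFrom utils read.delim write.table head
NULL

## log(sum(exp(x))) without overflow
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## x * log(y) with the 0 * log(0) = 0 convention (exponents of a density)
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

## Round half away from zero (the convention of printed percentage tables;
## base round() is round-half-even).
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Composite Simpson weights on a uniform closed grid of n nodes (n odd).
simpsonWeights <- function(n) {
  stopifnot(n >= 3L, n %% 2L == 1L)
  h <- 1 / (n - 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}

## Evaluate the RNG-consuming expression under a locally-set seed, restoring
## the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
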