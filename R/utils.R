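#' @import methods
#' @importFrom stats rexp runif rbinom setNames
#' @importFrom utils read.delim write.table combn
#' @importClassesFrom GenomicRanges GRanges
NULL

## round half-up (base round() is banker's and would turn 0.875 into 0.88 or
## 0.87 depending on representation; printed Mb/percent values are half-up)
.roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert a base-pair length to megabases
#'
#' Lengths are rendered the way physical-map papers print them: divided by
#' 10^6 and rounded half-up to two decimals (so 875,962 bp prints as 0.88 Mb).
#'
#' @param bp numeric vector of non-negative base-pair lengths.
#' @return numeric vector of Mb values rounded to 2 decimals.
#' @examples
#' toMb(1192012) # 1.19
#' @export
toMb <- function(bp) {
  bp <- as.numeric(bp)
  if (any(is.na(bp)) || any(bp < 0))
    stop("'bp' must be non-negative")
  .roundHalfUp(bp / 1e6, 2L)
}

## evaluate expr with a temporary RNG state seeded by `seed`; the caller's
## .Random.seed is restored afterwards so simulators do not clobber sessions
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.checkDna <- function(x, what = "sequence") {
  x <- toupper(as.character(x))
  if (length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a single non-empty string")
  if (grepl("[^ACGTN]", x))
    stop(what, " contains characters outside {A,C,G,T,N}")
  x
}
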