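#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix colSums rowSums t sparseMatrix Diagonal
#' @importFrom methods as is
#' @importFrom stats as.dist cmdscale cutree dist hclust kmeans p.adjust
#'   pchisq pt rbeta rlnorm rnorm rpois runif rgamma sd setNames var
#' @importFrom utils read.table write.table head modifyList
NULL

# run expr with a private RNG stream seeded from `seed`, restoring the
# caller's stream afterwards (bit-identical outputs for equal seeds)
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x > 0

# Euclidean distance between columns i and j of a dense matrix
col_dist <- function(m, i, j) sqrt(sum((m[, i] - m[, j])^2))
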