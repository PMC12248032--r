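#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# canonical string key for a sorted bit set, used for exact code lookup
bit_key <- function(bits) paste(sort(as.integer(bits)), collapse = "-")

# pairwise Euclidean distances between rows of two matrices
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_orfish <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "orfish_error")))
}
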