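#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two flat clusterings of the same items.
#' Returns \code{NA} when either partition has a single class and the other
#' does too (the index is undefined: expected and maximum agreement coincide).
#'
#' @param a,b vectors of cluster labels, same length, aligned element-wise.
#' @return a number in \[-1, 1\], or \code{NA} for the degenerate case.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps^0.5) return(NA_real_)
  (sum_ij - expected) / (max_index - expected)
}

# internal: stop with a classed condition so tests can assert on error types
abort <- function(message, class) {
  stop(structure(class = c(class, "somamap_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

# internal: euclidean norm of rows of a matrix
row_norms <- function(m) sqrt(rowSums(m^2))
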