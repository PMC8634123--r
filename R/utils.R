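#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones. Used to score recovered migration modes against the
#' simulator's planted ground truth.
#'
#' @param a,b Two label vectors of equal length (any atomic type).
#' @return The adjusted Rand index (numeric scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
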