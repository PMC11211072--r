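#' Pair-counting contingency summary of two partitions
#'
#' Cross-tabulates two labelings of the same subjects. The table and its
#' margins are the sufficient statistics for the Rand index and its
#' chance-adjusted form.
#'
#' @param p1,p2 Two partitions of the same subjects: atomic vectors (any
#'   label type) of equal length, or named vectors, in which case names must
#'   identify the same subject set and are used to align the two.
#' @return A list of class `contingency_counts` with elements `n_ij`
#'   (cross-tabulation matrix), `a_i` and `b_j` (margins) and `n`.
#' @export
contingency_counts <- function(p1, p2) {
  aligned <- align_partitions(p1, p2)
  n_ij <- unclass(table(aligned$p1, aligned$p2))
  structure(
    list(
      n_ij = n_ij,
      a_i = rowSums(n_ij),
      b_j = colSums(n_ij),
      n = length(aligned$p1)
    ),
    class = "contingency_counts"
  )
}

align_partitions <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      abort("`p1` and `p2` must label the same subject set (names differ).")
    }
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    abort("`p1` and `p2` must label the same subject set (lengths differ).")
  }
  if (length(p1) < 2L) {
    abort("Partitions must contain at least 2 subjects.")
  }
  list(p1 = as.vector(p1), p2 = as.vector(p2))
}

#' Rand index of two partitions
#'
#' The proportion of subject pairs on which two partitions agree: pairs
#' placed together in both partitions plus pairs placed apart in both,
#' divided by the total number of pairs `choose(n, 2)`.
#'
#' @inheritParams contingency_counts
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)) # 1
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)) # 1/3
rand_index <- function(p1, p2) {
  cc <- contingency_counts(p1, p2)
  n <- cc$n
  same_both <- sum(choose(cc$n_ij, 2))
  same_1 <- sum(choose(cc$a_i, 2))
  same_2 <- sum(choose(cc$b_j, 2))
  total <- choose(n, 2)
  # agreeing different-pairs = total - pairs same in p1 - pairs same in p2
  #                            + pairs same in both (inclusion-exclusion)
  diff_both <- total - same_1 - same_2 + same_both
  (same_both + diff_both) / total
}

#' Adjusted Rand index (Hubert-Arabie)
#'
#' Rand index corrected for chance under the permutation model with fixed
#' margins: equals 1 iff the partitions are identical up to relabeling, and
#' has expectation 0 for independent random partitions.
#'
#' Two trivial single-cluster partitions agree perfectly but leave the
#' adjustment undefined (expected index equals maximum index); that
#' degenerate case is returned as 1 with a message.
#'
#' @inheritParams contingency_counts
#' @return A scalar `<= 1` (can be negative).
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: same up to relabeling
adjusted_rand_index <- function(p1, p2) {
  cc <- contingency_counts(p1, p2)
  n <- cc$n
  index <- sum(choose(cc$n_ij, 2))
  e1 <- sum(choose(cc$a_i, 2))
  e2 <- sum(choose(cc$b_j, 2))
  total <- choose(n, 2)
  expected <- e1 * e2 / total
  max_index <- (e1 + e2) / 2
  if (abs(max_index - expected) < .Machine$double.eps * total) {
    # both partitions trivial: perfect but chance-degenerate agreement
    inform("Both partitions are single clusters; ARI defined as 1.")
    return(1)
  }
  (index - expected) / (max_index - expected)
}
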