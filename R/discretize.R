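#' Supervised MDL discretization of a continuous feature
#'
#' Recursive entropy-based binary splitting with the minimum-description-length
#' stopping rule (Fayyad & Irani). Candidate cut points are midpoints between
#' distinct adjacent values; the split maximizing information gain is accepted
#' iff
#'
#'   gain > (log2(n - 1) + log2(3^k - 2) - (k*H(S) - k1*H(S1) - k2*H(S2))) / n
#'
#' with `n` the number of instances in the node, `k`, `k1`, `k2` the number of
#' classes present in the node and in each half, and entropies in bits.
#' Accepted halves are split recursively. A constant vector, or one whose
#' labels are all of one class, yields no cuts (the gene collapses to a single
#' bin).
#'
#' @param values numeric vector of expression levels (length Z >= 2).
#' @param labels class label per value (two symbols at most).
#' @return ascending numeric vector of cut thresholds (possibly empty).
#' @examples
#' mdl_discretize(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)) # 6.5
#' @export
mdl_discretize <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 2L)
  y <- as.integer(factor(labels))
  ord <- order(values)
  cuts <- mdl_split(values[ord], y[ord])
  sort(cuts)
}

entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0L) {
    return(0)
  }
  p <- counts / n
  -sum(p * log2(p))
}

# values sorted ascending; returns unsorted cut list
mdl_split <- function(v, y, n_classes = max(y)) {
  n <- length(v)
  # counts per class, cumulative along the sorted axis
  cum <- vapply(seq_len(n_classes), function(c) cumsum(y == c), numeric(n))
  if (n == 1L) cum <- matrix(cum, nrow = 1L)
  total <- cum[n, ]
  ent_s <- entropy_bits(total)
  if (ent_s == 0) {
    return(numeric(0))
  }
  # candidate boundaries: between distinct adjacent values
  cand <- which(v[-n] < v[-1L])
  if (length(cand) == 0L) {
    return(numeric(0))
  }
  left_n <- cand
  ent_left <- apply(cum[cand, , drop = FALSE], 1L, entropy_bits)
  right_counts <- sweep(cum[cand, , drop = FALSE], 2L, total, function(a, b) b - a)
  ent_right <- apply(right_counts, 1L, entropy_bits)
  cond_ent <- (left_n * ent_left + (n - left_n) * ent_right) / n
  gain <- ent_s - cond_ent
  best <- which.max(gain) # ties -> lowest cut, deterministic
  i <- cand[best]
  k <- sum(total > 0)
  k1 <- sum(cum[i, ] > 0)
  k2 <- sum(right_counts[best, ] > 0)
  delta <- log2(3^k - 2) - (k * ent_s - k1 * ent_left[best] - k2 * ent_right[best])
  threshold <- (log2(n - 1) + delta) / n
  if (gain[best] <= threshold) {
    return(numeric(0))
  }
  cut <- (v[i] + v[i + 1L]) / 2
  c(
    cut,
    mdl_split(v[seq_len(i)], y[seq_len(i)], n_classes),
    mdl_split(v[(i + 1L):n], y[(i + 1L):n], n_classes)
  )
}

#' Map continuous values to discrete bin indices
#'
#' Bins follow the left-open/right-closed convention
#' `(-Inf, c1], (c1, c2], ...`: a value exactly at a cut falls in the lower
#' bin. Bin indices run from 0 to `length(cuts)`.
#'
#' @param values numeric vector.
#' @param cuts ascending cut thresholds (possibly empty).
#' @return integer bin index per value.
#' @export
apply_discretization <- function(values, cuts) {
  if (length(cuts) == 0L) {
    return(rep(0L, length(values)))
  }
  stopifnot(!is.unsorted(cuts, strictly = TRUE))
  findInterval(values, cuts, left.open = TRUE)
}

# Discretize every gene of a dataset once; returns Z x N integer bin matrix.
discretize_dataset <- function(dataset) {
  dataset <- as_expr_dataset(dataset)
  y <- dataset$labels
  apply(dataset$values, 2L, function(v) {
    apply_discretization(v, mdl_discretize(v, y))
  })
}
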