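#' Overlap (Jaccard) similarity between two gene sets
#'
#' The number of genes present in both signatures, normalized by the size of
#' their union: `|A intersect B| / |A union B|`. Ranges from 0 (no overlap)
#' to 1 (identical sets). Sets of unequal size are allowed.
#'
#' @param a,b gene sets ([gene_set] or character vectors), both non-empty.
#' @return a real in `[0, 1]`.
#' @examples
#' overlap_similarity(c("g1", "g2", "g3"), c("g2", "g3", "g4")) # 0.5
#' @export
overlap_similarity <- function(a, b) {
  a <- as_gene_set(a)
  b <- as_gene_set(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("overlap similarity is undefined for empty sets", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Kuncheva consistency index between two equal-sized gene sets
#'
#' Chance-corrected overlap for two signatures of size `t` drawn from
#' `n_total` genes:
#'
#'   (|A intersect B| - t^2 / n) / (t - t^2 / n)
#'
#' The correction term accounts for genes shared purely by chance; for small
#' signatures relative to `n_total` it is negligible and the index is close
#' to the plain overlap fraction `r / t`.
#'
#' @param a,b gene sets of identical size `t < n_total`.
#' @param n_total number of genes in the full dataset.
#' @return a real in `[-1, 1]`.
#' @export
kuncheva_index <- function(a, b, n_total) {
  a <- as_gene_set(a)
  b <- as_gene_set(b)
  t <- length(a)
  if (length(b) != t) {
    stop("the Kuncheva index requires sets of equal size", call. = FALSE)
  }
  if (t == 0L || t >= n_total) {
    stop("the Kuncheva index requires 0 < t < n_total", call. = FALSE)
  }
  r <- length(intersect(a, b))
  expected <- t^2 / n_total
  (r - expected) / (t - expected)
}

#' Pairwise similarity matrix over a collection of gene sets
#'
#' Evaluates each of the `M(M-1)/2` pairs once and mirrors the result; the
#' diagonal holds each index's self-similarity (1 for overlap, 1 for
#' Kuncheva). This is the matricial comparison used both across rankers on
#' one dataset and across subsamples for one ranker.
#'
#' @param sets named list of gene sets (names label rows/columns; unnamed
#'   lists are labeled by the sets' `ranker` attribute or `set1..setM`).
#' @param index `"overlap"` or `"kuncheva"`, or a function of two sets.
#' @param n_total required for `"kuncheva"`.
#' @return a [similarity_matrix].
#' @export
pairwise_similarity_matrix <- function(sets, index = c("overlap", "kuncheva"),
                                       n_total = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (is.character(index)) {
    index <- match.arg(index)
    index_name <- c(overlap = "I-overlap", kuncheva = "Kuncheva")[[index]]
    fun <- switch(index,
      overlap = overlap_similarity,
      kuncheva = function(a, b) {
        if (is.null(n_total)) {
          stop("`n_total` is required for the Kuncheva index", call. = FALSE)
        }
        kuncheva_index(a, b, n_total)
      }
    )
  } else {
    fun <- match.fun(index)
    index_name <- "custom"
  }
  labels <- names(sets)
  if (is.null(labels)) {
    labels <- vapply(seq_along(sets), function(i) {
      rk <- attr(sets[[i]], "ranker")
      if (is.null(rk)) paste0("set", i) else rk
    }, character(1))
  }
  m <- length(sets)
  values <- diag(1, m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        values[i, j] <- values[j, i] <- fun(sets[[i]], sets[[j]])
      }
    }
  }
  similarity_matrix(values, labels, index_name)
}

#' Construct a similarity matrix object
#'
#' @param values symmetric numeric M x M matrix.
#' @param labels length-M set identifiers.
#' @param index_name name of the similarity index the entries hold.
#' @return a `similarity_matrix` (a numeric matrix with dimnames and an
#'   `index_name` attribute).
#' @export
similarity_matrix <- function(values, labels, index_name = "I-overlap") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), length(labels) == nrow(values))
  if (!isSymmetric(unname(values), tol = 1e-12)) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("similarity_matrix", "matrix", "array"),
    index_name = index_name
  )
}

#' Average pairwise similarity, excluding the diagonal
#'
#' The mean of the `M(M-1)/2` upper-triangle entries: the overall degree of
#' similarity among the M signatures, with each set's comparison to itself
#' excluded.
#'
#' @param m a [similarity_matrix] (or plain symmetric matrix).
#' @return a real number.
#' @export
average_offdiagonal <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) {
    stop("need at least two sets to average pairwise similarities",
      call. = FALSE
    )
  }
  mean(m[upper.tri(m)])
}

#' @export
print.similarity_matrix <- function(x, digits = 3L, ...) {
  cat(sprintf(
    "<similarity_matrix> %s, %d sets, off-diagonal average %.4f\n",
    attr(x, "index_name"), nrow(x), average_offdiagonal(x)
  ))
  print(round(unclass_matrix(x), digits))
  invisible(x)
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  tibble::as_tibble(unclass_matrix(x), rownames = "set_a") |>
    tidyr::pivot_longer(-"set_a", names_to = "set_b", values_to = "similarity")
}

#' Heatmap of a similarity matrix
#'
#' @param object a [similarity_matrix].
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy(object)
  lv <- rownames(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = factor(.data$set_b, lv),
      y = factor(.data$set_a, rev(lv)),
      fill = .data$similarity
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$similarity)),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "grey30",
      limits = c(min(0, min(object)), 1)
    ) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = attr(object, "index_name"),
      title = sprintf(
        "%s (off-diagonal average %.2f)",
        attr(object, "index_name"), average_offdiagonal(object)
      )
    ) +
    ggplot2::theme_minimal()
}
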