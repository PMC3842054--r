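#' Available feature rankers
#'
#' @return character vector of the eight ranker names.
#' @export
ranker_names <- function() {
  c("CHI2", "IG", "SU", "GR", "ONER", "RELIEFF", "SVM_ONE", "SVM_RFE")
}

entropic_rankers <- c("CHI2", "IG", "SU", "GR")

#' Score every gene with one ranking criterion
#'
#' The univariate criteria (`CHI2`, `IG`, `SU`, `GR`) operate on the gene
#' after supervised MDL discretization ([mdl_discretize()]); `ONER` scores the
#' training accuracy of a one-gene rule; `RELIEFF` and the SVM-based criteria
#' are multivariate. For `SVM_RFE` the score is a rank-derived weight (see
#' [rank_features()]), since elimination order, not a single fit, defines its
#' ranking.
#'
#' @param dataset an [expr_dataset] or data frame (see [as_expr_dataset()]).
#' @param ranker one of [ranker_names()].
#' @param ... passed to the ranker backend: `k_neighbors` (ReliefF, default
#'   10), `min_bucket` (OneR, default 6), `c_parameter` (SVM, default 1),
#'   `removal_fraction` (SVM-RFE, default 0.10).
#' @return a tibble with columns `gene` and `score`, in dataset gene order.
#' @export
score_features <- function(dataset, ranker, ...) {
  dataset <- as_expr_dataset(dataset)
  ranker <- match.arg(toupper(ranker), ranker_names())
  scores <- ranker_scores(dataset, ranker, ...)
  tibble::tibble(gene = dataset$gene_ids, score = unname(scores))
}

ranker_scores <- function(dataset, ranker, bins = NULL, ...) {
  switch(ranker,
    CHI2 = ,
    IG = ,
    SU = ,
    GR = {
      if (is.null(bins)) bins <- discretize_dataset(dataset)
      entropic_scores(bins, dataset$labels, ranker)
    },
    ONER = oner_scores(dataset, ...),
    RELIEFF = relieff_scores(dataset, ...),
    SVM_ONE = svm_one_scores(dataset, ...),
    SVM_RFE = svm_rfe_scores(dataset, ...)
  )
}

#' Produce a full ranked gene list
#'
#' Scores every gene with the requested criterion and sorts in descending
#' relevance; ties are broken deterministically by ascending original gene
#' index, so rankings are reproducible bit-for-bit.
#'
#' @inheritParams score_features
#' @return a tibble of class `ranked_list` with columns `rank`, `gene`,
#'   `score` (a permutation of all N genes) and attribute `ranker`.
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_genes = 50, seed = 1))
#' rank_features(sim$dataset, "IG")
#' @export
rank_features <- function(dataset, ranker, ...) {
  dataset <- as_expr_dataset(dataset)
  ranker <- match.arg(toupper(ranker), ranker_names())
  scores <- ranker_scores(dataset, ranker, ...)
  new_ranked_list(dataset$gene_ids, scores, ranker)
}

new_ranked_list <- function(gene_ids, scores, ranker) {
  ord <- order(-scores, seq_along(scores))
  out <- tibble::tibble(
    rank = seq_along(gene_ids),
    gene = gene_ids[ord],
    score = unname(scores[ord])
  )
  class(out) <- c("ranked_list", class(out))
  attr(out, "ranker") <- ranker
  out
}

#' Cut a ranked list at a threshold
#'
#' @param ranking a `ranked_list` from [rank_features()].
#' @param t signature size, 1 <= t <= N.
#' @return a `gene_set`: the unordered top-`t` genes, with attributes
#'   `ranker` and `t`.
#' @export
cut_ranking <- function(ranking, t) {
  stopifnot(is.data.frame(ranking), all(c("gene", "score") %in% names(ranking)))
  n <- nrow(ranking)
  if (!is.numeric(t) || length(t) != 1L || t < 1L || t > n) {
    stop(sprintf("t must be in [1, %d]", n), call. = FALSE)
  }
  gene_set(ranking$gene[seq_len(as.integer(t))],
    ranker = attr(ranking, "ranker")
  )
}

#' Construct a gene set (signature)
#'
#' @param genes character vector of gene identifiers (duplicates removed).
#' @param ranker optional name of the ranker that produced it.
#' @return a `gene_set` object.
#' @export
gene_set <- function(genes, ranker = NULL) {
  genes <- unique(as.character(genes))
  structure(genes, class = "gene_set", ranker = ranker, t = length(genes))
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf(
    "<gene_set> t=%d%s: %s\n", length(x),
    if (!is.null(attr(x, "ranker"))) paste0(" [", attr(x, "ranker"), "]") else "",
    paste(utils::head(unclass(x), 10L), collapse = ", ")
  ))
  invisible(x)
}

as_gene_set <- function(x) {
  if (inherits(x, "gene_set")) x else gene_set(x)
}

## ---- univariate entropic / statistic scorers -------------------------------

entropic_scores <- function(bins, labels, ranker) {
  y <- as.integer(labels)
  apply(bins, 2L, function(b) entropic_score_vec(b, y, ranker))
}

entropic_score_vec <- function(bins, y, ranker) {
  tab <- table(bins, y)
  contingency_score(tab, ranker)
}

# tab: bins x classes contingency table
contingency_score <- function(tab, ranker) {
  tab <- as.matrix(tab)
  if (ranker == "CHI2") {
    return(chi2_stat(tab))
  }
  n <- sum(tab)
  h_c <- entropy_bits(colSums(tab))
  h_x <- entropy_bits(rowSums(tab))
  cond <- sum(apply(tab, 1L, function(r) sum(r) / n * entropy_bits(r)))
  ig <- h_c - cond
  switch(ranker,
    IG = ig,
    SU = if (h_c + h_x == 0) 0 else 2 * ig / (h_c + h_x),
    GR = if (h_x == 0) 0 else ig / h_x
  )
}

chi2_stat <- function(tab) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(0)
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - expected)^2 / expected)
}

## ---- OneR ------------------------------------------------------------------

# One-gene rule on the sorted value axis with minimum bucket size; a bucket
# closes once some class holds at least `min_bucket` members and the next
# instance has a new value and a different class. A trailing bucket without a
# clear majority is merged into its predecessor. Score = training accuracy %.
oner_scores <- function(dataset, min_bucket = 6L) {
  y <- as.integer(dataset$labels)
  apply(dataset$values, 2L, function(v) oner_score_vec(v, y, min_bucket))
}

oner_score_vec <- function(v, y, min_bucket) {
  ord <- order(v, seq_along(v))
  vs <- v[ord]
  ys <- y[ord]
  z <- length(v)
  buckets <- list()
  counts <- c(0, 0)
  for (i in seq_len(z)) {
    counts[ys[i]] <- counts[ys[i]] + 1
    majority <- which.max(counts)
    closes <- max(counts) >= min_bucket && i < z &&
      vs[i + 1L] > vs[i] && ys[i + 1L] != majority
    if (closes || i == z) {
      if (i == z && max(counts) < min_bucket && length(buckets) > 0L) {
        # deficient tail: merge into the previous bucket
        k <- length(buckets)
        buckets[[k]] <- buckets[[k]] + counts
      } else {
        buckets[[length(buckets) + 1L]] <- counts
      }
      counts <- c(0, 0)
    }
  }
  correct <- sum(vapply(buckets, max, numeric(1)))
  100 * correct / z
}

## ---- ReliefF ---------------------------------------------------------------

# Standard ReliefF over all instances: features min-max scaled to [0,1],
# Manhattan distance, k nearest hits and misses (truncated to availability),
# miss contributions weighted by P(class)/(1 - P(own class)).
relieff_scores <- function(dataset, k_neighbors = 10L) {
  x <- minmax_scale(dataset$values)$scaled
  y <- as.integer(dataset$labels)
  z <- nrow(x)
  class_n <- tabulate(y, 2L)
  if (any(class_n < 2L)) {
    stop("ReliefF needs at least 2 instances per class", call. = FALSE)
  }
  prior <- class_n / z
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  w <- numeric(ncol(x))
  for (i in seq_len(z)) {
    own <- y[i]
    for (cls in 1:2) {
      pool <- setdiff(which(y == cls), i)
      k <- min(k_neighbors, length(pool))
      if (k == 0L) next
      nb <- pool[order(d[i, pool], pool)][seq_len(k)]
      diffs <- abs(x[nb, , drop = FALSE] -
        matrix(x[i, ], k, ncol(x), byrow = TRUE))
      mean_diff <- colSums(diffs) / k
      if (cls == own) {
        w <- w - mean_diff / z
      } else {
        w <- w + (prior[cls] / (1 - prior[own])) * mean_diff / z
      }
    }
  }
  names(w) <- colnames(x)
  w
}

## ---- linear SVM weighting & RFE -------------------------------------------

# Min-max scale columns to [0,1]; constant columns map to 0. Returns the
# scaler so test data can be transformed with training-set ranges only.
minmax_scale <- function(x, ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- list(min = apply(x, 2L, min), max = apply(x, 2L, max))
  }
  span <- ranges$max - ranges$min
  span[span == 0] <- 1
  scaled <- sweep(sweep(x, 2L, ranges$min), 2L, span, "/")
  list(scaled = scaled, ranges = ranges)
}

fit_linear_svm <- function(x, y, cost = 1) {
  fit <- e1071::svm(x, y,
    kernel = "linear", cost = cost, scale = FALSE,
    type = "C-classification"
  )
  w <- drop(crossprod(fit$coefs, fit$SV))
  full <- numeric(ncol(x))
  names(full) <- colnames(x)
  full[colnames(fit$SV)] <- w
  list(fit = fit, weights = full)
}

svm_one_scores <- function(dataset, c_parameter = 1) {
  x <- minmax_scale(dataset$values)$scaled
  fit <- fit_linear_svm(x, dataset$labels, cost = c_parameter)
  fit$weights^2
}

# Backward elimination: refit on survivors, drop the ceiling(fraction * m)
# lowest-w^2 genes each round (at least 1, never all). Final ranking is the
# reverse elimination order; within a dropped batch, descending w^2. The
# returned scores encode that ordering (score = N - final rank + 1) so the
# generic sort in rank_features() reproduces it exactly.
svm_rfe_scores <- function(dataset, removal_fraction = 0.10, c_parameter = 1) {
  stopifnot(removal_fraction > 0, removal_fraction < 1)
  x <- minmax_scale(dataset$values)$scaled
  y <- dataset$labels
  n <- ncol(x)
  surviving <- seq_len(n)
  elimination <- integer(0) # gene indices, first eliminated first
  while (length(surviving) > 1L) {
    fit <- fit_linear_svm(x[, surviving, drop = FALSE], y, cost = c_parameter)
    w2 <- fit$weights^2
    n_drop <- min(
      max(1L, ceiling(removal_fraction * length(surviving))),
      length(surviving) - 1L
    )
    # lowest w^2 first; ties by higher original index (so the reversed
    # ranking breaks ties by ascending index)
    ord <- order(w2, -surviving)
    drop_local <- ord[seq_len(n_drop)]
    # within one batch the *ranking* orders by descending w^2, i.e. the
    # batch is appended worst-first
    elimination <- c(elimination, surviving[drop_local])
    surviving <- surviving[-drop_local]
  }
  final_order <- rev(c(elimination, surviving)) # best first
  scores <- numeric(n)
  scores[final_order] <- seq(n, 1)
  names(scores) <- colnames(x)
  scores
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> ranker=%s, N=%d\n", attr(x, "ranker"), nrow(x)))
  NextMethod()
}
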