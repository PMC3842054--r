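#' Draw P stratified train/test subsamples
#'
#' Extracts `p_count` reduced datasets, each holding `floor(fraction_f * Z)`
#' samples drawn without replacement (stratified by class so every reduced
#' dataset and every held-out remainder contains both classes); the test set
#' of split k is exactly the samples not drawn. Splits are drawn
#' independently of each other (not cross-validation folds) and are fully
#' reproducible from the master seed, which is expanded into one sub-seed
#' per split.
#'
#' @param dataset an [expr_dataset] or data frame.
#' @param p_count number of reduced datasets P (default 20).
#' @param fraction_f fraction of samples per reduced dataset (default 0.9).
#' @param seed integer master seed.
#' @return a `subsample_scheme`: list with `splits` (list of
#'   `list(train, test)` integer index vectors), `p_count`, `fraction_f`,
#'   `seed`.
#' @export
draw_subsamples <- function(dataset, p_count = 20L, fraction_f = 0.9, seed) {
  dataset <- as_expr_dataset(dataset)
  stopifnot(p_count >= 1L, fraction_f > 0, fraction_f < 1)
  y <- dataset$labels
  z <- length(y)
  target <- floor(fraction_f * z)
  class_idx <- split(seq_len(z), y)
  n_class <- lengths(class_idx)
  # proportional allocation, then largest remainders, keeping >= 1 train and
  # >= 1 test instance per class
  quota <- fraction_f * n_class
  take <- pmin(pmax(floor(quota), 1L), n_class - 1L)
  short <- target - sum(take)
  if (short > 0L) {
    room <- n_class - 1L - take
    pref <- order(-(quota - floor(quota)), seq_along(take))
    for (ci in rep_len(pref, sum(room))) {
      if (short == 0L) break
      if (take[ci] < n_class[ci] - 1L) {
        take[ci] <- take[ci] + 1L
        short <- short - 1L
      }
    }
  }
  bad <- which(n_class < 2L | take < 1L | take > n_class - 1L)
  if (length(bad) > 0L || sum(take) != target) {
    stop(sprintf(
      "class '%s' is too small to stratify %d training and >=1 test instance(s)",
      levels(y)[if (length(bad)) bad[1L] else which.min(n_class)], target
    ), call. = FALSE)
  }
  split_seeds <- withr::with_seed(
    seed,
    sample.int(.Machine$integer.max - 1L, p_count)
  )
  splits <- lapply(split_seeds, function(s) {
    train <- withr::with_seed(s, {
      sort(unlist(lapply(seq_along(class_idx), function(ci) {
        idx <- class_idx[[ci]]
        idx[sample.int(length(idx), take[ci])]
      }), use.names = FALSE))
    })
    list(train = train, test = setdiff(seq_len(z), train))
  })
  structure(
    list(
      splits = splits, p_count = as.integer(p_count),
      fraction_f = fraction_f, seed = as.integer(seed)
    ),
    class = "subsample_scheme"
  )
}

#' @export
print.subsample_scheme <- function(x, ...) {
  cat(sprintf(
    "<subsample_scheme> P=%d, f=%g, |train|=%d, |test|=%d, seed=%d\n",
    x$p_count, x$fraction_f, length(x$splits[[1L]]$train),
    length(x$splits[[1L]]$test), x$seed
  ))
  invisible(x)
}

# Rank every training subsample once per ranker; shared by stability and
# performance so both read the same lists L_ik. Discretization is computed
# once per split and reused across the four entropic criteria.
subsample_rankings <- function(dataset, rankers, scheme, ...) {
  dataset <- as_expr_dataset(dataset)
  rankers <- vapply(rankers, function(r) {
    match.arg(toupper(r), ranker_names())
  }, character(1))
  lapply(scheme$splits, function(sp) {
    train <- slice_dataset(dataset, samples = sp$train)
    bins <- if (any(rankers %in% entropic_rankers)) {
      discretize_dataset(train)
    }
    stats::setNames(lapply(rankers, function(rk) {
      scores <- ranker_scores(train, rk, bins = bins, ...)
      new_ranked_list(train$gene_ids, scores, rk)
    }), rankers)
  })
}

#' Signatures selected by one ranker across the P subsamples
#'
#' Rankings are computed from the training samples of each split only; the
#' held-out samples never influence selection.
#'
#' @inheritParams evaluate_stability
#' @param t signature size.
#' @return list of P [gene_set]s.
#' @export
subsample_signatures <- function(dataset, ranker, scheme, t, ...) {
  rankings <- subsample_rankings(dataset, ranker, scheme, ...)
  lapply(rankings, function(r) cut_ranking(r[[1L]], t))
}

#' Selection stability of rankers under subsampling
#'
#' For each threshold `t`, every ranker is applied to each of the P reduced
#' datasets, the resulting lists are cut at `t`, and the stability is the
#' average pairwise overlap similarity (off-diagonal mean of the P x P
#' I-overlap matrix) of the P signatures: the more similar the signatures a
#' ranker selects from perturbed versions of the data, the more stable it is.
#'
#' @param dataset an [expr_dataset] or data frame.
#' @param rankers one or more of [ranker_names()].
#' @param scheme a `subsample_scheme` from [draw_subsamples()].
#' @param thresholds signature sizes to evaluate (default `c(5, 10, 20, 30)`).
#' @param ... ranker backend options (see [score_features()]).
#' @return a tibble with columns `ranker`, `t`, `stability`.
#' @export
evaluate_stability <- function(dataset, rankers, scheme,
                               thresholds = c(5L, 10L, 20L, 30L), ...) {
  rankings <- subsample_rankings(dataset, rankers, scheme, ...)
  stability_from_rankings(rankings, thresholds)
}

stability_from_rankings <- function(rankings, thresholds) {
  rankers <- names(rankings[[1L]])
  tidyr::expand_grid(ranker = rankers, t = as.integer(thresholds)) |>
    dplyr::mutate(stability = purrr::map2_dbl(ranker, t, function(rk, tt) {
      sets <- lapply(rankings, function(rl) cut_ranking(rl[[rk]], tt))
      average_offdiagonal(pairwise_similarity_matrix(sets, "overlap"))
    }))
}

#' Train a linear SVM on a signature and score held-out samples
#'
#' Fits a linear soft-margin SVM (C = 1 by default) on the training samples
#' restricted to the given genes, with min-max scaling fitted on the
#' training data only, and returns signed decision values for the test
#' samples, positive toward the positive class.
#'
#' @param train,test [expr_dataset]s over the same genes (the test set is
#'   restricted to the training signature automatically).
#' @param genes optional [gene_set] restricting both datasets.
#' @param c_parameter SVM cost parameter.
#' @return numeric decision values, one per test sample.
#' @export
train_and_score <- function(train, test, genes = NULL, c_parameter = 1) {
  train <- as_expr_dataset(train)
  test <- as_expr_dataset(test)
  if (!is.null(genes)) {
    train <- slice_dataset(train, genes = as_gene_set(genes))
    test <- slice_dataset(test, genes = as_gene_set(genes))
  }
  stopifnot(identical(train$gene_ids, test$gene_ids))
  sc <- minmax_scale(train$values)
  fit <- fit_linear_svm(sc$scaled, train$labels, cost = c_parameter)
  x_test <- minmax_scale(test$values, ranges = sc$ranges)$scaled
  pred <- stats::predict(fit$fit, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm orients decision values toward the class named first in the
  # "A/B" column label; flip when that is not the positive class
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  sign <- if (identical(first, train$positive_class)) 1 else -1
  sign * as.numeric(dv[, 1L])
}

#' Area under the ROC curve from decision values
#'
#' Mann-Whitney statistic: the fraction of (positive, negative) sample pairs
#' in which the positive sample receives the larger score, ties counted 1/2.
#'
#' @param scores numeric decision values, larger meaning more positive.
#' @param labels class labels; a factor whose second level is the positive
#'   class (as in `expr_dataset$labels`), or a logical/0-1 vector.
#' @return a real in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, labels) {
  if (is.factor(labels)) {
    pos <- labels == levels(labels)[2L]
  } else {
    pos <- as.logical(labels)
  }
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC is undefined when only one class is present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Held-out predictive performance of ranker-selected signatures
#'
#' For each split k: rank on the reduced dataset, cut at `t`, train a linear
#' SVM on the reduced dataset restricted to the signature, and score the
#' held-out samples; the AUC of those decision values is averaged over the
#' P splits. Test instances are never seen by the ranker, so the estimate
#' carries no selection bias.
#'
#' @inheritParams evaluate_stability
#' @param c_parameter SVM cost for the induction classifier.
#' @return a tibble with columns `ranker`, `t`, `mean_auc`, `sd_auc`.
#' @export
evaluate_performance <- function(dataset, rankers, scheme,
                                 thresholds = c(5L, 10L, 20L, 30L),
                                 c_parameter = 1, ...) {
  rankings <- subsample_rankings(dataset, rankers, scheme, ...)
  performance_from_rankings(
    as_expr_dataset(dataset), rankings, scheme, thresholds, c_parameter
  )
}

performance_from_rankings <- function(dataset, rankings, scheme, thresholds,
                                      c_parameter = 1) {
  rankers <- names(rankings[[1L]])
  tidyr::expand_grid(ranker = rankers, t = as.integer(thresholds)) |>
    dplyr::mutate(purrr::map2_dfr(ranker, t, function(rk, tt) {
      aucs <- vapply(seq_along(scheme$splits), function(k) {
        sp <- scheme$splits[[k]]
        sig <- cut_ranking(rankings[[k]][[rk]], tt)
        train <- slice_dataset(dataset, samples = sp$train)
        test <- slice_dataset(dataset, samples = sp$test)
        dv <- train_and_score(train, test,
          genes = sig,
          c_parameter = c_parameter
        )
        auc_from_scores(dv, test$labels)
      }, numeric(1))
      tibble::tibble(mean_auc = mean(aucs), sd_auc = stats::sd(aucs))
    }))
}

#' Joint evaluation of stability and predictive performance
#'
#' One experimental setup covering both requirements of a biomarker
#' selection technique: the ranking on each reduced dataset is computed once
#' per ranker and shared by the stability and the AUC evaluation (both cut
#' the same lists at each threshold).
#'
#' @inheritParams evaluate_performance
#' @return a `joint_evaluation` object: list with `profiles` (tibble:
#'   `ranker`, `t`, `stability`, `mean_auc`, `sd_auc`), `scheme`,
#'   `thresholds`, `signatures` (per split, per ranker gene sets at the
#'   largest threshold are recoverable via [subsample_signatures()]).
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_genes = 60, seed = 7))
#' sch <- draw_subsamples(sim$dataset, p_count = 4, seed = 7)
#' je <- joint_evaluation(sim$dataset, c("IG", "RELIEFF"), sch, thresholds = 10)
#' tidy(je)
#' @export
joint_evaluation <- function(dataset, rankers = ranker_names(), scheme,
                             thresholds = c(5L, 10L, 20L, 30L),
                             c_parameter = 1, ...) {
  dataset <- as_expr_dataset(dataset)
  rankings <- subsample_rankings(dataset, rankers, scheme, ...)
  stab <- stability_from_rankings(rankings, thresholds)
  perf <- performance_from_rankings(
    dataset, rankings, scheme, thresholds, c_parameter
  )
  profiles <- dplyr::left_join(stab, perf, by = c("ranker", "t"))
  structure(
    list(
      profiles = profiles,
      scheme = scheme,
      thresholds = as.integer(thresholds)
    ),
    class = "joint_evaluation"
  )
}

#' @export
print.joint_evaluation <- function(x, ...) {
  cat(sprintf(
    "<joint_evaluation> P=%d, f=%g, t in {%s}\n",
    x$scheme$p_count, x$scheme$fraction_f,
    paste(x$thresholds, collapse = ", ")
  ))
  print(x$profiles)
  invisible(x)
}

#' @export
tidy.joint_evaluation <- function(x, ...) x$profiles

#' @export
glance.joint_evaluation <- function(x, ...) {
  x$profiles |>
    dplyr::group_by(.data$ranker) |>
    dplyr::summarise(
      mean_stability = mean(.data$stability),
      mean_auc = mean(.data$mean_auc),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_count = x$scheme$p_count,
      fraction_f = x$scheme$fraction_f,
      seed = x$scheme$seed
    )
}

#' Stability and AUC curves versus signature size
#'
#' @param object a `joint_evaluation`.
#' @param ... unused.
#' @return a ggplot object with one panel per metric.
#' @export
autoplot.joint_evaluation <- function(object, ...) {
  df <- object$profiles |>
    dplyr::select("ranker", "t", "stability", AUC = "mean_auc") |>
    tidyr::pivot_longer(c("stability", "AUC"),
      names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value,
    colour = .data$ranker
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(
      x = "number of genes (t)", y = NULL, colour = "ranker"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
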