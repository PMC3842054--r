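#' Construct an expression dataset
#'
#' An `expr_dataset` holds a samples-by-genes matrix of real-valued expression
#' levels together with a binary class label per sample. It is the common input
#' of every ranker and of the subsampling protocol.
#'
#' The two class symbols are mapped deterministically to a negative and a
#' positive class: unless `positive_class` is given, the lexicographically
#' smaller symbol is the negative class. AUC orientation depends on this
#' mapping, so it is never left to factor-level accidents.
#'
#' @param values numeric matrix, samples in rows, genes in columns. Column
#'   names are the gene identifiers; row names (optional) the sample ids.
#' @param labels vector of length `nrow(values)` over exactly two distinct
#'   symbols.
#' @param positive_class optional label symbol to treat as the positive class.
#' @return an object of class `expr_dataset` with fields `values`, `labels`
#'   (factor, negative level first), `gene_ids`, `sample_ids`,
#'   `negative_class`, `positive_class`.
#' @examples
#' x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
#' ds <- expr_dataset(x, rep(c("normal", "tumor"), 5))
#' ds
#' @export
expr_dataset <- function(values, labels, positive_class = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  if (nrow(values) < 2L) stop("need Z >= 2 samples", call. = FALSE)
  if (ncol(values) < 1L) stop("need N >= 1 genes", call. = FALSE)
  if (length(labels) != nrow(values)) {
    stop("`labels` length must equal the number of samples", call. = FALSE)
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "missing/non-finite expression value at sample %s, gene %s; rows with missing entries are rejected, not imputed",
      bad[1L, 1L], bad[1L, 2L]
    ), call. = FALSE)
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop(sprintf(
      "labels must hold exactly 2 classes, found %d (%s)",
      length(classes), paste(classes, collapse = ", ")
    ), call. = FALSE)
  }
  if (is.null(positive_class)) {
    negative <- classes[1L]
    positive <- classes[2L]
  } else {
    positive_class <- as.character(positive_class)
    if (!positive_class %in% classes) {
      stop(sprintf("positive_class '%s' is not a label symbol", positive_class),
        call. = FALSE
      )
    }
    positive <- positive_class
    negative <- setdiff(classes, positive)
  }
  gene_ids <- colnames(values)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%0*d", nchar(ncol(values)), seq_len(ncol(values)))
    colnames(values) <- gene_ids
  }
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop(sprintf("duplicate gene id: '%s'", dup), call. = FALSE)
  }
  sample_ids <- rownames(values)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%0*d", nchar(nrow(values)), seq_len(nrow(values)))
    rownames(values) <- sample_ids
  }
  structure(
    list(
      values = values,
      labels = factor(labels, levels = c(negative, positive)),
      gene_ids = gene_ids,
      sample_ids = sample_ids,
      negative_class = negative,
      positive_class = positive
    ),
    class = "expr_dataset"
  )
}

#' Coerce to an expression dataset
#'
#' Data frames are interpreted as samples in rows with one label column; all
#' remaining columns must be numeric gene columns.
#'
#' @param x an `expr_dataset`, or a data frame.
#' @param label_column name of the class-label column (data-frame method).
#' @param ... passed on to [expr_dataset()] (e.g. `positive_class`).
#' @return an `expr_dataset`.
#' @export
as_expr_dataset <- function(x, ...) UseMethod("as_expr_dataset")

#' @export
as_expr_dataset.expr_dataset <- function(x, ...) x

#' @rdname as_expr_dataset
#' @export
as_expr_dataset.data.frame <- function(x, label_column = "class", ...) {
  if (!label_column %in% names(x)) {
    stop(sprintf("label column '%s' not found", label_column), call. = FALSE)
  }
  labels <- x[[label_column]]
  rest <- x[setdiff(names(x), label_column)]
  non_num <- names(rest)[!vapply(rest, is.numeric, logical(1))]
  if (length(non_num) > 0L) {
    stop(sprintf(
      "non-numeric expression column(s): %s",
      paste(non_num, collapse = ", ")
    ), call. = FALSE)
  }
  values <- as.matrix(rest)
  rn <- attr(x, "row.names")
  if (is.character(rn)) rownames(values) <- rn
  expr_dataset(values, labels, ...)
}

#' @export
print.expr_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "<expr_dataset> %d samples x %d genes\n  classes: %s (negative, n=%d) vs %s (positive, n=%d)\n",
    nrow(x$values), ncol(x$values),
    x$negative_class, tab[[1L]], x$positive_class, tab[[2L]]
  ))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Subset an expression dataset by samples and/or genes
#'
#' @param x an `expr_dataset`.
#' @param samples sample indices or ids (default: all).
#' @param genes gene indices or ids (default: all).
#' @return an `expr_dataset` over the requested slice. Both classes must
#'   survive sample subsetting.
#' @export
slice_dataset <- function(x, samples = NULL, genes = NULL) {
  x <- as_expr_dataset(x)
  if (is.null(samples)) samples <- seq_along(x$sample_ids)
  if (is.null(genes)) genes <- x$gene_ids
  values <- x$values[samples, genes, drop = FALSE]
  expr_dataset(values, as.character(x$labels)[samples],
    positive_class = x$positive_class
  )
}

#' @importFrom generics tidy
#' @export
tidy.expr_dataset <- function(x, ...) {
  tibble::as_tibble(x$values) |>
    dplyr::mutate(
      sample = x$sample_ids,
      class = as.character(x$labels),
      .before = 1L
    ) |>
    tidyr::pivot_longer(-c("sample", "class"),
      names_to = "gene", values_to = "expression"
    )
}

#' @importFrom generics glance
#' @export
glance.expr_dataset <- function(x, ...) {
  tab <- table(x$labels)
  tibble::tibble(
    n_samples = nrow(x$values),
    n_genes = ncol(x$values),
    negative_class = x$negative_class,
    positive_class = x$positive_class,
    n_negative = as.integer(tab[[1L]]),
    n_positive = as.integer(tab[[2L]])
  )
}
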