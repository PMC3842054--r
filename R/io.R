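#' Read a delimited expression table
#'
#' Reads a comma- or tab-delimited text file with a header row into an
#' [expr_dataset]. The table may be laid out samples-in-rows (one label column)
#' or genes-in-rows (one label *row*, identified by its row id in the first
#' column); both orientations yield identical datasets. Gene order is
#' preserved as in the file. Files with missing or non-numeric expression
#' cells, duplicate gene ids, or more than two class symbols are rejected.
#'
#' @param path file location.
#' @param orientation `"samples"` if rows are samples (default) or `"genes"`
#'   if rows are genes and columns are samples.
#' @param label_column name of the column (or, for `orientation = "genes"`,
#'   of the row) holding the class labels.
#' @param sample_column optional name of a sample-id column (samples
#'   orientation only); used as sample ids when present, ignored otherwise.
#' @param positive_class optional symbol to treat as the positive class;
#'   by default the lexicographically larger symbol.
#' @param delim field delimiter; guessed from the file extension / first line
#'   when `NULL`.
#' @return an `expr_dataset`.
#' @export
read_expression_table <- function(path, orientation = c("samples", "genes"),
                                  label_column = "class",
                                  sample_column = "sample",
                                  positive_class = NULL, delim = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(delim)) delim <- guess_delim(path)
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (orientation == "genes") {
    first <- names(raw)[1L]
    ids <- raw[[first]]
    lab_row <- which(ids == label_column)
    if (length(lab_row) != 1L) {
      stop(sprintf("label row '%s' not found in first column", label_column),
        call. = FALSE
      )
    }
    labels <- unlist(raw[lab_row, -1L], use.names = FALSE)
    gene_ids <- ids[-lab_row]
    cells <- as.matrix(raw[-lab_row, -1L])
    values <- t(parse_numeric_cells(cells, gene_ids, names(raw)[-1L],
      rows_are_genes = TRUE
    ))
    rownames(values) <- names(raw)[-1L]
    colnames(values) <- gene_ids
  } else {
    if (!label_column %in% names(raw)) {
      stop(sprintf("label column '%s' not found", label_column), call. = FALSE)
    }
    labels <- raw[[label_column]]
    sample_ids <- NULL
    if (!is.null(sample_column) && sample_column %in% names(raw)) {
      sample_ids <- raw[[sample_column]]
      raw[[sample_column]] <- NULL
    }
    gene_ids <- setdiff(names(raw), label_column)
    cells <- as.matrix(raw[gene_ids])
    values <- parse_numeric_cells(
      cells, sample_ids %||% seq_len(nrow(raw)), gene_ids,
      rows_are_genes = FALSE
    )
    rownames(values) <- sample_ids
    colnames(values) <- gene_ids
  }
  expr_dataset(values, labels, positive_class = positive_class)
}

guess_delim <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) {
    return("\t")
  }
  if (ext == "csv") {
    return(",")
  }
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

parse_numeric_cells <- function(cells, row_ids, col_ids, rows_are_genes) {
  suppressWarnings(num <- array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is.na(cells) | is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]
    j <- bad[1L, 2L]
    what <- if (rows_are_genes) "gene" else "sample"
    stop(sprintf(
      "non-numeric expression cell at %s '%s', column '%s' (value: %s)",
      what, row_ids[i], col_ids[j],
      if (is.na(cells[i, j])) "<missing>" else dQuote(cells[i, j])
    ), call. = FALSE)
  }
  num
}

#' Write an expression dataset as delimited text
#'
#' Writes samples in rows with a `sample` id column and a `class` label
#' column. Doubles are written so that re-reading reproduces them bit-exactly.
#'
#' @param dataset an [expr_dataset] (or coercible data frame).
#' @param path output file; `.csv` or `.tsv` selects the delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(dataset, path) {
  dataset <- as_expr_dataset(dataset)
  df <- tibble::as_tibble(dataset$values)
  df <- dplyr::mutate(df,
    sample = dataset$sample_ids,
    class = as.character(dataset$labels), .before = 1L
  )
  if (tolower(tools::file_ext(path)) == "tsv") {
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a minimal ARFF expression file
#'
#' Minimal WEKA-heritage support: numeric attributes plus exactly one nominal
#' class attribute.
#'
#' @inheritParams read_expression_table
#' @return an `expr_dataset`.
#' @export
read_arff_expression <- function(path, positive_class = NULL) {
  if (!requireNamespace("foreign", quietly = TRUE)) {
    stop("reading ARFF requires the 'foreign' package", call. = FALSE)
  }
  df <- foreign::read.arff(path)
  nominal <- names(df)[vapply(df, is.factor, logical(1))]
  if (length(nominal) != 1L) {
    stop(sprintf(
      "expected exactly one nominal class attribute, found %d",
      length(nominal)
    ), call. = FALSE)
  }
  as_expr_dataset(df,
    label_column = nominal,
    positive_class = positive_class
  )
}

#' Write a ranked gene list as two-column TSV
#'
#' @param ranking a ranked list as returned by [rank_features()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranking, path) {
  readr::write_tsv(ranking[c("gene", "score")], path, progress = FALSE)
  invisible(path)
}

#' Write a similarity matrix as labeled TSV or JSON
#'
#' @param m a [similarity_matrix].
#' @param path output file; format chosen by `.json` vs anything else (TSV).
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path) {
  stopifnot(inherits(m, "similarity_matrix"))
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(
      list(
        index = attr(m, "index_name"),
        labels = rownames(m),
        values = unclass_matrix(m),
        average_offdiagonal = average_offdiagonal(m)
      ),
      path,
      digits = NA, auto_unbox = TRUE, pretty = TRUE
    )
  } else {
    df <- tibble::as_tibble(unclass_matrix(m), rownames = "set")
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

unclass_matrix <- function(m) {
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  m
}

#' Write stability / performance profiles as tidy TSV or JSON
#'
#' @param profiles a tibble of per-ranker, per-threshold metrics (as returned
#'   by [evaluate_stability()], [evaluate_performance()], or the `$profiles`
#'   element of [joint_evaluation()]).
#' @param path output file; `.json` selects JSON, otherwise TSV.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(profiles, path, digits = NA, pretty = TRUE)
  } else {
    readr::write_tsv(profiles, path, progress = FALSE)
  }
  invisible(path)
}
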