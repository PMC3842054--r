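#' Read a subset of an OBO ontology
#'
#' Parses OBO 1.2-style `[Term]` stanzas, interpreting only `id`, `name`,
#' `namespace`, `is_a` and `is_obsolete` tags. Obsolete terms and terms
#' outside the requested namespace are dropped. The surviving `is_a` graph
#' must be acyclic and every referenced parent must exist in the subset;
#' a dangling `is_a` reference is an error naming the missing id.
#'
#' @param path OBO file location.
#' @param namespace ontology aspect to keep (default `"molecular_function"`,
#'   the aspect used for functional signature comparison); `NULL` keeps all.
#' @return an `ontology_dag` with fields `terms`, `parents` (named list of
#'   character vectors), `children`, `roots`, `names`, `namespace`.
#' @export
read_obo_subset <- function(path, namespace = "molecular_function") {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  terms <- character(0)
  term_names <- character(0)
  parents <- list()
  for (s in term_starts) {
    after <- starts[starts > s]
    end <- if (length(after)) min(after) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    tag <- function(name) {
      sub(sprintf("^%s:\\s*", name), "", grep(sprintf("^%s:", name), block,
        value = TRUE
      ))
    }
    id <- tag("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    ns <- tag("namespace")[1L]
    if (!is.null(namespace) && !is.na(ns) && ns != namespace) next
    if (!is.null(namespace) && is.na(ns)) next
    isa <- sub("\\s*!.*$", "", tag("is_a"))
    isa <- trimws(isa)
    terms <- c(terms, id)
    nm <- tag("name")[1L]
    term_names <- c(term_names, if (is.na(nm)) id else nm)
    parents[[id]] <- isa[nzchar(isa)]
  }
  if (length(terms) == 0L) {
    stop(sprintf(
      "no non-obsolete terms in namespace '%s'", namespace %||% "<any>"
    ), call. = FALSE)
  }
  names(term_names) <- terms
  ontology_dag(terms, parents, term_names, namespace %||% NA_character_)
}

#' Construct an ontology DAG from terms and is_a parent links
#'
#' @param terms character vector of term identifiers.
#' @param parents named list mapping each term to its is_a parents (terms
#'   with no entry, or an empty entry, are roots).
#' @param term_names optional named character vector of human-readable names.
#' @param namespace ontology aspect label.
#' @return an `ontology_dag`.
#' @export
ontology_dag <- function(terms, parents, term_names = NULL,
                         namespace = "molecular_function") {
  terms <- as.character(terms)
  stopifnot(!anyDuplicated(terms))
  parents <- parents[intersect(names(parents), terms)]
  full <- stats::setNames(vector("list", length(terms)), terms)
  full[names(parents)] <- parents
  full <- lapply(full, function(p) as.character(p %||% character(0)))
  referenced <- unique(unlist(full, use.names = FALSE))
  missing <- setdiff(referenced, terms)
  if (length(missing) > 0L) {
    stop(sprintf(
      "is_a references unknown term(s): %s", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  # Kahn topological sort doubles as the cycle check
  indeg <- vapply(full, length, integer(1))
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (tm in terms) {
    for (p in full[[tm]]) children[[p]] <- c(children[[p]], tm)
  }
  queue <- terms[indeg == 0L]
  seen <- 0L
  indeg_work <- indeg
  while (length(queue) > 0L) {
    tm <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[tm]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) {
    cyc <- terms[indeg_work > 0L]
    stop(sprintf(
      "cyclic is_a chain involving: %s", paste(cyc, collapse = ", ")
    ), call. = FALSE)
  }
  if (is.null(term_names)) term_names <- stats::setNames(terms, terms)
  structure(
    list(
      terms = terms,
      parents = full,
      children = lapply(children, function(x) as.character(x %||% character(0))),
      roots = terms[indeg == 0L],
      names = term_names,
      namespace = namespace
    ),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf(
    "<ontology_dag> %d terms, %d root(s), namespace %s\n",
    length(x$terms), length(x$roots), x$namespace
  ))
  invisible(x)
}

# All is_a ancestors of a term, the term itself included.
term_ancestors <- function(term, ontology) {
  out <- character(0)
  frontier <- term
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- setdiff(
      unique(unlist(ontology$parents[frontier], use.names = FALSE)), out
    )
  }
  out
}

#' Read gene-to-term annotations
#'
#' Two-column delimited text (gene id, term id), or minimal GAF 2.x (gene
#' symbol in column 3, term id in column 5) when `format = "gaf"`. The
#' mapping is restricted to terms present in `ontology`; genes whose every
#' term falls outside it are recorded as unannotated. Malformed lines are
#' skipped with a warning carrying the final count.
#'
#' @param path annotation file.
#' @param ontology an `ontology_dag`.
#' @param format `"tsv"` (default) or `"gaf"`.
#' @return an `annotation_map`: a named list gene -> character vector of
#'   terms, with attribute `unannotated` listing genes that lost all terms.
#' @export
read_annotations <- function(path, ontology, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!")]
  gene_col <- if (format == "gaf") 3L else 1L
  term_col <- if (format == "gaf") 5L else 2L
  need <- max(gene_col, term_col)
  pairs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t|,")[[1L]]
    if (length(f) < need || !nzchar(f[gene_col]) || !nzchar(f[term_col])) {
      return(NULL)
    }
    c(trimws(f[gene_col]), trimws(f[term_col]))
  })
  skipped <- sum(vapply(pairs, is.null, logical(1)))
  if (skipped > 0L) {
    warning(sprintf(
      "skipped %d malformed annotation line(s); kept %d",
      skipped, length(pairs) - skipped
    ), call. = FALSE)
  }
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  if (length(pairs) == 0L) {
    return(annotation_map(list(), ontology))
  }
  df <- data.frame(
    gene = vapply(pairs, `[`, character(1), 1L),
    term = vapply(pairs, `[`, character(1), 2L)
  )
  raw <- split(df$term, df$gene)
  annotation_map(lapply(raw, unique), ontology)
}

#' Construct an annotation map
#'
#' @param gene_to_terms named list gene -> character vector of term ids.
#' @param ontology an `ontology_dag`; terms absent from it are dropped.
#' @return an `annotation_map`.
#' @export
annotation_map <- function(gene_to_terms, ontology) {
  stopifnot(inherits(ontology, "ontology_dag"))
  cleaned <- lapply(gene_to_terms, function(tt) {
    intersect(unique(as.character(tt)), ontology$terms)
  })
  unannotated <- names(cleaned)[lengths(cleaned) == 0L]
  cleaned <- cleaned[lengths(cleaned) > 0L]
  structure(cleaned,
    class = "annotation_map",
    unannotated = unannotated %||% character(0)
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf(
    "<annotation_map> %d annotated gene(s), %d term assignment(s), %d unannotated\n",
    length(x), sum(lengths(x)), length(attr(x, "unannotated"))
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
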