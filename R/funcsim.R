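#' Annotate a gene set with its ontology terms
#'
#' Collects the union of the terms annotating each gene of a signature, the
#' first step of functional (semantic) signature comparison. Genes with no
#' surviving annotation are listed separately rather than silently dropped.
#'
#' @param genes a [gene_set] or character vector of gene ids.
#' @param annotations an [annotation_map].
#' @return a `term_set`: list with `terms` (character), `source_genes`,
#'   `unannotated_genes`.
#' @export
annotate_gene_set <- function(genes, annotations) {
  genes <- as_gene_set(genes)
  stopifnot(inherits(annotations, "annotation_map"))
  hit <- intersect(genes, names(annotations))
  structure(
    list(
      terms = unique(unlist(annotations[hit], use.names = FALSE)) %||% character(0),
      source_genes = unclass(genes),
      unannotated_genes = setdiff(unclass(genes), hit)
    ),
    class = "term_set"
  )
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf(
    "<term_set> %d term(s) from %d gene(s) (%d unannotated)\n",
    length(x$terms), length(x$source_genes), length(x$unannotated_genes)
  ))
  invisible(x)
}

#' Information content of ontology terms
#'
#' The information content of a term is `-log2 p(term)`, where `p` is the
#' fraction of annotated genes annotated to the term or to any of its
#' descendants (annotations propagate up the is_a graph, so the root always
#' has `p = 1` and IC 0). The annotation corpus is the supplied map itself:
#' no external frequency tables, so results are self-contained.
#'
#' Terms that annotate no gene, even via descendants, have undefined IC and
#' are excluded with a warning.
#'
#' @param ontology an `ontology_dag`.
#' @param annotations an [annotation_map] over the same ontology.
#' @return named numeric vector of IC values (bits) for the covered terms.
#' @export
term_information_content <- function(ontology, annotations) {
  stopifnot(inherits(ontology, "ontology_dag"))
  stopifnot(inherits(annotations, "annotation_map"))
  n_genes <- length(annotations)
  if (n_genes == 0L) {
    stop("no annotated genes: information content is undefined", call. = FALSE)
  }
  counts <- stats::setNames(integer(length(ontology$terms)), ontology$terms)
  for (gene_terms in annotations) {
    closure <- unique(unlist(
      lapply(gene_terms, term_ancestors, ontology = ontology),
      use.names = FALSE
    ))
    counts[closure] <- counts[closure] + 1L
  }
  uncovered <- names(counts)[counts == 0L]
  if (length(uncovered) > 0L) {
    warning(sprintf(
      "%d term(s) annotate no gene (even via descendants) and are excluded: %s",
      length(uncovered), paste(utils::head(uncovered, 5L), collapse = ", ")
    ), call. = FALSE)
    counts <- counts[counts > 0L]
  }
  -log2(counts / n_genes)
}

#' Lin semantic similarity between two terms
#'
#' `2 * IC(MICA) / (IC(t1) + IC(t2))`, where MICA is the common is_a
#' ancestor with maximum information content. Identical informative terms
#' score 1; terms whose only common ancestor is the root (IC 0) score 0.
#'
#' @param t1,t2 term identifiers.
#' @param ontology an `ontology_dag`.
#' @param ic named IC vector from [term_information_content()] (or an
#'   [annotation_map], from which IC is computed on the fly).
#' @return a real in `[0, 1]`, or `NA` if either term has undefined IC.
#' @export
term_pair_similarity <- function(t1, t2, ontology, ic) {
  if (inherits(ic, "annotation_map")) {
    ic <- term_information_content(ontology, ic)
  }
  if (!t1 %in% names(ic) || !t2 %in% names(ic)) {
    return(NA_real_)
  }
  common <- intersect(
    term_ancestors(t1, ontology),
    term_ancestors(t2, ontology)
  )
  common <- intersect(common, names(ic))
  mica_ic <- if (length(common) == 0L) 0 else max(ic[common])
  denom <- ic[[t1]] + ic[[t2]]
  if (denom == 0) {
    return(0)
  }
  2 * mica_ic / denom
}

#' Functional similarity between two term sets (best-match average)
#'
#' Every term of one set is matched to its most similar term in the other
#' set (Lin similarity over is_a ancestors); the two directional averages
#' are themselves averaged. This is the semantic counterpart of the overlap
#' index: signatures sharing no genes can still score high when their genes
#' carry the same molecular functions.
#'
#' @param a,b `term_set` objects (or character vectors of term ids).
#' @param ontology an `ontology_dag`.
#' @param ic named IC vector (or an [annotation_map]).
#' @return a real in `[0, 1]`, or `NA` when either set is empty (undefined,
#'   reported as missing rather than 0).
#' @export
termset_similarity <- function(a, b, ontology, ic) {
  if (inherits(ic, "annotation_map")) {
    ic <- term_information_content(ontology, ic)
  }
  ta <- term_ids(a)
  tb <- term_ids(b)
  ta <- intersect(ta, names(ic))
  tb <- intersect(tb, names(ic))
  if (length(ta) == 0L || length(tb) == 0L) {
    return(NA_real_)
  }
  sim <- outer(ta, tb, Vectorize(function(x, y) {
    term_pair_similarity(x, y, ontology, ic)
  }))
  (mean(apply(sim, 1L, max)) + mean(apply(sim, 2L, max))) / 2
}

term_ids <- function(x) {
  if (inherits(x, "term_set")) x$terms else as.character(x)
}

#' Pairwise functional similarity matrix over term sets
#'
#' @param sets named list of `term_set`s (or character term vectors).
#' @param ontology an `ontology_dag`.
#' @param annotations an [annotation_map] (the IC corpus).
#' @return a [similarity_matrix] with index name `I-functional`; pairs
#'   involving an empty term set are `NA`.
#' @export
functional_similarity_matrix <- function(sets, ontology, annotations) {
  ic <- if (inherits(annotations, "annotation_map")) {
    term_information_content(ontology, annotations)
  } else {
    annotations
  }
  labels <- names(sets) %||% paste0("set", seq_along(sets))
  m <- length(sets)
  values <- diag(1, m)
  for (i in seq_len(m)) {
    if (length(intersect(term_ids(sets[[i]]), names(ic))) == 0L) {
      values[i, i] <- NA_real_
    }
  }
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        values[i, j] <- values[j, i] <-
          termset_similarity(sets[[i]], sets[[j]], ontology, ic)
      }
    }
  }
  similarity_matrix(values, labels, "I-functional")
}
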