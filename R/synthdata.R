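#' Specification of a synthetic two-class expression dataset
#'
#' Describes the statistical structure the generator plants: a small sample
#' count, thousands of background genes drawn i.i.d. standard normal, a
#' small set of truly informative genes whose mean is shifted in the
#' positive class, and optional redundant blocks of correlated markers
#' (one latent informative signal shared, with independent noise, by every
#' gene of the block). The defaults emulate a typical small two-class
#' microarray benchmark at a size convenient for simulation studies: 60
#' samples, 1000 genes, 10 informative genes shifted by 2 standard
#' deviations, balanced classes.
#'
#' @param z_samples number of samples Z.
#' @param n_genes number of genes N.
#' @param n_informative number of independently informative genes.
#' @param effect_size mean shift of informative genes in the positive class,
#'   in units of the noise standard deviation.
#' @param n_redundant_blocks number of correlated marker blocks.
#' @param block_size genes per block.
#' @param block_correlation target pairwise (within-class) correlation of
#'   block genes, in `[0, 1)`.
#' @param class_balance proportion of positive samples; labels are assigned
#'   deterministically (`ceiling(class_balance * Z)` positives) and rows
#'   shuffled under the seed, so class proportions are exact.
#' @param noise_sd standard deviation of the background noise.
#' @param seed integer seed; the same spec always generates the same matrix.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(z_samples = 60L, n_genes = 1000L,
                           n_informative = 10L, effect_size = 2.0,
                           n_redundant_blocks = 0L, block_size = 5L,
                           block_correlation = 0.9, class_balance = 0.5,
                           noise_sd = 1.0, seed = 1L) {
  spec <- list(
    z_samples = as.integer(z_samples), n_genes = as.integer(n_genes),
    n_informative = as.integer(n_informative), effect_size = effect_size,
    n_redundant_blocks = as.integer(n_redundant_blocks),
    block_size = as.integer(block_size),
    block_correlation = block_correlation,
    class_balance = class_balance, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (spec$z_samples < 4L) stop("need z_samples >= 4", call. = FALSE)
  if (spec$n_informative + spec$n_redundant_blocks * spec$block_size >
    spec$n_genes) {
    stop("informative + block genes exceed n_genes", call. = FALSE)
  }
  if (spec$block_correlation < 0 || spec$block_correlation >= 1) {
    stop("block_correlation must be in [0, 1)", call. = FALSE)
  }
  if (spec$class_balance <= 0 || spec$class_balance >= 1) {
    stop("class_balance must be in (0, 1)", call. = FALSE)
  }
  if (spec$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

#' The redundant-markers scenario
#'
#' A fixed scenario exhibiting marker redundancy: besides 4 independent
#' informative genes, two blocks of 5 highly correlated markers
#' (within-class correlation 0.9) carry the class signal. With signatures of
#' size 10 cut from 14 ground-truth genes, rankers that spread weight across
#' a correlated block select interchangeable representatives on different
#' subsamples — the mechanism by which redundancy depresses selection
#' stability without hurting predictive performance.
#'
#' @param seed integer seed.
#' @return a `synthetic_spec`.
#' @export
redundant_spec <- function(seed = 1L) {
  synthetic_spec(
    z_samples = 60L, n_genes = 300L, n_informative = 4L, effect_size = 2.0,
    n_redundant_blocks = 2L, block_size = 5L, block_correlation = 0.9,
    seed = seed
  )
}

#' Generate a synthetic expression dataset with planted markers
#'
#' Background genes are i.i.d. normal with standard deviation `noise_sd`;
#' informative genes additionally receive a `+effect_size * noise_sd` mean
#' shift in the positive class. Each redundant block shares one latent
#' informative signal: block gene `g = sqrt(rho) * latent +
#' sqrt(1 - rho) * eps_g`, which yields pairwise within-class correlation
#' `rho` and a class shift of `sqrt(rho) * effect_size` standard deviations,
#' while keeping unit marginal variance.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (an [expr_dataset], classes `negative` /
#'   `positive`) and `markers` (character vector of all planted gene ids:
#'   informative genes and block genes).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  z <- spec$z_samples
  n <- spec$n_genes
  n_pos <- ceiling(spec$class_balance * z)
  labels <- c(rep("positive", n_pos), rep("negative", z - n_pos))
  gene_ids <- sprintf("g%04d", seq_len(n))
  info_idx <- seq_len(spec$n_informative)
  block_idx <- if (spec$n_redundant_blocks > 0L) {
    split(
      spec$n_informative + seq_len(spec$n_redundant_blocks * spec$block_size),
      rep(seq_len(spec$n_redundant_blocks), each = spec$block_size)
    )
  } else {
    list()
  }
  values <- withr::with_seed(spec$seed, {
    x <- matrix(stats::rnorm(z * n, sd = spec$noise_sd), z, n)
    is_pos <- labels == "positive"
    shift <- spec$effect_size * spec$noise_sd
    for (g in info_idx) x[is_pos, g] <- x[is_pos, g] + shift
    rho <- spec$block_correlation
    for (idx in block_idx) {
      latent <- stats::rnorm(z, sd = spec$noise_sd)
      latent[is_pos] <- latent[is_pos] + shift
      for (g in idx) {
        x[, g] <- sqrt(rho) * latent +
          sqrt(1 - rho) * stats::rnorm(z, sd = spec$noise_sd)
      }
    }
    perm <- sample.int(z)
    x <- x[perm, , drop = FALSE]
    attr(x, "perm") <- perm
    x
  })
  perm <- attr(values, "perm")
  attr(values, "perm") <- NULL
  colnames(values) <- gene_ids
  rownames(values) <- sprintf("s%03d", seq_len(z))
  ds <- expr_dataset(values, labels[perm], positive_class = "positive")
  markers <- gene_ids[c(info_idx, unlist(block_idx, use.names = FALSE))]
  list(dataset = ds, markers = markers)
}

#' Generate a toy ontology and gene annotations
#'
#' Builds a random is_a tree of the stated depth (a single root; every
#' non-root term has exactly one parent) and annotates each gene to 1-3
#' random leaf terms. Deterministic under the seed; useful as a
#' self-contained fixture for functional-similarity analysis.
#'
#' @param n_terms total number of terms (>= 2).
#' @param depth tree depth (root = depth 0).
#' @param genes character vector of gene ids to annotate.
#' @param seed integer seed.
#' @param namespace ontology aspect label.
#' @return list with `ontology` (an `ontology_dag`) and `annotations`
#'   (an [annotation_map]).
#' @export
generate_toy_ontology <- function(n_terms, depth, genes, seed = 1L,
                                  namespace = "molecular_function") {
  stopifnot(n_terms >= 2L, depth >= 1L)
  terms <- sprintf("T%07d", seq_len(n_terms))
  withr::with_seed(seed, {
    level <- integer(n_terms)
    parents <- stats::setNames(vector("list", n_terms), terms)
    # guarantee the requested depth by chaining the first terms, then attach
    # the rest to random existing terms of level < depth
    spine <- seq_len(min(depth + 1L, n_terms))
    level[spine] <- spine - 1L
    for (i in spine[-1L]) parents[[terms[i]]] <- terms[i - 1L]
    rest <- setdiff(seq_len(n_terms), spine)
    for (i in rest) {
      eligible <- which(level[seq_len(i - 1L)] < depth)
      p <- eligible[sample.int(length(eligible), 1L)]
      parents[[terms[i]]] <- terms[p]
      level[i] <- level[p] + 1L
    }
    has_child <- terms %in% unlist(parents, use.names = FALSE)
    leaves <- terms[!has_child]
    ann <- stats::setNames(lapply(genes, function(g) {
      k <- sample.int(3L, 1L)
      leaves[sample.int(length(leaves), min(k, length(leaves)))]
    }), genes)
    ontology <- ontology_dag(terms, parents, namespace = namespace)
    list(ontology = ontology, annotations = annotation_map(ann, ontology))
  })
}
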