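# Fixtures and independent oracles shared across the suite.

# A small, perfectly separable two-gene dataset: gene A separates the
# classes, gene B is constant noise-free junk.
toy_separable <- function() {
  values <- cbind(
    A = c(0, 0.1, 0.2, 1.0, 1.1, 1.2),
    B = c(0.5, 0.4, 0.6, 0.5, 0.6, 0.4)
  )
  expr_dataset(values, c("n", "n", "n", "t", "t", "t"))
}

# Dataset built from an explicit bins x class contingency table, so the
# univariate scorers can be driven through the full pipeline. Bin index is
# used directly as the expression value with a gap > 1 between bins, which
# MDL-discretizes back to the same bins whenever the association is strong
# enough; for oracle tests we bypass discretization and score the table.
dataset_from_bins <- function(bins, labels) {
  expr_dataset(cbind(g = as.numeric(bins) * 10), labels)
}

# Independent entropy/chi-squared oracles: straightforward loops over an
# explicit contingency table, sharing no code with the package internals.
oracle_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    return(0)
  }
  p <- counts / sum(counts)
  s <- 0
  for (pi in p) s <- s - pi * log(pi, base = 2)
  s
}

oracle_scores <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  hc <- oracle_entropy(colSums(tab))
  hx <- oracle_entropy(rowSums(tab))
  hcx <- 0
  for (i in seq_len(nrow(tab))) {
    hcx <- hcx + sum(tab[i, ]) / n * oracle_entropy(tab[i, ])
  }
  ig <- hc - hcx
  chi2 <- 0
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  tt <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tt) >= 2 && ncol(tt) >= 2) {
    for (i in seq_len(nrow(tt))) {
      for (j in seq_len(ncol(tt))) {
        e <- sum(tt[i, ]) * sum(tt[, j]) / n
        chi2 <- chi2 + (tt[i, j] - e)^2 / e
      }
    }
  }
  list(
    chi2 = chi2,
    ig = ig,
    su = if (hc + hx == 0) 0 else 2 * ig / (hc + hx),
    gr = if (hx == 0) 0 else ig / hx
  )
}

# Score a discretized gene through the installed package path: build a
# one-gene dataset whose values are bin indices separated widely enough that
# MDL re-derives exactly those bins is NOT guaranteed for weak associations,
# so oracle comparisons call the internal contingency scorer directly.
package_table_scores <- function(tab) {
  list(
    chi2 = rankstab:::contingency_score(tab, "CHI2"),
    ig = rankstab:::contingency_score(tab, "IG"),
    su = rankstab:::contingency_score(tab, "SU"),
    gr = rankstab:::contingency_score(tab, "GR")
  )
}

# Random bins/labels pair with its contingency table.
random_contingency <- function(max_bins = 4, z = 12) {
  b <- sample.int(max_bins, z, replace = TRUE)
  y <- sample.int(2, z, replace = TRUE)
  table(b, y)
}

# Minimal OBO writer for parser tests.
write_toy_obo <- function(lines, path = tempfile(fileext = ".obo")) {
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

# A hand-specified five-term molecular-function DAG:
#       R
#      / \
#     A   B
#    / \
#   C   D
hand_dag <- function() {
  ontology_dag(
    terms = c("R", "A", "B", "C", "D"),
    parents = list(A = "R", B = "R", C = "A", D = "A")
  )
}

# Annotations over hand_dag(): 8 genes, leaf-level assignments chosen so the
# propagated term frequencies are easy to verify by hand.
hand_annotations <- function(dag = hand_dag()) {
  annotation_map(
    list(
      x1 = "C", x2 = "C", x3 = "D", x4 = "D",
      x5 = "B", x6 = "B", x7 = "B", x8 = "B"
    ),
    dag
  )
}

# Brute-force best-match-average over an explicit pair-similarity matrix.
oracle_bma <- function(ta, tb, pairsim) {
  fwd <- mean(vapply(ta, function(u) {
    max(vapply(tb, function(v) pairsim(u, v), numeric(1)))
  }, numeric(1)))
  rev <- mean(vapply(tb, function(v) {
    max(vapply(ta, function(u) pairsim(u, v), numeric(1)))
  }, numeric(1)))
  (fwd + rev) / 2
}

# Independent iterative (stack-based) Fayyad-Irani implementation used as
# the dual route for the recursive discretizer.
oracle_mdl <- function(values, labels) {
  y <- as.integer(factor(labels))
  cuts <- numeric(0)
  stack <- list(order(values))
  while (length(stack) > 0) {
    idx <- stack[[1]]
    stack <- stack[-1]
    v <- values[idx]
    yy <- y[idx]
    n <- length(idx)
    if (n < 2 || length(unique(yy)) < 2) next
    cand <- which(diff(v) > 0)
    if (length(cand) == 0) next
    ent <- function(t) oracle_entropy(tabulate(t, nbins = max(y)))
    es <- ent(yy)
    best_gain <- -Inf
    best_i <- NA
    for (i in cand) {
      e1 <- ent(yy[seq_len(i)])
      e2 <- ent(yy[(i + 1):n])
      gain <- es - (i * e1 + (n - i) * e2) / n
      if (gain > best_gain + 1e-12) {
        best_gain <- gain
        best_i <- i
      }
    }
    i <- best_i
    k <- length(unique(yy))
    k1 <- length(unique(yy[seq_len(i)]))
    k2 <- length(unique(yy[(i + 1):n]))
    e1 <- ent(yy[seq_len(i)])
    e2 <- ent(yy[(i + 1):n])
    delta <- log2(3^k - 2) - (k * es - k1 * e1 - k2 * e2)
    if (best_gain > (log2(n - 1) + delta) / n) {
      cuts <- c(cuts, (v[i] + v[i + 1]) / 2)
      stack <- c(stack, list(idx[seq_len(i)]), list(idx[(i + 1):n]))
    }
  }
  sort(cuts)
}
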