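test_that("scorers reproduce hand-computed values on the reference table", {
  tab <- matrix(c(3, 1, 1, 3), 2, 2) # bins x classes [[3,1],[1,3]]
  s <- package_table_scores(tab)
  expect_equal(s$chi2, 2.0)
  expect_equal(s$ig, 1 - (-0.75 * log2(0.75) - 0.25 * log2(0.25)),
    tolerance = 1e-12
  )
  expect_equal(s$ig, 0.18872, tolerance = 1e-4)
  # H(X) = H(C) = 1 here, so SU and GR coincide with IG
  expect_equal(s$su, s$ig, tolerance = 1e-12)
  expect_equal(s$gr, s$ig, tolerance = 1e-12)
})

test_that("perfect association scores at the theoretical maxima", {
  tab <- matrix(c(4, 0, 0, 4), 2, 2) # bin identical to class, Z = 8
  s <- package_table_scores(tab)
  expect_equal(s$chi2, 8) # chi2 = n under perfect association
  expect_equal(s$ig, 1)
  expect_equal(s$su, 1)
  expect_equal(s$gr, 1)
})

test_that("constant genes score zero under every univariate criterion", {
  tab <- matrix(c(4, 4), 1, 2) # single bin
  s <- package_table_scores(tab)
  expect_equal(unlist(s), c(chi2 = 0, ig = 0, su = 0, gr = 0))
  ds <- expr_dataset(
    cbind(flat = rep(1, 8), good = c(1, 1, 1, 1, 9, 9, 9, 9)),
    rep(c("a", "b"), each = 4)
  )
  for (rk in c("CHI2", "IG", "SU", "GR")) {
    sc <- score_features(ds, rk)
    expect_equal(sc$score[sc$gene == "flat"], 0)
    expect_gt(sc$score[sc$gene == "good"], 0)
  }
})

test_that("univariate scorers equal brute-force formula evaluation on random tables", {
  set.seed(2024)
  for (i in 1:1000) {
    tab <- random_contingency()
    got <- package_table_scores(tab)
    want <- oracle_scores(tab)
    for (nm in names(want)) {
      expect_equal(got[[nm]], want[[nm]],
        tolerance = 1e-10,
        label = sprintf("%s on table %d", nm, i)
      )
    }
  }
})

test_that("information-theoretic bounds hold on random tables", {
  set.seed(99)
  for (i in 1:300) {
    tab <- random_contingency(max_bins = 5)
    s <- package_table_scores(tab)
    hc <- oracle_entropy(colSums(tab))
    hx <- oracle_entropy(rowSums(tab))
    expect_gte(s$chi2, 0)
    expect_lte(s$ig, min(hc, hx) + 1e-12)
    expect_gte(s$ig, -1e-12)
    expect_true(s$su >= 0 && s$su <= 1 + 1e-12)
    expect_true(s$gr >= 0 && s$gr <= 1 + 1e-12)
  }
})

test_that("ranking sorts by descending score with index tie-breaks", {
  rl <- rankstab:::new_ranked_list(c("a", "b", "c"), c(0.2, 0.9, 0.2), "IG")
  expect_identical(rl$gene, c("b", "a", "c"))
  expect_identical(rl$rank, 1:3)
  tied <- rankstab:::new_ranked_list(c("a", "b", "c"), c(1, 1, 1), "IG")
  expect_identical(tied$gene, c("a", "b", "c")) # original gene order
})

test_that("scores are invariant under sample reordering", {
  sim <- generate_dataset(synthetic_spec(
    z_samples = 30, n_genes = 20, n_informative = 4, seed = 5
  ))
  ds <- sim$dataset
  perm <- withr::with_seed(1, sample.int(30))
  shuffled <- rankstab::slice_dataset(ds, samples = perm)
  for (rk in c("CHI2", "IG", "SU", "GR", "ONER", "RELIEFF", "SVM_ONE")) {
    # the SVM solver is iterative, so its weights are order-invariant only
    # up to solver tolerance
    tol <- if (rk == "SVM_ONE") 1e-3 else 1e-10
    expect_equal(
      score_features(ds, rk),
      score_features(shuffled, rk),
      tolerance = tol, label = rk
    )
  }
})

test_that("univariate scores do not depend on which other genes are present", {
  sim <- generate_dataset(synthetic_spec(
    z_samples = 24, n_genes = 12, n_informative = 3, seed = 8
  ))
  ds <- sim$dataset
  sub <- slice_dataset(ds, genes = ds$gene_ids[1:4])
  for (rk in c("CHI2", "IG", "SU", "GR", "ONER")) {
    full <- score_features(ds, rk)
    part <- score_features(sub, rk)
    expect_equal(
      full$score[match(part$gene, full$gene)], part$score,
      label = rk
    )
  }
})

test_that("rankings are invariant under gene-column permutation", {
  sim <- generate_dataset(synthetic_spec(
    z_samples = 40, n_genes = 15, n_informative = 5, seed = 13
  ))
  ds <- sim$dataset
  perm <- withr::with_seed(2, sample.int(15))
  permuted <- slice_dataset(ds, genes = ds$gene_ids[perm])
  for (rk in ranker_names()) {
    r1 <- rank_features(ds, rk)
    r2 <- rank_features(permuted, rk)
    # unique scores -> identical gene-id ordering regardless of column order
    if (!any(duplicated(signif(r1$score, 16)))) {
      expect_identical(r1$gene, r2$gene, info = rk)
    }
  }
})

test_that("cutting a ranked list yields the unordered top-t signature", {
  rl <- rankstab:::new_ranked_list(
    paste0("g", 1:5), c(5, 4, 3, 2, 1), "CHI2"
  )
  expect_identical(unclass(cut_ranking(rl, 1)), "g1", ignore_attr = TRUE)
  expect_setequal(cut_ranking(rl, 5), paste0("g", 1:5))
  s <- cut_ranking(rl, 3)
  expect_length(s, 3L)
  expect_identical(attr(s, "ranker"), "CHI2")
  expect_error(cut_ranking(rl, 0), "t must be")
  expect_error(cut_ranking(rl, 6), "t must be")
})

test_that("OneR scores a perfectly splitting gene at 100 and a constant at the base rate", {
  v <- c(rnorm(10, 0), rnorm(10, 20))
  ds <- expr_dataset(
    cbind(split = v, flat = rep(1, 20)),
    rep(c("a", "b"), each = 10)
  )
  sc <- score_features(ds, "ONER")
  expect_equal(sc$score[sc$gene == "split"], 100)
  expect_equal(sc$score[sc$gene == "flat"], 50) # majority class rate
  skew <- expr_dataset(
    cbind(flat = rep(1, 20)),
    c(rep("a", 14), rep("b", 6))
  )
  expect_equal(score_features(skew, "ONER")$score, 70)
})

test_that("OneR bucketing respects the minimum bucket size", {
  # alternating classes along the axis: no clear-majority bucket forms, so
  # one big bucket remains and accuracy equals the majority rate
  v <- 1:12
  y <- rep(c("a", "b"), 6)
  ds <- expr_dataset(cbind(g = v), y)
  expect_lte(score_features(ds, "ONER")$score, 100 * 7 / 12)
})

test_that("ReliefF weights separate informative from noise genes", {
  # two well-separated clusters of 4+4 on the informative gene
  informative <- c(0, 0.05, 0.1, 0.15, 1, 1.05, 1.1, 1.15)
  noise <- c(0.4, 0.9, 0.1, 0.6, 0.5, 0.2, 0.8, 0.3)
  ds <- expr_dataset(
    cbind(inf = informative, noi = noise),
    rep(c("a", "b"), each = 4)
  )
  sc <- score_features(ds, "RELIEFF", k_neighbors = 3)
  expect_gt(sc$score[sc$gene == "inf"], sc$score[sc$gene == "noi"])
  expect_gt(sc$score[sc$gene == "inf"], 0)
})

test_that("ReliefF hit terms vanish on duplicated instances and flat genes score 0", {
  base <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  dup <- rbind(base, base)
  y <- rep(c("x", "x", "y", "y"), 2)
  ds <- expr_dataset(dup, y)
  sc <- score_features(ds, "RELIEFF", k_neighbors = 1)
  # nearest hit of every instance is its duplicate (distance 0), so only
  # miss terms contribute: weights must be non-negative
  expect_true(all(sc$score >= 0))
  flat <- expr_dataset(
    cbind(g = rep(1, 8)),
    rep(c("x", "y"), 4)
  )
  expect_equal(score_features(flat, "RELIEFF")$score, 0)
})

test_that("ReliefF refuses single-instance classes", {
  ds <- expr_dataset(cbind(g = c(1, 2, 3)), c("a", "a", "b"))
  expect_error(score_features(ds, "RELIEFF"), "2 instances per class")
})
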