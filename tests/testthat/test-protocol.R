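make_protocol_dataset <- function(seed = 1) {
  generate_dataset(synthetic_spec(
    z_samples = 40, n_genes = 30, n_informative = 5, effect_size = 2,
    seed = seed
  ))$dataset
}

test_that("subsample sizes follow the floor(f * Z) convention", {
  # the 62-sample benchmark shape: |train| = floor(0.9 * 62) = 55, |test| = 7
  labels <- c(rep("tumor", 40), rep("normal", 22))
  ds <- expr_dataset(matrix(rnorm(62 * 5), 62, 5), labels)
  sch <- draw_subsamples(ds, p_count = 20, fraction_f = 0.9, seed = 1)
  expect_length(sch$splits, 20L)
  for (sp in sch$splits) {
    expect_length(sp$train, 55L)
    expect_length(sp$test, 7L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), 1:62)
    expect_length(unique(ds$labels[sp$train]), 2L)
    expect_length(unique(ds$labels[sp$test]), 2L)
  }
})

test_that("subsampling is reproducible from the master seed and varies across splits", {
  ds <- make_protocol_dataset()
  s1 <- draw_subsamples(ds, p_count = 5, seed = 99)
  s2 <- draw_subsamples(ds, p_count = 5, seed = 99)
  expect_identical(s1, s2)
  s3 <- draw_subsamples(ds, p_count = 5, seed = 100)
  expect_false(identical(s1$splits, s3$splits))
  trains <- lapply(s1$splits, `[[`, "train")
  expect_gt(length(unique(trains)), 1L)
})

test_that("classes too small to stratify are reported by name", {
  ds <- expr_dataset(
    matrix(rnorm(10 * 3), 10, 3),
    c(rep("big", 9), "tiny")
  )
  expect_error(draw_subsamples(ds, p_count = 2, fraction_f = 0.9, seed = 1),
    "tiny"
  )
})

test_that("stability is exactly 1 when every split selects the same set", {
  ds <- make_protocol_dataset()
  sch <- draw_subsamples(ds, p_count = 4, seed = 2)
  # t = N: every signature is the full gene set
  st <- evaluate_stability(ds, "IG", sch, thresholds = ncol(ds$values))
  expect_equal(st$stability, 1)
})

test_that("stability equals the average pairwise overlap of the selected sets", {
  sets <- list(
    gene_set(c("a", "b")), gene_set(c("b", "c")), gene_set(c("a", "b"))
  )
  m <- pairwise_similarity_matrix(sets)
  expect_equal(average_offdiagonal(m), mean(c(1 / 3, 1, 1 / 3)))
  expect_equal(average_offdiagonal(m), 0.5556, tolerance = 1e-4)
})

test_that("AUC is the Mann-Whitney statistic with half-credited ties", {
  expect_equal(auc_from_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_from_scores(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auc_from_scores(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  labs <- factor(c("n", "p", "n", "p"), levels = c("n", "p"))
  expect_equal(auc_from_scores(c(0.1, 0.9, 0.2, 0.8), labs), 1)
  expect_error(auc_from_scores(1:3, c(1, 1, 1)), "one class")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:20) {
    y <- sample(0:1, 30, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(30), 1) # coarse scores force ties
    want <- as.numeric(pROC::auc(pROC::roc(y, s,
      quiet = TRUE,
      direction = "<", levels = c(0, 1)
    )))
    expect_equal(auc_from_scores(s, y), want, tolerance = 1e-12)
  }
})

test_that("decision values point toward the positive class", {
  sim <- generate_dataset(synthetic_spec(
    z_samples = 24, n_genes = 6, n_informative = 3, effect_size = 3,
    seed = 21
  ))
  ds <- sim$dataset
  train <- slice_dataset(ds, samples = 1:18)
  test <- slice_dataset(ds, samples = 19:24)
  dv <- train_and_score(train, test)
  pos <- test$labels == "positive"
  expect_true(all(dv[pos] > 0))
  expect_true(all(dv[!pos] < 0))
  # test samples identical to training samples land on their own side
  i_pos <- which(train$labels == "positive")[1]
  i_neg <- which(train$labels == "negative")[1]
  test2 <- slice_dataset(ds, samples = c(i_pos, i_neg))
  dv2 <- train_and_score(train, test2)
  expect_gt(dv2[1], 0)
  expect_lt(dv2[2], 0)
})

test_that("training on a signature restricts both train and test genes", {
  ds <- make_protocol_dataset()
  train <- slice_dataset(ds, samples = 1:30)
  test <- slice_dataset(ds, samples = 31:40)
  sig <- gene_set(ds$gene_ids[1:5])
  dv <- train_and_score(train, test, genes = sig)
  expect_length(dv, 10L)
})

test_that("held-out AUC is perfect on cleanly separable synthetic data", {
  sim <- generate_dataset(synthetic_spec(
    z_samples = 40, n_genes = 50, n_informative = 10, effect_size = 3,
    seed = 4
  ))
  sch <- draw_subsamples(sim$dataset, p_count = 5, seed = 4)
  perf <- evaluate_performance(sim$dataset, "IG", sch, thresholds = 10)
  expect_equal(perf$mean_auc, 1)
  expect_equal(perf$sd_auc, 0)
})

test_that("a single-split scheme reduces to one fold's AUC", {
  ds <- make_protocol_dataset()
  sch <- draw_subsamples(ds, p_count = 1, seed = 6)
  perf <- evaluate_performance(ds, "IG", sch, thresholds = 5)
  sp <- sch$splits[[1]]
  sig <- subsample_signatures(ds, "IG", sch, t = 5)[[1]]
  dv <- train_and_score(
    slice_dataset(ds, samples = sp$train),
    slice_dataset(ds, samples = sp$test),
    genes = sig
  )
  expect_equal(perf$mean_auc, auc_from_scores(dv, ds$labels[sp$test]))
  expect_true(is.na(perf$sd_auc))
})

test_that("permuted labels drive held-out AUC to chance level", {
  set.seed(33)
  aucs <- vapply(1:12, function(s) {
    sim <- generate_dataset(synthetic_spec(
      z_samples = 40, n_genes = 30, n_informative = 5, seed = s
    ))
    ds <- sim$dataset
    null_ds <- expr_dataset(
      ds$values, withr::with_seed(1000 + s, sample(as.character(ds$labels))),
      positive_class = "positive"
    )
    sch <- draw_subsamples(null_ds, p_count = 3, seed = s)
    mean(evaluate_performance(null_ds, "IG", sch, thresholds = 5)$mean_auc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12) # Monte-Carlo slack
})

test_that("rankings never see the held-out samples (no selection bias)", {
  ds <- make_protocol_dataset()
  sch <- draw_subsamples(ds, p_count = 4, seed = 17)
  for (rk in c("IG", "RELIEFF", "SVM_RFE")) {
    sigs <- subsample_signatures(ds, rk, sch, t = 8)
    for (k in seq_along(sch$splits)) {
      # perturb only split k's held-out samples; its signature must not move
      perturbed <- ds
      test_idx <- sch$splits[[k]]$test
      perturbed$values[test_idx, ] <-
        perturbed$values[test_idx, ] * 5 + 1000
      sigs2 <- subsample_signatures(perturbed, rk, sch, t = 8)
      expect_setequal(unclass(sigs[[k]]), unclass(sigs2[[k]]))
    }
  }
})

test_that("the joint evaluation is consistent with the separate evaluations", {
  ds <- make_protocol_dataset()
  sch <- draw_subsamples(ds, p_count = 3, seed = 8)
  je <- joint_evaluation(ds, "SU", sch, thresholds = c(5, 10))
  st <- evaluate_stability(ds, "SU", sch, thresholds = c(5, 10))
  pf <- evaluate_performance(ds, "SU", sch, thresholds = c(5, 10))
  expect_equal(je$profiles$stability, st$stability)
  expect_equal(je$profiles$mean_auc, pf$mean_auc)
  expect_equal(je$profiles$sd_auc, pf$sd_auc)
  expect_true(all(je$profiles$stability >= 0 & je$profiles$stability <= 1))
  expect_true(all(je$profiles$mean_auc >= 0 & je$profiles$mean_auc <= 1))
})

test_that("tidy, glance and autoplot expose the joint profiles", {
  ds <- make_protocol_dataset()
  sch <- draw_subsamples(ds, p_count = 3, seed = 12)
  je <- joint_evaluation(ds, c("IG", "CHI2"), sch, thresholds = c(5, 10))
  td <- tidy(je)
  expect_identical(nrow(td), 4L)
  gl <- glance(je)
  expect_identical(nrow(gl), 2L)
  expect_true(all(c("mean_stability", "mean_auc") %in% names(gl)))
  expect_s3_class(ggplot2::autoplot(je), "ggplot")
})
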