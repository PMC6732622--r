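test_that("negative sampling is balanced, disjoint and uniform", {
  A <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("u1", "u2"), c("d1", "d2")))
  am <- association_matrix(A)
  ds <- sample_negatives(am, seed = 1)
  expect_equal(nrow(ds$negatives), 2)      # forced: only two zero cells
  expect_equal(nrow(ds$positives), 2)
  key <- function(df) paste(df$drug_index, df$disease_index)
  expect_length(intersect(key(ds$positives), key(ds$negatives)), 0)
  expect_identical(sample_negatives(am, seed = 7)$negatives,
                   sample_negatives(am, seed = 7)$negatives)

  # frequency of each zero cell across seeded draws is near-uniform
  A4 <- matrix(0, 4, 4, dimnames = list(paste0("u", 1:4), paste0("d", 1:4)))
  A4[1, 1] <- A4[2, 2] <- 1                # 2 positives, 14 zero cells
  am4 <- association_matrix(A4)
  counts <- integer(16)
  n_draw <- 2000
  for (s in seq_len(n_draw)) {
    neg <- sample_negatives(am4, seed = s)$negatives
    cells <- (neg$disease_index - 1) * 4 + neg$drug_index
    counts[cells] <- counts[cells] + 1
  }
  p <- 2 / 14
  expected <- n_draw * p
  sd3 <- 3 * sqrt(n_draw * p * (1 - p))
  zero_cells <- setdiff(1:16, c(1, 6))
  expect_true(all(abs(counts[zero_cells] - expected) <= sd3))
  expect_equal(sum(counts[c(1, 6)]), 0)
})

test_that("fold assignment balances sizes and classes", {
  fx <- small_fixture()
  ds <- sample_negatives(fx$assoc, seed = 2)
  ds <- assign_folds(ds, 10, seed = 3)
  s <- ds$samples
  sizes <- table(s$fold)
  expect_length(sizes, 10)
  expect_lte(diff(range(sizes)), 1)
  by_class <- table(s$fold, s$label)
  expect_lte(diff(range(by_class[, "1"])), 1)
  expect_lte(diff(range(by_class[, "0"])), 1)
  expect_equal(sort(unique(s$fold)), 1:10)
  # 23 samples over 10 folds: sizes in {2,3} with exactly three 3s
  ds23 <- ds; ds23$samples <- s[1:23, ]
  ds23 <- assign_folds(ds23, 10, seed = 4)
  t23 <- table(ds23$samples$fold)
  expect_equal(sort(unname(c(t23))), c(rep(2, 7), rep(3, 3)))
  expect_error(assign_folds(ds, 1, seed = 1), "k must be")
})

test_that("classifiers memorize a toy set and score within [0, 1]", {
  set.seed(15)
  X <- rbind(matrix(rnorm(20, 0), 5, 4), matrix(rnorm(20, 4), 5, 4))
  y <- rep(c(0, 1), each = 5)
  cfg <- run_config(n_trees = 50L)
  rf <- train_random_forest(X, y, cfg, seed = 1)
  sc <- predict_scores(rf, X)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(as.numeric(sc >= 0.5), y)
  # single tree votes 0/1
  rf1 <- train_random_forest(X, y, run_config(n_trees = 1L), seed = 1)
  expect_true(all(predict_scores(rf1, X) %in% c(0, 1)))
  # SVM is a drop-in: same contract on a separable toy
  sv <- train_svm(X, y, cfg, seed = 1)
  ssc <- predict_scores(sv, X)
  expect_true(all(ssc >= 0 & ssc <= 1))
  expect_equal(as.numeric(ssc >= 0.5), y)
  expect_error(train_random_forest(X, rep(1, 10), cfg), "single class")
  expect_error(train_svm(X, rep(0, 10), cfg), "single class")
})

test_that("confusion counts follow the >= threshold convention", {
  cc <- confusion(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 1, FP = 0, TN = 1, FN = 0))
  # scores equal to the threshold are predicted positive
  cc2 <- confusion(rep(0.5, 4), c(1, 1, 0, 0), 0.5)
  expect_equal(cc2$TP, 2); expect_equal(cc2$FP, 2)
  # random case vs an explicit tally
  set.seed(16)
  sc <- runif(200); y <- rbinom(200, 1, 0.5); t <- 0.37
  cc3 <- confusion(sc, y, t)
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in 1:200) {
    pred <- sc[i] >= t
    if (pred && y[i] == 1) tp <- tp + 1
    else if (pred) fp <- fp + 1
    else if (y[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_equal(unlist(cc3[c("TP", "FP", "TN", "FN")]),
               c(TP = tp, FP = fp, TN = tn, FN = fn))
  expect_error(confusion(1, c(1, 0)), "length")
})

test_that("metrics match hand arithmetic and report NA when undefined", {
  m <- confusion_metrics(structure(list(TP = 9, FP = 1, TN = 9, FN = 1),
                                   class = "confusion_counts"))
  expect_equal(unname(m), rep(0.9, 4))
  m2 <- confusion_metrics(structure(list(TP = 0, FP = 0, TN = 10, FN = 0),
                                    class = "confusion_counts"))
  expect_equal(unname(m2["acc"]), 1)
  expect_true(all(is.na(m2[c("prec", "recall", "f1")])))
  expect_error(confusion_metrics(structure(
    list(TP = 0, FP = 0, TN = 0, FN = 0), class = "confusion_counts")),
    "no evaluated")
})

test_that("F1 is the harmonic mean of precision and recall", {
  set.seed(17)
  for (i in 1:300) {
    cc <- structure(as.list(c(TP = sample(0:20, 1), FP = sample(0:20, 1),
                              TN = sample(0:20, 1), FN = sample(0:20, 1))),
                    class = "confusion_counts")
    if (sum(unlist(cc)) == 0) next
    m <- confusion_metrics(cc)
    if (!is.na(m["prec"]) && !is.na(m["recall"]) &&
        (m["prec"] + m["recall"]) > 0) {
      hm <- 2 * m["prec"] * m["recall"] / (m["prec"] + m["recall"])
      expect_equal(unname(m["f1"]), unname(hm), tolerance = 1e-12)
    }
    expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
  }
})

test_that("AUC equals pair counting, pROC, and known limits", {
  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  set.seed(18)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    sc <- round(runif(n), 2)   # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    got <- roc_auc(sc, y)$auc
    expect_equal(got, oracle_auc(sc, y))
    expect_equal(got,
                 as.numeric(pROC::roc(y, sc, levels = c(0, 1),
                                      direction = "<", quiet = TRUE)$auc))
  }
  # independent labels at large n sit near 1/2
  set.seed(19)
  sc <- runif(4000); y <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_auc(sc, y)$auc - 0.5), 0.05)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
  # ROC endpoints are (0,0) and (1,1)
  r <- roc_auc(c(0.2, 0.8, 0.5), c(0, 1, 1))$roc
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[nrow(r)], r$tpr[nrow(r)]), c(1, 1))
})

test_that("score distribution bins match an explicit histogram", {
  sd1 <- score_distribution(rep(0.95, 5), rep(1, 5))
  expect_equal(sd1$prop_positive[10], 1)
  set.seed(20)
  sc <- runif(500); y <- rbinom(500, 1, 0.4)
  d <- score_distribution(sc, y)
  expect_equal(sum(d$prop_positive), 1)
  expect_equal(sum(d$prop_negative), 1)
  for (b in 1:10) {
    lo <- (b - 1) / 10; hi <- b / 10
    inb <- if (b < 10) sc >= lo & sc < hi else sc >= lo & sc <= hi
    expect_equal(d$prop_positive[b], sum(inb & y == 1) / sum(y == 1))
    expect_equal(d$prop_negative[b], sum(inb & y == 0) / sum(y == 0))
  }
  expect_error(score_distribution(numeric(0), numeric(0)), "empty")
})

test_that("cross-validation reports are complete and deterministic", {
  fx <- small_fixture()
  cfg <- fast_config(rng_seed = 11)
  rep1 <- cross_validate(fx$assoc, fx$fingerprints, fx$semantic, cfg)
  expect_equal(nrow(rep1$per_fold), cfg$cv_folds)
  for (col in c("acc", "prec", "recall", "f1", "auc")) {
    expect_gte(rep1$mean[col], min(rep1$per_fold[[col]]))
    expect_lte(rep1$mean[col], max(rep1$per_fold[[col]]))
  }
  rep2 <- cross_validate(fx$assoc, fx$fingerprints, fx$semantic, cfg)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_identical(rep1$scores, rep2$scores)
})

test_that("masked-kernel mode keeps nulls near chance on small fixtures", {
  # labels placed uniformly at random: no learnable structure
  aucs <- numeric(3)
  for (s in 1:3) {
    fx <- small_fixture(seed = 100 + s)
    A <- fx$assoc$A
    Ap <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
    set.seed(900 + s)
    Ap[sample(length(Ap), sum(A))] <- 1
    cfg <- fast_config(rng_seed = s, gip_leakage_mode = "train_only")
    rep <- cross_validate(association_matrix(Ap), fx$fingerprints,
                          fx$semantic, cfg)
    aucs[s] <- rep$mean["auc"]
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("leave-disease-out ranking is complete and leak-free", {
  fx <- small_fixture()
  cfg <- fast_config(rng_seed = 21)
  target <- fx$assoc$disease_ids[1]
  rk <- rank_drugs_for_disease(target, fx$assoc, fx$fingerprints,
                               fx$semantic, cfg)
  expect_equal(nrow(rk$ranking), length(fx$assoc$drug_ids))
  expect_setequal(rk$ranking$drug_id, fx$assoc$drug_ids)
  expect_true(all(diff(rk$ranking$score) <= 0))
  expect_true(all(rk$ranking$score >= 0 & rk$ranking$score <= 1))
  # retraining with the target column already zeroed changes nothing
  A0 <- fx$assoc$A; A0[, 1] <- 0
  rk0 <- rank_drugs_for_disease(target, association_matrix(A0),
                                fx$fingerprints, fx$semantic, cfg)
  expect_identical(rk$ranking, rk0$ranking)
  expect_error(rank_drugs_for_disease("nope", fx$assoc, fx$fingerprints,
                                      fx$semantic, cfg), "unknown disease")
})
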