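#' Draw balanced negative samples from the unlabeled pairs
#'
#' All known associations become positive samples; an equal number of
#' negatives is drawn uniformly without replacement from the zero cells of
#' the association matrix.
#'
#' @param assoc an \code{\link{association_matrix}}.
#' @param seed integer RNG seed for the draw.
#' @return object of class \code{pair_dataset}: data frame \code{samples}
#'   with columns drug_index, disease_index, label (fold assignment added
#'   by \code{\link{assign_folds}}), plus \code{positives}/\code{negatives}
#'   index data frames.
#' @export
sample_negatives <- function(assoc, seed = 1L) {
  A <- assoc$A
  pos_cells <- which(A == 1)
  zero_cells <- which(A == 0)
  n_pos <- length(pos_cells)
  if (length(zero_cells) < n_pos)
    stop("not enough unlabeled pairs to draw balanced negatives")
  neg_cells <- with_seed(seed, sample(zero_cells, n_pos))
  to_df <- function(cells) {
    idx <- arrayInd(cells, dim(A))
    data.frame(drug_index = idx[, 1], disease_index = idx[, 2])
  }
  pos <- to_df(pos_cells); neg <- to_df(neg_cells)
  samples <- rbind(cbind(pos, label = 1), cbind(neg, label = 0))
  rownames(samples) <- NULL
  structure(list(samples = samples, positives = pos, negatives = neg),
            class = "pair_dataset")
}

#' Assign stratified cross-validation folds
#'
#' Samples are partitioned into k random folds whose sizes differ by at
#' most one; when labels are present each class is balanced across folds
#' to within one sample as well.
#'
#' @param dataset a \code{pair_dataset}.
#' @param k number of folds (2 <= k <= sample count).
#' @param seed RNG seed for the shuffle.
#' @return the dataset with a \code{fold} column added to \code{samples}.
#' @export
assign_folds <- function(dataset, k = 10L, seed = 1L) {
  s <- dataset$samples
  n <- nrow(s)
  if (k < 2 || k > n) stop("k must be in [2, number of samples]")
  lab <- rep(seq_len(k), length.out = n)
  ord <- with_seed(seed, {
    o <- unlist(lapply(split(seq_len(n), s$label), sample), use.names = FALSE)
    o
  })
  fold <- integer(n)
  fold[ord] <- lab
  dataset$samples$fold <- fold
  dataset
}

#' Train a random-forest pair classifier
#'
#' Seeded ensemble of randomized trees; prediction scores are the fraction
#' of trees voting positive, so thresholding at 0.5 reproduces the
#' majority vote.
#'
#' @param X feature matrix, one pair per row.
#' @param y binary labels (0/1).
#' @param cfg a \code{\link{run_config}} (uses \code{n_trees}).
#' @param seed RNG seed.
#' @return fitted classifier usable with \code{\link{predict_scores}}.
#' @export
train_random_forest <- function(X, y, cfg = run_config(), seed = 1L) {
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  with_seed(seed,
    randomForest::randomForest(x = as.matrix(X),
                               y = factor(y, levels = c(0, 1)),
                               ntree = cfg$n_trees))
}

#' Train an RBF support-vector-machine comparator
#'
#' Same interface as \code{\link{train_random_forest}}: probability-like
#' scores in [0, 1], deterministic under the seed. gamma defaults to
#' 1 / (n_features * overall feature variance), cost 1.
#'
#' @param X feature matrix.
#' @param y binary labels (0/1).
#' @param cfg a \code{\link{run_config}}.
#' @param seed RNG seed (the probability model is fit by internal
#'   cross-validation).
#' @return fitted classifier usable with \code{\link{predict_scores}}.
#' @export
train_svm <- function(X, y, cfg = run_config(), seed = 1L) {
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  X <- as.matrix(X)
  v <- stats::var(as.vector(X))
  gam <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  with_seed(seed,
    e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
               kernel = "radial", cost = 1, gamma = gam,
               probability = TRUE))
}

#' Predict association scores in [0, 1]
#'
#' @param model a classifier from \code{\link{train_random_forest}} or
#'   \code{\link{train_svm}}.
#' @param X feature matrix to score.
#' @return numeric vector of scores (probability of the positive class;
#'   for the random forest, the fraction of trees voting positive).
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  if (inherits(model, "randomForest")) {
    unname(predict(model, X, type = "prob")[, "1"])
  } else if (inherits(model, "svm")) {
    p <- predict(model, X, probability = TRUE)
    unname(attr(p, "probabilities")[, "1"])
  } else stop("unknown classifier type")
}

#' Confusion counts at a decision threshold
#'
#' A sample is called positive when its score is greater than or equal to
#' the threshold.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), same length.
#' @param threshold decision threshold.
#' @return object of class \code{confusion_counts} with TP, FP, TN, FN.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  pred <- scores >= threshold
  structure(list(TP = sum(pred & labels == 1),
                 FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0),
                 FN = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Prec = TP/(TP+FP), Recall = TP/(TP+FN), F1 = 2TP/(2TP+FN+FP),
#' Acc = (TP+TN)/total. A metric whose denominator is zero is reported as
#' NA (undefined), not as 0.
#'
#' @param cc \code{confusion_counts}.
#' @return named numeric vector \code{c(acc, prec, recall, f1)}.
#' @export
confusion_metrics <- function(cc) {
  total <- cc$TP + cc$FP + cc$TN + cc$FN
  if (total == 0) stop("no evaluated samples")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(acc = (cc$TP + cc$TN) / total,
    prec = safe(cc$TP, cc$TP + cc$FP),
    recall = safe(cc$TP, cc$TP + cc$FN),
    f1 = safe(2 * cc$TP, 2 * cc$TP + cc$FN + cc$FP))
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney statistic (probability that a random positive
#' outscores a random negative, ties counted one half); the ROC curve is a
#' threshold sweep over the distinct scores.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1); both classes must be present.
#' @return list with \code{roc} (data frame fpr, tpr, threshold) and
#'   \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("ROC needs both classes present")
  rk <- rank(scores)
  auc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Per-class score histogram over [0, 1]
#'
#' Bins scores into fixed-width bins ([0, 0.1), ..., [0.9, 1.0] by
#' default) and reports the proportion of each class per bin.
#'
#' @param scores numeric scores in [0, 1].
#' @param labels binary labels (0/1).
#' @param bin_width width of the score bins.
#' @return data frame with bin bounds and per-class proportions (each
#'   class's proportions sum to 1).
#' @export
score_distribution <- function(scores, labels, bin_width = 0.1) {
  if (length(scores) == 0) stop("empty score vector")
  nb <- as.integer(round(1 / bin_width))
  bin <- pmin(floor(scores / bin_width) + 1L, nb)
  prop <- function(cls) {
    s <- bin[labels == cls]
    tabulate(s, nbins = nb) / max(length(s), 1L)
  }
  data.frame(bin_low = (seq_len(nb) - 1) * bin_width,
             bin_high = seq_len(nb) * bin_width,
             prop_negative = prop(0), prop_positive = prop(1))
}

# Build the drug and disease descriptor spaces from aligned inputs:
# GIP kernels, cluster-boosted semantic similarity, autoencoder features.
#' Build drug and disease feature descriptors
#'
#' Runs the full feature side of the pipeline: drug and disease GIP
#' kernels from the association matrix, disease-sharing-network clustering
#' and semantic boost, autoencoder training and encoding, kernel/semantic
#' fusion (disease side) and kernel/fingerprint splicing (drug side).
#'
#' @param assoc an \code{\link{association_matrix}}.
#' @param fingerprints aligned \code{\link{fingerprint_matrix}}.
#' @param ds_r aligned \code{\link{semantic_matrix}}.
#' @param cfg a \code{\link{run_config}}.
#' @param ae_seed seed for autoencoder initialization (defaults from
#'   \code{cfg$rng_seed}).
#' @return list with \code{drugs} (\code{drug_descriptors}),
#'   \code{diseases} (\code{disease_descriptors}), plus the intermediate
#'   kernels, clusters and boosted semantic matrix.
#' @export
build_descriptors <- function(assoc, fingerprints, ds_r,
                              cfg = run_config(), ae_seed = NULL) {
  gip_u <- drug_gip(assoc, cfg)
  gip_d <- disease_gip(assoc, cfg)
  net <- build_sharing_network(assoc)
  cl <- cluster_one(net, cfg)
  ds <- boost_semantic(ds_r, cl)
  sim <- fuse_disease_similarity(gip_d, ds)
  ae <- train_autoencoder(fingerprints, cfg, seed = ae_seed)
  fg <- encode_all(fingerprints, ae)
  drugs <- build_drug_descriptors(gip_u, fg)
  list(drugs = drugs, diseases = sim, gip_drug = gip_u, gip_dis = gip_d,
       network = net, clusters = cl, boosted = ds, autoencoder = ae,
       encoded = fg)
}

# Train the configured classifier and score test features; refiner
# (batch norm + ReLU FC) applied when cfg$use_refiner.
fit_and_score <- function(train_pairs, test_X, cfg, refiner_seed, clf_seed) {
  Xtr <- train_pairs$X
  ytr <- train_pairs$samples$label
  if (cfg$use_refiner) {
    rp <- train_refiner(train_pairs, cfg, seed = refiner_seed)
    Xtr <- refine(train_pairs, rp)
    test_X <- refine(test_X, rp)
  }
  model <- if (cfg$classifier == "svm")
    train_svm(Xtr, ytr, cfg, seed = clf_seed)
  else
    train_random_forest(Xtr, ytr, cfg, seed = clf_seed)
  predict_scores(model, test_X)
}

#' k-fold cross-validation of the full pipeline
#'
#' Draws balanced negatives once, assigns stratified folds, and for each
#' fold trains the refiner and classifier on the training folds and scores
#' the held-out fold. In \code{full_matrix} mode the GIP kernels (and the
#' descriptors built from them) are computed once from the complete
#' association matrix — the reference protocol; in \code{train_only} mode
#' each fold's test positives are zeroed in the association matrix before
#' kernels, clustering and fusion are recomputed for that fold.
#'
#' @param assoc an \code{\link{association_matrix}}.
#' @param fingerprints aligned \code{\link{fingerprint_matrix}}.
#' @param ds_r aligned \code{\link{semantic_matrix}}.
#' @param cfg a \code{\link{run_config}}.
#' @return a \code{gipdr_report}: per-fold accuracy/precision/recall/F1/
#'   AUC, their means and standard deviations, the pooled ROC curve and
#'   pooled out-of-fold scores.
#' @export
cross_validate <- function(assoc, fingerprints, ds_r, cfg = run_config()) {
  seeds <- split_seed(cfg$rng_seed, 6)
  k <- cfg$cv_folds
  dset <- sample_negatives(assoc, seed = seeds[1])
  dset <- assign_folds(dset, k, seed = seeds[2])
  samples <- dset$samples
  refiner_seeds <- split_seed(seeds[3], k)
  clf_seeds <- split_seed(seeds[4], k)
  fold_seeds_ae <- seeds[5]

  spaces_full <- NULL
  if (cfg$gip_leakage_mode == "full_matrix")
    spaces_full <- build_descriptors(assoc, fingerprints, ds_r, cfg,
                                     ae_seed = fold_seeds_ae)

  per_fold <- vector("list", k)
  all_scores <- numeric(0); all_labels <- numeric(0)
  for (f in seq_len(k)) {
    test_i <- samples$fold == f
    spaces <- spaces_full
    if (is.null(spaces)) {           # train_only: mask test positives
      A2 <- assoc$A
      tp <- samples[test_i & samples$label == 1, ]
      A2[cbind(tp$drug_index, tp$disease_index)] <- 0
      spaces <- build_descriptors(association_matrix(A2), fingerprints,
                                  ds_r, cfg, ae_seed = fold_seeds_ae)
    }
    train_pairs <- assemble_pairs(samples[!test_i, ], spaces$drugs,
                                  spaces$diseases)
    test_pairs <- assemble_pairs(samples[test_i, ], spaces$drugs,
                                 spaces$diseases)
    sc <- fit_and_score(train_pairs, test_pairs$X, cfg,
                        refiner_seeds[f], clf_seeds[f])
    yte <- test_pairs$samples$label
    m <- confusion_metrics(confusion(sc, yte, cfg$decision_threshold))
    per_fold[[f]] <- c(fold = f, m, auc = roc_auc(sc, yte)$auc)
    all_scores <- c(all_scores, sc)
    all_labels <- c(all_labels, yte)
  }
  pf <- as.data.frame(do.call(rbind, per_fold))
  pooled <- roc_auc(all_scores, all_labels)
  new_report(pf, roc = pooled$roc, scores = all_scores,
             labels = all_labels)
}

#' Leave-disease-out drug ranking
#'
#' Removes every known association of the target disease, retrains the
#' whole pipeline on the remaining positives plus a balanced seeded
#' negative sample (drawn outside the target disease's column), scores
#' every drug against the target disease and returns the full descending
#' ranking (ties broken by drug ID).
#'
#' @param disease_id the target disease's ID.
#' @param assoc an \code{\link{association_matrix}}.
#' @param fingerprints aligned \code{\link{fingerprint_matrix}}.
#' @param ds_r aligned \code{\link{semantic_matrix}}.
#' @param cfg a \code{\link{run_config}}.
#' @return object of class \code{ranked_predictions} with the target
#'   \code{disease_id} and a data frame \code{ranking} (drug_id, score).
#' @export
rank_drugs_for_disease <- function(disease_id, assoc, fingerprints, ds_r,
                                   cfg = run_config()) {
  j <- match(disease_id, assoc$disease_ids)
  if (is.na(j)) stop(sprintf("unknown disease ID: %s", disease_id))
  seeds <- split_seed(cfg$rng_seed, 6)
  A2 <- assoc$A
  A2[, j] <- 0
  assoc2 <- association_matrix(A2)

  pos_cells <- which(A2 == 1)
  zero_cells <- which(A2 == 0)
  keep <- arrayInd(zero_cells, dim(A2))[, 2] != j  # never draw target column
  zero_cells <- zero_cells[keep]
  if (length(zero_cells) < length(pos_cells))
    stop("not enough unlabeled pairs outside the target disease")
  neg_cells <- with_seed(seeds[1], sample(zero_cells, length(pos_cells)))
  idx <- rbind(arrayInd(pos_cells, dim(A2)), arrayInd(neg_cells, dim(A2)))
  samples <- data.frame(drug_index = idx[, 1], disease_index = idx[, 2],
                        label = rep(c(1, 0), each = length(pos_cells)))

  spaces <- build_descriptors(assoc2, fingerprints, ds_r, cfg,
                              ae_seed = seeds[5])
  train_pairs <- assemble_pairs(samples, spaces$drugs, spaces$diseases)
  cand <- data.frame(drug_index = seq_along(assoc$drug_ids),
                     disease_index = j, label = 0)
  cand_pairs <- assemble_pairs(cand, spaces$drugs, spaces$diseases)
  sc <- fit_and_score(train_pairs, cand_pairs$X, cfg,
                      refiner_seed = seeds[3], clf_seed = seeds[4])
  ord <- order(-sc, assoc$drug_ids)
  structure(list(disease_id = disease_id,
                 ranking = data.frame(drug_id = assoc$drug_ids[ord],
                                      score = sc[ord],
                                      stringsAsFactors = FALSE)),
            class = "ranked_predictions")
}
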