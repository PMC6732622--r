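#' Run configuration
#'
#' Bundles every tunable of the pipeline with the defaults that reproduce
#' the reference configuration: GIP bandwidth scale 0.5 on both entity
#' sides, a 64-unit autoencoder trained 200 epochs at learning rate 0.1,
#' a 128-unit batch-norm + ReLU refiner, a 100-tree random forest, and
#' stratified 10-fold cross-validation at decision threshold 0.5.
#'
#' @param gamma_prime_drug,gamma_prime_disease positive bandwidth scale
#'   gamma' for the drug/disease GIP kernels.
#' @param ae_hidden_dim autoencoder hidden width (structural feature
#'   dimension of each drug).
#' @param ae_epochs,ae_learning_rate full-batch gradient-descent schedule
#'   for the autoencoder.
#' @param fc_width width of the ReLU fully-connected refiner layer.
#' @param refiner_epochs,refiner_learning_rate refiner training schedule.
#' @param use_refiner if FALSE the classifier consumes raw fused pair
#'   features and the refiner stage is bypassed.
#' @param n_trees number of trees in the random forest.
#' @param cv_folds number of cross-validation folds.
#' @param decision_threshold score cutoff (score >= threshold is called
#'   positive) for the confusion-matrix metrics.
#' @param rng_seed master seed; every stochastic stage draws its own seed
#'   deterministically from it.
#' @param gip_leakage_mode "full_matrix" computes GIP kernels once from the
#'   complete association matrix (the reference protocol, which lets test
#'   associations influence the kernels); "train_only" zeroes test-fold
#'   positives in the matrix before computing per-fold kernels.
#' @param cluster_penalty_per_node penalty p in the cohesiveness
#'   denominator P(K) = p * |K|.
#' @param cluster_overlap_merge overlap score above which two clusters are
#'   merged, in (0, 1].
#' @param classifier "rf" (random forest) or "svm" (RBF support vector
#'   machine comparator).
#' @return an object of class \code{gipdr_config}.
#' @export
run_config <- function(gamma_prime_drug = 0.5,
                       gamma_prime_disease = 0.5,
                       ae_hidden_dim = 64L,
                       ae_epochs = 200L,
                       ae_learning_rate = 0.1,
                       fc_width = 128L,
                       refiner_epochs = 50L,
                       refiner_learning_rate = 0.05,
                       use_refiner = TRUE,
                       n_trees = 100L,
                       cv_folds = 10L,
                       decision_threshold = 0.5,
                       rng_seed = 1L,
                       gip_leakage_mode = c("full_matrix", "train_only"),
                       cluster_penalty_per_node = 2,
                       cluster_overlap_merge = 0.8,
                       classifier = c("rf", "svm")) {
  gip_leakage_mode <- match.arg(gip_leakage_mode)
  classifier <- match.arg(classifier)
  stopifnot(
    gamma_prime_drug > 0, gamma_prime_disease > 0,
    ae_hidden_dim >= 1, ae_epochs >= 1, ae_learning_rate > 0,
    fc_width >= 1, refiner_epochs >= 1, refiner_learning_rate > 0,
    n_trees >= 1, cv_folds >= 2,
    decision_threshold > 0, decision_threshold < 1,
    cluster_penalty_per_node >= 0,
    cluster_overlap_merge > 0, cluster_overlap_merge <= 1
  )
  structure(list(
    gamma_prime_drug = gamma_prime_drug,
    gamma_prime_disease = gamma_prime_disease,
    ae_hidden_dim = as.integer(ae_hidden_dim),
    ae_epochs = as.integer(ae_epochs),
    ae_learning_rate = ae_learning_rate,
    fc_width = as.integer(fc_width),
    refiner_epochs = as.integer(refiner_epochs),
    refiner_learning_rate = refiner_learning_rate,
    use_refiner = isTRUE(use_refiner),
    n_trees = as.integer(n_trees),
    cv_folds = as.integer(cv_folds),
    decision_threshold = decision_threshold,
    rng_seed = as.integer(rng_seed),
    gip_leakage_mode = gip_leakage_mode,
    cluster_penalty_per_node = cluster_penalty_per_node,
    cluster_overlap_merge = cluster_overlap_merge,
    classifier = classifier
  ), class = "gipdr_config")
}

check_binary_matrix <- function(M, what) {
  bad <- which(!(M %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(M))
    stop(sprintf("%s: non-binary cell at row '%s', column '%s' (value %s)",
                 what, rownames(M)[i[1]], colnames(M)[i[2]], M[bad[1]]),
         call. = FALSE)
  }
  invisible(M)
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("%s: duplicate IDs: %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  invisible(ids)
}

#' Construct a validated binary drug-by-disease association matrix
#'
#' Drugs are rows and diseases are columns; a drug's interaction profile is
#' its row of \code{A}, a disease's profile its column.
#'
#' @param A numeric matrix of 0/1 with drug IDs as rownames and disease IDs
#'   as colnames.
#' @return an object of class \code{association_matrix} with fields
#'   \code{drug_ids}, \code{disease_ids}, \code{A}.
#' @export
association_matrix <- function(A) {
  A <- as.matrix(A)
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("association matrix needs drug rownames and disease colnames")
  if (nrow(A) < 1 || ncol(A) < 1)
    stop("association matrix needs at least one drug and one disease")
  check_unique_ids(rownames(A), "drug IDs")
  check_unique_ids(colnames(A), "disease IDs")
  storage.mode(A) <- "double"
  check_binary_matrix(A, "association matrix")
  structure(list(drug_ids = rownames(A), disease_ids = colnames(A), A = A),
            class = "association_matrix")
}

#' Construct a validated binary drug fingerprint matrix
#'
#' @param F_mat numeric 0/1 matrix, drugs as rows (rownames = drug IDs),
#'   substructure bits as columns.
#' @return an object of class \code{fingerprint_matrix} with fields
#'   \code{drug_ids}, \code{F}.
#' @export
fingerprint_matrix <- function(F_mat) {
  F_mat <- as.matrix(F_mat)
  if (is.null(rownames(F_mat)))
    stop("fingerprint matrix needs drug rownames")
  if (ncol(F_mat) < 1) stop("fingerprint matrix needs at least one bit")
  check_unique_ids(rownames(F_mat), "drug IDs")
  storage.mode(F_mat) <- "double"
  check_binary_matrix(F_mat, "fingerprint matrix")
  structure(list(drug_ids = rownames(F_mat), F = F_mat),
            class = "fingerprint_matrix")
}

#' Construct a validated disease semantic similarity matrix
#'
#' Entries must lie in [0, 1], the matrix must be symmetric, and the
#' diagonal must be 1 (the pre-boost state).
#'
#' @param S square numeric matrix with disease IDs as dimnames.
#' @param tol symmetry tolerance.
#' @return an object of class \code{semantic_matrix} with fields
#'   \code{disease_ids}, \code{S}.
#' @export
semantic_matrix <- function(S, tol = 1e-8) {
  S <- as.matrix(S)
  if (is.null(rownames(S))) stop("semantic matrix needs disease dimnames")
  if (is.null(colnames(S))) colnames(S) <- rownames(S)
  if (nrow(S) != ncol(S)) stop("semantic matrix must be square")
  check_unique_ids(rownames(S), "disease IDs")
  if (!identical(rownames(S), colnames(S)))
    stop("semantic matrix row/column IDs differ")
  storage.mode(S) <- "double"
  if (any(S < -tol) || any(S > 1 + tol))
    stop("semantic similarity entries must lie in [0, 1]")
  if (max(abs(S - t(S))) > tol) stop("semantic matrix must be symmetric")
  if (max(abs(diag(S) - 1)) > tol)
    stop("semantic matrix diagonal must be 1")
  S <- (S + t(S)) / 2
  S[S < 0] <- 0; S[S > 1] <- 1
  diag(S) <- 1
  structure(list(disease_ids = rownames(S), S = S),
            class = "semantic_matrix")
}

read_labeled_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (dialect == "tsv") "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Read a binary association matrix from an ID-labeled TSV/CSV file
#'
#' First row holds disease IDs, first column drug IDs, body cells 0/1.
#'
#' @param path file path.
#' @param dialect "tsv" (default) or "csv".
#' @param quiet suppress the size message.
#' @return an \code{\link{association_matrix}}.
#' @export
read_association_matrix <- function(path, dialect = c("tsv", "csv"),
                                    quiet = FALSE) {
  am <- association_matrix(read_labeled_matrix(path, dialect))
  if (!quiet)
    message(sprintf("associations: %d drugs x %d diseases, %d positives",
                    nrow(am$A), ncol(am$A), sum(am$A)))
  am
}

#' Write an ID-labeled matrix as TSV/CSV
#'
#' Inverse of \code{\link{read_association_matrix}} and friends: first row
#' column IDs, first column row IDs.
#'
#' @param M matrix with dimnames, or one of the package's matrix objects.
#' @param path destination path.
#' @param dialect "tsv" or "csv".
#' @export
write_matrix <- function(M, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (inherits(M, "association_matrix")) M <- M$A
  if (inherits(M, "fingerprint_matrix")) M <- M$F
  if (inherits(M, "semantic_matrix")) M <- M$S
  if (inherits(M, "kernel_matrix")) M <- M$K
  sep <- if (dialect == "tsv") "\t" else ","
  Mc <- M
  if (is.numeric(M)) {             # full precision so round trips are exact
    Mc <- matrix(sprintf("%.17g", M), nrow(M), ncol(M),
                 dimnames = dimnames(M))
  }
  df <- data.frame(id = rownames(Mc), Mc, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and align the three input matrices
#'
#' Reads the association, fingerprint and semantic similarity files and
#' reorders fingerprint rows and semantic rows/columns to the association
#' matrix's drug and disease order. Errors if the ID sets differ.
#'
#' @param assoc_path,fingerprint_path,semantic_path file paths.
#' @param dialect "tsv" or "csv".
#' @return list with elements \code{assoc}, \code{fingerprints},
#'   \code{semantic}.
#' @export
read_aligned_matrices <- function(assoc_path, fingerprint_path,
                                  semantic_path, dialect = c("tsv", "csv")) {
  assoc <- read_association_matrix(assoc_path, dialect, quiet = TRUE)
  fp <- fingerprint_matrix(read_labeled_matrix(fingerprint_path, dialect))
  sem <- semantic_matrix(read_labeled_matrix(semantic_path, dialect))
  align_inputs(assoc, fp, sem)
}

#' Align in-memory matrices to the association matrix's entity order
#'
#' @param assoc an \code{association_matrix}.
#' @param fingerprints a \code{fingerprint_matrix} over the same drug set.
#' @param semantic a \code{semantic_matrix} over the same disease set.
#' @return list(assoc, fingerprints, semantic) with orders reconciled.
#' @export
align_inputs <- function(assoc, fingerprints, semantic) {
  id_mismatch <- function(a, b, what) {
    miss <- setdiff(a, b); extra <- setdiff(b, a)
    if (length(miss) || length(extra))
      stop(sprintf("%s ID mismatch: missing [%s], unexpected [%s]", what,
                   paste(miss, collapse = ", "),
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  id_mismatch(assoc$drug_ids, fingerprints$drug_ids, "drug")
  id_mismatch(assoc$disease_ids, semantic$disease_ids, "disease")
  fp <- fingerprint_matrix(fingerprints$F[assoc$drug_ids, , drop = FALSE])
  sem <- semantic_matrix(
    semantic$S[assoc$disease_ids, assoc$disease_ids, drop = FALSE])
  list(assoc = assoc, fingerprints = fp, semantic = sem)
}

#' Write a cross-validation metrics report as TSV
#'
#' One row per fold (fold, acc, prec, recall, f1, auc) followed by a
#' summary row whose cells are "mean±sd" at six decimals.
#'
#' @param report a \code{gipdr_report} from \code{\link{cross_validate}}.
#' @param path destination path.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "gipdr_report") || nrow(report$per_fold) == 0)
    stop("empty or invalid metrics report")
  pf <- report$per_fold
  fmt <- function(x) sprintf("%.6f", x)
  body <- data.frame(fold = as.character(pf$fold),
                     acc = fmt(pf$acc), prec = fmt(pf$prec),
                     recall = fmt(pf$recall), f1 = fmt(pf$f1),
                     auc = fmt(pf$auc), stringsAsFactors = FALSE)
  pm <- function(m, s) sprintf("%.6f±%.6f", m, s)
  summ <- data.frame(fold = "summary",
                     acc = pm(report$mean["acc"], report$sd["acc"]),
                     prec = pm(report$mean["prec"], report$sd["prec"]),
                     recall = pm(report$mean["recall"], report$sd["recall"]),
                     f1 = pm(report$mean["f1"], report$sd["f1"]),
                     auc = pm(report$mean["auc"], report$sd["auc"]),
                     stringsAsFactors = FALSE)
  write.table(rbind(body, summ), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a metrics report written by \code{\link{write_report}}
#'
#' @param path report path.
#' @return a \code{gipdr_report} (per-fold table plus mean/sd vectors).
#' @export
read_report <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(df$fold[nrow(df)] == "summary")
  body <- df[-nrow(df), ]
  pf <- data.frame(fold = as.integer(body$fold),
                   acc = as.numeric(body$acc), prec = as.numeric(body$prec),
                   recall = as.numeric(body$recall),
                   f1 = as.numeric(body$f1), auc = as.numeric(body$auc))
  summ <- df[nrow(df), -1]
  split2 <- function(s) as.numeric(strsplit(s, "±")[[1]])
  ms <- vapply(unlist(summ), split2, numeric(2))
  new_report(pf, mean = ms[1, ], sd = ms[2, ])
}

new_report <- function(per_fold, mean = NULL, sd = NULL, roc = NULL,
                       scores = NULL, labels = NULL) {
  cols <- c("acc", "prec", "recall", "f1", "auc")
  if (is.null(mean)) mean <- colMeans(per_fold[cols])
  if (is.null(sd)) sd <- vapply(per_fold[cols], stats::sd, numeric(1))
  names(mean) <- cols; names(sd) <- cols
  structure(list(per_fold = per_fold, mean = mean, sd = sd,
                 mean_auc = unname(mean["auc"]), roc = roc,
                 scores = scores, labels = labels),
            class = "gipdr_report")
}

#' @export
print.gipdr_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation report\n", nrow(x$per_fold)))
  print(round(x$per_fold, 4), row.names = FALSE)
  cat(sprintf("mean  Acc %.4f±%.4f  Prec %.4f±%.4f  Recall %.4f±%.4f  F1 %.4f±%.4f  AUC %.4f\n",
              x$mean["acc"], x$sd["acc"], x$mean["prec"], x$sd["prec"],
              x$mean["recall"], x$sd["recall"], x$mean["f1"], x$sd["f1"],
              x$mean["auc"]))
  invisible(x)
}

#' Write ROC curve points as TSV (fpr, tpr, threshold)
#'
#' @param roc data frame from \code{\link{roc_auc}}.
#' @param path destination path.
#' @export
write_roc <- function(roc, path) {
  write.table(roc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ranked drug predictions as TSV (rank, drug_id, score)
#'
#' @param ranked a \code{ranked_predictions} object.
#' @param path destination path.
#' @export
write_ranking <- function(ranked, path) {
  df <- data.frame(rank = seq_len(nrow(ranked$ranking)),
                   drug_id = ranked$ranking$drug_id,
                   score = ranked$ranking$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Echo a run configuration to YAML
#'
#' @param cfg a \code{gipdr_config}.
#' @param path destination path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
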