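#' Fuse disease GIP kernel with boosted semantic similarity
#'
#' The disease descriptor matrix takes the GIP kernel value wherever an
#' informative kernel value exists and falls back to the (boosted)
#' semantic similarity otherwise. A disease with no known associations has
#' an empty interaction profile and therefore no GIP similarity — its
#' pairs are treated as kernel value 0 and filled from the semantic side,
#' as are any entries where the kernel itself is 0.
#'
#' @param gip_dis disease \code{kernel_matrix} (carries per-disease
#'   association counts used to detect empty profiles).
#' @param ds a \code{boosted_semantic} (or \code{semantic_matrix}) over the
#'   same diseases in the same order.
#' @return object of class \code{disease_descriptors} with fields
#'   \code{disease_ids}, \code{Sim}.
#' @export
fuse_disease_similarity <- function(gip_dis, ds) {
  S <- if (inherits(ds, "semantic_matrix")) ds$S else ds$DS
  K <- gip_dis$K
  if (!all(dim(K) == dim(S)))
    stop("disease similarity matrices have mismatched dimensions")
  if (!identical(gip_dis$entity_ids, ds$disease_ids))
    stop("disease orderings differ between kernel and semantic matrix")
  if (!is.null(gip_dis$n_assoc)) {
    empty <- gip_dis$n_assoc == 0
    K[outer(empty, empty, "|")] <- 0
  }
  Sim <- ifelse(K != 0, K, S)
  Sim <- (Sim + t(Sim)) / 2
  dimnames(Sim) <- dimnames(K)
  structure(list(disease_ids = gip_dis$entity_ids, Sim = Sim),
            class = "disease_descriptors")
}

#' Build drug descriptors: GIP kernel row spliced with encoded fingerprint
#'
#' @param gip_drug drug \code{kernel_matrix}.
#' @param fg \code{encoded_features} over the same drugs in the same order.
#' @return object of class \code{drug_descriptors} with fields
#'   \code{drug_ids}, \code{R} (n_drugs x (n_drugs + hidden_dim)).
#' @export
build_drug_descriptors <- function(gip_drug, fg) {
  if (!identical(gip_drug$entity_ids, fg$drug_ids))
    stop("drug orderings differ between kernel and encoded features")
  R <- cbind(gip_drug$K, fg$FG)
  colnames(R) <- c(paste0("gip_", gip_drug$entity_ids),
                   paste0("fg_", seq_len(ncol(fg$FG))))
  structure(list(drug_ids = gip_drug$entity_ids, R = R),
            class = "drug_descriptors")
}

#' Assemble labeled drug-disease pair feature vectors
#'
#' Each pair's vector is the drug descriptor row concatenated with the
#' disease similarity row; sample order is preserved.
#'
#' @param samples data frame with columns \code{drug_index},
#'   \code{disease_index}, \code{label}.
#' @param drugs \code{drug_descriptors}.
#' @param diseases \code{disease_descriptors}.
#' @return list with \code{samples} (the input data frame) and \code{X}
#'   (matrix, one feature vector per row).
#' @export
assemble_pairs <- function(samples, drugs, diseases) {
  di <- samples$drug_index; si <- samples$disease_index
  if (any(di < 1 | di > nrow(drugs$R)) ||
      any(si < 1 | si > nrow(diseases$Sim)))
    stop("pair index out of range")
  X <- cbind(drugs$R[di, , drop = FALSE],
             diseases$Sim[si, , drop = FALSE])
  rownames(X) <- NULL
  list(samples = samples, X = X)
}

#' Batch-normalization statistics from training vectors
#'
#' Per-feature mean and population (biased) variance estimated on the
#' training set only.
#'
#' @param X training matrix, one vector per row (>= 2 rows).
#' @param epsilon variance guard added before the square root.
#' @return list with \code{bn_mean}, \code{bn_var}, \code{bn_epsilon}.
#' @export
fit_batch_norm <- function(X, epsilon = 1e-8) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("batch norm needs at least 2 training vectors")
  mu <- colMeans(X)
  v <- colMeans(sweep(X, 2, mu)^2)   # population variance
  list(bn_mean = mu, bn_var = v, bn_epsilon = epsilon)
}

#' Apply batch normalization with frozen statistics
#'
#' @param X matrix of vectors to normalize (rows).
#' @param bn statistics from \code{\link{fit_batch_norm}}.
#' @return normalized matrix (x - mean) / sqrt(var + epsilon).
#' @export
apply_batch_norm <- function(X, bn) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, bn$bn_mean), 2, sqrt(bn$bn_var + bn$bn_epsilon), "/")
}

#' Rectified linear unit
#'
#' @param x numeric vector or matrix.
#' @return elementwise max(0, x).
#' @export
relu <- function(x) pmax(x, 0)

#' Train the batch-norm + ReLU fully-connected feature refiner
#'
#' Pipeline: batch normalization (statistics from the training vectors
#' only) feeding a fully-connected ReLU layer of width \code{fc_width},
#' trained with a logistic output head by seeded full-batch gradient
#' descent on the binary cross-entropy of the training labels. The head is
#' discarded at refinement time; \code{\link{refine}} returns the ReLU
#' hidden activations.
#'
#' @param pairs list from \code{\link{assemble_pairs}} (training folds
#'   only; both classes must be present).
#' @param cfg a \code{\link{run_config}}.
#' @param seed optional override of the training seed.
#' @return \code{refiner_params}.
#' @export
train_refiner <- function(pairs, cfg = run_config(), seed = NULL) {
  X <- pairs$X
  y <- pairs$samples$label
  if (length(unique(y)) < 2)
    stop("refiner training needs both classes present")
  if (is.null(seed)) seed <- split_seed(cfg$rng_seed, 8)[2]
  bn <- fit_batch_norm(X)
  Xn <- apply_batch_norm(X, bn)
  d <- ncol(Xn); hw <- cfg$fc_width; n <- nrow(Xn)
  r <- sqrt(6 / (d + hw))
  params <- with_seed(seed, list(
    W_fc = matrix(runif(hw * d, -r, r), hw, d),
    b_fc = numeric(hw),
    w_head = runif(hw, -r, r),
    b_head = 0))
  lr <- cfg$refiner_learning_rate
  for (ep in seq_len(cfg$refiner_epochs)) {
    Z <- tcrossprod(Xn, params$W_fc) +
      matrix(params$b_fc, n, hw, byrow = TRUE)
    H <- relu(Z)
    p <- sigmoid(drop(H %*% params$w_head) + params$b_head)
    dlogit <- (p - y) / n                 # BCE gradient wrt head logit
    g_w <- drop(crossprod(H, dlogit))
    g_b <- sum(dlogit)
    dH <- outer(dlogit, params$w_head)
    dZ <- dH * (Z > 0)
    gW <- crossprod(dZ, Xn)
    gb <- colSums(dZ)
    params$w_head <- params$w_head - lr * g_w
    params$b_head <- params$b_head - lr * g_b
    params$W_fc <- params$W_fc - lr * gW
    params$b_fc <- params$b_fc - lr * gb
  }
  structure(c(bn, params), class = "refiner_params")
}

#' Refine pair feature vectors with a trained refiner
#'
#' @param pairs list from \code{\link{assemble_pairs}}, or a bare feature
#'   matrix.
#' @param params \code{refiner_params} from \code{\link{train_refiner}}.
#' @return matrix of nonnegative hidden activations, \code{fc_width}
#'   columns.
#' @export
refine <- function(pairs, params) {
  X <- if (is.list(pairs) && !is.null(pairs$X)) pairs$X else as.matrix(pairs)
  Xn <- apply_batch_norm(X, params)
  relu(tcrossprod(Xn, params$W_fc) +
         matrix(params$b_fc, nrow(Xn), length(params$b_fc), byrow = TRUE))
}
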