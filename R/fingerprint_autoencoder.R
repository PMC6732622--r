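#' Numerically stable logistic sigmoid
#'
#' @param x numeric vector or matrix.
#' @return elementwise 1 / (1 + exp(-x)), stable for large |x|.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

new_ae_params <- function(W1, b1, W2, b2, curve = numeric(0)) {
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 training_curve = curve),
            class = "autoencoder_params")
}

#' Encode fingerprints into the autoencoder's hidden representation
#'
#' Y = sigmoid(W1 x + b1). Accepts a single fingerprint vector or a matrix
#' with one fingerprint per row.
#'
#' @param x binary vector of length n_bits, or an n x n_bits matrix.
#' @param params \code{autoencoder_params}.
#' @return hidden activation(s) in (0, 1); matrix in, matrix out.
#' @export
ae_encode <- function(x, params) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != ncol(params$W1))
    stop(sprintf("encode: expected %d input bits, got %d",
                 ncol(params$W1), ncol(X)))
  Y <- sigmoid(tcrossprod(X, params$W1) +
                 matrix(params$b1, nrow(X), length(params$b1), byrow = TRUE))
  if (single) drop(Y) else Y
}

#' Decode hidden activations back to fingerprint space
#'
#' x' = sigmoid(W2 Y + b2).
#'
#' @param y hidden vector of length hidden_dim, or an n x hidden_dim matrix.
#' @param params \code{autoencoder_params}.
#' @return reconstruction(s) in (0, 1).
#' @export
ae_decode <- function(y, params) {
  single <- is.null(dim(y))
  Y <- if (single) matrix(y, nrow = 1) else as.matrix(y)
  if (ncol(Y) != ncol(params$W2))
    stop(sprintf("decode: expected %d hidden units, got %d",
                 ncol(params$W2), ncol(Y)))
  X <- sigmoid(tcrossprod(Y, params$W2) +
                 matrix(params$b2, nrow(Y), length(params$b2), byrow = TRUE))
  if (single) drop(X) else X
}

# Mean squared reconstruction error (mean over samples of the summed
# squared per-bit error) and its analytic gradients.
ae_loss_grad <- function(X, params) {
  n <- nrow(X)
  Z1 <- tcrossprod(X, params$W1) +
    matrix(params$b1, n, length(params$b1), byrow = TRUE)
  Y <- sigmoid(Z1)
  Z2 <- tcrossprod(Y, params$W2) +
    matrix(params$b2, n, length(params$b2), byrow = TRUE)
  Xh <- sigmoid(Z2)
  R <- Xh - X
  loss <- sum(R^2) / n
  dZ2 <- (2 / n) * R * Xh * (1 - Xh)
  gW2 <- crossprod(dZ2, Y)            # n_bits x hidden
  gb2 <- colSums(dZ2)
  dY <- dZ2 %*% params$W2
  dZ1 <- dY * Y * (1 - Y)
  gW1 <- crossprod(dZ1, X)            # hidden x n_bits
  gb1 <- colSums(dZ1)
  list(loss = loss, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

#' Train the fingerprint autoencoder
#'
#' Single hidden layer with logistic activations on both layers, trained
#' by full-batch gradient descent on the mean squared reconstruction
#' error. Weights are initialized from a seeded uniform(-r, r) with
#' r = sqrt(6 / (n_bits + hidden_dim)); biases start at zero.
#'
#' @param fingerprints a \code{\link{fingerprint_matrix}} with at least
#'   two drugs.
#' @param cfg a \code{\link{run_config}} (hidden width, epochs, learning
#'   rate, seed).
#' @param seed optional override of the training seed.
#' @return \code{autoencoder_params} with the per-epoch loss curve.
#' @export
train_autoencoder <- function(fingerprints, cfg = run_config(),
                              seed = NULL) {
  X <- fingerprints$F
  if (nrow(X) < 2) stop("autoencoder training needs at least 2 drugs")
  check_binary_matrix(X, "fingerprint matrix")
  h <- cfg$ae_hidden_dim
  m <- ncol(X)
  if (is.null(seed)) seed <- split_seed(cfg$rng_seed, 8)[1]
  r <- sqrt(6 / (m + h))
  params <- with_seed(seed, new_ae_params(
    W1 = matrix(runif(h * m, -r, r), h, m),
    b1 = numeric(h),
    W2 = matrix(runif(m * h, -r, r), m, h),
    b2 = numeric(m)))
  lr <- cfg$ae_learning_rate
  curve <- numeric(cfg$ae_epochs)
  for (ep in seq_len(cfg$ae_epochs)) {
    g <- ae_loss_grad(X, params)
    if (!is.finite(g$loss))
      stop("autoencoder training diverged (non-finite loss); ",
           "try a smaller ae_learning_rate")
    curve[ep] <- g$loss
    params$W1 <- params$W1 - lr * g$gW1
    params$b1 <- params$b1 - lr * g$gb1
    params$W2 <- params$W2 - lr * g$gW2
    params$b2 <- params$b2 - lr * g$gb2
  }
  params$training_curve <- curve
  params
}

#' Encode all drug fingerprints into the structural feature matrix FG
#'
#' @param fingerprints a \code{\link{fingerprint_matrix}}.
#' @param params trained \code{autoencoder_params}.
#' @return object of class \code{encoded_features} with fields
#'   \code{drug_ids}, \code{FG} (n_drugs x hidden_dim, entries in (0, 1)).
#' @export
encode_all <- function(fingerprints, params) {
  FG <- ae_encode(fingerprints$F, params)
  rownames(FG) <- fingerprints$drug_ids
  structure(list(drug_ids = fingerprints$drug_ids, FG = FG),
            class = "encoded_features")
}

#' Save autoencoder parameters as flat text
#'
#' Format: one header line "gipdr_autoencoder hidden n_bits", then W1
#' (hidden rows), b1, W2 (n_bits rows), b2, one whitespace-separated row
#' per line.
#'
#' @param params \code{autoencoder_params}.
#' @param path destination path.
#' @export
save_autoencoder <- function(params, path) {
  con <- file(path, "w"); on.exit(close(con))
  h <- nrow(params$W1); m <- ncol(params$W1)
  writeLines(sprintf("gipdr_autoencoder %d %d", h, m), con)
  wr <- function(M) apply(M, 1, function(r)
    writeLines(paste(format(r, digits = 17), collapse = " "), con))
  wr(params$W1); writeLines(paste(format(params$b1, digits = 17),
                                  collapse = " "), con)
  wr(params$W2); writeLines(paste(format(params$b2, digits = 17),
                                  collapse = " "), con)
  invisible(path)
}

#' Load autoencoder parameters saved by \code{\link{save_autoencoder}}
#'
#' @param path file path.
#' @return \code{autoencoder_params} (without a training curve).
#' @export
load_autoencoder <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (hdr[1] != "gipdr_autoencoder") stop("not an autoencoder params file")
  h <- as.integer(hdr[2]); m <- as.integer(hdr[3])
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  at <- 1
  take <- function(k) {
    block <- lines[(at + 1):(at + k)]
    at <<- at + k
    do.call(rbind, lapply(block, num))
  }
  W1 <- take(h); b1 <- drop(take(1))
  W2 <- take(m); b2 <- drop(take(1))
  new_ae_params(W1, b1, W2, b2)
}
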