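#' Normalized Gaussian interaction profile kernel bandwidth
#'
#' The bandwidth is the scale gamma' divided by the mean squared Euclidean
#' norm of the interaction profiles; for binary profiles the squared norm
#' of a profile is its number of known associations. All entities enter the
#' mean, including those with empty profiles.
#'
#' @param profiles matrix with one binary interaction profile per row.
#' @param gamma_prime positive bandwidth scale.
#' @return the bandwidth actually used in the kernel exponent.
#' @export
compute_bandwidth <- function(profiles, gamma_prime) {
  profiles <- as.matrix(profiles)
  mean_sq <- mean(rowSums(profiles^2))
  if (mean_sq == 0)
    stop("degenerate bandwidth: every interaction profile is all-zero ",
         "(no known associations for this entity set)")
  gamma_prime / mean_sq
}

#' Gaussian interaction profile kernel matrix
#'
#' K[x, y] = exp(-bandwidth * ||Y_x - Y_y||^2) over binary interaction
#' profiles, with the bandwidth normalized by the mean squared profile
#' norm (\code{\link{compute_bandwidth}}). The result is symmetric with a
#' unit diagonal, entries in (0, 1], and positive semidefinite.
#'
#' @param profiles matrix with one binary profile per row; rownames become
#'   entity IDs.
#' @param gamma_prime positive bandwidth scale.
#' @return an object of class \code{kernel_matrix} with fields
#'   \code{entity_ids}, \code{K}, \code{bandwidth}.
#' @export
gip_kernel <- function(profiles, gamma_prime) {
  profiles <- as.matrix(profiles)
  bw <- compute_bandwidth(profiles, gamma_prime)
  # squared Euclidean distances via the Gram-matrix identity
  sq <- rowSums(profiles^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  D2[D2 < 0] <- 0
  K <- exp(-bw * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(profiles)))
  dimnames(K) <- list(ids, ids)
  # per-entity association counts: entities with an empty profile have no
  # interaction information, which downstream fusion treats as a missing
  # (zero) GIP similarity to be filled from the semantic side
  structure(list(entity_ids = ids, K = K, bandwidth = bw,
                 n_assoc = rowSums(profiles)),
            class = "kernel_matrix")
}

#' Disease GIP kernel from an association matrix
#'
#' Disease interaction profiles are the columns of the drug-by-disease
#' association matrix.
#'
#' @param assoc an \code{\link{association_matrix}}.
#' @param cfg a \code{\link{run_config}} (uses \code{gamma_prime_disease}).
#' @return a \code{kernel_matrix} over diseases.
#' @export
disease_gip <- function(assoc, cfg = run_config()) {
  gip_kernel(t(assoc$A), cfg$gamma_prime_disease)
}

#' Drug GIP kernel from an association matrix
#'
#' Drug interaction profiles are the rows of the drug-by-disease
#' association matrix.
#'
#' @param assoc an \code{\link{association_matrix}}.
#' @param cfg a \code{\link{run_config}} (uses \code{gamma_prime_drug}).
#' @return a \code{kernel_matrix} over drugs.
#' @export
drug_gip <- function(assoc, cfg = run_config()) {
  gip_kernel(assoc$A, cfg$gamma_prime_drug)
}
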