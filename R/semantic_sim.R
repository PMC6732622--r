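#' Weighted disease-sharing network from known associations
#'
#' Diseases are vertices; the weight of edge (i, j) is the number of drugs
#' associated with both diseases. The diagonal is zero.
#'
#' @param assoc an \code{\link{association_matrix}}.
#' @return object of class \code{sharing_network} with fields
#'   \code{disease_ids}, \code{W}.
#' @export
build_sharing_network <- function(assoc) {
  W <- crossprod(assoc$A)       # t(A) %*% A: shared-drug counts
  diag(W) <- 0
  dimnames(W) <- list(assoc$disease_ids, assoc$disease_ids)
  structure(list(disease_ids = assoc$disease_ids, W = W),
            class = "sharing_network")
}

#' Cohesiveness of a vertex set in a weighted network
#'
#' f(K) = C_in / (C_in + C_bound + P) where C_in is the total weight of
#' edges inside K, C_bound the total weight of edges crossing K's
#' boundary, and P = penalty_per_node * |K|. Returns 0 when all three
#' terms vanish.
#'
#' @param members integer vertex indices (non-empty).
#' @param net a \code{sharing_network} (or any list with a symmetric
#'   weight matrix \code{W}).
#' @param penalty_per_node nonnegative per-vertex penalty.
#' @return cohesiveness in [0, 1].
#' @export
cohesiveness <- function(members, net, penalty_per_node = 2) {
  if (length(members) == 0) stop("cluster must be non-empty")
  W <- net$W
  c_in <- sum(W[members, members, drop = FALSE]) / 2
  c_bound <- sum(W[members, -members, drop = FALSE])
  if (length(members) == nrow(W)) c_bound <- 0
  denom <- c_in + c_bound + penalty_per_node * length(members)
  if (denom == 0) return(0)
  c_in / denom
}

# Grow a vertex set to a strict local optimum of cohesiveness under
# single add/remove moves. Ties broken by lowest vertex index; removal
# never empties the set.
grow_cluster <- function(members, W, penalty) {
  n <- nrow(W)
  net <- list(W = W)
  f_cur <- cohesiveness(members, net, penalty)
  repeat {
    best_f <- f_cur
    best_set <- NULL
    outside <- setdiff(seq_len(n), members)
    for (v in outside) {
      f_new <- cohesiveness(c(members, v), net, penalty)
      if (f_new > best_f + 1e-12) { best_f <- f_new; best_set <- c(members, v) }
    }
    if (length(members) >= 2) {
      for (v in members) {
        f_new <- cohesiveness(setdiff(members, v), net, penalty)
        if (f_new > best_f + 1e-12) { best_f <- f_new; best_set <- setdiff(members, v) }
      }
    }
    if (is.null(best_set)) break
    members <- best_set
    f_cur <- best_f
  }
  list(members = sort(members), f = f_cur)
}

#' Greedy cohesive clustering of a weighted network
#'
#' ClusterONE-style procedure: repeatedly seed from the
#' highest-weighted-degree vertex not yet covered by a cluster, grow the
#' seed by the single add-or-remove move that maximally increases
#' cohesiveness until no move improves it, and record the cluster. Vertices
#' with zero degree become singleton clusters. Finally, any two clusters
#' whose overlap score |K1 n K2|^2 / (|K1| * |K2|) exceeds the merge
#' threshold are merged, and each merged set is re-grown to a local
#' optimum so that every returned cluster is a single-move local optimum.
#'
#' @param net a \code{sharing_network}.
#' @param cfg a \code{\link{run_config}} (uses
#'   \code{cluster_penalty_per_node} and \code{cluster_overlap_merge}).
#' @return object of class \code{cluster_set}: list of clusters, each a
#'   list with \code{members} (sorted vertex indices) and \code{f}.
#' @export
cluster_one <- function(net, cfg = run_config()) {
  W <- net$W
  n <- nrow(W)
  if (n < 1) stop("network must have at least one vertex")
  penalty <- cfg$cluster_penalty_per_node
  degree <- rowSums(W)
  covered <- rep(FALSE, n)
  clusters <- list()
  while (any(!covered)) {
    cand <- which(!covered)
    seed <- cand[which.max(degree[cand])]   # ties: lowest index
    if (degree[seed] == 0) {
      cl <- list(members = seed,
                 f = cohesiveness(seed, net, penalty))
    } else {
      cl <- grow_cluster(seed, W, penalty)
    }
    clusters[[length(clusters) + 1L]] <- cl
    covered[cl$members] <- TRUE
    covered[seed] <- TRUE
  }
  # overlap merge, then re-polish merged sets to local optima
  repeat {
    merged <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- clusters[[i]]$members; b <- clusters[[j]]$members
        ov <- length(intersect(a, b))^2 / (length(a) * length(b))
        if (ov > cfg$cluster_overlap_merge) {
          u <- sort(union(a, b))
          clusters[[i]] <- grow_cluster(u, W, penalty)
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  structure(list(clusters = clusters, disease_ids = net$disease_ids),
            class = "cluster_set")
}

#' Boost semantic similarity within cohesive clusters
#'
#' For every disease pair co-resident in at least one cluster, the
#' semantic similarity is scaled by (1 + f) with f the cohesiveness of the
#' best shared cluster: DS = (1 + f) * DS_r. Any off-diagonal value that
#' reaches 1 or more is replaced by 0.99. Pairs sharing no cluster keep
#' their original similarity.
#'
#' @param ds_r a \code{\link{semantic_matrix}}.
#' @param clusters a \code{cluster_set} from \code{\link{cluster_one}}.
#' @return object of class \code{boosted_semantic} with fields
#'   \code{disease_ids}, \code{DS}.
#' @export
boost_semantic <- function(ds_r, clusters) {
  S <- ds_r$S
  n <- nrow(S)
  fmax <- matrix(0, n, n)
  for (cl in clusters$clusters) {
    m <- cl$members
    if (any(m < 1 | m > n)) stop("cluster vertex index out of range")
    if (length(m) >= 2)
      fmax[m, m] <- pmax(fmax[m, m], cl$f)
  }
  DS <- (1 + fmax) * S
  DS[DS >= 1] <- 0.99
  diag(DS) <- diag(S)
  DS <- (DS + t(DS)) / 2
  dimnames(DS) <- dimnames(S)
  structure(list(disease_ids = ds_r$disease_ids, DS = DS),
            class = "boosted_semantic")
}
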