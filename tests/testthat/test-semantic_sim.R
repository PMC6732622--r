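net_from <- function(W) {
  dimnames(W) <- list(paste0("d", seq_len(nrow(W))),
                      paste0("d", seq_len(nrow(W))))
  structure(list(disease_ids = rownames(W), W = W),
            class = "sharing_network")
}

test_that("sharing network counts shared drugs", {
  # one drug associated with diseases 1 and 2
  A <- rbind(c(1, 1, 0))
  dimnames(A) <- list("u1", paste0("d", 1:3))
  W <- build_sharing_network(association_matrix(A))$W
  expect_equal(W["d1", "d2"], 1)
  expect_equal(diag(W), rep(0, 3), ignore_attr = TRUE)
  # orthogonal disease columns share nothing
  A2 <- diag(3); dimnames(A2) <- list(paste0("u", 1:3), paste0("d", 1:3))
  expect_true(all(build_sharing_network(association_matrix(A2))$W == 0))
  # seeded matrix equals explicit intersection counting
  set.seed(21)
  A3 <- matrix(rbinom(40, 1, 0.5), 8, 5,
               dimnames = list(paste0("u", 1:8), paste0("d", 1:5)))
  W3 <- build_sharing_network(association_matrix(A3))$W
  for (i in 1:5) for (j in 1:5) {
    expected <- if (i == j) 0 else
      length(intersect(which(A3[, i] == 1), which(A3[, j] == 1)))
    expect_equal(unname(W3[i, j]), expected)
  }
})

test_that("cohesiveness matches hand cases and edge enumeration", {
  tri <- matrix(0, 3, 3); tri[cbind(1:3, c(2, 3, 1))] <- 1
  tri <- tri + t(tri); tri[tri > 1] <- 1
  net <- net_from(tri)
  expect_equal(cohesiveness(1:3, net, 0), 1)          # isolated clique
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  expect_equal(cohesiveness(1:2, net_from(path), 0), 0.5)
  edgeless <- net_from(matrix(0, 3, 3))
  expect_equal(cohesiveness(1, edgeless, 2), 0)       # all-zero convention
  expect_error(cohesiveness(integer(0), net, 0), "non-empty")

  # all subsets of random weighted graphs vs the enumeration oracle
  set.seed(31)
  for (g in 1:10) {
    n <- sample(3:7, 1)
    W <- random_weight_matrix(n)
    net <- net_from(W)
    pen <- sample(c(0, 1, 2), 1)
    for (size in 1:n) {
      for (s in utils::combn(n, size, simplify = FALSE)) {
        expect_equal(cohesiveness(s, net, pen),
                     oracle_cohesiveness(s, W, pen))
      }
    }
  }
})

test_that("greedy clustering recovers planted cliques and local optima", {
  # two unit triangles joined by a bridge edge
  W <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6),
                 c(3, 4)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 1
  cfg <- run_config(cluster_penalty_per_node = 0,
                    cluster_overlap_merge = 0.8)
  cs <- cluster_one(net_from(W), cfg)
  sets <- lapply(cs$clusters, `[[`, "members")
  expect_true(list(1:3) %in% sets || any(vapply(sets, identical, TRUE, 1:3)))
  expect_true(any(vapply(sets, identical, TRUE, 4:6)))

  # complete graph on 4 vertices, penalty 0 -> one cluster with f = 1
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  cs4 <- cluster_one(net_from(K4), cfg)
  expect_equal(cs4$clusters[[1]]$members, 1:4)
  expect_equal(cs4$clusters[[1]]$f, 1)

  # edgeless graph -> all singletons with f = 0
  cs0 <- cluster_one(net_from(matrix(0, 4, 4)), run_config())
  expect_length(cs0$clusters, 4)
  expect_true(all(vapply(cs0$clusters, `[[`, numeric(1), "f") == 0))
})

test_that("every returned cluster is a strict single-move local optimum", {
  set.seed(41)
  for (g in 1:6) {
    n <- sample(8:16, 1)
    W <- random_weight_matrix(n, p_edge = 0.3)
    net <- net_from(W)
    cfg <- run_config(cluster_penalty_per_node = sample(c(0, 1, 2), 1))
    cs <- cluster_one(net, cfg)
    covered <- sort(unique(unlist(lapply(cs$clusters, `[[`, "members"))))
    expect_equal(covered, seq_len(n))
    for (cl in cs$clusters) {
      f0 <- cohesiveness(cl$members, net, cfg$cluster_penalty_per_node)
      expect_equal(f0, cl$f)
      for (v in setdiff(seq_len(n), cl$members))
        expect_lte(cohesiveness(c(cl$members, v), net,
                                cfg$cluster_penalty_per_node), f0 + 1e-12)
      if (length(cl$members) >= 2)
        for (v in cl$members)
          expect_lte(cohesiveness(setdiff(cl$members, v), net,
                                  cfg$cluster_penalty_per_node), f0 + 1e-12)
    }
  }
})

test_that("semantic boost follows the (1+f) rule with the 0.99 cap", {
  S <- matrix(0.1, 4, 4); diag(S) <- 1
  S[1, 2] <- S[2, 1] <- 0.4
  S[3, 4] <- S[4, 3] <- 0.8
  dimnames(S) <- list(paste0("d", 1:4), paste0("d", 1:4))
  ds_r <- semantic_matrix(S)
  cl <- structure(list(clusters = list(list(members = c(1L, 2L), f = 0.5),
                                       list(members = c(3L, 4L), f = 0.5)),
                       disease_ids = rownames(S)), class = "cluster_set")
  b <- boost_semantic(ds_r, cl)
  expect_equal(b$DS[1, 2], 0.6)           # (1 + 0.5) * 0.4
  expect_equal(b$DS[3, 4], 0.99)          # 1.2 capped
  expect_equal(b$DS[1, 3], 0.1)           # no shared cluster
  # monotone, capped, symmetric; capping is idempotent
  expect_true(all(b$DS + 1e-12 >= ds_r$S | b$DS == 0.99))
  off <- b$DS[upper.tri(b$DS)]
  expect_true(all(off <= 0.99))
  expect_identical(b$DS, t(b$DS))
  b2 <- boost_semantic(semantic_matrix(`diag<-`(b$DS, 1)),
                       structure(list(clusters = list(),
                                      disease_ids = rownames(S)),
                                 class = "cluster_set"))
  expect_equal(b2$DS, b$DS, tolerance = 1e-12)
  # out-of-range cluster index errors
  badcl <- structure(list(clusters = list(list(members = c(1L, 9L), f = 0.5)),
                          disease_ids = rownames(S)), class = "cluster_set")
  expect_error(boost_semantic(ds_r, badcl), "out of range")
})
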