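rand_corr <- function(n, seed) {
  tr <- withr::with_seed(seed, matrix(stats::rnorm(n * 120), n))
  rownames(tr) <- 0:(n - 1)
  pairwise_correlations(tr)
}

test_that("pairwise correlations match the direct-summation formula", {
  tr <- withr::with_seed(1, matrix(stats::rnorm(300), 3))
  rownames(tr) <- 0:2
  corr <- pairwise_correlations(tr)
  expect_equal(diag(corr$rho), rep(1, 3), ignore_attr = TRUE)
  # self and negation
  tr2 <- rbind(tr[1, ], -tr[1, ], tr[2, ])
  rownames(tr2) <- 0:2
  corr2 <- pairwise_correlations(tr2)
  expect_equal(corr2$rho[1, 2], -1)
  # formula oracle
  for (seed in 1:10) {
    ab <- withr::with_seed(seed + 50, matrix(stats::rnorm(200), 2))
    rownames(ab) <- 0:1
    got <- pairwise_correlations(ab)$rho[1, 2]
    expect_lt(abs(got - rho_direct(ab[1, ], ab[2, ])), 1e-12)
  }
  # short windows are withheld; flat traces undefined
  expect_null(pairwise_correlations(tr[, 1:10], min_samples = 30))
  tr3 <- rbind(tr[1, ], rep(5, 100))
  rownames(tr3) <- 0:1
  corr3 <- pairwise_correlations(tr3)
  expect_true(is.na(corr3$rho[1, 2]))
  expect_true(is.na(corr3$rho[2, 2]))
})

test_that("correlations are invariant to affine trace changes", {
  tr <- withr::with_seed(3, matrix(stats::rnorm(400), 4))
  rownames(tr) <- 0:3
  base <- pairwise_correlations(tr)$rho
  expect_equal(pairwise_correlations(tr + 17)$rho, base, tolerance = 1e-12)
  expect_equal(pairwise_correlations(tr * 3.2)$rho, base, tolerance = 1e-12)
})

test_that("the three-node MST picks the two strongest links", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[1, 3] <- rho[3, 1] <- 0.5
  rho[2, 3] <- rho[3, 2] <- 0.1
  corr <- structure(list(rho = rho, cell_ids = 0:2, window = c(1L, 100L)),
                    class = "correlation_matrix")
  g <- mst_network(corr)
  ed <- paste(g$edges$cell_i, g$edges$cell_j)
  expect_setequal(ed, c("0 1", "0 2"))
  # exhaustive check over all 3 spanning trees
  W <- 1 - abs(rho); diag(W) <- 0
  expect_equal(sum(g$edges$weight), min_spanning_weight_bruteforce(W))
})

test_that("MST invariants hold on random matrices vs exhaustive enumeration", {
  for (seed in 1:12) {
    n <- withr::with_seed(seed, sample(3:7, 1))
    corr <- rand_corr(n, seed + 100)
    g <- mst_network(corr)
    expect_equal(nrow(g$edges), n - 1)
    # connected & acyclic: n-1 edges with all nodes in one component
    comp <- seq_len(n)
    for (e in seq_len(nrow(g$edges))) {
      a <- comp[g$edges$cell_i[e] + 1]; b <- comp[g$edges$cell_j[e] + 1]
      comp[comp == b] <- a
    }
    expect_length(unique(comp), 1)
    W <- 1 - abs(corr$rho); diag(W) <- 0
    expect_equal(sum(g$edges$weight), min_spanning_weight_bruteforce(W),
                 tolerance = 1e-12)
  }
})

test_that("a 150-cell network keeps the N-1 edge contract", {
  tr <- withr::with_seed(42, matrix(stats::rnorm(150 * 200), 150))
  rownames(tr) <- 0:149
  g <- mst_network(pairwise_correlations(tr))
  expect_equal(nrow(g$edges), 149)
  comp <- seq_len(150)
  for (e in seq_len(nrow(g$edges))) {
    a <- comp[g$edges$cell_i[e] + 1]; b <- comp[g$edges$cell_j[e] + 1]
    comp[comp == b] <- a
  }
  expect_length(unique(comp), 1)
})

test_that("MST total weight agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  corr <- rand_corr(20, 7)
  g <- mst_network(corr)
  W <- 1 - abs(corr$rho); diag(W) <- 0
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE)
  expect_equal(sum(g$edges$weight),
               sum(igraph::E(igraph::mst(ig))$weight), tolerance = 1e-12)
})

test_that("threshold networks keep exactly the pairs above theta", {
  corr <- rand_corr(8, 5)
  g0 <- threshold_network(corr, 0)
  expect_equal(unname(g0$degree), rep(7L, 8))
  eps <- pmin(abs(corr$rho[upper.tri(corr$rho)]), 1)
  g1 <- threshold_network(corr, 1)
  expect_equal(nrow(g1$edges), sum(eps >= 1))
  th <- 0.1
  g <- threshold_network(corr, th)
  want <- which(abs(corr$rho) >= th & upper.tri(corr$rho), arr.ind = TRUE)
  expect_equal(nrow(g$edges), nrow(want))
  got <- paste(g$edges$cell_i, g$edges$cell_j)
  expect_setequal(got, paste(want[, 1] - 1, want[, 2] - 1))
})

test_that("degree ranking orders by degree then id", {
  # star: centre node 3 has top rank
  corr <- rand_corr(5, 9)
  g <- threshold_network(corr, 0)
  g$edges <- g$edges[g$edges$cell_i == 3 | g$edges$cell_j == 3, ]
  g <- calstream:::new_functional_graph(g$cell_ids, g$edges, "threshold")
  rk <- rank_by_degree(g)
  expect_equal(rk$cell_id[1], 3)
  # path 0-1-2-3: interior nodes outrank endpoints; ties break by id
  pg <- calstream:::new_functional_graph(0:3,
    data.frame(cell_i = c(0, 1, 2), cell_j = c(1, 2, 3),
               rho = 0.5, weight = 0.5), "threshold")
  rkp <- rank_by_degree(pg)
  expect_equal(rkp$cell_id, c(1, 2, 0, 3))
  # random graph: ordering equals an independent sort
  corr <- rand_corr(12, 13)
  g2 <- threshold_network(corr, 0.15)
  rk2 <- rank_by_degree(g2)
  ord <- order(-g2$degree, g2$cell_ids)
  expect_equal(rk2$cell_id, g2$cell_ids[ord])
})

test_that("ranking stability measures top-k turnover", {
  same <- replicate(5, 0:19, simplify = FALSE)
  expect_equal(ranking_stability(same), 0)
  disjoint <- list(0:9, 10:19, 0:9)
  expect_equal(ranking_stability(disjoint), 100)
  # surrogate random signals churn heavily (qualitative random control)
  ranks <- withr::with_seed(21, lapply(1:10, function(i) sample(0:59)))
  expect_gt(ranking_stability(ranks), 50)
  # positional variant counts position changes
  swap <- list(0:9, c(1, 0, 2:9))
  expect_equal(ranking_stability(swap, method = "positional"), 20)
})
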