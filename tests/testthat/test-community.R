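test_that("soft modularity: degenerate memberships give Q = 0", {
  net <- er_network(1, n = 10, p = 0.5)
  S_unif <- matrix(1 / 3, 10, 3)
  expect_equal(soft_modularity(net, S_unif), 0, tolerance = 1e-12)
  expect_equal(soft_modularity(net, matrix(1, 10, 1)), 0, tolerance = 1e-12)
})

test_that("two disjoint unit triangles, hard split: Q = 0.5", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  net <- weighted_network(W)
  expect_equal(soft_modularity(net, hard_S(rep(1:2, each = 3))), 0.5)
})

test_that("soft modularity is invariant to relabelling and weight scale", {
  set.seed(2)
  net <- er_network(2, n = 12, p = 0.5)
  S <- matrix(rgamma(12 * 2, 1), 12, 2)
  S <- S / rowSums(S)
  q0 <- soft_modularity(net, S)
  perm <- sample(12)
  net_p <- weighted_network(net$W[perm, perm])
  expect_equal(soft_modularity(net_p, S[perm, ]), q0, tolerance = 1e-12)
  net_s <- weighted_network(net$W * 7.5)
  expect_equal(soft_modularity(net_s, S), q0, tolerance = 1e-12)
})

test_that("soft modularity rejects bad input", {
  net <- er_network(3)
  expect_error(soft_modularity(net, matrix(0.7, 12, 2)), "sum to 1")
  empty <- weighted_network(matrix(0, 4, 4))
  expect_error(soft_modularity(empty, matrix(0.5, 4, 2)), "zero total weight")
})

test_that("fit is deterministic given a seed and objective is monotone", {
  net <- er_network(4, n = 15, p = 0.4)
  f1 <- fit_soft_communities(net, 2, n_restarts = 5, seed = 42)
  f2 <- fit_soft_communities(net, 2, n_restarts = 5, seed = 42)
  expect_identical(f1$S, f2$S)
  expect_identical(f1$Q_soft, f2$Q_soft)
  expect_true(f1$monotone)
  expect_true(all(abs(rowSums(f1$S) - 1) < 1e-9))
})

test_that("planted 2-block structure is recovered by dominant membership", {
  pn <- generate_planted_network(40, split = 0.6, q_in = 2, q_out = 0.2,
                                 sigma = 0.5, hours = 24, seed = 10)
  f <- fit_soft_communities(pn$network, 2, n_restarts = 10, seed = 20)
  lab <- apply(f$S, 1, which.max)
  tb <- table(lab, pn$truth_membership)
  acc <- max(sum(diag(tb)), sum(tb) - sum(diag(tb))) / sum(tb)
  expect_gte(acc, 0.9)
})

test_that("profile prefers the planted community number", {
  pn3 <- generate_planted_network(
    60, q_in = 2, q_out = 0.2, sigma = 0.5, hours = 24, seed = 31,
    membership = rep(c("A", "B", "C"), each = 20))
  prof <- modularity_profile(pn3$network, ks = 2:3, n_restarts = 6,
                             seed = 32)
  expect_gt(prof$Q[["3"]], prof$Q[["2"]])
})

test_that("unstructured dense count matrices have small fitted Q", {
  Qs <- vapply(1:3, function(s) {
    suppressWarnings(fit_soft_communities(dense_count_network(s, n = 60),
                                          2, n_restarts = 4,
                                          max_iter = 300, seed = s)$Q_soft)
  }, numeric(1))
  expect_lt(mean(Qs), 0.05)
})

test_that("permutation test with 0 swaps returns p = 1", {
  # two disjoint K4s: the optimizer reliably reaches the same optimum, so
  # identical null networks reproduce Q_obs exactly
  W <- matrix(0, 8, 8); W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  net <- weighted_network(W)
  pt <- modularity_permutation_test(net, k = 2, n_rewires = 20,
                                    n_restarts = 10, n_swap_multiplier = 0,
                                    seed = 5)
  expect_equal(pt$p, 1)
})

test_that("strongly planted networks beat every rewired null", {
  pn <- generate_planted_network(40, q_in = 2, q_out = 0.2, sigma = 0.5,
                                 hours = 24, seed = 6)
  pt <- suppressWarnings(
    modularity_permutation_test(pn$network, k = 2, n_rewires = 50,
                                n_restarts = 3, max_iter = 300, seed = 7))
  expect_equal(pt$p, 1 / 51)
})

test_that("social maturity orients by the queen and is column-invariant", {
  S <- rbind(c(0.9, 0.1),   # queen: less affiliated with column 2
             c(0.2, 0.8),
             c(0.5, 0.5))
  p <- fake_partition(S, ids = c("queen", "w1", "w2"))
  m <- social_maturity(p, queen_id = "queen")
  expect_equal(unname(m["w1"]), 0.8)
  expect_equal(unname(m["w2"]), 0.5)
  expect_equal(attr(m, "orientation"), "queen")

  # swapping columns must not change maturities
  p_swap <- fake_partition(S[, 2:1], ids = c("queen", "w1", "w2"))
  expect_equal(unname(social_maturity(p_swap, queen_id = "queen")["w1"]), 0.8)

  # exact tie is a hard error
  p_tie <- fake_partition(rbind(c(0.5, 0.5), c(0.2, 0.8)),
                          ids = c("queen", "w1"))
  expect_error(social_maturity(p_tie, queen_id = "queen"), "tied")

  # k != 2 violates the contract
  p3 <- fake_partition(matrix(1 / 3, 4, 3))
  expect_error(social_maturity(p3, queen_id = "ant_1"), "k = 2")
})

test_that("queenless orientation falls back to foraging proportions", {
  S <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.1, 0.9), c(0.2, 0.8))
  p <- fake_partition(S, ids = c("w1", "w2", "w3", "w4"))
  fp <- c(w1 = 0.5, w2 = 0.6, w3 = 0.0, w4 = 0.1)
  m <- social_maturity(p, queen_id = NULL, foraging_proportion = fp)
  expect_equal(attr(m, "orientation"), "foraging_fallback")
  expect_gt(m[["w1"]], m[["w3"]])  # foragers get high maturity
})

test_that("maturity correlates with foraging behaviour end-to-end", {
  col <- simulate_colony(colony_config(detection_frames = 0, seed = 14))
  f <- fit_soft_communities(col$network, 2, n_restarts = 8, seed = 15)
  m <- social_maturity(f, queen_id = "queen")
  w <- setdiff(col$ids, "queen")
  ct <- cor.test(m[w], col$foraging_proportion[w])
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.001)
})
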