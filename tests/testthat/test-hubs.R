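test_that("degree centrality sums absolute incident partial correlations", {
  z <- matrix(0, 4, 4)
  expect_equal(unname(centrality_scores(z)$scores), rep(0, 4))
  expect_true(centrality_scores(z)$degenerate)
  # star: center connected to 4 leaves at 0.2
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.2
  sc <- centrality_scores(star)$scores
  expect_equal(unname(sc), c(0.8, 0.2, 0.2, 0.2, 0.2))
  # permuting features permutes scores identically
  set.seed(2)
  r <- matrix(rnorm(36), 6, 6); r <- (r + t(r)) / 2; diag(r) <- 0
  perm <- sample(6)
  s1 <- centrality_scores(r)$scores
  s2 <- centrality_scores(r[perm, perm])$scores
  expect_equal(unname(s2), unname(s1)[perm])
})

test_that("alternative centralities behave on canonical small graphs", {
  # path graph on 3 nodes: middle node has strictly highest betweenness
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 0.5
  b <- centrality_scores(path3, "betweenness")$scores
  expect_gt(b[2], max(b[c(1, 3)]))
  # eigenvector scores: nonnegative, max 1, agree with a direct eigensolve
  chain5 <- matrix(0, 5, 5)
  for (i in 1:4) chain5[i, i + 1] <- chain5[i + 1, i] <- 0.4
  e <- centrality_scores(chain5, "eigenvector")$scores
  expect_true(all(e >= 0) && max(e) == 1)
  v <- abs(eigen(abs(chain5), symmetric = TRUE)$vectors[, 1])
  expect_equal(unname(e), v / max(v), tolerance = 1e-10)
  # symmetric about the middle of the chain
  expect_equal(e[[1]], e[[5]], tolerance = 1e-10)
  expect_equal(e[[2]], e[[4]], tolerance = 1e-10)
  expect_gt(e[[3]], e[[2]])
})

test_that("hub count follows the capped-proportion rule", {
  expect_identical(hub_count(337, 0.01), 3L)
  expect_identical(hub_count(337, 0.02), 6L)
  expect_identical(hub_count(337, 0.03), 10L)
  # tau = floor(80/16) = 5 caps nothing here; floor(60*0.06) = 3
  expect_identical(hub_count(60, 0.06), 3L)
  expect_identical(hub_count(60, 0.10), 5L)   # capped by tau
  expect_identical(hub_count(60, 0.10, tau = 20L), 6L)
  expect_identical(hub_count(16, 0.01), 0L)   # degenerates to plain adaptive lasso
  expect_error(hub_count(60, 0), "between 0 and 1")
  expect_error(hub_count(60, 1), "between 0 and 1")
})

test_that("hub selection takes the top scores with index tie-breaks", {
  hp <- select_hubs(c(0.9, 0.9, 0.1), 1L)
  expect_identical(hp$hub_indices, 1L)
  expect_identical(select_hubs(c(a = 1, b = 2, c = 3), 0L)$hub_indices, integer(0))
  all_h <- select_hubs(c(a = 1, b = 2, c = 3), 3L)
  expect_identical(sort(all_h$hub_indices), 1:3)
  expect_length(all_h$nonhub_indices, 0L)
  expect_error(select_hubs(c(1, 2), 3L), "between 0 and p")
  # partition property over random cases
  set.seed(9)
  for (i in 1:20) {
    p <- sample(3:40, 1)
    sc <- round(runif(p), 1)  # force ties
    h <- sample(0:p, 1)
    hp <- select_hubs(sc, h)
    expect_length(hp$hub_indices, h)
    expect_identical(sort(c(hp$hub_indices, hp$nonhub_indices)), seq_len(p))
    if (h > 0 && h < p)
      expect_gte(min(sc[hp$hub_indices]), max(sc[hp$nonhub_indices]) - 1e-12)
  }
})

test_that("degree ranking is invariant to positive rescaling", {
  set.seed(14)
  r <- matrix(rnorm(64), 8, 8); r <- (r + t(r)) / 2; diag(r) <- 0
  s1 <- centrality_scores(r)$scores
  s2 <- centrality_scores(3.7 * r)$scores
  expect_identical(order(-s1, seq_along(s1)), order(-s2, seq_along(s2)))
})

test_that("hubs on simulated strong-signal data sit in correlated feature groups", {
  # features 1-5 (clique plus its chain anchor) carry the structural degree
  hits <- 0L
  for (s in 1:8) {
    d <- sim_data(sim_scenario("II", "strong", seed = 600 + s, test_n = 5))
    net <- suppressWarnings(ggm_network(d$x_train))
    hp <- select_hubs(centrality_scores(net), hub_count(60, 0.06))
    hits <- hits + (mean(hp$hub_indices %in% 1:15) >= 2 / 3)
  }
  expect_gte(hits, 5L)
})

test_that("hub tables rank features and flag hubs", {
  sc <- centrality_scores(matrix(c(0, .5, .5, 0), 2, 2))
  hp <- select_hubs(sc, 1L)
  tab <- hub_table(sc, hp)
  expect_identical(tab$rank, 1:2)
  expect_identical(tab$is_hub, c(TRUE, FALSE))
})
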