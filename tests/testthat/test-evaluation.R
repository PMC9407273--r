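test_that("edge splitting partitions E with the documented rounding", {
  g <- rand_wgraph(8, 0.5, seed = 3, integer_weights = TRUE)
  m <- n_edges(g)
  split <- split_edges(g, 0.9, seed = 11)
  expect_equal(nrow(split$probe), floor(0.1 * m + 0.5))
  expect_equal(nrow(split$train) + nrow(split$probe), m)

  # same seed -> identical partition; different seed -> (usually) different
  split2 <- split_edges(g, 0.9, seed = 11)
  expect_identical(split$probe, split2$probe)

  # set algebra checked by brute force on canonical pair keys
  key <- function(df) paste(df$i, df$j)
  expect_length(intersect(key(split$train), key(split$probe)), 0)
  expect_setequal(c(key(split$train), key(split$probe)), key(edge_table(g)))
  expect_length(intersect(key(split$unknown), key(edge_table(g))), 0)
  expect_equal(nrow(split$unknown), 8 * 7 / 2 - m)

  # training graph keeps every node and only the training weights
  expect_equal(n_nodes(split$train_graph), 8)
  expect_equal(n_edges(split$train_graph), nrow(split$train))

  expect_error(split_edges(g, 0.999, seed = 1), "empty probe")
  expect_error(split_edges(g, 0.001, seed = 1), "empty training")
})

test_that("probe-size rounding: 10 edges at fraction 0.9 leave 1 probe edge", {
  # a 5-cycle plus 5 chords = 10 edges
  txt <- c("1 2 1", "2 3 1", "3 4 1", "4 5 1", "5 1 1",
           "1 3 1", "2 4 1", "3 5 1", "4 1 1", "5 2 1")
  g <- read_weighted_edge_list(text = txt)
  expect_equal(n_edges(g), 10)
  split <- split_edges(g, 0.9, seed = 5)
  expect_equal(nrow(split$probe), 1)
  expect_equal(nrow(split$train), 9)
})

test_that("mutual-most-similar ratio handles the worked example and extremes", {
  expect_identical(mutual_most_similar_ratio(ms_worked_example()), 0.2)

  # every node paired into a mutual couple -> 1.0
  s <- matrix(0, 6, 6)
  for (i in 1:3) s[2 * i - 1, 2 * i] <- s[2 * i, 2 * i - 1] <- 10 + i
  expect_equal(mutual_most_similar_ratio(similarity_matrix(s, "toy")), 1)

  # a strict (directed) preference cycle has no reciprocation -> 0
  chain <- matrix(0, 5, 5)
  for (x in 1:5) chain[x, (x %% 5) + 1] <- 1
  expect_equal(mutual_most_similar_ratio(chain), 0)

  # numerator is always even on random symmetric matrices
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    s <- matrix(runif(n * n), n, n)
    s <- (s + t(s)) / 2; diag(s) <- 0
    ms <- mutual_most_similar_ratio(similarity_matrix(s, "toy"))
    expect_equal((ms * n) %% 2, 0)
  }
})

test_that("most-similar table lists every node and flags general nodes", {
  mp <- most_similar_pairs(ms_worked_example())
  expect_equal(nrow(mp), 10)
  expect_equal(mp$most_similar[mp$node == "v1"], "v2")
  expect_equal(mp$most_similar[mp$node == "v2"], "v1")
  expect_length(attr(mp, "general_similar"), 0)

  # a hub that is most similar for > 50% of nodes gets flagged
  s <- matrix(0, 6, 6)
  s[1, 2:6] <- s[2:6, 1] <- 5     # everyone's best match is node 1
  s[2, 3] <- s[3, 2] <- 1
  mp2 <- most_similar_pairs(similarity_matrix(s, "toy"))
  expect_equal(attr(mp2, "general_similar"), "v1")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_most_similar_tsv(ms_worked_example(), path)
  expect_equal(length(readLines(path)), 11)
})

# split with controllable scores: n = 5, m = 6, fraction 0.5 -> 3 probe edges
scored_fixture <- function(probe_scores, unknown_scores, other = 0) {
  txt <- c("1 2 1", "1 3 1", "1 4 1", "2 3 1", "2 4 1", "3 4 1")
  g <- read_weighted_edge_list(text = c(txt, "1 5 1"))  # m = 7
  split <- split_edges(g, 4 / 7, seed = 2)              # 3 probe edges
  stopifnot(nrow(split$probe) == 3, nrow(split$unknown) == 3)
  s <- matrix(other, 5, 5); diag(s) <- 0
  for (r in seq_len(3)) {
    s[split$probe$i[r], split$probe$j[r]] <- probe_scores[r]
    s[split$probe$j[r], split$probe$i[r]] <- probe_scores[r]
    s[split$unknown$i[r], split$unknown$j[r]] <- unknown_scores[r]
    s[split$unknown$j[r], split$unknown$i[r]] <- unknown_scores[r]
  }
  list(sim = similarity_matrix(s, "toy"), split = split)
}

test_that("exact AUC matches hand enumeration and the two extremes", {
  # probe (3, 1, 2) vs unknown (0, 1, 2): wins 3 + 1 + 2 = 6, ties 2 -> 7/9
  fx <- scored_fixture(c(3, 1, 2), c(0, 1, 2))
  expect_equal(auc_exact(fx$sim, fx$split), (6 + 2 * 0.5) / 9)
  # perfect scorer
  fx1 <- scored_fixture(c(5, 6, 7), c(1, 2, 3))
  expect_equal(auc_exact(fx1$sim, fx1$split), 1)
  # constant scorer: all comparisons tie
  fx2 <- scored_fixture(c(2, 2, 2), c(2, 2, 2), other = 2)
  expect_equal(auc_exact(fx2$sim, fx2$split), 0.5)
})

test_that("sampled AUC is exact at the extremes and tracks the exact value", {
  fx1 <- scored_fixture(c(5, 6, 7), c(1, 2, 3))
  expect_equal(auc_sampled(fx1$sim, fx1$split, r = 2000, seed = 1), 1)
  fx2 <- scored_fixture(c(2, 2, 2), c(2, 2, 2), other = 2)
  expect_equal(auc_sampled(fx2$sim, fx2$split, r = 2000, seed = 1), 0.5)

  fx <- scored_fixture(c(3, 1, 2), c(0, 1, 2))
  exact <- auc_exact(fx$sim, fx$split)
  r <- 10000
  sampled <- auc_sampled(fx$sim, fx$split, r = r, seed = 7)
  expect_lt(abs(sampled - exact), 4 * sqrt(0.25 / r))
  # determinism per seed
  expect_identical(sampled, auc_sampled(fx$sim, fx$split, r = r, seed = 7))
})

test_that("AUC of a tie-free scorer and its negation sum to 1", {
  g <- rand_wgraph(9, 0.5, seed = 13)
  split <- split_edges(g, 0.8, seed = 4)
  set.seed(99)
  s <- matrix(runif(81), 9, 9); s <- (s + t(s)) / 2; diag(s) <- 0
  sim <- similarity_matrix(s, "toy")
  neg <- similarity_matrix(-s, "toy")
  expect_equal(auc_exact(sim, split) + auc_exact(neg, split), 1)
})

test_that("indices trained on a split never read probe-edge weights", {
  g <- rand_wgraph(10, 0.5, seed = 17, integer_weights = TRUE)
  split <- split_edges(g, 0.8, seed = 31)
  # poison the probe weights in a copy of the original graph
  w2 <- weight_matrix(g)
  w2[cbind(split$probe$i, split$probe$j)] <- 999
  w2[cbind(split$probe$j, split$probe$i)] <- 999
  split2 <- split_edges(weighted_graph(w2, g$labels), 0.8, seed = 31)
  expect_identical(split$probe[c("i", "j")], split2$probe[c("i", "j")])
  for (idx in c("redd", "wcn", "lrw", "lre")) {
    expect_identical(similarity_index(split$train_graph, idx, d = 4),
                     similarity_index(split2$train_graph, idx, d = 4))
  }
})

test_that("run_experiment aggregates replicates with the seed ladder", {
  g <- rand_wgraph(12, 0.5, seed = 23, integer_weights = TRUE)
  res <- run_experiment(g, "wcn", metric = "auc", train_fraction = 0.8,
                        replicates = 4, r = 500, base_seed = 100)
  expect_equal(res$value, mean(res$per_replicate))
  expect_equal(res$seeds, 101:104)
  expect_true(all(res$per_replicate >= 0 & res$per_replicate <= 1))

  # one replicate reduces to a single split evaluation
  res1 <- run_experiment(g, "wcn", metric = "auc", train_fraction = 0.8,
                         replicates = 1, r = 500, base_seed = 100)
  expect_equal(res1$value, res$per_replicate[[1]])

  # MS uses the full graph and no randomness
  ms1 <- run_experiment(g, "redd", metric = "ms", d = 4, base_seed = 1)
  ms2 <- run_experiment(g, "redd", metric = "ms", d = 4, base_seed = 999)
  expect_identical(ms1$value, ms2$value)
  expect_equal(ms1$replicates, 1L)
  expect_identical(ms1$value, mutual_most_similar_ratio(redd_similarity(g, d = 4)))
})
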