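toy_contacts <- function() {
  data.frame(t_start = c(1, 3, 7, 2, 9),
             t_end = c(2, 5, 8, 6, 12),
             i = c(1, 1, 1, 2, 3),
             j = c(2, 2, 3, 3, 4))
}

test_that("interduration extraction matches hand-computed gaps", {
  cc <- toy_contacts()
  # node 1 appears at starts 1, 3, 7 -> gaps 2, 4
  gn <- interdurations(cc[cc$i == 1, ], "node")
  expect_equal(sort(gn[1:2]), c(2, 4))
  # a single contact yields no gaps
  expect_length(interdurations(cc[5, , drop = FALSE], "node"), 0)
  # pair (1,2) interacts at 1 and 3 -> edge gap 2
  expect_true(2 %in% interdurations(cc, "edge"))
})

test_that("interdurations agree with the brute-force oracle and are
          order-invariant", {
  cc <- generate_fixture("contact_log",
                         list(n_nodes = 12, n_contacts = 50), seed = 91)
  for (lv in c("node", "edge")) {
    expect_equal(sort(interdurations(cc, lv)),
                 sort(brute_interdurations(cc, lv)))
  }
  shuffled <- cc[sample(nrow(cc)), ]
  expect_equal(sort(interdurations(shuffled, "node")),
               sort(interdurations(cc, "node")))
})

test_that("interaction scores follow the log-normalized construction", {
  # three pairs with summed durations e^2, e^1, e^0.5:
  # scores 1, 0.5, 0.25 -> only the first two exceed 0.4
  cc <- data.frame(t_start = c(0, 0, 0),
                   t_end = c(exp(2), exp(1), exp(0.5)),
                   i = c(1, 1, 2), j = c(2, 3, 3))
  g <- interaction_score_graph(cc, threshold = 0.4)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(sort(igraph::E(g)$score), c(0.5, 1))
  # a single interacting pair normalizes to score 1 and keeps its edge
  g1 <- interaction_score_graph(cc[1, ], threshold = 0.4)
  expect_equal(igraph::ecount(g1), 1)
  expect_equal(igraph::E(g1)$score, 1)
  # a pair whose total duration is one tick has log-score 0
  expect_error(interaction_score_graph(
    data.frame(t_start = 0, t_end = 1, i = 1, j = 2)), "undefined")
})

test_that("score ordering is invariant to global time-unit rescaling", {
  # the log transform shifts every (unfloored) score by log(c) before
  # max-normalization, so absolute scores change under a change of time
  # unit but their ordering cannot; the sub-tick floor is kept out of play
  # by using durations of at least one tick
  cc <- generate_fixture("contact_log",
                         list(n_nodes = 8, n_contacts = 40), seed = 92)
  set.seed(920)
  cc$t_end <- cc$t_start + pmax(cc$t_end - cc$t_start, 1.2) +
    runif(nrow(cc), 0.01, 0.2)   # no sub-tick sums, no exact ties
  score_of <- function(d, scale) {
    d$t_start <- d$t_start * scale; d$t_end <- d$t_end * scale
    g <- interaction_score_graph(d, threshold = -Inf)
    s <- igraph::E(g)$score
    names(s) <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
    s
  }
  s1 <- score_of(cc, 1)
  s2 <- score_of(cc, 10)[names(s1)]
  expect_equal(rank(s1), rank(s2))
})

test_that("aggregated metrics match closed forms on canonical graphs", {
  k4 <- igraph::make_full_graph(4)
  m <- aggregated_metrics(k4, louvain_seeds = 1:2)
  expect_equal(m[["clustering"]], 1)
  expect_equal(m[["transitivity"]], 1)
  expect_equal(m[["density"]], 1)
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  m0 <- aggregated_metrics(empty)
  expect_equal(m0[["density"]], 0)
  expect_true(is.na(m0[["modularity"]]))
})

test_that("metrics agree with an independent brute-force implementation", {
  set.seed(93)
  n <- 12
  adj <- matrix(0L, n, n)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    if (runif(1) < 0.3) adj[a, b] <- adj[b, a] <- 1L
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  m <- aggregated_metrics(g, louvain_seeds = 1:3)
  ref <- brute_graph_metrics(adj)
  expect_equal(m[["density"]], ref$density)
  expect_equal(m[["clustering"]], ref$clustering)
  expect_equal(m[["transitivity"]], ref$transitivity)
  # the Louvain partition's modularity matches Newman's formula
  set.seed(1)
  cl <- igraph::cluster_louvain(g, resolution = 1)
  expect_equal(igraph::modularity(cl),
               brute_modularity(adj, igraph::membership(cl)),
               tolerance = 1e-10)
})

test_that("metric deviations are normalized by the cross-model spread", {
  ms <- list(a = c(density = 0.2, clustering = 0.5),
             b = c(density = 0.4, clustering = 0.9))
  ref <- c(density = 0.3, clustering = 0.6)
  d <- metric_deviations(ms, ref)
  sd_d <- stats::sd(c(0.2, 0.4))
  expect_equal(d["a", "density"], 0.1 / sd_d)
  expect_equal(d["b", "clustering"], 0.3 / stats::sd(c(0.5, 0.9)))
})
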