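test_that("competitive displacement requires strictly higher affinity", {
  expect_true(competition_accept(0.4, 0.5))
  expect_false(competition_accept(0.5, 0.4))
  expect_false(competition_accept(0.5, 0.5))   # ties are rejected
  # with uniform affinities on both sides the acceptance fraction is 1/2
  set.seed(51)
  a <- runif(2e4); b <- runif(2e4)
  expect_equal(mean(competition_accept(a, b)), 0.5, tolerance = 0.02)
})

test_that("the affinity update contracts toward u and stays in [0, 1]", {
  expect_equal(affinity_update(0, 0.5, 10), 0.05)
  expect_equal(affinity_update(0.3, 0.3, 10), 0.3)   # fixed point at u = a
  # expected drift at a = 0.9 is (0.5 - 0.9)/10 = -0.04
  u <- seq(0.0005, 0.9995, by = 0.001)
  expect_equal(mean(affinity_update(0.9, u, 10) - 0.9), -0.04,
               tolerance = 1e-6)
  set.seed(52)
  a <- runif(5000); u <- runif(5000)
  d <- affinity_update(a, u, 10)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("dominance is the largest clone's share of the living pool", {
  expect_equal(dominance(c(5, 3, 2)), 0.5)
  expect_equal(dominance(7), 1)
  expect_equal(dominance(rep(3, 10)), 0.1)
  expect_error(dominance(numeric(0)), "empty")
  expect_error(dominance(c(0, 0)), "empty")
})

test_that("germinal-center runs are reproducible and well-formed", {
  r1 <- run_gc(n_b = 200, n_t = 4, t_end_days = 6, seed = 53)
  r2 <- run_gc(n_b = 200, n_t = 4, t_end_days = 6, seed = 53)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$cells, r2$cells)
  tr <- r1$trajectory
  # bound-pair conservation: never more simultaneous pairs than T cells
  expect_true(all(tr$n_bound <= 4))
  expect_true(all(tr$n_total == tr$n_free + tr$n_bound + tr$n_div))
  # affinities stay in [0, 1] for every cell ever created
  expect_true(all(r1$cells$affinity >= 0 & r1$cells$affinity <= 1))
  expect_true(all(tr$mean_affinity >= 0 & tr$mean_affinity <= 1,
                  na.rm = TRUE))
})

test_that("without division the population never grows", {
  r <- run_gc(n_b = 150, n_t = 3, t_end_days = 8, seed = 54, lambda_div = 0)
  expect_true(all(diff(r$trajectory$n_total) <= 0))
})

test_that("competition raises the population affinity over paired seeds", {
  seeds <- c(55, 56, 57)
  final_aff <- function(comp, s) {
    tr <- run_gc(n_b = 300, n_t = 5, t_end_days = 15, seed = s,
                 competition = comp)$trajectory
    tr$mean_affinity[nrow(tr)]
  }
  with_comp <- vapply(seeds, function(s) final_aff(TRUE, s), numeric(1))
  without <- vapply(seeds, function(s) final_aff(FALSE, s), numeric(1))
  expect_true(all(with_comp > without))
})

test_that("clonal dominance grows on average as selection proceeds", {
  doms <- sapply(1:6, function(s) {
    tr <- run_gc(n_b = 300, n_t = 5, t_end_days = 25, seed = 60 + s)$trajectory
    tr$dominance[match(c(5, 15, 25) * 24, tr$time)]
  })
  m <- rowMeans(doms)
  expect_true(all(diff(m) > 0))
})

test_that("thinning and direct Gillespie agree at reduced size", {
  # all channels are exponential, so the two simulators must be
  # distributionally equivalent; compare end-point populations and mean
  # affinities over replicates
  finals_m <- sapply(1:25, function(s) {
    tr <- run_gc(n_b = 100, n_t = 2, t_end_days = 5, seed = s)$trajectory
    c(tr$n_total[nrow(tr)], tr$mean_affinity[nrow(tr)])
  })
  finals_g <- sapply(1:25, function(s) {
    tr <- run_gc_gillespie(n_b = 100, n_t = 2, t_end_days = 5,
                           seed = 100 + s)$trajectory
    c(tr$n_total[nrow(tr)], tr$mean_affinity[nrow(tr)])
  })
  expect_gt(stats::ks.test(finals_m[1, ], finals_g[1, ])$p.value, 0.01)
  expect_gt(stats::ks.test(finals_m[2, ], finals_g[2, ])$p.value, 0.01)
})
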