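test_that("kernel bounds follow the closed forms", {
  b <- lambda_max_tn(alpha_a = 1, t_min = 1, lambda_a = 0.5, n_a = 2)
  expect_equal(b$lambda_max, 1)
  expect_equal(b$Lambda_max, 2)
  # the pair bound scales as 1/(N_A - 1)
  b10 <- lambda_max_tn(1, 1, 0.5, 11)
  expect_equal(b10$Lambda_max, b$Lambda_max / 10)
})

test_that("history-biased proposal weights follow the weight arithmetic", {
  expect_equal(biased_partner_weights(rep(FALSE, 5), 4), rep(0.2, 5))
  # one prior partner among 10 candidates with w = 9: probability 9/18
  pr <- c(TRUE, rep(FALSE, 9))
  expect_equal(biased_partner_weights(pr, 9)[1], 0.5)
  expect_equal(sum(biased_partner_weights(pr, 9)), 1)
})

test_that("a two-node network only ever proposes its single pair", {
  r <- run_facetoface(n_nodes = 2, t_end = 400, seed = 81)
  expect_true(all(r$contacts$i == 1 & r$contacts$j == 2))
  expect_gt(nrow(r$contacts), 0)
})

test_that("contact lists are reproducible and bound-safe", {
  r1 <- run_facetoface(n_nodes = 40, t_end = 800, seed = 82)
  r2 <- run_facetoface(n_nodes = 40, t_end = 800, seed = 82)
  expect_identical(r1$contacts, r2$contacts)
  expect_lte(r1$max_acceptance_ratio, 1)
  cc <- r1$contacts
  expect_true(all(cc$t_start < cc$t_end))
  expect_true(all(cc$t_end <= 800))
  # bound values match the closed form
  b <- lambda_max_tn(0.76, 2^(-1 / 0.76) / 0.4, 0.4, 40)
  expect_equal(r1$bounds$Lambda_max, b$Lambda_max)
})

test_that("node interdurations are heavy-tailed under Pareto activity", {
  gaps <- c()
  for (s in 83:86) {
    r <- run_facetoface(n_nodes = 150, t_end = 2000, seed = s)
    gaps <- c(gaps, interdurations(r$contacts, "node"))
  }
  expect_gt(length(gaps), 300)
  # survival beyond 10x the median decays far slower than the exponential
  # fitted to the same median
  med <- median(gaps)
  emp <- mean(gaps > 10 * med)
  expo <- 2^-10   # exponential with the same median
  expect_gt(emp, 5 * expo)
})

test_that("variant A is recovered at w = 1 and by the kernel route", {
  a <- run_facetoface(n_nodes = 20, t_end = 300, seed = 87, w = 1,
                      variant = "proposal")
  k <- run_facetoface(n_nodes = 20, t_end = 300, seed = 87, w = 1,
                      variant = "kernel")
  expect_identical(a$contacts, k$contacts)
})

test_that("history bias through the proposal saves an order of magnitude
          of rejections over the kernel route", {
  a <- run_facetoface(n_nodes = 50, t_end = 1000, w = 9.4, seed = 88,
                      variant = "proposal")
  k <- run_facetoface(n_nodes = 50, t_end = 1000, w = 9.4, seed = 88,
                      variant = "kernel")
  ratio <- (k$counters$rejected / k$counters$accepted) /
    (a$counters$rejected / a$counters$accepted)
  expect_gt(ratio, 3)
  expect_lt(ratio, 30)
})

test_that("node- and edge-driven simulations coincide for exponential
          activity", {
  nd <- run_facetoface(n_nodes = 6, t_end = 4000, activity = "exponential",
                       termination = "exponential", lambda_a = 0.4,
                       lambda_end = 0.61, seed = 89)
  ed <- run_edge_driven_exponential(6, 4000, 0.4, 0.61, seed = 90)
  expect_gt(suppressWarnings(
    stats::ks.test(interdurations(nd$contacts, "node"),
                   interdurations(ed$contacts, "node"))$p.value), 0.01)
  expect_gt(stats::ks.test(interaction_durations(nd$contacts),
                           interaction_durations(ed$contacts))$p.value, 0.01)
})
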