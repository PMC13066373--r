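test_that("time increments follow ln(1/u)/(N lambda_max)", {
  expect_equal(draw_time_increment(exp(-1), 1, 1), 1)
  expect_equal(draw_time_increment(1, 7, 3.2), 0)
  set.seed(1)
  dts <- draw_time_increment(runif(1e5), 10, 0.5)
  expect_equal(mean(dts), 1 / (10 * 0.5), tolerance = 0.01)
  expect_error(draw_time_increment(0.5, 0, 1), "n")
  expect_error(draw_time_increment(0.5, 1, -1), "lambda_max")
  expect_error(draw_time_increment(0, 1, 1), "u")
})

test_that("candidate selection is uniform over the registry", {
  expect_equal(select_candidate(1), 1L)
  expect_error(select_candidate(0), "empty")
  set.seed(2)
  draws <- replicate(2e4, select_candidate(4))
  freq <- tabulate(draws, 4) / 2e4
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 2e4)))
  # chi-square uniformity over a larger registry
  set.seed(3)
  draws <- replicate(1e5, select_candidate(50))
  expect_gt(stats::chisq.test(tabulate(draws, 50))$p.value, 0.01)
  # non-uniform proposal hook
  set.seed(4)
  draws <- replicate(5000, select_candidate(2, prob = c(0.9, 0.1)))
  expect_equal(mean(draws == 1L), 0.9, tolerance = 0.05)
})

test_that("acceptance probability is hazard over bound, never clipped", {
  expect_equal(acceptance_probability(ied_exponential(2), 5, 2), 1)
  p <- ied_pareto(1, 0.76)
  expect_equal(acceptance_probability(p, 2, hazard_bound(p)), 0.5)
  expect_equal(acceptance_probability(ied_gamma(3, 0.05), 0, 0.15), 0)
  expect_error(acceptance_probability(ied_exponential(2), 1, 0.5),
               "does not bound")
  expect_error(acceptance_probability(ied_exponential(1), -1, 1), "elapsed")
})

test_that("dominating-rate strategies cover the four scenarios", {
  # bounded: analytic per-family constants
  expect_equal(update_lambda_max(list(ied_gamma(3, 1 / 20)), 5), 0.15)
  expect_equal(update_lambda_max(list(ied_pareto(1, 0.76)), 3), 0.76)
  # increasing-unbounded: bound from the oldest clock equals the true
  # brute-force maximum over all clocks
  w <- ied_weibull(2, 1)
  elapsed <- c(0.3, 2.7, 1.1, 0.05)
  b <- update_lambda_max(rep(list(w), 4), elapsed)
  expect_equal(b, max(ied_hazard(w, elapsed)))
  # decreasing-unbounded: refused unless a user bound is supplied
  expect_error(update_lambda_max(list(ied_weibull(0.5, 1)), 1), "refused")
  expect_equal(update_lambda_max(list(ied_weibull(0.5, 1)), 1,
                                 user_bound = 10), 10)
  # mixed registry takes the max across scenarios
  b <- update_lambda_max(list(ied_exponential(0.1), w), c(1, 3))
  expect_equal(b, ied_hazard(w, 3))
})

test_that("runs are reproducible and respect the time horizon", {
  m <- renewal_model(ied_gamma(3, 0.2))
  r1 <- mosaic_run(m, t_end = 200, seed = 11)
  r2 <- mosaic_run(m, t_end = 200, seed = 11)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$counters, r2$counters)
  r0 <- mosaic_run(m, t_end = 0, seed = 11)
  expect_equal(nrow(r0$events), 0L)
  expect_error(mosaic_run(m, t_end = -1), "non-negative")
})

test_that("rejected iterations change nothing but the global time", {
  # a state counter incremented on every firing: rejected candidates must
  # never touch it, and accepted inter-event statistics must be unaffected
  # by the presence of rejections
  m <- mosaic_model(
    list(mosaic_channel(ied_gamma(3, 0.2))),
    state = list(fired = 0L),
    on_fire = function(state, ch, t) list(state = list(fired = state$fired + 1L))
  )
  r <- mosaic_run(m, t_end = 500, seed = 12, record = "all")
  expect_equal(r$state$fired, sum(r$events$accepted))
  expect_gt(r$counters$rejected, 0)
  rej <- r$events[!r$events$accepted, ]
  acc <- r$events[r$events$accepted, ]
  # rejected timestamps interleave but the accepted log alone determines
  # the inter-event times
  expect_equal(interevent_times(r), diff(c(0, acc$time)))
})

test_that("accepted single-channel statistics match renewal theory", {
  # exponential channel: inter-event times are Exp(rate)
  r <- mosaic_run(renewal_model(ied_exponential(2)), t_end = 2500, seed = 1)
  iet <- interevent_times(r)
  expect_gt(length(iet), 3000)
  expect_gt(stats::ks.test(iet, stats::pexp, 2)$p.value, 0.01)
  expect_equal(rejection_factor(r), 1)
  # two independent exponential channels: event share is rate / total
  m <- mosaic_model(list(mosaic_channel(ied_exponential(1), payload = "a"),
                         mosaic_channel(ied_exponential(3), payload = "b")))
  r <- mosaic_run(m, t_end = 2500, seed = 3)
  ev <- r$events[r$events$accepted, ]
  expect_equal(mean(ev$payload == "a"), 0.25,
               tolerance = 3 * sqrt(0.25 * 0.75 / nrow(ev)) / 0.25)
})

test_that("channel removal reproduces the pure-death extinction time", {
  pd_extinction <- function(s) {
    chans <- replicate(100, mosaic_channel(ied_exponential(1)),
                       simplify = FALSE)
    m <- mosaic_model(chans,
                      on_fire = function(state, ch, t) list(remove = ch$id))
    r <- mosaic_run(m, t_end = Inf, seed = s)
    expect_equal(nrow(r$events), 100L)
    max(r$events$time)
  }
  ext <- vapply(1:150, pd_extinction, numeric(1))
  # analytic mean extinction time: sum_{k=1}^{100} 1/k; per-run sd ~ 1.28
  expect_equal(mean(ext), sum(1 / (1:100)),
               tolerance = 3 * 1.28 / sqrt(150) / sum(1 / (1:100)))
})

test_that("the debug bound check passes for safe policies", {
  m <- mosaic_model(list(mosaic_channel(ied_gamma(3, 0.2)),
                         mosaic_channel(ied_pareto(0.5, 1.2)),
                         mosaic_channel(ied_exponential(0.3)),
                         mosaic_channel(ied_weibull(2, 4))))
  expect_no_error(mosaic_run(m, t_end = 150, seed = 5,
                             debug_check_bound = TRUE))
})

test_that("a fixed bound below the hazard is a hard error", {
  m <- renewal_model(ied_exponential(2), lambda_max = "fixed",
                     lambda_max_value = 1)
  expect_error(mosaic_run(m, t_end = 50, seed = 6), "bound violated")
})

test_that("state modifiers scale hazards and their declared bounds", {
  # a channel whose rate doubles via its modifier behaves like one with
  # twice the base rate
  m <- mosaic_model(list(mosaic_channel(ied_exponential(1),
                                        state_modifier = function(s, t) 2,
                                        modifier_bound = 2)))
  r <- mosaic_run(m, t_end = 2000, seed = 7)
  iet <- interevent_times(r)
  expect_gt(stats::ks.test(iet, stats::pexp, 2)$p.value, 0.01)
})
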