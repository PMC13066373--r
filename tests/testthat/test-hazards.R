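families <- list(
  exponential = ied_exponential(2),
  gamma = ied_gamma(3, 0.05),
  pareto = ied_pareto(1, 0.76),
  weibull_inc = ied_weibull(2, 1.5),
  lognormal = ied_lognormal(0.5, 0.8),
  delayed_exp = ied_delayed_exponential(0.5, 2)
)

grids <- list(
  exponential = seq(0.1, 10, length.out = 40),
  gamma = seq(0.5, 120, length.out = 40),
  pareto = seq(1.01, 50, length.out = 40),
  weibull_inc = seq(0.1, 4, length.out = 40),
  lognormal = seq(0.2, 10, length.out = 40),
  delayed_exp = seq(2.05, 12, length.out = 40)
)

test_that("hazard equals density over survival for every family", {
  for (nm in names(families)) {
    ied <- families[[nm]]
    t <- grids[[nm]]
    expect_equal(ied_hazard(ied, t),
                 ied_density(ied, t) / ied_survival(ied, t),
                 tolerance = 1e-8, info = nm)
  }
})

test_that("hazards have the documented shapes and limits", {
  # Pareto: alpha / t on the support, zero before t_min, monotone decreasing
  p <- ied_pareto(1, 0.76)
  expect_equal(ied_hazard(p, 1), 0.76)
  expect_equal(ied_hazard(p, 0.5), 0)
  tg <- seq(1, 100, length.out = 200)
  expect_true(all(diff(ied_hazard(p, tg)) < 0))
  # Gamma shape > 1: zero at origin, monotone increasing, saturating at
  # shape * lambda0 = 0.15
  g <- ied_gamma(3, 0.05)
  expect_equal(ied_hazard(g, 0), 0)
  tg <- seq(0, 400, length.out = 300)
  expect_true(all(diff(ied_hazard(g, tg)) > 0))
  expect_equal(ied_hazard(g, 1e6), 0.15, tolerance = 1e-4)
  expect_equal(hazard_bound(g), 0.15)
  # exponential: constant
  expect_equal(ied_hazard(ied_exponential(2), c(0, 1, 7)), c(2, 2, 2))
  # delayed exponential: dead time then flat
  d <- ied_delayed_exponential(0.5, 2)
  expect_equal(ied_hazard(d, c(1, 3)), c(0, 0.5))
  # log-normal: numeric bound dominates the hazard on a wide grid
  l <- ied_lognormal(0.5, 0.8)
  expect_true(all(ied_hazard(l, seq(0.01, 50, length.out = 500)) <=
                    hazard_bound(l)))
})

test_that("negative elapsed time is rejected", {
  expect_error(ied_hazard(ied_exponential(1), -0.1), "negative")
  expect_error(renewal_density(ied_gamma(3, 0.05), -1), "negative")
})

test_that("median and characteristic rate follow the Pareto closed forms", {
  p <- ied_pareto(1, 1)
  expect_equal(ied_median(p), 2)
  expect_equal(characteristic_rate(p), 0.5)
  # inverting the characteristic-rate parametrization
  p2 <- ied_pareto_from_rate(0.4, 0.76)
  expect_equal(p2$params$t_min, 2^(-1 / 0.76) / 0.4)
  expect_equal(characteristic_rate(p2), 0.4, tolerance = 1e-12)
  # sampling median matches the analytic median within 1%
  set.seed(41)
  x <- sample_oracle(p2, 2e5)
  expect_equal(median(x), ied_median(p2), tolerance = 0.01)
})

test_that("oracle samplers match their analytic distributions", {
  set.seed(42)
  expect_equal(mean(sample_oracle(ied_exponential(1), 5e4)), 1,
               tolerance = 0.02)
  # elongation parametrization: mean waiting time is 1 / lambda0 = 20 min
  g <- ied_gamma(3, 0.05)
  expect_equal(mean(sample_oracle(g, 5e4)), 20, tolerance = 0.01)
  for (nm in c("gamma", "pareto", "weibull_inc", "lognormal")) {
    x <- sample_oracle(families[[nm]], 4000)
    p <- stats::ks.test(x, function(q) ied_cdf(families[[nm]], q))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("renewal density matches the family density and normalizes", {
  t <- seq(0.1, 60, length.out = 30)
  expect_equal(renewal_density(ied_exponential(0.3), t),
               stats::dexp(t, 0.3))
  p <- ied_pareto(1, 0.76)
  tt <- seq(1, 40, length.out = 30)
  expect_equal(renewal_density(p, tt), 0.76 * 1^0.76 / tt^(0.76 + 1))
  # quadrature normalization of the Gamma elongation density
  total <- stats::integrate(function(x) renewal_density(ied_gamma(3, 0.05), x),
                            0, Inf)$value
  expect_equal(total, 1, tolerance = 1e-5)
})

test_that("custom hazards agree with their analytic counterparts", {
  lh <- ied_linear_hazard(1, 2)
  t <- seq(0, 3, length.out = 25)
  expect_equal(ied_survival(lh, t), exp(-t - t^2), tolerance = 1e-9)
  expect_equal(ied_cdf(lh, ied_quantile(lh, c(0.1, 0.5, 0.9))),
               c(0.1, 0.5, 0.9), tolerance = 1e-9)
  # quadrature path (no analytic cdf supplied)
  cq <- ied_custom(function(t) ifelse(t < 0, 0, 1 + 2 * t),
                   bound_scenario = "increasing_unbounded")
  expect_equal(ied_survival(cq, t), exp(-t - t^2), tolerance = 1e-6)
  expect_equal(renewal_density(cq, 1), (1 + 2) * exp(-2), tolerance = 1e-6)
  # bounded custom hazards require a bound
  expect_error(ied_custom(function(t) 1, bound_scenario = "bounded"),
               "bound")
})

test_that("bound scenarios are classified as documented", {
  expect_equal(ied_weibull(2)$bound_scenario, "increasing_unbounded")
  expect_equal(ied_weibull(0.7)$bound_scenario, "decreasing_unbounded")
  expect_equal(ied_gamma(0.5, 1)$bound_scenario, "decreasing_unbounded")
  expect_equal(ied_pareto(1, 0.5)$bound_scenario, "bounded")
  expect_equal(ied_lognormal()$bound_scenario, "bounded")
})
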