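#' Inter-event-time distribution (IED) families
#'
#' An `ied` object describes the waiting-time distribution of one stochastic
#' process through four equivalent views: the density \eqn{\psi(t)}, the
#' cumulative distribution \eqn{F(t)}, the survival \eqn{1 - F(t)}, and the
#' hazard (instantaneous rate) \eqn{\lambda(t) = \psi(t) / (1 - F(t))}.
#' The thinning engine only ever evaluates the hazard and an upper bound on
#' it; the other views are used by the oracle samplers and the validation
#' statistics.
#'
#' Every family declares a `bound_scenario` that tells the engine how a
#' dominating rate can be maintained:
#' \describe{
#'   \item{`bounded`}{a finite constant `B` with \eqn{\lambda(t) \le B} for
#'     all `t` exists and is known analytically (exponential, Pareto,
#'     Gamma with shape > 1, log-normal, delayed exponential).}
#'   \item{`increasing_unbounded`}{\eqn{\lambda(t)} grows without bound but
#'     monotonically (Weibull with shape > 1), so the process with the
#'     oldest clock dominates.}
#'   \item{`decreasing_unbounded`}{\eqn{\lambda(t)} diverges at short times
#'     (Weibull or Gamma with shape < 1).  Thinning is inefficient here and
#'     the engine refuses such channels unless the user supplies a bound.}
#'   \item{`piecewise`}{user-supplied interval bounds (custom hazards).}
#' }
#'
#' @param rate Positive rate (events per unit time).
#' @name ied
#' @return An object of class `c("<family>_ied", "ied")`.
NULL

new_ied <- function(family, params, bound_scenario, class) {
  structure(
    list(family = family, params = params, bound_scenario = bound_scenario),
    class = c(class, "ied")
  )
}

#' @rdname ied
#' @export
ied_exponential <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  new_ied("exponential", list(rate = rate), "bounded", "exponential_ied")
}

#' Gamma IED in the elongation parametrization
#'
#' Shape `shape` and rate `shape * lambda0`, so that the mean waiting time is
#' `1 / lambda0` regardless of the shape.  This is the natural form for a
#' multi-step completion process (e.g. transcript elongation) whose overall
#' throughput `lambda0` is the quantity of biological interest: for
#' `shape > 1` the hazard starts at zero, increases monotonically, and
#' saturates at the finite bound `shape * lambda0`.
#'
#' @param shape Positive shape parameter.
#' @param lambda0 Reciprocal mean waiting time (rate scale).
#' @export
ied_gamma <- function(shape, lambda0) {
  stopifnot(shape > 0, lambda0 > 0)
  scenario <- if (shape >= 1) "bounded" else "decreasing_unbounded"
  new_ied("gamma", list(shape = shape, lambda0 = lambda0, rate = shape * lambda0),
          scenario, "gamma_ied")
}

#' Pareto IED
#'
#' Density \eqn{\psi(t) = \alpha t_{min}^\alpha / t^{\alpha+1}} for
#' \eqn{t \ge t_{min}}, hazard \eqn{\alpha / t} on the support and 0 before
#' `t_min` (no event can occur before the minimum waiting time).  The hazard
#' is monotone decreasing on the support, so `alpha / t_min` is a global
#' bound.  The median is \eqn{t_{min} 2^{1/\alpha}}; its reciprocal is the
#' characteristic rate, which stays finite even in heavy-tailed regimes
#' (`alpha <= 1`) where the mean diverges.
#'
#' @param t_min Positive minimum waiting time.
#' @param alpha Positive tail exponent.
#' @export
ied_pareto <- function(t_min, alpha) {
  stopifnot(t_min > 0, alpha > 0)
  new_ied("pareto", list(t_min = t_min, alpha = alpha), "bounded", "pareto_ied")
}

#' @describeIn ied_pareto Construct a Pareto IED from its characteristic
#'   rate (reciprocal median) instead of `t_min`, inverting
#'   \eqn{\lambda = 2^{-1/\alpha} / t_{min}}.
#' @param lambda Characteristic rate, the reciprocal of the median.
#' @export
ied_pareto_from_rate <- function(lambda, alpha) {
  stopifnot(lambda > 0, alpha > 0)
  ied_pareto(t_min = 2^(-1 / alpha) / lambda, alpha = alpha)
}

#' @rdname ied
#' @param shape,scale Weibull shape and scale.
#' @export
ied_weibull <- function(shape, scale = 1) {
  stopifnot(shape > 0, scale > 0)
  scenario <- if (shape > 1) "increasing_unbounded"
              else if (shape < 1) "decreasing_unbounded"
              else "bounded"
  new_ied("weibull", list(shape = shape, scale = scale), scenario, "weibull_ied")
}

#' @rdname ied
#' @param meanlog,sdlog Log-scale mean and standard deviation.
#' @export
ied_lognormal <- function(meanlog = 0, sdlog = 1) {
  stopifnot(sdlog > 0)
  obj <- new_ied("lognormal", list(meanlog = meanlog, sdlog = sdlog),
                 "bounded", "lognormal_ied")
  # unimodal hazard; locate its finite maximum once, numerically
  med <- exp(meanlog)
  f <- function(t) -ied_hazard(obj, t)
  opt <- stats::optimize(f, interval = c(med * 1e-4, med * 1e4))
  obj$params$bound <- -opt$objective * (1 + 1e-8)
  obj
}

#' @rdname ied
#' @param delay Dead time before the exponential phase starts.
#' @export
ied_delayed_exponential <- function(rate, delay) {
  stopifnot(rate > 0, delay >= 0)
  new_ied("delayed_exponential", list(rate = rate, delay = delay),
          "bounded", "delayed_exponential_ied")
}

#' Custom hazard IED
#'
#' Wraps an arbitrary hazard function.  The survival and density are
#' obtained from the cumulative hazard by quadrature unless an analytic
#' `cdf`/`quantile` pair is supplied.
#'
#' @param hazard Vectorized function of time returning non-negative rates.
#' @param bound_scenario One of `"bounded"`, `"increasing_unbounded"`,
#'   `"decreasing_unbounded"`, `"piecewise"`.
#' @param bound Finite hazard bound (required for `"bounded"` /
#'   `"piecewise"`).
#' @param cdf,quantile Optional analytic CDF and quantile functions.
#' @param t_max Upper limit used by quadrature fallbacks.
#' @export
ied_custom <- function(hazard, bound_scenario, bound = NULL,
                       cdf = NULL, quantile = NULL, t_max = Inf) {
  stopifnot(is.function(hazard))
  bound_scenario <- match.arg(bound_scenario,
    c("bounded", "increasing_unbounded", "decreasing_unbounded", "piecewise"))
  if (bound_scenario %in% c("bounded", "piecewise") && is.null(bound)) {
    stop("a finite `bound` must be supplied for bounded/piecewise custom hazards")
  }
  new_ied("custom_piecewise",
          list(hazard = hazard, bound = bound, cdf = cdf,
               quantile = quantile, t_max = t_max),
          bound_scenario, "custom_ied")
}

#' Linear-hazard IED
#'
#' Hazard \eqn{\lambda(t) = a + b t}: the simplest strictly increasing,
#' unbounded hazard, with closed-form CDF
#' \eqn{F(t) = 1 - \exp(-a t - b t^2 / 2)}.  Used as a clean test bed for
#' the finite-step error law of the thinning engine, whose leading error
#' term is proportional to the mean hazard slope.
#'
#' @param a Hazard at `t = 0` (must be > 0 so the process can start).
#' @param b Hazard slope (> 0).
#' @export
ied_linear_hazard <- function(a, b) {
  stopifnot(a > 0, b > 0)
  ied_custom(
    hazard = function(t) ifelse(t < 0, 0, a + b * t),
    bound_scenario = "increasing_unbounded",
    cdf = function(t) ifelse(t < 0, 0, 1 - exp(-a * t - b * t^2 / 2)),
    quantile = function(p) (-a + sqrt(a^2 - 2 * b * log1p(-p))) / b
  )
}

# ---------------------------------------------------------------------------
# generics

#' Hazard, density, survival, CDF and quantile of an IED
#'
#' `ied_hazard()` returns the instantaneous rate \eqn{\lambda(t)};
#' `ied_density()` the renewal density \eqn{\psi(t)}; `ied_survival()` the
#' survival \eqn{1 - F(t)}; `ied_cdf()` and `ied_quantile()` the CDF and its
#' inverse.  All are vectorized over `t` (or `p`).
#'
#' @param ied An [ied] object.
#' @param t Non-negative times.
#' @export
ied_hazard <- function(ied, t) {
  if (any(t < 0)) stop("negative elapsed time")
  UseMethod("ied_hazard")
}

#' @rdname ied_hazard
#' @export
ied_density <- function(ied, t) {
  if (any(t < 0)) stop("negative time")
  UseMethod("ied_density")
}

#' @rdname ied_hazard
#' @export
ied_survival <- function(ied, t) UseMethod("ied_survival")

#' @rdname ied_hazard
#' @export
ied_cdf <- function(ied, t) 1 - ied_survival(ied, t)

#' @rdname ied_hazard
#' @param p Probabilities in `[0, 1)`.
#' @export
ied_quantile <- function(ied, p) UseMethod("ied_quantile")

#' Median waiting time and characteristic rate
#'
#' The characteristic rate of an IED is the reciprocal of its median
#' waiting time.  Unlike the mean rate, it remains finite for heavy-tailed
#' distributions.
#'
#' @param ied An [ied] object.
#' @export
ied_median <- function(ied) ied_quantile(ied, 0.5)

#' @rdname ied_median
#' @export
characteristic_rate <- function(ied) 1 / ied_median(ied)

#' Analytic upper bound on the hazard
#'
#' Returns the finite constant bound for `bounded` families and `Inf` for
#' unbounded scenarios (the engine then uses the per-scenario strategy).
#'
#' @param ied An [ied] object.
#' @export
hazard_bound <- function(ied) UseMethod("hazard_bound")

#' Exact oracle sampler
#'
#' Draws `n` waiting times directly from the distribution (inverse-CDF or
#' the corresponding `stats` sampler), independently of the thinning
#' engine.  Used as ground truth in validation.
#'
#' @param ied An [ied] object.
#' @param n Number of draws.
#' @export
sample_oracle <- function(ied, n) UseMethod("sample_oracle")

# ---------------------------------------------------------------------------
# exponential

#' @export
ied_hazard.exponential_ied <- function(ied, t) {
  if (any(t < 0)) stop("negative elapsed time")
  rep_len(ied$params$rate, length(t))
}
#' @export
ied_density.exponential_ied <- function(ied, t) stats::dexp(t, ied$params$rate)
#' @export
ied_survival.exponential_ied <- function(ied, t) stats::pexp(t, ied$params$rate, lower.tail = FALSE)
#' @export
ied_quantile.exponential_ied <- function(ied, p) stats::qexp(p, ied$params$rate)
#' @export
hazard_bound.exponential_ied <- function(ied) ied$params$rate
#' @export
sample_oracle.exponential_ied <- function(ied, n) stats::rexp(n, ied$params$rate)

# ---------------------------------------------------------------------------
# gamma (shape alpha, rate alpha * lambda0)

#' @export
ied_hazard.gamma_ied <- function(ied, t) {
  if (any(t < 0)) stop("negative elapsed time")
  p <- ied$params
  # log-space: psi(t) / upper-tail, stable for large rate * t
  lh <- stats::dgamma(t, shape = p$shape, rate = p$rate, log = TRUE) -
    stats::pgamma(t, shape = p$shape, rate = p$rate,
                  lower.tail = FALSE, log.p = TRUE)
  h <- exp(lh)
  if (p$shape > 1) h[t == 0] <- 0
  h
}
#' @export
ied_density.gamma_ied <- function(ied, t) {
  stats::dgamma(t, shape = ied$params$shape, rate = ied$params$rate)
}
#' @export
ied_survival.gamma_ied <- function(ied, t) {
  stats::pgamma(t, shape = ied$params$shape, rate = ied$params$rate, lower.tail = FALSE)
}
#' @export
ied_quantile.gamma_ied <- function(ied, p) {
  stats::qgamma(p, shape = ied$params$shape, rate = ied$params$rate)
}
#' @export
hazard_bound.gamma_ied <- function(ied) {
  p <- ied$params
  if (p$shape >= 1) p$shape * p$lambda0 else Inf
}
#' @export
sample_oracle.gamma_ied <- function(ied, n) {
  stats::rgamma(n, shape = ied$params$shape, rate = ied$params$rate)
}

# ---------------------------------------------------------------------------
# pareto

#' @export
ied_hazard.pareto_ied <- function(ied, t) {
  if (any(t < 0)) stop("negative elapsed time")
  p <- ied$params
  ifelse(t >= p$t_min, p$alpha / t, 0)
}
#' @export
ied_density.pareto_ied <- function(ied, t) {
  p <- ied$params
  ifelse(t >= p$t_min, p$alpha * p$t_min^p$alpha / t^(p$alpha + 1), 0)
}
#' @export
ied_survival.pareto_ied <- function(ied, t) {
  p <- ied$params
  ifelse(t >= p$t_min, (p$t_min / t)^p$alpha, 1)
}
#' @export
ied_quantile.pareto_ied <- function(ied, p) {
  q <- ied$params
  q$t_min * (1 - p)^(-1 / q$alpha)
}
#' @export
hazard_bound.pareto_ied <- function(ied) ied$params$alpha / ied$params$t_min
#' @export
sample_oracle.pareto_ied <- function(ied, n) ied_quantile(ied, stats::runif(n))

# ---------------------------------------------------------------------------
# weibull

#' @export
ied_hazard.weibull_ied <- function(ied, t) {
  if (any(t < 0)) stop("negative elapsed time")
  p <- ied$params
  h <- (p$shape / p$scale) * (t / p$scale)^(p$shape - 1)
  if (p$shape > 1) h[t == 0] <- 0
  h
}
#' @export
ied_density.weibull_ied <- function(ied, t) {
  stats::dweibull(t, ied$params$shape, ied$params$scale)
}
#' @export
ied_survival.weibull_ied <- function(ied, t) {
  stats::pweibull(t, ied$params$shape, ied$params$scale, lower.tail = FALSE)
}
#' @export
ied_quantile.weibull_ied <- function(ied, p) {
  stats::qweibull(p, ied$params$shape, ied$params$scale)
}
#' @export
hazard_bound.weibull_ied <- function(ied) {
  if (ied$params$shape == 1) 1 / ied$params$scale else Inf
}
#' @export
sample_oracle.weibull_ied <- function(ied, n) {
  stats::rweibull(n, ied$params$shape, ied$params$scale)
}

# ---------------------------------------------------------------------------
# lognormal

#' @export
ied_hazard.lognormal_ied <- function(ied, t) {
  if (any(t < 0)) stop("negative elapsed time")
  p <- ied$params
  lh <- stats::dlnorm(t, p$meanlog, p$sdlog, log = TRUE) -
    stats::plnorm(t, p$meanlog, p$sdlog, lower.tail = FALSE, log.p = TRUE)
  h <- exp(lh)
  h[t == 0] <- 0
  h
}
#' @export
ied_density.lognormal_ied <- function(ied, t) {
  stats::dlnorm(t, ied$params$meanlog, ied$params$sdlog)
}
#' @export
ied_survival.lognormal_ied <- function(ied, t) {
  stats::plnorm(t, ied$params$meanlog, ied$params$sdlog, lower.tail = FALSE)
}
#' @export
ied_quantile.lognormal_ied <- function(ied, p) {
  stats::qlnorm(p, ied$params$meanlog, ied$params$sdlog)
}
#' @export
hazard_bound.lognormal_ied <- function(ied) ied$params$bound
#' @export
sample_oracle.lognormal_ied <- function(ied, n) {
  stats::rlnorm(n, ied$params$meanlog, ied$params$sdlog)
}

# ---------------------------------------------------------------------------
# delayed exponential

#' @export
ied_hazard.delayed_exponential_ied <- function(ied, t) {
  if (any(t < 0)) stop("negative elapsed time")
  p <- ied$params
  ifelse(t >= p$delay, p$rate, 0)
}
#' @export
ied_density.delayed_exponential_ied <- function(ied, t) {
  p <- ied$params
  ifelse(t >= p$delay, stats::dexp(t - p$delay, p$rate), 0)
}
#' @export
ied_survival.delayed_exponential_ied <- function(ied, t) {
  p <- ied$params
  ifelse(t >= p$delay, stats::pexp(t - p$delay, p$rate, lower.tail = FALSE), 1)
}
#' @export
ied_quantile.delayed_exponential_ied <- function(ied, p) {
  q <- ied$params
  q$delay + stats::qexp(p, q$rate)
}
#' @export
hazard_bound.delayed_exponential_ied <- function(ied) ied$params$rate
#' @export
sample_oracle.delayed_exponential_ied <- function(ied, n) {
  ied$params$delay + stats::rexp(n, ied$params$rate)
}

# ---------------------------------------------------------------------------
# custom

cumhaz_custom <- function(ied, t) {
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    stats::integrate(ied$params$hazard, 0, ti,
                     rel.tol = 1e-9, subdivisions = 500L)$value
  }, numeric(1))
}

#' @export
ied_hazard.custom_ied <- function(ied, t) {
  if (any(t < 0)) stop("negative elapsed time")
  ied$params$hazard(t)
}
#' @export
ied_survival.custom_ied <- function(ied, t) {
  if (!is.null(ied$params$cdf)) return(1 - ied$params$cdf(t))
  exp(-cumhaz_custom(ied, t))
}
#' @export
ied_density.custom_ied <- function(ied, t) {
  ied$params$hazard(t) * ied_survival(ied, t)
}
#' @export
ied_quantile.custom_ied <- function(ied, p) {
  if (!is.null(ied$params$quantile)) return(ied$params$quantile(p))
  vapply(p, function(pi) {
    stopifnot(pi >= 0, pi < 1)
    if (pi == 0) return(0)
    upper <- if (is.finite(ied$params$t_max)) ied$params$t_max else 1
    while (ied_cdf(ied, upper) < pi) upper <- upper * 2
    stats::uniroot(function(x) ied_cdf(ied, x) - pi,
                   lower = 0, upper = upper, tol = 1e-10)$root
  }, numeric(1))
}
#' @export
hazard_bound.custom_ied <- function(ied) {
  if (!is.null(ied$params$bound)) ied$params$bound else Inf
}
#' @export
sample_oracle.custom_ied <- function(ied, n) ied_quantile(ied, stats::runif(n))

# ---------------------------------------------------------------------------

#' Renewal density of a hazard
#'
#' Evaluates \eqn{\psi(t) = \lambda(t) \exp(-\int_0^t \lambda(\tau) d\tau)},
#' analytically for the named families and by quadrature of the cumulative
#' hazard for custom ones.  For a proper IED this integrates to (at most) 1.
#'
#' @param ied An [ied] object.
#' @param t Non-negative times.
#' @export
renewal_density <- function(ied, t) {
  if (any(t < 0)) stop("negative time")
  if (inherits(ied, "custom_ied") && is.null(ied$params$cdf)) {
    ied$params$hazard(t) * exp(-cumhaz_custom(ied, t))
  } else {
    ied_density(ied, t)
  }
}

#' @export
print.ied <- function(x, ...) {
  pars <- x$params[!vapply(x$params, is.function, logical(1))]
  cat(sprintf("<ied: %s (%s)>\n", x$family, x$bound_scenario))
  cat(" ", paste(names(pars), signif(unlist(pars), 5), sep = " = ",
                 collapse = ", "), "\n")
  invisible(x)
}
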