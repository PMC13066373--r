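#' Germinal-center affinity maturation
#'
#' Agent-based model of B-cell selection: B cells carrying individual
#' receptor affinities compete for survival signals from a limited pool of
#' interchangeable T cells.  Five channels drive the dynamics -- binding,
#' competitive displacement (accepted only for a strictly higher-affinity
#' challenger), apoptosis of unrescued free cells, spontaneous unbinding
#' into a division-ready state, and division with stochastic affinity
#' updates.  Pairwise channels are sampled by rejection rather than
#' enumerated, so the cost per candidate event is O(1) in the population
#' size.
#'
#' Default rates (per hour) and scale: `lambda_bt = 0.146`,
#' `lambda_unbind = 2`, `lambda_apop = 0.084`, `lambda_div = 0.134`,
#' `beta = 10`; affinities start at 0.
#'
#' @name bcell
NULL

#' @describeIn bcell Competitive-displacement acceptance rule: a bound cell
#'   is displaced only by a challenger with strictly higher affinity
#'   (equal affinities are rejected).
#' @param affinity_bound Affinity of the currently bound cell.
#' @param affinity_challenger Affinity of the free challenger.
#' @export
competition_accept <- function(affinity_bound, affinity_challenger) {
  affinity_challenger > affinity_bound
}

#' @describeIn bcell Daughter affinity after division:
#'   \eqn{a_d = a_p + (u - a_p)/\beta} with `u` uniform on `[0, 1]`.  The
#'   update is a contraction toward `u`, so affinities stay in `[0, 1]`
#'   and gains become harder as the parent's affinity grows.
#' @param a_parent Parent affinity in `[0, 1]`.
#' @param u Uniform deviate in `[0, 1]`.
#' @param beta Mutation scale (> 0).
#' @export
affinity_update <- function(a_parent, u, beta) {
  stopifnot(all(a_parent >= 0 & a_parent <= 1), beta > 0)
  a_parent + (u - a_parent) / beta
}

#' @describeIn bcell Fraction of the living population in the largest
#'   clonal family.
#' @param clone_sizes Non-negative clone sizes (at least one positive).
#' @export
dominance <- function(clone_sizes) {
  total <- sum(clone_sizes)
  if (length(clone_sizes) == 0 || total <= 0) {
    stop("dominance is undefined for an empty population")
  }
  max(clone_sizes) / total
}

#' Simulate germinal-center affinity maturation
#'
#' @param n_b Initial number of B cells (each its own clone founder).
#' @param n_t Number of identical T cells.
#' @param t_end_days Simulated days.
#' @param seed Optional integer seed.
#' @param lambda_bt Per-pair binding and competition rate (per hour).
#' @param lambda_unbind Unbinding rate per bound pair (per hour).
#' @param lambda_apop Apoptosis rate per free B cell (per hour); bound and
#'   division-ready cells are protected (they have received or are acting
#'   on survival signals).
#' @param lambda_div Division rate per division-ready cell (per hour).
#' @param beta Affinity-update scale.
#' @param competition If `FALSE`, channel (ii) is disabled (no-selection
#'   control).
#' @param record_dt Trajectory sampling interval in hours.
#' @return List of class `"gc_run"`: `trajectory` (time in hours, `n_free`,
#'   `n_bound`, `n_div`, `n_total`, `mean_affinity`, `dominance`), `cells`
#'   (final registry: affinity, clone, status), `counters`, `extinct`.
#'   If the population dies out the run ends early with `extinct = TRUE`.
#' @export
run_gc <- function(n_b = 1000, n_t = 10, t_end_days = 50, seed = NULL,
                   lambda_bt = 0.146, lambda_unbind = 2, lambda_apop = 0.084,
                   lambda_div = 0.134, beta = 10, competition = TRUE,
                   record_dt = 1) {
  stopifnot(n_b >= 1, n_t >= 1, t_end_days >= 0, beta > 0,
            lambda_bt >= 0, lambda_unbind >= 0, lambda_apop >= 0,
            lambda_div >= 0)
  if (!is.null(seed)) set.seed(seed)
  res <- bcell_mosaic_cpp(n_b, n_t, t_end_days * 24, lambda_bt,
                          lambda_unbind, lambda_apop, lambda_div, beta,
                          competition, record_dt)
  res$params <- list(n_b = n_b, n_t = n_t, beta = beta,
                     lambda_bt = lambda_bt, lambda_unbind = lambda_unbind,
                     lambda_apop = lambda_apop, lambda_div = lambda_div)
  class(res) <- "gc_run"
  res
}

#' @export
print.gc_run <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat(sprintf(
    "<gc_run: %d cells at t = %g h, mean affinity %.3f, dominance %.3f%s>\n",
    last$n_total, last$time, last$mean_affinity, last$dominance,
    if (isTRUE(x$extinct)) ", EXTINCT" else ""))
  invisible(x)
}

#' Direct-Gillespie reference for the germinal-center model
#'
#' Exact SSA over the same five channels: the state-dependent competition
#' propensity is recomputed by explicit enumeration of qualifying
#' (bound, challenger) pairs after every event, which is O(N) per step and
#' only practical at reduced population sizes.  All channels are
#' exponential, so this is distributionally equivalent to [run_gc()] and
#' serves as its Markovian correctness reference.
#'
#' @inheritParams run_gc
#' @export
run_gc_gillespie <- function(n_b = 100, n_t = 2, t_end_days = 5, seed = NULL,
                             lambda_bt = 0.146, lambda_unbind = 2,
                             lambda_apop = 0.084, lambda_div = 0.134,
                             beta = 10, competition = TRUE, record_dt = 1) {
  if (!is.null(seed)) set.seed(seed)
  t_end <- t_end_days * 24
  aff <- rep(0, n_b)
  status <- rep(0L, n_b)  # 0 free, 1 bound, 2 division-ready, -1 dead
  clone <- seq_len(n_b)
  T_now <- 0

  grid <- seq(0, t_end, by = record_dt)
  rec <- matrix(NA_real_, nrow = length(grid), ncol = 6,
                dimnames = list(NULL, c("n_free", "n_bound", "n_div",
                                        "n_total", "mean_affinity",
                                        "dominance")))
  irec <- 1L
  snapshot <- function() {
    alive <- status >= 0L
    n_tot <- sum(alive)
    c(sum(status == 0L), sum(status == 1L), sum(status == 2L), n_tot,
      if (n_tot > 0) mean(aff[alive]) else NA_real_,
      if (n_tot > 0) max(tabulate(clone[alive], n_b)) / n_tot else NA_real_)
  }

  extinct <- FALSE
  repeat {
    free_i <- which(status == 0L)
    bound_i <- which(status == 1L)
    div_i <- which(status == 2L)
    n_f <- length(free_i); n_bd <- length(bound_i); n_d <- length(div_i)
    if (n_f + n_bd + n_d == 0L) { extinct <- TRUE; break }

    # per-bound-cell count of strictly higher-affinity free challengers
    comp_counts <- integer(0)
    if (competition && n_bd > 0L && n_f > 0L) {
      sf <- sort(aff[free_i])
      comp_counts <- n_f - findInterval(aff[bound_i], sf)
    }
    w_bind <- n_f * (n_t - n_bd) * lambda_bt
    w_comp <- lambda_bt * sum(comp_counts)
    w_apop <- n_f * lambda_apop
    w_unb <- n_bd * lambda_unbind
    w_div <- n_d * lambda_div
    total <- w_bind + w_comp + w_apop + w_unb + w_div
    if (total <= 0) break

    T_now <- T_now + stats::rexp(1, total)
    while (irec <= length(grid) && grid[irec] <= min(T_now, t_end)) {
      rec[irec, ] <- snapshot(); irec <- irec + 1L
    }
    if (T_now > t_end) break

    u <- stats::runif(1) * total
    if (u < w_bind) {
      status[free_i[sample.int(n_f, 1L)]] <- 1L
    } else if ((u <- u - w_bind) < w_comp) {
      b <- bound_i[sample.int(n_bd, 1L, prob = comp_counts)]
      qual <- free_i[aff[free_i] > aff[b]]
      f <- qual[sample.int(length(qual), 1L)]
      status[b] <- 0L; status[f] <- 1L
    } else if ((u <- u - w_comp) < w_apop) {
      status[free_i[sample.int(n_f, 1L)]] <- -1L
    } else if ((u <- u - w_apop) < w_unb) {
      status[bound_i[sample.int(n_bd, 1L)]] <- 2L
    } else {
      d <- div_i[sample.int(n_d, 1L)]
      a <- aff[d]
      aff[d] <- a + (stats::runif(1) - a) / beta
      status[d] <- 0L
      aff <- c(aff, a + (stats::runif(1) - a) / beta)
      status <- c(status, 0L)
      clone <- c(clone, clone[d])
    }
  }
  while (irec <= length(grid)) { rec[irec, ] <- snapshot(); irec <- irec + 1L }

  list(trajectory = data.frame(time = grid, rec),
       cells = data.frame(affinity = aff, clone = clone, status = status),
       extinct = extinct, t_final = min(T_now, t_end))
}
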