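#' Low-level thinning primitives
#'
#' One iteration of the rejection-based engine advances global time by an
#' exponential increment governed by the number of live processes `n` and a
#' dominating rate `lambda_max`, proposes one process uniformly at random,
#' and accepts it with probability hazard / bound.  These primitives are
#' exposed separately so the arithmetic can be tested in isolation; the
#' engine loop in [mosaic_run()] composes them.
#'
#' @param u A uniform(0, 1] deviate.
#' @param n Number of live processes (>= 1).
#' @param lambda_max Dominating rate (> 0).
#' @return `draw_time_increment()`: the time increment
#'   \eqn{\ln(1/u) / (n \lambda_{max})}, with expectation
#'   \eqn{1 / (n \lambda_{max})} over `u`.
#' @export
draw_time_increment <- function(u, n, lambda_max) {
  if (length(n) != 1L || n < 1) stop("`n` must be a single value >= 1")
  if (length(lambda_max) != 1L || lambda_max <= 0) {
    stop("`lambda_max` must be a single positive value")
  }
  if (any(u <= 0 | u > 1)) stop("`u` must lie in (0, 1]")
  log(1 / u) / (n * lambda_max)
}

#' @rdname draw_time_increment
#' @param prob Optional proposal weights over the `n` processes.  The
#'   default (`NULL`) is the uniform proposal `1/n`; a non-uniform proposal
#'   is admissible provided the bound still dominates all hazards.
#' @return `select_candidate()`: one index in `1:n`.
#' @export
select_candidate <- function(n, prob = NULL) {
  if (n < 1) stop("process registry is empty")
  if (is.null(prob)) {
    sample.int(n, 1L)
  } else {
    sample.int(n, 1L, prob = prob)
  }
}

#' @rdname draw_time_increment
#' @param ied The process's waiting-time distribution ([ied]).
#' @param elapsed Elapsed time since the process's last event,
#'   `T - tau_j` (>= 0).
#' @param modifier State-dependent multiplier on the hazard (default 1).
#' @return `acceptance_probability()`: the ratio
#'   \eqn{\lambda_j(t_j) / \lambda_{max}} in `[0, 1]`.  A ratio above 1
#'   means the bound was violated and is a hard error, never clipped.
#' @export
acceptance_probability <- function(ied, elapsed, lambda_max, modifier = 1) {
  if (elapsed < 0) stop("elapsed time is negative: tau_j exceeds current time")
  rate <- modifier * ied_hazard(ied, elapsed)
  p <- rate / lambda_max
  if (p > 1 + 1e-9) {
    stop(sprintf(
      "acceptance ratio %.6g > 1: lambda_max = %.6g does not bound the hazard %.6g",
      p, lambda_max, rate))
  }
  min(p, 1)
}

#' Dominating-rate bound for a set of processes
#'
#' Computes an upper bound on all instantaneous hazards given the bound
#' scenario of each waiting-time family:
#' \describe{
#'   \item{bounded}{the analytic per-family constant (e.g. `alpha/t_min` for
#'     Pareto, `shape * lambda0` for Gamma with shape > 1).}
#'   \item{increasing_unbounded}{the hazard of the oldest clock, evaluated
#'     at the current elapsed time; with a monotone family this process
#'     dominates, and the identity of the oldest clock only changes when
#'     it fires.}
#'   \item{decreasing_unbounded}{refused: the bound diverges as clocks
#'     reset.  Supply `user_bound` to override (accepting the extra
#'     rejections) if the short-time hazard is truncated in the model.}
#' }
#'
#' @param ieds List of [ied] objects, one per process.
#' @param elapsed Numeric vector of current elapsed times `T - tau_j`.
#' @param modifier_bounds Optional per-process upper bounds on the
#'   state-dependent hazard multipliers (default 1).
#' @param user_bound Optional fixed bound overriding the refusal of
#'   decreasing-unbounded families.
#' @return A positive dominating rate.
#' @export
update_lambda_max <- function(ieds, elapsed, modifier_bounds = NULL,
                              user_bound = NULL) {
  n <- length(ieds)
  stopifnot(length(elapsed) == n)
  if (is.null(modifier_bounds)) modifier_bounds <- rep(1, n)
  scen <- vapply(ieds, function(x) x$bound_scenario, character(1))
  bound <- 0
  idx_bounded <- which(scen %in% c("bounded", "piecewise"))
  if (length(idx_bounded)) {
    bs <- vapply(idx_bounded, function(i) {
      hazard_bound(ieds[[i]]) * modifier_bounds[i]
    }, numeric(1))
    bound <- max(bound, bs)
  }
  idx_inc <- which(scen == "increasing_unbounded")
  if (length(idx_inc)) {
    bs <- vapply(idx_inc, function(i) {
      ied_hazard(ieds[[i]], elapsed[i]) * modifier_bounds[i]
    }, numeric(1))
    bound <- max(bound, bs)
  }
  idx_dec <- which(scen == "decreasing_unbounded")
  if (length(idx_dec)) {
    if (is.null(user_bound)) {
      stop(paste(
        "processes with an unbounded, decreasing hazard (e.g. Weibull or",
        "Gamma with shape < 1) are refused by default: their bound diverges",
        "each time a clock resets and thinning becomes arbitrarily",
        "inefficient.  Supply `user_bound` to override."))
    }
    bound <- max(bound, user_bound)
  }
  if (!is.finite(bound) || bound <= 0) {
    stop("dominating rate is not a positive finite number")
  }
  bound
}

# ---------------------------------------------------------------------------

#' Define a process channel
#'
#' A channel is one elementary stochastic process: a waiting-time
#' distribution, the timestamp of its last event (managed by the engine),
#' an opaque payload identifying the agent(s) involved, and an optional
#' state-dependent multiplier on its hazard.
#'
#' @param ied An [ied] object.
#' @param payload Opaque agent/pair reference stored in the event log.
#' @param state_modifier Optional `function(state, t)` returning a
#'   non-negative multiplier applied to the hazard.
#' @param modifier_bound Upper bound on the multiplier (required for bound
#'   safety whenever `state_modifier` is given; default 1).
#' @export
mosaic_channel <- function(ied, payload = NULL, state_modifier = NULL,
                           modifier_bound = 1) {
  stopifnot(inherits(ied, "ied"))
  if (!is.null(state_modifier)) stopifnot(is.function(state_modifier))
  structure(list(ied = ied, payload = payload,
                 state_modifier = state_modifier,
                 modifier_bound = modifier_bound),
            class = "mosaic_channel")
}

#' Define a model for the thinning engine
#'
#' @param channels List of [mosaic_channel()] objects present at time 0.
#' @param state Arbitrary model state passed to modifiers and `on_fire`.
#' @param on_fire Optional `function(state, channel, time)` called when a
#'   channel fires.  It returns a list with any of: `state` (updated
#'   state), `add` (list of new channels), `remove` (integer ids of
#'   channels to retire, possibly including the fired one).  The fired
#'   channel's clock is reset by the engine before the callback.
#' @param lambda_max Bound policy: `"auto"` (per-scenario analytic bounds,
#'   exact, ratio > 1 is a hard error), `"fixed"` (a user-chosen constant
#'   `lambda_max_value`, hard error on violation), or `"adaptive_clip"`
#'   (`lambda_max_multiplier` times the current maximum rate, recomputed
#'   each iteration; overshoot within the step is clipped and counted).
#'   The adaptive mode reproduces the accuracy-efficiency trade-off of
#'   setting the bound from rates at the iteration start: its bias shrinks
#'   quadratically in the multiplier.
#' @param lambda_max_value Constant bound for `"fixed"`.
#' @param lambda_max_multiplier Multiplier for `"adaptive_clip"` (>= 1).
#' @param user_bound Override allowing decreasing-unbounded families under
#'   `"auto"`.
#' @param state_record Optional `function(state)` returning a named numeric
#'   vector to be recorded after every accepted event.
#' @param hazard_eval `"updated"` (default) evaluates the candidate's
#'   hazard at the post-advance elapsed time, which makes thinning exact
#'   for any valid bound.  `"stale"` evaluates it with the clock at the
#'   iteration start, one increment (mean `1/(N lambda_max)`) behind: this
#'   is the finite-step approximation whose expected error is
#'   \eqn{\langle\lambda'\rangle / (N \lambda_{max}^2)} -- it vanishes
#'   quadratically as the bound is raised -- and is provided so that the
#'   accuracy-efficiency trade-off can be measured.
#' @export
mosaic_model <- function(channels, state = NULL, on_fire = NULL,
                         lambda_max = c("auto", "fixed", "adaptive_clip"),
                         lambda_max_value = NULL, lambda_max_multiplier = 1,
                         user_bound = NULL, state_record = NULL,
                         hazard_eval = c("updated", "stale")) {
  lambda_max <- match.arg(lambda_max)
  hazard_eval <- match.arg(hazard_eval)
  stopifnot(is.list(channels),
            all(vapply(channels, inherits, logical(1), "mosaic_channel")))
  if (lambda_max == "fixed" && (is.null(lambda_max_value) ||
                                lambda_max_value <= 0)) {
    stop("`lambda_max_value` must be a positive number for the fixed policy")
  }
  if (lambda_max_multiplier < 1) stop("`lambda_max_multiplier` must be >= 1")
  structure(list(channels = channels, state = state, on_fire = on_fire,
                 lambda_max = lambda_max, lambda_max_value = lambda_max_value,
                 lambda_max_multiplier = lambda_max_multiplier,
                 user_bound = user_bound, state_record = state_record,
                 hazard_eval = hazard_eval),
            class = "mosaic_model")
}

#' Run the rejection-based engine
#'
#' Iterates the four-step loop: (i) refresh the dominating rate
#' `lambda_max`; (ii) advance global time by
#' \eqn{\Delta t = \ln(1/u) / (N \lambda_{max})}; (iii) draw one candidate
#' process uniformly from the live registry; (iv) accept it with
#' probability \eqn{\lambda_j(t_j) / \lambda_{max}}, where
#' \eqn{t_j = T - \tau_j} is the candidate's elapsed time at the advanced
#' clock.  On acceptance the candidate's clock resets and the model's
#' `on_fire` callback may update state and add/remove channels (removal
#' uses swap-and-pop, so the uniform proposal is always over the current
#' registry).  A rejected iteration changes nothing except the global
#' time.  The acceptance draw uses a fresh uniform deviate, independent of
#' the one used for the time increment; draws occur in the fixed order
#' (increment, candidate, acceptance) so a seed reproduces the log
#' bit-for-bit.
#'
#' @param model A [mosaic_model()].
#' @param t_end Time horizon (>= 0; `t_end = 0` yields an empty log,
#'   `Inf` runs until the registry empties).
#' @param seed Optional integer seed.
#' @param record `"accepted"` (default), `"all"` (include rejected
#'   iterations), or `"none"` (counters only).
#' @param debug_check_bound If `TRUE`, recompute the true maximum hazard by
#'   brute force at every iteration and fail hard if the bound is below it
#'   (except in the adaptive clipping mode, where the within-step overshoot
#'   is the documented approximation).
#' @param max_steps Safety cap on candidate iterations.
#' @return A list of class `"mosaic_run"` with `events` (data frame:
#'   `time`, `channel`, `accepted`, `payload`), `trajectory` (if
#'   `state_record` was given), `state`, and `counters`
#'   (accepted/rejected/clipped iterations).
#' @export
mosaic_run <- function(model, t_end, seed = NULL,
                       record = c("accepted", "all", "none"),
                       debug_check_bound = FALSE, max_steps = Inf) {
  stopifnot(inherits(model, "mosaic_model"))
  record <- match.arg(record)
  if (t_end < 0) stop("`t_end` must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  n0 <- length(model$channels)
  if (n0 < 1) stop("model has no channels")
  cap <- max(64L, 2L * n0)
  ieds <- vector("list", cap)
  payloads <- vector("list", cap)
  modifiers <- vector("list", cap)
  mod_bounds <- numeric(cap)
  taus <- numeric(cap)
  ids <- integer(cap)
  for (i in seq_len(n0)) {
    ch <- model$channels[[i]]
    ieds[[i]] <- ch$ied; payloads[[i]] <- ch$payload
    modifiers[[i]] <- ch$state_modifier; mod_bounds[i] <- ch$modifier_bound
    taus[i] <- 0; ids[i] <- i
  }
  n <- n0
  next_id <- n0 + 1L
  state <- model$state
  T_now <- 0
  accepted <- 0L; rejected <- 0L; clipped <- 0L; steps <- 0L

  ev_cap <- 1024L
  ev_time <- numeric(ev_cap); ev_channel <- integer(ev_cap)
  ev_acc <- logical(ev_cap); ev_payload <- character(ev_cap)
  n_ev <- 0L
  push_event <- function(time, id, acc, payload) {
    if (n_ev == ev_cap) {
      ev_cap <<- ev_cap * 2L
      length(ev_time) <<- ev_cap; length(ev_channel) <<- ev_cap
      length(ev_acc) <<- ev_cap; length(ev_payload) <<- ev_cap
    }
    n_ev <<- n_ev + 1L
    ev_time[n_ev] <<- time; ev_channel[n_ev] <<- id
    ev_acc[n_ev] <<- acc
    ev_payload[n_ev] <<- if (is.null(payload)) NA_character_
                         else as.character(payload)
  }

  traj_time <- numeric(0); traj_vals <- NULL
  if (!is.null(model$state_record)) {
    v0 <- model$state_record(state)
    traj_time <- c(traj_time, 0)
    traj_vals <- matrix(v0, nrow = 1,
                        dimnames = list(NULL, names(v0)))
  }

  adaptive <- model$lambda_max == "adaptive_clip"
  fixed <- model$lambda_max == "fixed"
  stale <- identical(model$hazard_eval, "stale")

  current_rates <- function() {
    vapply(seq_len(n), function(i) {
      m <- if (is.null(modifiers[[i]])) 1 else modifiers[[i]](state, T_now)
      m * ied_hazard(ieds[[i]], max(0, T_now - taus[i]))
    }, numeric(1))
  }

  while (n >= 1L && steps < max_steps) {
    lam_max <- if (fixed) {
      model$lambda_max_value
    } else if (adaptive) {
      mx <- max(current_rates())
      if (mx <= 0) stop("adaptive bound is zero: all hazards vanish")
      model$lambda_max_multiplier * mx
    } else {
      update_lambda_max(ieds[seq_len(n)], pmax(0, T_now - taus[seq_len(n)]),
                        mod_bounds[seq_len(n)], model$user_bound)
    }
    T_before <- T_now
    u <- stats::runif(1)
    T_now <- T_now + draw_time_increment(u, n, lam_max)
    if (T_now > t_end) break
    steps <- steps + 1L
    j <- select_candidate(n)
    t_j <- if (stale) max(0, T_before - taus[j]) else T_now - taus[j]
    m <- if (is.null(modifiers[[j]])) 1 else modifiers[[j]](state, T_now)
    rate <- m * ied_hazard(ieds[[j]], t_j)
    p <- rate / lam_max
    if (p > 1 + 1e-9) {
      if (adaptive) {
        clipped <- clipped + 1L
        p <- 1
      } else {
        stop(sprintf(
          "bound violated at T = %.6g: hazard %.6g > lambda_max %.6g (channel id %d)",
          T_now, rate, lam_max, ids[j]))
      }
    }
    if (debug_check_bound && !adaptive) {
      if (max(current_rates()) > lam_max * (1 + 1e-9)) {
        stop("debug bound check failed: lambda_max below the true maximum rate")
      }
    }
    acc <- stats::runif(1) < p
    if (acc) {
      accepted <- accepted + 1L
      taus[j] <- T_now
      if (record != "none") push_event(T_now, ids[j], TRUE, payloads[[j]])
      if (!is.null(model$on_fire)) {
        res <- model$on_fire(state, list(id = ids[j], payload = payloads[[j]]),
                             T_now)
        if (!is.null(res$state)) state <- res$state
        if (!is.null(res$remove)) {
          for (rid in res$remove) {
            pos <- match(rid, ids[seq_len(n)])
            if (is.na(pos)) next
            # swap-and-pop: uniformity holds over the current registry
            ieds[[pos]] <- ieds[[n]]; payloads[[pos]] <- payloads[[n]]
            modifiers[[pos]] <- modifiers[[n]]
            mod_bounds[pos] <- mod_bounds[n]
            taus[pos] <- taus[n]; ids[pos] <- ids[n]
            n <- n - 1L
          }
        }
        if (!is.null(res$add)) {
          for (ch in res$add) {
            if (n == length(ieds)) {
              newcap <- 2L * n
              length(ieds) <- newcap; length(payloads) <- newcap
              length(modifiers) <- newcap
              mod_bounds <- c(mod_bounds, numeric(n))
              taus <- c(taus, numeric(n)); ids <- c(ids, integer(n))
            }
            n <- n + 1L
            ieds[[n]] <- ch$ied; payloads[[n]] <- ch$payload
            modifiers[[n]] <- ch$state_modifier
            mod_bounds[n] <- ch$modifier_bound
            taus[n] <- T_now; ids[n] <- next_id
            next_id <- next_id + 1L
          }
        }
      }
      if (!is.null(model$state_record)) {
        v <- model$state_record(state)
        traj_time <- c(traj_time, T_now)
        traj_vals <- rbind(traj_vals, v)
      }
    } else {
      rejected <- rejected + 1L
      if (record == "all") push_event(T_now, ids[j], FALSE, payloads[[j]])
    }
  }

  events <- data.frame(time = ev_time[seq_len(n_ev)],
                       channel = ev_channel[seq_len(n_ev)],
                       accepted = ev_acc[seq_len(n_ev)],
                       payload = ev_payload[seq_len(n_ev)],
                       stringsAsFactors = FALSE)
  trajectory <- NULL
  if (!is.null(traj_vals)) {
    trajectory <- data.frame(time = traj_time, traj_vals, row.names = NULL)
  }
  structure(list(events = events, trajectory = trajectory, state = state,
                 t_final = min(T_now, t_end),
                 counters = list(accepted = accepted, rejected = rejected,
                                 clipped = clipped, candidates = steps)),
            class = "mosaic_run")
}

#' @export
print.mosaic_run <- function(x, ...) {
  cat(sprintf("<mosaic_run: %d accepted, %d rejected (r = %.3g), t = %.4g>\n",
              x$counters$accepted, x$counters$rejected,
              (x$counters$accepted + x$counters$rejected) /
                max(1L, x$counters$accepted),
              x$t_final))
  invisible(x)
}

#' Accepted inter-event times of one channel
#'
#' @param run A [mosaic_run()] result (or any data frame with `time`,
#'   `channel`, `accepted` columns).
#' @param channel Channel id; `NULL` pools all accepted events.
#' @export
interevent_times <- function(run, channel = NULL) {
  ev <- if (inherits(run, "mosaic_run")) run$events else run
  ev <- ev[ev$accepted, , drop = FALSE]
  if (!is.null(channel)) ev <- ev[ev$channel %in% channel, , drop = FALSE]
  if (nrow(ev) < 2) return(numeric(0))
  diff(c(0, sort(ev$time)))
}

#' Single-channel renewal model
#'
#' `n_channels` independent copies of one waiting-time distribution, each
#' resetting its own clock when it fires.  The workhorse for validating the
#' engine against analytic renewal densities.
#'
#' @param ied An [ied] object.
#' @param n_channels Number of parallel copies.
#' @param ... Passed to [mosaic_model()].
#' @export
renewal_model <- function(ied, n_channels = 1, ...) {
  mosaic_model(replicate(n_channels, mosaic_channel(ied), simplify = FALSE),
               ...)
}
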