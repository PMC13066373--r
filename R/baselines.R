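#' Direct Gillespie simulation of an all-exponential model
#'
#' Statistically exact reference for Markovian models, sharing the model
#' and log format of [mosaic_run()].  Every channel must carry an
#' exponential waiting time; rates may still be state-dependent through
#' the channels' modifiers (re-evaluated after every event, which is exact
#' because exponential hazards are constant between events).
#'
#' @param model A [mosaic_model()] whose channels are all
#'   [ied_exponential()].
#' @param t_end Time horizon.
#' @param seed Optional integer seed.
#' @param max_steps Safety cap on events.
#' @return A list of class `"mosaic_run"` (all iterations accepted).
#' @export
gillespie_run <- function(model, t_end, seed = NULL, max_steps = Inf) {
  stopifnot(inherits(model, "mosaic_model"))
  if (!all(vapply(model$channels, function(ch)
    inherits(ch$ied, "exponential_ied"), logical(1)))) {
    stop("gillespie_run() is exact only for exponential channels; ",
         "use mosaic_run() for non-exponential waiting times")
  }
  if (t_end < 0) stop("`t_end` must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  chans <- model$channels
  n <- length(chans)
  ids <- seq_len(n)
  next_id <- n + 1L
  state <- model$state
  T_now <- 0
  n_ev <- 0L
  ev_time <- numeric(0); ev_channel <- integer(0); ev_payload <- character(0)
  traj_time <- numeric(0); traj_vals <- NULL
  if (!is.null(model$state_record)) {
    v0 <- model$state_record(state)
    traj_time <- 0
    traj_vals <- matrix(v0, nrow = 1, dimnames = list(NULL, names(v0)))
  }

  while (n >= 1L && n_ev < max_steps) {
    rates <- vapply(seq_len(n), function(i) {
      ch <- chans[[i]]
      m <- if (is.null(ch$state_modifier)) 1 else ch$state_modifier(state, T_now)
      m * ch$ied$params$rate
    }, numeric(1))
    total <- sum(rates)
    if (total <= 0) break
    T_now <- T_now + stats::rexp(1, total)
    if (T_now > t_end) break
    j <- sample.int(n, 1L, prob = rates)
    n_ev <- n_ev + 1L
    ev_time <- c(ev_time, T_now)
    ev_channel <- c(ev_channel, ids[j])
    pl <- chans[[j]]$payload
    ev_payload <- c(ev_payload, if (is.null(pl)) NA_character_ else as.character(pl))
    if (!is.null(model$on_fire)) {
      res <- model$on_fire(state, list(id = ids[j], payload = pl), T_now)
      if (!is.null(res$state)) state <- res$state
      if (!is.null(res$remove)) {
        for (rid in res$remove) {
          pos <- match(rid, ids[seq_len(n)])
          if (is.na(pos)) next
          chans[[pos]] <- chans[[n]]; ids[pos] <- ids[n]
          n <- n - 1L
        }
        length(chans) <- n; length(ids) <- n
      }
      if (!is.null(res$add)) {
        for (ch in res$add) {
          n <- n + 1L
          chans[[n]] <- ch; ids[n] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
    if (!is.null(model$state_record)) {
      v <- model$state_record(state)
      traj_time <- c(traj_time, T_now)
      traj_vals <- rbind(traj_vals, v)
    }
  }

  events <- data.frame(time = ev_time, channel = ev_channel,
                       accepted = rep(TRUE, n_ev), payload = ev_payload,
                       stringsAsFactors = FALSE)
  trajectory <- NULL
  if (!is.null(traj_vals)) {
    trajectory <- data.frame(time = traj_time, traj_vals, row.names = NULL)
  }
  structure(list(events = events, trajectory = trajectory, state = state,
                 t_final = min(T_now, t_end),
                 counters = list(accepted = n_ev, rejected = 0L,
                                 clipped = 0L, candidates = n_ev)),
            class = "mosaic_run")
}

#' Bin an event-driven trajectory onto a fixed time grid
#'
#' Piecewise-constant (last value carried forward) resampling, the form
#' needed to compare ensembles of event-driven runs on a common grid.
#'
#' @param trajectory Data frame with a `time` column and numeric state
#'   columns (as returned in `$trajectory` of a run).
#' @param times Numeric grid (e.g. `seq(0, t_end, by = 1)` for 1-minute
#'   bins).
#' @return A matrix with `length(times)` rows, one column per state
#'   variable.
#' @export
bin_trajectory <- function(trajectory, times) {
  stopifnot(is.data.frame(trajectory), "time" %in% names(trajectory))
  cols <- setdiff(names(trajectory), "time")
  idx <- findInterval(times, trajectory$time)
  idx[idx < 1L] <- 1L
  out <- as.matrix(trajectory[idx, cols, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Ensemble comparison by root-mean-square deviation
#'
#' Implements the trajectory-comparison protocol used to validate the
#' rejection engine against the delay-queue reference: each replicate is
#' binned onto a fixed grid (1-minute bins by default), the binned
#' populations are averaged across replicates, normalized by the system
#' scale `beta`, and the RMSD between the two ensemble means is taken over
#' all grid points and species.  The replicate-to-replicate baseline is the
#' same statistic computed between two independent ensembles of the exact
#' reference.
#'
#' @param ens_a,ens_b Lists of runs (each with a `$trajectory` data frame
#'   sharing the same state columns).
#' @param times Common time grid.
#' @param beta Normalization scale.
#' @return The RMSD (dimensionless, populations in units of `beta`).
#' @export
rmsd_ensembles <- function(ens_a, ens_b, times, beta = 1) {
  mean_binned <- function(ens) {
    acc <- NULL
    for (r in ens) {
      b <- bin_trajectory(r$trajectory, times)
      acc <- if (is.null(acc)) b else acc + b
    }
    acc / length(ens)
  }
  ma <- mean_binned(ens_a) / beta
  mb <- mean_binned(ens_b) / beta
  sqrt(mean((ma - mb)^2))
}
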