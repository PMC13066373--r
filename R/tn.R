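#' Non-Markovian temporal contact networks
#'
#' Node-driven simulation of face-to-face interactions: each node carries a
#' clock recording the time since its last interaction and a Pareto
#' activity distribution, and pair-formation events are governed by the
#' multiplicative kernel
#' \eqn{\Lambda_{ij} = \lambda_i(t_i) \lambda_j(t_j) / ((N_A - 1) \lambda_A)},
#' which requires both partners to be concurrently available and makes each
#' node's interduration statistics converge to its intrinsic distribution
#' as the network grows.  Active edges terminate through their own Pareto
#' process.  All channels run in one thinning loop with constant bounds
#' (the Pareto hazard decreases beyond its minimum waiting time).
#'
#' Default parameters are the conference face-to-face fit: 274 nodes, 7249
#' time ticks, node activity `alpha_a = 0.76`, `lambda_a = 0.4`,
#' termination `alpha_end = 1.4`, `lambda_end = 0.61`.
#'
#' @name mosaic_tn
NULL

#' @describeIn mosaic_tn Constant global bounds for the Pareto kernel:
#'   \eqn{\lambda_{max} = \alpha_A / t_{min}} and
#'   \eqn{\Lambda_{max} = \lambda_{max}^2 / ((N_A - 1) \lambda_A)}, valid
#'   for a whole run.
#' @param alpha_a Pareto tail exponent of node activity.
#' @param t_min Minimum waiting time of the activity distribution.
#' @param lambda_a Characteristic activity rate (reciprocal median).
#' @param n_a Number of nodes (>= 2).
#' @return `lambda_max_tn()`: list with `lambda_max` (node-level bound) and
#'   `Lambda_max` (pair-level bound).
#' @export
lambda_max_tn <- function(alpha_a, t_min, lambda_a, n_a) {
  stopifnot(alpha_a > 0, t_min > 0, lambda_a > 0, n_a >= 2)
  lmax <- alpha_a / t_min
  list(lambda_max = lmax, Lambda_max = lmax^2 / ((n_a - 1) * lambda_a))
}

#' @describeIn mosaic_tn History-biased partner proposal weights: given
#'   which admissible partners are previous contacts, returns the
#'   normalized probability of proposing each (weight `w` for previous
#'   partners, 1 otherwise).  `w = 1` recovers the uniform proposal.
#' @param prior Logical vector over admissible partners (`TRUE` = has
#'   interacted before).
#' @param w History weight (>= 1).
#' @export
biased_partner_weights <- function(prior, w) {
  stopifnot(is.logical(prior), length(prior) >= 1, w >= 1)
  wts <- ifelse(prior, w, 1)
  wts / sum(wts)
}

#' Simulate a face-to-face contact network
#'
#' @param n_nodes Number of nodes.
#' @param t_end Horizon in data ticks.
#' @param alpha_a,lambda_a Pareto parameters of node activity (tail
#'   exponent and characteristic rate).
#' @param alpha_end,lambda_end Pareto parameters of edge termination.
#' @param w History weight for partner selection (`1` = no memory,
#'   variant A; `> 1` = previous partners `w` times more likely,
#'   variant B).
#' @param seed Optional integer seed.
#' @param variant `"proposal"` implements the history bias as a modified
#'   proposal with unchanged acceptance; `"kernel"` routes the same
#'   preference through the kernel under uniform proposals with bound
#'   `w * Lambda_max` (debug cross-check; ~`w`-fold more rejections).
#' @param activity,termination Waiting-time family of the two channels;
#'   `"exponential"` gives the Markovian limit in which node-driven and
#'   edge-driven simulation coincide.
#' @return List of class `"tn_run"`: `contacts` (data frame `t_start`,
#'   `t_end`, `i`, `j`, `censored` -- edges still open at the horizon are
#'   censored there), `counters`, `bounds`, `max_acceptance_ratio`.
#' @export
run_facetoface <- function(n_nodes = 274, t_end = 7249, alpha_a = 0.76,
                           lambda_a = 0.4, alpha_end = 1.4,
                           lambda_end = 0.61, w = 1, seed = NULL,
                           variant = c("proposal", "kernel"),
                           activity = c("pareto", "exponential"),
                           termination = c("pareto", "exponential")) {
  variant <- match.arg(variant)
  activity <- match.arg(activity)
  termination <- match.arg(termination)
  stopifnot(n_nodes >= 2, t_end >= 0, w >= 1)
  if (!is.null(seed)) set.seed(seed)
  mode <- if (variant == "kernel") 2L else if (w > 1) 1L else 0L
  res <- tn_mosaic_cpp(n_nodes, t_end, alpha_a, lambda_a, alpha_end,
                       lambda_end, w, mode,
                       if (activity == "pareto") 0L else 1L,
                       if (termination == "pareto") 0L else 1L)
  res$bounds <- list(lambda_max = res$lambda_max,
                     Lambda_max = res$Lambda_max)
  res$params <- list(n_nodes = n_nodes, t_end = t_end, alpha_a = alpha_a,
                     lambda_a = lambda_a, alpha_end = alpha_end,
                     lambda_end = lambda_end, w = w, variant = variant)
  class(res) <- "tn_run"
  res
}

#' @export
print.tn_run <- function(x, ...) {
  cat(sprintf(
    "<tn_run: %d nodes, %d contacts over %g ticks, w = %g, r = %.3g>\n",
    x$params$n_nodes, nrow(x$contacts), x$params$t_end, x$params$w,
    x$counters$candidates / max(1, x$counters$accepted)))
  invisible(x)
}

#' Edge-driven Markovian reference network
#'
#' Direct SSA in which every inactive pair carries an exponential formation
#' clock of rate `lambda_a / (n_nodes - 1)` and every active edge an
#' exponential termination clock of rate `lambda_end`.  With exponential
#' clocks the superposition of edge processes and the node-driven kernel
#' formulation generate the same process, so this serves as the
#' Markovian-equivalence reference for [run_facetoface()].
#'
#' @inheritParams run_facetoface
#' @export
run_edge_driven_exponential <- function(n_nodes, t_end, lambda_a,
                                        lambda_end, seed = NULL) {
  stopifnot(n_nodes >= 2, t_end >= 0)
  if (!is.null(seed)) set.seed(seed)
  rho <- lambda_a / (n_nodes - 1)
  active <- matrix(FALSE, n_nodes, n_nodes)
  ei <- integer(0); ej <- integer(0); estart <- numeric(0)
  cs <- numeric(0); ce <- numeric(0); ci <- integer(0); cj <- integer(0)
  cc <- integer(0)
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  T_now <- 0
  repeat {
    n_e <- length(ei)
    r_form <- (n_pairs - n_e) * rho
    r_term <- n_e * lambda_end
    total <- r_form + r_term
    if (total <= 0) break
    T_now <- T_now + stats::rexp(1, total)
    if (T_now > t_end) break
    if (stats::runif(1) * total < r_form) {
      repeat {
        i <- sample.int(n_nodes, 1L); j <- sample.int(n_nodes, 1L)
        if (i != j && !active[i, j]) break
      }
      active[i, j] <- active[j, i] <- TRUE
      ei <- c(ei, min(i, j)); ej <- c(ej, max(i, j)); estart <- c(estart, T_now)
    } else {
      k <- sample.int(n_e, 1L)
      cs <- c(cs, estart[k]); ce <- c(ce, T_now)
      ci <- c(ci, ei[k]); cj <- c(cj, ej[k]); cc <- c(cc, 0L)
      active[ei[k], ej[k]] <- active[ej[k], ei[k]] <- FALSE
      ei <- ei[-k]; ej <- ej[-k]; estart <- estart[-k]
    }
  }
  if (length(ei)) {
    cs <- c(cs, estart); ce <- c(ce, rep(t_end, length(ei)))
    ci <- c(ci, ei); cj <- c(cj, ej); cc <- c(cc, rep(1L, length(ei)))
  }
  list(contacts = data.frame(t_start = cs, t_end = ce, i = ci, j = cj,
                             censored = cc),
       t_final = min(T_now, t_end))
}
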