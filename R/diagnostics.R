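#' Earth Mover's Distance between a sample and an analytic IED
#'
#' One-dimensional first Wasserstein distance between the empirical
#' distribution of `x` and the analytic distribution, estimated on the
#' quantile scale: \eqn{W_1 = \int_0^1 |F_n^{-1}(p) - F^{-1}(p)| dp},
#' approximated by averaging over the sample's plotting positions
#' `(i - 0.5) / n`.
#'
#' For heavy-tailed families (Pareto with `alpha <= 1`) the untruncated
#' distance has infinite expectation, so `trunc` restricts the integral to
#' the quantile range `[0, trunc]`; the truncation level is part of the
#' diagnostic's definition and must be held fixed when distances are
#' compared.
#'
#' @param x Numeric sample of inter-event times.
#' @param ied The analytic [ied].
#' @param trunc Upper quantile of the integration range (default 1).
#' @return The (truncated) distance, in time units.
#' @export
emd_to_ied <- function(x, ied, trunc = 1) {
  stopifnot(length(x) >= 1, trunc > 0, trunc <= 1)
  n <- length(x)
  xs <- sort(x)
  p <- (seq_len(n) - 0.5) / n
  keep <- p <= trunc
  q <- ied_quantile(ied, p[keep])
  sum(abs(xs[keep] - q)) / n
}

#' @rdname emd_to_ied
#' @param y Second sample.
#' @return `emd_two_sample()`: the W1 distance between two empirical
#'   distributions (equal-weight quantile coupling).
#' @export
emd_two_sample <- function(x, y, trunc = 1) {
  n <- max(length(x), length(y))
  p <- (seq_len(n) - 0.5) / n
  keep <- p <= trunc
  qx <- stats::quantile(x, p[keep], names = FALSE, type = 4)
  qy <- stats::quantile(y, p[keep], names = FALSE, type = 4)
  sum(abs(qx - qy)) / n
}

#' Accuracy diagnostic for a simulated channel
#'
#' Compares the empirical inter-event-time distribution of one channel of a
#' finished run against its analytic renewal density via the Earth Mover's
#' Distance.  The expected finite-step error of the thinning scheme decays
#' quadratically in the dominating rate, so the diagnostic shrinks roughly
#' fourfold when `lambda_max` is doubled (until the Monte-Carlo noise floor
#' of the sample is reached).
#'
#' @param run A [mosaic_run()] result.
#' @param ied The analytic waiting-time distribution of the channel.
#' @param channel Channel id(s) whose events form the sample; `NULL` pools
#'   all accepted events (single-channel runs).
#' @param min_events Minimum accepted events required (default 100); with
#'   fewer events the diagnostic is unavailable (an error), not zero.
#' @param trunc Quantile truncation, see [emd_to_ied()].
#' @export
error_diagnostic <- function(run, ied, channel = NULL, min_events = 100,
                             trunc = 1) {
  iet <- interevent_times(run, channel)
  if (length(iet) < min_events) {
    stop(sprintf(
      "diagnostic unavailable: %d accepted events, need at least %d",
      length(iet), min_events))
  }
  emd_to_ied(iet, ied, trunc = trunc)
}

#' Rejection factor of a run
#'
#' Candidate iterations (accepted plus rejected) per accepted event.  For a
#' single renewal channel with a constant bound this grows linearly in
#' `lambda_max / lambda_0`, the ratio of the bound to the mean event rate.
#'
#' @param run A [mosaic_run()] result, or any list with an element
#'   `counters` holding `accepted` and `rejected` counts.
#' @export
rejection_factor <- function(run) {
  ct <- run$counters
  (ct$accepted + ct$rejected) / ct$accepted
}
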