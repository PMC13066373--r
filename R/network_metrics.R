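#' Interdurations of a contact log
#'
#' Gap times between successive interactions, pooled over entities.  At the
#' node level a gap is the interval between the start times of consecutive
#' contacts involving the same node; at the edge level, consecutive
#' contacts of the same unordered pair.  An entity with a single contact
#' contributes nothing.
#'
#' @param contacts Data frame with columns `t_start`, `t_end`, `i`, `j`
#'   (as produced by [run_facetoface()] or [read_contact_tsv()]).
#' @param level `"node"` or `"edge"`.
#' @return Numeric vector of pooled gap times.
#' @export
interdurations <- function(contacts, level = c("node", "edge")) {
  level <- match.arg(level)
  stopifnot(nrow(contacts) >= 1)
  if (level == "node") {
    keys <- c(contacts$i, contacts$j)
    times <- c(contacts$t_start, contacts$t_start)
  } else {
    keys <- paste(pmin(contacts$i, contacts$j),
                  pmax(contacts$i, contacts$j), sep = "-")
    times <- contacts$t_start
  }
  gaps <- lapply(split(times, keys), function(tt) {
    if (length(tt) < 2) numeric(0) else diff(sort(tt))
  })
  unname(unlist(gaps))
}

#' @rdname interdurations
#' @return `interaction_durations()`: the edge lifetimes
#'   `t_end - t_start`.
#' @export
interaction_durations <- function(contacts) {
  contacts$t_end - contacts$t_start
}

#' Aggregated interaction-score graph
#'
#' Sums the interaction durations of every pair, log-transforms the sums
#' (natural log; sums below one tick are floored at one so scores stay
#' non-negative), normalizes by the maximum over pairs, and connects the
#' pairs whose score exceeds `threshold`.  With a single interacting pair
#' the normalization makes its own score exactly 1, so that pair is always
#' connected -- a degenerate but well-defined case.
#'
#' @param contacts Contact data frame (`t_start`, `t_end`, `i`, `j`).
#' @param threshold Score threshold (default 0.4).
#' @param n_nodes Number of vertices; defaults to the largest node id
#'   observed.
#' @return An `igraph` graph with edge attributes `score` and
#'   `total_duration`.
#' @export
interaction_score_graph <- function(contacts, threshold = 0.4,
                                    n_nodes = NULL) {
  stopifnot(nrow(contacts) >= 1)
  if (is.null(n_nodes)) n_nodes <- max(contacts$i, contacts$j)
  key <- paste(pmin(contacts$i, contacts$j),
               pmax(contacts$i, contacts$j), sep = "-")
  dur <- tapply(contacts$t_end - contacts$t_start, key, sum)
  if (all(dur <= 0)) stop("all pairwise interaction durations are zero")
  score <- log(pmax(dur, 1))
  mx <- max(score)
  if (mx <= 0) {
    stop("all interaction scores are zero (no pair exceeds one tick in ",
         "total); the normalized score graph is undefined")
  }
  score <- score / mx
  keep <- score > threshold
  pairs <- do.call(rbind, strsplit(names(dur)[keep], "-"))
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (any(keep)) {
    g <- igraph::add_edges(g, as.integer(t(pairs)))
    igraph::E(g)$score <- as.numeric(score[keep])
    igraph::E(g)$total_duration <- as.numeric(dur[keep])
  }
  g
}

#' Aggregated network metrics
#'
#' The five scalar summaries used to compare simulated and empirical
#' aggregated graphs: average local clustering coefficient (isolated and
#' degree-1 vertices count as zero), global transitivity, edge density,
#' degree assortativity, and modularity of the Louvain partition at
#' resolution 1.  Louvain is stochastic, so the modularity is averaged over
#' `louvain_seeds`.  On a graph with no edges the density is 0 and the
#' remaining metrics are undefined (`NA`).
#'
#' @param g An `igraph` graph with at least 2 vertices.
#' @param louvain_seeds Integer seeds for the Louvain partitions.
#' @param resolution Louvain resolution parameter.
#' @return Named numeric vector `clustering`, `modularity`, `transitivity`,
#'   `density`, `assortativity`.
#' @export
aggregated_metrics <- function(g, louvain_seeds = 1:10, resolution = 1) {
  stopifnot(igraph::vcount(g) >= 2)
  if (igraph::ecount(g) == 0) {
    return(c(clustering = NA_real_, modularity = NA_real_,
             transitivity = NA_real_, density = 0,
             assortativity = NA_real_))
  }
  mods <- vapply(louvain_seeds, function(s) {
    set.seed(s)
    igraph::modularity(igraph::cluster_louvain(g, resolution = resolution))
  }, numeric(1))
  c(clustering = igraph::transitivity(g, type = "localaverage",
                                      isolates = "zero"),
    modularity = mean(mods),
    transitivity = igraph::transitivity(g, type = "global"),
    density = igraph::edge_density(g),
    assortativity = igraph::assortativity_degree(g))
}

#' Normalized metric deviations across models
#'
#' Absolute deviation of each model's aggregated metrics from a reference,
#' normalized per metric by the standard deviation of that metric across
#' models (so metrics on different scales are comparable).
#'
#' @param metrics_by_model Named list of metric vectors (as returned by
#'   [aggregated_metrics()]).
#' @param reference Named numeric vector of reference metric values.
#' @return Matrix (model x metric) of normalized absolute deviations.
#' @export
metric_deviations <- function(metrics_by_model, reference) {
  stopifnot(length(metrics_by_model) >= 2)
  m <- do.call(rbind, metrics_by_model)
  common <- intersect(colnames(m), names(reference))
  m <- m[, common, drop = FALSE]
  dev <- abs(sweep(m, 2, reference[common]))
  sds <- apply(m, 2, stats::sd)
  sweep(dev, 2, ifelse(sds > 0, sds, 1), "/")
}
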