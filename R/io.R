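#' Load and validate a run configuration
#'
#' Configurations are YAML (or JSON, by file extension) with at least
#' `model`, `seed`, and `t_end`, plus model-specific parameters under
#' `params`.  Validation failures name the offending field.  Times are
#' floating point in the model's own units (hours for the germinal-center
#' model, minutes for the Hes1 circuit, data ticks for temporal networks);
#' the engine itself is unit-agnostic.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `"run_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format '.", ext, "' (use .yaml or .json)")
  }
  validate_config(cfg)
}

known_models <- c("bcell", "hes1", "tn")

validate_config <- function(cfg) {
  for (field in c("model", "seed", "t_end")) {
    if (is.null(cfg[[field]])) {
      stop("config error: required field `", field, "` is missing")
    }
  }
  if (!cfg$model %in% known_models) {
    stop("config error: field `model` must be one of ",
         paste(known_models, collapse = ", "), " (got '", cfg$model, "')")
  }
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("config error: field `seed` must be an integer")
  }
  if (!is.numeric(cfg$t_end) || cfg$t_end < 0) {
    stop("config error: field `t_end` must be a non-negative number")
  }
  if (is.null(cfg$params)) cfg$params <- list()
  structure(cfg, class = "run_config")
}

#' Run a model from a configuration
#'
#' Dispatches to [run_gc()], [run_hes1()] or [run_facetoface()] and, if
#' `out_dir` is given, writes the tabular outputs (TSV), a summary JSON,
#' and a manifest (config, seed, package version) sufficient to reproduce
#' the run.
#'
#' @param config A `"run_config"` (see [load_config()]) or a path.
#' @param out_dir Optional output directory (created if needed).
#' @export
run_from_config <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  res <- switch(config$model,
    bcell = do.call(run_gc, c(list(seed = config$seed,
                                   t_end_days = config$t_end / 24), p)),
    hes1 = do.call(run_hes1, c(list(seed = config$seed,
                                    t_end = config$t_end), p)),
    tn = do.call(run_facetoface, c(list(seed = config$seed,
                                        t_end = config$t_end), p)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (config$model == "tn") {
      write_contact_log(res$contacts, file.path(out_dir, "contacts.tsv"))
    } else {
      utils::write.table(res$trajectory,
                         file.path(out_dir, "trajectory.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    summary <- list(model = config$model, t_final = res$t_final,
                    counters = res$counters)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(config = unclass(config), seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("mosaicsim")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Event-log and contact-log TSV round trips
#'
#' Tab-separated files with a header row; times are floating point in
#' model units.
#'
#' @param events Event data frame (`time`, `channel`, `accepted`,
#'   `payload`).
#' @param path File path.
#' @export
write_event_log <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname write_event_log
#' @param contacts Contact data frame (`t_start`, `t_end`, `i`, `j`, and
#'   optionally `censored`).
#' @export
write_contact_log <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a contact list TSV
#'
#' Expects a header with at least `t_start`, `t_end`, `i`, `j`.  Rows
#' violating `t_start < t_end` or with non-positive node ids raise an
#' error naming the first offending line (1-based, counting the header).
#'
#' @param path File path.
#' @export
read_contact_tsv <- function(path) {
  if (!file.exists(path)) stop("contact log not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed contact TSV '", path, "': ",
                             conditionMessage(e)))
  need <- c("t_start", "t_end", "i", "j")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("contact TSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop("contact TSV '", path, "': non-numeric `", col, "` at line ",
           bad + 1L)
    }
  }
  bad <- which(!(df$t_start < df$t_end))[1]
  if (!is.na(bad)) {
    stop("contact TSV '", path, "': t_start >= t_end at line ", bad + 1L)
  }
  bad <- which(df$i < 1 | df$j < 1 | df$i == df$j)[1]
  if (!is.na(bad)) {
    stop("contact TSV '", path, "': invalid node ids at line ", bad + 1L)
  }
  df
}

#' Instantaneous contact export
#'
#' Expands interval contacts into the instantaneous `t i j` triple format
#' used by face-to-face proximity datasets: one row per sampling tick at
#' which the edge is active (`t_start <= t < t_end`, ticks at multiples of
#' `dt`).
#'
#' @param contacts Contact data frame.
#' @param dt Sampling interval in ticks.
#' @param path Optional file to write (headerless, tab-separated).
#' @return Data frame with columns `t`, `i`, `j` (invisibly if written).
#' @export
export_sociopatterns <- function(contacts, dt = 1, path = NULL) {
  stopifnot(dt > 0)
  rows <- lapply(seq_len(nrow(contacts)), function(k) {
    t0 <- contacts$t_start[k]; t1 <- contacts$t_end[k]
    ticks <- seq(ceiling(t0 / dt) * dt, t1 - 1e-9, by = dt)
    if (!length(ticks)) return(NULL)
    data.frame(t = ticks, i = contacts$i[k], j = contacts$j[k])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(t = numeric(0), i = integer(0),
                                      j = integer(0))
  out <- out[order(out$t, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Synthetic fixtures for tests and examples
#'
#' Deterministic given `seed`.  Kinds: `"iet_sample"` (oracle draws from a
#' named waiting-time family), `"contact_log"` (a small random contact
#' list), `"gc_small"` (a reduced germinal-center run).
#'
#' @param kind Fixture kind.
#' @param params Named list of kind-specific parameters.
#' @param seed Integer seed.
#' @export
generate_fixture <- function(kind = c("iet_sample", "contact_log",
                                      "gc_small"),
                             params = list(), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  defaults <- switch(kind,
    iet_sample = list(family = "gamma", shape = 3, lambda0 = 0.05, n = 1000),
    contact_log = list(n_nodes = 10, n_contacts = 50, horizon = 100),
    gc_small = list(n_b = 50, n_t = 2, t_end_days = 2))
  p <- utils::modifyList(defaults, params)
  switch(kind,
    iet_sample = {
      ied <- switch(p$family,
        gamma = ied_gamma(p$shape, p$lambda0),
        pareto = ied_pareto(p$t_min, p$alpha),
        exponential = ied_exponential(p$rate),
        stop("fixture error: unknown family '", p$family, "'"))
      sample_oracle(ied, p$n)
    },
    contact_log = {
      pairs <- t(replicate(p$n_contacts,
                           sort(sample.int(p$n_nodes, 2))))
      t0 <- stats::runif(p$n_contacts, 0, p$horizon * 0.9)
      dur <- pmin(stats::rexp(p$n_contacts, 1 / 3) + 0.5,
                  p$horizon - t0)
      df <- data.frame(t_start = t0, t_end = t0 + dur,
                       i = pairs[, 1], j = pairs[, 2], censored = 0L)
      df[order(df$t_start), ]
    },
    gc_small = run_gc(n_b = p$n_b, n_t = p$n_t, t_end_days = p$t_end_days,
                      seed = seed))
}
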