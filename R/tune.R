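# Hyperparameter optimization: native random search with an append-safe
# JSON-lines trial log; targeted samplers (e.g. a Tree-structured Parzen
# Estimator from an external optimizer) plug in through the `sampler`
# argument.

sample_config <- function(space) {
  lapply(space, function(vals) {
    if (is.list(vals)) vals[[sample.int(length(vals), 1L)]]
    else vals[sample.int(length(vals), 1L)]
  })
}

#' Random-search hyperparameter optimization
#'
#' Runs `n_trials` training jobs with configurations drawn from `space`
#' and returns the configuration with the best validation metric. Each
#' completed trial is appended as one JSON line to `log_file`, so several
#' workers pointed at the same log can run in parallel and the combined log
#' stays valid; the reported best never worsens as trials accumulate.
#'
#' @param formula,data,task,... passed to [dmpnn()].
#' @param space named list of candidate values, e.g.
#'   `list(depth = 2:5, hidden = c(64, 128), dropout = c(0, 0.1))`.
#'   Recognized names: any architecture argument of [dmpnn()].
#' @param n_trials number of sampled configurations.
#' @param seed RNG seed for the sampling stream.
#' @param control a [train_control()] shared by all trials.
#' @param log_file JSON-lines trial log path (optional).
#' @param sampler function(space, trials) returning the next configuration;
#'   defaults to uniform random sampling. A targeted optimizer (such as a
#'   Tree-structured Parzen Estimator) can be plugged in here.
#' @return list with `best` (config + metric), `trials` (data.frame), and
#'   `log_file`.
#' @export
dmpnn_tune <- function(formula, data, space, n_trials = 10L, seed = 0L,
                       task = "regression", control = train_control(),
                       log_file = NULL, sampler = NULL, ...) {
  if (length(space) == 0L) stop("empty search space", call. = FALSE)
  trials <- list()
  best <- NULL
  minimize <- !default_val_metric(task) %in% c("auroc", "auprc", "accuracy",
                                               "r2")
  for (k in seq_len(n_trials)) {
    cfg <- with_seed(seed + k, {
      if (is.null(sampler)) sample_config(space) else sampler(space, trials)
    })
    ctl <- control
    ctl$seed <- control$seed + k
    args <- c(list(formula = formula, data = data, task = task,
                   control = ctl, verbose = FALSE), cfg, list(...))
    fit <- do.call(dmpnn, args)
    metric <- min(fit$history[[1]]$val_metric)
    if (!minimize) metric <- max(fit$history[[1]]$val_metric)
    rec <- c(list(trial = k, metric = metric,
                  metric_name = default_val_metric(task)), cfg)
    trials[[k]] <- rec
    if (!is.null(log_file)) {
      line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
      cat(line, "\n", file = log_file, append = TRUE, sep = "")
    }
    better <- is.null(best) ||
      (minimize && metric < best$metric) ||
      (!minimize && metric > best$metric)
    if (better) best <- list(config = cfg, metric = metric, trial = k)
  }
  tr <- do.call(rbind, lapply(trials, function(t)
    as.data.frame(t, stringsAsFactors = FALSE)))
  list(best = best, trials = tr, log_file = log_file)
}

#' Read a trial log written by one or more tuning workers
#'
#' @param log_file JSON-lines path.
#' @return data.frame of trial records.
#' @export
read_trial_log <- function(log_file) {
  lines <- readLines(log_file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}
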