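# Uncertainty estimation (ensemble, MC dropout, MVE, evidential,
# classification probabilities, spectra round-robin ensemble variance),
# calibration (z/t-scaling, CRUDE, MVE weighting; Platt, isotonic) and
# uncertainty evaluation metrics (NLL, Spearman, ENCE, miscalibration area).

#' Estimate predictive uncertainty
#'
#' @param object a fitted `dmpnn`.
#' @param newdata data.frame of inputs.
#' @param method `"ensemble"` (variance across submodels; for MVE heads the
#'   law-of-total-variance combination mean-of-variances +
#'   variance-of-means), `"dropout"` (variance across `passes` stochastic
#'   forward passes), `"mve"`, `"evidential"`, `"classification"` (the
#'   predicted probability is the uncertainty carrier), or
#'   `"spectra_roundrobin"` (leave-one-out ensemble variance per bin).
#' @param passes Monte-Carlo dropout passes (default 30).
#' @param ... passed to [predict.dmpnn()].
#' @return an `uncertainty_bundle`: predictions `mean`, variance-like `unc`,
#'   the `source` method, and calibration state.
#' @export
estimate_uncertainty <- function(object, newdata,
                                 method = c("ensemble", "dropout", "mve",
                                            "evidential", "classification",
                                            "spectra_roundrobin"),
                                 passes = 30L, ...) {
  method <- match.arg(method)
  spec <- object$spec
  M <- length(object$nets)
  bundle <- switch(method,
    ensemble = {
      if (M < 2L)
        stop("ensemble uncertainty needs ensemble_size >= 2", call. = FALSE)
      per <- lapply(seq_len(M), function(m) {
        raw <- forward_newdata(object, newdata, m, ...)$out
        task_response(object, raw)
      })
      means <- lapply(per, `[[`, "preds")
      mu <- Reduce(`+`, means) / M
      var_means <- Reduce(`+`, lapply(means, function(x) (x - mu)^2)) / M
      vars <- lapply(per, `[[`, "variance")
      unc <- if (!is.null(vars[[1]])) {
        Reduce(`+`, vars) / M + var_means   # law of total variance
      } else var_means
      list(mean = mu, unc = unc, member_means = means,
           member_variances = if (!is.null(vars[[1]])) vars)
    },
    dropout = {
      # a zero dropout rate simply yields zero variance across passes
      per <- lapply(seq_len(passes), function(k) {
        raw <- forward_newdata(object, newdata, 1L, training = TRUE, ...)$out
        task_response(object, raw)$preds
      })
      mu <- Reduce(`+`, per) / passes
      unc <- Reduce(`+`, lapply(per, function(x) (x - mu)^2)) / passes
      list(mean = mu, unc = unc)
    },
    mve = , evidential = {
      if (spec$loss != method)
        stop("method '", method, "' requires a model trained with the ",
             method, " loss", call. = FALSE)
      r <- task_response(object,
                         forward_newdata(object, newdata, 1L, ...)$out)
      list(mean = r$preds, unc = r$variance,
           aleatoric = r$aleatoric, epistemic = r$epistemic)
    },
    classification = {
      if (!spec$task %in% c("binary", "multiclass"))
        stop("classification uncertainty needs a classification task",
             call. = FALSE)
      p <- as.matrix(predict(object, newdata, ...))
      list(mean = p, unc = p)
    },
    spectra_roundrobin = {
      if (spec$task != "spectra")
        stop("spectra_roundrobin requires a spectra model", call. = FALSE)
      if (M < 2L)
        stop("spectra_roundrobin needs ensemble_size >= 2", call. = FALSE)
      qs <- lapply(seq_len(M), function(m)
        task_response(object,
                      forward_newdata(object, newdata, m, ...)$out)$preds)
      mu <- Reduce(`+`, qs) / M
      # leave-one-out: deviation of each member from the mean of the others
      unc <- Reduce(`+`, lapply(seq_len(M), function(m) {
        loo <- (Reduce(`+`, qs[-m])) / (M - 1)
        (qs[[m]] - loo)^2
      })) / M
      list(mean = mu, unc = unc)
    })
  structure(c(bundle, list(source = method, task = spec$task,
                           calibration = NULL)),
            class = "uncertainty_bundle")
}

#' @export
print.uncertainty_bundle <- function(x, ...) {
  cat("Uncertainty bundle (", x$source, ", ", nrow(as.matrix(x$mean)),
      " predictions)\n", sep = "")
  cat("  mean unc:", signif(mean(x$unc), 4),
      if (!is.null(x$calibration))
        paste0(" | calibrated: ", x$calibration$method) else
          " | uncalibrated", "\n")
  invisible(x)
}

#' Calibrate regression uncertainties on a held-out set
#'
#' Fits a recalibration of the variance-like uncertainties against observed
#' residuals and applies it. `"z_scaling"` multiplies variances by the
#' scalar making standardized residuals unit variance; `"t_scaling"` fits
#' the scale by Student-t maximum likelihood (df = n - 1), more robust for
#' small calibration sets; `"crude"` stores the empirical distribution of
#' standardized errors and rescales by its second moment (interval queries
#' use the empirical quantiles); `"mve_weighting"` reweights the ensemble
#' members' MVE variance estimates by held-out NLL.
#'
#' Calibration never changes the predicted means.
#'
#' @param bundle an `uncertainty_bundle` computed on the calibration set.
#' @param targets observed targets for the calibration set.
#' @param method one of `"z_scaling"`, `"t_scaling"`, `"crude"`,
#'   `"mve_weighting"`.
#' @return the bundle with `unc` recalibrated and the fitted parameters in
#'   `$calibration` (reusable via [apply_calibration()]).
#' @export
calibrate_regression <- function(bundle, targets,
                                 method = c("z_scaling", "t_scaling",
                                            "crude", "mve_weighting")) {
  method <- match.arg(method)
  targets <- as.matrix(targets)
  mu <- as.matrix(bundle$mean)
  v <- as.matrix(bundle$unc)
  ok <- !is.na(targets)
  if (sum(ok) < 10L)
    stop("refusing to calibrate on fewer than 10 points", call. = FALSE)
  r <- (targets - mu)[ok]
  vv <- pmax(v[ok], 1e-12)
  cal <- switch(method,
    z_scaling = list(method = method, factor = mean(r^2 / vv)),
    t_scaling = {
      df <- sum(ok) - 1L
      nll <- function(ls) {
        s <- exp(ls)
        sc <- sqrt(s * vv * (df - 2) / df)   # variance of t is df/(df-2)
        -sum(stats::dt(r / sc, df, log = TRUE) - log(sc))
      }
      op <- stats::optimize(nll, c(-10, 10))
      list(method = method, factor = exp(op$minimum), df = df)
    },
    crude = {
      z <- sort(r / sqrt(vv))
      list(method = method, factor = mean(z^2), z_empirical = z)
    },
    mve_weighting = {
      if (is.null(bundle$member_variances))
        stop("mve_weighting needs an ensemble-of-MVE bundle ",
             "(estimate_uncertainty(..., method = 'ensemble') on an ",
             "mve-loss ensemble)", call. = FALSE)
      Vm <- vapply(bundle$member_variances, function(m) as.matrix(m)[ok],
                   numeric(sum(ok)))
      nll <- function(theta) {
        w <- exp(theta) / sum(exp(theta))
        vw <- pmax(as.vector(Vm %*% w), 1e-12)
        sum(0.5 * (log(2 * pi * vw) + r^2 / vw))
      }
      op <- stats::optim(rep(0, ncol(Vm)), nll, method = "BFGS")
      w <- exp(op$par) / sum(exp(op$par))
      list(method = method, weights = w)
    })
  apply_calibration(bundle, cal)
}

#' Apply a fitted calibration to an uncertainty bundle
#'
#' @param bundle an `uncertainty_bundle`.
#' @param calibration the `$calibration` element of a calibrated bundle.
#' @return the bundle with recalibrated `unc` (means untouched).
#' @export
apply_calibration <- function(bundle, calibration) {
  if (!is.null(calibration$factor)) {
    bundle$unc <- bundle$unc * calibration$factor
  } else if (!is.null(calibration$weights)) {
    Vm <- bundle$member_variances
    w <- calibration$weights
    bundle$unc <- Reduce(`+`, Map(function(m, wi) m * wi, Vm, as.list(w)))
  } else if (!is.null(calibration$platt)) {
    lg <- stats::qlogis(pmin(pmax(as.matrix(bundle$mean), 1e-12), 1 - 1e-12))
    p <- stats::plogis(calibration$platt[1] + calibration$platt[2] * lg)
    bundle$calibrated_probs <- p
    bundle$unc <- p
  } else if (!is.null(calibration$isotonic)) {
    p <- matrix(calibration$isotonic(as.vector(as.matrix(bundle$mean))),
                nrow(as.matrix(bundle$mean)))
    bundle$calibrated_probs <- p
    bundle$unc <- p
  }
  bundle$calibration <- calibration
  bundle
}

#' Calibrate classification probabilities
#'
#' `"platt"`: logistic regression of the labels on the logit of the raw
#' score (monotone for any informative fit, so ranking metrics such as
#' AUROC are unchanged); `"isotonic"`: nondecreasing stepwise map fitted by
#' [stats::isoreg()].
#'
#' @param bundle an `uncertainty_bundle` from a binary classifier
#'   (probabilities in `mean`).
#' @param targets 0/1 labels of the calibration set.
#' @param method `"platt"` or `"isotonic"`.
#' @return the bundle with `calibrated_probs`; calibration reusable via
#'   [apply_calibration()].
#' @export
calibrate_classification <- function(bundle, targets,
                                     method = c("platt", "isotonic")) {
  method <- match.arg(method)
  y <- as.vector(as.matrix(targets))
  p <- as.vector(as.matrix(bundle$mean))
  ok <- !is.na(y)
  y <- y[ok]; p <- p[ok]
  if (length(unique(y)) < 2L)
    stop("calibration set contains a single class", call. = FALSE)
  cal <- if (method == "platt") {
    lg <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
    fit <- stats::glm(y ~ lg, family = stats::binomial())
    list(method = method, platt = unname(stats::coef(fit)))
  } else {
    o <- order(p)
    iso <- stats::isoreg(p[o], y[o])
    xs <- iso$x; ys <- iso$yf
    f <- stats::approxfun(xs, ys, method = "linear", rule = 2, ties = mean)
    list(method = method, isotonic = function(q) pmin(pmax(f(q), 0), 1))
  }
  apply_calibration(bundle, cal)
}

#' Evaluate the quality of uncertainty estimates
#'
#' @param bundle an `uncertainty_bundle`.
#' @param targets observed targets.
#' @param metric `"nll"` (Gaussian, using `unc` as variance), `"spearman"`
#'   (rank correlation between `unc` and absolute error), `"ence"`
#'   (expected normalized calibration error over `bins` equal-count bins:
#'   mean |RMSE_b - RMV_b| / RMV_b), or `"miscalibration_area"` (area
#'   between the empirical coverage of central Gaussian intervals and the
#'   ideal diagonal).
#' @param bins number of ENCE bins (default 10).
#' @return a numeric score.
#' @export
evaluate_uncertainty <- function(bundle, targets,
                                 metric = c("nll", "spearman", "ence",
                                            "miscalibration_area"),
                                 bins = 10L) {
  metric <- match.arg(metric)
  targets <- as.matrix(targets)
  mu <- as.matrix(bundle$mean)
  v <- pmax(as.matrix(bundle$unc), 1e-12)
  ok <- !is.na(targets)
  r <- (targets - mu)[ok]
  vv <- v[ok]
  switch(metric,
    nll = mean(0.5 * (log(2 * pi * vv) + r^2 / vv)),
    spearman = {
      if (stats::sd(vv) < 1e-14)
        stop("Spearman undefined: uncertainties are constant", call. = FALSE)
      stats::cor(vv, abs(r), method = "spearman")
    },
    ence = {
      o <- order(vv)
      idx <- split(o, cut(seq_along(o), bins, labels = FALSE))
      mean(vapply(idx, function(i) {
        rmse <- sqrt(mean(r[i]^2))
        rmv <- sqrt(mean(vv[i]))
        abs(rmse - rmv) / rmv
      }, 0))
    },
    miscalibration_area = {
      z <- abs(r) / sqrt(vv)
      ps <- seq(0.01, 0.99, by = 0.01)
      emp <- vapply(ps, function(p)
        mean(z <= stats::qnorm((1 + p) / 2)), 0)
      mean(abs(emp - ps))
    })
}

#' Central predictive interval from an uncertainty bundle
#'
#' Gaussian intervals by default; CRUDE-calibrated bundles use the stored
#' empirical distribution of standardized errors with linearly interpolated
#' quantiles.
#'
#' @param bundle an `uncertainty_bundle`.
#' @param level coverage level (default 0.9).
#' @return list with matrices `lower` and `upper`.
#' @export
predict_interval <- function(bundle, level = 0.9) {
  mu <- as.matrix(bundle$mean)
  v <- pmax(as.matrix(bundle$unc), 1e-12)
  cal <- bundle$calibration
  if (!is.null(cal) && identical(cal$method, "crude")) {
    z <- cal$z_empirical
    lo <- stats::quantile(z, (1 - level) / 2, type = 7)
    hi <- stats::quantile(z, (1 + level) / 2, type = 7)
    s <- sqrt(v / cal$factor)   # unc was rescaled; recover raw sd
    return(list(lower = mu + lo * s, upper = mu + hi * s))
  }
  q <- stats::qnorm((1 + level) / 2)
  list(lower = mu - q * sqrt(v), upper = mu + q * sqrt(v))
}
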