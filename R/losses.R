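# Training losses (value + exact gradient with respect to the raw network
# outputs) and hard evaluation metrics.
#
# Conventions: `raw` is the n x d matrix of pre-activation network outputs;
# `target` is the task-shaped target object; `mask` marks valid target
# entries (missing targets contribute zero loss and zero gradient); every
# loss returns list(value, grad, preds) with `preds` on the task scale.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Parse inequality-bounded regression targets
#'
#' Accepts numeric strings with optional `<` or `>` prefixes (e.g. `">5.0"`)
#' as produced by assays reporting censored values.
#'
#' @param x character or numeric vector; empty strings and NA are missing.
#' @return list with numeric `value` and character `relation`
#'   (`"="`, `"<"`, `">"`, NA for missing).
#' @export
#' @examples
#' parse_bounded_targets(c("1.5", ">5.0", "<2", NA))$relation
parse_bounded_targets <- function(x) {
  x <- as.character(x)
  n <- length(x)
  value <- rep(NA_real_, n)
  relation <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- trimws(x[i])
    if (is.na(s) || !nzchar(s)) next
    rel <- "="
    if (startsWith(s, ">")) { rel <- ">"; s <- substring(s, 2L) }
    else if (startsWith(s, "<")) { rel <- "<"; s <- substring(s, 2L) }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) {
      stop("malformed bounded target '", x[i], "' at row ", i, call. = FALSE)
    }
    value[i] <- v
    relation[i] <- rel
  }
  list(value = value, relation = relation)
}

# --- regression -------------------------------------------------------------

loss_mse <- function(raw, target, mask, spec, extra = NULL) {
  err <- (raw - target) * mask
  n <- max(1, sum(mask))
  list(value = sum(err^2) / n, grad = 2 * err / n, preds = raw)
}

#' Bounded mean squared error
#'
#' Squared error that is zeroed whenever an inequality target (`">5"`,
#' `"<2"`) is already satisfied by the prediction; equality targets use
#' plain squared error.
#'
#' @param raw predictions (matrix).
#' @param target numeric target matrix.
#' @param mask validity mask.
#' @param spec model spec (unused).
#' @param extra list with `relation`: character matrix of `"="`, `"<"`, `">"`.
#' @return list(value, grad, preds).
#' @keywords internal
loss_bounded_mse <- function(raw, target, mask, spec, extra) {
  rel <- extra$relation
  active <- mask &
    !((rel == ">" & raw > target) | (rel == "<" & raw < target))
  active[is.na(active)] <- FALSE
  err <- (raw - target) * active
  n <- max(1, sum(mask))
  list(value = sum(err^2) / n, grad = 2 * err / n, preds = raw)
}

# raw layout per task: [mean, raw variance]; variance through softplus
mve_unpack <- function(raw, n_tasks) {
  mu <- raw[, 2 * seq_len(n_tasks) - 1L, drop = FALSE]
  rv <- raw[, 2 * seq_len(n_tasks), drop = FALSE]
  list(mu = mu, rv = rv, v = softplus(rv) + 1e-8)
}

loss_mve <- function(raw, target, mask, spec, extra = NULL) {
  u <- mve_unpack(raw, spec$n_tasks)
  r <- u$mu - target
  nll <- 0.5 * (log(2 * pi * u$v) + r^2 / u$v)
  n <- max(1, sum(mask))
  dmu <- (r / u$v) * mask / n
  dv <- 0.5 * (1 / u$v - r^2 / u$v^2) * mask / n
  drv <- dv * sigmoid(u$rv)
  grad <- raw * 0
  grad[, 2 * seq_len(spec$n_tasks) - 1L] <- dmu
  grad[, 2 * seq_len(spec$n_tasks)] <- drv
  list(value = sum(nll * mask) / n, grad = grad,
       preds = u$mu, variance = u$v)
}

# raw layout per task: [gamma, raw_nu, raw_alpha, raw_beta]
evidential_unpack <- function(raw, n_tasks) {
  i4 <- function(k) 4L * (seq_len(n_tasks) - 1L) + k
  g <- raw[, i4(1L), drop = FALSE]
  rn <- raw[, i4(2L), drop = FALSE]
  ra <- raw[, i4(3L), drop = FALSE]
  rb <- raw[, i4(4L), drop = FALSE]
  list(gamma = g, rn = rn, ra = ra, rb = rb,
       nu = softplus(rn) + 1e-8, alpha = softplus(ra) + 1 + 1e-8,
       beta = softplus(rb) + 1e-8, i4 = i4)
}

#' Evidential regression loss (normal-inverse-gamma NLL + regularizer)
#'
#' The head predicts (gamma, nu, alpha, beta) per task; the loss is the NIG
#' negative log-likelihood plus `lambda` times the evidence-weighted
#' absolute error |y - gamma| (2 nu + alpha). Aleatoric variance is
#' beta/(alpha-1), epistemic beta/(nu (alpha-1)).
#'
#' @keywords internal
loss_evidential <- function(raw, target, mask, spec, extra = NULL) {
  lambda <- if (is.null(spec$evidential_lambda)) 0.2 else spec$evidential_lambda
  u <- evidential_unpack(raw, spec$n_tasks)
  r <- target - u$gamma
  Om <- 2 * u$beta * (1 + u$nu)
  D <- r^2 * u$nu + Om
  nll <- 0.5 * log(pi / u$nu) - u$alpha * log(Om) +
    (u$alpha + 0.5) * log(D) + lgamma(u$alpha) - lgamma(u$alpha + 0.5)
  reg <- lambda * abs(r) * (2 * u$nu + u$alpha)
  n <- max(1, sum(mask))
  dg <- ((u$alpha + 0.5) * (-2 * r * u$nu) / D + lambda * (2 * u$nu + u$alpha) *
           -sign(r)) * mask / n
  dnu <- (-0.5 / u$nu - u$alpha * 2 * u$beta / Om +
            (u$alpha + 0.5) * (r^2 + 2 * u$beta) / D +
            lambda * 2 * abs(r)) * mask / n
  dal <- (-log(Om) + log(D) + digamma(u$alpha) - digamma(u$alpha + 0.5) +
            lambda * abs(r)) * mask / n
  dbe <- (-u$alpha * 2 * (1 + u$nu) / Om +
            (u$alpha + 0.5) * 2 * (1 + u$nu) / D) * mask / n
  grad <- raw * 0
  grad[, u$i4(1L)] <- dg
  grad[, u$i4(2L)] <- dnu * sigmoid(u$rn)
  grad[, u$i4(3L)] <- dal * sigmoid(u$ra)
  grad[, u$i4(4L)] <- dbe * sigmoid(u$rb)
  list(value = sum((nll + reg) * mask) / n, grad = grad, preds = u$gamma,
       aleatoric = u$beta / (u$alpha - 1),
       epistemic = u$beta / (u$nu * (u$alpha - 1)))
}

# --- classification ---------------------------------------------------------

loss_bce <- function(raw, target, mask, spec, extra = NULL) {
  p <- sigmoid(raw)
  eps <- 1e-12
  nll <- -(target * log(p + eps) + (1 - target) * log(1 - p + eps))
  n <- max(1, sum(mask))
  list(value = sum(nll * mask) / n, grad = (p - target) * mask / n, preds = p)
}

# multiclass cross entropy; target = integer class (1-based) per task
loss_ce <- function(raw, target, mask, spec, extra = NULL) {
  K <- spec$n_classes
  n <- nrow(raw)
  total <- 0
  grad <- raw * 0
  preds <- raw * 0
  nvalid <- max(1, sum(mask))
  for (j in seq_len(spec$n_tasks)) {
    cols <- (j - 1L) * K + seq_len(K)
    Z <- raw[, cols, drop = FALSE]
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    preds[, cols] <- P
    y <- target[, j]
    valid <- which(mask[, j] & !is.na(y))
    if (length(valid) > 0L) {
      total <- total + sum(-log(pmax(P[cbind(valid, y[valid])], 1e-12)))
      G <- P[valid, , drop = FALSE]
      G[cbind(seq_along(valid), y[valid])] <-
        G[cbind(seq_along(valid), y[valid])] - 1
      grad[valid, cols] <- grad[valid, cols] + G / nvalid
    }
  }
  list(value = total / nvalid, grad = grad, preds = preds)
}

# soft Matthews correlation loss (binary): 1 - MCC of expected confusion
loss_mcc <- function(raw, target, mask, spec, extra = NULL) {
  p <- sigmoid(raw)
  total <- 0
  grad <- raw * 0
  for (j in seq_len(ncol(raw))) {
    ok <- mask[, j] & !is.na(target[, j])
    pj <- p[ok, j]; yj <- target[ok, j]
    if (sum(ok) == 0L) next
    TP <- sum(pj * yj); FP <- sum(pj * (1 - yj))
    FN <- sum((1 - pj) * yj); TN <- sum((1 - pj) * (1 - yj))
    s1 <- TP + FP; s2 <- TP + FN; s3 <- TN + FP; s4 <- TN + FN
    D <- sqrt(max(s1 * s2 * s3 * s4, 1e-12))
    N <- TP * TN - FP * FN
    mcc <- N / D
    total <- total + (1 - mcc)
    dN <- yj * s3 - (1 - yj) * s2
    dD <- D / 2 * (1 / max(s1, 1e-12) - 1 / max(s4, 1e-12))
    dmcc_dp <- (dN * D - N * dD) / D^2
    grad[ok, j] <- -dmcc_dp * pj * (1 - pj)
  }
  nt <- ncol(raw)
  list(value = total / nt, grad = grad / nt, preds = p)
}

# Dirichlet evidential classification: evidence via softplus, MSE-form loss
# with an annealed KL regularizer toward the uniform Dirichlet
loss_dirichlet <- function(raw, target, mask, spec, extra = NULL) {
  lambda <- if (is.null(spec$dirichlet_lambda)) 0.1 else spec$dirichlet_lambda
  K <- if (spec$task == "multiclass") spec$n_classes else 2L
  n <- nrow(raw)
  total <- 0
  grad <- raw * 0
  preds <- matrix(0, n, if (spec$task == "multiclass")
    spec$n_tasks * K else spec$n_tasks)
  nvalid <- 0
  for (j in seq_len(spec$n_tasks)) {
    cols <- (j - 1L) * K + seq_len(K)
    Z <- raw[, cols, drop = FALSE]
    alpha <- softplus(Z) + 1
    S <- rowSums(alpha)
    P <- alpha / S
    if (spec$task == "multiclass") {
      Y <- matrix(0, n, K)
      ok <- mask[, j] & !is.na(target[, j])
      Y[cbind(which(ok), target[ok, j])] <- 1
      preds[, cols] <- P
    } else {
      ok <- mask[, j] & !is.na(target[, j])
      Y <- cbind(1 - target[, j], target[, j])
      Y[is.na(Y)] <- 0
      preds[, j] <- P[, 2]
    }
    nvalid <- nvalid + sum(ok)
    idx <- which(ok)
    if (length(idx) == 0L) next
    for (i in idx) {
      y <- Y[i, ]; a <- alpha[i, ]; s <- S[i]; pr <- P[i, ]
      A <- sum((y - pr)^2)
      B <- sum(pr * (1 - pr)) / (s + 1)
      at <- y + (1 - y) * a
      st <- sum(at)
      KL <- lgamma(st) - lgamma(K) - sum(lgamma(at)) +
        sum((at - 1) * (digamma(at) - digamma(st)))
      total <- total + A + B + lambda * KL
      dA <- (2 / s) * ((pr - y) - sum((pr - y) * pr))
      dB <- ((1 - 2 * pr) - sum((1 - 2 * pr) * pr)) / (s * (s + 1)) -
        B / (s + 1)
      dKL <- (at - 1) * trigamma(at) - trigamma(st) * sum(at - 1)
      da <- dA + dB + lambda * dKL * (1 - y)
      grad[i, cols] <- da * sigmoid(Z[i, ])
    }
  }
  nvalid <- max(1, nvalid)
  list(value = total / nvalid, grad = grad / nvalid, preds = preds)
}

# --- spectra ----------------------------------------------------------------

# normalize raw outputs (softplus positivity) and targets over valid bins
spectra_normalize <- function(raw, target, mask) {
  s <- softplus(raw) * mask
  Ts <- rowSums(s)
  if (any(Ts <= 0)) stop("spectrum with no valid bins", call. = FALSE)
  q <- s / Ts
  ty <- ifelse(mask == 1, target, 0)
  Ty <- rowSums(ty)
  if (any(Ty <= 0)) stop("all-masked or zero target spectrum", call. = FALSE)
  p <- ty / Ty
  list(s = s, Ts = Ts, q = q, p = p)
}

#' Spectral information divergence loss
#'
#' Both spectra are restricted to valid bins, normalized to sum one, and
#' floored at `threshold`; the loss is the symmetric divergence
#' sum p log(p/q) + q log(q/p), averaged over molecules. Masked bins
#' receive zero gradient.
#'
#' @keywords internal
loss_sid <- function(raw, target, mask, spec, extra = NULL) {
  thr <- if (is.null(spec$sid_threshold)) 1e-8 else spec$sid_threshold
  nz <- spectra_normalize(raw, target, mask)
  q <- pmax(nz$q, thr) * mask
  p <- pmax(nz$p, thr) * mask
  lg <- ifelse(mask == 1, log(pmax(p, 1e-300) / pmax(q, 1e-300)), 0)
  val <- sum((p * lg - q * lg) * mask) / nrow(raw)
  # d/dq of [p log(p/q) + q log(q/p)] = -p/q + log(q/p) + 1
  dq <- ifelse(mask == 1 & nz$q >= thr, -p / pmax(q, 1e-300) - lg + 1, 0)
  # through q = s / Ts
  inner <- rowSums(dq * nz$q)
  ds <- (dq - inner) / nz$Ts * mask
  grad <- ds * sigmoid(raw) * mask / nrow(raw)
  list(value = val, grad = grad, preds = nz$q)
}

#' First-order Wasserstein (earthmover) spectrum loss
#'
#' L1 distance between the cumulative distributions of the normalized
#' spectra over valid bins, in bin units, averaged over molecules.
#'
#' @keywords internal
loss_wasserstein <- function(raw, target, mask, spec, extra = NULL) {
  nz <- spectra_normalize(raw, target, mask)
  n <- nrow(raw)
  val <- 0
  grad <- raw * 0
  for (i in seq_len(n)) {
    ok <- which(mask[i, ] == 1)
    qi <- nz$q[i, ok]; pi_ <- nz$p[i, ok]
    Qc <- cumsum(qi); Pc <- cumsum(pi_)
    val <- val + sum(abs(Pc - Qc))
    sg <- sign(Qc - Pc)
    # d/dq_k sum_j |P_j - Q_j| = sum_{j >= k} sign(Q_j - P_j)
    dq <- rev(cumsum(rev(sg)))
    inner <- sum(dq * qi)
    ds <- (dq - inner) / nz$Ts[i]
    grad[i, ok] <- ds * sigmoid(raw[i, ok])
  }
  list(value = val / n, grad = grad / n, preds = nz$q)
}

LOSSES <- list(
  mse = loss_mse, bounded_mse = loss_bounded_mse, mve = loss_mve,
  evidential = loss_evidential, bce = loss_bce, ce = loss_ce,
  mcc = loss_mcc, dirichlet = loss_dirichlet, sid = loss_sid,
  wasserstein = loss_wasserstein)

VALID_LOSSES <- list(
  regression = c("mse", "bounded_mse", "mve", "evidential"),
  binary = c("bce", "mcc", "dirichlet"),
  multiclass = c("ce", "mcc", "dirichlet"),
  spectra = c("sid", "wasserstein"),
  atom = c("mse", "bounded_mse"),
  bond = c("mse", "bounded_mse"))

#' Look up a training loss by key, validating task compatibility
#'
#' @param key one of `"mse"`, `"bounded_mse"`, `"mve"`, `"evidential"`,
#'   `"bce"`, `"ce"`, `"mcc"`, `"dirichlet"`, `"sid"`, `"wasserstein"`.
#' @param task the task type the loss will train.
#' @return the loss function `f(raw, target, mask, spec, extra)`.
#' @export
loss_function <- function(key, task = "regression") {
  if (!key %in% names(LOSSES))
    stop("unknown loss: ", key, call. = FALSE)
  if (key == "mcc" && task == "multiclass")
    stop("the differentiable MCC loss supports binary tasks only; ",
         "use 'ce' or 'dirichlet' for multiclass training ",
         "(hard multiclass MCC is available as an evaluation metric)",
         call. = FALSE)
  if (!key %in% VALID_LOSSES[[task]])
    stop("loss '", key, "' is not valid for task '", task, "'", call. = FALSE)
  LOSSES[[key]]
}

# --- evaluation metrics -----------------------------------------------------

metric_rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))
metric_mae <- function(pred, obs) mean(abs(pred - obs))
metric_r2 <- function(pred, obs) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

metric_auroc <- function(score, label) {
  label <- as.integer(label > 0.5)
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUROC undefined: calibration labels contain a single class")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metric_auprc <- function(score, label) {
  label <- as.integer(label > 0.5)
  if (sum(label) == 0L) {
    warning("AUPRC undefined: no positive labels")
    return(NA_real_)
  }
  o <- order(score, decreasing = TRUE)
  y <- label[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

metric_accuracy <- function(pred, obs) mean(pred == obs)

#' Hard Matthews correlation coefficient
#'
#' Binary from 0/1 vectors; multiclass (Gorodkin's R_K) from integer labels.
#'
#' @param pred predicted labels.
#' @param obs observed labels.
#' @return MCC in [-1, 1].
#' @export
metric_mcc <- function(pred, obs) {
  lv <- sort(unique(c(pred, obs)))
  C <- table(factor(pred, lv), factor(obs, lv))
  C <- matrix(as.numeric(C), nrow(C))
  n <- sum(C)
  num <- n * sum(diag(C)) - sum(rowSums(C) * colSums(C))
  den <- sqrt(n^2 - sum(rowSums(C)^2)) * sqrt(n^2 - sum(colSums(C)^2))
  if (den == 0) return(0)
  num / den
}

#' Evaluate predictions with a named metric
#'
#' @param preds predictions (probabilities for classification, intensities
#'   for spectra).
#' @param targets observed targets in the same shape.
#' @param metric one of `"rmse"`, `"mae"`, `"r2"`, `"auroc"`, `"auprc"`,
#'   `"accuracy"`, `"mcc"`, `"ce"`, `"bce"`, `"sid"`, `"wasserstein"`.
#' @param mask optional validity mask.
#' @return a numeric score.
#' @export
evaluation_metric <- function(preds, targets, metric, mask = NULL) {
  preds <- as.matrix(preds); targets <- as.matrix(targets)
  if (is.null(mask)) mask <- !is.na(targets)
  ok <- as.vector(mask & !is.na(targets))
  p <- as.vector(preds)[ok]; y <- as.vector(targets)[ok]
  switch(metric,
    rmse = metric_rmse(p, y),
    mae = metric_mae(p, y),
    r2 = metric_r2(p, y),
    auroc = metric_auroc(p, y),
    auprc = metric_auprc(p, y),
    accuracy = metric_accuracy(round(p), y),
    mcc = metric_mcc(round(p), y),
    bce = mean(-(y * log(pmax(p, 1e-12)) +
                   (1 - y) * log(pmax(1 - p, 1e-12)))),
    ce = mean(-log(pmax(p, 1e-12))),
    sid = spectrum_divergence(preds, targets, mask, kind = "sid"),
    wasserstein = spectrum_divergence(preds, targets, mask, kind = "w1"),
    stop("unknown metric: ", metric, call. = FALSE))
}

# evaluation-only whole-spectrum divergences (row-wise mean)
spectrum_divergence <- function(preds, targets, mask, kind = "sid",
                                threshold = 1e-8) {
  vals <- vapply(seq_len(nrow(preds)), function(i) {
    ok <- which(mask[i, ] & !is.na(targets[i, ]))
    q <- preds[i, ok] / sum(preds[i, ok])
    p <- targets[i, ok] / sum(targets[i, ok])
    if (kind == "sid") {
      q <- pmax(q, threshold); p <- pmax(p, threshold)
      sum(p * log(p / q) + q * log(q / p))
    } else {
      sum(abs(cumsum(p) - cumsum(q)))
    }
  }, 0)
  mean(vals)
}
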