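# S3 methods for fitted dmpnn models, latent extraction, and JSON
# checkpoints.

# featurize a new data.frame with the fit's featurization settings and run
# one ensemble member forward; returns raw outputs + latents
forward_newdata <- function(object, newdata, member = 1L, training = FALSE,
                            constraints = NULL, extra_mol_features = NULL,
                            extra_atom_features = NULL,
                            extra_bond_features = NULL) {
  spec <- object$spec
  for (sc in object$smiles_columns) {
    if (!sc %in% names(newdata))
      stop("newdata lacks SMILES column '", sc, "'", call. = FALSE)
  }
  graphs <- lapply(seq_along(object$smiles_columns), function(ci) {
    featurize_column(newdata[[object$smiles_columns[ci]]],
                     object$reaction[ci], object$feature_config,
                     object$reaction_mode, extra_atom_features,
                     extra_bond_features, object$extra_features_mode)
  })
  ew <- ncol(graphs[[1]][[1]]$edge_features)
  if (!spec$features_only && ew != spec$edge_width)
    stop("newdata featurizes to edge width ", ew, " but the model was ",
         "trained with ", spec$edge_width,
         " (molecule/reaction column mismatch?)", call. = FALSE)
  batches <- lapply(graphs, batch_graphs)
  x_mol <- if (!is.null(extra_mol_features)) as.matrix(extra_mol_features)
  if (spec$extra_mol_width > 0L && is.null(x_mol))
    stop("the model was trained with extra molecule features; supply ",
         "extra_mol_features at prediction time", call. = FALSE)
  net <- object$nets[[member]]
  fw <- net_forward(net, batches, x_mol = x_mol, training = training,
                    constraints = constraints)
  fw$batches <- batches
  fw
}

# map raw outputs to the response scale, undoing target standardization
task_response <- function(object, raw) {
  spec <- object$spec
  sc <- object$scalers
  switch(spec$loss,
    mse = , bounded_mse = {
      preds <- if (!is.null(sc) && !spec$task %in% c("atom", "bond"))
        unstandardize(raw, sc) else raw
      list(preds = preds)
    },
    mve = {
      u <- mve_unpack(raw, spec$n_tasks)
      mu <- if (!is.null(sc)) unstandardize(u$mu, sc) else u$mu
      v <- if (!is.null(sc)) sweep(u$v, 2, sc$sd^2, "*") else u$v
      list(preds = mu, variance = v)
    },
    evidential = {
      u <- evidential_unpack(raw, spec$n_tasks)
      mu <- if (!is.null(sc)) unstandardize(u$gamma, sc) else u$gamma
      s2 <- if (!is.null(sc)) sc$sd^2 else rep(1, spec$n_tasks)
      al <- sweep(u$beta / (u$alpha - 1), 2, s2, "*")
      ep <- sweep(u$beta / (u$nu * (u$alpha - 1)), 2, s2, "*")
      list(preds = mu, variance = al + ep, aleatoric = al, epistemic = ep)
    },
    bce = , mcc = list(preds = sigmoid(raw)),
    ce = {
      K <- spec$n_classes
      P <- raw * 0
      for (j in seq_len(spec$n_tasks)) {
        cols <- (j - 1L) * K + seq_len(K)
        Z <- raw[, cols, drop = FALSE]
        Z <- Z - apply(Z, 1, max)
        P[, cols] <- exp(Z) / rowSums(exp(Z))
      }
      list(preds = P)
    },
    dirichlet = {
      K <- if (spec$task == "multiclass") spec$n_classes else 2L
      out <- NULL
      unc <- NULL
      for (j in seq_len(spec$n_tasks)) {
        cols <- (j - 1L) * K + seq_len(K)
        alpha <- softplus(raw[, cols, drop = FALSE]) + 1
        S <- rowSums(alpha)
        P <- alpha / S
        if (spec$task == "multiclass") {
          out <- cbind(out, P)
        } else {
          out <- cbind(out, P[, 2])
        }
        unc <- cbind(unc, K / S)   # Dirichlet vacuity as the uncertainty
      }
      list(preds = out, variance = unc)
    },
    sid = , wasserstein = {
      s <- softplus(raw)
      list(preds = s / rowSums(s))
    },
    list(preds = raw))
}

#' Predict from a fitted dmpnn model
#'
#' @param object a fitted `dmpnn`.
#' @param newdata data.frame with the model's SMILES column(s); defaults to
#'   the training data.
#' @param type `"response"` (task-scale predictions, ensemble mean),
#'   `"fingerprint"` (the learned molecular embedding, post-aggregation),
#'   `"ffn_embedding"` (last hidden FFN activation), or `"raw"`.
#' @param members which ensemble members to use (default all).
#' @param constraints molecular net values for constrained atom/bond heads.
#' @param extra_mol_features,extra_atom_features,extra_bond_features extra
#'   features matching those used in training.
#' @param ... unused.
#' @return For molecular tasks a data.frame of predictions (per-task
#'   columns; multiclass adds `.classK` columns; spectra one column per
#'   bin). MVE/evidential fits attach a `variance` attribute. For atom/bond
#'   tasks, a list with one numeric matrix per molecule. Latent types
#'   return a matrix with `fp_0001`-style column names.
#' @export
predict.dmpnn <- function(object, newdata = NULL,
                          type = c("response", "fingerprint",
                                   "ffn_embedding", "raw"),
                          members = NULL, constraints = NULL,
                          extra_mol_features = NULL,
                          extra_atom_features = NULL,
                          extra_bond_features = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  members <- members %||% seq_along(object$nets)
  spec <- object$spec
  outs <- lapply(members, function(m)
    forward_newdata(object, newdata, m, constraints = constraints,
                    extra_mol_features = extra_mol_features,
                    extra_atom_features = extra_atom_features,
                    extra_bond_features = extra_bond_features))
  if (type == "fingerprint") {
    fp <- Reduce(`+`, lapply(outs, `[[`, "fingerprint")) / length(outs)
    colnames(fp) <- sprintf("fp_%04d", seq_len(ncol(fp)))
    return(fp)
  }
  if (type == "ffn_embedding") {
    fe <- Reduce(`+`, lapply(outs, `[[`, "ffn_hidden")) / length(outs)
    if (is.null(fe)) stop("model has no hidden FFN layer", call. = FALSE)
    colnames(fe) <- sprintf("fp_%04d", seq_len(ncol(fe)))
    return(fe)
  }
  raws <- lapply(outs, `[[`, "out")
  if (type == "raw") return(if (length(raws) == 1L) raws[[1]] else raws)

  resp <- lapply(raws, function(r) task_response(object, r))
  preds <- Reduce(`+`, lapply(resp, `[[`, "preds")) / length(resp)
  if (spec$task %in% c("atom", "bond")) {
    groups <- outs[[1]]$groups
    per_mol <- lapply(seq_len(nrow(newdata)), function(i) {
      m <- preds[groups == i, , drop = FALSE]
      colnames(m) <- object$target_columns
      m
    })
    return(per_mol)
  }
  df <- as.data.frame(preds)
  names(df) <- prediction_names(object)
  vars <- lapply(resp, `[[`, "variance")
  if (!is.null(vars[[1]])) {
    attr(df, "variance") <- Reduce(`+`, vars) / length(vars)
  }
  df
}

prediction_names <- function(object) {
  spec <- object$spec
  tc <- object$target_columns
  if (spec$task == "multiclass") {
    unlist(lapply(tc, function(t) paste0(t, ".class",
                                         seq_len(spec$n_classes))))
  } else tc
}

#' @export
print.dmpnn <- function(x, ...) {
  spec <- x$spec
  cat("Directed message passing neural network\n")
  cat("  task:", spec$task, " loss:", spec$loss,
      " targets:", length(x$target_columns), "\n")
  cat("  encoder: hidden", spec$hidden, "| depth", spec$depth,
      "|", spec$activation, "| aggregation", spec$aggregation, "\n")
  cat("  readout:", spec$ffn_layers, "layers x", spec$ffn_hidden, "\n")
  cat("  molecule columns:", paste(x$smiles_columns, collapse = ", "),
      if (any(x$reaction)) "(reaction)" else "", "\n")
  cat("  ensemble size:", length(x$nets),
      "| parameters:", sum(vapply(x$nets[[1]]$par, length, 0L)), "\n")
  if (nrow(x$history[[1]]) > 0L) {
    h <- x$history[[1]]
    cat("  final train loss:", signif(h$train_loss[nrow(h)], 4),
        "| best val", default_val_metric(spec$task), ":",
        signif(min(h$val_metric), 4), "\n")
  }
  invisible(x)
}

#' @export
summary.dmpnn <- function(object, ...) {
  print(object)
  cat("\nSplit sizes: train", length(object$split$train),
      "val", length(object$split$val), "test", length(object$split$test), "\n")
  if (!is.null(object$scalers))
    cat("Target standardization: mean",
        paste(signif(object$scalers$mean, 4), collapse = ", "),
        "| sd", paste(signif(object$scalers$sd, 4), collapse = ", "), "\n")
  if (length(object$frozen) > 0L)
    cat("Frozen tensors:", paste(object$frozen, collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.dmpnn <- function(object, member = 1L, ...) {
  object$nets[[member]]$par
}

#' @export
fitted.dmpnn <- function(object, ...) {
  predict(object, object$data, constraints = object$constraints)
}

#' @export
residuals.dmpnn <- function(object, ...) {
  if (!object$spec$task %in% c("regression")) {
    stop("residuals are defined for regression fits", call. = FALSE)
  }
  obs <- as.matrix(object$data[object$target_columns])
  obs - as.matrix(fitted(object))
}

#' @export
simulate.dmpnn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- predict(object, object$data)
  v <- attr(f, "variance")
  f <- as.matrix(f)
  if (is.null(v)) {
    r <- residuals(object)
    v <- matrix(rep(apply(r, 2, stats::var, na.rm = TRUE),
                    each = nrow(f)), nrow(f))
  }
  sims <- lapply(seq_len(nsim), function(s)
    f + matrix(stats::rnorm(length(f), sd = sqrt(as.vector(v))), nrow(f)))
  names(sims) <- paste0("sim_", seq_len(nsim))
  sims
}

#' @export
plot.dmpnn <- function(x, member = 1L, ...) {
  h <- x$history[[member]]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "loss")
  plot(h$epoch, h$val_metric, type = "l", xlab = "epoch",
       ylab = paste("validation", default_val_metric(x$spec$task)),
       main = "validation")
  invisible(x)
}

# --- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are single JSON files holding the weights, the full
#' architecture spec, target scalers and the featurization vocabulary,
#' version-stamped so incompatible files are rejected on load.
#'
#' @param object a fitted `dmpnn`.
#' @param path file path.
#' @return `load_model` returns the restored `dmpnn` object (without
#'   training data or history).
#' @export
save_model <- function(object, path) {
  # weights as 17-significant-digit strings: doubles round-trip exactly
  ser_par <- function(par) lapply(par, function(p)
    list(dim = dim(p), values = sprintf("%.17g", as.vector(p))))
  obj <- list(
    format = "dmpnn-checkpoint", version = object$version,
    spec = unclass(object$spec),
    scalers = object$scalers,
    feature_config = unclass(object$feature_config),
    smiles_columns = object$smiles_columns,
    target_columns = object$target_columns,
    reaction = object$reaction, reaction_mode = object$reaction_mode,
    extra_features_mode = object$extra_features_mode,
    control = unclass(object$control),
    data_hash = object$data_hash,
    seed = object$control$seed,
    nets = lapply(object$nets, function(nt) ser_par(nt$par)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("no such checkpoint file: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(obj$format, "dmpnn-checkpoint"))
    stop("not a dmpnn checkpoint: ", path, call. = FALSE)
  spec <- obj$spec
  class(spec) <- "dmpnn_spec"
  cfg <- obj$feature_config
  class(cfg) <- "feature_config"
  deser_par <- function(sp) {
    par <- lapply(sp, function(p)
      matrix(as.numeric(p$values), p$dim[1], p$dim[2]))
    par
  }
  nets <- lapply(obj$nets, function(np)
    structure(list(spec = spec, par = deser_par(np)), class = "dmpnn_net"))
  scalers <- obj$scalers
  history <- list(data.frame(epoch = integer(0), train_loss = numeric(0),
                             val_metric = numeric(0), lr = numeric(0)))
  structure(list(
    nets = nets, spec = spec, scalers = scalers, feature_config = cfg,
    smiles_columns = obj$smiles_columns, target_columns = obj$target_columns,
    reaction = obj$reaction, reaction_mode = obj$reaction_mode,
    extra_features_mode = obj$extra_features_mode %||% "extend",
    control = do.call(train_control, obj$control[c(
      "epochs", "batch_size", "init_lr", "max_lr", "final_lr",
      "warmup_epochs", "patience", "ensemble_size", "seed")]),
    split = NULL, history = history, frozen = character(0),
    call = NULL, data = NULL, constraints = NULL,
    data_hash = obj$data_hash, version = obj$version), class = "dmpnn")
}
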