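# End-to-end training: Adam with the warmup/decay learning-rate schedule,
# minibatching, early stopping, ensembling, data splitting (random and
# scaffold), target standardization, transfer learning with freezing, and
# random-search hyperparameter optimization.

#' Training configuration
#'
#' Defaults follow the standard D-MPNN recipe: 30 epochs, batches of 50
#' datapoints, Adam with a learning rate that rises linearly from `init_lr`
#' (1e-4) to `max_lr` (1e-3) over the first two warmup epochs and then
#' decays exponentially to `final_lr` (1e-4) at the last step.
#'
#' @param epochs training epochs.
#' @param batch_size datapoints per optimizer step.
#' @param init_lr,max_lr,final_lr learning-rate schedule endpoints.
#' @param warmup_epochs linear warmup length in epochs.
#' @param patience early-stopping patience in epochs (`Inf` disables).
#' @param ensemble_size number of independently initialized submodels
#'   trained on the same split.
#' @param seed base RNG seed; ensemble member k uses `seed + k - 1` for its
#'   weight initialization and batch shuffling.
#' @return a `train_control` list.
#' @export
train_control <- function(epochs = 30L, batch_size = 50L,
                          init_lr = 1e-4, max_lr = 1e-3, final_lr = 1e-4,
                          warmup_epochs = 2, patience = Inf,
                          ensemble_size = 1L, seed = 1L) {
  stopifnot(init_lr <= max_lr, final_lr <= max_lr, epochs >= 1,
            batch_size >= 1)
  # keep the warmup strictly inside the run so the decay phase exists
  warmup_epochs <- min(warmup_epochs, epochs / 2)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 init_lr = init_lr, max_lr = max_lr, final_lr = final_lr,
                 warmup_epochs = warmup_epochs, patience = patience,
                 ensemble_size = as.integer(ensemble_size),
                 seed = as.integer(seed)),
            class = "train_control")
}

#' Learning rate at a given optimizer step
#'
#' Piecewise linear-then-exponential: linear from `init_lr` to `max_lr`
#' over the warmup steps, then exponential decay parameterized to reach
#' `final_lr` exactly at the last step. Continuous at the warmup boundary.
#'
#' @param step 0-based optimizer step.
#' @param steps_per_epoch optimizer steps per epoch.
#' @param control a [train_control()].
#' @return the learning rate.
#' @export
#' @examples
#' ctl <- train_control()
#' lr_at_step(0, 10, ctl)                    # 1e-4
#' lr_at_step(2 * 10, 10, ctl)               # 1e-3 at end of warmup
#' lr_at_step(30 * 10 - 1, 10, ctl)          # 1e-4 at the final step
lr_at_step <- function(step, steps_per_epoch, control) {
  stopifnot(step >= 0)
  ws <- control$warmup_epochs * steps_per_epoch
  total <- control$epochs * steps_per_epoch
  if (step < ws) {
    control$init_lr + (control$max_lr - control$init_lr) * step / ws
  } else {
    decay_steps <- max(total - 1 - ws, 1)
    gamma <- (control$final_lr / control$max_lr)^(1 / decay_steps)
    control$max_lr * gamma^(min(step, total - 1) - ws)
  }
}

#' Split data into train/validation/test indices
#'
#' @param smiles character vector (only used by the scaffold scheme).
#' @param fractions length-3 vector summing to 1.
#' @param scheme `"random"` or `"scaffold"` (keeps molecules sharing a
#'   Bemis-Murcko scaffold in one partition).
#' @param seed RNG seed; identical seeds give identical indices.
#' @return list of integer vectors `train`, `val`, `test` that are disjoint
#'   and exhaustive.
#' @export
split_data <- function(smiles, fractions = c(0.8, 0.1, 0.1),
                       scheme = c("random", "scaffold"), seed = 0L) {
  scheme <- match.arg(scheme)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop("fractions must be three numbers summing to 1", call. = FALSE)
  n <- length(smiles)
  sizes <- floor(fractions * n)
  sizes[1] <- n - sizes[2] - sizes[3]
  if (any(sizes < 0) || (fractions[2] > 0 && sizes[2] == 0) ||
      (fractions[3] > 0 && sizes[3] == 0))
    stop("requested fractions are infeasible for ", n, " rows", call. = FALSE)
  if (scheme == "random") {
    perm <- with_seed(seed, sample.int(n))
    return(list(train = sort(perm[seq_len(sizes[1])]),
                val = sort(perm[sizes[1] + seq_len(sizes[2])]),
                test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])])))
  }
  keys <- vapply(smiles, scaffold_key, "", USE.NAMES = FALSE)
  groups <- split(seq_len(n), keys)
  ord <- with_seed(seed, {
    sh <- sample(length(groups))   # shuffle ties before the size sort
    sh[order(-lengths(groups)[sh])]
  })
  bins <- list(integer(0), integer(0), integer(0))
  for (gi in ord) {
    fill <- lengths(bins)
    # place the whole scaffold group in the emptiest bin relative to target
    deficit <- sizes - fill
    b <- which.max(deficit)
    bins[[b]] <- c(bins[[b]], groups[[gi]])
  }
  list(train = sort(bins[[1]]), val = sort(bins[[2]]), test = sort(bins[[3]]))
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, frozen = character(0),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# --- dataset assembly -------------------------------------------------------

featurize_column <- function(smiles, reaction = FALSE, config,
                             reaction_mode = "reac_diff",
                             extra_atom_features = NULL,
                             extra_bond_features = NULL,
                             extra_mode = "extend") {
  lapply(seq_along(smiles), function(i) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s))
      stop("missing molecule in row ", i, call. = FALSE)
    if (reaction) reaction_graph(s, config, mode = reaction_mode)
    else mol_graph(s, config,
                   extra_atom_features = extra_atom_features[[i]],
                   extra_bond_features = extra_bond_features[[i]],
                   extra_mode = extra_mode)
  })
}

standardize_fit <- function(y, mask) {
  mu <- sd <- numeric(ncol(y))
  for (j in seq_len(ncol(y))) {
    v <- y[mask[, j], j]
    mu[j] <- mean(v)
    sd[j] <- stats::sd(v)
    if (!is.finite(sd[j]) || sd[j] < 1e-12) sd[j] <- 1
  }
  list(mean = mu, sd = sd)
}

standardize_apply <- function(y, sc) sweep(sweep(y, 2, sc$mean), 2, sc$sd, "/")
unstandardize <- function(y, sc) sweep(sweep(y, 2, sc$sd, "*"), 2, sc$mean, "+")

# --- the fitting function ---------------------------------------------------

#' Fit a directed message passing neural network
#'
#' The main modelling entry point. Molecules (or atom-mapped reactions) in
#' `data` are featurized into directed graphs, encoded by the D-MPNN, and
#' mapped to targets by a feed-forward readout; all weights are trained
#' end-to-end with Adam under the warmup/decay schedule.
#'
#' @param formula optional formula such as `y ~ smiles`,
#'   `cbind(y1, y2) ~ smiles` or `y ~ solute + solvent`; alternatively give
#'   `smiles_columns` and `target_columns`.
#' @param data a data.frame with SMILES column(s) and target column(s). For
#'   atom/bond-level tasks target columns are list columns holding one
#'   numeric vector per molecule.
#' @param task `"regression"` (default), `"binary"`, `"multiclass"`,
#'   `"spectra"`, `"atom"` or `"bond"`.
#' @param smiles_columns,target_columns column names when no formula is
#'   given; targets default to all non-SMILES columns.
#' @param reaction logical (scalar or per SMILES column): treat the column
#'   as atom-mapped reaction SMILES and encode its condensed graph of
#'   reaction.
#' @param reaction_mode CGR feature combination, see [reaction_graph()].
#' @param loss training loss key (see [loss_function()]); defaults by task.
#' @param control a [train_control()].
#' @param hidden,depth,activation,aggregation,norm_scaler,ffn_layers,ffn_hidden,dropout
#'   architecture options, see [dmpnn_spec()].
#' @param mpn_shared share one encoder across molecule columns.
#' @param split fractions for train/validation/test, or a precomputed list
#'   of index vectors.
#' @param split_scheme `"random"` or `"scaffold"`.
#' @param n_classes number of classes (multiclass).
#' @param constraints optional numeric matrix (rows = datapoints) of
#'   molecular net values the per-atom/bond predictions must sum to.
#' @param extra_mol_features optional numeric matrix of molecule-level
#'   features appended to the learned embedding.
#' @param extra_atom_features,extra_bond_features optional per-row lists of
#'   matrices appended to atom/bond feature blocks.
#' @param extra_features_mode `"extend"` or `"replace"`.
#' @param features_only bypass the encoder and fit the FFN on
#'   `extra_mol_features` alone.
#' @param init_model a fitted `dmpnn` model or checkpoint path used to
#'   initialize weights (transfer learning).
#' @param freeze `"none"`, `"mpnn"`, or `list(mpnn = TRUE, ffn_layers = k)`
#'   to freeze the encoder plus the first k FFN layers during training.
#' @param evidential_lambda,sid_threshold loss hyperparameters.
#' @param verbose print per-epoch progress.
#' @return an object of class `dmpnn` with `print`, `summary`, `predict`,
#'   `coef`, `residuals`, `fitted`, `simulate` and `plot` methods.
#' @export
#' @examples
#' \donttest{
#' df <- fixture_dataset(60, task = "atom_count", seed = 1)
#' fit <- dmpnn(y ~ smiles, df, control = train_control(epochs = 3),
#'              hidden = 32, ffn_hidden = 32, verbose = FALSE)
#' predict(fit, df[1:3, ])
#' }
dmpnn <- function(formula = NULL, data, task = "regression",
                  smiles_columns = NULL, target_columns = NULL,
                  reaction = FALSE, reaction_mode = "reac_diff",
                  loss = NULL, control = train_control(),
                  hidden = 300L, depth = 3L, activation = "relu",
                  aggregation = "mean", norm_scaler = 100,
                  ffn_layers = 2L, ffn_hidden = 300L, dropout = 0,
                  mpn_shared = FALSE,
                  split = c(0.8, 0.1, 0.1), split_scheme = "random",
                  n_classes = NULL, constraints = NULL,
                  extra_mol_features = NULL,
                  extra_atom_features = NULL, extra_bond_features = NULL,
                  extra_features_mode = "extend",
                  features_only = FALSE,
                  init_model = NULL, freeze = "none",
                  evidential_lambda = 0.2, sid_threshold = 1e-8,
                  verbose = TRUE) {
  cl <- match.call()
  sch <- resolve_schema(formula, data, smiles_columns, target_columns)
  smiles_columns <- sch$smiles
  target_columns <- sch$targets
  n <- nrow(data)
  if (n < 3L) stop("need at least 3 rows to train", call. = FALSE)
  reaction <- rep_len(reaction, length(smiles_columns))
  if (mpn_shared && length(smiles_columns) < 2L)
    stop("mpn_shared requires at least two molecule columns", call. = FALSE)
  if (nrow(unique(data[smiles_columns])) < 1L) stop("empty data")

  if (task %in% c("atom", "bond") && !is.null(constraints)) {
    constraints <- as.matrix(constraints)
    if (nrow(constraints) != n || ncol(constraints) != length(target_columns))
      stop("constraints must be a ", n, " x ", length(target_columns),
           " matrix", call. = FALSE)
  }
  constrained <- task %in% c("atom", "bond") && !is.null(constraints)

  config <- feature_config()
  graphs <- lapply(seq_along(smiles_columns), function(ci) {
    featurize_column(data[[smiles_columns[ci]]], reaction[ci], config,
                     reaction_mode, extra_atom_features, extra_bond_features,
                     extra_features_mode)
  })
  edge_width <- ncol(graphs[[1]][[1]]$edge_features)
  atom_width <- ncol(graphs[[1]][[1]]$atom_features)

  x_mol <- if (!is.null(extra_mol_features)) as.matrix(extra_mol_features)
  if (!is.null(x_mol) && nrow(x_mol) != n)
    stop("extra_mol_features must have one row per datapoint", call. = FALSE)

  # targets
  tg <- build_targets(data, target_columns, task, n_classes, loss)
  loss <- tg$loss
  n_classes <- tg$n_classes

  spec <- dmpnn_spec(
    task = task, n_tasks = tg$n_tasks, n_classes = n_classes %||% 3L,
    loss = loss, n_mol_columns = length(smiles_columns),
    shared_encoder = mpn_shared, edge_width = edge_width,
    atom_width = atom_width, hidden = hidden, depth = depth,
    activation = activation, aggregation = aggregation,
    norm_scaler = norm_scaler, ffn_layers = ffn_layers,
    ffn_hidden = ffn_hidden, dropout = dropout,
    extra_mol_width = if (is.null(x_mol)) 0L else ncol(x_mol),
    features_only = features_only, constrained = constrained)
  spec$evidential_lambda <- evidential_lambda
  spec$sid_threshold <- sid_threshold

  idx <- if (is.list(split)) split
    else split_data(data[[smiles_columns[1]]], split, split_scheme,
                    control$seed)
  if (length(idx$train) == 0L) stop("empty training split", call. = FALSE)

  # standardization (regression-like tasks) over training targets
  scalers <- NULL
  target <- tg$target
  if (tg$standardize) {
    scalers <- standardize_fit(target[idx$train, , drop = FALSE],
                               tg$mask[idx$train, , drop = FALSE])
    target <- standardize_apply(target, scalers)
    target[!tg$mask] <- 0
  }

  dataset <- list(graphs = graphs, x_mol = x_mol, target = target,
                  mask = tg$mask, relation = tg$relation,
                  constraints = constraints, task = task, idx = idx)

  frozen <- frozen_names(freeze, spec)
  nets <- vector("list", control$ensemble_size)
  history <- vector("list", control$ensemble_size)
  for (m in seq_len(control$ensemble_size)) {
    member_seed <- control$seed + m - 1L
    net <- with_seed(member_seed, init_net(spec))
    if (!is.null(init_model)) net <- warm_start(net, init_model)
    fit <- with_seed(member_seed * 7919L %% 2147483629L,
                     fit_single(net, dataset, spec, control, frozen, verbose,
                                member = m))
    nets[[m]] <- fit$net
    history[[m]] <- fit$history
  }

  structure(list(
    nets = nets, spec = spec, scalers = scalers,
    feature_config = config, smiles_columns = smiles_columns,
    target_columns = target_columns, reaction = reaction,
    reaction_mode = reaction_mode, control = control, split = idx,
    history = history, frozen = frozen, call = cl, data = data,
    constraints = constraints,
    data_hash = dataset_hash(data, smiles_columns, target_columns),
    extra_features_mode = extra_features_mode,
    version = "1"), class = "dmpnn")
}

resolve_schema <- function(formula, data, smiles_columns, target_columns) {
  if (!is.null(formula)) {
    tms <- stats::terms(formula, data = data)
    rhs <- attr(tms, "term.labels")
    lhs_expr <- formula[[2]]
    lhs <- if (is.call(lhs_expr) && identical(lhs_expr[[1]], as.name("cbind")))
      vapply(as.list(lhs_expr)[-1], deparse, "") else deparse(lhs_expr)
    smiles_columns <- rhs
    target_columns <- lhs
  }
  if (is.null(smiles_columns))
    stop("give a formula or smiles_columns", call. = FALSE)
  missing_cols <- setdiff(smiles_columns, names(data))
  if (length(missing_cols) > 0L)
    stop("SMILES column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(target_columns))
    target_columns <- setdiff(names(data), smiles_columns)
  if (length(target_columns) == 0L)
    stop("no target columns", call. = FALSE)
  miss_t <- setdiff(target_columns, names(data))
  if (length(miss_t) > 0L)
    stop("target column(s) not in data: ", paste(miss_t, collapse = ", "),
         call. = FALSE)
  list(smiles = smiles_columns, targets = target_columns)
}

build_targets <- function(data, target_columns, task, n_classes, loss) {
  if (task %in% c("atom", "bond")) {
    target <- lapply(seq_len(nrow(data)), function(i) {
      sapply(target_columns, function(tc) data[[tc]][[i]], simplify = FALSE)
    })
    # atom/bond targets train in raw units: an affine standardization would
    # break the exactness of molecular sum constraints
    return(list(target = target, mask = NULL, relation = NULL,
                n_tasks = length(target_columns),
                loss = loss %||% "mse", n_classes = n_classes,
                standardize = FALSE))
  }
  n <- nrow(data)
  nt <- length(target_columns)
  raw <- data[target_columns]
  is_char <- vapply(raw, is.character, TRUE)
  relation <- NULL
  if (task == "regression" && any(is_char)) {
    # inequality-bounded targets
    value <- matrix(NA_real_, n, nt)
    relation <- matrix(NA_character_, n, nt)
    for (j in seq_len(nt)) {
      pb <- parse_bounded_targets(raw[[j]])
      value[, j] <- pb$value
      relation[, j] <- pb$relation
    }
    if (is.null(loss)) loss <- "bounded_mse"
    target <- value
  } else {
    target <- as.matrix(as.data.frame(lapply(raw, as.numeric)))
  }
  mask <- !is.na(target)
  if (task == "multiclass") {
    if (is.null(n_classes)) n_classes <- max(target, na.rm = TRUE)
    if (min(target, na.rm = TRUE) < 1L)
      stop("multiclass targets must be 1-based class indices", call. = FALSE)
    target[is.na(target)] <- 1L
  } else {
    target[is.na(target)] <- 0
  }
  if (is.null(loss)) loss <- default_loss(task)
  list(target = target, mask = mask, relation = relation, n_tasks =
         if (task == "spectra") nt else nt,
       loss = loss, n_classes = n_classes,
       standardize = task == "regression" &&
         loss %in% c("mse", "bounded_mse", "mve", "evidential"))
}

frozen_names <- function(freeze, spec) {
  if (identical(freeze, "none") || isFALSE(freeze)) return(character(0))
  enc_names <- unlist(lapply(seq_len(n_encoders(spec)), function(e)
    paste0("enc", e, ".", c("W_i", "W_h", "W_o", "b_i", "b_h", "b_o"))))
  if (identical(freeze, "mpnn")) return(enc_names)
  if (is.list(freeze)) {
    nms <- if (isTRUE(freeze$mpnn) || is.null(freeze$mpnn)) enc_names
           else character(0)
    k <- freeze$ffn_layers %||% 0L
    if (k > 0L)
      nms <- c(nms, paste0("ffn.", c(paste0("W", seq_len(k)),
                                     paste0("b", seq_len(k)))))
    return(nms)
  }
  stop("freeze must be 'none', 'mpnn', or list(mpnn=, ffn_layers=)",
       call. = FALSE)
}

warm_start <- function(net, init_model) {
  src <- if (is.character(init_model)) load_model(init_model) else init_model
  src_par <- if (inherits(src, "dmpnn")) src$nets[[1]]$par
             else if (inherits(src, "dmpnn_net")) src$par
             else stop("init_model must be a dmpnn fit, net, or checkpoint path",
                       call. = FALSE)
  for (nm in names(net$par)) {
    if (!is.null(src_par[[nm]])) {
      if (!all(dim(src_par[[nm]]) == dim(net$par[[nm]])))
        stop("checkpoint tensor ", nm, " has shape ",
             paste(dim(src_par[[nm]]), collapse = "x"),
             " but the new model expects ",
             paste(dim(net$par[[nm]]), collapse = "x"),
             " (featurization vocabularies or architecture differ)",
             call. = FALSE)
      net$par[[nm]] <- src_par[[nm]]
    }
  }
  net
}

default_val_metric <- function(task) {
  switch(task, regression = "rmse", binary = "auroc", multiclass = "ce",
         spectra = "sid", atom = "rmse", bond = "rmse")
}

# assemble loss inputs for a set of row indices and run forward/backward
batch_forward <- function(net, dataset, rows, training) {
  spec <- net$spec
  batches <- lapply(dataset$graphs, function(gl) batch_graphs(gl[rows]))
  x_mol <- if (!is.null(dataset$x_mol))
    dataset$x_mol[rows, , drop = FALSE]
  cons <- if (!is.null(dataset$constraints))
    dataset$constraints[rows, , drop = FALSE]
  fw <- net_forward(net, batches, x_mol = x_mol, training = training,
                    constraints = cons)
  if (spec$task %in% c("atom", "bond")) {
    tl <- dataset$target[rows]
    # one column per property; rows follow batched atom (or bond) order
    target <- matrix(unlist(lapply(seq_len(spec$n_tasks), function(j)
      unlist(lapply(tl, `[[`, j)))), ncol = spec$n_tasks)
    mask <- !is.na(target)
    extra <- NULL
  } else {
    target <- dataset$target[rows, , drop = FALSE]
    mask <- dataset$mask[rows, , drop = FALSE]
    extra <- if (!is.null(dataset$relation))
      list(relation = dataset$relation[rows, , drop = FALSE])
  }
  list(fw = fw, target = target, mask = mask, extra = extra,
       batches = batches)
}

fit_single <- function(net, dataset, spec, control, frozen, verbose,
                       member = 1L) {
  idx <- dataset$idx
  lossfn <- loss_function(spec$loss, spec$task)
  n_train <- length(idx$train)
  steps_per_epoch <- max(1L, ceiling(n_train / control$batch_size))
  state <- adam_init(net$par)
  step <- 0L
  best_metric <- Inf
  best_par <- net$par
  bad_epochs <- 0L
  vm <- default_val_metric(spec$task)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_metric = numeric(0), lr = numeric(0))
  for (ep in seq_len(control$epochs)) {
    ord <- idx$train[sample.int(n_train)]
    ep_loss <- 0; nb <- 0L
    for (b in seq_len(steps_per_epoch)) {
      rows <- ord[((b - 1L) * control$batch_size + 1L):
                    min(b * control$batch_size, n_train)]
      if (anyNA(rows) || length(rows) == 0L) next
      bf <- batch_forward(net, dataset, rows, training = TRUE)
      L <- lossfn(bf$fw$out, bf$target, bf$mask, spec, bf$extra)
      if (!is.finite(L$value))
        stop("non-finite loss at epoch ", ep, ", step ", b,
             " (try a lower learning rate or check targets)", call. = FALSE)
      grads <- net_backward(net, bf$fw, L$grad)
      lr <- lr_at_step(step, steps_per_epoch, control)
      upd <- adam_step(net$par, grads, state, lr, frozen)
      net$par <- upd$par
      state <- upd$state
      step <- step + 1L
      ep_loss <- ep_loss + L$value; nb <- nb + 1L
    }
    val <- if (length(idx$val) > 0L) {
      evaluate_split(net, dataset, idx$val, spec, vm)
    } else ep_loss / max(nb, 1L)
    score <- if (vm %in% c("auroc", "auprc", "accuracy", "r2")) -val else val
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / max(nb, 1L),
                                   val_metric = val,
                                   lr = lr_at_step(step - 1L, steps_per_epoch,
                                                   control)))
    if (verbose)
      message(sprintf("[member %d] epoch %3d  loss %.5f  val %s %.5f",
                      member, ep, ep_loss / max(nb, 1L), vm, val))
    if (is.finite(score) && score < best_metric - 1e-12) {
      best_metric <- score
      best_par <- net$par
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs > control$patience) break
    }
  }
  net$par <- best_par
  list(net = net, history = hist)
}

# validation metric on preds mapped to the task scale (no unstandardization:
# targets inside `dataset` are already on the training scale)
evaluate_split <- function(net, dataset, rows, spec, metric) {
  bf <- batch_forward(net, dataset, rows, training = FALSE)
  lossfn <- loss_function(spec$loss, spec$task)
  L <- lossfn(bf$fw$out, bf$target, bf$mask, spec, bf$extra)
  if (metric == "sid") {
    return(spectrum_divergence(L$preds, ifelse(bf$mask, bf$target, NA),
                               bf$mask))
  }
  if (spec$task == "multiclass" && metric == "ce") {
    # mean negative log-likelihood of the true class
    K <- spec$n_classes
    tot <- 0; cnt <- 0
    for (j in seq_len(spec$n_tasks)) {
      cols <- (j - 1L) * K + seq_len(K)
      ok <- which(bf$mask[, j])
      tot <- tot + sum(-log(pmax(
        L$preds[cbind(ok, cols[1] - 1L + bf$target[ok, j])], 1e-12)))
      cnt <- cnt + length(ok)
    }
    return(tot / max(cnt, 1))
  }
  evaluation_metric(L$preds, ifelse(bf$mask, bf$target, NA), metric, bf$mask)
}

dataset_hash <- function(data, smiles_columns, target_columns) {
  s <- paste(c(unlist(data[smiles_columns]),
               vapply(data[target_columns], function(x)
                 paste(format(unlist(x)), collapse = ","), "")),
             collapse = "|")
  # small rolling hash; stable across sessions
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
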