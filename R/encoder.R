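# The D-MPNN encoder and readout networks: parameter initialization,
# forward pass over batched graphs, and exact reverse-mode gradients.
#
# All learnable tensors live in one flat named list (`par`), e.g.
# enc1.W_i, enc1.W_h, enc1.W_o, ffn.W1, ffn.b1, ... so the optimizer,
# freezing logic and gradient checks can treat parameters uniformly.

ACTIVATIONS <- list(
  relu = list(f = function(x) pmax(x, 0), df = function(x) (x > 0) * 1),
  leakyrelu = list(f = function(x) ifelse(x > 0, x, 0.1 * x),
                   df = function(x) ifelse(x > 0, 1, 0.1)),
  tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2),
  identity = list(f = identity, df = function(x) x * 0 + 1))

xavier <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

#' Specify a D-MPNN model architecture
#'
#' Collects the architecture hyperparameters: message-passing hidden size
#' `hidden` (default 300), depth `depth` (number of message-passing steps
#' counting the initial edge state, default 3), activation (default ReLU),
#' aggregation (`"mean"` default, `"sum"`, or `"norm"` = sum divided by
#' `norm_scaler`), the feed-forward readout (`ffn_layers` linear layers,
#' default 2, of width `ffn_hidden`, default 300), and the task layout.
#'
#' @param task one of `"regression"`, `"binary"`, `"multiclass"`,
#'   `"spectra"`, `"atom"`, `"bond"`.
#' @param n_tasks number of target columns (bins for spectra).
#' @param n_classes classes per task (multiclass only).
#' @param loss loss key, see [loss_function()]; determines the raw output
#'   width (e.g. MVE doubles it).
#' @param n_mol_columns number of molecule columns per datapoint.
#' @param shared_encoder use one encoder for all molecule columns.
#' @param edge_width,atom_width featurization widths (from the graphs).
#' @param hidden,depth,activation,aggregation,norm_scaler encoder options.
#' @param ffn_layers,ffn_hidden readout options.
#' @param dropout dropout rate applied after every activation in training.
#' @param mpnn_bias,ffn_bias bias flags (defaults off / on).
#' @param extra_mol_width width of additional molecule-level features
#'   appended to the embedding (0 for none).
#' @param features_only bypass featurization/encoder and feed the extra
#'   molecule-level features directly to the FFN.
#' @param constrained (atom/bond tasks) use the attention constraint head.
#' @return a `dmpnn_spec` list.
#' @export
dmpnn_spec <- function(task = "regression", n_tasks = 1L, n_classes = 3L,
                       loss = NULL, n_mol_columns = 1L,
                       shared_encoder = FALSE,
                       edge_width, atom_width,
                       hidden = 300L, depth = 3L, activation = "relu",
                       aggregation = c("mean", "sum", "norm"),
                       norm_scaler = 100,
                       ffn_layers = 2L, ffn_hidden = 300L,
                       dropout = 0,
                       mpnn_bias = FALSE, ffn_bias = TRUE,
                       extra_mol_width = 0L, features_only = FALSE,
                       constrained = FALSE) {
  aggregation <- match.arg(aggregation)
  stopifnot(depth >= 1L, ffn_layers >= 1L, hidden >= 1L)
  if (is.null(loss)) loss <- default_loss(task)
  if (!activation %in% names(ACTIVATIONS))
    stop("unknown activation: ", activation, call. = FALSE)
  structure(list(
    task = task, n_tasks = as.integer(n_tasks),
    n_classes = as.integer(n_classes), loss = loss,
    n_mol_columns = as.integer(n_mol_columns),
    shared_encoder = shared_encoder,
    edge_width = as.integer(edge_width), atom_width = as.integer(atom_width),
    hidden = as.integer(hidden), depth = as.integer(depth),
    activation = activation, aggregation = aggregation,
    norm_scaler = norm_scaler,
    ffn_layers = as.integer(ffn_layers), ffn_hidden = as.integer(ffn_hidden),
    dropout = dropout, mpnn_bias = mpnn_bias, ffn_bias = ffn_bias,
    extra_mol_width = as.integer(extra_mol_width),
    features_only = features_only, constrained = constrained),
    class = "dmpnn_spec")
}

default_loss <- function(task) {
  switch(task, regression = "mse", binary = "bce", multiclass = "ce",
         spectra = "sid", atom = "mse", bond = "mse",
         stop("unknown task: ", task, call. = FALSE))
}

# raw network output width before task activation
output_dim <- function(spec) {
  per_task <- switch(spec$loss,
    mve = 2L, evidential = 4L,
    dirichlet = if (spec$task == "multiclass") spec$n_classes else 2L,
    ce = spec$n_classes,
    1L)
  if (spec$task == "multiclass" && !spec$loss %in% c("ce", "dirichlet"))
    per_task <- spec$n_classes
  spec$n_tasks * per_task
}

n_encoders <- function(spec) {
  if (spec$features_only) 0L
  else if (spec$shared_encoder) 1L else spec$n_mol_columns
}

embedding_width <- function(spec) {
  if (spec$features_only) return(spec$extra_mol_width)
  spec$n_mol_columns * spec$hidden + spec$extra_mol_width
}

#' Initialize model parameters
#'
#' Xavier-uniform weights; biases start at zero. Uses the current RNG state,
#' so seed beforehand for reproducibility.
#'
#' @param spec a [dmpnn_spec()].
#' @return a `dmpnn_net`: the spec plus the flat named parameter list.
#' @export
init_net <- function(spec) {
  par <- list()
  h <- spec$hidden
  for (e in seq_len(n_encoders(spec))) {
    pre <- paste0("enc", e, ".")
    par[[paste0(pre, "W_i")]] <- xavier(spec$edge_width, h)
    par[[paste0(pre, "W_h")]] <- xavier(h, h)
    par[[paste0(pre, "W_o")]] <- xavier(spec$atom_width + h, h)
    if (spec$mpnn_bias) {
      par[[paste0(pre, "b_i")]] <- matrix(0, 1, h)
      par[[paste0(pre, "b_h")]] <- matrix(0, 1, h)
      par[[paste0(pre, "b_o")]] <- matrix(0, 1, h)
    }
  }
  if (spec$task %in% c("atom", "bond")) {
    # one FFN per property, applied to atomic (or symmetrized bond) embeddings
    for (j in seq_len(spec$n_tasks)) {
      pre <- paste0("head", j, ".")
      par <- c(par, ffn_par(pre, h, spec$ffn_hidden, 1L, spec$ffn_layers,
                            spec$ffn_bias))
      if (spec$constrained)
        par[[paste0(pre, "attn")]] <- xavier(h, 1L)
    }
  } else {
    par <- c(par, ffn_par("ffn.", embedding_width(spec), spec$ffn_hidden,
                          output_dim(spec), spec$ffn_layers, spec$ffn_bias))
  }
  structure(list(spec = spec, par = par), class = "dmpnn_net")
}

ffn_par <- function(pre, n_in, n_hidden, n_out, n_layers, bias) {
  par <- list()
  dims_in <- c(n_in, rep(n_hidden, n_layers - 1L))
  dims_out <- c(rep(n_hidden, n_layers - 1L), n_out)
  for (l in seq_len(n_layers)) {
    par[[paste0(pre, "W", l)]] <- xavier(dims_in[l], dims_out[l])
    if (bias) par[[paste0(pre, "b", l)]] <- matrix(0, 1, dims_out[l])
  }
  par
}

# ---------------------------------------------------------------------------
# sparse structure matrices for one batched graph

#' @importFrom Matrix sparseMatrix t
graph_matrices <- function(batch) {
  ne <- batch$n_edges
  na <- batch$n_atoms
  if (ne > 0L) {
    # B[v, k] = 1 when directed edge k points into atom v
    B <- Matrix::sparseMatrix(i = batch$edge_dst, j = seq_len(ne),
                              dims = c(na, ne))
    # A[e, k] = 1 when k points into src(e) and k is not e's reverse twin
    src <- batch$edge_src
    reps <- lengths(batch$incoming[src])
    ii <- rep(seq_len(ne), reps)
    jj <- unlist(batch$incoming[src], use.names = FALSE)
    drop <- jj == batch$rev_index[ii]
    A <- Matrix::sparseMatrix(i = ii[!drop], j = jj[!drop], dims = c(ne, ne))
  } else {
    B <- Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = c(na, 0))
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = c(0, 0))
  }
  list(A = A, B = B)
}

scope_matrix <- function(batch, aggregation, norm_scaler) {
  sizes <- batch$scope[, "size"]
  if (any(sizes == 0L)) stop("empty molecule in batch", call. = FALSE)
  ii <- rep(seq_len(batch$n_mols), sizes)
  w <- switch(aggregation,
              mean = rep(1 / sizes, sizes),
              sum = rep(1, sum(sizes)),
              norm = rep(1 / norm_scaler, sum(sizes)))
  Matrix::sparseMatrix(i = ii, j = seq_len(batch$n_atoms), x = w,
                       dims = c(batch$n_mols, batch$n_atoms))
}

dense <- function(x) as.matrix(x)

drop_mask <- function(nr, nc, p) {
  matrix(stats::rbinom(nr * nc, 1L, 1 - p) / (1 - p), nr, nc)
}

add_bias <- function(Z, b) if (is.null(b)) Z else sweep(Z, 2, as.numeric(b), "+")

# ---------------------------------------------------------------------------
# forward

# One encoder over one batched graph. Returns the atomic embeddings and the
# caches needed for the backward pass.
encoder_forward <- function(par, pre, spec, batch, mats, training = FALSE) {
  act <- ACTIVATIONS[[spec$activation]]
  p <- if (training) spec$dropout else 0
  W_i <- par[[paste0(pre, "W_i")]]
  W_h <- par[[paste0(pre, "W_h")]]
  W_o <- par[[paste0(pre, "W_o")]]
  b_i <- par[[paste0(pre, "b_i")]]
  b_h <- par[[paste0(pre, "b_h")]]
  b_o <- par[[paste0(pre, "b_o")]]

  Ed <- batch$edge_features
  Z0 <- add_bias(Ed %*% W_i, b_i)
  H0 <- act$f(Z0)
  M0 <- if (p > 0) drop_mask(nrow(H0), ncol(H0), p) else NULL
  H0d <- if (is.null(M0)) H0 else H0 * M0

  H <- H0d
  Zs <- vector("list", spec$depth - 1L)
  Ms <- vector("list", spec$depth - 1L)
  masks <- vector("list", spec$depth - 1L)
  Hs <- vector("list", spec$depth - 1L)
  for (t in seq_len(spec$depth - 1L)) {
    Msg <- dense(mats$A %*% H)
    Z <- add_bias(H0d + Msg %*% W_h, b_h)
    Hn <- act$f(Z)
    mk <- if (p > 0) drop_mask(nrow(Hn), ncol(Hn), p) else NULL
    H <- if (is.null(mk)) Hn else Hn * mk
    Zs[[t]] <- Z; Ms[[t]] <- Msg; masks[t] <- list(mk); Hs[[t]] <- H
  }
  HT <- H
  Q <- cbind(batch$atom_features, dense(mats$B %*% HT))
  Zo <- add_bias(Q %*% W_o, b_o)
  Ha <- act$f(Zo)
  Mo <- if (p > 0) drop_mask(nrow(Ha), ncol(Ha), p) else NULL
  Had <- if (is.null(Mo)) Ha else Ha * Mo
  list(atom_embeddings = Had, edge_states = HT,
       cache = list(Ed = Ed, Z0 = Z0, H0 = H0, M0 = M0, H0d = H0d,
                    Zs = Zs, Ms = Ms, masks = masks, Hs = Hs,
                    Q = Q, Zo = Zo, Mo = Mo, mats = mats))
}

encoder_backward <- function(par, pre, spec, batch, fw, dHa) {
  act <- ACTIVATIONS[[spec$activation]]
  cc <- fw$cache
  W_h <- par[[paste0(pre, "W_h")]]
  W_o <- par[[paste0(pre, "W_o")]]
  grads <- list()

  if (!is.null(cc$Mo)) dHa <- dHa * cc$Mo
  dZo <- dHa * act$df(cc$Zo)
  grads[[paste0(pre, "W_o")]] <- crossprod(cc$Q, dZo)
  if (!is.null(par[[paste0(pre, "b_o")]]))
    grads[[paste0(pre, "b_o")]] <- matrix(colSums(dZo), 1)
  dQ <- dZo %*% t(W_o)
  aw <- ncol(batch$atom_features)
  dHT <- dense(Matrix::t(cc$mats$B) %*% dQ[, -(seq_len(aw)), drop = FALSE])

  dW_h <- matrix(0, nrow(W_h), ncol(W_h))
  db_h <- 0
  dH0d <- matrix(0, nrow(cc$H0d), ncol(cc$H0d))
  dH <- dHT
  for (t in rev(seq_len(spec$depth - 1L))) {
    if (!is.null(cc$masks[[t]])) dH <- dH * cc$masks[[t]]
    dZ <- dH * act$df(cc$Zs[[t]])
    dW_h <- dW_h + crossprod(cc$Ms[[t]], dZ)
    db_h <- db_h + colSums(dZ)
    dH0d <- dH0d + dZ
    dH <- dense(Matrix::t(cc$mats$A) %*% (dZ %*% t(W_h)))
  }
  dH0d <- dH0d + dH   # gradient reaching H^0 (directly when depth == 1)
  if (!is.null(cc$M0)) dH0d <- dH0d * cc$M0
  dZ0 <- dH0d * act$df(cc$Z0)
  grads[[paste0(pre, "W_i")]] <- crossprod(cc$Ed, dZ0)
  if (!is.null(par[[paste0(pre, "b_i")]]))
    grads[[paste0(pre, "b_i")]] <- matrix(colSums(dZ0), 1)
  grads[[paste0(pre, "W_h")]] <- dW_h
  if (!is.null(par[[paste0(pre, "b_h")]]))
    grads[[paste0(pre, "b_h")]] <- matrix(db_h, 1)
  grads
}

ffn_forward <- function(par, pre, spec, X, training = FALSE,
                        n_layers = spec$ffn_layers) {
  act <- ACTIVATIONS[[spec$activation]]
  p <- if (training) spec$dropout else 0
  Zs <- vector("list", n_layers)
  As <- vector("list", n_layers)   # post-activation(+dropout) inputs to next
  masks <- vector("list", n_layers)
  inp <- X
  for (l in seq_len(n_layers)) {
    Z <- add_bias(inp %*% par[[paste0(pre, "W", l)]], par[[paste0(pre, "b", l)]])
    Zs[[l]] <- Z
    if (l < n_layers) {
      Hl <- act$f(Z)
      mk <- if (p > 0) drop_mask(nrow(Hl), ncol(Hl), p) else NULL
      inp <- if (is.null(mk)) Hl else Hl * mk
      masks[l] <- list(mk)
      As[[l]] <- inp
    }
  }
  list(out = Zs[[n_layers]],
       hidden = if (n_layers > 1L) As[[n_layers - 1L]] else NULL,
       cache = list(X = X, Zs = Zs, As = As, masks = masks,
                    n_layers = n_layers))
}

ffn_backward <- function(par, pre, spec, fw, dOut) {
  act <- ACTIVATIONS[[spec$activation]]
  cc <- fw$cache
  grads <- list()
  dZ <- dOut
  for (l in rev(seq_len(cc$n_layers))) {
    inp <- if (l == 1L) cc$X else cc$As[[l - 1L]]
    grads[[paste0(pre, "W", l)]] <- crossprod(inp, dZ)
    if (!is.null(par[[paste0(pre, "b", l)]]))
      grads[[paste0(pre, "b", l)]] <- matrix(colSums(dZ), 1)
    if (l > 1L) {
      dA <- dZ %*% t(par[[paste0(pre, "W", l)]])
      if (!is.null(cc$masks[[l - 1L]])) dA <- dA * cc$masks[[l - 1L]]
      dZ <- dA * act$df(cc$Zs[[l - 1L]])
    } else {
      grads[["..dX"]] <- dZ %*% t(par[[paste0(pre, "W", l)]])
    }
  }
  grads
}

# ---------------------------------------------------------------------------
# full network forward/backward
#
# `batches`: list of batched_graph, one per molecule column (possibly length
# 0 in features_only mode). `x_mol`: optional matrix of molecule-level extra
# features (n_mols x extra_mol_width).

net_forward <- function(net, batches, x_mol = NULL, training = FALSE,
                        constraints = NULL) {
  spec <- net$spec
  par <- net$par
  if (spec$task %in% c("atom", "bond"))
    return(net_forward_atomic(net, batches[[1]], training, constraints))

  embeds <- list()
  enc_caches <- list()
  if (!spec$features_only) {
    for (col in seq_len(spec$n_mol_columns)) {
      e <- if (spec$shared_encoder) 1L else col
      pre <- paste0("enc", e, ".")
      batch <- batches[[col]]
      mats <- graph_matrices(batch)
      fw <- encoder_forward(par, pre, spec, batch, mats, training)
      S <- scope_matrix(batch, spec$aggregation, spec$norm_scaler)
      embeds[[col]] <- dense(S %*% fw$atom_embeddings)
      enc_caches[[col]] <- list(fw = fw, S = S, pre = pre, batch = batch)
    }
    Hm <- do.call(cbind, embeds)
    if (!is.null(x_mol) && spec$extra_mol_width > 0L) Hm <- cbind(Hm, x_mol)
  } else {
    Hm <- x_mol
  }
  fw_ffn <- ffn_forward(par, "ffn.", spec, Hm, training)
  list(out = fw_ffn$out,
       fingerprint = Hm,
       ffn_hidden = fw_ffn$hidden,
       cache = list(enc = enc_caches, ffn = fw_ffn, Hm = Hm))
}

net_backward <- function(net, fw, dOut) {
  spec <- net$spec
  par <- net$par
  if (spec$task %in% c("atom", "bond"))
    return(net_backward_atomic(net, fw, dOut))
  grads <- ffn_backward(par, "ffn.", spec, fw$cache$ffn, dOut)
  dHm <- grads[["..dX"]]
  grads[["..dX"]] <- NULL
  if (!spec$features_only) {
    h <- spec$hidden
    for (col in seq_len(spec$n_mol_columns)) {
      ec <- fw$cache$enc[[col]]
      dEmb <- dHm[, (col - 1L) * h + seq_len(h), drop = FALSE]
      dHa <- dense(Matrix::t(ec$S) %*% dEmb)
      g <- encoder_backward(par, ec$pre, spec, ec$batch, ec$fw, dHa)
      for (nm in names(g)) {
        grads[[nm]] <- if (is.null(grads[[nm]])) g[[nm]] else grads[[nm]] + g[[nm]]
      }
    }
  }
  grads
}

# ---------------------------------------------------------------------------
# atom/bond-level path: per-property FFN heads over atomic (or symmetrized
# bond) embeddings, with optional attention-based sum constraint

bond_embed <- function(batch, edge_states) {
  # symmetrized sum of the two directed states, one row per bond
  first <- which(seq_len(batch$n_edges) %% 2L == 1L)
  edge_states[first, , drop = FALSE] +
    edge_states[batch$rev_index[first], , drop = FALSE]
}

net_forward_atomic <- function(net, batch, training = FALSE,
                               constraints = NULL) {
  spec <- net$spec
  par <- net$par
  mats <- graph_matrices(batch)
  fw <- encoder_forward(par, "enc1.", spec, batch, mats, training)
  if (spec$task == "bond") {
    Emb <- bond_embed(batch, fw$edge_states)
    groups <- rep(seq_len(batch$n_mols), batch$edge_scope[, "size"] %/% 2L)
  } else {
    Emb <- fw$atom_embeddings
    groups <- rep(seq_len(batch$n_mols), batch$scope[, "size"])
  }
  preds <- matrix(0, nrow(Emb), spec$n_tasks)
  head_fw <- vector("list", spec$n_tasks)
  attn <- vector("list", spec$n_tasks)
  for (j in seq_len(spec$n_tasks)) {
    pre <- paste0("head", j, ".")
    hf <- ffn_forward(par, pre, spec, Emb, training)
    raw <- hf$out[, 1]
    if (spec$constrained) {
      if (is.null(constraints))
        stop("constrained atom/bond head needs a constraints matrix",
             call. = FALSE)
      sc <- as.numeric(Emb %*% par[[paste0(pre, "attn")]])
      w <- softmax_by_group(sc, groups)
      tot <- rowsum_by(raw, groups, batch$n_mols)
      resid <- constraints[, j] - tot
      preds[, j] <- raw + w * resid[groups]
      attn[[j]] <- list(sc = sc, w = w, resid = resid, raw = raw)
    } else {
      preds[, j] <- raw
    }
    head_fw[[j]] <- hf
  }
  list(out = preds, groups = groups,
       cache = list(fw = fw, head_fw = head_fw, attn = attn, Emb = Emb,
                    batch = batch, mats = mats, groups = groups))
}

softmax_by_group <- function(x, groups) {
  mx <- tapply(x, groups, max)[as.character(groups)]
  e <- exp(x - as.numeric(mx))
  s <- rowsum_by(e, groups, max(groups))
  e / s[groups]
}

rowsum_by <- function(x, groups, n) {
  out <- numeric(n)
  agg <- rowsum(x, groups)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

net_backward_atomic <- function(net, fw, dOut) {
  spec <- net$spec
  par <- net$par
  cc <- fw$cache
  groups <- cc$groups
  grads <- list()
  dEmb <- matrix(0, nrow(cc$Emb), ncol(cc$Emb))
  for (j in seq_len(spec$n_tasks)) {
    pre <- paste0("head", j, ".")
    dpj <- dOut[, j]
    if (spec$constrained) {
      at <- cc$attn[[j]]
      n_mols <- length(at$resid)
      # preds = raw + w * resid[groups], resid = c - sum(raw)
      # d/draw_i: dpj_i - sum_{k in mol} dpj_k w_k  (resid route)
      wsum <- rowsum_by(dpj * at$w, groups, n_mols)
      draw <- dpj - wsum[groups]
      # d/dsc via softmax: dL/dw_i = dpj_i * resid[mol]
      dw <- dpj * at$resid[groups]
      wd <- at$w * dw
      dsc <- wd - at$w * rowsum_by(wd, groups, n_mols)[groups]
      grads[[paste0(pre, "attn")]] <-
        crossprod(cc$Emb, matrix(dsc, ncol = 1))
      dEmb <- dEmb + matrix(dsc, ncol = 1) %*% t(par[[paste0(pre, "attn")]])
    } else {
      draw <- dpj
    }
    g <- ffn_backward(par, pre, spec, cc$head_fw[[j]],
                      matrix(draw, ncol = 1))
    dEmb <- dEmb + g[["..dX"]]
    g[["..dX"]] <- NULL
    grads <- c(grads, g)
  }
  if (spec$task == "bond") {
    ne <- cc$batch$n_edges
    dHT <- matrix(0, ne, spec$hidden)
    first <- which(seq_len(ne) %% 2L == 1L)
    dHT[first, ] <- dEmb
    dHT[cc$batch$rev_index[first], ] <-
      dHT[cc$batch$rev_index[first], ] + dEmb
    # route through W_o path is absent for bonds: gradient enters edge states
    genc <- encoder_backward_edges(par, "enc1.", spec, cc$batch, cc$fw, dHT)
  } else {
    genc <- encoder_backward(par, "enc1.", spec, cc$batch, cc$fw, dEmb)
  }
  for (nm in names(genc)) {
    grads[[nm]] <- if (is.null(grads[[nm]])) genc[[nm]] else grads[[nm]] + genc[[nm]]
  }
  grads
}

# gradient entering at the final edge states (bond-level heads): same loop
# as encoder_backward but skipping the W_o atom-embedding stage
encoder_backward_edges <- function(par, pre, spec, batch, fw, dHT) {
  act <- ACTIVATIONS[[spec$activation]]
  cc <- fw$cache
  W_h <- par[[paste0(pre, "W_h")]]
  grads <- list()
  dW_h <- matrix(0, nrow(W_h), ncol(W_h))
  db_h <- 0
  dH0d <- matrix(0, nrow(cc$H0d), ncol(cc$H0d))
  dH <- dHT
  for (t in rev(seq_len(spec$depth - 1L))) {
    if (!is.null(cc$masks[[t]])) dH <- dH * cc$masks[[t]]
    dZ <- dH * act$df(cc$Zs[[t]])
    dW_h <- dW_h + crossprod(cc$Ms[[t]], dZ)
    db_h <- db_h + colSums(dZ)
    dH0d <- dH0d + dZ
    dH <- dense(Matrix::t(cc$mats$A) %*% (dZ %*% t(W_h)))
  }
  dH0d <- dH0d + dH
  if (!is.null(cc$M0)) dH0d <- dH0d * cc$M0
  dZ0 <- dH0d * act$df(cc$Z0)
  grads[[paste0(pre, "W_i")]] <- crossprod(cc$Ed, dZ0)
  if (!is.null(par[[paste0(pre, "b_i")]]))
    grads[[paste0(pre, "b_i")]] <- matrix(colSums(dZ0), 1)
  grads[[paste0(pre, "W_h")]] <- dW_h
  if (!is.null(par[[paste0(pre, "b_h")]]))
    grads[[paste0(pre, "b_h")]] <- matrix(db_h, 1)
  # W_o receives no gradient on this path but must be present for shape
  grads[[paste0(pre, "W_o")]] <- matrix(0, spec$atom_width + spec$hidden,
                                        spec$hidden)
  if (!is.null(par[[paste0(pre, "b_o")]]))
    grads[[paste0(pre, "b_o")]] <- matrix(0, 1, spec$hidden)
  grads
}
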