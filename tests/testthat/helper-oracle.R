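# Independent reference implementations used as oracles. These deliberately
# avoid the package's vectorized/sparse code paths: everything is plain
# double loops over edges and atoms.

# index-free loop-based D-MPNN forward pass for a single (unbatched) graph;
# mirrors the mathematical definition edge by edge
naive_dmpnn_forward <- function(net, g, enc = "enc1.") {
  spec <- net$spec
  p <- net$par
  act <- switch(spec$activation,
                relu = function(x) pmax(x, 0),
                tanh = tanh,
                identity = identity)
  ne <- g$n_edges
  h <- spec$hidden
  H0 <- matrix(0, max(ne, 1L), h)
  for (e in seq_len(ne)) {
    H0[e, ] <- act(as.numeric(g$edge_features[e, , drop = FALSE] %*%
                                p[[paste0(enc, "W_i")]]))
  }
  H <- H0
  for (t in seq_len(spec$depth - 1L)) {
    Hn <- matrix(0, max(ne, 1L), h)
    for (e in seq_len(ne)) {
      v <- g$edge_src[e]
      m <- numeric(h)
      for (k in seq_len(ne)) {
        if (g$edge_dst[k] == v && k != g$rev_index[e]) m <- m + H[k, ]
      }
      Hn[e, ] <- act(H0[e, ] + as.numeric(m %*% p[[paste0(enc, "W_h")]]))
    }
    H <- Hn
  }
  Ha <- matrix(0, g$n_atoms, h)
  for (v in seq_len(g$n_atoms)) {
    s <- numeric(h)
    for (k in seq_len(ne)) if (g$edge_dst[k] == v) s <- s + H[k, ]
    q <- c(g$atom_features[v, ], s)
    Ha[v, ] <- act(as.numeric(q %*% p[[paste0(enc, "W_o")]]))
  }
  hm <- switch(spec$aggregation,
               mean = colMeans(Ha),
               sum = colSums(Ha),
               norm = colSums(Ha) / spec$norm_scaler)
  inp <- hm
  nl <- spec$ffn_layers
  for (l in seq_len(nl)) {
    z <- as.numeric(inp %*% p[[paste0("ffn.W", l)]])
    b <- p[[paste0("ffn.b", l)]]
    if (!is.null(b)) z <- z + as.numeric(b)
    inp <- if (l < nl) act(z) else z
  }
  inp
}

# finite-difference gradient check over every learnable tensor; returns the
# worst relative error
finite_diff_check <- function(net, batches, dOut = NULL, cons = NULL,
                              n_per_tensor = 8L, eps = 1e-6) {
  fw <- dmpnn:::net_forward(net, batches, constraints = cons)
  if (is.null(dOut)) dOut <- fw$out
  gr <- dmpnn:::net_backward(net, fw, dOut)
  worst <- 0
  for (nm in names(net$par)) {
    W <- net$par[[nm]]
    idxs <- if (length(W) <= n_per_tensor) seq_along(W)
            else sample(length(W), n_per_tensor)
    for (idx in idxs) {
      np <- net
      np$par[[nm]][idx] <- W[idx] + eps
      lp <- sum(dmpnn:::net_forward(np, batches, constraints = cons)$out * dOut)
      np$par[[nm]][idx] <- W[idx] - eps
      lm <- sum(dmpnn:::net_forward(np, batches, constraints = cons)$out * dOut)
      fd <- (lp - lm) / (2 * eps)
      an <- gr[[nm]][idx]
      worst <- max(worst, abs(fd - an) / max(1e-8, abs(fd) + abs(an)))
    }
  }
  worst
}

# optimal-transport cost between two 1D histograms by the northwest-corner
# rule, which is exact for the Monge cost |i - j|; independent of the
# package's cumulative-sum formula
transport_oracle <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  i <- 1L; j <- 1L; cost <- 0
  pi_ <- p; qi <- q
  while (i <= length(p) && j <= length(q)) {
    f <- min(pi_[i], qi[j])
    cost <- cost + f * abs(i - j)
    pi_[i] <- pi_[i] - f
    qi[j] <- qi[j] - f
    if (pi_[i] <= 1e-15) i <- i + 1L else j <- j + 1L
  }
  cost
}

# central-difference gradient of a loss function w.r.t. raw outputs
loss_fd_check <- function(f, raw, target, mask, spec, extra = NULL,
                          eps = 1e-6) {
  r <- f(raw, target, mask, spec, extra)
  worst <- 0
  for (idx in seq_along(raw)) {
    rp <- raw; rp[idx] <- rp[idx] + eps
    rm <- raw; rm[idx] <- rm[idx] - eps
    fd <- (f(rp, target, mask, spec, extra)$value -
             f(rm, target, mask, spec, extra)$value) / (2 * eps)
    worst <- max(worst, abs(fd - r$grad[idx]) /
                   max(1e-6, abs(fd) + abs(r$grad[idx])))
  }
  worst
}

# small shared fixture set, built once per test run
fixture_smiles_20 <- make_molecule_set(20, seed = 101)
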