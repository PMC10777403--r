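# D-MPNN forward-pass correctness (loop-based oracle), atom-order
# invariance, gradient exactness, readout activations, multimolecule
# composition, constrained atom/bond heads, latent extraction

cfg <- feature_config()

small_spec <- function(...) {
  dmpnn_spec(edge_width = cfg$atom_width + cfg$bond_width,
             atom_width = cfg$atom_width, hidden = 8L, depth = 3L,
             ffn_hidden = 6L, ...)
}

test_that("initial edge states follow tau(W_i e) including degenerate cases", {
  g <- mol_graph("CC")
  b <- batch_graphs(list(g))
  spec <- small_spec()
  net <- with_seed(1, init_net(spec))
  mats <- dmpnn:::graph_matrices(b)
  fw <- dmpnn:::encoder_forward(net$par, "enc1.", spec, b, mats)
  # hand-computed single-edge product under ReLU
  manual <- pmax(as.numeric(g$edge_features[1, , drop = FALSE] %*%
                              net$par[["enc1.W_i"]]), 0)
  expect_equal(fw$cache$H0[1, ], manual, tolerance = 1e-12)
  # zero weights give tau(0) = 0
  net0 <- net
  net0$par[["enc1.W_i"]][] <- 0
  fw0 <- dmpnn:::encoder_forward(net0$par, "enc1.", spec, b, mats)
  expect_true(all(fw0$cache$H0 == 0))
})

test_that("reverse-edge exclusion leaves ethane messages empty and routes one
          message along a path", {
  spec <- small_spec()
  net <- with_seed(2, init_net(spec))
  b2 <- batch_graphs(list(mol_graph("CC")))
  m2 <- dmpnn:::graph_matrices(b2)
  # each directed edge's only incoming edge is its own reverse -> A is empty
  expect_equal(Matrix::nnzero(m2$A), 0)
  b3 <- batch_graphs(list(mol_graph("CCC")))
  m3 <- dmpnn:::graph_matrices(b3)
  # path C1-C2-C3: the two center-outward edges receive exactly one message
  counts <- Matrix::rowSums(m3$A)
  expect_setequal(as.numeric(counts), c(0, 0, 1, 1))
})

test_that("full forward pass matches the loop-based oracle on small molecules", {
  mols <- c("C", "CC", "CCO", "CC(C)C", "C1CC1", "c1ccccc1", "C=CC=C",
            "OCC(O)CO")
  spec <- small_spec()
  with_seed(33, {
    for (rep in 1:5) {
      net <- init_net(spec)
      for (smi in sample(mols, 4)) {
        g <- mol_graph(smi)
        fw <- dmpnn:::net_forward(net, list(batch_graphs(list(g))))
        expect_equal(as.numeric(fw$out), naive_dmpnn_forward(net, g),
                     tolerance = 1e-6, info = smi)
      }
    }
  })
})

test_that("atomic embeddings respect symmetry and the isolated-atom case", {
  spec <- small_spec()
  net <- with_seed(5, init_net(spec))
  bb <- batch_graphs(list(mol_graph("c1ccccc1")))
  fw <- dmpnn:::encoder_forward(net$par, "enc1.", spec, bb,
                                dmpnn:::graph_matrices(bb))
  for (i in 2:6)
    expect_equal(fw$atom_embeddings[i, ], fw$atom_embeddings[1, ],
                 tolerance = 1e-10)
  # isolated atom: incoming sum is zero, h_v = tau(W_o cat(x_v, 0))
  b1 <- batch_graphs(list(mol_graph("C")))
  fw1 <- dmpnn:::encoder_forward(net$par, "enc1.", spec, b1,
                                 dmpnn:::graph_matrices(b1))
  q <- c(b1$atom_features[1, ], numeric(spec$hidden))
  expect_equal(fw1$atom_embeddings[1, ],
               pmax(as.numeric(q %*% net$par[["enc1.W_o"]]), 0),
               tolerance = 1e-12)
})

test_that("aggregation modes obey their algebra", {
  spec_m <- small_spec(aggregation = "mean")
  net <- with_seed(6, init_net(spec_m))
  b <- batch_graphs(list(mol_graph("c1ccccc1"), mol_graph("C")))
  fw <- dmpnn:::net_forward(net, list(b))
  emb_mean <- fw$fingerprint
  net_s <- net; net_s$spec$aggregation <- "sum"
  emb_sum <- dmpnn:::net_forward(net_s, list(b))$fingerprint
  # benzene: all atomic embeddings equal -> sum = 6 x mean
  expect_equal(emb_sum[1, ], 6 * emb_mean[1, ], tolerance = 1e-9)
  # single atom: mean = sum
  expect_equal(emb_sum[2, ], emb_mean[2, ], tolerance = 1e-12)
  net_n <- net; net_n$spec$aggregation <- "norm"; net_n$spec$norm_scaler <- 6
  emb_norm <- dmpnn:::net_forward(net_n, list(b))$fingerprint
  expect_equal(emb_norm[1, ], emb_mean[1, ], tolerance = 1e-9)
})

test_that("molecular embeddings are invariant to the SMILES atom order", {
  spec <- small_spec()
  net <- with_seed(7, init_net(spec))
  for (smi in fixture_smiles_20[1:8]) {
    base <- dmpnn:::net_forward(net,
      list(batch_graphs(list(mol_graph(smi)))))$fingerprint
    for (alt in unique(shuffle_smiles(smi, 4, seed = 11))) {
      alt_emb <- dmpnn:::net_forward(net,
        list(batch_graphs(list(mol_graph(alt)))))$fingerprint
      expect_equal(as.numeric(alt_emb), as.numeric(base), tolerance = 1e-6,
                   info = paste(smi, "->", alt))
    }
  }
})

test_that("readout activations produce valid probabilities", {
  with_seed(8, {
    specb <- small_spec(task = "binary", n_tasks = 2, loss = "bce")
    netb <- init_net(specb)
    b <- batch_graphs(lapply(fixture_smiles_20[1:6], mol_graph))
    raw <- dmpnn:::net_forward(netb, list(b))$out
    p <- dmpnn:::sigmoid(raw)
    expect_true(all(p > 0 & p < 1))
    specm <- small_spec(task = "multiclass", n_tasks = 2, n_classes = 4,
                        loss = "ce")
    netm <- init_net(specm)
    for (draw in 1:5) {
      netm2 <- init_net(specm)
      rawm <- dmpnn:::net_forward(netm2, list(b))$out
      L <- loss_function("ce", "multiclass")(
        rawm, matrix(1L, nrow(rawm), 2), matrix(TRUE, nrow(rawm), 2),
        specm, NULL)
      sums <- cbind(rowSums(L$preds[, 1:4]), rowSums(L$preds[, 5:8]))
      expect_true(all(abs(sums - 1) < 1e-6))
    }
    # zero weights and biases: uniform class scores
    netm$par[["ffn.W2"]][] <- 0
    netm$par[["ffn.b2"]][] <- 0
    raw0 <- dmpnn:::net_forward(netm, list(b))$out
    L0 <- loss_function("ce", "multiclass")(
      raw0, matrix(1L, nrow(raw0), 2), matrix(TRUE, nrow(raw0), 2),
      specm, NULL)
    expect_true(all(abs(L0$preds - 0.25) < 1e-12))
  })
})

test_that("gradients match finite differences on a 2-molecule batch", {
  b <- batch_graphs(list(mol_graph("CCO"), mol_graph("c1ccccc1")))
  with_seed(9, {
    for (spec in list(small_spec(n_tasks = 2),
                      small_spec(task = "binary", loss = "bce"),
                      small_spec(mpnn_bias = TRUE, activation = "tanh"))) {
      net <- init_net(spec)
      expect_lt(finite_diff_check(net, list(b)), 1e-4)
    }
  })
})

test_that("multimolecule composition concatenates embeddings in column order", {
  with_seed(10, {
    spec <- small_spec(n_mol_columns = 2, shared_encoder = TRUE)
    net <- init_net(spec)
    b1 <- batch_graphs(list(mol_graph("CCO")))
    # identical columns with a shared encoder: identical halves
    fw <- dmpnn:::net_forward(net, list(b1, b1))
    h <- spec$hidden
    expect_equal(fw$fingerprint[, 1:h], fw$fingerprint[, h + 1:h])
    # swapping non-identical columns changes the output
    spec2 <- small_spec(n_mol_columns = 2)
    net2 <- init_net(spec2)
    ba <- batch_graphs(list(mol_graph("CCO")))
    bb <- batch_graphs(list(mol_graph("c1ccccc1")))
    o1 <- dmpnn:::net_forward(net2, list(ba, bb))$out
    o2 <- dmpnn:::net_forward(net2, list(bb, ba))$out
    expect_gt(max(abs(o1 - o2)), 1e-6)
    # separate encoders: each column's embedding equals that encoder run alone
    fw12 <- dmpnn:::net_forward(net2, list(ba, bb))
    enc1 <- dmpnn:::encoder_forward(net2$par, "enc1.", spec2, ba,
                                    dmpnn:::graph_matrices(ba))
    S1 <- dmpnn:::scope_matrix(ba, "mean", 100)
    half1 <- as.matrix(S1 %*% enc1$atom_embeddings)
    expect_equal(fw12$fingerprint[, 1:h], half1[1, ], tolerance = 1e-10,
                 ignore_attr = TRUE)
    # gradient correctness for the shared-encoder path
    expect_lt(finite_diff_check(net, list(ba, bb)), 1e-4)
  })
})

test_that("constrained atom heads sum exactly to the constraint", {
  with_seed(11, {
    spec <- small_spec(task = "atom", n_tasks = 2, constrained = TRUE)
    net <- init_net(spec)
    b <- batch_graphs(lapply(c("CCO", "c1ccccc1", "CC(C)CC"), mol_graph))
    cons <- matrix(stats::rnorm(6), 3, 2)
    fw <- dmpnn:::net_forward(net, list(b), constraints = cons)
    sums <- rowsum(fw$out, fw$groups)
    expect_equal(unname(as.matrix(sums)), cons, tolerance = 1e-6)
    # single-atom molecule: prediction is exactly the constraint
    b1 <- batch_graphs(list(mol_graph("C")))
    c1 <- matrix(c(3.25, -1), 1, 2)
    fw1 <- dmpnn:::net_forward(net, list(b1), constraints = c1)
    expect_equal(as.numeric(fw1$out), as.numeric(c1), tolerance = 1e-9)
    # unconstrained heads return the raw per-atom FFN outputs
    specu <- small_spec(task = "atom", n_tasks = 1)
    netu <- init_net(specu)
    fwu <- dmpnn:::net_forward(netu, list(b))
    emb <- dmpnn:::encoder_forward(netu$par, "enc1.", specu, b,
                                   dmpnn:::graph_matrices(b))$atom_embeddings
    manual <- dmpnn:::ffn_forward(netu$par, "head1.", specu, emb)$out
    expect_equal(fwu$out[, 1], manual[, 1], tolerance = 1e-12)
    # constraint requested but not supplied
    expect_error(dmpnn:::net_forward(net, list(b)), "constraints")
  })
})

test_that("bond-level heads use symmetrized directed states and exact
          gradients", {
  with_seed(12, {
    spec <- small_spec(task = "bond", n_tasks = 1)
    net <- init_net(spec)
    b <- batch_graphs(list(mol_graph("CCO"), mol_graph("CCCC")))
    fw <- dmpnn:::net_forward(net, list(b))
    expect_equal(nrow(fw$out), b$n_edges / 2L)
    expect_lt(finite_diff_check(net, list(b)), 1e-4)
  })
})

test_that("latents have the documented widths and are deterministic", {
  df <- fixture_dataset(30, seed = 21)
  fit <- dmpnn(y ~ smiles, df, control = train_control(epochs = 2, seed = 4),
               hidden = 16, ffn_hidden = 12, verbose = FALSE)
  fp <- predict(fit, df[1:5, ], type = "fingerprint")
  expect_equal(dim(fp), c(5L, 16L))
  expect_equal(colnames(fp)[1], "fp_0001")
  fe <- predict(fit, df[1:5, ], type = "ffn_embedding")
  expect_equal(dim(fe), c(5L, 12L))
  expect_identical(fp, predict(fit, df[1:5, ], type = "fingerprint"))
})

test_that("fixed-embedding bypass uses the molecular features verbatim", {
  with_seed(13, {
    n <- 12
    xm <- matrix(stats::rnorm(n * 5), n, 5)
    df <- data.frame(smiles = make_molecule_set(n, seed = 2),
                     y = stats::rnorm(n))
    fit <- dmpnn(y ~ smiles, df, features_only = TRUE,
                 extra_mol_features = xm, split = list(train = 1:10,
                                                       val = 11:12,
                                                       test = integer(0)),
                 control = train_control(epochs = 2, seed = 1),
                 hidden = 8, ffn_hidden = 8, verbose = FALSE)
    fp <- predict(fit, df, type = "fingerprint", extra_mol_features = xm)
    expect_equal(unname(fp), unname(xm))
  })
})
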