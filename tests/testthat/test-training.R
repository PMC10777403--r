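# learning-rate schedule, splits, standardization, optimization behavior,
# transfer learning, and hyperparameter search

test_that("learning-rate schedule hits its endpoints and is continuous", {
  ctl <- train_control()   # 30 epochs, warmup 2, 1e-4 -> 1e-3 -> 1e-4
  spe <- 10L
  expect_equal(lr_at_step(0, spe, ctl), 1e-4)
  expect_equal(lr_at_step(2 * spe, spe, ctl), 1e-3)
  expect_equal(lr_at_step(30 * spe - 1, spe, ctl), 1e-4, tolerance = 1e-12)
  # continuity at the warmup boundary
  gap <- abs(lr_at_step(2 * spe, spe, ctl) - lr_at_step(2 * spe - 1, spe, ctl))
  expect_lt(gap, (1e-3 - 1e-4) / (2 * spe) + 1e-9)
  # monotone up then down
  lrs <- vapply(0:(30 * spe - 1), lr_at_step, 0, spe, ctl)
  expect_true(all(diff(lrs[1:(2 * spe + 1)]) > 0))
  expect_true(all(diff(lrs[(2 * spe + 1):(30 * spe)]) < 0))
})

test_that("random splits are seed-reproducible, disjoint and exhaustive", {
  smi <- make_molecule_set(100, seed = 5)
  s1 <- split_data(smi, c(0.8, 0.1, 0.1), "random", seed = 9)
  s2 <- split_data(smi, c(0.8, 0.1, 0.1), "random", seed = 9)
  expect_identical(s1, s2)
  expect_equal(lengths(s1), c(train = 80L, val = 10L, test = 10L))
  expect_setequal(unlist(s1), 1:100)
  s3 <- split_data(smi, c(0.8, 0.1, 0.1), "random", seed = 10)
  expect_false(identical(s1$train, s3$train))
  expect_error(split_data(smi[1:4], c(0.9, 0.05, 0.05)), "infeasible")
  expect_error(split_data(smi, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("scaffold splits never separate molecules sharing a scaffold", {
  smi <- make_molecule_set(80, seed = 6)
  s <- split_data(smi, c(0.7, 0.15, 0.15), "scaffold", seed = 3)
  expect_setequal(unlist(s), seq_along(smi))
  keys <- vapply(smi, scaffold_key, "")
  part <- integer(length(smi))
  part[s$train] <- 1L; part[s$val] <- 2L; part[s$test] <- 3L
  for (k in unique(keys)) {
    expect_length(unique(part[keys == k]), 1L)
  }
})

test_that("target standardization round-trips to 1e-10", {
  with_seed(50, {
    y <- matrix(stats::rnorm(40, 5, 3), 20, 2)
    mask <- matrix(TRUE, 20, 2)
    sc <- dmpnn:::standardize_fit(y, mask)
    z <- dmpnn:::standardize_apply(y, sc)
    expect_equal(colMeans(z), c(0, 0), tolerance = 1e-10)
    expect_equal(dmpnn:::unstandardize(z, sc), y, tolerance = 1e-10)
  })
})

test_that("predictions come back in original units", {
  df <- fixture_dataset(100, seed = 7)
  fit <- dmpnn(y ~ smiles, df, control = train_control(epochs = 30, seed = 2),
               hidden = 48, ffn_hidden = 48, verbose = FALSE)
  p <- predict(fit, df)
  # after modest training the predictions live on the atom-count scale
  expect_gt(stats::cor(p$y, df$y), 0.7)
  expect_lt(abs(mean(p$y) - mean(df$y)), 2)
})

test_that("training loss decreases over the first epochs for most seeds", {
  df <- fixture_dataset(60, seed = 8)
  drops <- vapply(1:6, function(s) {
    fit <- dmpnn(y ~ smiles, df, control = train_control(epochs = 5, seed = s),
                 hidden = 24, ffn_hidden = 24, verbose = FALSE)
    h <- fit$history[[1]]
    h$train_loss[5] < h$train_loss[1]
  }, TRUE)
  expect_gte(mean(drops), 5 / 6)
})

test_that("ensembles differ in weights but share config and split", {
  df <- fixture_dataset(40, seed = 9)
  fit <- dmpnn(y ~ smiles, df,
               control = train_control(epochs = 2, ensemble_size = 2, seed = 3),
               hidden = 12, ffn_hidden = 8, verbose = FALSE)
  expect_length(fit$nets, 2L)
  expect_gt(max(abs(fit$nets[[1]]$par[["enc1.W_i"]] -
                      fit$nets[[2]]$par[["enc1.W_i"]])), 1e-6)
  expect_identical(fit$nets[[1]]$spec, fit$nets[[2]]$spec)
})

test_that("training is deterministic under a fixed seed", {
  df <- fixture_dataset(40, seed = 10)
  f1 <- dmpnn(y ~ smiles, df, control = train_control(epochs = 3, seed = 11),
              hidden = 12, ffn_hidden = 8, verbose = FALSE)
  f2 <- dmpnn(y ~ smiles, df, control = train_control(epochs = 3, seed = 11),
              hidden = 12, ffn_hidden = 8, verbose = FALSE)
  expect_equal(f1$nets[[1]]$par, f2$nets[[1]]$par, tolerance = 1e-12)
})

test_that("early stopping restores the best checkpoint and stops in time", {
  df <- fixture_dataset(60, seed = 12)
  fit <- dmpnn(y ~ smiles, df,
               control = train_control(epochs = 40, seed = 1, patience = 3),
               hidden = 16, ffn_hidden = 12, verbose = FALSE)
  h <- fit$history[[1]]
  best <- which.min(h$val_metric)
  # never trained more than patience+1 epochs past the best epoch
  expect_lte(nrow(h), best + 4)
})

test_that("NaN-inducing configurations abort with a diagnostic", {
  df <- fixture_dataset(30, seed = 13)
  df$y <- df$y * 1e154   # overflows the squared error
  expect_error(
    dmpnn(y ~ smiles, df, control = train_control(epochs = 2, seed = 1),
          hidden = 8, ffn_hidden = 8, verbose = FALSE,
          split = list(train = 1:28, val = 29:30, test = integer(0))),
    "non-finite loss")
})

test_that("schema validation rejects broken inputs", {
  df <- fixture_dataset(20, seed = 14)
  expect_error(dmpnn(y ~ nope, df, verbose = FALSE), "not in data")
  expect_error(dmpnn(data = df, smiles_columns = "smiles",
                     target_columns = "zzz", verbose = FALSE),
               "not in data")
  expect_error(dmpnn(y ~ smiles, df, mpn_shared = TRUE, verbose = FALSE),
               "at least two molecule columns")
  df2 <- df; df2$smiles[3] <- ""
  expect_error(dmpnn(y ~ smiles, df2,
                     control = train_control(epochs = 1), verbose = FALSE),
               "missing molecule in row 3")
})

test_that("frozen encoder tensors are bit-identical after fine-tuning", {
  df <- fixture_dataset(50, seed = 15)
  base <- dmpnn(y ~ smiles, df, control = train_control(epochs = 3, seed = 5),
                hidden = 16, ffn_hidden = 12, verbose = FALSE)
  tuned <- dmpnn(y ~ smiles, df,
                 control = train_control(epochs = 3, seed = 6),
                 hidden = 16, ffn_hidden = 12, verbose = FALSE,
                 init_model = base, freeze = "mpnn")
  for (nm in c("enc1.W_i", "enc1.W_h", "enc1.W_o")) {
    expect_identical(tuned$nets[[1]]$par[[nm]], base$nets[[1]]$par[[nm]])
  }
  expect_gt(max(abs(tuned$nets[[1]]$par[["ffn.W1"]] -
                      base$nets[[1]]$par[["ffn.W1"]])), 0)
})

test_that("freezing all but the last FFN layer changes only that layer", {
  df <- fixture_dataset(50, seed = 16)
  base <- dmpnn(y ~ smiles, df, control = train_control(epochs = 3, seed = 5),
                hidden = 16, ffn_hidden = 12, ffn_layers = 3, verbose = FALSE)
  tuned <- dmpnn(y ~ smiles, df,
                 control = train_control(epochs = 3, seed = 7),
                 hidden = 16, ffn_hidden = 12, ffn_layers = 3, verbose = FALSE,
                 init_model = base, freeze = list(mpnn = TRUE, ffn_layers = 2))
  same <- c("enc1.W_i", "enc1.W_h", "enc1.W_o", "ffn.W1", "ffn.b1",
            "ffn.W2", "ffn.b2")
  for (nm in same)
    expect_identical(tuned$nets[[1]]$par[[nm]], base$nets[[1]]$par[[nm]])
  expect_gt(max(abs(tuned$nets[[1]]$par[["ffn.W3"]] -
                      base$nets[[1]]$par[["ffn.W3"]])), 0)
})

test_that("warm starting from a converged fit resumes near its loss", {
  df <- fixture_dataset(80, seed = 17)
  long <- dmpnn(y ~ smiles, df, control = train_control(epochs = 25, seed = 2),
                hidden = 24, ffn_hidden = 16, verbose = FALSE)
  final_loss <- tail(long$history[[1]]$train_loss, 1)
  resumed <- dmpnn(y ~ smiles, df,
                   control = train_control(epochs = 1, seed = 3),
                   hidden = 24, ffn_hidden = 16, verbose = FALSE,
                   init_model = long)
  first_loss <- resumed$history[[1]]$train_loss[1]
  untrained <- dmpnn(y ~ smiles, df,
                     control = train_control(epochs = 1, seed = 3),
                     hidden = 24, ffn_hidden = 16, verbose = FALSE)
  cold_loss <- untrained$history[[1]]$train_loss[1]
  expect_lt(first_loss, cold_loss / 2)
  expect_lt(abs(first_loss - final_loss), max(5 * final_loss, 0.2))
})

test_that("incompatible checkpoints are rejected with a clear error", {
  df <- fixture_dataset(30, seed = 18)
  base <- dmpnn(y ~ smiles, df, control = train_control(epochs = 1, seed = 1),
                hidden = 16, ffn_hidden = 12, verbose = FALSE)
  expect_error(
    dmpnn(y ~ smiles, df, control = train_control(epochs = 1, seed = 1),
          hidden = 8, ffn_hidden = 12, verbose = FALSE, init_model = base),
    "shape|vocabular")
})

test_that("random search returns its single trial and improves monotonically", {
  df <- fixture_dataset(30, seed = 19)
  space <- list(hidden = c(8L, 12L), depth = c(2L, 3L))
  r1 <- dmpnn_tune(y ~ smiles, df, space, n_trials = 1, seed = 1,
                   control = train_control(epochs = 2, seed = 1))
  expect_equal(r1$best$trial, 1L)
  expect_true(r1$best$config$hidden %in% c(8L, 12L))
  r3 <- dmpnn_tune(y ~ smiles, df, space, n_trials = 3, seed = 1,
                   control = train_control(epochs = 2, seed = 1))
  # best-of-log is monotone: the 3-trial best is at least the 1-trial best
  expect_lte(r3$best$metric, r1$best$metric + 1e-12)
  expect_error(dmpnn_tune(y ~ smiles, df, list(), n_trials = 1),
               "empty search space")
})

test_that("two workers appending to one trial log produce valid records", {
  df <- fixture_dataset(30, seed = 20)
  log <- tempfile(fileext = ".jsonl")
  space <- list(hidden = c(8L, 12L))
  dmpnn_tune(y ~ smiles, df, space, n_trials = 2, seed = 1, log_file = log,
             control = train_control(epochs = 1, seed = 1))
  dmpnn_tune(y ~ smiles, df, space, n_trials = 3, seed = 99, log_file = log,
             control = train_control(epochs = 1, seed = 50))
  recs <- read_trial_log(log)
  expect_equal(nrow(recs), 5L)
  expect_true(all(is.finite(recs$metric)))
})
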