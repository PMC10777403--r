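# loss values, exact gradients, invariants, and evaluation metrics

spec_r2 <- list(n_tasks = 2L, n_classes = 3L, task = "regression")

test_that("every loss gradient matches central differences", {
  with_seed(40, {
    n <- 5L
    mask <- matrix(TRUE, n, 2); mask[1, 2] <- FALSE
    y <- matrix(stats::rnorm(n * 2), n)
    expect_lt(loss_fd_check(dmpnn:::loss_mse, matrix(stats::rnorm(n * 2), n),
                            y, mask, spec_r2), 1e-5)
    rel <- matrix(sample(c("=", "<", ">"), n * 2, TRUE), n)
    expect_lt(loss_fd_check(dmpnn:::loss_bounded_mse,
                            matrix(stats::rnorm(n * 2), n), y, mask, spec_r2,
                            list(relation = rel)), 1e-5)
    expect_lt(loss_fd_check(dmpnn:::loss_mve,
                            matrix(stats::rnorm(n * 4), n), y, mask, spec_r2),
              1e-5)
    expect_lt(loss_fd_check(dmpnn:::loss_evidential,
                            matrix(stats::rnorm(n * 8), n), y, mask, spec_r2),
              1e-5)
    yb <- matrix(stats::rbinom(n * 2, 1, 0.5), n)
    expect_lt(loss_fd_check(dmpnn:::loss_bce,
                            matrix(stats::rnorm(n * 2), n), yb, mask, spec_r2),
              1e-5)
    expect_lt(loss_fd_check(dmpnn:::loss_mcc,
                            matrix(stats::rnorm(n * 2), n), yb, mask, spec_r2),
              1e-5)
    specm <- list(n_tasks = 2L, n_classes = 3L, task = "multiclass")
    ym <- matrix(sample(1:3, n * 2, TRUE), n)
    expect_lt(loss_fd_check(dmpnn:::loss_ce,
                            matrix(stats::rnorm(n * 6), n), ym, mask, specm),
              1e-5)
    expect_lt(loss_fd_check(dmpnn:::loss_dirichlet,
                            matrix(stats::rnorm(n * 6), n), ym, mask, specm),
              1e-5)
    specs <- list(n_tasks = 8L, task = "spectra")
    ys <- matrix(stats::runif(n * 8) + 0.05, n)
    msk <- matrix(1, n, 8); msk[2, 3:4] <- 0
    expect_lt(loss_fd_check(dmpnn:::loss_sid,
                            matrix(stats::rnorm(n * 8), n), ys, msk, specs),
              1e-5)
    expect_lt(loss_fd_check(dmpnn:::loss_wasserstein,
                            matrix(stats::rnorm(n * 8), n), ys, msk, specs),
              1e-5)
  })
})

test_that("bounded MSE zeroes satisfied inequalities", {
  f <- loss_function("bounded_mse", "regression")
  m1 <- matrix(TRUE)
  expect_equal(f(matrix(6), matrix(5), m1, spec_r2,
                 list(relation = matrix(">")))$value, 0)
  expect_equal(f(matrix(4), matrix(5), m1, spec_r2,
                 list(relation = matrix(">")))$value, 1)
  expect_equal(f(matrix(3), matrix(3), m1, spec_r2,
                 list(relation = matrix("=")))$value, 0)
  expect_equal(f(matrix(1.5), matrix(2), m1, spec_r2,
                 list(relation = matrix("<")))$value, 0)
})

test_that("bounded target strings parse with row-indexed errors", {
  pb <- parse_bounded_targets(c("1.5", ">5.0", "<2", "", NA))
  expect_equal(pb$value, c(1.5, 5, 2, NA, NA))
  expect_equal(pb$relation, c("=", ">", "<", NA, NA))
  expect_error(parse_bounded_targets(c("1", ">x")), "row 2")
})

test_that("MVE NLL has its closed-form minimum and optimal variance", {
  sp1 <- list(n_tasks = 1L, task = "regression")
  # mu = y and v = 1/(2 pi) give NLL exactly 0
  rv <- log(expm1(1 / (2 * pi) - 1e-8))
  L <- dmpnn:::loss_mve(matrix(c(2, rv), 1), matrix(2), matrix(TRUE), sp1)
  expect_equal(L$value, 0, tolerance = 1e-10)
  # at fixed residual r, NLL over v is minimized at v = r^2
  r <- 0.7
  nll_at <- function(v) {
    rv <- log(expm1(v - 1e-8))
    dmpnn:::loss_mve(matrix(c(0, rv), 1), matrix(r), matrix(TRUE), sp1)$value
  }
  vs <- seq(0.1, 2, by = 0.001)
  expect_equal(vs[which.min(vapply(vs, nll_at, 0))], r^2, tolerance = 2e-3)
  # matches the Gaussian density computed numerically
  for (i in 1:5) {
    mu <- stats::rnorm(1); v <- stats::runif(1, 0.2, 3); y <- stats::rnorm(1)
    rv <- log(expm1(v - 1e-8))
    L <- dmpnn:::loss_mve(matrix(c(mu, rv), 1), matrix(y), matrix(TRUE), sp1)
    expect_equal(L$value, -stats::dnorm(y, mu, sqrt(v), log = TRUE),
                 tolerance = 1e-8)
  }
})

test_that("evidential loss reduces to NIG NLL at lambda 0 and exposes the
          stated variance decomposition", {
  sp <- list(n_tasks = 1L, task = "regression", evidential_lambda = 0)
  raw <- matrix(stats::rnorm(4), 1)
  y <- matrix(0.3)
  L0 <- dmpnn:::loss_evidential(raw, y, matrix(TRUE), sp)
  u <- dmpnn:::evidential_unpack(raw, 1L)
  Om <- 2 * u$beta * (1 + u$nu)
  nig <- 0.5 * log(pi / u$nu) - u$alpha * log(Om) +
    (u$alpha + 0.5) * log((y - u$gamma)^2 * u$nu + Om) +
    lgamma(u$alpha) - lgamma(u$alpha + 0.5)
  expect_equal(L0$value, as.numeric(nig), tolerance = 1e-10)
  expect_equal(L0$aleatoric, u$beta / (u$alpha - 1))
  expect_equal(L0$epistemic, u$beta / (u$nu * (u$alpha - 1)))
  sp2 <- list(n_tasks = 1L, task = "regression", evidential_lambda = 0.5)
  L1 <- dmpnn:::loss_evidential(raw, y, matrix(TRUE), sp2)
  reg <- 0.5 * abs(y - u$gamma) * (2 * u$nu + u$alpha)
  expect_equal(L1$value - L0$value, as.numeric(reg), tolerance = 1e-10)
})

test_that("classification losses hit their closed-form anchors", {
  sp <- list(n_tasks = 1L, task = "binary")
  m1 <- matrix(TRUE)
  expect_equal(dmpnn:::loss_bce(matrix(0), matrix(1), m1, sp)$value, log(2),
               tolerance = 1e-9)
  expect_equal(dmpnn:::loss_bce(matrix(0), matrix(0), m1, sp)$value, log(2),
               tolerance = 1e-9)
  # perfect hard predictions: soft MCC 1, loss 0
  y <- matrix(c(1, 1, 0, 0), 4)
  m4 <- matrix(TRUE, 4, 1)
  L <- dmpnn:::loss_mcc(matrix(c(50, 50, -50, -50), 4), y, m4, sp)
  expect_equal(L$value, 0, tolerance = 1e-9)
  # uniform predictions on balanced labels: soft MCC 0, loss 1
  L0 <- dmpnn:::loss_mcc(matrix(0, 4, 1), y, m4, sp)
  expect_equal(L0$value, 1, tolerance = 1e-9)
})

test_that("spectrum losses are nonnegative, zero at equality, symmetric and
          scale invariant", {
  with_seed(41, {
    sp <- list(n_tasks = 6L, task = "spectra")
    msk <- matrix(1, 1, 6)
    for (i in 1:10) {
      p <- stats::runif(6) + 0.01
      q <- stats::runif(6) + 0.01
      raw_q <- matrix(log(expm1(q)), 1)
      raw_p <- matrix(log(expm1(p)), 1)
      s_pq <- dmpnn:::loss_sid(raw_q, matrix(p, 1), msk, sp)$value
      s_qp <- dmpnn:::loss_sid(raw_p, matrix(q, 1), msk, sp)$value
      expect_gte(s_pq, 0)
      expect_equal(s_pq, s_qp, tolerance = 1e-9)   # symmetry
      # invariance to common positive rescaling of the target
      s_scaled <- dmpnn:::loss_sid(raw_q, matrix(7.3 * p, 1), msk, sp)$value
      expect_equal(s_pq, s_scaled, tolerance = 1e-9)
      w_pq <- dmpnn:::loss_wasserstein(raw_q, matrix(p, 1), msk, sp)$value
      expect_gte(w_pq, 0)
      expect_equal(
        w_pq,
        dmpnn:::loss_wasserstein(raw_q, matrix(11 * p, 1), msk, sp)$value,
        tolerance = 1e-9)
    }
    # identical spectra: both losses 0
    p <- stats::runif(6) + 0.1
    pn <- p / sum(p)
    raw <- matrix(log(expm1(pn)), 1)
    expect_equal(dmpnn:::loss_sid(raw, matrix(p, 1), msk, sp)$value, 0,
                 tolerance = 1e-9)
    expect_equal(dmpnn:::loss_wasserstein(raw, matrix(p, 1), msk, sp)$value,
                 0, tolerance = 1e-9)
  })
})

test_that("two-bin SID and unit-mass Wasserstein match hand arithmetic", {
  sp <- list(n_tasks = 2L, task = "spectra")
  p <- c(0.8, 0.2); q <- c(0.2, 0.8)
  direct <- sum(p * log(p / q) + q * log(q / p))
  raw <- matrix(log(expm1(q)), 1)
  expect_equal(dmpnn:::loss_sid(raw, matrix(p, 1), matrix(1, 1, 2), sp)$value,
               direct, tolerance = 1e-9)
  # a unit mass moved from bin 1 to bin 4 costs 3 bin units
  sp5 <- list(n_tasks = 5L, task = "spectra")
  conc <- c(1, 0, 0, 0, 0) * 0.9999 + 2e-5
  raw5 <- matrix(log(expm1(conc)), 1)
  w <- dmpnn:::loss_wasserstein(raw5, matrix(c(0, 0, 0, 1, 0), 1),
                                matrix(1, 1, 5), sp5)$value
  expect_equal(w, 3, tolerance = 1e-3)
})

test_that("Wasserstein equals an independent transport oracle on random
          5-bin spectra", {
  with_seed(42, {
    sp <- list(n_tasks = 5L, task = "spectra")
    for (i in 1:20) {
      p <- stats::runif(5) + 0.01
      q <- stats::runif(5) + 0.01
      raw <- matrix(log(expm1(q / sum(q))), 1)
      w_pkg <- dmpnn:::loss_wasserstein(raw, matrix(p, 1), matrix(1, 1, 5),
                                        sp)$value
      expect_equal(w_pkg, transport_oracle(p, q), tolerance = 1e-6)
    }
  })
})

test_that("masked spectrum bins receive exactly zero gradient", {
  sp <- list(n_tasks = 6L, task = "spectra")
  msk <- matrix(1, 2, 6); msk[1, 2] <- 0; msk[2, 5:6] <- 0
  y <- matrix(stats::runif(12) + 0.05, 2)
  raw <- matrix(stats::rnorm(12), 2)
  for (f in list(dmpnn:::loss_sid, dmpnn:::loss_wasserstein)) {
    g <- f(raw, y, msk, sp)$grad
    expect_true(all(g[msk == 0] == 0))
    expect_true(any(g[msk == 1] != 0))
  }
  expect_error(dmpnn:::loss_sid(raw, y, matrix(0, 2, 6), sp), "no valid bins")
})

test_that("losses attain their minimum at prediction equal to target", {
  with_seed(43, {
    y <- matrix(stats::rnorm(4), 4)
    m <- matrix(TRUE, 4, 1)
    sp <- list(n_tasks = 1L, task = "regression")
    at_target <- dmpnn:::loss_mse(y, y, m, sp)$value
    expect_equal(at_target, 0)
    expect_gt(dmpnn:::loss_mse(y + 0.5, y, m, sp)$value, at_target)
  })
})

test_that("loss registry validates task compatibility", {
  expect_error(loss_function("mcc", "multiclass"), "binary tasks only")
  expect_error(loss_function("sid", "regression"), "not valid for task")
  expect_error(loss_function("nope", "regression"), "unknown loss")
  expect_s3_class(fixture_dataset(5, seed = 1), "data.frame")  # smoke anchor
})

test_that("evaluation metrics behave on anchors and degenerate inputs", {
  y <- c(0.2, 1.4, -0.5, 2.2)
  expect_equal(evaluation_metric(y, y, "rmse"), 0)
  expect_equal(evaluation_metric(y, y, "r2"), 1)
  expect_equal(evaluation_metric(y + 1, y, "mae"), 1)
  # AUROC of random scores vs random labels ~ 0.5
  with_seed(44, {
    s <- stats::runif(1e4)
    l <- stats::rbinom(1e4, 1, 0.5)
    expect_equal(evaluation_metric(s, l, "auroc"), 0.5, tolerance = 0.02)
  })
  # printed 2x2 table: TP 40 FP 10 FN 20 TN 30
  pred <- c(rep(1, 50), rep(0, 50))
  obs <- c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30))
  closed <- (40 * 30 - 10 * 20) /
    sqrt((40 + 10) * (40 + 20) * (30 + 10) * (30 + 20))
  expect_equal(evaluation_metric(pred, obs, "mcc"), closed)
  expect_equal(metric_mcc(pred, obs), closed)
  # single-class AUROC signals undefined instead of crashing
  expect_warning(v <- evaluation_metric(c(0.1, 0.9), c(1, 1), "auroc"),
                 "single class")
  expect_true(is.na(v))
})
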