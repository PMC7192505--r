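make_pair <- function(n_genes = 60, n_train = 15, n_test = 10, seed = 1,
                      shift = 0, mu = 7) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  train <- matrix(rnorm(n_genes * n_train, mu), n_genes,
                  dimnames = list(genes, sprintf("c%02d", seq_len(n_train))))
  test <- matrix(rnorm(n_genes * n_test, mu + shift), n_genes,
                 dimnames = list(genes, sprintf("p%02d", seq_len(n_test))))
  list(train = train, test = test)
}

test_that("every method preserves shape and gene/sample order", {
  pr <- make_pair(seed = 3)
  hk <- rownames(pr$train)[1:20]
  for (m in HOMOGENIZATIONS) {
    spec <- homogenization_spec(m, control_genes = hk)
    out <- homogenize(pr$train, pr$test, spec)
    expect_identical(dimnames(out$train), dimnames(pr$train), info = m)
    expect_identical(dimnames(out$test), dimnames(pr$test), info = m)
  }
  out <- homogenize_none(pr$train, pr$test)
  expect_identical(out$train, pr$train)
  expect_error(homogenize(pr$train, pr$test[rev(rownames(pr$test)), ]),
               "same gene set")
})

test_that("quantile normalization equalizes all sorted sample vectors", {
  train <- matrix(c(1, 3, 5), 3, dimnames = list(c("A", "B", "C"), "s1"))
  test <- matrix(c(2, 4, 8), 3, dimnames = list(c("A", "B", "C"), "p1"))
  out <- homogenize_quantile(train, test)
  expect_equal(unname(out$train[, 1]), c(1.5, 3.5, 6.5))
  expect_equal(unname(out$test[, 1]), c(1.5, 3.5, 6.5))

  pr <- make_pair(seed = 4, shift = 2)
  out2 <- homogenize_quantile(pr$train, pr$test)
  pooled <- cbind(out2$train, out2$test)
  ref <- sort(pooled[, 1])
  dev <- apply(pooled, 2, function(s) max(abs(sort(s) - ref)))
  expect_lt(max(dev), 1e-10)

  # identical samples unchanged
  same <- matrix(rep(c(1, 2, 3), 2), 3,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  out3 <- homogenize_quantile(same[, 1, drop = FALSE],
                              same[, 2, drop = FALSE])
  expect_equal(unname(out3$train[, 1]), c(1, 2, 3))
})

test_that("linear batch-term removal equalizes per-gene batch means", {
  pr <- make_pair(n_genes = 30, seed = 5, shift = 2)
  out <- homogenize_limma(pr$train, pr$test)
  gap <- rowMeans(out$train) - rowMeans(out$test)
  expect_lt(max(abs(gap)), 1e-10)

  # closed form at equal n: batch means meet at the midpoint
  tr <- matrix(5, 2, 3, dimnames = list(c("A", "B"), c("c1", "c2", "c3")))
  te <- matrix(7, 2, 3, dimnames = list(c("A", "B"), c("p1", "p2", "p3")))
  out2 <- homogenize_limma(tr, te)
  expect_equal(unname(out2$train[1, 1]), 6)
  expect_equal(unname(out2$test[1, 1]), 6)

  # a constant test-side shift is absorbed by the batch term: the output
  # changes only by a global constant (its centered structure is invariant)
  out3 <- homogenize_limma(pr$train, pr$test + 3.7)
  d <- out3$train - out$train
  expect_lt(diff(range(d)), 1e-10)
  expect_equal(out3$test - mean(d), out$test, tolerance = 1e-10)

  # no batch difference -> identity up to numerics
  pr0 <- make_pair(n_genes = 30, n_train = 12, n_test = 12, seed = 6)
  out4 <- homogenize_limma(pr0$train, pr0$test)
  expect_lt(max(abs(rowMeans(out4$train) - rowMeans(out4$test))), 1e-10)
})

test_that("empirical-Bayes adjustment removes a planted batch shift", {
  # within-batch sd 0.4: typical per-gene replicate spread on log2 scale
  set.seed(7)
  genes <- sprintf("g%03d", 1:200)
  train <- matrix(rnorm(200 * 50, 7, 0.4), 200,
                  dimnames = list(genes, sprintf("c%02d", 1:50)))
  test <- matrix(rnorm(200 * 50, 9, 0.4), 200,
                 dimnames = list(genes, sprintf("p%02d", 1:50)))
  out <- homogenize_combat(train, test)
  gap <- abs(rowMeans(out$train) - rowMeans(out$test))
  expect_lt(median(gap), 0.05)

  # identical batch distributions -> output close to input
  set.seed(8)
  tr0 <- matrix(rnorm(100 * 30, 7), 100,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("c%02d", 1:30)))
  te0 <- matrix(rnorm(100 * 30, 7), 100,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("p%02d", 1:30)))
  out0 <- homogenize_combat(tr0, te0)
  expect_lt(max(abs(out0$train - tr0)), 0.35)
  expect_lt(median(abs(out0$train - tr0)), 0.1)

  # zero-variance gene passes through with a warning
  tr1 <- tr0; tr1[1, ] <- 5
  expect_warning(out1 <- homogenize_combat(tr1, te0), "zero-variance")
  expect_equal(out1$train[1, ], tr1[1, ])

  expect_error(homogenize_combat(tr0[, 1, drop = FALSE], te0),
               ">= 2 samples")
})

test_that("EB location estimates are shrunk towards the common batch mean", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:150)
  train <- matrix(rnorm(150 * 40, 7, 0.5), 150,
                  dimnames = list(genes, sprintf("c%02d", 1:40)))
  shift <- rnorm(150, 2, 0.5)   # heterogeneous per-gene batch effect
  test <- matrix(rnorm(150 * 40, 7, 0.5), 150,
                 dimnames = list(genes, sprintf("p%02d", 1:40))) + shift
  out <- homogenize_combat(train, test)
  raw_gap <- rowMeans(test) - rowMeans(train)
  resid_gap <- rowMeans(out$test) - rowMeans(out$train)
  # shrinkage leaves a residual anti-correlated with the gene's deviation
  # from the mean batch effect, and far smaller than the raw gap
  expect_lt(stats::sd(resid_gap), 0.25 * stats::sd(raw_gap))
  expect_lt(abs(mean(resid_gap)), 0.05)
})

test_that("principal-component RUV residuals are orthogonal to the factors", {
  pr <- make_pair(n_genes = 80, n_train = 20, n_test = 15, seed = 10)
  hk <- rownames(pr$train)[1:30]
  spec <- homogenization_spec("ruv", n_unwanted_factors = 5,
                              control_genes = hk)
  out <- homogenize_ruv_custom(pr$train, pr$test, spec)
  pooled_in <- cbind(pr$train, pr$test)
  pooled_out <- cbind(out$train, out$test)
  W <- stats::prcomp(t(pooled_in[hk, ]))$x[, 1:5]
  centered <- pooled_out - rowMeans(pooled_out)
  dots <- abs(centered %*% W)
  expect_lt(max(dots), 1e-8)

  expect_error(homogenization_spec("ruv", n_unwanted_factors = 0,
                                   control_genes = hk), ">= 1")
  expect_error(homogenize(pr$train, pr$test,
                          homogenization_spec("ruv", control_genes =
                                                c("zz1", "zz2"))),
               "present")
  expect_error(homogenize(pr$train[, 1:3], pr$test[, 1:3],
                          homogenization_spec("ruv",
                                              n_unwanted_factors = 10,
                                              control_genes = hk)),
               "pooled samples")
})

test_that("RUV removes a planted batch factor that loads on the controls", {
  set.seed(11)
  n_genes <- 120; n <- 30
  genes <- sprintf("g%03d", seq_len(n_genes))
  hk <- genes[1:40]
  batch_factor <- c(rep(0, n), rep(3, n))          # train vs patient
  loadings <- runif(n_genes, 0.5, 1.5)
  base <- matrix(rnorm(n_genes * 2 * n), n_genes)
  pooled <- base + outer(loadings, batch_factor)
  dimnames(pooled) <- list(genes, sprintf("s%02d", seq_len(2 * n)))
  train <- pooled[, 1:n]; test <- pooled[, n + 1:n]

  auc_batch <- function(pair) {
    pc1 <- stats::prcomp(t(cbind(pair$train, pair$test)))$x[, 1]
    a <- roc_auc(pc1, rep(c(0, 1), each = n))
    max(a, 1 - a)
  }
  expect_gt(auc_batch(list(train = train, test = test)), 0.95)
  for (m in c("ruv", "ruv4")) {
    spec <- homogenization_spec(m, control_genes = hk)
    out <- homogenize(train, test, spec)
    expect_lt(auc_batch(out), 0.6)
  }

  # in the controls-carry-only-unwanted-variation regime the PCA and SVD
  # variants converge to the same projection
  s_ruv <- homogenize(train, test,
                      homogenization_spec("ruv", control_genes = hk))
  s_ruv4 <- homogenize(train, test,
                       homogenization_spec("ruv4", control_genes = hk))
  rms <- sqrt(mean((cbind(s_ruv$train, s_ruv$test) -
                      cbind(s_ruv4$train, s_ruv4$test))^2))
  expect_lt(rms, 0.05)
})

test_that("RUV4 is a near no-op when controls carry no unwanted variance", {
  pr <- make_pair(n_genes = 60, seed = 12)
  hk <- rownames(pr$train)[1:20]
  flat_train <- pr$train; flat_train[hk, ] <- 5
  flat_test <- pr$test; flat_test[hk, ] <- 5
  out <- homogenize(flat_train, flat_test,
                    homogenization_spec("ruv4", control_genes = hk))
  expect_equal(out$train, flat_train, tolerance = 1e-8)
  expect_equal(out$test, flat_test, tolerance = 1e-8)
})

test_that("RUV4 keeps signal genes that are uncorrelated with controls", {
  set.seed(13)
  n <- 40; n_genes <- 100
  genes <- sprintf("g%03d", seq_len(n_genes))
  hk <- genes[1:30]
  batch <- c(rep(0, n), rep(2, n))
  bio <- rnorm(2 * n)                      # biological signal
  pooled <- matrix(rnorm(n_genes * 2 * n, 0, 0.5), n_genes)
  dimnames(pooled) <- list(genes, sprintf("s%02d", seq_len(2 * n)))
  pooled <- pooled + outer(rep(1, n_genes), batch)  # batch on all genes
  sig <- genes[31:40]
  pooled[sig, ] <- pooled[sig, ] + outer(rep(1, 10), bio)
  out <- homogenize(pooled[, 1:n], pooled[, n + 1:n],
                    homogenization_spec("ruv4", control_genes = hk,
                                        n_unwanted_factors = 5))
  pooled_out <- cbind(out$train, out$test)
  cor_before <- abs(cor(pooled[sig[1], ], bio))
  cor_after <- abs(cor(pooled_out[sig[1], ], bio))
  expect_gt(cor_after, 0.8 * cor_before)
})

test_that("cumulative-proportion transform follows the stated formula", {
  tr <- matrix(c(3, 1, 2), 3, dimnames = list(c("A", "B", "C"), "s1"))
  te <- matrix(c(1, 1, 1), 3, dimnames = list(c("A", "B", "C"), "p1"))
  out <- homogenize_yugene(tr, te)
  expect_equal(unname(out$train[, 1]), c(0.5, 0, 1 / 6), tolerance = 1e-12)
  # constant sample: descending ties broken by gene index
  expect_equal(unname(out$test[, 1]), c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  # scale invariance per sample
  pr <- make_pair(seed = 14, mu = 10)
  pr$train <- abs(pr$train); pr$test <- abs(pr$test)
  a <- homogenize_yugene(pr$train, pr$test)
  b <- homogenize_yugene(pr$train * 5, pr$test * 5)
  expect_equal(a, b, tolerance = 1e-12)
  expect_true(all(a$train >= 0 & a$train < 1))

  neg <- pr; neg$train[1, 1] <- -1
  expect_error(homogenize_yugene(neg$train, neg$test), "non-negative")
  expect_equal(homogenize_yugene(neg$train, neg$test,
                                 shift_nonnegative = TRUE)$train[2, 1],
               homogenize_yugene(neg$train - min(neg$train[1, 1]),
                                 neg$test - min(neg$train[1, 1]))$train[2, 1])
  zero <- pr$train; zero[, 1] <- 0
  expect_error(homogenize_yugene(zero, pr$test), "zero-sum")
})

test_that("homogenization preserves a planted signal on batch-free data", {
  sim <- small_sim(seed = 15, effect_size = 2, batch_shift_sd = 0,
                   batch_scale_sd = 0, duplicate_gene_fraction = 0)
  train <- sim$screen$expression
  test <- sim$cohort$expression
  base_auc <- roc_auc(oracle_predict(sim$truth, test),
                      sim$cohort$response)
  hk <- sim$screen$housekeeping_genes
  for (m in HOMOGENIZATIONS) {
    spec <- homogenization_spec(m, control_genes = hk,
                                yugene_shift = TRUE)
    out <- homogenize(train, test, spec)
    sc <- if (m == "yugene") {
      # the transform rescales genes nonlinearly: the oracle on the
      # transformed scale weights per-gene standardized values
      X <- out$test[sim$truth$signal_genes, ]
      colSums(t(scale(t(X))) *
                sim$truth$cohort_weights[sim$truth$signal_genes])
    } else {
      roc <- oracle_predict(sim$truth, out$test)
      roc
    }
    auc <- roc_auc(sc, sim$cohort$response)
    expect_gt(auc, base_auc - 0.05)
  }
})
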