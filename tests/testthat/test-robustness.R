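test_that("the random-response null is centred, symmetric and size-aware", {
  set.seed(61)
  labels24 <- c(rep(1, 10), rep(0, 14))        # a small cohort
  null24 <- random_response_null(labels24, n_draws = 4000, seed = 2)
  se <- sd(null24$draws) / sqrt(null24$n_draws)
  expect_lt(abs(mean(null24$draws) - 0.5), 3 * se + 1e-3)

  g1 <- mean((null24$draws - mean(null24$draws))^3) /
    sd(null24$draws)^3
  expect_lt(abs(g1), 0.05)

  labels169 <- c(rep(1, 85), rep(0, 84))       # a large cohort
  null169 <- random_response_null(labels169, n_draws = 4000, seed = 2)
  expect_lt(sd(null169$draws), sd(null24$draws))

  expect_identical(random_response_null(labels24, 100, seed = 9)$draws,
                   random_response_null(labels24, 100, seed = 9)$draws)
  expect_error(random_response_null(rep(1, 10)), "both classes")

  perm <- random_response_null(labels24, 500, seed = 3,
                               generator = "permutation")
  expect_lt(abs(mean(perm$draws) - 0.5), 0.02)
})

test_that("gene permutation preserves the data but breaks planted signal", {
  sim <- small_sim(seed = 62, effect_size = 2, batch_shift_sd = 0,
                   batch_scale_sd = 0, duplicate_gene_fraction = 0,
                   n_cell_lines = 300)
  cfg <- enumerate_grid("drug01", "none", "limma", "all", "none",
                        "linear")
  null <- permuted_gene_null(cfg, sim$screen, sim$cohort, n_perm = 25,
                             seed = 4, control = fast_control)
  expect_equal(dim(null), c(25L, 1L))
  real <- run_pipeline(cfg[1, ], sim$screen, sim$cohort,
                       control = fast_control)$auc_roc
  expect_gt(real, quantile(null[, 1], 0.95))

  # with no planted signal, gene labels are exchangeable: across null
  # datasets, the real-label AUC and a permuted-label AUC are identically
  # distributed
  draw <- vapply(1:25, function(s) {
    simi <- small_sim(seed = 700 + s, effect_size = 0, n_genes = 100,
                      n_signal_genes = 10, n_housekeeping = 20,
                      n_landmark = 20, n_cell_lines = 160,
                      n_patients = 20)
    c(real = run_pipeline(cfg[1, ], simi$screen, simi$cohort,
                          control = fast_control)$auc_roc,
      perm = permuted_gene_null(cfg, simi$screen, simi$cohort,
                                n_perm = 1, seed = s,
                                control = fast_control)[1, 1])
  }, c(real = 0, perm = 0))
  ks <- suppressWarnings(stats::ks.test(draw["real", ], draw["perm", ]))
  expect_gt(ks$p.value, 0.01)

  # the shuffle itself only relabels rows
  set.seed(6)
  shuf <- sim$cohort$expression
  rownames(shuf) <- sample(rownames(shuf))
  expect_setequal(rownames(shuf), rownames(sim$cohort$expression))
  expect_equal(sort(unname(shuf[, 1])),
               sort(unname(sim$cohort$expression[, 1])))
})

test_that("setting enrichment matches the exact combinatorial oracle", {
  # N = 10, K = 4, n = 2, x = 2 -> C(4,2)/C(10,2) = 6/45
  expect_equal(stats::phyper(1, 4, 6, 2, lower.tail = FALSE), 6 / 45)

  mk_scan <- function(aucs, options) {
    data.frame(drug = "d", response_transform = options,
               homogenization = "none", feature_filter = "all",
               feature_preprocess = "none", black_box = "linear",
               pipeline_id = sprintf("p%02d", seq_along(aucs)),
               auc_roc = aucs, auc_pr = aucs, separation_p = 0.5,
               failure = NA_character_, stringsAsFactors = FALSE)
  }
  # option A occupies the top 2 of 10 -> p = 6/45 at top_frac 0.2
  sc <- mk_scan(seq(1, 0.1, length.out = 10),
                rep(c("A", "B"), c(4, 6))[c(1, 2, 5, 6, 7, 3, 4, 8, 9, 10)])
  enr <- setting_enrichment(sc, top_frac = 0.2, alpha = 0.05)
  rowA <- enr[enr$stage == "response_transform" & enr$option == "A", ]
  expect_equal(rowA$count_top, 2)
  expect_equal(rowA$p_value, 6 / 45, tolerance = 1e-12)
  expect_equal(rowA$p_value, exhaustive_hyper_p(10, 4, 2, 2),
               tolerance = 1e-12)

  # x = 0 -> p = 1
  rowB <- enr[enr$option == "B", ][1, ]
  expect_equal(rowB$p_value, 1)

  # pmf normalization against enumeration for small universes
  for (N in c(8, 12)) {
    K <- 5; n <- 4
    total <- sum(vapply(0:min(K, n), function(x)
      stats::dhyper(x, K, N - K, n), numeric(1)))
    expect_equal(total, 1, tolerance = 1e-12)
    for (x in 0:3)
      expect_equal(stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE),
                   exhaustive_hyper_p(N, K, n, x), tolerance = 1e-10)
  }

  expect_error(setting_enrichment(mk_scan(c(1, 0.5), c("A", "B")),
                                  top_frac = 0.05), "too small")
})

test_that("drug specificity ranks are a permutation and order-invariant", {
  p <- simulation_params(n_genes = 150, n_signal_genes = 15,
                         n_housekeeping = 30, n_landmark = 30,
                         n_cell_lines = 50, n_patients = 20,
                         n_drugs = 5, shared_fraction = 0.5, seed = 64)
  sim <- generate_paired_datasets(p)
  cfgs <- sample_configs(enumerate_grid(
    homogenizations = c("none", "limma"),
    black_boxes = c("linear", "ridge", "svm")), n = 4, seed = 7)
  out <- drug_specificity_scan(cfgs, sim$screen, sim$cohort, "drug01",
                               min_responses = 5, control = fast_control)
  expect_setequal(names(out$ranks), rownames(sim$screen$response))
  expect_equal(sort(unname(out$ranks)), 1:5)
  expect_equal(out$administered_rank, unname(out$ranks["drug01"]))

  # reordering the screen's drug table does not change the means
  scr2 <- sim$screen
  scr2$response <- scr2$response[c(3, 1, 5, 2, 4), , drop = FALSE]
  out2 <- drug_specificity_scan(cfgs, scr2, sim$cohort, "drug01",
                                min_responses = 5,
                                control = fast_control)
  expect_equal(out$drug_mean_auc[names(out2$drug_mean_auc)],
               out2$drug_mean_auc, tolerance = 1e-12)

  # a sparsely screened drug is skipped with a warning
  scr3 <- sim$screen
  scr3$response[2, -(1:3)] <- NA
  scr3$response[2, 1:3] <- c(1, 2, 3)
  expect_warning(
    out3 <- drug_specificity_scan(cfgs, scr3, sim$cohort, "drug01",
                                  min_responses = 5,
                                  control = fast_control),
    "skipped")
  expect_false("drug02" %in% names(out3$ranks))
})

test_that("configuration sampling is seeded and without replacement", {
  grid <- enumerate_grid()
  s1 <- sample_configs(grid, 100, seed = 8)
  s2 <- sample_configs(grid, 100, seed = 8)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100)
  expect_equal(anyDuplicated(s1$pipeline_id), 0)
  expect_false(identical(s1, sample_configs(grid, 100, seed = 9)))
})
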