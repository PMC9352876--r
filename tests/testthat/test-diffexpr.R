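test_that("low-expression filter keeps exactly the qualifying genes", {
  ab <- matrix(12, 3, 10, dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))
  ab[2, 1:2] <- 5    # 12 in 8/10 samples: 8 < ceil(0.9 * 10) = 9 -> removed
  ab[3, 1] <- 0      # one zero sample
  meta <- data.frame(cell_type = "daoy",
                     treatment = rep(c("h2o", "propranolol"), 5),
                     buffer = "h2o", plate = "p1")
  m <- experiment_matrix(ab, meta)
  f <- filter_low_expression(m, 10, 0.9)
  expect_setequal(f$gene_ids, c("g1", "g3"))  # g3: 9/10 samples pass
  # min_fraction = 1: any gene with one failing sample is removed
  f2 <- filter_low_expression(m, 10, 1)
  expect_identical(f2$gene_ids, "g1")
  expect_identical(f$sample_meta, m$sample_meta)
  expect_error(filter_low_expression(m, 1e6, 0.9), "no genes retained")
})

test_that("single-gene fit matches hand-computed normal equations", {
  # 6-sample design with printed response and dummies; oracle: explicit
  # (X'X)^{-1} X'y and classical standard error, computed in the test
  y_log2 <- c(5.1, 5.4, 4.9, 6.3, 6.8, 6.1)
  design <- data.frame(plate = c("p1", "p2", "p1", "p1", "p2", "p1"),
                       buffer = "h2o",
                       treatment = rep(c("ctrl", "drug"), each = 3))
  X <- cbind(1, c(0, 1, 0, 0, 1, 0), rep(c(0, 1), each = 3))
  xtxi <- solve(t(X) %*% X)
  beta_hat <- xtxi %*% t(X) %*% y_log2
  resid <- y_log2 - X %*% beta_hat
  s2 <- sum(resid^2) / (6 - 3)
  se_hat <- sqrt(s2 * xtxi[3, 3])

  fit <- fit_gene_model(2^y_log2 - 0.5, design,
                        control = "ctrl", drug = "drug")
  expect_equal(fit$beta, beta_hat[3, 1], tolerance = 1e-10)
  expect_equal(fit$se, se_hat, tolerance = 1e-10)
  expect_equal(fit$df, 3)
  # normal mode: z is exactly beta/se; t mode is p-calibrated
  fit_n <- fit_gene_model(2^y_log2 - 0.5, design, control = "ctrl",
                          drug = "drug", wald_reference = "normal")
  expect_equal(fit_n$z, beta_hat[3, 1] / se_hat, tolerance = 1e-10)
  expect_equal(fit_n$p, 2 * pnorm(-abs(fit_n$z)), tolerance = 1e-12)
  expect_equal(fit$p, 2 * pt(-abs(beta_hat[3, 1] / se_hat), df = 3),
               tolerance = 1e-12)
  expect_equal(fit$z, sign(fit$beta) * qnorm(fit$p / 2, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("degenerate fits take the sentinel paths", {
  design <- data.frame(plate = "p1", buffer = "h2o",
                       treatment = rep(c("ctrl", "drug"), each = 2))
  # constant response: beta = 0, z = 0, p = 1
  fit0 <- fit_gene_model(rep(7, 4), design, control = "ctrl", drug = "drug")
  expect_identical(c(fit0$beta, fit0$z, fit0$p), c(0, 0, 1))
  # exact fit (log2 response 1,1,2,2): beta = 1, se = 0, z = +Inf, p = 0
  fit1 <- fit_gene_model(2^c(1, 1, 2, 2) - 0.5, design,
                         control = "ctrl", drug = "drug")
  expect_equal(fit1$beta, 1, tolerance = 1e-12)
  expect_identical(fit1$se, 0)
  expect_identical(fit1$z, Inf)
  expect_identical(fit1$p, 0)
})

test_that("confounded designs fail naming the aliased term", {
  design <- data.frame(plate = rep(c("p1", "p2"), each = 2), buffer = "h2o",
                       treatment = rep(c("ctrl", "drug"), each = 2))
  expect_error(fit_gene_model(rnorm(4), design, "ctrl", "drug"),
               "confounded|rank deficient")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:60) {
    p <- round(runif(sample(1:12, 1)), sample(1:3, 1))  # ties likely
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("run_de orders by q, preserves z sign, and handles one gene", {
  sim <- generate_experiment(sim_config(n_genes = 400, seed = 17,
                                        frac_convergent = 0.05,
                                        effect_size_log2 = 2))
  de <- run_de(sim$matrix, "daoy", "propranolol")
  expect_s3_class(de, "de_result")
  expect_false(is.unsorted(de$q))
  expect_true(all(sign(de$z) == sign(de$log2fc) | de$z == 0))
  expect_true(all(de$q >= de$p - 1e-15))
  # single-gene matrix: q = p
  te <- tiny_experiment()
  one <- experiment_matrix(te$abundance[1, , drop = FALSE], te$sample_meta)
  de1 <- run_de(one, "daoy", "propranolol")
  expect_identical(de1$q, de1$p)
})

test_that("run_de is invariant to sample order and errors on missing arms", {
  sim <- generate_experiment(sim_config(n_genes = 200, seed = 23))
  de <- run_de(sim$matrix, "npc", "primidone")
  perm <- sample(ncol(sim$matrix$abundance))
  shuf <- experiment_matrix(sim$matrix$abundance[, perm],
                            sim$matrix$sample_meta[perm, ])
  de_shuf <- run_de(shuf, "npc", "primidone")
  expect_equal(de, de_shuf, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(run_de(sim$matrix, "hek", "propranolol"), "hek")
  expect_error(run_de(sim$matrix, "daoy", "lithium"), "lithium")
  only_drug <- sim$matrix$sample_meta$treatment != "h2o"
  trimmed <- experiment_matrix(sim$matrix$abundance[, only_drug],
                               sim$matrix$sample_meta[only_drug, ])
  expect_error(run_de(trimmed, "daoy", "propranolol"), "h2o")
})

test_that("strong true effects rank at the top and are recovered", {
  sim <- generate_experiment(sim_config(n_genes = 1000, seed = 29,
                                        frac_convergent = 0.1,
                                        frac_condition_specific = 0,
                                        effect_size_log2 = 3))
  de <- run_de(sim$matrix, "daoy", "propranolol")
  truth <- sim$truth$gene_id[sim$truth$convergent]
  truth <- intersect(truth, de$gene_id)
  top <- de$gene_id[order(-abs(de$z))][seq_along(truth)]
  expect_gte(mean(truth %in% top), 0.9)
  # recovered effect size is close to the simulated log2 fold change
  est <- coef(de)[truth]
  tru <- sim$truth[match(truth, sim$truth$gene_id), "effect_daoy_prop"]
  expect_equal(unname(sign(est)), sign(tru))
  expect_lt(median(abs(est - tru)), 0.5)
})
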