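test_that("o/e percentage transform applies the scale and the cap", {
  expect_identical(oe_to_percent(0.25), 25)
  expect_identical(oe_to_percent(12), 100)
  expect_identical(oe_to_percent(0), 0)
  expect_error(oe_to_percent(-0.1), "nonnegative")
  # monotone non-decreasing up to the cap point, bounded in [0, 1000]
  s <- seq(0, 10, by = 0.25)
  expect_true(all(diff(oe_to_percent(s)) >= 0))
  grid <- c(s, seq(10.01, 50, by = 0.5))
  expect_true(all(oe_to_percent(grid) >= 0 & oe_to_percent(grid) <= 1000))
  expect_true(all(oe_to_percent(seq(10.01, 50, by = 0.5)) == 100))
})

test_that("propensity scores come from the logistic model of DEG status", {
  ann <- generate_gene_annotation(500, seed = 7)
  # identical covariates: every score equals the DEG prevalence
  ann_flat <- ann
  ann_flat$cds_length <- 1000
  ann_flat$gc_fraction <- 0.4
  flags <- rep(c(TRUE, FALSE), c(100, 400))
  pr_flat <- propensity_scores(ann_flat, flags)
  expect_equal(as.numeric(pr_flat), rep(0.2, 500), tolerance = 1e-8)
  expect_error(propensity_scores(ann, rep(TRUE, 500)), "non-empty")
  # matches glm directly
  flags2 <- ann$constrained
  pr2 <- propensity_scores(ann, flags2)
  ref <- fitted(glm(flags2 ~ cds_length + gc_fraction, data = ann,
                    family = binomial()))
  expect_equal(pr2, unname(ref), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("propensity scores are uninformative under independence and track
           a planted covariate shift", {
  set.seed(101)
  ann <- generate_gene_annotation(2000, seed = 13)
  flags <- seq_len(2000) %in% sample.int(2000, 300)
  pr <- propensity_scores(ann, flags)
  # area under the ROC via the rank-sum identity
  r <- rank(pr)
  auc <- (sum(r[flags]) - 300 * 301 / 2) / (300 * 1700)
  expect_lt(abs(auc - 0.5), 0.05)
  # DEGs sampled preferentially at shorter CDS: negative fitted slope and
  # scores decreasing in cds_length
  w <- exp(-4 * rank(ann$cds_length) / 2000)
  short <- sample.int(2000, 300, prob = w)
  flags_s <- seq_len(2000) %in% short
  pr_s <- propensity_scores(ann, flags_s)
  fit <- attr(pr_s, "fit")
  expect_lt(coef(fit)["cds_length"], 0)
})

test_that("nearest-neighbour matching selects by distance with index
           tie-breaks", {
  # distances 0.02, 0.20, 0.40 -> controls 1 and 2
  m <- nn_match_with_replacement(0.5, c(0.48, 0.3, 0.9), 2)
  expect_identical(sort(m[1, ]), c(1L, 2L))
  # ratio = number of controls: every control used for each treated unit
  m2 <- nn_match_with_replacement(c(0.2, 0.8), c(0.1, 0.5, 0.9), 3)
  expect_identical(t(apply(m2, 1, sort)),
                   matrix(1:3, 2, 3, byrow = TRUE))
  # identical treated scores give identical match sets (determinism)
  m3 <- nn_match_with_replacement(c(0.4, 0.4), runif(50), 5)
  expect_identical(m3[1, ], m3[2, ])
  # exact ties broken by the smallest control index
  m4 <- nn_match_with_replacement(0.5, c(0.6, 0.4, 0.4, 0.6), 2)
  expect_identical(m4[1, ], c(1L, 2L))
  expect_error(nn_match_with_replacement(0.5, numeric(0), 1), "no control")
  expect_error(nn_match_with_replacement(0.5, c(0.1, 0.2), 3), "ratio")
})

test_that("Wilcoxon rank-sum matches exact enumeration and wilcox.test", {
  got <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_identical(got$W, 3)
  expect_equal(got$p, 1 / 3, tolerance = 1e-12)
  # identical multisets sit at the null mean: p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 5, 9), c(9, 2, 5))$p, 1)
  set.seed(103)
  for (i in 1:40) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    withties <- i %% 2 == 0
    x <- if (withties) sample(1:4, nx, TRUE) else rnorm(nx)
    y <- if (withties) sample(1:4, ny, TRUE) else rnorm(ny)
    got <- wilcoxon_rank_sum(x, y)
    ref <- wilcox_brute(x, y)
    expect_identical(got$W, ref$W)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
    if (!withties) {
      # independent cross-check: wilcox.test exact U + n_x(n_x+1)/2 = W
      wt <- wilcox.test(x, y, exact = TRUE)
      expect_equal(got$W, unname(wt$statistic) + nx * (nx + 1) / 2)
      expect_equal(got$p, wt$p.value, tolerance = 1e-12)
    }
  }
})

test_that("large-sample Wilcoxon holds its nominal type-I error", {
  set.seed(107)
  rej <- replicate(400, {
    x <- rnorm(500); y <- rnorm(500)
    wilcoxon_rank_sum(x, y)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("constraint analysis recovers a planted constraint difference and
           reports balanced matches", {
  ann <- generate_gene_annotation(3000, frac_constrained = 0.2, seed = 19)
  deg <- sample(ann$gene_id[ann$constrained], 200)
  rep_con <- run_constraint_analysis(ann, list(all = deg))
  expect_s3_class(rep_con, "constraint_report")
  expect_identical(rep_con$n_deg, 200L)
  expect_identical(rep_con$ratio, (3000L - 200L) %/% 200L)
  expect_lt(rep_con$median_deg_oe, rep_con$median_bg_oe)
  expect_lt(rep_con$p, 0.05)
  # matching improves covariate balance on these confounded covariates
  expect_lt(rep_con$smd_post_cds_length, rep_con$smd_pre_cds_length)
  expect_lt(rep_con$smd_post_gc_fraction, rep_con$smd_pre_gc_fraction)
  # deg set equal to the whole background: equal medians by construction
  rep_all <- run_constraint_analysis(ann,
                                     list(half = ann$gene_id[1:1500]),
                                     ratio = 1)
  expect_identical(rep_all$n_deg, 1500L)
  expect_error(run_constraint_analysis(ann, list(small = ann$gene_id[1:3])),
               "fewer than 5")
  expect_error(run_constraint_analysis(ann, list(bad = c(ann$gene_id[1:5],
                                                         "ghost"))),
               "absent")
})

test_that("uniformly drawn DEG sets give null constraint comparisons", {
  ann <- generate_gene_annotation(1500, frac_constrained = 0.15, seed = 23)
  set.seed(109)
  pvals <- replicate(40, {
    deg <- sample(ann$gene_id, 150)
    run_constraint_analysis(ann, list(all = deg))$p
  })
  expect_lte(mean(pvals < 0.05), 0.125)
})
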