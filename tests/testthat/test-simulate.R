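test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 150, seed = 42)
  s1 <- generate_experiment(cfg)
  s2 <- generate_experiment(cfg)
  expect_identical(s1$matrix$abundance, s2$matrix$abundance)
  expect_identical(s1$truth, s2$truth)

  a1 <- generate_gene_annotation(80, 0.3, seed = 5)
  expect_identical(a1, generate_gene_annotation(80, 0.3, seed = 5))

  p1 <- generate_sc_profiles(60, seed = 9)
  expect_identical(p1, generate_sc_profiles(60, seed = 9))

  z <- rnorm(50)
  expect_identical(generate_twas(z, 0.4, seed = 3),
                   generate_twas(z, 0.4, seed = 3))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_experiment(sim_config(n_genes = 20, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("truth flags match the configured fractions exactly", {
  sim <- generate_experiment(sim_config(n_genes = 1000,
                                        frac_convergent = 0.1,
                                        frac_condition_specific = 0.2,
                                        seed = 7))
  expect_identical(sum(sim$truth$convergent), 100L)
  expect_identical(sum(sim$truth$specific), 200L)
  expect_false(any(sim$truth$convergent & sim$truth$specific))
  # convergent genes share one signed effect across all four conditions
  eff <- as.matrix(sim$truth[sim$truth$convergent,
                             grep("^effect_", names(sim$truth))])
  expect_true(all(abs(eff) == 1))
  expect_true(all(apply(eff, 1, function(r) length(unique(r)) == 1)))
  # condition-specific genes have exactly one nonzero effect
  eff_s <- as.matrix(sim$truth[sim$truth$specific,
                               grep("^effect_", names(sim$truth))])
  expect_true(all(rowSums(eff_s != 0) == 1))
})

test_that("experiment metadata encodes the crossed design", {
  sim <- generate_experiment(sim_config(n_genes = 30, seed = 2))
  meta <- sim$matrix$sample_meta
  expect_setequal(unique(meta$treatment),
                  c("propranolol", "h2o", "primidone", "dmso"))
  # buffer is tied to the drug pair
  expect_true(all(meta$buffer[meta$treatment %in%
                                c("propranolol", "h2o")] == "h2o"))
  expect_true(all(meta$buffer[meta$treatment %in%
                                c("primidone", "dmso")] == "dmso"))
  # plate crosses treatment within every arm
  expect_true(all(tapply(meta$plate,
                         paste(meta$cell_type, meta$treatment),
                         function(p) length(unique(p))) == 2))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_convergent = 0.7,
                          frac_condition_specific = 0.6), "frac_convergent")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(plate_sd = -1), "plate_sd")
  expect_error(generate_gene_annotation(0), "n_genes")
  expect_error(generate_twas(rnorm(10), 1.5), "rho")
  expect_error(generate_sc_profiles(50, fold = 1), "fold")
  expect_error(
    generate_sc_profiles(50, enriched_sets = list(
      g = list(genes = "nope", cell_type = "Ast"))),
    "enriched_sets")
})

test_that("annotation invariants hold and constraint shifts the o/e median", {
  ann <- generate_gene_annotation(3000, frac_constrained = 0.3, seed = 11)
  expect_true(all(ann$cds_length <= ann$gene_length))
  expect_true(all(ann$gene_length > 0))
  expect_true(all(ann$gc_fraction > 0 & ann$gc_fraction < 1))
  expect_true(all(ann$oe_score >= 0))
  expect_identical(sum(ann$constrained), 900L)
  expect_lt(median(ann$oe_score[ann$constrained]),
            median(ann$oe_score[!ann$constrained]))
})

test_that("TWAS generator hits its target correlation", {
  set.seed(21)
  drug_z <- rnorm(10000)
  # rho = 1: affine transform, exact correlation 1
  t1 <- generate_twas(drug_z, 1, seed = 2)
  expect_equal(cor(t1, drug_z), 1, tolerance = 1e-12)
  expect_equal(cor(generate_twas(drug_z, -1, seed = 2), drug_z), -1,
               tolerance = 1e-12)
  # rho = 0 and rho = 0.5: Monte-Carlo bounds at n = 10000
  expect_lt(abs(cor(generate_twas(drug_z, 0, seed = 3), drug_z)), 0.05)
  expect_equal(cor(generate_twas(drug_z, 0.5, seed = 4), drug_z), 0.5,
               tolerance = 0.05)
})

test_that("profile spikes raise the target cell type above all others", {
  genes <- sprintf("g%05d", 1:40)
  prof <- generate_sc_profiles(500, fold = 2, seed = 13,
    enriched_sets = list(gs = list(genes = genes, cell_type = "Ast")))
  expect_true(all(prof >= 0))
  m <- colMeans(prof[genes, ])
  expect_identical(names(which.max(m)), "Ast")
  expect_true(all(m["Ast"] > m[setdiff(names(m), "Ast")]))
})
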