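test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_donors = 3), "at least 4")
  expect_error(sim_config(maf = 0.7), "maf")
  expect_error(sim_config(injected_sets = list(
    list(assay = "expression", ids = 1:5, cells = "monocyte",
         inflation = 0.5))), "inflation")
  expect_error(sim_config(n_genes = 10, injected_sets = list(
    list(assay = "expression", ids = 8:12, cells = "monocyte",
         inflation = 2))), "out of range")
  expect_error(sim_config(injected_sets = list(
    list(assay = "expression", ids = 1:5, cells = "nk_cell",
         inflation = 2))), "unknown cell type")
})

test_that("the cohort is bit-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 120, n_cpgs = 80, n_donors = 12,
                    injected_sets = list(list(assay = "expression",
                                              ids = 1:10,
                                              cells = "neutrophil",
                                              inflation = 3)),
                    seed = 19)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  t1 <- simulate_traits(c1)
  t2 <- simulate_traits(c2)
  expect_identical(t1, t2)
})

test_that("injected variance inflation is realized at the configured magnitude", {
  cfg <- sim_config(n_genes = 200, n_cpgs = 0, n_donors = 125,
                    injected_sets = list(list(assay = "expression",
                                              ids = 1:20,
                                              cells = "monocyte",
                                              inflation = 4)),
                    seed = 20)
  co <- simulate_cohort(cfg)
  va <- apply(unclass(co$expression$monocyte)[1:20, ], 1, var)
  vb <- apply(unclass(co$expression$neutrophil)[1:20, ], 1, var)
  ratio <- mean(va / vb)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
})

test_that("with no injections the truth table is empty and cell types are exchangeable", {
  co <- null_cohort(n_genes = 800, n_donors = 50, seed = 21)
  expect_identical(nrow(co$truth), 0L)
  va <- apply(unclass(co$expression[[1]]), 1, var)
  vb <- apply(unclass(co$expression[[2]]), 1, var)
  # paired F-type ratio has median ~ 1 over features
  expect_equal(median(va / vb), 1, tolerance = 0.1)
  # realized variance tracks the configured negative mean-variance trend
  mu <- rowMeans(unclass(co$expression[[1]]))
  expect_lt(cor(mu, va, method = "spearman"), -0.3)
})

test_that("cis-genetic injections inflate variance through donor mean shifts", {
  cfg <- sim_config(n_genes = 300, n_cpgs = 0, n_donors = 125,
                    injected_sets = list(list(assay = "expression",
                                              ids = 1:40,
                                              cells = "monocyte",
                                              inflation = 4)),
                    genetic_fraction = 1, maf = 0.3, seed = 22)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$genetic))
  va <- apply(unclass(co$expression$monocyte)[1:40, ], 1, var)
  vb <- apply(unclass(co$expression$neutrophil)[1:40, ], 1, var)
  # variance inflation emerges across donors without residual-noise scaling
  expect_gt(mean(va / vb), 2.5)
})

test_that("traits realize target rank correlations and the weather series behaves", {
  cfg <- sim_config(n_genes = 100, n_cpgs = 0, n_donors = 125,
                    trait_effect_features = list(
                      list(id = 1, trait = "granularity_link", rho = 0.6,
                           cell_type = "monocyte"),
                      list(id = 2, trait = "null_link", rho = 0,
                           cell_type = "monocyte")),
                    weather_missing = 0, seed = 23)
  co <- simulate_cohort(cfg)
  tr <- simulate_traits(co)
  x1 <- unclass(co$expression$monocyte)[1, tr$traits$donor_id]
  rho1 <- cor(x1, tr$traits$granularity_link, method = "spearman")
  expect_gt(rho1, 0.45); expect_lt(rho1, 0.75)
  x2 <- unclass(co$expression$monocyte)[2, tr$traits$donor_id]
  rho0 <- cor(x2, tr$traits$null_link, method = "spearman")
  expect_lt(abs(rho0), 1.96 / sqrt(125 - 1))  # analytic null bound
  expect_false(anyNA(tr$weather$tmin))        # missing fraction 0: no gaps
  # nonzero missing fraction produces gaps
  cfg2 <- sim_config(n_genes = 10, n_cpgs = 0, n_donors = 10,
                     weather_missing = 0.2, seed = 24)
  tr2 <- simulate_traits(simulate_cohort(cfg2))
  expect_true(anyNA(tr2$weather$tmax))
})

test_that("methylation baseline is bimodal on the beta scale", {
  co <- simulate_cohort(sim_config(n_genes = 10, n_cpgs = 2000,
                                   n_donors = 20, seed = 25))
  m <- rowMeans(unclass(co$methylation[[1]]))
  beta <- 2 ^ m / (2 ^ m + 1)
  expect_gt(mean(beta < 0.25), 0.3)  # low-methylation component
  expect_gt(mean(beta > 0.75), 0.3)  # high-methylation component
})

test_that("dropout removes samples and downstream pairing still works", {
  cfg <- sim_config(n_genes = 100, n_cpgs = 0, n_donors = 30,
                    dropout = 0.1, seed = 26)
  co <- simulate_cohort(cfg)
  expect_lt(nrow(co$design), 90)
  gs1 <- group_stats(co$expression[[1]])
  gs2 <- group_stats(co$expression[[2]])
  expect_silent(suppressMessages(
    paired_diffvar_test(gs1$absdev, gs2$absdev)))
})

test_that("recovery metrics follow their definitions", {
  truth <- data.frame(
    feature_id = sprintf("f%03d", 1:100),
    assay = "expression",
    label = "specific:monocyte",
    inflation = 4, genetic = FALSE)
  # perfect recovery
  cls_perfect <- data.frame(feature_id = sprintf("f%03d", 1:100),
                            label = "specific:monocyte")
  ev <- truth_eval(cls_perfect, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$label_accuracy, 1)
  # empty classification
  cls_none <- data.frame(feature_id = sprintf("f%03d", 1:100),
                         label = "none")
  expect_equal(truth_eval(cls_none, truth)$sensitivity, 0)
  # 80 of 100 recovered plus 5 false calls: sens 0.80, precision 80/85
  cls_part <- data.frame(
    feature_id = sprintf("f%03d", 1:120),
    label = c(rep("specific:monocyte", 80), rep("none", 20),
              rep("specific:monocyte", 5), rep("none", 15)))
  ev2 <- truth_eval(cls_part, truth)
  expect_equal(ev2$sensitivity, 0.80)
  expect_equal(ev2$precision, 80 / 85)
})
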