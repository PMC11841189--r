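test_that("generators are deterministic given the seed", {
  p <- sim_params(n_genes = 100, seed = 55)
  expect_identical(simulate_counts(p)$counts, simulate_counts(p)$counts)
  a <- simulate_de_tables(p); b <- simulate_de_tables(p)
  expect_identical(a$tables$h2o2, b$tables$h2o2)
  expect_identical(a$truth, b$truth)
  n1 <- simulate_network(30, 3, decoy_density = 1, seed = 9)
  n2 <- simulate_network(30, 3, decoy_density = 1, seed = 9)
  expect_identical(n1$network$edges, n2$network$edges)
  ct1 <- simulate_ct_table(a$truth, 5, ct_noise_sd = 0.3, seed = 2)
  ct2 <- simulate_ct_table(a$truth, 5, ct_noise_sd = 0.3, seed = 2)
  expect_identical(ct1, ct2)
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_de_tables(p)); after <- runif(1)
  expect_identical(before, after)
})

test_that("planted effects are consistent with the class definitions", {
  truth <- simulate_de_tables(sim_params(n_genes = 3000, seed = 31))$truth
  with_class <- function(k) truth[truth$true_class == k, ]
  expect_true(all(with_class("NULL")$lfc_h2o2 == 0))
  expect_true(all(with_class("STRICT_UP")$lfc_h2o2 >= 0.5 &
                    with_class("STRICT_UP")$lfc_combined == 0))
  pu <- with_class("PARTIAL_UP")
  expect_true(all(pu$lfc_h2o2 - pu$lfc_combined >= 1 &
                    sign(pu$lfc_combined) == sign(pu$lfc_h2o2) &
                    abs(pu$lfc_combined) < abs(pu$lfc_h2o2)))
  en <- with_class("ENHANCED_DOWN")
  expect_true(all(abs(en$lfc_combined) > abs(en$lfc_h2o2) &
                    abs(en$lfc_h2o2 - en$lfc_combined) >= 1))
  an <- with_class("ANTAG_UP_TO_DOWN")
  expect_true(all(sign(an$lfc_h2o2) != sign(an$lfc_combined)))
  la <- with_class("LACL3_ARTIFACT")
  expect_true(all(la$lfc_combined == la$lfc_lacl3))
  ind <- with_class("INDEPENDENT")
  expect_true(all(abs(ind$lfc_h2o2 - ind$lfc_combined) < 1))
  # all-null proportions give all-zero truth
  p0 <- sim_params(n_genes = 50, class_proportions = c("NULL" = 1), seed = 1)
  t0 <- simulate_de_tables(p0)$truth
  expect_true(all(t0$lfc_h2o2 == 0 & t0$lfc_combined == 0 & t0$lfc_lacl3 == 0))
})

test_that("negative-binomial counts match their planted means", {
  p <- sim_params(n_genes = 2000, nb_dispersion = 0.05, seed = 71)
  sim <- simulate_counts(p)
  ctrl <- sim$counts[, sim$design$sample[sim$design$condition == "control"]]
  mu <- sim$baseline_mean
  se <- sqrt((mu + p$nb_dispersion * mu^2) / ncol(ctrl))
  within <- abs(rowMeans(ctrl) - mu) <= 3 * se
  expect_gte(mean(within), 0.99)
  expect_error(sim_params(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_params(lfc_se = 0), "lfc_se")
})

test_that("full-null DE tables respect the BH guarantee", {
  p0 <- sim_params(n_genes = 20000, class_proportions = c("NULL" = 1), seed = 17)
  sim <- simulate_de_tables(p0)
  frac <- mean(sim$tables$h2o2$fdr < 0.01)
  mc_err <- 3 * sqrt(0.01 * 0.99 / 20000)
  expect_lte(frac, 0.01 + mc_err)
})

test_that("Ct tables reproduce planted fold changes through 2^-ddCt", {
  truth <- data.frame(gene_id = c("gA", "gB", "gC"),
                      true_class = c("STRICT_UP", "PARTIAL_DOWN", "INDEPENDENT"),
                      lfc_h2o2 = c(1, -2.5, 1.8),
                      lfc_combined = c(0, -1, 1.7),
                      lfc_lacl3 = c(0, 0, 0))
  ct <- simulate_ct_table(truth, 3, ct_noise_sd = 0, seed = 3)
  dd <- delta_delta_ct(ct, "gA", treated = "h2o2", control = "control")
  expect_equal(dd$ratio, 2.0, tolerance = 1e-12)
  lr <- vapply(truth$gene_id, function(g) {
    delta_delta_ct(ct, g, "h2o2_lacl3", "control")$log2_ratio
  }, numeric(1))
  expect_equal(unname(lr), truth$lfc_combined, tolerance = 1e-12)
  cc <- concordance(vapply(truth$gene_id, function(g) {
    delta_delta_ct(ct, g, "h2o2", "control")$log2_ratio
  }, numeric(1)), truth$lfc_h2o2)
  expect_equal(cc$pearson_r, 1, tolerance = 1e-12)
  expect_error(simulate_ct_table(truth, 3, ct_noise_sd = -1), "ct_noise_sd")
})

test_that("noisy qPCR regression slope stays near unity across seeds", {
  truth <- simulate_de_tables(sim_params(n_genes = 300, seed = 23))$truth
  ok <- 0
  for (s in 1:50) {
    ct <- simulate_ct_table(truth, 10, ct_noise_sd = 0.3, seed = s)
    g <- attr(ct, "assayed_genes")
    lr <- vapply(seq_len(nrow(g)), function(i) {
      delta_delta_ct(ct, g$gene_id[i], "h2o2", "control")$log2_ratio
    }, numeric(1))
    slope <- concordance(lr, g$lfc_h2o2)$slope
    ok <- ok + (slope >= 0.8 && slope <= 1.2)
  }
  expect_gte(ok, 45)
})

test_that("network planting validates capacity", {
  expect_error(simulate_network(5, 10, seed = 1), "capacity")
  expect_error(simulate_network(30, 0, seed = 1), "nothing to plant")
})
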