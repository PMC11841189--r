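# Build a DE table whose calls are forced: DEGs get fdr 1e-6, UC genes fdr 0.9.
forced_de <- function(genes, lfc, deg, contrast) {
  out <- data.frame(gene_id = genes, log2fc = lfc,
                    pvalue = ifelse(deg, 1e-7, 0.8),
                    fdr = ifelse(deg, 1e-6, 0.9),
                    stringsAsFactors = FALSE)
  attr(out, "contrast_id") <- contrast
  out
}

test_that("classify_gene reproduces the dependency taxonomy", {
  expect_equal(classify_gene("UP", 1.2, "UC", 0.1)$dep_class, "STRICT")
  expect_equal(classify_gene("UP", 1.2, "UC", 0.1)$direction, "UP")
  expect_equal(classify_gene("UP", 2.6, "UP", 1.2)$dep_class, "PARTIAL_ADDITIVE")
  expect_equal(classify_gene("UP", 0.8, "DOWN", -0.9)$dep_class, "ANTAGONISTIC")
  expect_equal(classify_gene("DOWN", -1.0, "DOWN", -2.3)$dep_class, "ENHANCED")
  expect_equal(classify_gene("DOWN", -1.0, "DOWN", -2.3)$direction, "DOWN")
  expect_equal(classify_gene("UP", 1.0, "UP", 0.7)$dep_class, "INDEPENDENT")
  expect_equal(classify_gene("UP", 1.0, "UP", 0.7)$delta_log2fc, 0.3)
  # combined UC beats the delta criterion even when |delta| < 1
  expect_equal(classify_gene("UP", 0.6, "UC", 0.45)$dep_class, "STRICT")
  expect_error(classify_gene("UC", 0.1, "UC", 0), "domain")
})

test_that("filter_lacl3_shared distinguishes identity and same-direction modes", {
  comb <- data.frame(gene_id = c("g1", "g2", "g3"),
                     status = c("UP", "UP", "UP"))
  la <- data.frame(gene_id = c("g1", "g2", "g3"),
                   status = c("UP", "UC", "DOWN"))
  expect_equal(filter_lacl3_shared(comb, la, "identity"), "g2")
  expect_setequal(filter_lacl3_shared(comb, la, "same_direction"), c("g2", "g3"))
})

test_that("classify_genes runs the full per-tissue inference", {
  genes <- c("strict", "partial", "antag", "indep", "artifact", "comb_only", "null")
  h2o2 <- forced_de(genes,
                    lfc = c(2.0, 3.0, 1.5, 2.0, 2.0, 0.0, 0.0),
                    deg = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                    "H2O2_vs_ctrl")
  comb <- forced_de(genes,
                    lfc = c(0.0, 1.2, -1.5, 1.9, 2.0, 1.0, 0.0),
                    deg = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                    "H2O2LaCl3_vs_ctrl")
  la <- forced_de(genes,
                  lfc = c(0, 0, 0, 0, 2.0, 0, 0),
                  deg = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
                  "LaCl3_vs_ctrl")
  cl <- classify_genes(h2o2, comb, la)
  expect_setequal(cl$gene_id, c("strict", "partial", "antag", "indep", "artifact"))
  got <- setNames(cl$dep_class, cl$gene_id)
  expect_equal(got[["strict"]], "STRICT")
  expect_equal(got[["partial"]], "PARTIAL_ADDITIVE")
  expect_equal(got[["antag"]], "ANTAGONISTIC")
  expect_equal(got[["indep"]], "INDEPENDENT")
  expect_true(is.na(got[["artifact"]]))
  expect_true(cl$excluded_lacl3_shared[cl$gene_id == "artifact"])
  expect_equal(attr(cl, "combined_only"), "comb_only")
})

test_that("tabulate_classes reproduces the count arithmetic", {
  tab <- tabulate_classes(c(rep("STRICT", 295),
                            rep("PARTIAL_ADDITIVE", 20),
                            rep("ENHANCED", 3),
                            rep("ANTAGONISTIC", 13),
                            rep("INDEPENDENT", 670)))
  expect_equal(tab$strict, 295)
  expect_equal(tab$partial_or_antagonistic, 36)
  expect_equal(tab$total_dependent, 331)
  expect_equal(tab$n_total, 1001)
  expect_equal(tab$dependent_fraction, 331 / 1001)

  empty <- tabulate_classes(character(0))
  expect_equal(empty$total_dependent, 0)
  expect_equal(unname(empty$per_class), rep(0L, 5))
  expect_equal(empty$dependent_fraction, 0)
})

test_that("classification partitions genes and is monotone in delta_cutoff", {
  sim <- simulate_de_tables(sim_params(n_genes = 1000, seed = 77))
  base <- classify_genes(sim$tables$h2o2, sim$tables$combined, sim$tables$lacl3)
  kept <- base[!base$excluded_lacl3_shared, ]
  expect_true(all(kept$dep_class %in%
                    c("STRICT", "PARTIAL_ADDITIVE", "ENHANCED",
                      "ANTAGONISTIC", "INDEPENDENT")))
  expect_true(all(table(kept$gene_id) == 1))
  # class invariants
  expect_true(all(kept$status_combined[kept$dep_class == "STRICT"] == "UC"))
  ant <- kept[kept$dep_class == "ANTAGONISTIC", ]
  expect_true(all(sign(ant$lfc_h2o2) != sign(ant$lfc_combined)))
  dep <- kept[kept$dep_class != "INDEPENDENT", ]
  expect_true(all(dep$status_combined == "UC" | abs(dep$delta_log2fc) >= 1))

  for (dc in c(1.5, 2, 3)) {
    cfg <- run_config(delta_cutoff = dc)
    harder <- classify_genes(sim$tables$h2o2, sim$tables$combined,
                             sim$tables$lacl3, config = cfg)
    was_indep <- base$gene_id[!base$excluded_lacl3_shared &
                                base$dep_class == "INDEPENDENT"]
    now <- harder$dep_class[match(was_indep, harder$gene_id)]
    expect_true(all(now == "INDEPENDENT"))
  }
})

test_that("noiseless simulation is classified exactly and artifacts are filtered", {
  params <- sim_params(n_genes = 2000, lfc_se = 1e-8, seed = 99)
  sim <- simulate_de_tables(params)
  cl <- classify_genes(sim$tables$h2o2, sim$tables$combined, sim$tables$lacl3)
  truth <- sim$truth
  expected <- expected_classification(truth$true_class)

  # every LaCl3 artifact is excluded by the unique-DEG filter
  artifacts <- truth$gene_id[truth$true_class == "LACL3_ARTIFACT"]
  expect_setequal(cl$gene_id[cl$excluded_lacl3_shared], artifacts)

  # every other planted non-null gene is recovered with its exact class
  m <- match(cl$gene_id, truth$gene_id)
  kept <- !cl$excluded_lacl3_shared
  expect_setequal(cl$gene_id[kept],
                  truth$gene_id[!(truth$true_class %in% c("NULL", "LACL3_ARTIFACT"))])
  expect_equal(cl$dep_class[kept], expected$dep_class[m][kept])
  dir_check <- kept & cl$dep_class != "INDEPENDENT"
  expect_equal(cl$direction[dir_check], expected$direction[m][dir_check])

  # exact count identity against planted truth
  tab <- tabulate_classes(cl)
  planted <- table(expected$dep_class[!(truth$true_class %in% c("NULL", "LACL3_ARTIFACT"))])
  expect_equal(unname(tab$per_class[names(planted)]),
               unname(as.integer(planted)))
  expect_equal(tab$total_dependent,
               tab$strict + unname(tab$per_class["PARTIAL_ADDITIVE"]) +
                 unname(tab$per_class["ENHANCED"]) +
                 unname(tab$per_class["ANTAGONISTIC"]))
})
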