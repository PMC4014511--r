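small_cfg <- function(...) {
  sim_config(n_animals_per_muscle = 10, n_genes = 60, seed = 7, ...)
}

test_that("sim_config validates its inputs", {
  expect_s3_class(small_cfg(), "sim_config")
  expect_error(sim_config(prop_de = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 0), "positive count")
  expect_error(sim_config(fc_min = 2, fc_max = 1.5), "fc_min")
  expect_error(sim_config(qpcr_efficiency = 2.5), "efficiency")
})

test_that("planted fold changes respect the stated distribution", {
  cfg <- sim_config(seed = 3)               # default world: 1000 genes
  sim <- generate_expression(cfg)
  fc <- sim$truth$genes$fc_ratio[sim$truth$genes$direction != "null"]
  expect_true(all(fc >= 1.1 & fc <= 15))
  expect_lt(stats::median(fc), 1.5)
  expect_true(all(sim$truth$genes$fc_ratio[
    sim$truth$genes$direction == "null"] == 1))
})

test_that("null configuration plants nothing", {
  sim <- generate_expression(small_cfg(prop_de = 0))
  expect_true(all(sim$truth$genes$direction == "null"))
})

test_that("noiseless single-gene world reproduces its fold change exactly", {
  # sdlog = 0 degenerates the FC draw to exactly 2
  cfg <- small_cfg(prop_de = 1 / 60, fc_log_mean = log(log(2)),
                   fc_log_sd = 0, noise_sd = 0, flag_prob = 0)
  sim <- generate_expression(cfg)
  g <- sim$truth$genes[sim$truth$genes$direction != "null", ]
  expect_equal(nrow(g), 1L)
  expect_equal(g$fc_ratio, 2)
  probes <- sim$truth$probe_map$probe_id[
    sim$truth$probe_map$gene_id == g$gene_id]
  lm_cols <- sim$meta$sample_id[sim$meta$muscle == "LM"]
  sm_cols <- sim$meta$sample_id[sim$meta$muscle == "SM"]
  for (p in probes) {
    ratio <- mean(sim$expr$values[p, lm_cols]) /
      mean(sim$expr$values[p, sm_cols])
    expect_equal(if (g$direction == "LM") ratio else 1 / ratio, 2,
                 tolerance = 1e-12)
  }
})

test_that("generation is deterministic under a fixed seed and paired", {
  a <- generate_expression(small_cfg())
  b <- generate_expression(small_cfg())
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$expr$flags, b$expr$flags)
  expect_identical(a$truth, b$truth)
  # paired design: every animal appears once per muscle
  expect_equal(unname(table(a$meta$animal)), rep(2L, 10),
               ignore_attr = TRUE)
  expect_error(generate_expression(sim_config(n_animals_per_muscle = 3)),
               "at least 4")
})

test_that("empirical flag rate sits within 3 binomial SDs of flag_prob", {
  cfg <- small_cfg(flag_prob = 0.05)
  sim <- generate_expression(cfg)
  n <- length(sim$expr$flags)
  phat <- mean(sim$expr$flags)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(phat - 0.05), 3 * se)
})

test_that("module subtrees separate gene similarities at purity 1", {
  cfg <- small_cfg(n_modules = 2, annotation_purity = 1,
                   annotation_rate = 1)
  go <- generate_go_dag(cfg)
  genes <- names(go$annotations)
  same <- outer(go$modules[genes], go$modules[genes], "==")
  sims <- matrix(NA_real_, length(genes), length(genes))
  for (i in seq_along(genes))
    for (j in seq_along(genes))
      if (i < j)
        sims[i, j] <- oracle_bma(go$annotations[[i]], go$annotations[[j]],
                                 go$dag)
  within <- mean(sims[upper.tri(sims) & same], na.rm = TRUE)
  between <- mean(sims[upper.tri(sims) & !same], na.rm = TRUE)
  expect_lt(between, within)
  # module labels partition the annotated gene set
  expect_setequal(names(go$modules), names(go$annotations))
  expect_equal(sort(unique(go$modules)), paste0("M", 1:2))
})

test_that("single-term ontology collapses all similarities to 1", {
  dag <- go_dag(data.frame(id = "T1", name = "only",
                           namespace = "biological_process",
                           stringsAsFactors = FALSE),
                data.frame(child = character(0), parent = character(0),
                           type = character(0), stringsAsFactors = FALSE))
  expect_equal(gene_similarity("T1", "T1", dag), 1)
})

test_that("qPCR generator honours the Ct model", {
  cfg <- small_cfg(prop_de = 0.5, qpcr_noise_sd = 0,
                   fc_log_mean = log(log(2)), fc_log_sd = 0,
                   qpcr_efficiency = 2)
  sim <- generate_expression(cfg)
  ct <- generate_qpcr(cfg, sim$truth, n_targets = 3, n_refs = 2,
                      ref_noise_sd = 0)
  tg <- attr(ct, "targets")
  for (a in tg$gene_id) {
    g <- ct[ct$assay == a, ]
    dct <- mean(g$Ct[g$muscle == "SM"]) - mean(g$Ct[g$muscle == "LM"])
    # FC = 2, E = 2: exactly one cycle separates the muscles
    expect_equal(abs(dct), 1, tolerance = 1e-12)
  }
  refs <- ct[ct$role == "reference", ]
  q <- tapply(refs$Ct, list(refs$sample, refs$assay), mean)
  expect_equal(stats::sd(log2(2^-q[, 1] / 2^-q[, 2])), 0)
  ct2 <- generate_qpcr(cfg, sim$truth, n_targets = 3, n_refs = 2,
                       ref_noise_sd = 0)
  expect_identical(ct$Ct, ct2$Ct)
  expect_error(generate_qpcr(cfg, sim$truth, n_refs = 1), "at least 2")
})

test_that("forward model and DE analysis agree in the noiseless limit", {
  cfg <- sim_config(n_animals_per_muscle = 12, n_genes = 40, prop_de = 0.3,
                    noise_sd = 1e-4, flag_prob = 0, seed = 5)
  sim <- generate_expression(cfg)
  # feed ln intensities directly: the model carries an intercept, and
  # median centering under asymmetric DE shifts all contrasts by a small
  # common constant that is not the DE module's doing
  lnm <- expr_matrix(log(sim$expr$values), scale = "ln")
  de <- de_analysis(lnm, sim$meta)
  truth <- sim$truth$genes
  gmap <- sim$truth$probe_map
  tr <- truth[match(gmap$gene_id[match(de$probe_id, gmap$probe_id)],
                    truth$gene_id), ]
  planted <- tr$direction != "null"
  expect_true(all(de$direction[planted] == tr$direction[planted]))
  expect_true(all(abs(de$fc[planted] / tr$fc_ratio[planted] - 1) < 0.01))
})
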