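make_design <- function(n = 8) design_spec(tiny_meta(n), tiny_meta(n)$sample_id)

test_that("noiseless additive response is recovered exactly", {
  meta <- tiny_meta(8)
  des <- make_design(8)
  d <- des$data
  y <- 1 + 0.5 * (d$sex == "M") + 0.3 * (d$slaughter_batch == "w") +
    0.01 * d$carcass_weight + log(2) * (d$muscle == "LM")
  # drop1 warns about the exact fit; that is the point of the test
  fit <- suppressWarnings(fit_probe_model(y, des))
  expect_lt(fit$pvals[["muscle"]], 1e-10)
  am <- adjusted_means(fit)
  expect_equal(unname(am[["LM"]] - am[["SM"]]), log(2), tolerance = 1e-8)
})

test_that("coefficients match a brute-force normal-equations solve", {
  set.seed(31)
  des <- make_design(8)
  y <- stats::rnorm(16)
  fit <- fit_probe_model(y, des)
  X <- stats::model.matrix(
    ~ sex + slaughter_batch + carcass_weight + muscle, des$data)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(stats::coef(fit$fit)), unname(drop(beta)),
               tolerance = 1e-10)
})

test_that("null muscle p-values are uniform", {
  # 1000 independent null probes analysed in one matrix call
  set.seed(32)
  meta <- tiny_meta(8)
  v <- matrix(stats::rnorm(1000 * 16), 1000, 16,
              dimnames = list(sprintf("p%04d", 1:1000), meta$sample_id))
  de <- de_analysis(ln_expr(v), meta)
  ks <- stats::ks.test(de$p_muscle, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("backward retention keeps muscle and drops weak effects", {
  set.seed(33)
  des <- make_design(8)
  # pure-noise response: nuisance p-values are large with high probability
  y <- stats::rnorm(16, sd = 5)
  fit <- fit_probe_model(y, des)
  fake <- fit
  fake$pvals[des$effects] <- 0.9
  red <- select_effects(fake)
  expect_equal(red$effects, character(0))
  expect_equal(red$forced, "muscle")
  fake$pvals[des$effects] <- 0.001
  expect_equal(select_effects(fake)$effects, des$effects)
  # muscle is forced even at p = 0.99
  fake$pvals[["muscle"]] <- 0.99
  expect_true("muscle" %in% c(select_effects(fake)$forced))
  # boundary: p exactly at alpha_keep is dropped ("P < 0.2 kept")
  fake$pvals[des$effects] <- 0.2
  expect_equal(select_effects(fake)$effects, character(0))
})

test_that("adjusted means equal group means in balanced designs", {
  set.seed(34)
  meta <- tiny_meta(8)
  des <- make_design(8)
  y <- stats::rnorm(16)
  # muscle-only model
  des0 <- des; des0$effects <- character(0)
  am <- adjusted_means(fit_probe_model(y, des0))
  expect_equal(unname(am[["LM"]]), mean(y[des$data$muscle == "LM"]))
  expect_equal(unname(am[["SM"]]), mean(y[des$data$muscle == "SM"]))
  # balanced factors, no covariate: adjusted means = raw group means
  des1 <- des; des1$effects <- c("sex", "slaughter_batch")
  am1 <- adjusted_means(fit_probe_model(y, des1))
  expect_equal(unname(am1[["LM"]]), mean(y[des$data$muscle == "LM"]),
               tolerance = 1e-10)
})

test_that("adjusted means match grid enumeration on unbalanced data", {
  set.seed(35)
  meta <- tiny_meta(9)[-c(2, 5, 11), ]      # unbalance by dropping samples
  des <- design_spec(meta, meta$sample_id)
  y <- stats::rnorm(nrow(meta))
  fit <- fit_probe_model(y, des)
  am <- adjusted_means(fit)
  # oracle: average predictions over the full factor grid per muscle
  d <- des$data
  grid <- expand.grid(sex = levels(factor(d$sex)),
                      slaughter_batch = levels(factor(d$slaughter_batch)),
                      muscle = c("LM", "SM"))
  grid$carcass_weight <- mean(d$carcass_weight)
  pr <- stats::predict(fit$fit, newdata = grid)
  expect_equal(unname(am[["LM"]]), mean(pr[grid$muscle == "LM"]),
               tolerance = 1e-10)
  expect_equal(unname(am[["SM"]]), mean(pr[grid$muscle == "SM"]),
               tolerance = 1e-10)
})

test_that("DE calling is inclusive at alpha and FC rules hold", {
  expect_equal(call_de(c(0.05, 0.050001, NA, 0.01)),
               c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(call_de(numeric(0)), logical(0))

  fc <- fold_change(log(2), 0)
  expect_equal(fc$fc, 2); expect_equal(fc$direction, "LM")
  fc <- fold_change(0, log(3))
  expect_equal(fc$fc, 3); expect_equal(fc$direction, "SM")
  tie <- fold_change(1, 1)
  expect_true(tie$tie); expect_equal(tie$fc, 1)
  expect_true(is.na(tie$direction))
})

test_that("fast matrix path equals the per-probe lm path", {
  set.seed(36)
  meta <- tiny_meta(10)
  n_probes <- 40
  v <- matrix(stats::rnorm(n_probes * 20), n_probes, 20,
              dimnames = list(sprintf("p%02d", 1:n_probes), meta$sample_id))
  v[1:10, ] <- v[1:10, ] + log(3) * rep(c(1, 0), each = 10)[col(v[1:10, ])]
  de <- de_analysis(ln_expr(v), meta)
  des <- design_spec(meta, meta$sample_id)
  for (i in sample(n_probes, 8)) {
    slow <- semde:::de_one_probe(v[i, ], des, 0.2)
    row <- de[de$probe_id == rownames(v)[i], ]
    expect_equal(row$p_muscle, slow$p_muscle, tolerance = 1e-9)
    expect_equal(row$mean_LM, slow$mean_LM, tolerance = 1e-9)
    expect_equal(row$fc, slow$fc, tolerance = 1e-9)
    expect_equal(row$retained_effects, slow$retained_effects)
  }
  # probes with masked spots go through the lm path and are still reported
  miss <- array(FALSE, dim(v)); miss[3, 1:2] <- TRUE
  de_m <- de_analysis(expr_matrix(v, missing = miss, scale = "ln"), meta)
  expect_true("p03" %in% de_m$probe_id)
})

test_that("swapping muscle labels inverts directions and keeps FC", {
  set.seed(37)
  meta <- tiny_meta(8)
  v <- matrix(stats::rnorm(30 * 16), 30, 16,
              dimnames = list(sprintf("p%02d", 1:30), meta$sample_id))
  v[1:10, meta$muscle == "LM"] <- v[1:10, meta$muscle == "LM"] + 1
  de1 <- de_analysis(ln_expr(v), meta)
  meta2 <- meta
  meta2$muscle <- ifelse(meta$muscle == "LM", "SM", "LM")
  de2 <- de_analysis(ln_expr(v), meta2)
  expect_equal(de1$fc, de2$fc, tolerance = 1e-12)
  flip <- c(LM = "SM", SM = "LM")
  same <- !is.na(de1$direction)
  expect_equal(unname(flip[de1$direction[same]]), de2$direction[same])
  expect_equal(de1$p_muscle, de2$p_muscle, tolerance = 1e-12)
})

test_that("gene collapse and relevance filtering follow the rules", {
  de <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5", "p6", "p7"),
    p_muscle = 1e-6, adj_p = c(1e-4, 1e-3, 1e-4, 1e-4, 0.5, 1e-4, 1e-4),
    mean_LM = 0, mean_SM = 0,
    fc = c(2.0, 1.6, 3.0, 2.5, 9.9, 1.51, 4),
    direction = c("LM", "LM", "LM", "SM", "LM", "SM", "LM"),
    tie = FALSE,
    retained_effects = "",
    de = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p6"),
                    gene_id = c("g1", "g1", "g2", "g2", "g3"),
                    stringsAsFactors = FALSE)
  calls <- collapse_to_genes(de, map)
  expect_equal(nrow(calls), 3)
  g1 <- calls[calls$gene_id == "g1", ]
  expect_equal(g1$fc, 2.0); expect_equal(g1$direction, "LM")
  expect_false(g1$conflict)
  expect_true(calls$conflict[calls$gene_id == "g2"])
  expect_equal(attr(calls, "n_unannotated"), 1L)  # p7 is DE but unmapped

  kept <- relevance_filter(calls)
  expect_false("g2" %in% kept$gene_id)            # conflict excluded
  expect_true("g3" %in% kept$gene_id)             # 1.51 > 1.5 kept
  expect_true("g1" %in% kept$gene_id)
  calls2 <- calls; calls2$fc[calls2$gene_id == "g3"] <- 1.5
  expect_false("g3" %in% relevance_filter(calls2)$gene_id)  # 1.5 dropped
  expect_equal(nrow(relevance_filter(calls, min_fc = 1)), 2)
})
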