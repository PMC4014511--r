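flag_fixture <- function(n_per_muscle = 10, flag_counts_lm = 0,
                         flag_counts_sm = 0, n_probes = 3) {
  meta <- data.frame(
    sample_id = c(sprintf("s%02d_LM", seq_len(n_per_muscle)),
                  sprintf("s%02d_SM", seq_len(n_per_muscle))),
    muscle = rep(c("LM", "SM"), each = n_per_muscle),
    stringsAsFactors = FALSE)
  v <- matrix(exp(stats::rnorm(n_probes * 2 * n_per_muscle, 8, 1)),
              n_probes, 2 * n_per_muscle,
              dimnames = list(sprintf("p%d", seq_len(n_probes)),
                              meta$sample_id))
  fl <- array(FALSE, dim(v), dimnames = dimnames(v))
  flag_counts_lm <- rep_len(flag_counts_lm, n_probes)
  flag_counts_sm <- rep_len(flag_counts_sm, n_probes)
  for (i in seq_len(n_probes)) {
    if (flag_counts_lm[i] > 0) fl[i, seq_len(flag_counts_lm[i])] <- TRUE
    if (flag_counts_sm[i] > 0)
      fl[i, n_per_muscle + seq_len(flag_counts_sm[i])] <- TRUE
  }
  list(expr = expr_matrix(v, flags = fl), meta = meta)
}

test_that("flag filter removes probes strictly above the muscle threshold", {
  set.seed(1)
  # 90-sample muscles: 46/90 flagged (51%) removed, 45/90 (exactly 50%) kept
  fx <- flag_fixture(n_per_muscle = 90,
                     flag_counts_lm = c(46, 45, 0),
                     flag_counts_sm = c(0, 45, 0))
  out <- filter_flagged_probes(fx$expr, fx$meta)
  expect_setequal(rownames(out$values), c("p2", "p3"))
  expect_equal(attr(out, "removed"), "p1")
  # zero flags anywhere: identity on values
  fx0 <- flag_fixture()
  out0 <- filter_flagged_probes(fx0$expr, fx0$meta)
  expect_identical(out0$values, fx0$expr$values)
  # missing muscle label errors
  bad_meta <- fx0$meta[-1, ]
  expect_error(filter_flagged_probes(fx0$expr, bad_meta), "missing")
})

test_that("log_median_center lns and zeroes each sample median", {
  v <- matrix(c(5, 5, 5, exp(1), exp(2), exp(3)), 3, 2,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  out <- log_median_center(expr_matrix(v))
  expect_equal(unname(out$values[, "a"]), rep(0, 3))
  expect_equal(unname(out$values[, "b"]), c(-1, 0, 1))
  expect_equal(out$scale, "ln")
  expect_error(log_median_center(out), "already")

  set.seed(2)
  v <- matrix(exp(stats::rnorm(200, 8, 2)), 20, 10,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  cen <- log_median_center(expr_matrix(v))
  meds <- apply(cen$values, 2, stats::median)
  expect_true(all(abs(meds) < 1e-12))

  v[3, 4] <- -1
  expect_error(log_median_center(expr_matrix(v, missing = v < 0)), NA)
  v2 <- v; v2[3, 4] <- 0
  expect_error(log_median_center(expr_matrix(v2)), "p3.*s4")
})

test_that("outlier masking follows the single-pass 3-SD rule", {
  # constant probe: SD 0, strict inequality masks nothing
  v <- matrix(1, 2, 6, dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
  out <- mask_probe_outliers(ln_expr(v))
  expect_equal(out$n_masked, 0L)

  # 20 zeros and one 10: compare against the direct 21-value computation
  x <- c(rep(0, 20), 10)
  v <- matrix(rep(x, each = 1), 1, 21, byrow = TRUE,
              dimnames = list("p1", paste0("s", 1:21)))
  out <- mask_probe_outliers(ln_expr(v))
  is_out <- abs(10 - mean(x)) > 3 * stats::sd(x)
  expect_equal(out$n_masked, as.integer(is_out))
  expect_equal(unname(out$expr$missing[1, 21]), is_out)

  # k_sd = Inf is the identity
  out_inf <- mask_probe_outliers(ln_expr(v), k_sd = Inf)
  expect_equal(out_inf$n_masked, 0L)

  # fewer than 3 usable spots: skipped with a warning
  v2 <- matrix(stats::rnorm(4), 2, 2,
               dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_warning(mask_probe_outliers(ln_expr(v2)), "skipped")
})

test_that("sparsity drop enforces the per-muscle majority rule", {
  fx <- flag_fixture(n_per_muscle = 6, n_probes = 3)
  m <- log_median_center(fx$expr)
  # mask 4/6 SM entries of probe 2 (> 50%)
  m$missing[2, 9:12] <- TRUE
  out <- drop_sparse_probes(m, fx$meta)
  expect_setequal(rownames(out$values), c("p1", "p3"))
  # threshold 1 is the identity
  out1 <- drop_sparse_probes(m, fx$meta, max_bad_fraction = 1)
  expect_equal(nrow(out1$values), 3)
})

test_that("k-means variance filter removes exactly the low band", {
  set.seed(9)
  n <- c(20, 20, 20)
  sds <- sqrt(c(0.01, 1, 100))
  v <- do.call(rbind, lapply(1:3, function(b)
    matrix(stats::rnorm(n[b] * 30, 0, sds[b]), n[b], 30)))
  dimnames(v) <- list(sprintf("p%02d", 1:60), sprintf("s%02d", 1:30))
  out <- variance_filter_kmeans(ln_expr(v), k = 3, seed = 42)
  vars <- apply(v, 1, stats::var)
  lab <- oracle_kmeans1d(log(vars), 3)
  low_band <- rownames(v)[lab == lab[which.min(vars)]]
  expect_setequal(out$removed, low_band)
  # determinism
  out2 <- variance_filter_kmeans(ln_expr(v), k = 3, seed = 42)
  expect_identical(out$removed, out2$removed)
  expect_error(variance_filter_kmeans(ln_expr(v), k = 1), ">= 2")
  # degenerate: all variances equal
  vc <- matrix(rep(c(-1, 1), 15), 4, 30, byrow = TRUE,
               dimnames = list(paste0("p", 1:4), sprintf("s%02d", 1:30)))
  expect_warning(res <- variance_filter_kmeans(ln_expr(vc), k = 3),
                 "identical")
  expect_equal(length(res$removed), 0L)
})

test_that("qc_pipeline report counts reconcile with the output", {
  cfg <- sim_config(n_animals_per_muscle = 10, n_genes = 80, seed = 21,
                    flag_prob = 0.03)
  sim <- generate_expression(cfg)
  qc <- qc_pipeline(sim$expr, sim$meta, verbose = FALSE)
  r <- qc$report
  expect_equal(r[["probes_in"]] - r[["probes_removed_by_flags"]] -
                 r[["probes_removed_by_missingness"]] -
                 r[["probes_removed_by_variability"]],
               r[["probes_remaining"]])
  expect_equal(nrow(qc$expr$values), r[["probes_remaining"]])
})

test_that("no strongly-DE probe lands in the removed low-variance cluster", {
  cfg <- sim_config(n_animals_per_muscle = 15, n_genes = 300, prop_de = 0.2,
                    fc_log_mean = log(log(2.5)), fc_log_sd = 0.2,
                    flag_prob = 0, seed = 13)
  sim <- generate_expression(cfg)
  qc <- qc_pipeline(sim$expr, sim$meta, verbose = FALSE)
  tg <- sim$truth$genes
  strong <- tg$gene_id[tg$direction != "null" & tg$fc_ratio >= 2]
  strong_probes <- sim$truth$probe_map$probe_id[
    sim$truth$probe_map$gene_id %in% strong]
  expect_true(all(strong_probes %in% rownames(qc$expr$values)))
})
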