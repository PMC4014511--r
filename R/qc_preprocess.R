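#' Remove probes with too many flagged spots within either muscle
#'
#' A probe is deleted when its fraction of quality-flagged spots exceeds
#' `max_flag_fraction` (strictly — "more than 50%") in at least one muscle
#' group; surviving probes pass through unchanged.  Flagged spots of
#' surviving probes are masked from further analysis.
#'
#' @param m an [expr_matrix()].
#' @param meta sample metadata with `sample_id` and `muscle` columns.
#' @param max_flag_fraction threshold fraction; default 0.5.
#' @return filtered [expr_matrix()] with flagged spots added to the
#'   missingness mask; attribute `removed` holds the dropped probe ids.
#' @export
filter_flagged_probes <- function(m, meta, max_flag_fraction = 0.5) {
  meta <- check_metadata(meta, m)
  muscle <- meta$muscle[match(colnames(m$values), meta$sample_id)]
  frac <- vapply(levels(muscle), function(g) {
    cols <- muscle == g
    rowMeans(m$flags[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  frac <- matrix(frac, nrow = nrow(m$values))
  drop <- apply(frac > max_flag_fraction, 1, any)
  out <- subset_probes(m, !drop)
  out$missing <- out$missing | out$flags
  attr(out, "removed") <- rownames(m$values)[drop]
  out
}

#' Natural-log transform and center within sample at the median
#'
#' Applies `ln` elementwise (masked entries ignored) and subtracts each
#' sample's median of non-missing values, so every column's median becomes
#' zero.  The scale tag transitions raw -> ln exactly once.
#'
#' @param m an [expr_matrix()] on the raw scale with strictly positive
#'   unmasked values.
#' @return centered [expr_matrix()] on the ln scale.
#' @export
log_median_center <- function(m) {
  if (m$scale != "raw") stop("matrix is already on the ln scale")
  v <- m$values
  bad <- which(!m$missing & v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("nonpositive intensity at probe %s, sample %s",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  ln <- v
  ln[!m$missing] <- log(v[!m$missing])
  med <- vapply(seq_len(ncol(ln)), function(j)
    stats::median(ln[!m$missing[, j], j]), 0)
  ln <- sweep(ln, 2, med)
  expr_matrix(ln, m$flags, m$missing, scale = "ln")
}

#' Mask within-probe outlier spots
#'
#' Within each probe, entries deviating from the probe mean by more than
#' `k_sd` standard deviations are masked.  Mean and SD are taken over the
#' probe's non-missing entries in a single pass — the candidate outlier is
#' included in its own estimate.  Probes with fewer than 3 usable entries
#' are skipped with a warning.
#'
#' @param m an [expr_matrix()] on the ln scale.
#' @param k_sd deviation threshold in SD units; default 3.
#' @return list with `expr` (masked matrix) and `n_masked` (spot count).
#' @export
mask_probe_outliers <- function(m, k_sd = 3) {
  if (m$scale != "ln") stop("outlier masking expects the ln scale")
  missing <- m$missing
  n_masked <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(m$values))) {
    use <- !missing[i, ]
    if (sum(use) < 3) { skipped <- skipped + 1L; next }
    x <- m$values[i, use]
    mu <- mean(x)
    s <- stats::sd(x)
    out <- abs(x - mu) > k_sd * s
    if (any(out)) {
      missing[i, use][out] <- TRUE
      n_masked <- n_masked + sum(out)
    }
  }
  if (skipped)
    warning(skipped, " probe(s) with <3 usable spots skipped by outlier mask")
  list(expr = expr_matrix(m$values, m$flags, missing, scale = m$scale),
       n_masked = n_masked)
}

#' Remove probes that are mostly flagged-or-outlier within either muscle
#'
#' After outlier masking, a probe whose flagged-or-masked fraction exceeds
#' `max_bad_fraction` in at least one muscle is removed.
#'
#' @param m an [expr_matrix()] with masking applied.
#' @param meta sample metadata.
#' @param max_bad_fraction threshold fraction; default 0.5.
#' @return filtered [expr_matrix()]; attribute `removed` lists dropped probes.
#' @export
drop_sparse_probes <- function(m, meta, max_bad_fraction = 0.5) {
  meta <- check_metadata(meta, m)
  muscle <- meta$muscle[match(colnames(m$values), meta$sample_id)]
  bad <- m$missing | m$flags
  frac <- vapply(levels(muscle), function(g) {
    cols <- muscle == g
    rowMeans(bad[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  frac <- matrix(frac, nrow = nrow(m$values))
  drop <- apply(frac > max_bad_fraction, 1, any)
  out <- subset_probes(m, !drop)
  attr(out, "removed") <- rownames(m$values)[drop]
  out
}

#' Filter out the lowest-variability probes by 1-D k-means
#'
#' Per-probe variance is computed over non-missing entries; k-means with
#' `k` clusters (10 restarts, seeded) partitions `ln(variance)` and the
#' cluster with the smallest center is removed, discarding probes whose
#' expression barely varies across samples and would only dilute the
#' multiple-testing burden.
#'
#' @param m an [expr_matrix()] on the ln scale.
#' @param k number of clusters; must be >= 2 (with k = 1 every probe would
#'   sit in the removed cluster).
#' @param seed RNG seed for the restarts.
#' @return list with `expr` (filtered matrix) and `removed` (probe ids).
#' @export
variance_filter_kmeans <- function(m, k = 3, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  v <- masked_values(m)
  vars <- apply(v, 1, stats::var, na.rm = TRUE)
  if (any(is.na(vars))) stop("probe variance undefined (fewer than 2 spots)")
  if (nrow(m$values) < k) stop("need at least k probes")
  if (diff(range(vars)) < .Machine$double.eps * max(vars)) {
    warning("all probe variances identical; variance filter removed nothing")
    return(list(expr = m, removed = character(0)))
  }
  lv <- log(vars)
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  set.seed(seed)
  km <- stats::kmeans(lv, centers = k, nstart = 10)
  low <- which.min(km$centers)
  drop <- km$cluster == low
  list(expr = subset_probes(m, !drop),
       removed = rownames(m$values)[drop])
}

#' Full quality-control pipeline
#'
#' Fixed stage order: flag filter -> ln + median centering -> outlier
#' masking -> sparsity drop -> k-means variability filter.  Stage counts are
#' logged to standard error and collected into a QC report.
#'
#' @param m raw-scale [expr_matrix()].
#' @param meta sample metadata.
#' @param max_flag_fraction,k_sd,max_bad_fraction,kmeans_k stage thresholds
#'   (defaults 0.5, 3, 0.5, 3).
#' @param seed k-means seed.
#' @param verbose log per-stage counts to stderr.
#' @return list with `expr` (filtered, centered ln matrix) and `report`
#'   (named counts: probes_in, probes_removed_by_flags,
#'   outlier_spots_masked, probes_removed_by_missingness,
#'   probes_removed_by_variability, probes_remaining).
#' @export
qc_pipeline <- function(m, meta, max_flag_fraction = 0.5, k_sd = 3,
                        max_bad_fraction = 0.5, kmeans_k = 3, seed = 1L,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[qc] ", sprintf(...))
  n0 <- nrow(m$values)
  m1 <- filter_flagged_probes(m, meta, max_flag_fraction)
  say("flag filter: %d -> %d probes", n0, nrow(m1$values))
  m2 <- log_median_center(m1)
  om <- mask_probe_outliers(m2, k_sd)
  say("outlier mask: %d spots masked", om$n_masked)
  m3 <- drop_sparse_probes(om$expr, meta, max_bad_fraction)
  say("sparsity drop: %d -> %d probes", nrow(om$expr$values), nrow(m3$values))
  vf <- variance_filter_kmeans(m3, kmeans_k, seed)
  say("variance filter: %d -> %d probes",
      nrow(m3$values), nrow(vf$expr$values))
  report <- c(probes_in = n0,
              probes_removed_by_flags = n0 - nrow(m1$values),
              outlier_spots_masked = om$n_masked,
              probes_removed_by_missingness =
                nrow(om$expr$values) - nrow(m3$values),
              probes_removed_by_variability =
                nrow(m3$values) - nrow(vf$expr$values),
              probes_remaining = nrow(vf$expr$values))
  list(expr = vf$expr, report = report)
}
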