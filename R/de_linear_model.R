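#' Design specification for the per-probe linear model
#'
#' Encodes the fixed-effects model
#' `Y = Sex + SlaughterBatch + HybridizationBatch(Sire) + CarcassWeight +
#' Muscle + E` fitted to each probe's centered ln expression.  The
#' hybridization-batch factor is nested within sire family: its levels are
#' the sire:batch combinations, never pooled across families.  Muscle is a
#' forced effect and is always retained.  Nuisance effects whose columns are
#' absent from the metadata, or which have fewer than two observed levels,
#' are dropped from the candidate set.
#'
#' @param meta sample metadata (`sample_id`, `muscle`, and optionally `sex`,
#'   `slaughter_batch`, `sire`, `hyb_batch`, `carcass_weight`).
#' @param sample_order character vector of sample ids giving the column
#'   order of the expression matrix.
#' @return object of class `design_spec`: list with `data` (model frame),
#'   `effects` (candidate nuisance effects) and `forced` (`"muscle"`).
#' @export
design_spec <- function(meta, sample_order) {
  meta <- check_metadata(meta)
  idx <- match(sample_order, meta$sample_id)
  if (anyNA(idx)) stop("samples absent from metadata: ",
                       paste(sample_order[is.na(idx)], collapse = ", "))
  meta <- meta[idx, , drop = FALSE]
  d <- data.frame(muscle = factor(meta$muscle), row.names = meta$sample_id)
  effects <- character(0)
  if (!is.null(meta$sex)) {
    d$sex <- factor(meta$sex)
    effects <- c(effects, "sex")
  }
  if (!is.null(meta$slaughter_batch)) {
    d$slaughter_batch <- factor(meta$slaughter_batch)
    effects <- c(effects, "slaughter_batch")
  }
  if (!is.null(meta$hyb_batch)) {
    hb <- if (!is.null(meta$sire))
      paste(meta$sire, meta$hyb_batch, sep = ":") else meta$hyb_batch
    d$hyb_batch <- factor(hb)
    effects <- c(effects, "hyb_batch")
  }
  if (!is.null(meta$carcass_weight)) {
    d$carcass_weight <- as.numeric(meta$carcass_weight)
    effects <- c(effects, "carcass_weight")
  }
  # factors collapsing to a single level carry no information
  keep <- vapply(effects, function(e)
    !is.factor(d[[e]]) || nlevels(droplevels(d[[e]])) > 1, TRUE)
  structure(list(data = d, effects = effects[keep], forced = "muscle"),
            class = "design_spec")
}

de_formula <- function(effects, forced = "muscle") {
  stats::reformulate(c(effects, forced), response = "y")
}

#' Fit the fixed-effects model to one probe
#'
#' Ordinary least squares on the probe's non-missing entries; per-effect
#' p-values come from partial F-tests (model-comparison / type-III-like:
#' each effect dropped from the otherwise full model), as required by the
#' backward retention rule on unbalanced data.
#'
#' @param y numeric response vector (NAs allowed), aligned with
#'   `design$data` rows.
#' @param design a [design_spec()]; its `effects` element defines the model.
#' @return list with `fit` (an `lm`), `pvals` (named per-effect partial-F
#'   p-values, forced effect included) and `design`; or `NULL` when the
#'   probe has no residual degrees of freedom left.
#' @export
fit_probe_model <- function(y, design) {
  stopifnot(inherits(design, "design_spec"))
  d <- design$data
  d$y <- y
  terms_all <- c(design$effects, design$forced)
  fit <- stats::lm(de_formula(design$effects, design$forced), data = d,
                   na.action = stats::na.exclude)
  if (stats::df.residual(fit) < 1) return(NULL)
  dr <- stats::drop1(fit, scope = de_formula(design$effects, design$forced),
                     test = "F")
  pv <- stats::setNames(dr[["Pr(>F)"]][match(terms_all, rownames(dr))],
                        terms_all)
  list(fit = fit, pvals = pv, design = design)
}

#' Backward effect retention
#'
#' One backward pass over the full model: every non-forced effect whose
#' partial-F p-value reaches `alpha_keep` or more is removed; the forced
#' muscle effect is always retained.  The reduced design is returned for a
#' single refit.
#'
#' @param fitinfo result of [fit_probe_model()] on the full design.
#' @param alpha_keep retention threshold; effects with p < `alpha_keep`
#'   stay (default 0.2).
#' @return a reduced [design_spec()].
#' @export
select_effects <- function(fitinfo, alpha_keep = 0.2) {
  design <- fitinfo$design
  pv <- fitinfo$pvals[design$effects]
  keep <- !is.na(pv) & pv < alpha_keep
  out <- design
  out$effects <- design$effects[keep]
  out
}

#' Least-squares adjusted means for the two muscles
#'
#' Model prediction for each muscle level, averaging every retained factor's
#' levels with equal weight and fixing covariates at their sample mean — the
#' conventional lsmeans definition.
#'
#' @param fitinfo result of [fit_probe_model()] on the final design.
#' @return named numeric: `mean_LM`-style entries keyed by muscle level
#'   (ln scale).
#' @export
adjusted_means <- function(fitinfo) {
  fit <- fitinfo$fit
  design <- fitinfo$design
  d <- design$data
  fac <- design$effects[vapply(design$effects,
                               function(e) is.factor(d[[e]]), TRUE)]
  cov <- setdiff(design$effects, fac)
  grid_vars <- c(stats::setNames(lapply(fac, function(e)
    levels(droplevels(d[[e]]))), fac),
    list(muscle = levels(d$muscle)))
  grid <- expand.grid(grid_vars, stringsAsFactors = TRUE)
  for (e in cov) grid[[e]] <- mean(d[[e]], na.rm = TRUE)
  pred <- stats::predict(fit, newdata = grid)
  vapply(levels(d$muscle), function(g)
    mean(pred[grid$muscle == g]), 0)
}

#' Select differentially expressed probes
#'
#' @param adj_p vector of BH-adjusted p-values.
#' @param alpha significance level; selection is inclusive
#'   (adjusted p of exactly `alpha` is selected).
#' @return logical vector.
#' @export
call_de <- function(adj_p, alpha = 0.05) {
  !is.na(adj_p) & adj_p <= alpha
}

#' Fold change and direction from two adjusted means
#'
#' FC is the anti-log ratio of the greatest to the least adjusted mean, so
#' FC >= 1 always; the direction is the muscle with the greater mean.  An
#' exact tie yields FC 1, no direction, and a tie flag.
#'
#' @param mean_lm,mean_sm adjusted means on the ln scale.
#' @return list with `fc`, `direction` (`"LM"`, `"SM"` or `NA`), `tie`.
#' @export
fold_change <- function(mean_lm, mean_sm) {
  if (mean_lm == mean_sm)
    return(list(fc = 1, direction = NA_character_, tie = TRUE))
  list(fc = exp(abs(mean_lm - mean_sm)),
       direction = if (mean_lm > mean_sm) "LM" else "SM",
       tie = FALSE)
}

# --- whole-matrix driver ----------------------------------------------------

# Shared-design fast path: with no missing entries every probe sees the same
# design matrices, so residual sums of squares for the full model and each
# drop-one model are obtained from a handful of QR projections applied to
# the whole probe x sample matrix at once.  Probes with missing entries fall
# back to the per-probe lm path; both routes are equivalence-tested.
lsmean_rows <- function(design, effects) {
  d <- design$data
  fac <- effects[vapply(effects, function(e) is.factor(d[[e]]), TRUE)]
  cov <- setdiff(effects, fac)
  grid_vars <- c(stats::setNames(lapply(fac, function(e)
    levels(droplevels(d[[e]]))), fac),
    list(muscle = levels(d$muscle)))
  grid <- expand.grid(grid_vars, stringsAsFactors = TRUE)
  for (e in cov) grid[[e]] <- mean(d[[e]], na.rm = TRUE)
  X <- stats::model.matrix(de_formula(effects, design$forced)[-2], grid)
  lapply(stats::setNames(levels(d$muscle), levels(d$muscle)), function(g)
    colMeans(X[grid$muscle == g, , drop = FALSE]))
}

#' Per-probe differential-expression analysis of a whole matrix
#'
#' For every probe: fit the full fixed-effects model, apply one backward
#' retention pass (effects with partial-F p >= `alpha_keep` dropped, muscle
#' forced), refit, take the muscle partial-F p-value and the least-squares
#' adjusted means, and derive fold change and direction.  Muscle p-values
#' are then BH-adjusted across all analysed probes.
#'
#' @param m an [expr_matrix()] on the ln scale (QC output).
#' @param meta sample metadata.
#' @param alpha_keep backward-retention threshold (default 0.2).
#' @param alpha BH-adjusted significance level recorded in the `de` column
#'   (default 0.05).
#' @return data.frame with one row per analysed probe: `probe_id`,
#'   `p_muscle`, `adj_p`, `mean_LM`, `mean_SM` (ln scale), `fc`,
#'   `direction`, `tie`, `retained_effects`, `de`.  Probes that could not be
#'   fitted are reported in attribute `skipped`.
#' @export
de_analysis <- function(m, meta, alpha_keep = 0.2, alpha = 0.05) {
  design <- design_spec(meta, colnames(m$values))
  v <- masked_values(m)
  if (m$scale != "ln") stop("de_analysis expects the centered ln matrix")
  lv <- levels(design$data$muscle)
  if (length(lv) != 2) stop("exactly two muscle levels are required")

  complete <- !apply(is.na(v), 1, any)
  res <- vector("list", nrow(v))
  names(res) <- rownames(v)
  skipped <- character(0)

  if (any(complete)) {
    res[complete] <- de_fast_path(v[complete, , drop = FALSE], design,
                                  alpha_keep)
  }
  for (i in which(!complete)) {
    row <- de_one_probe(v[i, ], design, alpha_keep)
    if (is.null(row)) skipped <- c(skipped, rownames(v)[i]) else res[[i]] <- row
  }
  res <- res[!vapply(res, is.null, TRUE)]
  tab <- do.call(rbind, res)
  tab <- data.frame(probe_id = names(res), tab, stringsAsFactors = FALSE,
                    row.names = NULL)
  tab$adj_p <- bh_adjust(tab$p_muscle)
  tab$de <- call_de(tab$adj_p, alpha)
  attr(tab, "skipped") <- skipped
  tab
}

de_one_probe <- function(y, design, alpha_keep) {
  full <- fit_probe_model(y, design)
  if (is.null(full)) return(NULL)
  red_design <- select_effects(full, alpha_keep)
  red <- fit_probe_model(y, red_design)
  if (is.null(red)) return(NULL)
  am <- adjusted_means(red)
  fcd <- fold_change(am[["LM"]], am[["SM"]])
  data.frame(p_muscle = red$pvals[[red_design$forced]],
             mean_LM = am[["LM"]], mean_SM = am[["SM"]],
             fc = fcd$fc,
             direction = fcd$direction %||% NA_character_,
             tie = fcd$tie,
             retained_effects = paste(red_design$effects, collapse = "+"),
             stringsAsFactors = FALSE)
}

de_fast_path <- function(V, design, alpha_keep) {
  d <- design$data
  effects <- design$effects
  Yt <- t(V)                                   # samples x probes
  n <- nrow(Yt)

  X_full <- stats::model.matrix(de_formula(effects, design$forced)[-2], d)
  q_full <- qr(X_full)
  sse_full <- colSums(qr.resid(q_full, Yt)^2)
  df_res <- n - q_full$rank

  n_probes <- nrow(V)
  # per-effect partial F against the full model
  pv <- matrix(NA_real_, n_probes, length(effects),
               dimnames = list(NULL, effects))
  for (e in effects) {
    Xe <- stats::model.matrix(de_formula(setdiff(effects, e),
                                         design$forced)[-2], d)
    qe <- qr(Xe)
    sse_e <- colSums(qr.resid(qe, Yt)^2)
    df_e <- q_full$rank - qe$rank
    f <- pmax(((sse_e - sse_full) / df_e) / (sse_full / df_res), 0)
    pv[, e] <- stats::pf(f, df_e, df_res, lower.tail = FALSE)
  }

  keep <- !is.na(pv) & pv < alpha_keep
  sig <- apply(keep, 1, function(z) paste(effects[z], collapse = "+"))
  out <- vector("list", n_probes)
  lv <- levels(d$muscle)
  for (s in unique(sig)) {
    idx <- which(sig == s)
    eff <- if (nzchar(s)) strsplit(s, "+", fixed = TRUE)[[1]] else character(0)
    X_red <- stats::model.matrix(de_formula(eff, design$forced)[-2], d)
    q_red <- qr(X_red)
    sse_red <- colSums(qr.resid(q_red, Yt[, idx, drop = FALSE])^2)
    df_red <- n - q_red$rank
    # null model for the muscle partial F: same nuisance effects, no muscle
    X_nom <- if (length(eff))
      stats::model.matrix(stats::reformulate(eff), d)
    else matrix(1, n, 1)
    q_nom <- qr(X_nom)
    sse_nom <- colSums(qr.resid(q_nom, Yt[, idx, drop = FALSE])^2)
    df_m <- q_red$rank - q_nom$rank
    f <- pmax(((sse_nom - sse_red) / df_m) / (sse_red / df_red), 0)
    p_muscle <- stats::pf(f, df_m, df_red, lower.tail = FALSE)

    beta <- qr.coef(q_red, Yt[, idx, drop = FALSE])
    beta[is.na(beta)] <- 0
    rows <- lsmean_rows(design, eff)
    m1 <- drop(rows[[lv[1]]] %*% beta)
    m2 <- drop(rows[[lv[2]]] %*% beta)
    tie <- m1 == m2
    fc <- exp(abs(m1 - m2))
    dir <- ifelse(tie, NA_character_, ifelse(m1 > m2, lv[1], lv[2]))
    for (k in seq_along(idx)) {
      out[[idx[k]]] <- data.frame(
        p_muscle = p_muscle[k], mean_LM = m1[k], mean_SM = m2[k],
        fc = fc[k], direction = dir[k], tie = tie[k],
        retained_effects = s, stringsAsFactors = FALSE)
    }
  }
  out
}

#' Collapse probe-level calls to gene-level calls
#'
#' Each gene is listed once; its representative fold change and direction
#' come from the significant probe with the largest FC.  Genes whose
#' significant probes disagree in direction get a conflict flag and are
#' excluded from downstream functional lists; probes without a gene mapping
#' are counted as unannotated and dropped.
#'
#' @param de_tab output of [de_analysis()].
#' @param probe_map data.frame `probe_id`, `gene_id`.
#' @param only_de collapse significant probes only (default TRUE).
#' @return data.frame: `gene_id`, `n_probes`, `probe_ids`, `fc`,
#'   `direction`, `adj_p` (best probe), `conflict`; attribute
#'   `n_unannotated` counts unmapped probes.
#' @export
collapse_to_genes <- function(de_tab, probe_map, only_de = TRUE) {
  tab <- if (only_de) de_tab[de_tab$de & !de_tab$tie, , drop = FALSE]
         else de_tab[!de_tab$tie, , drop = FALSE]
  gene <- probe_map$gene_id[match(tab$probe_id, probe_map$probe_id)]
  unannotated <- is.na(gene)
  tab <- tab[!unannotated, , drop = FALSE]
  gene <- gene[!unannotated]
  if (!nrow(tab)) {
    out <- data.frame(gene_id = character(0), n_probes = integer(0),
                      probe_ids = character(0), fc = numeric(0),
                      direction = character(0), adj_p = numeric(0),
                      conflict = logical(0), stringsAsFactors = FALSE)
    attr(out, "n_unannotated") <- sum(unannotated)
    return(out)
  }
  pieces <- lapply(split(seq_len(nrow(tab)), gene), function(ix) {
    g <- tab[ix, , drop = FALSE]
    best <- which.max(g$fc)
    data.frame(gene_id = NA_character_,
               n_probes = nrow(g),
               probe_ids = paste(g$probe_id, collapse = ","),
               fc = g$fc[best],
               direction = g$direction[best],
               adj_p = min(g$adj_p),
               conflict = length(unique(g$direction)) > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$gene_id <- names(pieces)
  rownames(out) <- NULL
  out <- out[, c("gene_id", "n_probes", "probe_ids", "fc", "direction",
                 "adj_p", "conflict")]
  attr(out, "n_unannotated") <- sum(unannotated)
  out
}

#' Biological-relevance fold-change filter
#'
#' Keeps gene calls whose fold change is strictly above `min_fc` (the
#' "ratio above 1.5" rule) and which carry no direction conflict.
#'
#' @param calls output of [collapse_to_genes()].
#' @param min_fc threshold ratio; default 1.5.
#' @return filtered data.frame.
#' @export
relevance_filter <- function(calls, min_fc = 1.5) {
  calls[calls$fc > min_fc & !calls$conflict, , drop = FALSE]
}
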