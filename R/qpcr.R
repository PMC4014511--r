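#' PCR efficiency from a calibration-curve slope
#'
#' A standard curve of Ct against log10 input gives slope
#' `-1 / log10(E)`; inverting, `E = 10^(-1/slope)`.  A perfectly efficient
#' assay doubles per cycle (slope about -3.32 gives E = 2).
#'
#' @param slope calibration-curve slope (must be negative).
#' @return amplification factor per cycle.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || any(slope >= 0))
    stop("calibration slope must be negative")
  10^(-1 / slope)
}

#' Efficiency-corrected relative quantity against a calibrator
#'
#' `q = E^-(Ct - Ct_calibrator)`; the calibrator's own quantity is 1.
#'
#' @param ct sample Ct value(s).
#' @param ct_calibrator calibrator Ct for the same assay.
#' @param e amplification efficiency E.
#' @return relative quantity (same length as `ct`).
#' @export
relative_quantity <- function(ct, ct_calibrator, e) {
  e^-(ct - ct_calibrator)
}

#' geNorm reference-gene stability values
#'
#' For reference j, `M_j` is the mean over the other references k of the
#' standard deviation across samples of `log2(q_j / q_k)`.  References are
#' excluded stepwise (largest M first, ties by column order), recomputing M
#' each round until two remain; the expression-stability ranking is the
#' reverse exclusion order.
#'
#' @param q sample-by-reference matrix of positive relative quantities with
#'   column names.
#' @return list with `M` (named stability values from the full panel),
#'   `ranking` (most stable first; the final pair is tied at rank 1) and
#'   `exclusion_order`.
#' @export
genorm_stability <- function(q) {
  q <- as.matrix(q)
  if (is.null(colnames(q))) stop("reference quantities need column names")
  if (ncol(q) < 2) stop("geNorm is undefined for fewer than 2 references")
  if (any(q <= 0)) stop("relative quantities must be strictly positive")
  m_values <- function(qq) {
    vapply(seq_len(ncol(qq)), function(j) {
      others <- setdiff(seq_len(ncol(qq)), j)
      mean(vapply(others, function(k)
        stats::sd(log2(qq[, j] / qq[, k])), 0))
    }, 0, USE.NAMES = FALSE)
  }
  M_full <- stats::setNames(m_values(q), colnames(q))
  remaining <- colnames(q)
  excluded <- character(0)
  while (length(remaining) > 2) {
    M <- m_values(q[, remaining, drop = FALSE])
    worst <- remaining[which.max(M)]
    excluded <- c(excluded, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(M = M_full,
       ranking = c(remaining, rev(excluded)),
       exclusion_order = excluded)
}

#' geNorm normalization factor per sample
#'
#' Geometric mean of the selected references' relative quantities within
#' each sample.
#'
#' @param q sample-by-reference matrix of the selected references.
#' @return named numeric NF per sample.
#' @export
normalization_factor <- function(q) {
  q <- as.matrix(q)
  if (any(q <= 0)) stop("relative quantities must be strictly positive")
  apply(q, 1, geometric_mean)
}

#' Normalized expression level
#'
#' `N_exp = E^-(Ct - Ct_calibrator) / NF`.
#'
#' @param ct sample Ct.
#' @param ct_calibrator calibrator Ct.
#' @param e efficiency.
#' @param nf per-sample normalization factor.
#' @return normalized expression.
#' @export
normalized_expression <- function(ct, ct_calibrator, e, nf) {
  relative_quantity(ct, ct_calibrator, e) / nf
}

#' Compare normalized expression between muscles per assay
#'
#' Two-sided pooled-variance (classical Student) t-test on the normalized
#' expression values; fold change is the ratio of the greater to the lesser
#' muscle mean and the direction is the muscle with the greater mean.
#'
#' @param nexp named numeric of per-sample normalized expression.
#' @param muscle factor/character of muscle labels aligned with `nexp`.
#' @param var_equal pooled variance (default TRUE; set FALSE for Welch).
#' @return one-row data.frame: means per muscle, `t`, `p`, `fc`,
#'   `direction`.
#' @export
muscle_compare <- function(nexp, muscle, var_equal = TRUE) {
  muscle <- factor(muscle)
  if (nlevels(muscle) != 2) stop("exactly two muscle levels required")
  g <- levels(muscle)
  x <- nexp[muscle == g[1]]
  y <- nexp[muscle == g[2]]
  mx <- mean(x); my <- mean(y)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate zero-variance case: identical groups are a clean null,
    # separated constants an unambiguous difference
    tt <- if (mx == my) list(statistic = 0, p.value = 1)
          else list(statistic = sign(mx - my) * Inf, p.value = 0)
  } else {
    tt <- stats::t.test(x, y, var.equal = var_equal)
  }
  out <- data.frame(t = unname(tt$statistic), p = tt$p.value,
                    fc = max(mx, my) / min(mx, my),
                    direction = if (mx == my) NA_character_
                                else g[which.max(c(mx, my))],
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", g[1])]] <- mx
  out[[paste0("mean_", g[2])]] <- my
  out
}

#' Run the full qPCR validation arm on a Ct table
#'
#' Collapses replicate wells by mean Ct, computes per-assay relative
#' quantities against the calibrator (per-assay mean Ct of all samples when
#' no explicit calibrator is given — the synthetic analogue of a pooled
#' sample), ranks reference stability with geNorm, normalizes target
#' quantities by the per-sample NF, and tests each target between muscles.
#'
#' @param ct_tab data.frame: `sample`, `muscle`, `assay`, `role`
#'   (`"target"`/`"reference"`), `Ct`, `efficiency` (optional `replicate`).
#' @param calibrator optional named per-assay calibrator Ct.
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return list with `stability` (geNorm output), `nf` (per-sample NF),
#'   `results` (per-assay stats data.frame) and `nexp`
#'   (sample-by-target matrix).
#' @export
qpcr_analysis <- function(ct_tab, calibrator = NULL, var_equal = TRUE) {
  req <- c("sample", "muscle", "assay", "role", "Ct", "efficiency")
  miss <- setdiff(req, names(ct_tab))
  if (length(miss)) stop("Ct table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(ct_tab$Ct <= 0)) stop("Ct values must be positive")
  # collapse technical replicates by arithmetic mean Ct
  key <- interaction(ct_tab$sample, ct_tab$assay, drop = TRUE)
  ct_tab <- do.call(rbind, lapply(split(ct_tab, key), function(g) {
    g$Ct[1] <- mean(g$Ct); g[1, , drop = FALSE]
  }))
  if (is.null(calibrator))
    calibrator <- tapply(ct_tab$Ct, ct_tab$assay, mean)

  eff <- tapply(ct_tab$efficiency, ct_tab$assay, function(e) e[1])
  samples <- sort(unique(ct_tab$sample))
  muscle <- ct_tab$muscle[match(samples, ct_tab$sample)]
  quant <- function(assay) {
    g <- ct_tab[ct_tab$assay == assay, ]
    stats::setNames(relative_quantity(g$Ct, calibrator[[assay]],
                                      eff[[assay]]),
                    g$sample)[samples]
  }
  refs <- unique(ct_tab$assay[ct_tab$role == "reference"])
  targets <- unique(ct_tab$assay[ct_tab$role == "target"])
  if (length(refs) < 2) stop("geNorm requires at least 2 reference assays")
  qref <- vapply(refs, quant, numeric(length(samples)))
  stability <- genorm_stability(qref)
  nf <- normalization_factor(qref)

  nexp <- vapply(targets, function(a) quant(a) / nf,
                 numeric(length(samples)))
  rownames(nexp) <- samples
  results <- do.call(rbind, lapply(targets, function(a)
    cbind(data.frame(assay = a, stringsAsFactors = FALSE),
          muscle_compare(nexp[, a], muscle, var_equal))))
  rownames(results) <- NULL
  list(stability = stability, nf = nf, results = results, nexp = nexp)
}

#' Direction concordance between qPCR and microarray calls
#'
#' @param qpcr_results `results` table from [qpcr_analysis()] (columns
#'   `assay`, `direction`).
#' @param array_calls gene-level table from [collapse_to_genes()] (columns
#'   `gene_id`, `direction`).
#' @return list with `table` (per-assay match flags) and `concordance`
#'   (fraction of shared assays with matching direction).
#' @export
concordance <- function(qpcr_results, array_calls) {
  shared <- intersect(qpcr_results$assay, array_calls$gene_id)
  if (!length(shared))
    stop("no assays shared between qPCR results and microarray calls")
  qd <- qpcr_results$direction[match(shared, qpcr_results$assay)]
  ad <- array_calls$direction[match(shared, array_calls$gene_id)]
  tab <- data.frame(assay = shared, qpcr_direction = qd,
                    array_direction = ad,
                    match = !is.na(qd) & !is.na(ad) & qd == ad,
                    stringsAsFactors = FALSE)
  list(table = tab, concordance = mean(tab$match))
}
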