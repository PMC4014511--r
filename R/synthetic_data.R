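#' Simulation configuration for the synthetic muscle-contrast experiment
#'
#' The generator is the analysis model run forward: a two-muscle design in
#' which every animal contributes one *Longissimus* (LM) and one
#' *Semimembranosus* (SM) sample, with additive fixed effects on the
#' natural-log intensity scale for sex (2 levels), slaughter batch (2
#' levels), hybridization batch nested within sire family (two half-sib
#' families in a 41:49 ratio, with 9 and 11 batch levels respectively at
#' full scale), a carcass-weight covariate, and a planted muscle effect for
#' a fraction of genes.  Planted absolute log fold changes are drawn
#' log-normally and truncated so that expression ratios span \[1.1, 15\]
#' with a median below 1.5.
#'
#' @param n_animals_per_muscle animals (= samples per muscle); default 90.
#' @param n_genes number of genes on the chip.
#' @param redundancy_rate fraction of genes carrying a second probe.
#' @param n_probes total probes; default `n_genes * (1 + redundancy_rate)`.
#' @param prop_de fraction of genes with a true muscle effect; default 0.37.
#' @param fc_log_mean,fc_log_sd meanlog / sdlog of the log-normal draw for
#'   the absolute natural-log fold change, truncated to
#'   \[ln `fc_min`, ln `fc_max`\].
#' @param fc_min,fc_max truncation bounds of the planted expression ratio;
#'   defaults 1.1 and 15.
#' @param noise_sd residual SD on the natural-log scale.
#' @param sex_effect,slaughter_effect additive effect sizes (ln scale).
#' @param hyb_batch_sd SD of per-batch effects (ln scale).
#' @param n_hyb_batches length-2 integer: batch levels per sire family.
#' @param weight_slope ln-expression change per kg of carcass weight.
#' @param weight_mean,weight_sd carcass-weight distribution (kg).
#' @param within_animal_cor correlation of the two muscles' residuals within
#'   an animal (the study design does not state one; default 0).
#' @param flag_prob per-spot probability of a quality flag.
#' @param n_modules number of planted functional modules in the ontology.
#' @param terms_per_module ontology terms per module subtree.
#' @param annotation_rate fraction of genes carrying any GO annotation.
#' @param annotation_purity probability that an annotated gene's terms come
#'   from its own module's subtree.
#' @param terms_per_gene mean number of terms per annotated gene.
#' @param part_of_prob probability that a non-root ontology edge is part_of
#'   rather than is_a.
#' @param qpcr_noise_sd Ct-scale technical noise SD (cycles).
#' @param qpcr_efficiency amplification factor per cycle, in (1, 2\].
#' @param seed integer RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_animals_per_muscle = 90,
                       n_genes = 1000,
                       redundancy_rate = 0.30,
                       n_probes = NULL,
                       prop_de = 0.37,
                       fc_log_mean = log(0.25),
                       fc_log_sd = 0.8,
                       fc_min = 1.1,
                       fc_max = 15,
                       noise_sd = 0.2,
                       sex_effect = 0.10,
                       slaughter_effect = 0.10,
                       hyb_batch_sd = 0.05,
                       n_hyb_batches = c(9L, 11L),
                       weight_slope = 0.005,
                       weight_mean = 108,
                       weight_sd = 8,
                       within_animal_cor = 0,
                       flag_prob = 0.01,
                       n_modules = 5,
                       terms_per_module = 12,
                       annotation_rate = 0.65,
                       annotation_purity = 0.9,
                       terms_per_gene = 3,
                       part_of_prob = 0.2,
                       qpcr_noise_sd = 0.05,
                       qpcr_efficiency = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_probes))
    cfg$n_probes <- cfg$n_genes + round(cfg$redundancy_rate * cfg$n_genes)
  counts <- c("n_animals_per_muscle", "n_genes", "n_probes", "n_modules",
              "terms_per_module")
  for (f in counts)
    if (cfg[[f]] < 1) stop(f, " must be a positive count")
  probs <- c("redundancy_rate", "prop_de", "flag_prob", "annotation_rate",
             "annotation_purity", "part_of_prob")
  for (f in probs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$n_probes < cfg$n_genes) stop("n_probes must be >= n_genes")
  if (cfg$noise_sd < 0 || cfg$qpcr_noise_sd < 0) stop("noise SDs must be >= 0")
  if (cfg$within_animal_cor < 0 || cfg$within_animal_cor > 1)
    stop("within_animal_cor must lie in [0, 1]")
  if (cfg$qpcr_efficiency <= 1 || cfg$qpcr_efficiency > 2)
    stop("qpcr_efficiency must lie in (1, 2]")
  if (cfg$fc_min < 1 || cfg$fc_max <= cfg$fc_min)
    stop("fc truncation bounds require 1 <= fc_min < fc_max")
  if (length(cfg$n_hyb_batches) != 2)
    stop("n_hyb_batches must give levels for exactly two sire families")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

# truncated log-normal draw of |ln FC|, ratio range [1.1, 15]
rtrunc_lfc <- function(n, meanlog, sdlog, lo = log(1.1), hi = log(15)) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * n, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic probe-by-sample experiment with known truth
#'
#' Runs the fixed-effects model forward on the natural-log scale and
#' exponentiates to raw intensities.  Both muscles are sampled from the same
#' animals (paired columns); animal identity is recorded in the metadata but
#' intentionally not modelled downstream.
#'
#' @param config a [sim_config()].
#' @return list with `expr` ([expr_matrix()], raw scale), `meta`
#'   (sample-metadata data.frame), and `truth` (list: `genes` data.frame with
#'   per-gene direction / fc_ratio / module, `probe_map` data.frame
#'   probe_id -> gene_id).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_animals_per_muscle < 4)
    stop("at least 4 animals per muscle are required for an identifiable model")
  set.seed(config$seed)
  n <- config$n_animals_per_muscle

  # animals: two half-sib sire families at the study's 41:49 ratio
  n_fam1 <- max(1L, round(n * 41 / 90))
  sire <- factor(rep(c("S1", "S2"), c(n_fam1, n - n_fam1)))
  animal <- sprintf("A%03d", seq_len(n))
  # randomized sex and alternating slaughter season avoid any systematic
  # aliasing among the nuisance factors
  sex <- factor(sample(rep_len(c("M", "F"), n)))
  slaughter <- factor(rep_len(c("summer", "winter"), n))
  # hybridization batches nested in sire family as consecutive processing
  # blocks; levels scale down with n
  nb <- pmax(2L, pmin(as.integer(config$n_hyb_batches),
                      as.integer(tabulate(sire) %/% 2)))
  hyb <- character(n)
  for (k in 1:2) {
    idx <- which(as.integer(sire) == k)
    hyb[idx] <- sprintf("S%d.H%02d", k,
                        rep(seq_len(nb[k]),
                            each = ceiling(length(idx) / nb[k]),
                            length.out = length(idx)))
  }
  hyb <- factor(hyb)
  weight <- stats::rnorm(n, config$weight_mean, config$weight_sd)

  meta <- data.frame(
    sample_id = c(paste0(animal, "_LM"), paste0(animal, "_SM")),
    animal = rep(animal, 2),
    muscle = rep(c("LM", "SM"), each = n),
    sex = rep(as.character(sex), 2),
    slaughter_batch = rep(as.character(slaughter), 2),
    sire = rep(as.character(sire), 2),
    hyb_batch = rep(as.character(hyb), 2),
    carcass_weight = rep(weight, 2),
    stringsAsFactors = FALSE)

  # gene-level truth
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  n_de <- round(config$prop_de * config$n_genes)
  de_idx <- if (n_de > 0) sample.int(config$n_genes, n_de) else integer(0)
  direction <- rep("null", config$n_genes)
  if (n_de > 0)
    direction[de_idx] <- sample(c("LM", "SM"), n_de, replace = TRUE)
  lfc <- numeric(config$n_genes)
  if (n_de > 0)
    lfc[de_idx] <- rtrunc_lfc(n_de, config$fc_log_mean, config$fc_log_sd,
                              lo = log(config$fc_min),
                              hi = log(config$fc_max))

  # probe -> gene map: every gene one probe, extras duplicate random genes
  n_extra <- config$n_probes - config$n_genes
  extra_gene <- if (n_extra > 0)
    sample.int(config$n_genes, n_extra, replace = n_extra > config$n_genes)
  else integer(0)
  gene_of_probe <- c(seq_len(config$n_genes), extra_gene)
  probes <- sprintf("P%05d", seq_len(config$n_probes))
  probe_map <- data.frame(probe_id = probes,
                          gene_id = genes[gene_of_probe],
                          stringsAsFactors = FALSE)

  # forward model on the ln scale
  mu <- stats::rnorm(config$n_probes, 8, 1)              # probe affinity
  eff_animal <- (sex == "M") * config$sex_effect +
    (slaughter == "winter") * config$slaughter_effect +
    stats::rnorm(nlevels(hyb), 0, config$hyb_batch_sd)[as.integer(hyb)] +
    config$weight_slope * (weight - mean(weight))
  muscle_shift <- ifelse(direction == "LM", lfc,
                         ifelse(direction == "SM", -lfc, 0))[gene_of_probe]

  ln <- matrix(mu, config$n_probes, 2 * n)
  ln <- ln + matrix(rep(eff_animal, 2), config$n_probes, 2 * n, byrow = TRUE)
  ln[, seq_len(n)] <- ln[, seq_len(n)] + muscle_shift   # LM columns carry +lfc
  if (config$noise_sd > 0) {
    rho <- config$within_animal_cor
    shared <- matrix(stats::rnorm(config$n_probes * n), config$n_probes, n)
    e_lm <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(stats::rnorm(config$n_probes * n),
                             config$n_probes, n)
    e_sm <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(stats::rnorm(config$n_probes * n),
                             config$n_probes, n)
    ln <- ln + config$noise_sd * cbind(e_lm, e_sm)
  }
  values <- exp(ln)
  dimnames(values) <- list(probes, meta$sample_id)
  flags <- matrix(stats::runif(length(values)) < config$flag_prob,
                  nrow(values), ncol(values), dimnames = dimnames(values))

  truth_genes <- data.frame(gene_id = genes, direction = direction,
                            fc_ratio = exp(lfc), module = NA_character_,
                            stringsAsFactors = FALSE)
  list(expr = expr_matrix(values, flags = flags, scale = "raw"),
       meta = meta,
       truth = list(genes = truth_genes, probe_map = probe_map))
}

#' Generate a synthetic ontology with planted functional modules
#'
#' Builds a rooted acyclic biological_process term graph in which each
#' functional module is a distinct subtree hanging off the root, then
#' annotates genes predominantly (with probability `annotation_purity`) to
#' their own module's subtree.  Module membership is recorded as ground
#' truth for clustering-recovery tests.
#'
#' @param config a [sim_config()].
#' @param truth optional truth list from [generate_expression()]; when given,
#'   its gene ids are annotated and its `genes$module` column is filled in.
#' @return list with `dag` (a [go_dag()]), `annotations` (named list:
#'   gene id -> character vector of term ids) and `modules` (named character
#'   vector of planted module labels for annotated genes).
#' @export
generate_go_dag <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_modules < 2) stop("at least 2 functional modules are required")
  set.seed(config$seed + 1L)
  m <- config$n_modules
  tpm <- config$terms_per_module

  root <- "GO:0000001"
  ids <- c(root, sprintf("GO:%07d", seq_len(m * tpm) + 1L))
  term_module <- c(NA_integer_, rep(seq_len(m), each = tpm))
  edges <- data.frame(child = character(0), parent = character(0),
                      type = character(0), stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    tidx <- which(term_module == j)            # indices into ids
    for (i in seq_along(tidx)) {
      if (i == 1) {
        parent <- root; type <- "is_a"         # module root attaches to root
      } else {
        parent <- ids[tidx[sample.int(i - 1, 1)]]
        type <- if (stats::runif(1) < config$part_of_prob) "part_of" else "is_a"
      }
      edges <- rbind(edges, data.frame(child = ids[tidx[i]], parent = parent,
                                       type = type, stringsAsFactors = FALSE))
    }
  }
  terms <- data.frame(id = ids,
                      name = c("process_root",
                               sprintf("module%d_term%d",
                                       term_module[-1],
                                       sequence(rep(tpm, m)))),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  dag <- go_dag(terms, edges)

  gene_ids <- if (is.null(truth)) sprintf("G%04d", seq_len(config$n_genes))
              else truth$genes$gene_id
  n_annot <- round(config$annotation_rate * length(gene_ids))
  annotated <- sort(sample(seq_along(gene_ids), n_annot))
  module_of <- sample(rep_len(seq_len(m), n_annot))
  annotations <- vector("list", n_annot)
  names(annotations) <- gene_ids[annotated]
  for (i in seq_len(n_annot)) {
    k <- 1L + stats::rpois(1, max(config$terms_per_gene - 1, 0))
    own <- stats::runif(k) < config$annotation_purity
    mod <- ifelse(own, module_of[i],
                  vapply(seq_len(k), function(z)
                    sample(setdiff(seq_len(m), module_of[i]), 1), 1L))
    annotations[[i]] <- unique(vapply(mod, function(mm)
      ids[which(term_module == mm)][sample.int(tpm, 1)], ""))
  }
  modules <- stats::setNames(paste0("M", module_of), gene_ids[annotated])
  if (!is.null(truth))
    truth$genes$module[annotated] <- modules
  list(dag = dag, annotations = annotations, modules = modules,
       truth = truth)
}

#' Generate a synthetic qPCR Ct table from shared ground truth
#'
#' Ct values follow `Ct = ct0 - log_E(quantity)`: a target with true fold
#' change FC and efficiency E separates the muscles by `log_E(FC)` cycles.
#' Reference assays have no muscle effect and configurable per-assay
#' stability noise; the calibrator quantity is the per-assay pooled
#' (mean-Ct) sample.
#'
#' @param config a [sim_config()].
#' @param truth truth list from [generate_expression()].
#' @param n_targets target assays, drawn from genes with a planted effect.
#' @param n_refs reference assays (>= 2; geNorm is undefined below that).
#' @param n_animals animals per muscle in the validation subset; default 8.
#' @param ref_noise_sd per-reference Ct noise SDs (cycles), ascending order
#'   = intended stability ranking; recycled to `n_refs`.
#' @return data.frame (class `ct_table`) with columns sample, muscle, assay,
#'   role, Ct, efficiency; attributes `targets` (data.frame with planted
#'   fc_ratio and direction) and `calibrator` (named per-assay pool Ct).
#' @export
generate_qpcr <- function(config, truth, n_targets = 7, n_refs = 3,
                          n_animals = 8,
                          ref_noise_sd = c(0.02, 0.05, 0.10)) {
  stopifnot(inherits(config, "sim_config"))
  if (n_refs < 2) stop("geNorm requires at least 2 reference assays")
  de <- truth$genes[truth$genes$direction != "null", ]
  if (nrow(de) < n_targets)
    stop("not enough genes with planted effects to draw targets from")
  set.seed(config$seed + 2L)
  targets <- de[sample.int(nrow(de), n_targets), ]
  E <- config$qpcr_efficiency

  samples <- c(sprintf("V%02d_LM", seq_len(n_animals)),
               sprintf("V%02d_SM", seq_len(n_animals)))
  muscle <- rep(c("LM", "SM"), each = n_animals)
  rows <- list()
  for (i in seq_len(n_targets)) {
    lq <- ifelse(muscle == targets$direction[i], log(targets$fc_ratio[i]), 0)
    ct <- 22 - lq / log(E) +
      stats::rnorm(length(samples), 0, config$qpcr_noise_sd)
    rows[[i]] <- data.frame(sample = samples, muscle = muscle,
                            assay = targets$gene_id[i], role = "target",
                            Ct = ct, efficiency = E,
                            stringsAsFactors = FALSE)
  }
  sd_ref <- rep_len(ref_noise_sd, n_refs)
  for (j in seq_len(n_refs)) {
    ct <- 18 + stats::rnorm(length(samples), 0, sd_ref[j])
    rows[[n_targets + j]] <- data.frame(sample = samples, muscle = muscle,
                                        assay = sprintf("REF%d", j),
                                        role = "reference",
                                        Ct = ct, efficiency = E,
                                        stringsAsFactors = FALSE)
  }
  ct_tab <- do.call(rbind, rows)
  calib <- tapply(ct_tab$Ct, ct_tab$assay, mean)
  attr(ct_tab, "targets") <- targets
  attr(ct_tab, "calibrator") <- calib
  class(ct_tab) <- c("ct_table", "data.frame")
  ct_tab
}

#' Write all synthetic artifacts of one simulation to a directory
#'
#' Emits expression, flags, metadata, probe map and truth as TSV, the
#' ontology as an OBO subset, annotations as a two-column GAF-like TSV, the
#' Ct table as TSV, and a run manifest (JSON) echoing the configuration.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_expression(config)
  go <- generate_go_dag(config, sim$truth)
  sim$truth <- go$truth
  qpcr <- generate_qpcr(config, sim$truth)

  write_tsv(sim$expr$values, file.path(dir, "expression.tsv"), "probe_id")
  write_tsv(sim$expr$flags * 1L, file.path(dir, "flags.tsv"), "probe_id")
  write_tsv(sim$meta, file.path(dir, "meta.tsv"))
  write_tsv(sim$truth$probe_map, file.path(dir, "probe_map.tsv"))
  write_tsv(sim$truth$genes, file.path(dir, "truth.tsv"))
  write_obo(go$dag, file.path(dir, "ontology.obo"))
  write_annotations(go$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(as.data.frame(qpcr), file.path(dir, "qpcr_ct.tsv"))
  jsonlite::write_json(unclass(config), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(expr = sim$expr, meta = sim$meta, truth = sim$truth,
                 dag = go$dag, annotations = go$annotations,
                 modules = go$modules, qpcr = qpcr))
}
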