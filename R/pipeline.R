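#' Default pipeline thresholds
#'
#' The stage thresholds of the published analysis: flag fraction 0.5,
#' outlier cut 3 SD, k-means k 3, effect retention 0.2, DE level 0.05,
#' relevance FC 1.5, 5 clusters, 5 genes minimum per enriched term,
#' enrichment level 0.05.
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(max_flag_fraction = 0.5, k_sd = 3, kmeans_k = 3,
       alpha_keep = 0.2, alpha_de = 0.05, min_fc = 1.5,
       cluster_k = 5, min_genes = 5, alpha_enrich = 0.05,
       seed = 1L)
}

#' Read a flat key = value run-configuration file
#'
#' Lines of the form `key = value` (or `key value`, `key: value`); `#`
#' starts a comment.  Unknown keys are kept verbatim (paths etc.); known
#' threshold keys are coerced to numeric.
#'
#' @param path config file.
#' @return named list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)(?:\\s*[=:]\\s*|\\s+)(.+)$",
                                ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (key %in% names(default_run_config())) val <- as.numeric(val)
    cfg[[key]] <- val
  }
  cfg
}

#' Validate cross-references between the pipeline's input tables
#'
#' Schema checks (required columns) and id cross-references: every
#' expression sample needs metadata, probe ids must be unique, annotation
#' genes should appear in the probe map.  Problems are returned as a report
#' data.frame (`level` = error/warning); an empty report means a consistent
#' fixture.
#'
#' @param expr [expr_matrix()] or NULL.
#' @param meta sample metadata or NULL.
#' @param probe_map probe -> gene map or NULL.
#' @param annotations named list gene -> terms, or NULL.
#' @return data.frame with columns `level`, `message`.
#' @export
validate_inputs <- function(expr = NULL, meta = NULL, probe_map = NULL,
                            annotations = NULL) {
  rep <- list()
  note <- function(level, msg)
    rep[[length(rep) + 1L]] <<- data.frame(level = level, message = msg,
                                           stringsAsFactors = FALSE)
  if (!is.null(expr) && anyDuplicated(rownames(expr$values)))
    note("error", "duplicated probe ids in expression matrix")
  if (!is.null(expr) && !is.null(meta)) {
    orphan <- setdiff(colnames(expr$values), meta$sample_id)
    if (length(orphan))
      note("error", paste("samples without metadata:",
                          paste(orphan, collapse = ", ")))
  }
  if (!is.null(probe_map)) {
    if (!all(c("probe_id", "gene_id") %in% names(probe_map)))
      note("error", "probe map must have probe_id and gene_id columns")
    else if (anyDuplicated(probe_map$probe_id))
      note("error", "duplicated probe ids in probe map")
    if (!is.null(expr) && all(c("probe_id", "gene_id") %in% names(probe_map))) {
      unmapped <- setdiff(rownames(expr$values), probe_map$probe_id)
      if (length(unmapped))
        note("warning", sprintf("%d probe(s) without gene mapping",
                                length(unmapped)))
    }
  }
  if (!is.null(annotations) && !is.null(probe_map) &&
      all(c("probe_id", "gene_id") %in% names(probe_map))) {
    orphan <- setdiff(names(annotations), probe_map$gene_id)
    if (length(orphan))
      note("warning", sprintf("%d annotated gene(s) absent from probe map",
                              length(orphan)))
  }
  if (!length(rep))
    return(data.frame(level = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rep)
}

#' Run the complete pipeline on in-memory inputs
#'
#' QC -> per-probe linear models -> gene collapse -> FC relevance filter ->
#' semantic-similarity clustering -> per-cluster enrichment, with an
#' optional qPCR arm.  The bookkeeping chain (probes in, expressed, DE,
#' FC-filtered, annotated, clustered) is logged to standard error and
#' returned, so a run can be audited stage by stage.
#'
#' @param expr raw-scale [expr_matrix()].
#' @param meta sample metadata.
#' @param probe_map probe -> gene map.
#' @param dag a [go_dag()].
#' @param annotations named list gene -> term ids.
#' @param pathway_sets optional named list of pathway collections.
#' @param ct_tab optional Ct table for the validation arm.
#' @param config threshold list (see [default_run_config()]).
#' @param verbose log stage counts to stderr.
#' @return list with `qc`, `de`, `gene_calls`, `relevant`, `clustering`,
#'   `enrichment`, `qpcr` (or NULL), `concordance` (or NULL), `chain`
#'   (named counts).
#' @export
run_pipeline <- function(expr, meta, probe_map, dag, annotations,
                         pathway_sets = list(), ct_tab = NULL,
                         config = default_run_config(), verbose = TRUE) {
  cfg <- utils::modifyList(default_run_config(), config)
  say <- function(...) if (verbose) message("[semde] ", sprintf(...))
  vr <- validate_inputs(expr, meta, probe_map, annotations)
  if (any(vr$level == "error"))
    stop("input validation failed:\n  ",
         paste(vr$message[vr$level == "error"], collapse = "\n  "))

  qc <- qc_pipeline(expr, meta, max_flag_fraction = cfg$max_flag_fraction,
                    k_sd = cfg$k_sd, max_bad_fraction = cfg$max_flag_fraction,
                    kmeans_k = cfg$kmeans_k, seed = cfg$seed,
                    verbose = verbose)
  n_expressed <- qc$report[["probes_remaining"]]
  say("expressed probes: %d", n_expressed)

  de <- de_analysis(qc$expr, meta, alpha_keep = cfg$alpha_keep,
                    alpha = cfg$alpha_de)
  n_de <- sum(de$de)
  say("differentially expressed probes: %d (%.0f%%)",
      n_de, 100 * n_de / nrow(de))

  gene_calls <- collapse_to_genes(de, probe_map)
  relevant <- relevance_filter(gene_calls, min_fc = cfg$min_fc)
  say("DE genes: %d; FC > %.1f: %d",
      nrow(gene_calls), cfg$min_fc, nrow(relevant))

  clustering <- NULL
  enrichment <- NULL
  n_annotated <- sum(relevant$gene_id %in% names(annotations))
  say("annotated relevant genes: %d", n_annotated)
  if (n_annotated >= 2) {
    clustering <- cluster_genes(relevant, annotations, dag,
                                k = cfg$cluster_k)
    say("clustered genes: %d in %d clusters",
        length(clustering$assign), length(unique(clustering$assign)))
    background <- unique(probe_map$gene_id)
    enrichment <- enrich_all(clustering$assign, annotations, dag,
                             background, pathway_sets,
                             min_genes = cfg$min_genes,
                             alpha = cfg$alpha_enrich)
    say("enriched rows retained: %d", nrow(enrichment))
  }

  qpcr <- NULL
  conc <- NULL
  if (!is.null(ct_tab)) {
    qpcr <- qpcr_analysis(ct_tab)
    conc <- tryCatch(concordance(qpcr$results, gene_calls),
                     error = function(e) NULL)
    if (!is.null(conc))
      say("qPCR/array direction concordance: %.0f%%",
          100 * conc$concordance)
  }

  chain <- c(probes_in = unname(qc$report[["probes_in"]]),
             probes_expressed = n_expressed,
             probes_de = n_de,
             genes_de = nrow(gene_calls),
             genes_fc_filtered = nrow(relevant),
             genes_annotated = n_annotated,
             genes_clustered = if (is.null(clustering)) 0L
                               else length(clustering$assign))
  list(qc = qc, de = de, gene_calls = gene_calls, relevant = relevant,
       clustering = clustering, enrichment = enrichment,
       qpcr = qpcr, concordance = conc, chain = chain)
}

#' Run the pipeline from files on disk and write all artifacts
#'
#' File-level wrapper around [run_pipeline()] matching the CLI contract:
#' reads TSV/OBO inputs, writes stage outputs and a resolved-config
#' manifest into `out_dir`.
#'
#' @param paths named list of input paths: `expr`, `flags`, `meta`,
#'   `probe_map`, `obo`, `annotations`, optional `pathways` (GMT),
#'   optional `qpcr`.
#' @param out_dir output directory.
#' @param config threshold list.
#' @param verbose log to stderr.
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_all_files <- function(paths, out_dir, config = default_run_config(),
                          verbose = TRUE) {
  for (p in unlist(paths))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  values <- read_tsv_matrix(paths$expr, "probe_id")
  flags <- if (!is.null(paths$flags))
    read_tsv_matrix(paths$flags, "probe_id") > 0 else NULL
  expr <- expr_matrix(values, flags = flags, scale = "raw")
  meta <- read_tsv(paths$meta)
  probe_map <- read_tsv(paths$probe_map)
  dag <- read_obo(paths$obo)
  annotations <- read_annotations(paths$annotations, dag)
  pathway_sets <- if (!is.null(paths$pathways)) {
    s <- read_gene_sets(paths$pathways)
    list(pathways = stats::setNames(s, names(s)))
  } else list()
  ct_tab <- if (!is.null(paths$qpcr)) read_tsv(paths$qpcr) else NULL

  res <- run_pipeline(expr, meta, probe_map, dag, annotations,
                      pathway_sets, ct_tab, config, verbose)

  write_tsv(masked_values(res$qc$expr), file.path(out_dir, "qc_matrix.tsv"),
            "probe_id")
  jsonlite::write_json(as.list(res$qc$report),
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tsv(res$de, file.path(out_dir, "de_probes.tsv"))
  write_tsv(res$gene_calls, file.path(out_dir, "de_genes.tsv"))
  write_tsv(res$relevant, file.path(out_dir, "de_genes_relevant.tsv"))
  if (!is.null(res$clustering)) {
    write_tsv(data.frame(gene_id = names(res$clustering$assign),
                         cluster = unname(res$clustering$assign),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "clusters.tsv"))
    write_tsv(res$clustering$summary, file.path(out_dir,
                                                "cluster_summary.tsv"))
    write_tsv(res$clustering$sim, file.path(out_dir, "similarity.tsv"),
              "gene_id")
    write_dendrogram(res$clustering$dendrogram,
                     file.path(out_dir, "dendrogram.nwk"))
    write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(res$qpcr)) {
    write_tsv(res$qpcr$results, file.path(out_dir, "qpcr_results.tsv"))
    if (!is.null(res$concordance))
      write_tsv(res$concordance$table, file.path(out_dir,
                                                 "qpcr_concordance.tsv"))
  }
  jsonlite::write_json(list(config = config, chain = as.list(res$chain)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

# --- command-line interface -------------------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `qc`, `de`, `semsim`, `cluster`, `enrich`,
#' `qpcr`, `run-all`.  Each reads/writes the standard TSV/OBO artifacts;
#' see the package vignette.  Installed alongside the package as
#' `inst/scripts/semde`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
semde_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: semde <simulate|qc|de|semsim|cluster|enrich|qpcr|run-all>",
            " [--key value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
         else default_run_config()
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)

  status <- tryCatch({
    switch(cmd,
      "simulate" = {
        cc <- sim_config(
          n_animals_per_muscle = num(opt$`n-animals`, 20),
          n_genes = num(opt$`n-genes`, 500),
          seed = num(opt$seed, cfg$seed))
        write_simulation(cc, opt$out %||% "sim")
      },
      "qc" = {
        values <- read_tsv_matrix(opt$expr, "probe_id")
        flags <- if (!is.null(opt$flags))
          read_tsv_matrix(opt$flags, "probe_id") > 0 else NULL
        expr <- expr_matrix(values, flags = flags, scale = "raw")
        meta <- read_tsv(opt$meta)
        qc <- qc_pipeline(expr, meta,
                          max_flag_fraction = cfg$max_flag_fraction,
                          k_sd = cfg$k_sd, kmeans_k = cfg$kmeans_k,
                          seed = cfg$seed)
        dir.create(opt$out %||% "qc", recursive = TRUE, showWarnings = FALSE)
        write_tsv(masked_values(qc$expr),
                  file.path(opt$out %||% "qc", "qc_matrix.tsv"), "probe_id")
        jsonlite::write_json(as.list(qc$report),
                             file.path(opt$out %||% "qc", "qc_report.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      "de" = {
        values <- read_tsv_matrix(opt$qc, "probe_id")
        expr <- expr_matrix(values, missing = is.na(values) * 1L > 0,
                            scale = "ln")
        expr$values[is.na(expr$values)] <- 0
        meta <- read_tsv(opt$meta)
        de <- de_analysis(expr, meta, alpha_keep = cfg$alpha_keep,
                          alpha = num(opt$alpha, cfg$alpha_de))
        dir.create(opt$out %||% "de", recursive = TRUE, showWarnings = FALSE)
        write_tsv(de, file.path(opt$out %||% "de", "de_probes.tsv"))
        if (!is.null(opt$map)) {
          calls <- collapse_to_genes(de, read_tsv(opt$map))
          write_tsv(calls, file.path(opt$out %||% "de", "de_genes.tsv"))
          write_tsv(relevance_filter(calls, num(opt$`min-fc`, cfg$min_fc)),
                    file.path(opt$out %||% "de", "de_genes_relevant.tsv"))
        }
      },
      "semsim" = {
        dag <- read_obo(opt$obo)
        ann <- read_annotations(opt$annotations, dag)
        genes <- if (!is.null(opt$genes))
          intersect(readLines(opt$genes), names(ann)) else names(ann)
        sim <- similarity_matrix(ann[genes], dag)
        write_tsv(sim, opt$out %||% "sim.tsv", "gene_id")
      },
      "cluster" = {
        sim <- read_tsv_matrix(opt$sim, "gene_id")
        dend <- ward_cluster(to_distance(sim))
        assign <- cut_clusters(dend, num(opt$k, cfg$cluster_k))
        write_tsv(data.frame(gene_id = names(assign),
                             cluster = unname(assign),
                             stringsAsFactors = FALSE),
                  opt$out %||% "clusters.tsv")
        if (!is.null(opt$tree)) write_dendrogram(dend, opt$tree)
      },
      "enrich" = {
        dag <- read_obo(opt$obo)
        ann <- read_annotations(opt$annotations, dag)
        cl <- read_tsv(opt$clusters)
        assign <- stats::setNames(cl$cluster, cl$gene_id)
        background <- readLines(opt$background)
        sets <- if (!is.null(opt$pathways))
          list(pathways = read_gene_sets(opt$pathways)) else list()
        res <- enrich_all(assign, ann, dag, background, sets,
                          min_genes = cfg$min_genes,
                          alpha = cfg$alpha_enrich)
        write_tsv(res, opt$out %||% "enrichment.tsv")
      },
      "qpcr" = {
        ct <- read_tsv(opt$ct)
        res <- qpcr_analysis(ct)
        write_tsv(res$results, opt$out %||% "qpcr_results.tsv")
      },
      "run-all" = {
        run_all_files(list(expr = opt$expr, flags = opt$flags,
                           meta = opt$meta, probe_map = opt$map,
                           obo = opt$obo, annotations = opt$annotations,
                           pathways = opt$pathways, qpcr = opt$qpcr),
                      opt$out %||% "out", cfg)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("semde error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
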