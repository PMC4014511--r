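#' Propagate annotations to ancestor terms
#'
#' Standard over-representation practice: a gene annotated to a term is
#' counted as annotated to every ancestor of that term as well.
#'
#' @param annotations named list gene -> term ids.
#' @param dag a [go_dag()].
#' @return named list gene -> term ids including all ancestors.
#' @export
propagate_annotations <- function(annotations, dag) {
  anc_cache <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (is.null(anc_cache[[t]])) anc_cache[[t]] <- ancestors_of(t, dag)
    anc_cache[[t]]
  }
  lapply(annotations, function(ts)
    unique(unlist(lapply(ts, get_anc), use.names = FALSE)))
}

#' Hypergeometric over-representation test for one term in one cluster
#'
#' With background size N, K background genes annotated to the term, a
#' cluster of n genes and x of them annotated, the upper-tail p-value
#' `P[X >= x]` is obtained by direct summation of the hypergeometric mass,
#' and the enrichment score is the observed/expected ratio
#' `ES = x / (n K / N)`.  Rows with fewer than `min_genes` cluster genes in
#' the term are suppressed (returned as NULL), as are terms with no
#' background annotation.
#'
#' @param cluster_genes character vector (subset of `background`).
#' @param term_genes character vector of genes annotated to the term.
#' @param background chip background gene ids.
#' @param min_genes minimum cluster genes in the term; default 5.
#' @return one-row data.frame (`n_G`, `expected`, `ES`, `p`) or NULL.
#' @export
hypergeom_enrich <- function(cluster_genes, term_genes, background,
                             min_genes = 5) {
  if (!length(background)) stop("background gene set is empty")
  if (!all(cluster_genes %in% background))
    stop("cluster genes must be a subset of the background")
  N <- length(background)
  K <- length(intersect(term_genes, background))
  if (K == 0) return(NULL)
  n <- length(cluster_genes)
  x <- length(intersect(cluster_genes, term_genes))
  if (x < min_genes) return(NULL)
  xs <- x:min(K, n)
  p <- sum(stats::dhyper(xs, K, N - K, n))
  p <- min(p, 1)
  expected <- n * K / N
  data.frame(n_G = x, expected = expected, ES = x / expected, p = p,
             stringsAsFactors = FALSE)
}

#' BH-adjust one cluster-by-collection enrichment run and filter
#'
#' The BH family is the full set of terms tested within one cluster and one
#' collection; rows with adjusted p above `alpha` are dropped.
#'
#' @param rows data.frame of [hypergeom_enrich()] rows with a `p` column.
#' @param alpha retention level (inclusive); default 0.05.
#' @return filtered data.frame with an `adj_p` column, sorted by `adj_p`.
#' @export
adjust_and_filter <- function(rows, alpha = 0.05) {
  if (is.null(rows) || !nrow(rows)) return(rows)
  rows$adj_p <- bh_adjust(rows$p)
  rows <- rows[!is.na(rows$adj_p) & rows$adj_p <= alpha, , drop = FALSE]
  rows[order(rows$adj_p, rows$p), , drop = FALSE]
}

# run one collection (named list set id -> gene ids) against one cluster
enrich_one <- function(cluster_genes, sets, set_names, background,
                       min_genes, alpha) {
  rows <- lapply(names(sets), function(id) {
    r <- hypergeom_enrich(cluster_genes, sets[[id]], background, min_genes)
    if (is.null(r)) return(NULL)
    cbind(data.frame(id = id, name = set_names[[id]] %||% id,
                     stringsAsFactors = FALSE), r)
  })
  rows <- do.call(rbind, rows)
  adjust_and_filter(rows, alpha)
}

#' Per-cluster term and pathway enrichment
#'
#' Runs the hypergeometric over-representation test for every GO BP term
#' (annotations propagated to ancestors by default) and for each pathway
#' collection, separately per cluster, with BH correction within each
#' cluster-by-collection run.
#'
#' @param assign named cluster vector from [cut_clusters()].
#' @param annotations named list gene -> term ids (direct annotations).
#' @param dag a [go_dag()].
#' @param background chip background gene ids.
#' @param pathway_sets optional named list of collections; each collection
#'   is a named list: set id -> gene ids.
#' @param min_genes minimum genes per reported row; default 5.
#' @param alpha BH-adjusted retention level; default 0.05.
#' @param propagate propagate annotations to ancestors; default TRUE.
#' @return data.frame with columns `cluster`, `collection`, `id`, `name`,
#'   `n_G`, `expected`, `ES`, `p`, `adj_p`, sorted by cluster then adj_p.
#' @export
enrich_all <- function(assign, annotations, dag, background,
                       pathway_sets = list(), min_genes = 5, alpha = 0.05,
                       propagate = TRUE) {
  ann <- if (propagate) propagate_annotations(annotations, dag)
         else annotations
  # invert gene -> terms to term -> genes
  flat <- data.frame(gene = rep(names(ann), lengths(ann)),
                     term = unlist(ann, use.names = FALSE),
                     stringsAsFactors = FALSE)
  flat <- flat[flat$gene %in% background, , drop = FALSE]
  term_sets <- split(flat$gene, flat$term)
  term_names <- stats::setNames(dag$terms$name, dag$terms$id)

  collections <- c(list(GO_BP = list(sets = term_sets,
                                     names = as.list(term_names))),
                   lapply(pathway_sets, function(s)
                     list(sets = s, names = as.list(names(s)))))
  out <- list()
  for (cl in sort(unique(assign))) {
    cg <- intersect(names(assign)[assign == cl], background)
    if (!length(cg)) next
    for (coll in names(collections)) {
      r <- enrich_one(cg, collections[[coll]]$sets,
                      collections[[coll]]$names, background,
                      min_genes, alpha)
      if (!is.null(r) && nrow(r))
        out[[length(out) + 1L]] <-
          cbind(data.frame(cluster = cl, collection = coll,
                           stringsAsFactors = FALSE), r)
    }
  }
  if (!length(out))
    return(data.frame(cluster = integer(0), collection = character(0),
                      id = character(0), name = character(0),
                      n_G = integer(0), expected = numeric(0),
                      ES = numeric(0), p = numeric(0), adj_p = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster, res$adj_p), , drop = FALSE]
}

#' Read gene-set collections from a GMT-style TSV
#'
#' Each line: set id, set name, then member gene ids (tab-separated).
#'
#' @param path file path.
#' @return named list: set id -> character vector of gene ids; names
#'   attribute `set_names` maps id -> display name.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1)
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  attr(sets, "set_names") <- stats::setNames(vapply(parts, `[`, "", 2), ids)
  sets
}
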