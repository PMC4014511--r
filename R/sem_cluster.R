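#' Convert a similarity matrix to a distance matrix
#'
#' `d = 1 - sim`: functionally similar genes lie close to zero.  The
#' diagonal is forced to exactly zero.
#'
#' @param sim symmetric gene similarity matrix in \[0, 1\].
#' @return a `dist` object (attribute `labels` = gene ids).
#' @export
to_distance <- function(sim) {
  if (!isSymmetric(unname(sim), tol = 1e-12))
    stop("similarity matrix must be symmetric")
  d <- 1 - sim
  diag(d) <- 0
  stats::as.dist(d)
}

#' Agglomerative Ward clustering of the semantic distance matrix
#'
#' Two Ward variants are offered: `"ward.D2"` (classical Ward criterion,
#' operating on squared input dissimilarities — the default) and
#' `"ward.D"` (the historical R behaviour that feeds the raw
#' dissimilarities into the Ward update, as 2008-era analyses did).
#' Deterministic for a given input; `hclust` breaks merge ties by lowest
#' pair index.
#'
#' @param d a `dist` object (from [to_distance()]).
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return an `hclust` dendrogram.
#' @export
ward_cluster <- function(d, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  if (!inherits(d, "dist")) stop("d must be a dist object (see to_distance)")
  if (attr(d, "Size") < 2) stop("clustering needs at least 2 genes")
  stats::hclust(d, method = variant)
}

#' Cut the dendrogram into k clusters
#'
#' @param dend an `hclust` tree.
#' @param k number of clusters (default 5); must satisfy 1 <= k <= n.
#' @return named integer vector gene -> cluster label in 1..k.
#' @export
cut_clusters <- function(dend, k = 5) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stop("k must lie between 1 and the number of genes")
  stats::cutree(dend, k = k)
}

#' Per-cluster direction bookkeeping
#'
#' Totals and overexpressed-in-LM / overexpressed-in-SM counts per cluster,
#' joined from the gene-level DE calls.
#'
#' @param assign named cluster vector from [cut_clusters()].
#' @param gene_calls gene-level table from [collapse_to_genes()].
#' @return data.frame: `cluster`, `n_genes`, `n_LM`, `n_SM`.
#' @export
summarize_clusters <- function(assign, gene_calls) {
  dirs <- gene_calls$direction[match(names(assign), gene_calls$gene_id)]
  out <- do.call(rbind, lapply(sort(unique(assign)), function(cl) {
    in_cl <- assign == cl
    data.frame(cluster = cl,
               n_genes = sum(in_cl),
               n_LM = sum(in_cl & !is.na(dirs) & dirs == "LM"),
               n_SM = sum(in_cl & !is.na(dirs) & dirs == "SM"))
  }))
  rownames(out) <- NULL
  out
}

#' Cluster annotated genes by GO semantic similarity, end to end
#'
#' Restricts the gene calls to genes with at least one annotation term (the
#' excluded, unannotated set is reported), computes the gene similarity
#' matrix, clusters on 1 - similarity with Ward aggregation and cuts at k.
#'
#' @param calls gene-level calls (after [relevance_filter()]).
#' @param annotations named list gene -> term ids.
#' @param dag a [go_dag()].
#' @param k number of clusters (default 5).
#' @param variant Ward variant, see [ward_cluster()].
#' @param method gene-similarity combination rule, see [gene_similarity()].
#' @return list with `assign`, `dendrogram`, `summary`, `sim`,
#'   `unannotated` (character vector of excluded gene ids).
#' @export
cluster_genes <- function(calls, annotations, dag, k = 5,
                          variant = "ward.D2", method = "BMA") {
  annotated <- calls$gene_id[calls$gene_id %in% names(annotations)]
  unannotated <- setdiff(calls$gene_id, annotated)
  if (length(annotated) < 2)
    stop("need at least 2 annotated genes to cluster")
  sim <- similarity_matrix(annotations[annotated], dag, method = method)
  dend <- ward_cluster(to_distance(sim), variant = variant)
  assign <- cut_clusters(dend, k = min(k, length(annotated)))
  list(assign = assign, dendrogram = dend,
       summary = summarize_clusters(assign, calls),
       sim = sim, unannotated = unannotated)
}

#' Write a dendrogram as a Newick tree with heights
#' @param dend an `hclust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}
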