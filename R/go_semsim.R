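#' Typed acyclic ontology term graph
#'
#' Directed acyclic graph of ontology terms with child -> parent edges typed
#' `is_a` or `part_of` — the substrate of Wang graph-based semantic
#' similarity.  Every term must be free of cycles and the graph must have at
#' least one root (a term that is nobody's child).
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `type`
#'   (`"is_a"` or `"part_of"`).
#' @return object of class `go_dag` with per-term parent adjacency lists.
#' @export
go_dag <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "type") %in% names(edges)))
  if (anyDuplicated(terms$id)) stop("duplicated term ids")
  bad <- setdiff(edges$type, c("is_a", "part_of"))
  if (length(bad)) stop("unsupported edge type(s): ", paste(bad, collapse = ", "))
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown))
    stop("edges reference unknown term(s): ", paste(unknown, collapse = ", "))

  n <- nrow(terms)
  idx <- stats::setNames(seq_len(n), terms$id)
  # Kahn's algorithm on child -> parent edges: peel leaves, decrementing
  # each removed node's parents; leftovers indicate a cycle
  indeg <- tabulate(idx[edges$parent], nbins = n)   # edges arriving at node
  pa_of <- split(idx[edges$parent], factor(edges$child, levels = terms$id))
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (pi in pa_of[[v]]) {
      indeg[pi] <- indeg[pi] - 1L
      if (indeg[pi] == 0L) queue <- c(queue, pi)
    }
  }
  if (seen < n) stop("ontology graph contains a cycle")
  parents <- split(data.frame(parent = edges$parent, type = edges$type,
                              stringsAsFactors = FALSE),
                   factor(edges$child, levels = terms$id))
  roots <- terms$id[!(terms$id %in% edges$child)]
  if (!length(roots)) stop("ontology has no root term")
  structure(list(terms = terms, edges = edges, parents = parents,
                 roots = roots),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d edges (%d is_a, %d part_of), root(s): %s\n",
              nrow(x$terms), nrow(x$edges), sum(x$edges$type == "is_a"),
              sum(x$edges$type == "part_of"),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Ancestor set of a term (the term itself included)
#' @keywords internal
ancestors_of <- function(term, dag) {
  anc <- term
  frontier <- term
  while (length(frontier)) {
    ps <- unique(unlist(lapply(dag$parents[frontier],
                               function(pe) pe$parent), use.names = FALSE))
    frontier <- setdiff(ps, anc)
    anc <- c(anc, frontier)
  }
  anc
}

#' Wang S-values of a term over its ancestor graph
#'
#' The semantic contribution of the anchor term A to itself is 1; the
#' contribution of an ancestor t is the maximum, over children c of t lying
#' inside A's ancestor graph, of `w * S_A(c)`, where w is the contribution
#' factor of the edge c -> t (0.8 for is_a, 0.6 for part_of by default, the
#' values of the cited graph-based similarity method).  The semantic value
#' SV(A) is the sum of S-values over the ancestor graph.
#'
#' @param term anchor term id.
#' @param dag a [go_dag()].
#' @param weights named numeric edge-type contribution factors.
#' @return list with `s` (named numeric S-values, anchor included) and
#'   `sv` (their sum, always >= 1).
#' @export
s_values <- function(term, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!term %in% dag$terms$id) stop("unknown term: ", term)
  anc <- ancestors_of(term, dag)
  # A-ward children within the ancestor graph: edges (c -> t), both in anc
  e <- dag$edges[dag$edges$child %in% anc & dag$edges$parent %in% anc, ]
  kids_of <- split(data.frame(child = e$child, w = unname(weights[e$type]),
                              stringsAsFactors = FALSE),
                   factor(e$parent, levels = anc))
  memo <- new.env(parent = emptyenv())
  assign(term, 1, envir = memo)
  s_of <- function(t) {
    if (!is.null(v <- memo[[t]])) return(v)
    kd <- kids_of[[t]]
    v <- max(vapply(seq_len(nrow(kd)),
                    function(i) kd$w[i] * s_of(kd$child[i]), 0))
    memo[[t]] <- v
    v
  }
  s <- vapply(anc, s_of, 0)
  list(s = s, sv = sum(s))
}

#' Wang semantic similarity between two ontology terms
#'
#' `sim(a, b) = sum over shared ancestors t of (S_a(t) + S_b(t)) /
#' (SV(a) + SV(b))`.  Symmetric, 1 for identical terms, and approaches 0 for
#' terms sharing only weakly contributing ancestors.
#'
#' @param a,b term ids.
#' @param dag a [go_dag()].
#' @param weights edge-type contribution factors (see [s_values()]).
#' @return similarity in \[0, 1\].
#' @export
term_similarity <- function(a, b, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  ns <- stats::setNames(dag$terms$namespace, dag$terms$id)
  if (!a %in% dag$terms$id) stop("unknown term: ", a)
  if (!b %in% dag$terms$id) stop("unknown term: ", b)
  if (ns[[a]] != ns[[b]]) {
    warning("terms belong to disjoint namespaces; similarity is 0")
    return(0)
  }
  sa <- s_values(a, dag, weights)
  sb <- s_values(b, dag, weights)
  shared <- intersect(names(sa$s), names(sb$s))
  sum(sa$s[shared] + sb$s[shared]) / (sa$sv + sb$sv)
}

# Term-by-term similarity matrix from precomputed S-value maps
sim_from_svals <- function(sv_a, sv_b) {
  shared <- intersect(names(sv_a$s), names(sv_b$s))
  sum(sv_a$s[shared] + sv_b$s[shared]) / (sv_a$sv + sv_b$sv)
}

#' Gene-to-gene functional similarity from annotation sets
#'
#' Combines the pairwise term similarities of two genes' annotation sets.
#' The default best-match average (BMA) takes, for each term of either gene,
#' its best match in the other gene's set, and averages all those maxima;
#' `"max"` and `"mean"` are alternatives.
#'
#' @param annots_a,annots_b non-empty character vectors of term ids.
#' @param dag a [go_dag()].
#' @param method `"BMA"` (default), `"max"` or `"mean"`.
#' @param sval_cache optional environment caching [s_values()] per term.
#' @param weights edge-type contribution factors.
#' @return similarity in \[0, 1\].
#' @export
gene_similarity <- function(annots_a, annots_b, dag, method = "BMA",
                            sval_cache = NULL,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!length(annots_a) || !length(annots_b))
    stop("annotation sets must be non-empty")
  method <- match.arg(method, c("BMA", "max", "mean"))
  get_sv <- function(t) {
    if (is.null(sval_cache)) return(s_values(t, dag, weights))
    if (is.null(sval_cache[[t]])) sval_cache[[t]] <- s_values(t, dag, weights)
    sval_cache[[t]]
  }
  sa <- lapply(annots_a, get_sv)
  sb <- lapply(annots_b, get_sv)
  tm <- matrix(0, length(annots_a), length(annots_b))
  for (i in seq_along(sa))
    for (j in seq_along(sb))
      tm[i, j] <- sim_from_svals(sa[[i]], sb[[j]])
  switch(method,
         BMA  = mean(c(apply(tm, 1, max), apply(tm, 2, max))),
         max  = max(tm),
         mean = mean(tm))
}

#' Pairwise gene similarity matrix
#'
#' Computes the full symmetric gene-by-gene semantic-similarity matrix for a
#' set of annotated genes, caching S-value maps per term and computing each
#' unordered pair once.  Genes without annotations must be excluded by the
#' caller (the pipeline reports them separately).
#'
#' @param annotations named list: gene id -> character vector of term ids.
#' @param dag a [go_dag()].
#' @param method gene-level combination rule, see [gene_similarity()].
#' @param weights edge-type contribution factors.
#' @return symmetric numeric matrix with gene ids as dimnames and unit
#'   diagonal; attribute `method` records the combination rule.
#' @export
similarity_matrix <- function(annotations, dag, method = "BMA",
                              weights = c(is_a = 0.8, part_of = 0.6)) {
  genes <- names(annotations)
  if (is.null(genes) || !length(genes)) stop("annotations must be a named list")
  if (any(!vapply(annotations, length, 0L)))
    stop("every gene must carry at least one annotation term")
  cache <- new.env(parent = emptyenv())
  n <- length(genes)
  sim <- diag(1, n)
  dimnames(sim) <- list(genes, genes)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        sim[i, j] <- sim[j, i] <-
          gene_similarity(annotations[[i]], annotations[[j]], dag,
                          method = method, sval_cache = cache,
                          weights = weights)
      }
      # self-similarity of a multi-term gene is 1 under BMA by construction
    }
  }
  attr(sim, "method") <- method
  sim
}

# --- ontology / annotation I/O ---------------------------------------------

#' Read an OBO-subset ontology file
#'
#' Parses `[Term]` stanzas with `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines.  Obsolete terms are skipped; by default
#' only the biological_process namespace is kept (edges crossing out of the
#' kept namespace are dropped with the terms).
#'
#' @param path OBO file path.
#' @param namespace namespace to keep, or `NULL` for all.
#' @return a [go_dag()].
#' @export
read_obo <- function(path, namespace = "biological_process") {
  lines <- readLines(path)
  starts <- grep("^\\[Term\\]", lines)
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- nms <- nss <- character(0)
  edges <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[bounds[k]:(bounds[k + 1] - 1L)]
    get1 <- function(key) {
      m <- grep(paste0("^", key, ":"), chunk, value = TRUE)
      if (!length(m)) return(NA_character_)
      trimws(sub(paste0("^", key, ":\\s*"), "", m[1]))
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    ids <- c(ids, id)
    nms <- c(nms, get1("name") %||% id)
    nss <- c(nss, get1("namespace") %||% NA_character_)
    isa <- grep("^is_a:", chunk, value = TRUE)
    for (x in isa) {
      p <- trimws(sub("!.*$", "", sub("^is_a:\\s*", "", x)))
      edges[[length(edges) + 1L]] <- c(id, p, "is_a")
    }
    rel <- grep("^relationship:\\s*part_of", chunk, value = TRUE)
    for (x in rel) {
      p <- trimws(sub("!.*$", "",
                      sub("^relationship:\\s*part_of\\s*", "", x)))
      edges[[length(edges) + 1L]] <- c(id, p, "part_of")
    }
  }
  terms <- data.frame(id = ids, name = nms, namespace = nss,
                      stringsAsFactors = FALSE)
  ed <- if (length(edges)) {
    e <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
    names(e) <- c("child", "parent", "type")
    e
  } else data.frame(child = character(0), parent = character(0),
                    type = character(0), stringsAsFactors = FALSE)
  if (!is.null(namespace)) {
    terms <- terms[terms$namespace %in% namespace, , drop = FALSE]
    ed <- ed[ed$child %in% terms$id & ed$parent %in% terms$id, , drop = FALSE]
  }
  go_dag(terms, ed)
}

#' Write a [go_dag()] as an OBO subset
#' @param dag a [go_dag()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    pe <- dag$parents[[id]]
    stanza <- c("[Term]",
                paste0("id: ", id),
                paste0("name: ", dag$terms$name[i]),
                paste0("namespace: ", dag$terms$namespace[i]))
    if (!is.null(pe) && nrow(pe)) {
      isa <- pe$parent[pe$type == "is_a"]
      po <- pe$parent[pe$type == "part_of"]
      stanza <- c(stanza,
                  paste0("is_a: ", isa),
                  if (length(po)) paste0("relationship: part_of ", po))
    }
    writeLines(c(stanza, ""), con)
  }
  invisible(path)
}

#' Read gene -> term annotations from a GAF-like two-column TSV
#' @param path TSV with header columns `gene_id`, `term_id`.
#' @param dag optional [go_dag()]; annotations to unknown terms are dropped
#'   with a warning.
#' @return named list: gene id -> character vector of term ids.
#' @export
read_annotations <- function(path, dag = NULL) {
  x <- read_tsv(path)
  if (!all(c("gene_id", "term_id") %in% names(x)))
    stop("annotation file must have columns gene_id and term_id")
  if (!is.null(dag)) {
    drop <- !(x$term_id %in% dag$terms$id)
    if (any(drop)) {
      warning(sum(drop), " annotation(s) to terms absent from the ontology",
              " were dropped")
      x <- x[!drop, , drop = FALSE]
    }
  }
  lapply(split(x$term_id, x$gene_id), unique)
}

#' Write annotations as a GAF-like two-column TSV
#' @param annotations named list: gene id -> term ids.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(gene_id = rep(names(annotations),
                                 lengths(annotations)),
                   term_id = unlist(annotations, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
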