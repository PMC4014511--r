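# Independent oracles used to freeze expected values.  These deliberately
# take the dumbest correct route (exhaustive enumeration, direct summation)
# and share no code with the implementation they check.

# All root-ward paths from `term`; S-value of an ancestor = max over paths
# reaching it of the product of edge weights along the path.
oracle_svalues <- function(term, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  s <- c(stats::setNames(1, term))
  walk <- function(node, prod) {
    pe <- dag$parents[[node]]
    if (is.null(pe) || !nrow(pe)) return(invisible())
    for (i in seq_len(nrow(pe))) {
      p <- pe$parent[i]
      w <- prod * weights[[pe$type[i]]]
      if (is.na(s[p]) || w > s[p]) s[p] <<- w
      walk(p, w)
    }
  }
  walk(term, 1)
  list(s = s, sv = sum(s))
}

oracle_term_sim <- function(a, b, dag) {
  sa <- oracle_svalues(a, dag)
  sb <- oracle_svalues(b, dag)
  shared <- intersect(names(sa$s), names(sb$s))
  sum(sa$s[shared] + sb$s[shared]) / (sa$sv + sb$sv)
}

oracle_bma <- function(ta, tb, dag) {
  tm <- outer(seq_along(ta), seq_along(tb),
              Vectorize(function(i, j) oracle_term_sim(ta[i], tb[j], dag)))
  tm <- matrix(tm, length(ta), length(tb))
  mean(c(apply(tm, 1, max), apply(tm, 2, max)))
}

# direct BH step-up: adj_(i) = min_{j >= i} m p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# hypergeometric upper tail by binomial-coefficient enumeration
oracle_hyper_tail <- function(N, K, n, x) {
  xs <- x:min(K, n)
  xs <- xs[xs >= max(0, n - (N - K))]
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# optimal 1-D partition into k contiguous groups minimising within-group SS
# (exhaustive over breakpoints) -- oracle for the k-means variance filter
oracle_kmeans1d <- function(x, k) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  best <- NULL
  best_ss <- Inf
  brks <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(brks))) {
    cuts <- c(0, brks[, j], n)
    ss <- 0
    lab <- integer(n)
    for (g in seq_len(k)) {
      ix <- (cuts[g] + 1):cuts[g + 1]
      ss <- ss + sum((xs[ix] - mean(xs[ix]))^2)
      lab[ix] <- g
    }
    if (ss < best_ss) { best_ss <- ss; best <- lab }
  }
  out <- integer(n)
  out[o] <- best
  out
}

# random typed DAG on <= n_terms nodes: node i attaches to earlier nodes
random_dag <- function(n_terms, seed, part_of_prob = 0.3, extra_edge_prob = 0.3) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  edges <- data.frame(child = character(0), parent = character(0),
                      type = character(0), stringsAsFactors = FALSE)
  etype <- function(k) ifelse(stats::runif(k) < part_of_prob,
                              "part_of", "is_a")
  for (i in 2:n_terms) {
    parents <- sample.int(i - 1, 1)
    if (i > 2 && stats::runif(1) < extra_edge_prob)
      parents <- unique(c(parents, sample.int(i - 1, 1)))
    for (p in parents)
      edges <- rbind(edges,
                     data.frame(child = ids[i], parent = ids[p],
                                type = etype(1), stringsAsFactors = FALSE))
  }
  go_dag(data.frame(id = ids, name = ids, namespace = "biological_process",
                    stringsAsFactors = FALSE), edges)
}

# tiny fixed fixtures used across files
chain_dag <- function() {
  go_dag(data.frame(id = c("A", "B"), name = c("a", "b"),
                    namespace = "biological_process",
                    stringsAsFactors = FALSE),
         data.frame(child = "A", parent = "B", type = "is_a",
                    stringsAsFactors = FALSE))
}

diamond_dag <- function() {
  go_dag(data.frame(id = c("A", "B", "C", "D"), name = letters[1:4],
                    namespace = "biological_process",
                    stringsAsFactors = FALSE),
         data.frame(child = c("A", "A", "B", "C"),
                    parent = c("B", "C", "D", "D"),
                    type = "is_a", stringsAsFactors = FALSE))
}

# small complete-data design shared by DE tests
tiny_meta <- function(n = 8) {
  data.frame(
    sample_id = c(sprintf("A%02d_LM", 1:n), sprintf("A%02d_SM", 1:n)),
    animal = rep(sprintf("A%02d", 1:n), 2),
    muscle = rep(c("LM", "SM"), each = n),
    sex = rep(rep_len(c("M", "F"), n), 2),
    slaughter_batch = rep(ifelse(seq_len(n) <= n / 2, "s", "w"), 2),
    carcass_weight = rep(seq(100, 116, length.out = n), 2),
    stringsAsFactors = FALSE)
}

ln_expr <- function(values) {
  expr_matrix(values, scale = "ln")
}
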