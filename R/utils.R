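#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classical step-up FDR adjustment: p_(i) is replaced by
#' min_{j >= i} ( m * p_(j) / j ), capped at 1.  NA entries are propagated
#' and excluded from the number of tests m.
#'
#' @param p numeric vector of raw p-values in \[0, 1\] (NAs allowed).
#' @return numeric vector of adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / seq(m, 1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects.
#' Used by the parameter-recovery tests of the clustering stage.
#'
#' @param a,b vectors of cluster labels (any atomic type), equal length.
#' @return scalar ARI; 1 for identical partitions, ~0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)
  (sij - expected) / (max_index - expected)
}

#' Geometric mean
#' @param x positive numeric vector
#' @return scalar geometric mean
#' @keywords internal
geometric_mean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# --- TSV helpers -----------------------------------------------------------
# All pipeline tables are tab-separated with a header row; matrices carry
# row names in the first column.

#' @keywords internal
write_tsv <- function(x, path, row_col = NULL) {
  if (!is.null(row_col)) {
    x <- cbind(stats::setNames(data.frame(rownames(x),
                                          stringsAsFactors = FALSE), row_col),
               as.data.frame(x, stringsAsFactors = FALSE))
    rownames(x) <- NULL
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path, row_col = NULL) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(row_col)) {
    rownames(x) <- x[[row_col]]
    x[[row_col]] <- NULL
  }
  x
}

#' @keywords internal
read_tsv_matrix <- function(path, row_col) {
  as.matrix(read_tsv(path, row_col = row_col))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
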