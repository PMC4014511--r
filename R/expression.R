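#' Probe-by-sample expression matrix with flags and missingness mask
#'
#' Lightweight container used throughout the QC and modelling stages.
#' `values` holds intensities (raw or natural-log scale, tracked by the
#' `scale` tag), `flags` marks spots failing the scanner's quality criteria
#' (intensity / uniformity / saturation) and `missing` marks entries excluded
#' from analysis (flagged spots and outliers end up here).
#'
#' @param values numeric probe x sample matrix with dimnames.
#' @param flags logical matrix, same shape; defaults to all-FALSE.
#' @param missing logical matrix, same shape; defaults to all-FALSE.
#' @param scale `"raw"` or `"ln"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, flags = NULL, missing = NULL, scale = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry probe and sample names as dimnames")
  scale <- match.arg(scale, c("raw", "ln"))
  if (is.null(flags)) flags <- array(FALSE, dim(values))
  if (is.null(missing)) missing <- array(FALSE, dim(values))
  storage.mode(flags) <- "logical"
  storage.mode(missing) <- "logical"
  if (!identical(dim(flags), dim(values)) ||
      !identical(dim(missing), dim(values)))
    stop("flags and missing must have the same shape as values")
  if (scale == "raw" && any(values[!missing] < 0, na.rm = TRUE))
    stop("raw intensities must be non-negative")
  dimnames(flags) <- dimnames(missing) <- dimnames(values)
  structure(list(values = values, flags = flags, missing = missing,
                 scale = scale),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  flagged spots: %d; masked entries: %d\n",
              sum(x$flags), sum(x$missing)))
  invisible(x)
}

#' Subset an expression matrix by probes
#' @keywords internal
subset_probes <- function(m, keep) {
  expr_matrix(m$values[keep, , drop = FALSE],
              m$flags[keep, , drop = FALSE],
              m$missing[keep, , drop = FALSE],
              scale = m$scale)
}

#' Values with masked entries set to NA
#' @param m an [expr_matrix()].
#' @return numeric matrix.
#' @export
masked_values <- function(m) {
  v <- m$values
  v[m$missing] <- NA_real_
  v
}

#' Validate a sample-metadata table against an expression matrix
#'
#' @param meta data.frame with columns `sample_id`, `muscle` and any design
#'   variables; `muscle` must have exactly two levels covering every sample.
#' @param m optional [expr_matrix()] whose columns must all be present.
#' @return `meta`, invisibly, with `muscle` as a factor.
#' @export
check_metadata <- function(meta, m = NULL) {
  req <- c("sample_id", "muscle")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample ids in metadata")
  meta$muscle <- factor(meta$muscle)
  if (!is.null(m)) {
    absent <- setdiff(colnames(m$values), meta$sample_id)
    if (length(absent))
      stop("samples missing muscle label in metadata: ",
           paste(utils::head(absent, 5), collapse = ", "))
  }
  invisible(meta)
}
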