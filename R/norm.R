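# Trimmed mean of M-values (TMM) cross-sample normalization.
#
# TMM (Robinson & Oshlack 2010) estimates a relative scaling factor per
# sample so that expression is comparable across libraries even when a
# biased (asymmetric) subset of genes is differentially expressed. Against a
# reference sample, each gene contributes a log-ratio M and a log-abundance
# A; after double trimming (30% on M, 5% on A by default) the factor is the
# inverse-variance-weighted mean of the remaining M values. Factors are
# rescaled to geometric mean 1.

#' TMM normalization factors
#'
#' @param x Nonnegative numeric matrix, genes x samples (counts or
#'   length-normalized abundances). Column names become factor names.
#' @param m_trim Two-sided trim fraction on the M (log-ratio) values
#'   (default 0.30).
#' @param a_trim Two-sided trim fraction on the A (log-abundance) values
#'   (default 0.05).
#' @param ref_column Reference sample index; by default the sample whose
#'   upper-quartile (of library-size-scaled values) is closest to the mean
#'   upper-quartile.
#' @param do_weighting Weight M values by inverse asymptotic (delta-method
#'   binomial) variance (default `TRUE`).
#' @param lib_sizes Library sizes used to scale each column before computing
#'   M/A values; defaults to the column sums. Supply explicit (e.g. equal)
#'   sizes to re-examine an already-normalized matrix, since with the
#'   default the factors are invariant to rescaling any column.
#' @return Positive per-sample factors with geometric mean 1.
#' @references Robinson MD, Oshlack A (2010). A scaling normalization method
#'   for differential expression analysis of RNA-seq data. Genome Biol
#'   11:R25.
#' @export
tmm_factors <- function(x, m_trim = 0.30, a_trim = 0.05, ref_column = NULL,
                        do_weighting = TRUE, lib_sizes = NULL) {
  x <- as.matrix(x)
  if (any(x < 0) || anyNA(x)) {
    stop("expression values must be nonnegative and non-missing",
         call. = FALSE)
  }
  if (ncol(x) < 2L) stop("need at least two samples", call. = FALSE)
  if (any(colSums(x) == 0)) {
    stop("sample(s) with all-zero expression: ",
         paste(which(colSums(x) == 0), collapse = ", "), call. = FALSE)
  }
  lib <- if (is.null(lib_sizes)) colSums(x) else lib_sizes
  stopifnot(length(lib) == ncol(x), all(lib > 0))
  if (is.null(ref_column)) {
    uq <- apply(sweep(x, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref_column <- which.min(abs(uq - mean(uq)))
  }
  obs_r <- x[, ref_column]
  n_r <- lib[ref_column]
  f <- vapply(seq_len(ncol(x)), function(j) {
    .tmm_pair(x[, j], obs_r, lib[j], n_r, m_trim, a_trim, do_weighting)
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  f
}

# One sample vs the reference. Genes with zero in either sample drop out
# (their M is infinite).
.tmm_pair <- function(obs, ref, n_o, n_r, m_trim, a_trim, do_weighting) {
  m <- log2((obs / n_o) / (ref / n_r))
  a <- (log2(obs / n_o) + log2(ref / n_r)) / 2
  v <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (!length(m)) stop("no genes expressed in both sample and reference",
                       call. = FALSE)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * m_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * a_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra_ <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep)) stop("trimming removed all genes", call. = FALSE)
  f <- if (do_weighting) {
    sum(m[keep] / v[keep]) / sum(1 / v[keep])
  } else {
    mean(m[keep])
  }
  2^f
}

#' Apply normalization factors to an expression matrix
#'
#' With `method = "tmm"` each column is divided by its effective library
#' size (library size x TMM factor) and rescaled to the mean effective
#' library size, so identical samples stay identical. With
#' `method = "total"` columns are scaled to a common column sum (plain
#' total-count scaling, no TMM).
#'
#' @param x Nonnegative genes x samples matrix.
#' @param factors Per-sample factors from [tmm_factors()]; computed if
#'   `NULL` (ignored for `method = "total"`).
#' @param method `"tmm"` or `"total"`.
#' @param target Common scale constant; defaults to the mean (effective)
#'   library size.
#' @return The normalized matrix, with the factors in
#'   `attr(, "tmm_factors")` and the mode in `attr(, "method")`.
#' @export
apply_factors <- function(x, factors = NULL, method = c("tmm", "total"),
                          target = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  lib <- colSums(x)
  if (any(lib == 0)) stop("sample(s) with all-zero expression", call. = FALSE)
  if (method == "tmm") {
    if (is.null(factors)) factors <- tmm_factors(x)
    if (any(factors <= 0)) stop("factors must be positive", call. = FALSE)
    eff <- lib * factors
  } else {
    factors <- rep(1, ncol(x))
    eff <- lib
  }
  if (is.null(target)) target <- mean(eff)
  out <- sweep(x, 2, eff, "/") * target
  attr(out, "tmm_factors") <- factors
  attr(out, "method") <- method
  out
}

#' Read / write a genes x samples expression matrix as TSV
#'
#' The file has a header row of sample ids and gene ids in the first column.
#'
#' @param path File path.
#' @return `read_expression_matrix()` returns a numeric matrix with gene row
#'   names and sample column names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric values in expression matrix", call. = FALSE)
  m
}

#' @rdname read_expression_matrix
#' @param x Numeric matrix to write.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
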