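#' Median-of-ratios size-factor normalization
#'
#' A light convenience normalizer for raw counts: each cell's size factor is
#' the median, over genes with all-positive counts, of that cell's count
#' divided by the gene's geometric mean across cells; columns are divided by
#' their size factor. This is the classic median-of-ratios scheme and is
#' provided only so the pipeline can be run end-to-end on raw counts; it does
#' not estimate dispersions and is not a replacement for a full RNA-seq
#' normalization workflow. By default the pipeline assumes the input is
#' already normalized.
#'
#' @param raw Matrix of raw non-negative counts (genes x cells).
#' @return Normalized matrix of the same shape; size factors are attached as
#'   attribute `"size_factors"`.
#' @export
normalize_median_ratios <- function(raw) {
  validate_expression(raw)
  pos <- rowSums(raw > 0) == ncol(raw)
  if (!any(pos))
    stop("no gene has all-positive counts; size factors are undefined - ",
         "supply pre-normalized input instead")
  loggeo <- rowMeans(log(raw[pos, , drop = FALSE]))
  ratios <- log(raw[pos, , drop = FALSE]) - loggeo
  sf <- exp(apply(ratios, 2, stats::median))
  out <- sweep(raw, 2, sf, "/")
  attr(out, "size_factors") <- stats::setNames(sf, colnames(raw))
  out
}

#' Remove non-informative genes by coefficient of variation
#'
#' A gene is kept only if its coefficient of variation (standard deviation
#' divided by mean, computed over the normalized counts of the cells of a
#' state, zeros included, sample-sd convention) is at least `cv_threshold` in
#' BOTH states; a gene falling below the threshold in either state is removed.
#' Genes with zero mean in a state (all zeros there) are removed. The
#' operation is idempotent and preserves gene order.
#'
#' @param x Expression matrix (genes x cells).
#' @param states A [state_assignment()] covering the cells of `x`.
#' @param cv_threshold Minimum per-state CV; default 0.25.
#' @return The filtered matrix. Errors if fewer than 2 genes survive.
#' @export
filter_low_cv <- function(x, states, cv_threshold = 0.25) {
  validate_expression(x)
  if (cv_threshold < 0) stop("cv_threshold must be >= 0")
  states <- align_states(x, states)
  keep <- rep(TRUE, nrow(x))
  for (s in 0:1) {
    xs <- x[, states == s, drop = FALSE]
    if (ncol(xs) < 2)
      stop("state ", s, " has fewer than 2 cells; CV is undefined")
    mu <- rowMeans(xs)
    sdv <- apply(xs, 1, stats::sd)
    cv <- ifelse(mu > 0, sdv / mu, NA_real_)
    keep <- keep & !is.na(cv) & cv >= cv_threshold
  }
  if (sum(keep) < 2)
    stop("too few informative genes: ", sum(keep),
         " gene(s) pass the CV filter")
  x[keep, , drop = FALSE]
}

#' Row-standardize an expression matrix
#'
#' Standardizes each gene to mean 0 and standard deviation 1 across all
#' retained cells (`(e - mu_g) / sigma_g`). The positions of exact zeros in
#' the input — the dropout mask — are recorded BEFORE transformation, because
#' a dropout stays a dropout regardless of its z-score; downstream
#' correlations use that mask, never the transformed values, to decide which
#' cells support a gene pair.
#'
#' Pearson correlation is invariant to per-gene affine transforms, so the
#' correlation stage gives identical results whether it is fed the normalized
#' counts or this standardized matrix; the transform is exposed for
#' inspection, plotting and parity with the standardized scale on which the
#' method's null theory is stated.
#'
#' @param x Expression matrix (genes x cells).
#' @param convention `"sample"` (divide by n-1; default) or `"population"`
#'   (divide by n) for the standard deviation.
#' @return An object of class `"zscore_matrix"`: list with `values` (the
#'   standardized matrix), `mu`, `sigma` (per-gene), `mask` (logical matrix,
#'   `TRUE` where the input was an exact zero) and `convention`.
#' @export
z_transform <- function(x, convention = c("sample", "population")) {
  convention <- match.arg(convention)
  validate_expression(x)
  mu <- rowMeans(x)
  if (convention == "sample") {
    sigma <- apply(x, 1, stats::sd)
  } else {
    sigma <- sqrt(rowMeans((x - mu)^2))
  }
  zerovar <- which(!(sigma > 0))
  if (length(zerovar))
    stop("zero-variance gene(s): ",
         paste(rownames(x)[zerovar], collapse = ", "),
         "; run filter_low_cv() first")
  vals <- (x - mu) / sigma
  structure(list(values = vals, mu = mu, sigma = sigma,
                 mask = x == 0, convention = convention),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat("Row-standardized expression matrix:", nrow(x$values), "genes x",
      ncol(x$values), "cells\n")
  cat(sprintf("  dropout (zero) fraction: %.3f\n", mean(x$mask)))
  cat("  sd convention:", x$convention, "\n")
  invisible(x)
}

#' Dropout mask of an expression matrix
#'
#' Logical matrix marking the entries that are exact zeros in the normalized
#' counts. These entries are treated as "not detected" and excluded from the
#' support of every gene pair involving that gene/cell.
#'
#' @param x Expression matrix.
#' @return Logical matrix of the same shape, `TRUE` at dropouts.
#' @export
dropout_mask <- function(x) {
  validate_expression(x)
  x == 0
}
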