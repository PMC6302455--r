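#' Fisher interaction score of a correlation
#'
#' Converts a Pearson correlation estimated from `n` observations into a
#' sample-size-adjusted interaction score
#' \deqn{I = \frac{\sqrt{n-3}}{2}\,\ln\frac{1+r}{1-r} = \sqrt{n-3}\,
#'   \mathrm{atanh}(r),}
#' which is standard normal under the null of no correlation. Scores computed
#' at different support sizes therefore live on one common scale and can be
#' compared directly.
#'
#' Correlations at or numerically indistinguishable from +/-1 (within 1e-12)
#' would map to +/-Inf; they are clamped to +/-(1 - 1e-7) so that downstream
#' differences of scores stay finite. The number of clamped values is attached
#' as attribute `"n_clamped"`.
#'
#' @param r Correlation coefficient(s), |r| <= 1 (values beyond 1 by rounding
#'   are clamped as above).
#' @param n Support size(s), integer >= 4 (so that n - 3 >= 1).
#' @return Numeric vector of interaction scores.
#' @export
fisher_interaction <- function(r, n) {
  if (any(n < 4, na.rm = TRUE))
    stop("fisher_interaction requires n >= 4 (n - 3 must be >= 1)")
  clamp <- is.finite(r) & abs(r) >= 1 - 1e-12
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE))
    stop("|r| > 1 is not a correlation")
  r[clamp] <- sign(r[clamp]) * (1 - 1e-7)
  out <- sqrt(n - 3) * atanh(r)
  nc <- sum(clamp, na.rm = TRUE)
  if (nc > 0) attr(out, "n_clamped") <- nc
  out
}

#' Two-sided p-value of an interaction score against zero
#'
#' Under no correlation the interaction score is standard normal, so
#' `p = 2 * (1 - pnorm(|I|))`. Used by the simulation engine (intra-state
#' test of each pair's score against zero) and for single-state screening.
#' The result is floored at `2^-1074` (the smallest representable double) so
#' extreme scores underflow toward, but never reach, zero.
#'
#' @param I_value Interaction score(s), finite.
#' @return p-value(s) in (0, 1].
#' @export
intra_state_pvalue <- function(I_value) {
  if (any(!is.finite(I_value)))
    stop("interaction score must be finite")
  pmax(2 * stats::pnorm(-abs(I_value)), 2^-1074)
}

#' Support of a gene pair within a state
#'
#' The ordered set of the state's cells in which BOTH genes are detected
#' (non-zero normalized count): the cells over which the pair's correlation
#' is computed. Order follows the matrix's column order.
#'
#' @param x Expression matrix.
#' @param states A [state_assignment()].
#' @param state 0 or 1.
#' @param i,j Gene ids or row indices, `i != j`.
#' @param mask Optional dropout mask (logical, `TRUE` = dropout); defaults to
#'   `x == 0`.
#' @return Character vector of cell ids (possibly empty), with the support
#'   size as attribute `"n"`.
#' @export
pair_support <- function(x, states, state, i, j, mask = NULL) {
  validate_expression(x)
  states <- align_states(x, states)
  if (is.null(mask)) mask <- x == 0
  if (is.character(i)) i <- match(i, rownames(x))
  if (is.character(j)) j <- match(j, rownames(x))
  if (is.na(i) || is.na(j)) stop("unknown gene id")
  if (i == j) stop("pair_support requires two distinct genes")
  in_state <- states == state
  supp <- colnames(x)[in_state & !mask[i, ] & !mask[j, ]]
  structure(supp, n = length(supp))
}

#' Per-state masked correlation, support-size and interaction matrices
#'
#' For one cellular state, computes for every unordered gene pair (i, j):
#' \itemize{
#'   \item `C[i, j]`: the Pearson correlation of the two genes over the
#'     pair's support — the cells of the state where both genes are non-zero;
#'   \item `S[i, j]`: the support size;
#'   \item `I[i, j]`: the Fisher interaction score
#'     [fisher_interaction]`(C[i, j], S[i, j])`.
#' }
#' Pairs whose support is smaller than `s_min`, or on which either gene has
#' zero variance, are missing (`NA`) in `C` and `I`; `S` always reports the
#' support size. Diagonals are `NA` (self-pairs are never tested).
#'
#' The computation is blocked via cross products (each gene centered by its
#' mean over the state's detected cells, to which Pearson correlation on any
#' support is invariant) and agrees with the per-pair definition to 1e-12;
#' the per-pair path is kept as the test oracle.
#'
#' @param x Expression matrix (normalized counts).
#' @param states A [state_assignment()].
#' @param state 0 or 1.
#' @param s_min Minimum support size for a pair to be scored; default 10,
#'   hard floor 4 (the Fisher transform needs S - 3 >= 1). Pairs below
#'   `s_min` in either state are excluded from differential testing.
#' @param mask Optional dropout mask (`TRUE` = dropout); default `x == 0`.
#'   Pass the mask of the original counts when `x` is a transformed matrix.
#' @return Object of class `"state_corr"`: list with `state`, `state_name`,
#'   `C`, `S`, `I` (G x G symmetric matrices), `n_cells`, `s_min`,
#'   `n_clamped` (correlations clamped from +/-1).
#' @export
state_correlation <- function(x, states, state, s_min = 10, mask = NULL) {
  if (!(state %in% c(0, 1))) stop("state must be 0 or 1")
  if (s_min < 4)
    stop("s_min must be >= 4: the Fisher transform needs S - 3 >= 1")
  validate_expression(x)
  states <- align_states(x, states)
  if (is.null(mask)) mask <- x == 0
  cells <- states == state
  X <- t(x[, cells, drop = FALSE])                    # cells x genes
  Mlog <- !t(mask[, cells, drop = FALSE])             # TRUE where detected
  M <- matrix(as.numeric(Mlog), nrow(Mlog), ncol(Mlog))
  G <- ncol(X)
  k <- nrow(X)

  # Center each gene on its detected cells; Pearson r over any support is
  # invariant to a per-gene shift, and centering avoids cancellation when
  # counts have large means.
  ndet <- colSums(M)
  ctr <- ifelse(ndet > 0, colSums(X * M) / pmax(ndet, 1), 0)
  A <- (X - rep(ctr, each = k)) * M

  S <- crossprod(M)                     # support sizes
  Sx <- crossprod(A, M)                 # Sx[i,j] = sum of gene i over supp(i,j)
  Sxy <- crossprod(A)
  Sxx <- crossprod(A^2, M)

  num <- S * Sxy - Sx * t(Sx)
  v1 <- S * Sxx - Sx^2                  # S * sum sq - (sum)^2 for gene i
  v2 <- t(v1)
  zerovar <- !(v1 > S * Sxx * 1e-12) | !(v2 > S * t(Sxx) * 1e-12)
  den <- sqrt(pmax(v1, 0) * pmax(v2, 0))
  C <- matrix(NA_real_, G, G)
  ok <- !zerovar & S >= s_min & den > 0
  C[ok] <- num[ok] / den[ok]
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- NA_real_

  n_clamped <- sum(abs(C[upper.tri(C)]) >= 1 - 1e-12, na.rm = TRUE)
  I <- matrix(NA_real_, G, G)
  def <- !is.na(C)
  I[def] <- fisher_interaction(C[def], S[def])

  storage.mode(S) <- "integer"
  diag(S) <- NA_integer_
  dimnames(C) <- dimnames(S) <- dimnames(I) <-
    list(rownames(x), rownames(x))
  structure(list(state = as.integer(state),
                 state_name = attr(states, "state_names")[[as.character(state)]],
                 C = C, S = S, I = I,
                 n_cells = sum(cells), s_min = s_min,
                 n_clamped = n_clamped),
            class = "state_corr")
}

#' @export
print.state_corr <- function(x, ...) {
  G <- nrow(x$C)
  np <- G * (G - 1) / 2
  def <- sum(!is.na(x$C[upper.tri(x$C)]))
  cat(sprintf("Masked correlation for state %d (%s): %d genes, %d cells\n",
              x$state, x$state_name, G, x$n_cells))
  cat(sprintf("  scored pairs: %d / %d (s_min = %d)\n", def, np, x$s_min))
  if (x$n_clamped > 0)
    cat(sprintf("  correlations clamped from +/-1: %d\n", x$n_clamped))
  invisible(x)
}
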