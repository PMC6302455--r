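# Gauss error function and complement, via the normal CDF.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

#' Change in interaction strength between states
#'
#' `delta = |I1| - |I0|`: positive when the pair interacts more strongly in
#' state 1, negative when in state 0.
#'
#' @param I0,I1 Finite interaction scores in states 0 and 1.
#' @return `abs(I1) - abs(I0)`.
#' @export
delta_interaction <- function(I0, I1) {
  if (any(!is.finite(I0)) || any(!is.finite(I1)))
    stop("interaction scores must be finite")
  abs(I1) - abs(I0)
}

#' Exact null CDF of the change in interaction strength
#'
#' If both states' interaction scores are independent standard normal (no
#' true correlation in either state), the change `d = |X| - |Y|` has the
#' closed-form CDF
#' \deqn{F(d) = \tfrac12 + \mathrm{erf}(d/2) - \tfrac12\,\mathrm{sgn}(d)\,
#'   \mathrm{erf}(d/2)^2,}
#' which this function evaluates in the algebraically equivalent, numerically
#' stable form `1 - erfc(d/2)^2 / 2` for `d >= 0` and `erfc(-d/2)^2 / 2`
#' for `d < 0`. Having the exact CDF makes p-values direct; no permutation or
#' simulation test is needed.
#'
#' @param d Change(s) in absolute interaction score, finite.
#' @return `F(d)` in [0, 1]; `F(0) = 0.5`, `F(-d) = 1 - F(d)`.
#' @export
delta_cdf <- function(d) {
  if (any(!is.finite(d))) stop("d must be finite")
  ifelse(d >= 0, 1 - 0.5 * erfc(d / 2)^2, 0.5 * erfc(-d / 2)^2)
}

#' P-value for a change in interaction strength
#'
#' Tail probabilities under the exact null of [delta_cdf()]. `"two_sided"`
#' (default) tests any change, `"gain"` tests for stronger interaction in
#' state 1, `"loss"` for stronger interaction in state 0. Floored at
#' `2^-1074` so extreme changes never return exactly zero.
#'
#' @param d Change(s) `|I1| - |I0|`, finite.
#' @param tail `"two_sided"`, `"gain"`, or `"loss"`.
#' @return p-value(s) in (0, 1].
#' @export
delta_pvalue <- function(d, tail = c("two_sided", "gain", "loss")) {
  tail <- match.arg(tail)
  if (any(!is.finite(d))) stop("d must be finite")
  # tail mass of the short tail, computed without cancellation; it is
  # at most 1/2, so the two-sided p is exactly twice it and swapping the
  # sign of d leaves the two-sided p bit-identical
  short <- 0.5 * erfc(abs(d) / 2)^2
  p <- switch(tail,
              two_sided = 2 * short,
              gain = ifelse(d >= 0, short, 1 - short),
              loss = ifelse(d >= 0, 1 - short, short))
  pmax(p, 2^-1074)
}

#' Assemble the differential network from two per-state correlation objects
#'
#' Tests every gene pair that is scored (non-missing) in BOTH states for a
#' change in interaction strength: `delta = |I1| - |I0|` is referred to the
#' exact null CDF of [delta_cdf()], p-values are Bonferroni-adjusted over the
#' `m` pairs actually tested (`p_adj = min(1, p * m)`), and pairs passing the
#' threshold become edges. An edge's `specific_state` is the state with the
#' larger absolute interaction (1 iff `delta > 0`): the state in which the
#' pair is specifically correlated.
#'
#' @param state0,state1 [state_correlation()] objects sharing gene indexing.
#' @param alpha Adjusted-p threshold for calling an edge; default 0.05.
#' @param adjusted_p_cut Optional stringent adjusted-p cutoff overriding
#'   `alpha` (e.g. `1e-5` for transcriptome-scale runs).
#' @param tail Sidedness of the test, see [delta_pvalue()].
#' @return Object of class `"diffnet"`: list with `edges` (data frame ordered
#'   by (p, gene_i, gene_j) with columns gene_i, gene_j, I0, I1, S0, S1,
#'   delta, p, p_adj, specific_state), `nodes`, `degree`, `m` (pairs tested),
#'   `alpha`, `cut`, `tail`, and the two state names.
#' @export
call_differential <- function(state0, state1, alpha = 0.05,
                              adjusted_p_cut = NULL,
                              tail = c("two_sided", "gain", "loss")) {
  tail <- match.arg(tail)
  stopifnot(inherits(state0, "state_corr"), inherits(state1, "state_corr"))
  if (!identical(rownames(state0$C), rownames(state1$C)))
    stop("the two states do not share gene indexing")
  genes <- rownames(state0$C)
  G <- length(genes)
  ut <- upper.tri(state0$C)
  tested <- ut & !is.na(state0$I) & !is.na(state1$I)
  m <- sum(tested)
  cut <- if (is.null(adjusted_p_cut)) alpha else adjusted_p_cut
  if (m == 0L) {
    warning("zero testable gene pairs; returning an empty network")
    return(empty_diffnet(state0, state1, m, alpha, cut, tail))
  }
  idx <- which(tested, arr.ind = TRUE)
  I0 <- state0$I[tested]
  I1 <- state1$I[tested]
  delta <- delta_interaction(I0, I1)
  p <- delta_pvalue(delta, tail)
  p_adj <- pmin(1, p * m)
  sig <- p_adj < cut
  edges <- data.frame(
    gene_i = genes[idx[sig, 1]],
    gene_j = genes[idx[sig, 2]],
    I0 = I0[sig], I1 = I1[sig],
    S0 = state0$S[tested][sig], S1 = state1$S[tested][sig],
    delta = delta[sig], p = p[sig], p_adj = p_adj[sig],
    specific_state = ifelse(delta[sig] > 0, 1L, 0L),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$p, edges$gene_i, edges$gene_j), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_i, edges$gene_j)))
  degree <- degree_table(edges, nodes)
  structure(list(edges = edges, nodes = nodes, degree = degree,
                 m = m, n_genes = G, alpha = alpha, cut = cut, tail = tail,
                 state_names = c(state0$state_name, state1$state_name)),
            class = "diffnet")
}

empty_diffnet <- function(state0, state1, m, alpha, cut, tail) {
  edges <- data.frame(gene_i = character(), gene_j = character(),
                      I0 = numeric(), I1 = numeric(),
                      S0 = integer(), S1 = integer(),
                      delta = numeric(), p = numeric(), p_adj = numeric(),
                      specific_state = integer(), stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = character(),
                 degree = stats::setNames(integer(), character()),
                 m = m, n_genes = nrow(state0$C), alpha = alpha, cut = cut,
                 tail = tail,
                 state_names = c(state0$state_name, state1$state_name)),
            class = "diffnet")
}

degree_table <- function(edges, nodes) {
  d <- table(factor(c(edges$gene_i, edges$gene_j), levels = nodes))
  stats::setNames(as.integer(d), nodes)
}

#' Fit a differential co-expression network
#'
#' The main entry point: runs the full analysis on a normalized genes x cells
#' matrix and a two-state cell assignment. Steps: (optional median-of-ratios
#' normalization;) removal of non-informative genes (per-state CV below
#' `cv_threshold`); recording of the dropout mask (exact zeros of the
#' normalized counts); per-state masked correlation, support and interaction
#' matrices; exact inter-state test of every pair scored in both states;
#' Bonferroni control; network assembly.
#'
#' @param x Expression matrix (genes x cells, non-negative normalized counts),
#'   or anything accepted by [validate_expression()].
#' @param states A [state_assignment()] (or named label vector coerced by
#'   [state_assignment()]) covering the cells of `x`.
#' @param normalize If `TRUE`, apply [normalize_median_ratios()] first
#'   (input is assumed pre-normalized by default).
#' @param cv_threshold Per-state CV filter threshold (default 0.25); set to
#'   `0` to keep all expressed genes.
#' @param s_min Minimum per-state support for a pair to be scored
#'   (default 10).
#' @param alpha,adjusted_p_cut,tail Passed to [call_differential()].
#' @return Object of class `"diffnet"` (see [call_differential()]) with the
#'   per-state `"state_corr"` objects in `$states`, the filtered matrix
#'   dimensions, the overall dropout fraction, and the configuration echo in
#'   `$config`.
#' @examples
#' fx <- make_fixture(genes = 12, cells0 = 40, cells1 = 40, sparsity = 0.2,
#'                    pairs = list(list(i = 1, j = 2, rho0 = 0, rho1 = 0.95)),
#'                    seed = 7)
#' fit <- diff_network(fx$E, fx$states)
#' fit
#' hub_table(fit, top_k = 5)
#' @export
diff_network <- function(x, states, normalize = FALSE, cv_threshold = 0.25,
                         s_min = 10, alpha = 0.05, adjusted_p_cut = NULL,
                         tail = c("two_sided", "gain", "loss")) {
  tail <- match.arg(tail)
  cl <- match.call()
  validate_expression(x)
  if (!inherits(states, "state_assignment")) states <- state_assignment(states)
  states <- align_states(x, states)
  if (normalize) x <- normalize_median_ratios(x)
  if (cv_threshold > 0) x <- filter_low_cv(x, states, cv_threshold)
  mask <- dropout_mask(x)
  sc0 <- state_correlation(x, states, 0, s_min = s_min, mask = mask)
  sc1 <- state_correlation(x, states, 1, s_min = s_min, mask = mask)
  net <- call_differential(sc0, sc1, alpha = alpha,
                           adjusted_p_cut = adjusted_p_cut, tail = tail)
  net$states <- list(sc0, sc1)
  net$call <- cl
  net$dims <- dim(x)
  net$sparsity <- mean(mask)
  net$cells_per_state <- c(sum(states == 0), sum(states == 1))
  net$config <- list(normalize = normalize, cv_threshold = cv_threshold,
                     s_min = s_min, alpha = alpha,
                     adjusted_p_cut = adjusted_p_cut, tail = tail,
                     version = as.character(utils::packageVersion("diffcornet")))
  net
}

#' @export
print.diffnet <- function(x, ...) {
  cat("Differential co-expression network\n")
  cat(sprintf("  states: %s (0) vs %s (1)\n",
              x$state_names[1], x$state_names[2]))
  if (!is.null(x$dims))
    cat(sprintf("  genes x cells after filtering: %d x %d (dropout %.1f%%)\n",
                x$dims[1], x$dims[2], 100 * x$sparsity))
  cat(sprintf("  gene pairs tested: %d; edges at adjusted p < %g: %d\n",
              x$m, x$cut, nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(sprintf("  nodes: %d, mean degree: %.2f\n", length(x$nodes),
                2 * nrow(x$edges) / length(x$nodes)))
    cat(sprintf("  state-specific edges: %d in state 1, %d in state 0\n",
                sum(x$edges$specific_state == 1L),
                sum(x$edges$specific_state == 0L)))
  }
  invisible(x)
}

#' @export
summary.diffnet <- function(object, top_k = 10, ...) {
  out <- list(net = object,
              hubs = hub_table(object, top_k = top_k),
              mean_degree = if (length(object$nodes))
                2 * nrow(object$edges) / length(object$nodes) else NA_real_)
  class(out) <- "summary.diffnet"
  out
}

#' @export
print.summary.diffnet <- function(x, ...) {
  print(x$net)
  if (nrow(x$hubs)) {
    cat("\nTop hub genes (number of incident differential pairs):\n")
    print(x$hubs, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.diffnet <- function(x, vertex.size = 6, vertex.label.cex = 0.6, ...) {
  if (!nrow(x$edges)) {
    warning("empty network; nothing to plot")
    return(invisible(NULL))
  }
  g <- as_igraph(x)
  igraph::plot.igraph(
    g, vertex.size = vertex.size, vertex.label.cex = vertex.label.cex,
    edge.color = ifelse(igraph::E(g)$specific_state == 1, "#d95f02",
                        "#1b9e77"),
    ...)
  invisible(g)
}

#' Convert a differential network to an igraph graph
#' @param x A `"diffnet"` object.
#' @return An undirected igraph graph with `delta`, `p_adj` and
#'   `specific_state` edge attributes.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "diffnet"))
  igraph::graph_from_data_frame(
    x$edges[, c("gene_i", "gene_j", "delta", "p_adj", "specific_state")],
    directed = FALSE,
    vertices = data.frame(name = x$nodes, stringsAsFactors = FALSE))
}

#' Rank hub genes by differential degree
#'
#' Genes sorted by the number of incident differential pairs (descending),
#' ties broken lexicographically, truncated to `top_k`.
#'
#' @param net A `"diffnet"` object.
#' @param top_k Number of genes to return (>= 1); lists all if larger than
#'   the node count.
#' @return Data frame with columns `gene` and `degree`.
#' @export
hub_table <- function(net, top_k = 10) {
  stopifnot(inherits(net, "diffnet"), top_k >= 1)
  if (!length(net$degree))
    return(data.frame(gene = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  ord <- order(-net$degree, names(net$degree))
  out <- data.frame(gene = names(net$degree)[ord],
                    degree = as.integer(net$degree[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, top_k)
}

#' Overlap between network genes and differentially expressed genes
#'
#' Differential co-expression is not differential expression: a pair can
#' change correlation with no change in either gene's mean. This check runs a
#' Welch two-sample t-test per gene (normalized counts, zeros included)
#' between the two states and summarizes the Venn overlap between the
#' network's genes and the differentially expressed genes.
#'
#' @param net A non-empty `"diffnet"` object.
#' @param x The expression matrix the network was fitted on (post-filter
#'   matrices are fine; genes absent from `x` are an error).
#' @param states The [state_assignment()].
#' @param de_alpha Unadjusted t-test p-value cutoff; default 0.05.
#' @return List of class `"de_overlap"`: `n_network_only`, `n_de_only`,
#'   `n_overlap`, `overlap_fraction` (overlap / network genes), and the
#'   per-gene p-values. Genes with zero variance in both groups are excluded
#'   from DE testing and counted network-only.
#' @export
compare_with_de <- function(net, x, states, de_alpha = 0.05) {
  stopifnot(inherits(net, "diffnet"))
  if (!nrow(net$edges)) stop("network is empty; nothing to compare")
  validate_expression(x)
  if (!inherits(states, "state_assignment")) states <- state_assignment(states)
  states <- align_states(x, states)
  if (!all(net$nodes %in% rownames(x)))
    stop("network genes missing from the expression matrix")
  g0 <- states == 0
  g1 <- states == 1
  pvals <- apply(x, 1, function(v) {
    if (stats::var(v[g0]) == 0 && stats::var(v[g1]) == 0) return(NA_real_)
    tryCatch(stats::t.test(v[g1], v[g0])$p.value, error = function(e) NA_real_)
  })
  de <- names(pvals)[!is.na(pvals) & pvals < de_alpha]
  overlap <- intersect(net$nodes, de)
  out <- list(n_network = length(net$nodes),
              n_de = length(de),
              n_overlap = length(overlap),
              n_network_only = length(setdiff(net$nodes, de)),
              n_de_only = length(setdiff(de, net$nodes)),
              overlap_fraction = length(overlap) / length(net$nodes),
              de_alpha = de_alpha,
              p_values = pvals)
  class(out) <- "de_overlap"
  out
}

#' @export
print.de_overlap <- function(x, ...) {
  cat("Network genes vs differential expression (Welch t-test, p <",
      x$de_alpha, ")\n")
  cat(sprintf("  network genes: %d; DE genes: %d; overlap: %d (%.1f%%)\n",
              x$n_network, x$n_de, x$n_overlap, 100 * x$overlap_fraction))
  invisible(x)
}
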