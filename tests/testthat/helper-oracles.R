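# Test helpers: independent per-pair oracles and random fixture builders.
# The oracles deliberately use stats::cor / set arithmetic, never the
# package's blocked code paths.

# Random sparse non-negative expression matrix with dimnames.
rand_expression <- function(G, K, sparsity = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(exp(rnorm(G * K) / 2) * 10, G, K)
  if (sparsity > 0) m[matrix(runif(G * K) < sparsity, G, K)] <- 0
  rownames(m) <- sprintf("g%03d", seq_len(G))
  colnames(m) <- sprintf("c%03d", seq_len(K))
  m
}

two_state_labels <- function(E, n0 = ceiling(ncol(E) / 2)) {
  lab <- c(rep("A", n0), rep("B", ncol(E) - n0))
  state_assignment(lab, cells = colnames(E))
}

# Brute-force per-pair reference for the masked correlation matrices:
# materialize every support set and call stats::cor.
ref_state_correlation <- function(E, states, state, s_min = 10) {
  cells <- names(states)[states == state]
  Es <- E[, cells, drop = FALSE]
  G <- nrow(Es)
  C <- matrix(NA_real_, G, G, dimnames = list(rownames(E), rownames(E)))
  S <- matrix(NA_integer_, G, G, dimnames = dimnames(C))
  I <- C
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      supp <- which(Es[i, ] != 0 & Es[j, ] != 0)
      S[i, j] <- S[j, i] <- length(supp)
      if (length(supp) >= s_min) {
        xi <- Es[i, supp]
        xj <- Es[j, supp]
        if (stats::sd(xi) > 0 && stats::sd(xj) > 0) {
          r <- stats::cor(xi, xj)
          C[i, j] <- C[j, i] <- r
          I[i, j] <- I[j, i] <- fisher_interaction(r, length(supp))
        }
      }
    }
  }
  list(C = C, S = S, I = I)
}

# Straight-line per-pair scoring of a generated simulation dataset
# (matrices with NA at eliminated entries): masked correlation on the joint
# support via stats::cor, Fisher score, two-sided normal p.
ref_sim_calls <- function(data, min_support = 4, rule_alpha = 0.05,
                          bonferroni = TRUE, score_threshold = NULL) {
  n <- ncol(data$x)
  p <- rep(NA_real_, n)
  score <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    ok <- !is.na(data$x[, k]) & !is.na(data$y[, k])
    if (sum(ok) < min_support) next
    xi <- data$x[ok, k]
    yi <- data$y[ok, k]
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) next
    r <- stats::cor(xi, yi)
    score[k] <- fisher_interaction(r, sum(ok))
    p[k] <- 2 * stats::pnorm(-abs(score[k]))
  }
  testable <- !is.na(p)
  sig <- rep(FALSE, n)
  if (!is.null(score_threshold)) {
    sig[testable] <- abs(score[testable]) > score_threshold
  } else if (bonferroni) {
    sig[testable] <- p[testable] < rule_alpha / sum(testable)
  } else {
    sig[testable] <- p[testable] < rule_alpha
  }
  list(score = score, p = p, sig = sig, testable = testable)
}

# Build a positive vector with a prescribed coefficient of variation
# (sample-sd convention): standardized 1..n has values in about [-1.7, 1.7],
# so mean 1/cv keeps everything positive for cv <= 0.5.
vector_with_cv <- function(cv, n = 20) {
  v <- seq_len(n)
  v <- (v - mean(v)) / stats::sd(v)    # mean 0, sd 1
  v + 1 / cv                           # mean 1/cv, sd 1 -> cv as requested
}
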