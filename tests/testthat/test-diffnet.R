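test_that("delta is the change in absolute interaction strength", {
  expect_identical(delta_interaction(-2, 2), 0)
  expect_identical(delta_interaction(1, 3), 2)
  expect_identical(delta_interaction(3, 1), -2)
  expect_error(delta_interaction(Inf, 1), "finite")
})

test_that("the exact null CDF has the stated closed form and symmetry", {
  expect_identical(delta_cdf(0), 0.5)
  # stable evaluation agrees with the published expression
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  grid <- seq(-4, 4, by = 0.25)
  direct <- 0.5 + erf(grid / 2) - 0.5 * sign(grid) * erf(grid / 2)^2
  expect_equal(delta_cdf(grid), direct, tolerance = 1e-15)
  # distributional symmetry to machine precision
  expect_equal(delta_cdf(-grid) + delta_cdf(grid), rep(1, length(grid)),
               tolerance = 1e-15)
  # Monte Carlo check of P(|X| - |Y| <= d)
  set.seed(99)
  draws <- abs(rnorm(1e6)) - abs(rnorm(1e6))
  for (d in c(-2, -1, 0.5, 1, 2))
    expect_lt(abs(delta_cdf(d) - mean(draws <= d)), 2e-3)
})

test_that("delta p-values cover both tails consistently", {
  expect_identical(delta_pvalue(0), 1)
  d <- c(-2.5, -0.3, 0, 0.7, 3)
  expect_equal(delta_pvalue(d, "gain") + delta_pvalue(d, "loss"),
               rep(1, 5), tolerance = 1e-12)
  expect_equal(delta_pvalue(d),
               2 * pmin(delta_pvalue(d, "gain"), delta_pvalue(d, "loss")),
               tolerance = 1e-12)
  # quantile: F(d) = 0.975 -> two-sided p = 0.05
  d975 <- uniroot(function(x) delta_cdf(x) - 0.975, c(0, 10),
                  tol = 1e-12)$root
  expect_equal(delta_pvalue(d975), 0.05, tolerance = 1e-9)
  expect_gt(delta_pvalue(80), 0)
})

test_that("identical states yield no differential pairs", {
  E <- rand_expression(8, 60, sparsity = 0.3, seed = 31)
  states <- two_state_labels(E)
  sc0 <- state_correlation(E, states, 0, s_min = 5)
  net <- call_differential(sc0, sc0, alpha = 0.999)
  expect_identical(nrow(net$edges), 0L)
  expect_gt(net$m, 0L)
})

test_that("a single planted state-specific pair is the only edge", {
  fx <- make_fixture(genes = 5, cells0 = 50, cells1 = 50, sparsity = 0,
                     pairs = list(list(i = 1, j = 2, rho0 = 0, rho1 = 0.95)),
                     seed = 77)
  fit <- diff_network(fx$E, fx$states, cv_threshold = 0)
  expect_identical(nrow(fit$edges), 1L)
  expect_identical(fit$edges$gene_i, "g001")
  expect_identical(fit$edges$gene_j, "g002")
  expect_identical(fit$edges$specific_state, 1L)
  expect_gt(fit$edges$delta, 0)
  expect_identical(fit$m, 10L)  # all C(5,2) pairs scored in both states
})

test_that("edge invariants hold on a dense differential fixture", {
  set.seed(5)
  fx <- make_fixture(genes = 16, cells0 = 60, cells1 = 60, sparsity = 0.15,
                     pairs = list(list(i = 1, j = 2, rho0 = 0, rho1 = 0.9),
                                  list(i = 3, j = 4, rho0 = 0.9, rho1 = 0),
                                  list(i = 5, j = 6, rho0 = 0, rho1 = 0.85)),
                     seed = 13)
  fit <- diff_network(fx$E, fx$states, cv_threshold = 0)
  e <- fit$edges
  expect_gt(nrow(e), 0)
  expect_equal(e$delta, abs(e$I1) - abs(e$I0), tolerance = 1e-12)
  expect_identical(e$specific_state, ifelse(e$delta > 0, 1L, 0L))
  expect_true(all(e$p > 0 & e$p <= 1))
  expect_equal(e$p_adj, pmin(1, e$p * fit$m), tolerance = 1e-12)
  expect_true(all(e$p_adj < fit$cut))
  expect_true(!is.unsorted(e$p))
  # degree bookkeeping
  expect_identical(sum(fit$degree), 2L * nrow(e))
  expect_true(all(c(e$gene_i, e$gene_j) %in% fit$nodes))
  expect_false(any(e$gene_i == e$gene_j))
  expect_identical(anyDuplicated(paste(e$gene_i, e$gene_j)), 0L)
})

test_that("swapping state labels negates deltas and preserves the edge set", {
  fx <- make_fixture(genes = 10, cells0 = 45, cells1 = 55, sparsity = 0.25,
                     pairs = list(list(i = 1, j = 2, rho0 = 0, rho1 = 0.95)),
                     seed = 101)
  swapped <- state_assignment(1L - unclass(fx$states),
                              cells = names(fx$states))
  fit <- diff_network(fx$E, fx$states, cv_threshold = 0)
  fit_sw <- diff_network(fx$E, swapped, cv_threshold = 0)
  expect_identical(fit$m, fit_sw$m)
  key <- function(f) paste(f$edges$gene_i, f$edges$gene_j)
  expect_identical(sort(key(fit)), sort(key(fit_sw)))
  o <- match(key(fit), key(fit_sw))
  expect_identical(fit$edges$delta, -fit_sw$edges$delta[o])
  expect_identical(fit$edges$p, fit_sw$edges$p[o])
  expect_identical(fit$edges$specific_state,
                   1L - fit_sw$edges$specific_state[o])
})

test_that("hub ranking sorts by degree with lexicographic ties", {
  edges <- data.frame(gene_i = c("a", "a", "a"),
                      gene_j = c("b", "c", "d"),
                      I0 = 0, I1 = 5, S0 = 20L, S1 = 20L, delta = 5,
                      p = c(1e-8, 2e-8, 3e-8), p_adj = c(3e-8, 6e-8, 9e-8),
                      specific_state = 1L, stringsAsFactors = FALSE)
  net <- structure(list(edges = edges, nodes = c("a", "b", "c", "d"),
                        degree = c(a = 3L, b = 1L, c = 1L, d = 1L),
                        m = 6L, alpha = 0.05, cut = 0.05,
                        tail = "two_sided",
                        state_names = c("s0", "s1")), class = "diffnet")
  expect_identical(unname(net$degree["a"]), 3L)
  top2 <- hub_table(net, top_k = 2)
  expect_identical(top2$gene, c("a", "b"))
  expect_identical(top2$degree, c(3L, 1L))
  # top_k beyond the node count returns the full list
  expect_identical(nrow(hub_table(net, top_k = 99)), 4L)
  # mean degree of the merged network: 2|E|/|V|
  expect_equal(2 * nrow(edges) / length(net$nodes), 1.5)
})

test_that("network genes are mostly not differentially expressed", {
  set.seed(207)
  G <- 10; K <- 40
  E <- rand_expression(G, 2 * K, sparsity = 0, seed = 207)
  states <- two_state_labels(E, n0 = K)
  # plant a strong mean shift in exactly 2 of the 10 "network" genes
  E[1, states == 1] <- E[1, states == 1] + 20
  E[2, states == 1] <- E[2, states == 1] + 20
  net <- structure(list(edges = data.frame(gene_i = rownames(E)[1:5],
                                           gene_j = rownames(E)[6:10],
                                           stringsAsFactors = FALSE),
                        nodes = rownames(E), m = 45L),
                   class = "diffnet")
  net$edges$p <- 1e-9
  ov <- compare_with_de(net, E, states, de_alpha = 1e-4)
  expect_identical(ov$n_overlap, 2L)
  expect_equal(ov$overlap_fraction, 0.2)
  # identical group means -> empty overlap
  E2 <- E
  E2[, states == 1] <- E2[, states == 0]
  ov2 <- compare_with_de(net, E2, states, de_alpha = 0.05)
  expect_identical(ov2$n_overlap, 0L)
  expect_equal(ov2$overlap_fraction, 0)
})
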