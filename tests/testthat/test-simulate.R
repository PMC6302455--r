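test_that("generated pairs have the requested joint distribution", {
  set.seed(1)
  p1 <- generate_pair(theta = 1, K = 30)
  expect_identical(p1$x, p1$y)            # degenerate bivariate normal
  set.seed(2)
  p0 <- generate_pair(theta = 0.9, K = 25, correlated = FALSE)
  expect_identical(p0$truth, "independent")
  set.seed(3)
  big <- generate_pair(theta = 0.7, K = 1e5)
  expect_equal(cor(big$x, big$y), 0.7, tolerance = 0.01)
  set.seed(4)
  nullcors <- replicate(200, {
    p <- generate_pair(theta = 0, K = 200)
    cor(p$x, p$y)
  })
  expect_lt(abs(mean(nullcors)), 3 / sqrt(200 * 200))
  expect_error(generate_pair(theta = 1.2, K = 10), "<= 1")
})

test_that("noise has relative power epsilon and attenuates correlation", {
  set.seed(5)
  p <- generate_pair(theta = 0.7, K = 1e5)
  expect_identical(add_noise(p, 0), p)
  noised <- add_noise(p, 1)
  expect_equal(var(noised$x), 2, tolerance = 0.05)      # 1 + epsilon
  expect_lt(abs(cor(noised$x, noised$y) - 0.35), 0.015)  # rho/(1+eps)
  set.seed(6)
  p2 <- add_noise(generate_pair(theta = 0.7, K = 1e5), 0.25)
  expect_lt(abs(cor(p2$x, p2$y) - 0.7 / 1.25), 0.015)
})

test_that("elimination removes a pinned-rounding fraction of observations", {
  set.seed(7)
  p <- generate_pair(theta = 0.5, K = 50)
  expect_identical(apply_elimination(p, 0)$support, 50L)
  pe <- apply_elimination(p, 0.25)             # remove round(12.5) = 13
  expect_identical(pe$support, 37L)
  expect_identical(which(is.na(pe$x)), which(is.na(pe$y)))  # paired removal
  expect_false(pe$untestable)

  p10 <- apply_elimination(generate_pair(0.5, 10), 0.75)    # support 2 < 4
  expect_identical(p10$support, 2L)
  expect_true(p10$untestable)

  set.seed(8)
  pi <- apply_elimination(generate_pair(0.5, 40), 0.5, mode = "independent")
  expect_identical(sum(is.na(pi$x)), 20L)
  expect_identical(sum(is.na(pi$y)), 20L)
  expect_identical(pi$support, sum(!is.na(pi$x) & !is.na(pi$y)))
  expect_lte(pi$support, 20L)
})

test_that("scenario runs are deterministic in the seed", {
  cfg <- sim_config(n_pairs = 500, theta = 0.7, epsilon = 0.05, K = 50,
                    tau = 0.25, seed = 42)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  a$elapsed_seconds <- b$elapsed_seconds <- 0
  expect_identical(a[names(a) != "elapsed_seconds"],
                   b[names(b) != "elapsed_seconds"])
})

test_that("perfect signal is fully recovered under the strict rule", {
  rep <- run_scenario(sim_config(n_pairs = 2000, theta = 1, epsilon = 0,
                                 K = 50, tau = 0, seed = 9))
  expect_identical(rep$sensitivity, 1)
  expect_gte(rep$specificity, 0.99)
  # null truth: correlated pairs drawn at theta = 0 are almost never called
  rep0 <- run_scenario(sim_config(n_pairs = 2000, theta = 0, epsilon = 0,
                                  K = 50, tau = 0, seed = 10))
  expect_lte(rep0$sensitivity, 0.01)
})

test_that("vectorized scoring equals the straight-line per-pair reference", {
  for (cs in list(list(theta = 0.7, epsilon = 0.05, K = 50, tau = 0.25,
                       elim = "paired", seed = 21),
                  list(theta = 0.3, epsilon = 0.5, K = 20, tau = 0.5,
                       elim = "independent", seed = 22))) {
    cfg <- sim_config(n_pairs = 1500, theta = cs$theta, epsilon = cs$epsilon,
                      K = cs$K, tau = cs$tau, seed = cs$seed,
                      elimination = cs$elim)
    set.seed(cfg$seed)
    data <- diffcornet:::sim_generate(cfg)
    got <- diffcornet:::sim_score(data, cfg)
    ref <- ref_sim_calls(data, min_support = 4, rule_alpha = cfg$alpha,
                         bonferroni = TRUE)
    expect_equal(got$score, ref$score, tolerance = 1e-10)
    expect_identical(got$sig, ref$sig)
    tr <- data$truth
    expect_identical(got$tp, sum(ref$sig & tr))
    expect_identical(got$tn, sum(!ref$sig & !tr))
  }
})

test_that("untestable scenarios are dashes, not numbers", {
  # K = 10, tau = 0.75: support 2 < 4 for every pair
  expect_error(run_scenario(sim_config(n_pairs = 50, theta = 0.7, K = 10,
                                       tau = 0.75, seed = 1)),
               "untestable")
  sw <- sweep_scenarios(theta = 0.7, epsilon = 0.05, K = c(10, 50),
                        tau = c(0.25, 0.75), n_pairs = 200, seed = 5)
  tab <- format_metric_table(sw, "sensitivity")
  expect_identical(tab["10", "0.75"], "-")
  expect_false(tab["50", "0.75"] == "-")
  expect_identical(dim(tab), c(2L, 2L))
})

test_that("per-test specificity is calibrated to its nominal level", {
  # unadjusted p < alpha on null pairs -> specificity ~ 1 - alpha
  cfg <- sim_config(n_pairs = 4000, frac_correlated = 0, theta = 0,
                    epsilon = 0, K = 50, tau = 0, seed = 33,
                    rule = "per_test", per_test_alpha = 0.05)
  rep <- run_scenario(cfg)
  expect_equal(rep$specificity, 0.95, tolerance = 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("calibrated thresholds hit their target specificity", {
  cfg <- sim_config(theta = 0.7, epsilon = 0.1, K = 50, tau = 0.25, seed = 3)
  cal <- calibrate_threshold(cfg, target_specificity = 0.85, n_null = 10000)
  expect_equal(cal$per_test_alpha, 2 * pnorm(-cal$score_threshold),
               tolerance = 1e-12)
  run <- run_scenario(sim_config(n_pairs = 5000, theta = 0.7, epsilon = 0.1,
                                 K = 50, tau = 0.25, seed = 91,
                                 rule = "per_test",
                                 score_threshold = cal$score_threshold))
  expect_equal(run$specificity, 0.85, tolerance = 0.02)
  sw <- threshold_sweep(cfg, per_test_alphas = c(0.01, 0.15))
  expect_identical(nrow(sw), 2L)
  expect_true(all(diff(sw$sensitivity) >= 0))   # looser threshold, more calls
  expect_true(all(diff(sw$specificity) <= 0))
})

test_that("replicated scenarios report mean and spread", {
  rep <- run_scenario(sim_config(n_pairs = 300, theta = 0.7, epsilon = 0.05,
                                 K = 50, tau = 0.25, seed = 2, n_reps = 3))
  expect_identical(nrow(rep$reps), 3L)
  expect_identical(rep$accuracy, mean(rep$reps$accuracy))
  expect_false(is.na(rep$sensitivity_sd))
})
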