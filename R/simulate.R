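# Round half away from zero; base round() rounds half to even. The rounding
# of tau * K decides edge-case support sizes, so the convention is pinned
# here and echoed in every report.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Simulation configuration
#'
#' One scenario of the simulation study: `n_pairs` gene pairs are drawn, a
#' fraction `frac_correlated` from a bivariate standard normal with
#' covariance `theta` and the rest independent; Gaussian noise of relative
#' power `epsilon` is added to each gene; a fraction `tau` of observations is
#' eliminated (the stand-in for scRNA-seq dropout zeros); each surviving
#' pair's correlation is Fisher-transformed and tested against zero.
#'
#' @param n_pairs Number of gene pairs; default 10000.
#' @param frac_correlated Fraction of truly correlated pairs; default 0.20.
#' @param theta Covariance of correlated pairs (unit variances), |theta| <= 1.
#' @param epsilon Relative noise power (noise variance / signal variance),
#'   >= 0; attenuates observable correlation by 1 / (1 + epsilon).
#' @param K Cells per pair, >= 4.
#' @param tau Fraction of observations eliminated, in [0, 1).
#' @param alpha Family-wise level for the Bonferroni rule; default 0.05.
#' @param seed Integer seed; every random draw in the scenario flows from it.
#' @param n_reps Replicates; default 1. With more, metrics are averaged.
#' @param elimination `"paired"` (default): the same uniformly chosen
#'   `round_half_away(tau * K)` observation indices are removed from both
#'   genes, leaving every pair a support of `K - round_half_away(tau * K)`.
#'   `"independent"`: each gene drops its own indices and the support is the
#'   intersection.
#' @param rule Decision rule: `"bonferroni"` (two-sided normal p, adjusted
#'   over testable pairs, called at `alpha` — the stated rule) or
#'   `"per_test"` (unadjusted comparison against `per_test_alpha` or
#'   `score_threshold`, used for calibrated operating points, see
#'   [calibrate_threshold()]).
#' @param per_test_alpha Per-test two-sided level for `rule = "per_test"`.
#' @param score_threshold Alternative to `per_test_alpha`: call pairs with
#'   `|score| > score_threshold`.
#' @param min_support Minimum support for a pair to be testable; default 4
#'   (the Fisher transform needs S - 3 >= 1). Untestable pairs are counted
#'   as negative calls and reported separately.
#' @param noise_order `"noise_first"` (default: sequencing noise precedes
#'   dropout) or `"eliminate_first"`.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_pairs = 10000, frac_correlated = 0.2, theta = 0.7,
                       epsilon = 0, K = 50, tau = 0, alpha = 0.05, seed = 1,
                       n_reps = 1,
                       elimination = c("paired", "independent"),
                       rule = c("bonferroni", "per_test"),
                       per_test_alpha = NULL, score_threshold = NULL,
                       min_support = 4,
                       noise_order = c("noise_first", "eliminate_first")) {
  elimination <- match.arg(elimination)
  rule <- match.arg(rule)
  noise_order <- match.arg(noise_order)
  if (n_pairs < 1) stop("n_pairs must be positive")
  if (frac_correlated < 0 || frac_correlated > 1)
    stop("frac_correlated must be in [0, 1]")
  if (abs(theta) > 1) stop("|theta| must be <= 1 for unit variances")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (K < 4) stop("K must be >= 4")
  if (tau < 0 || tau >= 1) stop("tau must be in [0, 1)")
  if (min_support < 4) stop("min_support must be >= 4")
  if (rule == "per_test" && is.null(per_test_alpha) &&
      is.null(score_threshold))
    stop("rule = \"per_test\" needs per_test_alpha or score_threshold")
  structure(list(n_pairs = as.integer(n_pairs),
                 frac_correlated = frac_correlated, theta = theta,
                 epsilon = epsilon, K = as.integer(K), tau = tau,
                 alpha = alpha, seed = as.integer(seed),
                 n_reps = as.integer(n_reps), elimination = elimination,
                 rule = rule, per_test_alpha = per_test_alpha,
                 score_threshold = score_threshold,
                 min_support = as.integer(min_support),
                 noise_order = noise_order,
                 rounding = "round-half-away-from-zero"),
            class = "sim_config")
}

#' Draw one synthetic gene pair
#'
#' K observations of two genes from a bivariate normal with unit variances
#' and covariance `theta` (if `correlated`) or 0. `theta = 1` yields
#' `y == x` exactly.
#'
#' @param theta Covariance, |theta| <= 1.
#' @param K Number of cells.
#' @param correlated Logical; independent pair if `FALSE`.
#' @return List of class `"gene_pair"`: `x`, `y` (length-K), `truth`.
#' @export
generate_pair <- function(theta, K, correlated = TRUE) {
  if (abs(theta) > 1) stop("|theta| must be <= 1 for unit variances")
  x <- stats::rnorm(K)
  z <- stats::rnorm(K)
  y <- if (correlated) theta * x + sqrt(1 - theta^2) * z else z
  structure(list(x = x, y = y,
                 truth = if (correlated) "correlated" else "independent"),
            class = "gene_pair")
}

#' Add relative-power Gaussian noise to a gene pair
#'
#' Each vector `v` becomes `v + sqrt(epsilon) * z`, `z` iid standard normal
#' and independent between the genes: the noise variance is `epsilon` times
#' the unit signal variance ("relative power"), mimicking sequencing error.
#' At large K the observable correlation attenuates to
#' `rho / (1 + epsilon)`.
#'
#' @param pair A `"gene_pair"`.
#' @param epsilon Relative noise power, >= 0; 0 is the identity.
#' @return The noised `"gene_pair"`.
#' @export
add_noise <- function(pair, epsilon) {
  stopifnot(inherits(pair, "gene_pair"))
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (epsilon == 0) return(pair)
  K <- length(pair$x)
  pair$x <- pair$x + sqrt(epsilon) * stats::rnorm(K)
  pair$y <- pair$y + sqrt(epsilon) * stats::rnorm(K)
  pair
}

#' Eliminate a fraction of a gene pair's observations
#'
#' Emulates scRNA-seq zeros: `round_half_away(tau * K)` observation indices
#' are removed (set to `NA`). In the default `"paired"` mode the same indices
#' are removed from both genes, leaving a support of exactly
#' `K - round_half_away(tau * K)`; in `"independent"` mode each gene drops
#' its own indices and the pair's support is the intersection of survivors.
#' A pair whose support falls below 4 is flagged untestable.
#'
#' @param pair A `"gene_pair"`.
#' @param tau Eliminated fraction, in [0, 1); 0 is the identity.
#' @param mode `"paired"` (default) or `"independent"`.
#' @return The `"gene_pair"` with eliminated entries `NA`, plus fields
#'   `support` (surviving count) and `untestable`.
#' @export
apply_elimination <- function(pair, tau, mode = c("paired", "independent")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "gene_pair"))
  if (tau < 0 || tau >= 1) stop("tau must be in [0, 1)")
  K <- length(pair$x)
  n_rm <- round_half_away(tau * K)
  if (n_rm > 0) {
    if (mode == "paired") {
      drop <- sample.int(K, n_rm)
      pair$x[drop] <- NA_real_
      pair$y[drop] <- NA_real_
    } else {
      pair$x[sample.int(K, n_rm)] <- NA_real_
      pair$y[sample.int(K, n_rm)] <- NA_real_
    }
  }
  pair$support <- sum(!is.na(pair$x) & !is.na(pair$y))
  pair$untestable <- pair$support < 4
  pair
}

# Vectorized scenario data: K x n_pairs matrices with NA at eliminated
# entries, first round(n_pairs * frac_correlated) columns truly correlated.
sim_generate <- function(config) {
  n <- config$n_pairs
  K <- config$K
  ncor <- round_half_away(n * config$frac_correlated)
  x <- matrix(stats::rnorm(K * n), K, n)
  z <- matrix(stats::rnorm(K * n), K, n)
  y <- z
  if (ncor > 0) {
    th <- config$theta
    y[, seq_len(ncor)] <- th * x[, seq_len(ncor)] +
      sqrt(1 - th^2) * z[, seq_len(ncor)]
  }
  noise <- function() {
    if (config$epsilon > 0) {
      x <<- x + sqrt(config$epsilon) * matrix(stats::rnorm(K * n), K, n)
      y <<- y + sqrt(config$epsilon) * matrix(stats::rnorm(K * n), K, n)
    }
  }
  eliminate <- function() {
    n_rm <- round_half_away(config$tau * K)
    if (n_rm > 0) {
      drop_mask <- function()
        apply(matrix(stats::runif(K * n), K, n), 2,
              function(u) rank(u, ties.method = "first") <= n_rm)
      if (config$elimination == "paired") {
        d <- drop_mask()
        x[d] <<- NA_real_
        y[d] <<- NA_real_
      } else {
        x[drop_mask()] <<- NA_real_
        y[drop_mask()] <<- NA_real_
      }
    }
  }
  if (config$noise_order == "noise_first") { noise(); eliminate() }
  else { eliminate(); noise() }
  list(x = x, y = y, truth = seq_len(n) <= ncor, n_correlated = ncor)
}

# Score one generated dataset: per-pair masked correlation over the joint
# support, Fisher interaction, two-sided normal p, decision per config rule.
sim_score <- function(data, config) {
  W <- !is.na(data$x) & !is.na(data$y)
  n_s <- colSums(W)
  x0 <- ifelse(W, data$x, 0)
  y0 <- ifelse(W, data$y, 0)
  sx <- colSums(x0); sy <- colSums(y0)
  sxx <- colSums(x0^2); syy <- colSums(y0^2); sxy <- colSums(x0 * y0)
  num <- n_s * sxy - sx * sy
  v1 <- n_s * sxx - sx^2
  v2 <- n_s * syy - sy^2
  zerovar <- !(v1 > n_s * sxx * 1e-12) | !(v2 > n_s * syy * 1e-12)
  r <- rep(NA_real_, length(n_s))
  ok <- !zerovar & n_s >= config$min_support
  r[ok] <- num[ok] / sqrt(v1[ok] * v2[ok])
  r[!is.na(r) & r > 1] <- 1
  r[!is.na(r) & r < -1] <- -1
  untestable <- !ok
  score <- rep(NA_real_, length(r))
  score[ok] <- fisher_interaction(r[ok], n_s[ok])
  p <- rep(NA_real_, length(r))
  p[ok] <- intra_state_pvalue(score[ok])
  m <- sum(ok)
  if (m == 0) stop("all pairs untestable under this scenario")
  sig <- rep(FALSE, length(r))
  if (config$rule == "bonferroni") {
    sig[ok] <- p[ok] < config$alpha / m
  } else if (!is.null(config$score_threshold)) {
    sig[ok] <- abs(score[ok]) > config$score_threshold
  } else {
    sig[ok] <- p[ok] < config$per_test_alpha
  }
  truth <- data$truth
  tp <- sum(sig & truth); fp <- sum(sig & !truth)
  fn <- sum(!sig & truth); tn <- sum(!sig & !truth)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       n_untestable = sum(untestable),
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       support = n_s, score = score, p = p, sig = sig)
}

#' Run one simulation scenario
#'
#' Generates `n_pairs` pairs under the scenario, applies noise and
#' elimination, computes each pair's masked correlation on its support, the
#' Fisher interaction score and its two-sided p-value against zero, applies
#' the configured decision rule, and scores the calls against the truth.
#' Fully reproducible from `config$seed`. Untestable pairs (support below
#' `min_support`) are counted as negative calls and reported separately.
#'
#' @param config A [sim_config()].
#' @return Object of class `"sim_report"`: configuration echo; for each
#'   replicate the counts tp/fp/tn/fn, `n_untestable`, accuracy, sensitivity,
#'   specificity; their means (and sds when `n_reps > 1`); and
#'   `elapsed_seconds`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)
  reps <- vector("list", config$n_reps)
  for (r in seq_len(config$n_reps)) {
    data <- sim_generate(config)
    s <- sim_score(data, config)
    reps[[r]] <- data.frame(rep = r, tp = s$tp, fp = s$fp, tn = s$tn,
                            fn = s$fn, n_untestable = s$n_untestable,
                            accuracy = s$accuracy,
                            sensitivity = s$sensitivity,
                            specificity = s$specificity)
  }
  reps <- do.call(rbind, reps)
  metric <- function(col) mean(reps[[col]])
  structure(list(config = config, reps = reps,
                 tp = sum(reps$tp), fp = sum(reps$fp),
                 tn = sum(reps$tn), fn = sum(reps$fn),
                 n_untestable = sum(reps$n_untestable),
                 accuracy = metric("accuracy"),
                 sensitivity = metric("sensitivity"),
                 specificity = metric("specificity"),
                 accuracy_sd = stats::sd(reps$accuracy),
                 sensitivity_sd = stats::sd(reps$sensitivity),
                 specificity_sd = stats::sd(reps$specificity),
                 elapsed_seconds = proc.time()[["elapsed"]] - t0),
            class = "sim_report")
}

#' @export
print.sim_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulation scenario: theta=%g, epsilon=%g, K=%d, tau=%g (%s elimination)\n",
    cfg$theta, cfg$epsilon, cfg$K, cfg$tau, cfg$elimination))
  cat(sprintf("  %d pairs (%.0f%% correlated), rule: %s, seed %d, %d rep(s)\n",
              cfg$n_pairs, 100 * cfg$frac_correlated,
              if (cfg$rule == "bonferroni")
                sprintf("Bonferroni alpha=%g", cfg$alpha)
              else "per-test (calibrated)",
              cfg$seed, cfg$n_reps))
  fmt <- function(m, s) if (cfg$n_reps > 1)
    sprintf("%.3f +/- %.3f", m, s) else sprintf("%.3f", m)
  cat(sprintf("  accuracy: %s  sensitivity: %s  specificity: %s\n",
              fmt(x$accuracy, x$accuracy_sd),
              fmt(x$sensitivity, x$sensitivity_sd),
              fmt(x$specificity, x$specificity_sd)))
  if (x$n_untestable > 0)
    cat(sprintf("  untestable pairs (support < %d): %d\n",
                cfg$min_support, x$n_untestable))
  cat(sprintf("  elapsed: %.2f s; rounding: %s\n",
              x$elapsed_seconds, cfg$rounding))
  invisible(x)
}

#' Sweep simulation scenarios over a parameter grid
#'
#' Runs [run_scenario()] on every combination of the supplied parameter
#' vectors. Scenario i uses seed `seed + i - 1` so each cell is independently
#' reproducible. Cells where every pair is untestable (support below 4, the
#' dashes of a K-by-tau table) report `NA` metrics rather than failing.
#'
#' @param theta,epsilon,K,tau Parameter vectors to cross.
#' @param ... Further arguments to [sim_config()] (e.g. `n_pairs`, `rule`).
#' @param seed Base seed.
#' @return Data frame with one row per scenario: the four parameters, the
#'   metrics, counts, `n_untestable` and `elapsed_seconds`.
#' @export
sweep_scenarios <- function(theta = 0.7, epsilon = 0.05, K = 50, tau = 0.25,
                            ..., seed = 1) {
  grid <- expand.grid(theta = theta, epsilon = epsilon, K = K, tau = tau,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(theta = grid$theta[i], epsilon = grid$epsilon[i],
                      K = grid$K[i], tau = grid$tau[i],
                      seed = seed + i - 1, ...)
    rep <- tryCatch(run_scenario(cfg), error = function(e) NULL)
    rows[[i]] <- data.frame(
      theta = grid$theta[i], epsilon = grid$epsilon[i], K = grid$K[i],
      tau = grid$tau[i],
      accuracy = if (is.null(rep)) NA_real_ else rep$accuracy,
      sensitivity = if (is.null(rep)) NA_real_ else rep$sensitivity,
      specificity = if (is.null(rep)) NA_real_ else rep$specificity,
      tp = if (is.null(rep)) NA_integer_ else rep$tp,
      fp = if (is.null(rep)) NA_integer_ else rep$fp,
      tn = if (is.null(rep)) NA_integer_ else rep$tn,
      fn = if (is.null(rep)) NA_integer_ else rep$fn,
      n_untestable = if (is.null(rep)) sim_config(..., theta = grid$theta[i],
        epsilon = grid$epsilon[i], K = grid$K[i], tau = grid$tau[i],
        seed = seed)$n_pairs else rep$n_untestable,
      elapsed_seconds = if (is.null(rep)) NA_real_ else rep$elapsed_seconds)
  }
  do.call(rbind, rows)
}

#' Lay a sweep out as a cells-by-elimination table
#'
#' Reshapes a [sweep_scenarios()] result for one metric into a K-by-tau
#' table, printing an en dash where the scenario was fully untestable.
#'
#' @param sweep Data frame from [sweep_scenarios()].
#' @param metric `"accuracy"`, `"sensitivity"` or `"specificity"`.
#' @param digits Decimal places; default 2.
#' @return Character matrix with K values as rows and tau values as columns.
#' @export
format_metric_table <- function(sweep,
                                metric = c("accuracy", "sensitivity",
                                           "specificity"),
                                digits = 2) {
  metric <- match.arg(metric)
  Ks <- sort(unique(sweep$K))
  taus <- sort(unique(sweep$tau))
  out <- matrix("-", length(Ks), length(taus),
                dimnames = list(K = Ks, tau = taus))
  for (i in seq_len(nrow(sweep))) {
    v <- sweep[[metric]][i]
    out[as.character(sweep$K[i]), as.character(sweep$tau[i])] <-
      if (is.na(v)) "-" else formatC(v, digits = digits, format = "f")
  }
  out
}

#' Calibrate a per-test score threshold to a target specificity
#'
#' The stated Bonferroni rule fixes the family-wise error, not the per-pair
#' operating point. This utility locates the per-test |score| threshold that
#' attains a target specificity empirically: it simulates null
#' (uncorrelated) pairs under the scenario's noise/cells/elimination
#' settings and returns the target quantile of the null |score|
#' distribution, together with the implied per-test two-sided alpha.
#'
#' @param config A [sim_config()]; its `theta`/`frac_correlated` are ignored
#'   (null pairs only are generated).
#' @param target_specificity Desired fraction of null pairs NOT called;
#'   default 0.85.
#' @param n_null Number of null pairs to simulate; default 20000.
#' @return List of class `"sim_calibration"`: `score_threshold`,
#'   `per_test_alpha`, `target_specificity`, `n_null`.
#' @seealso [threshold_sweep()] for the full operating-characteristic sweep.
#' @export
calibrate_threshold <- function(config, target_specificity = 0.85,
                                n_null = 20000) {
  stopifnot(inherits(config, "sim_config"))
  nullcfg <- config
  nullcfg$n_pairs <- as.integer(n_null)
  nullcfg$frac_correlated <- 0
  nullcfg$rule <- "bonferroni"
  set.seed(config$seed)
  data <- sim_generate(nullcfg)
  s <- sim_score(data, nullcfg)
  sc <- abs(s$score[!is.na(s$score)])
  thr <- unname(stats::quantile(sc, probs = target_specificity, type = 7))
  structure(list(score_threshold = thr,
                 per_test_alpha = 2 * stats::pnorm(-thr),
                 target_specificity = target_specificity,
                 n_null = length(sc)),
            class = "sim_calibration")
}

#' @export
print.sim_calibration <- function(x, ...) {
  cat(sprintf(
    "Calibrated operating point: |score| > %.3f (per-test alpha %.4f)\n",
    x$score_threshold, x$per_test_alpha))
  cat(sprintf("  target specificity %.2f estimated from %d null pairs\n",
              x$target_specificity, x$n_null))
  invisible(x)
}

#' Operating characteristics across per-test thresholds
#'
#' Generates one dataset under `config` and evaluates sensitivity,
#' specificity and accuracy at each per-test alpha in `per_test_alphas`,
#' tracing the operating curve of the intra-state test so a desired
#' operating point can be located.
#'
#' @param config A [sim_config()].
#' @param per_test_alphas Vector of per-test two-sided levels.
#' @return Data frame with columns `per_test_alpha`, `score_threshold`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
threshold_sweep <- function(config,
                            per_test_alphas = c(1e-6, 1e-5, 1e-4, 1e-3,
                                                0.01, 0.05, 0.1, 0.15, 0.2,
                                                0.3, 0.5)) {
  stopifnot(inherits(config, "sim_config"))
  config$rule <- "bonferroni"
  set.seed(config$seed)
  data <- sim_generate(config)
  s <- sim_score(data, config)
  ok <- !is.na(s$p)
  truth <- data$truth
  rows <- lapply(per_test_alphas, function(a) {
    sig <- rep(FALSE, length(truth))
    sig[ok] <- s$p[ok] < a
    tp <- sum(sig & truth); fp <- sum(sig & !truth)
    fn <- sum(!sig & truth); tn <- sum(!sig & !truth)
    data.frame(per_test_alpha = a,
               score_threshold = stats::qnorm(1 - a / 2),
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               accuracy = (tp + tn) / length(truth))
  })
  do.call(rbind, rows)
}
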