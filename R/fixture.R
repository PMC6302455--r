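#' Generate a synthetic two-state expression fixture
#'
#' Builds a genes x cells matrix shaped like a normalized scRNA-seq dataset:
#' per state, gene signals are drawn standard normal with chosen pairs given
#' a planted correlation (`rho0` in state 0, `rho1` in state 1), shifted and
#' scaled into a non-negative range (`4 + z/2`, truncated at zero — an event
#' of negligible probability — so the planted Pearson correlations are
#' preserved exactly), and zeros are planted independently at the requested
#' sparsity to emulate dropout. Deterministic from `seed`; with `dir` set,
#' the matrix and label files are written and repeated seeds give
#' byte-identical files.
#'
#' @param genes Number of genes G.
#' @param cells0,cells1 Cells in state 0 / state 1.
#' @param pairs List of planted pairs, each `list(i, j, rho0, rho1)` with
#'   distinct gene indices; pairs may not share genes.
#' @param sparsity Fraction of entries set to zero, in [0, 1).
#' @param seed Integer seed.
#' @param dir Optional output directory; written files are `matrix.tsv` and
#'   `labels.tsv`.
#' @param s_min Feasibility floor: expected planted-pair support per state,
#'   `min(cells0, cells1) * (1 - sparsity)^2`, must reach it.
#' @return List with `E` (expression matrix), `states`
#'   ([state_assignment()]), `pairs`, and `paths` when `dir` was given.
#' @export
make_fixture <- function(genes = 20, cells0 = 50, cells1 = 50,
                         pairs = list(), sparsity = 0.25, seed = 1,
                         dir = NULL, s_min = 10) {
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  if (genes < 2) stop("need at least 2 genes")
  planted <- unlist(lapply(pairs, function(p) c(p$i, p$j)))
  if (anyDuplicated(planted))
    stop("planted pairs must not share genes")
  if (length(pairs) &&
      min(cells0, cells1) * (1 - sparsity)^2 < s_min)
    stop("infeasible fixture: expected planted-pair support ",
         sprintf("%.1f", min(cells0, cells1) * (1 - sparsity)^2),
         " is below s_min = ", s_min)
  set.seed(seed)
  gen_state <- function(K, rho_field) {
    z <- matrix(stats::rnorm(genes * K), genes, K)
    for (p in pairs) {
      rho <- p[[rho_field]]
      if (abs(rho) > 1) stop("|rho| must be <= 1")
      z[p$j, ] <- rho * z[p$i, ] + sqrt(1 - rho^2) * z[p$j, ]
    }
    v <- pmax(4 + z / 2, 0)               # linear map into positive range
    if (sparsity > 0)
      v[matrix(stats::runif(genes * K) < sparsity, genes, K)] <- 0
    v
  }
  E0 <- gen_state(cells0, "rho0")
  E1 <- gen_state(cells1, "rho1")
  E <- cbind(E0, E1)
  rownames(E) <- sprintf("g%03d", seq_len(genes))
  colnames(E) <- c(sprintf("s0_c%03d", seq_len(cells0)),
                   sprintf("s1_c%03d", seq_len(cells1)))
  states <- state_assignment(
    c(rep("state0", cells0), rep("state1", cells1)), cells = colnames(E))
  out <- list(E = E, states = states, pairs = pairs, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    mpath <- file.path(dir, "matrix.tsv")
    lpath <- file.path(dir, "labels.tsv")
    write_expression(E, mpath, "tsv")
    write_states(states, lpath)
    out$paths <- c(matrix = mpath, labels = lpath)
  }
  out
}
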