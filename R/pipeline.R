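#' Run the full file-to-files analysis pipeline
#'
#' Orchestrates preprocess -> per-state masked correlation -> differential
#' test -> network assembly from files on disk, and writes the output bundle:
#' `edges.tsv`, `network.sif`, `network.graphml`, `hubs.tsv`, `nodes.txt`
#' (gene list for external annotation tools) and `run_log.json` (config
#' echo, package version, sparsity and result summary). Optionally the
#' per-state C/S/I matrices. Any stage error aborts with a stage-named
#' message and removes partial outputs.
#'
#' @param matrix Path to the expression matrix (or a matrix object).
#' @param labels Path to the two-column label file (or a
#'   [state_assignment()]).
#' @param out_dir Output directory, created if needed.
#' @param format Matrix format, see [read_expression()].
#' @param normalize,cv_threshold,s_min,alpha,adjusted_p_cut,tail Passed to
#'   [diff_network()].
#' @param state0,state1 Optional label-to-state overrides, see
#'   [read_states()].
#' @param write_matrices If `TRUE`, also export the C/S/I matrices of both
#'   states.
#' @return Invisibly, a list with the fitted `"diffnet"` object and the
#'   output `paths`.
#' @export
run_pipeline <- function(matrix, labels, out_dir, format = "auto",
                         normalize = FALSE, cv_threshold = 0.25, s_min = 10,
                         alpha = 0.05, adjusted_p_cut = NULL,
                         tail = "two_sided", state0 = NULL, state1 = NULL,
                         write_matrices = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  E <- stage("read", {
    if (is.character(matrix)) read_expression(matrix, format)
    else validate_expression(matrix)
  })
  states <- stage("labels", {
    if (is.character(labels)) read_states(labels, state0, state1)
    else if (inherits(labels, "state_assignment")) labels
    else state_assignment(labels, state0 = state0, state1 = state1)
  })
  fit <- stage("fit", diff_network(
    E, states, normalize = normalize, cv_threshold = cv_threshold,
    s_min = s_min, alpha = alpha, adjusted_p_cut = adjusted_p_cut,
    tail = tail))

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("edges.tsv", "network.sif",
                                "network.graphml", "hubs.tsv", "nodes.txt",
                                "run_log.json"))
  names(paths) <- c("edges", "sif", "graphml", "hubs", "nodes", "log")
  written <- character()
  on.exit(if (length(written) && !done) unlink(written), add = TRUE)
  done <- FALSE
  stage("write", {
    write_edges(fit, paths["edges"]); written <- c(written, paths["edges"])
    write_sif(fit, paths["sif"]); written <- c(written, paths["sif"])
    write_graphml(fit, paths["graphml"])
    written <- c(written, paths["graphml"])
    write_hubs(fit, paths["hubs"]); written <- c(written, paths["hubs"])
    writeLines(fit$nodes, paths["nodes"])
    written <- c(written, paths["nodes"])
    if (write_matrices) {
      mp <- c(write_state_matrices(fit, 0, out_dir),
              write_state_matrices(fit, 1, out_dir))
      written <- c(written, mp)
    }
    log <- list(
      package = "diffcornet",
      version = fit$config$version,
      config = fit$config[setdiff(names(fit$config), "version")],
      states = list(state0 = fit$state_names[1],
                    state1 = fit$state_names[2],
                    cells = fit$cells_per_state),
      input = list(genes = fit$dims[1], cells = fit$dims[2],
                   zero_fraction = fit$sparsity),
      result = list(pairs_tested = fit$m, edges = nrow(fit$edges),
                    nodes = length(fit$nodes)))
    jsonlite::write_json(log, paths["log"], auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    written <- c(written, paths["log"])
  })
  done <- TRUE
  if (nrow(fit$edges) == 0)
    warning("no differential pairs at the chosen threshold; ",
            "outputs written with an empty edge list")
  invisible(list(fit = fit, paths = paths))
}
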