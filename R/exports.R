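# Config echo written atop every text output for provenance.
config_header <- function(net) {
  cfg <- net$config
  if (is.null(cfg)) return(character())
  c(sprintf("# diffcornet %s", cfg$version),
    sprintf("# states: %s (0) vs %s (1)", net$state_names[1],
            net$state_names[2]),
    sprintf("# cv_threshold=%g s_min=%d alpha=%g adjusted_p_cut=%s tail=%s",
            cfg$cv_threshold, cfg$s_min, cfg$alpha,
            if (is.null(cfg$adjusted_p_cut)) "NA" else
              format(cfg$adjusted_p_cut), cfg$tail),
    sprintf("# pairs_tested=%d edges=%d", net$m, nrow(net$edges)))
}

#' Write the differential edge list as TSV
#'
#' Columns: gene_i, gene_j, I0, I1, S0, S1, delta, p, p_adj, specific_state.
#' A commented header echoes the configuration and package version.
#'
#' @param net A `"diffnet"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path) {
  stopifnot(inherits(net, "diffnet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(net), con)
  utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a Cytoscape SIF file
#'
#' One line per edge, `gene_i<TAB>diff<TAB>gene_j`.
#' @inheritParams write_edges
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "diffnet"))
  writeLines(paste(net$edges$gene_i, "diff", net$edges$gene_j, sep = "\t"),
             path)
  invisible(path)
}

#' Write the network as GraphML
#'
#' Cytoscape-readable GraphML with `delta`, `p_adj` and `specific_state` as
#' edge attributes.
#' @inheritParams write_edges
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "diffnet"))
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Write the hub table as TSV
#' @inheritParams write_edges
#' @param top_k Number of hubs to write; default all nodes.
#' @export
write_hubs <- function(net, path, top_k = length(net$nodes)) {
  stopifnot(inherits(net, "diffnet"))
  tab <- hub_table(net, top_k = max(top_k, 1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(net), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export one state's C/S/I matrices as TSV
#'
#' Writes the correlation, support-size and interaction matrices of a fitted
#' network's chosen state as gene x gene TSV files with missing values as
#' "NA".
#'
#' @param net A `"diffnet"` object from [diff_network()] (which retains the
#'   per-state `"state_corr"` objects).
#' @param state 0 or 1.
#' @param dir Output directory; files are `C<state>.tsv`, `S<state>.tsv`,
#'   `I<state>.tsv`.
#' @return Character vector of the three paths, invisibly.
#' @export
write_state_matrices <- function(net, state, dir) {
  stopifnot(inherits(net, "diffnet"))
  if (is.null(net$states)) stop("network does not carry state matrices")
  sc <- net$states[[state + 1]]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s%d.tsv", c("C", "S", "I"), state))
  mats <- list(sc$C, sc$S, sc$I)
  for (k in 1:3)
    utils::write.table(mats[[k]], paths[k], sep = "\t", quote = FALSE,
                       na = "NA", col.names = NA)
  invisible(paths)
}
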