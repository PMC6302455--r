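#' Read a genes-by-cells expression matrix
#'
#' Reads a matrix of normalized, non-negative read counts with genes as rows
#' and cells as columns. Dense input is TSV/CSV with the first column holding
#' gene identifiers and a header row of cell identifiers. Sparse input is
#' MatrixMarket coordinate format; entries absent from the triplet file are
#' exact zeros, and gene/cell identifiers are read from companion
#' one-id-per-line files (by default `genes.txt` and `cells.txt` next to the
#' matrix file).
#'
#' Zeros are preserved exactly and are never converted to missing values:
#' downstream, a zero means "not detected" (dropout) and defines the support
#' over which each gene pair's correlation is computed.
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`. Default guesses from the
#'   file extension.
#' @param genes,cells For `"mtx"` only: paths to the row/column identifier
#'   files. Defaults to `genes.txt` / `cells.txt` in the matrix's directory.
#' @return A numeric matrix with unique `rownames` (genes) and `colnames`
#'   (cells), validated by [validate_expression()].
#' @seealso [write_expression()], [read_states()]
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                            genes = NULL, cells = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    dir <- dirname(path)
    if (is.null(genes)) genes <- file.path(dir, "genes.txt")
    if (is.null(cells)) cells <- file.path(dir, "cells.txt")
    if (!file.exists(genes)) stop("gene id file not found: ", genes)
    if (!file.exists(cells)) stop("cell id file not found: ", cells)
    m <- as.matrix(Matrix::readMM(path))
    gid <- readLines(genes)
    cid <- readLines(cells)
    if (nrow(m) != length(gid))
      stop("gene id file has ", length(gid), " ids but matrix has ",
           nrow(m), " rows")
    if (ncol(m) != length(cid))
      stop("cell id file has ", length(cid), " ids but matrix has ",
           ncol(m), " columns")
    dimnames(m) <- list(gid, cid)
    return(validate_expression(m))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2) stop("parse error: expected gene id column plus at least ",
                         "one cell column in ", path)
  gid <- as.character(df[[1]])
  vals <- df[-1]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      x <- suppressWarnings(as.numeric(vals[[j]]))
      bad <- which(is.na(x) & !is.na(vals[[j]]))
      if (length(bad))
        stop("parse error in ", path, " line ", bad[1] + 1L,
             ": non-numeric value \"", vals[[j]][bad[1]], "\" in column ",
             names(vals)[j])
      vals[[j]] <- x
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gid
  validate_expression(m)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: values are written with 17 significant
#' digits so that a write/read round trip reproduces the matrix exactly.
#' For `"mtx"`, companion `genes.txt` / `cells.txt` files are written next to
#' the matrix file and zero entries are omitted from the triplet list.
#'
#' @param x Expression matrix (genes x cells with dimnames).
#' @param path Output file.
#' @param format `"tsv"`, `"csv"`, or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  validate_expression(x)
  if (format == "mtx") {
    dir <- dirname(path)
    nz <- which(x != 0, arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("%%MatrixMarket matrix coordinate real general", con)
    writeLines(sprintf("%d %d %d", nrow(x), ncol(x), nrow(nz)), con)
    if (nrow(nz))
      writeLines(sprintf("%d %d %.17g", nz[, 1], nz[, 2], x[nz]), con)
    writeLines(rownames(x), file.path(dir, "genes.txt"))
    writeLines(colnames(x), file.path(dir, "cells.txt"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  header <- paste(c("gene_id", colnames(x)), collapse = sep)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = sep),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the contract assumed everywhere else in the package: a numeric
#' matrix of finite, non-negative values with at least 2 genes and 2 cells and
#' duplicate-free gene and cell identifiers. Non-finite values are a hard
#' error, never silently treated as zero.
#'
#' @param x Matrix to validate.
#' @return `x`, invisibly usable (returned unchanged).
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix")
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("expression matrix must have at least 2 genes and 2 cells, got ",
         nrow(x), " x ", ncol(x))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate cell ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values (NA/NaN/Inf)")
  if (any(x < 0))
    stop("expression matrix contains negative values; expected non-negative ",
         "normalized counts")
  x
}

#' Construct a two-state cell assignment
#'
#' Maps every cell to one of two cellular states coded 0 and 1. When `labels`
#' is a character or factor vector, the two distinct labels are mapped to
#' {0, 1} lexicographically unless `state0`/`state1` override the order.
#'
#' @param labels Named vector: either integers in {0, 1} or state labels,
#'   named by cell id. Unnamed vectors require `cells`.
#' @param cells Optional cell ids, used when `labels` has no names.
#' @param state0,state1 Optional label values to map to state 0 / state 1.
#' @return An integer vector of 0/1 named by cell id, with a `state_names`
#'   attribute giving the display label of each state; class
#'   `"state_assignment"`.
#' @export
state_assignment <- function(labels, cells = NULL,
                             state0 = NULL, state1 = NULL) {
  if (!is.null(cells)) {
    if (length(cells) != length(labels))
      stop("labels and cells differ in length")
    names(labels) <- cells
  }
  if (is.null(names(labels)))
    stop("state labels must be named by cell id")
  if (anyDuplicated(names(labels)))
    stop("duplicate cell id in state labels: ",
         names(labels)[duplicated(names(labels))][1])
  if (is.numeric(labels) && all(labels %in% c(0, 1)) &&
      is.null(state0) && is.null(state1)) {
    out <- as.integer(labels)
    names(out) <- names(labels)
    state_names <- c("0" = "state0", "1" = "state1")
  } else {
    lab <- as.character(labels)
    uniq <- sort(unique(lab))
    if (length(uniq) != 2)
      stop("exactly two distinct state labels required, found ",
           length(uniq), ": ", paste(uniq, collapse = ", "))
    if (!is.null(state0) || !is.null(state1)) {
      if (is.null(state0)) state0 <- setdiff(uniq, state1)
      if (is.null(state1)) state1 <- setdiff(uniq, state0)
      if (!setequal(c(state0, state1), uniq))
        stop("state0/state1 overrides do not match the labels present: ",
             paste(uniq, collapse = ", "))
      uniq <- c(state0, state1)
    }
    out <- ifelse(lab == uniq[2], 1L, 0L)
    names(out) <- names(labels)
    state_names <- c("0" = uniq[1], "1" = uniq[2])
  }
  if (!all(c(0L, 1L) %in% out))
    stop("both states must be non-empty")
  structure(out, state_names = state_names, class = "state_assignment")
}

#' Read a cell-state label file
#'
#' Two-column tab-separated file, `cell_id<TAB>state_label`, no header.
#' Labels are mapped to states {0, 1} lexicographically unless overridden.
#'
#' @inheritParams state_assignment
#' @param path Path to the label file.
#' @return A [state_assignment()] object.
#' @export
read_states <- function(path, state0 = NULL, state1 = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) != 2)
    stop("parse error: label file must have exactly two tab-separated ",
         "columns (cell_id, state_label), found ", ncol(df))
  state_assignment(df[[2]], cells = as.character(df[[1]]),
                   state0 = state0, state1 = state1)
}

#' Write a cell-state label file
#' @param states A [state_assignment()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(states, path) {
  nm <- attr(states, "state_names")
  writeLines(paste(names(states), nm[as.character(states)], sep = "\t"), path)
  invisible(path)
}

#' @export
print.state_assignment <- function(x, ...) {
  nm <- attr(x, "state_names")
  cat("Two-state cell assignment for", length(x), "cells\n")
  cat(sprintf("  state 0 (%s): %d cells\n", nm[["0"]], sum(x == 0L)))
  cat(sprintf("  state 1 (%s): %d cells\n", nm[["1"]], sum(x == 1L)))
  invisible(x)
}

# Check that states cover the matrix cells exactly; reorder to column order.
align_states <- function(x, states) {
  missing <- setdiff(colnames(x), names(states))
  if (length(missing))
    stop("no state label for cell: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(states), colnames(x))
  if (length(extra))
    stop("state label for unknown cell: ", paste(extra, collapse = ", "))
  out <- states[colnames(x)]
  attributes(out) <- c(attributes(out),
                       list(state_names = attr(states, "state_names")))
  class(out) <- "state_assignment"
  if (!all(c(0L, 1L) %in% out)) stop("both states must be non-empty")
  out
}
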