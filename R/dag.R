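#' Directed acyclic graphs as binary adjacency matrices
#'
#' A network structure over `d` measured species is represented by a `d x d`
#' binary adjacency matrix `A` with `A[i, j] = 1` meaning a directed edge from
#' node `i` to node `j` (node `i` is a parent of node `j`). The diagonal is
#' zero and the directed graph must be acyclic.
#'
#' @param d Number of nodes.
#' @param edges Optional two-column matrix or data frame of (from, to) pairs,
#'   given as integer indices or as variable names.
#' @param variable_names Optional character vector of node labels.
#' @return A `d x d` binary adjacency matrix with dimnames.
#' @examples
#' dag(3, edges = cbind(1, 2))
#' @export
dag <- function(d, edges = NULL, variable_names = NULL) {
  if (is.null(variable_names)) variable_names <- paste0("x", seq_len(d))
  stopifnot(length(variable_names) == d)
  adj <- matrix(0L, d, d, dimnames = list(variable_names, variable_names))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    from <- edges[, 1]
    to <- edges[, 2]
    if (is.character(from)) from <- match(from, variable_names)
    if (is.character(to)) to <- match(to, variable_names)
    from <- as.integer(from)
    to <- as.integer(to)
    if (anyNA(from) || anyNA(to) || any(from < 1 | from > d | to < 1 | to > d))
      stop("edge endpoints must be valid node indices or names", call. = FALSE)
    adj[cbind(from, to)] <- 1L
  }
  validate_dag(adj)
  adj
}

validate_dag <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("adjacency must be a square matrix", call. = FALSE)
  a <- adj != 0
  if (any(diag(a)))
    stop("adjacency must have a zero diagonal", call. = FALSE)
  if (!is_acyclic(adj))
    stop("graph contains a directed cycle; a DAG is required", call. = FALSE)
  invisible(adj)
}

#' Test whether a directed graph is acyclic
#'
#' @param adjacency Square binary matrix; `adjacency[i, j] = 1` encodes the
#'   edge `i -> j`.
#' @return `TRUE` if the graph has no directed cycle (equivalently, a
#'   topological order of the nodes exists).
#' @examples
#' is_acyclic(matrix(0, 2, 2))
#' is_acyclic(rbind(c(0, 1), c(1, 0)))
#' @export
is_acyclic <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix", call. = FALSE)
  storage.mode(adjacency) <- "integer"
  cpp_is_acyclic(adjacency)
}

#' Tidy the edges of an adjacency matrix
#'
#' @param adj Adjacency matrix.
#' @return A tibble with columns `from`, `to` (node labels).
#' @export
dag_edges <- function(adj) {
  validate_dag(adj)
  nm <- rownames(adj)
  if (is.null(nm)) nm <- paste0("x", seq_len(nrow(adj)))
  idx <- which(adj != 0, arr.ind = TRUE)
  tibble::tibble(from = nm[idx[, 1]], to = nm[idx[, 2]])
}

#' Enumerate all DAGs on a small number of nodes
#'
#' Exhaustive enumeration over all binary zero-diagonal matrices, keeping the
#' acyclic ones. Intended for small `d` (the count grows super-exponentially:
#' 1, 3, 25, 543, ...).
#'
#' @param d Number of nodes (at most 5).
#' @return List of adjacency matrices.
#' @export
enumerate_dags <- function(d) {
  stopifnot(d >= 1, d <= 5)
  off <- which(diag(d) == 0)
  m <- length(off)
  out <- list()
  for (code in 0:(2^m - 1)) {
    adj <- matrix(0L, d, d)
    adj[off] <- as.integer(intToBits(code)[seq_len(m)] == 1)
    if (is_acyclic(adj)) out[[length(out) + 1L]] <- adj
  }
  out
}

#' Read and write DAGs as CSV adjacency matrices or edge lists
#'
#' `write_dag_csv()`/`read_dag_csv()` use a square adjacency matrix with a
#' header row of variable names; `write_dag_edges()`/`read_dag_edges()` use a
#' two-column (from, to) edge list.
#'
#' @param adj Adjacency matrix.
#' @param path File path.
#' @param variable_names Node labels used when reading an edge list.
#' @return The adjacency matrix (invisibly for writers).
#' @export
write_dag_csv <- function(adj, path) {
  validate_dag(adj)
  write.csv(adj, path, row.names = FALSE)
  invisible(adj)
}

#' @rdname write_dag_csv
#' @export
read_dag_csv <- function(path) {
  m <- as.matrix(read.csv(path, check.names = FALSE))
  storage.mode(m) <- "integer"
  rownames(m) <- colnames(m)
  validate_dag(m)
  m
}

#' @rdname write_dag_csv
#' @export
write_dag_edges <- function(adj, path) {
  write.csv(as.data.frame(dag_edges(adj)), path, row.names = FALSE)
  invisible(adj)
}

#' @rdname write_dag_csv
#' @export
read_dag_edges <- function(path, variable_names) {
  e <- read.csv(path)
  dag(length(variable_names), edges = e, variable_names = variable_names)
}
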