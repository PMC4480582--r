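#' Log marginal likelihood of a DAG under the Normal-Wishart prior
#'
#' Closed-form marginal sampling distribution \eqn{L(G \mid X)} of a Gaussian
#' Bayesian network structure: for each node the linear-Gaussian conditional
#' given its parents is integrated against the prior, yielding a product of
#' node-wise family scores. Each family score is the ratio of two subset
#' marginals evaluated with subset-adjusted degrees of freedom, which makes
#' the score identical across Markov-equivalent DAGs.
#'
#' @param data Numeric matrix or data frame (cells in rows, species in
#'   columns). Zero rows are allowed and give a log marginal likelihood of 0.
#' @param dag Binary adjacency matrix (see [dag()]).
#' @param prior A [normal_wishart_prior()]; defaults to the standard prior
#'   for `ncol(data)` variables.
#' @param cache Optional environment used to memoise subset marginals across
#'   calls on the same data (keyed by column subset); results are unchanged
#'   by caching.
#' @return The log marginal likelihood (a scalar).
#' @examples
#' x <- matrix(rnorm(20), 10, 2)
#' log_marginal_likelihood(x, dag(2, cbind(1, 2)))
#' @export
log_marginal_likelihood <- function(data, dag, prior = NULL, cache = NULL) {
  validate_dag(dag)
  X <- as_data_matrix(data, nrow(dag))
  if (is.null(prior)) prior <- normal_wishart_prior(ncol(X))
  stopifnot(inherits(prior, "unpbn_prior"))
  if (prior$d != ncol(X))
    stop("prior dimension does not match the data", call. = FALSE)
  if (nrow(X) == 0) return(0)
  sum(family_scores(X, dag, prior, cache))
}

family_scores <- function(X, adj, prior, cache = NULL) {
  d <- ncol(X)
  sub_ml <- function(S) {           # S: sorted 0-based column subset
    if (length(S) == 0) return(0)
    if (!is.null(cache)) {
      key <- paste0("s", paste(S, collapse = "."))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
    }
    v <- cpp_subset_logml(X, as.integer(S), prior$mean_precision_scale,
                          prior$dof, prior$precision, prior$mean0)
    if (!is.null(cache)) cache[[key]] <- v
    v
  }
  vapply(seq_len(d), function(j) {
    P <- which(adj[, j] != 0) - 1L
    sub_ml(sort(c(P, j - 1L))) - sub_ml(sort(P))
  }, numeric(1))
}

#' Log prior over DAG structures
#'
#' Structure prior uniform over the cardinality of each node's parent set:
#' \eqn{\log p(G) = -\sum_j \log \binom{d-1}{|pa(j)|} - \log Z_d}, so that
#' large parent sets are not favoured merely because there are many of them.
#' The normalising constant \eqn{Z_d} (sum of the unnormalised weight over
#' all DAGs on `d` nodes) is computed exactly by a weighted
#' inclusion-exclusion over sink sets; normalisation matters in the mixture
#' model because the number of structure-prior factors changes with the
#' number of components.
#'
#' @param dag Binary adjacency matrix.
#' @return Log prior probability of the structure.
#' @examples
#' log_prior_dag(dag(3)) - log_prior_dag(dag(3, cbind(1, 2)))
#' @export
log_prior_dag <- function(dag) {
  validate_dag(dag)
  d <- nrow(dag)
  -sum(lchoose(d - 1, colSums(dag != 0))) - cpp_log_dag_prior_normconst(d)
}
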