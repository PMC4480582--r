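#' Normal-Wishart prior for Gaussian Bayesian networks
#'
#' Conjugate prior over the mean vector and precision matrix of a multivariate
#' Gaussian, under which the marginal likelihood of any DAG decomposes into
#' closed-form node-wise family scores. The defaults follow the standard
#' choice for score-based structure learning on standardized single-cell
#' data: zero prior mean, identity parametric precision matrix and `d + 2`
#' degrees of freedom, so that the prior is vague but proper and the score is
#' invariant across Markov-equivalent structures.
#'
#' @param d Number of variables (nodes).
#' @param mean0 Length-`d` prior mean vector (default zeros).
#' @param precision `d x d` symmetric positive-definite parametric matrix of
#'   the Wishart prior (default identity).
#' @param dof Degrees of freedom; must exceed `d - 1` (default `d + 2`).
#' @param mean_precision_scale Positive scalar weighting the prior precision
#'   of the mean (default 1).
#' @return An object of class `unpbn_prior`.
#' @examples
#' normal_wishart_prior(3)
#' @export
normal_wishart_prior <- function(d, mean0 = rep(0, d), precision = diag(d),
                                 dof = d + 2, mean_precision_scale = 1) {
  stopifnot(d >= 1, length(mean0) == d)
  if (!is.matrix(precision) || any(dim(precision) != d) ||
      max(abs(precision - t(precision))) > 1e-8)
    stop("prior precision must be a symmetric d x d matrix", call. = FALSE)
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("prior precision must be positive-definite", call. = FALSE)
  if (dof <= d - 1)
    stop("degrees of freedom must exceed d - 1", call. = FALSE)
  if (mean_precision_scale <= 0)
    stop("mean_precision_scale must be positive", call. = FALSE)
  structure(
    list(d = d, mean0 = as.numeric(mean0), precision = precision,
         dof = dof, mean_precision_scale = mean_precision_scale),
    class = "unpbn_prior")
}

#' @export
print.unpbn_prior <- function(x, ...) {
  cat("Normal-Wishart prior: d =", x$d, ", dof =", x$dof,
      ", mean precision scale =", x$mean_precision_scale, "\n")
  invisible(x)
}

as_data_matrix <- function(data, d_expected = NULL) {
  if (is.data.frame(data)) {
    num <- vapply(data, is.numeric, logical(1))
    data <- as.matrix(data[num])
  }
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  data <- as.matrix(data)
  if (nrow(data) > 0 && any(!is.finite(data)))
    stop("data must contain only finite values", call. = FALSE)
  if (!is.null(d_expected) && ncol(data) != d_expected)
    stop("data has ", ncol(data), " columns but ", d_expected,
         " were expected", call. = FALSE)
  data
}
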