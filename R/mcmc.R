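#' MCMC configuration for the mixture-of-networks sampler
#'
#' The default run length matches the published schedule for two-component
#' problems (2.8e6 iterations, burn-in 1.4e6, thinning 350); four-component
#' problems were run at 5e6/2e6/500. Desk-scale analyses override these.
#'
#' @param n_iterations Total number of sweeps.
#' @param burn_in Discarded initial sweeps (must be `< n_iterations`).
#' @param thinning Keep every `thinning`-th sweep after burn-in.
#' @param seed Integer seed; every source of randomness in a run derives
#'   from it.
#' @param alpha Dirichlet concentration of the (integrated-out) mixture
#'   weights.
#' @param lambda_poisson Rate of the Poisson prior on the number of
#'   components (truncated to `N >= 1`).
#' @param move_probabilities Named weights for the four move types
#'   `edge`, `gibbs`, `eject`, `absorb`; normalised to sum to 1.
#' @param max_parents Cap on parent-set size (default `d - 1`, i.e. no cap).
#' @return An object of class `unpbn_config`.
#' @export
mcmc_config <- function(n_iterations = 2.8e6, burn_in = 1.4e6, thinning = 350,
                        seed = 1L, alpha = 1, lambda_poisson = 1,
                        move_probabilities = c(edge = 0.45, gibbs = 0.45,
                                               eject = 0.05, absorb = 0.05),
                        max_parents = NULL) {
  n_iterations <- as.double(n_iterations)
  burn_in <- as.double(burn_in)
  if (n_iterations < 1 || burn_in < 0 || burn_in >= n_iterations)
    stop("need 0 <= burn_in < n_iterations", call. = FALSE)
  if (thinning < 1) stop("thinning must be >= 1", call. = FALSE)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (lambda_poisson <= 0) stop("lambda_poisson must be positive", call. = FALSE)
  mp <- move_probabilities
  if (length(mp) != 4 || any(mp < 0) || sum(mp) <= 0)
    stop("move_probabilities must be 4 non-negative weights", call. = FALSE)
  if (is.null(names(mp))) names(mp) <- c("edge", "gibbs", "eject", "absorb")
  structure(
    list(n_iterations = n_iterations, burn_in = burn_in,
         thinning = as.integer(thinning), seed = as.integer(seed),
         alpha = alpha, lambda_poisson = lambda_poisson,
         move_probabilities = mp / sum(mp), max_parents = max_parents),
    class = "unpbn_config")
}

#' Mixture state: allocation vector plus per-component DAGs
#'
#' @param allocation Length-`n` integer labels in `1..N`; every component must
#'   be non-empty.
#' @param dags List of `N` adjacency matrices, one per component.
#' @return An object of class `unpbn_state` with fields `n_components`,
#'   `allocation`, `dags` and `component_sizes`.
#' @export
mixture_state <- function(allocation, dags) {
  allocation <- as.integer(allocation)
  N <- length(dags)
  sizes <- tabulate(allocation, nbins = N)
  if (any(allocation < 1) || any(allocation > N) || any(sizes == 0))
    stop("allocation labels must cover 1..N with no empty component",
         call. = FALSE)
  lapply(dags, validate_dag)
  d <- nrow(dags[[1]])
  if (!all(vapply(dags, nrow, 1L) == d))
    stop("all component DAGs must have the same dimension", call. = FALSE)
  structure(list(n_components = N, allocation = allocation, dags = dags,
                 component_sizes = sizes),
            class = "unpbn_state")
}

#' Dirichlet-multinomial log probability of an allocation vector
#'
#' The allocation prior \eqn{p_N(m)} with the mixture weights integrated out:
#' \eqn{\Gamma(N\alpha)/\Gamma(n + N\alpha) \prod_h \Gamma(n_h +
#' \alpha)/\Gamma(\alpha)} for component sizes \eqn{m = (n_1, ..., n_N)}.
#'
#' @param sizes Integer vector of component sizes.
#' @param alpha Dirichlet concentration.
#' @return Log probability of one particular labelled allocation vector.
#' @export
log_allocation_prior <- function(sizes, alpha = 1) {
  stopifnot(all(sizes >= 1), alpha > 0)
  N <- length(sizes)
  n <- sum(sizes)
  lgamma(N * alpha) - lgamma(n + N * alpha) +
    sum(lgamma(sizes + alpha) - lgamma(alpha))
}

log_n_components_prior <- function(N, lambda) {
  N * log(lambda) - lgamma(N + 1) - log(expm1(lambda))
}

#' Log posterior of a mixture state
#'
#' \eqn{\sum_h [\log L(G_h \mid X_{(I_h)}) + \log p(G_h)] + \log p_N(m) +
#' \log p(N)} with the Dirichlet-multinomial allocation prior and a Poisson
#' prior on `N` truncated to `N >= 1`.
#'
#' @param state A [mixture_state()].
#' @param data Observation matrix or data frame.
#' @param prior A [normal_wishart_prior()] (default constructed from the
#'   data dimension).
#' @param config An [mcmc_config()] supplying `alpha` and `lambda_poisson`.
#' @return Unnormalised log posterior density.
#' @export
log_posterior <- function(state, data, prior = NULL,
                          config = mcmc_config()) {
  stopifnot(inherits(state, "unpbn_state"))
  X <- as_data_matrix(data)
  if (length(state$allocation) != nrow(X))
    stop("state allocation length does not match the data", call. = FALSE)
  if (is.null(prior)) prior <- normal_wishart_prior(ncol(X))
  comp_terms <- vapply(seq_len(state$n_components), function(h) {
    rows <- state$allocation == h
    log_marginal_likelihood(X[rows, , drop = FALSE], state$dags[[h]], prior) +
      log_prior_dag(state$dags[[h]])
  }, numeric(1))
  sum(comp_terms) +
    log_allocation_prior(state$component_sizes, config$alpha) +
    log_n_components_prior(state$n_components, config$lambda_poisson)
}

#' Single-edge neighbourhood of a DAG
#'
#' All DAGs reachable by one single-edge operation (add, delete or reverse one
#' edge) that keep the graph acyclic and respect the parent-set cap.
#'
#' @param dag Adjacency matrix.
#' @param max_parents Parent-set cap (default `d - 1`).
#' @return List of adjacency matrices; attribute `"kind"` records the
#'   operation generating each neighbour.
#' @export
dag_neighbors <- function(dag, max_parents = NULL) {
  validate_dag(dag)
  if (is.null(max_parents)) max_parents <- nrow(dag) - 1L
  storage.mode(dag) <- "integer"
  cpp_dag_neighbors(dag, as.integer(max_parents))
}

#' Propose a single-edge structure move for one component
#'
#' Draws uniformly among the valid single-edge neighbours of the component's
#' DAG. The log proposal ratio accounts for the neighbourhood-size asymmetry
#' (`log |nbhd(G)| - log |nbhd(G')|`). A DAG with no valid neighbour proposes
#' itself with ratio 0.
#'
#' @param state A [mixture_state()].
#' @param component Component index.
#' @param max_parents Parent-set cap.
#' @return List with elements `state` (the proposal) and
#'   `log_proposal_ratio`.
#' @export
propose_edge_move <- function(state, component, max_parents = NULL) {
  stopifnot(inherits(state, "unpbn_state"),
            component >= 1, component <= state$n_components)
  nb <- dag_neighbors(state$dags[[component]], max_parents)
  if (length(nb) == 0)
    return(list(state = state, log_proposal_ratio = 0))
  pick <- floor(runif(1) * length(nb)) + 1
  newdag <- nb[[min(pick, length(nb))]]
  dimnames(newdag) <- dimnames(state$dags[[component]])
  k2 <- length(dag_neighbors(newdag, max_parents))
  dags <- state$dags
  dags[[component]] <- newdag
  list(state = mixture_state(state$allocation, dags),
       log_proposal_ratio = log(length(nb)) - log(k2))
}

#' Gibbs reallocation of one observation
#'
#' Reassigns observation `observation` among the current components with
#' probability proportional to its predictive contribution to each
#' component's marginal likelihood times the allocation-prior factor
#' `(n_h^(-i) + alpha)`. A move that would empty a component is disallowed
#' (component-count changes happen only through eject/absorb), so the sole
#' member of a component keeps its label.
#'
#' @param state A [mixture_state()].
#' @param data Observation matrix.
#' @param observation Row index of the observation to reassign.
#' @param prior A [normal_wishart_prior()].
#' @param alpha Dirichlet concentration.
#' @return The updated [mixture_state()].
#' @export
gibbs_reallocate <- function(state, data, observation, prior = NULL,
                             alpha = 1) {
  stopifnot(inherits(state, "unpbn_state"))
  X <- as_data_matrix(data)
  i <- as.integer(observation)
  stopifnot(i >= 1, i <= nrow(X))
  if (state$n_components == 1) return(state)
  if (state$component_sizes[state$allocation[i]] == 1) return(state)
  if (is.null(prior)) prior <- normal_wishart_prior(ncol(X))
  lw <- gibbs_logweights(X, state, i, prior, alpha)
  hnew <- sample_categorical_log(lw)
  if (hnew != state$allocation[i]) {
    alloc <- state$allocation
    alloc[i] <- hnew
    state <- mixture_state(alloc, state$dags)
  }
  state
}

gibbs_logweights <- function(X, state, i, prior, alpha) {
  dags <- lapply(state$dags, function(a) { storage.mode(a) <- "integer"; a })
  cpp_gibbs_logweights(X, as.integer(state$allocation), dags, as.integer(i),
                       prior$mean_precision_scale, prior$dof,
                       prior$precision, prior$mean0, alpha)
}

# inverse-CDF draw with a fixed-order cumulative sum, for seed reproducibility
sample_categorical_log <- function(logw) {
  w <- exp(logw - max(logw))
  which(runif(1) * sum(w) <= cumsum(w))[1]
}

#' Propose a trans-dimensional component change (eject or absorb)
#'
#' Anchored split-merge with a restricted-Gibbs launch: an ordered pair of
#' distinct observations `(i, j)` is drawn; if they share a component, that
#' component is ejected apart (the side of `i` keeps the component's DAG,
#' the side of `j` becomes a new component with a DAG drawn uniformly over
#' all DAGs, and the remaining members are allocated by a restricted Gibbs
#' scan started from a short launch run); if they lie in different
#' components, the two components are absorbed into one, which keeps the DAG
#' of `i`'s component. The Metropolis-Hastings acceptance term contains the
#' posterior ratio (including `p(N)`, `p_N(m)` and the structure prior), the
#' final-scan allocation probability and the DAG-draw density, so the pair
#' of moves is reversible; eject followed by the exact inverse absorb
#' restores the original state. A proposal that cannot change the state
#' (fewer than two observations, or `type = "absorb"` with `N = 1`) returns
#' the current state with acceptance term 0.
#'
#' @param state A [mixture_state()].
#' @param data Observation matrix.
#' @param prior A [normal_wishart_prior()].
#' @param config An [mcmc_config()].
#' @param type `"eject"`, `"absorb"`, or `NULL` to let the anchor pair
#'   decide (the pair is then drawn unconditionally).
#' @param launch_scans Number of restricted-Gibbs launch scans.
#' @return List with elements `state` (the proposal), `log_acceptance_term`
#'   and `type`.
#' @export
propose_component_change <- function(state, data, prior = NULL,
                                     config = mcmc_config(), type = NULL,
                                     launch_scans = 3) {
  stopifnot(inherits(state, "unpbn_state"))
  X <- as_data_matrix(data)
  if (is.null(prior)) prior <- normal_wishart_prior(ncol(X))
  alpha <- config$alpha
  lambda <- config$lambda_poisson
  n <- nrow(X)
  d <- ncol(X)
  N <- state$n_components
  if (n < 2)
    return(list(state = state, log_acceptance_term = 0, type = type))
  if (N < 2 && identical(type, "absorb"))
    return(list(state = state, log_acceptance_term = 0, type = type))
  # draw anchors, honouring a forced move type
  repeat {
    ai <- sample.int(n, 1)
    aj <- sample.int(n - 1, 1)
    if (aj >= ai) aj <- aj + 1L
    same_comp <- state$allocation[ai] == state$allocation[aj]
    if (is.null(type) || (same_comp && type == "eject") ||
        (!same_comp && type == "absorb")) break
  }
  score <- function(rows, adj)
    log_marginal_likelihood(X[rows, , drop = FALSE], adj, prior)
  restricted_scan <- function(S, z, dag0, dag1, side0, side1, scans,
                              final_actual = NULL) {
    # side0/side1: current member index sets including anchors
    logq <- 0
    for (scan in seq_len(scans + 1)) {
      final <- scan == scans + 1
      for (m in seq_along(S)) {
        i <- S[m]
        side0 <- setdiff(side0, i); side1 <- setdiff(side1, i)
        lw0 <- score(c(side0, i), dag0) - score(side0, dag0) +
          log(length(side0) + alpha)
        lw1 <- score(c(side1, i), dag1) - score(side1, dag1) +
          log(length(side1) + alpha)
        pz <- exp(c(lw0, lw1) - max(lw0, lw1))
        if (final && !is.null(final_actual)) {
          pick <- final_actual[m]
        } else {
          pick <- if (runif(1) * sum(pz) <= pz[1]) 0L else 1L
        }
        if (final)
          logq <- logq + (c(lw0, lw1)[pick + 1] - max(lw0, lw1)) -
            log(sum(pz))
        z[m] <- pick
        if (pick == 0L) side0 <- c(side0, i) else side1 <- c(side1, i)
      }
    }
    list(z = z, logq = logq, side0 = side0, side1 = side1)
  }

  if (same_comp) {
    h <- state$allocation[ai]
    members <- which(state$allocation == h)
    S <- setdiff(members, c(ai, aj))
    Gnew <- random_uniform_dag(d, dimnames(state$dags[[h]]))
    z0 <- as.integer(runif(length(S)) < 0.5)
    res <- restricted_scan(S, z0, state$dags[[h]], Gnew,
                           c(ai, S[z0 == 0L]), c(aj, S[z0 == 1L]),
                           launch_scans)
    side0 <- res$side0; side1 <- res$side1
    alloc <- state$allocation
    alloc[side1] <- N + 1L
    dags <- state$dags
    dags[[N + 1L]] <- Gnew
    dlp <- score(side0, state$dags[[h]]) + score(side1, Gnew) -
      score(members, state$dags[[h]]) + log_prior_dag(Gnew) +
      log_alloc_ratio_split(N, alpha, length(side0), length(side1), n) +
      log(lambda)
    list(state = mixture_state(alloc, dags),
         log_acceptance_term = dlp + log(cpp_count_dags(d)) - res$logq,
         type = "eject")
  } else {
    c1 <- state$allocation[ai]; c2 <- state$allocation[aj]
    m1 <- which(state$allocation == c1)
    m2 <- which(state$allocation == c2)
    S <- setdiff(c(m1, m2), c(ai, aj))
    z0 <- as.integer(runif(length(S)) < 0.5)
    actual <- as.integer(!(S %in% m1))
    res <- restricted_scan(S, z0, state$dags[[c1]], state$dags[[c2]],
                           c(ai, S[z0 == 0L]), c(aj, S[z0 == 1L]),
                           launch_scans, final_actual = actual)
    alloc <- state$allocation
    alloc[alloc == c2] <- c1
    alloc[alloc > c2] <- alloc[alloc > c2] - 1L
    dags <- state$dags
    dags[[min(c1, c2)]] <- state$dags[[c1]]
    dags[[max(c1, c2)]] <- NULL
    dlp <- score(c(m1, m2), state$dags[[c1]]) -
      score(m1, state$dags[[c1]]) - score(m2, state$dags[[c2]]) -
      log_prior_dag(state$dags[[c2]]) -
      log_alloc_ratio_split(N - 1, alpha, length(m1), length(m2), n) -
      log(lambda)
    list(state = mixture_state(alloc, dags),
         log_acceptance_term = dlp - log(cpp_count_dags(d)) + res$logq,
         type = "absorb")
  }
}

log_alloc_ratio_split <- function(N, alpha, n1, n2, n) {
  nb <- n1 + n2
  lgamma((N + 1) * alpha) - lgamma(N * alpha) +
    lgamma(n + N * alpha) - lgamma(n + (N + 1) * alpha) +
    lgamma(n1 + alpha) + lgamma(n2 + alpha) -
    lgamma(alpha) - lgamma(nb + alpha)
}

random_uniform_dag <- function(d, dn = NULL) {
  repeat {
    a <- matrix(0L, d, d)
    a[which(diag(d) == 0)] <- as.integer(runif(d * d - d) < 0.5)
    if (is_acyclic(a)) break
  }
  dimnames(a) <- dn
  a
}

#' Fit the mixture-of-Gaussian-Bayesian-networks model
#'
#' Trans-dimensional MCMC over the allocation vector, the number of
#' components and one DAG per component, with all continuous parameters
#' (means, variances, regression coefficients and mixture weights) integrated
#' out analytically. The chain starts from a single component with an empty
#' DAG; each sweep performs, according to `move_probabilities`, either one
#' Metropolis-Hastings single-edge move per component, a full Gibbs
#' reallocation pass over the observations, or an eject/absorb proposal on
#' the number of components. Identical `config` (including seed) gives
#' bit-identical traces.
#'
#' @param data Data frame or matrix of observations (cells in rows, measured
#'   species in columns); non-numeric columns of a data frame are dropped.
#' @param config An [mcmc_config()]; run length, seed and prior
#'   concentrations live here.
#' @param prior A [normal_wishart_prior()] (default: standard prior for the
#'   data dimension).
#' @param center Subtract each column's pooled mean before sampling
#'   (default `TRUE`). The prior mean vector is zero, so uncentred
#'   concentration data (all-positive levels) would make the prior's
#'   mean-discrepancy term distort subset determinants and blur structure
#'   recovery.
#' @param standardize Additionally z-score each column to unit variance.
#'   The default is `FALSE`: the marginal-likelihood prior has a fixed unit
#'   parametric precision, and raw concentration-scale measurements
#'   (variance much larger than 1) let the data dominate it, which sharpens
#'   structure recovery; scaling to unit variance blurs weak conditional
#'   independencies under that prior. Use `TRUE` when columns are on wildly
#'   different or non-concentration scales. The returned fit records both
#'   choices.
#' @param prior_only Diagnostic mode that scores every component as if its
#'   data were empty (constant likelihood), so the chain samples the prior
#'   over allocations and the number of components.
#' @return An object of class `unpbn_fit` with the retained samples, the
#'   data actually scored, acceptance-rate diagnostics and full config
#'   provenance. Use [tidy()], [glance()], [posterior_edge_probabilities()],
#'   [consensus_allocation()] and [pco()] on it.
#' @examples
#' x <- generate_gbn_mixture(gbn_mixture_spec_2pop(n_cells = 30), seed = 1)
#' fit <- unpbn(dplyr::select(x, -cell_id, -true_label),
#'              mcmc_config(n_iterations = 200, burn_in = 100, thinning = 10))
#' glance(fit)
#' @export
unpbn <- function(data, config = mcmc_config(), prior = NULL,
                  center = TRUE, standardize = FALSE, prior_only = FALSE) {
  stopifnot(inherits(config, "unpbn_config"))
  X <- as_data_matrix(data)
  if (nrow(X) < 1) stop("at least one observation is required", call. = FALSE)
  vn <- colnames(X)
  if (is.null(vn)) vn <- paste0("x", seq_len(ncol(X)))
  if (center || standardize) {
    X <- scale(X, center = center || standardize, scale = standardize)
    if (standardize) {
      sds <- attr(X, "scaled:scale")
      if (any(sds == 0 | !is.finite(sds)))
        stop("cannot standardize a constant column", call. = FALSE)
    }
    X <- as.matrix(X)
  }
  d <- ncol(X)
  if (is.null(prior)) prior <- normal_wishart_prior(d)
  if (prior$d != d) stop("prior dimension does not match data", call. = FALSE)
  max_parents <- if (is.null(config$max_parents)) d - 1L else config$max_parents
  set.seed(config$seed)
  res <- cpp_run_mcmc(X, prior$mean_precision_scale, prior$dof,
                      prior$precision, prior$mean0,
                      as.integer(config$n_iterations),
                      as.integer(config$burn_in), config$thinning,
                      config$alpha, config$lambda_poisson,
                      as.numeric(config$move_probabilities),
                      as.integer(max_parents), isTRUE(prior_only))
  samples <- res$samples
  for (s in seq_along(samples)) {
    for (h in seq_along(samples[[s]]$dags))
      dimnames(samples[[s]]$dags[[h]]) <- list(vn, vn)
  }
  moves <- c("edge", "gibbs", "eject", "absorb")
  acc <- tibble::tibble(move = moves,
                        proposed = as.integer(res$proposed),
                        accepted = as.integer(res$accepted)) |>
    dplyr::mutate(rate = ifelse(.data$proposed > 0,
                                .data$accepted / .data$proposed, NA_real_))
  structure(
    list(samples = samples, data = X, variable_names = vn,
         centered = center, standardized = standardize, prior = prior,
         config = config, acceptance = acc, n = nrow(X), d = d),
    class = "unpbn_fit")
}

#' @export
print.unpbn_fit <- function(x, ...) {
  tab <- table(vapply(x$samples, `[[`, 1L, "n_components"))
  cat("Mixture-of-networks fit:", x$n, "observations,", x$d, "variables\n")
  cat("Retained samples:", length(x$samples),
      "(iterations:", format(x$config$n_iterations, big.mark = ","),
      ", burn-in:", format(x$config$burn_in, big.mark = ","),
      ", thinning:", x$config$thinning, ")\n")
  cat("Posterior over number of components:\n")
  print(round(tab / sum(tab), 3))
  invisible(x)
}

#' Number of retained MCMC samples
#' @param fit An `unpbn_fit`.
#' @return Integer count of retained samples.
#' @export
n_samples <- function(fit) length(fit$samples)

sample_allocations <- function(fit) {
  if (inherits(fit, "unpbn_fit"))
    lapply(fit$samples, `[[`, "allocation")
  else if (is.list(fit) && length(fit) > 0 && is.numeric(fit[[1]]))
    lapply(fit, as.integer)
  else if (is.numeric(fit))
    list(as.integer(fit))
  else stop("expected an unpbn_fit, a list of label vectors, or one label vector",
            call. = FALSE)
}
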