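# Unit tests for the mixture posterior, the individual move kernels and the
# run-level contracts of the trans-dimensional sampler.

test_that("the Dirichlet-multinomial allocation term matches direct Gamma evaluation", {
  # n = 4, N = 2, m = (2, 2), alpha = 1:
  # Gamma(2)Gamma(3)Gamma(3) / (Gamma(6)Gamma(1)Gamma(1)) = 4/120 = 1/30
  expect_equal(log_allocation_prior(c(2, 2), alpha = 1), log(1 / 30))
  a <- 0.7
  expect_equal(log_allocation_prior(c(3, 1), alpha = a),
               lgamma(2 * a) - lgamma(4 + 2 * a) +
                 lgamma(3 + a) + lgamma(1 + a) - 2 * lgamma(a))
})

test_that("log_posterior reduces to a single-network score for N = 1", {
  set.seed(1)
  X <- matrix(rnorm(12), 6, 2)
  g <- dag(2, cbind(1, 2))
  st <- mixture_state(rep(1, 6), list(g))
  cfg <- mcmc_config(n_iterations = 10, burn_in = 0, thinning = 1)
  expect_equal(log_posterior(st, X, config = cfg),
               log_marginal_likelihood(X, g) + log_prior_dag(g) +
                 log_allocation_prior(6, 1) + log(1) - lgamma(2) -
                 log(expm1(1)))
})

test_that("log_posterior is invariant to relabelling the components", {
  set.seed(2)
  X <- matrix(rnorm(16), 8, 2)
  g1 <- dag(2, cbind(1, 2)); g2 <- dag(2)
  l <- c(1, 1, 2, 2, 1, 2, 1, 2)
  s12 <- mixture_state(l, list(g1, g2))
  s21 <- mixture_state(3L - l, list(g2, g1))
  expect_equal(log_posterior(s12, X), log_posterior(s21, X))
})

test_that("doubling a component's rows changes only that component's term", {
  set.seed(3)
  X <- matrix(rnorm(12), 6, 2)
  g <- dag(2)
  l <- c(1, 1, 1, 2, 2, 2)
  base <- log_posterior(mixture_state(l, list(g, g)), X)
  X2 <- rbind(X, X[4:6, ])
  l2 <- c(l, c(2, 2, 2))
  aug <- log_posterior(mixture_state(l2, list(g, g)), X2)
  # the difference must equal the change in component 2's likelihood plus
  # the allocation-prior change; component 1's likelihood term is untouched
  delta_lik <- log_marginal_likelihood(X2[l2 == 2, ], g) -
    log_marginal_likelihood(X[l == 2, ], g)
  delta_alloc <- log_allocation_prior(c(3, 6), 1) -
    log_allocation_prior(c(3, 3), 1)
  expect_equal(aug - base, delta_lik + delta_alloc)
})

test_that("single-edge neighbourhoods are exactly the one-edit acyclic graphs", {
  # d = 2, empty graph: exactly {add 1->2, add 2->1}
  nb <- dag_neighbors(dag(2))
  expect_length(nb, 2)
  kinds <- attr(nb, "kind")
  expect_setequal(as.character(kinds), c("add", "add"))
  # reverse applied to 1->2 yields 2->1
  nb12 <- dag_neighbors(dag(2, cbind(1, 2)))
  rev_idx <- which(attr(nb12, "kind") == "reverse")
  expect_equal(unname(nb12[[rev_idx]]), unname(dag(2, cbind(2, 1))))

  # 3-node chain: compare against brute-force enumeration of one-edit DAGs
  chain <- dag(3, rbind(c(1, 2), c(2, 3)))
  one_edit <- Filter(function(a) {
    de <- sum(abs(a - chain))
    same_edges <- sum(a) == sum(chain)
    (de == 1) ||                       # add or delete one edge
      (de == 2 && same_edges && any(a + t(a) != chain + t(chain)) == FALSE)
  }, enumerate_dags(3))
  one_edit <- Filter(function(a) any(a != chain), one_edit)
  nb3 <- dag_neighbors(chain)
  key <- function(a) paste(a, collapse = "")
  expect_setequal(vapply(nb3, key, character(1)),
                  vapply(one_edit, key, character(1)))
})

test_that("parent-set cap restricts the neighbourhood", {
  coll <- dag(3, rbind(c(1, 3), c(2, 3)))
  nb_capped <- dag_neighbors(dag(3), max_parents = 1)
  expect_false(any(vapply(nb_capped, function(a) max(colSums(a)) > 1,
                          logical(1))))
  # with cap 1 the collider itself would not be reachable
  expect_true(all(vapply(dag_neighbors(coll, max_parents = 2),
                         function(a) max(colSums(a)) <= 2, logical(1))))
})

test_that("propose_edge_move returns a one-edit proposal with the correct ratio", {
  set.seed(4)
  X <- matrix(rnorm(12), 6, 2)
  st <- mixture_state(rep(1, 6), list(dag(2)))
  prop <- propose_edge_move(st, 1)
  expect_equal(sum(abs(prop$state$dags[[1]] - st$dags[[1]])), 1)
  # empty d=2 graph has 2 neighbours; each neighbour has 3 (delete, reverse,
  # and nothing else: adding the opposite edge would create a cycle)
  expect_equal(prop$log_proposal_ratio, log(2) - log(2))
})

test_that("Gibbs reallocation weights equal direct marginal-likelihood ratios", {
  set.seed(5)
  X <- matrix(rnorm(6), 6, 1)
  g <- dag(1)
  st <- mixture_state(c(1, 1, 1, 2, 2, 2), list(g, g))
  lw <- unpbn:::gibbs_logweights(X, st, 2L, normal_wishart_prior(1), 1)
  direct <- function(h) {
    keep <- setdiff(which(st$allocation == h), 2L)
    log_marginal_likelihood(X[c(keep, 2L), , drop = FALSE], g) -
      log_marginal_likelihood(X[keep, , drop = FALSE], g) +
      log(length(keep) + 1)
  }
  expect_equal(as.numeric(lw), c(direct(1), direct(2)))
})

test_that("two identical components give reassignment probabilities 1/2", {
  X <- matrix(c(1, 2, 3, 1, 2, 3), 6, 1)
  g <- dag(1)
  st <- mixture_state(c(1, 1, 1, 2, 2, 2), list(g, g))
  # observation 1's component (without it) duplicates component 2 exactly
  lw <- unpbn:::gibbs_logweights(X, st, 1L, normal_wishart_prior(1), 1)
  # sizes without observation 1: 2 vs 3 -> allocation factor differs, so
  # compare the likelihood parts only with equal-size components
  X2 <- matrix(c(1, 2, 1, 2), 4, 1)
  st2 <- mixture_state(c(1, 1, 2, 2), list(g, g))
  lw2 <- unpbn:::gibbs_logweights(rbind(X2, 0),
                                  mixture_state(c(1, 1, 2, 2, 1), list(g, g)),
                                  5L, normal_wishart_prior(1), 1)
  expect_equal(lw2[1], lw2[2], tolerance = 1e-12)
})

test_that("Gibbs reallocation keeps singletons and single components fixed", {
  set.seed(6)
  X <- matrix(rnorm(4), 4, 1)
  st1 <- mixture_state(rep(1, 4), list(dag(1)))
  expect_identical(gibbs_reallocate(st1, X, 1), st1)
  st2 <- mixture_state(c(1, 2, 2, 2), list(dag(1), dag(1)))
  expect_identical(gibbs_reallocate(st2, X, 1), st2)
})

test_that("eject followed by the inverse absorb restores the allocation", {
  set.seed(7)
  X <- matrix(rnorm(10), 10, 2)
  st <- mixture_state(rep(1, 10), list(dag(2, cbind(1, 2))))
  prop <- propose_component_change(st, X, type = "eject")
  expect_equal(prop$state$n_components, 2)
  expect_true(is.finite(prop$log_acceptance_term))
  back <- propose_component_change(prop$state, X, type = "absorb")
  expect_equal(back$state$n_components, 1)
  expect_equal(back$state$allocation, st$allocation)
  # absorb with one component cannot change the state: acceptance term 0
  idp <- propose_component_change(st, X, type = "absorb")
  expect_identical(idp$state, st)
  expect_identical(idp$log_acceptance_term, 0)
})

test_that("run bookkeeping: r = (iterations - burn_in) / thinning samples", {
  set.seed(8)
  X <- matrix(rnorm(10), 5, 2)
  fit <- unpbn(X, mcmc_config(n_iterations = 10, burn_in = 0, thinning = 1,
                              seed = 1))
  expect_equal(n_samples(fit), 10)
  fit2 <- unpbn(X, mcmc_config(n_iterations = 100, burn_in = 30,
                               thinning = 7, seed = 1))
  expect_equal(n_samples(fit2), floor(70 / 7))
  expect_true(all(vapply(fit2$samples, function(s)
    sum(s$component_sizes) == 5 &&
      all(tabulate(s$allocation, s$n_components) == s$component_sizes) &&
      all(vapply(s$dags, is_acyclic, logical(1))), logical(1))))
})

test_that("identical seed and config give bit-identical traces", {
  set.seed(9)
  X <- matrix(rnorm(30), 15, 2)
  cfg <- mcmc_config(n_iterations = 600, burn_in = 100, thinning = 5,
                     seed = 123)
  f1 <- unpbn(X, cfg)
  f2 <- unpbn(X, cfg)
  expect_identical(f1$samples, f2$samples)
  f3 <- unpbn(X, mcmc_config(n_iterations = 600, burn_in = 100, thinning = 5,
                             seed = 124))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("invalid configurations error before sampling", {
  expect_error(mcmc_config(n_iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(thinning = 0), "thinning")
  expect_error(mcmc_config(alpha = 0), "alpha")
  expect_error(mcmc_config(lambda_poisson = -1), "lambda")
  expect_error(mcmc_config(move_probabilities = c(1, 2)), "4 non-negative")
  expect_error(mixture_state(c(1, 1, 3), list(dag(1), dag(1), dag(1))),
               "empty component")
})

test_that("prior-only sampling matches the enumerated allocation prior over N", {
  # constant likelihood (components scored as if empty): the chain samples
  # the Poisson(1) prior restricted to allocations with no empty component
  set.seed(10)
  X <- matrix(rnorm(6), 6, 1)
  fit <- unpbn(X, mcmc_config(n_iterations = 6e4, burn_in = 5e3,
                              thinning = 2, seed = 3,
                              move_probabilities = c(0.05, 0.35, 0.3, 0.3)),
               prior_only = TRUE)
  emp <- tabulate(vapply(fit$samples, `[[`, 1L, "n_components"), nbins = 6)
  parts <- partitions_of(6)
  lp <- vapply(parts, function(l)
    log_allocation_prior(tabulate(l), 1) - log(expm1(1)), numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  pn <- as.numeric(tapply(p, vapply(parts, max, 1L), sum))
  expect_gt(suppressWarnings(
    chisq.test(emp[1:length(pn)], p = pn)$p.value), 0.01)
})

test_that("stronger component separation does not reduce allocation accuracy", {
  # monotone data strength: average pco over seeds is non-decreasing in the
  # separation between the two synthetic components
  mean_pco <- function(shift) {
    mean(vapply(1:5, function(s) {
      x <- generate_gbn_mixture(gbn_mixture_spec_2pop(n_cells = 40,
                                                      mean_shift = shift),
                                seed = s)
      fit <- unpbn(dplyr::select(x, -cell_id, -true_label),
                   mcmc_config(n_iterations = 2000, burn_in = 1000,
                               thinning = 5, seed = s))
      pco(fit, x$true_label)
    }, numeric(1)))
  }
  accs <- vapply(c(0, 15, 40), mean_pco, numeric(1))
  expect_true(all(diff(accs) > -2))  # non-decreasing up to Monte-Carlo slack
})
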