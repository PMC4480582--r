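# Post-processing of traces: posterior edge probabilities, co-clustering,
# consensus allocation, pco and the adjusted Rand index, each against
# hand-computed or exhaustively enumerated values.

g2 <- function(...) dag(2, ...)

test_that("pooled pep equals the direct formula on hand-built traces", {
  e12 <- g2(cbind(1, 2))
  # all samples carry the same single dag -> pep equals its adjacency
  fit <- make_toy_fit(list(rep(1, 3), rep(1, 3)), list(list(e12), list(e12)))
  pep <- pep_matrix(posterior_edge_probabilities(fit))
  expect_equal(unname(pep), unname(e12) * 1.0)
  # edge present in exactly one of two samples -> pep 0.5
  fit2 <- make_toy_fit(list(rep(1, 3), rep(1, 3)), list(list(e12), list(g2())))
  expect_equal(pep_matrix(posterior_edge_probabilities(fit2))["x1", "x2"], 0.5)
  # empty trace errors
  fit0 <- make_toy_fit(list(rep(1, 2)), list(list(g2())))
  fit0$samples <- list()
  expect_error(posterior_edge_probabilities(fit0), "empty")
})

test_that("pooled pep weights components by occupancy", {
  e12 <- g2(cbind(1, 2))
  # one sample, two components of sizes 3 and 1, edge only in the large one
  fit <- make_toy_fit(list(c(1, 1, 1, 2)), list(list(e12, g2())))
  expect_equal(pep_matrix(posterior_edge_probabilities(fit))["x1", "x2"],
               3 / 4)
})

test_that("per-component pep matches a hand tally after majority matching", {
  e12 <- g2(cbind(1, 2))
  e21 <- g2(cbind(2, 1))
  # 4 samples over 4 observations; truth-like split {1,2} vs {3,4}
  allocs <- list(c(1, 1, 2, 2), c(2, 2, 1, 1), c(1, 1, 2, 2), c(1, 1, 1, 2))
  dags <- list(list(e12, g2()), list(g2(), e12), list(e12, e21),
               list(e12, e21))
  fit <- make_toy_fit(allocs, dags)
  cons <- structure(list(labels = c(1L, 1L, 2L, 2L), n_components = 2L,
                         similarity = diag(4), expected_ari = 1),
                    class = "unpbn_consensus")
  pep <- posterior_edge_probabilities(fit, cons)
  m1 <- pep_matrix(pep, 1); m2 <- pep_matrix(pep, 2)
  # hand tally with occupancy weights (component sizes):
  # consensus comp 1 receives: s1 comp1 (e12, w2), s2 comp2 (e12, w2),
  # s3 comp1 (e12, w2), s4 comp1 (e12, w3: members 1,2,3 majority in cons 1)
  expect_equal(m1["x1", "x2"], (2 + 2 + 2 + 3) / (2 + 2 + 2 + 3))
  expect_equal(m1["x2", "x1"], 0)
  # consensus comp 2 receives: s1 comp2 (empty, w2), s2 comp1 (empty, w2),
  # s3 comp2 (e21, w2), s4 comp2 (e21, w1)
  expect_equal(m2["x2", "x1"], (2 + 1) / (2 + 2 + 2 + 1))
  expect_equal(m2["x1", "x2"], 0)
})

test_that("pep is invariant to the order of retained samples", {
  set.seed(11)
  x <- generate_gbn_mixture(gbn_mixture_spec_2pop(n_cells = 25), seed = 2)
  fit <- unpbn(dplyr::select(x, -cell_id, -true_label),
               mcmc_config(n_iterations = 400, burn_in = 100, thinning = 3,
                           seed = 1))
  shuf <- fit
  shuf$samples <- fit$samples[rev(seq_along(fit$samples))]
  expect_equal(posterior_edge_probabilities(fit)$pep,
               posterior_edge_probabilities(shuf)$pep)
})

test_that("co-clustering matrix matches hand counts and is label-invariant", {
  # single sample -> binary partition matrix, unit diagonal
  f1 <- make_toy_fit(list(c(1, 1, 2)), list(list(dag(1), dag(1))), d = 1)
  expect_equal(co_clustering_matrix(f1),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  # 3 hand-built samples over n = 4
  allocs <- list(c(1, 1, 2, 2), c(2, 2, 1, 1), c(1, 2, 2, 1))
  S <- co_clustering_matrix(allocs)
  expect_equal(S[1, 2], 2 / 3)
  expect_equal(S[1, 4], 1 / 3)
  expect_equal(S[3, 4], 2 / 3)
  expect_true(all(diag(S) == 1))
  # relabelling within a sample does not change the matrix
  relab <- list(c(2, 2, 1, 1), c(1, 1, 2, 2), c(3, 1, 1, 3))
  expect_equal(co_clustering_matrix(relab), S)
})

test_that("consensus allocation agrees with exhaustive partition search (n = 6)", {
  allocs <- list(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 2, 2),
                 c(2, 2, 2, 1, 1, 1), c(1, 1, 1, 2, 2, 1),
                 c(1, 1, 1, 2, 2, 2))
  cons <- consensus_allocation(allocs)
  parts <- partitions_of(6)
  ear <- vapply(parts, function(cand)
    mean(vapply(allocs, adjusted_rand_index, numeric(1), cand)), numeric(1))
  best <- parts[[which.max(ear)]]
  expect_equal(cons$labels, match(best, unique(best)))
  expect_equal(cons$expected_ari, max(ear))
})

test_that("consensus handles degenerate and constrained cases", {
  allocs <- list(c(1, 1, 2, 2), c(1, 1, 2, 2))
  cons <- consensus_allocation(allocs)
  expect_equal(cons$labels, c(1, 1, 2, 2))
  expect_equal(cons$expected_ari, 1)
  # label-permuted copies of one partition give the same partition
  perm <- list(c(1, 1, 2, 2), c(2, 2, 1, 1))
  expect_equal(consensus_allocation(perm)$labels, c(1, 1, 2, 2))
  # k_fixed = 1 returns the trivial partition
  expect_equal(consensus_allocation(allocs, k_fixed = 1)$labels, rep(1L, 4))
  # constrained to k = 3 yields exactly 3 blocks
  expect_equal(max(consensus_allocation(allocs, k_fixed = 3)$labels), 3)
  expect_error(consensus_allocation(allocs, k_fixed = 9), "between 1 and n")
})

test_that("pco matches the hand-evaluated formula", {
  # allocation identical to truth in every sample -> 100
  expect_equal(pco(list(c(1, 1, 2, 2), c(2, 2, 1, 1)), c("A", "A", "B", "B")),
               100)
  # single sample, truth (A,A,B,B), allocation (1,1,1,2):
  # components {A,A,B} and {B} -> (1/2)(2/3 + 1) * 100
  expect_equal(pco(c(1, 1, 1, 2), c("A", "A", "B", "B")),
               (1 / 2) * (2 / 3 + 1) * 100)
  # one component, truth half A half B -> 50
  expect_equal(pco(rep(1, 4), c("A", "A", "B", "B")), 50)
  # relabelling either side leaves pco unchanged
  expect_equal(pco(c(2, 2, 2, 1), c("B", "B", "A", "A")),
               pco(c(1, 1, 1, 2), c("A", "A", "B", "B")))
  expect_error(pco(c(1, 2), c("A", "B", "B")), "length")
})

test_that("adjusted Rand index matches the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  a <- c(1, 1, 1, 2, 2, 2); b <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, b), ari_paircount(a, b))
  set.seed(12)
  for (rep in 1:10) {
    x <- sample(1:3, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    if (length(unique(x)) > 1 && length(unique(y)) > 1)
      expect_equal(adjusted_rand_index(x, y), ari_paircount(x, y))
  }
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(13)
  for (rep in 1:10) {
    x <- sample(1:3, 12, replace = TRUE)
    y <- sample(1:3, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y))
  }
})
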