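#' Posterior edge probabilities from an MCMC trace
#'
#' For each ordered pair of nodes, the fraction of retained samples in which
#' the directed edge is present: \eqn{pep_{ij} = \sum_s a_{ij}^s / r}.
#' Without a consensus map the adjacencies of all components in a sample are
#' pooled, weighted by component occupancy \eqn{n_h / n}. With a consensus
#' allocation, each sampled component is matched to the consensus component
#' sharing the most members (ties broken toward the larger consensus
#' component, then the lower index) and one pep matrix per consensus
#' component is returned. Since two Markov-equivalent DAGs carry the same
#' statistical information, the undirected summary
#' `pep[i, j] + pep[j, i]` (the posterior probability that an edge connects
#' `i` and `j` in either direction) is usually the quantity to report.
#'
#' @param fit An `unpbn_fit`.
#' @param consensus Optional [consensus_allocation()] result.
#' @param undirected Return the symmetrised edge probabilities instead of
#'   the directed ones.
#' @return A tibble with columns `component` (`NA` when pooled), `from`,
#'   `to`, `pep`. Use [pep_matrix()] to reshape one component into a matrix.
#' @export
posterior_edge_probabilities <- function(fit, consensus = NULL,
                                         undirected = FALSE) {
  stopifnot(inherits(fit, "unpbn_fit"))
  if (length(fit$samples) == 0) stop("empty trace", call. = FALSE)
  vn <- fit$variable_names
  d <- fit$d
  n <- fit$n
  if (is.null(consensus)) {
    acc <- matrix(0, d, d)
    for (s in fit$samples) {
      w <- s$component_sizes / n
      for (h in seq_along(s$dags)) acc <- acc + w[h] * s$dags[[h]]
    }
    peps <- list(acc / length(fit$samples))
    comp_ids <- NA_integer_
  } else {
    stopifnot(inherits(consensus, "unpbn_consensus"))
    K <- consensus$n_components
    csize <- tabulate(consensus$labels, nbins = K)
    acc <- replicate(K, matrix(0, d, d), simplify = FALSE)
    wsum <- numeric(K)
    for (s in fit$samples) {
      for (h in seq_along(s$dags)) {
        members <- which(s$allocation == h)
        ov <- tabulate(consensus$labels[members], nbins = K)
        best <- which(ov == max(ov))
        if (length(best) > 1) best <- best[order(-csize[best], best)][1]
        w <- length(members)  # occupancy weight: small stray components
                              # should not dominate the average
        acc[[best]] <- acc[[best]] + w * s$dags[[h]]
        wsum[best] <- wsum[best] + w
      }
    }
    peps <- lapply(seq_len(K), function(k)
      if (wsum[k] > 0) acc[[k]] / wsum[k] else matrix(0, d, d))
    comp_ids <- seq_len(K)
  }
  out <- purrr::map2_dfr(peps, comp_ids, function(m, id) {
    if (undirected) m <- m + t(m)
    dimnames(m) <- list(vn, vn)
    idx <- which(upper.tri(m) | (!undirected & lower.tri(m)), arr.ind = TRUE)
    tibble::tibble(component = id,
                   from = vn[idx[, 1]], to = vn[idx[, 2]],
                   pep = m[idx])
  })
  attr(out, "undirected") <- undirected
  attr(out, "variable_names") <- vn
  out
}

#' Reshape a pep tibble into a matrix
#'
#' @param pep_tbl Output of [posterior_edge_probabilities()].
#' @param component Consensus component to extract (`NA` for the pooled
#'   matrix).
#' @return A `d x d` numeric matrix.
#' @export
pep_matrix <- function(pep_tbl, component = NA) {
  rows <- if (is.na(component)) is.na(pep_tbl$component)
          else !is.na(pep_tbl$component) & pep_tbl$component == component
  tb <- pep_tbl[rows, ]
  vn <- attr(pep_tbl, "variable_names")
  if (is.null(vn)) vn <- sort(unique(c(tb$from, tb$to)))
  m <- matrix(0, length(vn), length(vn), dimnames = list(vn, vn))
  m[cbind(tb$from, tb$to)] <- tb$pep
  if (isTRUE(attr(pep_tbl, "undirected"))) m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Posterior co-clustering (similarity) matrix
#'
#' Entry `(i, j)` is the fraction of retained samples in which observations
#' `i` and `j` share a component; it is invariant to the arbitrary component
#' labels within each sample, which is what makes it usable despite label
#' switching.
#'
#' @param fit An `unpbn_fit` or a list of allocation vectors.
#' @return An `n x n` symmetric matrix with unit diagonal.
#' @export
co_clustering_matrix <- function(fit) {
  allocs <- sample_allocations(fit)
  if (length(allocs) == 0) stop("empty trace", call. = FALSE)
  n <- length(allocs[[1]])
  S <- matrix(0, n, n)
  for (l in allocs) S <- S + outer(l, l, "==")
  S / length(allocs)
}

#' Consensus allocation by maximising the posterior-expected adjusted Rand
#' index
#'
#' Resolves label switching by searching for the single partition whose
#' expected adjusted Rand index against the posterior sample of allocation
#' vectors is maximal. The search is over a documented candidate set: every
#' sampled partition plus average-linkage hierarchical cuts of the
#' co-clustering dissimilarity `1 - S` at each feasible number of blocks.
#' With `k_fixed`, candidates are restricted to partitions with exactly
#' `k_fixed` blocks (the constrained summary used when a component count is
#' imposed downstream).
#'
#' @param fit An `unpbn_fit` or list of allocation vectors.
#' @param k_fixed Optional required number of components.
#' @return An object of class `unpbn_consensus`: `labels` (canonical,
#'   first-occurrence order), `n_components`, `similarity` (the co-clustering
#'   matrix) and `expected_ari` of the chosen partition.
#' @export
consensus_allocation <- function(fit, k_fixed = NULL) {
  allocs <- sample_allocations(fit)
  if (length(allocs) == 0) stop("empty trace", call. = FALSE)
  n <- length(allocs[[1]])
  if (!is.null(k_fixed)) {
    if (k_fixed < 1 || k_fixed > n)
      stop("k_fixed must be between 1 and n", call. = FALSE)
  }
  S <- co_clustering_matrix(allocs)
  cands <- unique(lapply(allocs, canonical_labels))
  kmax <- min(n, max(vapply(cands, max, 1L)) + 2L,
              if (is.null(k_fixed)) n else max(k_fixed, 1L))
  kmax <- max(kmax, if (is.null(k_fixed)) 1L else k_fixed)
  if (n >= 2) {
    hc <- hclust(as.dist(1 - S), method = "average")
    for (k in seq_len(min(n, kmax)))
      cands[[length(cands) + 1L]] <- canonical_labels(cutree(hc, k))
  } else {
    cands[[length(cands) + 1L]] <- 1L
  }
  cands <- unique(cands)
  if (!is.null(k_fixed)) {
    cands <- cands[vapply(cands, max, 1L) == k_fixed]
    if (length(cands) == 0)
      stop("no candidate partition with exactly ", k_fixed, " components",
           call. = FALSE)
  }
  ear <- vapply(cands, function(cand)
    mean(vapply(allocs, adjusted_rand_index, numeric(1), cand)), numeric(1))
  best <- which.max(ear)
  structure(
    list(labels = cands[[best]], n_components = max(cands[[best]]),
         similarity = S, expected_ari = ear[best]),
    class = "unpbn_consensus")
}

#' @export
print.unpbn_consensus <- function(x, ...) {
  cat("Consensus allocation:", x$n_components, "components over",
      length(x$labels), "observations (expected ARI ",
      round(x$expected_ari, 3), ")\n", sep = " ")
  print(table(component = x$labels))
  invisible(x)
}

#' @export
tidy.unpbn_consensus <- function(x, ...) {
  tibble::tibble(cell = seq_along(x$labels), component = x$labels)
}

canonical_labels <- function(l) {
  l <- as.integer(l)
  match(l, unique(l))
}

#' Percentage of correctly allocated observations (pco)
#'
#' The trace-level accuracy of sampled allocations against a known ground
#' truth: for every retained sample and every component, the component's
#' "true" subpopulation is the majority true label among its members, members
#' carrying that label count as correct, and the three-level average (over
#' members, components, samples) is reported as a percentage:
#' \deqn{pco = \frac{1}{r} \sum_s \frac{1}{N^s} \sum_h \frac{1}{n_h^s}
#'   \sum_i I(l_i^{s,h}) \cdot 100.}
#' Ties in the majority vote leave the count unchanged (all tied labels give
#' the same number of matching members), so the tie-break is immaterial to
#' the value; the first tied label in sort order is used.
#'
#' @param fit An `unpbn_fit`, a list of allocation vectors, or a single
#'   allocation vector (e.g. a clustering result).
#' @param true_labels Ground-truth labels, length `n`.
#' @return A percentage in `[0, 100]`.
#' @export
pco <- function(fit, true_labels) {
  allocs <- sample_allocations(fit)
  truth <- as.integer(as.factor(true_labels))
  if (length(truth) != length(allocs[[1]]))
    stop("true_labels length does not match the allocation", call. = FALSE)
  per_sample <- vapply(allocs, function(l) {
    comps <- unique(l)
    mean(vapply(comps, function(h) {
      tl <- truth[l == h]
      max(tabulate(tl)) / length(tl)
    }, numeric(1)))
  }, numeric(1))
  mean(per_sample) * 100
}

#' Adjusted Rand index (Hubert-Arabie)
#'
#' Agreement between two partitions, corrected for chance: 1 for identical
#' partitions (up to relabelling), expected value 0 under independent random
#' partitions, and symmetric in its arguments.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  n <- length(labels_a)
  if (n == 0) stop("empty label vectors", call. = FALSE)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial in the same way
  (sum_ij - expected) / denom
}
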