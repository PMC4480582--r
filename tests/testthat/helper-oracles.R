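# Independent oracles used across the suite. Each recomputes a quantity by
# a different route than the implementation under test: numerical
# quadrature for the closed-form marginal likelihood, exhaustive
# enumeration for posteriors and partitions, pair counting for the adjusted
# Rand index, and a direct Lance-Williams recursion for Ward clustering.

# ---- quadrature oracle for the node-wise family marginal -------------------
# Integrates the family likelihood against the Normal-inverse-gamma prior
# induced on (intercept, regression weights, residual variance) by the
# Normal-Wishart prior with parameters (mu0 = 0, T = t I, dof = aw,
# mean_precision_scale = am):
#   sigma2 ~ InvGamma(shape = (aw - d + p + 1)/2, rate = t/2)
#   beta | sigma2 ~ N(0, sigma2 / t I_p)
#   intercept | sigma2, beta ~ N(mu0_j - beta' mu0_P, sigma2 / am)
quad_family_logml <- function(xj, XP, d, am = 1, aw = d + 2, t = 1,
                              mu0j = 0, mu0P = rep(0, ncol(XP))) {
  p <- ncol(XP)
  stopifnot(p <= 1)
  shape <- (aw - d + p + 1) / 2
  rate <- t / 2
  # Underflow control: the integrand is a product of n densities (~e^-20),
  # below integrate()'s effective noise floor, so everything is rescaled by
  # a constant offset on the log scale; the variance is integrated on the
  # log scale, where its peak is well conditioned.
  offset <- -sum(dnorm(xj, mean(xj), stats::sd(xj) + 0.05, log = TRUE))
  lik <- function(cc, beta, s2) {
    mu <- cc + if (p > 0) as.numeric(XP %*% beta) else 0
    exp(sum(dnorm(xj, mu, sqrt(s2), log = TRUE)) + offset)
  }
  # integration ranges must cover both the prior and the likelihood peak
  mxj <- mean(xj)
  sxj <- stats::sd(xj) + 0.1
  bhat <- if (p > 0 && stats::sd(XP[, 1]) > 0)
    stats::coef(stats::lm(xj ~ XP[, 1]))[2] else 0
  inner_c <- function(beta, s2) {
    m <- mu0j - if (p > 0) sum(beta * mu0P) else 0
    sdc <- sqrt(s2 / am)
    lo <- min(m - 12 * sdc, mxj - 12 * sxj)
    hi <- max(m + 12 * sdc, mxj + 12 * sxj)
    stats::integrate(function(cv) sapply(cv, function(cc)
      lik(cc, beta, s2) * dnorm(cc, m, sdc)),
      lo, hi, rel.tol = 1e-10, subdivisions = 400L)$value
  }
  inner_b <- function(s2) {
    if (p == 0) return(inner_c(numeric(0), s2))
    sdb <- sqrt(s2 / t)
    lo <- min(-12 * sdb, bhat - 8)
    hi <- max(12 * sdb, bhat + 8)
    stats::integrate(function(bv) sapply(bv, function(b)
      inner_c(b, s2) * dnorm(b, 0, sdb)),
      lo, hi, rel.tol = 1e-9, subdivisions = 400L)$value
  }
  ldig <- function(s2) shape * log(rate) - lgamma(shape) -
    (shape + 1) * log(s2) - rate / s2
  val <- stats::integrate(function(lv) sapply(lv, function(ls2) {
    s2 <- exp(ls2)
    inner_b(s2) * exp(ldig(s2) + ls2)   # Jacobian of the log transform
  }), log(1e-5), log(max(60, 40 * stats::var(xj))), rel.tol = 1e-9,
  subdivisions = 800L)$value
  log(val) - offset
}

# quadrature-based full-graph score for d <= 2
quad_graph_logml <- function(X, adj) {
  d <- ncol(X)
  total <- 0
  for (j in seq_len(d)) {
    P <- which(adj[, j] != 0)
    total <- total + quad_family_logml(X[, j], X[, P, drop = FALSE], d)
  }
  total
}

# ---- partitions and exact posterior ---------------------------------------
partitions_of <- function(n) {
  out <- list()
  rec <- function(pre, mx) {
    if (length(pre) == n) {
      out[[length(out) + 1L]] <<- pre
      return()
    }
    for (v in seq_len(mx + 1)) rec(c(pre, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

canon_partition <- function(l) paste(match(l, unique(l)), collapse = ".")

# Exact posterior over set partitions (per-component DAGs marginalised by
# enumeration), on the state space of allocations with no empty component.
# The N! labellings of a partition cancel the 1/N! of the Poisson prior.
exact_partition_posterior <- function(X, alpha = 1, lambda = 1) {
  dags <- enumerate_dags(ncol(X))
  parts <- partitions_of(nrow(X))
  lp <- vapply(parts, function(l) {
    N <- max(l)
    comp <- vapply(seq_len(N), function(h) {
      Xh <- X[l == h, , drop = FALSE]
      ls <- vapply(dags, function(a)
        log_marginal_likelihood(Xh, a) + log_prior_dag(a), numeric(1))
      m <- max(ls)
      m + log(sum(exp(ls - m)))
    }, numeric(1))
    sum(comp) + log_allocation_prior(tabulate(l), alpha) +
      N * log(lambda) - log(expm1(lambda))
  }, numeric(1))
  p <- exp(lp - max(lp))
  names(p) <- vapply(parts, canon_partition, character(1))
  p / sum(p)
}

# exhaustive posterior edge probabilities for a single data set (d = 3)
exact_pep <- function(X) {
  dags <- enumerate_dags(ncol(X))
  sc <- vapply(dags, function(a)
    log_marginal_likelihood(X, a) + log_prior_dag(a), numeric(1))
  w <- exp(sc - max(sc))
  w <- w / sum(w)
  Reduce(`+`, Map(function(a, wi) wi * (a + t(a)), dags, w))
}

# ---- pair-counting adjusted Rand oracle -----------------------------------
ari_paircount <- function(a, b) {
  n <- length(a)
  agree_both <- 0; agree_a <- 0; agree_b <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    agree_both <- agree_both + (sa && sb)
    agree_a <- agree_a + sa
    agree_b <- agree_b + sb
  }
  tot <- choose(n, 2)
  expected <- agree_a * agree_b / tot
  denom <- (agree_a + agree_b) / 2 - expected
  (agree_both - expected) / denom
}

# ---- Lance-Williams Ward oracle -------------------------------------------
# Agglomerates by the Ward criterion using the Lance-Williams update on
# squared Euclidean distances; returns the sequence of merged cluster
# member sets.
ward_merge_sets <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  merges <- list()
  repeat {
    k <- length(active)
    if (k == 1) break
    best <- c(NA, NA); bestv <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (D[i, j] < bestv) { bestv <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merged <- sort(c(active[[i]], active[[j]]))
    merges[[length(merges) + 1L]] <- merged
    ni <- sizes[i]; nj <- sizes[j]
    newd <- sapply(seq_len(k), function(m) {
      if (m %in% best) return(NA)
      nm <- sizes[m]
      ((ni + nm) * D[i, m] + (nj + nm) * D[j, m] - nm * D[i, j]) /
        (ni + nj + nm)
    })
    keep <- setdiff(seq_len(k), best)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], list(merged))
    sizes <- c(sizes[keep], ni + nj)
  }
  merges
}

# ---- CPDAG key for Markov-equivalence grouping ----------------------------
# two DAGs are Markov equivalent iff same skeleton and same v-structures
cpdag_key <- function(adj) {
  d <- nrow(adj)
  skel <- (adj + t(adj)) != 0
  vstr <- character(0)
  for (j in seq_len(d)) {
    pa <- which(adj[, j] != 0)
    if (length(pa) >= 2) {
      for (a in seq_along(pa)) for (b in seq_along(pa)) {
        if (a < b && !skel[pa[a], pa[b]])
          vstr <- c(vstr, paste(pa[a], pa[b], j, sep = "-"))
      }
    }
  }
  paste(paste(which(skel[upper.tri(skel)]), collapse = ","),
        paste(sort(vstr), collapse = ";"), sep = "|")
}

# ---- misc ------------------------------------------------------------------
make_toy_fit <- function(allocations, dags_per_sample, d = NULL,
                         variable_names = NULL) {
  # assemble a minimal unpbn_fit-shaped object from hand-built samples
  if (is.null(d)) d <- nrow(dags_per_sample[[1]][[1]])
  if (is.null(variable_names)) variable_names <- paste0("x", seq_len(d))
  samples <- Map(function(l, gs, idx) {
    list(iteration = idx, n_components = length(gs),
         allocation = as.integer(l),
         component_sizes = tabulate(l, nbins = length(gs)),
         dags = lapply(gs, function(g) {
           dimnames(g) <- list(variable_names, variable_names); g
         }),
         log_posterior = NA_real_)
  }, allocations, dags_per_sample, seq_along(allocations))
  structure(list(samples = samples, n = length(allocations[[1]]), d = d,
                 variable_names = variable_names),
            class = "unpbn_fit")
}
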