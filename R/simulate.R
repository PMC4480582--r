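#' Reduced EGF/NGF MAPK cascade model
#'
#' A compact rate-equation model of the Raf-Mek-Erk cascade in EGF- or
#' NGF-stimulated PC12 cells, built to reproduce the hallmark behaviour of
#' the full published reaction network: transient Erk activation under EGF
#' (receptor signal decays quickly and active Erk feeds back negatively on
#' the Ras exchange activity) versus sustained Erk activation under NGF
#' (the negative feedback is neutralised and a slowly deactivating Rap1
#' branch keeps Raf active). States are the active fractions of the cascade:
#' receptor activity `Rec` (dimensionless), `Ras`-GTP, `Rap1`-GTP, `pRaf`
#' (Raf bound to Ras-GTP), `ppMek` and `ppErk` (concentrations in nM).
#'
#' Rate equations (t in seconds):
#' \deqn{dRec/dt = -k_{rec} Rec}
#' \deqn{dRas/dt = k_{ras} Rec (Ras_T - Ras) / (1 + (ppErk/K_i)^2) - g_{ras} Ras}
#' \deqn{dRap/dt = k_{rap} Rec (Rap_T - Rap) - g_{rap} Rap}
#' \deqn{dpRaf/dt = (k_1 Ras + k_{1r} Rap)(Raf_T - pRaf) - g_1 pRaf}
#' \deqn{dppMek/dt = k_2 pRaf (Mek_T - ppMek) - g_2 ppMek}
#' \deqn{dppErk/dt = (k_{cat}/K_m) ppMek (Erk_T - ppErk) - g_3 ppErk}
#' Total Raf, Mek and Erk are conserved within a run; the Mek catalytic
#' constant `mek_kcat` is 0.15 s^-1 for the wild type and 0.015 s^-1 for the
#' low-activity mutant.
#'
#' @param stimulus `"EGF"` or `"NGF"`.
#' @param mek_variant `"wt"` or `"mut"`.
#' @return Named list of rate constants and mean total levels.
#' @export
mapk_parameters <- function(stimulus = c("EGF", "NGF"),
                            mek_variant = c("wt", "mut")) {
  stimulus <- match.arg(stimulus)
  mek_variant <- match.arg(mek_variant)
  list(
    stimulus = stimulus,
    mek_variant = mek_variant,
    krec = if (stimulus == "EGF") 1 / 120 else 1 / 500,
    ki = if (stimulus == "EGF") 30 else 3000,
    krap = if (stimulus == "NGF") 0.004 else 0,
    kras = 0.02, gras = 0.01,
    grap = 0.0008,
    k1 = 5e-4, k1r = 5e-4, g1 = 0.02,
    k2 = 2e-4, g2 = 0.02,
    mek_kcat = if (mek_variant == "wt") 0.15 else 0.015,
    km3 = 600, g3 = 0.015,
    ras_total = 120, rap_total = 120,
    raf_total = 100, mek_total = 300, erk_total = 500)
}

mapk_rhs <- function(t, y, p) {
  fb <- 1 / (1 + (y[["ppErk"]] / p$ki)^2)
  list(c(
    Rec   = -p$krec * y[["Rec"]],
    Ras   = p$kras * y[["Rec"]] * (p$ras_total - y[["Ras"]]) * fb -
            p$gras * y[["Ras"]],
    Rap   = p$krap * y[["Rec"]] * (p$rap_total - y[["Rap"]]) -
            p$grap * y[["Rap"]],
    pRaf  = (p$k1 * y[["Ras"]] + p$k1r * y[["Rap"]]) *
            (p$raf_tot_cell - y[["pRaf"]]) - p$g1 * y[["pRaf"]],
    ppMek = p$k2 * y[["pRaf"]] * (p$mek_tot_cell - y[["ppMek"]]) -
            p$g2 * y[["ppMek"]],
    ppErk = (p$mek_kcat / p$km3) * y[["ppMek"]] *
            (p$erk_tot_cell - y[["ppErk"]]) - p$g3 * y[["ppErk"]]))
}

#' Deterministic trajectory of the reduced MAPK model
#'
#' One stiff ODE solve (lsoda, relative/absolute tolerances 1e-6/1e-9) of the
#' cascade for one cell with the given total protein levels.
#'
#' @inheritParams mapk_parameters
#' @param totals Named vector of this cell's total Raf/Mek/Erk levels (nM).
#' @param times Output time grid in seconds (must include 0 implicitly;
#'   default every 60 s over 600 s).
#' @param rtol,atol Solver tolerances.
#' @return Tibble with columns `time_s`, `pRaf`, `ppMek`, `ppErk`.
#' @export
mapk_trajectory <- function(stimulus = "EGF", mek_variant = "wt",
                            totals = c(raf = 100, mek = 300, erk = 500),
                            times = seq(60, 600, by = 60),
                            rtol = 1e-6, atol = 1e-9) {
  p <- mapk_parameters(stimulus, mek_variant)
  p$raf_tot_cell <- totals[["raf"]]
  p$mek_tot_cell <- totals[["mek"]]
  p$erk_tot_cell <- totals[["erk"]]
  y0 <- c(Rec = 1, Ras = 0, Rap = 0, pRaf = 0, ppMek = 0, ppErk = 0)
  out <- deSolve::ode(y0, times = union(0, times), func = mapk_rhs,
                      parms = p, method = "lsoda", rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  out <- out[out$time %in% times, , drop = FALSE]
  if (any(!is.finite(as.matrix(out)))) stop("ODE solver failure")
  tibble::tibble(time_s = out$time, pRaf = out$pRaf,
                 ppMek = out$ppMek, ppErk = out$ppErk)
}

#' Simulate one cell with expression noise
#'
#' Cell-to-cell variability in expression is modelled on the total protein
#' levels: each of total Raf, Mek and Erk is drawn from a Normal around its
#' mean with standard deviation `sigma = mu * fd` (fractional deviation) and
#' truncated at 0, and the deterministic cascade is solved with those
#' totals. `fd = 0` reproduces the deterministic trajectory exactly. A
#' failed solve is retried with fresh totals (with a warning) a bounded
#' number of times.
#'
#' @inheritParams mapk_trajectory
#' @param fd Fractional deviation of the expression noise (>= 0).
#' @param max_retries Bounded number of resampling retries on solver failure.
#' @return Tibble with columns `time_s`, `pRaf`, `ppMek`, `ppErk` plus the
#'   drawn totals as an attribute `"totals"`.
#' @export
simulate_cell <- function(stimulus = "EGF", mek_variant = "wt", fd = 0.1,
                          times = seq(60, 600, by = 60), rtol = 1e-6,
                          atol = 1e-9, max_retries = 5) {
  stopifnot(fd >= 0)
  p <- mapk_parameters(stimulus, mek_variant)
  mu <- c(raf = p$raf_total, mek = p$mek_total, erk = p$erk_total)
  for (try in seq_len(max_retries + 1)) {
    totals <- pmax(rnorm(3, mu, mu * fd), 0)
    names(totals) <- names(mu)
    tr <- tryCatch(
      mapk_trajectory(stimulus, mek_variant, totals, times, rtol, atol),
      error = function(e) NULL)
    if (!is.null(tr)) {
      attr(tr, "totals") <- totals
      return(tr)
    }
    warning("ODE solve failed for one cell; resampling totals", call. = FALSE)
  }
  stop("ODE solver failed repeatedly", call. = FALSE)
}

#' Simulate a population of cells for one subpopulation
#'
#' Repeated single-cell simulations (default 175 repeats) under one stimulus
#' and Mek variant, each with independently drawn total protein levels.
#'
#' @inheritParams simulate_cell
#' @param n_cells Number of repeats.
#' @param seed Optional seed.
#' @param normalize `"none"` (raw concentrations) or `"max"` (divide each
#'   species by its population maximum).
#' @return Tibble with columns `cell_id`, `stimulus`, `mek_variant`,
#'   `time_s`, `pRaf`, `ppMek`, `ppErk`.
#' @export
simulate_mapk_population <- function(stimulus = "EGF", mek_variant = "wt",
                                     n_cells = 175, fd = 0.1,
                                     times = seq(60, 600, by = 60),
                                     seed = NULL,
                                     normalize = c("none", "max")) {
  normalize <- match.arg(normalize)
  if (!is.null(seed)) set.seed(seed)
  cells <- purrr::map_dfr(seq_len(n_cells), function(i) {
    tr <- simulate_cell(stimulus, mek_variant, fd, times)
    dplyr::mutate(tr, cell_id = i, .before = 1)
  })
  cells <- dplyr::mutate(cells, stimulus = stimulus,
                         mek_variant = mek_variant, .after = "cell_id")
  if (normalize == "max") {
    for (v in c("pRaf", "ppMek", "ppErk")) {
      m <- max(cells[[v]])
      if (m > 0) cells[[v]] <- cells[[v]] / m
    }
  }
  cells
}

#' Mixture design: which subpopulations are mixed, and in what proportion
#'
#' @param stimuli Character vector of stimuli to cross.
#' @param mek_variants Character vector of Mek variants to cross.
#' @param n_cells Cells per subpopulation (used when `proportions` is
#'   `NULL`; default 175, the published repeat count).
#' @param proportions Optional mixing proportions (summing to 1) applied to
#'   `n_total`, e.g. `c(0.1, 0.9)` for the 1:9 abundance variant.
#' @param n_total Total cells when `proportions` is given.
#' @param fd Fractional deviation of the expression noise.
#' @param time_points Sampling grid in seconds.
#' @return A list of class `unpbn_design`.
#' @export
mixture_design <- function(stimuli = c("EGF", "NGF"), mek_variants = "wt",
                           n_cells = 175, proportions = NULL, n_total = NULL,
                           fd = 0.1, time_points = seq(60, 600, by = 60)) {
  subpop <- tidyr::expand_grid(stimulus = stimuli, mek_variant = mek_variants)
  if (!is.null(proportions)) {
    if (length(proportions) != nrow(subpop) ||
        abs(sum(proportions) - 1) > 1e-8)
      stop("proportions must match the subpopulations and sum to 1",
           call. = FALSE)
    if (is.null(n_total)) stop("n_total is required with proportions",
                               call. = FALSE)
    subpop$n_cells <- round(proportions * n_total)
  } else {
    subpop$n_cells <- n_cells
  }
  structure(list(subpopulations = subpop, fd = fd,
                 time_points = time_points),
            class = "unpbn_design")
}

#' Build a snapshot mixture of simulated subpopulations
#'
#' Simulates every subpopulation in the design, extracts the requested
#' snapshot time point, pools and shuffles the observations. Each time point
#' is analysed independently downstream.
#'
#' @param design An [mixture_design()].
#' @param time_point Snapshot time in seconds; must lie on the design's
#'   sampling grid.
#' @param seed Optional seed (controls both the simulations and the
#'   shuffle).
#' @param normalize Passed to [simulate_mapk_population()].
#' @return Tibble with columns `cell_id`, `true_label`, `pRaf`, `ppMek`,
#'   `ppErk`, in shuffled order.
#' @export
build_mixture <- function(design, time_point, seed = NULL,
                          normalize = c("none", "max")) {
  stopifnot(inherits(design, "unpbn_design"))
  if (!time_point %in% design$time_points)
    stop("time_point ", time_point, " is not on the sampling grid",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pops <- purrr::pmap_dfr(design$subpopulations, function(stimulus,
                                                          mek_variant,
                                                          n_cells) {
    pop <- simulate_mapk_population(stimulus, mek_variant, n_cells,
                                    design$fd, design$time_points,
                                    seed = NULL, normalize = normalize)
    pop <- pop[pop$time_s == time_point, ]
    dplyr::transmute(pop,
                     true_label = paste(stimulus, mek_variant, sep = "."),
                     pRaf = .data$pRaf, ppMek = .data$ppMek,
                     ppErk = .data$ppErk)
  })
  pops <- pops[sample.int(nrow(pops)), ]
  dplyr::mutate(pops, cell_id = dplyr::row_number(), .before = 1)
}

#' Specify a synthetic Gaussian-Bayesian-network mixture
#'
#' A download-free generator emulating the statistical structure of the
#' benchmark: each component is a Gaussian Bayesian network (DAG, node
#' means, noise variances and regression weights) sampled ancestrally; the
#' mixture is the shuffled union. Useful defaults are provided by
#' [gbn_mixture_spec_2pop()] and [gbn_mixture_spec_4pop()].
#'
#' @param components List of components, each a list with fields `dag`
#'   (adjacency), `mu`, `sigma2`, `beta` (d x d matrix, `beta[j, k]` the
#'   weight of parent `k` on child `j`, non-zero only where `k -> j` in the
#'   DAG) and `n_cells`.
#' @param variable_names Node labels.
#' @return A list of class `unpbn_gbn_spec`.
#' @export
gbn_mixture_spec <- function(components, variable_names = NULL) {
  stopifnot(length(components) >= 1)
  d <- nrow(components[[1]]$dag)
  if (is.null(variable_names)) variable_names <- paste0("x", seq_len(d))
  for (cmp in components) {
    validate_dag(cmp$dag)
    stopifnot(length(cmp$mu) == d, length(cmp$sigma2) == d,
              all(cmp$sigma2 > 0), all(dim(cmp$beta) == d), cmp$n_cells >= 1)
    if (any(cmp$beta[t(cmp$dag) == 0] != 0))
      stop("beta[j, k] may be non-zero only where k -> j is an edge",
           call. = FALSE)
  }
  structure(list(components = components, variable_names = variable_names,
                 d = d),
            class = "unpbn_gbn_spec")
}

#' Implied joint Gaussian of one mixture component
#'
#' Closed-form mean and covariance of the ancestral-sampling distribution:
#' with `B[j, k]` the regression weights, `x - mu = B (x - mu) + e` gives
#' `Sigma = (I - B)^{-1} D (I - B)^{-T}` with `D = diag(sigma2)`.
#'
#' @param component One element of a [gbn_mixture_spec()]'s `components`.
#' @return List with `mean` and `covariance`.
#' @export
gbn_implied_moments <- function(component) {
  d <- length(component$mu)
  A <- solve(diag(d) - component$beta)
  list(mean = component$mu,
       covariance = A %*% diag(component$sigma2, d) %*% t(A))
}

#' Draw observations from a Gaussian-Bayesian-network mixture
#'
#' @param spec A [gbn_mixture_spec()].
#' @param seed Optional seed.
#' @return Tibble with columns `cell_id`, `true_label` and one column per
#'   variable, in shuffled order.
#' @export
generate_gbn_mixture <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "unpbn_gbn_spec"))
  if (!is.null(seed)) set.seed(seed)
  d <- spec$d
  out <- purrr::imap_dfr(spec$components, function(cmp, idx) {
    n <- cmp$n_cells
    ord <- topological_order(cmp$dag)
    X <- matrix(0, n, d)
    for (j in ord) {
      pa <- which(cmp$dag[, j] != 0)
      mean_j <- cmp$mu[j]
      if (length(pa) > 0)
        mean_j <- mean_j +
          (X[, pa, drop = FALSE] -
             matrix(cmp$mu[pa], n, length(pa), byrow = TRUE)) %*%
          cmp$beta[j, pa]
      X[, j] <- mean_j + rnorm(n, 0, sqrt(cmp$sigma2[j]))
    }
    colnames(X) <- spec$variable_names
    dplyr::mutate(tibble::as_tibble(X), true_label = idx, .before = 1)
  })
  out <- out[sample.int(nrow(out)), ]
  dplyr::mutate(out, cell_id = dplyr::row_number(), .before = 1)
}

topological_order <- function(adj) {
  d <- nrow(adj)
  ord <- integer(0)
  placed <- rep(FALSE, d)
  while (length(ord) < d) {
    ready <- which(!placed & colSums(adj[!placed, , drop = FALSE] != 0) == 0)
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  ord
}

#' Default two-component benchmark spec
#'
#' Two equally sized components over three species with distinct collider
#' topologies: `x1 -> x3 <- x2` with positive weights versus
#' `x2 -> x1 <- x3` with negative weights, plus a modest shift in mean
#' levels (subpopulations in real samples differ in both topology and
#' expression level). Weights of magnitude 1.5 give well-separated
#' correlation structures; node scales are concentration-like (standard
#' deviation `scale = 10` around a mean of 50 arbitrary units) so the data
#' dominate the fixed unit-precision prior the way raw single-cell
#' concentration measurements do, and the collision-node noise variance is
#' `2 * beta^2 * scale^2` so every node splits explained and unexplained
#' variance evenly.
#'
#' @param n_cells Cells per component.
#' @param beta Regression-weight magnitude.
#' @param mean_shift Difference in mean level between the components.
#' @param scale Within-component standard deviation of the root nodes.
#' @return A [gbn_mixture_spec()].
#' @export
gbn_mixture_spec_2pop <- function(n_cells = 200, beta = 1.5, mean_shift = 30,
                                  scale = 10) {
  d <- 3
  coll3 <- dag(d, rbind(c(1, 3), c(2, 3)))
  coll1 <- dag(d, rbind(c(2, 1), c(3, 1)))
  b1 <- matrix(0, d, d); b1[3, 1] <- beta; b1[3, 2] <- beta
  b2 <- matrix(0, d, d); b2[1, 2] <- -beta; b2[1, 3] <- -beta
  s_root <- scale^2
  s_child <- 2 * beta^2 * scale^2
  gbn_mixture_spec(list(
    list(dag = coll3, mu = rep(50, d), sigma2 = c(s_root, s_root, s_child),
         beta = b1, n_cells = n_cells),
    list(dag = coll1, mu = rep(50 + mean_shift, d),
         sigma2 = c(s_child, s_root, s_root), beta = b2,
         n_cells = n_cells)))
}

#' Default four-component benchmark spec
#'
#' Four components crossing the two collider topologies of
#' [gbn_mixture_spec_2pop()] with four mean levels, emulating the
#' two-stimuli-times-two-Mek-variants benchmark.
#'
#' @param n_cells Cells per component.
#' @param beta Regression-weight magnitude.
#' @param mean_shift Spacing of the component mean levels.
#' @param scale Within-component standard deviation of the root nodes.
#' @return A [gbn_mixture_spec()].
#' @export
gbn_mixture_spec_4pop <- function(n_cells = 100, beta = 1.5, mean_shift = 100,
                                  scale = 10) {
  d <- 3
  coll3 <- dag(d, rbind(c(1, 3), c(2, 3)))
  coll1 <- dag(d, rbind(c(2, 1), c(3, 1)))
  b1 <- matrix(0, d, d); b1[3, 1] <- beta; b1[3, 2] <- beta
  b2 <- matrix(0, d, d); b2[1, 2] <- -beta; b2[1, 3] <- -beta
  s_root <- scale^2
  s_child <- 2 * beta^2 * scale^2
  mk <- function(dg, b, s2, shift)
    list(dag = dg, mu = rep(50 + shift, 3), sigma2 = s2, beta = b,
         n_cells = n_cells)
  gbn_mixture_spec(list(
    mk(coll3, b1, c(s_root, s_root, s_child), 0),
    mk(coll1, b2, c(s_child, s_root, s_root), mean_shift),
    mk(coll3, b1, c(s_root, s_root, s_child), 2 * mean_shift),
    mk(coll1, b2, c(s_child, s_root, s_root), 3 * mean_shift)))
}
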