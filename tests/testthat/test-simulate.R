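# The reduced MAPK cascade simulator and the synthetic GBN-mixture generator.

test_that("noise-free simulation reproduces the deterministic trajectory", {
  set.seed(31)
  c1 <- simulate_cell("EGF", "wt", fd = 0)
  c2 <- simulate_cell("EGF", "wt", fd = 0)
  det <- mapk_trajectory("EGF", "wt")
  expect_equal(c1, det, ignore_attr = TRUE)
  expect_equal(c2, det, ignore_attr = TRUE)
})

test_that("totals are drawn Normal(mu, mu * fd) truncated at zero", {
  set.seed(32)
  totals <- t(replicate(400, attr(simulate_cell("EGF", "wt", fd = 0.2,
                                                times = 60), "totals")))
  # total Raf has mean 100 -> sd 20 at fd = 0.2; truncation is negligible
  expect_equal(mean(totals[, "raf"]), 100, tolerance = 0.05)
  expect_equal(sd(totals[, "raf"]), 20, tolerance = 0.15)
  expect_true(all(totals >= 0))
})

test_that("EGF responses are transient while NGF responses are sustained", {
  egf <- mapk_trajectory("EGF", "wt")
  ngf <- mapk_trajectory("NGF", "wt")
  expect_lt(egf$ppErk[egf$time_s == 600], 0.5 * max(egf$ppErk))
  expect_gt(ngf$ppErk[ngf$time_s == 600], 0.7 * max(ngf$ppErk))
  # late-time ordering between the stimuli
  expect_gt(ngf$ppErk[ngf$time_s == 600], egf$ppErk[egf$time_s == 600])
})

test_that("the Mek mutant attenuates ppErk while totals stay conserved", {
  totals <- c(raf = 100, mek = 300, erk = 500)
  wt <- mapk_trajectory("EGF", "wt", totals)
  mut <- mapk_trajectory("EGF", "mut", totals)
  expect_gt(max(wt$ppErk), 2 * max(mut$ppErk))
  # active forms never exceed the conserved totals
  expect_true(all(wt$ppErk >= 0 & wt$ppErk <= totals[["erk"]]))
  expect_true(all(wt$ppMek >= 0 & wt$ppMek <= totals[["mek"]]))
  expect_true(all(wt$pRaf >= 0 & wt$pRaf <= totals[["raf"]]))
})

test_that("expression noise propagates to a skewed observation cloud", {
  set.seed(33)
  pop <- simulate_mapk_population("EGF", "wt", n_cells = 150, fd = 0.7,
                                  times = 120)
  skew <- function(v) mean(((v - mean(v)) / sd(v))^3)
  # Gaussian noise on totals, non-Gaussian downstream: at least one of the
  # observed species is clearly skewed
  skews <- abs(vapply(pop[c("pRaf", "ppMek", "ppErk")], skew, numeric(1)))
  expect_gt(max(skews), 0.3)
})

test_that("mixture bookkeeping: sizes, proportions and grid errors", {
  des <- mixture_design(n_cells = 10, fd = 0, time_points = c(60, 120))
  mix <- build_mixture(des, 120, seed = 1)
  expect_equal(nrow(mix), 20)
  expect_equal(sort(table(mix$true_label), decreasing = TRUE),
               sort(table(c(rep("EGF.wt", 10), rep("NGF.wt", 10))),
                    decreasing = TRUE), ignore_attr = TRUE)
  # 1:9 abundance variant
  des19 <- mixture_design(proportions = c(0.1, 0.9), n_total = 350, fd = 0,
                          time_points = 60)
  expect_equal(sort(des19$subpopulations$n_cells), c(35, 315))
  expect_error(build_mixture(des, 90, seed = 1), "sampling grid")
  expect_error(mixture_design(proportions = c(0.5, 0.6), n_total = 100),
               "sum to 1")
  # shuffling is seed-reproducible
  expect_identical(build_mixture(des, 120, seed = 5),
                   build_mixture(des, 120, seed = 5))
  # four-subpopulation design crosses stimuli and Mek variants
  des4 <- mixture_design(mek_variants = c("wt", "mut"), n_cells = 2, fd = 0,
                         time_points = 60)
  mix4 <- build_mixture(des4, 60, seed = 2)
  expect_setequal(unique(mix4$true_label),
                  c("EGF.wt", "EGF.mut", "NGF.wt", "NGF.mut"))
})

test_that("GBN sampling matches the closed-form Gaussian moments", {
  # chain 1 -> 2 with beta 1 and unit variances: covariance [[1,1],[1,2]]
  b <- matrix(0, 2, 2); b[2, 1] <- 1
  cmp <- list(dag = dag(2, cbind(1, 2)), mu = c(0, 0), sigma2 = c(1, 1),
              beta = b, n_cells = 10000)
  mom <- gbn_implied_moments(cmp)
  expect_equal(mom$covariance, rbind(c(1, 1), c(1, 2)))
  x <- generate_gbn_mixture(gbn_mixture_spec(list(cmp)), seed = 41)
  S <- cov(as.matrix(x[, c("x1", "x2")]))
  # within 3 standard errors at n = 1e4 (se of a covariance ~ sqrt(2/n)*var)
  expect_lt(max(abs(S - mom$covariance)), 3 * sqrt(2 / 10000) * 2.5)
  # single component, empty dag: off-diagonal correlation vanishes
  cmp0 <- list(dag = dag(3), mu = rep(0, 3), sigma2 = rep(1, 3),
               beta = matrix(0, 3, 3), n_cells = 8000)
  x0 <- generate_gbn_mixture(gbn_mixture_spec(list(cmp0)), seed = 42)
  C0 <- cor(as.matrix(x0[, c("x1", "x2", "x3")]))
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.05)
})

test_that("opposite-sign weights cancel in the pooled correlation", {
  b1 <- matrix(0, 2, 2); b1[2, 1] <- 1
  b2 <- -b1
  mk <- function(b) list(dag = dag(2, cbind(1, 2)), mu = c(0, 0),
                         sigma2 = c(1, 1), beta = b, n_cells = 4000)
  x <- generate_gbn_mixture(gbn_mixture_spec(list(mk(b1), mk(b2))), seed = 43)
  X <- as.matrix(x[, c("x1", "x2")])
  pooled <- cor(X)[1, 2]
  c1 <- cor(X[x$true_label == 1, ])[1, 2]
  c2 <- cor(X[x$true_label == 2, ])[1, 2]
  expect_lt(abs(pooled), 0.1)
  expect_gt(c1, 0.5)
  expect_lt(c2, -0.5)
})

test_that("the mixture spec validates its weights against the DAG", {
  b <- matrix(0, 2, 2); b[1, 2] <- 1  # weight where no edge exists
  expect_error(gbn_mixture_spec(list(list(dag = dag(2, cbind(1, 2)),
                                          mu = c(0, 0), sigma2 = c(1, 1),
                                          beta = b, n_cells = 5))),
               "only where")
})
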