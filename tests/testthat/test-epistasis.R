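test_that("pair pruning removes local LD and low-occupancy pairs", {
  set.seed(121)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  G <- cbind(m1 = x, m2 = x,                       # perfect local LD
             m3 = rbinom(n, 1, 0.5),
             m4 = rbinom(n, 1, 0.02),              # fails MAF floor
             m5 = rbinom(n, 1, 0.5))
  pr <- prune_pairs(G, chrom = rep("c1", 5), pos = 1:5 * 1000)
  expect_true(sum(c(1, 2) %in% pr$markers) <= 1)   # one of the pair
  expect_false(4 %in% pr$markers)
  # a pair with a genotype class below min_class is excluded
  gi <- c(rep(0, 60), rep(1, 60))
  gj <- c(rep(0, 58), 1, 1, rep(1, 60))            # class (1,0) has 2 lines
  G2 <- cbind(gi, gj)
  pr2 <- prune_pairs(G2, chrom = c("c1", "c2"), pos = c(1, 1) * 1e6)
  expect_equal(nrow(pr2$pairs), 0)
  # hand-enumerated eligible pairs on a 6-marker panel
  set.seed(122)
  G6 <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  pr6 <- prune_pairs(G6, chrom = rep("c1", 6), pos = 1:6 * 1e6,
                     window_bp = 5e5)
  kept <- pr6$markers
  oracle <- NULL
  for (i in kept) for (j in kept) if (i < j) {
    tab <- table(factor(G6[, i], 0:1), factor(G6[, j], 0:1))
    if (min(tab) >= 3) oracle <- rbind(oracle, c(i, j))
  }
  expect_equal(unname(pr6$pairs), unname(oracle))
})

test_that("interaction LR matches the Gaussian closed form and logLik", {
  set.seed(123)
  n <- 50
  gi <- rbinom(n, 1, 0.5); gj <- rbinom(n, 1, 0.5)
  y <- 0.4 * gi - 0.3 * gj + 0.8 * gi * gj + rnorm(n)
  tst <- lr_interaction_test(y, gi, gj)
  m0 <- lm(y ~ gi + gj)
  m1 <- lm(y ~ gi + gj + gi:gj)
  expect_equal(tst$LR, n * log(sum(residuals(m0)^2) /
                                 sum(residuals(m1)^2)), tolerance = 1e-10)
  expect_equal(tst$LR, 2 * as.numeric(logLik(m1) - logLik(m0)),
               tolerance = 1e-8)
  expect_gte(tst$LR, 0)
  # exact interaction with no noise: LR at its cap, p at floor
  y2 <- gi * gj
  tst2 <- lr_interaction_test(y2, gi, gj)
  expect_gt(tst2$LR, 1000)
  expect_lt(tst2$p, 1e-200)
  # collinear interaction column: LR = 0, flagged
  tst3 <- lr_interaction_test(y, gi, gi)
  expect_equal(tst3$LR, 0)
  expect_equal(tst3$flag, "collinear")
})

test_that("bootstrap nulls preserve main effects and are reproducible", {
  set.seed(124)
  n <- 200
  gi <- rbinom(n, 1, 0.4); gj <- rbinom(n, 1, 0.5)
  y <- 1.5 * gi - 2 * gj + rnorm(n)
  a <- bootstrap_null(y, gi, gj, B = 30, seed = 7)
  b <- bootstrap_null(y, gi, gj, B = 30, seed = 7)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  expect_error(bootstrap_null(y, gi, gj, B = 0), "B must be")
  # responses built exactly from M0 with zero residual: every null LR 0
  y0 <- 2 * gi + 3 * gj
  expect_equal(bootstrap_null(y0, gi, gj, B = 10, seed = 8), rep(0, 10))
  # mean refitted main effects match the M0 estimates within 3 SE
  f0 <- lm.fit(cbind(1, gi, gj), y)
  s0 <- sqrt(sum(f0$residuals^2) / n)
  set.seed(125)
  coefs <- t(replicate(400, {
    ystar <- f0$fitted.values + rnorm(n, 0, s0)
    lm.fit(cbind(1, gi, gj), ystar)$coefficients[2:3]
  }))
  se <- apply(coefs, 2, sd) / sqrt(nrow(coefs))
  expect_lt(abs(mean(coefs[, 1]) - f0$coefficients[2]), 3 * se[1])
  expect_lt(abs(mean(coefs[, 2]) - f0$coefficients[3]), 3 * se[2])
})

test_that("the observed LR's rank among null LRs is uniform under H0", {
  set.seed(126)
  n <- 150
  B <- 49
  ranks <- replicate(400, {
    gi <- rbinom(n, 1, 0.4); gj <- rbinom(n, 1, 0.5)
    y <- rnorm(1) * gi + rnorm(1) * gj + rnorm(n)
    obs <- lr_interaction_test(y, gi, gj)$LR
    nulls <- bootstrap_null(y, gi, gj, B = B)
    sum(nulls < obs)   # 0..B
  })
  # chi-square goodness of fit over 10 equal rank bins
  bins <- table(cut(ranks, breaks = seq(-0.5, B + 0.5, length.out = 11)))
  gof <- chisq.test(bins, p = rep(0.1, 10))
  expect_gt(gof$p.value, 0.001)
})

test_that("mixture calibration recovers pi0 and df", {
  set.seed(127)
  # pure chi-square(1) nulls
  x <- rchisq(3000, 1)
  cal <- calibrate_mixture(x)
  expect_lt(cal$table$pi0[1], 0.02)
  expect_lt(abs(cal$table$df[1] - 1), 3 * sqrt(2 / 3000) + 0.02)
  # all-zero nulls: pi0 = 1, any positive LR gets the floor
  cal0 <- calibrate_mixture(rep(0, 500))
  expect_equal(cal0$table$pi0[1], 1)
  expect_lte(mixture_p(5, cal0), 1 / 501)
  expect_equal(rank_p(5, rep(0, 500)), 1 / 501)
  # 50/50 zero + chi-square(1)
  xm <- c(rep(0, 1500), rchisq(1500, 1))
  calm <- calibrate_mixture(xm)
  expect_lt(abs(calm$table$pi0[1] - 0.5), 0.03)
  expect_lt(abs(calm$table$df[1] - 1), 0.1)
  # empirical p decreasing in LR; p = 1 at LR = 0
  pv <- mixture_p(c(0, 0.5, 2, 8, 20), calm)
  expect_equal(pv[1], 1)
  expect_true(all(diff(pv) < 0))
  # sparse strata fall back to the pooled fit
  cs <- calibrate_mixture(x, strata = factor(c(rep("a", 2950),
                                               rep("b", 50))))
  b_row <- cs$table[cs$table$stratum == "b", ]
  expect_equal(b_row$pi0, cs$table$pi0[1])
})

test_that("pairwise M_eff and Bonferroni threshold follow the formulas", {
  # the printed worked example: M_eff 6236 at alpha 0.1
  expect_equal(0.1 / ((6236 * (6236 - 1)) / 2), 5.143824e-09,
               tolerance = 1e-6)
  # independent markers, n >> m: M_eff approaches m
  set.seed(128)
  G <- matrix(rbinom(500 * 40, 1, 0.5), 500, 40)
  pc <- meff_pairwise(G)
  expect_gte(pc$meff, 36)
  expect_equal(pc$threshold, 0.1 / (pc$meff * (pc$meff - 1) / 2))
  # duplicating every marker never loosens the correction: M_eff does not
  # drop, and the 99%-variance rule bounds the inflation below 2x (the
  # shrunken copies of the null spectrum can push extra eigenvalues over
  # the threshold, always in the conservative direction)
  pc2 <- meff_pairwise(cbind(G, G))
  expect_gte(pc2$meff, pc$meff)
  expect_lt(pc2$meff, 2 * pc$meff)
  expect_error(meff_pairwise(G[, 1, drop = FALSE]), "2 markers")
})

test_that("joint-MAF strata are the geometric-mean deciles", {
  s <- joint_maf_stratum(c(0.05, 0.5, 0.2), c(0.05, 0.5, 0.45))
  expect_equal(s, as.integer(cut(sqrt(c(0.0025, 0.25, 0.09)),
                                 seq(0, 0.5, length.out = 11),
                                 include.lowest = TRUE)))
})
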