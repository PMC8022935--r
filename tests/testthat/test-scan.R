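test_that("trait components realize their configured variance fractions", {
  p <- mid_panel()
  # pure noise when both focal and background are absent
  tr0 <- simulate_trait(p, 0, background = 0, h2_total = 0.5, seed = 91)
  expect_equal(mean(tr0$y), 0, tolerance = 1e-12)
  expect_equal(var(tr0$y), 0.5, tolerance = 1e-9)
  expect_equal(tr0$realized_r2, 0)
  # realized focal r2 averages the target over replicates (Monte Carlo)
  set.seed(92)
  r2 <- replicate(300, simulate_trait(p, 0.04, background = 50)$realized_r2)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 0.04), 3 * se)
  # determinism and domain restriction
  a <- simulate_trait(p, 0.05, seed = 93)
  b <- simulate_trait(p, 0.05, seed = 93)
  expect_identical(a$y, b$y)
  tra <- simulate_trait(p, 0.05, focal_domain = "arm", seed = 94)
  expect_equal(p$markers$domain[tra$focal], "arm")
  expect_error(simulate_trait(p, 0.05, background = 1e6), "eligible")
  expect_error(simulate_trait(p, 0.6, h2_total = 0.5), "h2_focal")
})

test_that("REML heritability matches a brute-force grid at n = 20", {
  set.seed(95)
  n <- 20
  g <- matrix(rbinom(n * 60, 1, 0.5), n, 60)
  A <- grm(g)
  ev <- eigen(A$A, symmetric = TRUE)
  for (h_true in c(0.2, 0.7)) {
    y <- drop(ev$vectors %*% (sqrt(h_true * pmax(ev$values, 0)) *
                                rnorm(n))) + sqrt(1 - h_true) * rnorm(n)
    fit <- fit_lmm_null(y, A)
    # independent oracle: dense-matrix REML over a 1e-4 grid
    X <- matrix(1, n, 1)
    ll <- vapply(seq(0, 0.9999, by = 1e-4), function(h) {
      V <- h * A$A + (1 - h) * diag(n)
      Vi <- solve(V)
      b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
      r <- y - X %*% b
      rss <- drop(t(r) %*% Vi %*% r)
      -0.5 * (determinant(V)$modulus + log(det(t(X) %*% Vi %*% X)) +
                (n - 1) * log(rss))
    }, numeric(1))
    h_grid <- seq(0, 0.9999, by = 1e-4)[which.max(ll)]
    expect_lt(abs(fit$h2 - h_grid), 2e-4)
    expect_gte(fit$sigma_g2, 0)
    expect_gte(fit$sigma_e2, 0)
  }
})

test_that("variance components hit their boundaries in limiting cases", {
  set.seed(96)
  p <- mid_panel()
  eng <- mid_engine()
  # unstructured y: heritability estimate near 0
  h0 <- replicate(10, fit_lmm_null(rnorm(eng$n), eng$eig)$h2)
  expect_lt(median(h0), 0.15)
  # y generated from A with vanishing noise: estimate near 1
  ev <- eng$eig
  y1 <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(eng$n))) +
    0.02 * rnorm(eng$n)
  expect_gt(fit_lmm_null(y1, ev)$h2, 0.9)
  expect_error(fit_lmm_null(rnorm(4), matrix(c(1, 2, 2, -3), 2)))
})

test_that("the scan reduces to OLS likelihood ratios at sigma_g2 = 0", {
  set.seed(97)
  p <- mid_panel()
  eng <- mid_engine()
  tr <- simulate_trait(p, 0.05, background = 50)
  sc <- scan_additive(tr$y, eng, h2 = 0)
  G <- p$genotypes
  for (j in c(tr$focal, 3, 500, 1200)) {
    if (sd(G[, j]) == 0) next
    m0 <- lm(tr$y ~ 1)
    m1 <- lm(tr$y ~ G[, j])
    lr <- 2 * (logLik(m1) - logLik(m0))
    expect_equal(sc$LR[j], as.numeric(lr), tolerance = 1e-8)
    expect_equal(sc$p[j], pchisq(as.numeric(lr), 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("scan statistics are invariant to y shifts and allele flips", {
  set.seed(98)
  p <- mid_panel()
  eng <- mid_engine()
  tr <- simulate_trait(p, 0.06, background = 50)
  sc1 <- scan_additive(tr$y, eng)
  sc2 <- scan_additive(tr$y + 5, eng)
  # invariant up to the REML optimizer's tolerance on the refitted h2
  expect_equal(sc1$p, sc2$p, tolerance = 1e-6)
  # polarity flip of a marker leaves p unchanged, flips beta
  G2 <- p$genotypes
  G2[, tr$focal] <- 1 - G2[, tr$focal]
  sc3 <- scan_additive(tr$y, scan_engine(G2, grm(p$genotypes)),
                       h2 = attr(sc1, "h2"))
  expect_equal(sc3$p[tr$focal], sc1$p[tr$focal], tolerance = 1e-9)
  expect_equal(sc3$beta[tr$focal], -sc1$beta[tr$focal], tolerance = 1e-9)
  # constant markers are flagged with p = 1
  G3 <- cbind(p$genotypes[, 1:50], const = 1)
  sc4 <- scan_additive(tr$y[seq_len(nrow(G3))],
                       scan_engine(G3, grm(p$genotypes[, 1:500])))
  expect_equal(sc4$p[51], 1)
  expect_equal(sc4$flag[51], "constant")
})

test_that("null-marker p-values are uniform (KS) and LOD = LR/2ln10", {
  set.seed(99)
  eng <- mid_engine()
  p <- mid_panel()
  # an unlinked permuted marker tested against fresh polygenic traits
  pv <- replicate(300, {
    tr <- simulate_trait(p, 0, background = 50)
    j <- sample(ncol(p$genotypes), 1)
    sc <- scan_additive(tr$y, eng)
    sc$p[j]
  })
  pv <- pv[!is.na(pv) & pv < 1]
  expect_gt(ks.test(pv, "punif")$p.value, 0.001)
  tr <- simulate_trait(p, 0.08, seed = 100)
  sc <- scan_additive(tr$y, eng)
  expect_equal(sc$LOD, sc$LR / (2 * log(10)))
  expect_true(all(sc$LR >= 0))
})

test_that("threshold calibration: shrinkage, permutation and fixed", {
  # near-independent markers: M_eff close to m
  set.seed(101)
  G <- matrix(rbinom(400 * 60, 1, 0.5), 400, 60)
  ms <- meff_shrinkage(G)
  expect_gte(ms$meff, 54)
  expect_lte(ms$meff, 60)
  cal <- calibrate_threshold(G, method = "shrinkage")
  expect_equal(cal$threshold, 0.1 / cal$meff)
  # duplicating every marker never loosens the correction (see the
  # redundancy check in test-epistasis.R for the bound)
  ms2 <- meff_shrinkage(cbind(G, G))
  expect_gte(ms2$meff, ms$meff)
  expect_lt(ms2$meff, 2 * ms$meff)
  # fixed method echoes its input
  calf <- calibrate_threshold(G, method = "fixed", fixed_p = 3.23e-6)
  expect_equal(calf$threshold, 3.23e-6)
  expect_error(calibrate_threshold(G, method = "nope"))
})
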