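test_that("GRM scaling contract: mean diagonal 1, PSD, forced 2x2 form", {
  # two lines opposite at all markers
  g <- rbind(c(0, 1, 0, 1, 0), c(1, 0, 1, 0, 1))
  A <- grm(g)
  expect_equal(A$A, matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)
  p <- small_panel()
  A <- grm(p$genotypes)
  expect_equal(mean(diag(A$A)), 1, tolerance = 1e-12)
  expect_equal(A$A, t(A$A))
  ev <- eigen(A$A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  expect_error(grm(matrix(1, 4, 5)), "monomorphic")
})

test_that("GRM equals the element-wise standardized dot product oracle", {
  set.seed(81)
  g <- matrix(rbinom(5 * 50, 1, 0.4), 5, 50)
  A <- grm(g)
  keep <- apply(g, 2, function(x) sd(x) > 0)
  xs <- scale(g[, keep])
  m <- sum(keep)
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    oracle[i, j] <- sum(xs[i, ] * xs[j, ]) / m
  oracle <- oracle / mean(diag(oracle))
  expect_equal(unname(A$A), oracle, tolerance = 1e-12)
  expect_equal(A$m, m)
})

test_that("ambiguous fractional dosages are excluded from the GRM", {
  set.seed(82)
  g <- matrix(rbinom(6 * 40, 1, 0.5), 6, 40)
  g2 <- g
  g2[1, 1:5] <- 0.5     # ambiguous: treated as missing, mean-imputed
  A <- grm(g2)
  gna <- g
  gna[1, 1:5] <- NA
  mu <- colMeans(gna, na.rm = TRUE)
  sd_ <- apply(gna, 2, sd, na.rm = TRUE)
  keep <- !is.na(sd_) & sd_ > 0
  xs <- sweep(sweep(gna[, keep], 2, mu[keep]), 2, sd_[keep], `/`)
  xs[is.na(xs)] <- 0
  oracle <- tcrossprod(xs) / sum(keep)
  oracle <- oracle / mean(diag(oracle))
  expect_equal(unname(A$A), unname(oracle), tolerance = 1e-12)
})

test_that("PCA of the GRM matches an SVD oracle and sums fractions to 1", {
  set.seed(83)
  g <- matrix(rbinom(10 * 80, 1, 0.5), 10, 80)
  A <- grm(g)
  pc <- grm_pca(A)
  expect_equal(sum(pc$var_frac), 1)
  expect_true(all(diff(pc$values) <= 1e-12))
  # eigenvalues via SVD of the scaled genotype matrix (independent route)
  keep <- apply(g, 2, function(x) sd(x) > 0)
  xs <- scale(g[, keep]) / sqrt(A$scaling)
  sv <- svd(xs / sqrt(sum(keep)))$d^2
  expect_equal(pc$values[seq_along(sv)], sv, tolerance = 1e-8)
  expect_error(grm_pca(matrix(c(1, NA, NA, 1), 2)), "non-finite")
})

test_that("two clusters of identical lines separate on PC1", {
  g <- rbind(matrix(rep(c(0, 0, 1, 1, 0, 1), 4), 4, byrow = TRUE),
             matrix(rep(c(1, 1, 0, 0, 1, 0), 4), 4, byrow = TRUE))
  pc <- grm_pca(grm(g))
  expect_gt(pc$var_frac[1], 0.99)
  expect_equal(length(unique(sign(round(pc$scores[, 1], 6)))), 2)
})

test_that("Hudson Fst limits and the ratio-of-averages estimator", {
  expect_lt(abs(hudson_fst(0.5, 10000, 0.5, 10000)$fst), 1e-3)
  expect_equal(hudson_fst(1, 50, 0, 50)$fst, 1)
  # ratio of averages, not average of ratios
  p1 <- c(0.2, 0.9); p2 <- c(0.25, 0.5)
  hf <- hudson_fst(p1, 100, p2, 100)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / 99 - p2 * (1 - p2) / 99
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(hf$fst, mean(num) / mean(den))
  expect_error(hudson_fst(0, 50, 0, 50), "undefined")
})

test_that("Fst is ~0 for a resplit sample and grows with divergence", {
  map <- tiny_map()
  fs <- simulate_founders(map, 300, seed = 84)
  des <- lineage_design(data.frame(
    label = c("anc", "d15", "d70"), parent = c(NA, "anc", "anc"),
    generations = c(25, 15, 70), outcross_p = 0.5,
    n_lines = c(80, 60, 60)))
  p <- simulate_structured_panel(fs, map, des, census = 200,
                                 selfing_gens = 5, seed = 85)
  a <- round(p$genotypes)
  freq <- function(pop) colMeans(a[p$population == pop, , drop = FALSE])
  n_anc <- 2 * sum(p$population == "anc")
  # random split of one population: differentiation ~ 0
  anc_idx <- which(p$population == "anc")
  s1 <- anc_idx[1:40]; s2 <- anc_idx[41:80]
  f0 <- hudson_fst(colMeans(a[s1, ]), 80, colMeans(a[s2, ]), 80)$fst
  expect_lt(abs(f0), 0.02)
  f15 <- hudson_fst(freq("anc"), n_anc, freq("d15"), 120)$fst
  f70 <- hudson_fst(freq("anc"), n_anc, freq("d70"), 120)$fst
  expect_gt(f15, f0)
  expect_gt(f70, f15)
})

test_that("haplotype entropy matches hand values and null expectations", {
  expect_equal(haplotype_entropy(matrix(rep(1 / 16, 16)))$S, 4)
  one <- matrix(c(1, rep(0, 15)))
  expect_equal(haplotype_entropy(one)$S, 0)
  two <- matrix(c(0.5, 0.5, 0.5, 0.5), 2)
  expect_equal(haplotype_entropy(two)$S, 2)
  # nulls: drift = equal founder frequencies; selection = distinct SNV haps
  hb <- haplotype_entropy(matrix(rep(1 / 16, 32), 16, 2), n_distinct = 4)
  expect_equal(hb$S_drift, 8)
  expect_equal(hb$S_selection, 4)
  # invariant to founder relabeling, bounded by log2(f * n)
  set.seed(86)
  pm <- matrix(rexp(16 * 3), 16, 3)
  pm <- sweep(pm, 2, colSums(pm), `/`)
  S <- haplotype_entropy(pm)$S
  expect_equal(haplotype_entropy(pm[sample(16), ])$S, S)
  # each population contributes at most log2(f) bits
  expect_lte(S, 3 * log2(16))
  expect_error(haplotype_entropy(matrix(c(-0.1, 1.1))), "negative")
  expect_error(haplotype_entropy(matrix(c(0.4, 0.4))), "sum to 1")
})

test_that("pairwise identity at segregating sites matches hand counts", {
  g <- rbind(a = c(0, 0, 1, 1, 0),
             b = c(0, 0, 1, 1, 0),
             c = c(1, 1, 0, 0, 1),
             d = c(0, 1, 1, 0, 0))
  pi_ <- pairwise_identity(g)
  get <- function(i, j) pi_$pairs$identity[pi_$pairs$i == i &
                                             pi_$pairs$j == j]
  expect_equal(get(1, 2), 1)     # identical lines
  expect_equal(get(1, 3), 0)     # complementary lines
  expect_equal(get(1, 4), 3 / 5) # hand count
  expect_equal(get(3, 4), 2 / 5)
  # grouped summaries by chromosome
  chrom <- c("c1", "c1", "c1", "c2", "c2")
  bc <- pairwise_identity(g, chrom)$by_chrom
  expect_equal(bc$mean[bc$chrom == "c1"],
               mean(c(1, 0, 0, 2 / 3, 2 / 3, 1 / 3)))
  expect_error(pairwise_identity(matrix(0, 3, 4)), "no segregating")
})
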