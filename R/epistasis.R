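#' Marker pruning and eligible pair sampling for interaction tests
#'
#' Prunes markers of strong local LD (no retained pair within
#' `window_bp` exceeds r2 of `r2_max`) and of low minor allele frequency,
#' then returns marker pairs in which all four two-locus homozygote
#' classes are present in at least `min_class` lines.
#'
#' @param G n x m homozygous dosage matrix (calls are rounded to 0/1).
#' @param r2_max local LD ceiling among retained markers (default 0.5).
#' @param maf_min minor-allele-frequency floor (default 0.05).
#' @param min_class minimum lines per two-locus genotype class (default 3).
#' @param window_bp physical span within which LD is considered local
#'   (needs `pos`); default 1 Mb.
#' @param chrom,pos optional per-marker coordinates; when absent, LD
#'   pruning considers the previous 50 retained markers.
#' @param n_pairs number of eligible pairs to return; when NULL and the
#'   pruned set is small (<= 200 markers) all eligible pairs are
#'   enumerated, otherwise pairs are sampled.
#' @param seed optional integer seed.
#' @return list with `markers` (retained indices into the columns of G)
#'   and `pairs` (two-column matrix of marker indices).
#' @export
prune_pairs <- function(G, r2_max = 0.5, maf_min = 0.05, min_class = 3,
                        window_bp = 1e6, chrom = NULL, pos = NULL,
                        n_pairs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- as.matrix(G)
  a <- round(G)
  p <- colMeans(a)
  maf_ok <- pmin(p, 1 - p) >= maf_min
  kept <- integer(0)
  for (j in which(maf_ok)) {
    if (length(kept)) {
      if (!is.null(pos)) {
        local <- kept[chrom[kept] == chrom[j] &
                        abs(pos[kept] - pos[j]) <= window_bp]
      } else local <- utils::tail(kept, 50L)
      if (length(local)) {
        r2 <- suppressWarnings(
          stats::cor(a[, j], a[, local, drop = FALSE]))^2
        if (any(r2 > r2_max, na.rm = TRUE)) next
      }
    }
    kept <- c(kept, j)
  }
  ok_pair <- function(i, j) {
    gi <- a[, i] > 0.5
    gj <- a[, j] > 0.5
    min(sum(!gi & !gj), sum(!gi & gj), sum(gi & !gj), sum(gi & gj)) >=
      min_class
  }
  pairs <- NULL
  if (is.null(n_pairs) && length(kept) <= 200L) {
    if (length(kept) >= 2L) {
      cmb <- t(utils::combn(kept, 2L))
      keep <- vapply(seq_len(nrow(cmb)), function(k)
        ok_pair(cmb[k, 1], cmb[k, 2]), logical(1))
      pairs <- cmb[keep, , drop = FALSE]
    } else pairs <- matrix(integer(0), 0, 2)
  } else {
    if (is.null(n_pairs)) n_pairs <- 1000L
    pairs <- matrix(integer(0), 0, 2)
    tries <- 0L
    while (nrow(pairs) < n_pairs && tries < 50L * n_pairs &&
           length(kept) >= 2L) {
      ij <- sample(kept, 2L)
      tries <- tries + 1L
      if (ok_pair(ij[1], ij[2]))
        pairs <- rbind(pairs, sort(ij))
    }
  }
  colnames(pairs) <- c("i", "j")
  list(markers = kept, pairs = pairs)
}

.ols_rss <- function(X, y) {
  f <- stats::lm.fit(X, y)
  sum(f$residuals^2)
}

#' Two-locus interaction likelihood-ratio test
#'
#' Tests the full model `y = b0 + bi gi + bj gj + bij gi gj + e` against
#' the additive null (no `bij` term) by likelihood ratio under Gaussian
#' maximum likelihood, so `LR = n log(RSS0 / RSS1)` exactly.  A collinear
#' interaction column gives LR = 0 with a flag.
#'
#' @param y phenotype vector.
#' @param gi,gj marker dosage vectors.
#' @return list with `LR`, `p` (chi-square(1) reference), `rss0`, `rss1`,
#'   `coef0` (null-model coefficients), `flag`.
#' @export
lr_interaction_test <- function(y, gi, gj) {
  n <- length(y)
  X0 <- cbind(1, gi, gj)
  X1 <- cbind(X0, gi * gj)
  f0 <- stats::lm.fit(X0, y)
  f1 <- stats::lm.fit(X1, y)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  flag <- ""
  if (is.na(f1$coefficients[4]) || f1$rank < 4L) {
    rss1 <- rss0
    flag <- "collinear"
  }
  lr <- max(n * (log(rss0) - log(max(rss1, 1e-300))), 0)
  list(LR = lr, p = stats::pchisq(lr, 1, lower.tail = FALSE),
       rss0 = rss0, rss1 = rss1, coef0 = f0$coefficients, flag = flag)
}

#' Bootstrap null likelihood-ratio statistics controlling for main effects
#'
#' Draws `B` parametric-bootstrap responses from the fitted additive null
#' model (fitted values plus Gaussian noise at the ML residual standard
#' deviation), refits both models to each, and returns the B null LRs.
#' Unlike trait permutation, this preserves the main effects by
#' construction and isolates the interaction term's null distribution.
#'
#' @param y,gi,gj as in [lr_interaction_test()].
#' @param B number of bootstrap replicates (default 100).
#' @param seed optional integer seed.
#' @return numeric vector of B null LRs.
#' @export
bootstrap_null <- function(y, gi, gj, B = 100, seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  X0 <- cbind(1, gi, gj)
  X1 <- cbind(X0, gi * gj)
  f0 <- stats::lm.fit(X0, y)
  fit0 <- f0$fitted.values
  s0 <- sqrt(sum(f0$residuals^2) / n)  # ML scale
  # degenerate null with zero residual variance: every resampled response
  # equals the fitted values exactly, so every null LR is 0
  if (s0 <= 1e-10 * max(stats::sd(y), .Machine$double.xmin))
    return(rep(0, B))
  vapply(seq_len(B), function(b) {
    ystar <- fit0 + stats::rnorm(n, 0, s0)
    r0 <- .ols_rss(X0, ystar)
    r1 <- .ols_rss(X1, ystar)
    max(n * (log(r0) - log(max(r1, 1e-300))), 0)
  }, numeric(1))
}

#' Chi-square mixture calibration of null interaction statistics
#'
#' Null interaction LRs follow a mixture of a point mass at zero and a
#' chi-square with df > 0.  The mixture is estimated from pooled null
#' statistics, optionally stratified (e.g. by joint-MAF decile): pi0 is
#' the fraction of null LRs at numerical zero and df is estimated from
#' the positive LRs by method of moments (mean of chi-square(d) = d).
#' Strata with fewer than `min_per_stratum` nulls fall back to the pooled
#' calibration.
#'
#' @param null_lrs pooled null LR statistics.
#' @param strata optional factor of the same length assigning each null
#'   LR to a stratum.
#' @param min_per_stratum minimum nulls per stratum (default 100).
#' @param zero_tol numerical-zero tolerance (default 1e-8).
#' @return object of class `mixture_calibration`: per-stratum (plus
#'   "pooled") `pi0` and `df`, and the pooled null count.
#' @export
calibrate_mixture <- function(null_lrs, strata = NULL,
                              min_per_stratum = 100, zero_tol = 1e-8) {
  stopifnot(length(null_lrs) >= 1)
  est <- function(x) {
    pi0 <- mean(x <= zero_tol)
    pos <- x[x > zero_tol]
    df <- if (length(pos)) mean(pos) else 1
    c(pi0 = pi0, df = df)
  }
  pooled <- est(null_lrs)
  tab <- data.frame(stratum = "pooled", pi0 = pooled["pi0"],
                    df = pooled["df"], n = length(null_lrs),
                    row.names = NULL)
  if (!is.null(strata)) {
    stopifnot(length(strata) == length(null_lrs))
    for (s in levels(factor(strata))) {
      x <- null_lrs[strata == s]
      e <- if (length(x) >= min_per_stratum) est(x) else pooled
      tab <- rbind(tab, data.frame(stratum = s, pi0 = e["pi0"],
                                   df = e["df"], n = length(x),
                                   row.names = NULL))
    }
  }
  structure(list(table = tab, n_pooled = length(null_lrs),
                 zero_tol = zero_tol), class = "mixture_calibration")
}

#' Convert interaction LRs to empirical p-values via the fitted mixture
#'
#' `p(LR) = (1 - pi0) * Pr(chisq_df >= LR)` for LR > 0 and p = 1 at
#' LR = 0, using the stratum's mixture parameters (pooled parameters when
#' the stratum is unknown).  The mixture provides parametric tail
#' extrapolation beyond the pooled null sample; p-values are guarded
#' against numerical underflow only.
#'
#' @param lr observed LR statistics.
#' @param calib a [calibrate_mixture()] object.
#' @param stratum optional stratum label(s) matching the calibration.
#' @param floor smallest returned p-value (numerical guard).
#' @return p-values in (0, 1].
#' @export
mixture_p <- function(lr, calib, stratum = NULL,
                      floor = .Machine$double.xmin) {
  stopifnot(inherits(calib, "mixture_calibration"))
  tab <- calib$table
  row <- function(s) {
    i <- match(as.character(s), tab$stratum)
    if (is.na(i)) i <- match("pooled", tab$stratum)
    i
  }
  idx <- if (is.null(stratum)) rep(match("pooled", tab$stratum),
                                   length(lr)) else
    vapply(rep_len(stratum, length(lr)), row, integer(1))
  p <- (1 - tab$pi0[idx]) *
    stats::pchisq(lr, tab$df[idx], lower.tail = FALSE)
  p[lr <= calib$zero_tol] <- 1
  pmin(pmax(p, floor), 1)
}

#' Rank-based empirical p-value against pooled nulls
#'
#' `(1 + #\{null >= LR\}) / (n_null + 1)`, floored at `1/(n_null + 1)`.
#' Provided as the non-parametric alternative to [mixture_p()]; it cannot
#' resolve p-values below its floor and is therefore unsuitable for
#' genome-wide thresholds far beyond `1/n_null`.
#'
#' @param lr observed LR statistics.
#' @param null_lrs pooled null LRs.
#' @return empirical p-values.
#' @export
rank_p <- function(lr, null_lrs) {
  vapply(lr, function(x) (1 + sum(null_lrs >= x)) /
           (length(null_lrs) + 1), numeric(1))
}

#' Effective number of tests and pairwise Bonferroni threshold
#'
#' Applies the Ledoit-Wolf shrinkage estimator to the marker correlation
#' matrix before eigendecomposition and defines M_eff as the number of
#' eigenvalues explaining at least 99% of the variance; the pairwise
#' interaction threshold is `alpha / (M_eff (M_eff - 1) / 2)`.
#'
#' @param G n x m dosage matrix (the pruned marker set).
#' @param alpha family-wise level (default 0.10).
#' @param var_explained variance fraction defining M_eff (default 0.99).
#' @return list of class `pair_calibration`: `meff`, `alpha`,
#'   `threshold`, `delta` (shrinkage intensity).
#' @export
meff_pairwise <- function(G, alpha = 0.10, var_explained = 0.99) {
  ms <- meff_shrinkage(G, var_explained)
  structure(list(meff = ms$meff, alpha = alpha,
                 threshold = alpha / (ms$meff * (ms$meff - 1) / 2),
                 delta = ms$delta, m = ms$m),
            class = "pair_calibration")
}

#' Joint minor-allele-frequency stratum of a marker pair
#'
#' Geometric mean of the two markers' MAFs, cut at the supplied decile
#' boundaries (the stratification used when calibrating the null
#' mixture).
#'
#' @param maf_i,maf_j minor allele frequencies of the two markers.
#' @param breaks decile boundaries (default: deciles of \[0, 0.5\]).
#' @return integer stratum labels.
#' @export
joint_maf_stratum <- function(maf_i, maf_j,
                              breaks = seq(0, 0.5, length.out = 11)) {
  jm <- sqrt(maf_i * maf_j)
  as.integer(cut(jm, breaks, include.lowest = TRUE))
}
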