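#' Trait simulation on panel genotypes
#'
#' Simulates a quantitative trait as the sum of a single focal-marker
#' effect, a polygenic background spread over a configurable number of
#' markers, and Gaussian noise, with all effect sizes drawn from the
#' standard normal and components rescaled so their realized population
#' variance fractions match the configuration (focal h2, total
#' heritability, remainder noise).  Focal and background loci are sampled
#' from markers with minor allele frequency above the floor.
#'
#' @param panel a [panel_realization], or a dosage matrix.
#' @param h2_focal variance fraction of the focal marker (0 allowed for
#'   null traits; must be < `h2_total`).
#' @param background number of background polygenic markers (0, 50, 100,
#'   500, ...).
#' @param h2_total total heritability (default 0.5).
#' @param maf_floor minor-allele-frequency floor for sampled loci.
#' @param focal_domain optional recombination-domain class ("arm",
#'   "center", "tip") restricting the focal marker (panels only).
#' @param focal_chrom optional chromosome restriction for the focal marker.
#' @param seed optional integer seed.
#' @return list of class `simulated_trait`: `y` (mean-centered phenotype),
#'   `focal` (marker index), `beta_focal`, `background` (indices),
#'   `h2_focal`, `realized_r2` (adjusted r2 of y on the focal marker).
#' @export
simulate_trait <- function(panel, h2_focal, background = 100,
                           h2_total = 0.5, maf_floor = 0.05,
                           focal_domain = NULL, focal_chrom = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- if (inherits(panel, "panel_realization")) panel$genotypes else
    as.matrix(panel)
  stopifnot(h2_focal >= 0, h2_focal < h2_total, h2_total <= 1)
  n <- nrow(G)
  p <- colMeans(G)
  maf <- pmin(p, 1 - p)
  elig <- which(maf >= maf_floor)
  pool <- elig
  if (!is.null(focal_domain) || !is.null(focal_chrom)) {
    stopifnot(inherits(panel, "panel_realization"))
    ok <- rep(TRUE, ncol(G))
    if (!is.null(focal_domain)) ok <- ok & panel$markers$domain %in% focal_domain
    if (!is.null(focal_chrom)) ok <- ok & panel$markers$chrom %in% focal_chrom
    pool <- intersect(elig, which(ok))
  }
  nb <- as.integer(background)
  if (length(pool) < 1L || length(elig) < nb + 1L)
    stop("not enough eligible markers after MAF screening")
  focal <- if (h2_focal > 0) sample(pool, 1L) else NA_integer_
  bg <- if (nb > 0) sample(setdiff(elig, focal), nb) else integer(0)

  comp <- function(x, target_var) {
    v <- stats::var(x)
    if (v <= 0 || target_var <= 0) return(rep(0, n))
    x <- x - mean(x)
    x * sqrt(target_var / v)
  }
  beta_focal <- if (h2_focal > 0) stats::rnorm(1) else 0
  yf <- if (h2_focal > 0) comp(G[, focal] * beta_focal, h2_focal) else
    rep(0, n)
  yb <- if (nb > 0) comp(drop(G[, bg, drop = FALSE] %*% stats::rnorm(nb)),
                         h2_total - h2_focal) else rep(0, n)
  ye <- comp(stats::rnorm(n), 1 - h2_total)
  y <- yf + yb + ye
  y <- y - mean(y)
  r2 <- if (h2_focal > 0)
    summary(stats::lm(y ~ G[, focal]))$adj.r.squared else 0
  structure(list(y = y, focal = focal, beta_focal = beta_focal,
                 background = bg, h2_focal = h2_focal, h2_total = h2_total,
                 realized_r2 = r2), class = "simulated_trait")
}

#' Fit the null linear mixed model y = mu + u + e
#'
#' Restricted-likelihood estimation of the variance components of
#' `u ~ N(0, sg2 A)`, `e ~ N(0, se2 I)` via a one-time eigendecomposition
#' of A and 1-D optimization over the heritability ratio
#' `h = sg2 / (sg2 + se2)`, boundary-clamped to \[0, 1\].
#'
#' @param y phenotype vector (an intercept is always fitted).
#' @param A a [relatedness_matrix], symmetric matrix, or the cached
#'   eigendecomposition from a [scan_engine()].
#' @return list with `h2`, `sigma_g2`, `sigma_e2`, `reml_loglik`.
#' @export
fit_lmm_null <- function(y, A) {
  eig <- .as_eig(A)
  n <- length(y)
  stopifnot(nrow(eig$vectors) == n)
  yt <- crossprod(eig$vectors, y)
  ot <- eig$ones
  obj <- function(h) .reml_ll(h, yt, ot, eig$values, n)
  op <- stats::optimize(obj, c(0, 1 - 1e-6), maximum = TRUE, tol = 1e-9)
  h <- op$maximum
  # check the boundary at exactly 0 (optimize never evaluates endpoints)
  if (obj(0) >= op$objective) {
    h <- 0
    op$objective <- obj(0)
  }
  d <- h * eig$values + (1 - h)
  w <- 1 / d
  a <- sum(w * ot * yt) / sum(w * ot^2)
  s2 <- sum(w * (yt - a * ot)^2) / (n - 1)
  list(h2 = h, sigma_g2 = h * s2, sigma_e2 = (1 - h) * s2,
       reml_loglik = op$objective)
}

# REML log-likelihood (up to a constant) for heritability ratio h
.reml_ll <- function(h, yt, ot, lam, n) {
  d <- h * lam + (1 - h)
  w <- 1 / d
  sxx <- sum(w * ot^2)
  a <- sum(w * ot * yt) / sxx
  rss <- sum(w * (yt - a * ot)^2)
  -0.5 * (sum(log(d)) + log(sxx) + (n - 1) * log(rss))
}

.as_eig <- function(A) {
  if (is.list(A) && !is.null(A$values) && !is.null(A$ones)) return(A)
  if (inherits(A, "relatedness_matrix")) A <- A$A
  ev <- eigen(A, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(ev$values))
    stop("relatedness matrix is not positive semi-definite")
  list(values = pmax(ev$values, 0), vectors = ev$vectors,
       ones = drop(crossprod(ev$vectors, rep(1, nrow(A)))))
}

#' Precomputed engine for repeated single-marker mixed-model scans
#'
#' Caches the eigendecomposition of A and the rotated genotype matrix so
#' that scanning many simulated traits on the same panel costs a few
#' matrix-vector products per trait.
#'
#' @param G n x m dosage matrix.
#' @param A a [relatedness_matrix] (default: [grm()] of `G`).
#' @return object of class `scan_engine`.
#' @export
scan_engine <- function(G, A = grm(G)) {
  G <- as.matrix(G)
  eig <- .as_eig(A)
  Gt <- crossprod(eig$vectors, G)
  structure(list(eig = eig, Gt = Gt, Gt2 = Gt * Gt, n = nrow(G),
                 m = ncol(G), markers = colnames(G)),
            class = "scan_engine")
}

#' Single-marker linear mixed-model genome scan
#'
#' Tests each marker for a fixed additive effect in
#' `y = X beta + Z u + e` with `u ~ N(0, sg2 A)`, `e ~ N(0, se2 I)`.
#' Variance components are estimated once under the no-marker null and
#' reused across markers; each marker is then tested by a likelihood-ratio
#' statistic of the GLS fits on the eigen-rotated data,
#' `LR = n log(RSS0/RSS1)`, with p from chi-square(1) and
#' `LOD = LR / (2 ln 10)`.  Constant markers get p = 1 and are flagged.
#'
#' @param y phenotype vector (mean-centered or not; an intercept is
#'   always included).
#' @param engine a [scan_engine()]; alternatively pass `G` (and optionally
#'   `A`) to build one on the fly.
#' @param G,A genotypes/relatedness, used only when `engine` is NULL.
#' @param h2 heritability ratio to condition on; default: REML estimate
#'   from the null model.
#' @return object of class `scan_result`: data.frame with columns
#'   `marker`, `beta`, `LR`, `LOD`, `p`, `flag`, plus attributes `h2`,
#'   `n`.
#' @export
scan_additive <- function(y, engine = NULL, G = NULL, A = NULL, h2 = NULL) {
  if (is.null(engine)) {
    if (is.null(G)) stop("supply a scan_engine or genotypes G")
    engine <- scan_engine(G, if (is.null(A)) grm(G) else A)
  }
  stopifnot(inherits(engine, "scan_engine"))
  n <- engine$n
  stopifnot(length(y) == n)
  if (is.null(h2)) h2 <- fit_lmm_null(y, engine$eig)$h2
  yt <- drop(crossprod(engine$eig$vectors, y))
  ot <- engine$eig$ones
  w <- 1 / (h2 * engine$eig$values + (1 - h2))
  s00 <- sum(w * ot^2)
  s0y <- sum(w * ot * yt)
  syy <- sum(w * yt^2)
  rss0 <- syy - s0y^2 / s00
  wo <- w * ot
  wy <- w * yt
  s0g <- drop(crossprod(engine$Gt, wo))
  sgy <- drop(crossprod(engine$Gt, wy))
  sgg <- drop(crossprod(engine$Gt2, w))
  varg <- sgg - s0g^2 / s00
  cross <- sgy - s0g * s0y / s00
  const <- varg <= 1e-10 * pmax(sgg, 1e-300)
  beta <- ifelse(const, 0, cross / pmax(varg, 1e-300))
  rss1 <- pmax(rss0 - ifelse(const, 0, cross^2 / pmax(varg, 1e-300)),
               1e-300)
  lr <- pmax(n * (log(rss0) - log(rss1)), 0)
  lr[const] <- 0
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  p[const] <- 1
  out <- data.frame(marker = if (is.null(engine$markers))
    seq_len(engine$m) else engine$markers,
    beta = beta, LR = lr, LOD = lr / (2 * log(10)), p = p,
    flag = ifelse(const, "constant", ""))
  attr(out, "h2") <- h2
  attr(out, "n") <- n
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Ledoit-Wolf shrinkage estimate of the effective number of tests
#'
#' Computes the marker correlation matrix spectrum through its n x n dual,
#' applies Ledoit-Wolf shrinkage toward the identity with the analytically
#' optimal intensity, and returns M_eff as the smallest number of leading
#' eigenvalues explaining at least `var_explained` of the total variance.
#'
#' @param G n x m dosage matrix (monomorphic markers are dropped).
#' @param var_explained variance fraction defining M_eff (default 0.99).
#' @return list with `meff`, `m` (polymorphic markers), `n`, `delta`
#'   (shrinkage intensity).
#' @export
meff_shrinkage <- function(G, var_explained = 0.99) {
  X <- as.matrix(G)
  n <- nrow(X)
  if (ncol(X) < 2L) stop("need at least 2 markers")
  if (n < 3L) stop("need at least 3 lines")
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2L, mu)^2))  # population sd => diag(R) = 1
  keep <- sd > 0
  X <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, sd[keep],
             `/`)
  m <- ncol(X)
  if (m < 2L) stop("need at least 2 polymorphic markers")
  lam <- pmax(eigen(tcrossprod(X), symmetric = TRUE,
                    only.values = TRUE)$values, 0) / n
  tr_s2 <- sum(lam^2)
  d2 <- tr_s2 / m - 1                     # ||S - I||^2 (normalized), mu = 1
  row2 <- rowSums(X^2)
  b2bar <- sum(row2^2) / (n^2 * m) - tr_s2 / (n * m)
  b2 <- min(max(b2bar, 0), max(d2, 0))
  delta <- if (d2 <= 0) 0 else b2 / d2
  lam_full <- c(lam, rep(0, max(0L, m - length(lam))))[seq_len(m)]
  lam_s <- (1 - delta) * lam_full + delta  # shrunk spectrum; trace = m
  lam_s <- sort(lam_s, decreasing = TRUE)
  meff <- which(cumsum(lam_s) >= var_explained * sum(lam_s))[1]
  list(meff = as.integer(meff), m = m, n = n, delta = delta)
}

#' Genome-wide significance threshold calibration
#'
#' Three routes to a genome-wide p-value threshold at family-wise level
#' `alpha`: `"shrinkage"` applies the Ledoit-Wolf shrinkage-eigenvalue
#' M_eff estimator per chromosome, sums the per-chromosome effective test
#' counts and Bonferroni-corrects (`alpha / M_eff`); `"permutation"` scans
#' `n_perm` null phenotypes drawn from the fitted relatedness structure
#' (`y* ~ N(0, h2 A + (1 - h2) I)`, so the calibration reflects LD,
#' relatedness and trait heritability together) and takes the `alpha`
#' quantile of the minimum p-value — the exact-FWER analogue of
#' heritability-aware effective-test estimators; `"fixed"` passes a user
#' threshold through (default 3.23e-6, the calibrated threshold
#' appropriate when emulating the real 763-line panel).  Any threshold can
#' be expressed as an implied effective test count `alpha / threshold`
#' (reported as `meff_implied` for the permutation method).
#'
#' @param G n x m dosage matrix.
#' @param A relatedness (permutation method; default [grm()] of G).
#' @param method "shrinkage", "permutation" or "fixed".
#' @param alpha family-wise significance level (default 0.10).
#' @param chrom per-marker chromosome labels (shrinkage method; default:
#'   one block).
#' @param n_perm permutations for the permutation method (>= 100).
#' @param h2_null heritability ratio of the permutation null model.
#' @param fixed_p threshold returned by the fixed method.
#' @param engine optional [scan_engine()] reused by the permutation method.
#' @return list of class `calibration`: `method`, `alpha`, `meff` (NA for
#'   permutation/fixed), `threshold`.
#' @export
calibrate_threshold <- function(G, A = NULL, method = c("shrinkage",
                                                        "permutation",
                                                        "fixed"),
                                alpha = 0.10, chrom = NULL, n_perm = 100,
                                h2_null = 0.5, fixed_p = 3.23e-6,
                                engine = NULL) {
  method <- match.arg(method)
  if (method == "fixed")
    return(structure(list(method = method, alpha = alpha, meff = NA,
                          threshold = fixed_p), class = "calibration"))
  G <- as.matrix(G)
  if (method == "shrinkage") {
    if (is.null(chrom)) chrom <- rep("all", ncol(G))
    meff <- sum(vapply(unique(chrom), function(ch)
      meff_shrinkage(G[, chrom == ch, drop = FALSE])$meff, integer(1)))
    meff <- max(1L, min(meff, ncol(G)))
    return(structure(list(method = method, alpha = alpha, meff = meff,
                          threshold = alpha / meff), class = "calibration"))
  }
  stopifnot(n_perm >= 100)
  if (is.null(engine)) engine <- scan_engine(G, if (is.null(A)) grm(G)
                                             else A)
  ev <- engine$eig
  sdg <- sqrt(h2_null * ev$values)
  minp <- vapply(seq_len(n_perm), function(i) {
    y <- drop(ev$vectors %*% (sdg * stats::rnorm(engine$n))) +
      sqrt(1 - h2_null) * stats::rnorm(engine$n)
    min(scan_additive(y, engine)$p)
  }, numeric(1))
  thr <- stats::quantile(minp, alpha, names = FALSE)
  structure(list(method = method, alpha = alpha,
                 meff = NA, meff_implied = alpha / thr, threshold = thr),
            class = "calibration")
}
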