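#' Additive genetic relatedness matrix (GRM)
#'
#' Computes A = X X' / m from marker dosages, with each marker column
#' scaled to mean 0 and variance 1 and A rescaled to a mean diagonal value
#' of 1.  Ambiguous fractional dosages (strictly between 0 and 1, e.g.
#' residual heterozygotes or uncertain imputations) are treated as missing
#' and mean-imputed after scaling; monomorphic markers are excluded before
#' scaling.
#'
#' @param dosages n x m matrix of dosages in \[0,1\] (lines in rows).
#' @param drop_ambiguous treat dosages strictly inside (0,1) as missing.
#' @return object of class `relatedness_matrix`: list with `A` (n x n),
#'   `m` (markers used) and `scaling` (the rescaling factor applied).
#' @export
grm <- function(dosages, drop_ambiguous = TRUE) {
  x <- as.matrix(dosages)
  stopifnot(nrow(x) >= 2)
  if (drop_ambiguous) x[x > 0 & x < 1] <- NA
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sd) & sd > 0
  if (!any(keep)) stop("all markers are monomorphic")
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L, sd[keep],
              `/`)
  xs[is.na(xs)] <- 0  # mean imputation after scaling
  m <- sum(keep)
  A <- tcrossprod(xs) / m
  sc <- mean(diag(A))
  A <- A / sc
  structure(list(A = A, m = m, scaling = sc), class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat("<relatedness_matrix> ", nrow(x$A), " lines, ", x$m,
      " markers, mean diagonal 1\n", sep = "")
  invisible(x)
}

#' Principal components of a relatedness matrix
#'
#' Eigendecomposition of A, returning components in decreasing eigenvalue
#' order with variance fractions summing to 1.
#'
#' @param A a [relatedness_matrix] or a symmetric numeric matrix.
#' @return list with `values` (eigenvalues, negatives clamped to 0),
#'   `vectors`, `scores` (vectors scaled by sqrt(values)) and
#'   `var_frac`.
#' @export
grm_pca <- function(A) {
  if (inherits(A, "relatedness_matrix")) A <- A$A
  if (!all(is.finite(A))) stop("non-finite entries in relatedness matrix")
  e <- eigen(A, symmetric = TRUE)
  v <- pmax(e$values, 0)
  list(values = v, vectors = e$vectors,
       scores = sweep(e$vectors, 2L, sqrt(v), `*`),
       var_frac = v / sum(v))
}

#' Hudson's Fst estimator
#'
#' Per-site numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; the multi-site estimate is the ratio
#' of averages (mean numerator over mean denominator), not the average of
#' per-site ratios.
#'
#' @param p1,p2 per-site allele frequencies in the two populations.
#' @param n1,n2 sample sizes (haploid counts; >= 2).
#' @return list with `fst` (ratio of averages), `num`, `den` (per site).
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  stopifnot(length(p1) == length(p2), n1 >= 2, n2 >= 2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (all(den == 0)) stop("denominator zero at all sites: Fst undefined")
  list(fst = mean(num) / mean(den), num = num, den = den)
}

#' Founder-haplotype entropy of windowed frequency tables
#'
#' Shannon entropy S = -sum_ij p_ij log2 p_ij of founder-haplotype
#' frequencies p (founder i, population j), summed over populations, with
#' 0 log 0 = 0.  Also returns the expectations under two nulls: pure
#' drift (equal frequency of all `f` founder haplotypes in every
#' population) and selection of the distinct SNV haplotypes observed in
#' the window (`n_distinct` equal frequencies).
#'
#' @param p matrix of frequencies, founders x populations; each column
#'   must sum to 1 (within 1e-9).
#' @param n_distinct number of distinct observed SNV haplotypes in the
#'   window (for the selection null; default: number of founders).
#' @return list with `S`, `S_drift`, `S_selection` (bits).
#' @export
haplotype_entropy <- function(p, n_distinct = nrow(p)) {
  p <- as.matrix(p)
  if (any(p < 0)) stop("negative frequencies")
  cs <- colSums(p)
  if (any(abs(cs - 1) > 1e-9)) stop("per-population frequencies must sum to 1")
  ent <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  list(S = sum(apply(p, 2L, ent)),
       S_drift = ncol(p) * log2(nrow(p)),
       S_selection = ncol(p) * log2(n_distinct))
}

#' Pairwise identity at segregating sites
#'
#' Fraction of matching calls between pairs of lines, at sites segregating
#' among the supplied lines, with grouped mean and standard error (e.g. by
#' chromosome).
#'
#' @param dosages n x m dosage matrix; calls are rounded to alleles.
#' @param chrom optional per-marker chromosome labels for per-chromosome
#'   summaries.
#' @return list with `pairs` (data.frame i, j, identity over all
#'   segregating sites) and, when `chrom` is given, `by_chrom`
#'   (data.frame chrom, mean, se over pairs).
#' @export
pairwise_identity <- function(dosages, chrom = NULL) {
  a <- round(as.matrix(dosages))
  n <- nrow(a)
  stopifnot(n >= 2)
  seg <- apply(a, 2L, function(x) length(unique(x[!is.na(x)])) > 1L)
  if (!any(seg)) stop("no segregating sites")
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idf <- function(cols) {
    vapply(seq_len(nrow(pr)), function(k)
      mean(a[pr[k, 1], cols] == a[pr[k, 2], cols], na.rm = TRUE),
      numeric(1))
  }
  pairs <- data.frame(i = pr[, 1], j = pr[, 2], identity = idf(which(seg)))
  out <- list(pairs = pairs)
  if (!is.null(chrom)) {
    stopifnot(length(chrom) == ncol(a))
    out$by_chrom <- do.call(rbind, lapply(unique(chrom), function(ch) {
      cols <- which(seg & chrom == ch)
      if (!length(cols)) return(NULL)
      v <- idf(cols)
      data.frame(chrom = ch, mean = mean(v),
                 se = stats::sd(v) / sqrt(length(v)))
    }))
  }
  out
}
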