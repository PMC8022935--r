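#' Transition/transversion ratio
#'
#' Ratio of transitions (A<->G, C<->T) to transversions among diallelic
#' substitutions.  New laboratory-derived mutations typically show a lower
#' Ts/Tv than standing variation.
#'
#' @param x a data.frame with `ref` and `alt` single-base columns (e.g. a
#'   mutation registry or `variant_table$info`), or a [variant_table].
#' @return the Ts/Tv ratio; an error is signalled when no transversions
#'   are present (ratio undefined).
#' @examples
#' titv_ratio(data.frame(ref = c("A", "C", "A", "G"),
#'                       alt = c("G", "T", "C", "T")))  # 1.0
#' @export
titv_ratio <- function(x) {
  if (inherits(x, "variant_table")) x <- x$info
  stopifnot(all(c("ref", "alt") %in% names(x)))
  ts <- (x$ref == "A" & x$alt == "G") | (x$ref == "G" & x$alt == "A") |
    (x$ref == "C" & x$alt == "T") | (x$ref == "T" & x$alt == "C")
  n_tv <- sum(!ts)
  if (n_tv == 0L) stop("no transversions: Ts/Tv undefined")
  sum(ts) / n_tv
}

#' Gini coefficient of per-window counts
#'
#' Standard Gini inhomogeneity measure of a non-negative count vector:
#' mean absolute pairwise difference divided by twice the mean.  Equal
#' counts give 0; all mass in one of k windows gives (k-1)/k.
#'
#' @param counts non-negative counts, not all zero.
#' @return value in \[0, (k-1)/k\].
#' @export
gini_coefficient <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(counts < 0) || any(is.na(counts)))
    stop("counts must be non-negative and non-missing")
  if (all(counts == 0)) stop("all counts are zero: Gini undefined")
  n <- length(counts)
  s <- sort(counts)
  # mean abs difference via the sorted-sum identity; O(n log n)
  mad2 <- 2 * sum((2 * seq_len(n) - n - 1) * s) / n^2
  mad2 / (2 * mean(s))
}

#' X-chromosome depletion of new mutations relative to standing variation
#'
#' Builds the 2x2 table {new, SGV} x {X, autosomes} and tests it with
#' Fisher's exact test; reports per-chromosome ratios of new mutations to
#' standing variants normalized by the same ratio on the remaining
#' chromosomes, so 1 means no depletion and values below 1 mean fewer new
#' mutations than expected from standing variation.
#'
#' @param new_counts,sgv_counts named per-chromosome counts of new
#'   mutations and standing variants (same names; all SGV counts > 0).
#' @param x_chrom name of the X chromosome in the count vectors.
#' @return list with `ratio` (named per-chromosome normalized ratios),
#'   `ratio_x` (the X value), `table` (the 2x2 X-vs-autosomes table),
#'   `odds_ratio` and `p_value` (Fisher exact, two-sided).
#' @export
x_depletion_test <- function(new_counts, sgv_counts, x_chrom = "X") {
  stopifnot(length(new_counts) == length(sgv_counts),
            !is.null(names(new_counts)),
            all(names(new_counts) %in% names(sgv_counts)))
  sgv_counts <- sgv_counts[names(new_counts)]
  if (any(sgv_counts <= 0)) stop("all SGV counts must be positive")
  if (!x_chrom %in% names(new_counts)) stop("X chromosome not found")
  ratio <- vapply(names(new_counts), function(ch) {
    oth <- setdiff(names(new_counts), ch)
    (new_counts[[ch]] / sgv_counts[[ch]]) /
      (sum(new_counts[oth]) / sum(sgv_counts[oth]))
  }, numeric(1))
  auto <- setdiff(names(new_counts), x_chrom)
  tab <- matrix(c(new_counts[[x_chrom]], sum(new_counts[auto]),
                  sgv_counts[[x_chrom]], sum(sgv_counts[auto])),
                2, 2, dimnames = list(c("X", "autosomes"),
                                      c("new", "SGV")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the X-vs-autosomes table")
  ft <- stats::fisher.test(tab)
  list(ratio = ratio, ratio_x = ratio[[x_chrom]], table = tab,
       odds_ratio = tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]),
       p_value = ft$p.value)
}
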