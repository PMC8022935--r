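#' Simulate founder haplotypes with a skewed allele-frequency spectrum
#'
#' Draws diallelic marker haplotypes for a set of inbred founders.  The
#' founder allele-count spectrum is configurable: counts k (number of
#' founders carrying the alternate allele, 1..n_founders-1) are sampled with
#' probability proportional to `k^(-sfs_skew)`, so larger `sfs_skew` gives a
#' stronger excess of founder singletons, as seen in panels founded from
#' wild isolates where most variants are rare.  Every emitted marker is
#' segregating among the founders by construction.
#'
#' @param map a [genetic_map].
#' @param m_markers markers per chromosome (single count, recycled).
#' @param n_founders number of founders (default 16).
#' @param sfs_skew exponent of the allele-count spectrum (0 = uniform over
#'   counts, 1 = neutral-like 1/k, larger = more singletons).
#' @param allele_count optional fixed alternate-allele count forced at every
#'   site (overrides `sfs_skew`), e.g. 8 for founder MAF 0.5 throughout.
#' @param ld_block_bp mean length (bp) of founder haplotype-sharing blocks.
#'   Wild isolates of a predominantly selfing species share haplotypes over
#'   hundreds of kb, which is what gives a derived panel its linkage
#'   disequilibrium; within a block the sets of founders carrying minor
#'   alleles at nearby markers are strongly correlated, and the sharing
#'   structure is redrawn at exponentially spaced block boundaries.  Set to
#'   NULL for independent markers (no founder LD).
#' @param perturb per-marker probability of a small perturbation of the
#'   local founder-sharing order, giving gradual within-block LD decay.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @return An object of class `founder_set`: list with `haplotypes`
#'   (n_founders x m 0/1 matrix), `markers` (data.frame chrom, pos, id) and
#'   `founders` (labels F01..).
#' @examples
#' fs <- simulate_founders(default_genetic_map(), 50, seed = 1)
#' range(colSums(fs$haplotypes))  # always segregating
#' @export
simulate_founders <- function(map, m_markers, n_founders = 16L,
                              sfs_skew = 1.3, allele_count = NULL,
                              ld_block_bp = 2.5e5, perturb = 0.15,
                              seed = NULL) {
  stopifnot(inherits(map, "genetic_map"), m_markers >= 2, n_founders >= 2)
  if (!is.null(seed)) set.seed(seed)
  markers <- do.call(rbind, lapply(map$chromosomes, function(ch) {
    pos <- sort(sample.int(map$lengths[[ch]] - 1L, m_markers)) + 0
    data.frame(chrom = ch, pos = as.numeric(pos))
  }))
  markers$id <- paste0(markers$chrom, "_", markers$pos)
  m <- nrow(markers)
  if (is.null(allele_count)) {
    k <- seq_len(n_founders - 1L)
    counts <- sample(k, m, replace = TRUE, prob = k^(-sfs_skew))
  } else {
    stopifnot(allele_count >= 1, allele_count <= n_founders - 1L)
    counts <- rep.int(as.integer(allele_count), m)
  }
  hap <- matrix(0L, n_founders, m)
  if (is.null(ld_block_bp) || ld_block_bp <= 0) {
    for (j in seq_len(m)) hap[sample.int(n_founders, counts[j]), j] <- 1L
  } else {
    # minor-allele carrier sets are prefixes of a founder-sharing order that
    # is reshuffled at block boundaries and gently perturbed within blocks
    ord <- sample.int(n_founders)
    for (j in seq_len(m)) {
      new_chrom <- j == 1L || markers$chrom[j] != markers$chrom[j - 1L]
      d <- if (new_chrom) Inf else markers$pos[j] - markers$pos[j - 1L]
      if (stats::runif(1) < 1 - exp(-d / ld_block_bp)) {
        ord <- sample.int(n_founders)
      } else if (stats::runif(1) < perturb) {
        i <- sample.int(n_founders - 1L, 1L)
        ord[c(i, i + 1L)] <- ord[c(i + 1L, i)]
      }
      hap[ord[seq_len(counts[j])], j] <- 1L
    }
  }
  rownames(hap) <- sprintf("F%02d", seq_len(n_founders))
  colnames(hap) <- markers$id
  structure(list(haplotypes = hap, markers = markers,
                 founders = rownames(hap)),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat("<founder_set> ", nrow(x$haplotypes), " founders x ",
      ncol(x$haplotypes), " markers\n", sep = "")
  invisible(x)
}
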