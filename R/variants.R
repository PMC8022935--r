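#' Variant table: diallelic SNVs with site annotations and sample calls
#'
#' A light container for hard-filterable variant calls: a site table with
#' the GATK-style annotations used by the filters (QUAL, MQ, DP, QD, SOR,
#' ReadPosRankSum) and a per-sample genotype matrix coded 0 (hom-ref),
#' 1 (het), 2 (hom-alt), NA (missing).
#'
#' @param info data.frame with columns chrom, pos, ref, alt and any of
#'   QUAL, MQ, DP, QD, SOR, ReadPosRankSum (missing annotations may be NA).
#' @param geno integer matrix, sites x samples, codes 0/1/2/NA; column
#'   names are sample names.
#' @return object of class `variant_table`.
#' @export
variant_table <- function(info, geno) {
  info <- as.data.frame(info)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(info)))
  if (any(info$ref == info$alt)) stop("ref and alt alleles must differ")
  for (a in c("QUAL", "MQ", "DP", "QD", "SOR", "ReadPosRankSum"))
    if (is.null(info[[a]])) info[[a]] <- NA_real_
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == nrow(info))
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(info$id)) info$id <- paste0(info$chrom, "_", info$pos)
  structure(list(info = info, geno = geno,
                 samples = colnames(geno)), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", nrow(x$info), " sites x ", ncol(x$geno),
      " samples\n", sep = "")
  invisible(x)
}

n_sites <- function(vt) nrow(vt$info)

subset_variants <- function(vt, i) {
  variant_table(vt$info[i, , drop = FALSE], vt$geno[i, , drop = FALSE])
}

#' Hard-filter criteria for founder SNVs and new-mutation candidates
#'
#' Named threshold sets matching the stringent founder-SNV filter
#' (QUAL > 1000, < 50% heterozygous or missing founder calls, MQ > 40,
#' absolute depth deviation from the median below its 0.995 batch
#' quantile, SOR < 3, QD >= 15) and the conservative new-mutation
#' candidate filter (MQ >= 40, QD >= 5, DP >= 30, positive depth deviation
#' below its 0.95 batch quantile, SOR < 4, ReadPosRankSum > -4,
#' heterozygote frequency < 10%, at least 3 homozygote carriers, and no
#' missing calls).  Depth-quantile thresholds are resolved against the
#' supplied record batch on first use and frozen into the returned
#' criteria (`dp_dev_max`), so that re-filtering a retained set with the
#' returned criteria is a no-op.
#'
#' @param qual_min,founder_het_miss_max,mq_min,dp_dev_quantile,sor_max,qd_min
#'   founder-SNV thresholds.
#' @return a list of class `filter_criteria`.
#' @export
founder_filter_criteria <- function(qual_min = 1000,
                                    founder_het_miss_max = 0.5,
                                    mq_min = 40, dp_dev_quantile = 0.995,
                                    sor_max = 3, qd_min = 15) {
  structure(list(set = "founder_snv", qual_min = qual_min,
                 founder_het_miss_max = founder_het_miss_max,
                 mq_min = mq_min, dp_dev_quantile = dp_dev_quantile,
                 dp_dev_max = NULL, sor_max = sor_max, qd_min = qd_min),
            class = "filter_criteria")
}

#' @rdname founder_filter_criteria
#' @param dp_min,rprs_min,het_freq_max,min_hom_carriers new-mutation
#'   thresholds (see Description).
#' @export
new_mutation_criteria <- function(mq_min = 40, qd_min = 5, dp_min = 30,
                                  dp_dev_quantile = 0.95, sor_max = 4,
                                  rprs_min = -4, het_freq_max = 0.10,
                                  min_hom_carriers = 3) {
  structure(list(set = "new_mutation", mq_min = mq_min, qd_min = qd_min,
                 dp_min = dp_min, dp_dev_quantile = dp_dev_quantile,
                 dp_dev_max = NULL, sor_max = sor_max, rprs_min = rprs_min,
                 het_freq_max = het_freq_max,
                 min_hom_carriers = min_hom_carriers),
            class = "filter_criteria")
}

# a missing annotation fails its criterion (conservative)
.fails <- function(value, ok) is.na(value) | !ok

.collect_reasons <- function(fail_list) {
  nm <- names(fail_list)
  apply(do.call(cbind, fail_list), 1L, function(f)
    paste(nm[which(f)], collapse = ";"))
}

#' Hard-filter founder SNVs
#'
#' Applies the stringent founder-SNV criteria (see
#' [founder_filter_criteria()]).  The depth criterion is evaluated against
#' the empirical distribution of `|DP - median(DP)|` across the supplied
#' records unless the criteria object already carries a frozen threshold.
#'
#' @param vt a [variant_table].
#' @param founders character vector of founder sample names in `vt`.
#' @param criteria a [founder_filter_criteria()] object.
#' @return list with `retained` (variant_table), `rejected` (data.frame of
#'   site id and semicolon-separated failing criteria) and `criteria`
#'   (with the resolved depth threshold frozen in).
#' @export
filter_founder_snvs <- function(vt, founders,
                                criteria = founder_filter_criteria()) {
  stopifnot(inherits(vt, "variant_table"),
            all(founders %in% vt$samples))
  cr <- criteria
  info <- vt$info
  if (is.null(cr$dp_dev_max)) {
    dev <- abs(info$DP - stats::median(info$DP, na.rm = TRUE))
    cr$dp_dev_max <- stats::quantile(dev, cr$dp_dev_quantile, na.rm = TRUE,
                                     names = FALSE)
  }
  fg <- vt$geno[, founders, drop = FALSE]
  het_miss <- rowMeans(fg == 1L | is.na(fg))
  dev <- abs(info$DP - stats::median(info$DP, na.rm = TRUE))
  fails <- list(
    QUAL = .fails(info$QUAL, info$QUAL > cr$qual_min),
    founder_het_missing = het_miss >= cr$founder_het_miss_max,
    MQ = .fails(info$MQ, info$MQ > cr$mq_min),
    DP_deviation = .fails(info$DP, dev < cr$dp_dev_max),
    SOR = .fails(info$SOR, info$SOR < cr$sor_max),
    QD = .fails(info$QD, info$QD >= cr$qd_min))
  bad <- Reduce(`|`, fails)
  list(retained = subset_variants(vt, !bad),
       rejected = data.frame(id = info$id[bad],
                             reason = .collect_reasons(fails)[bad]),
       criteria = cr)
}

#' Filter candidate new mutations
#'
#' Applies the conservative new-mutation candidate criteria (see
#' [new_mutation_criteria()]) to records absent from the founder variant
#' set.  Sites flagged in `external_mask` (known variable in an
#' independent data set) are excluded, candidate sites must have no
#' missing calls, fewer than 10% heterozygous calls and at least 3
#' homozygote-alternate carriers.  The depth criterion uses the one-sided
#' positive deviation `DP - median(DP)` against its batch quantile.
#'
#' @param vt a [variant_table] of records absent from the founder set.
#' @param external_mask logical vector (one per site): TRUE = site known
#'   variable in independent data, excluded.
#' @param criteria a [new_mutation_criteria()] object.
#' @return list with `retained`, `rejected` and resolved `criteria`, as in
#'   [filter_founder_snvs()].
#' @export
filter_new_mutations <- function(vt, external_mask = NULL,
                                 criteria = new_mutation_criteria()) {
  stopifnot(inherits(vt, "variant_table"))
  cr <- criteria
  info <- vt$info
  if (is.null(external_mask)) external_mask <- rep(FALSE, n_sites(vt))
  stopifnot(length(external_mask) == n_sites(vt))
  if (is.null(cr$dp_dev_max)) {
    dev <- info$DP - stats::median(info$DP, na.rm = TRUE)
    cr$dp_dev_max <- stats::quantile(dev, cr$dp_dev_quantile, na.rm = TRUE,
                                     names = FALSE)
  }
  dev <- info$DP - stats::median(info$DP, na.rm = TRUE)
  g <- vt$geno
  n_miss <- rowSums(is.na(g))
  het_freq <- rowMeans(g == 1L, na.rm = TRUE)
  hom_alt <- rowSums(g == 2L, na.rm = TRUE)
  fails <- list(
    MQ = .fails(info$MQ, info$MQ >= cr$mq_min),
    QD = .fails(info$QD, info$QD >= cr$qd_min),
    DP = .fails(info$DP, info$DP >= cr$dp_min),
    DP_deviation = .fails(info$DP, dev < cr$dp_dev_max),
    SOR = .fails(info$SOR, info$SOR < cr$sor_max),
    ReadPosRankSum = .fails(info$ReadPosRankSum,
                            info$ReadPosRankSum > cr$rprs_min),
    het_frequency = het_freq >= cr$het_freq_max,
    hom_carriers = hom_alt < cr$min_hom_carriers,
    missing_calls = n_miss > 0L,
    external_mask = as.logical(external_mask))
  bad <- Reduce(`|`, fails)
  list(retained = subset_variants(vt, !bad),
       rejected = data.frame(id = info$id[bad],
                             reason = .collect_reasons(fails)[bad]),
       criteria = cr)
}

#' RIL quality control and relatedness pruning
#'
#' Applies per-line inclusion rules in order: (1) relatedness — among
#' pairs of lines whose identity at segregating sites exceeds
#' `identity_max`, the lower-depth member of each pair is removed,
#' greedily from the highest-identity pair down; (2) sequencing depth
#' below `depth_min`; (3) zygosity — lines where both alleles were seen
#' at more than `het_frac_max` of sites with mean minor-allele proportion
#' above `het_maf_min`; (4) haplotype-reconstruction outliers — lines
#' whose log-likelihood falls beyond the `1 - ll_quantile` population
#' quantile of deviation from the per-chromosome median for more than
#' `max_chroms` chromosomes.
#'
#' @param genotypes n x m dosage matrix (rows = lines).
#' @param depth named per-line expected sequencing depth.
#' @param het_summary optional data.frame with per-line `het_frac` and
#'   `mean_minor_af`; rule 3 is skipped when NULL.
#' @param ll_dev optional lines x chromosomes matrix of haplotype
#'   reconstruction log-likelihoods; rule 4 is skipped when NULL.
#' @param identity_max,depth_min,het_frac_max,het_maf_min thresholds (see
#'   Description).
#' @param ll_quantile tail mass defining a reconstruction outlier.
#' @param max_chroms chromosomes allowed beyond the outlier threshold.
#' @return data.frame with one row per line: `line`, `pass`, `reason`
#'   (first failing rule, "" if retained).
#' @export
qc_rils <- function(genotypes, depth, het_summary = NULL, ll_dev = NULL,
                    identity_max = 0.90, depth_min = 0.1,
                    het_frac_max = 0.20, het_maf_min = 0.20,
                    ll_quantile = 0.001, max_chroms = 3) {
  g <- as.matrix(genotypes)
  n <- nrow(g)
  lines <- rownames(g)
  if (is.null(lines)) lines <- paste0("L", seq_len(n))
  stopifnot(length(depth) == n)
  reason <- rep("", n)

  # rule 1: relatedness (greedy, highest identity first, keep higher depth)
  a <- round(g)
  seg <- apply(a, 2L, function(x) length(unique(x[!is.na(x)])) > 1L)
  if (any(seg) && n >= 2) {
    as_ <- a[, seg, drop = FALSE]
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ident <- vapply(seq_len(nrow(pr)), function(k) {
      mean(as_[pr[k, 1], ] == as_[pr[k, 2], ], na.rm = TRUE)
    }, numeric(1))
    ord <- order(ident, decreasing = TRUE)
    alive <- rep(TRUE, n)
    for (k in ord) {
      if (ident[k] <= identity_max) break
      i <- pr[k, 1]; j <- pr[k, 2]
      if (alive[i] && alive[j]) {
        drop <- if (depth[i] < depth[j]) i else j
        alive[drop] <- FALSE
        reason[drop] <- "relatedness"
      }
    }
  }

  # rule 2: depth
  fail <- reason == "" & depth < depth_min
  reason[fail] <- "low_depth"

  # rule 3: zygosity
  if (!is.null(het_summary)) {
    stopifnot(nrow(het_summary) == n)
    fail <- reason == "" & het_summary$het_frac > het_frac_max &
      het_summary$mean_minor_af > het_maf_min
    reason[fail] <- "heterozygosity"
  }

  # rule 4: reconstruction outliers
  if (!is.null(ll_dev)) {
    ll_dev <- as.matrix(ll_dev)
    stopifnot(nrow(ll_dev) == n)
    dev <- sweep(-ll_dev, 2L, -apply(ll_dev, 2L, stats::median))
    thr <- apply(dev, 2L, stats::quantile, probs = 1 - ll_quantile)
    n_out <- rowSums(sweep(dev, 2L, thr, `>`))
    fail <- reason == "" & n_out > max_chroms
    reason[fail] <- "reconstruction_outlier"
  }

  data.frame(line = lines, pass = reason == "", reason = reason,
             stringsAsFactors = FALSE)
}
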