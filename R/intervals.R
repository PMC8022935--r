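#' QTL detection intervals by LOD drop with LD ranking
#'
#' Defines detection intervals around significant scan peaks: the genome
#' is tiled with windows of `window_bp`; in each window containing a
#' significant marker the maximum-LOD marker is the peak (ties broken
#' leftmost), the remaining window markers are ranked by decreasing LD
#' (r2) with the peak, and markers are admitted down this ranking while
#' their LOD is within `lod_drop` of the peak, stopping at the first
#' failure.  The interval spans the admitted markers, or the flanking
#' marker pair at minimum.  At most one interval is defined per window;
#' the procedure is repeated on windows offset by half, and overlapping or
#' book-ended (adjacent-marker) intervals are merged by union.  LD ranking
#' accommodates the non-monotonic relationship between physical distance
#' and association that local haplotype structure creates; a plain
#' contiguous-LOD-drop rule is available for sensitivity checks.
#'
#' @param scan a [scan_additive()] result.
#' @param G dosage matrix whose columns align with `scan` rows.
#' @param markers data.frame with per-marker `chrom` and `pos`.
#' @param threshold genome-wide p-value threshold (numeric, or a
#'   `calibration` object).
#' @param window_bp window size in bp (default 300 kb).
#' @param lod_drop LOD units defining the drop (default 1.5).
#' @param method "ld_rank" (default) or "lod_drop" (contiguous fallback).
#' @return data.frame of class `qtl_intervals`: chrom, start, end (bp,
#'   1-based inclusive), peak marker index/position/LOD/p, n_markers;
#'   member marker indices in attribute "members".  Empty (zero rows) when
#'   no marker is significant.
#' @export
define_intervals <- function(scan, G, markers, threshold,
                             window_bp = 300000, lod_drop = 1.5,
                             method = c("ld_rank", "lod_drop")) {
  method <- match.arg(method)
  if (inherits(threshold, "calibration")) threshold <- threshold$threshold
  G <- as.matrix(G)
  stopifnot(nrow(scan) == ncol(G), nrow(markers) == ncol(G))
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak = integer(),
                      peak_pos = numeric(), peak_lod = numeric(),
                      peak_p = numeric(), n_markers = integer())
  sig <- which(scan$p <= threshold & scan$flag == "")
  if (!length(sig)) {
    attr(empty, "members") <- list()
    class(empty) <- c("qtl_intervals", "data.frame")
    return(empty)
  }
  one_window <- function(widx) {
    lod <- scan$LOD[widx]
    peak <- widx[order(-lod, markers$pos[widx])[1]]
    if (method == "ld_rank") {
      others <- setdiff(widx, peak)
      admitted <- peak
      if (length(others)) {
        r2 <- suppressWarnings(
          stats::cor(G[, peak], G[, others, drop = FALSE]))^2
        r2[is.na(r2)] <- 0
        ord <- others[order(-r2, markers$pos[others])]
        for (k in ord) {
          if (scan$LOD[k] >= scan$LOD[peak] - lod_drop)
            admitted <- c(admitted, k)
          else break
        }
      }
    } else {
      ordpos <- widx[order(markers$pos[widx])]
      ip <- match(peak, ordpos)
      lo <- ip
      while (lo > 1 && scan$LOD[ordpos[lo - 1]] >=
             scan$LOD[peak] - lod_drop) lo <- lo - 1
      hi <- ip
      while (hi < length(ordpos) && scan$LOD[ordpos[hi + 1]] >=
             scan$LOD[peak] - lod_drop) hi <- hi + 1
      admitted <- ordpos[lo:hi]
    }
    ch <- markers$chrom[peak]
    if (length(admitted) == 1L) {
      onchr <- which(markers$chrom == ch)
      i <- match(peak, onchr)
      admitted <- onchr[max(1L, i - 1L):min(length(onchr), i + 1L)]
    }
    list(chrom = ch, start = min(markers$pos[admitted]),
         end = max(markers$pos[admitted]), peak = peak,
         members = sort(admitted))
  }
  iv <- list()
  for (offset in c(0, window_bp / 2)) {
    win <- paste0(markers$chrom, "@",
                  floor((markers$pos - 1 + offset) / window_bp))
    for (w in unique(win[sig]))
      iv[[length(iv) + 1L]] <- one_window(which(win == w))
  }
  merge_intervals(iv, scan, markers)
}

# merge overlapping or book-ended (no marker strictly between) intervals
merge_intervals <- function(iv, scan, markers) {
  ord <- order(vapply(iv, `[[`, character(1), "chrom"),
               vapply(iv, `[[`, numeric(1), "start"),
               vapply(iv, `[[`, numeric(1), "end"))
  iv <- iv[ord]
  merged <- list()
  for (x in iv) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    contiguous <- !is.null(last) && last$chrom == x$chrom &&
      (x$start <= last$end ||
         !any(markers$chrom == x$chrom & markers$pos > last$end &
                markers$pos < x$start))
    if (contiguous) {
      last$end <- max(last$end, x$end)
      last$start <- min(last$start, x$start)
      last$members <- sort(union(last$members, x$members))
      if (scan$LOD[x$peak] > scan$LOD[last$peak]) last$peak <- x$peak
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- x
  }
  out <- data.frame(
    chrom = vapply(merged, `[[`, character(1), "chrom"),
    start = vapply(merged, `[[`, numeric(1), "start"),
    end = vapply(merged, `[[`, numeric(1), "end"),
    peak = vapply(merged, `[[`, integer(1), "peak"),
    stringsAsFactors = FALSE)
  out$peak_pos <- markers$pos[out$peak]
  out$peak_lod <- scan$LOD[out$peak]
  out$peak_p <- scan$p[out$peak]
  out$n_markers <- vapply(merged, function(x) length(x$members),
                          integer(1))
  attr(out, "members") <- lapply(merged, `[[`, "members")
  class(out) <- c("qtl_intervals", "data.frame")
  out
}

#' Summarize mapping resolution by recombination domain
#'
#' Per-domain and per-heritability-bin medians and interquartile ranges of
#' detection-interval width and peak-to-causal-marker distance.
#'
#' @param detections data.frame with one row per detected simulation:
#'   columns `width` (bp), `peak_dist` (bp), `domain` and `realized_r2`
#'   (as produced by [run_additive_power()]).
#' @param bin_width realized-r2 bin width (default 0.01; bins labeled by
#'   midpoint).
#' @return data.frame with domain, r2 bin midpoint, n, and median/IQR of
#'   width and peak distance.
#' @export
summarize_resolution <- function(detections, bin_width = 0.01) {
  d <- as.data.frame(detections)
  if (nrow(d) == 0L) stop("no detections to summarize")
  if (is.null(d$domain)) d$domain <- "all"
  if (is.null(d$realized_r2)) d$realized_r2 <- NA_real_
  d$bin <- floor(d$realized_r2 / bin_width) * bin_width + bin_width / 2
  iqr <- function(x) diff(stats::quantile(x, c(0.25, 0.75), names = FALSE,
                                          na.rm = TRUE))
  out <- do.call(rbind, lapply(split(d, list(d$domain, d$bin), drop = TRUE),
    function(g) data.frame(domain = g$domain[1], r2_bin = g$bin[1],
                           n = nrow(g),
                           width_median = stats::median(g$width,
                                                        na.rm = TRUE),
                           width_iqr = iqr(g$width),
                           dist_median = stats::median(g$peak_dist),
                           dist_iqr = iqr(g$peak_dist))))
  rownames(out) <- NULL
  out[order(out$domain, out$r2_bin), ]
}
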