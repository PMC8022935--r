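#' Additive QTL detection power over a heritability grid
#'
#' For each replicate: simulate a trait ([simulate_trait()]), scan it
#' ([scan_additive()]), apply the genome-wide threshold, and build
#' detection intervals ([define_intervals()]).  Two detection criteria
#' are recorded side by side: the peak interval contains the true causal
#' marker, or the global significant peak lies within `detect_dist` of
#' it; `detected` is their union.
#'
#' @param panel a [panel_realization].
#' @param h2_grid focal heritability value(s); replicates cycle through
#'   the grid.
#' @param reps number of replicates (>= 1).
#' @param background,h2_total,maf_floor passed to [simulate_trait()].
#' @param threshold a `calibration`, numeric threshold, or NULL (then
#'   calibrated once by the shrinkage method).
#' @param engine optional [scan_engine()] (built once if NULL).
#' @param focal_domain optional domain restriction for causal markers.
#' @param detect_dist peak-distance detection radius in bp (default 1 Mb).
#' @param window_bp,lod_drop interval parameters.
#' @param seed optional integer seed.
#' @return list of class `power_summary`: `records` (one row per
#'   replicate), `power` (overall power with binomial SE under each
#'   criterion), `by_bin` (power by realized-r2 bin), `resolution`
#'   (from [summarize_resolution()] over detections), `threshold`,
#'   `seed`.
#' @export
run_additive_power <- function(panel, h2_grid = 0.04, reps = 200,
                               background = 100, h2_total = 0.5,
                               maf_floor = 0.05, threshold = NULL,
                               engine = NULL, focal_domain = NULL,
                               detect_dist = 1e6, window_bp = 300000,
                               lod_drop = 1.5, seed = NULL) {
  stopifnot(inherits(panel, "panel_realization"), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  G <- panel$genotypes
  if (is.null(engine)) engine <- scan_engine(G)
  if (is.null(threshold))
    threshold <- calibrate_threshold(G, method = "shrinkage",
                                     chrom = panel$markers$chrom)
  thr <- if (inherits(threshold, "calibration")) threshold$threshold else
    threshold
  rec <- vector("list", reps)
  for (r in seq_len(reps)) {
    h2 <- h2_grid[(r - 1L) %% length(h2_grid) + 1L]
    tr <- simulate_trait(panel, h2, background = background,
                         h2_total = h2_total, maf_floor = maf_floor,
                         focal_domain = focal_domain)
    sc <- scan_additive(tr$y, engine)
    sig <- which(sc$p <= thr & sc$flag == "")
    focal_pos <- panel$markers$pos[tr$focal]
    focal_chr <- panel$markers$chrom[tr$focal]
    any_sig <- length(sig) > 0L
    peak <- covered <- FALSE
    peak_dist <- width <- NA_real_
    if (any_sig) {
      iv <- define_intervals(sc, G, panel$markers, thr,
                             window_bp = window_bp, lod_drop = lod_drop)
      # the detection attributable to the simulated locus: the interval
      # covering the true site, else the best significant marker nearby
      k <- which(iv$chrom == focal_chr & iv$start <= focal_pos &
                   iv$end >= focal_pos)[1]
      loc <- sig[panel$markers$chrom[sig] == focal_chr &
                   abs(panel$markers$pos[sig] - focal_pos) <= detect_dist]
      if (!is.na(k)) {
        covered <- TRUE
        width <- iv$end[k] - iv$start[k]
        peak_dist <- abs(iv$peak_pos[k] - focal_pos)
      } else if (length(loc)) {
        peak_dist <- abs(panel$markers$pos[loc[which.max(sc$LOD[loc])]] -
                           focal_pos)
      }
      peak <- isTRUE(peak_dist <= detect_dist)
    }
    rec[[r]] <- data.frame(rep = r, h2_sim = h2,
                           realized_r2 = tr$realized_r2,
                           chrom = focal_chr, pos = focal_pos,
                           domain = panel$markers$domain[tr$focal],
                           any_sig = any_sig, covered = covered,
                           peak_near = peak, peak_dist = peak_dist,
                           width = width,
                           detected = any_sig && (covered || peak))
  }
  records <- do.call(rbind, rec)
  bse <- function(x) sqrt(mean(x) * (1 - mean(x)) / length(x))
  power <- data.frame(
    criterion = c("interval_covers", "peak_near", "either"),
    power = c(mean(records$any_sig & records$covered),
              mean(records$any_sig & records$peak_near),
              mean(records$detected)),
    se = c(bse(records$any_sig & records$covered),
           bse(records$any_sig & records$peak_near),
           bse(records$detected)))
  det <- records[records$detected, , drop = FALSE]
  resolution <- if (nrow(det)) summarize_resolution(det) else NULL
  structure(list(records = records, power = power,
                 by_bin = .bin_power(records), resolution = resolution,
                 threshold = thr, reps = reps),
            class = "power_summary")
}

.bin_power <- function(records, bin_width = 0.01, min_reps = 5) {
  records$bin <- floor(records$realized_r2 / bin_width) * bin_width +
    bin_width / 2
  out <- do.call(rbind, lapply(split(records, records$bin), function(g)
    data.frame(r2_bin = g$bin[1], n = nrow(g), power = mean(g$detected),
               se = sqrt(mean(g$detected) * (1 - mean(g$detected)) /
                           nrow(g)))))
  rownames(out) <- NULL
  out[out$n >= min_reps, , drop = FALSE]
}

#' Two-locus epistasis detection power
#'
#' For each replicate: sample an eligible marker pair, simulate a trait
#' with the target interaction variance fraction (interaction effect
#' scaled so its component explains `h2_int` of the total trait variance;
#' main effects drawn from the standard normal, unconstrained; unit
#' Gaussian noise; no polygenic background), run the interaction LR test
#' with `B` bootstrap null LRs, and convert LRs to empirical p-values via
#' the chi-square mixture calibrated on the pooled nulls stratified by
#' joint-MAF decile.  Power is the fraction of replicates significant at
#' the pairwise Bonferroni threshold.
#'
#' @param panel a [panel_realization] or dosage matrix.
#' @param pairs eligible pairs from [prune_pairs()] (list or matrix); when
#'   NULL, pruning is run with defaults.
#' @param h2_int interaction variance fraction(s); replicates cycle.
#' @param reps number of replicates.
#' @param B bootstrap null LRs per test (default 100).
#' @param calibration a [meff_pairwise()] result or numeric threshold;
#'   when NULL, computed from the pruned marker set.
#' @param seed optional integer seed.
#' @return list of class `power_summary`: `records`, `power`, `mixture`
#'   (the fitted null mixture), `threshold`.
#' @export
run_epistasis_power <- function(panel, pairs = NULL, h2_int = 0.07,
                                reps = 200, B = 100, calibration = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- if (inherits(panel, "panel_realization")) panel$genotypes else
    as.matrix(panel)
  mk <- if (inherits(panel, "panel_realization")) panel$markers else NULL
  if (is.null(pairs))
    pairs <- prune_pairs(G, chrom = mk$chrom, pos = mk$pos,
                         n_pairs = max(1000L, reps))
  pmat <- if (is.list(pairs)) pairs$pairs else pairs
  kept <- if (is.list(pairs)) pairs$markers else unique(as.vector(pmat))
  if (nrow(pmat) < 1L) stop("no eligible marker pairs")
  if (is.null(calibration))
    calibration <- meff_pairwise(G[, kept, drop = FALSE])
  thr <- if (inherits(calibration, "pair_calibration"))
    calibration$threshold else calibration
  a <- round(G)
  maf <- pmin(colMeans(a), 1 - colMeans(a))
  n <- nrow(G)
  std <- function(x) {
    v <- stats::var(x)
    if (v <= 0) return(NULL)
    (x - mean(x)) / sqrt(v)
  }
  obs <- numeric(reps)
  strat <- integer(reps)
  r2 <- numeric(reps)
  nulls <- vector("list", reps)
  for (r in seq_len(reps)) {
    h2 <- h2_int[(r - 1L) %% length(h2_int) + 1L]
    repeat {
      ij <- pmat[sample.int(nrow(pmat), 1L), ]
      zi <- std(a[, ij[1]])
      zj <- std(a[, ij[2]])
      zw <- std(a[, ij[1]] * a[, ij[2]])
      if (!is.null(zi) && !is.null(zj) && !is.null(zw)) break
    }
    ab <- stats::rnorm(2)
    main <- ab[1] * zi + ab[2] * zj
    vw <- if (h2 > 0) h2 * (stats::var(main) + 1) / (1 - h2) else 0
    y <- main + sqrt(vw) * sign(stats::rnorm(1)) * zw + stats::rnorm(n)
    y <- y - mean(y)
    tst <- lr_interaction_test(y, a[, ij[1]], a[, ij[2]])
    obs[r] <- tst$LR
    # realized interaction h2: adjusted-r2 difference between M1 and M0
    tss <- sum((y - mean(y))^2)
    r2[r] <- (tst$rss0 / (n - 3) - tst$rss1 / (n - 4)) * (n - 1) / tss
    strat[r] <- joint_maf_stratum(maf[ij[1]], maf[ij[2]])
    nulls[[r]] <- bootstrap_null(y, a[, ij[1]], a[, ij[2]], B = B)
  }
  null_lrs <- unlist(nulls)
  null_strata <- rep(strat, each = B)
  mix <- calibrate_mixture(null_lrs, factor(null_strata))
  p <- mixture_p(obs, mix, stratum = strat)
  records <- data.frame(rep = seq_len(reps), h2_int = rep_len(h2_int, reps),
                        realized_r2 = r2, LR = obs, stratum = strat,
                        p = p, detected = p <= thr)
  pw <- mean(records$detected)
  structure(list(records = records,
                 power = data.frame(criterion = "pairwise_bonferroni",
                                    power = pw,
                                    se = sqrt(pw * (1 - pw) / reps)),
                 mixture = mix, threshold = thr, reps = reps),
            class = "power_summary")
}

#' @export
print.power_summary <- function(x, ...) {
  cat("<power_summary> ", x$reps, " replicates, threshold ",
      format(x$threshold, digits = 3), "\n", sep = "")
  print(x$power)
  invisible(x)
}

#' Panel accounting table
#'
#' Sums per-population line counts into a panel total, in the style of a
#' panel-composition table.
#'
#' @param counts named integer vector of retained lines per population.
#' @param sequenced optional named vector of sequenced-line counts before
#'   the inclusion filter.
#' @return data.frame with one row per population plus a "total" row.
#' @export
line_count_table <- function(counts, sequenced = NULL) {
  out <- data.frame(population = names(counts), retained = unname(counts))
  if (!is.null(sequenced)) out$sequenced <- unname(sequenced[names(counts)])
  tot <- data.frame(population = "total", retained = sum(counts))
  if (!is.null(sequenced)) tot$sequenced <- sum(sequenced)
  rbind(out, tot)
}

#' Assemble a reproducible power report
#'
#' Collects power summaries, panel metadata and the run configuration
#' into a deterministic list of tables suitable for writing with
#' [write_report()]; rerunning on the same inputs yields identical
#' output.
#'
#' @param summaries named list of `power_summary` objects.
#' @param metadata optional list (panel configuration, seeds, counts).
#' @return list of class `power_report` with `power`, `resolution`,
#'   `metadata`.
#' @export
power_report <- function(summaries, metadata = list()) {
  stopifnot(length(summaries) >= 1)
  power <- do.call(rbind, lapply(names(summaries), function(nm) {
    p <- summaries[[nm]]$power
    p$analysis <- nm
    p[c("analysis", setdiff(names(p), "analysis"))]
  }))
  resol <- do.call(rbind, lapply(names(summaries), function(nm) {
    r <- summaries[[nm]]$resolution
    if (is.null(r)) return(NULL)
    r$analysis <- nm
    r[c("analysis", setdiff(names(r), "analysis"))]
  }))
  structure(list(power = power, resolution = resol, metadata = metadata),
            class = "power_report")
}
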