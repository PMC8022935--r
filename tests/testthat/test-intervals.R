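# hand-built scan results over a small marker set with controllable LD
fake_scan <- function(lod, n = 80, seed = 111, G = NULL, pos = NULL) {
  m <- length(lod)
  if (is.null(G)) {
    set.seed(seed)
    G <- matrix(rbinom(n * m, 1, 0.5), n, m)
  }
  if (is.null(pos)) pos <- seq_len(m) * 10000
  markers <- data.frame(chrom = "c1", pos = pos)
  lr <- lod * 2 * log(10)
  sc <- data.frame(marker = seq_len(m), beta = 0, LR = lr, LOD = lod,
                   p = pchisq(lr, 1, lower.tail = FALSE), flag = "")
  class(sc) <- c("scan_result", "data.frame")
  list(sc = sc, G = G, markers = markers)
}

test_that("no significant markers gives an empty interval set", {
  fx <- fake_scan(rep(0.5, 20))
  iv <- define_intervals(fx$sc, fx$G, fx$markers, 1e-5)
  expect_equal(nrow(iv), 0)
})

test_that("an isolated peak falls back to the flanking-marker span", {
  lod <- rep(0.1, 21)
  lod[11] <- 8   # neighbors far below peak - 1.5
  fx <- fake_scan(lod)
  iv <- define_intervals(fx$sc, fx$G, fx$markers, 1e-4)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$peak, 11)
  expect_equal(iv$start, fx$markers$pos[10])
  expect_equal(iv$end, fx$markers$pos[12])
  expect_gte(iv$n_markers, 2)
})

test_that("a perfect-LD plateau of equal LOD spans the plateau", {
  lod <- rep(0.1, 21)
  lod[9:13] <- 7
  set.seed(112)
  G <- matrix(rbinom(80 * 21, 1, 0.5), 80, 21)
  G[, 10:13] <- G[, 9]   # perfect LD across the plateau
  fx <- fake_scan(lod, G = G)
  iv <- define_intervals(fx$sc, fx$G, fx$markers, 1e-4)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$peak, 9)   # tie broken leftmost
  expect_lte(iv$start, fx$markers$pos[9])
  expect_gte(iv$end, fx$markers$pos[13])
})

test_that("LD ranking admits markers until the first LOD failure", {
  # marker 5 is in high LD with the peak but below the drop: admission
  # stops there even though lower-LD markers would pass
  lod <- c(0.2, 6.8, 0.2, 7, 5.2, 6.9, 0.2, 0.2)
  set.seed(113)
  x <- rbinom(200, 1, 0.5)
  flip <- function(x, k) { i <- sample(length(x), k); x[i] <- 1 - x[i]; x }
  G <- cbind(rbinom(200, 1, 0.5), flip(x, 30), rbinom(200, 1, 0.5),
             x, flip(x, 5), flip(x, 15), rbinom(200, 1, 0.5),
             rbinom(200, 1, 0.5))
  fx <- fake_scan(lod, G = G, pos = seq_len(8) * 1000)
  iv <- define_intervals(fx$sc, fx$G, fx$markers, 1e-4)
  mem <- attr(iv, "members")[[1]]
  expect_equal(iv$peak, 4)
  # marker 5 (LOD 5.2 < 7 - 1.5) blocks the ranking: 6 and 2 not admitted
  # even though their own LODs are within the drop
  expect_false(6 %in% mem)
  expect_false(2 %in% mem)
})

test_that("contiguous-LOD-drop fallback spans the contiguous run", {
  lod <- c(0.2, 0.2, 6, 6.5, 7, 6.2, 0.3, 0.2)
  fx <- fake_scan(lod)
  iv <- define_intervals(fx$sc, fx$G, fx$markers, 1e-4,
                         method = "lod_drop")
  expect_equal(iv$start, fx$markers$pos[3])
  expect_equal(iv$end, fx$markers$pos[6])
})

test_that("merging is idempotent and order-independent", {
  lod <- rep(0.1, 60)
  lod[20:45] <- 6 + seq(0, 1, length.out = 26)  # spans window boundaries
  set.seed(114)
  G <- matrix(rbinom(80 * 60, 1, 0.5), 80, 60)
  G[, 21:45] <- G[, 20]
  fx <- fake_scan(lod, G = G, pos = seq_len(60) * 20000)
  iv <- define_intervals(fx$sc, fx$G, fx$markers, 1e-4,
                         window_bp = 300000)
  expect_equal(nrow(iv), 1)  # overlapping windows merged by union
  # re-merging the merged interval list changes nothing
  ivl <- lapply(seq_len(nrow(iv)), function(k)
    list(chrom = iv$chrom[k], start = iv$start[k], end = iv$end[k],
         peak = iv$peak[k], members = attr(iv, "members")[[k]]))
  again <- mppqtl:::merge_intervals(ivl, fx$sc, fx$markers)
  expect_equal(again$start, iv$start)
  expect_equal(again$end, iv$end)
  rev_ <- mppqtl:::merge_intervals(rev(ivl), fx$sc, fx$markers)
  expect_equal(rev_$start, iv$start)
})

test_that("resolution summaries give medians and IQRs by domain and bin", {
  d <- data.frame(width = c(10, 20, 30, 100) * 1000,
                  peak_dist = c(0, 0, 5000, 0),
                  domain = "arm", realized_r2 = 0.042)
  s <- summarize_resolution(d)
  expect_equal(s$width_median, 25000)
  expect_equal(s$r2_bin, 0.045)
  expect_equal(s$dist_median, 0)
  one <- summarize_resolution(data.frame(width = 7000, peak_dist = 100,
                                         domain = "center",
                                         realized_r2 = 0.03))
  expect_equal(one$width_median, 7000)
  expect_equal(one$width_iqr, 0)
  expect_error(summarize_resolution(d[0, ]), "no detections")
})
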