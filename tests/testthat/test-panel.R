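test_that("degenerate design returns unrecombined founder haplotype pairs", {
  map <- tiny_map()
  fs <- simulate_founders(map, 50, n_founders = 2, seed = 11)
  cfg <- evolution_config(census = 30, generations = 0, selfing_gens = 0,
                          n_lines = 10, seed = 12)
  p <- simulate_panel(fs, map, cfg)
  # every line is an F1: one haplotype from each founder, no breakpoints
  segs <- p$paths
  expect_equal(nrow(segs), 10 * 2 * 2)  # one segment per line/hap/chrom
  expect_true(all(tapply(segs$founder, list(segs$line, segs$chrom),
                         function(f) setequal(f, 1:2))))
  ra <- estimate_map_expansion(p)
  expect_equal(unname(ra), c(0, 0), ignore_attr = TRUE)
})

test_that("selfing halves heterozygosity each generation (Monte Carlo)", {
  map <- tiny_map()
  fs <- simulate_founders(map, 1000, n_founders = 2, seed = 13)
  # founders differ at every marker, so F1s are fully heterozygous
  cfg <- evolution_config(census = 150, generations = 0, selfing_gens = 10,
                          n_lines = 150, seed = 14)
  p <- simulate_panel(fs, map, cfg)
  het <- residual_heterozygosity(p)   # per line, over 2000 sites
  se <- sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - 2^-10), 3 * se + 1e-12)
})

test_that("transmitted crossovers per meiosis match map length in Morgans", {
  map <- tiny_map()   # 50 cM per chromosome -> 0.5 expected per gamete
  g <- sim_meioses(map, 12000, seed = 15)
  for (ch in map$chromosomes) {
    nbp <- tabulate(g$gamete[g$chrom == ch], nbins = 12000) - 1L
    se <- sd(nbp) / sqrt(length(nbp))
    expect_lt(abs(mean(nbp) - 0.5), 3 * se)
  }
})

test_that("crossover positions respect domain recombination rates", {
  map <- tiny_map()
  g <- sim_meioses(map, 12000, seed = 16)
  bp <- g[g$chrom == "c1" & g$end < map$lengths[["c1"]], ]
  cls <- domain_of(map, bp$chrom, bp$end)
  # center holds 50% of length but rate is 1/3 of arms: expected share
  # = 0.5 / (0.5 + 3 * 0.5) = 0.25
  p_center <- mean(cls == "center")
  se <- sqrt(0.25 * 0.75 / nrow(bp))
  expect_lt(abs(p_center - 0.25), 4 * se)
})

test_that("genotypes agree with truth paths at every marker", {
  p <- small_panel()
  fs <- p$founders
  mk <- p$markers
  idx <- seq(1, nrow(p$genotypes), by = 7)  # spot-check lines exhaustively
  for (i in idx) {
    expected <- rep(0, nrow(mk))
    for (h in 1:2) {
      seg <- p$paths[p$paths$line == i & p$paths$hap == h, ]
      for (ch in unique(mk$chrom)) {
        s <- seg[seg$chrom == ch, ]
        on <- which(mk$chrom == ch)
        k <- findInterval(mk$pos[on], c(0, s$end), left.open = TRUE)
        expected[on] <- expected[on] +
          0.5 * fs$haplotypes[cbind(s$founder[k], on)]
      }
    }
    expect_equal(unname(p$genotypes[i, ]), expected)
  }
})

test_that("identical seeds reproduce identical panels bit for bit", {
  map <- tiny_map()
  fs <- simulate_founders(map, 100, seed = 21)
  cfg <- evolution_config(census = 60, generations = 8, n_lines = 25,
                          selfing_gens = 4, seed = 22)
  a <- simulate_panel(fs, map, cfg)
  b <- simulate_panel(fs, map, cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$paths, b$paths)
})

test_that("outcrossing with a census below two is impossible", {
  map <- tiny_map()
  fs <- simulate_founders(map, 20, n_founders = 2, seed = 23)
  cfg <- evolution_config(census = 1, generations = 3, outcross_p = 1,
                          n_lines = 1, selfing_gens = 0, seed = 24)
  expect_error(simulate_panel(fs, map, cfg), "population size < 2")
})

test_that("map expansion is ~1 for single-meiosis doubled haploids", {
  map <- tiny_map()
  g <- sim_meioses(map, 1000, seed = 25)
  ra <- estimate_map_expansion(g, map)
  for (ch in map$chromosomes) {
    nbp <- tabulate(g$gamete[g$chrom == ch], nbins = 1000) - 1L
    se3 <- 3 * sd(nbp) / sqrt(length(nbp)) / 0.5
    expect_lt(abs(ra[[ch]] - 1), se3)
  }
})

test_that("map expansion grows with evolution generations", {
  map <- tiny_map()
  fs <- simulate_founders(map, 200, seed = 26)
  ra <- sapply(c(10, 40, 80), function(g) {
    cfg <- evolution_config(census = 120, generations = g, n_lines = 60,
                            selfing_gens = 5, seed = 27)
    attr(estimate_map_expansion(simulate_panel(fs, map, cfg)), "overall")
  })
  expect_true(all(diff(ra) > 0))
})

test_that("structured lineage designs label populations and branch state", {
  map <- tiny_map()
  fs <- simulate_founders(map, 150, seed = 31)
  des <- lineage_design(data.frame(
    label = c("base", "d10", "d60"),
    parent = c(NA, "base", "base"),
    generations = c(20, 10, 60),
    outcross_p = 0.5,
    n_lines = c(40, 30, 30)))
  p <- simulate_structured_panel(fs, map, des, census = 150,
                                 selfing_gens = 5, seed = 32)
  expect_equal(unname(table(p$population)[c("base", "d10", "d60")]),
               c(40L, 30L, 30L), ignore_attr = TRUE)
  # longer-evolved lineage shows larger realized map expansion
  ra <- function(pop) {
    idx <- which(p$population == pop)
    attr(estimate_map_expansion(
      p$paths[p$paths$line %in% idx, ], map), "overall")
  }
  expect_gt(ra("d60"), ra("d10"))
  expect_equal(sum(cemee_v2_design()$n_lines), 763)
})
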