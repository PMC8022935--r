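# Shared fixtures, built once per test run and memoised.

.cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

# compact two-chromosome map for unit tests
tiny_map <- function(total_cM = 50) {
  chrs <- c("c1", "c2")
  len <- c(1e7, 1.2e7)
  doms <- do.call(rbind, lapply(1:2, function(i) {
    b <- c(0, 0.25, 0.75, 1) * len[i]
    rc <- total_cM / (len[i] / 1e6) / (2 * 0.25 * 3 + 0.5)
    data.frame(chrom = chrs[i], start = b[-4], end = b[-1],
               rate = c(3 * rc, rc, 3 * rc),
               class = c("arm", "center", "arm"))
  }))
  genetic_map(chrs, len, doms)
}

small_panel <- function() memo("small_panel", {
  map <- default_genetic_map()
  fs <- simulate_founders(map, 300, seed = 101)
  cfg <- evolution_config(census = 150, generations = 40, n_lines = 120,
                          selfing_gens = 10, seed = 102)
  simulate_panel(fs, map, cfg)
})

mid_panel <- function() memo("mid_panel", {
  map <- default_genetic_map()
  fs <- simulate_founders(map, 500, seed = 201)
  cfg <- evolution_config(census = 300, generations = 60, n_lines = 250,
                          selfing_gens = 10, seed = 202)
  simulate_panel(fs, map, cfg)
})

mid_engine <- function() memo("mid_engine", scan_engine(mid_panel()$genotypes))

# the full-scale panel used by the end-to-end checks, shared across blocks
acceptance_panel <- function() memo("acceptance_panel", {
  map <- default_genetic_map()
  fs <- simulate_founders(map, 2000, seed = 1001)
  simulate_structured_panel(fs, map, seed = 1002)
})

acceptance_engine <- function() memo("acceptance_engine", {
  scan_engine(acceptance_panel()$genotypes)
})

acceptance_threshold <- function() memo("acceptance_threshold", {
  set.seed(1003)
  calibrate_threshold(acceptance_panel()$genotypes, method = "permutation",
                      n_perm = 100, engine = acceptance_engine())
})

# --- variant-table fixtures (expected survivor counts hold by construction)

# one clean founder-SNV record passing every criterion
clean_info <- function(n, chrom = "I") {
  data.frame(chrom = chrom, pos = seq_len(n) * 1000,
             ref = "A", alt = "G", QUAL = 2000, MQ = 60, DP = 50,
             QD = 20, SOR = 1, ReadPosRankSum = 0)
}

# 20 founder-SNV records: 7 violate exactly one criterion each -> 13 retained
founder_fixture <- function() {
  info <- clean_info(20)
  geno <- matrix(rep(c(0L, 2L), each = 8), nrow = 20, ncol = 16,
                 byrow = TRUE)
  colnames(geno) <- sprintf("F%02d", 1:16)
  info$QUAL[1] <- 900        # QUAL <= 1000
  info$QUAL[2] <- 1000       # boundary: QUAL > 1000 is strict
  geno[3, 1:8] <- 1L         # 50% heterozygous founder calls
  info$MQ[4] <- 30           # MQ <= 40
  info$DP[5] <- 500          # |DP - median| beyond the 0.995 quantile
  info$SOR[6] <- 5           # SOR >= 3
  info$QD[7] <- 14.9         # QD < 15
  variant_table(info, geno)
}

# 30 new-mutation candidates over 20 samples: 9 engineered failures
newmut_fixture <- function() {
  info <- clean_info(30, chrom = "II")
  geno <- matrix(0L, 30, 20)
  colnames(geno) <- sprintf("S%02d", 1:20)
  geno[, 1:4] <- 2L           # 4 homozygous carriers everywhere
  info$MQ[1] <- 39
  info$QD[2] <- 4
  info$DP[3] <- 20            # DP < 30
  info$DP[4] <- 400           # positive depth deviation outlier
  info$SOR[5] <- 4.5
  info$ReadPosRankSum[6] <- -5
  geno[7, 5:8] <- 1L          # het frequency 20% >= 10%
  geno[8, 3:4] <- 0L          # only 2 homozygote carriers
  geno[9, 20] <- NA           # missing call
  mask <- rep(FALSE, 30)
  mask[10] <- TRUE            # known variable in independent data
  cr <- new_mutation_criteria()
  cr$dp_dev_max <- 100        # frozen depth threshold, batch-independent
  list(vt = variant_table(info, geno), mask = mask, criteria = cr,
       n_expected = 20)
}
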