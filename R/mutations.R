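empty_mutation_registry <- function() {
  data.frame(id = character(), chrom = character(), pos = numeric(),
             ref = character(), alt = character(), is_transition = logical(),
             origin_gen = integer(), final_count = integer(),
             frequency = numeric(), n_carriers = integer(),
             carriers = character(), stringsAsFactors = FALSE)
}

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

#' Inject de novo mutations into a simulated panel
#'
#' Draws Poisson numbers of new base substitutions per genome copy per
#' generation of the evolution phase, follows each mutation's copy number
#' generation by generation under neutral Wright-Fisher binomial sampling,
#' and assigns surviving mutations to carrier lines binomially at their
#' final population frequency.  The mutation process has a configurable
#' transition:transversion ratio, and the X chromosome can be given a
#' deflated effective size (fewer copies at risk and faster drift) to
#' emulate reduced X transmission in partially outcrossing populations.
#' Marker genotypes are left untouched; mutations live in the registry.
#'
#' @param panel a [panel_realization].
#' @param mu haploid per-site per-generation mutation rate (defaults to the
#'   panel's `evolution_config`).
#' @param ts_tv transition:transversion ratio of the mutation process.
#' @param generations generations over which mutations arise (default: the
#'   panel's evolution-phase generation count).
#' @param keep_lost keep mutations lost before sampling in the registry.
#' @param seed optional integer seed.
#' @return the panel with its `mutations` registry filled: one row per
#'   mutation with position, ref/alt alleles, transition flag, origin
#'   generation, final copy number and frequency, and carrier lines.
#' @export
inject_mutations <- function(panel, mu = NULL, ts_tv = 1, generations = NULL,
                             keep_lost = TRUE, seed = NULL) {
  stopifnot(inherits(panel, "panel_realization"))
  if (is.null(mu)) mu <- panel$config$mu
  if (mu < 0) stop("mutation rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(generations)) generations <- panel$config$generations
  map <- panel$map
  if (mu == 0 || generations == 0) {
    panel$mutations <- empty_mutation_registry()
    return(panel)
  }
  twoN <- 2 * panel$config$census
  is_x <- map$chromosomes == "X"
  copies <- ifelse(is_x, round(twoN * panel$config$x_ne_factor), twoN)
  rate_per_gen <- mu * map$lengths * copies  # expected new mutations/chrom/gen

  reg <- vector("list", generations)
  alive_cnt <- integer(0)    # current copy number per live mutation
  alive_id <- integer(0)     # row index into the registry once assembled
  alive_2n <- integer(0)
  next_id <- 1L
  for (g in seq_len(generations)) {
    n_new <- stats::rpois(length(rate_per_gen), rate_per_gen)
    tot <- sum(n_new)
    if (tot > 0) {
      chrom <- rep(map$chromosomes, n_new)
      pos <- floor(stats::runif(tot, 0, map$lengths[chrom])) + 1
      ref <- sample(c("A", "C", "G", "T"), tot, replace = TRUE)
      is_ts <- stats::runif(tot) < ts_tv / (ts_tv + 1)
      alt <- ifelse(is_ts, .TS_PARTNER[ref],
                    vapply(ref, function(r) sample(.TV_PARTNERS[[r]], 1),
                           character(1)))
      reg[[g]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                             alt = unname(alt), is_transition = is_ts,
                             origin_gen = g, stringsAsFactors = FALSE)
      alive_cnt <- c(alive_cnt, rep.int(1L, tot))
      alive_id <- c(alive_id, seq.int(next_id, next_id + tot - 1L))
      alive_2n <- c(alive_2n, copies[match(chrom, map$chromosomes)])
      next_id <- next_id + tot
    }
    # one generation of neutral drift for everything alive
    if (length(alive_cnt)) {
      alive_cnt <- stats::rbinom(length(alive_cnt), alive_2n,
                                 alive_cnt / alive_2n)
      keep <- alive_cnt > 0L
      alive_cnt <- alive_cnt[keep]
      alive_id <- alive_id[keep]
      alive_2n <- alive_2n[keep]
    }
  }
  reg <- do.call(rbind, reg)
  if (is.null(reg)) {
    panel$mutations <- empty_mutation_registry()
    return(panel)
  }
  reg$final_count <- 0L
  reg$final_count[alive_id] <- alive_cnt
  reg$frequency <- reg$final_count /
    ifelse(reg$chrom == "X", copies[match("X", map$chromosomes)], twoN)
  n_lines <- nrow(panel$genotypes)
  lines <- rownames(panel$genotypes)
  reg$n_carriers <- 0L
  reg$carriers <- ""
  surv <- which(reg$final_count > 0L)
  if (length(surv)) {
    nc <- stats::rbinom(length(surv), n_lines, reg$frequency[surv])
    reg$n_carriers[surv] <- nc
    reg$carriers[surv] <- vapply(seq_along(surv), function(i) {
      if (nc[i] == 0L) "" else
        paste(sort(sample(lines, nc[i])), collapse = ",")
    }, character(1))
  }
  if (!keep_lost) reg <- reg[reg$final_count > 0L, ]
  reg$id <- sprintf("NM%06d", seq_len(nrow(reg)))
  rownames(reg) <- NULL
  panel$mutations <- reg[c("id", "chrom", "pos", "ref", "alt",
                           "is_transition", "origin_gen", "final_count",
                           "frequency", "n_carriers", "carriers")]
  panel
}

#' Expected cumulative number of new mutations
#'
#' Closed-form expectation `mu * genome_size * 2 * Ne * generations` for
#' the total number of base substitutions arising in a diploid population:
#' e.g. a haploid rate of 2.5e-9 per site per generation over a 1e8 bp
#' genome, 1000 diploids and 140 generations gives 70,000.
#'
#' @param mu haploid per-site per-generation mutation rate (> 0).
#' @param genome_size genome size in bp (> 0).
#' @param ne effective number of diploid individuals (> 0).
#' @param generations number of generations (>= 0).
#' @return expected mutation count.
#' @export
expected_mutation_count <- function(mu, genome_size, ne, generations) {
  if (mu <= 0 || genome_size <= 0 || ne <= 0)
    stop("mu, genome_size and ne must be > 0")
  if (generations < 0) stop("generations must be >= 0")
  mu * genome_size * 2 * ne * generations
}

#' Classify the fate of a mutation in a derived population
#'
#' @param ancestral_detected logical: was the variant detected in the
#'   ancestral population?
#' @param derived_freq frequency in the derived population, in \[0,1\].
#' @param floor detection floor: the smallest frequency counted as
#'   "detected" (default: one carrier among `n`, if `n` supplied via
#'   `floor`).
#' @return factor with levels gained/fixed/maintained/lost: variants absent
#'   from the ancestor but at/above the floor are `gained`; ancestral
#'   variants at frequency 1 are `fixed`, at/above the floor `maintained`,
#'   below it `lost`.  Variants seen in neither population are `NA`.
#' @export
classify_mutation_fate <- function(ancestral_detected, derived_freq,
                                   floor = 1e-9) {
  stopifnot(all(derived_freq >= 0 & derived_freq <= 1))
  n <- max(length(ancestral_detected), length(derived_freq))
  anc <- rep_len(as.logical(ancestral_detected), n)
  f <- rep_len(derived_freq, n)
  out <- rep(NA_character_, n)
  out[!anc & f >= floor] <- "gained"
  out[anc & f >= 1] <- "fixed"
  out[anc & f < 1 & f >= floor] <- "maintained"
  out[anc & f < floor] <- "lost"
  factor(out, levels = c("gained", "fixed", "maintained", "lost"))
}
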