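#' Configuration for an experimental-evolution panel simulation
#'
#' Describes the evolutionary design used to derive recombinant inbred
#' lines from a multiparental funnel cross: a Wright-Fisher population of
#' hermaphrodites reproducing by selfing or random outcrossing, followed by
#' RIL derivation through single-descendant selfing.  Defaults emulate a
#' lab-evolution design with census/effective size on the order of 10^3,
#' 140 generations of mixed selfing/outcrossing at 50% outcrossing, and 10
#' generations of selfing.
#'
#' @param census Wright-Fisher census size N during the evolution phase.
#' @param generations number of evolution generations after the funnel.
#' @param outcross_p per-individual outcrossing probability per generation.
#' @param selfing_gens selfing generations for RIL derivation.
#' @param n_lines number of RILs to sample (must be <= census).
#' @param mu haploid per-site per-generation mutation rate (used by
#'   [inject_mutations()]).
#' @param x_ne_factor optional effective-size deflator for the X chromosome
#'   applied by [inject_mutations()] (1 = treat X as autosomal).
#' @param label population label assigned to the sampled lines.
#' @param seed optional integer seed.
#' @return list of class `evolution_config`.
#' @export
evolution_config <- function(census = 1000L, generations = 140L,
                             outcross_p = 0.5, selfing_gens = 10L,
                             n_lines = 100L, mu = 2.5e-9, x_ne_factor = 1,
                             label = "SIM", seed = NULL) {
  stopifnot(census >= 1, generations >= 0, selfing_gens >= 0, n_lines >= 1,
            outcross_p >= 0, outcross_p <= 1, mu >= 0,
            x_ne_factor > 0, x_ne_factor <= 1)
  structure(list(census = as.integer(census),
                 generations = as.integer(generations),
                 outcross_p = outcross_p,
                 selfing_gens = as.integer(selfing_gens),
                 n_lines = as.integer(n_lines), mu = mu,
                 x_ne_factor = x_ne_factor, label = label, seed = seed),
            class = "evolution_config")
}

#' Simulate a multiparental RIL panel with full truth tracking
#'
#' Runs the funnel intercross (pairwise crosses halving the number of
#' subpopulations each generation until one hybrid population carrying all
#' founders remains), the mixed selfing/outcrossing Wright-Fisher evolution
#' phase, and RIL derivation by selfing, recording the exact
#' founder-of-origin path of every chromosome.  Meiosis places an obligate
#' crossover on each bivalent plus Poisson extras from the residual
#' bivalent map length, positions sampled proportional to the local cM/Mb
#' rate; each crossover reaches the transmitted chromatid with probability
#' 1/2, so transmitted crossovers average the map length in Morgans.
#'
#' @param founders a [founder_set] (number of founders must be a power of
#'   two so the funnel closes).
#' @param map the [genetic_map] used for crossover counts and positions.
#' @param config an [evolution_config].
#' @return An object of class `panel_realization`: list with
#'   \describe{
#'     \item{genotypes}{n_lines x m dosage matrix in \[0,1\] (0.5 =
#'       residual heterozygote), lines in rows.}
#'     \item{paths}{data.frame of truth segments (line, hap, chrom, end,
#'       founder) tiling each chromosome, 1-based inclusive ends in bp.}
#'     \item{markers}{marker table (chrom, pos, id) plus `domain` class.}
#'     \item{population}{population label per line.}
#'     \item{mutations}{registry of injected mutations (empty until
#'       [inject_mutations()] is used).}
#'   }
#' @examples
#' fs <- simulate_founders(default_genetic_map(), 20, n_founders = 4, seed = 1)
#' cfg <- evolution_config(census = 50, generations = 5, n_lines = 10,
#'                         selfing_gens = 3, seed = 1)
#' p <- simulate_panel(fs, default_genetic_map(), cfg)
#' @export
simulate_panel <- function(founders, map, config) {
  stopifnot(inherits(founders, "founder_set"), inherits(map, "genetic_map"),
            inherits(config, "evolution_config"))
  nf <- nrow(founders$haplotypes)
  if (bitwAnd(nf, nf - 1L) != 0L)
    stop("number of founders must be a power of two for the funnel design")
  if (!is.null(config$seed)) set.seed(config$seed)
  a <- .map_cpp_args(map)
  seg <- cpp_simulate_panel(a$chrom_len, a$dom_chrom, a$dom_start, a$dom_end,
                            a$dom_rate, nf, config$census,
                            config$generations, config$outcross_p,
                            config$n_lines, config$selfing_gens)
  paths <- data.frame(line = seg$line, hap = seg$hap,
                      chrom = map$chromosomes[seg$chrom], end = seg$end,
                      founder = seg$founder)
  mk <- founders$markers
  geno <- cpp_paths_to_geno(seg$line, seg$hap, seg$chrom, seg$end,
                            seg$founder, founders$haplotypes,
                            match(mk$chrom, map$chromosomes), mk$pos,
                            config$n_lines)
  dimnames(geno) <- list(sprintf("L%04d", seq_len(config$n_lines)), mk$id)
  mk$domain <- domain_of(map, mk$chrom, mk$pos)
  structure(list(genotypes = geno, paths = paths, markers = mk,
                 founders = founders, map = map, config = config,
                 population = rep(config$label, config$n_lines),
                 mutations = empty_mutation_registry()),
            class = "panel_realization")
}

#' @export
print.panel_realization <- function(x, ...) {
  cat("<panel_realization> ", nrow(x$genotypes), " lines x ",
      ncol(x$genotypes), " markers (", x$config$generations,
      " evolution + ", x$config$selfing_gens, " selfing generations; ",
      nrow(x$mutations), " injected mutations)\n", sep = "")
  invisible(x)
}

#' Experimentally structured panel designs
#'
#' `lineage_design()` validates a lineage table for
#' [simulate_structured_panel()]: one base row (parent NA) giving the
#' common ancestral population, and derived lineages that branch from the
#' stored state of their parent population and evolve further generations
#' at their own outcrossing rate.  `cemee_v2_design()` returns the
#' default design emulating version 2 of the C. elegans multiparental
#' experimental evolution (CeMEE) panel, 763 lines in total: a
#' 140-generation lab-adapted base population (251 lines), three control
#' replicate lineages sampled at +50 (152 lines) and +100 generations
#' (144 lines), three further androdioecious lineages at +50 (133), two
#' high-outcrossing trioecious lineages (78) and two selfing monoecious
#' lineages (5).
#'
#' @param design data.frame with columns `label`, `parent` (NA for the
#'   base row), `generations`, `outcross_p`, `n_lines`.
#' @return the validated design data.frame.
#' @export
lineage_design <- function(design) {
  design <- as.data.frame(design)
  stopifnot(all(c("label", "parent", "generations", "outcross_p",
                  "n_lines") %in% names(design)),
            sum(is.na(design$parent)) == 1L,
            all(design$generations >= 0), all(design$n_lines >= 0),
            all(design$outcross_p >= 0 & design$outcross_p <= 1))
  base <- which(is.na(design$parent))
  design <- design[c(base, setdiff(seq_len(nrow(design)), base)), ]
  idx <- match(design$parent[-1], design$label)
  if (any(is.na(idx)) || any(idx >= seq_len(nrow(design) - 1L) + 1L))
    stop("every lineage's parent must be an earlier row")
  design
}

#' @rdname lineage_design
#' @export
cemee_v2_design <- function() {
  lineage_design(data.frame(
    label = c("A6140", "CA150", "CA250", "CA350", "CA1100", "CA2100",
              "CA3100", "GA150", "GA250", "GA450", "GT150", "GT250",
              "GM150", "GM350"),
    parent = c(NA, "A6140", "A6140", "A6140", "CA150", "CA250", "CA350",
               "A6140", "A6140", "A6140", "A6140", "A6140", "A6140",
               "A6140"),
    generations = c(140, rep(50, 13)),
    outcross_p = c(rep(0.5, 10), 0.8, 0.8, 0, 0),
    n_lines = c(251, 51, 51, 50, 48, 48, 48, 44, 44, 45, 39, 39, 3, 2)))
}

#' Simulate a structured multi-population RIL panel
#'
#' Like [simulate_panel()], but following a lineage design: the funnel
#' and base evolution produce a common ancestral population, whose stored
#' state seeds derived replicate lineages that evolve further generations
#' before RIL sampling.  This reproduces the population structure of
#' panels whose lines are drawn from several related experimental
#' populations.
#'
#' @param founders a [founder_set].
#' @param map a [genetic_map].
#' @param design a [lineage_design()] (default [cemee_v2_design()]).
#' @param census Wright-Fisher census size for every population.
#' @param selfing_gens RIL-derivation selfing generations.
#' @param seed optional integer seed.
#' @return a [simulate_panel()]-style `panel_realization`; `population`
#'   holds each line's lineage label.
#' @export
simulate_structured_panel <- function(founders, map,
                                      design = cemee_v2_design(),
                                      census = 1000L, selfing_gens = 10L,
                                      seed = NULL) {
  stopifnot(inherits(founders, "founder_set"), inherits(map, "genetic_map"))
  design <- lineage_design(design)
  nf <- nrow(founders$haplotypes)
  if (bitwAnd(nf, nf - 1L) != 0L)
    stop("number of founders must be a power of two for the funnel design")
  if (!is.null(seed)) set.seed(seed)
  a <- .map_cpp_args(map)
  dv <- design[-1L, , drop = FALSE]
  parent <- match(dv$parent, dv$label)  # NA -> base
  parent[dv$parent == design$label[1L]] <- 0L
  parent[is.na(parent)] <- 0L
  seg <- cpp_simulate_structured(a$chrom_len, a$dom_chrom, a$dom_start,
                                 a$dom_end, a$dom_rate, nf,
                                 as.integer(census),
                                 as.integer(design$generations[1L]),
                                 design$outcross_p[1L],
                                 as.integer(design$n_lines[1L]),
                                 as.integer(parent - 1L),
                                 as.integer(dv$generations),
                                 dv$outcross_p, as.integer(dv$n_lines),
                                 as.integer(selfing_gens))
  n_total <- sum(design$n_lines)
  paths <- data.frame(line = seg$line, hap = seg$hap,
                      chrom = map$chromosomes[seg$chrom], end = seg$end,
                      founder = seg$founder)
  mk <- founders$markers
  geno <- cpp_paths_to_geno(seg$line, seg$hap, seg$chrom, seg$end,
                            seg$founder, founders$haplotypes,
                            match(mk$chrom, map$chromosomes), mk$pos,
                            n_total)
  dimnames(geno) <- list(sprintf("L%04d", seq_len(n_total)), mk$id)
  mk$domain <- domain_of(map, mk$chrom, mk$pos)
  config <- evolution_config(census = census,
                             generations = design$generations[1L],
                             outcross_p = design$outcross_p[1L],
                             selfing_gens = selfing_gens,
                             n_lines = n_total, seed = seed)
  structure(list(genotypes = geno, paths = paths, markers = mk,
                 founders = founders, map = map, config = config,
                 design = design,
                 population = rep(design$label, design$n_lines),
                 mutations = empty_mutation_registry()),
            class = "panel_realization")
}

#' Sample single meioses from a fully heterozygous F1
#'
#' Low-level access to the crossover model: generates `n` gametes from an
#' F1 carrying founder 1 and founder 2 chromosomes, returning their truth
#' paths.  Useful for checking the crossover-count/map-length contract and
#' for building doubled-haploid panels that have experienced exactly one
#' meiosis.
#'
#' @param map a [genetic_map].
#' @param n number of gametes.
#' @param seed optional integer seed.
#' @return data.frame with columns gamete, chrom, end, founder.
#' @export
sim_meioses <- function(map, n, seed = NULL) {
  stopifnot(inherits(map, "genetic_map"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- .map_cpp_args(map)
  g <- cpp_sim_meioses(a$chrom_len, a$dom_chrom, a$dom_start, a$dom_end,
                       a$dom_rate, as.integer(n))
  data.frame(gamete = g$gamete, chrom = map$chromosomes[g$chrom],
             end = g$end, founder = g$founder)
}

#' Realized map expansion from truth paths
#'
#' Map expansion Ra is the mean number of realized founder-switch
#' breakpoints per line and chromosome, relative to the expected
#' transmitted crossover count of a single meiosis under the map (the map
#' length in Morgans).  A panel of unrecombined founder chromosomes has
#' Ra = 0; doubled haploids of single-meiosis gametes have Ra near 1; Ra
#' grows with the number of effective outcrossing generations.
#'
#' @param x a [panel_realization], or a truth-path data.frame with columns
#'   `chrom`, `end`, `founder` and either `line` (+ optional `hap`) or
#'   `gamete` (as returned by [sim_meioses()]).
#' @param map the [genetic_map]; taken from `x` when `x` is a panel.
#' @return named numeric vector of per-chromosome Ra, with attribute
#'   `"overall"` (mean across chromosomes).
#' @export
estimate_map_expansion <- function(x, map = NULL) {
  if (inherits(x, "panel_realization")) {
    map <- x$map
    paths <- x$paths
  } else {
    paths <- as.data.frame(x)
    if (is.null(map)) stop("map is required when x is a paths data.frame")
    if (is.null(paths$line)) paths$line <- paths$gamete
    if (is.null(paths$hap)) paths$hap <- 1L
  }
  if (nrow(paths) == 0L) stop("empty truth paths")
  n_units <- nrow(unique(paths[c("line", "hap")]))
  ra <- vapply(map$chromosomes, function(ch) {
    p <- paths[paths$chrom == ch, ]
    # breakpoints = segments - 1 per (line, hap); absent rows impossible
    nbp <- nrow(p) - n_units
    exp1 <- map$cM[[ch]] / 100  # transmitted crossovers per meiosis
    (nbp / n_units) / exp1
  }, numeric(1))
  names(ra) <- map$chromosomes
  attr(ra, "overall") <- mean(ra)
  ra
}

#' Residual marker heterozygosity per line
#'
#' Fraction of markers with dosage strictly between 0 and 1 for each line.
#' After s generations of selfing from a fully heterozygous hybrid the
#' expectation is 2^-s.
#'
#' @param panel a [panel_realization].
#' @return numeric vector, one value per line.
#' @export
residual_heterozygosity <- function(panel) {
  stopifnot(inherits(panel, "panel_realization"))
  g <- panel$genotypes
  rowMeans(g > 0 & g < 1)
}
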