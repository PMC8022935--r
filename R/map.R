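#' Domain-structured genetic map
#'
#' A genetic map for a set of chromosomes, each tiled by recombination-rate
#' domains (half-open physical intervals with a constant cM/Mb rate).  The
#' default map emulates the C. elegans karyotype: six chromosomes (I-V, X),
#' a 50 cM total map per chromosome, near-zero-rate tips, high-rate arms and
#' a low-rate center occupying roughly the middle half of the physical length.
#'
#' @param chromosomes character vector of chromosome labels.
#' @param lengths physical chromosome lengths in bp, same order.
#' @param domains data.frame with columns `chrom`, `start`, `end` (bp,
#'   half-open `[start, end)`), `rate` (cM/Mb) and optionally `class`
#'   (e.g. "tip"/"arm"/"center").  Domains must tile each chromosome
#'   exactly, with no gaps or overlaps, and rates must be non-negative.
#' @return An object of class `genetic_map`: a list with elements
#'   `chromosomes`, `lengths` (named, bp), `domains` and `cM` (named total
#'   map length per chromosome).
#' @examples
#' map <- default_genetic_map()
#' map$cM  # 50 cM per chromosome
#' @export
genetic_map <- function(chromosomes, lengths, domains) {
  stopifnot(length(chromosomes) == length(lengths), all(lengths > 0))
  domains <- as.data.frame(domains)
  need <- c("chrom", "start", "end", "rate")
  if (!all(need %in% names(domains)))
    stop("domains must have columns chrom, start, end, rate")
  if (is.null(domains$class)) domains$class <- NA_character_
  if (any(domains$rate < 0)) stop("recombination rates must be >= 0")
  domains <- domains[order(match(domains$chrom, chromosomes), domains$start), ]
  for (i in seq_along(chromosomes)) {
    d <- domains[domains$chrom == chromosomes[i], ]
    if (nrow(d) == 0L) stop("chromosome ", chromosomes[i], " has no domains")
    if (d$start[1] != 0 || abs(d$end[nrow(d)] - lengths[i]) > 1e-6 ||
        (nrow(d) > 1 && any(abs(d$start[-1] - d$end[-nrow(d)]) > 1e-6)))
      stop("domains must tile chromosome ", chromosomes[i],
           " exactly with no gaps or overlaps")
  }
  cm <- vapply(seq_along(chromosomes), function(i) {
    d <- domains[domains$chrom == chromosomes[i], ]
    sum(d$rate * (d$end - d$start) / 1e6)
  }, numeric(1))
  names(cm) <- chromosomes
  lengths <- stats::setNames(as.numeric(lengths), chromosomes)
  structure(list(chromosomes = chromosomes, lengths = lengths,
                 domains = domains, cM = cm),
            class = "genetic_map")
}

#' @rdname genetic_map
#' @param total_cM total map length per chromosome (cM).
#' @param arm_center_ratio ratio of the arm to the center cM/Mb rate.
#' @details `default_genetic_map()` places, on each chromosome, two tips
#'   (3.5% of physical length each, rate 0), two arms (23.5% each) and a
#'   center (46%), with the arm rate `arm_center_ratio` times the center
#'   rate and both solved so the chromosome totals `total_cM`.
#' @export
default_genetic_map <- function(total_cM = 50, arm_center_ratio = 3.5) {
  chrs <- c("I", "II", "III", "IV", "V", "X")
  len <- c(15.07, 15.28, 13.78, 17.49, 20.92, 17.72) * 1e6  # ~WS220 sizes
  fr <- c(tip = 0.035, arm = 0.235, center = 0.46)
  doms <- do.call(rbind, lapply(seq_along(chrs), function(i) {
    L <- len[i]
    b <- cumsum(c(0, fr["tip"], fr["arm"], fr["center"], fr["arm"],
                  fr["tip"])) * L
    # total_cM = L/1e6 * rc * (ratio*2*arm_frac + center_frac)
    rc <- total_cM / (L / 1e6) /
      (arm_center_ratio * 2 * fr[["arm"]] + fr[["center"]])
    data.frame(chrom = chrs[i], start = b[-6], end = b[-1],
               rate = c(0, arm_center_ratio * rc, rc,
                        arm_center_ratio * rc, 0),
               class = c("tip", "arm", "center", "arm", "tip"))
  }))
  genetic_map(chrs, len, doms)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map> ", length(x$chromosomes), " chromosomes, ",
      sum(x$lengths) / 1e6, " Mb, ", sum(x$cM), " cM total\n", sep = "")
  invisible(x)
}

#' Recombination-rate domain of physical positions
#'
#' @param map a [genetic_map].
#' @param chrom,pos chromosome labels and physical positions (bp, 1-based).
#' @return character vector of domain classes ("tip", "arm", "center" for
#'   the default map) for each position.
#' @export
domain_of <- function(map, chrom, pos) {
  stopifnot(inherits(map, "genetic_map"), length(chrom) == length(pos))
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    d <- map$domains[map$domains$chrom == ch, ]
    if (nrow(d) == 0L) stop("unknown chromosome: ", ch)
    i <- which(chrom == ch)
    k <- findInterval(pos[i] - 1e-9, d$start)  # [start, end)
    k[k < 1] <- 1
    out[i] <- d$class[k]
  }
  out
}

# map passed to the C++ core as flat vectors
.map_cpp_args <- function(map) {
  d <- map$domains
  list(chrom_len = unname(map$lengths),
       dom_chrom = match(d$chrom, map$chromosomes) - 1L,
       dom_start = d$start, dom_end = d$end, dom_rate = d$rate)
}
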