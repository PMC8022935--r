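#' Write panel genotypes as a VCF 4.2 file
#'
#' Emits diploid GT calls for each line (phased `0|0` / `1|1` where
#' homozygous, `0/1` for residual heterozygotes) against placeholder
#' ref/alt alleles, one record per marker.
#'
#' @param panel a [panel_realization].
#' @param path output file (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "panel_realization"))
  g <- panel$genotypes
  mk <- panel$markers
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=mppqtl", " simulate"),
               paste0("##contig=<ID=", panel$map$chromosomes, ",length=",
                      format(panel$map$lengths, scientific = FALSE,
                             trim = TRUE), ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(g)),
                     collapse = "\t")), con)
  gt <- matrix("0/1", nrow(g), ncol(g))
  gt[g == 0] <- "0|0"
  gt[g == 1] <- "1|1"
  lines <- paste(mk$chrom, format(mk$pos, scientific = FALSE, trim = TRUE),
                 mk$id, "A", "T", ".", "PASS", ".", "GT",
                 apply(gt, 2L, function(col) paste(col, collapse = "\t")),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a variant table as VCF 4.2 with GATK-style INFO annotations
#'
#' @param vt a [variant_table].
#' @param path output file (plain text).
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  info <- vt$info
  con <- file(path, "w")
  on.exit(close(con))
  keys <- c("MQ", "DP", "QD", "SOR", "ReadPosRankSum")
  writeLines(c("##fileformat=VCFv4.2",
               vapply(keys, function(k) paste0(
                 "##INFO=<ID=", k, ",Number=1,Type=Float,Description=\"",
                 k, "\">"), character(1)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", vt$samples),
                     collapse = "\t")), con)
  fmt_info <- function(i) {
    vals <- vapply(keys, function(k) {
      v <- info[[k]][i]
      if (is.na(v)) NA_character_ else paste0(k, "=", format(v, digits = 8))
    }, character(1))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) "." else paste(vals, collapse = ";")
  }
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(info), length(vt$samples))
  for (k in 0:2) gt[which(vt$geno == k)] <- code[k + 1]
  lines <- vapply(seq_len(nrow(info)), function(i) {
    paste(c(info$chrom[i],
            format(info$pos[i], scientific = FALSE, trim = TRUE),
            info$id[i], info$ref[i], info$alt[i],
            if (is.na(info$QUAL[i])) "." else
              format(info$QUAL[i], digits = 8),
            "PASS", fmt_info(i), "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Reads VCF 4.2 via vcfR and extracts the QUAL column, the INFO
#' annotations used by the hard filters (MQ, DP, QD, SOR,
#' ReadPosRankSum) and per-sample GT calls coded 0/1/2/NA.
#'
#' @param path VCF file.
#' @return a [variant_table].
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     QUAL = suppressWarnings(as.numeric(fix$QUAL)))
  if (!all(is.na(fix$ID)) && !any(fix$ID == ".")) info$id <- fix$ID
  for (k in c("MQ", "DP", "QD", "SOR", "ReadPosRankSum"))
    info[[k]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = k)))
  gtc <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "0|1", "1/0", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  geno <- apply(gtc, 2L, code)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(info))
  colnames(geno) <- colnames(gtc)
  variant_table(info, geno)
}

#' Write genotype dosages as TSV
#'
#' @param panel a [panel_realization] or dosage matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(panel, path) {
  g <- if (inherits(panel, "panel_realization")) panel$genotypes else
    as.matrix(panel)
  df <- data.frame(line = rownames(g), g, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write truth founder-haplotype paths as BED-like segments
#'
#' One row per segment, 0-based half-open coordinates, with the founder
#' label in the name column and line/haplotype identifiers.
#'
#' @param panel a [panel_realization].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paths_bed <- function(panel, path) {
  stopifnot(inherits(panel, "panel_realization"))
  p <- panel$paths
  p <- p[order(p$line, p$hap, p$chrom, p$end), ]
  key <- split(seq_len(nrow(p)), list(p$line, p$hap, p$chrom), drop = TRUE)
  p$start <- 0
  for (idx in key) p$start[idx] <- c(0, utils::head(p$end[idx], -1))
  out <- data.frame(chrom = p$chrom,
                    start = format(p$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(p$end, scientific = FALSE, trim = TRUE),
                    name = sprintf("F%02d", p$founder),
                    line = p$line, hap = p$hap)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a mutation registry as TSV
#'
#' @param panel a [panel_realization] (after [inject_mutations()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_registry_tsv <- function(panel, path) {
  utils::write.table(panel$mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a scan result as TSV
#'
#' @param scan a [scan_additive()] result.
#' @param markers optional marker table (chrom, pos) to prepend.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path, markers = NULL) {
  out <- as.data.frame(scan)
  if (!is.null(markers)) out <- cbind(markers[c("chrom", "pos")], out)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write detection intervals as BED (0-based half-open)
#'
#' @param iv a [define_intervals()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(iv, path) {
  out <- data.frame(chrom = iv$chrom,
                    start = format(iv$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(iv$end, scientific = FALSE, trim = TRUE),
                    name = paste0("QTL_", seq_len(nrow(iv))),
                    peak_pos = iv$peak_pos, peak_lod = iv$peak_lod,
                    peak_p = iv$peak_p)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a power report as TSV + JSON
#'
#' @param report a [power_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "power_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$power, file.path(dir, "power.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$resolution))
    utils::write.table(report$resolution, file.path(dir, "resolution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$metadata, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an evolution configuration from YAML
#'
#' Accepts a flat YAML file mirroring [evolution_config()] fields (plus
#' optional `n_founders`, `m_markers`, `sfs_skew`).
#'
#' @param path YAML file.
#' @return list with `config` (an [evolution_config()]) and `extra`
#'   (founder/marker settings).
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("census", "generations", "outcross_p", "selfing_gens",
             "n_lines", "mu", "x_ne_factor", "label", "seed")
  cfg <- do.call(evolution_config, y[intersect(names(y), known)])
  list(config = cfg, extra = y[setdiff(names(y), known)])
}
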