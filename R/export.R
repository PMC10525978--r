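#' Export a population as PLINK .ped/.map text files
#'
#' SNPs only; alleles coded 1/2; the .map genetic-distance column is in
#' centimorgans (map positions in Morgans x 100) and the base-pair column
#' is a synthetic integer position (Morgans x 1e6, rounded).
#'
#' @param pop a `Population`.
#' @param spec the `GenomeSpec`.
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(pop, spec, prefix) {
  snp <- spec$snp_idx
  map <- data.frame(chr = spec$loci$chr[snp],
                    id = paste0("snp", seq_along(snp)),
                    cm = spec$loci$pos[snp] * 100,
                    bp = as.integer(round(spec$loci$pos[snp] * 1e6)))
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE)
  n <- n_ind(pop)
  H <- pop$haplo[, snp, drop = FALSE] + 1L  # alleles 1/2
  h1 <- H[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- H[seq(2L, 2L * n, 2L), , drop = FALSE]
  geno <- matrix(0L, n, 2L * length(snp))
  geno[, seq(1L, ncol(geno), 2L)] <- h1
  geno[, seq(2L, ncol(geno), 2L)] <- h2
  ped <- data.frame(fid = pop$generation, iid = pop$id,
                    pat = ifelse(is.na(pop$sire), 0L, pop$sire),
                    mat = ifelse(is.na(pop$dam), 0L, pop$dam),
                    sex = ifelse(pop$sex == "M", 1L, 2L),
                    pheno = -9L)
  data.table::fwrite(cbind(ped, as.data.frame(geno)), paste0(prefix, ".ped"),
                     sep = " ", col.names = FALSE)
  invisible(prefix)
}

#' Export a population as an uncompressed VCF with phased genotypes
#'
#' @param pop a `Population`.
#' @param spec the `GenomeSpec`.
#' @param path output `.vcf` path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(pop, spec, path) {
  snp <- spec$snp_idx
  n <- n_ind(pop)
  h1 <- pop$haplo[seq(1L, 2L * n, 2L), snp, drop = FALSE]
  h2 <- pop$haplo[seq(2L, 2L * n, 2L), snp, drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = length(snp))
  body <- data.frame(CHROM = spec$loci$chr[snp],
                     POS = as.integer(round(spec$loci$pos[snp] * 1e6)),
                     ID = paste0("snp", seq_along(snp)),
                     REF = "A", ALT = "B", QUAL = ".", FILTER = "PASS",
                     INFO = ".", FORMAT = "GT")
  header <- c("##fileformat=VCFv4.2",
              "##source=breedopt",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0("ind", pop$id)),
                    collapse = "\t"))
  writeLines(header, path)
  data.table::fwrite(cbind(body, as.data.frame(gt)), path, sep = "\t",
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write GEBV / WSG tables as CSV
#'
#' @param ids individual ids.
#' @param values named list or data.frame of per-individual columns
#'   (e.g. per-trait GEBVs, WSG).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_evaluation <- function(ids, values, path) {
  data.table::fwrite(cbind(data.frame(id = ids), as.data.frame(values)), path)
  invisible(path)
}
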