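#' Build a genome map for forward simulation
#'
#' Lays out `n_snps` biallelic SNPs evenly across `n_chr` chromosomes of
#' genetic length `chr_len` Morgans (midpoint grid, so a chromosome with
#' `m` SNPs has spacing `chr_len / m`), and places `n_qtl` QTL uniformly at
#' random on the same map. QTL are simulated as loci distinct from the SNP
#' grid: SNP-based statistics (kinship, heterozygosity, GBLUP) use SNPs
#' only, while trait machinery uses QTL only. `n_dominant` of the QTL are
#' flagged as carrying dominance effects.
#'
#' @param n_chr number of chromosomes.
#' @param chr_len genetic length of each chromosome in Morgans.
#' @param n_snps total number of evenly spaced SNPs across the genome.
#' @param n_qtl total number of QTL, placed uniformly at random.
#' @param n_dominant number of QTL carrying dominance effects
#'   (`n_dominant <= n_qtl`).
#' @param mutation_rate per-locus, per-transmitted-gamete allele flip
#'   probability.
#' @param rng_seed optional integer; if given, QTL placement is drawn from
#'   a local RNG stream seeded with it (the global RNG state is restored).
#' @return An object of class `GenomeSpec`: a list with the locus table
#'   (`loci`: chromosome, position, type), index vectors `snp_idx` and
#'   `qtl_idx` into the locus table, `dominant_qtl_ids` (locus indices),
#'   per-chromosome locus ranges, and the scalar parameters.
#' @export
build_genome_spec <- function(n_chr, chr_len, n_snps, n_qtl, n_dominant,
                              mutation_rate, rng_seed = NULL) {
  if (n_chr < 1 || chr_len <= 0)
    stop("invalid genome specification: need n_chr >= 1 and chr_len > 0")
  if (n_snps < 0 || n_qtl < 0 || n_dominant < 0)
    stop("invalid genome specification: counts must be non-negative")
  if (n_snps + n_qtl < 1)
    stop("invalid genome specification: at least one locus required")
  if (n_dominant > n_qtl)
    stop("invalid genome specification: n_dominant must not exceed n_qtl")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("invalid genome specification: mutation_rate must lie in [0, 1]")

  if (!is.null(rng_seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(rng_seed)
  }

  # distribute SNPs across chromosomes as evenly as possible
  snp_per_chr <- rep(n_snps %/% n_chr, n_chr)
  extra <- n_snps %% n_chr
  if (extra > 0) snp_per_chr[seq_len(extra)] <- snp_per_chr[seq_len(extra)] + 1
  qtl_chr <- if (n_qtl > 0) sample.int(n_chr, n_qtl, replace = TRUE) else integer(0)

  chr <- integer(0); pos <- numeric(0); type <- character(0)
  for (c in seq_len(n_chr)) {
    m <- snp_per_chr[c]
    sp <- if (m > 0) (seq_len(m) - 0.5) * chr_len / m else numeric(0)
    qp <- sort(stats::runif(sum(qtl_chr == c), 0, chr_len))
    cp <- c(sp, qp)
    ct <- c(rep("snp", length(sp)), rep("qtl", length(qp)))
    o <- order(cp)
    chr <- c(chr, rep(c, length(cp)))
    pos <- c(pos, cp[o])
    type <- c(type, ct[o])
  }
  loci <- data.frame(chr = chr, pos = pos, type = type)
  qtl_idx <- which(loci$type == "qtl")
  dom <- if (n_dominant > 0) sort(sample(qtl_idx, n_dominant)) else integer(0)

  spec <- list(
    n_chromosomes = n_chr,
    chr_length = chr_len,
    mutation_rate = mutation_rate,
    loci = loci,
    snp_idx = which(loci$type == "snp"),
    qtl_idx = qtl_idx,
    dominant_qtl_ids = dom,
    # empty chromosomes get (first, last) = (1, 0) so locus loops skip them
    chr_first = vapply(seq_len(n_chr), function(c) {
      w <- which(loci$chr == c); if (length(w)) min(w) else 1L
    }, 1L),
    chr_last = vapply(seq_len(n_chr), function(c) {
      w <- which(loci$chr == c); if (length(w)) max(w) else 0L
    }, 1L)
  )
  class(spec) <- "GenomeSpec"
  spec
}

#' @export
print.GenomeSpec <- function(x, ...) {
  cat("GenomeSpec:", x$n_chromosomes, "chromosomes x", x$chr_length, "M;",
      length(x$snp_idx), "SNPs,", length(x$qtl_idx), "QTL (",
      length(x$dominant_qtl_ids), "with dominance ); mutation rate",
      x$mutation_rate, "\n")
  invisible(x)
}

n_loci <- function(spec) nrow(spec$loci)
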