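#' Sample a quantitative-trait architecture
#'
#' For each trait, additive QTL effects are drawn i.i.d. standard normal
#' and dominance effects (at the dominance-flagged QTL only) i.i.d. normal
#' at half the additive scale. Effects are then rescaled so the variance of
#' true genetic values in `reference_pop` equals 1, putting all gains in
#' founder genetic-SD units; the residual variance is set to
#' `(1 - h2) / h2` so the narrow-ish-sense heritability in the reference
#' population matches the target.
#'
#' Traits are genetically independent: each draws its own effect vectors.
#'
#' @param spec a `GenomeSpec` with at least one QTL.
#' @param heritabilities numeric vector of per-trait heritabilities in
#'   (0, 1).
#' @param reference_pop the `Population` used to calibrate the genetic
#'   scale (typically the founder generation).
#' @return a list of `TraitArchitecture` objects (fields `trait_id`, `a`,
#'   `d`, `h2`, `env_variance`).
#' @export
sample_architecture <- function(spec, heritabilities, reference_pop) {
  if (any(heritabilities <= 0 | heritabilities >= 1))
    stop("invalid heritability: must lie in (0, 1)")
  if (length(spec$qtl_idx) == 0)
    stop("genome has no QTL; cannot build a trait architecture")
  if (n_ind(reference_pop) < 2)
    stop("reference population too small to calibrate genetic variance")
  n_qtl <- length(spec$qtl_idx)
  dom <- match(spec$dominant_qtl_ids, spec$qtl_idx)
  X <- dosage_matrix(reference_pop, spec, "qtl")
  lapply(seq_along(heritabilities), function(t) {
    a <- stats::rnorm(n_qtl)
    d <- numeric(n_qtl)
    if (length(dom)) d[dom] <- stats::rnorm(length(dom), sd = 0.5)
    g <- as.vector(X %*% a + (X == 1L) %*% d)
    s <- stats::sd(g)
    if (s == 0) stop("reference population has no genetic variance at QTL")
    arch <- list(trait_id = t, a = a / s, d = d / s,
                 h2 = heritabilities[t],
                 env_variance = (1 - heritabilities[t]) / heritabilities[t])
    class(arch) <- "TraitArchitecture"
    arch
  })
}

#' True genetic values under a trait architecture
#'
#' Returns, per individual, `sum_i dosage_i * a_i + sum_i het_i * d_i`
#' where dosage is the QTL allele-1 count in \{0, 1, 2\} and `het_i`
#' indicates heterozygosity.
#'
#' @param pop a `Population`.
#' @param arch a `TraitArchitecture`.
#' @param spec the `GenomeSpec`.
#' @return numeric vector, one value per member of `pop`.
#' @export
true_genetic_values <- function(pop, arch, spec) {
  X <- dosage_matrix(pop, spec, "qtl")
  as.vector(X %*% arch$a + (X == 1L) %*% arch$d)
}

#' True genetic value of one individual
#' @inheritParams true_genetic_values
#' @param ind member index within `pop`.
#' @return scalar.
#' @export
true_genetic_value <- function(pop, ind, arch, spec) {
  true_genetic_values(pop_subset(pop, ind), arch, spec)
}

#' Simulate phenotypes
#'
#' Phenotype = true genetic value + Normal(0, `env_variance`) residual.
#'
#' @param pop a `Population`.
#' @param archs list of `TraitArchitecture` (one per trait).
#' @param spec the `GenomeSpec`.
#' @return numeric matrix, individuals x traits.
#' @export
phenotypes <- function(pop, archs, spec) {
  n <- n_ind(pop)
  ph <- vapply(archs, function(arch) {
    true_genetic_values(pop, arch, spec) +
      stats::rnorm(n, sd = sqrt(arch$env_variance))
  }, numeric(n))
  matrix(ph, nrow = n)  # keep matrix shape even for a single individual
}

#' Write a trait architecture as a table
#'
#' One row per QTL: locus index, chromosome, position, additive and
#' dominance effect per trait.
#'
#' @param archs list of `TraitArchitecture`.
#' @param spec the `GenomeSpec`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_architecture <- function(archs, spec, path) {
  tab <- data.frame(locus = spec$qtl_idx,
                    chr = spec$loci$chr[spec$qtl_idx],
                    pos = spec$loci$pos[spec$qtl_idx])
  for (arch in archs) {
    tab[[paste0("a_trait", arch$trait_id)]] <- arch$a
    tab[[paste0("d_trait", arch$trait_id)]] <- arch$d
  }
  data.table::fwrite(tab, path)
  invisible(path)
}
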