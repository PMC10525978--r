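#' Genetic gain relative to a founder baseline
#'
#' Mean of the current generation's (GE)BVs minus the mean of the founder
#' population's; replicate averaging is applied at the experiment level.
#'
#' @param current numeric vector for the current generation.
#' @param founder_baseline numeric vector for the founder population.
#' @return scalar gain.
#' @export
genetic_gain <- function(current, founder_baseline) {
  if (length(current) == 0 || length(founder_baseline) == 0)
    stop("metric error: empty input")
  mean(current) - mean(founder_baseline)
}

#' Pairwise genomic kinship (identity-in-state based)
#'
#' Per locus, `f_IIS` is the probability that one random allele from each
#' individual is identical in state: 1 for identical homozygotes, 0 for
#' opposite homozygotes, 0.5 when either is heterozygous. The kinship is
#' the mean over polymorphic loci of
#' `(f_IIS - p^2 - q^2) / (2 p q)`, with `p`, `q` the current-generation
#' allele frequencies.
#'
#' @param gi,gj dosage vectors in \{0, 1, 2\} of the two individuals.
#' @param freqs allele-1 frequency per locus in the current generation.
#' @return scalar kinship coefficient.
#' @export
pairwise_kinship <- function(gi, gj, freqs) {
  stopifnot(length(gi) == length(gj), length(gi) == length(freqs))
  poly <- freqs > 0 & freqs < 1
  if (!any(poly)) stop("metric error: no polymorphic loci")
  gi <- gi[poly]; gj <- gj[poly]; p <- freqs[poly]; q <- 1 - p
  f_iis <- (gi * gj + (2 - gi) * (2 - gj)) / 4
  mean((f_iis - p^2 - q^2) / (2 * p * q))
}

#' All-pairs IIS kinship matrix
#'
#' Vectorized form of [pairwise_kinship()] for a whole population:
#' `K[i, j]` is the IIS kinship between individuals `i` and `j` at the
#' polymorphic loci of `X`. By default the standardizing allele
#' frequencies are `X`'s own; passing `freqs` (e.g. founder-generation
#' frequencies) anchors the statistic so that it accumulates across
#' generations instead of being re-centered to ~0 every generation. The
#' diagonal holds self-kinship (excluded from [average_kinship()]).
#'
#' @param X individuals x loci dosage matrix in \{0, 1, 2\}.
#' @param freqs optional per-locus allele-1 frequencies to standardize
#'   against (length `ncol(X)`); default: frequencies of `X` itself.
#' @return symmetric `n x n` matrix.
#' @export
iis_kinship_matrix <- function(X, freqs = NULL) {
  p <- if (is.null(freqs)) colMeans(X) / 2 else freqs
  stopifnot(length(p) == ncol(X))
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("metric error: no polymorphic loci")
  X <- X[, poly, drop = FALSE]; p <- p[poly]; q <- 1 - p
  w <- 1 / (2 * p * q)
  m <- length(p)
  Xw <- sweep(X, 2, w, `*`)
  Yw <- sweep(2 - X, 2, w, `*`)
  Fw <- (tcrossprod(Xw, X) + tcrossprod(Yw, 2 - X)) / 4
  (Fw - sum((p^2 + q^2) * w)) / m
}

#' Average kinship coefficient of a generation
#'
#' Mean of [pairwise_kinship()] over all unordered distinct pairs
#' (self-pairs excluded). With `freqs = NULL` the current generation's own
#' frequencies standardize the statistic; note that in that case the
#' distinct-pair average is constrained near `-(1 + F) / (2 (n - 1))`
#' (summing identity-in-state over all ordered pairs including self-pairs
#' recovers exactly the gene-pool homozygosity), so a kinship level that
#' accumulates over generations requires anchoring `freqs` at a reference
#' (founder) generation.
#'
#' @param X individuals x SNP dosage matrix.
#' @param freqs optional anchoring allele frequencies (see
#'   [iis_kinship_matrix()]).
#' @return scalar average kinship.
#' @export
average_kinship <- function(X, freqs = NULL) {
  if (nrow(X) < 2) stop("metric error: need at least two individuals")
  K <- iis_kinship_matrix(X, freqs)
  mean(K[upper.tri(K)])
}

#' QTL effect variance
#'
#' `sigma^2 = mean over QTL of 2 p_i (1 - p_i) a_i^2`: the usable additive
#' variance remaining at the QTL.
#'
#' @param freqs QTL allele-frequency vector.
#' @param a additive-effect vector, same length.
#' @return scalar variance.
#' @export
qtl_effect_variance <- function(freqs, a) {
  if (length(freqs) == 0) stop("metric error: empty input")
  stopifnot(length(freqs) == length(a))
  mean(2 * freqs * (1 - freqs) * a^2)
}

#' Observed heterozygosity
#'
#' Fraction of heterozygous calls per individual over all loci of `X`
#' (monomorphic included), averaged over individuals.
#'
#' @param X individuals x SNP dosage matrix.
#' @return scalar in \[0, 1\].
#' @export
observed_heterozygosity <- function(X) {
  if (nrow(X) == 0 || ncol(X) == 0) stop("metric error: empty genotypes")
  mean(rowMeans(X == 1))
}
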