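#' Genomic relationship matrix (VanRaden method 1)
#'
#' `K = Z Z' / (2 * sum p_k (1 - p_k))` with `Z = M - 2P`, allele
#' frequencies taken from the evaluated genotypes themselves. Monomorphic
#' SNPs are excluded.
#'
#' @param M individuals x SNP dosage matrix with entries in \{0, 1, 2\}.
#' @return symmetric `n x n` relationship matrix.
#' @export
compute_grm <- function(M) {
  if (nrow(M) < 2) stop("need at least two individuals for a GRM")
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("degenerate genotypes: all SNPs monomorphic")
  M <- M[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(M, 2, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  (K + t(K)) / 2
}

#' Solve GBLUP with known variance ratio
#'
#' Single-trait mixed model `y = mu + g + e`, `g ~ N(0, K sigma_g^2)`,
#' `e ~ N(0, I sigma_e^2)`, with the variance ratio plugged in as
#' `lambda = h2 / (1 - h2)`. The BLUP of `g` is
#' `g_hat = lambda K (lambda K + I)^{-1} (y - ybar)`.
#'
#' A small ridge (default `1e-6`) is added to the diagonal of `K` for
#' numerical stability.
#'
#' @param y numeric phenotype vector.
#' @param K genomic relationship matrix, `length(y)` square.
#' @param h2 heritability in (0, 1).
#' @param ridge diagonal stabilizer added to `K`.
#' @return numeric vector of GEBVs (mean approximately 0).
#' @export
solve_gblup <- function(y, K, h2, ridge = 1e-6) {
  if (h2 <= 0 || h2 >= 1) stop("invalid heritability: must lie in (0, 1)")
  if (length(y) != nrow(K)) stop("phenotype / relationship dimension mismatch")
  lambda <- h2 / (1 - h2)
  Kr <- K + diag(ridge, nrow(K))
  yc <- y - mean(y)
  C <- lambda * Kr + diag(nrow(Kr))
  sol <- tryCatch(solve(C, yc),
                  error = function(e) stop("GBLUP system not solvable: ",
                                           conditionMessage(e)))
  as.vector(lambda * (Kr %*% sol))
}

#' Weighted sum of GEBVs (multi-trait selection index)
#'
#' `WSG_i = sum_k w_k GEBV_ik` over the first four traits with default
#' weights 0.35 / 0.25 / 0.25 / 0.15 (which sum to 1).
#'
#' @param gebvs individuals x traits matrix of GEBVs (at least as many
#'   columns as weights).
#' @param weights trait weights; non-negative, summing to 1.
#' @return numeric vector of WSG values.
#' @export
compute_wsg <- function(gebvs, weights = c(0.35, 0.25, 0.25, 0.15)) {
  gebvs <- as.matrix(gebvs)
  if (ncol(gebvs) < length(weights))
    stop("incomplete evaluation: fewer traits than weights")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  as.vector(gebvs[, seq_along(weights), drop = FALSE] %*% weights)
}
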