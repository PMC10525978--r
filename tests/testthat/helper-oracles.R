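# Independent oracles used to validate the optimizers and the mixed-model
# solver, plus small fixture builders.

# Exhaustive enumeration over all binary assignment matrices with the
# transportation constraints; returns the maximal objective.
lp_bruteforce <- function(I, male_cap, female_cap, required) {
  a <- nrow(I); b <- ncol(I)
  cells <- expand.grid(r = seq_len(a), c = seq_len(b))
  comb <- utils::combn(nrow(cells), required)
  best <- -Inf
  for (k in seq_len(ncol(comb))) {
    s <- comb[, k]
    rs <- tabulate(cells$r[s], a); cs <- tabulate(cells$c[s], b)
    if (all(rs <= male_cap) && all(cs <= female_cap))
      best <- max(best, sum(I[cbind(cells$r[s], cells$c[s])]))
  }
  best
}

# Dense grid search (step 0.01) over the sex-constrained simplex for small
# OCS instances (3 males + 3 females). Returns the optimal objective.
ocs_grid <- function(g, K, sex, mode, bound, baseline, step = 0.01) {
  m <- which(sex == "M"); f <- which(sex == "F")
  stopifnot(length(m) == 3, length(f) == 3)
  k <- round(0.5 / step)
  comp <- as.matrix(expand.grid(i = 0:k, j = 0:k))
  comp <- comp[rowSums(comp) <= k, , drop = FALSE]
  Cs <- cbind(comp[, 1], comp[, 2], k - rowSums(comp)) * step
  n_c <- nrow(Cs)
  qm <- rowSums((Cs %*% K[m, m]) * Cs)
  qf <- rowSums((Cs %*% K[f, f]) * Cs)
  cross <- 2 * (Cs %*% K[m, f] %*% t(Cs))
  kin <- outer(qm, qf, `+`) + cross
  gain <- outer(as.vector(Cs %*% g[m]), as.vector(Cs %*% g[f]), `+`) - baseline
  if (mode == "maxBVE") {
    feas <- kin <= bound + 1e-12
    if (!any(feas)) return(NA_real_)
    max(gain[feas])
  } else {
    feas <- gain >= bound - 1e-12
    if (!any(feas)) return(NA_real_)
    min(kin[feas])
  }
}

# Mixed-model oracle on an independent algebraic path: inverts K and solves
# the MME form (I + K^-1 / lambda) g = y - ybar.
gblup_mme_oracle <- function(y, K, h2) {
  lambda <- h2 / (1 - h2)
  yc <- y - mean(y)
  solve(diag(length(y)) + solve(K) / lambda, yc)
}

# Build a Population directly from a haplotype matrix (2 rows per
# individual) for hand-constructed genotype cases.
make_pop <- function(haplo, sex, generation = 1L) {
  n <- length(sex)
  breedopt:::new_population(generation, seq_len(n), sex,
                            rep(NA_integer_, n), rep(NA_integer_, n),
                            matrix(as.integer(haplo), nrow = 2L * n))
}

# A random PD kinship-like matrix for solver tests.
random_kinship <- function(n, n_loci = 60) {
  X <- matrix(stats::rbinom(n * n_loci, 2, 0.5), n, n_loci)
  iis_kinship_matrix(X)
}
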