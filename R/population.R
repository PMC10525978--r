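#' @useDynLib breedopt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_population <- function(generation, id, sex, sire, dam, haplo) {
  stopifnot(length(id) == length(sex), nrow(haplo) == 2L * length(id))
  structure(list(generation = generation, id = as.integer(id),
                 sex = sex, sire = as.integer(sire), dam = as.integer(dam),
                 haplo = haplo),
            class = "Population")
}

#' Number of individuals in a Population
#' @param pop a `Population`.
#' @return integer count.
#' @export
n_ind <- function(pop) length(pop$id)

#' @export
print.Population <- function(x, ...) {
  cat("Population, generation", x$generation, ":", n_ind(x), "individuals (",
      sum(x$sex == "M"), "M /", sum(x$sex == "F"), "F ),",
      ncol(x$haplo), "loci\n")
  invisible(x)
}

#' Subset a Population by individual index
#' @param pop a `Population`.
#' @param idx integer vector of member positions to keep.
#' @return a `Population` with the selected members.
#' @export
pop_subset <- function(pop, idx) {
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  new_population(pop$generation, pop$id[idx], pop$sex[idx],
                 pop$sire[idx], pop$dam[idx], pop$haplo[rows, , drop = FALSE])
}

haplo_rows <- function(idx) as.vector(rbind(2L * idx - 1L, 2L * idx))

#' Genotype dosage matrix of a Population
#'
#' @param pop a `Population`.
#' @param spec the `GenomeSpec` the population was simulated under.
#' @param loci `"snp"`, `"qtl"` or `"all"`: which locus set to return.
#' @return an `n x m` integer matrix of allele-1 dosages in \{0, 1, 2\}.
#' @export
dosage_matrix <- function(pop, spec, loci = c("snp", "qtl", "all")) {
  loci <- match.arg(loci)
  H <- pop$haplo
  n <- n_ind(pop)
  D <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  keep <- switch(loci, snp = spec$snp_idx, qtl = spec$qtl_idx,
                 all = seq_len(ncol(D)))
  D[, keep, drop = FALSE]
}

#' Initialize the base (historical) population
#'
#' Alleles are drawn independently per locus at frequency `freq` (default
#' 0.5); the burn-in then establishes the frequency spectrum and LD. Males
#' are the first `floor(male_fraction * n)` individuals.
#'
#' @param spec a `GenomeSpec`.
#' @param n population size (>= 2).
#' @param male_fraction fraction of males (floor rounding).
#' @param freq initial allele frequency at every locus.
#' @return a `Population` with `generation = 1`.
#' @export
init_base_population <- function(spec, n, male_fraction = 0.5, freq = 0.5) {
  if (n < 2) stop("invalid population: need n >= 2")
  L <- n_loci(spec)
  haplo <- matrix(as.integer(stats::rbinom(2L * n * L, 1L, freq)),
                  nrow = 2L * n, ncol = L)
  n_m <- floor(male_fraction * n)
  sex <- c(rep("M", n_m), rep("F", n - n_m))
  new_population(1L, seq_len(n), sex, rep(NA_integer_, n), rep(NA_integer_, n),
                 haplo)
}

#' Simulate one gamete from a parent
#'
#' Per chromosome the crossover count is Poisson with mean equal to the
#' chromosome's genetic length in Morgans, crossover positions are uniform,
#' and strands alternate from a random starting strand; each locus then
#' mutates (allele flip) with probability `spec$mutation_rate`.
#'
#' @param pop a `Population` containing the parent.
#' @param ind index of the parent within `pop`.
#' @param spec the `GenomeSpec`.
#' @return integer vector of length `n_loci(spec)`.
#' @export
gamete <- function(pop, ind, spec) {
  as.vector(cpp_make_gametes(pop$haplo, 2L * as.integer(ind) - 1L,
                             spec$loci$pos, spec$chr_first, spec$chr_last,
                             rep(spec$chr_length, spec$n_chromosomes),
                             spec$mutation_rate))
}

make_gametes <- function(pop, inds, spec) {
  cpp_make_gametes(pop$haplo, 2L * as.integer(inds) - 1L,
                   spec$loci$pos, spec$chr_first, spec$chr_last,
                   rep(spec$chr_length, spec$n_chromosomes),
                   spec$mutation_rate)
}

#' Mate two individuals
#'
#' @param pop a `Population` containing both parents.
#' @param sire index of the sire (must be male).
#' @param dam index of the dam (must be female).
#' @param spec the `GenomeSpec`.
#' @param sex sex of the offspring, `"M"` or `"F"`.
#' @return a one-member `Population` holding the offspring.
#' @export
mate <- function(pop, sire, dam, spec, sex = c("M", "F")) {
  sex <- match.arg(sex)
  if (pop$sex[sire] != "M" || pop$sex[dam] != "F")
    stop("invalid mating: sire must be male and dam female")
  pat <- make_gametes(pop, sire, spec)
  mat <- make_gametes(pop, dam, spec)
  new_population(pop$generation + 1L, max(pop$id) + 1L, sex,
                 pop$id[sire], pop$id[dam], rbind(pat[1, ], mat[1, ]))
}

#' Breed the next generation
#'
#' With `plan = NULL` parents are drawn uniformly at random (each offspring
#' an independent sire and dam draw); otherwise `plan` is a mating plan
#' (`data.frame` with columns `sire`, `dam`, `n_offspring` of member ids in
#' `pop`). Generations are non-overlapping: the returned population
#' replaces `pop`.
#'
#' @param pop parental `Population`.
#' @param spec the `GenomeSpec`.
#' @param n_offspring number of offspring to produce (ignored when a plan
#'   is given: the plan's counts govern).
#' @param male_fraction fraction of male offspring (floor rounding).
#' @param plan optional `MatingPlan` data frame.
#' @param n_males exact male offspring count; overrides `male_fraction`.
#' @return offspring `Population` with `generation = pop$generation + 1`.
#' @export
breed_generation <- function(pop, spec, n_offspring, male_fraction = 0.5,
                             plan = NULL, n_males = NULL) {
  if (is.null(plan)) {
    males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
    if (n_offspring > 0 && (length(males) == 0 || length(females) == 0))
      stop("breeding impossible: a parental sex class is empty")
    sires <- if (n_offspring > 0) males[sample.int(length(males), n_offspring, replace = TRUE)] else integer(0)
    dams  <- if (n_offspring > 0) females[sample.int(length(females), n_offspring, replace = TRUE)] else integer(0)
  } else {
    si <- match(plan$sire, pop$id); di <- match(plan$dam, pop$id)
    if (anyNA(si) || anyNA(di))
      stop("mating plan references parents absent from the population")
    reps <- as.integer(plan$n_offspring)
    sires <- rep(si, reps); dams <- rep(di, reps)
    n_offspring <- length(sires)
  }
  L <- n_loci(spec)
  if (n_offspring == 0) {
    return(new_population(pop$generation + 1L, integer(0), character(0),
                          integer(0), integer(0),
                          matrix(integer(0), nrow = 0, ncol = L)))
  }
  pat <- make_gametes(pop, sires, spec)
  mat <- make_gametes(pop, dams, spec)
  haplo <- matrix(0L, nrow = 2L * n_offspring, ncol = L)
  haplo[seq(1L, 2L * n_offspring, by = 2L), ] <- pat
  haplo[seq(2L, 2L * n_offspring, by = 2L), ] <- mat
  n_m <- if (is.null(n_males)) floor(male_fraction * n_offspring) else as.integer(n_males)
  sex <- c(rep("M", n_m), rep("F", n_offspring - n_m))
  off_id <- max(pop$id, 0L) + seq_len(n_offspring)
  new_population(pop$generation + 1L, off_id, sex,
                 pop$id[sires], pop$id[dams], haplo)
}

#' Random-mating burn-in
#'
#' Creates a base population of size `n` (1:1 sex ratio) and runs
#' `n_generations` of non-overlapping random mating at constant size to
#' establish linkage disequilibrium and mutation-drift equilibrium.
#'
#' @param spec a `GenomeSpec`.
#' @param n_generations number of random-mating generations.
#' @param n constant population size.
#' @param freq initial allele frequency (see [init_base_population()]).
#' @return the final `Population` (generation index `n_generations + 1`).
#' @export
run_burn_in <- function(spec, n_generations, n, freq = 0.5) {
  pop <- init_base_population(spec, n, 0.5, freq)
  for (g in seq_len(n_generations))
    pop <- breed_generation(pop, spec, n, 0.5)
  pop
}

#' Expand a population along a linear schedule
#'
#' Interpolates total size and male count linearly (rounded) from the
#' current values to `target_n` / `target_males` over `n_generations` of
#' random mating, e.g. 1000 (500 M) to 1400 (200 M) over 5 generations.
#'
#' @param pop starting `Population`.
#' @param spec the `GenomeSpec`.
#' @param target_n final population size.
#' @param target_males final male count.
#' @param n_generations number of generations in the schedule.
#' @return the final `Population` with exactly `target_n` members of whom
#'   `target_males` are male.
#' @export
run_expansion <- function(pop, spec, target_n, target_males, n_generations) {
  if (target_males > target_n)
    stop("invalid schedule: target_males exceeds target_n")
  n0 <- n_ind(pop); m0 <- sum(pop$sex == "M")
  sizes <- round(seq(n0, target_n, length.out = n_generations + 1))[-1]
  males <- round(seq(m0, target_males, length.out = n_generations + 1))[-1]
  if (any(males > sizes) || any(males < 0))
    stop("invalid schedule: male count incompatible with size")
  for (g in seq_len(n_generations))
    pop <- breed_generation(pop, spec, sizes[g], n_males = males[g])
  pop
}

#' Split a population into two founder populations
#'
#' Random split stratified by sex: half of each sex (counts must be even)
#' goes to each founder population.
#'
#' @param pop a `Population` with even counts of each sex.
#' @return a list of two `Population`s (`fp1`, `fp2`).
#' @export
split_founders <- function(pop) {
  males <- which(pop$sex == "M"); females <- which(pop$sex == "F")
  if (length(males) %% 2L != 0L || length(females) %% 2L != 0L)
    stop("split error: sex-class counts must be even")
  m1 <- sort(sample(males, length(males) / 2))
  f1 <- sort(sample(females, length(females) / 2))
  i1 <- sort(c(m1, f1))
  i2 <- setdiff(seq_len(n_ind(pop)), i1)
  list(fp1 = pop_subset(pop, i1), fp2 = pop_subset(pop, i2))
}
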