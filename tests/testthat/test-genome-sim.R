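test_that("genome spec lays out SNPs evenly and validates inputs", {
  spec <- build_genome_spec(29, 2.33, 100000, 750, 125, 1e-5, rng_seed = 1)
  expect_equal(spec$n_chromosomes, 29)
  per_chr <- table(spec$loci$chr[spec$loci$type == "snp"])
  expect_true(all(per_chr %in% c(3448, 3449)))
  expect_length(spec$qtl_idx, 750)
  expect_length(spec$dominant_qtl_ids, 125)
  # positions strictly increasing within chromosome, inside [0, chr_len]
  for (c in c(1, 15, 29)) {
    p <- spec$loci$pos[spec$loci$chr == c]
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p <= 2.33))
  }

  s2 <- build_genome_spec(1, 1.0, 10, 0, 0, 0)
  expect_equal(diff(s2$loci$pos), rep(0.1, 9), tolerance = 1e-12)

  s3 <- build_genome_spec(2, 1.0, 4, 4, 4, 0, rng_seed = 7)
  expect_length(s3$dominant_qtl_ids, 4)
  expect_setequal(s3$dominant_qtl_ids, s3$qtl_idx)

  expect_error(build_genome_spec(0, 1, 10, 0, 0, 0), "invalid")
  expect_error(build_genome_spec(1, -1, 10, 0, 0, 0), "invalid")
  expect_error(build_genome_spec(1, 1, 4, 2, 3, 0), "invalid")
  expect_error(build_genome_spec(1, 1, 4, 0, 0, 2), "invalid")

  # reproducible QTL placement under seed, global RNG untouched
  set.seed(99); before <- runif(1)
  set.seed(99)
  a <- build_genome_spec(3, 1, 30, 10, 2, 0, rng_seed = 5)
  b <- build_genome_spec(3, 1, 30, 10, 2, 0, rng_seed = 5)
  expect_identical(a$loci, b$loci)
  expect_equal(runif(1), before)
})

test_that("base population has exact sex counts and binomial allele draws", {
  spec <- build_genome_spec(1, 1, 400, 0, 0, 0)
  set.seed(1)
  pop <- init_base_population(spec, 1000, 0.5)
  expect_equal(sum(pop$sex == "M"), 500)
  expect_equal(sum(pop$sex == "F"), 500)

  pop3 <- init_base_population(spec, 3, 0.5)
  expect_equal(sum(pop3$sex == "M"), 1)
  expect_equal(sum(pop3$sex == "F"), 2)
  expect_error(init_base_population(spec, 1, 0.5), "invalid")

  # mean allele frequency within 3 binomial SE of the initialization value
  p_hat <- mean(pop$haplo)
  se <- sqrt(0.25 / length(pop$haplo))
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("gametes respect homozygosity, forced mutation, and Poisson crossovers", {
  spec <- build_genome_spec(1, 2.33, 500, 0, 0, 0)
  n_l <- 500
  set.seed(2)
  # homozygous parent, no mutation: gamete deterministic
  hom <- make_pop(rbind(rep(1, n_l), rep(1, n_l)), "M")
  expect_equal(gamete(hom, 1, spec), rep(1L, n_l))

  # mutation_rate 1 flips every locus
  spec_mut <- build_genome_spec(1, 2.33, 500, 0, 0, 1)
  zero <- make_pop(rbind(rep(0, n_l), rep(0, n_l)), "M")
  expect_equal(gamete(zero, 1, spec_mut), rep(1L, n_l))

  # fully heterozygous phased parent: strand switches count crossovers
  het <- make_pop(rbind(rep(0, n_l), rep(1, n_l)), "M")
  G <- breedopt:::make_gametes(het, rep(1L, 10000), spec)
  switches <- rowSums(abs(G[, -1, drop = FALSE] - G[, -n_l, drop = FALSE]))
  se <- sqrt(2.33 / 10000)
  expect_lt(abs(mean(switches) - 2.33), 3 * se + 0.02)  # 0.02: unobserved double-crossover bias bound
  expect_lt(abs(var(switches) - 2.33), 0.15)
})

test_that("mating is Mendelian", {
  spec <- build_genome_spec(1, 1, 1, 0, 0, 0)
  set.seed(3)
  # sire AA x dam aa -> always Aa
  pop <- make_pop(rbind(1, 1, 0, 0), c("M", "F"))
  off <- breed_generation(pop, spec, 200,
                          plan = data.frame(sire = 1, dam = 2, n_offspring = 200))
  expect_true(all(dosage_matrix(off, spec, "all") == 1))
  expect_equal(unique(off$sire), 1L)
  expect_equal(unique(off$dam), 2L)

  # Aa x Aa -> 1:2:1 within 3 SE
  pop2 <- make_pop(rbind(0, 1, 0, 1), c("M", "F"))
  off2 <- breed_generation(pop2, spec, 10000,
                           plan = data.frame(sire = 1, dam = 2, n_offspring = 10000))
  d <- dosage_matrix(off2, spec, "all")
  for (k in 0:2) {
    p_exp <- c(0.25, 0.5, 0.25)[k + 1]
    se <- sqrt(p_exp * (1 - p_exp) / 10000)
    expect_lt(abs(mean(d == k) - p_exp), 3 * se)
  }

  expect_error(mate(pop2, 2, 1, spec), "invalid mating")
})

test_that("breed_generation handles plans, sexes and degenerate cases", {
  spec <- build_genome_spec(1, 1, 20, 0, 0, 0)
  set.seed(4)
  pop <- init_base_population(spec, 20, 0.5)
  off <- breed_generation(pop, spec, 1000, 0.5)
  expect_equal(n_ind(off), 1000)
  expect_equal(sum(off$sex == "M"), 500)
  expect_true(all(off$sire %in% pop$id[pop$sex == "M"]))
  expect_true(all(off$dam %in% pop$id[pop$sex == "F"]))

  sibs <- breed_generation(pop, spec, 0,
                           plan = data.frame(sire = 1, dam = 20, n_offspring = 7))
  expect_equal(n_ind(sibs), 7)
  expect_equal(unique(paste(sibs$sire, sibs$dam)), "1 20")

  empty <- breed_generation(pop, spec, 0)
  expect_equal(n_ind(empty), 0)

  males_only <- pop_subset(pop, which(pop$sex == "M"))
  expect_error(breed_generation(males_only, spec, 10), "breeding impossible")
})

test_that("burn-in advances generations and drifts neutrally", {
  spec <- build_genome_spec(1, 1, 1000, 0, 0, 0)
  set.seed(5)
  p0 <- run_burn_in(spec, 0, 100)
  expect_equal(p0$generation, 1L)
  pop <- run_burn_in(spec, 3, 100)
  expect_equal(pop$generation, 4L)
  expect_equal(n_ind(pop), 100)

  # allele-frequency conservation: mean per-locus change ~ 0 over 1000 loci
  d0 <- colMeans(dosage_matrix(pop, spec, "all")) / 2
  nxt <- breed_generation(pop, spec, 100, 0.5)
  d1 <- colMeans(dosage_matrix(nxt, spec, "all")) / 2
  dp <- d1 - d0
  se <- sd(dp) / sqrt(length(dp))
  expect_lt(abs(mean(dp)), 3 * se + 1e-4)
})

test_that("heterozygosity decays at ~1/(2N) under drift", {
  spec <- build_genome_spec(1, 1, 200, 0, 0, 0)
  N <- 30; n_gen <- 80
  set.seed(6)
  slopes <- replicate(10, {
    pop <- init_base_population(spec, N, 0.5)
    het <- numeric(n_gen + 1)
    het[1] <- observed_heterozygosity(dosage_matrix(pop, spec, "all"))
    for (g in seq_len(n_gen)) {
      pop <- breed_generation(pop, spec, N, 0.5)
      het[g + 1] <- observed_heterozygosity(dosage_matrix(pop, spec, "all"))
    }
    -coef(lm(log(het) ~ seq_along(het)))[2]
  })
  expected <- -log(1 - 1 / (2 * N))
  expect_lt(abs(mean(slopes) - expected) / expected, 0.5)
})

test_that("expansion follows the linear schedule with exact endpoints", {
  spec <- build_genome_spec(1, 1, 50, 0, 0, 0)
  set.seed(7)
  pop <- init_base_population(spec, 100, 0.5)
  out <- run_expansion(pop, spec, 140, 20, 5)
  expect_equal(n_ind(out), 140)
  expect_equal(sum(out$sex == "M"), 20)

  # identity schedule leaves size and ratio unchanged
  same <- run_expansion(pop, spec, 100, 50, 3)
  expect_equal(n_ind(same), 100)
  expect_equal(sum(same$sex == "M"), 50)

  # the interpolated male fraction is non-increasing for the 1000->1400 /
  # 500->200 schedule (same arithmetic as the implementation)
  sizes <- round(seq(1000, 1400, length.out = 6))
  males <- round(seq(500, 200, length.out = 6))
  expect_true(all(diff(males / sizes) <= 0))

  expect_error(run_expansion(pop, spec, 10, 20, 2), "invalid schedule")
})

test_that("founder split is a sex-stratified partition", {
  spec <- build_genome_spec(1, 1, 30, 0, 0, 0)
  set.seed(8)
  pop <- init_base_population(spec, 140, 0.5)
  pop$sex <- c(rep("M", 20), rep("F", 120))
  fps <- split_founders(pop)
  expect_equal(n_ind(fps$fp1), 70)
  expect_equal(sum(fps$fp1$sex == "M"), 10)
  expect_equal(sum(fps$fp2$sex == "F"), 60)
  expect_length(intersect(fps$fp1$id, fps$fp2$id), 0)
  expect_setequal(c(fps$fp1$id, fps$fp2$id), pop$id)

  pop$sex[1] <- "F"  # odd counts
  expect_error(split_founders(pop), "split error")
})
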