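# The forward simulator: founder exactness, mutation accounting, meiosis,
# QTN effect scaling, design realization, determinism, LD shape.

test_that("zero generations and zero mutation give exact founder frequencies", {
  g <- genome_spec(n_chromosomes = 2, n_snps = 40, mutation_rate = 0)
  pool <- simulate_historical(g, sizes = 30, prop_male = 0.5, seed = 1)
  dos <- gwasim:::cpp_dosage(pool$hap, 0:29, seq_len(nrow(g$map)) - 1L)
  expect_equal(unname(colMeans(dos) / 2), rep(0.5, nrow(g$map)))
})

test_that("recurrent mutation introduces the expected number of allele flips", {
  g <- genome_spec(n_chromosomes = 2, n_snps = 2000, mutation_rate = 2.5e-5)
  g0 <- genome_spec(n_chromosomes = 2, n_snps = 2000, mutation_rate = 0)
  n <- 200; L <- nrow(g$map)
  flips <- sapply(1:5, function(s) {
    # same seed: offspring are built identically, mutation applied after,
    # so the elementwise difference counts the flips
    a <- simulate_historical(g,  sizes = c(n, n), prop_male = 0.5, seed = s)
    b <- simulate_historical(g0, sizes = c(n, n), prop_male = 0.5, seed = s)
    sum(as.integer(a$hap) != as.integer(b$hap))
  })
  expected <- 2 * n * L * 2.5e-5
  expect_lt(abs(mean(flips) - expected), 4 * sqrt(expected / 5))
})

test_that("historical phase aborts when a generation has no males", {
  g <- genome_spec(n_chromosomes = 2, n_snps = 40)
  expect_error(simulate_historical(g, sizes = c(10, 10), prop_male = 0.01),
               "zero males")
})

test_that("meiosis returns an intact haplotype without crossovers and mixes with them", {
  g1 <- genome_spec(n_chromosomes = 1, chrom_length_cM = 1e-9, n_snps = 50)
  h1 <- rep(0L, nrow(g1$map)); h2 <- rep(1L, nrow(g1$map))
  set.seed(2)
  gam <- meiosis(h1, h2, g1)               # ~zero map length: no crossover
  expect_true(all(gam == 0L) || all(gam == 1L))
  # homozygous parent: gamete identical regardless of crossovers
  g2 <- genome_spec(n_chromosomes = 1, chrom_length_cM = 300, n_snps = 50)
  ho <- rep(1L, nrow(g2$map))
  expect_equal(meiosis(ho, ho, g2), ho)
  # 100 cM chromosome: mean crossovers ~ Poisson(1), counted as strand
  # switches between distinguishable parental haplotypes
  g3 <- genome_spec(n_chromosomes = 1, chrom_length_cM = 100, n_snps = 1000)
  h1 <- rep(0L, nrow(g3$map)); h2 <- rep(1L, nrow(g3$map))
  set.seed(3)
  nx <- replicate(2000, sum(diff(meiosis(h1, h2, g3)) != 0))
  expect_lt(abs(mean(nx) - 1), 3 * sd(nx) / sqrt(length(nx)))
})

test_that("QTN effects are gamma-skewed, sign-balanced and scaled to the target variance", {
  g <- genome_spec(n_chromosomes = 1, n_snps = 20)
  tr <- trait_spec(0.25)
  # single QTN with founder dosages in exact HWE at p = 0.5:
  # population variance 2pq = 0.5, so |effect| = sqrt(V / 0.5)
  dos <- matrix(c(0L, 1L, 1L, 2L), ncol = 1)
  eff <- assign_qtn_effects(g, tr, dos, seed = 4)
  V <- 0.25 / 0.75
  expect_equal(abs(eff$effects), sqrt(V / 0.5), tolerance = 1e-12)
  expect_equal(eff$sigma2_a, V)
  # monomorphic QTN cannot be scaled
  expect_error(assign_qtn_effects(g, tr, matrix(2L, 5, 1)), "monomorphic")
  # gamma(0.40) magnitudes are right-skewed
  g29 <- genome_spec(n_chromosomes = 29, n_snps = 580)
  set.seed(5)
  dmany <- matrix(sample(0:2, 29 * 200, replace = TRUE), 200, 29)
  e2 <- assign_qtn_effects(g29, tr, dmany, seed = 6)
  a <- abs(e2$effects)
  expect_gt(mean((a - mean(a))^3) / sd(a)^3, 0)
})

test_that("full-size fish preset realizes its stated design counts", {
  g <- genome_spec(n_chromosomes = 2, n_snps = 40)   # genome size irrelevant
  pool <- simulate_historical(g, sizes = rep(150, 3), prop_male = 0.32,
                              seed = 7)
  sim <- simulate_recent("fish", pool, trait_spec(0.25),
                         params = scenario_params("fish", "small",
                                                  scaled_down = FALSE)$recent,
                         seed = 8)
  ped <- sim$pedigree
  newline <- ped$gen == max(ped$gen)
  expect_equal(sum(newline), 2000)                   # 20 dams x litter 100
  expect_equal(sum(ped$phenotyped), 2040)            # new line + parents
  expect_equal(sum(ped$genotyped), 1040)             # parents + half offspring
  expect_true(all(ped$sire[ped$gen > 0] < ped$id[ped$gen > 0]))
  expect_true(all(ped$dam[ped$gen > 0] < ped$id[ped$gen > 0]))
})

test_that("dairy design is sex-limited with genotyped sires only", {
  g <- genome_spec(n_chromosomes = 2, n_snps = 40)
  pool <- simulate_historical(g, sizes = rep(120, 3), prop_male = 0.3,
                              seed = 9)
  sim <- simulate_recent("dairy", pool, trait_spec(0.35, sex_limited = TRUE),
                         params = list(n_sires = 4, n_dams = 12, n_gens = 4,
                                       off_per_dam = 2, geno_gen = 3),
                         seed = 10)
  ped <- sim$pedigree
  expect_equal(sum(ped$genotyped & ped$sex == "F"), 0)
  expect_equal(sum(ped$phenotyped & ped$sex == "M"), 0)
  expect_gt(sum(ped$genotyped), 0)
  # ~off_per_dam * dams/sires phenotyped daughters per genotyped sire
  gid <- ped$id[ped$genotyped]
  dtr <- ped$phenotyped & ped$sire %in% gid
  # dams/sire * offspring/dam, half of them daughters
  expect_equal(sum(dtr) / length(gid), (12 / 4) * 2 / 2, tolerance = 0.3)
})

test_that("a fixed seed reproduces pedigree, genotypes and phenotypes exactly", {
  g <- genome_spec(n_chromosomes = 2, n_snps = 60)
  pool <- simulate_historical(g, sizes = rep(100, 4), prop_male = 0.4,
                              seed = 12)
  p <- list(n_sires = 5, n_dams = 5, n_gen_random = 2, off_per_dam = 2,
            litter = 6, geno_frac = 0.5)
  s1 <- simulate_recent("fish", pool, trait_spec(0.25), params = p, seed = 13)
  s2 <- simulate_recent("fish", pool, trait_spec(0.25), params = p, seed = 13)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$panel$dosage, s2$panel$dosage)
  expect_identical(s1$phenotypes, s2$phenotypes)
})

test_that("allele frequencies are conserved in expectation under drift", {
  g <- genome_spec(n_chromosomes = 2, n_snps = 100, mutation_rate = 0)
  drift <- sapply(1:6, function(s) {
    pool <- simulate_historical(g, sizes = rep(80, 6), prop_male = 0.5,
                                seed = s)
    dos <- gwasim:::cpp_dosage(pool$hap, 0:79, seq_len(nrow(g$map)) - 1L)
    mean(colMeans(dos) / 2 - 0.5)
  })
  expect_lt(abs(mean(drift)), 0.02)
})

test_that("phenotypes regress on true breeding values with slope 1 and R2 near h2", {
  sim <- tiny_fish()
  fit <- lm(value ~ tbv, data = sim$phenotypes)
  expect_lt(abs(unname(coef(fit)[2]) - 1), 0.25)
  expect_lt(abs(summary(fit)$r.squared - 0.25), 0.12)
})

test_that("LD decays with map distance in a drifted population", {
  g <- genome_spec(n_chromosomes = 2, n_snps = 300, mutation_rate = 0)
  pool <- simulate_historical(g, sizes = round(seq(100, 60, length.out = 31)),
                              prop_male = 0.5, seed = 21)
  dos <- gwasim:::cpp_dosage(pool$hap, 0:59,
                             which(g$map$type == "snp") - 1L)
  m <- g$map[g$map$type == "snp", ]
  ld <- ld_decay(dos, m, max_dist_cM = 50, bin_width = 5)
  expect_gt(ld$mean_r2[1], ld$mean_r2[10])          # near > far
  expect_true(all(ld$mean_r2 >= 0 & ld$mean_r2 <= 1, na.rm = TRUE))
})
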