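# The four association methods against closed forms, lm(), brute-force
# back-solving, and each other (equivalence/reduction properties).

test_that("the normal-reference p-value transform behaves as specified", {
  expect_equal(pvalue_from_effect(0, 1), 1)
  expect_equal(pvalue_from_effect(3, 1), 2 * (1 - pnorm(3)), tolerance = 1e-12)
  expect_equal(pvalue_from_effect(3, 1), 0.0027, tolerance = 1e-4)
  z <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(pvalue_from_effect(z, 1)) < 0))   # monotone
  expect_error(pvalue_from_effect(1, 0), "positive")
})

test_that("single-SNP least squares matches lm() and handles edge cases", {
  set.seed(61)
  n <- 6
  d <- cbind(x1 = c(0L,1L,2L,0L,1L,2L), x2 = c(2L,2L,0L,1L,0L,1L),
             mono = rep(1L, 6))
  y <- rnorm(n)
  sc <- ssa_nocor(y, d)
  for (j in 1:2) {
    f <- summary(lm(y ~ d[, j]))
    expect_equal(sc$effect[j], unname(coef(f)[2, 1]), tolerance = 1e-10)
    expect_equal(sc$se[j], unname(coef(f)[2, 2]), tolerance = 1e-10)
  }
  expect_equal(sc$flag[3], "monomorphic")
  expect_equal(sc$pvalue[3], 1)
  # y identical to a SNP: unit effect, zero residual
  sc2 <- ssa_nocor(as.numeric(d[, 1]), d[, 1, drop = FALSE])
  expect_equal(sc2$effect[1], 1, tolerance = 1e-10)
  # centered-orthogonal SNP: zero effect
  x <- c(0, 1, 2, 2, 1, 0)
  yo <- c(1, -1, 1, 1, -1, 1)             # orthogonal to centered x
  expect_equal(sum((x - mean(x)) * (yo - mean(yo))), 0)
  expect_equal(ssa_nocor(yo, cbind(x = as.integer(x)))$effect[1], 0,
               tolerance = 1e-12)
})

test_that("EMMAX collapses to least squares when the kinship carries no variance", {
  set.seed(62)
  d <- toy_dosage(n = 40, k = 12, seed = 20)
  y <- rnorm(40)
  ols <- ssa_nocor(y, d)
  e0 <- emmax(y, d, G = build_G_gemma(d),
              vc = list(sigma2_a = 0, sigma2_e = 1))
  expect_equal(e0$effect, ols$effect, tolerance = 1e-8)
  eI <- emmax(y, d, G = diag(40), vc = list(sigma2_a = 2, sigma2_e = 1))
  expect_equal(eI$effect, ols$effect, tolerance = 1e-8)  # V proportional to I
})

test_that("EMMAX holds its nominal type-I error on a structured null", {
  sim <- tiny_fish()
  f <- qc_filter(sim$panel)
  ids <- f$panel$ids
  d <- f$panel$dosage
  set.seed(63)
  y <- rnorm(nrow(d))                     # no genetic signal at all
  sc <- emmax(y, d)
  expect_lt(abs(mean(sc$pvalue < 0.05) - 0.05), 0.035)
  # and no Bonferroni-significant SNPs in the typical null replicate
  expect_equal(sum(sc$pvalue < 0.05 / nrow(sc)), 0)
})

test_that("GBLUP back-solving matches the brute-force evaluation of its formulas", {
  set.seed(64)
  n <- 10; k <- 15
  d <- toy_dosage(n = n, k = k, seed = 30)
  y <- rnorm(n)
  lam <- 0.95
  G <- blend_G(build_G_vanraden(d), lam, 0.05)
  vc <- list(sigma2_a = 0.6, sigma2_e = 1.1)
  sc <- gblup_gwas(y, d, G = G, vc = vc)
  # oracle: direct inversion of the MME, then the linear transformation
  p <- attr(G, "p"); s2pq <- attr(G, "sum2pq")
  oro <- oracle_mme(y, matrix(1, n, 1), diag(n), solve(G),
                    vc$sigma2_a, vc$sigma2_e)
  M <- sweep(d, 2, 2 * p)
  gh <- (lam / s2pq) * drop(t(M) %*% solve(G) %*% oro$u)
  expect_equal(sc$effect, gh, tolerance = 1e-8)
  Vg <- (lam / s2pq)^2 *
    diag(t(M) %*% solve(G) %*% (G * vc$sigma2_a - oro$C22) %*% solve(G) %*% M)
  expect_equal(sc$se^2, Vg, tolerance = 1e-8)
  expect_equal(sc$pvalue, 2 * (1 - pnorm(abs(sc$effect / sc$se))),
               tolerance = 1e-12)
})

test_that("per-SNP variance is bounded by the no-information variance", {
  set.seed(65)
  n <- 10
  d <- toy_dosage(n = n, k = 12, seed = 31)
  y <- rnorm(n)
  G <- blend_G(build_G_vanraden(d))
  vc <- list(sigma2_a = 0.6, sigma2_e = 1.1)
  sc <- gblup_gwas(y, d, G = G, vc = vc)
  p <- attr(G, "p"); s2pq <- attr(G, "sum2pq")
  M <- sweep(d, 2, 2 * p)
  nodata <- (0.95 / s2pq)^2 * vc$sigma2_a *
    diag(t(M) %*% solve(G) %*% M)
  expect_true(all(sc$se^2 <= nodata + 1e-10))
})

test_that("single-step reduces to GBLUP when everyone is genotyped and G matches A22", {
  set.seed(66)
  n <- 12
  d <- toy_dosage(n = n, k = 30, seed = 33)
  y <- rnorm(n) + rowSums(d[, 1:2]) * 0.3
  ped <- ped_df(rep(0L, n), rep(0L, n))           # founders: A = A22 = I
  G <- blend_G(build_G_vanraden(d))
  vc <- list(sigma2_a = 0.5, sigma2_e = 1)
  sg <- gblup_gwas(y, d, G = G, vc = vc)
  ss <- ssgwas(y, pheno_idx = 1:n, pedigree = ped, dosage = d,
               geno_idx = 1:n, vc = vc, G = G)
  # delta rescales effect and sd identically, so p-values are unchanged
  expect_equal(ss$pvalue, sg$pvalue, tolerance = 1e-6)
  delta <- attr(ss, "delta")
  expect_equal(ss$effect, delta * sg$effect, tolerance = 1e-8)
  # matched bases: delta = 1 recovers the GBLUP effects exactly
  Gm <- tune_G_to_A22(G, diag(n))
  ssm <- ssgwas(y, 1:n, ped, d, 1:n, vc = vc, G = Gm)
  expect_equal(attr(ssm, "delta"), 1, tolerance = 1e-10)
})

test_that("single-step accepts phenotypes on non-genotyped relatives", {
  sim <- tiny_fish()
  f <- qc_filter(sim$panel)
  sc <- gwas_scan(sim, "ssgwas", vc = "true")
  expect_equal(nrow(sc), ncol(f$panel$dosage))
  expect_true(all(sc$pvalue >= 0 & sc$pvalue <= 1))
  expect_false(attr(sc, "drp_used"))
  expect_error(ssgwas(rnorm(3), c(1, 2, nrow(sim$pedigree) + 5L),
                      sim$pedigree, f$panel$dosage, f$panel$ids,
                      vc = sim$vc_true), "mismatch")
})

test_that("EMMAX and GBLUP rank SNPs identically on shared data", {
  sim <- tiny_fish()
  f <- qc_filter(sim$panel)
  own <- f$panel$ids[sim$pedigree$phenotyped[f$panel$ids]]
  y <- sim$phenotypes$value[match(own, sim$phenotypes$id)]
  d <- f$panel$dosage[match(own, f$panel$ids), ]
  e <- emmax(y, d)
  g <- gblup_gwas(y, d)
  lp <- function(s) -log10(pmax(s$pvalue, 1e-300))
  expect_gte(cor(lp(e), lp(g), method = "spearman"), 0.99)
})

test_that("permuting phenotypes destroys QTN-window enrichment", {
  # drifted population large enough for distance-localized LD (a handful of
  # nucleus founders would make LD noisy and the window enrichment luck)
  g <- genome_spec(n_chromosomes = 2, n_snps = 300)
  pool <- simulate_historical(g, sizes = rep(300, 101), prop_male = 0.5,
                              seed = 68)
  all_idx <- seq_len(nrow(g$map)) - 1L
  qtn_rows <- which(g$map$type == "qtn")
  snp_rows <- which(g$map$type == "snp")
  dq <- gwasim:::cpp_dosage(pool$hap, 0:299, qtn_rows - 1L)
  set.seed(69)
  tbv <- dq %*% c(1, 1) * sqrt(1 / max(var(dq %*% c(1, 1)), 1e-9))
  y <- drop(tbv) + rnorm(300)                       # h2 ~ 0.5, two QTN
  d <- gwasim:::cpp_dosage(pool$hap, 0:299, snp_rows - 1L)
  qcf <- qc_filter(d)
  d <- qcf$panel
  map <- g$map[snp_rows, ][qcf$report$retained, ]
  names(map)[names(map) == "locus_id"] <- "snp_id"
  f <- list(panel = list(map = map))
  qtn <- g$map[qtn_rows, ]
  near <- gwasim:::snp_near_qtn(map, qtn, 2)
  enrich <- function(p) {
    lp <- -log10(pmax(p, 1e-300))
    mean(lp[near]) - mean(lp[!near])
  }
  obs <- enrich(ssa_nocor(y, d, map = f$panel$map)$pvalue)
  set.seed(67)
  perm <- replicate(20, enrich(ssa_nocor(sample(y), d,
                                         map = f$panel$map)$pvalue))
  expect_gt(obs, quantile(perm, 0.75))    # true labels enrich small p
  expect_lt(abs(median(perm)), 0.5)       # permuted labels: no enrichment
})
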