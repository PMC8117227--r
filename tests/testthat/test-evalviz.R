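# Thresholding, TP/FP windows, ROC, LD, PCA, effective population size.

test_that("Bonferroni thresholds match their closed forms", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(35000), 0.05 / 35000)
  expect_equal(bonferroni_threshold(35000), 1.43e-6, tolerance = 1e-2)
  expect_equal(bonferroni_threshold(58000), 8.62e-7, tolerance = 1e-3)
  expect_error(bonferroni_threshold(0), "SNPs")
})

test_that("TP/FP windows are inclusive at the boundary and count per SNP", {
  qtn <- data.frame(chrom = 1L, pos_cM = 50)
  scan <- data.frame(chrom = 1L,
                     pos_cM = c(50, 48.0, 52.5, 10),
                     pvalue = c(1e-9, 1e-9, 1e-9, 0.5))
  ev <- classify_tp_fp(scan, qtn, threshold = 1e-6, window_cM = 2)
  expect_equal(ev$classification, c("TP", "TP", "FP", "ns"))
  expect_equal(ev$tp, 2); expect_equal(ev$fp, 1)
  # ordering invariance and insensitivity to extra non-significant SNPs
  perm <- c(3, 1, 4, 2)
  ev2 <- classify_tp_fp(scan[perm, ], qtn, threshold = 1e-6)
  expect_equal(ev2$tp, ev$tp); expect_equal(ev2$fp, ev$fp)
  more <- rbind(scan, data.frame(chrom = 1L, pos_cM = 77, pvalue = 0.9))
  ev3 <- classify_tp_fp(more, qtn, threshold = 1e-6)
  expect_equal(c(ev3$tp, ev3$fp), c(ev$tp, ev$fp))
  # stricter thresholds never gain detections
  for (thr in 10^seq(-12, -2)) {
    e <- classify_tp_fp(scan, qtn, threshold = thr)
    if (thr < 1e-6)
      expect_lte(e$tp + e$fp, ev$tp + ev$fp)
  }
  expect_error(classify_tp_fp(scan, data.frame(chrom = 9L, pos_cM = 1),
                              threshold = 1e-6), "chromosome")
})

test_that("ROC sweep matches brute-force enumeration and the Mann-Whitney identity", {
  qtn <- data.frame(chrom = 1L, pos_cM = 4)
  scan <- data.frame(chrom = 1L,
                     pos_cM = c(3, 4, 5, 20, 30, 40, 50, 60),
                     pvalue = c(1e-8, 2e-6, 0.03, 1e-4, 0.2, 0.5, 0.8, 0.6))
  r <- roc_curve(scan, qtn, window_cM = 2)
  lab <- abs(scan$pos_cM - 4) <= 2
  # brute force over every threshold
  ths <- sort(unique(scan$pvalue))
  bf <- t(sapply(ths, function(t) c(sum(scan$pvalue[!lab] <= t) / sum(!lab),
                                    sum(scan$pvalue[lab] <= t) / sum(lab))))
  expect_equal(r$fpr, c(0, bf[, 1]))
  expect_equal(r$tpr, c(0, bf[, 2]))
  # trapezoidal area equals the Mann-Whitney statistic
  W <- sum(outer(scan$pvalue[lab], scan$pvalue[!lab], "<") +
             0.5 * outer(scan$pvalue[lab], scan$pvalue[!lab], "=="))
  expect_equal(r$auc, W / (sum(lab) * sum(!lab)), tolerance = 1e-12)
  # perfect separation
  ps <- scan; ps$pvalue <- ifelse(lab, 1e-8, 0.5)
  expect_equal(roc_curve(ps, qtn, 2)$auc, 1)
  # permuted labels average one half
  set.seed(81)
  null_auc <- replicate(300, {
    s <- scan; s$pvalue <- sample(s$pvalue)
    roc_curve(s, qtn, 2)$auc
  })
  expect_equal(mean(null_auc), 0.5, tolerance = 0.05)
  expect_error(roc_curve(data.frame(chrom = 1L, pos_cM = 3, pvalue = .1),
                         qtn, 2), "positive")
})

test_that("LD curve honors coding invariance and the small-sample baseline", {
  # duplicated locus with flipped coding: r^2 = 1
  set.seed(82)
  x <- sample(0:2, 60, replace = TRUE)
  d <- cbind(a = x, b = 2L - x)
  m <- data.frame(chrom = 1L, pos_cM = c(1, 2))
  ld <- ld_decay(d, m, max_dist_cM = 5, bin_width = 5)
  expect_equal(ld$mean_r2[1], 1)
  # independent loci: mean r^2 near the 1/n sampling baseline
  n <- 50
  di <- sapply(1:200, function(i) rbinom(n, 2, 0.5))
  mi <- data.frame(chrom = 1L, pos_cM = seq(0.1, 20, length.out = 200))
  ldi <- ld_decay(di, mi, max_dist_cM = 20, bin_width = 20,
                  max_pairs_per_chrom = 5000)
  expect_equal(ldi$mean_r2[1], 1 / n, tolerance = 0.3)
  # monomorphic member pairs are skipped, not propagated
  dm <- cbind(d, mono = rep(1L, 60))
  mm <- data.frame(chrom = 1L, pos_cM = c(1, 2, 3))
  ldm <- ld_decay(dm, mm, max_dist_cM = 5, bin_width = 5)
  expect_equal(ldm$n_pairs[1], 1)
})

test_that("PCA of G separates family blocks and returns a proper spectrum", {
  G <- as.matrix(Matrix::bdiag(matrix(0.8, 5, 5) + 0.2 * diag(5),
                               matrix(0.8, 5, 5) + 0.2 * diag(5)))
  p <- pca_of_G(G)
  s1 <- p$scores[1:5, 1]; s2 <- p$scores[6:10, 1]
  expect_true(all(sign(s1) == sign(s1[1])))
  expect_true(all(sign(s2) == sign(s2[1])))
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-12)
  expect_equal(sum(p$scores[, 1] * p$scores[, 2]), 0, tolerance = 1e-8)
  expect_error(pca_of_G(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("Ne follows the closed form of the inbreeding-rate relation", {
  expect_equal(ne_from_deltaF(rep(0.0125, 5)), 40)
  expect_equal(ne_from_deltaF(rep(1 / 180, 4)), 90)
  expect_true(is.na(ne_from_deltaF(rep(0, 3))))
  # pedigree with no inbreeding: constant F, undefined Ne
  ped <- ped_df(c(0, 0, 0, 0, 1, 3), c(0, 0, 0, 0, 2, 4),
                gen = c(0, 0, 0, 0, 1, 1))
  tr <- effective_population_size(ped)
  expect_true(is.na(tr$Ne))
  expect_equal(tr$delta_F, 0)
  expect_error(effective_population_size(ped_df(0, 0)), "generations")
})

test_that("a closed full-sib line realizes the textbook rate of inbreeding", {
  # repeated full-sib mating: F follows 1 - F_t ~ 0.809^t, Delta F -> 0.191
  sire <- c(0, 0); dam <- c(0, 0); gen <- c(0L, 0L)
  for (g in 1:8) {
    n <- length(sire)
    sire <- c(sire, n - 1L, n - 1L); dam <- c(dam, n, n)
    gen <- c(gen, g, g)
  }
  tr <- effective_population_size(data.frame(sire = sire, dam = dam,
                                             gen = gen))
  expect_equal(tr$delta_F[8], 0.191, tolerance = 0.01)
  expect_equal(tr$Ne, ne_from_deltaF(tr$delta_F[-1]), tolerance = 1e-10)
})

test_that("the pedigree Ne estimator is centered on the nucleus design value", {
  # pedigree-only replicas of the 20 x 20 nucleus under random union of
  # gametes: the estimator should center on 4*Nm*Nf/(Nm+Nf) = 40
  one <- function(seed) {
    set.seed(seed)
    sire <- dam <- integer(40); sex <- rep(c("M", "F"), each = 20)
    gen <- rep(0L, 40); cur <- 1:40
    for (g in 1:5) {
      s <- cur[sex[cur] == "M"]; d <- cur[sex[cur] == "F"]
      os <- sample(s, 40, TRUE); od <- sample(d, 40, TRUE)
      ids <- length(sire) + 1:40
      sire <- c(sire, os); dam <- c(dam, od)
      sex <- c(sex, sample(rep(c("M", "F"), 20)))
      gen <- c(gen, rep(g, 40)); cur <- ids
    }
    effective_population_size(data.frame(sire = sire, dam = dam,
                                         gen = gen))$Ne
  }
  nes <- vapply(1:40, one, numeric(1))
  expect_lt(abs(mean(nes) - 40), 5)
})
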